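mk_grid <- function(values, folded = FALSE) spectrum_grid(values, folded = folded)

test_that("Poisson composite log-likelihood matches hand arithmetic", {
  # 2x2 grids: corners (0,0) and (1,1) are masked; cells (1,0) and (0,1) count
  obs <- mk_grid(matrix(c(0, 1, 0, 0), 2, 2))
  ex <- mk_grid(matrix(c(0, 1, 1, 0), 2, 2))
  # (1,0): 1*ln(1) - 1 - ln(1!) = -1 ; (0,1): 0 - 1 - 0 = -1
  expect_equal(composite_loglik(obs, ex), -2)
  # all-zero observed -> -sum(expected)
  zero <- mk_grid(matrix(0, 2, 2))
  expect_equal(suppressWarnings(composite_loglik(zero, ex)), -2)
  # shape / folding mismatches error
  expect_error(composite_loglik(obs, mk_grid(matrix(0, 3, 2))), "shapes differ")
  expect_error(composite_loglik(obs, fold_sfs(ex)), "folding")
})

test_that("a mis-scaled expectation is strictly worse at the optimum", {
  mod <- model_catalog("sc2ns")[[1]]$build(c(nu = 3, T = 0.2))
  shape <- expected_sfs(mod, 8, 8)
  obs <- shape; obs$values <- shape$values * 5
  ll <- vapply(c(0.5, 0.9, 1, 1.1, 2), function(cc) {
    ex <- shape; ex$values <- shape$values * 5 * cc
    composite_loglik(obs, ex)
  }, 1)
  expect_equal(which.max(ll), 3L)
})

test_that("profiled theta is the analytic Poisson maximizer", {
  mod <- demographic_model()
  shape <- expected_sfs(mod, 6, 6)
  obs2 <- shape; obs2$values <- 2 * shape$values
  expect_equal(profile_theta(obs2, shape), 2)
  expect_equal(profile_theta(shape, shape), 1)
  # matches a brute-force 1-D scan on random grids
  set.seed(7)
  for (r in 1:5) {
    o <- mk_grid(matrix(rexp(36, 1 / 3), 6, 6))
    s <- mk_grid(matrix(rexp(36), 6, 6))
    th <- profile_theta(o, s)
    scan <- optimize(function(t) {
      e <- s; e$values <- s$values * t
      -suppressWarnings(composite_loglik(o, e))
    }, c(1e-3, 100))$minimum
    expect_equal(th, scan, tolerance = 1e-4)
  }
  expect_error(profile_theta(shape, mk_grid(matrix(0, 7, 7))), "zero unmasked")
})

test_that("fitting data generated from a catalog expectation attains the optimum", {
  entry <- model_catalog("sc2ns")[[1]]
  truth <- c(nu = 4, T = 0.15)
  obs <- fold_sfs(expected_sfs(entry$build(truth), 12, 12, theta = 800))
  fit <- fit_model(obs, entry, restarts = 4, seed = 3, maxit = 800,
                   min_integration_n = 12)
  sh <- fold_sfs(expected_sfs(entry$build(truth), 12, 12))
  th <- profile_theta(obs, sh)
  sh$values <- sh$values * th
  ll_truth <- composite_loglik(obs, sh)
  expect_gte(fit$loglik, ll_truth - 1e-4)
  expect_equal(fit$AIC, 2 * fit$k - 2 * fit$loglik)
})

test_that("best log-likelihood is stable across restart seeds", {
  entry <- model_catalog("sc2ns")[[1]]
  d <- jointsfs:::sim_dataset(entry, c(nu = 5, T = 0.1), seed = 31,
                              grid = c(12, 12))
  f1 <- fit_model(d$obs, entry, restarts = 3, seed = 1, min_integration_n = 12)
  f2 <- fit_model(d$obs, entry, restarts = 3, seed = 2, min_integration_n = 12)
  expect_lt(abs(f1$loglik - f2$loglik), 0.5)
})

test_that("asymmetric migration dominates its symmetric restriction", {
  entry_m <- model_catalog("s2m")[[1]]
  entry_s <- model_catalog("s2msm")[[1]]
  d <- jointsfs:::sim_dataset(entry_m,
                              c(nu1 = 2, nu2 = 1, T = 0.4, M12 = 2, M21 = 0.3),
                              seed = 17, grid = c(10, 10),
                              n_contigs = 800)
  fs <- fit_model(d$obs, entry_s, restarts = 2, seed = 5, maxit = 200,
                  min_integration_n = 10)
  start_m <- c(nu1 = unname(fs$par["nu1"]), nu2 = unname(fs$par["nu2"]),
               T = unname(fs$par["T"]), M12 = unname(fs$par["M"]),
               M21 = unname(fs$par["M"]))
  fm <- fit_model(d$obs, entry_m, restarts = 2, seed = 5, maxit = 200,
                  start = start_m, min_integration_n = 10)
  expect_gte(fm$loglik, fs$loglik - 1e-3)
})

test_that("median-AIC ranking reproduces the published worked example", {
  med <- bonnethead_reference("medians")
  rk <- rank_models(data.frame(model = med$model, AIC = med$median_AIC))
  expect_equal(rk$model[1], "sc2ns")
  expect_equal(rk$delta_AIC[1], 0)
  expect_equal(rk$rel_likelihood[1], 1)
  expect_equal(sum(rk$AIC_weight), 1, tolerance = 1e-12)
  expect_equal(round(rk$AIC_weight[rk$model == "sc2ns"], 2), 0.66)
  expect_equal(round(rk$rel_likelihood[rk$model == "sc1ns"], 2), 0.36)
  expect_equal(round(rk$AIC_weight[rk$model == "sc1ns"], 2), 0.24)
  expect_equal(rk$delta_AIC[rk$model == "sc3ns"], 3.91)
  expect_equal(signif(rk$rel_likelihood[rk$model == "s2msm"], 3), 6.25e-5)
  expect_error(rank_models(data.frame(x = 1)), "model")
})

test_that("physical conversions reproduce the published derived quantities", {
  ref <- bonnethead_bestfit_genetic(G = 4)
  ph <- to_physical(ref$fit, ref$scale)
  expect_equal(round(ph$Ne_anc), 10263)
  expect_equal(round(ph$Ne_current[1]), 158639)
  expect_equal(round(ph$Ne_current[2]), 1026319)
  expect_equal(round(ph$split_years), 1532)
  expect_equal(round(unname(ph$migrants_per_gen["1to2"])), 77)
  ref12 <- bonnethead_bestfit_genetic(G = 4)
  ph12 <- to_physical(ref12$fit, physical_scale(ref12$scale$mu, G = 12,
                                                L = ref12$scale$L))
  expect_equal(round(ph12$split_years), 3 * 1532)
  # theta = 0 collapses every physical size to zero
  z <- ref$fit; z$theta_hat <- 0
  phz <- to_physical(z, ref$scale)
  expect_equal(phz$Ne_anc, 0)
  expect_true(all(phz$Ne_current == 0))
})

test_that("bootstrap intervals collapse when replicates are identical", {
  entry <- model_catalog("sc2ns")[[1]]
  mod <- entry$build(c(nu = 3, T = 0.2))
  obs <- fold_sfs(expected_sfs(mod, 10, 10, theta = 500))
  fit <- fit_model(obs, entry, restarts = 2, seed = 1, min_integration_n = 10)
  boots <- replicate(5, {
    u <- expected_sfs(mod, 10, 10, theta = 500)
    u
  }, simplify = FALSE)
  bu <- bootstrap_uncertainty(entry, fit, boots, seed = 1, restarts = 1,
                              min_integration_n = 10)
  width <- bu$quantiles[, 3] - bu$quantiles[, 1]
  expect_true(all(width / pmax(bu$quantiles[, 2], 1e-12) < 1e-3))
})
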