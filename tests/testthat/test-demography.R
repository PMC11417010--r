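test_that("equilibrium spectrum matches the Watterson closed form", {
  expect_lt(watterson_check(20), 1e-10)
  expect_lt(watterson_check(10, theta = 3.7), 1e-10)
})

test_that("expected SFS is linear in theta", {
  mod <- model_catalog("s2m")[[1]]$build(c(nu1 = 2, nu2 = 0.5, T = 0.3,
                                           M12 = 1, M21 = 0.2))
  e1 <- expected_sfs(mod, 8, 8, theta = 1)
  e3 <- expected_sfs(mod, 8, 8, theta = 3)
  expect_equal(e3$values, 3 * e1$values, tolerance = 1e-10)
})

test_that("symmetric split models give exchangeable demes", {
  mod <- model_catalog("s2msm")[[1]]$build(c(nu1 = 1.5, nu2 = 1.5,
                                             T = 0.4, M = 1))
  e <- expected_sfs(mod, 8, 8)
  expect_lt(max(abs(e$values - t(e$values))), 1e-8)
})

test_that("a vanishing split reduces to the pooled no-split spectrum", {
  mod <- model_catalog("s2m")[[1]]$build(c(nu1 = 1, nu2 = 1, T = 1e-6,
                                           M12 = 0, M21 = 0))
  e <- expected_sfs(mod, 6, 6)
  e0 <- expected_sfs(demographic_model(), 6, 6)
  use <- !e0$mask & e0$values > 1e-6
  expect_lt(max(abs(e$values[use] - e0$values[use]) / e0$values[use]), 0.01)
})

test_that("one-way migration monotonically builds shared polymorphism", {
  shared <- vapply(c(0.2, 1, 3, 8), function(M) {
    mod <- model_catalog("s2m")[[1]]$build(c(nu1 = 1, nu2 = 1, T = 1.5,
                                             M12 = M, M21 = 0))
    e <- expected_sfs(mod, 6, 6)
    sum(e$values[2:6, 2:6])
  }, 1)
  expect_true(all(diff(shared) > 0))
})

test_that("catalog bounds have the advertised dimensions", {
  cat_ <- model_catalog()
  expect_length(cat_$sc2ns$bounds$lower, 2)
  expect_length(cat_$s2m$bounds$lower, 5)
  expect_length(cat_$gadma_best$bounds$lower, 6)
  expect_length(cat_$sc2el$bounds$lower, 7)
  expect_error(model_catalog("nonexistent"), "unknown model")
  # k counts free parameters plus theta
  for (en in cat_) expect_equal(en$k, length(en$params) + 1L)
})

test_that("the jackknife closure is exact on densities it can represent", {
  for (n in c(8, 16)) {
    J <- jointsfs:::jackknife_matrix(n)
    # phi(x) = 1: Phi_n(j) = 1/(n+1) -> Phi_{n+1}(i) = 1/(n+2)
    flat <- rep(1 / (n + 1), n + 1)
    up <- as.vector(J %*% flat)
    expect_equal(up[2:(n + 1)], rep(1 / (n + 2), n), tolerance = 1e-9)
    # phi(x) = 1/x: Phi_n(j) = 1/j -> interior rows reproduce 1/i
    sing <- c(0, 1 / (1:n)) # j = 0 entry unused by interior fits
    up2 <- as.vector(J %*% sing)
    interior <- 2:(n %/% 2)
    expect_equal(up2[interior + 1], 1 / interior, tolerance = 1e-6)
  }
})

test_that("model construction enforces the structural invariants", {
  expect_error(epoch(T = -1, nu = 1), "T > 0")
  expect_error(epoch(T = 1, nu = c(1, 1), dynamics = "quadratic"), "dynamics")
  expect_error(demographic_model(list(epoch(T = 1, nu = 1, M_1to2 = 1))),
               "two-deme")
  expect_error(demographic_model(list(
    epoch(T = 1, nu = c(1, 1)), epoch(T = 1, nu = 1))),
    "at most one split")
})
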