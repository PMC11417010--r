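#' Validation harnesses
#'
#' Self-contained experiments used to validate the pipeline end-to-end on
#' synthetic data: engine-vs-oracle agreement, parameter-recovery coverage,
#' model-selection sanity, and the PERMANOVA type-I error rate. They are part
#' of the package (rather than test-only code) so that validation runs are
#' reproducible one-liners.
#'
#' @name harness
NULL

#' @describeIn harness Relative error of the engine's equilibrium spectrum
#'   against the Watterson closed form `E[xi_i] = theta / i` at pooled sample
#'   size `n`. Returns the maximum relative error over entries `1..n-1`.
#' @param n pooled haploid sample size.
#' @param theta scaled mutation rate.
#' @export
watterson_check <- function(n = 20, theta = 1) {
  stopifnot(n >= 4)
  n1 <- n %/% 2; n2 <- n - n1
  e <- expected_sfs(demographic_model(), n1, n2, theta = theta)
  tot <- outer(0:n1, 0:n2, `+`)
  pooled <- vapply(1:(n - 1), function(k) sum(e$values[tot == k]), 1)
  max(abs(pooled * (1:(n - 1)) / theta - 1))
}

#' @describeIn harness Compare [expected_sfs()] against the structured
#'   coalescent Monte-Carlo oracle for every catalog entry at `(n1, n2)`,
#'   with one reproducible parameter draw per entry from study-typical ranges
#'   (`nu` log-uniform in \[0.5, 3\], `T` uniform in \[0.2, 0.8\], `M` uniform
#'   in \[0.5, 3\]). Returns a data.frame with per-model maximum |z| and the
#'   fraction of unmasked entries within 3 Monte-Carlo standard errors.
#' @param n1,n2 haploid sizes of the compared grid.
#' @param nreps Monte-Carlo replicates per model.
#' @param seed integer seed (drives both the parameter draw and the MC).
#' @param models optional subset of catalog names.
#' @export
engine_oracle_check <- function(n1 = 6, n2 = 6, nreps = 1e6, seed = 1,
                                models = NULL) {
  cat_ <- model_catalog(models)
  set.seed(seed) # parameter draws first, decoupled from the MC streams
  pars <- lapply(cat_, function(en)
    vapply(en$params, function(p) {
      k <- substr(p, 1, 1)
      if (k == "n") exp(runif(1, log(0.5), log(3)))
      else if (k == "T") runif(1, 0.2, 0.8)
      else runif(1, 0.5, 3)
    }, 1))
  out <- lapply(seq_along(cat_), function(ix) {
    nm <- names(cat_)[ix]
    mod <- cat_[[ix]]$build(pars[[ix]])
    e <- expected_sfs(mod, n1, n2)
    set.seed(seed + 1000L * ix)
    m <- mc_expected_sfs(mod, n1, n2, nreps = nreps)
    z <- (e$values - m$mean) / pmax(m$se, 1e-15)
    z[e$mask] <- 0
    data.frame(model = nm, max_abs_z = max(abs(z)),
               frac_within_3se = mean(abs(z[!e$mask]) <= 3))
  })
  do.call(rbind, out)
}

# simulate a dataset under a catalog truth and return its folded SFS +
# per-contig data for bootstrapping
sim_dataset <- function(entry, par, seed, deme_sizes = c(10, 10),
                        n_contigs = 2000, contig_length = 3000,
                        Ne_anc = 2e4, mu = 3.92e-9, missing_rate = 0.1,
                        grid = c(12, 12)) {
  mod <- entry$build(par)
  cfg <- coalescent_config(deme_sizes = deme_sizes, n_contigs = n_contigs,
                           contig_length = contig_length, mu = mu,
                           Ne_anc = Ne_anc, model = mod,
                           missing_rate = missing_rate, seed = seed)
  sim <- emit_genotype_matrix(cfg)
  obs <- fold_sfs(observed_sfs(sim$gm, grid[1], grid[2]))
  list(gm = sim$gm, obs = obs, truth = sim$truth)
}

#' @describeIn harness Parameter-recovery coverage: simulate `n_rep` datasets
#'   under a catalog truth, fit the true model, bootstrap the SFS over
#'   contigs (`B` replicates, warm-started refits), and report the fraction
#'   of (replicate, parameter) pairs whose true value lies inside the
#'   bootstrap 95% interval.
#' @param entry_name catalog entry simulated and refitted.
#' @param par named true parameter vector (genetic units).
#' @param n_rep number of simulated datasets.
#' @param B bootstrap replicates per dataset.
#' @param grid haploid grid size used for the folded SFS.
#' @param restarts optimizer restarts for the initial fit.
#' @export
recovery_experiment <- function(entry_name = "sc2ns",
                                par = c(nu = 5, T = 0.1),
                                n_rep = 20, B = 20, seed = 1,
                                grid = c(12, 12), restarts = 3,
                                maxit = 200) {
  entry <- model_catalog(entry_name)[[1L]]
  hits <- 0L; total <- 0L
  detail <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    d <- sim_dataset(entry, par, seed = seed * 1000L + r, grid = grid)
    fit <- fit_model(d$obs, entry, restarts = restarts, seed = seed + r,
                     maxit = maxit, min_integration_n = grid[1])
    boots <- bootstrap_contigs(d$gm, grid[1], grid[2], B = B,
                               seed = seed * 77L + r)
    bu <- bootstrap_uncertainty(entry, fit, boots, seed = seed + r,
                                restarts = 1L, maxit = 150L, n_polish = 1L,
                                min_integration_n = grid[1])
    q <- bu$quantiles
    tol <- 1e-9
    inside <- vapply(names(par), function(p)
      par[[p]] >= q[p, 1] * (1 - tol) && par[[p]] <= q[p, 3] * (1 + tol), TRUE)
    hits <- hits + sum(inside); total <- total + length(inside)
    detail[[r]] <- inside
  }
  list(coverage = hits / total, n_pairs = total,
       per_replicate = do.call(rbind, detail))
}

#' @describeIn harness Model-selection sanity: simulate `n_data` datasets
#'   under a no-split two-epoch truth at roughly the study's SNP count, run
#'   the reduced median-AIC ranking over the seven-model catalog (`B`
#'   contig-bootstrap spectra per dataset, warm-started refits), and report
#'   the fraction of datasets for which a no-split model wins.
#' @param n_data number of simulated datasets.
#' @export
selection_experiment <- function(n_data = 20, par = c(nu = 5, T = 0.1),
                                 B = 2, seed = 1, grid = c(10, 10),
                                 restarts = 1, maxit = 120) {
  truth <- model_catalog("sc2ns")[[1L]]
  seven <- model_catalog(c("sc1ns", "sc2ns", "sc3ns", "s2m", "s2msm",
                           "sc2el", "sc2elsm"))
  wins <- character(n_data)
  for (d in seq_len(n_data)) {
    ds <- sim_dataset(truth, par, seed = seed * 2000L + d, grid = grid)
    boots <- bootstrap_contigs(ds$gm, grid[1], grid[2], B = B,
                               seed = seed * 99L + d)
    aic <- list()
    for (nm in names(seven)) {
      f0 <- fit_model(ds$obs, seven[[nm]], restarts = restarts,
                      seed = seed + d, maxit = maxit,
                      min_integration_n = grid[1])
      av <- vapply(seq_along(boots), function(b) {
        ob <- fold_sfs(boots[[b]])
        fb <- fit_model(ob, seven[[nm]], restarts = 1L, seed = seed + b,
                        start = if (length(f0$par)) f0$par else NULL,
                        maxit = maxit, n_polish = 1L,
                        min_integration_n = grid[1])
        fb$AIC
      }, 1)
      aic[[nm]] <- av
    }
    rk <- rank_models(aic)
    wins[d] <- rk$model[1L]
  }
  no_split <- c("sc1ns", "sc2ns", "sc3ns")
  list(rate_no_split = mean(wins %in% no_split), winners = wins)
}

#' @describeIn harness PERMANOVA type-I error under label exchange: simulate
#'   `n_sim` panmictic datasets, assign arbitrary two-group labels, and
#'   report the rejection rate at `alpha`.
#' @param n_sim number of null simulations.
#' @param n_per_group samples per (arbitrary) group.
#' @param alpha test level.
#' @param n_perm permutations per test.
#' @export
permanova_type1 <- function(n_sim = 400, n_per_group = c(8, 12),
                            alpha = 0.05, n_perm = 999, seed = 1) {
  n_dip <- sum(n_per_group)
  labels <- rep(c("a", "b"), n_per_group)
  rej <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    cfg <- coalescent_config(deme_sizes = n_dip, n_contigs = 150,
                             contig_length = 2000, mu = 3.92e-9,
                             Ne_anc = 2e4, model = demographic_model(),
                             missing_rate = 0, seed = seed * 5000L + s)
    gm <- emit_genotype_matrix(cfg)$gm
    D <- ibs_distance(gm)
    p <- permanova(D, labels, n_perm = n_perm, seed = seed + s)$p_value
    rej[s] <- p <= alpha
  }
  list(rate = mean(rej), n_sim = n_sim)
}
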