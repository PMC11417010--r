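# Local-interpolation jackknife: estimate the size-(n+1) spectrum from the
# size-n spectrum (the closure for the migration terms). The density is fitted
# locally with three basis functions whose Bernstein moments are closed-form;
# near the frequency boundaries the bases include the 1/x (resp. 1/(1-x))
# singularity that the neutral-influx spectrum carries, which a plain
# quadratic cannot represent.
jackknife_matrix <- function(n) {
  stopifnot(n >= 4)
  mom <- function(kind, m, j) {
    switch(kind,
           invx  = 1 / j,
           one   = rep(1 / (m + 1), length(j)),
           x     = (j + 1) / ((m + 1) * (m + 2)),
           x2    = (j + 1) * (j + 2) / ((m + 1) * (m + 2) * (m + 3)),
           inv1x = 1 / (m - j),
           omx   = (m - j + 1) / ((m + 1) * (m + 2)),
           omx2  = (m - j + 1) * (m - j + 2) / ((m + 1) * (m + 2) * (m + 3)))
  }
  J <- matrix(0, n + 2, n + 1)
  for (i in 0:(n + 1)) {
    if (i == 0) {
      basis <- c("one", "x", "x2"); js <- 0:2
    } else if (i == n + 1) {
      basis <- c("one", "omx", "omx2"); js <- (n - 2):n
    } else if (i <= (n + 1) / 2) {
      basis <- c("invx", "one", "x")
      j0 <- min(max(round(i * n / (n + 1)), 1L), n - 2L)
      js <- j0:(j0 + 2L) - 1L
      js <- pmin(pmax(js, 1L), n) # keep off j = 0 (1/x moment undefined)
      if (length(unique(js)) < 3L) js <- 1:3
    } else {
      basis <- c("inv1x", "one", "omx")
      j0 <- min(max(round(i * n / (n + 1)), 2L), n - 1L)
      js <- (j0 - 1L):(j0 + 1L)
      js <- pmin(pmax(js, 0L), n - 1L) # keep off j = n (1/(1-x) undefined)
      if (length(unique(js)) < 3L) js <- (n - 3):(n - 1)
    }
    Mm <- sapply(basis, function(b) mom(b, n, js))
    tv <- vapply(basis, function(b) mom(b, n + 1, i), 1)
    w <- solve(t(Mm), tv) # coefficients s.t. J row reproduces target moment
    J[i + 1, js + 1] <- w
  }
  J
}

.sfs_cache <- new.env(parent = emptyenv())
cached_mat <- function(key, maker) {
  if (is.null(.sfs_cache[[key]])) .sfs_cache[[key]] <- maker()
  .sfs_cache[[key]]
}

# hypergeometric redistribution of a pooled 1D spectrum over two subsamples
pooled_to_joint <- function(phi1, n1, n2) {
  ntot <- n1 + n2
  stopifnot(length(phi1) == ntot + 1)
  w <- outer(0:n1, 0:n2, function(i, j)
    exp(lchoose(n1, i) + lchoose(n2, j) - lchoose(ntot, i + j)))
  k <- outer(0:n1, 0:n2, `+`)
  matrix(phi1[k + 1], n1 + 1, n2 + 1) * w
}

#' Expected joint SFS under a demographic model
#'
#' Deterministic integration of the moment equations for the sample SFS:
#' drift is a closed tridiagonal operator advanced by Crank-Nicolson steps;
#' size changes enter through the epoch dynamics; migration (which couples to
#' order-(n+1) moments) is closed by a singularity-aware local-interpolation
#' jackknife; new mutations feed the singleton classes at rate
#' `n * theta / 2` per deme.
#' Models without a split are integrated in one dimension at the pooled size
#' and the result spread hypergeometrically over the two samples. Entries are
#' expected site counts and are exactly linear in `theta`.
#'
#' For small sample sizes the integration runs at an oversampled size (at
#' least `min_integration_n` per axis) and is then projected down exactly,
#' which reduces the closure error of the migration terms.
#'
#' @param model a [demographic_model()].
#' @param n1,n2 haploid sample sizes of the returned grid.
#' @param theta scaled mutation rate `4 Ne_anc mu L` (default 1).
#' @param dt_fac time-step control; smaller is more accurate.
#' @param max_steps cap on integration steps per epoch.
#' @param min_integration_n two-deme models with `n < min_integration_n` on an
#'   axis are integrated at this size and projected down.
#' @return unfolded [spectrum_grid()] of expected counts.
#' @export
expected_sfs <- function(model, n1, n2, theta = 1, dt_fac = 0.2,
                         max_steps = 20000L, min_integration_n = 32L) {
  stopifnot(inherits(model, "demographic_model"), n1 >= 1, n2 >= 1, theta >= 0)
  ep <- epoch_matrix(model)
  if (!has_split(model)) {
    ntot <- n1 + n2
    phi1 <- .sfs_1d_engine_cpp(ntot, ep, 1, dt_fac, as.integer(max_steps))
    v <- pooled_to_joint(phi1, n1, n2)
  } else {
    N1 <- max(n1, min_integration_n)
    N2 <- max(n2, min_integration_n)
    J1 <- cached_mat(sprintf("J%d", N1), function() jackknife_matrix(N1))
    J2 <- cached_mat(sprintf("J%d", N2), function() jackknife_matrix(N2))
    P1 <- cached_mat(sprintf("P%d", N1), function() projection_matrix(N1, N1 - 1L))
    P2 <- cached_mat(sprintf("P%d", N2), function() projection_matrix(N2, N2 - 1L))
    v <- .sfs_2d_engine_cpp(N1, N2, ep, 1, dt_fac, as.integer(max_steps),
                            J1, J2, P1, P2)
    if (N1 > n1 || N2 > n2) {
      v <- projection_matrix(N1, n1) %*% v %*% t(projection_matrix(N2, n2))
    }
  }
  v <- v * theta
  v[1, 1] <- 0
  v[n1 + 1, n2 + 1] <- 0
  spectrum_grid(v, folded = FALSE)
}

#' Monte-Carlo (coalescent) expected joint SFS
#'
#' Stochastic oracle for [expected_sfs()]: simulates many independent
#' genealogies under the structured coalescent and averages the branch length
#' subtending each (i, j) leaf configuration; the expected SFS entry is
#' `theta/2` times that mean. Returns the estimate and its Monte-Carlo
#' standard error per entry.
#'
#' @inheritParams expected_sfs
#' @param nreps number of genealogy replicates.
#' @param time_cap guard against non-coalescing configurations.
#' @return list with `mean` and `se` matrices (expected counts at `theta`),
#'   and `nreps`.
#' @export
mc_expected_sfs <- function(model, n1, n2, theta = 1, nreps = 1e5,
                            time_cap = 5000) {
  kk <- sim_counts(n1, n2, model)
  res <- .mc_branch_sfs_cpp(kk[1], kk[2], epoch_matrix(model),
                            as.integer(nreps), time_cap)
  if (kk[2] == 0L && n2 > 0L) {
    # panmictic: redistribute the pooled 1D branch spectrum over the demes
    pooled <- rowSums(res$mean) # index by i (j always 0)
    m <- pooled_to_joint(pooled, n1, n2)
    # the redistribution is a fixed linear map, so SEs scale with the weights
    sep <- pooled_to_joint(rowSums(res$se), n1, n2)
    res$mean <- m
    res$se <- sep
  }
  list(mean = res$mean * theta / 2, se = res$se * theta / 2,
       nreps = res$nreps)
}
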