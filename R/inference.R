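#' Poisson composite log-likelihood of an observed SFS
#'
#' Treats every unmasked spectrum entry as an independent Poisson count with
#' mean given by the expected spectrum:
#' \eqn{\sum [S_{obs} \ln S_{exp} - S_{exp} - \ln\Gamma(S_{obs}+1)]}.
#' Expected entries are floored at `1e-12` (with a warning) to guard the
#' logarithm.
#'
#' @param observed,expected [spectrum_grid()] objects of identical shape,
#'   folding and mask.
#' @return log-likelihood (scalar).
#' @export
composite_loglik <- function(observed, expected) {
  if (observed$n1 != expected$n1 || observed$n2 != expected$n2)
    stop("spectrum shapes differ")
  if (observed$folded != expected$folded)
    stop("folding status differs")
  use <- !(observed$mask | expected$mask)
  so <- observed$values[use]
  se <- expected$values[use]
  if (any(se < 1e-12)) {
    warning("expected entries floored at 1e-12")
    se <- pmax(se, 1e-12)
  }
  sum(so * log(se) - se - lgamma(so + 1))
}

#' Analytic profile of the spectrum scaling theta
#'
#' For a Poisson composite likelihood the optimal multiplicative scaling of an
#' expected shape is available in closed form:
#' `theta_hat = sum(S_obs) / sum(S_shape)` over unmasked entries.
#'
#' @param observed observed [spectrum_grid()].
#' @param shape expected spectrum computed at `theta = 1` (same shape/mask).
#' @return the Poisson-maximizing scale.
#' @export
profile_theta <- function(observed, shape) {
  use <- !(observed$mask | shape$mask)
  denom <- sum(shape$values[use])
  if (denom <= 0) stop("expected shape has zero unmasked mass")
  sum(observed$values[use]) / denom
}

# expected spectrum matched to the observed grid's folding
expected_for <- function(model, observed, theta = 1, ...) {
  e <- expected_sfs(model, observed$n1, observed$n2, theta = theta, ...)
  if (observed$folded) e <- fold_sfs(e)
  e
}

#' Fit one catalog model to an observed SFS
#'
#' Multi-start Nelder-Mead in log10-parameter space within the catalog entry's
#' bounds. Theta is profiled out analytically at every evaluation
#' ([profile_theta()]), but still counts as an estimated parameter in the AIC
#' (`AIC = 2k - 2 logL` with `k =` free parameters + 1). Start points are
#' drawn log-uniformly within bounds from a seeded generator; the best restart
#' is returned. Deterministic given `seed`.
#'
#' @param observed observed [spectrum_grid()] (folded or unfolded; the
#'   expected spectrum is folded to match before the likelihood).
#' @param entry a [model_catalog()] entry or model name.
#' @param restarts number of random restarts.
#' @param seed integer seed.
#' @param start optional named start vector (natural scale) used as the first
#'   start.
#' @param maxit Nelder-Mead iteration cap per restart.
#' @param dt_fac,max_steps,min_integration_n passed to [expected_sfs()].
#' @param n_polish maximum simplex-restart polishing rounds after the best
#'   restart (0 disables).
#' @return object of class `sfs_fit`: model name, `par` (natural scale),
#'   `theta_hat`, `loglik`, `AIC`, `k`, diagnostics.
#' @export
fit_model <- function(observed, entry, restarts = 6L, seed = 1L,
                      start = NULL, maxit = 400L, dt_fac = 0.2,
                      max_steps = 800L, min_integration_n = 16L,
                      n_polish = 3L) {
  if (is.character(entry)) entry <- model_catalog(entry)[[1L]]
  pn <- entry$params
  np <- length(pn)
  mk_fit <- function(par, ll, th, restart, conv) {
    structure(list(model = entry$name, par = par, theta_hat = th,
                   loglik = ll, k = entry$k, AIC = 2 * entry$k - 2 * ll,
                   restart_best = restart, convergence = conv,
                   n1 = observed$n1, n2 = observed$n2,
                   folded = observed$folded),
              class = "sfs_fit")
  }
  eval_par <- function(par) {
    shape <- expected_for(entry$build(par), observed, theta = 1,
                          dt_fac = dt_fac, max_steps = max_steps,
                          min_integration_n = min_integration_n)
    th <- profile_theta(observed, shape)
    sh <- shape
    sh$values <- sh$values * th
    ll <- suppressWarnings(composite_loglik(observed, sh))
    list(ll = ll, theta = th)
  }
  if (np == 0L) {
    ev <- eval_par(setNames(numeric(0), character(0)))
    return(mk_fit(setNames(numeric(0), character(0)), ev$ll, ev$theta, 0L, 0L))
  }
  lo <- log10(entry$bounds$lower)
  hi <- log10(entry$bounds$upper)
  obj <- function(y) {
    pen <- sum(pmax(0, y - hi)^2 + pmax(0, lo - y)^2)
    yc <- pmin(pmax(y, lo), hi)
    par <- setNames(10^yc, pn)
    ev <- tryCatch(eval_par(par), error = function(e) NULL)
    if (is.null(ev) || !is.finite(ev$ll)) return(1e12)
    -ev$ll + 1e4 * pen
  }
  set.seed(seed)
  starts <- matrix(runif(restarts * np, rep(lo, each = restarts),
                         rep(hi, each = restarts)), restarts, np)
  if (!is.null(start)) {
    starts[1L, ] <- pmin(pmax(log10(start[pn]), lo), hi)
  } else if (restarts >= 2L) {
    # anchor one start at a mild default (nu = 1, T = 0.1, M = 1)
    anchor <- ifelse(substr(pn, 1, 1) == "T", log10(0.1), 0)
    starts[1L, ] <- pmin(pmax(anchor, lo), hi)
  }
  best <- NULL
  fails <- character(0)
  for (r in seq_len(restarts)) {
    res <- tryCatch(
      optim(starts[r, ], obj, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-8)),
      error = function(e) { fails <<- c(fails, conditionMessage(e)); NULL })
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$restart <- r
    }
  }
  if (is.null(best))
    stop("all restarts failed: ", paste(unique(fails), collapse = "; "))
  # polish: restart Nelder-Mead at its own optimum with a fresh simplex until
  # the gain drops below 0.01 log-likelihood units
  if (np > 0L && n_polish > 0L) {
    for (pol in seq_len(n_polish)) {
      res <- tryCatch(
        optim(best$par, obj, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(res) || best$value - res$value < 0.01) {
        if (!is.null(res) && res$value < best$value) {
          res$restart <- best$restart; best <- res
        }
        break
      }
      res$restart <- best$restart
      best <- res
    }
  }
  y <- pmin(pmax(best$par, lo), hi)
  par <- setNames(10^y, pn)
  ev <- eval_par(par)
  mk_fit(par, ev$ll, ev$theta, best$restart, best$convergence)
}

#' @export
print.sfs_fit <- function(x, ...) {
  cat(sprintf("<sfs_fit> %s: logL=%.3f AIC=%.3f theta=%.4g (k=%d)\n",
              x$model, x$loglik, x$AIC, x$theta_hat, x$k))
  if (length(x$par))
    cat("  ", paste(sprintf("%s=%.4g", names(x$par), x$par), collapse = " "), "\n")
  invisible(x)
}

#' Rank models by median AIC over bootstrap replicates
#'
#' Computes, per model, the median AIC across replicates, the difference from
#' the best median (`delta_AIC`), the relative likelihood
#' `exp(-delta_AIC / 2)`, and the AIC weight (relative likelihoods normalized
#' over the catalog).
#'
#' @param aic_table data.frame with columns `model` and `AIC` (one row per
#'   model x replicate), or a named list of numeric AIC vectors.
#' @return data.frame ordered by `median_AIC` with columns `model`,
#'   `median_AIC`, `delta_AIC`, `rel_likelihood`, `AIC_weight`.
#' @export
rank_models <- function(aic_table) {
  if (is.list(aic_table) && !is.data.frame(aic_table)) {
    aic_table <- data.frame(
      model = rep(names(aic_table), lengths(aic_table)),
      AIC = unlist(aic_table, use.names = FALSE))
  }
  if (!all(c("model", "AIC") %in% names(aic_table)))
    stop("need columns 'model' and 'AIC'")
  med <- tapply(aic_table$AIC, aic_table$model, median)
  delta <- med - min(med)
  rel <- exp(-delta / 2)
  w <- rel / sum(rel)
  out <- data.frame(model = names(med), median_AIC = as.numeric(med),
                    delta_AIC = as.numeric(delta),
                    rel_likelihood = as.numeric(rel),
                    AIC_weight = as.numeric(w))
  out[order(out$median_AIC), , drop = FALSE]
}

#' Physical scaling constants
#'
#' @param mu per-base per-generation mutation rate.
#' @param G generation time in years.
#' @param L total analyzed sequence length (bases) so that
#'   `theta = 4 Ne_anc mu L`.
#' @return object of class `physical_scale`.
#' @export
physical_scale <- function(mu = 3.92e-9, G = 4, L) {
  if (missing(L) || is.null(L)) stop("sequence length L is required")
  stopifnot(mu > 0, G > 0, L > 0)
  structure(list(mu = mu, G = G, L = L), class = "physical_scale")
}

#' Convert a fitted model to physical units
#'
#' Applies the standard conversions: ancestral size
#' `Ne_anc = theta / (4 mu L)`; current sizes `nu_d * Ne_anc` (from the final
#' epoch); per-generation migrant fraction `m = M / (2 Ne_anc)`; years since
#' the split `2 T Ne_anc G` with `T` the summed post-split duration; migrants
#' per generation `m * Ne_current` of the source deme.
#'
#' @param fit an `sfs_fit` (or a list with `theta_hat` and `par`, plus
#'   `model`).
#' @param scale a [physical_scale()].
#' @return object of class `physical_params`.
#' @export
to_physical <- function(fit, scale) {
  stopifnot(inherits(scale, "physical_scale"))
  entry <- model_catalog(fit$model)[[1L]]
  model <- entry$build(fit$par)
  Ne <- fit$theta_hat / (4 * scale$mu * scale$L)
  eps <- model$epochs
  last <- if (length(eps)) eps[[length(eps)]] else NULL
  nu_cur <- if (is.null(last)) 1 else last$nu
  Ne_cur <- nu_cur * Ne
  if (has_split(model)) {
    Tsplit <- sum(vapply(eps[model$split:length(eps)], `[[`, 1, "T"))
    years <- 2 * Tsplit * Ne * scale$G
    M12 <- last$M_1to2; M21 <- last$M_2to1
    m12 <- M12 / (2 * Ne); m21 <- M21 / (2 * Ne)
    mig12 <- m12 * Ne_cur[1]  # migrants counted from the source deme
    mig21 <- m21 * Ne_cur[2]
  } else {
    years <- NA_real_
    m12 <- m21 <- mig12 <- mig21 <- NA_real_
  }
  structure(list(model = fit$model, theta = fit$theta_hat,
                 Ne_anc = Ne, Ne_current = Ne_cur,
                 split_years = years,
                 m = c(`1to2` = m12, `2to1` = m21),
                 migrants_per_gen = c(`1to2` = mig12, `2to1` = mig21),
                 scale = scale),
            class = "physical_params")
}

#' @export
print.physical_params <- function(x, ...) {
  cat(sprintf("<physical_params> %s: Ne_anc=%.0f", x$model, x$Ne_anc))
  cat(sprintf("; Ne_now=(%s)", paste(sprintf("%.0f", x$Ne_current), collapse = ", ")))
  if (is.finite(x$split_years))
    cat(sprintf("; split %.0f y; m=(%.3g, %.3g); migrants/gen=(%.1f, %.1f)",
                x$split_years, x$m[1], x$m[2],
                x$migrants_per_gen[1], x$migrants_per_gen[2]))
  cat("\n")
  invisible(x)
}

#' Bootstrap uncertainty of a fitted model
#'
#' Refits the model to each bootstrap spectrum (warm-started at the original
#' estimate) and reports 2.5/50/97.5 percentiles of theta and of every free
#' parameter, in physical units when a [physical_scale()] is supplied.
#' Deterministic given `seed`; errors if more than 20% of replicate fits fail.
#'
#' @param entry catalog entry or model name.
#' @param fit the original `sfs_fit` (used as warm start).
#' @param boot_sfs list of bootstrap [spectrum_grid()]s (will be folded to
#'   match the original fit if needed).
#' @param seed integer seed.
#' @param scale optional [physical_scale()].
#' @param restarts restarts per replicate (warm start counts as the first).
#' @param n_polish polishing rounds per replicate refit (see [fit_model()]).
#' @param ... passed to [fit_model()].
#' @return list with `quantiles` (matrix: parameters x c(2.5%, 50%, 97.5%)),
#'   `draws` (replicates x parameters), `n_failed`.
#' @export
bootstrap_uncertainty <- function(entry, fit, boot_sfs, seed = 1L,
                                  scale = NULL, restarts = 1L,
                                  n_polish = 1L, ...) {
  if (is.character(entry)) entry <- model_catalog(entry)[[1L]]
  draws <- list()
  n_failed <- 0L
  for (b in seq_along(boot_sfs)) {
    obs <- boot_sfs[[b]]
    if (fit$folded && !obs$folded) obs <- fold_sfs(obs)
    fb <- tryCatch(
      fit_model(obs, entry, restarts = restarts, seed = seed + b,
                start = if (length(fit$par)) fit$par else NULL,
                n_polish = n_polish, ...),
      error = function(e) NULL)
    if (is.null(fb)) { n_failed <- n_failed + 1L; next }
    if (!is.null(scale)) {
      ph <- to_physical(fb, scale)
      row <- c(theta = ph$theta, Ne_anc = ph$Ne_anc,
               setNames(ph$Ne_current, paste0("Ne_current", seq_along(ph$Ne_current))),
               split_years = ph$split_years,
               m_1to2 = unname(ph$m[1]), m_2to1 = unname(ph$m[2]))
    } else {
      row <- c(theta = fb$theta_hat, fb$par)
    }
    draws[[length(draws) + 1L]] <- row
  }
  if (n_failed > 0.2 * length(boot_sfs))
    stop(n_failed, " of ", length(boot_sfs), " replicate fits failed")
  D <- do.call(rbind, draws)
  # type-6 quantiles: at small B the 2.5/97.5% tails cannot be resolved
  # between order statistics, so the tail estimates fall on the extreme draws
  q <- t(apply(D, 2, quantile, probs = c(0.025, 0.5, 0.975),
               na.rm = TRUE, type = 6))
  list(quantiles = q, draws = D, n_failed = n_failed)
}
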