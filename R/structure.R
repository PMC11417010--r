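#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric MDS: double-center `-D^2/2`, eigendecompose, keep axes
#' with positive eigenvalues (negative eigenvalues are reported but their axes
#' dropped). Wraps [stats::cmdscale()].
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param k maximum number of axes to return.
#' @return object of class `pcoa_result`: `coordinates` (samples x axes,
#'   column-centered), `eigenvalues` (all, decreasing), `prop_variance`
#'   (share of the positive eigenvalue total per kept axis).
#' @export
pcoa <- function(D, k = NULL) {
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have zero diagonal")
  n <- nrow(D)
  if (is.null(k)) k <- n - 1L
  res <- suppressWarnings(cmdscale(as.dist(D), k = min(k, n - 1L), eig = TRUE))
  ev <- res$eig
  pos <- ev > max(ev) * 1e-9
  coords <- res$points
  keep <- seq_len(min(ncol(coords), sum(pos)))
  coords <- coords[, keep, drop = FALSE]
  colnames(coords) <- paste0("PCo", keep)
  structure(list(coordinates = coords,
                 eigenvalues = ev,
                 prop_variance = ev[keep] / sum(ev[pos])),
            class = "pcoa_result")
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA of group labels against a distance
#' matrix, delegated to `vegan::adonis2` (999 free sample permutations by
#' default, matching the standard procedure). `R2` is the fraction of
#' Gower-centered sum-of-squares explained by the grouping; the p-value is
#' `(1 + #{permuted F >= observed F}) / (1 + n_perm)`. Deterministic given
#' `seed`.
#'
#' @param D symmetric distance matrix.
#' @param labels group label per sample (>= 2 groups, each with >= 2 members).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return object of class `permanova_result`: `R2`, `pseudo_F`, `p_value`,
#'   `n_permutations`.
#' @export
permanova <- function(D, labels, n_perm = 999L, seed = 1L) {
  D <- as.matrix(D)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need at least two groups")
  if (any(table(labels) < 2L)) stop("every group needs at least two members")
  if (length(labels) != nrow(D)) stop("labels must match the distance matrix")
  df <- data.frame(group = labels)
  set.seed(seed)
  fit <- vegan::adonis2(as.dist(D) ~ group, data = df, permutations = n_perm)
  structure(list(R2 = fit$R2[1L], pseudo_F = fit$F[1L],
                 p_value = fit$`Pr(>F)`[1L], n_permutations = n_perm),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova> R2=%.5f F=%.3f p=%.4g (%d permutations)\n",
              x$R2, x$pseudo_F, x$p_value, x$n_permutations))
  invisible(x)
}

#' Hudson-style FST from genotype calls
#'
#' Per-site Hudson estimator from per-deme allele counts; the global value is
#' the ratio of averages (summed numerators over summed denominators across
#' sites), which is robust to low-information sites, unlike the average of
#' per-site ratios. Sites monomorphic across both demes, or without at least
#' two called genomes per deme, are excluded from the global sums.
#'
#' @param gm a [genotype_matrix()] with exactly two demes.
#' @return list: `global` (weighted FST), `per_site` (data.frame with
#'   per-site numerator, denominator and FST; `NA` where undefined).
#' @export
fst_hudson <- function(gm) {
  demes <- deme_levels(gm)
  if (length(demes) != 2L) stop("fst_hudson needs exactly two demes")
  tal <- site_allele_counts(gm)
  n1 <- tal$g1; n2 <- tal$g2
  p1 <- ifelse(n1 > 0, tal$c1 / n1, NA_real_)
  p2 <- ifelse(n2 > 0, tal$c2 / n2, NA_real_)
  ok <- n1 >= 2 & n2 >= 2
  num <- (p1 - p2)^2 -
    p1 * (1 - p1) / pmax(n1 - 1, 1) -
    p2 * (1 - p2) / pmax(n2 - 1, 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  poly <- ok & den > 0
  per_site <- data.frame(contig = gm$sites$contig, pos = gm$sites$pos,
                         numerator = ifelse(ok, num, NA_real_),
                         denominator = ifelse(ok, den, NA_real_),
                         fst = ifelse(poly, pmin(num / den, 1), NA_real_))
  global <- sum(num[poly]) / sum(den[poly])
  list(global = global, per_site = per_site)
}
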