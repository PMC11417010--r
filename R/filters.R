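#' Site filter configuration
#'
#' The standard RAD-style site filters: minimum call fraction (site genotyped
#' in at least this fraction of samples), minimum pooled minor allele
#' frequency (retained if MAF `>=` the threshold, i.e. sites *below* it are
#' removed), and an optional cap on the observed heterozygote fraction
#' (paralog-collapse guard; collapsed paralogs show up as ~100% heterozygous
#' sites).
#'
#' @param min_call_fraction minimum fraction of samples with a genotype call.
#' @param min_maf minimum pooled minor allele frequency (computed over
#'   non-missing calls, demes pooled).
#' @param max_het_fraction optional maximum observed heterozygote fraction
#'   among called genotypes (`NULL` disables; 0.5 is a common choice).
#' @return object of class `site_filter_config`.
#' @export
site_filter_config <- function(min_call_fraction = 0.75, min_maf = 0.025,
                               max_het_fraction = NULL) {
  stopifnot(min_call_fraction >= 0, min_call_fraction <= 1,
            min_maf >= 0, min_maf <= 1,
            is.null(max_het_fraction) ||
              (max_het_fraction >= 0 && max_het_fraction <= 1))
  structure(list(min_call_fraction = min_call_fraction,
                 min_maf = min_maf,
                 max_het_fraction = max_het_fraction),
            class = "site_filter_config")
}

#' Apply site filters to a genotype matrix
#'
#' Retains exactly the sites with call fraction `>= min_call_fraction`,
#' pooled MAF `>= min_maf`, and (when configured) heterozygote fraction
#' `<= max_het_fraction`. Samples and site order are untouched. If every site
#' is removed a warning (not an error) is raised. The returned object carries
#' an `audit` attribute: a data.frame of dropped sites and the first rule each
#' one violated.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [site_filter_config()].
#' @return filtered [genotype_matrix()].
#' @export
apply_site_filters <- function(gm, cfg = site_filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(cfg, "site_filter_config"))
  if (ncol(gm$calls) == 0L) stop("empty genotype matrix")
  G <- gm$calls
  n_samp <- nrow(G)
  called <- colSums(!is.na(G))
  call_frac <- called / n_samp
  alt <- colSums(G, na.rm = TRUE)
  af <- ifelse(called > 0, alt / (2 * called), NA_real_)
  maf <- pmin(af, 1 - af)
  het_frac <- ifelse(called > 0, colSums(G == 1L, na.rm = TRUE) / called, NA_real_)
  fail_call <- call_frac < cfg$min_call_fraction
  fail_maf <- !fail_call & (is.na(maf) | maf < cfg$min_maf)
  fail_het <- if (is.null(cfg$max_het_fraction)) rep(FALSE, ncol(G)) else
    !fail_call & !fail_maf & het_frac > cfg$max_het_fraction
  keep <- !(fail_call | fail_maf | fail_het)
  if (!any(keep)) warning("all sites removed by the filters")
  reason <- rep(NA_character_, ncol(G))
  reason[fail_call] <- "call_fraction"
  reason[fail_maf] <- "maf"
  reason[fail_het] <- "het_fraction"
  out <- genotype_matrix(G[, keep, drop = FALSE], gm$samples,
                         gm$sites[keep, , drop = FALSE])
  attr(out, "audit") <- data.frame(
    contig = gm$sites$contig[!keep], pos = gm$sites$pos[!keep],
    reason = reason[!keep])
  out
}

#' Identity-by-state distance between all sample pairs
#'
#' `d(a, b)` is the mean over sites non-missing in both samples of
#' `|g_a - g_b| / 2`, i.e. the average allele-sharing mismatch, in `[0, 1]`.
#' Pairs with no overlapping called site get `NA` (flagged, not silently 0).
#'
#' @param gm a [genotype_matrix()].
#' @return symmetric matrix with zero diagonal.
#' @export
ibs_distance <- function(gm) {
  G <- gm$calls
  n <- nrow(G)
  if (n < 2L) stop("need at least two samples")
  Gz <- G
  Gz[is.na(Gz)] <- 0L
  M <- !is.na(G)
  storage.mode(Gz) <- "double"
  storage.mode(M) <- "double"
  # sum over shared sites of |ga - gb| via the identity
  # |ga-gb| = ga^2 + gb^2 - 2 ga gb restricted to {0,1,2}? not linear; loop demes
  D <- matrix(0, n, n, dimnames = list(gm$samples$id, gm$samples$id))
  overlap <- M %*% t(M)
  # decompose |ga - gb| over shared sites with indicator algebra:
  # |ga-gb| in {0,1,2}; sum = sum((ga-gb)^2) - #"{|diff|=2} pairs" * 2 ... use
  # direct per-pair computation instead (n is modest in this setting)
  for (a in seq_len(n - 1L)) {
    ga <- G[a, ]
    for (b in (a + 1L):n) {
      sh <- !is.na(ga) & !is.na(G[b, ])
      if (!any(sh)) { D[a, b] <- D[b, a] <- NA_real_; next }
      d <- mean(abs(ga[sh] - G[b, sh])) / 2
      D[a, b] <- D[b, a] <- d
    }
  }
  attr(D, "overlap") <- overlap
  D
}

#' Per-sample heterozygosity
#'
#' Fraction of heterozygous calls among non-missing calls per sample. Samples
#' with no called genotype get `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @return named numeric vector in `[0, 1]`.
#' @export
sample_heterozygosity <- function(gm) {
  G <- gm$calls
  called <- rowSums(!is.na(G))
  het <- rowSums(G == 1L, na.rm = TRUE)
  out <- ifelse(called > 0, het / called, NA_real_)
  setNames(out, gm$samples$id)
}
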