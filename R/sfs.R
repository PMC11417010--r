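#' Joint site-frequency-spectrum grids
#'
#' A `spectrum_grid` is an `(n1+1) x (n2+1)` non-negative matrix whose entry
#' `(i, j)` (0-based indices) holds the (possibly fractional, expected) number
#' of sites at which the derived/alternate allele was seen `i` times among
#' `n1` genomes from deme 1 and `j` times among `n2` genomes from deme 2. The
#' monomorphic corners `(0,0)` and `(n1,n2)` are always masked; a folded grid
#' additionally masks (and zeroes) all entries with `i + j > (n1+n2)/2`.
#'
#' @param values numeric matrix, `(n1+1) x (n2+1)`.
#' @param folded logical flag.
#' @param mask optional logical matrix of entries to exclude from likelihoods;
#'   the monomorphic corners are always added.
#' @return object of class `spectrum_grid`.
#' @export
spectrum_grid <- function(values, folded = FALSE, mask = NULL) {
  stopifnot(is.matrix(values), all(values >= -1e-9))
  values[values < 0] <- 0
  n1 <- nrow(values) - 1L
  n2 <- ncol(values) - 1L
  if (is.null(mask)) mask <- matrix(FALSE, n1 + 1L, n2 + 1L)
  stopifnot(identical(dim(mask), dim(values)))
  mask[1L, 1L] <- TRUE
  mask[n1 + 1L, n2 + 1L] <- TRUE
  if (folded) {
    tot <- outer(0:n1, 0:n2, `+`)
    mask[tot > (n1 + n2) / 2] <- TRUE
  }
  structure(list(values = values, n1 = n1, n2 = n2,
                 folded = folded, mask = mask),
            class = "spectrum_grid")
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat(sprintf("<spectrum_grid> n1=%d n2=%d %s, total mass %.4g\n",
              x$n1, x$n2, if (x$folded) "folded" else "unfolded",
              sum(x$values)))
  invisible(x)
}

#' @rdname spectrum_grid
#' @param x a `spectrum_grid`.
#' @export
sfs_mass <- function(x) sum(x$values)

#' Fold a joint SFS onto minor-allele counts
#'
#' Entry `(i, j)` with `i + j` above half the total sample size is added into
#' its complement `(n1-i, n2-j)`; entries exactly at half are split
#' half-and-half between the two (so they stay in place). Total mass is
#' conserved.
#'
#' @param sfs an unfolded [spectrum_grid()].
#' @return folded `spectrum_grid`.
#' @export
fold_sfs <- function(sfs) {
  if (sfs$folded) stop("spectrum is already folded")
  n1 <- sfs$n1; n2 <- sfs$n2
  v <- sfs$values
  rev_v <- v[(n1 + 1L):1L, (n2 + 1L):1L, drop = FALSE]
  tot <- outer(0:n1, 0:n2, `+`)
  half <- (n1 + n2) / 2
  out <- v + rev_v
  out[tot == half] <- out[tot == half] / 2
  out[tot > half] <- 0
  spectrum_grid(out, folded = TRUE)
}

# exact hypergeometric projection matrix: rows a = 0..m, cols i = 0..n
projection_matrix <- function(n, m) {
  outer(0:m, 0:n, function(a, i) dhyper(a, i, n - i, m))
}

#' Project a joint SFS to smaller sample sizes
#'
#' Exact hypergeometric down-sampling: the projected entry is the expectation
#' of the allele count in a subsample of `m1` (resp. `m2`) genomes drawn
#' without replacement. Mass is conserved; projecting to the same sizes is the
#' identity.
#'
#' @param sfs an unfolded [spectrum_grid()].
#' @param m1,m2 target haploid sample sizes, `<=` the current sizes.
#' @return projected `spectrum_grid`.
#' @export
project_sfs <- function(sfs, m1, m2) {
  if (sfs$folded) stop("project before folding")
  if (m1 > sfs$n1 || m2 > sfs$n2) stop("cannot project up (m > n)")
  P1 <- projection_matrix(sfs$n1, m1)
  P2 <- projection_matrix(sfs$n2, m2)
  spectrum_grid(P1 %*% sfs$values %*% t(P2), folded = FALSE)
}

#' Observed joint SFS from a genotype matrix
#'
#' For each biallelic site the alternate-allele count and the number of
#' non-missing genomes are tallied per deme. Sites with at least `n1`/`n2`
#' called genomes in the respective demes contribute; sites called in more
#' genomes than the target are spread hypergeometrically over the target cells
#' (projection at accumulation time), so every contributing site adds exactly
#' unit mass and total mass equals the number of contributing sites.
#'
#' @param gm a [genotype_matrix()] with exactly two demes.
#' @param n1,n2 target haploid sample sizes per deme.
#' @return unfolded [spectrum_grid()]; attribute `n_dropped` counts sites with
#'   insufficient calls in either deme.
#' @export
observed_sfs <- function(gm, n1, n2) {
  demes <- deme_levels(gm)
  if (length(demes) != 2L) stop("observed_sfs needs exactly two demes")
  tal <- site_allele_counts(gm)
  if (n1 > 2L * sum(gm$samples$deme == demes[1]) ||
      n2 > 2L * sum(gm$samples$deme == demes[2]))
    stop("projection target exceeds available haploid sample size")
  keep <- tal$g1 >= n1 & tal$g2 >= n2
  v <- matrix(0, n1 + 1L, n2 + 1L)
  if (any(keep)) {
    c1 <- tal$c1[keep]; g1 <- tal$g1[keep]
    c2 <- tal$c2[keep]; g2 <- tal$g2[keep]
    for (s in seq_along(c1)) {
      w1 <- dhyper(0:n1, c1[s], g1[s] - c1[s], n1)
      w2 <- dhyper(0:n2, c2[s], g2[s] - c2[s], n2)
      v <- v + tcrossprod(w1, w2)
    }
  }
  out <- spectrum_grid(v, folded = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# per-site alt-allele counts and called-genome counts per deme
site_allele_counts <- function(gm) {
  demes <- deme_levels(gm)
  in1 <- gm$samples$deme == demes[1]
  in2 <- gm$samples$deme == demes[2]
  G <- gm$calls
  called <- !is.na(G)
  list(
    c1 = colSums(G[in1, , drop = FALSE], na.rm = TRUE),
    g1 = 2L * colSums(called[in1, , drop = FALSE]),
    c2 = colSums(G[in2, , drop = FALSE], na.rm = TRUE),
    g2 = 2L * colSums(called[in2, , drop = FALSE])
  )
}

#' Contig bootstrap of the joint SFS
#'
#' Resamples contigs with replacement to the original contig count and
#' rebuilds the observed SFS from the resampled sites, which respects physical
#' linkage of SNPs within a contig. Deterministic given `seed`.
#'
#' @inheritParams observed_sfs
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @return list of `B` unfolded [spectrum_grid()] objects.
#' @export
bootstrap_contigs <- function(gm, n1, n2, B, seed) {
  contigs <- unique(gm$sites$contig)
  nc <- length(contigs)
  if (nc < 2L) stop("contig bootstrap needs at least two contigs")
  # per-contig grids, flattened; replicate = multiplicity %*% grid matrix
  demes <- deme_levels(gm)
  tal <- site_allele_counts(gm)
  keep <- tal$g1 >= n1 & tal$g2 >= n2
  ncell <- (n1 + 1L) * (n2 + 1L)
  contig_of_site <- match(gm$sites$contig, contigs)
  gridmat <- matrix(0, nc, ncell)
  idx <- which(keep)
  for (s in idx) {
    w <- tcrossprod(dhyper(0:n1, tal$c1[s], tal$g1[s] - tal$c1[s], n1),
                    dhyper(0:n2, tal$c2[s], tal$g2[s] - tal$c2[s], n2))
    k <- contig_of_site[s]
    gridmat[k, ] <- gridmat[k, ] + as.vector(w)
  }
  set.seed(seed)
  out <- vector("list", B)
  for (b in seq_len(B)) {
    mult <- tabulate(sample.int(nc, nc, replace = TRUE), nbins = nc)
    v <- matrix(as.vector(mult %*% gridmat), n1 + 1L, n2 + 1L)
    out[[b]] <- spectrum_grid(v, folded = FALSE)
  }
  out
}

#' Read and write spectra in the plain-text dadi/moments format
#'
#' Header line: `"<n1+1> <n2+1> <folded|unfolded>"`; second line: the
#' `(n1+1)*(n2+1)` values in row-major order (C order: the second index moves
#' fastest); third line: the mask as 0/1 in the same order. Round-trips
#' bit-exactly through `format(..., digits = 17)`.
#'
#' @param sfs a [spectrum_grid()].
#' @param path file path.
#' @return `read_sfs()` returns a [spectrum_grid()].
#' @export
write_sfs <- function(sfs, path) {
  hdr <- sprintf("%d %d %s", sfs$n1 + 1L, sfs$n2 + 1L,
                 if (sfs$folded) "folded" else "unfolded")
  vals <- as.vector(t(sfs$values)) # row-major
  msk <- as.integer(as.vector(t(sfs$mask)))
  writeLines(c(hdr,
               paste(format(vals, digits = 17, trim = TRUE, scientific = TRUE),
                     collapse = " "),
               paste(msk, collapse = " ")), path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  d1 <- as.integer(hdr[1]); d2 <- as.integer(hdr[2])
  folded <- identical(hdr[3], "folded")
  vals <- as.numeric(strsplit(trimws(ln[2]), "\\s+")[[1]])
  msk <- as.integer(strsplit(trimws(ln[3]), "\\s+")[[1]])
  stopifnot(length(vals) == d1 * d2, length(msk) == d1 * d2)
  v <- matrix(vals, d1, d2, byrow = TRUE)
  m <- matrix(as.logical(msk), d1, d2, byrow = TRUE)
  spectrum_grid(v, folded = folded, mask = m)
}
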