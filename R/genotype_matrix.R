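#' Diploid genotype matrices with contig/position metadata
#'
#' The central data container: integer calls in `{0, 1, 2, NA}` counting
#' alternate alleles, one row per sample and one column per biallelic site,
#' plus a sample table (`id`, `deme`) and a site table (`contig`, `pos`,
#' `ref`, `alt`). Positions must be strictly increasing within a contig.
#'
#' @param calls integer matrix (samples x sites), values 0/1/2/NA.
#' @param samples data.frame with columns `id`, `deme`.
#' @param sites data.frame with columns `contig`, `pos`, `ref`, `alt`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, samples, sites) {
  stopifnot(is.matrix(calls),
            nrow(calls) == nrow(samples),
            ncol(calls) == nrow(sites),
            all(c("id", "deme") %in% names(samples)),
            all(c("contig", "pos") %in% names(sites)))
  ok <- calls %in% c(0L, 1L, 2L, NA)
  if (!all(ok)) stop("calls must be 0, 1, 2 or NA")
  ord_ok <- tapply(sites$pos, sites$contig, function(p) all(diff(p) > 0))
  if (!all(unlist(ord_ok))) stop("positions must be strictly increasing within contig")
  if (is.null(sites$ref)) sites$ref <- "A"
  if (is.null(sites$alt)) sites$alt <- "T"
  rownames(calls) <- samples$id
  structure(list(calls = calls, samples = samples, sites = sites),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d sites, %d contigs, %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$sites$contig)),
              100 * mean(is.na(x$calls))))
  tb <- table(x$samples$deme)
  cat("  demes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`.
#' @export
deme_levels <- function(gm) {
  if (is.factor(gm$samples$deme)) levels(gm$samples$deme) else unique(gm$samples$deme)
}

#' @rdname genotype_matrix
#' @export
n_sites <- function(gm) ncol(gm$calls)

#' Write a genotype matrix as VCF 4.2
#'
#' Plain-text VCF with `##contig` headers and diploid unphased GT fields
#' (missing calls as `./.`). Heterozygotes are written `0/1`; homozygotes
#' `0/0` / `1/1`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (`.vcf`).
#' @export
write_vcf <- function(gm, path) {
  contigs <- unique(gm$sites$contig)
  clen <- tapply(gm$sites$pos, gm$sites$contig, max)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=jointsfs",
           sprintf("##contig=<ID=%s,length=%d>", contigs,
                   as.integer(clen[contigs]) + 1L),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples$id), collapse = "\t"))
  gt <- matrix("./.", nrow(gm$calls), ncol(gm$calls))
  gt[!is.na(gm$calls) & gm$calls == 0L] <- "0/0"
  gt[!is.na(gm$calls) & gm$calls == 1L] <- "0/1"
  gt[!is.na(gm$calls) & gm$calls == 2L] <- "1/1"
  body <- paste(gm$sites$contig, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a biallelic-SNP VCF plus population map into a genotype matrix
#'
#' Uses `vcfR` for parsing. Multiallelic or non-SNP records are dropped with
#' a message. The population map is a two-column (sample, deme) table without
#' header.
#'
#' @param vcf_path VCF file (plain text or gzip).
#' @param popmap_path two-column population map; may be `NULL` if `demes`
#'   supplied.
#' @param demes optional named character vector sample -> deme.
#' @return a [genotype_matrix()].
#' @export
read_genotype_vcf <- function(vcf_path, popmap_path = NULL, demes = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  n_multi <- sum(!biallelic)
  if (n_multi > 0)
    message(n_multi, " multiallelic/non-SNP record(s) dropped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  calls <- t(matrix(code(as.vector(gt)), nrow = nrow(gt))) # samples x sites
  rownames(calls) <- colnames(gt)
  if (is.null(demes)) {
    pm <- read_popmap(popmap_path)
    demes <- setNames(pm$deme, pm$id)
  }
  ids <- rownames(calls)
  if (!all(ids %in% names(demes))) stop("population map is missing samples")
  samples <- data.frame(id = ids, deme = unname(demes[ids]))
  sites <- data.frame(contig = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"])
  genotype_matrix(calls, samples, sites)
}

#' @rdname read_genotype_vcf
#' @param pm data.frame with columns `id`, `deme` (for writing).
#' @param path file path.
#' @export
write_popmap <- function(pm, path) {
  write.table(pm[, c("id", "deme")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_genotype_vcf
#' @export
read_popmap <- function(path) {
  pm <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("id", "deme"),
                   colClasses = "character")
  pm
}
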