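#' Configuration for the structured-coalescent simulator
#'
#' Physical-unit front end to the simulator: the demographic model is given in
#' genetic units (see [demographic_model()]) together with the ancestral
#' effective size `Ne_anc` in diploids, so that branch lengths, mutation
#' counts and migration rates all resolve to physical quantities.
#'
#' @param deme_sizes integer vector (length 1 or 2): diploid sample size per
#'   deme.
#' @param n_contigs number of independent, non-recombining contigs.
#' @param contig_length contig length in bp.
#' @param mu per-base per-generation mutation rate.
#' @param Ne_anc ancestral effective population size (diploids).
#' @param model a [demographic_model()] (genetic units).
#' @param missing_rate probability a genotype call is missing, in `[0, 1)`.
#' @param time_cap error guard: maximum genealogy depth in units of
#'   `2 Ne_anc` generations before a non-coalescing configuration aborts.
#' @param seed integer seed used by [emit_genotype_matrix()].
#' @return object of class `coalescent_config`.
#' @export
coalescent_config <- function(deme_sizes, n_contigs, contig_length, mu,
                              Ne_anc, model = demographic_model(),
                              missing_rate = 0, time_cap = 5000, seed = 1L) {
  stopifnot(all(deme_sizes >= 1), length(deme_sizes) %in% 1:2,
            n_contigs >= 1, contig_length >= 1, mu > 0, Ne_anc > 0,
            missing_rate >= 0, missing_rate < 1, time_cap > 0,
            inherits(model, "demographic_model"))
  structure(list(deme_sizes = as.integer(deme_sizes),
                 n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 mu = mu, Ne_anc = Ne_anc, model = model,
                 missing_rate = missing_rate, time_cap = time_cap,
                 seed = as.integer(seed)),
            class = "coalescent_config")
}

# lineage counts for the core: models without a split are panmictic, so both
# sampled demes are simulated as one deme and labels reattached afterwards
sim_counts <- function(k1, k2, model) {
  if (has_split(model) || k2 == 0L) c(k1, k2) else c(k1 + k2, 0L)
}

#' Simulate one genealogy under the structured coalescent
#'
#' Draws a single binary genealogy for `lineages[1]` haploid lineages sampled
#' in deme 1 and `lineages[2]` in deme 2, under the epochs of the model (size
#' changes handled by exponential thinning, migration by the backward-time
#' convention: a lineage now in deme e traces back into deme d at the forward
#' rate of gene flow d -> e). Branch lengths are returned in generations.
#'
#' @param model a [demographic_model()].
#' @param lineages haploid lineage counts per deme (length 1 or 2).
#' @param Ne_anc ancestral effective size (diploids), used to convert
#'   coalescent time units to generations.
#' @param time_cap see [coalescent_config()].
#' @return a `genealogy`: list with `edge` (child, parent; leaves are
#'   `1..n`), `length` (generations), `node_time`, `leaf_deme`, `n_leaves`,
#'   `total_length`.
#' @export
simulate_genealogy <- function(model, lineages, Ne_anc = 1, time_cap = 5000) {
  stopifnot(all(lineages >= 0), sum(lineages) >= 1)
  k1 <- lineages[1]; k2 <- if (length(lineages) > 1L) lineages[2] else 0L
  kk <- sim_counts(k1, k2, model)
  tr <- .sim_tree_cpp(kk[1], kk[2], epoch_matrix(model), time_cap)
  if (kk[1] != k1) { # panmictic relabel: first k1 leaves are "deme 1"
    tr$leaf_deme <- c(rep(1L, k1), rep(2L, k2))
  }
  tr$length <- tr$length * 2 * Ne_anc
  tr$node_time <- tr$node_time * 2 * Ne_anc
  tr$total_length <- tr$total_length * 2 * Ne_anc
  class(tr) <- "genealogy"
  tr
}

#' Drop infinite-sites mutations on a genealogy
#'
#' The number of mutations is Poisson with mean
#' `mu * contig_length * total branch length (generations)`; each mutation is
#' placed on a branch with probability proportional to its length and yields
#' one biallelic site whose derived allele is carried by the leaves below that
#' branch. Monomorphic outcomes (zero mutations) return an empty list.
#'
#' @param genealogy output of [simulate_genealogy()].
#' @param contig_length contig length (bp).
#' @param mu per-base per-generation mutation rate.
#' @return list of integer vectors, one per site, holding carrier leaf ids.
#' @export
drop_mutations <- function(genealogy, contig_length, mu) {
  stopifnot(all(is.finite(genealogy$length)))
  tot <- genealogy$total_length
  n_mut <- rpois(1L, mu * contig_length * tot)
  if (n_mut == 0L || tot <= 0) return(list())
  n <- genealogy$n_leaves
  edge <- genealogy$edge
  len <- genealogy$length
  kids <- split(edge[, 1L], edge[, 2L]) # parent -> children
  pick <- sample.int(nrow(edge), n_mut, replace = TRUE, prob = len)
  lapply(pick, function(e) {
    stack <- edge[e, 1L]
    out <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= n) out <- c(out, v)
      else stack <- c(stack, kids[[as.character(v)]])
    }
    sort(out)
  })
}

#' Simulate a genotype matrix with contig structure and missingness
#'
#' Runs the structured coalescent independently on each contig, drops
#' infinite-sites mutations, pairs haplotypes within deme into diploids,
#' inserts missing calls independently at `missing_rate`, and returns the
#' genotype matrix together with a truth record echoing the configuration.
#' Fully reproducible given `config$seed`.
#'
#' @param config a [coalescent_config()].
#' @return list with elements `gm` (a [genotype_matrix()]) and `truth` (a
#'   `truth_record`: the config plus realized counts).
#' @export
emit_genotype_matrix <- function(config) {
  set.seed(config$seed)
  ds <- config$deme_sizes
  k1 <- 2L * ds[1]
  k2 <- if (length(ds) > 1L) 2L * ds[2] else 0L
  kk <- sim_counts(k1, k2, config$model)
  mut_per_unit <- config$mu * config$contig_length * 2 * config$Ne_anc
  sim <- .sim_contig_sites_cpp(kk[1], kk[2], epoch_matrix(config$model),
                               config$n_contigs, mut_per_unit, config$time_cap)
  hap <- sim$haplotypes          # sites x haploids (0/1)
  contig_idx <- sim$contig
  n_hap <- k1 + k2
  # within-contig positions: distinct, sorted (infinite sites on finite bp)
  pos <- integer(nrow(hap))
  keep <- rep(TRUE, nrow(hap))
  for (s in split(seq_along(contig_idx), contig_idx)) {
    if (length(s) > config$contig_length) {
      keep[s[-seq_len(config$contig_length)]] <- FALSE
      s <- s[seq_len(config$contig_length)]
    }
    pos[s] <- sort(sample.int(config$contig_length, length(s)))
  }
  hap <- hap[keep, , drop = FALSE]
  contig_idx <- contig_idx[keep]
  pos <- pos[keep]
  # haplotype pairing within deme (consecutive pairs)
  geno <- hap[, seq(1L, n_hap, by = 2L), drop = FALSE] +
    hap[, seq(2L, n_hap, by = 2L), drop = FALSE] # sites x diploids
  calls <- t(geno)
  storage.mode(calls) <- "integer"
  if (config$missing_rate > 0) {
    miss <- matrix(runif(length(calls)) < config$missing_rate,
                   nrow(calls), ncol(calls))
    calls[miss] <- NA_integer_
  }
  n_dip <- sum(ds)
  deme <- rep(c("deme1", "deme2")[seq_along(ds)], ds)
  samples <- data.frame(id = sprintf("s%03d", seq_len(n_dip)), deme = deme)
  cg_names <- sprintf("ctg%05d", contig_idx)
  ord <- order(contig_idx, pos)
  calls <- calls[, ord, drop = FALSE]
  sites <- data.frame(contig = cg_names[ord], pos = pos[ord],
                      ref = "A", alt = "T")
  gm <- genotype_matrix(calls, samples, sites)
  truth <- structure(list(config = config,
                          n_segregating = ncol(calls),
                          called_per_sample = rowSums(!is.na(calls))),
                     class = "truth_record")
  list(gm = gm, truth = truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("<truth_record> %d segregating sites; model '%s'; Ne_anc=%g\n",
              x$n_segregating,
              if (is.null(x$config$model$name)) "custom" else x$config$model$name,
              x$config$Ne_anc))
  invisible(x)
}

#' Write a truth record as YAML
#'
#' @param truth a `truth_record` from [emit_genotype_matrix()].
#' @param path output path.
#' @export
write_truth_yaml <- function(truth, path) {
  cfg <- truth$config
  eps <- lapply(cfg$model$epochs, function(e)
    list(T = e$T, nu = e$nu, dynamics = e$dynamics,
         M_1to2 = e$M_1to2, M_2to1 = e$M_2to1))
  yaml::write_yaml(list(
    deme_sizes = cfg$deme_sizes, n_contigs = cfg$n_contigs,
    contig_length = cfg$contig_length, mu = cfg$mu, Ne_anc = cfg$Ne_anc,
    missing_rate = cfg$missing_rate, seed = cfg$seed,
    model = list(name = cfg$model$name, epochs = eps),
    n_segregating = truth$n_segregating), path)
  invisible(path)
}

#' Study-emulation preset: two bonnethead shark bays
#'
#' A [coalescent_config()] emulating the statistical shape of the motivating
#' bonnethead shark dataset: 20 + 69 diploids, short (36 bp) 2bRAD-like tags,
#' mu = 3.92e-9, and the best-fit demographic history in physical units
#' (ancestral Ne 10,263; sudden ancestral growth to ~51,000 around 390 kya;
#' split ~1,532 years ago with linear growth to ~158,639 in deme 1 (Tampa
#' Bay), sudden growth to ~1,026,319 in deme 2 (Biscayne Bay), and one-way
#' gene flow deme 1 -> deme 2 at m = 4.87e-4 per generation). Generation time
#' 4 years. The tag count is calibrated once so that roughly 10,000-11,000
#' SNPs survive the standard filters (75% call rate, MAF 0.025); uniform
#' missingness thins genotype calls.
#'
#' @param n_contigs number of 36-bp tags (default calibrated to the target
#'   SNP count).
#' @param missing_rate per-genotype missing probability.
#' @param seed integer seed.
#' @return a [coalescent_config()].
#' @export
bonnethead_preset <- function(n_contigs = 129000, missing_rate = 0.15, seed = 1L) {
  Ne <- 10263
  G <- 4
  yrs_split <- 1532
  yrs_growth <- 390000
  T_split <- yrs_split / (2 * Ne * G)
  T_growth <- (yrs_growth - yrs_split) / (2 * Ne * G)
  m <- 4.87e-4
  model <- demographic_model(list(
    epoch(T = T_growth, nu = 51000 / Ne, dynamics = "sudden"),
    epoch(T = T_split, nu = c(158639 / Ne, 1026319 / Ne),
          dynamics = c("linear", "sudden"),
          M_1to2 = 2 * Ne * m, M_2to1 = 0)
  ), name = "gadma_best")
  coalescent_config(deme_sizes = c(20L, 69L), n_contigs = n_contigs,
                    contig_length = 36L, mu = 3.92e-9, Ne_anc = Ne,
                    model = model, missing_rate = missing_rate, seed = seed)
}
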