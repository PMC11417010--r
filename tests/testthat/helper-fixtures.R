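# small hand-built genotype matrices used across tests

toy_gm <- function(calls, demes = NULL, contig = NULL) {
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(demes)) demes <- rep("deme1", n)
  if (is.null(contig)) contig <- rep("c1", m)
  genotype_matrix(
    calls,
    samples = data.frame(id = sprintf("s%02d", seq_len(n)), deme = demes),
    sites = data.frame(contig = contig,
                       pos = as.integer(stats::ave(seq_len(m), contig,
                                                   FUN = seq_along)),
                       ref = "A", alt = "T"))
}

# random complete-call genotype matrix
random_gm <- function(n, m, seed) {
  set.seed(seed)
  toy_gm(matrix(sample(0:2, n * m, replace = TRUE), n, m))
}

# MRCA depth of two leaves in a genealogy
pair_tmrca <- function(tr, a, b) {
  parent <- integer(2 * tr$n_leaves - 1)
  parent[tr$edge[, 1]] <- tr$edge[, 2]
  anc <- function(v) {
    out <- v
    while (parent[v] != 0) { v <- parent[v]; out <- c(out, v) }
    out
  }
  common <- intersect(anc(a), anc(b))
  min(tr$node_time[common])
}
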