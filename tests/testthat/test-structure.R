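test_that("PCoA recovers simple geometries", {
  # equilateral triangle: two equal positive eigenvalues
  D <- matrix(1, 3, 3); diag(D) <- 0
  p <- pcoa(D)
  ev <- p$eigenvalues[p$eigenvalues > 1e-9]
  expect_length(ev, 2)
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  # distances from a 2-D cloud are reproduced exactly
  set.seed(1)
  X <- matrix(rnorm(20), 10, 2)
  D2 <- as.matrix(dist(X))
  p2 <- pcoa(D2)
  rec <- as.matrix(dist(p2$coordinates[, 1:2]))
  expect_lt(max(abs(rec - D2)), 1e-8)
  expect_lt(max(abs(colMeans(p2$coordinates))), 1e-10)
  # two samples: one axis, separation equals the distance
  D3 <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  p3 <- pcoa(D3)
  expect_equal(abs(diff(p3$coordinates[, 1])), 0.4, tolerance = 1e-12)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PERMANOVA statistics behave as a permutation test should", {
  set.seed(2)
  X <- rbind(matrix(rnorm(24), 8, 3), matrix(rnorm(24, mean = 6), 8, 3))
  D <- as.matrix(dist(X))
  labels <- rep(c("a", "b"), each = 8)
  res <- permanova(D, labels, n_perm = 199, seed = 3)
  expect_equal(res$p_value, 1 / 200) # saturated: clusters are far apart
  expect_gt(res$R2, 0.5)
  expect_lte(res$R2, 1)
  # renaming groups leaves the statistic unchanged
  res2 <- permanova(D, rep(c("zzz", "a"), each = 8), n_perm = 199, seed = 3)
  expect_equal(res2$pseudo_F, res$pseudo_F)
  expect_equal(res2$R2, res$R2)
  # determinism given seed
  res3 <- permanova(D, labels, n_perm = 199, seed = 3)
  expect_equal(res3$p_value, res$p_value)
  expect_error(permanova(D, c("a", rep("b", 15))), "at least two members")
})

test_that("Hudson FST matches constructed cases", {
  # identical allele frequencies -> near zero; fixed difference -> 1
  block <- rbind(c(0L, 2L), c(1L, 2L), c(2L, 0L),
                 c(1L, 1L), c(0L, 2L), c(2L, 1L))
  calls <- rbind(block, block) # both demes share the same genotype profile
  gm <- toy_gm(calls, demes = rep(c("deme1", "deme2"), each = 6))
  f <- fst_hudson(gm)
  expect_lt(abs(f$global), 0.12) # identical frequencies, finite-sample correction
  fixed <- toy_gm(rbind(c(0L), c(0L), c(2L), c(2L)),
                  demes = c("deme1", "deme1", "deme2", "deme2"))
  ff <- fst_hudson(fixed)
  expect_equal(ff$per_site$fst[1], 1)
  expect_equal(ff$global, 1)
})

test_that("global FST is a ratio of averages, not an average of ratios", {
  # two sites engineered so the two aggregation orders differ: a fixed
  # difference (high-information) plus a shared rare variant (low-information)
  calls <- cbind(c(2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L),
                 c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L))
  gm <- toy_gm(calls, demes = rep(c("deme1", "deme2"), each = 4))
  f <- fst_hudson(gm)
  ps <- f$per_site
  roa <- sum(ps$numerator) / sum(ps$denominator)
  aor <- mean(ps$fst)
  expect_equal(f$global, roa)
  expect_gt(abs(roa - aor), 1e-3)
  # invariant to site order
  gm_rev <- toy_gm(calls[, 2:1], demes = rep(c("deme1", "deme2"), each = 4))
  expect_equal(fst_hudson(gm_rev)$global, f$global)
})

test_that("island-model FST approaches the drift-migration balance", {
  # symmetric two-deme island model at equilibrium-ish depth: coalescent
  # arithmetic gives T_within = 2, T_between = 2 + 1/(2M), so
  # FST = 1 - Tw/Tb = 1/(1 + 4M) with M = 2*Ne*m
  M <- 2.5
  mod <- demographic_model(list(
    epoch(T = 8, nu = c(1, 1), M_1to2 = M, M_2to1 = M)))
  cfg <- coalescent_config(deme_sizes = c(10, 10), n_contigs = 1500,
                           contig_length = 2000, mu = 3.92e-9, Ne_anc = 2e4,
                           model = mod, seed = 23)
  gm <- emit_genotype_matrix(cfg)$gm
  f <- fst_hudson(gm)$global
  fst_pred <- 1 / (1 + 4 * M) # Hudson-style expectation for 2 demes
  expect_lt(abs(f - fst_pred) / fst_pred, 0.25)
})

test_that("strong divergence separates demes on the first PCoA axis", {
  mod <- demographic_model(list(
    epoch(T = 6, nu = c(1, 1), M_1to2 = 0, M_2to1 = 0)))
  ok <- vapply(1:10, function(r) {
    cfg <- coalescent_config(deme_sizes = c(6, 6), n_contigs = 250,
                             contig_length = 1000, mu = 1e-7, Ne_anc = 5e3,
                             model = mod, seed = 100 + r)
    gm <- emit_genotype_matrix(cfg)$gm
    co <- pcoa(ibs_distance(gm))$coordinates[, 1]
    g1 <- co[gm$samples$deme == "deme1"]
    g2 <- co[gm$samples$deme == "deme2"]
    max(min(g1), min(g2)) > min(max(g1), max(g2)) # no overlap on axis 1
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})
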