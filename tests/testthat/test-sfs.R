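test_that("observed SFS places unit mass per site and conserves totals", {
  # 2+2 diploids, one site with alt counts (1, 0)
  calls <- matrix(c(1L, 0L, 0L, 0L), 4, 1)
  gm <- toy_gm(calls, demes = c("deme1", "deme1", "deme2", "deme2"))
  s <- observed_sfs(gm, 4, 4)
  expect_equal(s$values[2, 1], 1)
  expect_equal(sfs_mass(s), 1)
  # several sites, some with missing calls below the projection threshold
  set.seed(3)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 40, replace = TRUE,
                         prob = c(.4, .3, .2, .1)), 4, 10)
  gm <- toy_gm(calls, demes = c("deme1", "deme1", "deme2", "deme2"))
  s <- observed_sfs(gm, 3, 3)
  tal <- jointsfs:::site_allele_counts(gm)
  n_ok <- sum(tal$g1 >= 3 & tal$g2 >= 3)
  expect_equal(sfs_mass(s), n_ok)
  expect_equal(attr(s, "n_dropped"), 10 - n_ok)
})

test_that("partially missing sites spread hypergeometrically", {
  # one site: deme1 has 2 diploids, one call missing -> g1 = 2 genomes with
  # 1 alt; projecting to 2 keeps the exact counts; projecting a full site
  # with alt count 2 of 4 genomes to 2 gives (1/6, 4/6, 1/6)
  calls <- matrix(c(1L, NA, 0L, 0L), 4, 1)
  gm <- toy_gm(calls, demes = c("deme1", "deme1", "deme2", "deme2"))
  s <- observed_sfs(gm, 2, 2)
  expect_equal(s$values[2, 1], 1) # (1,0) with certainty
  calls2 <- matrix(c(1L, 1L, 0L, 0L), 4, 1)
  gm2 <- toy_gm(calls2, demes = c("deme1", "deme1", "deme2", "deme2"))
  s2 <- observed_sfs(gm2, 2, 4)
  expect_equal(s2$values[, 1], c(1 / 6, 4 / 6, 1 / 6))
})

test_that("folding moves mass to minor-allele entries and conserves it", {
  n1 <- 4; n2 <- 3
  v <- matrix(0, n1 + 1, n2 + 1)
  v[n1 + 1, n2] <- 1 # (n1, n2-1) -> complement (0, 1)
  f <- fold_sfs(spectrum_grid(v))
  expect_equal(f$values[1, 2], 1)
  expect_equal(sfs_mass(f), 1)
  expect_error(fold_sfs(f), "already folded")
  # tie entries (i + j = half) are split half-and-half (stay in place)
  v2 <- matrix(0, 3, 3)
  v2[2, 2] <- 1 # (1,1) with n1 = n2 = 2: i + j = 2 = half
  f2 <- fold_sfs(spectrum_grid(v2))
  expect_equal(f2$values[2, 2], 1)
  # random grids conserve mass
  set.seed(1)
  for (r in 1:5) {
    g <- spectrum_grid(matrix(runif(30), 5, 6))
    expect_equal(sfs_mass(fold_sfs(g)), sfs_mass(g))
  }
})

test_that("projection is exact hypergeometric downsampling", {
  # single-axis case: mass 1 at i=2 of n=4 projected to 2 -> (1/6, 4/6, 1/6)
  v <- matrix(0, 5, 2)
  v[3, 1] <- 1
  p <- project_sfs(spectrum_grid(v), 2, 1)
  expect_equal(p$values[, 1], c(1 / 6, 4 / 6, 1 / 6))
  # identity and mass conservation
  set.seed(2)
  g <- spectrum_grid(matrix(runif(42), 6, 7))
  expect_equal(project_sfs(g, 5, 6)$values, g$values)
  pr <- project_sfs(g, 3, 4)
  expect_lt(abs(sfs_mass(pr) - sfs_mass(g)), 1e-9)
  expect_error(project_sfs(g, 7, 4), "cannot project up")
})

test_that("projection commutes with allele relabeling, so folding is stable", {
  # swapping ancestral/derived labels (reversing both axes) before projection
  # must give the same folded spectrum: this is what makes the folded SFS
  # independent of polarization
  set.seed(4)
  for (r in 1:5) {
    g <- spectrum_grid(matrix(runif(8 * 9), 8, 9))
    swapped <- spectrum_grid(g$values[8:1, 9:1])
    a <- fold_sfs(project_sfs(g, 5, 6))
    b <- fold_sfs(project_sfs(swapped, 5, 6))
    expect_equal(a$values, b$values, tolerance = 1e-12)
    expect_equal(sfs_mass(a), sfs_mass(g), tolerance = 1e-9)
  }
})

test_that("contig bootstrap is reproducible and mass-consistent", {
  set.seed(5)
  calls <- matrix(sample(c(0L, 1L, 2L), 8 * 60, replace = TRUE), 8, 60)
  gm <- toy_gm(calls, demes = rep(c("deme1", "deme2"), each = 4),
               contig = rep(sprintf("c%02d", 1:10),
                            times = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 15)))
  b1 <- bootstrap_contigs(gm, 6, 6, B = 1, seed = 99)
  b2 <- bootstrap_contigs(gm, 6, 6, B = 1, seed = 99)
  expect_identical(b1[[1]]$values, b2[[1]]$values)
  base <- observed_sfs(gm, 6, 6)
  boots <- bootstrap_contigs(gm, 6, 6, B = 200, seed = 1)
  masses <- vapply(boots, sfs_mass, 1)
  se <- stats::sd(masses) / sqrt(length(masses))
  expect_lt(abs(mean(masses) - sfs_mass(base)), 3 * se)
  # single contig cannot be resampled
  gm1 <- toy_gm(calls[, 1:5], demes = rep(c("deme1", "deme2"), each = 4))
  expect_error(bootstrap_contigs(gm1, 6, 6, B = 2, seed = 1),
               "at least two contigs")
})

test_that("SFS text format round-trips bit-exactly", {
  set.seed(6)
  g <- fold_sfs(spectrum_grid(matrix(rexp(5 * 4), 5, 4)))
  p <- tempfile(fileext = ".fs")
  write_sfs(g, p)
  r <- read_sfs(p)
  expect_identical(r$values, g$values)
  expect_identical(r$mask, g$mask)
  expect_identical(r$folded, g$folded)
})

test_that("observed SFS equals direct tabulation without missing data", {
  cfg <- coalescent_config(deme_sizes = c(3, 3), n_contigs = 300,
                           contig_length = 500, mu = 1e-7, Ne_anc = 5e3,
                           model = demographic_model(), missing_rate = 0,
                           seed = 21)
  gm <- emit_genotype_matrix(cfg)$gm
  s <- observed_sfs(gm, 6, 6)
  in1 <- gm$samples$deme == "deme1"
  c1 <- colSums(gm$calls[in1, , drop = FALSE])
  c2 <- colSums(gm$calls[!in1, , drop = FALSE])
  tab <- matrix(0, 7, 7)
  for (k in seq_along(c1)) tab[c1[k] + 1, c2[k] + 1] <- tab[c1[k] + 1, c2[k] + 1] + 1
  expect_equal(s$values, tab)
})
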