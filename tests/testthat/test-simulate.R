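test_that("single-lineage genealogy is a degenerate zero-length tree", {
  tr <- simulate_genealogy(demographic_model(), lineages = c(1, 0))
  expect_equal(tr$n_leaves, 1)
  expect_equal(nrow(tr$edge), 0)
  expect_equal(tr$total_length, 0)
})

test_that("pairwise coalescence time has mean 2N generations", {
  set.seed(1)
  Ne <- 500
  tm <- replicate(4000, {
    tr <- simulate_genealogy(demographic_model(), c(2, 0), Ne_anc = Ne)
    max(tr$node_time)
  })
  # E[T2] = 2N generations, SD = 2N
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2 * Ne), 3 * se)
})

test_that("between-deme pairs coalesce later than within-deme pairs", {
  set.seed(2)
  mod <- demographic_model(list(
    epoch(T = 4, nu = c(1, 1), M_1to2 = 0.5, M_2to1 = 0.5)))
  win <- bet <- numeric(1500)
  for (r in seq_len(1500)) {
    tr <- simulate_genealogy(mod, c(2, 2))
    win[r] <- (pair_tmrca(tr, 1, 2) + pair_tmrca(tr, 3, 4)) / 2
    bet[r] <- pair_tmrca(tr, 1, 3)
  }
  se <- sqrt(stats::var(bet - win) / length(win))
  expect_gt(mean(bet) - mean(win), 3 * se)
})

test_that("non-coalescing configurations hit the time cap with an error", {
  isolated <- demographic_model(list(
    epoch(T = 1e7, nu = c(1, 1), M_1to2 = 0, M_2to1 = 0)))
  expect_error(simulate_genealogy(isolated, c(2, 2), time_cap = 50),
               "time cap")
})

test_that("zero-length genealogy yields no mutations", {
  tr <- simulate_genealogy(demographic_model(), c(1, 0))
  expect_identical(drop_mutations(tr, 1000, 1e-8), list())
})

test_that("segregating sites and pairwise diversity match closed forms", {
  # one deme, constant N: E[S] = theta * sum 1/i, E[pi] = theta (per contig)
  cfg <- coalescent_config(deme_sizes = 5, n_contigs = 4000,
                           contig_length = 1000, mu = 3.92e-9, Ne_anc = 1e4,
                           model = demographic_model(), seed = 42)
  sim <- emit_genotype_matrix(cfg)
  theta_c <- 4 * cfg$Ne_anc * cfg$mu * cfg$contig_length
  n_hap <- 10
  # Watterson
  s_per_contig <- tabulate(match(sim$gm$sites$contig,
                                 unique(sim$gm$sites$contig)),
                           nbins = length(unique(sim$gm$sites$contig)))
  exp_S <- theta_c * sum(1 / (1:(n_hap - 1)))
  obs_S <- sim$truth$n_segregating / cfg$n_contigs
  se_S <- stats::sd(c(s_per_contig,
                      rep(0, cfg$n_contigs - length(s_per_contig)))) /
    sqrt(cfg$n_contigs)
  expect_lt(abs(obs_S - exp_S), 3 * se_S)
  # pairwise diversity from allele counts (no missing data)
  cnt <- colSums(sim$gm$calls)
  pi_site <- cnt * (n_hap - cnt) / choose(n_hap, 2)
  obs_pi <- sum(pi_site) / cfg$n_contigs
  expect_lt(abs(obs_pi - theta_c) / theta_c, 0.1)
})

test_that("genotype emission is reproducible and respects missing_rate", {
  cfg <- coalescent_config(deme_sizes = c(4, 4), n_contigs = 200,
                           contig_length = 500, mu = 1e-7, Ne_anc = 5e3,
                           model = demographic_model(), missing_rate = 0,
                           seed = 7)
  a <- emit_genotype_matrix(cfg)
  b <- emit_genotype_matrix(cfg)
  expect_identical(a$gm$calls, b$gm$calls)
  expect_false(anyNA(a$gm$calls))
  cfg$missing_rate <- 0.3
  cc <- emit_genotype_matrix(cfg)$gm
  expect_gt(mean(is.na(cc$calls)), 0.2)
  expect_lt(mean(is.na(cc$calls)), 0.4)
})

test_that("deeply diverged isolated demes show strong differentiation", {
  mod <- demographic_model(list(
    epoch(T = 10, nu = c(1, 1), M_1to2 = 0, M_2to1 = 0)))
  cfg <- coalescent_config(deme_sizes = c(6, 6), n_contigs = 400,
                           contig_length = 1000, mu = 1e-7, Ne_anc = 5e3,
                           model = mod, seed = 9)
  gm <- emit_genotype_matrix(cfg)$gm
  expect_gt(fst_hudson(gm)$global, 0.5)
})

test_that("one-way migration produces the expected sharing asymmetry", {
  # forward flow deme1 -> deme2 only: the recipient deme carries resident plus
  # immigrant alleles, so its private polymorphism is elevated relative to the
  # donor; the mirrored model transposes the grid
  m12 <- demographic_model(list(
    epoch(T = 3, nu = c(1, 1), M_1to2 = 3, M_2to1 = 0)))
  m21 <- demographic_model(list(
    epoch(T = 3, nu = c(1, 1), M_1to2 = 0, M_2to1 = 3)))
  set.seed(4)
  g12 <- mc_expected_sfs(m12, 5, 5, nreps = 2e4)$mean
  g21 <- mc_expected_sfs(m21, 5, 5, nreps = 2e4)$mean
  priv1 <- function(g) sum(g[2:5, 1])  # polymorphic in deme 1 only
  priv2 <- function(g) sum(g[1, 2:5])
  expect_gt(priv2(g12), priv1(g12))
  expect_gt(priv1(g21), priv2(g21))
  expect_lt(max(abs(g21 - t(g12))), 0.05) # mirrored model transposes
  # the deterministic engine agrees on the orientation (convention mapping)
  e12 <- expected_sfs(m12, 5, 5)$values
  expect_gt(priv2(e12), priv1(e12))
  expect_lt(abs(priv2(e12) - priv2(g12)) / priv2(g12), 0.1)
})

test_that("samples within a deme are exchangeable", {
  cfg <- coalescent_config(deme_sizes = 16, n_contigs = 300,
                           contig_length = 2000, mu = 3.92e-9, Ne_anc = 2e4,
                           model = demographic_model(), seed = 13)
  gm <- emit_genotype_matrix(cfg)$gm
  labels <- rep(c("a", "b"), each = 8) # arbitrary split of one deme
  p <- permanova(ibs_distance(gm), labels, n_perm = 499, seed = 1)$p_value
  expect_gt(p, 0.01)
})
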