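test_that("call-rate, MAF and heterozygosity rules remove the right sites", {
  # 10 samples; site 1: 7/10 calls (0.70 < 0.75) -> removed
  calls <- matrix(0L, 10, 1)
  calls[1:3, 1] <- NA_integer_
  calls[4:7, 1] <- 1L
  gm <- toy_gm(calls)
  expect_warning(out <- apply_site_filters(gm, site_filter_config()),
                 "all sites removed")
  expect_equal(n_sites(out), 0)
  expect_equal(attr(out, "audit")$reason, "call_fraction")

  # MAF boundary: frequency 0.02 removed, exactly 0.025 retained (>= rule)
  mk_freq <- function(nalt, n = 20) { # n diploids, nalt alt alleles spread
    g <- integer(n); g[seq_len(nalt)] <- 1L
    toy_gm(matrix(g, ncol = 1))
  }
  low <- mk_freq(1, 20)   # 1/40 = 0.025 -> retained
  expect_equal(n_sites(apply_site_filters(low)), 1)
  lower <- mk_freq(1, 25) # 1/50 = 0.02 -> removed
  expect_equal(n_sites(suppressWarnings(apply_site_filters(lower))), 0)
})

test_that("a toy matrix with one violation per rule keeps the predicted set", {
  # 4 samples x 4 sites; brute-force expectations with min_call 0.75,
  # min_maf 0.2, max_het 0.5
  calls <- cbind(
    c(0L, 1L, 2L, 1L),          # maf 0.5, call 1.0, het 0.5 -> keep
    c(NA, NA, 0L, 1L),          # call 0.5 -> drop (call_fraction)
    c(0L, 0L, 0L, 1L),          # maf 1/8 < 0.2 -> drop (maf)
    c(1L, 1L, 1L, 0L))          # het 0.75 > 0.5 -> drop (het_fraction)
  gm <- toy_gm(calls)
  cfg <- site_filter_config(0.75, 0.2, 0.5)
  out <- apply_site_filters(gm, cfg)
  expect_equal(out$sites$pos, gm$sites$pos[1])
  expect_equal(sort(attr(out, "audit")$reason),
               sort(c("call_fraction", "maf", "het_fraction")))
  # idempotence
  again <- apply_site_filters(out, cfg)
  expect_identical(again$calls, out$calls)
  # commutes with sample reordering
  ord <- c(3, 1, 4, 2)
  gm2 <- toy_gm(calls[ord, ])
  out2 <- apply_site_filters(gm2, cfg)
  expect_equal(out2$sites$pos, out$sites$pos)
})

test_that("all sites removed warns rather than errors", {
  gm <- toy_gm(matrix(c(0L, 0L, 0L, 1L), 4, 1)) # maf 0.125
  expect_warning(out <- apply_site_filters(gm, site_filter_config(min_maf = 0.4)),
                 "all sites removed")
  expect_equal(n_sites(out), 0)
})

test_that("IBS distance matches hand computations and handles missingness", {
  gm <- toy_gm(rbind(c(0L, 1L, 2L, NA),
                     c(0L, 2L, 2L, 1L)))
  D <- ibs_distance(gm)
  expect_equal(D[1, 2], (0 + 0.5 + 0) / 3) # = 1/6
  expect_equal(diag(D), c(s01 = 0, s02 = 0))
  # identical vectors -> 0; opposite homozygotes -> 1
  gm2 <- toy_gm(rbind(c(0L, 2L, 1L), c(0L, 2L, 1L), c(2L, 0L, NA)))
  D2 <- ibs_distance(gm2)
  expect_equal(D2[1, 2], 0)
  expect_equal(D2[1, 3], 1)
  # no overlapping sites -> NA, not 0
  gm3 <- toy_gm(rbind(c(0L, NA), c(NA, 1L)))
  expect_true(is.na(ibs_distance(gm3)[1, 2]))
})

test_that("IBS distance obeys the triangle inequality on complete data", {
  for (s in 1:10) {
    D <- ibs_distance(random_gm(5, 30, seed = s))
    for (a in 1:5) for (b in 1:5) for (cc in 1:5)
      expect_lte(D[a, b], D[a, cc] + D[cc, b] + 1e-12)
  }
})

test_that("per-sample heterozygosity is the fraction of het calls", {
  gm <- toy_gm(rbind(c(0L, 1L, 1L, 2L, NA),
                     c(0L, 0L, 2L, 2L, 0L),
                     c(1L, 1L, 1L, 1L, 1L),
                     c(NA, NA, NA, NA, NA)))
  h <- sample_heterozygosity(gm)
  expect_equal(unname(h), c(2 / 4, 0, 1, NA))
})
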