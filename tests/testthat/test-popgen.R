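# Diversity, differentiation and haplotype-homozygosity statistics against
# independently coded oracles.

test_that("pi matches closed forms and the all-pairs oracle", {
  # two chromatids differing at 3 of 500 sites in one window
  hap <- matrix(0L, 2, 500)
  hap[2, c(10, 250, 490)] <- 1L
  gm <- gm_from_hap(hap, pos = 0:499)
  sc <- pi_scan(gm, window_bp = 500, step_bp = 500, region = c(0, 500))
  expect_equal(sc$value, 3 / 500)
  # identical sequences: zero everywhere
  gm0 <- gm_from_hap(matrix(1L, 4, 200), pos = 0:199)
  expect_true(all(pi_scan(gm0, 100, 50, region = c(0, 200))$value == 0))
  # n = 6 chromatids, random window equals brute force over all 15 pairs
  gm6 <- random_gm(6, 40, seed = 21)
  sc6 <- pi_scan(gm6, window_bp = 4000, step_bp = 4000, region = c(0, 4000))
  expect_equal(sc6$value[1], oracle_pi(gm6$hap), tolerance = 1e-12)
  # windows with no sites are NA, and reported at fixed step
  sc_na <- pi_scan(gm6, 100, 100, region = c(0, 8000))
  expect_true(anyNA(sc_na$value))
  expect_equal(unique(diff(sc_na$start)), 100)
  expect_error(pi_scan(gm_from_hap(matrix(0L, 0, 3))), "chromatids")
})

test_that("Tajima's D matches the textbook formula and handles S = 0", {
  gm <- random_gm(4, 10, seed = 31)
  d <- tajimas_d(gm, bin_bp = 2000, region = c(0, 2000))
  expect_equal(d$value[1], oracle_tajima_d(gm$hap), tolerance = 1e-12)
  # larger random instances
  for (s in 1:5) {
    gmr <- random_gm(8, 25, seed = 100 + s)
    dr <- tajimas_d(gmr, bin_bp = 3000, region = c(0, 3000))
    expect_equal(dr$value[1], oracle_tajima_d(gmr$hap), tolerance = 1e-10)
  }
  # monomorphic bin is undefined, not zero
  gm0 <- gm_from_hap(matrix(0L, 6, 10))
  expect_true(is.na(tajimas_d(gm0, 2000, region = c(0, 2000))$value[1]))
  # theta_pi == theta_W by construction gives exactly 0: one singleton
  # class arrangement where k equals S/a1
  n <- 4; a1 <- sum(1 / 1:3)
  # with n=4, a site with derived count 2 contributes pairwise 4/6; choose
  # S sites all at count 2 so k = S*2/3; D = 0 requires k = S/a1 -> no; use
  # direct check that the numerator sign matches k - S/a1
  hap <- matrix(0L, 4, 6); hap[1:2, 1:6] <- 1L
  gmx <- gm_from_hap(hap)
  dd <- tajimas_d(gmx, 2000, region = c(0, 2000))
  k <- 6 * (2 * 2 * 2) / (4 * 3)
  expect_equal(sign(dd$value[1]), sign(k - 6 / a1))
})

test_that("haplotype diversity follows Nei & Tajima's estimator", {
  expect_equal(hap_diversity(c("a", "a", "a")), 0)
  expect_equal(hap_diversity(c("a", "b")), 1)
  expect_equal(hap_diversity(c("a", "a", "b", "c")), (4 / 3) * (1 - 0.375))
  # scan form agrees with direct counting on random data
  gm <- random_gm(8, 12, seed = 41)
  sc <- hap_diversity_scan(gm, bin_bp = 2000, region = c(0, 2000))
  strings <- apply(gm$hap, 1, paste, collapse = "")
  expect_equal(sc$value[1], hap_diversity(strings))
  gu <- gm_from_hap(matrix(0L, 4, 3), phased = FALSE)
  expect_error(hap_diversity_scan(gu), "phased")
})

test_that("Hudson Fst matches the component oracle and its bounds", {
  # fixed difference
  a <- gm_from_hap(matrix(1L, 10, 5)); b <- gm_from_hap(matrix(0L, 10, 5))
  fx <- fst_scan(a, b)
  expect_true(all(fx$value == 1))
  # identical populations: near zero (small negative finite-sample bias)
  gm <- random_gm(20, 30, seed = 51)
  f0 <- fst_scan(gm, gm, window_bp = 3000, region = c(0, 3000))
  expect_lt(abs(f0$value[1]), 0.06)
  # counts 12/20 vs 3/20 equal the directly coded Hudson formula
  h1 <- matrix(0L, 20, 1); h1[1:12] <- 1L
  h2 <- matrix(0L, 20, 1); h2[1:3] <- 1L
  fs <- fst_scan(gm_from_hap(h1), gm_from_hap(h2))
  expect_equal(fs$value, oracle_hudson_fst(20, 12, 20, 3), tolerance = 1e-12)
  # pooled-monomorphic sites are undefined per site
  m0 <- fst_scan(gm_from_hap(matrix(0L, 4, 2)), gm_from_hap(matrix(0L, 4, 2)))
  expect_true(all(is.na(m0$value)))
  # Weir-Cockerham variant agrees with Hudson at equal large counts
  fw <- fst_scan(gm_from_hap(h1), gm_from_hap(h2), estimator = "wc")
  expect_equal(fw$value, fs$value, tolerance = 0.05)
})

test_that("EHH equals enumerated homozygosity and decays monotonically", {
  # 4-haplotype toy panel
  hap <- rbind(c(1L, 1L, 0L, 0L, 1L),
               c(1L, 1L, 0L, 1L, 0L),
               c(0L, 0L, 0L, 1L, 1L),
               c(0L, 1L, 0L, 0L, 1L))
  gm <- gm_from_hap(hap)
  dec <- ehh_decay(gm, core_idx = 3L)
  for (r in seq_len(nrow(dec))) {
    expect_equal(dec$ehh[r], oracle_ehh(hap, 3L, dec$idx[r]),
                 label = sprintf("marker %d", dec$idx[r]))
  }
  # non-increasing outward on each side (side rows are ordered core-out)
  core_ehh <- dec$ehh[dec$side == 0]
  expect_true(all(diff(c(core_ehh, dec$ehh[dec$side == 1])) <= 1e-12))
  expect_true(all(diff(c(core_ehh, dec$ehh[dec$side == -1])) <= 1e-12))
  # single haplotype: EHH identically 1
  one <- gm_from_hap(matrix(rep(c(1L, 0L, 1L), each = 6), 6, 3))
  d1 <- ehh_decay(one, 2L)
  expect_true(all(d1$ehh == 1))
})

test_that("XP-EHH is zero for identical panels and antisymmetric", {
  map <- genetic_map(2.8, 0, 10000)
  gm <- random_gm(12, 20, seed = 61)
  core <- 10L
  expect_equal(xpehh(gm, gm, core, map), 0)
  gm2 <- random_gm(12, 20, seed = 62)
  raw <- xpehh(gm, gm2, core, map)
  expect_equal(xpehh(gm2, gm, core, map), -raw, tolerance = 1e-12)
  # scan-level z-normalisation has mean 0, sd 1
  sc <- xpehh_scan(gm, gm2, map)
  expect_equal(mean(sc$value, na.rm = TRUE), 0, tolerance = 1e-10)
  expect_equal(sd(sc$value, na.rm = TRUE), 1, tolerance = 1e-10)
  expect_error(xpehh(gm_from_hap(matrix(0L, 4, 3)),
                     gm_from_hap(matrix(0L, 4, 3)), 1L, map), "polymorphic")
})

test_that("windowed Tajima's D is near zero on neutral-spectrum data", {
  gm <- neutral_sfs_gm(20, 2000, seed = 71, pos_step = 10L)
  d <- tajimas_d(gm, bin_bp = 100, region = c(0, 20000))
  vals <- d$value[!is.na(d$value)]
  expect_gte(length(vals), 200)
  expect_lt(abs(mean(vals)), 0.3)
})
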