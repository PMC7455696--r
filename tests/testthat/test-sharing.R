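# Haplotype-sharing scan: bin frequencies, Q differential, region merging.

test_that("bin haplotype frequencies equal direct chromatid counting", {
  set.seed(171)
  hap <- matrix(rbinom(20 * 3, 1, 0.5), 20, 3)
  gm <- gm_from_hap(hap, pos = c(100, 700, 1500))
  pops <- rep(c("P1", "P2"), each = 5)
  bh <- bin_haplotypes(gm, pops, bin_bp = 2000, region = c(0, 2000))
  strings <- apply(hap, 1, paste, collapse = "")
  for (p in c("P1", "P2")) {
    rows <- rep(pops, each = 2) == p
    tab <- table(strings[rows]) / sum(rows)
    expect_equal(bh$freq[[1]][p, names(tab)], c(tab), ignore_attr = TRUE)
  }
  # single SNP per bin: haplotypes are the alleles
  gm1 <- gm_from_hap(hap[, 1, drop = FALSE], pos = 10L)
  bh1 <- bin_haplotypes(gm1, pops, 2000, region = c(0, 2000))
  expect_setequal(colnames(bh1$freq[[1]]), c("0", "1"))
  # two perfectly linked SNPs: exactly two haplotypes
  lnk <- cbind(hap[, 1], hap[, 1])
  bh2 <- bin_haplotypes(gm_from_hap(lnk, pos = c(5L, 50L)), pops, 2000,
                        region = c(0, 2000))
  expect_equal(ncol(bh2$freq[[1]]), 2L)
  expect_error(bin_haplotypes(gm, pops[1:3], 2000), "population label")
})

test_that("Q differential is signed and uses the modal reference haplotype", {
  # construct groups with known Q frequencies: high 0.9, low 0.45
  mk <- function(q_freq, n, pop) {
    hap <- t(replicate(n, if (runif(1) < q_freq) c(1L, 1L) else
      c(0L, rbinom(1, 1, 0.5))))
    hap
  }
  set.seed(181)
  hap <- rbind(mk(1, 20, "REF"), mk(0.9, 40, "HI"), mk(0.45, 40, "LO"))
  gm <- gm_from_hap(hap, pos = c(10L, 20L))
  pops <- rep(c("REF", "HI", "LO"), c(10, 20, 20))
  bh <- bin_haplotypes(gm, pops, 2000, region = c(0, 2000))
  qd <- q_delta_af(bh, "REF", c(REF = "high", HI = "high", LO = "low"))
  expect_equal(qd$q_hap[1], "11")
  expect_equal(qd$delta_q[1], qd$freq_high[1] - qd$freq_low[1])
  expect_lt(abs(qd$freq_high[1] - 0.9), 0.12)
  expect_lt(abs(qd$delta_q[1] - 0.45), 0.2)
  # identical groups: zero differential
  pops2 <- rep(c("REF", "G1", "G2"), c(10, 20, 20))
  gm2 <- gm
  gm2$hap[21:100, ] <- gm$hap[c(21:60, 21:60), ]  # G1 == G2
  bh2 <- bin_haplotypes(gm2, pops2, 2000, region = c(0, 2000))
  qd2 <- q_delta_af(bh2, "REF", c(G1 = "high", G2 = "low"))
  expect_equal(abs(qd2$delta_q[1]) < 1e-12, TRUE)
})

test_that("region merging follows adjacency runs and is idempotent", {
  qdf <- data.frame(bin = 1:4, start = c(0, 2000, 4000, 6000),
                    end = c(2000, 4000, 6000, 8000), n_sites = 2,
                    q_hap = "x", freq_high = NA, freq_low = NA,
                    delta_q = c(0.5, 0.6, 0.3, 0.45))
  reg <- merge_q_regions(qdf)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$name, c("Q1", "Q2"))
  expect_equal(reg$start, c(0, 6000))
  expect_equal(reg$end, c(4000, 8000))
  expect_equal(reg$length_bp, c(4000, 2000))
  expect_true(all(reg$max_delta >= 0.4))
  # empty bins break adjacency
  qdf2 <- qdf; qdf2$delta_q[3] <- NA; qdf2$n_sites[3] <- 0
  expect_equal(nrow(merge_q_regions(qdf2)), 2L)
  # no bin above threshold / all bins above threshold
  expect_equal(nrow(merge_q_regions(transform(qdf, delta_q = 0.1))), 0L)
  all_reg <- merge_q_regions(transform(qdf, delta_q = 0.8))
  expect_equal(nrow(all_reg), 1L)
  expect_equal(all_reg$n_bins, 4L)
  # merging a merged result changes nothing (regions stay disjoint, ordered)
  expect_true(all(diff(reg$start) > 0))
})

test_that("planted shared Q sub-haplotypes are recovered by the scan", {
  panel <- simulate_breed_panel(default_panel_spec(), seed = 23)
  grp <- unique(panel$samples[, c("breed", "group")])
  sc <- q_scan(panel$geno,
               stats::setNames(panel$samples$breed, panel$samples$sample),
               ref_pop = "HQLA",
               groups = stats::setNames(grp$group, grp$breed),
               region = c(min(panel$geno$pos), max(panel$geno$pos) + 1))
  truth <- panel$truth
  # overlap of recovered regions with each planted interval >= 80% of its length
  for (i in seq_len(nrow(truth))) {
    ov <- sum(pmax(0, pmin(sc$regions$end, truth$end[i]) -
                      pmax(sc$regions$start, truth$start[i])))
    expect_gte(ov / (truth$end[i] - truth$start[i]), 0.8)
  }
  # and few false-positive bins outside the planted intervals
  outside <- sc$bins$delta_q
  in_truth <- rep(FALSE, nrow(sc$bins))
  for (i in seq_len(nrow(truth)))
    in_truth <- in_truth | (sc$bins$start < truth$end[i] &
                            sc$bins$end > truth$start[i])
  expect_lt(mean(outside[!in_truth] >= 0.4, na.rm = TRUE), 0.02)
})
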