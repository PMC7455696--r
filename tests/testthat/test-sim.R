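# Forward simulator: founder sampling, meiosis, pedigree, phenotypes.

test_that("founder sampling follows pool weights and degenerate pools", {
  pos <- seq(0L, by = 2000L, length.out = 50L)
  map <- genetic_map(2.8, 0, 1e5)
  one <- founder_pool("A", matrix(1L, 1, 50))
  two <- founder_pool("B", rbind(rep(0L, 50), rep(1L, 50)), c(0.7, 0.3))
  # degenerate pool: all chromatids identical
  f <- make_founders(one, two, 5, 5, pos, map, seed = 1)
  a_haps <- do.call(rbind, lapply(f[1:5], `[[`, "hap"))
  expect_true(all(a_haps == 1L))
  # origin painting is one segment with the pool label
  expect_equal(f[[1]]$paint[[1]],
               data.frame(start = 0, end = 1e5, origin = "A"))
  # realized pool frequencies within 3 binomial SD of the weights
  f2 <- make_founders(two, one, 500, 2, pos, map, seed = 2)
  b_haps <- do.call(rbind, lapply(f2[1:500], `[[`, "hap"))
  freq1 <- mean(b_haps[, 1] == 1L)  # haplotype 2 carries allele 1 everywhere
  se <- sqrt(0.3 * 0.7 / 1000)
  expect_lt(abs(freq1 - 0.3), 3 * se)
  # fixed alternative alleles give |dAF| = 1
  expect_equal(delta_af(1, 0), 1)
  expect_error(founder_pool("X", matrix(1L, 0, 5)), "empty")
})

test_that("meiosis copies a chromatid exactly at map rate 0", {
  pos <- seq(0L, by = 1000L, length.out = 100L)
  map0 <- genetic_map(0, 0, 1e5)
  parent <- list(hap = rbind(rep(0L, 100), rep(1L, 100)),
                 paint = list(data.frame(start = 0, end = 1e5, origin = "A"),
                              data.frame(start = 0, end = 1e5, origin = "B")))
  set.seed(1)
  for (i in 1:5) {
    g <- meiosis(parent, map0, pos)
    expect_true(all(g$hap == 0L) || all(g$hap == 1L))
    expect_equal(nrow(g$paint), 1L)
  }
})

test_that("crossover counts are Poisson with the map's Morgan length", {
  # 3.1 Mb at 2.8 cM/Mb: mean 0.0868 crossovers per meiosis
  map <- genetic_map(2.8, 168600000, 171700000)
  pos <- seq(map$start, map$end - 1, by = 31000)
  parent <- list(hap = rbind(rep(0L, length(pos)), rep(1L, length(pos))),
                 paint = list(data.frame(start = map$start, end = map$end, origin = "A"),
                              data.frame(start = map$start, end = map$end, origin = "B")))
  set.seed(42)
  n_gam <- 20000L
  switches <- integer(n_gam)
  for (i in seq_len(n_gam)) {
    g <- meiosis(parent, map, pos)
    switches[i] <- nrow(g$paint) - 1L  # origin switches = crossovers here
  }
  mu <- genetic_length_cM(map) / 100
  expect_equal(mu, 3.1 * 2.8 / 100)
  se <- sqrt(mu / n_gam)
  expect_lt(abs(mean(switches) - mu), 3 * se)
  # 100 cM map: mean about 1 crossover
  map1 <- genetic_map(100, 0, 1e6)
  pos1 <- seq(0L, by = 1e4, length.out = 100L)
  parent1 <- list(hap = rbind(rep(0L, 100), rep(1L, 100)),
                  paint = list(data.frame(start = 0, end = 1e6, origin = "A"),
                               data.frame(start = 0, end = 1e6, origin = "B")))
  k <- replicate(5000, nrow(meiosis(parent1, map1, pos1)$paint) - 1L)
  expect_lt(abs(mean(k) - 1), 3 * sqrt(1 / 5000))
  # goodness of fit of the count distribution to Poisson(1)
  obs <- table(factor(pmin(k, 4), levels = 0:4))
  pp <- c(dpois(0:3, 1), 1 - ppois(3, 1))
  expect_gt(suppressWarnings(chisq.test(obs, p = pp)$p.value), 0.001)
})

test_that("AIL pedigrees are reproducible and tile paintings consistently", {
  pos <- seq(0L, by = 2000L, length.out = 80L)
  map <- genetic_map(20, 0, 160000)  # high rate: plenty of recombination
  pools <- default_founder_pools(pos, seed = 5)
  f <- make_founders(pools$A, pools$B, 6, 6, pos, map, seed = 5)
  ped1 <- simulate_ail(f, c(20, 20, 30), seed = 9)
  ped2 <- simulate_ail(f, c(20, 20, 30), seed = 9)
  expect_identical(ped1, ped2)
  # paintings tile the region without overlap, and every allele matches the
  # founder-pool allele of the covering origin segment
  pool_of <- list(HQLA = pools$A, HB = pools$B)
  for (id in ped1$generations[["3"]]) {
    ind <- ped1$individuals[[id]]
    for (k in 1:2) {
      p <- ind$paint[[k]]
      expect_equal(p$start[1], map$start)
      expect_equal(p$end[nrow(p)], map$end)
      if (nrow(p) > 1) expect_equal(p$start[-1], p$end[-nrow(p)])
      for (s in seq_len(nrow(p))) {
        cols <- which(pos >= p$start[s] & pos < p$end[s])
        pool <- pool_of[[p$origin[s]]]
        al <- ind$hap[k, cols]
        ok <- apply(pool$haps[, cols, drop = FALSE], 1,
                    function(h) all(h == al))
        expect_true(any(ok), label = sprintf("%s chrom %d seg %d", id, k, s))
      }
    }
  }
})

test_that("founder-line contribution stays near one half without selection", {
  pos <- seq(0L, by = 2000L, length.out = 40L)
  map <- genetic_map(2.8, 0, 80000)
  pools <- default_founder_pools(pos, seed = 3, p_divergent = 1)  # all divergent
  f <- make_founders(pools$A, pools$B, 10, 10, pos, map, seed = 3)
  fr <- replicate(8, {
    ped <- simulate_ail(f, c(40, 40, 60), seed = sample.int(1e6, 1))
    mean(dosage(ped_genotypes(ped))) / 2  # allele 1 = line A everywhere
  })
  expect_lt(abs(mean(fr) - 0.5), 3 * sd(fr) / sqrt(length(fr)))
})

test_that("phenotypes follow the additive model exactly when noiseless", {
  pos <- seq(0L, by = 2000L, length.out = 30L)
  map <- genetic_map(2.8, 0, 60000)
  pools <- default_founder_pools(pos, seed = 7, qtl_sites = c(5L, 20L))
  f <- make_founders(pools$A, pools$B, 6, 6, pos, map, seed = 7)
  ped <- simulate_ail(f, c(20, 30), seed = 7)
  arch0 <- qtl_architecture(data.frame(pos = pos[c(5, 20)], effect = 0,
                                       high_allele = 1L),
                            baseline = 500, residual_sd = 0)
  ph <- simulate_phenotypes(ped, arch0, seed = 1)
  expect_equal(ph$phenotype,
               500 + arch0$sex_effect[ph$sex] + arch0$batch_effect[ph$batch],
               ignore_attr = TRUE)
  expect_error(simulate_phenotypes(ped,
    qtl_architecture(data.frame(pos = 123L, effect = 1, high_allele = 1L))),
    "off the SNP grid")
})

test_that("single-locus genetic variance matches 2p(1-p)a^2 at Hardy-Weinberg", {
  set.seed(11)
  n <- 2000; p <- 0.4; a <- 30
  d <- rbinom(n, 2, p)
  g <- d * a
  expect_lt(abs(var(g) - 2 * p * (1 - p) * a^2) / (2 * p * (1 - p) * a^2), 0.15)
  # two fully coupled loci: variance gains twice the covariance term
  g2 <- d * a + d * a  # full coupling, equal effects
  expect_equal(var(g2), 4 * var(g), tolerance = 1e-12)
})
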