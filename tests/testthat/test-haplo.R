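# EM haplotype frequencies, rare grouping, substitution effects,
# backward elimination.

test_that("EM equals gamete counting when phase is unambiguous", {
  # no double heterozygotes: every genotype resolves uniquely
  geno <- rbind(c(0, 0), c(2, 2), c(1, 0), c(0, 1), c(2, 0))
  em <- em_haplotype_freqs(geno)
  direct <- c("00" = 4, "11" = 2, "10" = 3, "01" = 1) / 10
  expect_equal(em$freq[names(direct)], direct[names(direct)],
               tolerance = 1e-8, ignore_attr = TRUE)
  # monomorphic tag set: a single haplotype at frequency 1
  em0 <- em_haplotype_freqs(matrix(2, 5, 3))
  expect_equal(unname(em0$freq), 1)
  expect_equal(names(em0$freq), "111")
})

test_that("EM fixed point maximises the double-heterozygote likelihood", {
  # classic 2-SNP sample of only double heterozygotes plus anchors: the EM
  # stationary point must match a likelihood grid search over the coupling
  # proportion
  geno <- rbind(matrix(1, 10, 2), c(2, 2), c(0, 0))
  em <- em_haplotype_freqs(geno, tol = 1e-10)
  # grid oracle: freq of coupling haplotypes p for '11'/'00', (1-2p)/2 each
  # for '10'/'01' with the anchor counts added
  ll <- function(q) {
    # q = P(11)=P(00) among the 4 haplotype classes, r = P(10)=P(01)
    r <- (1 - 2 * q) / 2
    10 * log(2 * (q^2 + r^2)) + 2 * log(q^2)
  }
  grid <- seq(0.01, 0.49999, by = 1e-5)
  q_star <- grid[which.max(vapply(grid, ll, 0))]
  expect_lt(abs(unname(em$freq["11"]) - q_star), 1e-3)
  # log-likelihood is monotonically non-decreasing
  expect_true(all(diff(em$ll_path) >= -1e-9))
})

test_that("rare haplotypes pool into Other with summed frequency", {
  g <- group_rare(c(a = 0.6, b = 0.3, c = 0.095, d = 0.004, e = 0.001))
  expect_equal(unname(g$freq["Other"]), 0.005)
  expect_equal(setdiff(names(g$freq), "Other"), c("a", "b", "c"))
  g2 <- group_rare(c(a = 0.6, b = 0.3, c = 0.1))
  expect_false("Other" %in% names(g2$freq))
  g3 <- group_rare(c(a = 0.005, b = 0.003, rep(0.001, 992) |> setNames(paste0("h", 1:992))))
  expect_equal(unname(g3$freq["Other"]), 1)
  expect_error(group_rare(c(a = 0.5, b = 0.4)), "sum to 1")
})

test_that("hap_design rows sum to two copies", {
  strings <- c("00", "01", "00", "00", "11", "01")
  grouping <- group_rare(c("00" = 0.5, "01" = 0.33, "11" = 0.17), min_freq = 0.2)
  Z <- hap_design(strings, grouping)
  expect_true(all(rowSums(Z) == 2))
  expect_equal(unname(Z[1, "00"]), 1L)  # chromatids 1-2: 00 + 01
  expect_equal(unname(Z[2, "00"]), 2L)  # chromatids 3-4: 00 + 00
})

test_that("substitution effects are exact in the noiseless case and flag aliasing", {
  set.seed(151)
  n <- 200
  strings <- sample(c("00", "01", "11"), 2 * n, replace = TRUE,
                    prob = c(.5, .3, .2))
  grouping <- group_rare(table(strings) / (2 * n) |> c())
  Z <- hap_design(strings, grouping)
  u_true <- c("00" = -10, "01" = 2, "11" = 8)
  u_true <- u_true - mean(u_true)  # sum-to-zero truth
  sex <- rep_len(c("M", "F"), n)
  y <- 50 + 5 * (sex == "M") + as.vector(Z %*% u_true[colnames(Z)])
  fit <- suppressWarnings(substitution_effects(y, data.frame(sex = sex), Z))
  est <- stats::setNames(fit$effects$effect, fit$effects$haplotype)
  expect_equal(est[names(u_true)], u_true, tolerance = 1e-8)
  # output sorted ascending by effect
  expect_true(!is.unsorted(fit$effects$effect))
  # y independent of Z, noise-free: all effects zero
  fit0 <- suppressWarnings(substitution_effects(rep(3, n), data.frame(sex = sex), Z))
  expect_equal(max(abs(fit0$effects$effect)), 0, tolerance = 1e-10)
  # a haplotype class with no carriers leaves an aliased (empty) column
  grouping_extra <- group_rare(c("00" = .45, "01" = .3, "11" = .2, "22" = .05),
                               min_freq = 0.01)
  Zz <- hap_design(strings, grouping_extra)  # "22" never observed: zero column
  expect_error(suppressWarnings(substitution_effects(y, data.frame(sex = sex), Zz)),
               "alias")
  # fitted values invariant to which column anchors the constraint
  Zperm <- Z[, c(2, 3, 1)]
  fitp <- suppressWarnings(substitution_effects(y, data.frame(sex = sex), Zperm))
  expect_equal(unname(fitp$fitted), unname(fit$fitted), tolerance = 1e-8)
})

test_that("backward elimination keeps planted signals and drops null ones", {
  set.seed(161)
  n <- 600
  run_one <- function(s, planted = 1L) {
    gm <- sim_unlinked_geno(n, 30, seed = 5000 + s)
    d <- dosage(gm)
    set.seed(6000 + s)
    y <- rnorm(n)
    if (planted >= 1) y <- y + d[, 10] * 0.5 / sd(d[, 10])
    if (planted >= 2) y <- y + d[, 25] * 0.5 / sd(d[, 25])
    be <- backward_elimination(y, d, positions = gm$pos)
    list(ret = be$retained, ids = gm$ids[c(10, 25)])
  }
  # one planted SNP at 0.5 SD among 29 null: retained in >= 80%
  r1 <- sapply(1:15, function(s) { r <- run_one(s); r$ids[1] %in% r$ret })
  expect_gte(mean(r1), 0.8)
  # two independent planted SNPs: both retained at this n
  r2 <- sapply(1:10, function(s) { r <- run_one(s, 2); all(r$ids %in% r$ret) })
  expect_gte(mean(r2), 0.8)
  # rerunning on its own output is a fixed point
  s <- 3
  gm <- sim_unlinked_geno(n, 30, seed = 5000 + s)
  d <- dosage(gm)
  set.seed(6000 + s)
  y <- rnorm(n) + d[, 10] * 0.5 / sd(d[, 10])
  be <- backward_elimination(y, d, positions = gm$pos)
  be2 <- backward_elimination(y, d[, be$retained_index, drop = FALSE],
                              positions = gm$pos[be$retained_index])
  expect_equal(be2$retained, be$retained)
  # collinear candidates: later-position member dropped, run completes
  dd <- cbind(d[, 1:5], d[, 5])
  colnames(dd) <- c(colnames(d)[1:5], "copy")
  be3 <- backward_elimination(y, dd, positions = c(gm$pos[1:5], gm$pos[5] + 1))
  expect_false("copy" %in% be3$retained)
})
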