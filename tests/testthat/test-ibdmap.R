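# IBD painting, block calling, block phenotype contrasts.

# build a geno_matrix for given per-chromatid origin strings over divergent
# markers (allele 1 = founder A)
gm_from_origins <- function(o1, o2, pos = NULL) {
  h1 <- as.integer(strsplit(o1, "")[[1]] == "A")
  h2 <- as.integer(strsplit(o2, "")[[1]] == "A")
  gm_from_hap(rbind(h1, h2), pos = pos %||% seq(0L, by = 1000L,
                                                length.out = nchar(o1)))
}

simple_key <- function(gm) data.frame(id = gm$ids, pos = gm$pos,
                                      allele_a = 1L)

test_that("homozygous and heterozygous paintings resolve correctly", {
  # all founder-A alleles: one segment, origin A, both chromatids
  gm <- gm_from_origins(strrep("A", 12), strrep("A", 12))
  p <- paint_ibd(gm, simple_key(gm), region = c(0, 12000))
  for (k in 1:2) {
    expect_equal(nrow(p$paintings[[1]][[k]]), 1L)
    expect_equal(p$paintings[[1]][[k]]$origin, "A")
  }
  # A-alleles for markers 1-10 then B for 11-20: one breakpoint at the
  # midpoint of the flanking marker interval
  gm2 <- gm_from_origins(paste0(strrep("A", 10), strrep("B", 10)),
                         paste0(strrep("A", 10), strrep("B", 10)))
  p2 <- paint_ibd(gm2, simple_key(gm2), region = c(0, 20000))
  seg <- p2$paintings[[1]][[1]]
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$origin, c("A", "B"))
  expect_equal(seg$end[1], floor((9000 + 10000) / 2))
  # heterozygous at every marker: A/B diplotype, zero breakpoints
  het <- gm_from_hap(matrix(rep(c(1L, 0L), 12), 2), pos = seq(0, by = 1000, length.out = 12))
  p3 <- paint_ibd(het, simple_key(het), region = c(0, 12000))
  orgs <- sort(c(p3$paintings[[1]][[1]]$origin, p3$paintings[[1]][[2]]$origin))
  expect_equal(orgs, c("A", "B"))
  # all markers missing: single unknown segment
  gm4 <- gm_from_hap(matrix(NA_integer_, 2, 5))
  p4 <- paint_ibd(gm4, data.frame(id = gm4$ids, pos = gm4$pos, allele_a = 1L),
                  region = c(0, 500))
  expect_equal(p4$paintings[[1]][[1]]$origin, "unknown")
})

test_that("painting minimises switch count (brute-force oracle)", {
  # enumerate all phase assignments at het markers and count switches
  brute_min_switches <- function(acount) {
    het <- which(acount == 1L)
    best <- Inf
    combos <- if (length(het)) expand.grid(rep(list(0:1), length(het)))
              else data.frame(row.names = 1)
    for (r in seq_len(max(1, nrow(combos)))) {
      o1 <- ifelse(acount >= 1L, "A", "B")
      o2 <- ifelse(acount == 2L, "A", "B")
      if (length(het)) for (j in seq_along(het)) {
        if (combos[r, j] == 1) { o1[het[j]] <- "B"; o2[het[j]] <- "A" }
      }
      sw <- sum(o1[-1] != o1[-length(o1)]) + sum(o2[-1] != o2[-length(o2)])
      best <- min(best, sw)
    }
    best
  }
  set.seed(131)
  for (rep in 1:12) {
    acount <- sample(0:2, 10, replace = TRUE)
    h1 <- as.integer(acount >= 1L)  # any compatible genotype encoding
    h2 <- as.integer(acount == 2L)
    gm <- gm_from_hap(rbind(h1, h2), pos = seq(0, by = 1000, length.out = 10))
    p <- paint_ibd(gm, simple_key(gm), min_support = 1L, region = c(0, 10000))
    sw <- (nrow(p$paintings[[1]][[1]]) - 1) + (nrow(p$paintings[[1]][[2]]) - 1)
    expect_lte(sw, brute_min_switches(acount))
  }
})

test_that("block calling classifies recombinants and preserves counts", {
  gms <- list(
    gm_from_origins(strrep("A", 8), strrep("A", 8)),     # unrecombined AA
    gm_from_origins(strrep("A", 8), strrep("B", 8)),     # unrecombined AB
    gm_from_origins(strrep("B", 8), strrep("B", 8)),     # unrecombined BB
    gm_from_origins(paste0(strrep("A", 4), strrep("B", 4)), strrep("B", 8)))
  hap <- do.call(rbind, lapply(gms, function(g) g$hap))
  gm <- geno_matrix(hap, gms[[1]]$pos, samples = paste0("I", 1:4))
  p <- paint_ibd(gm, simple_key(gms[[1]]), region = c(0, 8000))
  b <- call_blocks(p)
  expect_equal(nrow(b$blocks), 2L)      # one switch interval -> two blocks
  expect_equal(sum(b$recombinant), 1L)
  expect_equal(unname(b$classes[, 1]), c("AA", "AB", "BB", "AB"))
  expect_equal(unname(b$classes[, 2]), c("AA", "AB", "BB", "BB"))
  # class counts sum to n in every block
  expect_true(all(colSums(!is.na(b$classes)) == 4))
  # no-switch case: one block, zero recombinants
  b0 <- call_blocks(paint_ibd(gms[[1]], simple_key(gms[[1]]), region = c(0, 8000)))
  expect_equal(nrow(b0$blocks), 1L)
  expect_equal(sum(b0$recombinant), 0L)
})

test_that("painting recovers simulated F9 breakpoints at marker resolution", {
  cfg <- default_pipeline_config(seed = 17)
  cfg$generation_sizes <- c(rep(60L, 8L), 120L)
  sim <- ailqtl:::pipeline_simulate(cfg)
  gm_a <- ailqtl:::founder_genotypes(sim$founders, sim$pos, "HQLA")
  gm_b <- ailqtl:::founder_genotypes(sim$founders, sim$pos, "HB")
  diffs <- founder_delta_af(gm_a, gm_b)
  t1 <- which(!is.na(diffs$delta_af) & diffs$delta_af >= 0.95)
  key <- founder_marker_key(subset_geno(gm_a, sites = t1),
                            subset_geno(gm_b, sites = t1))
  gm9 <- ped_genotypes(sim$ped)
  p <- paint_ibd(gm9, key, region = c(sim$map$start, sim$map$end))
  truth <- ped_paintings(sim$ped)
  # painted breakpoints must sit within one marker interval of a true
  # origin switch of the individual (chromatid phase labels are not
  # identifiable from unphased genotypes, so breakpoints are compared at
  # the individual level)
  mpos <- key$pos
  near_some <- function(x, true_bp, slack) {
    if (!length(true_bp)) return(FALSE)
    any(abs(true_bp - x) <= slack)
  }
  ok <- 0; tot <- 0
  for (id in names(truth)) {
    tp <- truth[[id]]; pp <- p$paintings[[id]]
    # true origin switches (only changes of origin label are observable)
    true_bp <- c(tp[[1]]$start[-1], tp[[2]]$start[-1])
    for (k in 1:2) {
      called_bp <- pp[[k]]$start[-1]
      slack_ok <- vapply(called_bp, function(b) {
        i <- findInterval(b, mpos)
        slack <- mpos[min(i + 1, length(mpos))] - mpos[max(i, 1)]
        near_some(b, true_bp, slack + 1)
      }, TRUE)
      ok <- ok + as.integer(all(slack_ok))
      tot <- tot + 1
    }
  }
  expect_gte(ok / tot, 0.95)
})

test_that("block t-test matches the Welch formula and finds the causal block", {
  set.seed(141)
  # two groups N(0,1) vs N(1,1), n = 50 each, via a constructed block set
  n <- 100
  cls <- rep(c("AA", "BB"), each = 50)
  y <- c(rnorm(50, 1), rnorm(50, 0))
  bs <- structure(list(blocks = data.frame(start = 0, end = 1000),
                       classes = matrix(cls, ncol = 1),
                       recombinant = rep(TRUE, n),
                       samples = sprintf("I%03d", 1:n)),
                  class = "block_set")
  phen <- data.frame(id = bs$samples, phenotype = y)
  bt <- block_ttest(bs, phen, 1)
  # chromatid-level duplication: compare to Welch on duplicated samples
  expect_equal(bt$p, oracle_welch(rep(y[1:50], each = 2), rep(y[51:100], each = 2)),
               tolerance = 1e-10)
  expect_equal(bt$class_summary$n, c(50L, 0L, 50L))
  # degenerate group: undefined with reason
  bs2 <- bs; bs2$classes[] <- "AA"
  expect_true(is.na(block_ttest(bs2, phen, 1)$p))
})
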