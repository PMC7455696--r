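# Shared fixtures and independent oracles for the test suite.
options(ailqtl.verbose = FALSE)

# tiny geno_matrix from a chromatid x site matrix
gm_from_hap <- function(hap, pos = NULL, phased = TRUE, chrom = "1") {
  hap <- as.matrix(hap)
  if (is.null(pos)) pos <- seq(0L, by = 100L, length.out = ncol(hap))
  geno_matrix(hap, pos, chrom = chrom, phased = phased)
}

# random small geno_matrix with optional missingness
random_gm <- function(n_chrom, m, seed, p_missing = 0) {
  set.seed(seed)
  hap <- matrix(rbinom(n_chrom * m, 1L, runif(m, 0.2, 0.8)[rep(seq_len(m),
                each = n_chrom)]), n_chrom, m)
  if (p_missing > 0) hap[runif(length(hap)) < p_missing] <- NA
  gm_from_hap(hap)
}

# neutral frequency-spectrum sites: each segregating site gets a derived
# count k with P(k) proportional to 1/k, placed on a random chromatid
# subset; no linkage. Matches the standard neutral site-frequency spectrum
# so Watterson and pairwise estimators agree in expectation.
neutral_sfs_gm <- function(n_chrom, m, seed, pos_step = 10L) {
  set.seed(seed)
  kprob <- (1 / seq_len(n_chrom - 1))
  hap <- matrix(0L, n_chrom, m)
  for (j in seq_len(m)) {
    k <- sample.int(n_chrom - 1, 1L, prob = kprob)
    hap[sample.int(n_chrom, k), j] <- 1L
  }
  gm_from_hap(hap, pos = seq(0L, by = pos_step, length.out = m))
}

# --- independent oracles (textbook formulas, coded separately from R/) ---

# brute-force pi over all chromatid pairs in a window of sites
oracle_pi <- function(hap) {
  n <- nrow(hap)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    tot <- tot + mean(hap[i, ] != hap[j, ])
    np <- np + 1
  }
  tot / np
}

# Tajima 1989 D from an alignment (no missing data)
oracle_tajima_d <- function(hap) {
  n <- nrow(hap)
  cnt <- colSums(hap)
  S <- sum(cnt > 0 & cnt < n)
  if (S == 0) return(NA_real_)
  k <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    k <- k + sum(hap[i, ] != hap[j, ])
  k <- k / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Hudson Fst from allele counts at one site
oracle_hudson_fst <- function(n1, c1, n2, c2) {
  p1 <- c1 / n1; p2 <- c2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num / den
}

# EHH by direct enumeration of haplotype identity classes
oracle_ehh <- function(hap, core, upto) {
  idx <- if (upto >= core) core:upto else core:upto
  key <- apply(hap[, sort(unique(idx)), drop = FALSE], 1, paste, collapse = "")
  cnt <- table(key)
  sum(cnt * (cnt - 1)) / (nrow(hap) * (nrow(hap) - 1))
}

# Welch two-sample t-test from first principles
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}
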