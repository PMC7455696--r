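# Windowed diversity, differentiation and haplotype-homozygosity statistics.
# Window coordinates are 0-based half-open internally; write_scan_tsv()
# emits 1-based inclusive coordinates.

# per-site stats after the call-rate filter; returns NULL columns for empty
scan_sites <- function(gm, min_call = 0.9) {
  sc <- site_counts(gm)
  n_chrom <- nrow(gm$hap)
  ok <- sc$n >= min_call * n_chrom & sc$n >= 2
  list(pos = gm$pos[ok], n = sc$n[ok], c1 = sc$c1[ok], idx = which(ok))
}

scan_region <- function(gm, region = NULL) {
  if (!is.null(region)) return(as.numeric(region))
  if (!n_sites(gm)) stop_input("empty genotype matrix and no region given")
  c(min(gm$pos), max(gm$pos) + 1)
}

#' Nucleotide diversity in sliding windows
#'
#' Per-site diversity is the average pairwise difference
#' `2*c1*c0 / (n*(n-1))` over non-missing chromatids; a window's value is
#' the mean over its accessible (genotyped, call-rate-passing) sites, so
#' monomorphic sites contribute 0 and windows with no accessible site are
#' `NA`. Windows are reported at fixed step even when undefined.
#'
#' @param gm a `geno_matrix` with at least 2 chromatids.
#' @param window_bp,step_bp window and step sizes in bp (defaults 500/250;
#'   the large-scale preset is 50 kb / 25 kb).
#' @param region scan region `c(start, end)`, 0-based half-open (default:
#'   the span of `gm`).
#' @param min_call minimum per-site call rate (default 0.9).
#' @return data.frame `chrom`, `start`, `end`, `stat`, `value`, `n_sites`.
#' @export
pi_scan <- function(gm, window_bp = 500, step_bp = 250, region = NULL,
                    min_call = 0.9) {
  if (nrow(gm$hap) < 2L) stop_input("need >= 2 chromatids")
  if (!(window_bp >= step_bp && step_bp > 0)) stop_input("need window >= step > 0")
  region <- scan_region(gm, region)
  ss <- scan_sites(gm, min_call)
  pi_site <- 2 * ss$c1 * (ss$n - ss$c1) / (ss$n * (ss$n - 1))
  starts <- seq(region[1], max(region[1], region[2] - window_bp), by = step_bp)
  cs_pi <- c(0, cumsum(pi_site)); cs_n <- c(0, cumsum(rep(1, length(ss$pos))))
  lo <- findInterval(starts - 0.5, ss$pos)
  hi <- findInterval(starts + window_bp - 0.5, ss$pos)
  nsite <- hi - lo
  val <- ifelse(nsite > 0, (cs_pi[hi + 1] - cs_pi[lo + 1]) / nsite, NA_real_)
  data.frame(chrom = gm$chrom, start = starts, end = starts + window_bp,
             stat = "pi", value = val, n_sites = nsite,
             stringsAsFactors = FALSE)
}

# Tajima (1989) constants for sample size n chromatids
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D in non-overlapping bins
#'
#' Standard frequency-spectrum D from the segregating-site count S and the
#' mean pairwise difference, using the a1/a2/b1/b2/c1/c2/e1/e2 constants.
#' Bins with S = 0 are undefined (`NA`), not 0. Sites with any missing call
#' are excluded so a single sample size applies per bin.
#'
#' @param gm a `geno_matrix` (>= 2, recommended >= 4 chromatids).
#' @param bin_bp bin width in bp (presets 250 bp or 25 kb).
#' @param region scan region `c(start, end)` (default: span of `gm`).
#' @return data.frame `chrom`, `start`, `end`, `stat`, `value`, `n_sites`
#'   (segregating sites per bin).
#' @export
tajimas_d <- function(gm, bin_bp = 250, region = NULL) {
  n <- nrow(gm$hap)
  if (n < 2L) stop_input("need >= 2 chromatids")
  region <- scan_region(gm, region)
  complete <- colSums(is.na(gm$hap)) == 0L
  pos <- gm$pos[complete]
  c1 <- colSums(gm$hap[, complete, drop = FALSE])
  seg <- c1 > 0 & c1 < n
  k_site <- 2 * c1 * (n - c1) / (n * (n - 1))
  starts <- seq(region[1], region[2] - 1, by = bin_bp)
  bin <- findInterval(pos, starts)
  S <- tabulate(bin[seg], nbins = length(starts))
  ksum <- rep(0, length(starts))
  if (length(bin)) {
    agg <- rowsum(k_site, bin)
    ksum[as.integer(rownames(agg))] <- agg[, 1]
  }
  cons <- tajima_constants(n)
  denom <- sqrt(cons$e1 * S + cons$e2 * S * (S - 1))
  D <- ifelse(S > 0, (ksum - S / cons$a1) / denom, NA_real_)
  data.frame(chrom = gm$chrom, start = starts,
             end = pmin(starts + bin_bp, region[2]),
             stat = "tajimas_d", value = D, n_sites = S,
             stringsAsFactors = FALSE)
}

#' Haplotype diversity (Nei & Tajima)
#'
#' `H = n/(n-1) * (1 - sum(p_i^2))` over the distinct haplotype frequencies
#' `p_i` among `n` chromatids.
#'
#' @param haps character vector of haplotype strings (one per chromatid),
#'   or a factor.
#' @return H in `[0, 1]`; `NA` if n < 2.
#' @export
hap_diversity <- function(haps) {
  haps <- haps[!is.na(haps)]
  n <- length(haps)
  if (n < 2L) return(NA_real_)
  p <- table(haps) / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Haplotype diversity in non-overlapping bins
#'
#' @param gm a phased `geno_matrix`.
#' @param bin_bp bin width in bp (default 2000).
#' @param region scan region `c(start, end)`.
#' @return data.frame `chrom`, `start`, `end`, `stat`, `value`, `n_sites`.
#' @export
hap_diversity_scan <- function(gm, bin_bp = 2000, region = NULL) {
  if (!gm$phased) stop_input("haplotype diversity needs phased input")
  region <- scan_region(gm, region)
  starts <- seq(region[1], region[2] - 1, by = bin_bp)
  bin <- findInterval(gm$pos, starts)
  val <- rep(NA_real_, length(starts))
  nsite <- tabulate(bin, nbins = length(starts))
  for (b in unique(bin)) {
    cols <- which(bin == b)
    sub <- gm$hap[, cols, drop = FALSE]
    ok <- rowSums(is.na(sub)) == 0L
    strings <- apply(sub[ok, , drop = FALSE], 1L, paste, collapse = "")
    val[b] <- hap_diversity(strings)
  }
  data.frame(chrom = gm$chrom, start = starts,
             end = pmin(starts + bin_bp, region[2]),
             stat = "hap_diversity", value = val, n_sites = nsite,
             stringsAsFactors = FALSE)
}

# Hudson two-population Fst components per site (Bhatia et al. ratio-of-
# averages form). Returns NA components where the pooled sample is
# monomorphic or a population has < 2 calls.
hudson_components <- function(n1, c1, n2, c2) {
  p1 <- c1 / n1; p2 <- c2 / n2
  pooled_poly <- (c1 + c2) > 0 & (c1 + c2) < (n1 + n2)
  ok <- pooled_poly & n1 >= 2 & n2 >= 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num[!ok] <- NA; den[!ok] <- NA
  list(num = num, den = den, ok = ok)
}

# Weir & Cockerham style two-population components for haploid (chromatid)
# samples: a = among-population, a + b = total.
wc_components <- function(n1, c1, n2, c2) {
  r <- 2
  p1 <- c1 / n1; p2 <- c2 / n2
  ni <- cbind(n1, n2)
  pi_ <- cbind(p1, p2)
  nbar <- rowMeans(ni)
  nc <- (rowSums(ni) - rowSums(ni^2) / rowSums(ni)) / (r - 1)
  pbar <- rowSums(ni * pi_) / rowSums(ni)
  s2 <- rowSums(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2)
  a <- nbar / nc * (s2 - b / nbar)
  ok <- (c1 + c2) > 0 & (c1 + c2) < (n1 + n2) & n1 >= 2 & n2 >= 2
  num <- a; den <- a + b
  num[!ok] <- NA; den[!ok] <- NA
  list(num = num, den = den, ok = ok)
}

#' Fst between two populations, per site or windowed
#'
#' Hudson's two-population estimator (default) computed per site; windowed
#' values are the ratio of averaged numerator and denominator components
#' over defined sites ("ratio of averages"), which is bounded by 1 and
#' reaches 1 at fixed differences. Sites monomorphic in the pooled sample
#' are undefined per site and excluded from window averages. A
#' Weir-Cockerham variant is available for cross-checking.
#'
#' @param gm_a,gm_b `geno_matrix` objects over the same sites.
#' @param window_bp window size in bp, or `NULL` for per-site output
#'   (presets: per-site or 20 kb bins).
#' @param region scan region for windowed output.
#' @param estimator `"hudson"` (default) or `"wc"`.
#' @param min_call minimum per-site call rate within each population.
#' @return data.frame `chrom`, `start`, `end`, `stat`, `value`, `n_sites`
#'   (per-site output has `start` = `pos`, `end` = `pos + 1`).
#' @export
fst_scan <- function(gm_a, gm_b, window_bp = NULL, region = NULL,
                     estimator = c("hudson", "wc"), min_call = 0.9) {
  estimator <- match.arg(estimator)
  if (!identical(gm_a$pos, gm_b$pos)) stop_input("populations must share the same sites")
  sa <- site_counts(gm_a); sb <- site_counts(gm_b)
  callable <- sa$n >= min_call * nrow(gm_a$hap) & sb$n >= min_call * nrow(gm_b$hap)
  comp <- if (estimator == "hudson") hudson_components(sa$n, sa$c1, sb$n, sb$c1)
          else wc_components(sa$n, sa$c1, sb$n, sb$c1)
  comp$num[!callable] <- NA; comp$den[!callable] <- NA
  if (is.null(window_bp)) {
    val <- comp$num / comp$den
    return(data.frame(chrom = gm_a$chrom, start = gm_a$pos, end = gm_a$pos + 1,
                      stat = paste0("fst_", estimator), value = val,
                      n_sites = as.integer(!is.na(val)), stringsAsFactors = FALSE))
  }
  region <- scan_region(gm_a, region)
  starts <- seq(region[1], region[2] - 1, by = window_bp)
  bin <- findInterval(gm_a$pos, starts)
  ok <- !is.na(comp$num)
  num <- den <- rep(0, length(starts)); nsite <- rep(0L, length(starts))
  if (any(ok)) {
    agn <- rowsum(comp$num[ok], bin[ok]); agd <- rowsum(comp$den[ok], bin[ok])
    cnt <- table(bin[ok])
    ix <- as.integer(rownames(agn))
    num[ix] <- agn[, 1]; den[ix] <- agd[, 1]
    nsite[as.integer(names(cnt))] <- as.integer(cnt)
  }
  val <- ifelse(nsite > 0 & den != 0, num / den, NA_real_)
  data.frame(chrom = gm_a$chrom, start = starts,
             end = pmin(starts + window_bp, region[2]),
             stat = paste0("fst_", estimator), value = val, n_sites = nsite,
             stringsAsFactors = FALSE)
}

# haplotype homozygosity of identity classes: sum choose(n_h,2)/choose(n,2)
hap_homozygosity <- function(class_id) {
  n <- length(class_id)
  cnt <- tabulate(class_id)
  sum(cnt * (cnt - 1)) / (n * (n - 1))
}

#' Extended haplotype homozygosity decay from a core site
#'
#' EHH at marker x (on either side of the core) is the probability that two
#' randomly drawn chromatids are identical over all markers from the core
#' out to x, the core site included ("pooled-core" definition: haplotypes
#' are not split by core allele). EHH at the core itself is the core-site
#' homozygosity, and is 1 when a single haplotype is present.
#'
#' @param gm a phased `geno_matrix` with no missing calls at the used sites.
#' @param core_idx site index of the core.
#' @return data.frame `idx`, `pos`, `side` (-1 left / 0 core / +1 right),
#'   `ehh`, ordered outward per side.
#' @export
ehh_decay <- function(gm, core_idx) {
  if (!gm$phased) stop_input("EHH needs phased haplotypes")
  h <- gm$hap
  complete <- rowSums(is.na(h)) == 0L
  h <- h[complete, , drop = FALSE]
  if (nrow(h) < 2L) stop_input("need >= 2 complete chromatids")
  m <- ncol(h)
  run_side <- function(idxs, side) {
    cls <- h[, core_idx] + 1L
    out <- data.frame(idx = integer(), pos = integer(), side = integer(),
                      ehh = numeric())
    for (j in idxs) {
      if (j != core_idx) cls <- (cls - 1L) * 2L + h[, j] + 1L
      cls <- match(cls, unique(cls))  # re-factor to keep ids small
      out <- rbind(out, data.frame(idx = j, pos = gm$pos[j], side = side,
                                   ehh = hap_homozygosity(cls)))
    }
    out
  }
  rbind(run_side(core_idx:1, if (core_idx > 1) -1L else 0L)[-1, ],
        data.frame(idx = core_idx, pos = gm$pos[core_idx], side = 0L,
                   ehh = hap_homozygosity(h[, core_idx] + 1L)),
        run_side(core_idx:m, 1L)[-1, ])
}

# integrated EHH: trapezoid over genetic distance (Morgans), truncated at
# the last marker with EHH >= cutoff on each side
ihh_from_decay <- function(decay, map, cutoff = 0.05) {
  one_side <- function(side) {
    d <- decay[decay$side == side, ]
    d <- d[order(abs(d$pos - decay$pos[decay$side == 0][1])), ]
    core <- decay[decay$side == 0, ]
    x <- c(core$pos, d$pos); y <- c(core$ehh, d$ehh)
    below <- which(y < cutoff)
    if (length(below)) { x <- x[seq_len(below[1] - 1)]; y <- y[seq_len(below[1] - 1)] }
    if (length(x) < 2L) return(0)
    gx <- abs(x - x[1]) / 1e6 * map$rate / 100  # Morgans
    sum(diff(gx) * (head(y, -1) + tail(y, -1)) / 2)
  }
  one_side(-1L) + one_side(1L)
}

#' Cross-population EHH score at one core site
#'
#' Unstandardised XP-EHH: `ln(iHH_A / iHH_B)` where iHH is the trapezoid
#' integral of the population's EHH decay over genetic distance, truncated
#' where EHH drops below `cutoff`. Positive values mean longer haplotype
#' homozygosity in population A.
#'
#' @param gm_a,gm_b phased `geno_matrix` objects over the same sites.
#' @param core_idx core site index (must be polymorphic in the pooled
#'   sample).
#' @param map a `genetic_map` for bp-to-cM conversion.
#' @param cutoff EHH truncation level (default 0.05).
#' @return raw score, or `NA` when either integral has no support.
#' @export
xpehh <- function(gm_a, gm_b, core_idx, map, cutoff = 0.05) {
  if (!identical(gm_a$pos, gm_b$pos)) stop_input("populations must share the same sites")
  pooled <- c(gm_a$hap[, core_idx], gm_b$hap[, core_idx])
  if (length(unique(pooled[!is.na(pooled)])) < 2L)
    stop_input("core site must be polymorphic in the pooled sample")
  ia <- ihh_from_decay(ehh_decay(gm_a, core_idx), map, cutoff)
  ib <- ihh_from_decay(ehh_decay(gm_b, core_idx), map, cutoff)
  if (ia == 0 || ib == 0) return(NA_real_)
  log(ia / ib)
}

#' XP-EHH scan with z-normalisation
#'
#' Computes the raw XP-EHH score at every pooled-polymorphic site and
#' standardises scores by the scan mean and SD (the usual locus-level
#' normalisation).
#'
#' @inheritParams xpehh
#' @return data.frame `chrom`, `start`, `end`, `stat`, `value` (normalised),
#'   `raw`, `n_sites`.
#' @export
xpehh_scan <- function(gm_a, gm_b, map, cutoff = 0.05) {
  pooled_c1 <- site_counts(gm_a)$c1 + site_counts(gm_b)$c1
  pooled_n <- site_counts(gm_a)$n + site_counts(gm_b)$n
  poly <- which(pooled_c1 > 0 & pooled_c1 < pooled_n)
  raw <- vapply(poly, function(i) xpehh(gm_a, gm_b, i, map, cutoff), 0)
  z <- (raw - mean(raw, na.rm = TRUE)) / sd(raw, na.rm = TRUE)
  data.frame(chrom = gm_a$chrom, start = gm_a$pos[poly], end = gm_a$pos[poly] + 1,
             stat = "xpehh", value = z, raw = raw,
             n_sites = as.integer(!is.na(raw)), stringsAsFactors = FALSE)
}
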