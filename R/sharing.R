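# Multi-breed haplotype-sharing scan: per-bin haplotype frequencies,
# Q-haplotype frequency differential between high- and low-weight groups,
# and merging of above-threshold bins into Q regions.

#' Per-bin haplotype frequencies by group
#'
#' Tiles the region with `bin_bp` bins anchored at the region start, builds
#' the distinct haplotype strings over the SNPs of each bin from phased
#' chromatids, and tabulates their frequencies per population label. Bins
#' without SNPs are flagged (`n_sites = 0`) and skipped by the scan.
#'
#' @param gm a phased `geno_matrix`.
#' @param populations per-sample population labels (named by sample id, or
#'   in sample order).
#' @param bin_bp bin width (default 2000).
#' @param region scan region `c(start, end)`, 0-based half-open.
#' @return object of class `bin_haps`: `bins` (data.frame `bin`, `start`,
#'   `end`, `n_sites`), `freq` (per non-empty bin, a populations x
#'   haplotypes frequency matrix), `bin_bp`.
#' @export
bin_haplotypes <- function(gm, populations, bin_bp = 2000, region = NULL) {
  if (!gm$phased) stop_input("haplotype binning needs phased input")
  region <- scan_region(gm, region)
  if (!is.null(names(populations))) populations <- populations[gm$samples]
  if (length(populations) != n_samples(gm) || anyNA(populations))
    stop_input("every sample needs a population label")
  chrom_pop <- rep(as.character(populations), each = 2L)
  starts <- seq(region[1], region[2] - 1, by = bin_bp)
  bin_of <- findInterval(gm$pos, starts)
  bins <- data.frame(bin = seq_along(starts), start = starts,
                     end = pmin(starts + bin_bp, region[2]),
                     n_sites = tabulate(bin_of, nbins = length(starts)))
  freq <- counts <- vector("list", length(starts))
  for (b in which(bins$n_sites > 0L)) {
    cols <- which(bin_of == b)
    sub <- gm$hap[, cols, drop = FALSE]
    ok <- rowSums(is.na(sub)) == 0L
    strings <- apply(sub[ok, , drop = FALSE], 1L, paste, collapse = "")
    tab <- unclass(table(pop = chrom_pop[ok], hap = strings))
    counts[[b]] <- tab
    freq[[b]] <- sweep(tab, 1L, rowSums(tab), "/")
  }
  structure(list(bins = bins, freq = freq, counts = counts, bin_bp = bin_bp,
                 region = region),
            class = "bin_haps")
}

#' Q-haplotype frequency differential per bin
#'
#' The Q haplotype of a bin is the modal haplotype of the reference
#' population (ties broken by the lexicographically smallest string); its
#' differential is the *signed* frequency difference between the pooled
#' high-weight and pooled low-weight chromatids,
#' `dAF_Q = freq(Q | high) - freq(Q | low)`.
#'
#' @param bh a `bin_haps` from [bin_haplotypes()].
#' @param ref_pop reference population defining Q (e.g. the "HQLA"
#'   founders).
#' @param groups named vector mapping population label to `"high"`/`"low"`.
#' @param mode `"pooled"` (default: pool chromatids within each group) or
#'   `"breed_mean"` (average per-population frequencies within each group).
#' @return data.frame `bin`, `start`, `end`, `n_sites`, `q_hap`,
#'   `freq_high`, `freq_low`, `delta_q` (`NA` for empty bins or bins where
#'   the reference population has no calls).
#' @export
q_delta_af <- function(bh, ref_pop, groups, mode = c("pooled", "breed_mean")) {
  mode <- match.arg(mode)
  out <- bh$bins
  out$q_hap <- NA_character_
  out$freq_high <- out$freq_low <- out$delta_q <- NA_real_
  high_pops <- names(groups)[groups == "high"]
  low_pops <- names(groups)[groups == "low"]
  for (b in which(out$n_sites > 0L)) {
    fr <- bh$freq[[b]]
    if (!(ref_pop %in% rownames(fr)) || all(is.na(fr[ref_pop, ]))) next
    rf <- fr[ref_pop, ]
    q <- names(rf)[rf == max(rf)]
    q <- sort(q)[1L]
    fh <- NA_real_; fl <- NA_real_
    if (mode == "breed_mean") {
      hi <- intersect(high_pops, rownames(fr))
      lo <- intersect(low_pops, rownames(fr))
      if (length(hi)) fh <- mean(fr[hi, q])
      if (length(lo)) fl <- mean(fr[lo, q])
    } else {
      cnts <- bh$counts[[b]]
      hi <- intersect(high_pops, rownames(cnts))
      lo <- intersect(low_pops, rownames(cnts))
      if (length(hi)) fh <- sum(cnts[hi, q, drop = FALSE]) / sum(cnts[hi, ])
      if (length(lo)) fl <- sum(cnts[lo, q, drop = FALSE]) / sum(cnts[lo, ])
    }
    out$q_hap[b] <- q
    out$freq_high[b] <- fh
    out$freq_low[b] <- fl
    out$delta_q[b] <- fh - fl
  }
  out
}

#' Merge above-threshold bins into Q regions
#'
#' Maximal runs of *adjacent* bins with `delta_q >= threshold` become one
#' region; empty (SNP-less) or undefined bins break adjacency. Regions are
#' named Q1..Qk left to right.
#'
#' @param qdf data.frame from [q_delta_af()] (bin-ordered).
#' @param threshold differential threshold (default 0.4).
#' @return data.frame `name`, `start`, `end`, `n_bins`, `length_bp`,
#'   `max_delta`, `mean_delta` (empty when no bin passes).
#' @export
merge_q_regions <- function(qdf, threshold = 0.4) {
  pass <- !is.na(qdf$delta_q) & qdf$delta_q >= threshold
  if (!any(pass))
    return(data.frame(name = character(), start = numeric(), end = numeric(),
                      n_bins = integer(), length_bp = numeric(),
                      max_delta = numeric(), mean_delta = numeric()))
  r <- rle(pass)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- data.frame(
    name = paste0("Q", seq_along(runs)),
    start = qdf$start[starts[runs]],
    end = qdf$end[ends[runs]],
    n_bins = r$lengths[runs],
    length_bp = vapply(runs, function(k)
      sum(qdf$end[starts[k]:ends[k]] - qdf$start[starts[k]:ends[k]]), 0),
    max_delta = vapply(runs, function(k)
      max(qdf$delta_q[starts[k]:ends[k]]), 0),
    mean_delta = vapply(runs, function(k)
      mean(qdf$delta_q[starts[k]:ends[k]]), 0),
    stringsAsFactors = FALSE)
  out
}

#' Haplotype-sharing Q-region scan
#'
#' Convenience wrapper: bins the region, computes the per-bin Q
#' differential and merges above-threshold bins into Q regions.
#'
#' @inheritParams bin_haplotypes
#' @inheritParams q_delta_af
#' @inheritParams merge_q_regions
#' @return list `bins` (per-bin table with `delta_q`), `regions`.
#' @export
q_scan <- function(gm, populations, ref_pop, groups, bin_bp = 2000,
                   region = NULL, threshold = 0.4,
                   mode = c("pooled", "breed_mean")) {
  bh <- bin_haplotypes(gm, populations, bin_bp, region)
  qdf <- q_delta_af(bh, ref_pop, groups, mode = match.arg(mode))
  list(bins = qdf, regions = merge_q_regions(qdf, threshold))
}
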