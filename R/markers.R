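#' Founder allele-frequency differential
#'
#' Absolute difference in allele frequency between two founder populations
#' at a site; the quantity driving informative-marker selection.
#'
#' @param af_a,af_b allele frequencies in the two populations, each in
#'   `[0, 1]` (vectorised).
#' @return `|af_a - af_b|`.
#' @export
delta_af <- function(af_a, af_b) {
  if (any(af_a < 0 | af_a > 1 | af_b < 0 | af_b > 1, na.rm = TRUE))
    stop_input("allele frequencies must be in [0, 1]")
  abs(af_a - af_b)
}

#' Per-site founder differentials for two genotype sets
#'
#' @param gm_a,gm_b `geno_matrix` objects for the two founder populations
#'   over the same sites.
#' @param annotation optional data.frame `id`, `class` with class in
#'   `c("none", "missense_splice", "utr")`; unlisted sites get `"none"`.
#' @return data.frame `id`, `pos`, `af_a`, `af_b`, `delta_af`, `annotation`,
#'   sorted by position.
#' @export
founder_delta_af <- function(gm_a, gm_b, annotation = NULL) {
  if (!identical(gm_a$pos, gm_b$pos)) stop_input("founder sets must share the same sites")
  d <- data.frame(id = gm_a$ids, pos = gm_a$pos,
                  af_a = allele_freq(gm_a), af_b = allele_freq(gm_b),
                  stringsAsFactors = FALSE)
  d$delta_af <- delta_af(d$af_a, d$af_b)
  d$annotation <- "none"
  if (!is.null(annotation)) {
    i <- match(d$id, annotation$id)
    d$annotation[!is.na(i)] <- annotation$class[i[!is.na(i)]]
  }
  d
}

#' Tiered informative-marker selection
#'
#' Three nested admission rules over founder differentials: tier 1 keeps
#' near-fixed markers (`delta_af >= tier1`); tier 2 relaxes the threshold
#' (`>= tier2`) and then thins the set so no two retained markers are closer
#' than `spacing_bp` (the marker with the larger differential wins; ties go
#' to the smaller position); functionally annotated markers
#' (missense/splice or UTR) are admitted at the softer `annot_tier`
#' threshold. A marker can belong to several tiers; the annotation tier is
#' only reported for markers below `tier2`.
#'
#' @param diffs data.frame from [founder_delta_af()] (must be
#'   position-sorted).
#' @param tier1,tier2,annot_tier differential thresholds (defaults 0.95,
#'   0.75, 0.3).
#' @param spacing_bp minimum spacing within the tier-2 set (default 100).
#' @return `diffs` with logical columns `tier1`, `tier2`, `annot` plus
#'   `selected` (any tier); attribute `"counts"` records the attrition.
#' @export
select_informative <- function(diffs, tier1 = 0.95, tier2 = 0.75,
                               annot_tier = 0.3, spacing_bp = 100) {
  if (is.unsorted(diffs$pos, strictly = FALSE)) stop_input("diffs must be sorted by position")
  d <- diffs
  d$tier1 <- !is.na(d$delta_af) & d$delta_af >= tier1
  pre2 <- !is.na(d$delta_af) & d$delta_af >= tier2
  # spacing thinning: greedy by decreasing delta_af, ties by smaller position
  keep <- rep(FALSE, nrow(d))
  ord <- order(-d$delta_af, d$pos)
  ord <- ord[pre2[ord]]
  kept_pos <- numeric(0)
  for (i in ord) {
    if (!length(kept_pos) || all(abs(kept_pos - d$pos[i]) >= spacing_bp)) {
      keep[i] <- TRUE
      kept_pos <- c(kept_pos, d$pos[i])
    }
  }
  d$tier2 <- keep
  d$annot <- !is.na(d$delta_af) & d$delta_af >= annot_tier & !pre2 &
    d$annotation %in% c("missense_splice", "utr")
  d$selected <- d$tier1 | d$tier2 | d$annot
  attr(d, "counts") <- c(input = nrow(d), tier1 = sum(d$tier1),
                         tier2_pre_spacing = sum(pre2), tier2 = sum(d$tier2),
                         annot = sum(d$annot), selected = sum(d$selected))
  log_info(sprintf("marker selection: %d sites -> tier1 %d, tier2 %d (of %d before spacing), annot %d",
                   nrow(d), sum(d$tier1), sum(d$tier2), sum(pre2), sum(d$annot)))
  d
}

#' Squared genotype correlation between two sites
#'
#' Squared Pearson correlation of dosage vectors over pairwise-complete
#' samples; `NA` if either site is monomorphic among the shared samples.
#'
#' @param g_i,g_j dosage vectors (0/1/2, `NA` allowed).
#' @return r-squared, or `NA`.
#' @export
ld_r2 <- function(g_i, g_j) {
  ok <- !is.na(g_i) & !is.na(g_j)
  if (sum(ok) < 2L) return(NA_real_)
  x <- g_i[ok]; y <- g_j[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Sliding-window LD pruning
#'
#' Deterministic greedy pruning: within each window of `window_snps`
#' consecutive (surviving) sites, while any pair exceeds `r2_max`, the
#' member of the currently worst pair with the lower minor-allele frequency
#' is removed (tie: the larger position); the window then advances by
#' `step_snps`. Mirrors the `--indep-pairwise` style construction used to
#' count independent markers for Bonferroni correction.
#'
#' @param gm a `geno_matrix` (position-sorted by construction).
#' @param window_snps,step_snps window and step in SNP counts (defaults
#'   50 / 5).
#' @param r2_max pruning threshold.
#' @return data.frame of kept sites (`id`, `pos`, `index`).
#' @export
ld_prune <- function(gm, window_snps = 50, step_snps = 5, r2_max = 0.4) {
  d <- dosage(gm)
  m <- ncol(d)
  maf <- pmin(allele_freq(gm), 1 - allele_freq(gm))
  alive <- rep(TRUE, m)
  one_pass <- function(alive) {
    start <- 1L
    repeat {
      idx <- which(alive)
      idx <- idx[idx >= start]
      win <- head(idx, window_snps)
      if (length(win) >= 2L) {
        r2 <- suppressWarnings(cor(d[, win, drop = FALSE],
                                   use = "pairwise.complete.obs")^2)
        diag(r2) <- NA
        repeat {
          if (all(is.na(r2)) || max(r2, na.rm = TRUE) <= r2_max) break
          worst <- which(r2 == max(r2, na.rm = TRUE), arr.ind = TRUE)[1L, ]
          a <- win[worst[1L]]; b <- win[worst[2L]]
          drop_site <- if (isTRUE(maf[a] < maf[b])) a
                       else if (isTRUE(maf[b] < maf[a])) b
                       else max(a, b)
          alive[drop_site] <- FALSE
          k <- match(drop_site, win)
          r2[k, ] <- NA; r2[, k] <- NA
        }
      }
      if (length(idx) <= window_snps) break
      surv <- which(alive); surv <- surv[surv >= start]
      if (length(surv) <= step_snps) break
      start <- surv[step_snps + 1L]
    }
    alive
  }
  # repeat sliding passes until no further removals: survivors of later
  # windows can slide into a common window only after removals, so a single
  # pass does not guarantee the no-remaining-pair property
  repeat {
    alive_new <- one_pass(alive)
    if (identical(alive_new, alive)) break
    alive <- alive_new
  }
  keep <- which(alive)
  log_info(sprintf("LD pruning at r2 > %.2f: %d -> %d sites", r2_max, m, length(keep)))
  data.frame(id = gm$ids[keep], pos = gm$pos[keep], index = keep,
             stringsAsFactors = FALSE)
}

#' Bonferroni threshold over independent markers
#'
#' @param alpha genome-wide significance level, in (0, 1).
#' @param n_independent number of independent markers (>= 1), e.g. the size
#'   of an [ld_prune()] output.
#' @return the p-value threshold `alpha / n_independent` (report at 3
#'   significant digits via [signif()]).
#' @export
bonferroni_threshold <- function(alpha, n_independent) {
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  if (n_independent < 1) stop_input("n_independent must be >= 1")
  alpha / n_independent
}
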