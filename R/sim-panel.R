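#' Default multi-breed panel specification
#'
#' Emulates a resequencing panel of high- and low-body-weight chicken
#' breeds segregating shared "Q" sub-haplotypes: three planted intervals in
#' the proximal candidate region where the high-weight breeds carry a common
#' Q allele string at high frequency and the low-weight breeds carry it at
#' low frequency. Breed names and sample sizes mirror a typical
#' commercial-broiler vs native-breed contrast; the reference population for
#' the Q definition is the "HQLA" breed in the high group.
#'
#' @param region candidate region `c(start, end)` in bp (default the 1.2 Mb
#'   proximal block, 168.6-169.8 Mb).
#' @param snp_step panel SNP spacing in bp (default 500, i.e. 4 SNPs per
#'   2 kb sharing bin).
#' @param q_intervals data.frame `start`, `end` of planted shared
#'   sub-haplotypes (default three intervals of 6, 12 and 4 kb, aligned to
#'   the 2 kb bin grid).
#' @param breeds data.frame `name`, `group` (`"high"`/`"low"`), `n`,
#'   `q_freq` (per-chromatid probability of carrying the Q string in each
#'   planted interval).
#' @return list specification consumed by [simulate_breed_panel()].
#' @export
default_panel_spec <- function(region = c(168600000, 169800000), snp_step = 500,
                               q_intervals = NULL, breeds = NULL) {
  if (is.null(q_intervals))
    q_intervals <- data.frame(start = c(168700000, 169100000, 169560000),
                              end   = c(168706000, 169112000, 169564000))
  if (is.null(breeds))
    breeds <- data.frame(
      name = c("HQLA", "CB1", "CB2", "SK", "CH", "TBC", "DWS", "XSD", "SUM", "RJF"),
      group = c("high", "high", "high", rep("low", 7)),
      n = c(16L, 20L, 20L, 15L, 15L, 15L, 15L, 15L, 15L, 15L),
      q_freq = c(0.95, 0.90, 0.85, 0.10, 0.05, 0.10, 0.05, 0.10, 0.15, 0.20),
      stringsAsFactors = FALSE)
  list(region = region, snp_step = snp_step, q_intervals = q_intervals,
       breeds = breeds, ref_breed = "HQLA")
}

#' Simulate a multi-breed resequencing panel with shared Q sub-haplotypes
#'
#' Background alleles are drawn per chromatid from per-site base frequencies
#' shared across breeds (so outside the planted intervals, the modal-
#' haplotype frequency differential between breed groups is centred on
#' zero). Inside each planted interval a chromatid either copies the Q
#' allele template (with its breed's `q_freq` probability) or keeps its
#' random background alleles.
#'
#' @param spec a specification from [default_panel_spec()].
#' @param seed integer seed.
#' @return list with `geno` (phased `geno_matrix`), `samples` (data.frame
#'   `sample`, `breed`, `group`), `truth` (planted intervals with the Q
#'   templates), `ref_breed`.
#' @export
simulate_breed_panel <- function(spec = default_panel_spec(), seed = 1) {
  set.seed(child_seed(seed, 61))
  pos <- seq(spec$region[1], spec$region[2] - 1, by = spec$snp_step)
  m <- length(pos)
  p0 <- runif(m, 0.05, 0.95)
  q_template <- rbinom(m, 1L, 0.5)
  in_q <- rep(FALSE, m)
  for (i in seq_len(nrow(spec$q_intervals)))
    in_q <- in_q | (pos >= spec$q_intervals$start[i] & pos < spec$q_intervals$end[i])
  qi_idx <- lapply(seq_len(nrow(spec$q_intervals)), function(i)
    which(pos >= spec$q_intervals$start[i] & pos < spec$q_intervals$end[i]))

  hap_rows <- list(); samp <- list(); r <- 0L
  for (b in seq_len(nrow(spec$breeds))) {
    br <- spec$breeds[b, ]
    for (i in seq_len(br$n)) {
      pair <- matrix(0L, 2L, m)
      for (ch in 1:2) {
        h <- rbinom(m, 1L, p0)
        for (qi in qi_idx) if (runif(1) < br$q_freq) h[qi] <- q_template[qi]
        pair[ch, ] <- h
      }
      r <- r + 1L
      hap_rows[[r]] <- pair
      samp[[r]] <- data.frame(sample = sprintf("%s_%02d", br$name, i),
                              breed = br$name, group = br$group,
                              stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, samp)
  gm <- geno_matrix(do.call(rbind, hap_rows), pos, chrom = "1",
                    samples = samples$sample, phased = TRUE)
  truth <- spec$q_intervals
  truth$q_template <- vapply(qi_idx, function(ix) paste(q_template[ix], collapse = ""), "")
  list(geno = gm, samples = samples, truth = truth, ref_breed = spec$ref_breed)
}
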