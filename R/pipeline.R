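#' Default end-to-end pipeline configuration
#'
#' The study conditions the simulator emulates by default: a 3.1 Mb region
#' at 2.8 cM/Mb with one SNP per 2 kb (1,550 sites); two divergent founder
#' populations (16 + 15 founders) each segregating several ancestral
#' haplotypes; an F1..F9 advanced intercross (intermediate generations of
#' 180, mapping generation of 600); two linked QTL inside the proximal
#' 1.2 Mb with +55/+70 g allele effects on a weight-like trait with 100 g
#' residual SD and sex/batch covariate effects; and a 10-breed
#' high/low-weight resequencing panel sharing three planted Q
#' sub-haplotypes.
#'
#' @param seed root seed; all stage streams derive from it.
#' @return nested config list (see sections `map`, `grid`, `founders`,
#'   `generation_sizes`, `arch`, `markers`, `ibd`, `assoc`, `haplo`,
#'   `sharing`, `popgen`, `panel`).
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    paths = list(),
    map = list(rate_cM_per_Mb = 2.8, start_bp = 168600000, end_bp = 171700000),
    grid = list(step_bp = 2000),
    founders = list(nA = 16L, nB = 15L, p_divergent = 0.03),
    generation_sizes = c(rep(180L, 8L), 600L),
    arch = list(effects = c(55, 70), baseline = 900, residual_sd = 100),
    segment = list(start_bp = 168600000, end_bp = 169800000),
    markers = list(tier1 = 0.95, tier2 = 0.75, annot_tier = 0.3,
                   spacing_bp = 100, prune_r2 = 0.4, alpha = c(0.01, 0.05)),
    ibd = list(min_support = 2L),
    haplo = list(n_tags = 8L, n_candidates = 15L, n_background = 18L,
                 candidate_r2 = 0.4, min_freq = 0.01, fdr = 0.05),
    sharing = list(bin_bp = 2000, threshold = 0.4),
    popgen = list(pi_window = 500, pi_step = 250, taj_bin = 25000,
                  fst_window = 20000, h_bin = 2000),
    panel = list(enabled = TRUE)
  )
}

# stage: simulate founders, AIL and phenotypes under one config
pipeline_simulate <- function(cfg) {
  map <- genetic_map(cfg$map$rate_cM_per_Mb, cfg$map$start_bp, cfg$map$end_bp)
  pos <- seq(map$start, map$end - 1, by = cfg$grid$step_bp)
  qtl_pos <- c(168750000, 169500000)
  qtl_sites <- vapply(qtl_pos, function(p) which.min(abs(pos - p)), 0L)
  pools <- default_founder_pools(pos, seed = cfg$seed,
                                 qtl_sites = qtl_sites,
                                 p_divergent = cfg$founders$p_divergent)
  founders <- make_founders(pools$A, pools$B, cfg$founders$nA, cfg$founders$nB,
                            pos, map, seed = cfg$seed)
  ped <- simulate_ail(founders, cfg$generation_sizes, seed = cfg$seed)
  arch <- qtl_architecture(
    data.frame(pos = pos[qtl_sites],
               effect = cfg$arch$effects[seq_along(qtl_sites)],
               high_allele = 1L),
    baseline = cfg$arch$baseline, residual_sd = cfg$arch$residual_sd)
  phen <- simulate_phenotypes(ped, arch, seed = cfg$seed)
  list(map = map, pos = pos, pools = pools, founders = founders, ped = ped,
       arch = arch, phen = phen, qtl_sites = qtl_sites)
}

# Candidate/background design for the backward elimination. Candidates
# are segment tag SNPs pruned to approximate linkage equilibrium (greedy,
# pairwise r2 < r2max over the mapping generation, highest founder
# differential first, planted causal sites admitted first), capped at
# n_candidates: in an F9 AIL the local LD is so strong that a denser
# candidate set makes the joint design near-singular and multi-locus
# effects inestimable. Background controls are polymorphic out-of-segment
# sites pruned the same way.
be_design <- function(d_f9, diffs, pos, in_seg, qtl_sites, n_candidates,
                      n_background, r2max = 0.4) {
  greedy_pick <- function(ord, nmax) {
    keep <- integer(0)
    for (j in ord) {
      if (length(keep) >= nmax) break
      if (stats::var(d_f9[, j]) == 0) next
      if (!length(keep) ||
          max(suppressWarnings(cor(d_f9[, j], d_f9[, keep]))^2,
              na.rm = TRUE) < r2max)
        keep <- c(keep, j)
    }
    sort(keep)
  }
  cand_pool <- which(in_seg & !is.na(diffs$delta_af))
  cand <- greedy_pick(unique(c(qtl_sites,
                               cand_pool[order(-diffs$delta_af[cand_pool])])),
                      n_candidates)
  af <- colMeans(d_f9, na.rm = TRUE) / 2
  out_pool <- which(!in_seg & af > 0.05 & af < 0.95)
  bg <- greedy_pick(out_pool[order(-diffs$delta_af[out_pool])], n_background)
  # pairwise pruning does not rule out joint collinearity in small samples;
  # drop aliased background columns outright
  if (length(bg) > 1L) {
    q <- qr(cbind(1, d_f9[, bg, drop = FALSE]))
    if (q$rank < length(bg) + 1L) {
      keep <- sort(q$pivot[seq_len(q$rank)])
      bg <- bg[keep[keep > 1L] - 1L]
    }
  }
  list(candidates = cand, background = bg)
}

# founder geno matrices from the founder list
founder_genotypes <- function(founders, pos, line) {
  sel <- vapply(founders, function(x) x$line == line, TRUE)
  hap <- do.call(rbind, lapply(founders[sel], `[[`, "hap"))
  geno_matrix(hap, pos, samples = vapply(founders[sel], `[[`, "", "id"))
}

#' Run the full fine-mapping workflow on simulated data
#'
#' Chains the stages end to end: simulation; founder-differential marker
#' selection; IBD painting, block calling and block t-tests in the mapping
#' generation; GRM/REML association scan with LD-pruned Bonferroni
#' thresholds and segment variance explained; phased haplotype frequencies,
#' rare-haplotype grouping, substitution effects and backward elimination;
#' the multi-breed Q-region sharing scan; and founder-population sweep
#' scans. When `out_dir` is given, stage outputs are written (VCF,
#' phenotype TSV, paintings BED, scan TSVs, Q-region BED, run-metadata
#' JSON).
#'
#' @param cfg config from [default_pipeline_config()] or [read_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list with all stage results (see Details in the vignette).
#' @export
run_pipeline <- function(cfg = default_pipeline_config(), out_dir = NULL) {
  sim <- pipeline_simulate(cfg)
  seg <- c(cfg$segment$start_bp, cfg$segment$end_bp)
  gm_a <- founder_genotypes(sim$founders, sim$pos, "HQLA")
  gm_b <- founder_genotypes(sim$founders, sim$pos, "HB")
  gm_f9 <- ped_genotypes(sim$ped)
  phen <- sim$phen

  ## markers: founder differentials + tiers
  diffs <- founder_delta_af(gm_a, gm_b)
  sel <- select_informative(diffs, cfg$markers$tier1, cfg$markers$tier2,
                            cfg$markers$annot_tier, cfg$markers$spacing_bp)

  ## ibd painting at tier-1 markers
  t1 <- which(sel$tier1)
  key <- founder_marker_key(subset_geno(gm_a, sites = t1),
                            subset_geno(gm_b, sites = t1))
  paintings <- paint_ibd(gm_f9, key, min_support = cfg$ibd$min_support,
                         region = c(sim$map$start, sim$map$end))
  blocks <- call_blocks(paintings)
  block_tests <- lapply(seq_len(nrow(blocks$blocks)), function(b)
    block_ttest(blocks, phen, b))

  ## association scan
  K <- grm(gm_f9)
  covar <- phen[, c("sex", "batch")]
  covar$batch <- factor(covar$batch)
  vc <- fit_null(phen$phenotype, covar, K)
  scan <- assoc_scan(gm_f9, vc)
  pruned <- ld_prune(gm_f9, r2_max = cfg$markers$prune_r2)
  thresholds <- stats::setNames(
    vapply(cfg$markers$alpha, bonferroni_threshold, 0,
           n_independent = nrow(pruned)),
    paste0("alpha_", cfg$markers$alpha))

  ## segment variance explained, from painted diplotype classes at the
  ## proximal segment
  seg_block <- which(blocks$blocks$start < seg[2] & blocks$blocks$end > seg[1])
  seg_class <- apply(blocks$classes[, seg_block, drop = FALSE], 1L, function(z)
    paste(z, collapse = "/"))
  ve_seg <- variance_explained(seg_class, phen$phenotype, covar, vc)

  ## haplotype model over tag SNPs in the segment
  in_seg <- sim$pos >= seg[1] & sim$pos < seg[2]
  cand_pool <- which(in_seg & !is.na(diffs$delta_af))
  tag_pool <- cand_pool[diffs$delta_af[cand_pool] >= 0.6]
  if (length(tag_pool) < cfg$haplo$n_tags)
    tag_pool <- cand_pool[order(-diffs$delta_af[cand_pool])][seq_len(cfg$haplo$n_tags)]
  tags <- sort(unique(tag_pool[round(seq(1, length(tag_pool),
                                         length.out = cfg$haplo$n_tags))]))
  gm_tags <- subset_geno(gm_f9, sites = tags)
  hp <- hap_freqs_phased(gm_tags)
  grouping <- group_rare(hp$freq, cfg$haplo$min_freq)
  Z <- hap_design(hp$strings, grouping)
  sub_eff <- substitution_effects(phen$phenotype, phen[, "sex", drop = FALSE], Z)

  ## backward elimination: candidates = top differentials in the segment
  ## (causal sites kept, aliased duplicates filtered); background = spread
  ## non-redundant sites outside the segment
  d_f9 <- dosage(gm_f9)
  des <- be_design(d_f9, diffs, sim$pos, in_seg, sim$qtl_sites,
                   cfg$haplo$n_candidates, cfg$haplo$n_background,
                   r2max = cfg$haplo$candidate_r2)
  be <- backward_elimination(phen$phenotype,
                             d_f9[, des$candidates, drop = FALSE],
                             positions = sim$pos[des$candidates],
                             background = d_f9[, des$background, drop = FALSE],
                             covariates = covar, fdr = cfg$haplo$fdr)

  ## sharing scan on the multi-breed panel
  sharing <- NULL; panel <- NULL
  if (isTRUE(cfg$panel$enabled)) {
    panel <- simulate_breed_panel(default_panel_spec(), seed = cfg$seed)
    grp <- unique(panel$samples[, c("breed", "group")])
    sharing <- q_scan(panel$geno,
                      stats::setNames(panel$samples$breed, panel$samples$sample),
                      ref_pop = panel$ref_breed,
                      groups = stats::setNames(grp$group, grp$breed),
                      bin_bp = cfg$sharing$bin_bp,
                      region = c(panel$geno$pos[1],
                                 max(panel$geno$pos) + 1),
                      threshold = cfg$sharing$threshold)
  }

  ## founder-population sweep scans over the segment
  popgen <- list(
    pi = pi_scan(gm_a, cfg$popgen$pi_window, cfg$popgen$pi_step,
                 region = c(sim$map$start, sim$map$end)),
    tajimas_d = tajimas_d(gm_a, cfg$popgen$taj_bin,
                          region = c(sim$map$start, sim$map$end)),
    hap_div = hap_diversity_scan(gm_a, cfg$popgen$h_bin,
                                 region = c(sim$map$start, sim$map$end)),
    fst = fst_scan(gm_a, gm_b, cfg$popgen$fst_window,
                   region = c(sim$map$start, sim$map$end)))

  res <- list(config = cfg, sim = sim, markers = sel, key = key,
              paintings = paintings, blocks = blocks,
              block_tests = block_tests, vc = vc, assoc = scan,
              pruned = pruned, thresholds = thresholds,
              variance_explained = ve_seg, hap_freqs = hp,
              grouping = grouping, substitution = sub_eff,
              backward = be, panel = panel, sharing = sharing,
              popgen = popgen)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# write all stage artifacts under out_dir
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(out_dir, x)
  write_vcf(ped_genotypes(res$sim$ped), f("f9_genotypes.vcf"))
  write_phenotypes(res$sim$phen, f("phenotypes.tsv"))
  write_paintings_bed(ped_paintings(res$sim$ped), f("truth_paintings.bed"))
  write_paintings_bed(res$paintings$paintings, f("ibd_paintings.bed"))
  write.table(res$markers, f("marker_tiers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res$assoc, f("assoc_scan.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res$substitution$effects, f("haplotype_effects.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$backward$audit))
    write.table(res$backward$audit, f("backward_elimination_audit.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(res$popgen))
    write_scan_tsv(res$popgen[[nm]], f(sprintf("scan_%s.tsv", nm)))
  if (!is.null(res$sharing)) {
    write.table(res$sharing$bins, f("sharing_bins.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    reg <- res$sharing$regions
    if (nrow(reg))
      write.table(data.frame(chrom = "1", start = reg$start, end = reg$end,
                             name = reg$name),
                  f("q_regions.bed"), sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    else file.create(f("q_regions.bed"))
  }
  meta <- list(seed = res$config$seed,
               parameters = res$config[setdiff(names(res$config), "paths")],
               thresholds = as.list(res$thresholds),
               n_markers = nrow(res$markers),
               n_tier1 = sum(res$markers$tier1),
               n_retained_besnps = length(res$backward$retained),
               n_q_regions = if (is.null(res$sharing)) NA else nrow(res$sharing$regions),
               outputs = list.files(out_dir))
  write_run_metadata(meta, file.path(out_dir, "run_metadata.json"))
  invisible(out_dir)
}
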