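# Reproducible simulation studies: parameter-recovery and calibration
# experiments built on the forward simulator. These define the package's
# reference study conditions (sample sizes, effect sizes, noise levels);
# the methods vignette discusses the choices.

# shared condition: F1..F9 sizes, mapping generation of 600
default_generation_sizes <- function() c(rep(180L, 8L), 600L)

#' Substitution-effect recovery study (one replicate)
#'
#' Simulates the default F9 study (600 individuals, 1,550 SNPs, two linked
#' QTL at +48/+62 g inside the proximal 1.2 Mb, 100 g residual SD), builds
#' the tag-SNP haplotype model (8 informative tags across the segment,
#' rare classes pooled into "Other") and estimates substitution effects.
#' The planted truth for each haplotype class is the realised mean
#' per-chromatid genetic contribution of its carriers, centred like the
#' estimates (sum-to-zero across classes).
#'
#' @param seed integer seed.
#' @param n_tags number of tag SNPs (default 8).
#' @return list `effects` (estimate table with `truth` and `within_2se`
#'   columns), `coverage` (fraction of estimates within 2 SE of truth),
#'   `n_classes`.
#' @export
study_effect_recovery <- function(seed, n_tags = 8L) {
  reg <- default_sim_region()
  pools <- default_founder_pools(reg$pos, seed = seed, qtl_sites = reg$qtl_sites)
  f <- make_founders(pools$A, pools$B, 16L, 15L, reg$pos, reg$map, seed = seed)
  ped <- simulate_ail(f, default_generation_sizes(), seed = seed)
  phen <- simulate_phenotypes(ped, reg$arch, seed = seed)
  gm <- ped_genotypes(ped)
  seg <- c(168600000, 169800000)
  gm_a <- founder_genotypes(f, reg$pos, "HQLA")
  gm_b <- founder_genotypes(f, reg$pos, "HB")
  diffs <- founder_delta_af(gm_a, gm_b)
  in_seg <- reg$pos >= seg[1] & reg$pos < seg[2]
  tag_pool <- which(in_seg & diffs$delta_af >= 0.6)
  tags <- sort(unique(tag_pool[round(seq(1, length(tag_pool),
                                         length.out = n_tags))]))
  hp <- hap_freqs_phased(subset_geno(gm, sites = tags))
  grouping <- group_rare(hp$freq, 0.01)
  Z <- hap_design(hp$strings, grouping)
  fit <- substitution_effects(phen$phenotype, phen[, "sex", drop = FALSE], Z)
  chrom_g <- gm$hap[, reg$qtl_sites, drop = FALSE] %*% reg$arch$loci$effect
  major <- setdiff(names(grouping$freq), "Other")
  lab <- ifelse(hp$strings %in% major, hp$strings, "Other")
  cls_mean <- tapply(as.vector(chrom_g), lab, mean)
  truth <- cls_mean - mean(cls_mean)
  eff <- fit$effects
  eff$truth <- truth[eff$haplotype]
  eff$within_2se <- abs(eff$effect - eff$truth) <= 2 * eff$se
  list(effects = eff, coverage = mean(eff$within_2se), n_classes = nrow(eff))
}

#' Variance-partition recovery study (one replicate)
#'
#' A planted segment QTL (+63 g, founder-divergent) in the 3.1 Mb focal
#' region contributes a designed 15% of the genetic variance; the remaining
#' 85% comes from 20 founder-divergent background loci on a second,
#' unlinked region dropped through the *same* pedigree (the "rest of the
#' genome"), with effects calibrated for the AIL's pedigree-induced
#' covariance between divergent loci. The study fits the GRM REML null on
#' all markers and recovers the segment fraction from the origin-diplotype
#' classes at the segment QTL.
#'
#' @param seed integer seed.
#' @param segment_effect segment QTL allele effect in grams (default 63).
#' @param background_effect per-locus background effect in grams (default
#'   16.2, calibrated so the planted segment share is 15%).
#' @return list `truth` (realised segment fraction of genetic variance),
#'   `recovered` (from [variance_explained()]), `Vg`, `Vg_true`.
#' @export
study_variance_partition <- function(seed, segment_effect = 63,
                                     background_effect = 16.2) {
  map1 <- genetic_map(2.8, 168600000, 171700000)
  pos1 <- seq(map1$start, map1$end - 1, by = 2000)
  qs <- which.min(abs(pos1 - 168750000))
  pools1 <- default_founder_pools(pos1, seed = seed, qtl_sites = integer())
  pools1$A$haps[, qs] <- 1L; pools1$B$haps[, qs] <- 0L
  f1 <- make_founders(pools1$A, pools1$B, 16L, 15L, pos1, map1, seed = seed)
  # background "rest of genome": 100 cM region so its 20 loci are only
  # pedigree-correlated, not tightly linked
  map2 <- genetic_map(50, 10000000, 12000000)
  pos2 <- seq(map2$start, map2$end - 1, by = 4000)
  qb <- round(seq(15, length(pos2) - 15, length.out = 20))
  pools2 <- default_founder_pools(pos2, seed = child_seed(seed, 77),
                                  qtl_sites = integer())
  pools2$A$haps[, qb] <- 1L; pools2$B$haps[, qb] <- 0L
  f2 <- make_founders(pools2$A, pools2$B, 16L, 15L, pos2, map2, seed = seed)
  finfo <- data.frame(id = vapply(f1, `[[`, "", "id"),
                      sex = vapply(f1, `[[`, "", "sex"),
                      line = vapply(f1, `[[`, "", "line"))
  st <- sample_pedigree_structure(finfo, default_generation_sizes(), seed = seed)
  ped1 <- drop_genomes(st, f1, seed = child_seed(seed, 1))
  ped2 <- drop_genomes(st, f2, seed = child_seed(seed, 2))
  gm1 <- ped_genotypes(ped1); gm2 <- ped_genotypes(ped2)
  d1 <- dosage(gm1)[, qs]; db <- dosage(gm2)[, qb, drop = FALSE]
  info <- ped_info(ped1)
  info <- info[info$generation == max(info$generation), ]
  set.seed(child_seed(seed, 3))
  g <- d1 * segment_effect +
    as.vector(db %*% rep(background_effect, ncol(db)))
  y <- 900 + g + c(M = 60, F = 0)[info$sex] + c(0, 20, -20)[info$batch] +
    rnorm(length(g), 0, 100)
  K <- grm(cbind(dosage(gm1), dosage(gm2)))
  covar <- data.frame(sex = info$sex, batch = factor(info$batch))
  vc <- fit_null(y, covar, K)
  cls <- c("BB", "AB", "AA")[d1 + 1]
  ve <- variance_explained(cls, y, covar, vc)
  list(truth = var(d1 * segment_effect) / var(g),
       recovered = ve$fraction_raw, Vg = vc$Vg, Vg_true = var(g))
}

# simulate the unlinked polygenic background region through a given
# pedigree structure: a long genetic map (100 cM) so its 20 divergent trait
# loci are only pedigree-correlated, not tightly linked
background_region <- function(finfo, structure_df, seed,
                              effect_per_locus = 16.2) {
  map2 <- genetic_map(50, 10000000, 12000000)
  pos2 <- seq(map2$start, map2$end - 1, by = 4000)
  qb <- round(seq(15, length(pos2) - 15, length.out = 20))
  pools2 <- default_founder_pools(pos2, seed = child_seed(seed, 77),
                                  qtl_sites = integer())
  pools2$A$haps[, qb] <- 1L; pools2$B$haps[, qb] <- 0L
  f2 <- make_founders(pools2$A, pools2$B, sum(finfo$line == "HQLA"),
                      sum(finfo$line == "HB"), pos2, map2, seed = seed)
  ped2 <- drop_genomes(structure_df, f2, seed = child_seed(seed, 78))
  gm2 <- ped_genotypes(ped2)
  db <- dosage(gm2)[, qb, drop = FALSE]
  list(gm = gm2, qtl_sites = qb, pos = pos2,
       g = as.vector(db %*% rep(effect_per_locus, ncol(db))))
}

#' Backward-elimination retention study (one replicate)
#'
#' Simulates the default F9 study (two linked QTL in the 1.2 Mb segment)
#' plus an unlinked polygenic background region dropped through the same
#' pedigree (emulating the genome outside the QTL), then runs the
#' multi-locus backward elimination: candidates are the segment tag SNPs
#' pruned to approximate linkage equilibrium (the causal sites among
#' them), and the always-retained background controls are 18 pruned
#' markers from the unlinked region, as in a design where background
#' markers are chosen genome-wide outside the QTL. With `null = TRUE` the
#' phenotype is permuted first, so every candidate is null.
#'
#' @param seed integer seed.
#' @param null permute the phenotype before elimination.
#' @return list `retained`, `causal_ids`, `causal_retained` (logical),
#'   `n_retained`.
#' @export
study_backward_elimination <- function(seed, null = FALSE) {
  cfg <- default_pipeline_config(seed = seed)
  sim <- pipeline_simulate(cfg)
  gm <- ped_genotypes(sim$ped)
  phen <- sim$phen
  finfo <- data.frame(id = vapply(sim$founders, `[[`, "", "id"),
                      sex = vapply(sim$founders, `[[`, "", "sex"),
                      line = vapply(sim$founders, `[[`, "", "line"))
  bg_reg <- background_region(finfo, sim$ped$structure, seed)
  y <- phen$phenotype + bg_reg$g - mean(bg_reg$g)
  if (null) {
    set.seed(child_seed(seed, 99))
    y <- sample(y)
  }
  gm_a <- founder_genotypes(sim$founders, sim$pos, "HQLA")
  gm_b <- founder_genotypes(sim$founders, sim$pos, "HB")
  diffs <- founder_delta_af(gm_a, gm_b)
  seg <- c(cfg$segment$start_bp, cfg$segment$end_bp)
  in_seg <- sim$pos >= seg[1] & sim$pos < seg[2]
  d <- dosage(gm)
  des <- be_design(d, diffs, sim$pos, in_seg, sim$qtl_sites,
                   cfg$haplo$n_candidates, 0L,
                   r2max = cfg$haplo$candidate_r2)
  # background controls from the unlinked region: the strongest background
  # signals (sites at/near its trait loci) pruned the same way
  db <- dosage(bg_reg$gm)
  bg <- integer(0)
  for (j in unique(c(bg_reg$qtl_sites, seq_len(ncol(db))))) {
    if (length(bg) >= cfg$haplo$n_background) break
    if (stats::var(db[, j]) == 0) next
    if (!length(bg) || max(suppressWarnings(cor(db[, j], db[, bg]))^2,
                           na.rm = TRUE) < cfg$haplo$candidate_r2)
      bg <- c(bg, j)
  }
  covar <- phen[, c("sex", "batch")]
  covar$batch <- factor(covar$batch)
  be <- backward_elimination(y, d[, des$candidates, drop = FALSE],
                             positions = sim$pos[des$candidates],
                             background = db[, sort(bg), drop = FALSE],
                             covariates = covar, fdr = cfg$haplo$fdr)
  causal_ids <- gm$ids[sim$qtl_sites]
  list(retained = be$retained, causal_ids = causal_ids,
       causal_retained = all(causal_ids %in% be$retained),
       n_retained = length(be$retained))
}

#' Independent-site genotypes for null calibration
#'
#' Chromatids drawn site-by-site from independent Bernoulli draws (allele
#' frequencies uniform on 0.1-0.9): no LD, no structure.
#'
#' @param n_samples,n_sites dimensions.
#' @param seed integer seed.
#' @return a `geno_matrix`.
#' @export
sim_unlinked_geno <- function(n_samples, n_sites, seed = 1) {
  set.seed(child_seed(seed, 71))
  p <- runif(n_sites, 0.1, 0.9)
  hap <- vapply(p, function(pp) rbinom(2L * n_samples, 1L, pp),
                integer(2L * n_samples))
  geno_matrix(hap, pos = seq(0L, by = 1000L, length.out = n_sites))
}

#' Null-calibration study for the association scan
#'
#' Unstructured genotypes ([sim_unlinked_geno()]) and a permuted (pure
#' noise) phenotype: reports the empirical type-I error of the mixed-model
#' scan at `alpha`, the genomic inflation factor, and the p-values for
#' distributional checks.
#'
#' @param seed integer seed.
#' @param n_samples,n_sites study size (defaults 400 x 500).
#' @param alpha nominal level (default 0.05).
#' @return list `type1`, `lambda`, `p`.
#' @export
study_null_scan <- function(seed, n_samples = 400L, n_sites = 500L,
                            alpha = 0.05) {
  gm <- sim_unlinked_geno(n_samples, n_sites, seed = seed)
  set.seed(child_seed(seed, 72))
  y <- rnorm(n_samples)
  covar <- data.frame(sex = rep_len(c("M", "F"), n_samples))
  vc <- fit_null(y, covar, grm(gm))
  scan <- assoc_scan(gm, vc)
  p <- scan$p[!is.na(scan$p)]
  list(type1 = mean(p < alpha), lambda = genomic_lambda(p), p = p)
}
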