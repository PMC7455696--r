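#' Genetic map for a simulated region
#'
#' Constant-rate map over one region. The genetic length in centimorgans is
#' `(end - start)/1e6 * rate`, the chicken chromosome-1 default being
#' 2.8 cM/Mb.
#'
#' @param rate_cM_per_Mb recombination rate (> 0, or 0 for a no-recombination
#'   control map).
#' @param start_bp,end_bp region bounds, 0-based half-open.
#' @return object of class `genetic_map`.
#' @export
genetic_map <- function(rate_cM_per_Mb = 2.8, start_bp = 168600000,
                        end_bp = 171700000) {
  if (rate_cM_per_Mb < 0) stop_input("map rate must be >= 0")
  if (end_bp <= start_bp) stop_input("end_bp must exceed start_bp")
  structure(list(rate = rate_cM_per_Mb, start = as.numeric(start_bp),
                 end = as.numeric(end_bp)), class = "genetic_map")
}

#' Genetic length of a map in centimorgans
#' @param map a `genetic_map`.
#' @return numeric, cM.
#' @export
genetic_length_cM <- function(map) (map$end - map$start) / 1e6 * map$rate

#' Founder haplotype pool
#'
#' A founder population is modelled as a pool of ancestral haplotypes with
#' sampling weights: each founder chromatid is an i.i.d. draw from the pool.
#' This is the "standing ancestral haplotypes" view of a closed outbred
#' stock: a handful of old haplotypes segregate, rather than every founder
#' being unique.
#'
#' @param label population label (e.g. `"HQLA"`, `"HB"`).
#' @param haps `k x m` 0/1 matrix of pool haplotypes over the SNP grid.
#' @param weights sampling probabilities, length k, summing to 1.
#' @return object of class `founder_pool`.
#' @export
founder_pool <- function(label, haps, weights = NULL) {
  haps <- as.matrix(haps)
  if (nrow(haps) < 1L) stop_input("empty haplotype pool")
  if (is.null(weights)) weights <- rep(1 / nrow(haps), nrow(haps))
  if (length(weights) != nrow(haps)) stop_input("one weight per pool haplotype")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop_input("weights must be in [0,1] and sum to 1")
  storage.mode(haps) <- "integer"
  structure(list(label = as.character(label), haps = haps, weights = weights),
            class = "founder_pool")
}

#' Default divergent founder pools
#'
#' Builds the two founder-population haplotype pools the simulator uses by
#' default: a fast-growing line ("HQLA"-like, 5 major + 25 rare ancestral
#' haplotypes) and a slow-growing line ("HB"-like, 3 major + 17 rare). A
#' fraction
#' `p_divergent` of grid sites is fixed for alternative alleles between the
#' pools (these become tier-1 informative markers, |dAF| = 1; the default density
#' reproduces a realistic count of near-fixed SNPs for a ~3 Mb region,
#' about 46); remaining
#' sites get per-pool allele frequencies drawn around a shared base so the
#' founder dAF spectrum is continuous. QTL sites, when given, are assigned
#' fixed allele patterns that segregate *within* each pool, so that each
#' founder line carries more than one haplotype effect class.
#'
#' @param pos SNP grid (0-based positions).
#' @param seed integer seed.
#' @param qtl_sites integer vector of site indices to receive QTL patterns
#'   (at most 2 patterned; extras are made pool-divergent).
#' @param p_divergent fraction of sites fixed between pools (default 0.03).
#' @param weights_a,weights_b pool sampling weights; the defaults give each
#'   line a few major ancestral haplotypes plus a geometric tail of rare
#'   ones (a realistic haplotype spectrum: tens of distinct haplotypes, a
#'   handful common).
#' @return list with `founder_pool` elements `A` and `B`.
#' @export
default_founder_pools <- function(pos, seed = 1, qtl_sites = integer(),
                                  p_divergent = 0.03,
                                  weights_a = pool_weights(
                                    c(0.25, 0.18, 0.13, 0.10, 0.06), 25L),
                                  weights_b = pool_weights(
                                    c(0.55, 0.14, 0.09), 17L)) {
  m <- length(pos)
  ka <- length(weights_a); kb <- length(weights_b)
  set.seed(child_seed(seed, 11))
  divergent <- runif(m) < p_divergent
  pA <- runif(m)
  pB <- pmin(1, pmax(0, pA + rnorm(m, 0, 0.35)))
  hapA <- matrix(0L, ka, m)
  hapB <- matrix(0L, kb, m)
  for (k in seq_len(ka)) hapA[k, ] <- rbinom(m, 1L, pA)
  for (k in seq_len(kb)) hapB[k, ] <- rbinom(m, 1L, pB)
  hapA[, divergent] <- 1L
  hapB[, divergent] <- 0L
  # QTL patterns: high allele common-but-not-fixed in pool A, rare in pool
  # B, so that both founder lines segregate several effect haplotypes
  if (length(qtl_sites) >= 1L) {
    s <- qtl_sites[1L]
    hapA[, s] <- as.integer(cumsum(weights_a) <= 0.85)
    hapB[, s] <- 0L
    hapB[min(2L, kb), s] <- 1L
  }
  # second locus segregates in both lines (the mapped region's haplotype
  # analysis supports effect haplotypes in both founder populations)
  if (length(qtl_sites) >= 2L) {
    s <- qtl_sites[2L]
    hapA[, s] <- 0L
    hapA[unique(c(1L, 2L, if (ka >= 6L) seq.int(6L, ka, by = 3L))), s] <- 1L
    hapB[, s] <- 0L
    hapB[unique(c(2L, 3L)[c(2L, 3L) <= kb]), s] <- 1L
  }
  if (length(qtl_sites) > 2L) {
    for (s in qtl_sites[-(1:2)]) { hapA[, s] <- 1L; hapB[, s] <- 0L }
  }
  list(A = founder_pool("HQLA", hapA, weights_a),
       B = founder_pool("HB", hapB, weights_b))
}

#' Pool weights: major haplotypes plus a geometric tail of rare ones
#'
#' @param major frequencies of the major haplotypes (sum < 1).
#' @param k_rare number of rare haplotypes sharing the remaining mass with
#'   geometrically decaying weights.
#' @param decay geometric decay rate of the tail (default 0.9).
#' @return weight vector of length `length(major) + k_rare` summing to 1.
#' @export
pool_weights <- function(major, k_rare, decay = 0.9) {
  rest <- 1 - sum(major)
  if (rest < 0) stop_input("major weights exceed 1")
  tail_w <- decay^seq_len(k_rare)
  c(major, rest * tail_w / sum(tail_w))
}

#' Multi-locus additive trait architecture
#'
#' @param loci data.frame with columns `pos` (0-based bp, must sit on the
#'   SNP grid), `effect` (grams per copy of the high allele) and
#'   `high_allele` (0 or 1, which allele carries the effect).
#' @param baseline intercept in grams.
#' @param sex_effect named vector, offsets in grams for `M`/`F`.
#' @param batch_effect numeric vector of per-batch offsets in grams.
#' @param residual_sd residual standard deviation in grams (>= 0).
#' @return object of class `qtl_architecture`.
#' @export
qtl_architecture <- function(loci, baseline = 900,
                             sex_effect = c(M = 60, F = 0),
                             batch_effect = c(0, 20, -20),
                             residual_sd = 100) {
  loci <- as.data.frame(loci)
  stopifnot(all(c("pos", "effect", "high_allele") %in% names(loci)))
  if (residual_sd < 0) stop_input("residual_sd must be >= 0")
  structure(list(loci = loci, baseline = baseline, sex_effect = sex_effect,
                 batch_effect = batch_effect, residual_sd = residual_sd),
            class = "qtl_architecture")
}

#' Default simulated region: SNP grid and trait architecture
#'
#' One SNP every 2 kb across 168.6-171.7 Mb (1,550 sites), with two linked
#' QTL inside the proximal 1.2 Mb (at ~168.75 and ~169.5 Mb) whose
#' per-allele effects (+55 g, +70 g) produce an F9 haplotype substitution
#' effect span of roughly -60 to +62 g around the mean on a trait with
#' 100 g residual SD.
#'
#' @param map a `genetic_map` (defaults to the 3.1 Mb, 2.8 cM/Mb region).
#' @param step_bp grid spacing (default 2000).
#' @return list with `pos` (grid), `map`, `qtl_sites` (grid indices) and
#'   `arch` (a `qtl_architecture`).
#' @export
default_sim_region <- function(map = genetic_map(), step_bp = 2000) {
  pos <- seq(map$start, map$end - 1, by = step_bp)
  qtl_sites <- vapply(c(168750000, 169500000), function(p) which.min(abs(pos - p)), 0L)
  if (map$start > 168600000 || map$end < 169600000) {
    qtl_sites <- unique(pmin(length(pos), c(ceiling(length(pos) * 0.1),
                                            ceiling(length(pos) * 0.3))))
  }
  arch <- qtl_architecture(data.frame(pos = pos[qtl_sites],
                                      effect = c(55, 70)[seq_along(qtl_sites)],
                                      high_allele = 1L))
  list(pos = pos, map = map, qtl_sites = qtl_sites, arch = arch)
}

#' Draw founder individuals from two haplotype pools
#'
#' Each founder receives two chromatids drawn i.i.d. from its pool by the
#' pool weights; its true origin painting is a single segment labelled with
#' the pool label. Sexes alternate within each line so both sexes are
#' available for the first intercross.
#'
#' @param poolA,poolB `founder_pool` objects over the same grid.
#' @param nA,nB founder counts (>= 1).
#' @param pos SNP grid the pools are defined over.
#' @param map `genetic_map` giving the region bounds for paintings.
#' @param seed integer seed.
#' @return list of founder individuals (class `ail_founders`), each with
#'   fields `id`, `generation`, `sex`, `batch`, `line`, `hap` (2 x m),
#'   `paint` (list of two painting data.frames).
#' @export
make_founders <- function(poolA, poolB, nA, nB, pos, map = genetic_map(), seed = 1) {
  if (ncol(poolA$haps) != length(pos) || ncol(poolB$haps) != length(pos))
    stop_input("pool haplotype length must match the SNP grid")
  if (nA < 1 || nB < 1) stop_input("need at least one founder per line")
  set.seed(child_seed(seed, 21))
  one_line <- function(pool, n, prefix) {
    lapply(seq_len(n), function(i) {
      k <- sample.int(nrow(pool$haps), 2L, replace = TRUE, prob = pool$weights)
      seg <- data.frame(start = map$start, end = map$end, origin = pool$label,
                        stringsAsFactors = FALSE)
      list(id = sprintf("F0_%s_%03d", prefix, i), generation = 0L,
           sire = NA_character_, dam = NA_character_,
           sex = if (i %% 2L == 1L) "M" else "F", batch = 1L,
           line = pool$label,
           hap = pool$haps[k, , drop = FALSE],
           paint = list(seg, seg))
    })
  }
  founders <- c(one_line(poolA, nA, "A"), one_line(poolB, nB, "B"))
  attr(founders, "pos") <- as.integer(pos)
  attr(founders, "map") <- map
  class(founders) <- "ail_founders"
  founders
}
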