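# Founder-origin painting of descendant chromatids from near-fixed
# informative markers, breakpoint/block calling, and per-block phenotype
# contrasts.

#' Founder allele key for informative markers
#'
#' For each tier-1 informative marker, records which allele (0/1) indicates
#' founder-line A origin, taken as the major allele among the A founders.
#'
#' @param gm_a,gm_b founder `geno_matrix` objects restricted to the
#'   informative markers.
#' @return data.frame `id`, `pos`, `allele_a`.
#' @export
founder_marker_key <- function(gm_a, gm_b) {
  fa <- allele_freq(gm_a)
  data.frame(id = gm_a$ids, pos = gm_a$pos,
             allele_a = as.integer(fa >= 0.5), stringsAsFactors = FALSE)
}

# Viterbi-style minimisation of origin switches over the two chromatids.
# obs: per-marker count of A-origin alleles (0/1/2/NA). States code the
# ordered origin pair (chromatid1, chromatid2): 1=AA, 2=BB, 3=AB, 4=BA.
# Returns a 2 x n_marker matrix of "A"/"B" (NA markers interpolated later).
paint_one <- function(obs) {
  state_orig <- rbind(c("A", "B", "A", "B"), c("A", "B", "B", "A"))
  allowed <- list(`0` = 2L, `1` = c(3L, 4L), `2` = 1L)
  sw <- matrix(0L, 4, 4)
  for (s in 1:4) for (t in 1:4)
    sw[s, t] <- sum(state_orig[, s] != state_orig[, t])
  mk <- which(!is.na(obs))
  if (!length(mk)) return(NULL)
  n <- length(mk)
  cost <- matrix(Inf, n, 4); back <- matrix(0L, n, 4)
  cost[1, allowed[[as.character(obs[mk[1]])]]] <- 0
  if (n > 1) for (i in 2:n) {
    for (t in allowed[[as.character(obs[mk[i]])]]) {
      tot <- cost[i - 1, ] + sw[, t]
      back[i, t] <- which.min(tot)  # ties: lowest state index, deterministic
      cost[i, t] <- tot[back[i, t]]
    }
  }
  path <- integer(n)
  path[n] <- which.min(cost[n, ])
  if (n > 1) for (i in (n - 1):1) path[i] <- back[i + 1, path[i + 1]]
  full <- matrix(NA_character_, 2, length(obs))
  full[, mk] <- state_orig[, path]
  full
}

# relabel origin runs shorter than min_support markers to the flanking
# consensus (only when both flanks agree, or at the sequence ends)
smooth_origins <- function(orig, min_support) {
  mk <- which(!is.na(orig))
  if (length(mk) < 2L || min_support <= 1L) return(orig)
  repeat {
    o <- orig[mk]
    r <- rle(o)
    if (length(r$lengths) <= 1L) break
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    changed <- FALSE
    for (j in seq_along(r$lengths)) {
      if (r$lengths[j] >= min_support) next
      left <- if (j > 1L) r$values[j - 1L] else NA
      right <- if (j < length(r$values)) r$values[j + 1L] else NA
      target <- if (is.na(left)) right
                else if (is.na(right)) left
                else if (left == right) left else NA
      if (!is.na(target) && (r$lengths[j] < min_support)) {
        # avoid flip-flop: only relabel if the neighbours are longer runs
        nb <- c(if (j > 1L) r$lengths[j - 1L], if (j < length(r$values)) r$lengths[j + 1L])
        if (max(nb) >= min_support) {
          orig[mk[starts[j]:ends[j]]] <- target
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  orig
}

# turn a per-marker origin vector into bp segments using the midpoint
# convention between flanking informative markers
origins_to_segments <- function(orig, pos, region) {
  mk <- which(!is.na(orig))
  if (!length(mk))
    return(data.frame(start = region[1], end = region[2], origin = "unknown",
                      stringsAsFactors = FALSE))
  o <- orig[mk]; p <- pos[mk]
  r <- rle(o)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  cuts <- if (length(r$lengths) > 1L)
    floor((p[ends_i[-length(ends_i)]] + p[starts_i[-1L]]) / 2) else numeric(0)
  data.frame(start = c(region[1], cuts), end = c(cuts, region[2]),
             origin = r$values, stringsAsFactors = FALSE)
}

#' Paint founder-line origin along chromatids
#'
#' Assigns each chromatid of each individual to founder line A or B at
#' every informative marker. Homozygous marker genotypes assign both
#' chromatids; heterozygous genotypes assign one chromatid to each line,
#' with the phase across markers resolved by minimising the total number of
#' origin switches (dynamic programming over the two phase choices per
#' heterozygous marker). Origin runs shorter than `min_support` markers are
#' relabelled to the flanking consensus as a genotyping-noise guard, and
#' markers with missing genotypes inherit the flanking origin. Breakpoints
#' are placed at the midpoint of the flanking marker interval.
#'
#' @param gm `geno_matrix` of the individuals at the informative markers
#'   (may be unphased).
#' @param key founder allele key from [founder_marker_key()], matched by
#'   position.
#' @param min_support minimum run length in markers (default 2).
#' @param region painting extent `c(start, end)` 0-based half-open
#'   (default: marker span padded to the marker grid).
#' @return object of class `ibd_paintings`: per individual a list of two
#'   segment data.frames (`start`, `end`, `origin`), plus the per-marker
#'   origin matrices used by [call_blocks()].
#' @export
paint_ibd <- function(gm, key, min_support = 2L, region = NULL) {
  ki <- match(key$pos, gm$pos)
  if (anyNA(ki)) stop_input("key markers missing from genotype matrix")
  sub <- subset_geno(gm, sites = ki)
  region <- region %||% c(min(sub$pos), max(sub$pos) + 1)
  d <- dosage(sub)
  a_count <- sweep(d, 2, key$allele_a, function(g, a) ifelse(a == 1L, g, 2 - g))
  res <- vector("list", n_samples(sub))
  orig1 <- orig2 <- matrix(NA_character_, n_samples(sub), n_sites(sub))
  for (i in seq_len(n_samples(sub))) {
    pm <- paint_one(a_count[i, ])
    if (is.null(pm)) {
      res[[i]] <- list(
        data.frame(start = region[1], end = region[2], origin = "unknown"),
        data.frame(start = region[1], end = region[2], origin = "unknown"))
      next
    }
    pm[1, ] <- smooth_origins(pm[1, ], min_support)
    pm[2, ] <- smooth_origins(pm[2, ], min_support)
    orig1[i, ] <- pm[1, ]; orig2[i, ] <- pm[2, ]
    res[[i]] <- list(origins_to_segments(pm[1, ], sub$pos, region),
                     origins_to_segments(pm[2, ], sub$pos, region))
  }
  structure(list(paintings = stats::setNames(res, sub$samples),
                 origin1 = orig1, origin2 = orig2,
                 marker_pos = sub$pos, samples = sub$samples, region = region),
            class = "ibd_paintings")
}

#' Call recombination blocks from a set of paintings
#'
#' Breakpoints are the union over chromatids of observed origin-switch
#' intervals (midpoint convention); the blocks they delimit partition the
#' region. Each individual gets a per-block diplotype class (`AA`, `AB`,
#' `BB`, or `NA` when unknown) and an unrecombined/recombinant flag
#' (unrecombined = no switch on either chromatid).
#'
#' @param paintings an `ibd_paintings` from [paint_ibd()].
#' @return object of class `block_set`: `breakpoints`, `blocks`
#'   (data.frame `start`, `end`), `classes` (individuals x blocks),
#'   `recombinant` (logical), `samples`.
#' @export
call_blocks <- function(paintings) {
  p <- paintings
  cuts <- sort(unique(unlist(lapply(p$paintings, function(pr)
    c(pr[[1]]$start[-1], pr[[2]]$start[-1])))))
  bounds <- c(p$region[1], cuts, p$region[2])
  blocks <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  nb <- nrow(blocks)
  cls <- matrix(NA_character_, length(p$paintings), nb,
                dimnames = list(p$samples, NULL))
  origin_at <- function(segs, x) {
    j <- which(segs$start <= x & segs$end > x)
    if (length(j)) segs$origin[j[1]] else "unknown"
  }
  mid <- (blocks$start + blocks$end) / 2
  for (i in seq_along(p$paintings)) {
    o1 <- vapply(mid, function(x) origin_at(p$paintings[[i]][[1]], x), "")
    o2 <- vapply(mid, function(x) origin_at(p$paintings[[i]][[2]], x), "")
    known <- o1 %in% c("A", "B") & o2 %in% c("A", "B")
    cl <- ifelse(o1 == o2, paste0(o1, o2),
                 "AB")  # unordered heterozygous class
    cl[o1 == "B" & o2 == "B"] <- "BB"
    cl[!known] <- NA_character_
    cls[i, ] <- cl
  }
  recomb <- vapply(p$paintings, function(pr)
    nrow(pr[[1]]) > 1L || nrow(pr[[2]]) > 1L, TRUE)
  structure(list(breakpoints = cuts, blocks = blocks, classes = cls,
                 recombinant = unname(recomb), samples = p$samples,
                 paintings = p),
            class = "block_set")
}

#' Per-block phenotype contrast between founder-origin chromatids
#'
#' Welch unpaired t-test of the phenotype between chromatids of A-origin
#' and B-origin within one block (each chromatid contributes its carrier's
#' phenotype), plus a three-genotype-class summary (mean, SD, n per
#' AA/AB/BB diplotype).
#'
#' @param blockset a `block_set` from [call_blocks()].
#' @param phenotype data.frame with columns `id` and `phenotype`.
#' @param block block index.
#' @param individuals `"recombinant"` (default: only individuals carrying a
#'   recombinant chromosome, the classical design) or `"all"`.
#' @return list `p`, `t`, `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `class_summary`; `p` is `NA` with `reason` when a group has < 2
#'   chromatids.
#' @export
block_ttest <- function(blockset, phenotype, block,
                        individuals = c("recombinant", "all")) {
  individuals <- match.arg(individuals)
  use <- if (individuals == "recombinant") blockset$recombinant
         else rep(TRUE, length(blockset$samples))
  ids <- blockset$samples[use]
  y <- phenotype$phenotype[match(ids, phenotype$id)]
  cl <- blockset$classes[use, block]
  # chromatid-level origin groups: AA -> 2 A, AB -> 1 A + 1 B, BB -> 2 B
  n_a_chr <- c(AA = 2L, AB = 1L, BB = 0L)[cl]
  ya <- rep(y, times = ifelse(is.na(n_a_chr), 0L, n_a_chr))
  yb <- rep(y, times = ifelse(is.na(n_a_chr), 0L, 2L - n_a_chr))
  summ <- do.call(rbind, lapply(c("AA", "AB", "BB"), function(g) {
    yy <- y[!is.na(cl) & cl == g]
    data.frame(class = g, n = length(yy),
               mean = if (length(yy)) mean(yy) else NA_real_,
               sd = if (length(yy) > 1) sd(yy) else NA_real_)
  }))
  if (length(ya) < 2L || length(yb) < 2L)
    return(list(p = NA_real_, t = NA_real_, mean_a = mean(ya), mean_b = mean(yb),
                n_a = length(ya), n_b = length(yb), class_summary = summ,
                reason = "fewer than 2 chromatids in a group"))
  tt <- t.test(ya, yb)  # Welch by default
  list(p = tt$p.value, t = unname(tt$statistic),
       mean_a = mean(ya), mean_b = mean(yb),
       n_a = length(ya), n_b = length(yb), class_summary = summ)
}
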