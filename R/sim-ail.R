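# Forward simulation of an advanced intercross line: gamete formation with
# Poisson crossovers (no interference), pedigree structure by random
# non-self mating, and true founder-origin paintings carried through.

# cut a painting data.frame to [s, e)
slice_painting <- function(paint, s, e) {
  keep <- paint$end > s & paint$start < e
  p <- paint[keep, , drop = FALSE]
  if (nrow(p)) {
    p$start[1L] <- max(p$start[1L], s)
    p$end[nrow(p)] <- min(p$end[nrow(p)], e)
  }
  p
}

# merge consecutive segments with identical origin
merge_painting <- function(paint) {
  if (nrow(paint) <= 1L) return(paint)
  new_run <- c(TRUE, paint$origin[-1L] != paint$origin[-nrow(paint)])
  grp <- cumsum(new_run)
  data.frame(start = tapply(paint$start, grp, min),
             end = tapply(paint$end, grp, max),
             origin = paint$origin[new_run],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate one meiosis
#'
#' Crossover count is Poisson with mean equal to the map length in Morgans;
#' crossover positions are uniform on the region (no interference). The
#' gamete alternates between the two parental chromatids at the crossovers,
#' and the true origin painting is spliced accordingly.
#'
#' @param parent an individual (as produced by [make_founders()] or
#'   [simulate_ail()]) with fields `hap` (2 x m) and `paint`.
#' @param map a `genetic_map`.
#' @param pos SNP grid positions.
#' @return list with `hap` (allele vector) and `paint` (painting
#'   data.frame). Consumes the current RNG stream.
#' @export
meiosis <- function(parent, map, pos) {
  if (map$end <= map$start) stop_input("zero-length region")
  n_cross <- rpois(1L, genetic_length_cM(map) / 100)
  first <- sample.int(2L, 1L)
  if (n_cross == 0L) {
    return(list(hap = parent$hap[first, ], paint = parent$paint[[first]]))
  }
  cuts <- sort(runif(n_cross, map$start, map$end))
  src <- ((findInterval(pos, cuts) + first - 1L) %% 2L) + 1L
  hap <- ifelse(src == 1L, parent$hap[1L, ], parent$hap[2L, ])
  bounds <- c(map$start, cuts, map$end)
  pieces <- lapply(seq_len(length(bounds) - 1L), function(j) {
    k <- ((j + first - 2L) %% 2L) + 1L
    slice_painting(parent$paint[[k]], bounds[j], bounds[j + 1L])
  })
  list(hap = as.integer(hap), paint = merge_painting(do.call(rbind, pieces)))
}

#' Sample the mating structure of an AIL pedigree
#'
#' Generation 1 is produced by interline crosses (one parent from each
#' founder line); later generations by random non-self mating (sire drawn
#' from the previous generation's males, dam from its females, with
#' replacement). Sexes alternate within each generation so the ratio is
#' enforced at creation; batches are assigned uniformly at random.
#'
#' @param founder_info data.frame with columns `id`, `sex`, `line` for the
#'   F0 individuals.
#' @param generation_sizes integer vector of offspring counts for F1, F2, ...
#' @param seed integer seed.
#' @param n_batches number of rearing batches (default 3).
#' @return data.frame with one row per non-founder individual: `id`,
#'   `generation`, `sire`, `dam`, `sex`, `batch`.
#' @export
sample_pedigree_structure <- function(founder_info, generation_sizes, seed = 1,
                                      n_batches = 3L) {
  if (!length(generation_sizes)) stop_input("generation_sizes must be non-empty")
  set.seed(child_seed(seed, 31))
  prev <- founder_info
  out <- list()
  for (g in seq_along(generation_sizes)) {
    n <- generation_sizes[g]
    if (g == 1L) {
      for (ln in unique(founder_info$line)) {
        sub <- founder_info[founder_info$line == ln, ]
        if (!any(sub$sex == "M") || !any(sub$sex == "F"))
          stop_input("each founder line needs both sexes for the interline cross")
      }
    } else {
      if (sum(prev$sex == "M") < 2L || sum(prev$sex == "F") < 2L)
        stop_input(sprintf("generation %d has fewer than 2 individuals of one sex", g - 1L))
    }
    sire <- dam <- character(n)
    if (g == 1L) {
      lines <- unique(founder_info$line)
      if (length(lines) != 2L) stop_input("interline F1 needs exactly two founder lines")
      for (i in seq_len(n)) {
        dir <- sample.int(2L, 1L)
        msel <- founder_info$line == lines[dir] & founder_info$sex == "M"
        fsel <- founder_info$line == lines[3L - dir] & founder_info$sex == "F"
        sire[i] <- sample(founder_info$id[msel], 1L)
        dam[i] <- sample(founder_info$id[fsel], 1L)
      }
    } else {
      males <- prev$id[prev$sex == "M"]
      females <- prev$id[prev$sex == "F"]
      sire <- sample(males, n, replace = TRUE)
      dam <- sample(females, n, replace = TRUE)
    }
    gen <- data.frame(id = sprintf("F%d_%03d", g, seq_len(n)),
                      generation = g, sire = sire, dam = dam,
                      sex = rep_len(c("M", "F"), n),
                      batch = sample.int(n_batches, n, replace = TRUE),
                      stringsAsFactors = FALSE)
    out[[g]] <- gen
    prev <- gen
  }
  do.call(rbind, out)
}

#' Drop genomes through a fixed pedigree structure
#'
#' Runs gamete formation ([meiosis()]) for every individual of a pedigree
#' structure, for one genomic region. Separating structure from gene-drop
#' lets several unlinked regions be simulated through the *same* pedigree.
#'
#' @param structure_df data.frame from [sample_pedigree_structure()].
#' @param founders `ail_founders` for this region.
#' @param seed integer seed for the gamete stream.
#' @return an `ail_pedigree` (see [simulate_ail()]).
#' @export
drop_genomes <- function(structure_df, founders, seed = 1) {
  pos <- attr(founders, "pos"); map <- attr(founders, "map")
  set.seed(child_seed(seed, 41))
  inds <- stats::setNames(founders, vapply(founders, `[[`, "", "id"))
  for (i in seq_len(nrow(structure_df))) {
    row <- structure_df[i, ]
    gs <- meiosis(inds[[row$sire]], map, pos)
    gd <- meiosis(inds[[row$dam]], map, pos)
    inds[[row$id]] <- list(id = row$id, generation = row$generation,
                           sire = row$sire, dam = row$dam, sex = row$sex,
                           batch = row$batch, line = NA_character_,
                           hap = rbind(gs$hap, gd$hap),
                           paint = list(gs$paint, gd$paint))
  }
  gens <- split(names(inds), vapply(inds, `[[`, 0L, "generation"))
  structure(list(individuals = inds, generations = gens, pos = pos, map = map,
                 chrom = "1", structure = structure_df),
            class = "ail_pedigree")
}

#' Simulate an advanced intercross line
#'
#' Interline F1 followed by random-mating F2+ generations, carrying phased
#' haplotypes and true founder-origin paintings for every individual.
#' Reproducible: the same seed gives a byte-identical pedigree.
#'
#' @param founders `ail_founders` from [make_founders()].
#' @param generation_sizes offspring counts for F1, F2, ... (last entry is
#'   the mapping generation).
#' @param seed integer root seed (structure and gametes use derived child
#'   seeds).
#' @param n_batches rearing batches for the covariate model.
#' @return an `ail_pedigree`: list with `individuals` (named list),
#'   `generations` (ids per generation), `pos`, `map`.
#' @export
simulate_ail <- function(founders, generation_sizes, seed = 1, n_batches = 3L) {
  finfo <- data.frame(id = vapply(founders, `[[`, "", "id"),
                      sex = vapply(founders, `[[`, "", "sex"),
                      line = vapply(founders, `[[`, "", "line"),
                      stringsAsFactors = FALSE)
  structure_df <- sample_pedigree_structure(finfo, generation_sizes,
                                            seed = child_seed(seed, 1),
                                            n_batches = n_batches)
  drop_genomes(structure_df, founders, seed = child_seed(seed, 2))
}

#' Pedigree accessors
#'
#' `ped_info()` returns one row per individual; `ped_genotypes()` builds a
#' phased [geno_matrix()] for one generation; `ped_paintings()` returns the
#' true origin paintings for one generation.
#'
#' @param ped an `ail_pedigree`.
#' @param generation generation number (default: last).
#' @return see description.
#' @export
ped_info <- function(ped) {
  inds <- ped$individuals
  data.frame(id = vapply(inds, `[[`, "", "id"),
             generation = vapply(inds, `[[`, 0L, "generation"),
             sire = vapply(inds, function(x) x$sire %||% NA_character_, ""),
             dam = vapply(inds, function(x) x$dam %||% NA_character_, ""),
             sex = vapply(inds, `[[`, "", "sex"),
             batch = vapply(inds, `[[`, 0L, "batch"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname ped_info
#' @export
ped_genotypes <- function(ped, generation = NULL) {
  generation <- generation %||% max(as.integer(names(ped$generations)))
  ids <- ped$generations[[as.character(generation)]]
  hap <- do.call(rbind, lapply(ids, function(i) ped$individuals[[i]]$hap))
  geno_matrix(hap, ped$pos, ped$chrom, samples = ids, phased = TRUE)
}

#' @rdname ped_info
#' @export
ped_paintings <- function(ped, generation = NULL) {
  generation <- generation %||% max(as.integer(names(ped$generations)))
  ids <- ped$generations[[as.character(generation)]]
  stats::setNames(lapply(ids, function(i) ped$individuals[[i]]$paint), ids)
}

#' Simulate phenotypes under an additive architecture
#'
#' Phenotype = baseline + sum over QTL of (high-allele dosage x effect) +
#' sex offset + batch offset + Normal(0, residual_sd) noise.
#'
#' @param ped an `ail_pedigree`.
#' @param arch a `qtl_architecture`; all loci must sit on the SNP grid.
#' @param seed integer seed for the residuals.
#' @param generation which generation to phenotype (default: last).
#' @return data.frame `id`, `generation`, `sex`, `batch`, `genetic_value`,
#'   `phenotype`.
#' @export
simulate_phenotypes <- function(ped, arch, seed = 1, generation = NULL) {
  generation <- generation %||% max(as.integer(names(ped$generations)))
  gm <- ped_genotypes(ped, generation)
  li <- match(arch$loci$pos, ped$pos)
  if (anyNA(li)) stop_input("QTL position off the SNP grid: ",
                            paste(arch$loci$pos[is.na(li)], collapse = ", "))
  d <- dosage(gm)[, li, drop = FALSE]
  high <- matrix(rep(arch$loci$high_allele, each = nrow(d)), nrow = nrow(d))
  d_high <- ifelse(high == 1L, d, 2 - d)
  g <- as.vector(d_high %*% arch$loci$effect)
  info <- ped_info(ped)
  info <- info[match(gm$samples, info$id), ]
  set.seed(child_seed(seed, 51))
  y <- arch$baseline + g + arch$sex_effect[info$sex] +
    arch$batch_effect[info$batch] + rnorm(length(g), 0, arch$residual_sd)
  data.frame(id = info$id, generation = info$generation, sex = info$sex,
             batch = info$batch, genetic_value = g, phenotype = as.numeric(y),
             row.names = NULL, stringsAsFactors = FALSE)
}
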