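#' Genotype matrix container
#'
#' A light container for diploid genotypes over a set of biallelic sites.
#' Haplotypes are stored as a `2n x m` integer matrix of 0/1 alleles
#' (`NA` = missing call), two consecutive rows per sample. Positions are
#' 0-based internally; VCF/TSV writers emit 1-based coordinates and BED
#' writers emit 0-based half-open intervals.
#'
#' @param hap integer matrix, `2n x m`, entries 0/1/`NA`.
#' @param pos integer vector of 0-based site positions, strictly increasing.
#' @param chrom chromosome name (single string).
#' @param samples character vector of n sample ids (default `S001`...).
#' @param phased logical; `FALSE` means the two rows per sample carry no
#'   phase information (dosages are still valid).
#' @param ids site ids (default `<chrom>_<1-based pos>`).
#' @param ref,alt reference/alternate allele letters used when writing VCF.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(hap, pos, chrom = "1", samples = NULL, phased = TRUE,
                        ids = NULL, ref = NULL, alt = NULL) {
  hap <- as.matrix(hap)
  if (nrow(hap) %% 2L != 0L) stop_input("hap must have an even number of rows (2 per sample)")
  if (ncol(hap) != length(pos)) stop_input("ncol(hap) must equal length(pos)")
  if (length(pos) && any(diff(pos) <= 0)) stop_input("pos must be strictly increasing")
  bad <- hap[!is.na(hap)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) stop_input("alleles must be 0/1/NA")
  n <- nrow(hap) / 2L
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(n))
  if (length(samples) != n) stop_input("length(samples) must equal nrow(hap)/2")
  if (is.null(ids)) ids <- sprintf("%s_%d", chrom, as.integer(pos) + 1L)
  storage.mode(hap) <- "integer"
  if (n > 0L) rownames(hap) <- paste0(rep(samples, each = 2L), c("_1", "_2"))
  structure(list(hap = hap, pos = as.integer(pos), chrom = as.character(chrom)[1L],
                 samples = as.character(samples), phased = isTRUE(phased),
                 ids = as.character(ids),
                 ref = ref %||% rep("A", length(pos)),
                 alt = alt %||% rep("G", length(pos))),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d sites on %s [%s], %s\n",
              n_samples(x), n_sites(x), x$chrom,
              if (n_sites(x)) sprintf("%d-%d", min(x$pos), max(x$pos)) else "empty",
              if (x$phased) "phased" else "unphased"))
  invisible(x)
}

#' Number of samples / sites in a `geno_matrix`
#' @param gm a `geno_matrix`.
#' @return integer count.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_sites <- function(gm) length(gm$pos)

#' Diploid dosage matrix
#'
#' Sums the two chromatid alleles per sample: an `n x m` matrix of 0/1/2
#' alternate-allele counts (`NA` when either chromatid is missing).
#'
#' @param gm a `geno_matrix`.
#' @return numeric matrix with samples as rows.
#' @export
dosage <- function(gm) {
  h <- gm$hap
  d <- h[seq(1L, nrow(h), by = 2L), , drop = FALSE] +
       h[seq(2L, nrow(h), by = 2L), , drop = FALSE]
  rownames(d) <- gm$samples
  colnames(d) <- gm$ids
  d
}

#' Subset a `geno_matrix` by sites or samples
#'
#' @param gm a `geno_matrix`.
#' @param sites integer/logical index over sites, or `NULL`.
#' @param region length-2 numeric `c(start, end)` 0-based half-open; applied
#'   after `sites`.
#' @param samples character/integer/logical index over samples, or `NULL`.
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(gm, sites = NULL, region = NULL, samples = NULL) {
  si <- seq_along(gm$pos)
  if (!is.null(sites)) si <- si[sites]
  if (!is.null(region)) si <- si[gm$pos[si] >= region[1] & gm$pos[si] < region[2]]
  keep_s <- seq_along(gm$samples)
  if (!is.null(samples)) {
    keep_s <- if (is.character(samples)) match(samples, gm$samples) else keep_s[samples]
    if (anyNA(keep_s)) stop_input("unknown sample id in subset")
  }
  rows <- as.vector(rbind(2L * keep_s - 1L, 2L * keep_s))
  geno_matrix(gm$hap[rows, si, drop = FALSE], gm$pos[si], gm$chrom,
              gm$samples[keep_s], gm$phased, gm$ids[si], gm$ref[si], gm$alt[si])
}

# per-site allele summaries over non-missing chromatids
site_counts <- function(gm) {
  h <- gm$hap
  nn <- colSums(!is.na(h))
  c1 <- colSums(h, na.rm = TRUE)
  list(n = nn, c1 = c1, freq = ifelse(nn > 0, c1 / nn, NA_real_))
}

#' Alternate-allele frequencies per site
#' @param gm a `geno_matrix`.
#' @return numeric vector over sites (`NA` where all calls missing).
#' @export
allele_freq <- function(gm) site_counts(gm)$freq
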