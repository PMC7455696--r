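# Format I/O: VCF via vcfR, TSV/BED writers, YAML configuration and JSON
# run metadata. Coordinate conventions: VCF and TSV positions are 1-based
# inclusive; BED output is 0-based half-open; geno_matrix positions are
# 0-based internally.

#' Read genotypes from a VCF file
#'
#' Loads GT fields into a [geno_matrix()]. 1-based POS is mapped to the
#' internal 0-based coordinate; missing genotypes are preserved as `NA`;
#' multi-allelic records are skipped with a message (default) or an error
#' per `multiallelic`. The phased flag is `TRUE` only when every call uses
#' the `|` separator; mixed separators give an unphased matrix with a
#' warning.
#'
#' @param path VCF file (optionally bgzipped).
#' @param region optional `c(start, end)` filter, 0-based half-open.
#' @param multiallelic `"skip"` (default) or `"error"`.
#' @return a `geno_matrix` (possibly with zero sites).
#' @export
read_vcf <- function(path, region = NULL, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop_input("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix))
    return(geno_matrix(matrix(integer(), 0L, 0L), integer(), samples = character()))
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    if (multiallelic == "error") stop_input(sum(multi), " multi-allelic records")
    log_info(sprintf("skipping %d multi-allelic records", sum(multi)))
  }
  keep <- !multi
  pos0 <- as.integer(fix$POS) - 1L
  if (!is.null(region)) keep <- keep & pos0 >= region[1] & pos0 < region[2]
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  pos0 <- pos0[keep]
  samples <- colnames(gt)
  if (!nrow(gt))
    return(geno_matrix(matrix(integer(), 2L * length(samples), 0L),
                       integer(), samples = samples))
  sep_bar <- grepl("|", gt, fixed = TRUE)
  sep_slash <- grepl("/", gt, fixed = TRUE)
  phased <- all(sep_bar | is.na(gt))
  if (!phased && any(sep_bar & !is.na(gt)) && any(sep_slash & !is.na(gt)))
    warning("mixed phased/unphased records; phased flag set to FALSE")
  parse_allele <- function(k) {
    a <- sub(if (k == 1L) "^([^/|]*)[/|].*$" else "^[^/|]*[/|](.*)$", "\\1", gt)
    a[a %in% c(".", "")] <- NA
    suppressWarnings(matrix(as.integer(a), nrow = nrow(gt)))
  }
  a1 <- parse_allele(1L); a2 <- parse_allele(2L)
  if (any(c(a1, a2) > 1L, na.rm = TRUE)) stop_input("non-biallelic allele index in GT")
  hap <- matrix(NA_integer_, 2L * length(samples), nrow(gt))
  for (s in seq_along(samples)) {
    hap[2L * s - 1L, ] <- a1[, s]
    hap[2L * s, ] <- a2[, s]
  }
  ord <- order(pos0)
  geno_matrix(hap[, ord, drop = FALSE], pos0[ord],
              chrom = fix$CHROM[keep][ord][1L] %||% "1", samples = samples,
              phased = phased, ids = fix$ID[keep][ord],
              ref = fix$REF[keep][ord], alt = fix$ALT[keep][ord])
}

#' Write a `geno_matrix` to VCF (v4.2, GT only)
#'
#' Phased matrices use the `|` separator, unphased `/`; missing alleles are
#' written as `.`. Internal 0-based positions become 1-based POS.
#'
#' @param gm a `geno_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sep <- if (gm$phased) "|" else "/"
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", gm$chrom),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  if (n_sites(gm)) {
    h <- gm$hap
    h[is.na(h)] <- "."
    o <- seq(1L, nrow(h), by = 2L)
    gtcol <- matrix(paste(h[o, , drop = FALSE], h[o + 1L, , drop = FALSE],
                          sep = sep), nrow = length(o))
    lines <- vapply(seq_len(n_sites(gm)), function(j)
      paste(c(gm$chrom, gm$pos[j] + 1L, gm$ids[j], gm$ref[j], gm$alt[j], ".",
              "PASS", ".", "GT", gtcol[, j]), collapse = "\t"), "")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a windowed scan as TSV (1-based inclusive coordinates)
#'
#' @param scan data.frame from [pi_scan()], [tajimas_d()], [fst_scan()],
#'   [hap_diversity_scan()] or [xpehh_scan()] (internal 0-based half-open
#'   `start`/`end`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  out <- scan
  out$start <- out$start + 1L  # 1-based inclusive
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write origin paintings as BED-like TSV
#'
#' 0-based half-open intervals, one row per segment, names suffixed with
#' the chromatid index (`_1`/`_2`).
#'
#' @param paintings named list (id -> list of two painting data.frames), as
#'   from [ped_paintings()] or `paint_ibd()$paintings`.
#' @param path output path.
#' @param chrom chromosome label.
#' @return `path`, invisibly.
#' @export
write_paintings_bed <- function(paintings, path, chrom = "1") {
  rows <- list()
  for (id in names(paintings)) {
    for (k in 1:2) {
      p <- paintings[[id]][[k]]
      rows[[paste(id, k)]] <- data.frame(chrom = chrom,
                                         start = format(p$start, scientific = FALSE, trim = TRUE),
                                         end = format(p$end, scientific = FALSE, trim = TRUE),
                                         name = sprintf("%s_%d", id, k),
                                         origin = p$origin)
    }
  }
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Phenotype/covariate table I/O
#'
#' Plain TSV with header: `id`, `sex`, `batch`, `generation`, trait
#' columns.
#'
#' @param x data.frame (for writing).
#' @param path file path.
#' @return the data.frame (read) or `path` invisibly (write).
#' @export
write_phenotypes <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a pipeline configuration from YAML
#'
#' Fills missing entries from [default_pipeline_config()] and validates
#' parameter ranges and referenced paths.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("no such config: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_pipeline_config(), user)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$map$rate_cM_per_Mb >= 0,
            cfg$map$end_bp > cfg$map$start_bp,
            cfg$generation_sizes == floor(cfg$generation_sizes),
            all(cfg$generation_sizes >= 2),
            cfg$markers$tier1 >= cfg$markers$tier2,
            cfg$sharing$threshold > 0, cfg$sharing$threshold <= 1,
            cfg$haplo$fdr > 0, cfg$haplo$fdr < 1)
  for (p in cfg$paths) if (!is.null(p) && !file.exists(p))
    stop_input("configured path does not exist: ", p)
  invisible(cfg)
}

#' Write run metadata JSON
#'
#' Records the stage parameters, seed and output file list of a pipeline
#' run.
#'
#' @param meta named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
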