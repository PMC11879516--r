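# Plain-text readers and writers for the package's data interchange
# formats: genotype dosages in a PLINK .raw-style layout, a SNP map, GWAS
# summary statistics, long-format ESM tables, YAML configs and JSON/TSV
# report bundles.

#' Write / read genotype dosages in PLINK .raw-style text
#'
#' Tab-delimited with header `FID IID <snp>_<a1> ...`; one row per subject,
#' dosages count the `a1` allele.
#'
#' @param geno `genotype_matrix`.
#' @param path output file.
#' @export
write_genotypes_raw <- function(geno, path) {
  hdr <- paste0(geno$map$snp, "_", geno$map$a1)
  df <- data.frame(FID = rownames(geno$dosages), IID = rownames(geno$dosages),
                   geno$dosages, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("FID", "IID", hdr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param path file written by [write_genotypes_raw()] (or PLINK
#'   `--recode A`).
#' @param map SNP map data frame; if `NULL`, a minimal map is reconstructed
#'   from the header (counted allele only).
#' @rdname write_genotypes_raw
#' @export
read_genotypes_raw <- function(path, map = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  # tolerate the full PLINK .raw header (PAT/MAT/SEX/PHENOTYPE)
  drop <- intersect(c("FID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(df))
  ids <- df$IID
  snp_cols <- setdiff(names(df), c(drop, "IID"))
  D <- as.matrix(df[, snp_cols, drop = FALSE])
  snp <- sub("_[ACGT]$", "", snp_cols)
  a1 <- sub("^.*_", "", snp_cols)
  colnames(D) <- snp
  rownames(D) <- ids
  if (is.null(map))
    map <- data.frame(snp = snp, chr = "1", bp = seq_along(snp), a1 = a1,
                      a2 = NA_character_, stringsAsFactors = FALSE)
  genotype_matrix(D, map)
}

#' Write / read a SNP map
#'
#' Whitespace-delimited columns `CHR SNP BP A1` with an optional fifth `A2`
#' column.
#' @param map data frame with `snp`, `chr`, `bp`, `a1` (optionally `a2`).
#' @param path file path.
#' @export
write_snp_map <- function(map, path) {
  df <- data.frame(CHR = map$chr, SNP = map$snp, BP = map$bp, A1 = map$a1,
                   stringsAsFactors = FALSE)
  if (!is.null(map$a2)) df$A2 <- map$a2
  utils::write.table(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_map
#' @export
read_snp_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  out <- data.frame(snp = df$SNP, chr = as.character(df$CHR), bp = df$BP,
                    a1 = df$A1, stringsAsFactors = FALSE)
  out$a2 <- if ("A2" %in% names(df)) df$A2 else NA_character_
  out
}

#' Write / read GWAS summary statistics
#'
#' Whitespace-delimited `SNP CHR BP A1 BETA P` (optional `A2`).
#' @param stats_df summary statistics data frame.
#' @param path file path.
#' @export
write_summary_stats <- function(stats_df, path) {
  df <- data.frame(SNP = stats_df$snp, CHR = stats_df$chr, BP = stats_df$bp,
                   A1 = stats_df$a1, BETA = stats_df$beta, P = stats_df$p,
                   stringsAsFactors = FALSE)
  if (!is.null(stats_df$a2)) df$A2 <- stats_df$a2
  utils::write.table(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  out <- data.frame(snp = df$SNP, chr = as.character(df$CHR), bp = df$BP,
                    a1 = df$A1, beta = df$BETA, p = df$P,
                    stringsAsFactors = FALSE)
  out$a2 <- if ("A2" %in% names(df)) df$A2 else NA_character_
  class(out) <- c("gwas_sumstats", "data.frame")
  out
}

#' Write / read a long-format ESM table as CSV
#' @param esm beep-level data frame.
#' @param path file path.
#' @export
write_esm_csv <- function(esm, path) {
  utils::write.csv(esm, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_esm_csv
#' @export
read_esm_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$observed <- as.logical(df$observed)
  df
}

#' Read a YAML pipeline configuration
#' @param path YAML file.
#' @return configuration list for [run_pipeline()].
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Write a report bundle to disk
#'
#' Serializes a [run_pipeline()] report as `report.json` (cells, plan, seed,
#' SNP counts) plus a human-readable `cells.tsv` mirroring the
#' estimate/SE/label table layout.
#'
#' @param report a `gxe_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    schema = "esmgxe-report/1",
    seed = report$seed,
    plan = unclass(report$plan),
    prs_n_snps = as.list(report$prs_n_snps),
    cells = report$cells
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.table(report$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
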