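# Clumping + thresholding polygenic scores.
#
# Scores are the classic C+T construction: greedily keep the most significant
# SNP per LD neighbourhood (r^2 < 0.1 within a 1000 kb window by default),
# then for each p-value threshold sum dosage * effect size over the retained
# SNPs passing the threshold.  The LD reference is the analysis genotype
# matrix itself.

#' Construct a genotype matrix object from components
#'
#' @param dosages numeric subjects x SNPs matrix with values in `[0, 2]`;
#'   row names are subject ids, column names SNP ids.
#' @param map data frame with columns `snp`, `chr`, `bp`, `a1` and
#'   optionally `a2`, one row per SNP.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, map) {
  if (is.null(colnames(dosages))) stopf("dosages must have SNP column names")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("S%04d", seq_len(nrow(dosages)))
  if (anyDuplicated(colnames(dosages)) || anyDuplicated(rownames(dosages)))
    stopf("subject and SNP ids must be unique")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stopf("dosages must lie in [0, 2]")
  if (!all(colnames(dosages) %in% map$snp))
    stopf("every SNP in dosages must appear in the map")
  map <- map[match(colnames(dosages), map$snp), , drop = FALSE]
  if (is.null(map$a2)) map$a2 <- NA_character_
  structure(list(dosages = dosages, map = map), class = "genotype_matrix")
}

#' Linkage-disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of the two dosage vectors (pairwise-complete).
#' A monomorphic SNP cannot tag anything, so a zero-variance vector yields
#' `r^2 = 0` with a warning.
#'
#' @param geno a `genotype_matrix`.
#' @param snp_a,snp_b SNP ids.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(geno, snp_a, snp_b) {
  for (s in c(snp_a, snp_b))
    if (!s %in% colnames(geno$dosages)) stopf("SNP '%s' not in genotype matrix", s)
  x <- geno$dosages[, snp_a]
  y <- geno$dosages[, snp_b]
  ok <- stats::complete.cases(x, y)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warnf("monomorphic SNP in ld_r2 (%s, %s); returning 0", snp_a, snp_b)
    return(0)
  }
  stats::cor(x[ok], y[ok])^2
}

# Vectorized r^2 of one SNP against several, for clumping.
ld_r2_many <- function(D, a, others) {
  x <- D[, a]
  if (stats::sd(x) == 0) return(stats::setNames(rep(0, length(others)), others))
  r <- suppressWarnings(stats::cor(x, D[, others, drop = FALSE]))
  r2 <- drop(r)^2
  r2[is.na(r2)] <- 0   # zero-variance partner
  stats::setNames(r2, others)
}

#' Greedy LD clumping of GWAS summary statistics
#'
#' Visits SNPs in ascending p-value order (ties broken by chromosome,
#' position, then SNP id).  Each visited SNP that has not already been
#' removed becomes an index SNP; all not-yet-kept SNPs on the same chromosome
#' within `window_kb` kilobases and with `r^2 >= r2_max` against it are
#' removed.  The result does not depend on the input row order.
#'
#' @param stats_df summary statistics (`gwas_sumstats` or data frame with
#'   `snp`, `chr`, `bp`, `p`); all SNPs must be present in `geno`.
#' @param geno `genotype_matrix` used as the LD reference.
#' @param r2_max clumping r-squared cutoff (default 0.1).
#' @param window_kb clumping window half-width in kb (default 1000).
#' @return character vector of retained SNP ids in genomic order.
#' @export
clump <- function(stats_df, geno, r2_max = 0.1, window_kb = 1000) {
  if (!nrow(stats_df)) return(character(0))
  missing_snps <- setdiff(stats_df$snp, colnames(geno$dosages))
  if (length(missing_snps))
    stopf("summary-stat SNPs absent from genotype matrix: %s",
          paste(utils::head(missing_snps, 5), collapse = ", "))
  ord <- order(stats_df$p, stats_df$chr, stats_df$bp, stats_df$snp)
  s <- stats_df[ord, , drop = FALSE]
  removed <- stats::setNames(rep(FALSE, nrow(s)), s$snp)
  kept <- stats::setNames(rep(FALSE, nrow(s)), s$snp)
  D <- geno$dosages
  win <- window_kb * 1000
  for (i in seq_len(nrow(s))) {
    id <- s$snp[i]
    if (removed[[id]]) next
    kept[[id]] <- TRUE
    near <- setdiff(which(s$chr == s$chr[i] & abs(s$bp - s$bp[i]) <= win &
                            !kept & !removed), i)
    if (length(near)) {
      r2 <- ld_r2_many(D, id, s$snp[near])
      removed[s$snp[near[r2 >= r2_max]]] <- TRUE
    }
  }
  kept_ids <- names(kept)[kept]
  m <- stats_df[match(kept_ids, stats_df$snp), ]
  kept_ids[order(m$chr, m$bp, m$snp)]
}

#' Polygenic scores by thresholding clumped summary statistics
#'
#' For each threshold `tau`, `score_i = sum_j dosage_ij * beta_j` over the
#' retained SNPs with `p_j < tau` (strict).  Alleles are aligned between the
#' genotype matrix and the summary statistics: when the counted allele in the
#' genotype data is the summary statistics' other allele, the dosage is
#' flipped to `2 - dosage`; SNPs whose alleles match neither orientation are
#' dropped with a warning.  Missing dosages are mean-imputed per SNP before
#' scoring.  No standardization is applied here; z-scoring happens in the
#' modelling stage.
#'
#' @param geno `genotype_matrix`.
#' @param stats_df summary statistics with `snp`, `a1`, `beta`, `p`
#'   (optionally `a2`).
#' @param retained character vector of clumped SNP ids (subset of
#'   `stats_df$snp`).
#' @param thresholds numeric p-value thresholds (default
#'   `c(0.001, 0.01, 0.05, 0.1)`).
#' @return object of class `prs_profile`: a data frame with `subject_id` and
#'   one `score_<tau>` column per threshold; attributes `n_snps_used` (named
#'   count per threshold), `retained_snps` (per-threshold id lists) and
#'   `n_dropped` (allele-incompatible SNPs).
#' @export
prs_score <- function(geno, stats_df, retained,
                      thresholds = c(0.001, 0.01, 0.05, 0.1)) {
  if (!all(retained %in% stats_df$snp))
    stopf("retained SNPs must be a subset of the summary statistics")
  thresholds <- sort(thresholds)
  s <- stats_df[match(retained, stats_df$snp), , drop = FALSE]
  gm <- geno$map[match(retained, geno$map$snp), , drop = FALSE]
  s_a2 <- if (!is.null(s$a2)) s$a2 else rep(NA_character_, nrow(s))
  g_a2 <- if (!is.null(gm$a2)) gm$a2 else rep(NA_character_, nrow(gm))
  both_known <- !is.na(s_a2) & !is.na(g_a2)
  same <- s$a1 == gm$a1 & (!both_known | s_a2 == g_a2)
  # palindromic (A/T, C/G) pairs cannot be strand-resolved when the coded
  # allele disagrees, so they are dropped rather than flipped
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  pal <- both_known & !is.na(comp[s$a1]) & comp[s$a1] == s_a2
  flip <- !same & !pal & ((both_known & s$a1 == g_a2 & s_a2 == gm$a1) |
                            (!both_known & s$a1 != gm$a1))
  bad <- !same & !flip
  if (any(bad))
    warnf("%d SNP(s) dropped: alleles match neither orientation", sum(bad))
  use <- !bad
  D <- geno$dosages[, retained[use], drop = FALSE]
  # mean-impute missing dosages per SNP
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  D[, flip[use]] <- 2 - D[, flip[use]]
  beta <- s$beta[use]
  p <- s$p[use]
  out <- data.frame(subject_id = rownames(geno$dosages), stringsAsFactors = FALSE)
  n_used <- integer(length(thresholds))
  ret_lists <- vector("list", length(thresholds))
  for (t in seq_along(thresholds)) {
    pass <- p < thresholds[t]
    out[[paste0("score_", format(thresholds[t], drop0trailing = TRUE))]] <-
      if (any(pass)) drop(D[, pass, drop = FALSE] %*% beta[pass]) else 0
    n_used[t] <- sum(pass)
    ret_lists[[t]] <- retained[use][pass]
  }
  names(n_used) <- names(ret_lists) <- as.character(thresholds)
  structure(out, class = c("prs_profile", "data.frame"),
            thresholds = thresholds, n_snps_used = n_used,
            retained_snps = ret_lists, n_dropped = sum(bad))
}

#' @export
print.prs_profile <- function(x, ...) {
  cat("Polygenic score profile\n")
  nu <- attr(x, "n_snps_used")
  for (t in names(nu)) cat(sprintf("  p < %s: %d SNPs\n", t, nu[[t]]))
  NextMethod()
}
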