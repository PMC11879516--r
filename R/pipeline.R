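# End-to-end orchestration: synthetic generation (or file input), ancestry
# principal components, polygenic scoring, index construction, per-cell
# time-lagged screening models, FDR correction within each outcome-context
# family, and the competitive-confirmatory classification of the surviving
# interactions.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement.  The intended
#' family is the set of threshold-specific interaction p-values within one
#' outcome-context combination.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stopf("pvals must be numeric")
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Ancestry principal components from a genotype matrix
#'
#' Top-k principal components of the column-standardized dosage matrix
#' (monomorphic SNPs are skipped).  Each component's sign is fixed by making
#' its largest-magnitude SNP loading positive, so the output is reproducible
#' across linear-algebra backends.
#'
#' @param geno `genotype_matrix`.
#' @param k number of components (default 2); `k = 0` returns a zero-column
#'   matrix.
#' @return subjects x k matrix with columns `PC1..PCk` and subject row names.
#' @export
ancestry_pcs <- function(geno, k = 2) {
  n <- nrow(geno$dosages)
  if (k == 0)
    return(matrix(numeric(0), n, 0, dimnames = list(rownames(geno$dosages), NULL)))
  if (n < k + 1) stopf("need at least k + 1 subjects for %d components", k)
  sds <- apply(geno$dosages, 2, stats::sd)
  keep <- which(sds > 0)
  if (!length(keep)) stopf("all SNPs are monomorphic; no ancestry structure")
  Z <- scale(geno$dosages[, keep, drop = FALSE])
  sv <- svd(Z, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(geno$dosages), paste0("PC", seq_len(k)))
  scores
}

#' Default analysis plan
#'
#' Enumerates the outcome x context x threshold cells of the study design:
#' five momentary outcomes, two contextual appraisals, four PRS p-value
#' thresholds, screening alpha 0.05, FDR families formed by the four
#' thresholds within each outcome-context pair.
#'
#' @param outcomes,contexts,thresholds,alpha plan components.
#' @return list of class `analysis_plan`.
#' @export
analysis_plan <- function(outcomes = c("paranoia", "ple", "negative_like", "na", "pa"),
                          contexts = c("positive", "stressful"),
                          thresholds = c(0.001, 0.01, 0.05, 0.1),
                          alpha = 0.05) {
  structure(list(outcomes = outcomes, contexts = contexts,
                 thresholds = sort(thresholds), alpha = alpha),
            class = "analysis_plan")
}

#' Run the full analysis pipeline
#'
#' Sequences the study analogue end to end: synthetic generation (or file
#' input), ancestry PCs, clumping + thresholding PRS, momentary indices,
#' per-cell time-lagged random-intercept screening models with PC
#' covariates, Wald tests, Benjamini-Hochberg correction across thresholds
#' within each outcome-context family, and - for FDR-significant
#' interactions - covariate trimming followed by the six-model
#' competitive-confirmatory classification.
#'
#' @param config configuration list (or path to a YAML file readable by
#'   [read_config()]).  Recognized entries: `seed`; `synth` (arguments to
#'   [synth_config()]) or `inputs` (paths: `genotypes`, `snp_map`,
#'   `summary_stats`, `esm`); `plan` (arguments to [analysis_plan()]);
#'   `prs` (`r2_max`, `window_kb`); `n_boot`; `true_threshold` (which PRS
#'   threshold's z-scored score drives the generator, default the largest).
#' @return object of class `gxe_report`: `cells` (one row per plan cell with
#'   screening estimates, FDR-adjusted p, and classification label),
#'   `classifications` (the `gxe_classification` objects for gated cells),
#'   `descriptives`, `plan`, `seed` and `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  seed <- config$seed %||% 1L
  plan <- do.call(analysis_plan, config$plan %||% list())
  prs_opts <- config$prs %||% list()
  n_boot <- config$n_boot %||% 500L

  # ---- inputs ----
  if (!is.null(config$inputs)) {
    geno <- read_genotypes_raw(config$inputs$genotypes,
                               read_snp_map(config$inputs$snp_map))
    sumstats <- read_summary_stats(config$inputs$summary_stats)
    esm_raw <- read_esm_csv(config$inputs$esm)
    truth <- NULL
  } else {
    scfg <- do.call(synth_config, c(list(seed = seed), config$synth %||% list()))
    geno <- simulate_genotypes(scfg)
    sumstats <- simulate_summary_stats(geno$map, scfg)
  }

  # ---- genetics ----
  kept <- clump(sumstats, geno, r2_max = prs_opts$r2_max %||% 0.1,
                window_kb = prs_opts$window_kb %||% 1000)
  prof <- prs_score(geno, sumstats, kept, thresholds = plan$thresholds)
  pcs <- ancestry_pcs(geno, k = 2)
  score_cols <- setdiff(names(prof), "subject_id")
  zscores <- as.data.frame(lapply(prof[score_cols], function(x)
    if (stats::sd(x) > 0) as.numeric(scale(x)) else x * 0))
  names(zscores) <- score_cols
  zscores$subject_id <- prof$subject_id

  # ---- phenotypes ----
  if (is.null(config$inputs)) {
    tt <- config$true_threshold %||% max(plan$thresholds)
    tt_col <- paste0("score_", format(tt, drop0trailing = TRUE))
    if (!tt_col %in% names(zscores)) stopf("true_threshold %s not in plan", tt)
    gvec <- stats::setNames(zscores[[tt_col]], zscores$subject_id)
    sim <- simulate_esm(gvec, scfg)
    esm_raw <- sim$esm
    truth <- sim$truth
  }
  esm <- build_indices(esm_raw)
  subj_cov <- data.frame(subject_id = rownames(pcs), pcs,
                         stringsAsFactors = FALSE)

  # ---- screening + confirmatory ----
  cells <- list()
  classifications <- list()
  for (ctx in plan$contexts) for (outc in plan$outcomes) {
    lag0 <- make_lagged_pairs(esm, predictor = ctx, outcome = outc)
    lag0 <- merge(lag0, subj_cov, by = "subject_id", sort = FALSE)
    fam <- list()
    for (tau in plan$thresholds) {
      col <- paste0("score_", format(tau, drop0trailing = TRUE))
      lag <- merge(lag0, zscores[, c("subject_id", col)],
                   by = "subject_id", sort = FALSE)
      names(lag)[names(lag) == col] <- "G"
      row <- list(outcome = outc, context = ctx, threshold = tau,
                  n_pairs = nrow(lag))
      fit <- tryCatch(
        lmm_ml(y ~ G + E + G:E + PC1 + PC2, lag, group = "subject_id"),
        error = function(e) e)
      if (inherits(fit, "error")) {
        row$error <- conditionMessage(fit)
      } else {
        wt <- wald_tests(fit)
        for (term in c("G", "E", "G:E")) {
          key <- c(G = "g", E = "e", `G:E` = "gxe")[[term]]
          i <- match(term, wt$term)
          row[[paste0("est_", key)]] <- wt$estimate[i]
          row[[paste0("se_", key)]] <- wt$se[i]
          row[[paste0("p_", key)]] <- wt$p[i]
        }
        row$data <- lag
      }
      fam[[as.character(tau)]] <- row
    }
    p_raw <- vapply(fam, function(r) r$p_gxe %||% NA_real_, numeric(1))
    p_fdr <- rep(NA_real_, length(p_raw))
    p_fdr[!is.na(p_raw)] <- fdr_adjust(p_raw[!is.na(p_raw)])
    for (i in seq_along(fam)) {
      row <- fam[[i]]
      row$p_gxe_fdr <- p_fdr[i]
      row$significant <- !is.na(p_fdr[i]) && p_fdr[i] < plan$alpha
      row$label <- "-"
      row$c_hat <- NA_real_; row$c_lo <- NA_real_; row$c_hi <- NA_real_
      if (row$significant) {
        trim <- trim_covariates(row$data, covariates = c("PC1", "PC2"))
        cls <- classify_gxe(row$data, covariates = trim$covariates,
                            n_boot = n_boot,
                            seed = stage_seed(seed, 10 + length(classifications)))
        row$label <- cls$label
        if (!is.na(cls$c_hat)) {
          row$c_hat <- cls$c_hat
          row$c_lo <- cls$c_ci[1]; row$c_hi <- cls$c_ci[2]
        }
        classifications[[paste(outc, ctx, row$threshold, sep = ".")]] <- cls
      }
      row$data <- NULL
      cells[[paste(outc, ctx, row$threshold, sep = ".")]] <- row
    }
  }
  cell_df <- do.call(rbind, lapply(cells, function(r) {
    data.frame(outcome = r$outcome, context = r$context, threshold = r$threshold,
               n_pairs = r$n_pairs,
               est_g = r$est_g %||% NA_real_, se_g = r$se_g %||% NA_real_,
               est_e = r$est_e %||% NA_real_, se_e = r$se_e %||% NA_real_,
               est_gxe = r$est_gxe %||% NA_real_, se_gxe = r$se_gxe %||% NA_real_,
               p_gxe = r$p_gxe %||% NA_real_, p_gxe_fdr = r$p_gxe_fdr,
               significant = r$significant, label = r$label,
               c_hat = r$c_hat, c_lo = r$c_lo, c_hi = r$c_hi,
               error = r$error %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(cell_df) <- NULL
  desc <- person_descriptives(
    esm, vars = c(plan$outcomes, plan$contexts),
    extra = zscores[, c("subject_id", score_cols)])
  structure(list(cells = cell_df, classifications = classifications,
                 descriptives = desc, plan = plan, seed = seed,
                 prs_n_snps = attr(prof, "n_snps_used"),
                 truth = truth, config = config),
            class = "gxe_report")
}

#' @export
print.gxe_report <- function(x, ...) {
  cat(sprintf("G-by-E analysis report (seed %s)\n", format(x$seed)))
  cat(sprintf("  %d cells (%d outcomes x %d contexts x %d thresholds), %d FDR-significant\n",
              nrow(x$cells), length(x$plan$outcomes), length(x$plan$contexts),
              length(x$plan$thresholds), sum(x$cells$significant, na.rm = TRUE)))
  sig <- x$cells[x$cells$significant %in% TRUE, ]
  if (nrow(sig))
    print(format(sig[, c("outcome", "context", "threshold", "est_gxe",
                         "se_gxe", "p_gxe_fdr", "label")], digits = 3),
          row.names = FALSE)
  invisible(x)
}
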