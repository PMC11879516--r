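# Beep-level ESM data handling: analysis indices, within-day time-lagged
# pairs, person-level descriptives and two-level reliabilities.

#' Default momentary index definitions
#'
#' The standard index set for this protocol: a 2-item paranoia index, an
#' 8-item psychotic-like-experiences (PLE) index, a single-item
#' negative-symptom proxy, 4-item negative affect, 2-item positive affect,
#' and the two single-item contextual appraisals (stressful / positive
#' situation).  All items are rated 1-7.
#'
#' @return named list mapping index name to character vector of item columns.
#' @export
default_index_defs <- function() esm_item_sets

#' Compute index columns as item means
#'
#' Each index is the arithmetic mean of its items at that beep, and is
#' missing whenever any constituent item is missing (a strict policy: a
#' partially answered beep does not contribute).
#'
#' @param data long beep-level data frame.
#' @param defs named list of index definitions (default
#'   [default_index_defs()]).
#' @return `data` with one appended numeric column per index.
#' @export
build_indices <- function(data, defs = default_index_defs()) {
  for (nm in names(defs)) {
    items <- defs[[nm]]
    missing_items <- setdiff(items, names(data))
    if (length(missing_items))
      stopf("index '%s' refers to unknown item(s): %s", nm,
            paste(missing_items, collapse = ", "))
    m <- as.matrix(data[, items, drop = FALSE])
    v <- rowMeans(m)              # NA if any item missing
    data[[nm]] <- v
  }
  data
}

#' Build within-day time-lagged (t, t+1) pairs
#'
#' Pairs every beep with the *next issued signal* of the same subject-day: a
#' pair (beep k, beep k+1) is emitted when the predictor and all beep-level
#' covariates are observed at time t and the outcome is observed at time
#' t+1.  Pairs never cross a day boundary, so the last beep of a day is
#' never linked to the first beep of the next.
#'
#' @param data beep-level data frame with `subject_id`, `day`, `beep` and the
#'   named index columns (indices already built).
#' @param predictor column name used as the momentary context `E` at time t.
#' @param outcome column name of the outcome at time t+1.
#' @param covariates beep-level covariate columns required observed at time t
#'   (subject-level covariates are better joined onto the result).
#' @return data frame with columns `subject_id`, `day`, `beep` (the t beep),
#'   `E`, `y`, and the covariates at time t.
#' @export
make_lagged_pairs <- function(data, predictor, outcome, covariates = character()) {
  for (v in c(predictor, outcome, covariates))
    if (!v %in% names(data)) stopf("column '%s' not found", v)
  d <- data[order(data$subject_id, data$day, data$beep), , drop = FALSE]
  same_run <- d$subject_id[-1] == d$subject_id[-nrow(d)] &
    d$day[-1] == d$day[-nrow(d)] &
    d$beep[-1] == d$beep[-nrow(d)] + 1
  t_idx <- which(c(same_run, FALSE))
  ok <- !is.na(d[[predictor]][t_idx]) & !is.na(d[[outcome]][t_idx + 1])
  if (length(covariates))
    for (v in covariates) ok <- ok & !is.na(d[[v]][t_idx])
  t_idx <- t_idx[ok]
  out <- data.frame(subject_id = d$subject_id[t_idx],
                    day = d$day[t_idx],
                    beep = d$beep[t_idx],
                    E = d[[predictor]][t_idx],
                    y = d[[outcome]][t_idx + 1],
                    stringsAsFactors = FALSE)
  for (v in covariates) out[[v]] <- d[[v]][t_idx]
  out
}

#' Person-level descriptive statistics and correlations
#'
#' Computes each subject's mean of every variable over their observed beeps,
#' then summarizes those person means (mean, SD, min, max) and returns their
#' Pearson correlation matrix.  Subject-level columns (e.g. polygenic
#' scores) can be supplied via `extra` and enter the correlation matrix
#' untouched.
#'
#' @param data beep-level data frame with indices built.
#' @param vars character vector of beep-level variables to summarize.
#' @param extra optional data frame with `subject_id` plus subject-level
#'   columns.
#' @return list with `person_means` (subjects x variables), `summary` (per
#'   variable M/SD/min/max of person means) and `correlations`.  Constant
#'   variables get `NA` correlations with a warning.  Subjects without a
#'   single observed beep are excluded with a warning.
#' @export
person_descriptives <- function(data, vars, extra = NULL) {
  for (v in vars) if (!v %in% names(data)) stopf("column '%s' not found", v)
  subj <- unique(data$subject_id)
  pm <- vapply(vars, function(v)
    tapply(data[[v]], factor(data$subject_id, levels = subj),
           function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)),
    numeric(length(subj)))
  pm <- as.data.frame(pm)
  pm$subject_id <- subj
  empty <- rowSums(!is.na(pm[, vars, drop = FALSE])) == 0
  if (any(empty)) {
    warnf("%d subject(s) without observed beeps excluded", sum(empty))
    pm <- pm[!empty, , drop = FALSE]
  }
  if (!is.null(extra)) pm <- merge(pm, extra, by = "subject_id", sort = FALSE)
  num_vars <- setdiff(names(pm), "subject_id")
  M <- as.matrix(pm[, num_vars, drop = FALSE])
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warnf("constant variable(s): %s; correlations undefined",
          paste(num_vars[which(sds == 0)], collapse = ", "))
  summary_tab <- data.frame(
    variable = num_vars,
    mean = colMeans(M, na.rm = TRUE),
    sd = sds,
    min = apply(M, 2, min, na.rm = TRUE),
    max = apply(M, 2, max, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  cors <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
  list(person_means = pm, summary = summary_tab, correlations = cors)
}

# Cronbach's alpha from an items matrix (rows = observations).
cronbach_alpha <- function(M) {
  M <- M[stats::complete.cases(M), , drop = FALSE]
  k <- ncol(M)
  if (k < 2 || nrow(M) < 3) return(NA_real_)
  S <- stats::cov(M)
  tot <- sum(S)
  if (tot <= 0) return(NA_real_)
  k / (k - 1) * (1 - sum(diag(S)) / tot)
}

#' Between- and within-person reliability of a multi-item index
#'
#' Decomposes item scores into person means and person-mean-centered
#' (momentary) deviations, and reports Cronbach's alpha at each level:
#' `between_alpha` over the subjects x items matrix of person means, and
#' `within_alpha` over the beep-level centered scores.
#'
#' @param data beep-level data frame containing the items.
#' @param items character vector of item columns (>= 2 items required).
#' @return list with `between_alpha` and `within_alpha`; both `NA` for a
#'   single-item index.
#' @export
esm_reliability <- function(data, items) {
  if (length(items) < 2)
    return(list(between_alpha = NA_real_, within_alpha = NA_real_))
  for (v in items) if (!v %in% names(data)) stopf("column '%s' not found", v)
  M <- as.matrix(data[, items, drop = FALSE])
  f <- factor(data$subject_id)
  pm <- apply(M, 2, function(x) tapply(x, f, mean, na.rm = TRUE))
  centered <- M - pm[as.integer(f), , drop = FALSE]
  list(between_alpha = cronbach_alpha(pm),
       within_alpha = cronbach_alpha(centered))
}
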