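# Synthetic study generator: block-LD genotypes, GWAS-like summary statistics
# and hierarchical experience-sampling data under a configurable true G-by-E
# regime.  The defaults emulate a one-week ESM protocol in ~217 young adults:
# eight random signals a day between 10:00 and 22:00, consecutive signals
# 10-170 minutes apart, roughly 40.7 completed questionnaires per person, and
# 7-point momentary items with strong floor effects on the symptom outcomes.

#' Configuration for the synthetic study generator
#'
#' Collects and validates every knob of the generator.  Defaults encode the
#' emulated study design: 217 subjects signalled 8 times/day for 7 days in a
#' 10:00-22:00 window with gaps of 10-170 minutes, and a compliance rate
#' chosen so the expected number of completed beeps is about 40.7 out of the
#' 56 issued.
#'
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @param n_subjects number of subjects.
#' @param n_blocks,snps_per_block genotype LD structure: `n_blocks`
#'   independent blocks of `snps_per_block` SNPs each.
#' @param block_corr latent pairwise correlation within a block, in `[0, 1)`.
#' @param maf_range range the per-SNP minor-allele frequency is drawn from.
#' @param prop_causal probability a SNP carries a true effect in the
#'   simulated GWAS.
#' @param beta_sd standard deviation of true causal effect sizes.
#' @param gwas_n nominal sample size of the simulated GWAS, which sets the
#'   sampling noise (hence p-values) of the summary statistics.
#' @param n_days,signals_per_day ESM schedule dimensions.
#' @param window signalling window as minutes since midnight (default
#'   `c(600, 1320)`, i.e. 10:00-22:00).
#' @param min_gap,max_gap bounds in minutes on the gap between consecutive
#'   signals.
#' @param compliance probability each issued beep is completed.
#' @param true_model a [gxe_spec()] naming the framework/strength the true
#'   outcome-generating crossover model belongs to (strong variants force
#'   `s0 = 0`).
#' @param true_params named list with elements `b0`, `s0`, `s1`, `c`,
#'   `sigma_u`, `sigma_e`: the crossover-model truth
#'   `y = b0 + u_i + (s0 + s1 G_i)(E - c) + e` used for the target outcome.
#' @param true_outcome,true_context which index the G-by-E regime acts on;
#'   all other outcomes are generated as context-independent noise around
#'   their typical level.
#' @param item_noise_sd SD of item-level noise added around the latent index
#'   before rounding to the 1-7 grid.
#' @param round_items if `FALSE`, items are kept continuous and unclipped
#'   (an exact-oracle test mode); default `TRUE`.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_subjects = 217L,
                         n_blocks = 20L,
                         snps_per_block = 10L,
                         block_corr = 0.7,
                         maf_range = c(0.05, 0.5),
                         prop_causal = 0.3,
                         beta_sd = 0.1,
                         gwas_n = 10000L,
                         n_days = 7L,
                         signals_per_day = 8L,
                         window = c(600, 1320),
                         min_gap = 10,
                         max_gap = 170,
                         compliance = 40.7 / 56,
                         true_model = gxe_spec("differential_susceptibility", "weak"),
                         true_params = list(b0 = 1.4, s0 = -0.08, s1 = -0.05,
                                            c = 4.5, sigma_u = 0.25, sigma_e = 0.45),
                         true_outcome = "paranoia",
                         true_context = "positive",
                         item_noise_sd = 0.3,
                         round_items = TRUE) {
  cfg <- list(seed = seed, n_subjects = n_subjects, n_blocks = n_blocks,
              snps_per_block = snps_per_block, block_corr = block_corr,
              maf_range = maf_range, prop_causal = prop_causal,
              beta_sd = beta_sd, gwas_n = gwas_n, n_days = n_days,
              signals_per_day = signals_per_day, window = window,
              min_gap = min_gap, max_gap = max_gap, compliance = compliance,
              true_model = true_model, true_params = true_params,
              true_outcome = true_outcome, true_context = true_context,
              item_noise_sd = item_noise_sd, round_items = round_items)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (!is_count(n_subjects) || !is_count(n_blocks) || !is_count(snps_per_block) ||
        !is_count(n_days) || !is_count(signals_per_day))
      stopf("counts must be positive integers")
    if (!(block_corr >= 0 && block_corr < 1))
      stopf("block_corr must be in [0, 1)")
    if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
        maf_range[1] <= 0 || maf_range[2] > 0.5)
      stopf("maf_range must be an increasing pair within (0, 0.5]")
    if (!(prop_causal > 0 && prop_causal <= 1))
      stopf("prop_causal must be in (0, 1]")
    if (beta_sd < 0) stopf("beta_sd must be >= 0")
    if (window[1] >= window[2]) stopf("window start must precede end")
    if (min_gap >= max_gap) stopf("min_gap must be < max_gap")
    if (!(compliance > 0 && compliance <= 1))
      stopf("compliance must be in (0, 1]")
    if (compliance * n_days * signals_per_day < 2)
      stopf("expected number of completed beeps must be at least 2")
    if (item_noise_sd < 0) stopf("item_noise_sd must be >= 0")
    req <- c("b0", "s0", "s1", "c", "sigma_u", "sigma_e")
    if (!all(req %in% names(true_params)))
      stopf("true_params must name %s", paste(req, collapse = ", "))
    if (true_params$sigma_u < 0 || true_params$sigma_e < 0)
      stopf("variance components must be non-negative")
  })
  invisible(cfg)
}

# ---- genotypes -------------------------------------------------------------

#' Simulate a block-LD genotype dosage matrix
#'
#' Generates `n_subjects x (n_blocks * snps_per_block)` dosages in {0, 1, 2}
#' under a latent-Gaussian threshold model: each gamete's allele indicators
#' within a block share an exchangeable latent correlation `block_corr`, and
#' the dosage is the sum of two independent gametes.  Blocks are placed 3 Mb
#' apart so that a 1000 kb clumping window can never span two blocks.
#'
#' @param cfg a [synth_config()].
#' @return an object of class `genotype_matrix`: a list with `dosages` (a
#'   named subjects-by-SNPs matrix) and `map` (data frame with `snp`, `chr`,
#'   `bp`, `a1`, `a2`; `a1` is the counted/effect allele).
#' @export
simulate_genotypes <- function(cfg) {
  validate_synth_config(cfg)
  with_seed(stage_seed(cfg$seed, 1), {
    n <- cfg$n_subjects
    m_block <- cfg$snps_per_block
    n_snp <- cfg$n_blocks * m_block
    maf <- stats::runif(n_snp, cfg$maf_range[1], cfg$maf_range[2])
    rho <- cfg$block_corr
    dos <- matrix(0L, n, n_snp)
    for (b in seq_len(cfg$n_blocks)) {
      cols <- (b - 1) * m_block + seq_len(m_block)
      thr <- stats::qnorm(1 - maf[cols])
      for (gamete in 1:2) {
        # exchangeable latent correlation via a shared factor
        f <- stats::rnorm(n)
        eps <- matrix(stats::rnorm(n * m_block), n, m_block)
        z <- sqrt(rho) * f + sqrt(1 - rho) * eps
        dos[, cols] <- dos[, cols] + (z > rep(thr, each = n))
      }
    }
    alleles <- c("A", "C", "G", "T")
    a1 <- sample(alleles, n_snp, replace = TRUE)
    a2 <- vapply(a1, function(a) sample(setdiff(alleles, a), 1), character(1))
    block_id <- rep(seq_len(cfg$n_blocks), each = m_block)
    map <- data.frame(
      snp = sprintf("rs%06d", seq_len(n_snp)),
      chr = "1",
      bp = (block_id - 1) * 3000000L + (seq_len(n_snp) - (block_id - 1) * m_block) * 1000L,
      a1 = unname(a1), a2 = unname(a2),
      maf = maf,
      stringsAsFactors = FALSE
    )
    dimnames(dos) <- list(sprintf("S%04d", seq_len(n)), map$snp)
    structure(list(dosages = dos, map = map), class = "genotype_matrix")
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype dosage matrix: %d subjects x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

# ---- GWAS summary statistics ----------------------------------------------

#' Simulate GWAS-like summary statistics for a SNP map
#'
#' Each SNP is causal with probability `prop_causal`; causal SNPs get a true
#' effect drawn from `N(0, beta_sd^2)` and non-causal SNPs get 0-centered
#' sampling noise with the standard error implied by `gwas_n` and the SNP's
#' allele frequency, `se = 1 / sqrt(gwas_n * 2 maf (1 - maf))`.  The p-value
#' is the two-sided normal tail of `beta / se`, so p is strictly decreasing
#' in `|beta| * sqrt(2 maf (1 - maf))` and uniform under the null.
#'
#' @param snp_map SNP metadata data frame with columns `snp` and `maf` (a
#'   `genotype_matrix$map` works directly).
#' @param cfg a [synth_config()].
#' @return data frame of class `gwas_sumstats` with columns `snp`, `chr`,
#'   `bp`, `a1`, `a2`, `beta`, `p`, `causal`.
#' @export
simulate_summary_stats <- function(snp_map, cfg) {
  if (!nrow(snp_map)) stopf("snp_map must be nonempty")
  validate_synth_config(cfg)
  with_seed(stage_seed(cfg$seed, 2), {
    m <- nrow(snp_map)
    maf <- snp_map$maf %||% stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    se <- 1 / sqrt(cfg$gwas_n * 2 * maf * (1 - maf))
    causal <- stats::runif(m) < cfg$prop_causal
    beta <- ifelse(causal, stats::rnorm(m, 0, cfg$beta_sd), stats::rnorm(m, 0, se))
    z <- beta / se
    p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
    out <- data.frame(snp = snp_map$snp,
                      chr = snp_map$chr %||% "1",
                      bp = snp_map$bp %||% seq_len(m),
                      a1 = snp_map$a1 %||% "A",
                      a2 = snp_map$a2 %||% "G",
                      beta = beta, p = p, causal = causal,
                      stringsAsFactors = FALSE)
    class(out) <- c("gwas_sumstats", "data.frame")
    out
  })
}

# ---- ESM data --------------------------------------------------------------

# Beta-shaped context presets on the latent (0,1) scale, rescaled to [1,7]
# and rounded to the item grid.  Moment-matched so the rounded means land
# near the typical levels of daily-life appraisals: stressful situations are
# rated low (mean near 2.15) with a strong floor, positive situations high
# (mean near 5.35) with a ceiling-leaning left skew.
context_presets <- list(
  stress_like = c(shape1 = 0.553, shape2 = 2.33),
  positive_like = c(shape1 = 2.89, shape2 = 1.09)
)

# Items making up each analysis index; the generator produces all of them.
esm_item_sets <- list(
  paranoia = c("suspicious", "mistreated"),
  ple = c("fear_losing_control", "feel_weird", "difficulty_controlling_thoughts",
          "strange_thoughts", "strange_perception", "heard_seen_things",
          "thought_control_external", "familiar_seems_strange"),
  negative_like = "no_thoughts_emotions",
  na = c("sad", "anxious", "angry", "guilty"),
  pa = c("happy", "relaxed"),
  stressful = "situation_stressful",
  positive = "situation_positive"
)

# Typical person-level means of each outcome index on the 1-7 scale; the
# symptom indices sit near the scale floor, positive affect near 4.7.
null_outcome_levels <- c(paranoia = 1.2, ple = 1.1, negative_like = 1.35,
                         na = 1.5, pa = 4.7)

# Draw one subject-day signal schedule: signals_per_day integer-minute times
# inside the window with consecutive gaps in [min_gap, max_gap].  Gaps are
# drawn uniformly on the integer minutes of the legal range (so the bounds
# hold exactly on the stored times); gap vectors whose sum exceeds the
# window are resampled.
draw_schedule <- function(cfg) {
  k <- cfg$signals_per_day
  span <- cfg$window[2] - cfg$window[1]
  rint <- function(lo, hi) lo + sample.int(hi - lo + 1, 1) - 1
  if (k == 1) return(rint(cfg$window[1], cfg$window[2]))
  gap_lo <- ceiling(cfg$min_gap); gap_hi <- floor(cfg$max_gap)
  if (gap_lo > gap_hi || (k - 1) * gap_lo > span)
    stopf("schedule infeasible: %d signals with gaps in [%g, %g] cannot fit the %g-minute window",
          k, cfg$min_gap, cfg$max_gap, span)
  repeat {
    gaps <- gap_lo + sample.int(gap_hi - gap_lo + 1, k - 1, replace = TRUE) - 1
    if (sum(gaps) <= span) break
  }
  start <- rint(cfg$window[1], cfg$window[2] - sum(gaps))
  start + c(0L, cumsum(gaps))
}

#' Simulate a hierarchical experience-sampling dataset
#'
#' Generates the full beep-level item table for every subject: random
#' within-window signal schedules, Bernoulli compliance, context appraisals
#' from skewed Beta presets, and outcomes from the crossover-model truth
#' `y_(t+1) = b0 + u_i + (s0 + s1 G_i)(E_t - c) + e`, where `E_t` is the
#' subject's observed context rating at the previous beep of the same day.
#' The first beep of each day carries no lagged dependence.  All items are
#' the latent index plus `N(0, item_noise_sd^2)` noise, rounded and clipped
#' to the 1-7 grid (unless `round_items = FALSE`).
#'
#' @param prs numeric vector of sensitivity scores `G_i`, one per subject
#'   (named or in subject order), on whatever scale the `true_params` refer
#'   to; z-scored PRS values are the typical input.
#' @param cfg a [synth_config()].
#' @return list with `esm` (long beep-level data frame: `subject_id`, `day`,
#'   `beep`, `time_min`, `observed`, one column per item) and `truth`
#'   (generator ground truth: `u` random intercepts, `G`, the parameter list,
#'   and the latent outcome table), of class `esm_simulation`.
#' @export
simulate_esm <- function(prs, cfg) {
  validate_synth_config(cfg)
  n <- cfg$n_subjects
  if (length(prs) != n)
    stopf("prs must supply one value per subject (%d)", n)
  subj_ids <- names(prs) %||% sprintf("S%04d", seq_len(n))
  tp <- cfg$true_params
  if (identical(cfg$true_model$strength, "strong")) tp$s0 <- 0
  with_seed(stage_seed(cfg$seed, 3), {
    u <- stats::rnorm(n, 0, tp$sigma_u)
    # other outcomes get their own stable person level
    other <- setdiff(names(null_outcome_levels), cfg$true_outcome)
    u_other <- matrix(stats::rnorm(n * length(other), 0, tp$sigma_u),
                      n, length(other), dimnames = list(NULL, other))
    k <- cfg$signals_per_day
    total <- n * cfg$n_days * k
    subj_of_row <- rep(seq_len(n), each = cfg$n_days * k)
    # schedules: one draw per subject-day
    times <- unlist(lapply(seq_len(n * cfg$n_days), function(sd) draw_schedule(cfg)))
    obs <- stats::runif(total) < cfg$compliance
    # context appraisals for every issued beep
    ctx_all <- matrix(NA_real_, total, 2,
                      dimnames = list(NULL, c("stressful", "positive")))
    for (cn in colnames(ctx_all)) {
      pr <- context_presets[[if (cn == "stressful") "stress_like" else "positive_like"]]
      x <- 1 + 6 * stats::rbeta(total, pr[1], pr[2])
      ctx_all[, cn] <- if (cfg$round_items) pmin(7, pmax(1, round(x))) else x
    }
    # latent outcomes; the target outcome lags on the previous same-day
    # beep's context (on the scale the context is stored on)
    lat_all <- matrix(NA_real_, total, length(null_outcome_levels),
                      dimnames = list(NULL, names(null_outcome_levels)))
    for (o in other)
      lat_all[, o] <- null_outcome_levels[[o]] + u_other[subj_of_row, o] +
        stats::rnorm(total, 0, tp$sigma_e)
    beep_no <- rep(seq_len(k), times = n * cfg$n_days)
    slope <- (tp$s0 + tp$s1 * prs)[subj_of_row]
    E_prev <- c(NA_real_, ctx_all[-total, cfg$true_context])
    lagged_part <- ifelse(beep_no == 1, 0, slope * (E_prev - tp$c))
    lat_all[, cfg$true_outcome] <- tp$b0 + u[subj_of_row] + lagged_part +
      stats::rnorm(total, 0, tp$sigma_e)
    out <- data.frame(
      subject_id = subj_ids[subj_of_row],
      day = rep(rep(seq_len(cfg$n_days), each = k), times = n),
      beep = beep_no,
      time_min = times,
      observed = obs,
      stringsAsFactors = FALSE
    )
    gridify <- function(x) if (cfg$round_items) pmin(7, pmax(1, round(x))) else x
    for (idx in names(esm_item_sets)) {
      items <- esm_item_sets[[idx]]
      base <- if (idx %in% colnames(ctx_all)) ctx_all[, idx] else lat_all[, idx]
      for (it in items) {
        v <- if (idx %in% colnames(ctx_all)) base
             else gridify(base + stats::rnorm(total, 0, cfg$item_noise_sd))
        v[!out$observed] <- NA_real_
        out[[it]] <- v
      }
    }
    truth <- list(u = stats::setNames(u, subj_ids),
                  G = stats::setNames(as.numeric(prs), subj_ids),
                  params = tp, model = cfg$true_model,
                  latent = data.frame(subject_id = out$subject_id, day = out$day,
                                      beep = out$beep, lat_all,
                                      stringsAsFactors = FALSE))
    structure(list(esm = out, truth = truth), class = "esm_simulation")
  })
}

#' @export
print.esm_simulation <- function(x, ...) {
  cat(sprintf("Simulated ESM dataset: %d beep rows, %d subjects, %.1f%% observed\n",
              nrow(x$esm), length(unique(x$esm$subject_id)),
              100 * mean(x$esm$observed)))
  invisible(x)
}
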