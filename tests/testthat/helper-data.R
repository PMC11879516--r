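# Fixture builders used across the test files.

# Direct simulation of a lagged-pair dataset from the crossover model,
# bypassing the ESM generator: used by the lmm/gxe unit tests.
sim_lagged <- function(n_subj = 50, n_per = 10, b0 = 2, s0 = 1, s1 = 0.5,
                       c = 4, su = 0.5, se = 0.7, seed = 1, G = NULL) {
  set.seed(seed)
  G <- G %||% stats::rnorm(n_subj)
  u <- if (su > 0) stats::rnorm(n_subj, 0, su) else numeric(n_subj)
  sid <- rep(seq_len(n_subj), each = n_per)
  E <- stats::runif(n_subj * n_per, 1, 7)
  y <- b0 + u[sid] + (s0 + s1 * G[sid]) * (E - c) +
    if (se > 0) stats::rnorm(length(E), 0, se) else 0
  data.frame(subject_id = sid, G = G[sid], E = E, y = y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny genotype matrix built by hand.
toy_geno <- function(dosages, chr = NULL, bp = NULL, a1 = NULL, a2 = NULL) {
  m <- ncol(dosages)
  map <- data.frame(
    snp = colnames(dosages),
    chr = chr %||% rep("1", m),
    bp = bp %||% seq_len(m) * 1000L,
    a1 = a1 %||% rep("A", m),
    a2 = a2 %||% rep("G", m),
    stringsAsFactors = FALSE)
  genotype_matrix(dosages, map)
}

# One full study replicate through the ESM generator: simulate beep-level
# data under a crossover-model truth on paranoia x positive context, build
# indices and within-day lagged pairs, and attach G.  Baseline level and
# slopes sit mid-scale so the 1-7 grid does not truncate the signal.
sim_study_lagged <- function(seed, n_subj, strength = "weak",
                             s1 = 0.3, s0 = 0.4, b0 = 4, c = 4,
                             su = 0.4, se = 0.7, compliance = 0.92) {
  cfg <- synth_config(
    seed = seed, n_subjects = n_subj, compliance = compliance,
    true_model = gxe_spec("differential_susceptibility", strength),
    true_params = list(b0 = b0, s0 = s0, s1 = s1, c = c,
                       sigma_u = su, sigma_e = se),
    true_outcome = "paranoia", true_context = "positive",
    item_noise_sd = 0.2)
  set.seed(seed * 2 + 1)
  G <- stats::setNames(stats::rnorm(n_subj), sprintf("S%04d", seq_len(n_subj)))
  sim <- simulate_esm(G, cfg)
  e <- build_indices(sim$esm)
  lag <- make_lagged_pairs(e, "positive", "paranoia")
  lag$G <- G[lag$subject_id]
  lag
}

# Random small beep-level table with missingness, for lag-construction tests.
random_esm_fixture <- function(n_subj = 4, n_days = 3, n_beeps = 6,
                               miss = 0.2, seed = 1) {
  set.seed(seed)
  d <- expand.grid(beep = seq_len(n_beeps), day = seq_len(n_days),
                   subject_id = sprintf("S%02d", seq_len(n_subj)),
                   stringsAsFactors = FALSE)[, c("subject_id", "day", "beep")]
  n <- nrow(d)
  d$x <- ifelse(stats::runif(n) < miss, NA_real_, round(stats::runif(n, 1, 7)))
  d$z <- ifelse(stats::runif(n) < miss, NA_real_, round(stats::runif(n, 1, 7)))
  d
}
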