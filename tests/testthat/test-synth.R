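# Synthetic study generator: genotypes, summary statistics, ESM data.

test_that("config validation rejects impossible designs", {
  expect_error(synth_config(maf_range = c(0.6, 0.7)), "maf_range")
  expect_error(synth_config(maf_range = c(0.3, 0.1)), "maf_range")
  expect_error(synth_config(block_corr = 1), "block_corr")
  expect_error(synth_config(min_gap = 200, max_gap = 100), "min_gap")
  expect_error(synth_config(compliance = 0.01, n_days = 1, signals_per_day = 2),
               "completed beeps")
  expect_error(
    simulate_esm(rnorm(10), synth_config(n_subjects = 10, signals_per_day = 80)),
    "infeasible")
})

test_that("genotype generation is deterministic and respects block structure", {
  cfg <- synth_config(seed = 42, n_subjects = 100, n_blocks = 4, snps_per_block = 5)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  expect_true(all(g1$dosages %in% 0:2))
  expect_equal(dim(g1$dosages), c(100, 20))
  # blocks far enough apart that a 1000 kb window cannot span two of them
  block_of <- rep(1:4, each = 5)
  for (b in 1:3) {
    last_bp <- max(g1$map$bp[block_of == b])
    first_bp <- min(g1$map$bp[block_of == b + 1])
    expect_gte(first_bp - last_bp, 2e6)
  }
})

test_that("block_corr = 0 gives essentially independent SNPs within a block", {
  cfg <- synth_config(seed = 1, n_subjects = 500, n_blocks = 3,
                      snps_per_block = 8, block_corr = 0)
  g <- simulate_genotypes(cfg)
  for (b in 1:3) {
    cols <- (b - 1) * 8 + 1:8
    cm <- cor(g$dosages[, cols])
    off <- abs(cm[upper.tri(cm)])
    expect_lt(mean(off), 0.1)
  }
})

test_that("within-block dosage r2 matches a direct Monte-Carlo oracle", {
  cfg <- synth_config(seed = 9, n_subjects = 1000, n_blocks = 2,
                      snps_per_block = 10, block_corr = 0.9,
                      maf_range = c(0.2, 0.4))
  g <- simulate_genotypes(cfg)
  mean_r2 <- function(D) {
    cm <- cor(D)^2
    mean(cm[upper.tri(cm)])
  }
  obs <- mean(vapply(1:2, function(b)
    mean_r2(g$dosages[, (b - 1) * 10 + 1:10]), numeric(1)))
  # independent re-simulation of the same latent-Gaussian threshold scheme
  set.seed(777)
  n <- 1000; m <- 10; rho <- 0.9
  maf <- runif(m, 0.2, 0.4)
  thr <- qnorm(1 - maf)
  D <- matrix(0, n, m)
  for (gam in 1:2) {
    z <- sqrt(rho) * rnorm(n) + sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
    D <- D + (z > rep(thr, each = n))
  }
  expect_lt(abs(obs - mean_r2(D)), 0.15)
})

test_that("summary statistics have the advertised beta/p structure", {
  map <- data.frame(snp = sprintf("s%d", 1:5000),
                    maf = runif(5000, 0.05, 0.5))
  # degenerate: every SNP causal with zero effect-size spread
  cfg0 <- synth_config(seed = 3, prop_causal = 1, beta_sd = 0)
  ss0 <- simulate_summary_stats(map, cfg0)
  expect_true(all(ss0$beta == 0))
  expect_true(all(ss0$p > 0 & ss0$p <= 1))
  # p monotone decreasing in |beta| * sqrt(2 maf (1 - maf))
  cfg <- synth_config(seed = 4, prop_causal = 0.3, beta_sd = 0.1)
  ss <- simulate_summary_stats(map, cfg)
  std <- abs(ss$beta) * sqrt(2 * map$maf * (1 - map$maf))
  expect_lt(cor(ss$p, std, method = "spearman"), 0)
  # effectively pure-null generation: uniform p-values
  cfg_null <- synth_config(seed = 5, prop_causal = 1e-9, beta_sd = 0.1)
  ssn <- simulate_summary_stats(map, cfg_null)
  expect_lt(abs(mean(ssn$p < 0.05) - 0.05), 0.02)
})

test_that("signal schedules are legal and complete under full compliance", {
  cfg <- synth_config(seed = 6, n_subjects = 20, compliance = 1)
  sim <- simulate_esm(rnorm(20), cfg)
  e <- sim$esm
  expect_true(all(tapply(e$observed, e$subject_id, sum) == 56))
  expect_true(all(e$time_min >= 600 & e$time_min <= 1320))
  gaps <- unlist(tapply(e$time_min, interaction(e$subject_id, e$day), diff))
  expect_true(all(gaps >= 10 & gaps <= 170))
})

test_that("default compliance reproduces the target completed-beep rate", {
  cfg <- synth_config(seed = 8)   # 217 subjects, default compliance
  sim <- simulate_esm(rnorm(217), cfg)
  per_subj <- tapply(sim$esm$observed, sim$esm$subject_id, sum)
  expect_lt(abs(mean(per_subj) - 40.7), 2)
})

test_that("ESM generation is deterministic and records ground truth", {
  cfg <- synth_config(seed = 10, n_subjects = 15)
  G <- rnorm(15)
  s1 <- simulate_esm(G, cfg)
  s2 <- simulate_esm(G, cfg)
  expect_identical(s1, s2)
  expect_named(s1$truth, c("u", "G", "params", "model", "latent"))
  expect_length(s1$truth$u, 15)
})

test_that("with no item noise and no rounding the index equals the latent outcome", {
  cfg <- synth_config(seed = 12, n_subjects = 10, item_noise_sd = 0,
                      round_items = FALSE, compliance = 1)
  sim <- simulate_esm(rnorm(10), cfg)
  e <- build_indices(sim$esm)
  expect_equal(e$paranoia, sim$truth$latent$paranoia, tolerance = 1e-12)
  expect_equal(e$pa, sim$truth$latent$pa, tolerance = 1e-12)
})

test_that("a null G-by-E regime yields no spurious interaction slope", {
  zs <- vapply(1:20, function(s) {
    cfg <- synth_config(seed = 100 + s, n_subjects = 40, compliance = 1,
                        true_params = list(b0 = 4, s0 = 0.3, s1 = 0, c = 4,
                                           sigma_u = 0, sigma_e = 0.6),
                        item_noise_sd = 0, round_items = FALSE)
    set.seed(500 + s)
    G <- rnorm(40)
    sim <- simulate_esm(G, cfg)
    e <- build_indices(sim$esm)
    lag <- make_lagged_pairs(e, "positive", "paranoia")
    lag$G <- G[match(lag$subject_id, unique(e$subject_id))]
    f <- lm(y ~ I(G * (E - 4)) + I(E - 4), data = lag)
    coef(summary(f))[2, "t value"]
  }, numeric(1))
  expect_true(all(abs(zs) < 3))
})
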