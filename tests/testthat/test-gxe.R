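# Crossover-model fitting, bootstrap CI, and AIC classification.

test_that("specs tie frameworks to crossover anchors and strength to s0", {
  expect_equal(gxe_spec("differential_susceptibility")$crossover, "free")
  expect_equal(gxe_spec("diathesis_stress")$crossover, "fixed_at_max")
  expect_equal(gxe_spec("vantage_sensitivity")$crossover, "fixed_at_min")
  expect_length(gxe_specs_all(), 6)
  d <- sim_lagged(n_subj = 30, n_per = 8, seed = 20)
  f <- fit_crossover(d, gxe_spec("diathesis_stress", "strong"))
  expect_equal(f$s0, 0)
})

test_that("fixed-crossover fits are invariant to affine recoding of E", {
  d <- sim_lagged(n_subj = 30, n_per = 8, seed = 21)
  f1 <- fit_crossover(d, gxe_spec("diathesis_stress", "weak"))
  d2 <- transform(d, E = E - max(d$E))
  f2 <- fit_crossover(d2, gxe_spec("diathesis_stress", "weak"))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
})

test_that("noiseless crossover data are interpolated exactly", {
  d <- sim_lagged(n_subj = 25, n_per = 8, b0 = 0, s0 = 2, s1 = 1.5, c = 4,
                  su = 0, se = 0, seed = 22)
  f <- fit_crossover(d, gxe_spec("differential_susceptibility", "weak"))
  expect_equal(f$c, 4, tolerance = 1e-6)
  expect_equal(f$s0, 2, tolerance = 1e-6)
  expect_equal(f$s1, 1.5, tolerance = 1e-6)
  # strong truth recovered by the strong profile
  ds <- sim_lagged(n_subj = 25, n_per = 8, b0 = 1, s0 = 0, s1 = 1.5, c = 4,
                   su = 0, se = 0, seed = 23)
  fs <- fit_crossover(ds, gxe_spec("differential_susceptibility", "strong"))
  expect_equal(fs$c, 4, tolerance = 1e-5)
  expect_equal(fs$s1, 1.5, tolerance = 1e-5)
  expect_equal(fs$b0, 1, tolerance = 1e-5)
})

test_that("the weak free crossover is the exact interaction reparameterization", {
  for (case in 1:5) {
    d <- sim_lagged(n_subj = 40, n_per = 8, s0 = runif(1, -1, 1),
                    s1 = runif(1, 0.2, 0.8), c = runif(1, 2, 6),
                    seed = 8000 + case)
    f <- fit_crossover(d, gxe_spec("differential_susceptibility", "weak"))
    std <- lmm_ml(y ~ G + E + G:E, d)
    expect_equal(f$loglik, std$loglik, tolerance = 1e-6)
    expect_equal(f$aic, std$aic, tolerance = 1e-6)
    cf <- std$coefficients
    expect_equal(f$c, -cf[["G"]] / cf[["G:E"]], tolerance = 1e-6)
  }
})

test_that("the strong free-crossover profile matches a dense grid search", {
  d <- sim_lagged(n_subj = 20, n_per = 6, b0 = 2, s0 = 0, s1 = 0.6, c = 3.5,
                  su = 0.4, se = 0.6, seed = 24)
  f <- fit_crossover(d, gxe_spec("differential_susceptibility", "strong"))
  # brute force: dense grid over the same extended range
  dd <- d[complete.cases(d), ]
  B <- cbind(1, G = dd$G, GE = dd$G * dd$E)
  stB <- esmgxe:::lmm_stats(B, dd$y, dd$subject_id)
  r <- diff(range(dd$E))
  cs <- seq(min(dd$E) - 0.5 * r, max(dd$E) + 0.5 * r, length.out = 10001)
  lls <- vapply(cs, function(cc)
    esmgxe:::lmm_loglik_stats(
      esmgxe:::lmm_stats_transform(stB, esmgxe:::strong_T(3, cc)), tol = 1e-6),
    numeric(1))
  expect_lt(max(lls) - f$loglik, 1e-4)
  expect_lt(abs(f$c - cs[which.max(lls)]), 0.01)
})

test_that("model nesting is respected in log-likelihood", {
  d <- sim_lagged(n_subj = 35, n_per = 8, s0 = 0.4, s1 = 0.3, seed = 25)
  fits <- lapply(gxe_specs_all(), function(sp) fit_crossover(d, sp))
  for (fw in c("differential_susceptibility", "diathesis_stress",
               "vantage_sensitivity")) {
    wk <- fits[[paste0(fw, ".weak")]]
    st <- fits[[paste0(fw, ".strong")]]
    expect_lte(st$loglik, wk$loglik + 1e-6)
  }
  # fixed-c weak models are restrictions of the free-c weak model
  expect_lte(fits[["diathesis_stress.weak"]]$loglik,
             fits[["differential_susceptibility.weak"]]$loglik + 1e-6)
  expect_lte(fits[["vantage_sensitivity.weak"]]$loglik,
             fits[["differential_susceptibility.weak"]]$loglik + 1e-6)
})

test_that("AIC bookkeeping counts the free crossover point", {
  d <- sim_lagged(n_subj = 30, n_per = 6, seed = 26)
  wk_free <- fit_crossover(d, gxe_spec("differential_susceptibility", "weak"))
  wk_fix <- fit_crossover(d, gxe_spec("diathesis_stress", "weak"))
  st_free <- fit_crossover(d, gxe_spec("differential_susceptibility", "strong"))
  st_fix <- fit_crossover(d, gxe_spec("diathesis_stress", "strong"))
  expect_equal(wk_free$n_params, wk_fix$n_params + 1L)
  expect_equal(st_free$n_params, st_fix$n_params + 1L)
  for (f in list(wk_free, wk_fix, st_free, st_fix))
    expect_equal(f$aic, 2 * f$n_params - 2 * f$loglik, tolerance = 1e-10)
})

test_that("near-zero interaction makes the weak crossover non-identifiable", {
  d <- sim_lagged(n_subj = 20, n_per = 5, s1 = 0, su = 0, se = 0, seed = 27)
  expect_warning(f <- fit_crossover(d, gxe_spec("differential_susceptibility",
                                                "weak")),
                 "non-identifiable")
  expect_false(f$identifiable)
  expect_true(is.na(f$c))
})

test_that("bootstrap CIs are seeded, and collapse in the noiseless limit", {
  d <- sim_lagged(n_subj = 40, n_per = 10, s0 = 0.5, s1 = 0.5, c = 4,
                  su = 0, se = 1e-4, seed = 28)
  f <- fit_crossover(d, gxe_spec("differential_susceptibility", "weak"))
  ci <- crossover_ci(f, n_boot = 100, seed = 99)
  expect_lt(diff(ci), 0.01)
  expect_lt(abs(mean(ci) - 4), 0.01)
  ci2 <- crossover_ci(f, n_boot = 100, seed = 99)
  expect_identical(as.numeric(ci), as.numeric(ci2))
  # strong-model bootstrap is deterministic too
  ds <- sim_lagged(n_subj = 30, n_per = 8, s0 = 0, s1 = 0.6, c = 4,
                   su = 0.3, se = 0.5, seed = 29)
  fs <- fit_crossover(ds, gxe_spec("differential_susceptibility", "strong"))
  ci3 <- crossover_ci(fs, n_boot = 50, seed = 7)
  ci4 <- crossover_ci(fs, n_boot = 50, seed = 7)
  expect_identical(as.numeric(ci3), as.numeric(ci4))
  expect_true(ci3[1] < fs$c && fs$c < ci3[2])
})

test_that("classification always produces a six-row AIC table", {
  d <- sim_lagged(n_subj = 40, n_per = 8, s0 = 0.4, s1 = 0, seed = 30)
  cl <- classify_gxe(d, n_boot = 50, seed = 1)
  expect_equal(nrow(cl$aic_table), 6)
  expect_true(all(is.finite(cl$aic_table$aic)))
  expect_equal(cl$aic_table$aic[1], min(cl$aic_table$aic))
  expect_true(is.character(cl$label) && nchar(cl$label) > 0)
})

test_that("a strong differential-susceptibility truth is classified DS S", {
  d <- sim_lagged(n_subj = 120, n_per = 20, b0 = 3, s0 = 0, s1 = 0.5, c = 4,
                  su = 0.4, se = 0.7, seed = 31)
  cl <- classify_gxe(d, n_boot = 100, seed = 2)
  expect_equal(cl$label, "DS S")
  expect_true(cl$within_bounds)
  expect_lt(abs(cl$c_hat - 4), 0.3)
})
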