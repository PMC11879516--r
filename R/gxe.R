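# Competitive-confirmatory G-by-E classification via crossover-point models.
#
# All six candidate models share the mean structure
#   y = b0 + u_i + sum_k gamma_k cov_k + (s0 + s1 G_i) (E - c)
# with a random intercept u_i.  The frameworks differ only in the crossover
# point c and the baseline environmental slope s0:
#   differential susceptibility : c free (estimated)
#   diathesis-stress            : c fixed at the observed maximum of E
#   vantage sensitivity         : c fixed at the observed minimum of E
# and the "strong" variant of each constrains s0 = 0.  For fixed c the model
# is linear in its coefficients and is fitted directly by the random-intercept
# ML engine.  The weak free-c model is an exact reparameterization of the
# ordinary G + E + G:E interaction model (c = -beta_G / beta_GxE).  The
# strong free-c model is genuinely nonlinear in c and is fitted by profiling
# the ML over a grid of crossover points spanning the observed E bounds
# extended by 50% of the range on each side, followed by local refinement.
#
# Model competition is by AIC (ML); a differential-susceptibility winner is
# labelled "DS" only when the 95% parametric-bootstrap interval of the
# crossover point lies within the observed bounds of E.

#' Specify a crossover G-by-E model
#'
#' @param framework one of `"differential_susceptibility"`,
#'   `"diathesis_stress"`, `"vantage_sensitivity"`.
#' @param strength `"weak"` (baseline environmental slope s0 free) or
#'   `"strong"` (s0 constrained to 0).
#' @return list of class `gxe_spec` with fields `framework`, `strength` and
#'   `crossover` (`"free"`, `"fixed_at_max"` or `"fixed_at_min"`, implied by
#'   the framework).
#' @export
gxe_spec <- function(framework = c("differential_susceptibility",
                                   "diathesis_stress", "vantage_sensitivity"),
                     strength = c("weak", "strong")) {
  framework <- match.arg(framework)
  strength <- match.arg(strength)
  crossover <- switch(framework,
                      differential_susceptibility = "free",
                      diathesis_stress = "fixed_at_max",
                      vantage_sensitivity = "fixed_at_min")
  structure(list(framework = framework, strength = strength,
                 crossover = crossover), class = "gxe_spec")
}

#' All six candidate crossover-model specifications
#' @return list of six [gxe_spec()] objects (3 frameworks x weak/strong).
#' @export
gxe_specs_all <- function() {
  fw <- c("differential_susceptibility", "diathesis_stress", "vantage_sensitivity")
  specs <- list()
  for (f in fw) for (s in c("weak", "strong"))
    specs[[paste(f, s, sep = ".")]] <- gxe_spec(f, s)
  specs
}

spec_label <- function(spec) {
  pretty <- c(differential_susceptibility = "DS",
              diathesis_stress = "Diathesis-stress",
              vantage_sensitivity = "Vantage-sensitivity")
  paste(pretty[[spec$framework]], if (spec$strength == "strong") "S" else "W")
}

# Shared preparation: complete cases, group codes, observed E bounds.
gxe_prepare <- function(data, covariates, group) {
  need <- c("y", "G", "E", covariates, group)
  for (v in need) if (!v %in% names(data)) stopf("column '%s' not found", v)
  d <- data[stats::complete.cases(data[, need, drop = FALSE]), , drop = FALSE]
  if (!nrow(d)) stopf("no complete cases")
  list(d = d, e_bounds = range(d$E), grp = d[[group]])
}

#' Fit one crossover-reparameterized G-by-E mixed model
#'
#' @param data lagged-pair data frame with columns `y` (outcome at t+1),
#'   `E` (context at t), `G` (sensitivity score), the covariates, and the
#'   grouping column.
#' @param spec a [gxe_spec()].
#' @param covariates covariate columns entering additively (never multiplied
#'   by `E - c`).
#' @param group grouping column name.
#' @param grid_points number of crossover candidates in the strong free-c
#'   profile grid (default 61, spanning the observed E bounds extended by
#'   50% of the range on each side).
#' @return object of class `crossover_fit` with the crossover parameters
#'   (`b0`, `s0`, `s1`, `c`), full `coefficients`/`se`, variance components,
#'   `loglik`, `n_params` (fixed effects + 2 variance components + the
#'   crossover point when free), `aic`, `e_bounds` and bookkeeping needed by
#'   [crossover_ci()].  In the weak free-c model `|beta_GxE| < 1e-10` makes
#'   the crossover non-identifiable: `c` is `NA` and `identifiable = FALSE`.
#' @export
fit_crossover <- function(data, spec, covariates = character(),
                          group = "subject_id", grid_points = 61) {
  prep <- gxe_prepare(data, covariates, group)
  d <- prep$d
  covM <- if (length(covariates)) as.matrix(d[, covariates, drop = FALSE]) else
    matrix(0, nrow(d), 0)
  colnames(covM) <- covariates
  base <- list(spec = spec, covariates = covariates, e_bounds = prep$e_bounds,
               grp = prep$grp)
  fit <- switch(spec$crossover,
    free = if (spec$strength == "weak")
      fit_weak_free(d, covM, base) else
      fit_strong_free(d, covM, base, grid_points),
    fit_fixed_c(d, covM, base,
                c0 = if (spec$crossover == "fixed_at_max") prep$e_bounds[2]
                     else prep$e_bounds[1])
  )
  fit
}

# Assemble a crossover_fit from an lmm_fit plus crossover bookkeeping.
as_crossover_fit <- function(lf, base, b0, s0, s1, cc, n_params, X, y,
                             identifiable = TRUE, st = NULL, extra = list()) {
  out <- c(list(
    spec = base$spec, covariates = base$covariates,
    coefficients = lf$coefficients, se = lf$se, vcov = lf$vcov,
    b0 = b0, s0 = s0, s1 = s1, c = cc,
    sigma_u2 = lf$sigma_u2, sigma_e2 = lf$sigma_e2, lambda = lf$lambda,
    loglik = lf$loglik, n_params = n_params,
    aic = 2 * n_params - 2 * lf$loglik,
    n_obs = lf$n_obs, n_groups = lf$n_groups,
    converged = lf$converged, identifiable = identifiable,
    e_bounds = base$e_bounds,
    X = X, y = y, grp = base$grp, st = st
  ), extra)
  class(out) <- c("crossover_fit", "lmm_fit")
  out
}

fit_fixed_c <- function(d, covM, base, c0) {
  Ec <- d$E - c0
  if (base$spec$strength == "weak") {
    X <- cbind(`(Intercept)` = 1, covM, E_c = Ec, `G:E_c` = d$G * Ec)
  } else {
    X <- cbind(`(Intercept)` = 1, covM, `G:E_c` = d$G * Ec)
  }
  st <- lmm_stats(X, d$y, base$grp)
  lf <- lmm_fit_stats(st)
  cf <- lf$coefficients
  as_crossover_fit(lf, base,
                   b0 = cf[["(Intercept)"]],
                   s0 = if (base$spec$strength == "weak") cf[["E_c"]] else 0,
                   s1 = cf[["G:E_c"]],
                   cc = c0, n_params = lf$n_params, X = X, y = d$y, st = st)
}

fit_weak_free <- function(d, covM, base) {
  X <- cbind(`(Intercept)` = 1, covM, G = d$G, E = d$E, `G:E` = d$G * d$E)
  st <- lmm_stats(X, d$y, base$grp)
  lf <- lmm_fit_stats(st)
  cf <- lf$coefficients
  s1 <- cf[["G:E"]]
  identifiable <- abs(s1) >= 1e-10
  cc <- if (identifiable) -cf[["G"]] / s1 else NA_real_
  s0 <- cf[["E"]]
  b0 <- if (identifiable) cf[["(Intercept)"]] + s0 * cc else NA_real_
  if (!identifiable)
    warnf("weak free-crossover model non-identifiable: |beta_GxE| < 1e-10")
  # same parameter count as the interaction model: (b0, s0, s1, c) <-> 4 betas
  as_crossover_fit(lf, base, b0 = b0, s0 = s0, s1 = s1, cc = cc,
                   n_params = lf$n_params, X = X, y = d$y,
                   identifiable = identifiable, st = st)
}

# Strong free-c: profile the ML over the crossover point.  The design at any
# c is a linear map of the fixed basis [1, covs, G, G*E], so each candidate
# costs only a small-matrix transformation of precomputed statistics.
strong_T <- function(q, c) {
  # basis columns: 1, covs..., G, GE ; model columns: 1, covs..., GE - c*G
  Tm <- diag(q)[, -(q - 1), drop = FALSE]
  Tm[q - 1, q - 1] <- -c     # G row, last model column
  Tm
}

strong_grid <- function(e_bounds, grid_points) {
  r <- diff(e_bounds)
  if (r == 0) r <- 1
  seq(e_bounds[1] - 0.5 * r, e_bounds[2] + 0.5 * r, length.out = grid_points)
}

profile_strong_c <- function(stB, e_bounds, grid_points) {
  q <- stB$p
  ll_at <- function(c) lmm_loglik_stats(lmm_stats_transform(stB, strong_T(q, c)))
  cs <- strong_grid(e_bounds, grid_points)
  lls <- vapply(cs, ll_at, numeric(1))
  i <- which.max(lls)
  lo <- cs[max(i - 1, 1)]; hi <- cs[min(i + 1, length(cs))]
  opt <- stats::optimize(ll_at, c(lo, hi), maximum = TRUE, tol = 1e-8)
  if (opt$objective >= lls[i]) list(c = opt$maximum, ll = opt$objective)
  else list(c = cs[i], ll = lls[i])
}

# Warm-started refit of the strong free-c model, used by the parametric
# bootstrap: coordinate ascent alternating a 1-D search over c (at fixed
# variance ratio) with the 1-D lambda profile (at fixed c), starting from
# the parent fit's optimum.  Bootstrap outcomes are perturbations of data
# whose optimum is already located, so a few sweeps suffice.
profile_strong_c_warm <- function(stB, e_bounds, lambda0, max_sweeps = 4) {
  q <- stB$p
  r <- diff(e_bounds); if (r == 0) r <- 1
  c_range <- c(e_bounds[1] - 0.5 * r, e_bounds[2] + 0.5 * r)
  lam <- lambda0
  ll_old <- -Inf
  cc <- NA_real_
  for (s in seq_len(max_sweeps)) {
    oc <- stats::optimize(function(c)
      lmm_profile(lmm_stats_transform(stB, strong_T(q, c)), lam)$ll,
      c_range, maximum = TRUE, tol = 1e-6)
    cc <- oc$maximum
    stc <- lmm_stats_transform(stB, strong_T(q, cc))
    ol <- stats::optimize(function(loglam) lmm_profile(stc, exp(loglam))$ll,
                          log(c(1e-8, 1e8)), maximum = TRUE, tol = 1e-4)
    lam <- exp(ol$maximum)
    if (lmm_profile(stc, 0)$ll >= ol$objective) lam <- 0
    ll <- max(ol$objective, lmm_profile(stc, 0)$ll)
    if (ll - ll_old < 1e-6) break
    ll_old <- ll
  }
  list(c = cc, lambda = lam)
}

fit_strong_free <- function(d, covM, base, grid_points) {
  B <- cbind(`(Intercept)` = 1, covM, G = d$G, GE = d$G * d$E)
  stB <- lmm_stats(B, d$y, base$grp)
  prof <- profile_strong_c(stB, base$e_bounds, grid_points)
  q <- stB$p
  terms <- c(colnames(B)[seq_len(q - 2)], "G:E_c")
  lf <- lmm_fit_stats(lmm_stats_transform(stB, strong_T(q, prof$c), terms))
  cf <- lf$coefficients
  n_params <- lf$n_params + 1L   # the free crossover point
  as_crossover_fit(lf, base, b0 = cf[["(Intercept)"]], s0 = 0,
                   s1 = cf[["G:E_c"]], cc = prof$c, n_params = n_params,
                   X = B %*% strong_T(q, prof$c), y = d$y,
                   st = stB, extra = list(basis = B, grid_points = grid_points))
}

#' @export
print.crossover_fit <- function(x, ...) {
  cat(sprintf("Crossover G-by-E model: %s (%s, crossover %s)\n",
              spec_label(x$spec), x$spec$strength, x$spec$crossover))
  cat(sprintf("  b0 = %.4f, s0 = %.4f, s1 = %.4f, c = %.4f\n",
              x$b0, x$s0, x$s1, x$c))
  if (!is.null(x$c_ci))
    cat(sprintf("  95%% CI for c: [%.3f, %.3f]\n", x$c_ci[1], x$c_ci[2]))
  cat(sprintf("  logLik = %.4f, AIC = %.4f (%d parameters), n = %d in %d subjects\n",
              x$loglik, x$aic, x$n_params, x$n_obs, x$n_groups))
  invisible(x)
}

#' Parametric-bootstrap confidence interval for the crossover point
#'
#' Simulates `n_boot` outcome vectors from the fitted model (drawing fresh
#' random intercepts and residuals around the fitted fixed-effect mean),
#' refits the same free-crossover specification to each, and returns the
#' 2.5/97.5 percentiles of the bootstrap crossover estimates.  Bootstrap
#' replicates whose refit is non-identifiable are dropped; if more than 10%
#' are dropped the interval is flagged and a warning raised.  Strong-model
#' refits use warm-started coordinate ascent from the parent fit's optimum,
#' since each bootstrap replicate only perturbs an already-located optimum.
#'
#' @param fit a `crossover_fit` with a free, identifiable crossover.
#' @param n_boot number of bootstrap replicates (default 500).
#' @param seed integer seed making the interval reproducible; `NULL` uses
#'   the current RNG stream.
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)` with attributes `boot_c` (the bootstrap
#'   draws) and `widened` (flag: >10% of refits non-identifiable).
#' @export
crossover_ci <- function(fit, n_boot = 500, seed = NULL, level = 0.95) {
  if (!identical(fit$spec$crossover, "free"))
    stopf("crossover_ci requires a free-crossover fit")
  if (!isTRUE(fit$identifiable)) stopf("crossover point is not identifiable")
  mu <- drop(fit$X %*% fit$coefficients)
  gidx <- match(fit$grp, unique(fit$grp))
  G <- max(gidx)
  su <- sqrt(fit$sigma_u2); se <- sqrt(fit$sigma_e2)
  n <- length(mu)
  weak <- fit$spec$strength == "weak"
  if (weak) {
    stX <- fit$st
    Xw <- fit$X
  } else {
    stB <- fit$st
    q <- stB$p
    B <- fit$basis
  }
  cs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ys <- mu + stats::rnorm(G, 0, su)[gidx] + stats::rnorm(n, 0, se)
      if (weak) {
        lf <- lmm_fit_stats(lmm_stats_newy(stX, Xw, ys))
        s1 <- lf$coefficients[["G:E"]]
        if (abs(s1) < 1e-10) NA_real_ else -lf$coefficients[["G"]] / s1
      } else {
        stb <- lmm_stats_newy(stB, B, ys)
        profile_strong_c_warm(stb, fit$e_bounds, lambda0 = fit$lambda)$c
      }
    }, numeric(1))
  })
  bad <- mean(is.na(cs))
  widened <- bad > 0.1
  if (widened)
    warnf("%.0f%% of bootstrap refits were non-identifiable; CI unreliable",
          100 * bad)
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(cs, c(alpha, 1 - alpha), na.rm = TRUE))
  attr(ci, "boot_c") <- cs
  attr(ci, "widened") <- widened
  ci
}

#' Competitive-confirmatory classification of a G-by-E interaction
#'
#' Fits all six crossover models (3 frameworks x weak/strong), compares them
#' by AIC, and classifies the interaction.  Ties are broken toward fewer
#' parameters, then toward fixed-crossover specifications (parsimony).  When
#' a differential-susceptibility model wins, the 95% parametric-bootstrap
#' interval of its crossover point is computed: the interaction is labelled
#' `"DS S"`/`"DS W"` only if that interval lies within the observed bounds
#' of `E`, and `"unclassified DS (out-of-bounds)"` otherwise.  Other winners
#' are labelled by framework and strength as in standard reporting
#' (`"Diathesis-stress W"`, `"Vantage-sensitivity S"`, ...).
#'
#' @param data lagged-pair data frame (see [fit_crossover()]).
#' @param covariates additive covariate columns (post-trimming).
#' @param group grouping column name.
#' @param n_boot bootstrap replicates for the crossover CI (default 500).
#' @param seed seed for the bootstrap.
#' @return object of class `gxe_classification`: `aic_table` (six rows),
#'   `best` (winning [gxe_spec()]), `fits`, `c_hat`, `c_ci`, `e_bounds`,
#'   `within_bounds` and `label`.
#' @export
classify_gxe <- function(data, covariates = character(), group = "subject_id",
                         n_boot = 500, seed = NULL) {
  specs <- gxe_specs_all()
  fits <- lapply(specs, function(sp)
    tryCatch(fit_crossover(data, sp, covariates = covariates, group = group),
             error = function(e) {
               warnf("fit failed for %s: %s", spec_label(sp), conditionMessage(e))
               NULL
             }))
  ok <- !vapply(fits, is.null, logical(1)) &
    vapply(fits, function(f) is.null(f) || isTRUE(f$converged), logical(1))
  if (sum(ok) < 2) stopf("fewer than 2 crossover models converged; cannot classify")
  tab <- do.call(rbind, lapply(names(specs)[ok], function(nm) {
    f <- fits[[nm]]
    data.frame(model = spec_label(f$spec), framework = f$spec$framework,
               strength = f$spec$strength, crossover = f$spec$crossover,
               n_params = f$n_params, loglik = f$loglik, aic = f$aic,
               stringsAsFactors = FALSE)
  }))
  # min AIC; ties -> fewer parameters, then fixed-c before free-c
  o <- order(tab$aic, tab$n_params, tab$crossover == "free")
  tab <- tab[o, ]
  best_nm <- names(specs)[ok][o[1]]
  best_fit <- fits[[best_nm]]
  c_hat <- NA_real_; c_ci <- NULL; within <- NA
  label <- spec_label(best_fit$spec)
  if (best_fit$spec$framework == "differential_susceptibility") {
    if (isTRUE(best_fit$identifiable)) {
      c_hat <- best_fit$c
      c_ci <- crossover_ci(best_fit, n_boot = n_boot, seed = seed)
      within <- c_ci[1] >= best_fit$e_bounds[1] && c_ci[2] <= best_fit$e_bounds[2]
      if (!isTRUE(within)) label <- "unclassified DS (out-of-bounds)"
    } else {
      within <- FALSE
      label <- "unclassified DS (non-identifiable)"
    }
  }
  structure(list(aic_table = tab, best = best_fit$spec, fits = fits,
                 best_fit = best_fit, c_hat = c_hat,
                 c_ci = if (is.null(c_ci)) NULL else as.numeric(c_ci),
                 e_bounds = best_fit$e_bounds, within_bounds = within,
                 label = label),
            class = "gxe_classification")
}

#' @export
print.gxe_classification <- function(x, ...) {
  cat("Competitive-confirmatory G-by-E classification\n")
  print(format(x$aic_table[, c("model", "n_params", "loglik", "aic")],
               digits = 6), row.names = FALSE)
  if (!is.na(x$c_hat))
    cat(sprintf("  crossover c = %.3f, 95%% CI [%.3f, %.3f], observed E in [%.2f, %.2f]\n",
                x$c_hat, x$c_ci[1], x$c_ci[2], x$e_bounds[1], x$e_bounds[2]))
  cat(sprintf("  label: %s\n", x$label))
  invisible(x)
}
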