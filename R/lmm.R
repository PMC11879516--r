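# Random-intercept linear mixed models fitted by maximum likelihood.
#
# The marginal model for subject (group) g is
#   y_g = X_g beta + u_g 1 + e_g,  u_g ~ N(0, sigma_u^2), e_g ~ N(0, sigma_e^2 I)
# so Cov(y_g) = sigma_e^2 (I + lambda J) with lambda = sigma_u^2 / sigma_e^2 and
# J the all-ones matrix.  For fixed lambda the GLS estimate of beta and the
# profiled sigma_e^2 are closed-form, leaving a one-dimensional maximization
# over log(lambda).  Everything is computed from per-group sufficient
# statistics, which makes refits with a new outcome vector (parametric
# bootstrap) and refits under a reparameterized design (crossover profiling)
# cheap: no pass over the raw data is needed beyond two cross-products.
#
# ML rather than REML throughout: AICs must be comparable across models with
# different fixed-effect structures.

# ---- sufficient statistics -------------------------------------------------

# Per-group sufficient statistics of a design/outcome/grouping triple.
lmm_stats <- function(X, y, group) {
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n || length(group) != n)
    stopf("X, y and group must have matching lengths")
  g <- match(group, unique(group))
  G <- max(g)
  list(
    XtX = crossprod(X),
    Xty = drop(crossprod(X, y)),
    yty = sum(y * y),
    Sx  = rowsum(X, g),            # group sums of design rows (G x p)
    Sy  = drop(rowsum(y, g)),      # group sums of outcome
    n_g = tabulate(g, G),
    n = n, p = ncol(X), G = G,
    gidx = g,
    terms = colnames(X)
  )
}

# Replace the outcome in an existing stats object (design unchanged).
# Used by the parametric bootstrap; X and the grouping are fixed there.
lmm_stats_newy <- function(st, X, y) {
  st$Xty <- drop(crossprod(X, y))
  st$yty <- sum(y * y)
  st$Sy <- drop(rowsum(y, st$gidx))
  st
}

# Map stats of a basis B to stats of X = B %*% Tm.  The crossover profile
# rebuilds the design for each candidate crossover point this way without
# touching the raw data.
lmm_stats_transform <- function(st, Tm, terms = NULL) {
  out <- st
  out$XtX <- crossprod(Tm, st$XtX %*% Tm)
  out$Xty <- drop(crossprod(Tm, st$Xty))
  out$Sx <- st$Sx %*% Tm
  out$p <- ncol(Tm)
  out$terms <- terms %||% paste0("t", seq_len(ncol(Tm)))
  out
}

# ---- profiled likelihood ---------------------------------------------------

# GLS solution and profile log-likelihood at a fixed variance ratio lambda.
lmm_profile <- function(st, lambda, want_vcov = FALSE) {
  w <- lambda / (1 + st$n_g * lambda)
  A <- st$XtX - crossprod(st$Sx, w * st$Sx)
  b <- st$Xty - drop(crossprod(st$Sx, w * st$Sy))
  qy <- st$yty - sum(w * st$Sy^2)
  beta <- tryCatch(solve(A, b), error = function(e)
    stopf("design matrix is rank deficient or ill-conditioned: %s", conditionMessage(e)))
  rss <- max(qy - sum(b * beta), 0)
  sigma_e2 <- max(rss / st$n, .Machine$double.xmin)
  ll <- -0.5 * st$n * (log(2 * pi) + log(sigma_e2) + 1) -
    0.5 * sum(log1p(st$n_g * lambda))
  out <- list(ll = ll, beta = beta, sigma_e2 = sigma_e2, lambda = lambda)
  if (want_vcov) out$vcov <- sigma_e2 * solve(A)
  out
}

# Maximize over log(lambda); lambda = 0 (no subject clustering) is checked
# explicitly as a boundary candidate.
lmm_fit_stats <- function(st, lambda_range = c(1e-8, 1e8)) {
  f <- function(loglam) lmm_profile(st, exp(loglam))$ll
  opt <- stats::optimize(f, log(lambda_range), maximum = TRUE, tol = 1e-7)
  lam <- exp(opt$maximum)
  at_zero <- lmm_profile(st, 0)
  if (at_zero$ll >= opt$objective) lam <- 0
  prof <- lmm_profile(st, lam, want_vcov = TRUE)
  se <- sqrt(pmax(diag(prof$vcov), 0))
  beta <- drop(prof$beta)
  names(beta) <- names(se) <- st$terms
  n_params <- st$p + 2L
  structure(list(
    coefficients = beta,
    se = se,
    vcov = prof$vcov,
    sigma_u2 = lam * prof$sigma_e2,
    sigma_e2 = prof$sigma_e2,
    lambda = lam,
    loglik = prof$ll,
    n_params = n_params,
    aic = 2 * n_params - 2 * prof$ll,
    n_obs = st$n,
    n_groups = st$G,
    converged = is.finite(prof$ll)
  ), class = "lmm_fit")
}

# Log-likelihood only, skipping SE extraction; used inside crossover
# profiles.  The looser default tolerance is safe there: near the optimum
# the profile is locally quadratic in log(lambda), so the loglik error is
# second order in tol and far below the accuracy of the outer c-search.
lmm_loglik_stats <- function(st, lambda_range = c(1e-8, 1e8), tol = 1e-4) {
  f <- function(loglam) lmm_profile(st, exp(loglam))$ll
  opt <- stats::optimize(f, log(lambda_range), maximum = TRUE, tol = tol)
  max(opt$objective, lmm_profile(st, 0)$ll)
}

# ---- user interface --------------------------------------------------------

#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Fits the Gaussian model `y = X beta + u_group + e` with a random intercept
#' per group, by profiling the likelihood over the variance ratio
#' `sigma_u^2 / sigma_e^2`.  ML (not REML) is used so that AIC values are
#' comparable across models with different fixed effects.  Rows with missing
#' values on any model variable are dropped.
#'
#' @param formula model formula for the fixed effects, e.g.
#'   `y ~ G + E + G:E + PC1 + PC2`.
#' @param data data frame containing the model variables and the grouping
#'   column.
#' @param group name of the grouping (subject) column.
#' @return an object of class `lmm_fit` with elements `coefficients`, `se`,
#'   `vcov`, `sigma_u2`, `sigma_e2`, `loglik`, `n_params`, `aic`, `n_obs`,
#'   `n_groups`, and `converged`.  `n_params` counts the fixed effects plus
#'   the two variance components; `aic = 2 n_params - 2 loglik`.
#' @examples
#' d <- data.frame(subject_id = rep(1:10, each = 5),
#'                 x = rnorm(50))
#' d$y <- 1 + 0.5 * d$x + rnorm(10)[d$subject_id] + rnorm(50)
#' fit <- lmm_ml(y ~ x, d)
#' coef(fit)
#' @export
lmm_ml <- function(formula, data, group = "subject_id") {
  if (!group %in% names(data))
    stopf("grouping column '%s' not found in data", group)
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stopf("model variables not found in data: %s", paste(missing_vars, collapse = ", "))
  keep <- stats::complete.cases(data[, c(vars, group), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  mf <- stats::model.frame(formula, d)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  grp <- d[[group]]
  if (length(unique(grp)) < 2) stopf("need at least 2 groups")
  fit <- lmm_fit_stats(lmm_stats(X, y, grp))
  fit$formula <- formula
  fit$group <- group
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept linear mixed model (ML)\n")
  cat(sprintf("  %d observations in %d groups\n", x$n_obs, x$n_groups))
  wt <- wald_tests(x)
  print(format(wt, digits = 4), row.names = FALSE)
  cat(sprintf("  sigma_u^2 = %.4g, sigma_e^2 = %.4g\n", x$sigma_u2, x$sigma_e2))
  cat(sprintf("  logLik = %.4f, AIC = %.4f (%d parameters)\n",
              x$loglik, x$aic, x$n_params))
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$coefficients

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' Wald tests for the fixed effects of a mixed-model fit
#'
#' Computes `z = estimate / SE` and two-sided p-values from the standard
#' normal for every fixed-effect coefficient.  Normal rather than
#' t/Satterthwaite inference is used: the beep-level sample sizes these models
#' are fitted to (thousands of lagged pairs) make the difference negligible.
#'
#' @param fit an `lmm_fit` (or `crossover_fit`) object.
#' @return data frame with columns `term`, `estimate`, `se`, `z`, `p`.
#'   Coefficients with `se == 0` get `NA` statistics and a warning.
#' @export
wald_tests <- function(fit) {
  if (!isTRUE(fit$converged)) stopf("fit did not converge; no Wald tests")
  est <- fit$coefficients
  se <- fit$se
  z <- ifelse(se > 0, est / se, NA_real_)
  if (any(se == 0)) warnf("zero standard error for: %s",
                          paste(names(est)[se == 0], collapse = ", "))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}

#' Trim nonsignificant ancestry covariates from a screening model
#'
#' Fits the screening interaction model
#' `outcome ~ G + E + G:E + covariates` with a random intercept, and drops
#' every candidate covariate whose Wald p-value is at or above `alpha`.  The
#' retained covariate set is what the confirmatory crossover-model stage then
#' adjusts for.
#'
#' @param data lagged-pair data frame with columns `y`, `G`, `E`, the
#'   candidate covariates, and the grouping column.
#' @param covariates character vector of candidate covariate names
#'   (typically `c("PC1", "PC2")`).
#' @param alpha significance level used for trimming (default 0.05).
#' @param group name of the grouping column.
#' @return list with `covariates` (retained names), `dropped`, and `fit`
#'   (the screening `lmm_fit`).
#' @export
trim_covariates <- function(data, covariates = c("PC1", "PC2"),
                            alpha = 0.05, group = "subject_id") {
  fml <- stats::as.formula(paste(
    "y ~ G + E + G:E",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  fit <- lmm_ml(fml, data, group = group)
  wt <- wald_tests(fit)
  pv <- wt$p[match(covariates, wt$term)]
  keep <- covariates[!is.na(pv) & pv < alpha]
  list(covariates = keep, dropped = setdiff(covariates, keep), fit = fit)
}
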