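# Independent reference implementations used as oracles.  These are written
# from the definitions, not from the package's code paths: dense-matrix
# likelihoods, double-loop pair enumeration, pick-the-minimum clumping and a
# literal step-up FDR.

# Brute-force ML for the random-intercept model: numerical maximization of
# the dense multivariate-normal likelihood over (beta, log su2, log se2).
oracle_lmm_dense <- function(X, y, group) {
  X <- as.matrix(X)
  g <- match(group, unique(group))
  n <- length(y)
  Z <- outer(g, seq_len(max(g)), `==`) * 1
  p <- ncol(X)
  nll <- function(par) {
    beta <- par[1:p]
    su2 <- exp(par[p + 1]); se2 <- exp(par[p + 2])
    V <- su2 * tcrossprod(Z) + se2 * diag(n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    r <- as.numeric(y - X %*% beta)
    w <- backsolve(ch, r, transpose = TRUE)
    0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(w * w))
  }
  b0 <- qr.solve(X, y)
  s2 <- stats::var(y - X %*% b0)
  best <- NULL
  for (start_u in c(1e-6, 0.1, 1)) {
    st <- c(b0, log(max(s2 * start_u, 1e-8)), log(max(s2, 1e-8)))
    o <- stats::optim(st, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    o <- stats::optim(o$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(loglik = -best$value, beta = unname(best$par[1:p]),
       sigma_u2 = exp(best$par[p + 1]), sigma_e2 = exp(best$par[p + 2]))
}

# Pick-the-smallest-p clumping, removing the neighbourhood each round.
oracle_clump <- function(stats_df, geno, r2_max = 0.1, window_kb = 1000) {
  remaining <- stats_df
  kept <- character(0)
  cor2 <- function(a, b) {
    x <- geno$dosages[, a]; y <- geno$dosages[, b]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  }
  while (nrow(remaining)) {
    o <- order(remaining$p, remaining$chr, remaining$bp, remaining$snp)
    top <- remaining[o[1], ]
    kept <- c(kept, top$snp)
    drop <- vapply(seq_len(nrow(remaining)), function(i) {
      r <- remaining[i, ]
      r$snp == top$snp ||
        (r$chr == top$chr && abs(r$bp - top$bp) <= window_kb * 1000 &&
           cor2(r$snp, top$snp) >= r2_max)
    }, logical(1))
    remaining <- remaining[!drop, , drop = FALSE]
  }
  m <- stats_df[match(kept, stats_df$snp), ]
  kept[order(m$chr, m$bp, m$snp)]
}

# Exhaustive double-loop enumeration of within-day consecutive-beep pairs.
oracle_pairs <- function(data, predictor, outcome) {
  out <- list()
  for (s in unique(data$subject_id)) for (d in unique(data$day)) {
    dd <- data[data$subject_id == s & data$day == d, ]
    for (k in sort(dd$beep)) {
      r_t <- dd[dd$beep == k, ]
      r_t1 <- dd[dd$beep == k + 1, ]
      if (nrow(r_t) == 1 && nrow(r_t1) == 1 &&
          !is.na(r_t[[predictor]]) && !is.na(r_t1[[outcome]])) {
        out[[length(out) + 1]] <- data.frame(
          subject_id = s, day = d, beep = k,
          E = r_t[[predictor]], y = r_t1[[outcome]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(subject_id = character(0), day = integer(0),
                                      beep = integer(0), E = numeric(0),
                                      y = numeric(0)))
  do.call(rbind, out)
}

# Literal Benjamini-Hochberg step-up with monotonicity enforcement.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
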