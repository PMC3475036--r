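## Profiled-likelihood fitter for the one-random-intercept model
##
##   y = X beta + Z u + e,  u_j ~ N(0, sigma2_f),  e ~ N(0, sigma2_e I)
##
## with Z the family indicator. Writing lambda = sigma2_f / sigma2_e,
## the marginal covariance is sigma2_e * (I + lambda Z Z'), block
## diagonal by family. For a family block of size n_j,
## (I + lambda J)^{-1/2} = I - c_j/n_j J with c_j = 1 - 1/sqrt(1 + n_j
## lambda), so GLS reduces to OLS on family-shrunken data and both the
## ML and REML criteria profile down to a one-dimensional search over
## lambda. This is orders of magnitude faster than a general mixed-model
## fit and is what makes permutation thresholds affordable; it is
## validated against lme4 in the test suite.

## transform y (vector) and X (matrix) for a given lambda; fam_code is
## an integer grouping vector with values 1..K, n_j the group sizes
.fam_transform <- function(y, X, fam_code, n_j, lambda) {
  c_over_n <- (1 - 1 / sqrt(1 + n_j * lambda)) / n_j
  M <- cbind(y, X)
  S <- rowsum(M, fam_code)  # K x (p+1), row k = sums of group k
  Mt <- M - S[fam_code, , drop = FALSE] * c_over_n[fam_code]
  list(y = Mt[, 1L], X = Mt[, -1L, drop = FALSE])
}

## -2 profiled log-likelihood at lambda (ML or REML)
.lmm_crit <- function(lambda, y, X, fam_code, n_j, REML) {
  tr <- .fam_transform(y, X, fam_code, n_j, lambda)
  fit <- stats::lm.fit(tr$X, tr$y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  p <- fit$rank
  logdet_omega <- sum(log1p(n_j * lambda))
  if (REML) {
    XtX <- crossprod(tr$X[, seq_len(ncol(tr$X)), drop = FALSE])
    ld_xtx <- determinant(XtX, logarithm = TRUE)$modulus
    s2 <- rss / (n - p)
    (n - p) * log(2 * pi * s2) + (n - p) + logdet_omega + as.numeric(ld_xtx)
  } else {
    s2 <- rss / n
    n * log(2 * pi * s2) + n + logdet_omega
  }
}

## fit the model; returns coefficients, SEs, variance components and the
## (ML or REML) log-likelihood at the optimum
fit_family_lmm <- function(y, X, family, REML = FALSE, lambda_max = 50) {
  n <- length(y)
  X <- as.matrix(X)
  fam_code <- match(family, unique(family))
  n_j <- tabulate(fam_code)

  if (stats::var(y) < .Machine$double.eps * max(1, mean(y)^2)) {
    beta <- numeric(ncol(X))
    beta[1] <- y[1]
    return(list(beta = beta, se = rep(0, ncol(X)), sigma2_e = 0,
                sigma2_f = 0, lambda = 0, logLik = Inf, REML = REML,
                singular = TRUE))
  }

  crit <- function(l) .lmm_crit(l, y, X, fam_code, n_j, REML)
  lambda <- 0
  c0 <- crit(0)
  if (length(n_j) >= 2L) {
    opt <- stats::optimize(crit, c(0, lambda_max), tol = 1e-9)
    if (opt$objective < c0 - 1e-10) {
      lambda <- opt$minimum
      c0 <- opt$objective
    }
  }

  tr <- .fam_transform(y, X, fam_code, n_j, lambda)
  fit <- stats::lm.fit(tr$X, tr$y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  rss <- sum(fit$residuals^2)
  p <- fit$rank
  sigma2_e <- if (REML) rss / (n - p) else rss / n
  sigma2_f <- lambda * sigma2_e
  XtXinv <- tryCatch(solve(crossprod(tr$X)), error = function(e) NULL)
  se <- if (is.null(XtXinv)) rep(NA_real_, ncol(X)) else {
    sqrt(pmax(diag(XtXinv), 0) * sigma2_e)
  }
  list(beta = as.numeric(beta), se = as.numeric(se), sigma2_e = sigma2_e,
       sigma2_f = sigma2_f, lambda = lambda, logLik = -c0 / 2,
       REML = REML, singular = FALSE)
}
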