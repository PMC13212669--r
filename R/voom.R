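#' Fit per-gene (weighted) linear models
#'
#' Fits `y_g = X beta_g + e_g` for every gene by least squares, with optional
#' strictly positive per-observation precision weights. With no weights all
#' genes share one factorization of `X`; with gene-specific weights the
#' normal equations are solved per gene in compiled code.
#'
#' @param y A [log_cpm()] object or a gene x sample numeric matrix.
#' @param X Design matrix from [build_design()] (full column rank, fewer
#'   columns than samples).
#' @param weights Optional gene x sample matrix of positive weights.
#' @return An object of class `"voom_fit"`: `beta` (gene x coefficient),
#'   `sd` (residual standard deviations `s_g`), `sigma2`, `df_resid`,
#'   `fitted`, `weights` (or `NULL`), `vdiag`/`xtwxinv` (unscaled coefficient
#'   covariances), and the design `X` with its block map.
#' @export
fit_linear_models <- function(y, X, weights = NULL) {
  ymat <- if (inherits(y, "log_cpm")) y$y else as.matrix(y)
  G <- nrow(ymat); n <- ncol(ymat); k <- ncol(X)
  if (nrow(X) != n) stop("design matrix rows must match the number of samples")
  if (qr(X)$rank < k) stop("design matrix is rank-deficient")
  if (n - k < 1L) stop("no residual degrees of freedom (n - rank(X) = 0)")
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!all(dim(weights) == dim(ymat)))
      stop("weights must match the response matrix dimensions")
    if (any(!is.finite(weights)) || any(weights <= 0))
      stop("weights must be strictly positive and finite")
    res <- .wls_batch(ymat, X, weights)
    beta <- res$beta; sigma2 <- res$sigma2
    vdiag <- res$vdiag; xtwxinv <- res$xtwxinv
  } else {
    xtx_inv <- chol2inv(chol(crossprod(X)))
    coef <- xtx_inv %*% crossprod(X, t(ymat))   # k x G
    beta <- t(coef)
    resid <- t(ymat) - X %*% coef
    sigma2 <- colSums(resid^2) / (n - k)
    vdiag <- matrix(diag(xtx_inv), G, k, byrow = TRUE)
    xtwxinv <- xtx_inv                           # shared across genes
  }
  dimnames(beta) <- list(rownames(ymat), colnames(X))
  structure(list(beta = beta,
                 sd = sqrt(sigma2),
                 sigma2 = sigma2,
                 df_resid = n - k,
                 fitted = beta %*% t(X),
                 weights = weights,
                 vdiag = vdiag,
                 xtwxinv = xtwxinv,
                 X = X),
            class = "voom_fit")
}

#' Per-gene mean log-count
#'
#' `c_tilde_g = mean_i(y_gi) + mean_i(log2(R_i + 1)) - log2(1e6)`, the
#' abundance coordinate on which the mean-variance trend is fitted. Equals
#' the direct mean of `log2(c_gi + 0.5)`.
#'
#' @param lc A [log_cpm()] object.
#' @return Numeric vector, one value per gene.
#' @export
mean_log_count <- function(lc) {
  stopifnot(inherits(lc, "log_cpm"))
  rowMeans(lc$y) + mean(log2(lc$libsize + 1)) - log2(1e6)
}

#' voom precision weights from an unweighted first-pass fit
#'
#' Fits a LOWESS trend (span 0.5, 3 robustness iterations) of the
#' quarter-root residual variance `s_g^(1/2)` on the mean log-count
#' `c_tilde_g`, evaluates the trend at every fitted log-count
#' `yhat_gi + log2(R_i + 1) - log2(1e6)` by linear interpolation (constant
#' beyond the observed range), and returns the inverse fourth power as the
#' per-observation precision weight. Trend values are floored at `1e-6`
#' before the `-4` power so weights stay finite.
#'
#' @param fit A [fit_linear_models()] result from an unweighted first pass.
#' @param lc The [log_cpm()] object the fit was computed from.
#' @param span LOWESS span, default 0.5.
#' @return Gene x sample matrix of strictly positive weights.
#' @export
voom_weights <- function(fit, lc, span = 0.5) {
  stopifnot(inherits(fit, "voom_fit"), inherits(lc, "log_cpm"))
  G <- nrow(fit$beta)
  if (G < 10L) stop("fewer than 10 genes: mean-variance trend unfittable")
  sx <- mean_log_count(lc)
  sy <- sqrt(fit$sd)
  l <- stats::lowess(sx, sy, f = span)
  lo <- stats::approxfun(l$x, l$y, rule = 2, ties = list("ordered", mean))
  fitted_logcount <- sweep(fit$fitted, 2L, log2(lc$libsize + 1) - log2(1e6),
                           `+`)
  trend <- pmax(lo(fitted_logcount), 1e-6)
  w <- matrix(trend^-4, nrow = G, dimnames = dimnames(fit$fitted))
  w
}

#' Two-pass voom fit
#'
#' Runs the unweighted first pass, derives precision weights from the
#' mean-variance trend, and refits by weighted least squares. Weights are
#' computed once per model (not iterated).
#'
#' @inheritParams voom_weights
#' @param X Design matrix from [build_design()].
#' @return A `"voom_fit"` from the weighted second pass, with the weight
#'   matrix stored in `$weights`.
#' @export
fit_voom <- function(lc, X, span = 0.5) {
  fit0 <- fit_linear_models(lc, X)
  w <- voom_weights(fit0, lc, span = span)
  fit_linear_models(lc, X, weights = w)
}

# Newton inversion of the trigamma function (solves trigamma(x) = y).
trigamma_inverse <- function(y) {
  if (length(y) == 0L) return(numeric(0))
  out <- y
  out[y > 1e7] <- 1 / sqrt(y[y > 1e7])
  out[y < 1e-6] <- 1 / y[y < 1e-6]
  todo <- y <= 1e7 & y >= 1e-6
  if (any(todo)) {
    x <- 0.5 + 1 / y[todo]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[todo]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(-dif / x) < 1e-8) break
    }
    out[todo] <- x
  }
  out
}

#' Empirical-Bayes moderation of residual variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2` of
#' a scaled inverse-chi-square prior by matching the first two moments of
#' `log(s_g^2)` to a scaled-F distribution (digamma/trigamma moment
#' matching), then shrinks each gene's variance to
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`. Zero empirical excess
#' variability yields `d0 = Inf` (complete shrinkage to the common value);
#' `d0 = 0` is the no-shrinkage limit with `s_tilde^2 = s^2`.
#'
#' @param fit A `"voom_fit"`.
#' @param d0 Optional fixed prior df, overriding estimation (`0` and `Inf`
#'   allowed).
#' @param s0sq Optional fixed prior variance.
#' @return An object of class `"moderated_tests"`: `d0`, `s0sq`,
#'   `s_tilde_sq`, `df_total = d0 + df_resid`, `df_resid`.
#' @export
ebayes_moderate <- function(fit, d0 = NULL, s0sq = NULL) {
  stopifnot(inherits(fit, "voom_fit"))
  x <- fit$sigma2
  df <- fit$df_resid
  if (length(x) < 2L && is.null(d0))
    stop("need at least 2 genes to estimate the variance prior")
  if (is.null(d0)) {
    xx <- pmax(x, 0)
    m <- stats::median(xx)
    if (m == 0) m <- 1
    xx <- pmax(xx, 1e-5 * m)
    z <- log(xx)
    e <- z - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (length(e) - 1L) - trigamma(df / 2)
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0sq <- mean(xx)
    }
  } else if (is.null(s0sq)) {
    s0sq <- if (is.infinite(d0)) mean(x) else stats::median(x)
  }
  s_tilde_sq <- if (is.infinite(d0)) {
    rep(s0sq, length(x))
  } else if (d0 == 0) {
    x
  } else {
    (d0 * s0sq + df * x) / (d0 + df)
  }
  structure(list(d0 = d0, s0sq = s0sq, s_tilde_sq = s_tilde_sq,
                 df_total = d0 + df, df_resid = df),
            class = "moderated_tests")
}

.resolve_block <- function(fit, block) {
  if (is.character(block)) {
    blocks <- attr(fit$X, "blocks")
    if (is.null(blocks[[block]]))
      stop("unknown variable block: ", block)
    block <- blocks[[block]]
  }
  block <- as.integer(block)
  if (length(block) < 1L || any(block < 1L) || any(block > ncol(fit$X)))
    stop("block indices out of range")
  if (1L %in% block) stop("the intercept column cannot be tested")
  block
}

#' Moderated t/F test of a coefficient block
#'
#' Tests `H0: beta_gj = 0` per gene with the empirical-Bayes shrunken
#' variance in the denominator: a moderated t-statistic on `d0 + d` degrees
#' of freedom for single-column blocks, a moderated F comparing the block
#' against zero for multi-column (categorical) blocks.
#'
#' @param fit A `"voom_fit"`.
#' @param tests A `"moderated_tests"` object from [ebayes_moderate()].
#' @param block Column indices of the tested coefficients, or a variable
#'   name resolved through the design's block map. Must not contain the
#'   intercept.
#' @return Numeric vector of two-sided p-values in (0, 1], with the
#'   per-gene statistics in attribute `"stat"`.
#' @export
test_variable <- function(fit, tests, block) {
  stopifnot(inherits(fit, "voom_fit"), inherits(tests, "moderated_tests"))
  block <- .resolve_block(fit, block)
  s2 <- tests$s_tilde_sq
  dft <- tests$df_total
  G <- nrow(fit$beta)
  if (length(block) == 1L) {
    b <- fit$beta[, block]
    se2 <- s2 * fit$vdiag[, block]
    stat <- ifelse(b == 0, 0, b / sqrt(se2))
    p <- 2 * stats::pt(-abs(stat), df = dft)
  } else {
    m <- length(block)
    stat <- numeric(G)
    shared <- is.matrix(fit$xtwxinv)  # unweighted fit: one (X'X)^{-1}
    if (shared)
      Vinv <- solve(fit$xtwxinv[block, block, drop = FALSE])
    for (g in seq_len(G)) {
      b <- fit$beta[g, block]
      if (all(b == 0)) { stat[g] <- 0; next }
      Vi <- if (shared) Vinv else
        solve(fit$xtwxinv[block, block, g, drop = TRUE])
      stat[g] <- drop(b %*% Vi %*% b) / (m * s2[g])
    }
    p <- stats::pf(stat, df1 = m, df2 = dft, lower.tail = FALSE)
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  attr(p, "stat") <- stat
  p
}
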