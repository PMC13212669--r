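#' Pseudo-augmented backward-selection paths
#'
#' For each of `B` Monte-Carlo replicates, generates a fresh set of `k_p`
#' pseudo-variables and runs [backward_path()] over the real candidates plus
#' the pseudo-variables. Each replicate gets its own derived seed so results
#' are reproducible and independent of execution order.
#'
#' @inheritParams backward_path
#' @param mechanism Pseudo-variable generator, see [generate_pseudo()].
#' @param k_p Number of pseudo-variables per set.
#' @param B Number of pseudo-variable sets.
#' @param seed Optional integer seed; per-replicate seeds are derived from
#'   it. `NULL` uses the current RNG state to draw them.
#' @return List of `B` `"selection_path"` objects with pseudo removals
#'   flagged.
#' @export
pseudo_paths <- function(cm, spec, data, mechanism = "ORX", k_p = 7L,
                         B = 100L, seed = NULL, span = 0.5) {
  lc <- if (inherits(cm, "log_cpm")) cm else log_cpm(cm)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, B)
  lapply(seq_len(B), function(b) {
    set.seed(seeds[b])
    Z <- generate_pseudo(mechanism, spec, data, k_p)
    backward_path(lc, spec, data, pseudo = Z, span = span)
  })
}

# Selected-set sizes of one path at a threshold: total and pseudo-only.
.path_counts <- function(path, lambda) {
  sel <- select_at(path, lambda)
  pv <- path$removals$covariate[path$removals$pseudo]
  c(S = length(sel), Istar = sum(sel %in% pv))
}

# Across-replicate means of pseudo-selected and total selected counts on a
# lambda grid. Returns a matrix with columns Ibar_star, Sbar.
.pseudo_means <- function(paths, lambda_grid) {
  acc <- vapply(lambda_grid, function(l) {
    m <- vapply(paths, .path_counts, numeric(2), lambda = l)
    c(Ibar_star = mean(m["Istar", ]), Sbar = mean(m["S", ]))
  }, numeric(2))
  t(acc)
}

#' Ratio-of-expectations FSR estimate on the pseudo scale
#'
#' `alpha_RE,P(lambda)` estimated by `Ibar*_P(lambda) / (1 + Sbar_P(lambda))`
#' where `Ibar*_P` and `Sbar_P` are across-replicate means of the number of
#' selected pseudo-variables and the total number selected in the augmented
#' paths.
#'
#' @param paths List of pseudo-augmented `"selection_path"`s.
#' @param lambda Threshold(s) at which to evaluate.
#' @return Numeric vector, one estimate per lambda.
#' @export
alpha_re_hat <- function(paths, lambda) {
  m <- .pseudo_means(paths, lambda)
  unname(m[, "Ibar_star"] / (1 + m[, "Sbar"]))
}

#' Expectation-of-ratio FSR estimate on the pseudo scale
#'
#' `alpha_ER,P(lambda)` estimated by `Ibar*_P(lambda) / (1 + S(lambda))`
#' with `S(lambda)` taken from the original (non-augmented) path.
#'
#' @inheritParams alpha_re_hat
#' @param original_path The `"selection_path"` of the un-augmented data.
#' @return Numeric vector, one estimate per lambda.
#' @export
alpha_er_hat <- function(paths, original_path, lambda) {
  m <- .pseudo_means(paths, lambda)
  S <- vapply(lambda, function(l) length(select_at(original_path, l)),
              numeric(1))
  unname(m[, "Ibar_star"] / (1 + S))
}

#' Critical value of the pseudo-scale FSR curve
#'
#' For target FSR `alpha0`, the cutoff applied to the estimated pseudo-scale
#' curve: `c = k_p alpha0 / (k_p alpha0 + k_i)` for the RE estimator and
#' `c = (k_p / k_i) alpha0` for ER. Increasing in `alpha0`, decreasing in
#' `k_i`.
#'
#' @param alpha0 Target FSR in (0, 1).
#' @param k_p Number of pseudo-variables per set.
#' @param k_i (Estimated) number of truly irrelevant candidates, >= 1.
#' @param estimator `"RE"` or `"ER"`.
#' @return Scalar threshold.
#' @export
fsr_threshold <- function(alpha0, k_p, k_i, estimator = c("RE", "ER")) {
  estimator <- match.arg(estimator)
  stopifnot(alpha0 > 0, alpha0 < 1, k_p >= 1, k_i >= 1)
  if (estimator == "RE") k_p * alpha0 / (k_p * alpha0 + k_i)
  else k_p * alpha0 / k_i
}

#' Joint estimation of k_I and the selection threshold lambda*
#'
#' Fixed-point iteration coupling the unknown number of irrelevant
#' candidates `k_I` with the critical threshold: starting from
#' `k_I = k_C` (all candidates irrelevant), repeat — compute the cutoff
#' [fsr_threshold()], take `lambda*` as the smallest grid value whose
#' estimated pseudo-scale FSR is below the cutoff, update
#' `k_I = k_C - S(lambda*)` (floored at 1) from the original path — until
#' `k_I` stabilizes (at most `k_C` iterations).
#'
#' @param alpha_curve Data frame with columns `lambda` and `alpha`, the
#'   estimated pseudo-scale FSR on the threshold grid.
#' @param original_path The un-augmented `"selection_path"`.
#' @param alpha0 Target FSR.
#' @param k_p Number of pseudo-variables per set.
#' @param estimator `"RE"` or `"ER"`.
#' @return List with `k_i_hat` and `lambda_star_hat` (`Inf`, with a warning,
#'   when no grid point meets the cutoff).
#' @export
estimate_ki_lambda <- function(alpha_curve, original_path, alpha0 = 0.05,
                               k_p = 7L, estimator = c("RE", "ER")) {
  estimator <- match.arg(estimator)
  stopifnot(is.data.frame(alpha_curve),
            all(c("lambda", "alpha") %in% names(alpha_curve)))
  k_c <- sum(!original_path$removals$pseudo)
  if (k_c == 0L)  # nothing to select: trivially empty result
    return(list(k_i_hat = 0L, lambda_star_hat = Inf))
  k_i <- k_c
  lambda <- Inf
  for (iter in seq_len(max(k_c, 1L))) {
    cutoff <- fsr_threshold(alpha0, k_p, k_i, estimator)
    ok <- which(alpha_curve$alpha <= cutoff)
    lambda <- if (length(ok) == 0L) Inf else min(alpha_curve$lambda[ok])
    k_i_new <- max(k_c - length(select_at(original_path, lambda)), 1L)
    if (k_i_new == k_i) break
    k_i <- k_i_new
  }
  if (is.infinite(lambda))
    warning("no threshold meets the FSR cutoff; selecting no covariates")
  list(k_i_hat = k_i, lambda_star_hat = lambda)
}

#' FSR-controlled covariate selection
#'
#' The full procedure: (1) backward selection on the original data; (2) `B`
#' backward-selection runs augmented with freshly generated pseudo-variable
#' sets; (3) estimation of the pseudo-scale FSR curve on the grid of all
#' recorded relevance values, joint estimation of `k_I` and the critical
#' threshold `lambda*`; (4) the covariates of the original path surviving at
#' `lambda*` are the selected set, ready for differential expression
#' analysis.
#'
#' @inheritParams pseudo_paths
#' @param alpha0 Target false selection rate, default 0.05.
#' @param estimator FSR functional: `"RE"` (ratio of expectations) or
#'   `"ER"` (expectation of ratios).
#' @return An object of class `"fsr_result"` with the threshold grid, the
#'   averaged pseudo-selection counts, the estimated FSR curves (pseudo
#'   scale and inverted to the real-covariate scale), `k_i_hat`,
#'   `lambda_star_hat`, the selected covariate set, the original path and
#'   the call parameters.
#' @examples
#' sc <- sim_scenario(G = 60, n = 24, k_candidates = 3, k_relevant = 1,
#'                    seed = 1)
#' cm <- simulate_counts(sc, seed = 2)
#' res <- fsr_select(cm, sc$spec, sc$data, k_p = 2, B = 5, seed = 3)
#' res$selected
#' @export
fsr_select <- function(cm, spec, data, alpha0 = 0.05, k_p = 7L, B = 100L,
                       mechanism = c("ORX", "OWN", "RX", "WN"),
                       estimator = c("RE", "ER"), seed = NULL, span = 0.5) {
  mechanism <- match.arg(mechanism)
  estimator <- match.arg(estimator)
  lc <- if (inherits(cm, "log_cpm")) cm else log_cpm(cm)
  original <- backward_path(lc, spec, data, span = span)
  paths <- pseudo_paths(lc, spec, data, mechanism = mechanism, k_p = k_p,
                        B = B, seed = seed, span = span)
  grid <- sort(unique(c(0, original$removals$r,
                        unlist(lapply(paths, function(p) p$removals$r)))))
  m <- .pseudo_means(paths, grid)
  alpha_p <- if (estimator == "RE") {
    m[, "Ibar_star"] / (1 + m[, "Sbar"])
  } else {
    S <- vapply(grid, function(l) length(select_at(original, l)), numeric(1))
    m[, "Ibar_star"] / (1 + S)
  }
  curve <- data.frame(lambda = grid, alpha = unname(alpha_p))
  est <- estimate_ki_lambda(curve, original, alpha0 = alpha0, k_p = k_p,
                            estimator = estimator)
  k_i <- est$k_i_hat
  # invert the pseudo-scale curve to the real-covariate FSR scale
  alpha_inv <- if (estimator == "RE") {
    k_i * curve$alpha / (k_p * pmax(1 - curve$alpha, .Machine$double.eps))
  } else {
    k_i * curve$alpha / k_p
  }
  structure(list(lambda_grid = grid,
                 Ibar_star = unname(m[, "Ibar_star"]),
                 Sbar_P = unname(m[, "Sbar"]),
                 alpha_hat_pseudo = curve$alpha,
                 alpha_hat = alpha_inv,
                 k_i_hat = k_i,
                 lambda_star_hat = est$lambda_star_hat,
                 selected = select_at(original, est$lambda_star_hat),
                 original_path = original,
                 pseudo_paths = paths,
                 mechanism = mechanism, estimator = estimator,
                 alpha0 = alpha0, k_p = k_p, B = B),
            class = "fsr_result")
}

#' @export
print.fsr_result <- function(x, ...) {
  cat(sprintf("fsr_result (%s_%s): alpha0 = %g, k_P = %d, B = %d\n",
              x$mechanism, x$estimator, x$alpha0, x$k_p, x$B))
  cat(sprintf("  k_I_hat = %d, lambda*_hat = %.4g\n", x$k_i_hat,
              x$lambda_star_hat))
  cat(sprintf("  selected (%d): %s\n", length(x$selected),
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "<none>"))
  invisible(x)
}

#' Differential expression analysis with a chosen covariate set
#'
#' Fits the two-pass voom model with the primary variables plus the given
#' covariates, computes moderated-test p-values for a primary variable,
#' converts them to q-values with the histogram pi0 estimate, and declares
#' DE at the given level.
#'
#' @inheritParams backward_path
#' @param covariates Candidate covariates to adjust for (e.g.
#'   `fsr_select(...)$selected`).
#' @param primary Which primary variable to test; default the first.
#' @param level Nominal FDR level.
#' @return Data frame with columns `gene`, `p`, `q`, `de`; the pi0 estimate
#'   is in attribute `"pi0"`.
#' @export
de_analysis <- function(cm, spec, data, covariates = character(),
                        primary = spec$primary[1L], level = 0.05,
                        span = 0.5) {
  lc <- if (inherits(cm, "log_cpm")) cm else log_cpm(cm)
  X <- build_design(spec, data, subset = covariates)
  fit <- fit_voom(lc, X, span = span)
  mod <- ebayes_moderate(fit)
  p <- as.numeric(test_variable(fit, mod, primary))
  qr_ <- qvalues(p)
  out <- data.frame(gene = rownames(lc$y) %||% seq_along(p),
                    p = p, q = qr_$qvals, de = declare_de(qr_, level))
  attr(out, "pi0") <- qr_$pi0
  out
}
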