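# True quarter-root mean-variance trend used by the generator: decreasing in
# abundance (log2 count scale), mirroring the voom trend shape on bulk data.
# Flat beyond the realistic abundance range, like the analysis-side trend.
.true_trend <- function(u) 0.65 + 0.45 * exp(-(pmin(pmax(u, 0), 16) - 3) / 2.5)

#' Build a synthetic covariate-selection scenario
#'
#' Draws the true parameters of per-gene Gaussian linear models on the
#' log-CPM scale: a balanced two-level primary variable, `k_candidates`
#' continuous candidate covariates of which the first `k_relevant` are
#' relevant, per-gene scaled error variances from a scaled inverse
#' chi-square, per-observation precision weights from a decreasing
#' mean-variance trend, and upper-quartile-scale library sizes. A designated
#' fraction of genes is differentially expressed with respect to the primary
#' variable (nonzero primary coefficient); relevant covariates carry nonzero
#' coefficients on a fraction of genes with standardized effect sizes
#' `N(0, effect_sd^2)` times the gene's error scale. Irrelevant covariates
#' have all coefficients identically zero.
#'
#' @param G Number of genes.
#' @param n Number of samples (default 31).
#' @param k_candidates Number of candidate covariates (default 13).
#' @param k_relevant Number of truly relevant covariates (`0 <=
#'   k_relevant <= k_candidates`).
#' @param de_fraction Fraction of genes DE for the primary variable
#'   (default 0.2, i.e. an 80/20 EE/DE split; the EE count is exact).
#' @param nonnull_fraction Fraction of genes with a nonzero coefficient on
#'   each relevant covariate (default 0.4).
#' @param effect_sd Standard deviation of standardized effect sizes.
#' @param confound_rho Correlation between the first relevant covariate and
#'   the primary variable (default 0 = independent); emulates a covariate
#'   strongly associated with the primary variable, the regime in which
#'   selection-free analyses lose FDR control.
#' @param d0,s0sq Prior df and prior scaled variance of the inverse
#'   chi-square variance distribution.
#' @param libsize_meanlog,libsize_sdlog Log-normal parameters of the
#'   upper-quartile library sizes.
#' @param seed Optional integer seed.
#' @return An object of class `"sim_scenario"`: `spec`, `data`, `X` (full
#'   true design), `beta`, `sigma2`, `weights`, `libsize`, `relevant_set`,
#'   `de_truth`, `G`, `n`.
#' @export
sim_scenario <- function(G = 2000L, n = 31L, k_candidates = 13L,
                         k_relevant = 0L, de_fraction = 0.2,
                         nonnull_fraction = 0.4, effect_sd = 1,
                         confound_rho = 0, d0 = 4, s0sq = 1,
                         libsize_meanlog = log(300), libsize_sdlog = 0.2,
                         seed = NULL) {
  if (k_relevant > k_candidates)
    stop("k_relevant exceeds the number of candidate covariates")
  if (!is.null(seed)) set.seed(seed)
  prim <- factor(rep(c("L", "H"), length.out = n), levels = c("L", "H"))
  cand_names <- paste0("cov", seq_len(k_candidates))
  data <- data.frame(line = prim)
  for (j in seq_len(k_candidates)) data[[cand_names[j]]] <- stats::rnorm(n)
  if (k_relevant >= 1L && confound_rho != 0)
    data[[cand_names[1L]]] <-
      make_confounded_covariate(prim, confound_rho)
  spec <- design_spec(primary = "line", candidates = cand_names)
  X <- build_design(spec, data)
  blocks <- attr(X, "blocks")

  # cap the inverse-chi-square tail: residual sd above 5x the prior scale is
  # not representable as meaningful counts on the log2 scale
  sigma2 <- pmin(s0sq * d0 / stats::rchisq(G, df = d0), 25 * s0sq)
  beta <- matrix(0, G, ncol(X), dimnames = list(paste0("gene", seq_len(G)),
                                                colnames(X)))
  beta[, 1L] <- stats::rnorm(G, mean = 16.7, sd = 1.5)  # abundance intercepts
  n_de <- G - round((1 - de_fraction) * G)
  de_idx <- if (n_de > 0L) sample.int(G, n_de) else integer()
  beta[de_idx, blocks[["line"]]] <-
    stats::rnorm(n_de, sd = effect_sd) * sqrt(sigma2[de_idx])
  relevant <- cand_names[seq_len(k_relevant)]
  for (v in relevant) {
    n_nn <- round(nonnull_fraction * G)
    idx <- if (n_nn > 0L) sample.int(G, n_nn) else integer()
    beta[idx, blocks[[v]]] <-
      stats::rnorm(n_nn, sd = effect_sd) * sqrt(sigma2[idx])
  }
  libsize <- stats::rlnorm(n, meanlog = libsize_meanlog,
                           sdlog = libsize_sdlog)
  mu <- beta %*% t(X)
  logcount <- sweep(mu, 2L, log2(libsize + 1) - log2(1e6), `+`)
  weights <- .true_trend(logcount)^-4
  de_truth <- logical(G)
  de_truth[de_idx] <- TRUE
  structure(list(spec = spec, data = data, X = X, beta = beta,
                 sigma2 = sigma2, weights = weights, libsize = libsize,
                 relevant_set = relevant, de_truth = de_truth,
                 G = G, n = n),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(paste0("sim_scenario: %d genes x %d samples; %d candidates, ",
                     "%d relevant (%s); %d DE genes\n"),
              x$G, x$n, length(x$spec$candidates), length(x$relevant_set),
              if (length(x$relevant_set))
                paste(x$relevant_set, collapse = ", ") else "none",
              sum(x$de_truth)))
  invisible(x)
}

#' Simulate a count matrix from a scenario
#'
#' Draws `y_gi = x_i' beta_g + e_gi` with `e_gi ~ N(0, sigma_g^2 / w_gi)`
#' and inverts the log-CPM transform:
#' `c_gi = round(2^y_gi (R_i + 1) / 1e6 - 0.5)`, clamped at zero.
#'
#' @param sc A `"sim_scenario"` (or a list with fields `X`, `beta`,
#'   `sigma2`, `weights`, `libsize`).
#' @param seed Optional integer seed.
#' @return A [count_matrix()] (library sizes left unset: the analysis
#'   pipeline recomputes upper-quartile sizes from the simulated counts).
#' @export
simulate_counts <- function(sc, seed = NULL) {
  stopifnot(all(c("X", "beta", "sigma2", "weights", "libsize") %in% names(sc)))
  if (!is.null(seed)) set.seed(seed)
  G <- nrow(sc$beta); n <- nrow(sc$X)
  mu <- sc$beta %*% t(sc$X)
  sdmat <- sqrt(sc$sigma2 / sc$weights)
  y <- mu + matrix(stats::rnorm(G * n), G, n) * sdmat
  counts <- pmax(round(t(t(2^y) * (sc$libsize + 1)) / 1e6 - 0.5), 0)
  rownames(counts) <- rownames(sc$beta)
  colnames(counts) <- paste0("sample", seq_len(n))
  count_matrix(counts)
}

#' Covariate with a target correlation to the primary variable
#'
#' Returns `rho * standardized(primary) + sqrt(1 - rho^2) * noise`, whose
#' population correlation with the primary variable is `rho`. Used to build
#' the confounded scenario in which a relevant covariate is strongly
#' associated with the primary variable.
#'
#' @param primary Numeric vector or a factor (converted to level codes).
#' @param rho Target correlation, `|rho| < 1`.
#' @param seed Optional integer seed.
#' @return Numeric covariate vector of the same length.
#' @export
make_confounded_covariate <- function(primary, rho, seed = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (!is.null(seed)) set.seed(seed)
  x <- as.numeric(if (is.factor(primary)) unclass(primary) else primary)
  xs <- as.numeric(scale(x))
  rho * xs + sqrt(1 - rho^2) * stats::rnorm(length(xs))
}
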