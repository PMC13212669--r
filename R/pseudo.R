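#' White-noise pseudo-variables
#'
#' `n x k_P` matrix of i.i.d. standard normal entries, independent of the
#' count data by construction. Uses the current RNG state; seed at the call
#' site for reproducibility.
#'
#' @param n Number of samples.
#' @param k_p Number of pseudo-variables (>= 1).
#' @return Numeric matrix with columns named `.pv1 ... .pvk`, attribute
#'   `"mechanism" = "WN"`.
#' @export
generate_wn <- function(n, k_p) {
  stopifnot(k_p >= 1, n >= 1)
  Z <- matrix(stats::rnorm(n * k_p), n, k_p,
              dimnames = list(NULL, paste0(".pv", seq_len(k_p))))
  attr(Z, "mechanism") <- "WN"
  Z
}

#' Row-permuted real-column pseudo-variables
#'
#' Selects `k_p` columns at random without replacement from a pool of real
#' covariate columns and applies one shared random permutation to the rows
#' of the selected block, so each pseudo-variable has the same marginal
#' distribution as a real covariate but is decoupled from the responses.
#'
#' @param pool Numeric matrix whose columns are the candidate-covariate
#'   design columns (see [candidate_column_pool()]).
#' @param k_p Number of pseudo-variables; at most `ncol(pool)`.
#' @return Numeric matrix as in [generate_wn()], `"mechanism" = "RX"`.
#' @export
generate_rx <- function(pool, k_p) {
  pool <- as.matrix(pool)
  stopifnot(k_p >= 1)
  if (ncol(pool) < k_p)
    stop("pool has fewer columns than requested pseudo-variables")
  cols <- sample.int(ncol(pool), k_p)
  perm <- sample.int(nrow(pool))
  Z <- pool[perm, cols, drop = FALSE]
  colnames(Z) <- paste0(".pv", seq_len(k_p))
  rownames(Z) <- NULL
  attr(Z, "mechanism") <- "RX"
  Z
}

#' Expanded candidate-covariate column pool
#'
#' Design-matrix columns of the candidate covariates only (no intercept, no
#' primary variables) — the pool the RX mechanism permutes. Restricting to
#' candidates avoids injecting copies of the primary signal.
#'
#' @param spec A [design_spec()].
#' @param data Sample covariate data frame.
#' @return Numeric `n x (total candidate block width)` matrix.
#' @export
candidate_column_pool <- function(spec, data) {
  X <- build_design(spec, data)
  blocks <- attr(X, "blocks")
  cols <- unlist(blocks[spec$candidates], use.names = FALSE)
  X[, cols, drop = FALSE]
}

#' Orthogonalize pseudo-variables against the full design
#'
#' Replaces `Z` by `(I - H) Z` where `H` projects onto the column space of
#' the intercept-augmented full design, so every pseudo-variable has sample
#' mean zero and exactly zero sample correlation with every real column.
#' Requires `rank(X_full) + k_P <= n - 1` so at least one residual degree of
#' freedom remains in the augmented first-stage model.
#'
#' @param Z Pseudo-variable matrix (from [generate_wn()]/[generate_rx()]).
#' @param X_full Full design matrix including the intercept, all primary
#'   variables and all candidate covariates.
#' @return The projected matrix; `"mechanism"` gains an `"O"` prefix.
#' @export
orthogonalize <- function(Z, X_full) {
  Z <- as.matrix(Z)
  n <- nrow(X_full)
  r <- qr(X_full)$rank
  if (r + ncol(Z) > n - 1L)
    stop(sprintf(paste0("too many pseudo-variables for the design: ",
                        "rank(X) = %d with n = %d admits at most k_P = %d"),
                 r, n, n - 1L - r))
  qrX <- qr(X_full)
  Zo <- Z - qr.fitted(qrX, Z)
  dimnames(Zo) <- dimnames(Z)
  attr(Zo, "mechanism") <- paste0("O", sub("^O", "", attr(Z, "mechanism") %||% ""))
  Zo
}

#' Generate one pseudo-variable set
#'
#' Dispatches on the mechanism: `WN` (white noise), `RX` (permuted real
#' columns), and their orthogonalized variants `OWN`/`ORX` obtained by
#' projecting onto the orthogonal complement of the full design.
#'
#' @param mechanism One of `"WN"`, `"RX"`, `"OWN"`, `"ORX"`.
#' @param spec,data Design declaration and covariate values.
#' @param k_p Number of pseudo-variables.
#' @return Numeric `n x k_p` matrix.
#' @export
generate_pseudo <- function(mechanism = c("ORX", "OWN", "RX", "WN"),
                            spec, data, k_p) {
  mechanism <- match.arg(mechanism)
  n <- nrow(data)
  Z <- switch(sub("^O", "", mechanism),
              WN = generate_wn(n, k_p),
              RX = generate_rx(candidate_column_pool(spec, data), k_p))
  if (grepl("^O", mechanism))
    Z <- orthogonalize(Z, build_design(spec, data))
  Z
}
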