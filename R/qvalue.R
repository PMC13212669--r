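#' Histogram estimate of the true-null proportion
#'
#' Bins the p-values into `bins` equal-width right-closed intervals over
#' \[0, 1\] and scans from the left for the first bin whose count does not
#' exceed the average count of that bin and all bins to its right; the
#' tail average over those bins, relative to the uniform expectation,
#' estimates the proportion of true null hypotheses pi0 (capped at 1 and
#' floored at 1/G so downstream q-values never collapse to zero).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param bins Number of histogram bins, default 20.
#' @return Scalar pi0 estimate in (0, 1\].
#' @export
estimate_pi0_histogram <- function(p, bins = 20L) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  G <- length(p)
  idx <- pmax(ceiling(p * bins), 1L)  # right-closed bins; p = 0 into bin 1
  counts <- tabulate(idx, nbins = bins)
  i <- 1L
  for (b in seq_len(bins)) {
    tail_mean <- mean(counts[b:bins])
    if (counts[b] <= tail_mean) { i <- b; break }
    i <- b
  }
  pi0 <- sum(counts[i:bins]) / (G * (bins - i + 1) / bins)
  min(max(pi0, 1 / G), 1)
}

#' Storey q-values
#'
#' `q_(i) = min_(j >= i) pi0 * G * p_(j) / j`, capped at 1 and mapped back
#' to the input order; with `pi0 = 1` this is exactly the Benjamini-Hochberg
#' adjustment. Ties are handled by stable sorting.
#'
#' @param p Numeric vector of p-values.
#' @param pi0 Proportion of true nulls in (0, 1\]; default from
#'   [estimate_pi0_histogram()].
#' @return An object of class `"qvalue_result"`: `pi0`, `qvals` (input
#'   order), `n_true_null_hat = pi0 * G`.
#' @export
qvalues <- function(p, pi0 = estimate_pi0_histogram(p)) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  G <- length(p)
  o <- order(p)                      # stable in R
  q_sorted <- rev(cummin(rev(pi0 * G * p[o] / seq_len(G))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(G)
  q[o] <- q_sorted
  structure(list(pi0 = pi0, qvals = q, n_true_null_hat = pi0 * G),
            class = "qvalue_result")
}

#' Declare differential expression at a q-value cutoff
#'
#' @param q A `"qvalue_result"` or a numeric vector of q-values.
#' @param level Nominal FDR level in (0, 1); the boundary is inclusive.
#' @return Logical vector, `TRUE` for genes declared DE.
#' @export
declare_de <- function(q, level = 0.05) {
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  qv <- if (inherits(q, "qvalue_result")) q$qvals else q
  qv <= level
}
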