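#' Covariate relevance measure
#'
#' The ratio of the number of small p-values to one-fifth of the number of
#' large p-values, `r = sum(p <= 0.05) / max(sum(p >= 0.75) / 5, 1)` (both
#' comparisons inclusive). Under a truly irrelevant covariate the p-values
#' are uniform, both numerator and scaled denominator estimate `0.05 * G`,
#' and r is close to 1; values far above 1 indicate relevance.
#'
#' @param p Numeric vector of per-gene p-values in \[0, 1\].
#' @return Scalar r >= 0.
#' @export
relevance <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  sum(p <= 0.05) / max(sum(p >= 0.75) / 5, 1)
}

#' Backward elimination over candidate covariates
#'
#' Starting from the model with all primary variables and all candidate
#' covariates (plus optional pseudo-variables), repeatedly fits the two-pass
#' voom pipeline, computes each remaining candidate's relevance r from its
#' moderated-test p-values, removes the least relevant candidate (ties
#' broken by declaration order) and records its r, until no candidates
#' remain.
#'
#' @param cm A [count_matrix()] (library sizes computed on the fly when
#'   unset) or a precomputed [log_cpm()] object.
#' @param spec A [design_spec()].
#' @param data Data frame of sample covariates, rows aligned with the count
#'   matrix columns (checked by name when row names are present).
#' @param pseudo Optional `n x k_P` matrix of pseudo-variables appended as
#'   additional single-column candidates; their removals are flagged.
#' @param span LOWESS span passed to [fit_voom()].
#' @return An object of class `"selection_path"`: a data frame `removals`
#'   with columns `iteration`, `covariate`, `r`, `pseudo`, plus the
#'   candidate and primary name sets.
#' @export
backward_path <- function(cm, spec, data, pseudo = NULL, span = 0.5) {
  stopifnot(inherits(spec, "design_spec"), is.data.frame(data))
  lc <- if (inherits(cm, "log_cpm")) cm else log_cpm(cm)
  if (nrow(data) != ncol(lc$y))
    stop("covariate table rows must match count-matrix columns")
  if (!is.null(rownames(data)) && !is.null(colnames(lc$y)) &&
      !all(rownames(data) == seq_len(nrow(data))) &&
      !identical(rownames(data), colnames(lc$y)))
    stop("covariate table sample ids do not match count-matrix sample ids")
  if (!is.null(pseudo)) {
    pseudo <- as.matrix(pseudo)
    if (is.null(colnames(pseudo)))
      colnames(pseudo) <- paste0(".pv", seq_len(ncol(pseudo)))
  }
  real <- spec$candidates
  pv <- if (is.null(pseudo)) character() else colnames(pseudo)
  remaining <- c(real, pv)
  removals <- data.frame(iteration = integer(), covariate = character(),
                         r = numeric(), pseudo = logical())
  it <- 0L
  while (length(remaining) > 0L) {
    it <- it + 1L
    sub_real <- real[real %in% remaining]
    sub_pv <- pv[pv %in% remaining]
    X <- build_design(spec, data, subset = sub_real,
                      pseudo = if (length(sub_pv) > 0L)
                        pseudo[, sub_pv, drop = FALSE] else NULL)
    fit <- tryCatch(fit_voom(lc, X, span = span), error = function(e)
      stop("model fit failed with candidates {",
           paste(remaining, collapse = ", "), "}: ", conditionMessage(e),
           call. = FALSE))
    mod <- ebayes_moderate(fit)
    rvals <- vapply(remaining, function(v)
      relevance(test_variable(fit, mod, v)), numeric(1))
    drop_i <- which.min(rvals)  # ties -> earliest declared
    removals <- rbind(removals, data.frame(
      iteration = it, covariate = remaining[drop_i], r = rvals[[drop_i]],
      pseudo = remaining[drop_i] %in% pv))
    remaining <- remaining[-drop_i]
  }
  rownames(removals) <- NULL
  structure(list(removals = removals,
                 candidates = c(real, pv),
                 primary = spec$primary),
            class = "selection_path")
}

#' Assemble a selection path from a known removal sequence
#'
#' Builds a `"selection_path"` directly from an ordered removal record, for
#' querying published backward-selection traces with [select_at()].
#'
#' @param covariates Covariate names in removal order.
#' @param r Relevance value recorded at each removal.
#' @param pseudo Logical flags marking pseudo-variable removals.
#' @param primary Primary variable names (annotation only).
#' @return A `"selection_path"`.
#' @export
selection_path <- function(covariates, r, pseudo = rep(FALSE, length(r)),
                           primary = character()) {
  stopifnot(length(covariates) == length(r), length(r) == length(pseudo),
            all(r >= 0), !anyDuplicated(covariates))
  structure(list(removals = data.frame(iteration = seq_along(r),
                                       covariate = as.character(covariates),
                                       r = as.numeric(r),
                                       pseudo = as.logical(pseudo)),
                 candidates = as.character(covariates),
                 primary = primary),
            class = "selection_path")
}

#' @export
print.selection_path <- function(x, ...) {
  cat(sprintf("selection_path: %d removals (%d pseudo)\n",
              nrow(x$removals), sum(x$removals$pseudo)))
  print(x$removals, ...)
  invisible(x)
}

#' @export
as.data.frame.selection_path <- function(x, ...) x$removals

#' Covariates selected at a relevance threshold
#'
#' Scans the removal sequence in order and stops at the first removal whose
#' recorded r is at least `lambda`; the selected set is that covariate
#' together with every covariate removed later (i.e. everything still in the
#' model at that point). When no removal reaches `lambda` the selection is
#' empty. `S(lambda) = length(select_at(path, lambda))` is a nonincreasing
#' step function with `S(0)` = all candidates.
#'
#' @param path A `"selection_path"`.
#' @param lambda Threshold >= 0.
#' @return Character vector of selected covariate names (possibly empty).
#' @export
select_at <- function(path, lambda) {
  stopifnot(inherits(path, "selection_path"), lambda >= 0)
  if (is.infinite(lambda)) return(character())
  r <- path$removals$r
  hit <- which(r >= lambda)
  if (length(hit) == 0L) return(character())
  path$removals$covariate[seq.int(hit[1L], length(r))]
}
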