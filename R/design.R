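#' Declare primary variables and candidate covariates
#'
#' A design specification names the explanatory variables of the per-gene
#' linear models, splits them into primary variables (always in the model,
#' never subject to selection, e.g. a treatment line) and candidate
#' covariates (subject to backward selection), and records each variable's
#' type. Categorical variables with L levels expand to L-1 treatment-contrast
#' indicator columns against the first declared level.
#'
#' @param primary Character vector of primary variable names (at least one).
#' @param candidates Character vector of candidate covariate names.
#' @param types Named character vector/list mapping variable names to
#'   `"continuous"` or `"categorical"`. Variables absent from `types` are
#'   typed from the data when a design matrix is built (factor/character
#'   columns are categorical).
#' @param levels Optional named list giving the ordered level set of
#'   categorical variables; defaults to the levels observed in the data.
#' @return An object of class `"design_spec"`.
#' @export
design_spec <- function(primary, candidates = character(),
                        types = NULL, levels = NULL) {
  primary <- as.character(primary)
  candidates <- as.character(candidates)
  if (length(primary) < 1L) stop("at least one primary variable is required")
  if (anyDuplicated(c(primary, candidates)))
    stop("primary and candidate variable names must be disjoint and unique")
  types <- as.list(types %||% list())
  bad <- setdiff(unlist(types), c("continuous", "categorical"))
  if (length(bad) > 0L)
    stop("unknown variable type(s): ", paste(bad, collapse = ", "))
  structure(list(primary = primary, candidates = candidates,
                 types = types, levels = as.list(levels %||% list())),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("design_spec: %d primary (%s); %d candidate (%s)\n",
              length(x$primary), paste(x$primary, collapse = ", "),
              length(x$candidates), paste(x$candidates, collapse = ", ")))
  invisible(x)
}

#' Read a design specification from a YAML or JSON config
#'
#' The config must contain `primary` (list of names) and may contain
#' `candidates`, `types` (name -> continuous/categorical) and `levels`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [design_spec()].
#' @export
read_design_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  design_spec(primary = cfg$primary,
              candidates = cfg$candidates %||% character(),
              types = cfg$types, levels = cfg$levels)
}

.variable_type <- function(spec, name, data) {
  t <- spec$types[[name]]
  if (!is.null(t)) return(t)
  col <- data[[name]]
  if (is.factor(col) || is.character(col) || is.logical(col))
    "categorical" else "continuous"
}

.variable_columns <- function(spec, name, data) {
  col <- data[[name]]
  if (is.null(col)) stop("variable not found in covariate table: ", name)
  if (.variable_type(spec, name, data) == "continuous") {
    m <- matrix(as.numeric(col), ncol = 1L,
                dimnames = list(NULL, name))
    if (anyNA(m)) stop("missing/non-numeric values in variable: ", name)
    return(m)
  }
  lev <- spec$levels[[name]] %||%
    (if (is.factor(col)) base::levels(col) else sort(unique(as.character(col))))
  f <- factor(as.character(col), levels = lev)
  if (anyNA(f)) stop("value outside declared levels for variable: ", name)
  if (nlevels(f) < 2L) stop("categorical variable with a single level: ", name)
  m <- stats::model.matrix(~f)[, -1L, drop = FALSE]
  colnames(m) <- paste0(name, lev[-1L])
  m
}

#' Build a design matrix with named column blocks
#'
#' Assembles the matrix `[1, primary blocks, candidate blocks]` for the
#' model restricted to a subset of the candidate covariates, keeping the
#' declaration order, plus optional pseudo-variable columns appended last.
#'
#' @param spec A [design_spec()].
#' @param data Data frame of sample covariate values, one row per sample in
#'   the same order as the count-matrix columns.
#' @param subset Character vector of candidate names to include (must be a
#'   subset of `spec$candidates`); defaults to all candidates.
#' @param pseudo Optional numeric `n x k_P` matrix of pseudo-variables; each
#'   column becomes its own single-column block named from its column name.
#' @return Numeric design matrix with attribute `"blocks"`: a named list
#'   mapping each variable (excluding the intercept) to its column indices.
#'   An error naming a collinear block is raised when the matrix is
#'   rank-deficient.
#' @export
build_design <- function(spec, data, subset = spec$candidates, pseudo = NULL) {
  stopifnot(inherits(spec, "design_spec"), is.data.frame(data))
  extra <- setdiff(subset, spec$candidates)
  if (length(extra) > 0L)
    stop("not declared candidates: ", paste(extra, collapse = ", "))
  n <- nrow(data)
  pieces <- list(`(Intercept)` = matrix(1, n, 1L,
                                        dimnames = list(NULL, "(Intercept)")))
  blocks <- list()
  at <- 2L
  for (v in c(spec$primary, spec$candidates[spec$candidates %in% subset])) {
    m <- .variable_columns(spec, v, data)
    pieces[[v]] <- m
    blocks[[v]] <- seq.int(at, length.out = ncol(m))
    at <- at + ncol(m)
  }
  if (!is.null(pseudo)) {
    pseudo <- as.matrix(pseudo)
    if (nrow(pseudo) != n) stop("pseudo-variable rows must match samples")
    if (is.null(colnames(pseudo)))
      colnames(pseudo) <- paste0(".pv", seq_len(ncol(pseudo)))
    for (j in seq_len(ncol(pseudo))) {
      nm <- colnames(pseudo)[j]
      pieces[[nm]] <- pseudo[, j, drop = FALSE]
      blocks[[nm]] <- at
      at <- at + 1L
    }
  }
  X <- do.call(cbind, pieces)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]
    culprit <- names(blocks)[vapply(blocks, function(b) any(b %in% dropped),
                                    logical(1L))]
    stop("design matrix is rank-deficient; collinear block(s): ",
         paste(culprit, collapse = ", "))
  }
  attr(X, "blocks") <- blocks
  X
}
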