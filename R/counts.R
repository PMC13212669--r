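#' Construct a validated count matrix
#'
#' Container for a gene x sample matrix of non-negative integer RNA-seq read
#' counts. Library sizes (the per-sample normalization constants `R_i`) are
#' left unset until computed, typically with [upper_quartile_libsize()].
#'
#' @param counts Numeric matrix of non-negative integers, genes in rows,
#'   samples in columns. Row and column names are used as gene and sample
#'   identifiers; defaults are generated when absent.
#' @param libsize Optional per-sample positive library sizes.
#' @return An object of class `"count_matrix"`: a list with elements
#'   `counts`, `gene_ids`, `sample_ids` and `libsize` (possibly `NULL`).
#' @seealso [read_counts()], [log_cpm()], [filter_genes()]
#' @export
count_matrix <- function(counts, libsize = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts))
    stop("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("invalid count (negative, non-integer or missing) at row %s, column %s",
                 rownames(counts)[bad[1L, 1L]] %||% bad[1L, 1L],
                 colnames(counts)[bad[1L, 2L]] %||% bad[1L, 2L]))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup) > 0L)
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup) > 0L)
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  if (!is.null(libsize)) {
    if (length(libsize) != ncol(counts) || any(!is.finite(libsize)) ||
        any(libsize <= 0))
      stop("libsize must be one positive finite value per sample")
  }
  structure(list(counts = counts,
                 gene_ids = rownames(counts),
                 sample_ids = colnames(counts),
                 libsize = libsize),
            class = "count_matrix")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples; library sizes %s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$libsize)) "unset" else "set"))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from a delimited file
#'
#' Expects genes in rows with the gene identifier in the first column and one
#' column per sample with sample identifiers in the header row.
#'
#' @param path Path to a TSV or CSV file.
#' @param sep Field separator; inferred from the file extension when `NULL`
#'   (`.csv` gives `","`, anything else tab).
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("need a gene-id column plus at least one sample")
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  count_matrix(m)
}

#' Upper-quartile library sizes
#'
#' The per-sample normalization constant `R_i` is the 75th percentile of the
#' sample's read counts (Bullard-style upper-quartile normalization),
#' computed with the type-7 linear interpolation of order statistics.
#'
#' @param cm A [count_matrix()].
#' @param p Quantile used, default `0.75`.
#' @return Numeric vector of positive library sizes, one per sample.
#' @export
upper_quartile_libsize <- function(cm, p = 0.75) {
  stopifnot(inherits(cm, "count_matrix"))
  if (nrow(cm$counts) < 1L) stop("need at least one gene")
  r <- apply(cm$counts, 2L, stats::quantile, probs = p, names = FALSE,
             type = 7)
  zero <- which(r <= 0)
  if (length(zero) > 0L)
    stop("zero upper-quartile library size for sample(s): ",
         paste(cm$sample_ids[zero], collapse = ", "))
  names(r) <- cm$sample_ids
  r
}

#' Attach library sizes to a count matrix
#'
#' @param cm A [count_matrix()].
#' @param libsize Per-sample positive sizes; defaults to
#'   [upper_quartile_libsize()].
#' @return The count matrix with `libsize` set.
#' @export
set_libsize <- function(cm, libsize = upper_quartile_libsize(cm)) {
  count_matrix(cm$counts, libsize = libsize)
}

#' Log counts per million
#'
#' Transforms counts to `y_gi = log2((c_gi + 0.5) / (R_i + 1) * 1e6)`. The
#' half-count offset keeps every value finite; with upper-quartile `R_i` the
#' values are no longer literal counts per million, which is irrelevant for
#' the downstream linear modelling.
#'
#' @param cm A [count_matrix()] with library sizes set (or computable; when
#'   unset, upper-quartile sizes are computed on the fly).
#' @return An object of class `"log_cpm"`: list with `y` (gene x sample
#'   matrix), `offsets` (`log2(R_i + 1) - log2(1e6)`) and `libsize`.
#' @export
log_cpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  libsize <- cm$libsize %||% upper_quartile_libsize(cm)
  offsets <- log2(libsize + 1) - log2(1e6)
  y <- log2(t(t(cm$counts + 0.5) / (libsize + 1)) * 1e6)
  structure(list(y = y, offsets = offsets, libsize = libsize),
            class = "log_cpm")
}

#' Invert the log-CPM transform back to integer counts
#'
#' @param lc A [log_cpm()] object.
#' @return Matrix of non-negative integer counts; exact for values produced
#'   by [log_cpm()].
#' @export
inverse_log_cpm <- function(lc) {
  stopifnot(inherits(lc, "log_cpm"))
  c0 <- t(t(2^lc$y) * (lc$libsize + 1)) / 1e6 - 0.5
  round(c0)
}

#' Filter genes on mean count and zero count
#'
#' Keeps genes whose mean count is at least `min_avg` and whose number of
#' zero entries does not exceed `max_zeros` (both boundaries inclusive),
#' preserving gene order. Mirrors the common RNA-seq preprocessing of
#' retaining moderately expressed genes; not applied silently anywhere.
#'
#' @param cm A [count_matrix()].
#' @param min_avg Minimum mean count, default 8.
#' @param max_zeros Maximum number of zero counts per gene; default scales
#'   27-zeros-in-31-samples to the actual sample count.
#' @return The filtered [count_matrix()] (library sizes dropped; recompute
#'   after filtering).
#' @export
filter_genes <- function(cm, min_avg = 8,
                         max_zeros = round(ncol(cm$counts) * 27 / 31)) {
  stopifnot(inherits(cm, "count_matrix"), min_avg >= 0, max_zeros >= 0)
  keep <- rowMeans(cm$counts) >= min_avg &
    rowSums(cm$counts == 0) <= max_zeros
  if (!any(keep))
    stop("no genes pass the filter; lower min_avg or raise max_zeros")
  count_matrix(cm$counts[keep, , drop = FALSE])
}
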