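# Small reusable fixture builders; all data is generated in code.

# Random count matrix with moderate abundances.
tiny_counts <- function(G = 50, n = 8, seed = 1, lambda = 60) {
  set.seed(seed)
  m <- matrix(rpois(G * n, lambda), G, n,
              dimnames = list(paste0("g", seq_len(G)),
                              paste0("s", seq_len(n))))
  count_matrix(m)
}

# Covariate table with a binary primary variable and continuous candidates.
tiny_data <- function(n = 8, k = 2, seed = 2) {
  set.seed(seed)
  d <- data.frame(line = factor(rep(c("L", "H"), length.out = n)))
  for (j in seq_len(k)) d[[paste0("cov", j)]] <- rnorm(n)
  d
}

tiny_spec <- function(k = 2) {
  design_spec(primary = "line", candidates = paste0("cov", seq_len(k)))
}

# Write a temporary counts file and return its path.
write_counts_file <- function(m, sep = "\t", ext = ".tsv") {
  path <- tempfile(fileext = ext)
  df <- data.frame(gene = rownames(m) %||% paste0("g", seq_len(nrow(m))), m,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
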