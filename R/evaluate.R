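#' Score a selected covariate set against the truth
#'
#' Per-replicate false selection: `I = # selected irrelevant`,
#' `S = # selected`, contribution `I / (1 + S)`; and the number of selected
#' truly relevant covariates.
#'
#' @param selected Character vector of selected covariate names.
#' @param relevant_truth Character vector of truly relevant covariates.
#' @return List with `fsr` (the per-replicate ratio) and `s_count`.
#' @export
eval_selection <- function(selected, relevant_truth) {
  I <- length(setdiff(selected, relevant_truth))
  S <- length(selected)
  list(fsr = I / (1 + S), s_count = length(intersect(selected,
                                                     relevant_truth)))
}

#' Score declared differential expression against the truth
#'
#' @param qvals Numeric vector of q-values (or a `"qvalue_result"`).
#' @param de_truth Logical vector of true DE status.
#' @param level Nominal FDR level; declaration is `q <= level`.
#' @return List with `fdr` (false discoveries over `max(1, discoveries)`)
#'   and `ntp` (true positives).
#' @export
eval_de <- function(qvals, de_truth, level = 0.05) {
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  qv <- if (inherits(qvals, "qvalue_result")) qvals$qvals else qvals
  stopifnot(length(qv) == length(de_truth))
  disc <- qv <= level
  list(fdr = sum(disc & !de_truth) / max(1, sum(disc)),
       ntp = sum(disc & de_truth))
}

#' Standardized partial AUC at low false positive rates
#'
#' Trapezoidal area under the ROC curve restricted to
#' `FPR <= fpr_max`, divided by `fpr_max` so that 1 is perfect separation.
#' Smaller scores rank as more DE (p-values). Ties advance the curve
#' diagonally; an uninformative ranking scores `fpr_max / 2`.
#'
#' @param scores Numeric vector (e.g. p-values).
#' @param de_truth Logical vector; both classes must be present.
#' @param fpr_max Upper FPR bound, default 0.05.
#' @return Scalar in \[0, 1\].
#' @export
partial_auc <- function(scores, de_truth, fpr_max = 0.05) {
  de_truth <- as.logical(de_truth)
  stopifnot(length(scores) == length(de_truth), fpr_max > 0, fpr_max <= 1)
  n1 <- sum(de_truth); n0 <- sum(!de_truth)
  if (n1 == 0L || n0 == 0L)
    stop("both DE and EE genes are required to form a ROC curve")
  thr <- sort(unique(scores))
  tp <- vapply(thr, function(t) sum(scores <= t & de_truth), numeric(1))
  fp <- vapply(thr, function(t) sum(scores <= t & !de_truth), numeric(1))
  fpr <- c(0, fp / n0, 1)
  tpr <- c(0, tp / n1, 1)
  # trapezoid integration over [0, fpr_max] with interpolation at the cut
  area <- 0
  for (i in seq_len(length(fpr) - 1L)) {
    x0 <- fpr[i]; x1 <- fpr[i + 1L]
    if (x0 >= fpr_max) break
    y0 <- tpr[i]; y1 <- tpr[i + 1L]
    if (x1 > fpr_max) {
      y1 <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      x1 <- fpr_max
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area / fpr_max
}

# Selected sets for several FSR variants on one dataset, sharing the
# original path across all variants and the pseudo paths across the two
# estimators of each mechanism.
.fsr_select_multi <- function(lc, spec, data, alpha0, k_p, B,
                              mechanisms, estimators, seed, span = 0.5) {
  original <- backward_path(lc, spec, data, span = span)
  out <- list()
  for (mi in seq_along(mechanisms)) {
    mech <- mechanisms[mi]
    paths <- pseudo_paths(lc, spec, data, mechanism = mech, k_p = k_p,
                          B = B, seed = seed + mi, span = span)
    grid <- sort(unique(c(0, original$removals$r,
                          unlist(lapply(paths, function(p) p$removals$r)))))
    m <- .pseudo_means(paths, grid)
    S <- vapply(grid, function(l) length(select_at(original, l)), numeric(1))
    for (est in estimators) {
      alpha_p <- if (est == "RE") m[, "Ibar_star"] / (1 + m[, "Sbar"])
                 else m[, "Ibar_star"] / (1 + S)
      curve <- data.frame(lambda = grid, alpha = unname(alpha_p))
      fit <- suppressWarnings(
        estimate_ki_lambda(curve, original, alpha0 = alpha0, k_p = k_p,
                           estimator = est))
      out[[paste0(mech, "_", est)]] <-
        select_at(original, fit$lambda_star_hat)
    }
  }
  out
}

#' Multi-strategy simulation study
#'
#' Runs the full comparison: for each scenario and replicate, simulates a
#' count dataset, obtains a selected covariate set per strategy — the FSR
#' variants (mechanism x estimator), `Full` (all candidates), `LineOnly`
#' (primary variable only) and `Oracle` (the true relevant set) — then
#' performs differential expression analysis with each selected set and
#' scores selection (FSR, S) and DE performance (FDR, NTP, PAUC) against
#' the simulation truth.
#'
#' @param scenarios Named list; each element is a list of arguments for
#'   [sim_scenario()] (`seed` is managed per replicate).
#' @param n_reps Number of simulation replicates per scenario.
#' @param mechanisms,estimators FSR variants to run (crossed).
#' @param strategies Extra selection-free strategies among `"Full"`,
#'   `"LineOnly"`, `"Oracle"`.
#' @param alpha0 Target FSR; `level` nominal FDR for DE calls.
#' @param k_p,B Pseudo-variable count and number of sets.
#' @param level Nominal FDR level for DE declaration.
#' @param seed Base seed; replicate seeds are derived deterministically.
#' @param span LOWESS span for all voom fits.
#' @return Data frame `(scenario, strategy, metric, mean, se)` where `se`
#'   is the Monte-Carlo standard error `sd / sqrt(n_reps)`; the per-replicate
#'   records are in attribute `"replicates"`.
#' @export
run_study <- function(scenarios, n_reps = 100L,
                      mechanisms = c("WN", "RX", "OWN", "ORX"),
                      estimators = c("RE", "ER"),
                      strategies = c("Full", "LineOnly", "Oracle"),
                      alpha0 = 0.05, k_p = 7L, B = 100L, level = 0.05,
                      seed = 1L, span = 0.5) {
  stopifnot(is.list(scenarios), length(names(scenarios)) == length(scenarios))
  reps <- list()
  for (sc_name in names(scenarios)) {
    args <- scenarios[[sc_name]]
    for (rep in seq_len(n_reps)) {
      rep_seed <- seed + 7919L * (match(sc_name, names(scenarios)) - 1L) +
        101L * rep
      sc <- do.call(sim_scenario, c(args, list(seed = rep_seed)))
      cm <- simulate_counts(sc)
      lc <- log_cpm(cm)
      sel <- list()
      if (length(mechanisms) > 0L && length(estimators) > 0L)
        sel <- .fsr_select_multi(lc, sc$spec, sc$data, alpha0, k_p, B,
                                 mechanisms, estimators,
                                 seed = rep_seed + 1L, span = span)
      if ("Full" %in% strategies) sel$Full <- sc$spec$candidates
      if ("LineOnly" %in% strategies) sel$LineOnly <- character()
      if ("Oracle" %in% strategies) sel$Oracle <- sc$relevant_set
      de_cache <- list()
      for (strat in names(sel)) {
        s <- eval_selection(sel[[strat]], sc$relevant_set)
        key <- paste0("set:", paste(sort(sel[[strat]]), collapse = "|"))
        if (is.null(de_cache[[key]]))
          de_cache[[key]] <- de_analysis(lc, sc$spec, sc$data,
                                         covariates = sel[[strat]],
                                         level = level, span = span)
        de <- de_cache[[key]]
        d <- eval_de(de$q, sc$de_truth, level = level)
        reps[[length(reps) + 1L]] <- data.frame(
          scenario = sc_name, rep = rep, strategy = strat,
          fsr = s$fsr, s_count = s$s_count, fdr = d$fdr, ntp = d$ntp,
          pauc = partial_auc(de$p, sc$de_truth))
      }
    }
  }
  repdf <- do.call(rbind, reps)
  agg <- do.call(rbind, lapply(split(repdf,
                                     repdf[c("scenario", "strategy")],
                                     drop = TRUE), function(d) {
    do.call(rbind, lapply(c("fsr", "s_count", "fdr", "ntp", "pauc"),
                          function(mname) data.frame(
      scenario = d$scenario[1L], strategy = d$strategy[1L], metric = mname,
      mean = mean(d[[mname]]),
      se = stats::sd(d[[mname]]) / sqrt(nrow(d)))))
  }))
  rownames(agg) <- NULL
  attr(agg, "replicates") <- repdf
  agg
}
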