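# Expensive simulation fixtures shared across test files, built once per
# test run and cached. All sizes are scaled-down study conditions chosen up
# front: n = 31 samples as in the motivating dataset, moderate gene counts
# and replicate numbers suited to a single-core run.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# Relevance of a single truly irrelevant covariate over repeated null
# simulations: should average to 1.
null_relevance_values <- function() cache_fixture("null_r", function() {
  set.seed(402)
  replicate(300, {
    sc <- sim_scenario(G = 400, n = 31, k_candidates = 1, k_relevant = 0)
    cm <- simulate_counts(sc)
    fit <- fit_voom(log_cpm(cm), build_design(sc$spec, sc$data))
    relevance(test_variable(fit, ebayes_moderate(fit), "cov1"))
  })
})

# All eight FSR variants plus the Oracle on three relevant-covariate counts.
calibration_study <- function() cache_fixture("calibration", function() {
  run_study(
    scenarios = list(
      kR0 = list(G = 500, n = 31, k_candidates = 8, k_relevant = 0),
      kR2 = list(G = 500, n = 31, k_candidates = 8, k_relevant = 2),
      kR6 = list(G = 500, n = 31, k_candidates = 8, k_relevant = 6)),
    n_reps = 15,
    mechanisms = c("WN", "RX", "OWN", "ORX"),
    estimators = c("RE", "ER"),
    strategies = "Oracle",
    alpha0 = 0.05, k_p = 4, B = 15, level = 0.05, seed = 314)
})

# A relevant covariate strongly correlated with the primary variable:
# the regime where ignoring covariates breaks FDR control.
confounded_study <- function() cache_fixture("confounded", function() {
  run_study(
    scenarios = list(conf = list(G = 500, n = 31, k_candidates = 6,
                                 k_relevant = 2, confound_rho = 0.9,
                                 nonnull_fraction = 0.5)),
    n_reps = 25, mechanisms = character(), estimators = character(),
    strategies = c("LineOnly", "Oracle"), seed = 2718)
})

study_metric <- function(study, scen, strat, metric) {
  row <- study$scenario == scen & study$strategy == strat &
    study$metric == metric
  list(mean = study$mean[row], se = study$se[row])
}
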