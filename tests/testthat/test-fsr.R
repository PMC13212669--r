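# Hand-built augmented paths for enumeration oracles: two pseudo-augmented
# replicates over candidates a, b with pseudo-variables z1, z2.
two_path_fixture <- function() {
  list(selection_path(c("z1", "a", "z2", "b"), c(0.5, 1.0, 2.0, 6.0),
                      pseudo = c(TRUE, FALSE, TRUE, FALSE)),
       selection_path(c("a", "z1", "b", "z2"), c(0.7, 1.5, 5.0, 0.9),
                      pseudo = c(FALSE, TRUE, FALSE, TRUE)))
}

test_that("pseudo-scale FSR estimates match direct enumeration", {
  paths <- two_path_fixture()
  # lambda = 1.2: path1 selects {z2, b} (first r >= 1.2 is z2), Istar = 1,
  # S = 2; path2 selects {z1, b, z2} (first r >= 1.2 is z1), Istar = 2, S = 3
  expect_equal(alpha_re_hat(paths, 1.2), mean(c(1, 2)) / (1 + mean(c(2, 3))))
  # above every recorded r: nothing selected
  expect_equal(alpha_re_hat(paths, 10), 0)
  # ER variant uses S(lambda) from the original path
  orig <- selection_path(c("a", "b"), c(0.8, 4.0))
  expect_equal(alpha_er_hat(paths, orig, 1.2), mean(c(1, 2)) / (1 + 1))
  expect_equal(alpha_er_hat(paths, orig, 0), 2 / (1 + 2))  # Istar=k_P, S=k_C
  # arithmetic spot checks of the estimator forms
  expect_equal(0.5 / (1 + 9), 0.05)      # Ibar*=0.5, Sbar=9 -> 0.05
  expect_equal(0.35 / (1 + 6), 0.05)     # Ibar*=0.35, S=6 -> 0.05
})

test_that("FSR cutoffs follow the closed forms and are monotone", {
  expect_equal(fsr_threshold(0.05, 7, 7, "RE"), 0.35 / 7.35)
  expect_equal(fsr_threshold(0.05, 7, 7, "RE"), 0.0476190476, tolerance = 1e-8)
  expect_equal(fsr_threshold(0.05, 7, 7, "ER"), 0.05)
  a0 <- seq(0.01, 0.3, by = 0.01)
  expect_true(all(diff(vapply(a0, fsr_threshold, numeric(1), k_p = 7,
                              k_i = 5)) > 0))
  ki <- 1:13
  expect_true(all(diff(vapply(ki, function(k)
    fsr_threshold(0.05, 7, k), numeric(1))) < 0))
  # cutoff and curve inversion are mutually consistent: pushing the RE
  # cutoff back through the inversion recovers alpha0 exactly
  for (ki in c(1, 5, 13)) {
    cc <- fsr_threshold(0.05, 7, ki, "RE")
    expect_equal(ki * cc / (7 * (1 - cc)), 0.05, tolerance = 1e-12)
  }
})

test_that("k_I and lambda* estimation converges on simple curves", {
  orig <- selection_path(c("a", "b", "c"), c(0.4, 2, 5))
  # pseudo-variables never selected: lambda* is the smallest grid value
  curve0 <- data.frame(lambda = c(0, 0.4, 2, 5), alpha = 0)
  est <- estimate_ki_lambda(curve0, orig, alpha0 = 0.05, k_p = 2)
  expect_equal(est$lambda_star_hat, 0)
  expect_equal(select_at(orig, est$lambda_star_hat), c("a", "b", "c"))
  # single candidate, pseudo selected only at lambda = 0
  orig1 <- selection_path("a", 3)
  curve1 <- data.frame(lambda = c(0, 3), alpha = c(0.6, 0))
  est1 <- estimate_ki_lambda(curve1, orig1, alpha0 = 0.05, k_p = 1)
  expect_equal(est1$lambda_star_hat, 3)
  expect_equal(est1$k_i_hat, 1)
  # impossible cutoff: infinite threshold with a warning, empty selection
  curve_bad <- data.frame(lambda = c(0, 1), alpha = c(0.9, 0.8))
  expect_warning(est_bad <- estimate_ki_lambda(curve_bad, orig, 0.05, 2),
                 "no threshold")
  expect_equal(est_bad$lambda_star_hat, Inf)
  expect_equal(select_at(orig, est_bad$lambda_star_hat), character())
})

test_that("pseudo-augmented paths flag exactly k_P pseudo removals", {
  d <- tiny_data(n = 14, k = 0)
  sp <- design_spec("line")
  cm <- tiny_counts(G = 40, n = 14, seed = 51)
  paths <- pseudo_paths(cm, sp, d, mechanism = "WN", k_p = 1, B = 1,
                        seed = 5)
  expect_length(paths, 1L)
  expect_equal(nrow(paths[[1]]$removals), 1L)
  expect_true(all(paths[[1]]$removals$pseudo))
  # with real candidates present, pseudo flags per path sum to k_P
  d2 <- tiny_data(n = 14, k = 3)
  paths2 <- pseudo_paths(cm, tiny_spec(3), d2, mechanism = "ORX", k_p = 3,
                         B = 2, seed = 6)
  for (p in paths2) expect_equal(sum(p$removals$pseudo), 3L)
  # per-replicate seeding: same seed reproduces the same paths
  paths3 <- pseudo_paths(cm, tiny_spec(3), d2, mechanism = "ORX", k_p = 3,
                         B = 2, seed = 6)
  expect_equal(paths2[[2]]$removals, paths3[[2]]$removals)
})

test_that("the full selection procedure returns a coherent result object", {
  sc <- sim_scenario(G = 250, n = 24, k_candidates = 4, k_relevant = 2,
                     seed = 71)
  cm <- simulate_counts(sc, seed = 72)
  res <- fsr_select(cm, sc$spec, sc$data, alpha0 = 0.05, k_p = 3, B = 8,
                    mechanism = "ORX", estimator = "RE", seed = 73)
  expect_s3_class(res, "fsr_result")
  # averaged pseudo counts live in [0, k_P] and are nonincreasing in lambda
  expect_true(all(res$Ibar_star >= 0 & res$Ibar_star <= res$k_p))
  expect_true(all(diff(res$Ibar_star) <= 1e-12))
  expect_true(all(diff(res$Sbar_P) <= 1e-12))
  expect_gte(res$k_i_hat, 1)
  expect_lte(res$k_i_hat, length(sc$spec$candidates))
  expect_equal(res$selected,
               select_at(res$original_path, res$lambda_star_hat))
  # no candidates: trivially valid empty result
  d0 <- tiny_data(n = 14, k = 0)
  cm0 <- tiny_counts(G = 40, n = 14, seed = 74)
  res0 <- fsr_select(cm0, design_spec("line"), d0, k_p = 2, B = 2,
                     mechanism = "WN", seed = 75)
  expect_equal(res0$selected, character())
})

test_that("the selected set is invariant to threshold-grid refinement", {
  sc <- sim_scenario(G = 250, n = 24, k_candidates = 4, k_relevant = 1,
                     seed = 81)
  cm <- simulate_counts(sc, seed = 82)
  res <- fsr_select(cm, sc$spec, sc$data, k_p = 3, B = 6, seed = 83)
  # recompute lambda* on a doubled grid (midpoints added): the step curves
  # only change value at recorded r values, so the selection cannot move
  grid <- res$lambda_grid
  fine <- sort(unique(c(grid, grid[-length(grid)] + diff(grid) / 2)))
  m <- fsrcov:::.pseudo_means(res$pseudo_paths, fine)
  curve <- data.frame(lambda = fine,
                      alpha = m[, "Ibar_star"] / (1 + m[, "Sbar"]))
  est <- suppressWarnings(
    estimate_ki_lambda(curve, res$original_path, 0.05, 3, "RE"))
  expect_equal(select_at(res$original_path, est$lambda_star_hat),
               res$selected)
})

test_that("all eight variants run and agree on a clear-cut dataset", {
  sc <- sim_scenario(G = 300, n = 24, k_candidates = 4, k_relevant = 2,
                     nonnull_fraction = 0.5, seed = 91)
  cm <- simulate_counts(sc, seed = 92)
  lc <- log_cpm(cm)
  sel <- list()
  for (mech in c("WN", "RX", "OWN", "ORX"))
    for (est in c("RE", "ER")) {
      res <- fsr_select(lc, sc$spec, sc$data, k_p = 3, B = 8,
                        mechanism = mech, estimator = est, seed = 93)
      expect_s3_class(res, "fsr_result")
      expect_true(all(res$alpha_hat_pseudo >= 0))
      sel[[paste(mech, est)]] <- sort(res$selected)
    }
  # with two strongly relevant and two null covariates every variant should
  # land on the same selected set
  expect_length(unique(sel), 1L)
  expect_setequal(sel[[1]], sc$relevant_set)
})
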