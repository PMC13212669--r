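test_that("linear-model fits agree with a brute-force normal-equations oracle", {
  set.seed(31)
  n <- 12; G <- 25
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y <- matrix(rnorm(G * n), G, n)
  w <- matrix(rexp(G * n) + 0.1, G, n)
  fit <- fit_linear_models(y, X, weights = w)
  for (g in c(1, 7, G)) {
    Wg <- diag(w[g, ])
    beta_o <- solve(t(X) %*% Wg %*% X, t(X) %*% Wg %*% y[g, ])
    expect_equal(unname(fit$beta[g, ]), drop(beta_o), tolerance = 1e-10)
    r <- y[g, ] - X %*% beta_o
    expect_equal(fit$sigma2[g],
                 drop(t(r) %*% Wg %*% r) / (n - ncol(X)), tolerance = 1e-10)
  }
  # unweighted path: exact fit recovers coefficients with zero residual sd
  b <- c(2, -1, 0.5)
  y0 <- matrix(rep(drop(X %*% b), each = 3), 3, n, byrow = FALSE)
  fit0 <- fit_linear_models(y0, X)
  expect_equal(unname(fit0$beta), matrix(rep(b, each = 3), 3), tolerance = 1e-12)
  expect_equal(fit0$sd, rep(0, 3), tolerance = 1e-10)
  # intercept-only fit is the per-gene weighted mean
  fitm <- fit_linear_models(y, matrix(1, n, 1), weights = w)
  expect_equal(drop(fitm$beta), rowSums(y * w) / rowSums(w), tolerance = 1e-12)
  expect_error(fit_linear_models(y, cbind(X, X[, 2])), "rank")
})

test_that("scaling all weights by a constant changes nothing downstream", {
  set.seed(5)
  n <- 10; G <- 30
  X <- cbind(1, rnorm(n))
  y <- matrix(rnorm(G * n), G, n)
  w <- matrix(rexp(G * n) + 0.5, G, n)
  f1 <- fit_linear_models(y, X, weights = w)
  f2 <- fit_linear_models(y, X, weights = 100 * w)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-12)
  m1 <- ebayes_moderate(f1, d0 = 0)
  m2 <- ebayes_moderate(f2, d0 = 0)
  p1 <- test_variable(f1, m1, 2L)
  p2 <- test_variable(f2, m2, 2L)
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-10)
})

test_that("mean log-count equals the direct mean of log2(counts + 0.5)", {
  cm <- tiny_counts(G = 30, n = 5, seed = 4)
  lc <- log_cpm(cm)
  expect_equal(mean_log_count(lc), rowMeans(log2(cm$counts + 0.5)))
  # offsets cancel when every R_i + 1 = 1e6
  cmo <- set_libsize(cm, rep(1e6 - 1, 5))
  lco <- log_cpm(cmo)
  expect_equal(mean_log_count(lco), rowMeans(lco$y))
  # single sample
  cm1 <- set_libsize(count_matrix(matrix(9, 1, 1)), 999)
  lc1 <- log_cpm(cm1)
  expect_equal(unname(mean_log_count(lc1)),
               unname(drop(lc1$y)) + log2(1000) - log2(1e6))
})

test_that("voom weights equal the inverse fourth power of the trend", {
  # constant mean-variance trend: identical sd for every gene
  set.seed(8)
  n <- 6; G <- 12
  X <- matrix(1, n, 1)
  cm <- tiny_counts(G = G, n = n, seed = 8)
  lc <- log_cpm(cm)
  fit <- fit_linear_models(lc, X)
  fit$sd <- rep(4, G)  # s^(1/2) = 2 everywhere
  w <- voom_weights(fit, lc)
  expect_equal(unname(w), matrix(2^-4, G, n), tolerance = 1e-10)
  expect_true(all(is.finite(w)) && all(w > 0))
  lc5 <- lc; lc5$y <- lc5$y[1:5, , drop = FALSE]
  expect_error(voom_weights(fit_linear_models(lc5$y, X), lc5), "10 genes")
})

test_that("weights increase with abundance under a decreasing sd trend", {
  sc <- sim_scenario(G = 500, n = 16, k_candidates = 1, k_relevant = 0,
                     seed = 77)
  cm <- simulate_counts(sc, seed = 78)
  lc <- log_cpm(cm)
  X <- build_design(sc$spec, sc$data)
  fit0 <- fit_linear_models(lc, X)
  w <- voom_weights(fit0, lc)
  flc <- sweep(fit0$fitted, 2, log2(lc$libsize + 1) - log2(1e6), `+`)
  expect_gt(cor(as.vector(flc), as.vector(w), method = "spearman"), 0)
})

test_that("empirical-Bayes moment matching recovers the variance prior", {
  # degenerate prior: identical variances give complete shrinkage
  set.seed(3)
  fit <- fit_linear_models(matrix(rnorm(40), 4, 10), cbind(1, rnorm(10)))
  fit$sigma2 <- rep(4, 4); fit$sd <- rep(2, 4)
  mod <- ebayes_moderate(fit)
  expect_equal(mod$d0, Inf)
  expect_equal(mod$s_tilde_sq, rep(4, 4))
  # no-shrinkage limit
  mod0 <- ebayes_moderate(fit, d0 = 0)
  expect_equal(mod0$s_tilde_sq, fit$sigma2)
  # parameter recovery on simulated scaled-F draws
  set.seed(101)
  G <- 5000; df <- 10; d0 <- 4; s0 <- 1
  sigma2 <- s0 * d0 / rchisq(G, d0)
  s2 <- sigma2 * rchisq(G, df) / df
  fake <- fit; fake$sigma2 <- s2; fake$sd <- sqrt(s2); fake$df_resid <- df
  est <- ebayes_moderate(fake)
  expect_lt(abs(est$d0 - d0) / d0, 0.25)
  expect_lt(abs(est$s0sq - s0) / s0, 0.10)
})

test_that("moderated tests reduce to classical t-tests when d0 = 0", {
  set.seed(12)
  n <- 9; G <- 40
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- matrix(rnorm(G * n), G, n)
  fit <- fit_linear_models(y, X)
  mod <- ebayes_moderate(fit, d0 = 0)
  p <- test_variable(fit, mod, 2L)
  for (g in c(1, 13, G)) {
    cl <- summary(lm(y[g, ] ~ X[, 2] + X[, 3]))$coefficients
    expect_equal(as.numeric(p[g]), cl[2, 4], tolerance = 1e-8)
  }
  # a zero coefficient block gives statistic 0, p = 1
  fit$beta[1, 2] <- 0
  p2 <- test_variable(fit, mod, 2L)
  expect_equal(as.numeric(p2[1]), 1)
  expect_equal(attr(p2, "stat")[1], 0)
  expect_error(test_variable(fit, mod, 1L), "intercept")
})

test_that("the full pipeline reproduces limma's voom-lmFit-eBayes exactly", {
  skip_if_not_installed("limma")
  sc <- sim_scenario(G = 300, n = 16, k_candidates = 3, k_relevant = 1,
                     seed = 21)
  cm <- simulate_counts(sc, seed = 22)
  lc <- log_cpm(cm)
  X <- build_design(sc$spec, sc$data)
  fit <- fit_voom(lc, X)
  mod <- ebayes_moderate(fit)
  v <- limma::voom(cm$counts, design = X, lib.size = lc$libsize)
  expect_equal(unname(fit$weights), unname(v$weights), tolerance = 1e-10)
  lf <- limma::eBayes(limma::lmFit(v, X))
  expect_equal(mod$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0sq, lf$s2.prior, tolerance = 1e-6)
  for (v_name in c("cov1", "cov2")) {
    j <- attr(X, "blocks")[[v_name]]
    expect_equal(as.numeric(test_variable(fit, mod, v_name)),
                 unname(lf$p.value[, j]), tolerance = 1e-8)
  }
})

test_that("null continuous covariates yield approximately uniform p-values", {
  sc <- sim_scenario(G = 2000, n = 31, k_candidates = 3, k_relevant = 0,
                     seed = 7)
  cm <- simulate_counts(sc, seed = 8)
  lc <- log_cpm(cm)
  fit <- fit_voom(lc, build_design(sc$spec, sc$data))
  p <- test_variable(fit, ebayes_moderate(fit), "cov2")
  expect_gt(suppressWarnings(ks.test(as.numeric(p), "punif"))$p.value, 0.01)
})

test_that("categorical blocks are tested with a moderated F on L-1 columns", {
  set.seed(44)
  n <- 20
  d <- data.frame(line = factor(rep(c("L", "H"), 10)),
                  grp = factor(sample(letters[1:4], n, TRUE)),
                  x = rnorm(n))
  sp <- design_spec("line", c("grp", "x"))
  X <- build_design(sp, d)
  cm <- tiny_counts(G = 60, n = n, seed = 45)
  lc <- log_cpm(cm)
  fitw <- fit_voom(lc, X)
  pw <- test_variable(fitw, ebayes_moderate(fitw), "grp")
  expect_true(all(pw > 0 & pw <= 1))
  skip_if_not_installed("limma")
  # oracle on the unweighted fit, where limma's shared coefficient
  # correlation is exact (with gene-specific weights limma approximates the
  # multi-coefficient F through one common correlation matrix)
  fit <- fit_linear_models(lc, X)
  mod <- ebayes_moderate(fit)
  p <- test_variable(fit, mod, "grp")
  lf <- limma::eBayes(limma::lmFit(lc$y, X))
  tt <- limma::topTable(lf, coef = attr(X, "blocks")$grp, number = Inf,
                        sort.by = "none")
  expect_equal(as.numeric(p), tt$P.Value, tolerance = 1e-8)
})
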