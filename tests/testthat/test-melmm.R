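test_that("design construction enumerates fixed and genetic levels", {
  trial <- make_small_trial(n_lines = 30, seed = 61)
  spec <- build_design(trial$obs)
  # 3 environment means + 2 checks x 3 environments
  expect_equal(ncol(spec$X), 3 + 6)
  expect_equal(spec$r, 30)
  expect_equal(spec$t, 3)
  # brute-force level enumeration
  expect_equal(sum(startsWith(colnames(spec$X), "check:")),
               nrow(unique(trial$obs[trial$obs$is_check, c("env", "genotype")])))
  # unknown genotype id errors with the plot named
  bad <- trial$obs
  bad$genotype[5] <- NA
  expect_error(build_design(bad))
})

test_that("REML equals closed-form ANOVA estimators on a balanced RCB", {
  obs <- make_rcb(g = 30, b = 4, seed = 10)
  spec <- build_design(obs, random_row = FALSE, random_col = FALSE,
                       block = "block", estimate_spatial_rho = FALSE)
  fit <- reml_fit(spec, tol = 1e-10, maxit = 200)
  truth <- anova_rcb_estimates(obs)
  expect_true(fit$converged)
  expect_equal(fit$par$genetic[[1]]$d[1], unname(truth["sigma_g"]),
               tolerance = 1e-7)
  expect_equal(fit$par$iid[1], unname(truth["sigma_b"]), tolerance = 1e-7)
  expect_equal(fit$par$sp_var[1], unname(truth["sigma_e"]), tolerance = 1e-7)
})

test_that("zero genetic variance drives the estimate to the boundary floor", {
  obs <- make_rcb(g = 25, b = 4, sg = 0, sb = 0.5, se = 1, seed = 11)
  spec <- build_design(obs, random_row = FALSE, random_col = FALSE,
                       block = "block", estimate_spatial_rho = FALSE)
  fit <- reml_fit(spec, tol = 1e-9, maxit = 200)
  floor_ <- 1e-8 * stats::var(spec$y)
  expect_lt(fit$par$genetic[[1]]$d[1], 100 * floor_)
})

test_that("the log-likelihood is invariant to fixed-effect reparameterisation", {
  trial <- make_small_trial(n_lines = 40, seed = 62)
  spec <- build_design(trial$obs)
  fit <- reml_fit(spec, tol = 1e-8, maxit = 100)
  # recode environment means as intercept + contrasts (same column space)
  spec2 <- spec
  C <- matrix(0, ncol(spec$X), ncol(spec$X))
  diag(C) <- 1
  C[1, 1:3] <- 1  # first column becomes an overall mean over environments
  spec2$X <- spec$X %*% C
  colnames(spec2$X) <- colnames(spec$X)
  fit2 <- reml_fit(spec2, start = fit$par, tol = 1e-8, maxit = 100)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("doubling responses scales variances by 4, correlations unchanged", {
  trial <- make_small_trial(n_lines = 50, seed = 63)
  spec <- build_design(trial$obs, random_row = FALSE, random_col = FALSE)
  fit1 <- reml_fit(spec, tol = 1e-8, maxit = 100)
  spec2 <- spec
  spec2$y <- 2 * spec$y
  fit2 <- reml_fit(spec2, tol = 1e-8, maxit = 100)
  expect_equal(fit2$par$sp_var, 4 * fit1$par$sp_var, tolerance = 1e-3)
  expect_equal(fa_covariance(fit2$fa), 4 * fa_covariance(fit1$fa),
               tolerance = 5e-3)
  expect_equal(fit2$par$sp_rho_row, fit1$par$sp_rho_row, tolerance = 1e-3)
  expect_equal(genetic_correlations(fit2), genetic_correlations(fit1),
               tolerance = 1e-4)
})

test_that("genetic correlations have unit diagonal and recover high-h2 truth", {
  # strong genetic signal with a single factor and no specific variance:
  # all between-environment correlations near +/- 1
  trial <- make_small_trial(n_lines = 80, load = 0.9, psi = 0, sigma2 = 0.15,
                            seed = 64)
  spec <- build_design(trial$obs, random_row = FALSE, random_col = FALSE)
  fit <- reml_fit(spec, tol = 1e-7, maxit = 150)
  C <- genetic_correlations(fit)
  expect_equal(unname(diag(C)), rep(1, 3))
  expect_true(all(abs(C) > 0.8))
  # matches the correlation of genotype-by-environment BLUPs
  Cb <- stats::cor(fit$blup$ge)
  expect_lt(max(abs(sign(C) - sign(Cb))), 1e-12)
})

test_that("FA parameter recovery is unbiased over replicate simulations", {
  truth <- tcrossprod(matrix(rep(0.5, 3), 3)) + diag(rep(0.1, 3))
  est <- array(NA_real_, c(3, 3, 6))
  for (i in seq_len(6)) {
    trial <- make_small_trial(n_lines = 100, seed = 700 + i)
    spec <- build_design(trial$obs, random_row = FALSE, random_col = FALSE)
    fit <- reml_fit(spec, tol = 1e-6, maxit = 100)
    est[, , i] <- fa_covariance(fit$fa)
  }
  bias <- apply(est, c(1, 2), mean) - truth
  expect_lt(max(abs(bias)), 0.12)
})

test_that("interval coverage for the residual variance is near nominal", {
  # single-environment genotype + residual model; log-scale Wald intervals
  hits <- 0L; n_rep <- 120L
  for (i in seq_len(n_rep)) {
    obs <- make_rcb(g = 25, b = 3, sg = 1, sb = 0.3, se = 1.5,
                    seed = 2000 + i)
    spec <- build_design(obs, random_row = FALSE, random_col = FALSE,
                         block = "block", estimate_spatial_rho = FALSE)
    fit <- reml_fit(spec, tol = 1e-7, maxit = 100)
    # SE of sigma2_e from the AI matrix at the optimum
    spec_p <- climqtl:::pad_kernels(spec)
    lags <- climqtl:::spatial_lags(spec_p)
    aux <- climqtl:::build_aux(spec_p)
    fp <- climqtl:::flatten_params(spec_p, fit$par)
    ev <- climqtl:::reml_eval(spec_p, climqtl:::build_V(spec_p, fit$par, lags, aux))
    sc <- climqtl:::reml_scores(spec_p, fit$par, ev, lags, aux, fp$desc)
    j <- which(vapply(fp$desc, function(d) d$kind == "sp_var", logical(1)))
    se <- sqrt(diag(solve(sc$AI))[j])
    est <- fit$par$sp_var[1]
    lo <- est * exp(-1.96 * se / est)
    hi <- est * exp(1.96 * se / est)
    if (lo <= 1.5 && 1.5 <= hi) hits <- hits + 1L
  }
  cover <- hits / n_rep
  expect_gte(cover, 0.90)
  expect_lte(cover, 0.99)
})

test_that("tidiers expose variance components and fit summaries", {
  obs <- make_rcb(seed = 12)
  spec <- build_design(obs, random_row = FALSE, random_col = FALSE,
                       block = "block", estimate_spatial_rho = FALSE)
  fit <- reml_fit(spec, tol = 1e-8)
  td <- tidy(fit)
  expect_true(all(c("component", "term", "env", "estimate") %in% names(td)))
  expect_true(any(td$component == "ge"))
  fx <- tidy(fit, effects = "fixed")
  expect_equal(nrow(fx), ncol(spec$X))
  expect_true(all(fx$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(obs))
  expect_true(gl$converged)
})
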