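# Shared builders for small simulated trials used across test files.

three_env_frame <- function() data.frame(env = c("E1", "E2", "E3"), year = 2015L)

# a small three-environment trial with optional planted QTL
make_small_trial <- function(n_lines = 120, n_chr = 2, m_per_chr = 12,
                             len = 100, qtl = qtl_spec(), covariates = NULL,
                             seed = 42, rho_row = 0.3, rho_col = 0.2,
                             sigma2 = 0.5, load = 0.5, psi = 0.1,
                             check_lines = c("CK1", "CK2")) {
  map <- simulate_linkage_map(n_chr, m_per_chr, len, seed = seed)
  geno <- simulate_dh_population(map, n_lines, seed = seed + 1)
  env <- three_env_frame()
  design <- generate_prep_design(rownames(geno), env, check_lines, 2L,
                                 grid_columns = 10L, seed = seed + 2)
  fa <- fa_params(matrix(rep(load, 3), 3), rep(psi, 3), envs = env$env)
  sp <- spatial_params(env$env, rep(sigma2, 3), rho_row, rho_col)
  obs <- simulate_phenotypes(design, geno, qtl, covariates,
                             env_means = c(E1 = 3, E2 = 4, E3 = 5),
                             fa = fa, spatial = sp, seed = seed + 3)
  list(map = map, geno = geno, design = design, obs = obs, fa = fa,
       spatial = sp, M = make_interval_markers(geno, map))
}

# line x environment covariate with between- and within-environment spread
make_test_covariate <- function(lines, envs = c("E1", "E2", "E3"),
                                env_levels = c(20, 23, 26), sd_within = 0.5,
                                name = "cvx", seed = 99) {
  withr::with_seed(seed, purrr::map_dfr(seq_along(envs), function(i) {
    tibble::tibble(line = lines, env = envs[i], covariate = name,
                   value = env_levels[i] + stats::rnorm(length(lines), 0, sd_within))
  }))
}

# balanced randomized-complete-block data in one environment
make_rcb <- function(g = 30, b = 4, sg = 2.0, sb = 0.7, se = 1.2, seed = 10) {
  withr::with_seed(seed, {
    geno_eff <- stats::rnorm(g, 0, sqrt(sg))
    blk_eff <- stats::rnorm(b, 0, sqrt(sb))
    y <- outer(geno_eff, blk_eff, "+") + 10 + stats::rnorm(g * b, 0, sqrt(se))
    tibble::tibble(env = "E1", column = rep(seq_len(b), each = g),
                   row = rep(seq_len(g), b),
                   genotype = rep(sprintf("G%02d", seq_len(g)), b),
                   is_check = FALSE, block = rep(seq_len(b), each = g),
                   y = as.vector(y))
  })
}

anova_rcb_estimates <- function(obs) {
  av <- stats::anova(stats::lm(y ~ factor(genotype) + factor(block), data = obs))
  b <- length(unique(obs$block)); g <- length(unique(obs$genotype))
  mse <- av["Residuals", "Mean Sq"]
  c(sigma_g = (av["factor(genotype)", "Mean Sq"] - mse) / b,
    sigma_b = (av["factor(block)", "Mean Sq"] - mse) / g,
    sigma_e = mse)
}
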