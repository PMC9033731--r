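# Simulation studies of the pipeline's operating characteristics: null
# false-positive calibration of the thresholded genome scan, and power /
# localisation for planted performance and responsiveness QTL. These are
# the package's own reproducible evaluation harnesses; the methods
# vignette documents the study conditions.

study_conditions <- function(n_lines, t_envs) {
  if (t_envs == 3L) {
    list(envs = data.frame(env = c("E1", "E2", "E3"), year = 2015L),
         env_means = c(E1 = 3, E2 = 4, E3 = 5),
         fa_loadings = rep(0.5, 3), fa_psi = rep(0.1, 3),
         sigma2 = rep(0.5, 3), rho_row = 0.4, rho_col = 0.25,
         grid_columns = 10L,
         map = list(n_chr = 3L, m_per_chr = 20L, len = 100))
  } else {
    list(envs = data.frame(env = c("AV15", "RS15", "WT15", "AV16", "RS16", "WT16"),
                           year = c(2015L, 2015L, 2015L, 2016L, 2016L, 2016L)),
         env_means = c(AV15 = 2.3, RS15 = 2.8, WT15 = 2.7, AV16 = 3.5,
                       RS16 = 6.5, WT16 = 7.0),
         fa_loadings = rep(0.45, 6), fa_psi = rep(0.08, 6),
         sigma2 = rep(0.5, 6), rho_row = 0.4, rho_col = 0.25,
         grid_columns = 12L,
         map = list(n_chr = 3L, m_per_chr = 21L, len = 150))
  }
}

study_phenotypic_sd <- function(cond) {
  sqrt(mean(cond$fa_loadings^2 + cond$fa_psi) + mean(cond$sigma2))
}

simulate_study_data <- function(cond, n_lines, seed, qtl = qtl_spec(),
                                covariates = NULL) {
  map <- simulate_linkage_map(cond$map$n_chr, cond$map$m_per_chr,
                              cond$map$len, seed = seed)
  geno <- simulate_dh_population(map, n_lines, seed = seed + 1L)
  design <- generate_prep_design(rownames(geno), cond$envs,
                                 check_lines = c("CK1", "CK2"), check_reps = 2L,
                                 grid_columns = cond$grid_columns,
                                 seed = seed + 2L)
  fa <- fa_params(matrix(cond$fa_loadings, ncol = 1), cond$fa_psi,
                  envs = cond$envs$env)
  sp <- spatial_params(cond$envs$env, cond$sigma2, cond$rho_row, cond$rho_col)
  obs <- simulate_phenotypes(design, geno, qtl, covariates,
                             env_means = cond$env_means, fa = fa, spatial = sp,
                             seed = seed + 3L)
  list(map = map, geno = geno, design = design, obs = obs,
       M = make_interval_markers(geno, map))
}

# six-environment climate draw reusing the pipeline's climate conditions
simulate_study_covariates <- function(cond, lines, seed,
                                      covariate = "grainfill_avg_max") {
  cfg <- default_pipeline_config(seed)
  envs <- cond$envs$env
  thermal <- list(); temps <- list()
  for (e in envs) {
    temps[[e]] <- simulate_temperature_series(
      cfg$climate$n_days, cfg$climate$base_mean[[e]],
      cfg$climate$seasonal_amplitude, cfg$climate$diurnal_range,
      cfg$climate$heatwave_rate[[e]], cfg$climate$heatwave_boost,
      cfg$climate$noise_sd, seed = seed + 10L + match(e, envs),
      start_date = cfg$climate$sowing[[e]])
    thermal[[e]] <- thermal_time(temps[[e]], cfg$climate$sowing[[e]])
  }
  emergence <- withr_seed(seed + 30L, tibble::tibble(
    line = lines,
    emergence_dd = stats::rnorm(length(lines),
                                cfg$phenology$emergence_mean_dd,
                                cfg$phenology$emergence_sd_dd)))
  anth <- estimate_anthesis(emergence, cfg$phenology$anthesis_offset_dd, thermal)
  compute_covariates(temps, anth, thermal, covariates = covariate)
}

#' Null false-positive calibration of the thresholded genome scan
#'
#' Simulates multi-environment trials with no planted QTL, runs the
#' performance scan with its per-chromosome polygenic null models, applies
#' the effective-test-count threshold, and records whether any marker
#' exceeds it. The empirical genome-wide false-positive rate should not
#' exceed the nominal level by more than sampling noise.
#'
#' @param n_reps Number of simulated trials.
#' @param n_lines DH lines per trial.
#' @param t_envs 3 or 6 environments (two preset study conditions).
#' @param alpha Genome-wide level.
#' @param seed Integer seed.
#' @param tol,maxit REML controls for the null fits.
#' @return A tibble with one row per replicate: `rep`, `max_wald`,
#'   `threshold`, `false_positive`; the empirical rate and its binomial
#'   standard error are attached as attributes `fpr` and `fpr_se`.
#' @export
null_fpr_study <- function(n_reps = 200, n_lines = 150, t_envs = 3L,
                           alpha = 0.05, seed = 1L, tol = 1e-4, maxit = 20) {
  cond <- study_conditions(n_lines, t_envs)
  res <- purrr::map_dfr(seq_len(n_reps), function(i) {
    dat <- simulate_study_data(cond, n_lines, seed = seed + 1000L * i)
    spec <- build_design(dat$obs, random_row = FALSE, random_col = FALSE)
    sc <- scan_performance(spec, dat$M, tol = tol, maxit = maxit)
    thr <- li_ji_threshold(dat$M, alpha)
    mw <- max(sc$wald, na.rm = TRUE)
    tibble::tibble(rep = i, max_wald = mw, threshold = thr$wald_threshold,
                   false_positive = mw > thr$wald_threshold)
  })
  fpr <- mean(res$false_positive)
  attr(res, "fpr") <- fpr
  attr(res, "fpr_se") <- sqrt(alpha * (1 - alpha) / n_reps)
  res
}

#' Power and localisation for planted performance and responsiveness QTL
#'
#' Each replicate trial plants one performance QTL (effect in phenotypic
#' SD units) at the centre of chromosome C1 and one responsiveness QTL
#' (covariate-range-normalised effect in phenotypic SD units) at the
#' centre of chromosome C2, then runs the performance scan and the
#' responsiveness scan against shared per-chromosome null models. A
#' planted QTL counts as detected when the maximum-Wald marker of the
#' relevant scan on its chromosome exceeds the genome-wide threshold, lies
#' within `window` cM of the planted position, and carries the planted
#' sign.
#'
#' @param n_reps Number of replicate trials.
#' @param n_lines DH lines per trial.
#' @param t_envs 3 or 6 environments.
#' @param perf_effect_sd Planted performance effect in phenotypic SD units.
#' @param resp_effect_sd Planted covariate-range-normalised responsiveness
#'   effect in phenotypic SD units.
#' @param covariate Climatic covariate carrying the responsiveness effect.
#' @param window Localisation window in cM.
#' @param alpha Genome-wide level.
#' @param seed Integer seed.
#' @param tol,maxit REML controls.
#' @return A tibble with two rows (one per QTL kind) per replicate: `rep`,
#'   `kind`, `detected`, `top_position`, `planted_position`, `top_effect`,
#'   `true_effect`, `max_wald`, `threshold`. Detection rates per kind are
#'   attached as attributes `rate_performance` and `rate_responsiveness`.
#' @export
power_study <- function(n_reps = 12, n_lines = 400, t_envs = 6L,
                        perf_effect_sd = 0.4, resp_effect_sd = 0.35,
                        covariate = "grainfill_avg_max",
                        window = 15, alpha = 0.05, seed = 1L,
                        tol = 1e-3, maxit = 15) {
  cond <- study_conditions(n_lines, t_envs)
  sdP <- study_phenotypic_sd(cond)
  res <- purrr::map_dfr(seq_len(n_reps), function(i) {
    sd_i <- seed + 1000L * i
    map <- simulate_linkage_map(cond$map$n_chr, cond$map$m_per_chr,
                                cond$map$len, seed = sd_i)
    m_perf <- nearest_marker(map, "C1", cond$map$len / 2)
    m_resp <- nearest_marker(map, "C2", cond$map$len / 2)
    pos <- c(performance = map$position[map$marker == m_perf],
             responsiveness = map$position[map$marker == m_resp])
    lines_tmp <- sprintf("L%03d", seq_len(n_lines))
    covs <- simulate_study_covariates(cond, lines_tmp, seed = sd_i,
                                      covariate = covariate)
    rng <- unname(covariate_range(covs, covariate))
    eff <- c(performance = perf_effect_sd * sdP,
             responsiveness = resp_effect_sd * sdP / rng)
    qtl <- qtl_spec(c(m_perf, m_resp), c("performance", "responsiveness"),
                    unname(eff), c(NA, covariate))
    dat <- simulate_study_data(cond, n_lines, seed = sd_i, qtl = qtl,
                               covariates = covs)
    spec <- build_design(dat$obs, random_row = FALSE, random_col = FALSE)
    scans <- scan_genome(spec, dat$M, covariates = covs,
                         covariate_names = covariate, tol = tol,
                         maxit = maxit)
    thr <- li_ji_threshold(dat$M, alpha)
    info <- marker_info(dat$M)
    score <- function(sc, kd, chrom) {
      sub <- sc[sc$chromosome == chrom, ]
      top <- sub[which.max(sub$wald), ]
      tibble::tibble(
        rep = i, kind = kd,
        detected = isTRUE(top$wald > thr$wald_threshold &&
                            abs(top$position - pos[[kd]]) <= window &&
                            sign(top$effect) == sign(eff[[kd]])),
        top_position = top$position, planted_position = pos[[kd]],
        top_effect = top$effect, true_effect = eff[[kd]],
        max_wald = top$wald, threshold = thr$wald_threshold)
    }
    dplyr::bind_rows(
      score(scans$performance, "performance", "C1"),
      score(scans[[paste0("resp_", covariate)]], "responsiveness", "C2"))
  })
  attr(res, "rate_performance") <-
    mean(res$detected[res$kind == "performance"])
  attr(res, "rate_responsiveness") <-
    mean(res$detected[res$kind == "responsiveness"])
  res
}
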