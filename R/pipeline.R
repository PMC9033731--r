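# End-to-end pipeline: simulate -> covariates -> baseline fit -> scans ->
# final models -> clustering and classification, with every artefact
# written to a run directory.

#' Default pipeline configuration
#'
#' A complete nested configuration for [run_pipeline()], sized for a small
#' but fully featured run: one biparental DH population over six
#' environments (three locations x two years), a three-chromosome map, one
#' planted performance QTL and one planted responsiveness QTL. All fields
#' can be overridden before passing to [run_pipeline()]; the configuration
#' can also be written to / read from YAML.
#'
#' @param seed Integer seed controlling every stochastic stage.
#' @return A named list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    population = list(name = "SIM1", n_lines = 150L,
                      parents = c(A = "ParentA", B = "ParentB")),
    map = list(n_chromosomes = 3L, markers_per_chromosome = 25L,
               chromosome_length = 120),
    design = list(
      environments = data.frame(
        env = c("AV15", "RS15", "WT15", "AV16", "RS16", "WT16"),
        year = c(2015L, 2015L, 2015L, 2016L, 2016L, 2016L)),
      check_lines = c("Check1", "Check2"),
      check_reps = 2L, grid_columns = 12L),
    climate = list(
      n_days = 200L,
      base_mean = c(AV15 = 17, RS15 = 15.5, WT15 = 14, AV16 = 14.5,
                    RS16 = 13.5, WT16 = 12.5),
      seasonal_amplitude = 6, diurnal_range = 12,
      heatwave_rate = c(AV15 = 6, RS15 = 4, WT15 = 2, AV16 = 1.5,
                        RS16 = 1, WT16 = 0.5),
      heatwave_boost = 8, noise_sd = 2,
      rainfall_mm = c(AV15 = 100, RS15 = 190, WT15 = 210, AV16 = 220,
                      RS16 = 480, WT16 = 380),
      sowing = as.Date(c(AV15 = "2015-05-15", RS15 = "2015-05-21",
                         WT15 = "2015-05-12", AV16 = "2016-06-01",
                         RS16 = "2016-05-15", WT16 = "2016-05-18"))),
    phenology = list(emergence_mean_dd = 1100, emergence_sd_dd = 60,
                     anthesis_offset_dd = 100),
    trait = list(
      name = "yield",
      env_means = c(AV15 = 2.3, RS15 = 2.8, WT15 = 2.7, AV16 = 3.5,
                    RS16 = 6.5, WT16 = 7.0),
      fa_loadings = rep(0.45, 6), fa_psi = rep(0.08, 6),
      sigma2 = rep(0.5, 6), rho_row = 0.4, rho_col = 0.25),
    qtl = list(
      list(marker = NULL, chromosome = "C1", position = 60,
           kind = "performance", effect = 0.35),
      list(marker = NULL, chromosome = "C2", position = 60,
           kind = "responsiveness", covariate = "grainfill_avg_max",
           effect = 0.08)),
    scan = list(alpha = 0.05, covariates = c("grainfill_avg_max",
                                             "grainfill_days_gt30"),
                prune_window = 30, cluster_window = 10),
    reml = list(tol = 1e-6, maxit = 60)
  )
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @param config Configuration list.
#' @return The configuration list (reader) or `path` invisibly (writer).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$design$environments <- as.data.frame(cfg$design$environments)
  if (!is.null(cfg$climate$sowing))
    cfg$climate$sowing <- as.Date(unlist(cfg$climate$sowing))
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  config$climate$sowing <- as.character(config$climate$sowing)
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_config <- function(config) {
  need <- c("seed", "population", "map", "design", "climate", "phenology",
            "trait", "qtl", "scan", "reml")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0L)
    stop(sprintf("config missing block(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (is.null(config$scan$covariates))
    stop("config missing key: scan$covariates", call. = FALSE)
  invisible(config)
}

#' Run the whole simulation-to-QTL pipeline
#'
#' Executes simulate (map, DH genotypes, p-rep design, climate) ->
#' covariates -> baseline mixed-model fit -> performance scan and one
#' responsiveness scan per configured covariate -> thresholding, pruning
#' and joint final models -> clustering and framework classification.
#' Every table is written to `outdir` as delimited text together with the
#' seed and a hash of the configuration; scan and responsiveness plots are
#' saved alongside. A stage failure aborts with the stage name; outputs of
#' completed stages persist.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or a
#'   YAML path.
#' @param outdir Output directory (created if needed).
#' @param stop_after Last stage to execute: one of `"simulate"`,
#'   `"covariates"`, `"fit"`, `"scan"`, `"finalize"`, `"report"` (default:
#'   run everything).
#' @return Invisibly, a list with all intermediate objects and result
#'   tables.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         outdir = tempfile("climqtl_"),
                         stop_after = "report") {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  order_ <- c("simulate", "covariates", "fit", "scan", "finalize", "report")
  stop_after <- match.arg(stop_after, order_)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  seed <- config$seed
  done <- FALSE
  stage <- function(name, code) {
    if (done) return(NULL)
    out <- tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    if (name == stop_after) done <<- TRUE
    out
  }

  res <- c(res, stage("simulate", {
    map <- simulate_linkage_map(config$map$n_chromosomes,
                                config$map$markers_per_chromosome,
                                config$map$chromosome_length, seed = seed)
    geno <- simulate_dh_population(map, config$population$n_lines,
                                   seed = seed + 1L)
    envs <- config$design$environments
    design <- generate_prep_design(
      rownames(geno), envs, config$design$check_lines,
      config$design$check_reps, config$design$grid_columns,
      seed = seed + 2L)
    climate <- purrr::imap(stats::setNames(envs$env, envs$env), function(e, nm) {
      list(temps = simulate_temperature_series(
        config$climate$n_days, config$climate$base_mean[[e]],
        config$climate$seasonal_amplitude, config$climate$diurnal_range,
        config$climate$heatwave_rate[[e]], config$climate$heatwave_boost,
        config$climate$noise_sd, seed = seed + 10L + match(e, envs$env),
        start_date = config$climate$sowing[[e]]),
        rain = simulate_rainfall_series(
          config$climate$n_days, config$climate$rainfall_mm[[e]],
          seed = seed + 20L + match(e, envs$env),
          start_date = config$climate$sowing[[e]]))
    })
    write_linkage_map(map, file.path(outdir, "linkage_map.csv"))
    write_genotypes(geno, file.path(outdir, "genotypes.csv"))
    readr::write_csv(design, file.path(outdir, "design.csv"))
    for (e in envs$env) {
      write_climate_table(climate[[e]]$temps,
                          file.path(outdir, sprintf("temperature_%s.csv", e)))
      write_climate_table(climate[[e]]$rain,
                          file.path(outdir, sprintf("rainfall_%s.csv", e)))
    }
    list(map = map, geno = geno, design = design, climate = climate)
  }))

  res <- c(res, stage("covariates", {
    envs <- config$design$environments$env
    thermal <- lapply(stats::setNames(envs, envs), function(e)
      thermal_time(res$climate[[e]]$temps, config$climate$sowing[[e]]))
    emergence <- withr_seed(seed + 3L, tibble::tibble(
      line = rownames(res$geno),
      emergence_dd = stats::rnorm(nrow(res$geno),
                                  config$phenology$emergence_mean_dd,
                                  config$phenology$emergence_sd_dd)))
    anth <- estimate_anthesis(emergence, config$phenology$anthesis_offset_dd,
                              thermal)
    covs <- compute_covariates(
      temps = lapply(res$climate, `[[`, "temps"), anthesis = anth,
      thermal = thermal, rainfall = lapply(res$climate, `[[`, "rain"))
    write_climate_table(covs, file.path(outdir, "covariates.csv"))
    list(thermal = thermal, anthesis = anth, covariates = covs)
  }))

  res <- c(res, stage("phenotypes", {
    map <- res$map
    qtl_rows <- purrr::map_dfr(config$qtl, function(q) {
      mk <- q$marker %||% nearest_marker(map, q$chromosome, q$position)
      tibble::tibble(marker = mk, kind = q$kind, effect = q$effect,
                     covariate = q$covariate %||% NA_character_)
    })
    qtl <- qtl_spec(qtl_rows$marker, qtl_rows$kind, qtl_rows$effect,
                    qtl_rows$covariate)
    envs <- config$design$environments$env
    fa <- fa_params(matrix(config$trait$fa_loadings, ncol = 1),
                    config$trait$fa_psi, envs = envs)
    sp <- spatial_params(envs, config$trait$sigma2,
                         config$trait$rho_row, config$trait$rho_col)
    obs <- simulate_phenotypes(res$design, res$geno, qtl, res$covariates,
                               env_means = config$trait$env_means, fa = fa,
                               spatial = sp, seed = seed + 4L,
                               trait = config$trait$name)
    readr::write_csv(obs, file.path(outdir, "phenotypes.csv"))
    list(qtl_true = qtl, observations = obs)
  }))

  res <- c(res, stage("markers", {
    M <- make_interval_markers(res$geno, res$map)
    list(M = M)
  }))

  res <- c(res, stage("fit", {
    spec <- build_design(res$observations)
    baseline <- reml_fit(spec, tol = config$reml$tol, maxit = config$reml$maxit)
    readr::write_csv(tidy(baseline), file.path(outdir, "baseline_varcomp.csv"))
    list(spec = spec, baseline = baseline)
  }))

  res <- c(res, stage("scan", {
    thr <- li_ji_threshold(res$M, config$scan$alpha)
    scans <- scan_genome(res$spec, res$M, covariates = res$covariates,
                         covariate_names = config$scan$covariates,
                         baseline = res$baseline,
                         tol = config$reml$tol, maxit = config$reml$maxit)
    for (nm in names(scans))
      readr::write_csv(scans[[nm]], file.path(outdir, sprintf("scan_%s.csv", nm)))
    list(threshold = thr, scans = scans)
  }))

  res <- c(res, stage("finalize", {
    records <- purrr::map_dfr(names(res$scans), function(nm) {
      sc <- res$scans[[nm]]
      sel <- prune_30cM(sc, res$threshold, config$scan$prune_window)
      fit_final_model(res$spec, sel, res$M, covariates = res$covariates,
                      window = config$scan$prune_window,
                      trait = config$trait$name,
                      population = config$population$name,
                      parents = config$population$parents,
                      tol = config$reml$tol, maxit = config$reml$maxit)
    })
    readr::write_csv(records, file.path(outdir, "qtl_records.csv"))
    list(records = records)
  }))

  res <- c(res, stage("report", {
    clusters <- cluster_qtl(res$records, config$scan$cluster_window)
    clusters <- flag_anthesis_association(clusters,
                                          res$records[0, , drop = FALSE])
    framework <- classify_framework(clusters)
    readr::write_csv(framework, file.path(outdir, "framework.csv"))
    readr::write_csv(dplyr::select(clusters, -"members"),
                     file.path(outdir, "clusters.csv"))
    for (nm in names(res$scans)) {
      p <- ggplot2::autoplot(res$scans[[nm]], threshold = res$threshold)
      ggplot2::ggsave(file.path(outdir, sprintf("scan_%s.pdf", nm)), p,
                      width = 8, height = 4)
    }
    resp_rec <- res$records[res$records$type == "responsiveness", ]
    if (nrow(resp_rec) > 0L) {
      p <- plot_responsiveness(resp_rec, res$covariates)
      ggplot2::ggsave(file.path(outdir, "responsiveness_effects.pdf"), p,
                      width = 7, height = 4)
    }
    writeLines(c(sprintf("seed: %d", seed),
                 sprintf("config_hash: %s", config_hash(config))),
               file.path(outdir, "run_info.txt"))
    list(clusters = clusters, framework = framework, outdir = outdir)
  }))

  invisible(res)
}

# closest mapped marker to a requested chromosome/position
nearest_marker <- function(map, chromosome, position) {
  sub <- map[map$chromosome == chromosome, ]
  if (nrow(sub) == 0L) stop(sprintf("no markers on %s", chromosome), call. = FALSE)
  sub$marker[which.min(abs(sub$position - position))]
}

# order-insensitive hash of the configuration (no external digest dependency)
config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 251 + 1)) %%
            .Machine$integer.max)
}
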