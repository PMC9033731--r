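#' Generate a partially replicated (p-rep) multi-environment field design
#'
#' Every DH line is sown once in every environment of its year and receives
#' one duplicate plot in exactly one randomly chosen environment of that
#' year, so with three environments per year lines are replicated 4/3 ~ 1.33
#' times per environment on average. Check varieties are fully replicated
#' (`check_reps` plots in every environment). Plots are assigned at random
#' to a column x row grid; grid cells beyond the required plot count are
#' left unsown.
#'
#' @param dh_lines Character vector of DH line ids.
#' @param environments Tibble/data frame with columns `env` and `year`
#'   grouping environments into years.
#' @param check_lines Character vector of check ids (may be empty).
#' @param check_reps Replicates of each check per environment.
#' @param grid_columns Number of field columns per environment; rows are
#'   sized to fit the required plots.
#' @param grid_rows Optional fixed number of rows per environment; if
#'   supplied, capacity `grid_columns * grid_rows` must cover the plots.
#' @param seed Integer seed.
#' @return A tibble of class `field_design` with columns `env`, `year`,
#'   `column`, `row`, `genotype`, `is_check`.
#' @export
generate_prep_design <- function(dh_lines, environments, check_lines = character(),
                                 check_reps = 2L, grid_columns, grid_rows = NULL,
                                 seed) {
  stopifnot(length(dh_lines) >= 1, nrow(environments) >= 1,
            all(c("env", "year") %in% names(environments)))
  withr_seed(seed, {
    plots <- purrr::map_dfr(unique(environments$year), function(yr) {
      envs <- environments$env[environments$year == yr]
      # one duplicate env per line, uniform over the year's environments
      dup_env <- sample(envs, length(dh_lines), replace = TRUE)
      purrr::map_dfr(envs, function(e) {
        geno <- c(dh_lines, dh_lines[dup_env == e],
                  rep(check_lines, each = check_reps))
        tibble::tibble(env = e, year = yr, genotype = geno,
                       is_check = geno %in% check_lines)
      })
    })
    out <- plots |>
      dplyr::group_by(.data$env) |>
      dplyr::group_modify(function(d, key) {
        n <- nrow(d)
        rows <- grid_rows %||% ceiling(n / grid_columns)
        cells <- tidyr::expand_grid(column = seq_len(grid_columns),
                                    row = seq_len(rows))
        if (nrow(cells) < n) {
          stop(sprintf(
            "grid %d x %d (%d plots) cannot hold the %d plots required in %s",
            grid_columns, rows, nrow(cells), n, key$env), call. = FALSE)
        }
        pick <- cells[sample.int(nrow(cells), n), ]
        dplyr::bind_cols(d[sample.int(n), ], pick)
      }) |>
      dplyr::ungroup() |>
      dplyr::select("env", "year", "column", "row", "genotype", "is_check") |>
      dplyr::arrange(.data$env, .data$column, .data$row)
    class(out) <- c("field_design", class(tibble::tibble()))
    out
  })
}

#' Mean replication of DH lines per environment
#'
#' @param design A `field_design`.
#' @return A tibble with per-environment mean plots per DH line and the
#'   overall mean.
#' @export
mean_replication <- function(design) {
  per_env <- design |>
    dplyr::filter(!.data$is_check) |>
    dplyr::count(.data$env, .data$genotype) |>
    dplyr::group_by(.data$env) |>
    dplyr::summarise(mean_reps = mean(.data$n))
  dplyr::bind_rows(per_env,
                   tibble::tibble(env = "overall",
                                  mean_reps = mean(per_env$mean_reps)))
}

#' Published field-layout presets
#'
#' Grid dimensions and plot counts of the six experiment layouts used in
#' the heat-adaptation multi-environment trials this package emulates: the
#' pooled three-population series ("GSM") and the two single-population
#' series ("X32", "X4"), each with a large 2015 and a compact 2016 layout.
#'
#' @param name One of `"GSM15"`, `"GSM16"`, `"X3215"`, `"X3216"`, `"X415"`,
#'   `"X416"`; `NULL` lists all presets.
#' @return A tibble with `preset`, `columns`, `rows`, `plots`,
#'   `dh_genotypes`, `check_genotypes`, `mean_reps`.
#' @export
#' @examples
#' design_preset("GSM15") # 12 columns x 108 rows = 1296 plots
design_preset <- function(name = NULL) {
  presets <- tibble::tribble(
    ~preset, ~columns, ~rows, ~plots, ~dh_genotypes, ~check_genotypes, ~mean_reps,
    "GSM15",  12L, 108L, 1296L, 922L, 7L, 1.49,
    "GSM16",  24L,  14L,  336L, 245L, 7L, 1.37,
    "X3215",  12L,  18L,  216L, 142L, 8L, 1.52,
    "X3216",  24L,   6L,  144L,  86L, 9L, 1.67,
    "X415",   12L,  20L,  240L, 161L, 8L, 1.49,
    "X416",   24L,   8L,  192L, 117L, 8L, 1.62
  )
  if (is.null(name)) return(presets)
  out <- presets[presets$preset == name, ]
  if (nrow(out) == 0L)
    stop(sprintf("unknown preset '%s'", name), call. = FALSE)
  out
}
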