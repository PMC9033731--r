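#' Simulate a daily temperature series for one environment
#'
#' Daily means follow a half-cosine seasonal trend from `base_mean -
#' seasonal_amplitude` at sowing up to `base_mean + seasonal_amplitude` at
#' season end (emulating a winter-sown crop running into a hot grain fill),
#' plus Gaussian noise. Daily max/min sit half the diurnal range above/below
#' the mean. Heatwaves are random consecutive-day runs (2-5 days) whose
#' daily maxima are boosted by `heatwave_boost`.
#'
#' @param n_days Season length in days (>= 1).
#' @param base_mean Mid-season mean temperature (deg C).
#' @param seasonal_amplitude Half-range of the seasonal trend (deg C).
#' @param diurnal_range Daily max - min (deg C, >= 0).
#' @param heatwave_rate Expected number of heatwave events per season.
#' @param heatwave_boost Added to daily max during a heatwave (deg C).
#' @param noise_sd SD of daily mean noise (deg C).
#' @param seed Integer seed.
#' @param start_date First day of the record (sowing), a `Date`.
#' @return A tibble with columns `date`, `tmin`, `tmax` (strictly
#'   increasing dates, `tmin <= tmax` everywhere).
#' @export
simulate_temperature_series <- function(n_days, base_mean, seasonal_amplitude = 0,
                                        diurnal_range = 10, heatwave_rate = 0,
                                        heatwave_boost = 8, noise_sd = 1, seed,
                                        start_date = as.Date("2015-05-01")) {
  stopifnot(n_days >= 1, diurnal_range >= 0, noise_sd >= 0, heatwave_rate >= 0)
  withr_seed(seed, {
    i <- seq_len(n_days)
    trend <- if (n_days == 1L) 0 else
      -seasonal_amplitude * cos(pi * (i - 1) / (n_days - 1))
    mean_t <- base_mean + trend + stats::rnorm(n_days, 0, noise_sd)
    tmax <- mean_t + diurnal_range / 2
    tmin <- mean_t - diurnal_range / 2
    n_events <- stats::rpois(1, heatwave_rate)
    if (n_events > 0L) {
      for (k in seq_len(n_events)) {
        len <- sample(2:5, 1)
        s <- sample.int(max(1L, n_days - len + 1L), 1)
        run <- s:min(n_days, s + len - 1L)
        tmax[run] <- tmax[run] + heatwave_boost
      }
    }
    tibble::tibble(date = start_date + i - 1L, tmin = tmin, tmax = tmax)
  })
}

#' Cumulative thermal time (degree days) from sowing
#'
#' Each day after sowing contributes `max(0, (tmin + tmax) / 2)` degree
#' days (base temperature 0 deg C); the cumulative series starts at 0 on
#' the sowing date. Gap days in the record are an error - no silent
#' interpolation.
#'
#' @param series Temperature tibble (`date`, `tmin`, `tmax`).
#' @param sowing_date A `Date` within the record.
#' @return A tibble (`date`, `degree_days`) from the sowing date onwards,
#'   with `degree_days` non-decreasing and 0 at sowing.
#' @export
thermal_time <- function(series, sowing_date) {
  stopifnot(all(c("date", "tmin", "tmax") %in% names(series)))
  if (is.unsorted(series$date, strictly = TRUE))
    stop("dates must be strictly increasing", call. = FALSE)
  if (any(series$tmin > series$tmax))
    stop("tmin > tmax in record", call. = FALSE)
  if (any(diff(as.integer(series$date)) != 1L))
    stop("temperature record has gap days", call. = FALSE)
  if (!sowing_date %in% series$date)
    stop("sowing date outside the temperature record", call. = FALSE)
  sub <- series[series$date >= sowing_date, ]
  contrib <- pmax(0, (sub$tmin + sub$tmax) / 2)
  # the sowing day itself accumulates nothing; day k after sowing closes
  # with the sum of contributions of days 1..k
  dd <- cumsum(c(0, contrib[-1]))
  tibble::tibble(date = sub$date, degree_days = dd)
}

#' Estimate anthesis dates from spike-emergence thermal time
#'
#' Reference-environment spike-emergence thermal time per line, plus a
#' fixed emergence-to-anthesis offset, gives each line a thermal target;
#' the anthesis date in every environment is the first date whose
#' cumulative degree days reach that target.
#'
#' @param emergence Tibble (`line`, `emergence_dd`): thermal time at 50%
#'   spike emergence in the reference environment (deg Cd).
#' @param offset Emergence-to-anthesis offset in deg Cd (>= 0, default 100).
#' @param thermal Named list of [thermal_time()] tibbles, one per
#'   environment.
#' @return A tibble (`line`, `env`, `anthesis_date`, `anthesis_dd`) of
#'   class `anthesis_schedule`.
#' @export
estimate_anthesis <- function(emergence, offset = 100, thermal) {
  stopifnot(offset >= 0, all(c("line", "emergence_dd") %in% names(emergence)))
  out <- purrr::map_dfr(names(thermal), function(e) {
    tt <- thermal[[e]]
    purrr::map_dfr(seq_len(nrow(emergence)), function(i) {
      target <- emergence$emergence_dd[i] + offset
      hit <- which(tt$degree_days >= target)
      if (length(hit) == 0L)
        stop(sprintf(
          "line %s in %s: anthesis target %.0f degree days beyond season total %.0f",
          emergence$line[i], e, target, max(tt$degree_days)), call. = FALSE)
      tibble::tibble(line = emergence$line[i], env = e,
                     anthesis_date = tt$date[hit[1]], anthesis_dd = target)
    })
  })
  class(out) <- c("anthesis_schedule", class(tibble::tibble()))
  out
}

#' Developmental-window bounds in calendar days
#'
#' The anthesis window runs from 300 deg Cd before to 100 deg Cd after
#' anthesis; the grain-fill window from 100 to 600 deg Cd post anthesis.
#' A window opens on the first day its opening threshold is crossed and
#' closes the day before its closing threshold is crossed, so under a
#' constant 25 deg C mean the anthesis window spans 400/25 = 16 days.
#'
#' @param anthesis_dd Thermal time at anthesis (deg Cd).
#' @param thermal A [thermal_time()] tibble for the environment.
#' @param window `"anthesis"` or `"grainfill"`.
#' @return A list with `start` and `end` dates (inclusive span).
#' @export
window_bounds <- function(anthesis_dd, thermal, window = c("anthesis", "grainfill")) {
  window <- match.arg(window)
  b <- switch(window,
              anthesis = c(anthesis_dd - 300, anthesis_dd + 100),
              grainfill = c(anthesis_dd + 100, anthesis_dd + 600))
  open <- which(thermal$degree_days >= b[1])
  close <- which(thermal$degree_days >= b[2])
  if (length(open) == 0L || length(close) == 0L) {
    short <- b[2] - max(thermal$degree_days)
    stop(sprintf("%s window truncated by record end: %.0f degree days short",
                 window, max(short, b[1] - max(thermal$degree_days))),
         call. = FALSE)
  }
  list(start = thermal$date[open[1]], end = thermal$date[close[1]] - 1L)
}

#' Climatic covariates per line and environment
#'
#' For each line x environment developmental window: average daily maximum
#' temperature, number of days with max strictly above 30 deg C and above
#' 35 deg C; plus growing-season rainfall (total mm, May 1 to Oct 31,
#' environment-level and copied to every line). Covariate names follow the
#' window: `anthesis_avg_max`, `anthesis_days_gt30`, `grainfill_avg_max`,
#' `grainfill_days_gt30`, `grainfill_days_gt35`, `gs_rainfall`.
#'
#' @param temps Named list of temperature tibbles per environment.
#' @param anthesis An `anthesis_schedule` ([estimate_anthesis()]).
#' @param thermal Named list of [thermal_time()] tibbles per environment.
#' @param rainfall Optional named list of rainfall tibbles (`date`, `mm`)
#'   per environment; required for the `gs_rainfall` covariate.
#' @param covariates Character vector of covariate names to compute.
#' @return A tibble (`line`, `env`, `covariate`, `value`) of class
#'   `climatic_covariates`.
#' @export
compute_covariates <- function(temps, anthesis, thermal, rainfall = NULL,
                               covariates = c("anthesis_avg_max",
                                              "anthesis_days_gt30",
                                              "grainfill_avg_max",
                                              "grainfill_days_gt30",
                                              "grainfill_days_gt35",
                                              "gs_rainfall")) {
  if ("gs_rainfall" %in% covariates && is.null(rainfall))
    stop("rainfall records required for the gs_rainfall covariate", call. = FALSE)
  window_of <- c(anthesis_avg_max = "anthesis", anthesis_days_gt30 = "anthesis",
                 grainfill_avg_max = "grainfill", grainfill_days_gt30 = "grainfill",
                 grainfill_days_gt35 = "grainfill")
  win_covs <- intersect(covariates, names(window_of))
  out <- purrr::map_dfr(seq_len(nrow(anthesis)), function(i) {
    e <- anthesis$env[i]
    res <- list()
    for (w in unique(window_of[win_covs])) {
      b <- window_bounds(anthesis$anthesis_dd[i], thermal[[e]], w)
      tmax <- temps[[e]]$tmax[temps[[e]]$date >= b$start &
                                temps[[e]]$date <= b$end]
      vals <- c(avg_max = mean(tmax),
                days_gt30 = sum(tmax > 30),
                days_gt35 = sum(tmax > 35))
      for (cv in win_covs[window_of[win_covs] == w]) {
        stat <- sub("^(anthesis|grainfill)_", "", cv)
        res[[cv]] <- vals[[stat]]
      }
    }
    if (length(res) == 0L) return(NULL)
    tibble::tibble(line = anthesis$line[i], env = e,
                   covariate = names(res), value = unname(unlist(res)))
  })
  if ("gs_rainfall" %in% covariates) {
    gs <- purrr::map_dfr(unique(anthesis$env), function(e) {
      r <- rainfall[[e]]
      if (is.null(r)) stop(sprintf("no rainfall record for %s", e), call. = FALSE)
      yr <- as.integer(format(r$date[1], "%Y"))
      total <- sum(r$mm[r$date >= as.Date(sprintf("%d-05-01", yr)) &
                          r$date <= as.Date(sprintf("%d-10-31", yr))])
      tibble::tibble(env = e, value = total)
    })
    out <- dplyr::bind_rows(
      out,
      anthesis |>
        dplyr::distinct(.data$line, .data$env) |>
        dplyr::left_join(gs, by = "env") |>
        dplyr::mutate(covariate = "gs_rainfall") |>
        dplyr::select("line", "env", "covariate", "value"))
  }
  class(out) <- c("climatic_covariates", class(tibble::tibble()))
  out
}

#' Numerical range of a climatic covariate
#'
#' The max - min of a covariate over all line x environment values; used
#' to normalise responsiveness effects onto the trait scale.
#'
#' @param cov A `climatic_covariates` tibble (or any tibble with `covariate`
#'   and `value`).
#' @param name Optional covariate name to restrict to.
#' @return Named numeric vector of ranges (one per covariate present).
#' @export
covariate_range <- function(cov, name = NULL) {
  if (!is.null(name)) cov <- cov[cov$covariate %in% name, ]
  if (nrow(cov) == 0L) stop("no covariate values", call. = FALSE)
  r <- tapply(cov$value, cov$covariate, function(v) max(v) - min(v))
  stats::setNames(as.numeric(r), names(r))
}

#' Write / read climate records as delimited text
#'
#' @param x Tibble to write (temperature: `date`, `tmin`, `tmax`; rainfall:
#'   `date`, `mm`; covariates: `line`, `env`, `covariate`, `value`).
#' @param path File path.
#' @return The path (writers, invisibly) or the tibble (readers).
#' @export
write_climate_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_climate_table
#' @export
read_climate_table <- function(path) readr::read_csv(path, show_col_types = FALSE)
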