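test_that("temperature simulation honours its deterministic limits", {
  s <- simulate_temperature_series(30, 20, seasonal_amplitude = 0,
                                   diurnal_range = 10, heatwave_rate = 0,
                                   noise_sd = 0, seed = 1)
  expect_true(all(s$tmax == 25))
  expect_true(all(s$tmin == 15))
  expect_true(all(diff(as.integer(s$date)) == 1L))

  s2 <- simulate_temperature_series(120, 16, 5, 12, heatwave_rate = 3,
                                    noise_sd = 2, seed = 2)
  expect_true(all(s2$tmin <= s2$tmax))
})

test_that("long-run mean of daily means approaches the base mean", {
  s <- simulate_temperature_series(4000, 18, seasonal_amplitude = 0,
                                   diurnal_range = 8, heatwave_rate = 0,
                                   noise_sd = 2, seed = 3)
  m <- mean((s$tmin + s$tmax) / 2)
  expect_lt(abs(m - 18), 4 * 2 / sqrt(4000))
})

test_that("thermal time accumulates mean temperature above 0C from sowing", {
  d0 <- as.Date("2015-05-01")
  s <- tibble::tibble(date = d0 + 0:10, tmin = 15, tmax = 25)
  tt <- thermal_time(s, d0)
  expect_equal(tt$degree_days[1], 0)
  expect_equal(tt$degree_days[11], 200)  # 10 days after sowing at 20 C

  # a freezing day contributes nothing
  s2 <- s; s2$tmin[3] <- -6; s2$tmax[3] <- 2
  tt2 <- thermal_time(s2, d0)
  expect_equal(diff(tt2$degree_days)[2], 0)

  # random series equals a naive loop
  set.seed(4)
  s3 <- tibble::tibble(date = d0 + 0:49, tmin = rnorm(50, 5, 6))
  s3$tmax <- s3$tmin + runif(50, 0, 12)
  tt3 <- thermal_time(s3, d0)
  acc <- 0; naive <- 0
  for (i in 2:50) {
    acc <- acc + max(0, (s3$tmin[i] + s3$tmax[i]) / 2)
    naive[i] <- acc
  }
  expect_equal(tt3$degree_days, naive, tolerance = 1e-12)

  # gap days are refused
  expect_error(thermal_time(s[-3, ], d0), "gap")
})

test_that("anthesis dates come from first crossing of the thermal target", {
  d0 <- as.Date("2015-05-01")
  mk_tt <- function(mean_t, n = 120)
    thermal_time(tibble::tibble(date = d0 + 0:n, tmin = mean_t - 5,
                                tmax = mean_t + 5), d0)
  thermal <- list(E1 = mk_tt(20), E2 = mk_tt(25))
  em <- tibble::tibble(line = "L1", emergence_dd = 1200)
  a <- estimate_anthesis(em, offset = 0, thermal)
  expect_equal(a$anthesis_date[a$env == "E1"], d0 + 60)  # 1200/20
  expect_equal(a$anthesis_date[a$env == "E2"], d0 + 48)  # 1200/25

  # linear-scan oracle on a stepwise series
  set.seed(5)
  s <- tibble::tibble(date = d0 + 0:199,
                      tmin = rep(c(8, 14, 20), length.out = 200))
  s$tmax <- s$tmin + 10
  tt <- thermal_time(s, d0)
  target <- 1500
  hit <- NA
  for (i in seq_len(nrow(tt))) if (tt$degree_days[i] >= target) { hit <- i; break }
  a2 <- estimate_anthesis(tibble::tibble(line = "L1", emergence_dd = target),
                          0, list(E1 = tt))
  expect_equal(a2$anthesis_date, tt$date[hit])

  # target beyond season total errors
  expect_error(estimate_anthesis(
    tibble::tibble(line = "L1", emergence_dd = 1e6), 0, list(E1 = tt)),
    "beyond season total")
})

test_that("window day spans follow the degree-day bounds", {
  d0 <- as.Date("2015-05-01")
  mk_tt <- function(mean_t, n = 200)
    thermal_time(tibble::tibble(date = d0 + 0:n, tmin = mean_t - 5,
                                tmax = mean_t + 5), d0)
  span <- function(mean_t, window, target = 2000) {
    tt <- mk_tt(mean_t)
    b <- window_bounds(target, tt, window)
    as.integer(b$end - b$start) + 1L
  }
  expect_equal(span(25, "anthesis"), 16L)    # 400 Cd / 25
  expect_equal(span(25, "grainfill"), 20L)   # 500 Cd / 25
  expect_equal(span(14, "anthesis", 1990), 29L)  # lower bound of field range

  tt <- mk_tt(25, n = 60)
  expect_error(window_bounds(1400, tt, "grainfill"), "truncated")
})

test_that("covariates count hot days and average maxima per window", {
  d0 <- as.Date("2015-06-01")
  temps <- list(E1 = tibble::tibble(date = d0 + 0:99, tmin = 20, tmax = 32))
  thermal <- list(E1 = thermal_time(temps$E1, d0))
  anth <- estimate_anthesis(tibble::tibble(line = "L1", emergence_dd = 800),
                            0, thermal)
  cov <- compute_covariates(temps, anth, thermal,
                            covariates = c("anthesis_avg_max",
                                           "anthesis_days_gt30",
                                           "grainfill_days_gt35"))
  g <- function(nm) cov$value[cov$covariate == nm]
  expect_equal(g("anthesis_avg_max"), 32)
  # window span at mean 26: (400/26 Cd) days, all above 30
  expect_equal(g("anthesis_days_gt30"),
               as.numeric(diff(unlist(window_bounds(800, thermal$E1,
                                                    "anthesis")))) + 1)
  expect_equal(g("grainfill_days_gt35"), 0)

  # strict thresholds: max exactly 30 does not count, 36 counts twice
  temps2 <- list(E1 = tibble::tibble(date = d0 + 0:99, tmin = 20, tmax = 30))
  cov2 <- compute_covariates(temps2, anth,
                             list(E1 = thermal_time(temps2$E1, d0)),
                             covariates = "anthesis_days_gt30")
  expect_equal(cov2$value, 0)

  # loop-count oracle on a random window
  set.seed(6)
  tmax <- runif(100, 24, 40)
  temps3 <- list(E1 = tibble::tibble(date = d0 + 0:99, tmin = tmax - 10,
                                     tmax = tmax))
  th3 <- list(E1 = thermal_time(temps3$E1, d0))
  cov3 <- compute_covariates(temps3, anth, th3,
                             covariates = c("grainfill_days_gt30",
                                            "grainfill_days_gt35",
                                            "grainfill_avg_max"))
  b <- window_bounds(800, th3$E1, "grainfill")
  inwin <- temps3$E1$tmax[temps3$E1$date >= b$start & temps3$E1$date <= b$end]
  n30 <- 0; n35 <- 0
  for (v in inwin) { if (v > 30) n30 <- n30 + 1; if (v > 35) n35 <- n35 + 1 }
  g3 <- function(nm) cov3$value[cov3$covariate == nm]
  expect_equal(g3("grainfill_days_gt30"), n30)
  expect_equal(g3("grainfill_days_gt35"), n35)
  expect_equal(g3("grainfill_avg_max"), mean(inwin))
  expect_lte(g3("grainfill_days_gt35"), g3("grainfill_days_gt30"))
})

test_that("rainfall covariate totals May through October per environment", {
  d0 <- as.Date("2015-05-01")
  temps <- list(E1 = tibble::tibble(date = d0 + 0:199, tmin = 15, tmax = 25))
  thermal <- list(E1 = thermal_time(temps$E1, d0))
  anth <- estimate_anthesis(tibble::tibble(line = c("L1", "L2"),
                                           emergence_dd = c(900, 950)),
                            0, thermal)
  rain <- list(E1 = tibble::tibble(date = d0 + 0:199, mm = 1))
  cov <- compute_covariates(temps, anth, thermal, rainfall = rain,
                            covariates = "gs_rainfall")
  # May 1 .. Oct 31 = 184 days, record covers 200 days from May 1
  expect_equal(unique(cov$value), 184)
  expect_equal(nrow(cov), 2)  # copied to every line
  expect_error(compute_covariates(temps, anth, thermal,
                                  covariates = "gs_rainfall"),
               "rainfall records required")
})

test_that("covariate ranges are max minus min", {
  cov <- tibble::tibble(line = "L1", env = sprintf("E%d", 1:5),
                        covariate = "x", value = c(20.8, 22, 21.4, 24.3, 23))
  expect_equal(unname(covariate_range(cov)), 3.5)
  cov$value <- 7
  expect_equal(unname(covariate_range(cov)), 0)
  set.seed(7)
  v <- rnorm(50)
  cov2 <- tibble::tibble(line = "L", env = as.character(1:50),
                         covariate = "x", value = v)
  expect_equal(unname(covariate_range(cov2)),
               sort(v)[50] - sort(v)[1])
})
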