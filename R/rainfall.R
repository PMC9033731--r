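#' Simulate a daily rainfall series for one environment
#'
#' A simple wet-day process: each day rains with probability `wet_prob`,
#' and wet-day amounts are exponential with mean chosen so the expected
#' season total equals `season_total_mm`.
#'
#' @param n_days Number of days.
#' @param season_total_mm Expected total rainfall over the record (mm).
#' @param wet_prob Probability a given day is wet.
#' @param seed Integer seed.
#' @param start_date First day of the record.
#' @return A tibble with columns `date`, `mm`.
#' @export
simulate_rainfall_series <- function(n_days, season_total_mm, wet_prob = 0.3,
                                     seed, start_date = as.Date("2015-05-01")) {
  stopifnot(n_days >= 1, season_total_mm >= 0, wet_prob > 0, wet_prob <= 1)
  withr_seed(seed, {
    wet <- stats::runif(n_days) < wet_prob
    amt <- numeric(n_days)
    mu <- season_total_mm / (n_days * wet_prob)
    amt[wet] <- stats::rexp(sum(wet), rate = 1 / mu)
    tibble::tibble(date = start_date + seq_len(n_days) - 1L, mm = amt)
  })
}
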