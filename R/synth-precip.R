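#' Simulate a daily precipitation series with controllable dry-spell statistics
#'
#' Occurrence follows a first-order two-state (wet/dry) Markov chain, the
#' simplest process whose dry-run-length distribution is tunable: runs of dry
#' days are geometric with parameter `p_dry_to_wet`, so the expected dry-run
#' length is `1 / p_dry_to_wet`. Wet-day depths are exponential with mean
#' `mean_depth` (a standard stochastic weather-generator choice).
#'
#' @param n_days series length in days (>= 365).
#' @param p_wet_to_wet probability a wet day is followed by a wet day, in
#'   `[0, 1)` (1 would trap the chain in the wet state).
#' @param p_dry_to_wet probability a dry day is followed by a wet day, in
#'   `(0, 1]`; small values produce long dry spells.
#' @param mean_depth mean wet-day precipitation depth (mm).
#' @param seed integer RNG seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param start initial state: `"stationary"` (drawn from the chain's
#'   stationary distribution), `"wet"` or `"dry"`.
#' @param start_date calendar date of day 1.
#' @param station_id identifier recorded as an attribute.
#' @return a `data.frame` with columns `date` and `precip_mm` (class
#'   `precip_series`), attributes `station_id` and `params`.
#' @examples
#' p <- gen_precip(730, p_dry_to_wet = 0.2, seed = 1)
#' mean(p$precip_mm > 0)
#' @export
gen_precip <- function(n_days, p_wet_to_wet = 0.7, p_dry_to_wet = 0.15,
                       mean_depth = 8, seed = 1,
                       start = c("stationary", "wet", "dry"),
                       start_date = as.Date("2001-01-01"),
                       station_id = "CZU01") {
  start <- match.arg(start)
  if (!is.finite(p_wet_to_wet) || p_wet_to_wet < 0 || p_wet_to_wet >= 1)
    stop_rwlr("parameter", "p_wet_to_wet must lie in [0, 1)")
  if (!is.finite(p_dry_to_wet) || p_dry_to_wet <= 0 || p_dry_to_wet > 1)
    stop_rwlr("parameter", "p_dry_to_wet must lie in (0, 1]")
  if (n_days < 365) stop_rwlr("parameter", "n_days must be >= 365")
  if (mean_depth <= 0) stop_rwlr("parameter", "mean_depth must be positive")

  set.seed(seed)
  # stationary P(wet) of the two-state chain
  pi_wet <- p_dry_to_wet / (1 - p_wet_to_wet + p_dry_to_wet)
  u <- runif(n_days)
  wet <- logical(n_days)
  wet[1] <- switch(start,
                   stationary = u[1] < pi_wet,
                   wet = TRUE,
                   dry = FALSE)
  for (t in 2:n_days) {
    p <- if (wet[t - 1]) p_wet_to_wet else p_dry_to_wet
    wet[t] <- u[t] < p
  }
  precip <- numeric(n_days)
  precip[wet] <- rexp(sum(wet), rate = 1 / mean_depth)

  out <- data.frame(date = start_date + 0:(n_days - 1), precip_mm = precip)
  class(out) <- c("precip_series", "data.frame")
  attr(out, "station_id") <- station_id
  attr(out, "params") <- list(n_days = n_days, p_wet_to_wet = p_wet_to_wet,
                              p_dry_to_wet = p_dry_to_wet,
                              mean_depth = mean_depth, seed = seed,
                              start = start)
  out
}

#' Write / read a precipitation series as CSV
#'
#' @param precip a `precip_series` (or any data.frame with `date`,
#'   `precip_mm`).
#' @param path CSV path.
#' @return `path` invisibly; `read_precip_csv` returns a `precip_series`.
#' @export
write_precip_csv <- function(precip, path) {
  utils::write.csv(precip[, c("date", "precip_mm")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_precip_csv
#' @export
read_precip_csv <- function(path) {
  d <- utils::read.csv(path)
  d$date <- as.Date(d$date)
  class(d) <- c("precip_series", "data.frame")
  d
}
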