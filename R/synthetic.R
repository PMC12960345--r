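#' Configuration of the synthetic register generator
#'
#' Defines the statistical structure the analysis assumes, so every stage
#' of the pipeline can be exercised without archival data: an annual
#' temperature cycle anchored to monthly afternoon means, AR(1)
#' day-to-day anomalies, and monthly Weibull wind speeds which are emitted
#' as measured speeds (contemporary mode) or discretized to an ordinal
#' force scale (historical modes). Defaults emulate a coastal sub-Arctic
#' station like Nuuk: monthly afternoon temperatures from about -8 degC in
#' late winter to +9 degC in July, 10 m winds averaging about 6 m/s.
#'
#' @param mode `"contemporary"` (daily 15:00 anemometer series),
#'   `"historical_1767"` or `"historical_1789"` (twice-daily register at
#'   08:00/14:00 with Fahrenheit temperatures and ordinal wind forces on
#'   the six- or five-point scale).
#' @param seed Integer seed; the generator is fully reproducible.
#' @param start,end Period covered (Dates or ISO strings).
#' @param temp_monthly Twelve monthly target means of the afternoon
#'   temperature, degC (Jan..Dec).
#' @param wind10_monthly Twelve monthly target mean wind speeds at 10 m,
#'   m/s.
#' @param phi AR(1) coefficient of daily temperature anomalies, |phi| < 1.
#' @param sigma Innovation SD of the anomalies, degC, >= 0.
#' @param weibull_shape Shape of the monthly Weibull wind distribution
#'   (scale is set from the monthly target mean).
#' @param missing_rate Fraction of days removed as contiguous blocks
#'   (archival gaps), in `[0, 1)`.
#' @param morning_offset degC added to the 14:00 value for the 08:00
#'   observation (historical modes).
#' @param fahrenheit_precision Rounding grid of emitted Fahrenheit values
#'   (historical modes), degF.
#' @param station Station name for the emitted series.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(mode = c("contemporary", "historical_1767",
                                      "historical_1789"),
                             seed = 1L,
                             start = "1991-01-01", end = "2020-12-31",
                             temp_monthly = c(-7.6, -8.2, -7.4, -2.6, 2.3, 6.3,
                                              8.9, 8.2, 3.9, 0.1, -3.2, -5.3),
                             wind10_monthly = c(7.0, 6.9, 7.0, 6.3, 5.5, 5.3,
                                                5.2, 5.3, 6.0, 5.8, 6.6, 6.9),
                             phi = 0.7, sigma = 3.0, weibull_shape = 2,
                             missing_rate = 0, morning_offset = -2.5,
                             fahrenheit_precision = 0.5,
                             station = NULL) {
  mode <- match.arg(mode)
  start <- as.Date(start)
  end <- as.Date(end)
  stopifnot(end >= start, length(temp_monthly) == 12L,
            length(wind10_monthly) == 12L)
  if (abs(phi) >= 1) stop("AR(1) coefficient must satisfy |phi| < 1", call. = FALSE)
  if (sigma < 0) stop("innovation SD must be non-negative", call. = FALSE)
  if (weibull_shape <= 0 || any(wind10_monthly <= 0)) {
    stop("Weibull parameters must be positive", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(mode = mode, seed = as.integer(seed), start = start, end = end,
         temp_monthly = as.numeric(temp_monthly),
         wind10_monthly = as.numeric(wind10_monthly),
         phi = phi, sigma = sigma, weibull_shape = weibull_shape,
         missing_rate = missing_rate, morning_offset = morning_offset,
         fahrenheit_precision = fahrenheit_precision,
         station = station %||% paste0("synthetic_", mode)),
    class = "synthetic_config"
  )
}

#' Seasonal temperature cycle of a synthetic configuration
#'
#' Piecewise-linear annual cycle through mid-month knots, with the knots
#' iteratively corrected so that the calendar-month mean of the cycle over
#' the given dates equals the configured monthly target exactly
#' (mean-preserving interpolation; plain mid-month interpolation biases
#' monthly means near the cycle extremes).
#'
#' @param config A [synthetic_config()].
#' @param dates Dates at which to evaluate the cycle.
#'
#' @return Numeric vector of cycle temperatures, degC, one per date.
#' @export
seasonal_cycle <- function(config, dates) {
  stopifnot(inherits(config, "synthetic_config"))
  target <- config$temp_monthly
  doy <- doy366(dates)
  months <- as.integer(format(dates, "%m"))
  knot_pos <- doy366(as.Date(sprintf("2000-%02d-15", 1:12)))

  interp <- function(knots) {
    x <- c(knot_pos - 366, knot_pos, knot_pos + 366)
    y <- rep(knots, 3L)
    stats::approx(x, y, xout = doy)$y
  }
  knots <- target
  for (it in 1:200) {
    vals <- interp(knots)
    m <- tapply(vals, factor(months, levels = 1:12), mean)
    have <- !is.na(m)
    err <- target[have] - m[have]
    if (max(abs(err)) < 1e-12) break
    knots[have] <- knots[have] + err
  }
  interp(knots)
}

# Stationary AR(1) anomaly series: a_t = phi a_{t-1} + sigma eps_t.
ar1_anomalies <- function(n, phi, sigma) {
  if (n == 0L) return(numeric())
  a <- numeric(n)
  sd0 <- if (sigma == 0) 0 else sigma / sqrt(1 - phi^2)
  a[1L] <- rnorm(1L, sd = sd0)
  if (n > 1L) {
    eps <- rnorm(n - 1L, sd = sigma)
    for (t in 2:n) a[t] <- phi * a[t - 1L] + eps[t - 1L]
  }
  a
}

# Contiguous blocks of missing days covering about rate * n days.
missing_day_blocks <- function(n, rate) {
  if (rate <= 0 || n == 0L) return(integer())
  target <- round(rate * n)
  gone <- logical(n)
  guard <- 0L
  while (sum(gone) < target && guard < 1000L) {
    len <- sample(5:15, 1L)
    start <- sample.int(n, 1L)
    gone[start:min(n, start + len - 1L)] <- TRUE
    guard <- guard + 1L
  }
  which(gone)
}

#' Simulate a contemporary station series
#'
#' Daily 15:00 LT records: temperature (degC, 0.1 degC precision) equal to
#' the mean-preserving seasonal cycle plus AR(1) anomalies, and wind speed
#' (m/s at the 10 m anemometer, 0.1 m/s precision) drawn from the monthly
#' Weibull model. Reproducible given the config seed.
#'
#' @param config A [synthetic_config()] with `mode = "contemporary"`.
#' @return An `obs_series` with a `speed_ms` schema at 10 m.
#' @export
simulate_contemporary <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$mode != "contemporary") {
    stop("config mode must be 'contemporary'", call. = FALSE)
  }
  dates <- seq(config$start, config$end, by = "1 day")
  months <- as.integer(format(dates, "%m"))
  cyc <- seasonal_cycle(config, dates)
  withr::with_seed(config$seed, {
    temp <- cyc + ar1_anomalies(length(dates), config$phi, config$sigma)
    scale_m <- config$wind10_monthly / gamma(1 + 1 / config$weibull_shape)
    wind <- rweibull(length(dates), shape = config$weibull_shape,
                     scale = scale_m[months])
    drop <- missing_day_blocks(length(dates), config$missing_rate)
  })
  rec <- tibble::tibble(
    date = dates,
    hour_lt = "15:00",
    temperature = round(temp, 1),
    wind = round(wind, 1)
  )
  if (length(drop)) rec <- rec[-drop, , drop = FALSE]
  observation_series(
    rec,
    schema = register_schema(temperature_unit = "C", wind_kind = "speed_ms",
                             anemometer_height_m = 10),
    station = config$station,
    metadata = list(generator = "histbioclim::simulate_contemporary",
                    seed = config$seed)
  )
}

#' Simulate a historical register
#'
#' Twice-daily records at 08:00 and 14:00 LT: the 14:00 temperature is the
#' seasonal cycle plus AR(1) anomaly, the 08:00 one sits `morning_offset`
#' degC below it; both are emitted in Fahrenheit rounded to the configured
#' manuscript precision (default 0.5 degF). Winds are drawn from the
#' monthly Weibull model at 10 m and discretized to the mode's ordinal
#' force scale. Missing data are applied as contiguous date blocks, the
#' gap structure of archival registers.
#'
#' @param config A [synthetic_config()] with mode `"historical_1767"` or
#'   `"historical_1789"`.
#' @param scales Named list of [wind_scale()]s.
#' @return An `obs_series` with an `ordinal_force` schema.
#' @export
simulate_historical <- function(config, scales = default_wind_scales()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!config$mode %in% c("historical_1767", "historical_1789")) {
    stop("config mode must be 'historical_1767' or 'historical_1789'", call. = FALSE)
  }
  scale_id <- if (config$mode == "historical_1767") "scale_1767_6pt" else "scale_1789_5pt"
  scale <- scales[[scale_id]]
  dates <- seq(config$start, config$end, by = "1 day")
  months <- as.integer(format(dates, "%m"))
  cyc <- seasonal_cycle(config, dates)
  withr::with_seed(config$seed, {
    t14 <- cyc + ar1_anomalies(length(dates), config$phi, config$sigma)
    t08 <- t14 + config$morning_offset
    scale_m <- config$wind10_monthly / gamma(1 + 1 / config$weibull_shape)
    v <- matrix(rweibull(2L * length(dates), shape = config$weibull_shape,
                         scale = rep(scale_m[months], each = 2L)),
                nrow = 2L)
    drop <- missing_day_blocks(length(dates), config$missing_rate)
  })
  p <- config$fahrenheit_precision
  to_f <- function(t_c) round((t_c * 9 / 5 + 32) / p) * p
  rec <- tibble::tibble(
    date = rep(dates, each = 2L),
    hour_lt = rep(c("08:00", "14:00"), times = length(dates)),
    temperature = as.vector(rbind(to_f(t08), to_f(t14))),
    wind = as.numeric(discretize_wind(as.vector(v), scale))
  )
  if (length(drop)) rec <- rec[!(rec$date %in% dates[drop]), , drop = FALSE]
  observation_series(
    rec,
    schema = register_schema(temperature_unit = "F",
                             wind_kind = "ordinal_force", scale_id = scale_id),
    station = config$station,
    metadata = list(generator = "histbioclim::simulate_historical",
                    seed = config$seed)
  )
}
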