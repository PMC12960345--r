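#' Convert Fahrenheit to Celsius
#'
#' @param t_f Temperature(s) in degrees Fahrenheit.
#' @return Temperature(s) in degrees Celsius: `(t_f - 32) * 5/9`.
#' @export
#' @examples
#' fahrenheit_to_celsius(c(32, 212, -4))
fahrenheit_to_celsius <- function(t_f) {
  (t_f - 32) * 5 / 9
}

#' Adjust a wind speed between measurement heights
#'
#' Power-law wind profile with exponent 0.2 (configurable):
#' `v_to = v * (h_to / h_from)^alpha`. Used to move between the 10 m
#' reference height of the force-scale speeds and anemometers and the
#' 1.2 m chest height conventional in bioclimatology.
#'
#' @param v Wind speed(s), m/s, non-negative.
#' @param h_from Height of `v`, metres, positive.
#' @param h_to Target height, metres, positive.
#' @param alpha Profile exponent (default 0.2).
#'
#' @return Wind speed(s) at `h_to`, m/s.
#' @export
#' @examples
#' adjust_wind_height(8, 10, 1.2)   # 10 m -> chest height
#' adjust_wind_height(6.1, 1.2, 10) # chest height -> 10 m
adjust_wind_height <- function(v, h_from, h_to, alpha = 0.2) {
  if (any(h_from <= 0) || any(h_to <= 0)) {
    stop("heights must be positive", call. = FALSE)
  }
  if (any(v < 0, na.rm = TRUE)) {
    stop("wind speed must be non-negative", call. = FALSE)
  }
  v * (h_to / h_from)^alpha
}

#' Standardize an observation series to canonical units
#'
#' Converts every record to the canonical triple: air temperature in degC
#' (`t_c`), wind speed at 10 m (`v10`) and at 1.2 m chest height (`v12`),
#' both m/s. Fahrenheit temperatures go through
#' [fahrenheit_to_celsius()]; ordinal force codes through
#' [wind_force_to_speed10()] then the 0.2-power height law down to 1.2 m;
#' measured speeds are height-adjusted from the anemometer height to both
#' targets. Missing inputs propagate as missing outputs; no record is
#' invented or dropped.
#'
#' @param series An `obs_series` (see [observation_series()]).
#' @param scales Named list of [wind_scale()]s.
#' @param heights Named numeric vector `c(v10 = 10, v12 = 1.2)` giving the
#'   two target heights in metres.
#' @param alpha Wind-profile exponent passed to [adjust_wind_height()].
#'
#' @return A tibble (class `std_obs`) with columns `date`, `hour_lt`,
#'   `t_c`, `v10`, `v12`, `t_converted` (was the temperature converted
#'   from degF) and `v_from` (`"force"` or `"speed"`).
#' @export
standardize <- function(series, scales = default_wind_scales(),
                        heights = c(v10 = 10, v12 = 1.2), alpha = 0.2) {
  stopifnot(inherits(series, "obs_series"))
  rec <- series$records
  schema <- series$schema

  t_c <- if (schema$temperature_unit == "F") {
    fahrenheit_to_celsius(rec$temperature)
  } else {
    rec$temperature
  }

  if (schema$wind_kind == "ordinal_force") {
    scale <- scales[[schema$scale_id]]
    if (is.null(scale)) stop("unknown scale_id: ", schema$scale_id, call. = FALSE)
    v10 <- wind_force_to_speed10(rec$wind, scale)
    v10 <- adjust_wind_height(v10, 10, heights[["v10"]], alpha = alpha)
    v12 <- adjust_wind_height(v10, heights[["v10"]], heights[["v12"]], alpha = alpha)
    v_from <- "force"
  } else {
    h <- schema$anemometer_height_m
    v10 <- adjust_wind_height(rec$wind, h, heights[["v10"]], alpha = alpha)
    v12 <- adjust_wind_height(rec$wind, h, heights[["v12"]], alpha = alpha)
    v_from <- "speed"
  }

  out <- tibble::tibble(
    date = rec$date,
    hour_lt = rec$hour_lt,
    t_c = t_c,
    v10 = v10,
    v12 = v12,
    t_converted = schema$temperature_unit == "F" & !is.na(rec$temperature),
    v_from = ifelse(is.na(rec$wind), NA_character_, v_from)
  )
  class(out) <- c("std_obs", class(out))
  out
}
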