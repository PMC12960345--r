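# Independent re-implementations used as oracles. Deliberately coded in a
# different style from the package (log/exp power, rearranged algebra) so
# agreement is a genuine cross-check, not a tautology.

oracle_f2c <- function(f) (f - 32) / 1.8

oracle_wct <- function(t, v10) {
  p <- exp(0.16 * log(v10))
  terms <- cbind(13.12, 0.6215 * t, -11.37 * p, 0.3965 * t * p)
  rowSums(terms)
}

oracle_iclp <- function(t, v, M) {
  required <- 0.082 * (59.4 - 1.8 * t) / (0.01724 * M)
  air_layer <- (0.61 + sqrt(1.9 * v))^-1
  required - air_layer
}

oracle_height <- function(v, h_from, h_to) v * exp(0.2 * (log(h_to) - log(h_from)))

# Nearest representative code by exhaustive search, ties to the lower code.
oracle_nearest_code <- function(v, scale) {
  vapply(v, function(x) {
    d <- abs(scale$speeds_ms_10m - x)
    scale$codes[which(d == min(d))[1L]]
  }, integer(1))
}

# Independent classification of interdiurnal changes (band logic restated).
oracle_stimulus <- function(d) {
  d <- floor(d * 10 + 0.5) / 10
  out <- character(length(d))
  out[d >= 6.1] <- "severe"
  out[d >= 4.1 & d <= 6.0] <- "significant"
  out[d >= 2.1 & d <= 4.0] <- "perceptible"
  out[d <= 2.0] <- "neutral"
  out
}

# Small valid register series for round-trip and validation tests.
make_series <- function(n = 10, unit = "F", seed = 1,
                        wind_kind = "ordinal_force",
                        scale_id = "scale_1767_6pt") {
  withr::with_seed(seed, {
    dates <- rep(as.Date("1767-09-01") + 0:(n - 1), each = 2)
    schema <- if (wind_kind == "ordinal_force") {
      register_schema(temperature_unit = unit, wind_kind = wind_kind,
                      scale_id = scale_id)
    } else {
      register_schema(temperature_unit = unit, wind_kind = "speed_ms",
                      anemometer_height_m = 10)
    }
    wind <- if (wind_kind == "ordinal_force") {
      sample(1:6, 2 * n, replace = TRUE)
    } else {
      round(rweibull(2 * n, 2, 5), 1)
    }
    observation_series(
      tibble::tibble(
        date = dates,
        hour_lt = rep(c("08:00", "14:00"), n),
        temperature = round(rnorm(2 * n, if (unit == "F") 30 else 0, 10), 1),
        wind = wind
      ),
      schema = schema, station = "fixture"
    )
  })
}
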