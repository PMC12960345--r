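#' Register file schema
#'
#' A register CSV carries four columns (`date`, `hour`, `temp`, `wind`);
#' the schema sidecar declares, once per file, what the columns mean: the
#' temperature unit, whether wind is an ordinal force code or a measured
#' speed, and the missing-value token. Units are never inferred per row —
#' silent unit mixing is the classic data-rescue failure.
#'
#' @param temperature_unit `"F"` or `"C"`.
#' @param wind_kind `"ordinal_force"` (historical registers) or
#'   `"speed_ms"` (anemometer series).
#' @param scale_id Wind-scale identifier; required when
#'   `wind_kind = "ordinal_force"`.
#' @param anemometer_height_m Measurement height in metres; required (and
#'   positive) when `wind_kind = "speed_ms"`.
#' @param missing_token Token(s) marking a missing value (default `"NA"`).
#' @param columns Named character vector mapping the roles
#'   `date`, `hour`, `temp`, `wind` to the column names in the file.
#'
#' @return A list of class `register_schema`.
#' @export
register_schema <- function(temperature_unit = c("C", "F"),
                            wind_kind = c("speed_ms", "ordinal_force"),
                            scale_id = NULL,
                            anemometer_height_m = NULL,
                            missing_token = "NA",
                            columns = c(date = "date", hour = "hour",
                                        temp = "temp", wind = "wind")) {
  temperature_unit <- match.arg(temperature_unit)
  wind_kind <- match.arg(wind_kind)
  if (wind_kind == "ordinal_force") {
    if (is.null(scale_id)) {
      stop("wind_kind = 'ordinal_force' requires a `scale_id`", call. = FALSE)
    }
    anemometer_height_m <- NULL
  } else {
    if (is.null(anemometer_height_m)) anemometer_height_m <- 10
    if (!is.numeric(anemometer_height_m) || anemometer_height_m <= 0) {
      stop("`anemometer_height_m` must be a positive number", call. = FALSE)
    }
    scale_id <- NULL
  }
  need <- c("date", "hour", "temp", "wind")
  if (!all(need %in% names(columns))) {
    stop("`columns` must name all of: ", paste(need, collapse = ", "), call. = FALSE)
  }
  structure(
    list(temperature_unit = temperature_unit, wind_kind = wind_kind,
         scale_id = scale_id, anemometer_height_m = anemometer_height_m,
         missing_token = missing_token, columns = columns[need]),
    class = "register_schema"
  )
}

#' Read/write a register schema sidecar (YAML)
#'
#' @param path Path to a YAML sidecar file.
#' @return [read_schema()] returns a `register_schema`;
#'   [write_schema()] returns `path` invisibly.
#' @export
read_schema <- function(path) {
  s <- yaml::read_yaml(path)
  register_schema(
    temperature_unit = s$temperature_unit,
    wind_kind = s$wind_kind,
    scale_id = s$scale_id,
    anemometer_height_m = s$anemometer_height_m,
    missing_token = s$missing_token %||% "NA",
    columns = unlist(s$columns %||% c(date = "date", hour = "hour",
                                      temp = "temp", wind = "wind"))
  )
}

#' @param schema A [register_schema()].
#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "register_schema"))
  yaml::write_yaml(
    list(temperature_unit = schema$temperature_unit,
         wind_kind = schema$wind_kind,
         scale_id = schema$scale_id,
         anemometer_height_m = schema$anemometer_height_m,
         missing_token = schema$missing_token,
         columns = as.list(schema$columns)),
    path
  )
  invisible(path)
}

#' Observation series
#'
#' The canonical in-memory form of a weather register: a date-ordered
#' tibble of raw observations plus the unit/scale metadata of its schema.
#' One temperature unit and one wind representation per series.
#'
#' @param records A data frame with columns `date` (Date), `hour_lt`
#'   (character, e.g. `"14:00"`), `temperature` (numeric, in the schema's
#'   unit) and `wind` (numeric: force code or speed in m/s).
#' @param schema A [register_schema()].
#' @param station Station name.
#' @param metadata Free-form provenance list.
#'
#' @return An object of class `obs_series`.
#' @export
observation_series <- function(records, schema, station = "unknown",
                               metadata = list()) {
  stopifnot(inherits(schema, "register_schema"))
  records <- tibble::as_tibble(records)
  need <- c("date", "hour_lt", "temperature", "wind")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  records$date <- as.Date(records$date)
  records$hour_lt <- as.character(records$hour_lt)
  records$temperature <- as.numeric(records$temperature)
  records$wind <- as.numeric(records$wind)
  if (anyNA(records$date)) {
    stop("records contain unparseable dates", call. = FALSE)
  }
  records <- dplyr::arrange(records, .data$date, .data$hour_lt)
  key <- paste(records$date, records$hour_lt)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop(sprintf("duplicate observation for (date, hour): %s", dup), call. = FALSE)
  }
  structure(
    list(station = station, schema = schema, records = records,
         metadata = metadata),
    class = "obs_series"
  )
}

#' @export
print.obs_series <- function(x, ...) {
  cat(sprintf("<obs_series> %s: %d records", x$station, nrow(x$records)))
  if (nrow(x$records) > 0) {
    cat(sprintf(" (%s to %s)", min(x$records$date), max(x$records$date)))
  }
  cat(sprintf("\n  temperature unit: %s; wind: %s%s\n",
              x$schema$temperature_unit, x$schema$wind_kind,
              if (x$schema$wind_kind == "ordinal_force") {
                paste0(" [", x$schema$scale_id, "]")
              } else {
                sprintf(" @ %g m", x$schema$anemometer_height_m)
              }))
  print(x$records, n = 5)
  invisible(x)
}

#' Read a register CSV
#'
#' Parses a transcribed register against its schema. Dates must be
#' ISO-8601; ASCII and typographic minus signs are accepted and
#' normalized. Rows whose temperature or wind token is neither the missing
#' token nor a parseable number are collected in the `parse_issues`
#' attribute of the result — they become missing values, never silently
#' dropped rows.
#'
#' @param path CSV file path.
#' @param schema A [register_schema()] (or path to a YAML sidecar).
#' @param station,metadata Passed to [observation_series()].
#'
#' @return An `obs_series`; see attribute `parse_issues` for a tibble of
#'   tokens that could not be parsed.
#' @export
read_register <- function(path, schema, station = "unknown", metadata = list()) {
  if (is.character(schema)) schema <- read_schema(schema)
  stopifnot(inherits(schema, "register_schema"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  cols <- schema$columns
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: mandatory column(s) missing from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  temp <- parse_number(raw[[cols[["temp"]]]], schema$missing_token)
  wind <- parse_number(raw[[cols[["wind"]]]], schema$missing_token)
  issues <- list()
  for (fld in c("temp", "wind")) {
    tok <- trimws(raw[[cols[[fld]]]])
    val <- if (fld == "temp") temp else wind
    bad <- which(is.na(val) & !(tok %in% schema$missing_token) & tok != "")
    if (length(bad) > 0) {
      issues[[fld]] <- tibble::tibble(row = bad, field = fld, token = tok[bad])
    }
  }
  series <- observation_series(
    tibble::tibble(
      date = as.Date(trimws(raw[[cols[["date"]]]])),
      hour_lt = trimws(raw[[cols[["hour"]]]]),
      temperature = temp,
      wind = wind
    ),
    schema = schema, station = station, metadata = metadata
  )
  attr(series, "parse_issues") <- if (length(issues)) {
    dplyr::bind_rows(issues)
  } else {
    tibble::tibble(row = integer(), field = character(), token = character())
  }
  series
}

#' Write a register CSV
#'
#' Inverse of [read_register()]: emits the four-column CSV (plus optional
#' YAML sidecar) such that reading it back reproduces the series
#' field-for-field.
#'
#' @param series An `obs_series`.
#' @param path Output CSV path.
#' @param sidecar Optional path for the YAML schema sidecar.
#'
#' @return `path`, invisibly.
#' @export
write_register <- function(series, path, sidecar = NULL) {
  stopifnot(inherits(series, "obs_series"))
  schema <- series$schema
  units <- unique(schema$temperature_unit)
  if (length(units) != 1L) {
    stop("a register file carries exactly one temperature unit", call. = FALSE)
  }
  rec <- series$records
  tok <- schema$missing_token[1L]
  fmt <- function(x) {
    out <- as.character(x)
    out[is.na(x)] <- tok
    out
  }
  df <- data.frame(date = format(rec$date, "%Y-%m-%d"),
                   hour = rec$hour_lt,
                   temp = fmt(rec$temperature),
                   wind = fmt(rec$wind))
  names(df) <- unname(schema$columns[c("date", "hour", "temp", "wind")])
  write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  if (!is.null(sidecar)) write_schema(schema, sidecar)
  invisible(path)
}

#' Validate an observation series
#'
#' Pure check returning typed issues as data; the input is never mutated
#' and nothing is dropped. Issue types: `out_of_range` (temperature
#' outside the physical range of -80..+60 degC after unit conversion),
#' `unknown_force_code` (non-integer or outside the scale's domain),
#' `gap` (calendar days absent between the first and last date).
#'
#' @param series An `obs_series`.
#' @param scales Named list of [wind_scale()]s used to resolve the
#'   series' `scale_id`.
#'
#' @return A tibble with columns `date`, `hour_lt`, `field`, `issue`,
#'   `value`; zero rows when the series is clean.
#' @export
validate_series <- function(series, scales = default_wind_scales()) {
  stopifnot(inherits(series, "obs_series"))
  rec <- series$records
  schema <- series$schema
  issue <- function(date, hour, field, what, value) {
    tibble::tibble(date = as.Date(date), hour_lt = as.character(hour),
                   field = field, issue = what, value = as.numeric(value))
  }
  out <- list()

  t_c <- if (schema$temperature_unit == "F") {
    fahrenheit_to_celsius(rec$temperature)
  } else {
    rec$temperature
  }
  bad_t <- which(!is.na(t_c) & (t_c < -80 | t_c > 60))
  if (length(bad_t)) {
    out$t <- issue(rec$date[bad_t], rec$hour_lt[bad_t], "temperature",
                   "out_of_range", rec$temperature[bad_t])
  }

  if (schema$wind_kind == "ordinal_force") {
    scale <- scales[[schema$scale_id]]
    if (is.null(scale)) {
      stop("unknown scale_id: ", schema$scale_id, call. = FALSE)
    }
    w <- rec$wind
    bad_w <- which(!is.na(w) & (w != round(w) | !(w %in% scale$codes)))
    if (length(bad_w)) {
      out$w <- issue(rec$date[bad_w], rec$hour_lt[bad_w], "wind",
                     "unknown_force_code", w[bad_w])
    }
  } else {
    bad_w <- which(!is.na(rec$wind) & rec$wind < 0)
    if (length(bad_w)) {
      out$w <- issue(rec$date[bad_w], rec$hour_lt[bad_w], "wind",
                     "out_of_range", rec$wind[bad_w])
    }
  }

  if (nrow(rec) > 0) {
    all_days <- seq(min(rec$date), max(rec$date), by = "1 day")
    gaps <- all_days[!(all_days %in% rec$date)]
    if (length(gaps)) {
      out$g <- issue(gaps, NA_character_, "date", "gap", NA_real_)
    }
  }

  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(date = as.Date(character()), hour_lt = character(),
                   field = character(), issue = character(), value = numeric())
}
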