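#' Ordinal wind-force scales
#'
#' Historical weather registers record wind as an ordinal visual force
#' estimate rather than a measured speed. A `wind_scale` maps each force
#' code to a representative wind speed in m/s at the 10 m reference
#' height, so that ordinal registers can be standardized to the same
#' units as contemporary anemometer series.
#'
#' @param scale_id Identifier for the scale (e.g. `"scale_1767_6pt"`).
#' @param codes Integer force codes, strictly increasing.
#' @param speeds_ms_10m Representative speeds (m/s at 10 m), one per code,
#'   non-negative and strictly increasing with force.
#' @param description Optional free-text description.
#'
#' @return An object of class `wind_scale`.
#' @export
#' @examples
#' sc <- wind_scale("toy_3pt", codes = 0:2, speeds_ms_10m = c(0.5, 4, 10))
#' wind_force_to_speed10(1, sc)
wind_scale <- function(scale_id, codes, speeds_ms_10m, description = "") {
  stopifnot(is.character(scale_id), length(scale_id) == 1L)
  codes <- as.integer(codes)
  speeds <- as.numeric(speeds_ms_10m)
  if (length(codes) != length(speeds) || length(codes) < 1L) {
    stop("`codes` and `speeds_ms_10m` must have equal, positive length", call. = FALSE)
  }
  if (anyNA(codes) || anyNA(speeds)) {
    stop("wind scale must not contain missing values", call. = FALSE)
  }
  if (any(diff(codes) <= 0L)) {
    stop("force codes must be strictly increasing", call. = FALSE)
  }
  if (any(speeds < 0) || any(diff(speeds) <= 0)) {
    stop("representative speeds must be non-negative and strictly increasing in force",
         call. = FALSE)
  }
  structure(
    list(scale_id = scale_id, codes = codes, speeds_ms_10m = speeds,
         description = description),
    class = "wind_scale"
  )
}

#' @export
print.wind_scale <- function(x, ...) {
  cat("<wind_scale> ", x$scale_id, "\n", sep = "")
  print(tibble::tibble(force = x$codes, speed_ms_10m = x$speeds_ms_10m))
  invisible(x)
}

#' Built-in wind-force scales
#'
#' Loads the scale definitions shipped with the package: the six-point
#' scale of the 1767-68 register (`scale_1767_6pt`) and the five-point
#' scale of the 1789-92 register (`scale_1789_5pt`). Additional scales can
#' be supplied in the same JSON layout via [read_wind_scales()].
#'
#' @return A named list of [wind_scale()] objects.
#' @export
default_wind_scales <- function() {
  read_wind_scales(system.file("extdata", "wind_scales.json",
                               package = "histbioclim", mustWork = TRUE))
}

#' Read wind-force scales from a JSON file
#'
#' @param path Path to a JSON file mapping scale ids to objects with
#'   `codes` and `speeds_ms_10m` arrays (and optional `description`).
#'
#' @return A named list of [wind_scale()] objects.
#' @export
read_wind_scales <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(raw), function(id) {
    wind_scale(id, raw[[id]]$codes, raw[[id]]$speeds_ms_10m,
               description = raw[[id]]$description %||% "")
  })
  stats::setNames(out, names(raw))
}

#' Convert an ordinal wind-force code to a wind speed at 10 m
#'
#' Exact table lookup of the representative speed for a force code.
#'
#' @param force Integer force code(s).
#' @param scale A [wind_scale()].
#'
#' @return Wind speed(s) in m/s at 10 m. `NA` force yields `NA`.
#' @export
#' @examples
#' scales <- default_wind_scales()
#' wind_force_to_speed10(5, scales$scale_1767_6pt) # 20.75
#' wind_force_to_speed10(0, scales$scale_1789_5pt) # 0.3
wind_force_to_speed10 <- function(force, scale) {
  stopifnot(inherits(scale, "wind_scale"))
  ok <- is.na(force) | (force == as.integer(force) & force %in% scale$codes)
  if (!all(ok)) {
    bad <- unique(force[!ok])
    stop(sprintf("force code(s) %s outside the domain of scale '%s' (codes %s)",
                 paste(bad, collapse = ", "), scale$scale_id,
                 paste(range(scale$codes), collapse = "-")),
         call. = FALSE)
  }
  scale$speeds_ms_10m[match(as.integer(force), scale$codes)]
}

#' Discretize a wind speed to the nearest force code of a scale
#'
#' Inverse of [wind_force_to_speed10()]: assigns the code whose
#' representative speed is closest to `v10`. Bin edges are the midpoints
#' between consecutive representative speeds; a value exactly on an edge
#' is assigned to the lower code.
#'
#' @param v10 Wind speed(s), m/s at 10 m, non-negative.
#' @param scale A [wind_scale()].
#'
#' @return Integer force code(s); `NA` input yields `NA`.
#' @export
discretize_wind <- function(v10, scale) {
  stopifnot(inherits(scale, "wind_scale"))
  if (any(v10 < 0, na.rm = TRUE)) {
    stop("wind speed must be non-negative", call. = FALSE)
  }
  sp <- scale$speeds_ms_10m
  edges <- (sp[-length(sp)] + sp[-1L]) / 2
  # (edge[i], edge[i+1]] intervals: an exact midpoint falls to the lower code
  idx <- findInterval(v10, edges, left.open = TRUE) + 1L
  out <- scale$codes[idx]
  out[is.na(v10)] <- NA_integer_
  out
}
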