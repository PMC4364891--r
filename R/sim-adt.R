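#' Gridded weekly ADT field
#'
#' Container for a weekly absolute dynamic topography raster: values in cm
#' on a regular lon/lat grid, one layer per week.
#'
#' @param lon,lat Cell-center coordinates (degrees), strictly increasing.
#' @param week_start Date vector: start (Monday) of each 7-day week.
#' @param values Numeric array `[length(lon), length(lat),
#'   length(week_start)]`, finite.
#' @param cell_size Cell edge in degrees.
#' @return Object of class `"adt_field"`.
#' @export
adt_field <- function(lon, lat, week_start, values, cell_size = 1 / 3) {
  values <- array(values, dim = c(length(lon), length(lat),
                                  length(week_start)))
  if (any(!is.finite(values))) stop("ADT values must be finite")
  structure(list(lon = lon, lat = lat, week_start = as.Date(week_start),
                 values = values, cell_size = cell_size),
            class = "adt_field")
}

#' @export
print.adt_field <- function(x, ...) {
  cat(sprintf("ADT field: %d x %d cells (%.3f deg), %d weeks from %s\n",
              length(x$lon), length(x$lat), x$cell_size,
              length(x$week_start), format(min(x$week_start))))
  cat(sprintf("  range %.1f to %.1f cm\n", min(x$values), max(x$values)))
  invisible(x)
}

# Value of the field at given positions/dates; NA where uncovered.
adt_lookup <- function(field, lon, lat, date) {
  ix <- round((lon - field$lon[1]) / field$cell_size) + 1
  iy <- round((lat - field$lat[1]) / field$cell_size) + 1
  iw <- findInterval(as.numeric(as.Date(date)),
                     as.numeric(field$week_start))
  ok <- ix >= 1 & ix <= length(field$lon) &
    iy >= 1 & iy <= length(field$lat) &
    iw >= 1 &
    as.numeric(as.Date(date)) <
      as.numeric(field$week_start[pmax(iw, 1)]) + 7
  out <- rep(NA_real_, length(ix))
  if (any(ok)) {
    out[ok] <- field$values[cbind(ix[ok], iy[ok], iw[ok])]
  }
  out
}

#' Simulate a smooth weekly ADT field
#'
#' Emulates a satellite-altimetry ADT product at 1/3-degree resolution: a
#' fixed low-order spatial harmonic pattern of amplitude `spatial_amp`,
#' perturbed week-to-week by an AR(1) process (coefficient `ar_coef`, noise
#' SD `noise_sd`) acting on both the overall level and a secondary spatial
#' mode.  Values are clamped to `adt_range` so the field stays within a
#' realistic span of dynamic topography.  No attempt is made to mimic real
#' eastern-Pacific oceanography, only the statistical structure (smoothness
#' in space, persistence in time) the model assumes.
#'
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return An [adt_field()] covering the configured extent and weeks.
#' @export
simulate_adt_field <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  grid <- sim_grid(config)
  with_seed(seed, {
    lon <- grid$lon_min + (seq_len(grid$nx) - 0.5) * grid$cell_size
    lat <- grid$lat_min + (seq_len(grid$ny) - 0.5) * grid$cell_size
    u <- (lon - grid$lon_min) / (grid$lon_max - grid$lon_min)
    v <- (lat - grid$lat_min) / (grid$lat_max - grid$lat_min)
    ph <- stats::runif(4, 0, 2 * pi)
    fr <- sample(1:2, 4, replace = TRUE)
    uu <- matrix(u, grid$nx, grid$ny)
    vv <- matrix(v, grid$nx, grid$ny, byrow = TRUE)
    p0 <- (sin(2 * pi * (fr[1] * uu + fr[2] * vv) + ph[1]) +
             0.6 * sin(2 * pi * (fr[3] * uu - fr[4] * vv) + ph[2])) / 1.6
    p1 <- sin(2 * pi * (fr[2] * uu - fr[1] * vv) + ph[3]) *
      cos(pi * vv + ph[4])
    nw <- config$n_weeks
    z <- numeric(nw)   # weekly level anomaly, AR(1)
    m <- numeric(nw)   # weekly weight of the secondary spatial mode
    sd_inn <- config$noise_sd * sqrt(1 - config$ar_coef^2)
    z[1] <- stats::rnorm(1, 0, config$noise_sd)
    m[1] <- stats::rnorm(1, 0, 1)
    for (w in seq_len(nw)[-1]) {
      z[w] <- config$ar_coef * z[w - 1] + stats::rnorm(1, 0, sd_inn)
      m[w] <- config$ar_coef * m[w - 1] +
        stats::rnorm(1, 0, sqrt(1 - config$ar_coef^2))
    }
    vals <- array(0, dim = c(grid$nx, grid$ny, nw))
    for (w in seq_len(nw)) {
      layer <- config$adt_mean +
        config$spatial_amp * (p0 + 0.3 * m[w] * p1) + z[w]
      vals[, , w] <- pmin(pmax(layer, config$adt_range[1]),
                          config$adt_range[2])
    }
    weeks <- config$week_start + 7 * (seq_len(nw) - 1)
    adt_field(lon, lat, weeks, vals, config$cell_size)
  })
}

#' Read/write an ADT field as delimited text
#'
#' Long-format CSV with columns `lon`, `lat`, `week_start`, `adt` (cm), the
#' plain-text exchange format used in place of NetCDF.
#'
#' @param field An [adt_field()].
#' @param path File path.
#' @param cell_size Cell edge in degrees (for reading).
#' @return `read_adt_csv` returns an [adt_field()].
#' @export
write_adt_csv <- function(field, path) {
  g <- expand.grid(lon = field$lon, lat = field$lat,
                   week_start = field$week_start)
  g$adt <- as.vector(field$values)
  utils::write.csv(g, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adt_csv
#' @export
read_adt_csv <- function(path, cell_size = 1 / 3) {
  g <- utils::read.csv(path)
  lon <- sort(unique(g$lon))
  lat <- sort(unique(g$lat))
  weeks <- sort(unique(as.Date(g$week_start)))
  vals <- array(NA_real_, dim = c(length(lon), length(lat), length(weeks)))
  ix <- match(g$lon, lon)
  iy <- match(g$lat, lat)
  iw <- match(as.Date(g$week_start), weeks)
  vals[cbind(ix, iy, iw)] <- g$adt
  adt_field(lon, lat, weeks, vals, cell_size)
}
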