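#' Grid specification for survey gridding
#'
#' Defines the regular lon/lat grid onto which effort and sightings are
#' accumulated, normally 1/3 x 1/3-degree cells matching the resolution of
#' the altimetry product.  Cells are half-open intervals
#' `[lon, lon + cell_size) x [lat, lat + cell_size)` anchored at
#' (`lon_min`, `lat_min`), so boundary points are assigned unambiguously.
#'
#' @param lon_min,lon_max,lat_min,lat_max Grid extent in degrees.
#' @param cell_size Cell edge in degrees (default 1/3).
#' @return Object of class `"grid_spec"`.
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, cell_size = 1 / 3) {
  if (cell_size <= 0) stop("cell_size must be positive")
  if (lon_max <= lon_min || lat_max <= lat_min) stop("empty grid extent")
  nx <- ceiling((lon_max - lon_min) / cell_size - 1e-9)
  ny <- ceiling((lat_max - lat_min) / cell_size - 1e-9)
  structure(list(lon_min = lon_min, lat_min = lat_min,
                 lon_max = lon_min + nx * cell_size,
                 lat_max = lat_min + ny * cell_size,
                 cell_size = cell_size, nx = nx, ny = ny),
            class = "grid_spec")
}

cell_index <- function(grid, lon, lat) {
  ix <- floor((lon - grid$lon_min) / grid$cell_size + 1e-9)
  iy <- floor((lat - grid$lat_min) / grid$cell_size + 1e-9)
  inside <- ix >= 0 & ix < grid$nx & iy >= 0 & iy < grid$ny
  id <- ifelse(inside, ix + grid$nx * iy, NA_integer_)
  list(id = as.integer(id), ix = as.integer(ix), iy = as.integer(iy),
       inside = inside)
}

cell_center <- function(grid, id) {
  ix <- id %% grid$nx
  iy <- id %/% grid$nx
  list(lon = grid$lon_min + (ix + 0.5) * grid$cell_size,
       lat = grid$lat_min + (iy + 0.5) * grid$cell_size)
}

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lon0,lat0,lon1,lat1 Coordinates in degrees, vectorised.
#' @return Distance in km.
#' @export
haversine_km <- function(lon0, lat0, lon1, lat1) {
  rad <- pi / 180
  dlat <- (lat1 - lat0) * rad
  dlon <- (lon1 - lon0) * rad
  a <- sin(dlat / 2)^2 + cos(lat0 * rad) * cos(lat1 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

# Split one segment at grid lines; returns data.frame of pieces with
# endpoints, cell id and length share.  Splitting is linear in lon/lat
# (adequate at 1/3-degree scale); piece lengths are proportional shares of
# the segment's length so total length is conserved exactly.
split_segment <- function(grid, lon0, lat0, lon1, lat1, length_km) {
  crossings <- function(p0, p1, origin, step) {
    if (p1 == p0) return(numeric())
    ks <- seq(ceiling(min(p0, p1) / step - origin / step),
              floor(max(p0, p1) / step - origin / step))
    t <- (origin + ks * step - p0) / (p1 - p0)
    t[t > 1e-12 & t < 1 - 1e-12]
  }
  t <- sort(unique(c(0, 1,
                     crossings(lon0, lon1, grid$lon_min, grid$cell_size),
                     crossings(lat0, lat1, grid$lat_min, grid$cell_size))))
  ta <- t[-length(t)]
  tb <- t[-1]
  la <- lon0 + ta * (lon1 - lon0); fa <- lat0 + ta * (lat1 - lat0)
  lb <- lon0 + tb * (lon1 - lon0); fb <- lat0 + tb * (lat1 - lat0)
  gc <- haversine_km(la, fa, lb, fb)
  share <- if (sum(gc) > 0) gc / sum(gc) else (tb - ta)
  mid <- cell_index(grid, (la + lb) / 2, (fa + fb) / 2)
  data.frame(lon0 = la, lat0 = fa, lon1 = lb, lat1 = fb,
             cell_id = mid$id, length_km = length_km * share)
}

#' Grid line-transect effort onto cells
#'
#' Splits each effort segment at cell boundaries and accumulates, per cell
#' and year, the transect effort \eqn{L_i} (km) and the effort-weighted
#' Beaufort sea state \eqn{B_i}.  Total effort is conserved exactly.  The
#' piece-level breakdown (with dates) is kept as attribute `"pieces"` so
#' that [match_adt()] can form effort-weighted weekly ADT means.
#'
#' @param segments Data frame with columns `date` (Date), `lon0`, `lat0`,
#'   `lon1`, `lat1` (degrees), `length_km`, `beaufort`.  If `length_km` is
#'   missing it is computed with the haversine formula.
#' @param grid A [grid_spec()].
#' @return Data frame of class `"effort_cells"` with columns `cell_id`,
#'   `lon`, `lat` (cell centers), `year`, `effort_km`, `beaufort`
#'   (effort-weighted mean), ordered by cell and year.
#' @export
grid_effort <- function(segments, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  need <- c("date", "lon0", "lat0", "lon1", "lat1", "beaufort")
  if (!all(need %in% names(segments))) {
    stop("segments must have columns: ", paste(need, collapse = ", "))
  }
  co <- c(segments$lon0, segments$lat0, segments$lon1, segments$lat1)
  if (any(!is.finite(co))) stop("segment coordinates must be finite")
  if (is.null(segments$length_km)) {
    segments$length_km <- haversine_km(segments$lon0, segments$lat0,
                                       segments$lon1, segments$lat1)
  }
  if (any(segments$length_km < 0)) stop("segment lengths must be >= 0")
  keep <- segments$length_km > 0
  segments <- segments[keep, , drop = FALSE]
  pieces <- vector("list", nrow(segments))
  for (k in seq_len(nrow(segments))) {
    p <- split_segment(grid, segments$lon0[k], segments$lat0[k],
                       segments$lon1[k], segments$lat1[k],
                       segments$length_km[k])
    p$date <- rep(segments$date[k], nrow(p))
    p$beaufort <- segments$beaufort[k]
    pieces[[k]] <- p
  }
  pieces <- do.call(rbind, pieces)
  if (is.null(pieces) || nrow(pieces) == 0) {
    pieces <- data.frame(lon0 = numeric(), lat0 = numeric(),
                         lon1 = numeric(), lat1 = numeric(),
                         cell_id = integer(), length_km = numeric(),
                         date = as.Date(character()), beaufort = numeric())
  }
  if (any(is.na(pieces$cell_id))) {
    stop("effort extends outside the grid extent")
  }
  pieces$year <- as.integer(format(pieces$date, "%Y"))
  key <- interaction(pieces$cell_id, pieces$year, drop = TRUE)
  L <- tapply(pieces$length_km, key, sum)
  Bw <- tapply(pieces$length_km * pieces$beaufort, key, sum)
  ids <- as.integer(tapply(pieces$cell_id, key, `[`, 1))
  yrs <- as.integer(tapply(pieces$year, key, `[`, 1))
  ctr <- cell_center(grid, ids)
  cells <- data.frame(cell_id = ids, lon = ctr$lon, lat = ctr$lat,
                      year = yrs, effort_km = as.numeric(L),
                      beaufort = as.numeric(Bw / L))
  cells <- cells[order(cells$cell_id, cells$year), , drop = FALSE]
  rownames(cells) <- NULL
  attr(cells, "pieces") <- pieces
  attr(cells, "grid") <- grid
  class(cells) <- c("effort_cells", "data.frame")
  cells
}

#' Assign sightings to grid cells
#'
#' Each sighting is assigned to exactly one cell by its position, under the
#' half-open cell convention of [grid_spec()].  Sightings falling outside
#' the grid are excluded with a warning.
#'
#' @param sightings Data frame with columns `date`, `lon`, `lat` (plus any
#'   others, carried through).
#' @param grid A [grid_spec()].
#' @return The sightings with `cell_id` and `year` columns added; excluded
#'   rows dropped.  Attribute `"n_excluded"` records how many were outside
#'   the grid.
#' @export
assign_sightings <- function(sightings, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(sightings) == 0) {
    sightings$cell_id <- integer()
    sightings$year <- integer()
    attr(sightings, "n_excluded") <- 0L
    return(sightings)
  }
  idx <- cell_index(grid, sightings$lon, sightings$lat)
  if (any(!idx$inside)) {
    warning(sum(!idx$inside), " sighting(s) outside the grid extent excluded")
  }
  out <- sightings[idx$inside, , drop = FALSE]
  out$cell_id <- idx$id[idx$inside]
  out$year <- as.integer(format(out$date, "%Y"))
  attr(out, "n_excluded") <- sum(!idx$inside)
  rownames(out) <- NULL
  out
}

#' Attach weekly ADT values to surveyed cells
#'
#' For every cell-year, looks up the ADT value of the week containing each
#' effort date and forms the effort-weighted mean across weeks, so a cell
#' surveyed in a single week gets that week's value verbatim.
#'
#' @param cells Output of [grid_effort()] (must carry the `"pieces"`
#'   attribute).
#' @param field An [adt_field()] covering the surveyed weeks and area.
#' @return `cells` with an `adt` column (cm) added.
#' @export
match_adt <- function(cells, field) {
  stopifnot(inherits(field, "adt_field"))
  pieces <- attr(cells, "pieces")
  if (is.null(pieces)) {
    stop("'cells' must be the output of grid_effort() (pieces attribute lost)")
  }
  grid <- attr(cells, "grid")
  ctr <- cell_center(grid, pieces$cell_id)
  val <- adt_lookup(field, ctr$lon, ctr$lat, pieces$date)
  if (any(is.na(val))) {
    bad <- unique(pieces$cell_id[is.na(val)])
    stop("no ADT coverage for surveyed cell(s): ",
         paste(utils::head(bad, 20), collapse = ", "))
  }
  key_p <- paste(pieces$cell_id, pieces$year)
  num <- tapply(pieces$length_km * val, key_p, sum)
  den <- tapply(pieces$length_km, key_p, sum)
  key_c <- paste(cells$cell_id, cells$year)
  cells$adt <- as.numeric(num[key_c] / den[key_c])
  cells
}

#' Build a model-ready cell table from raw survey data
#'
#' Convenience pipeline: grids effort, counts sightings per cell-year, and
#' attaches weekly ADT, producing the table consumed by [cetadens()].
#'
#' @param segments Effort segments (see [grid_effort()]).
#' @param sightings Sightings table (see [assign_sightings()]).
#' @param grid A [grid_spec()].
#' @param field An [adt_field()], or `NULL` to skip ADT matching.
#' @return Data frame with columns `cell_id`, `lon`, `lat`, `year`,
#'   `effort_km`, `beaufort`, `n_groups` and (unless `field` is `NULL`)
#'   `adt`.
#' @export
build_cells <- function(segments, sightings, grid, field = NULL) {
  cells <- grid_effort(segments, grid)
  if (!is.null(field)) cells <- match_adt(cells, field)
  s <- assign_sightings(sightings, grid)
  key_c <- paste(cells$cell_id, cells$year)
  if (nrow(s) > 0) {
    tab <- table(paste(s$cell_id, s$year))
    cells$n_groups <- as.integer(tab[key_c])
    cells$n_groups[is.na(cells$n_groups)] <- 0L
    orphan <- !paste(s$cell_id, s$year) %in% key_c
    if (any(orphan)) {
      warning(sum(orphan), " sighting(s) in cells without recorded effort ",
              "ignored")
    }
  } else {
    cells$n_groups <- 0L
  }
  cells
}
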