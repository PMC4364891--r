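# Zig-zag transect path across the extent: waypoints alternating between
# the south and north margins while advancing eastward; repeated passes
# (slightly offset) if more effort is requested than one pass provides.
zigzag_waypoints <- function(grid, effort_km, pass = 0) {
  margin <- grid$cell_size / 2
  lat_lo <- grid$lat_min + margin
  lat_hi <- grid$lat_max - margin
  leg_km <- haversine_km(0, lat_lo, 0, lat_hi)
  n_leg <- max(2, ceiling(effort_km / leg_km))
  lon0 <- grid$lon_min + margin + pass * grid$cell_size / 3
  lons <- seq(lon0, grid$lon_max - margin, length.out = n_leg + 1)
  lats <- rep(c(lat_lo, lat_hi), length.out = n_leg + 1)
  if (pass %% 2 == 1) lats <- rev(lats)
  cbind(lon = lons, lat = lats)
}

# Chop a polyline into segments of ~seg_km, stopping at effort_km_total
# (last segment shortened so total effort is exact).
chop_path <- function(wp, seg_km, effort_target) {
  out <- list()
  carried <- 0
  total <- 0
  for (k in seq_len(nrow(wp) - 1)) {
    p0 <- unname(wp[k, ]); p1 <- unname(wp[k + 1, ])
    leg <- haversine_km(p0[1], p0[2], p1[1], p1[2])
    if (leg <= 0) next
    t0 <- 0
    while (t0 < 1 - 1e-12) {
      want <- seg_km - carried
      dt <- min(1 - t0, want / leg)
      len <- dt * leg
      if (total + len >= effort_target) {
        dt <- dt * (effort_target - total) / len
        len <- effort_target - total
      }
      t1 <- t0 + dt
      out[[length(out) + 1]] <- c(
        lon0 = p0[1] + t0 * (p1[1] - p0[1]),
        lat0 = p0[2] + t0 * (p1[2] - p0[2]),
        lon1 = p0[1] + t1 * (p1[1] - p0[1]),
        lat1 = p0[2] + t1 * (p1[2] - p0[2]),
        length_km = len)
      total <- total + len
      carried <- if (carried + len >= seg_km - 1e-9) 0 else carried + len
      t0 <- t1
      if (total >= effort_target - 1e-9) {
        return(list(segments = do.call(rbind, out), total = total))
      }
    }
  }
  list(segments = do.call(rbind, out), total = total)
}

#' Simulate a complete line-transect survey
#'
#' Generates zig-zag transect effort over the configured extent, grids it,
#' and draws sightings from the full generative model: per surveyed
#' cell-year the expected group count is
#' \eqn{\lambda_i = 2 w_i L_i d_i g(0) / \bar s} with the cell ESW
#' \eqn{w_i} and density \eqn{d_i} evaluated at the configured true
#' parameters (including per-cell residuals), and the observed count is
#' Poisson.  Each simulated group receives a position on the effort inside
#' its cell, a group size (zero-truncated Poisson for whale-like,
#' log-normal for dolphin-like), the Beaufort state of its segment, and a
#' half-normal perpendicular distance with sighting-level scale
#' \eqn{\sigma_j = w_j\sqrt{2/\pi}}.
#'
#' The returned object carries the latent truth (per-cell \eqn{\lambda_i},
#' \eqn{w_i}, \eqn{d_i}, residuals; per-sighting \eqn{w_j}, \eqn{\sigma_j})
#' so tests can assert against exact oracles.
#'
#' @param config A [sim_config()].
#' @param field An [adt_field()] covering the configured weeks, normally
#'   from [simulate_adt_field()].
#' @param seed Seed; defaults to `config$seed + 1` so the field and the
#'   survey can be varied independently.
#' @return List of class `"cetadens_sim"` with elements `segments`,
#'   `sightings`, `cells` (model-ready, with `n_groups` and `adt`),
#'   `reference_mean` (effort-weighted mean ADT, cm), `truth`, `grid`,
#'   `config`.
#' @export
simulate_survey <- function(config, field, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(field, "adt_field"))
  grid <- sim_grid(config)
  whale <- config$species_form == "whale_like"
  det <- config$true_detection
  gs <- config$true_groupsize
  hp <- config$true_habitat
  with_seed(seed, {
    # --- effort ---
    segs <- list()
    total <- 0
    pass <- 0
    while (total < config$effort_km_total - 1e-9) {
      wp <- zigzag_waypoints(grid, config$effort_km_total - total, pass)
      ch <- chop_path(wp, config$seg_km, config$effort_km_total - total)
      if (!is.null(ch$segments)) segs[[pass + 1]] <- ch$segments
      total <- total + ch$total
      pass <- pass + 1
      if (ch$total <= 0) break
    }
    empty_sightings <- data.frame(
      date = as.Date(character()), lon = numeric(), lat = numeric(),
      species = character(), distance_km = numeric(),
      group_size = numeric(), beaufort = integer(),
      true_w = numeric(), true_sigma = numeric(), cell_id = integer())
    if (length(segs) == 0) {
      return(structure(list(segments = NULL, sightings = empty_sightings,
                            cells = NULL, reference_mean = NA_real_,
                            truth = NULL, grid = grid, config = config),
                       class = "cetadens_sim"))
    }
    segments <- as.data.frame(do.call(rbind, segs))
    n_seg <- nrow(segments)
    wk <- pmin(config$n_weeks,
               ceiling(seq_len(n_seg) / (n_seg / config$n_weeks)))
    segments$date <- config$week_start + 7 * (wk - 1) + 3
    segments$beaufort <- sample(0:5, n_seg, replace = TRUE,
                                prob = config$beaufort_probs)

    # --- gridding & ADT ---
    cells <- grid_effort(segments, grid)
    cells <- match_adt(cells, field)
    pieces <- attr(cells, "pieces")
    ref <- stats::weighted.mean(cells$adt, cells$effort_km)
    a_sc <- rescale_adt(cells$adt, ref)

    # --- latent truth and counts ---
    I <- nrow(cells)
    eps1 <- stats::rnorm(I, 0, det$sigma_eps1)
    eps2 <- stats::rnorm(I, 0, hp$sigma_eps2)
    w_i <- esw_cell(det, cells$beaufort, true_size_covariate(config),
                    config$species_form, eps1)
    d_i <- true_density(hp, a_sc, eps2)
    lam <- expected_group_count(w_i, cells$effort_km, d_i,
                                config$true_g0, true_mean_size(config))
    n_i <- stats::rpois(I, lam)
    cells$n_groups <- n_i

    # --- sightings ---
    n_tot <- sum(n_i)
    if (n_tot > 0) {
      key_piece <- paste(pieces$cell_id, format(pieces$date, "%Y"))
      key_cell <- paste(cells$cell_id, cells$year)
      piece_groups <- split(seq_len(nrow(pieces)), key_piece)
      # each group gets a position on the effort inside its cell,
      # length-weighted across the cell's transect pieces
      p_idx <- integer(n_tot)
      pos <- 1L
      for (i in which(n_i > 0)) {
        idx <- piece_groups[[key_cell[i]]]
        k <- n_i[i]
        p_idx[pos:(pos + k - 1L)] <- if (length(idx) == 1L) rep(idx, k) else
          sample(idx, k, replace = TRUE, prob = pieces$length_km[idx])
        pos <- pos + k
      }
      tt <- stats::runif(n_tot)
      s <- if (whale) {
        # zero-truncated Poisson: observed groups have >= 1 individual
        out <- stats::rpois(n_tot, gs$lambda_s)
        while (any(out == 0L)) {
          out[out == 0L] <- stats::rpois(sum(out == 0L), gs$lambda_s)
        }
        out
      } else {
        pmax(1, stats::rlnorm(n_tot, gs$mu_s, gs$sigma_s))
      }
      e0 <- stats::rnorm(n_tot, 0, det$sigma_eps0)
      w_j <- esw_sighting(det, pieces$beaufort[p_idx], s,
                          config$species_form, e0)
      sig <- sigma_from_esw(w_j)
      sightings <- data.frame(
        date = pieces$date[p_idx],
        lon = pieces$lon0[p_idx] + tt * (pieces$lon1[p_idx] -
                                           pieces$lon0[p_idx]),
        lat = pieces$lat0[p_idx] + tt * (pieces$lat1[p_idx] -
                                           pieces$lat0[p_idx]),
        species = config$species_form,
        distance_km = abs(stats::rnorm(n_tot, 0, sig)),
        group_size = s,
        beaufort = pieces$beaufort[p_idx],
        true_w = w_j, true_sigma = sig,
        cell_id = rep(cells$cell_id, n_i))
    } else {
      sightings <- empty_sightings
    }
    rownames(sightings) <- NULL
    structure(list(
      segments = segments, sightings = sightings, cells = cells,
      reference_mean = ref,
      truth = list(lambda = lam, w_cell = w_i, density = d_i,
                   eps1 = eps1, eps2 = eps2, scaled_adt = a_sc),
      grid = grid, config = config), class = "cetadens_sim")
  })
}

#' @export
print.cetadens_sim <- function(x, ...) {
  cat("Synthetic line-transect survey (", x$config$species_form, ")\n",
      sep = "")
  if (is.null(x$cells)) {
    cat("  no effort\n")
  } else {
    cat(sprintf("  %d cell-years, %.0f km effort, %d sightings\n",
                nrow(x$cells), sum(x$cells$effort_km), nrow(x$sightings)))
  }
  invisible(x)
}
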