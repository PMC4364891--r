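# Shared fixtures, built once per test run.  Surveys are small so the whole
# suite stays fast; MCMC fixtures use short chains except where a test
# needs the default protocol.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

whale_sim <- function() {
  fixture("whale_sim", function() {
    cfg <- sim_config("whale_like", seed = 3)
    simulate_survey(cfg, simulate_adt_field(cfg))
  })
}

# short-chain whale fit used by inference/prediction structure tests
whale_fit_small <- function() {
  fixture("whale_fit_small", function() {
    sim <- whale_sim()
    suppressWarnings(cetadens(
      sim$cells, sim$sightings, "whale_like", "poly2",
      config = mcmc_config(2000, 500, 3, 2, seed = 42)))
  })
}

# a fit whose posterior is a single repeated draw (degenerate), for
# pD = 0 / identical-quantile tests
degenerate_fit <- function() {
  fixture("degenerate_fit", function() {
    fit <- whale_fit_small()
    one <- function(m) m[rep(1, nrow(m)), , drop = FALSE]
    fit$draws <- one(fit$draws)
    fit$lambda <- one(fit$lambda)
    first <- fit$chains[[1]]
    fit$chains <- lapply(fit$chains, function(ch) {
      for (nm in c("globals", "lambda", "eps0", "eps1", "eps2")) {
        ch[[nm]] <- first[[nm]][rep(1, nrow(ch[[nm]])), , drop = FALSE]
      }
      ch
    })
    fit$draws <- fit$chains[[1]]$globals
    fit$lambda <- fit$chains[[1]]$lambda
    dev1 <- -2 * cetadens:::joint_loglik(
      fit, fit$chains[[1]]$globals[1, ], fit$chains[[1]]$eps0[1, ],
      fit$chains[[1]]$eps1[1, ], fit$chains[[1]]$eps2[1, ])
    fit$deviance <- rep(dev1, length(fit$deviance))
    fit
  })
}

# tiny one-cell grid helpers for gridding arithmetic
unit_grid <- function() grid_spec(0, 2, 0, 2, cell_size = 1 / 3)

seg <- function(lon0, lat0, lon1, lat1, beaufort = 0, length_km = NULL,
                date = as.Date("2000-07-05")) {
  d <- data.frame(date = date, lon0 = lon0, lat0 = lat0, lon1 = lon1,
                  lat1 = lat1, beaufort = beaufort)
  if (!is.null(length_km)) d$length_km <- length_km
  d
}

constant_field <- function(grid, value, weeks = as.Date("2000-07-03"),
                           cell_size = 1 / 3) {
  lon <- grid$lon_min + (seq_len(grid$nx) - 0.5) * grid$cell_size
  lat <- grid$lat_min + (seq_len(grid$ny) - 0.5) * grid$cell_size
  vals <- array(rep(value, each = grid$nx * grid$ny),
                dim = c(grid$nx, grid$ny, length(weeks)))
  adt_field(lon, lat, weeks, vals, cell_size = grid$cell_size)
}
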