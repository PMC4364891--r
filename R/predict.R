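#' Predict a density surface from posterior habitat parameters
#'
#' Evaluates the fitted habitat function at every retained posterior draw
#' for each ADT value supplied and returns the 0.025, 0.5 and 0.975
#' quantiles across draws — a density surface with 95% credible bands.
#' The per-cell habitat residual \eqn{\epsilon_2} is excluded by default
#' (predictions convert ADT through the parameter posteriors; residuals are
#' specific to the fitted cells); `include_residual = TRUE` adds a fresh
#' \eqn{\epsilon_2 \sim N(0, \sigma_{\epsilon 2})} per draw for wider,
#' predictive bands.
#'
#' @param object A fitted [cetadens()] model.
#' @param adt ADT raster: numeric vector of cm values, or a data frame with
#'   an `adt` column (other columns, e.g. `lon`/`lat`, carried through).
#' @param include_residual Include the cell residual in predictions.
#' @param seed Seed for residual draws (only used with
#'   `include_residual = TRUE`).
#' @param ... Unused.
#' @return Data frame of class `"density_surface"` with columns `adt`,
#'   `q025`, `median`, `q975` (individuals per km^2) and `extrapolated`
#'   (TRUE outside the fitted ADT range), plus any carried-through columns.
#' @export
predict.cetadens <- function(object, adt, include_residual = FALSE,
                             seed = NULL, ...) {
  carried <- NULL
  if (is.data.frame(adt)) {
    if (!"adt" %in% names(adt)) stop("'adt' data frame needs an 'adt' column")
    carried <- adt[setdiff(names(adt), "adt")]
    adt <- adt$adt
  }
  if (any(!is.finite(adt))) stop("ADT values must be finite")
  a <- rescale_adt(adt, object$reference_mean)
  d <- object$draws
  M <- nrow(d)
  A <- length(a)
  eps2 <- if (include_residual) {
    with_seed(seed, stats::rnorm(M, 0, d[, "sigma_eps2"]))
  } else {
    numeric(M)
  }
  # draws x cells matrix of densities
  dens <- switch(object$habitat_form,
    poly2 = exp(outer(d[, "omega0"] + eps2, rep(1, A)) +
                  outer(d[, "omega1"], a) + outer(d[, "omega2"], a^2)),
    poly3 = exp(outer(d[, "theta0"] + eps2, rep(1, A)) +
                  outer(d[, "theta1"], a) + outer(d[, "theta2"], a^2) +
                  outer(d[, "theta3"], a^3)),
    average = {
      d2 <- exp(outer(d[, "omega0"] + eps2, rep(1, A)) +
                  outer(d[, "omega1"], a) + outer(d[, "omega2"], a^2))
      d3 <- exp(outer(d[, "theta0"] + eps2, rep(1, A)) +
                  outer(d[, "theta1"], a) + outer(d[, "theta2"], a^2) +
                  outer(d[, "theta3"], a^3))
      d[, "vartheta"] * d2 + (1 - d[, "vartheta"]) * d3
    })
  q <- apply(dens, 2, stats::quantile, c(0.025, 0.5, 0.975))
  rng <- range(object$cells$adt)
  out <- data.frame(adt = adt, q025 = q[1, ], median = q[2, ],
                    q975 = q[3, ],
                    extrapolated = adt < rng[1] | adt > rng[2])
  if (!is.null(carried) && ncol(carried) > 0) out <- cbind(carried, out)
  class(out) <- c("density_surface", "data.frame")
  out
}

#' Yearly density surfaces stratified by ENSO state
#'
#' Produces one predicted density surface per year from that year's ADT
#' raster and annotates it with the July-December mean of a monthly ENSO
#' index series and a categorical label (El Nino >= +0.5, La Nina <= -0.5,
#' else neutral).  The index is annotation only: identical rasters give
#' identical surfaces regardless of ENSO state.
#'
#' @param fit A fitted [cetadens()] model.
#' @param adt_by_year Named list (names = years) of ADT rasters, each a
#'   numeric vector or data frame accepted by [predict.cetadens()].
#' @param mei Monthly index data frame (`year`, `month`, `mei`), e.g. from
#'   [simulate_mei()]; may omit years (label `"unknown"`, with a warning).
#' @return Named list of `"density_surface"` objects with attributes
#'   `year`, `mei_jul_dec` and `enso`.
#' @export
enso_yearly_surfaces <- function(fit, adt_by_year, mei) {
  stopifnot(inherits(fit, "cetadens"))
  years <- as.integer(names(adt_by_year))
  if (any(is.na(years))) stop("'adt_by_year' must be named by year")
  jd <- mei_jul_dec(mei)
  out <- vector("list", length(years))
  names(out) <- names(adt_by_year)
  for (k in seq_along(years)) {
    surf <- predict(fit, adt_by_year[[k]])
    m <- jd$mei_jul_dec[match(years[k], jd$year)]
    if (is.na(m)) {
      warning("no Jul-Dec MEI values for year ", years[k],
              "; ENSO label set to \"unknown\"")
    }
    attr(surf, "year") <- years[k]
    attr(surf, "mei_jul_dec") <- m
    attr(surf, "enso") <- enso_label(m)
    out[[k]] <- surf
  }
  out
}

#' Write a density surface as delimited text
#'
#' @param surface A `"density_surface"` data frame.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  df <- as.data.frame(surface)
  for (at in c("year", "mei_jul_dec", "enso")) {
    if (!is.null(attr(surface, at))) df[[at]] <- attr(surface, at)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot the fitted density-ADT response
#'
#' Median predicted density with the 95% credible band over the range of
#' surveyed ADT, rug marks at surveyed cell ADT values, and (for unimodal
#' second-order fits) the posterior-median optimum ADT.
#'
#' @param x A fitted [cetadens()] model.
#' @param n_grid Number of ADT grid points.
#' @param ... Passed to [graphics::plot()].
#' @return The prediction grid, invisibly.
#' @export
plot.cetadens <- function(x, n_grid = 200, ...) {
  rng <- range(x$cells$adt)
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  surf <- predict(x, grid)
  graphics::plot(grid, surf$median, type = "n",
                 ylim = c(0, max(surf$q975)),
                 xlab = "ADT (cm)",
                 ylab = expression(Density ~ (ind ~ km^-2)), ...)
  graphics::polygon(c(grid, rev(grid)), c(surf$q025, rev(surf$q975)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(grid, surf$median, lwd = 2, col = "steelblue4")
  graphics::rug(x$cells$adt)
  if (x$habitat_form == "poly2") {
    om <- apply(x$draws[, c("omega0", "omega1", "omega2")], 2,
                stats::median)
    if (om[3] < 0) {
      opt <- optimum_adt(om, x$reference_mean)
      if (opt$optimum_cm >= rng[1] && opt$optimum_cm <= rng[2]) {
        graphics::abline(v = opt$optimum_cm, lty = 2, col = "red")
      }
    }
  }
  invisible(surf)
}
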