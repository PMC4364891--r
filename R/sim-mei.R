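#' Simulate a monthly ENSO index series
#'
#' Emulates a multivariate ENSO index (MEI)-like monthly series: a yearly
#' state (El Nino-like positive, La Nina-like negative) evolving as blocks,
#' plus AR(1) monthly noise.  Yearly states can be forced exactly via
#' `yearly_mean`, in which case setting `monthly_sd = 0` makes every month
#' of a year equal to its state.
#'
#' @param years Integer vector of years (non-empty).
#' @param seed Integer seed.
#' @param yearly_mean Optional numeric vector (recycled to `length(years)`)
#'   forcing each year's state; default draws persistent blocks.
#' @param monthly_sd SD of monthly AR(1) noise around the yearly state.
#' @param ar Monthly AR(1) coefficient.
#' @return Data frame with columns `year`, `month`, `mei`.
#' @export
simulate_mei <- function(years, seed = 1L, yearly_mean = NULL,
                         monthly_sd = 0.25, ar = 0.6) {
  if (length(years) == 0) stop("'years' must be non-empty")
  with_seed(seed, {
    ny <- length(years)
    if (is.null(yearly_mean)) {
      # block-persistent yearly states in roughly the observed MEI range
      state <- numeric(ny)
      state[1] <- stats::rnorm(1, 0, 1)
      for (k in seq_len(ny)[-1]) {
        state[k] <- if (stats::runif(1) < 0.6) state[k - 1] else
          stats::rnorm(1, 0, 1)
      }
      yearly_mean <- pmin(pmax(state, -2.5), 2.5)
    } else {
      yearly_mean <- rep_len(yearly_mean, ny)
    }
    n <- 12 * ny
    noise <- numeric(n)
    if (monthly_sd > 0) {
      noise[1] <- stats::rnorm(1, 0, monthly_sd)
      sd_inn <- monthly_sd * sqrt(1 - ar^2)
      for (t in 2:n) noise[t] <- ar * noise[t - 1] + stats::rnorm(1, 0, sd_inn)
    }
    data.frame(year = rep(years, each = 12),
               month = rep(1:12, ny),
               mei = rep(yearly_mean, each = 12) + noise)
  })
}

#' July-December mean ENSO index per year
#'
#' The yearly ENSO attribute used to stratify prediction surfaces: the mean
#' index over July-December of each year.
#'
#' @param mei Data frame with columns `year`, `month`, `mei`.
#' @return Data frame with columns `year`, `mei_jul_dec`.
#' @export
mei_jul_dec <- function(mei) {
  sub <- mei[mei$month >= 7 & mei$month <= 12, , drop = FALSE]
  agg <- tapply(sub$mei, sub$year, mean)
  data.frame(year = as.integer(names(agg)),
             mei_jul_dec = as.numeric(agg), row.names = NULL)
}

#' Categorical ENSO label from a July-December MEI mean
#'
#' Thresholds at +/- 0.5 (an implementation choice; the index itself is
#' continuous): `"El Nino"` for >= +0.5, `"La Nina"` for <= -0.5, else
#' `"neutral"`; `NA` gives `"unknown"`.
#'
#' @param mei_jd Numeric July-December mean index, vectorised.
#' @return Character vector of labels.
#' @export
enso_label <- function(mei_jd) {
  out <- ifelse(is.na(mei_jd), "unknown",
                ifelse(mei_jd >= 0.5, "El Nino",
                       ifelse(mei_jd <= -0.5, "La Nina", "neutral")))
  as.character(out)
}
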