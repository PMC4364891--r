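#' Half-normal detection scale from effective strip half-width
#'
#' In line-transect distance sampling with a half-normal detection function
#' \eqn{g(x) = \exp(-x^2 / 2\sigma^2)}, the effective strip half-width (ESW)
#' is the width \eqn{w} such that \eqn{\int_0^\infty g(x)\,dx = w}.  For the
#' half-normal this gives \eqn{w = \sigma\sqrt{\pi/2}}, i.e.
#' \eqn{\sigma = w\sqrt{2/\pi}}.
#'
#' @param w Effective strip half-width in km (positive).
#' @param sigma Half-normal scale in km (positive).
#' @return `sigma_from_esw` returns the half-normal scale \eqn{\sigma};
#'   `esw_from_sigma` the corresponding ESW.  Both are vectorised.
#' @examples
#' sigma_from_esw(1)            # 0.7978846
#' esw_from_sigma(sigma_from_esw(3.1))  # round trip: 3.1
#' @export
sigma_from_esw <- function(w) {
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("effective strip half-width 'w' must be positive and finite")
  }
  w * sqrt(2 / pi)
}

#' @rdname sigma_from_esw
#' @export
esw_from_sigma <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("'sigma' must be positive and finite")
  }
  sigma * sqrt(pi / 2)
}

#' Detection (strip-width) model parameters
#'
#' Container for the coefficients of the log-linear effective strip
#' half-width model.  The sighting-level model is
#' \eqn{w_j = \exp(\alpha_0 + \alpha_1 b_j + \alpha_2 s'_j + \epsilon_0)},
#' where \eqn{b_j} is Beaufort sea state and \eqn{s'_j} is the group size
#' (whale-like species) or its natural log (dolphin-like species).  The
#' cell-level model replaces \eqn{b_j} by the effort-weighted Beaufort
#' \eqn{B_i} and \eqn{s'_j} by the predicted mean group size on the same
#' scale, with its own residual \eqn{\epsilon_1}.
#'
#' @param alpha0,alpha1,alpha2 Intercept, Beaufort slope, group-size slope.
#' @param sigma_eps0 SD of the per-sighting residual effect (>= 0).
#' @param sigma_eps1 SD of the per-cell residual effect (>= 0).
#' @return An object of class `"detection_params"`.
#' @export
detection_params <- function(alpha0 = 0, alpha1 = 0, alpha2 = 0,
                             sigma_eps0 = 0, sigma_eps1 = 0) {
  stopifnot(is.numeric(alpha0), is.numeric(alpha1), is.numeric(alpha2))
  if (sigma_eps0 < 0 || sigma_eps1 < 0) {
    stop("residual SDs must be non-negative")
  }
  structure(list(alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
                 sigma_eps0 = sigma_eps0, sigma_eps1 = sigma_eps1),
            class = "detection_params")
}

check_species_form <- function(form) {
  if (length(form) != 1L || !form %in% c("whale_like", "dolphin_like")) {
    stop("'form' must be \"whale_like\" or \"dolphin_like\"")
  }
  form
}

#' Sighting-level effective strip half-width
#'
#' Evaluates the log-linear ESW model at a sighting.  For whale-like species
#' the group-size covariate enters untransformed; for dolphin-like species
#' (large, skewed groups) it enters as \eqn{\ln s_j}.  The residual
#' `eps0` is added on the log scale, so the returned width is always
#' positive.
#'
#' @param params A [detection_params()] object.
#' @param beaufort Beaufort sea state of the sighting.
#' @param group_size Observed group size (>= 1).
#' @param form `"whale_like"` or `"dolphin_like"`.
#' @param eps0 Per-sighting residual effect (log scale), default 0.
#' @return ESW \eqn{w_j} in km.
#' @examples
#' p <- detection_params(alpha0 = 1.111, alpha1 = -0.008098, alpha2 = 0.02194)
#' esw_sighting(p, beaufort = 3, group_size = 2, form = "whale_like")
#' @export
esw_sighting <- function(params, beaufort, group_size, form, eps0 = 0) {
  check_species_form(form)
  if (any(group_size < 1)) stop("group_size must be >= 1")
  scov <- if (form == "whale_like") group_size else log(group_size)
  exp(params$alpha0 + params$alpha1 * beaufort + params$alpha2 * scov + eps0)
}

#' Cell-level effective strip half-width
#'
#' Same log-linear model as [esw_sighting()], evaluated with cell covariates:
#' the effort-weighted Beaufort state \eqn{B_i} and the predicted mean group
#' size.  `size_covariate` must already be on the scale the sighting model
#' uses: the Poisson mean \eqn{\lambda_{(s)}} for whale-like species, and the
#' log-scale mean \eqn{\mu_{(s)} + \sigma_{(s)}^2/2} (i.e. \eqn{\ln\tilde S})
#' for dolphin-like species, so that the slope \eqn{\alpha_2} shared between
#' the two levels multiplies commensurate quantities.
#'
#' @param params A [detection_params()] object.
#' @param beaufort Effort-weighted Beaufort sea state \eqn{B_i}.
#' @param size_covariate Mean group size covariate (see Details).
#' @param form `"whale_like"` or `"dolphin_like"`.
#' @param eps1 Per-cell residual effect (log scale), default 0.
#' @return ESW \eqn{w_i} in km.
#' @export
esw_cell <- function(params, beaufort, size_covariate, form, eps1 = 0) {
  check_species_form(form)
  exp(params$alpha0 + params$alpha1 * beaufort +
        params$alpha2 * size_covariate + eps1)
}

#' Half-normal log-density of a perpendicular distance
#'
#' Log of the half-normal density \eqn{2\phi(x; 0, \sigma)} for \eqn{x \ge 0},
#' the likelihood of a perpendicular sighting distance given the
#' sighting-level detection scale.
#'
#' @param x Perpendicular distance in km (>= 0), vectorised.
#' @param sigma Half-normal scale in km (> 0).
#' @return Log-density, same length as `x`.
#' @examples
#' exp(distance_loglik(0, 1))  # 0.7978846, the half-normal mode
#' @export
distance_loglik <- function(x, sigma) {
  if (any(x < 0)) stop("perpendicular distances must be non-negative")
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  log(2) + stats::dnorm(x, mean = 0, sd = sigma, log = TRUE)
}
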