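#' Rescale absolute dynamic topography for model fitting
#'
#' ADT (cm) enters the habitat model centred on a reference mean and divided
#' by 100, which leaves the model invariant but greatly improves MCMC
#' mixing of the polynomial coefficients.  The reference mean used in a fit
#' is stored with the fitted model so predictions use the same centring.
#'
#' @param adt ADT values in cm.
#' @param reference_mean Centring constant in cm.
#' @param scaled Rescaled ADT values (for the inverse).
#' @return `rescale_adt` returns `(adt - reference_mean)/100`;
#'   `unscale_adt` inverts it.
#' @export
rescale_adt <- function(adt, reference_mean) {
  if (any(!is.finite(adt)) || !is.finite(reference_mean)) {
    stop("ADT values and reference mean must be finite")
  }
  (adt - reference_mean) / 100
}

#' @rdname rescale_adt
#' @export
unscale_adt <- function(scaled, reference_mean) {
  scaled * 100 + reference_mean
}

#' Habitat (density-ADT) model parameters
#'
#' Coefficients of the log-polynomial density response to rescaled ADT:
#' second-order (`omega`), third-order (`theta`), and the mixing weight
#' `vartheta` of the model average.
#'
#' @param omega Numeric length 3: second-order coefficients
#'   \eqn{\omega_0, \omega_1, \omega_2}.
#' @param theta Numeric length 4: third-order coefficients
#'   \eqn{\theta_0, \dots, \theta_3}.
#' @param vartheta Mixing weight in \[0, 1\] of the second-order model in the
#'   model average.
#' @param sigma_eps2 SD of the per-cell habitat residual (>= 0).
#' @param adt_reference_mean Centring constant (cm) the coefficients refer to.
#' @return Object of class `"habitat_params"`.
#' @export
habitat_params <- function(omega = NULL, theta = NULL, vartheta = NULL,
                           sigma_eps2 = 0, adt_reference_mean = NA_real_) {
  if (!is.null(omega) && length(omega) != 3L) stop("'omega' must have length 3")
  if (!is.null(theta) && length(theta) != 4L) stop("'theta' must have length 4")
  if (!is.null(vartheta) && (vartheta < 0 || vartheta > 1)) {
    stop("'vartheta' must be in [0, 1]")
  }
  if (sigma_eps2 < 0) stop("sigma_eps2 must be >= 0")
  structure(list(omega = omega, theta = theta, vartheta = vartheta,
                 sigma_eps2 = sigma_eps2,
                 adt_reference_mean = adt_reference_mean),
            class = "habitat_params")
}

#' Log-quadratic density response to ADT
#'
#' Population density (individuals per km^2) as the exponential of a
#' second-order polynomial in rescaled ADT:
#' \eqn{\hat d_i = \exp(\omega_0 + \omega_1 A + \omega_2 A^2 + \epsilon_2)}.
#' With \eqn{\omega_2 < 0} the response is unimodal with an interior optimum.
#'
#' @param omega Numeric length 3.
#' @param scaled_adt Rescaled ADT (see [rescale_adt()]), vectorised.
#' @param eps2 Per-cell residual (log scale), default 0.
#' @return Density, strictly positive.
#' @export
density_poly2 <- function(omega, scaled_adt, eps2 = 0) {
  stopifnot(length(omega) == 3L)
  exp(omega[1] + omega[2] * scaled_adt + omega[3] * scaled_adt^2 + eps2)
}

#' Log-cubic density response to ADT
#'
#' Third-order analogue of [density_poly2()]:
#' \eqn{\hat d_i = \exp(\theta_0 + \theta_1 A + \theta_2 A^2 + \theta_3 A^3
#' + \epsilon_2)}.
#'
#' @param theta Numeric length 4.
#' @inheritParams density_poly2
#' @return Density, strictly positive.
#' @export
density_poly3 <- function(theta, scaled_adt, eps2 = 0) {
  stopifnot(length(theta) == 4L)
  exp(theta[1] + theta[2] * scaled_adt + theta[3] * scaled_adt^2 +
        theta[4] * scaled_adt^3 + eps2)
}

#' Model-averaged density response
#'
#' Convex combination of the second- and third-order responses with mixing
#' weight \eqn{\vartheta}:
#' \eqn{\hat d_i = \vartheta\, \hat d_i^{(2)} + (1-\vartheta)\, \hat d_i^{(3)}}.
#'
#' @param vartheta Mixing weight in \[0, 1\].
#' @param d2 Second-order density.
#' @param d3 Third-order density.
#' @return Averaged density, between `d2` and `d3` elementwise.
#' @export
density_average <- function(vartheta, d2, d3) {
  if (any(vartheta < 0 | vartheta > 1)) stop("'vartheta' must be in [0, 1]")
  vartheta * d2 + (1 - vartheta) * d3
}

#' Optimum habitat in terms of ADT
#'
#' The ADT value at which the log-quadratic response attains its maximum:
#' the vertex of the exponent, at scaled ADT \eqn{-\omega_1 / (2\omega_2)},
#' defined only when \eqn{\omega_2 < 0}.
#'
#' @param omega Numeric length 3 with `omega[3] < 0`.
#' @param reference_mean Centring constant (cm) used when the coefficients
#'   were fitted.
#' @return List with `scaled_optimum`, `optimum_cm` (on the original ADT
#'   scale) and `max_density` (individuals per km^2 at the optimum,
#'   residual excluded).
#' @examples
#' optimum_adt(c(-9.973, -16.14, -47.1), reference_mean = 66)
#' @export
optimum_adt <- function(omega, reference_mean) {
  stopifnot(length(omega) == 3L)
  if (omega[3] >= 0) stop("no interior maximum: omega[3] must be negative")
  a_star <- unname(-omega[2] / (2 * omega[3]))
  list(scaled_optimum = a_star,
       optimum_cm = unscale_adt(a_star, reference_mean),
       max_density = unname(density_poly2(omega, a_star)))
}
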