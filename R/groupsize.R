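#' Group-size model parameters
#'
#' Whale-like species use a Poisson group-size likelihood with mean
#' \eqn{\lambda_{(s)}}; dolphin-like species a log-normal with log-scale
#' location \eqn{\mu_{(s)}} and SD \eqn{\sigma_{(s)}}.
#'
#' @param lambda_s Poisson mean group size (whale-like form), > 0.
#' @param mu_s,sigma_s Log-normal location and SD (dolphin-like form).
#' @return An object of class `"groupsize_params"`.
#' @export
groupsize_params <- function(lambda_s = NULL, mu_s = NULL, sigma_s = NULL) {
  if (!is.null(lambda_s) && lambda_s <= 0) stop("lambda_s must be > 0")
  if (!is.null(sigma_s) && sigma_s < 0) stop("sigma_s must be >= 0")
  structure(list(lambda_s = lambda_s, mu_s = mu_s, sigma_s = sigma_s),
            class = "groupsize_params")
}

#' Group-size log-likelihood
#'
#' Poisson log-pmf (whale-like) or log-normal log-density (dolphin-like) of
#' observed group sizes.  The Poisson form is used exactly as specified
#' (untruncated), although observed groups always have size >= 1; at small
#' means the discrepancy is negligible.
#'
#' @param s Observed group size(s), >= 1.  Must be integer-valued under the
#'   whale-like form.
#' @param params A [groupsize_params()] object.
#' @param form `"whale_like"` or `"dolphin_like"`.
#' @param zero_truncated If `TRUE` (whale-like form only), use the
#'   zero-truncated Poisson pmf \eqn{Pois(s;\lambda)/(1 - e^{-\lambda})},
#'   the likelihood consistent with groups that are only observed when
#'   \eqn{s \ge 1}.  Default `FALSE` (the plain Poisson pmf).
#' @return Log-likelihood, same length as `s`.
#' @examples
#' exp(groupsize_loglik(2, groupsize_params(lambda_s = 1.802), "whale_like"))
#' @export
groupsize_loglik <- function(s, params, form, zero_truncated = FALSE) {
  check_species_form(form)
  if (any(s < 1)) stop("group sizes must be >= 1")
  if (form == "whale_like") {
    if (any(s != round(s))) {
      stop("whale-like (Poisson) group sizes must be integers")
    }
    ll <- stats::dpois(s, params$lambda_s, log = TRUE)
    if (zero_truncated) ll <- ll - log(1 - exp(-params$lambda_s))
    ll
  } else {
    stats::dlnorm(s, meanlog = params$mu_s, sdlog = params$sigma_s, log = TRUE)
  }
}

#' Arithmetic mean group size of the log-normal model
#'
#' The predicted mean group size \eqn{\tilde S = \exp(\mu_{(s)} +
#' \sigma_{(s)}^2/2)}, i.e. the arithmetic mean of a log-normal variate.
#' This is the quantity (in individuals per group) that divides individual
#' density in the group-count model, and whose log is the cell-level
#' detection covariate for dolphin-like species.
#'
#' @param mu_s Log-scale location.
#' @param sigma_s Log-scale SD (>= 0).
#' @return \eqn{\tilde S} in individuals.
#' @examples
#' mean_group_size(log(200), sqrt(0.5))  # 200 * exp(0.25)
#' @export
mean_group_size <- function(mu_s, sigma_s) {
  if (any(sigma_s < 0)) stop("sigma_s must be >= 0")
  exp(mu_s + sigma_s^2 / 2)
}
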