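#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance ratio:
#' \eqn{\hat R = \sqrt{((n-1)/n\, W + B/n) / W}} with \eqn{W} the mean
#' within-chain variance and \eqn{B} the between-chain variance of the
#' chain means (times n).  Values close to 1 indicate convergence; fits
#' flag any parameter with \eqn{\hat R > 1.1}.
#'
#' @param chains List of numeric vectors (one per chain, equal length), or
#'   a matrix with one chain per column.
#' @return The R-hat statistic (>= 1 up to numerical tolerance).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(k) chains[, k])
  m <- length(chains)
  if (m < 2) stop("at least 2 chains are required")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 10) stop("chains too short (need >= 10 draws)")
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Batch-means Monte Carlo standard error
#'
#' Standard error of the posterior mean estimated from consecutive batch
#' means, robust to autocorrelation of the retained chain.
#'
#' @param draws Numeric vector of retained draws (>= 50).
#' @param n_batches Number of batches (default 50).
#' @return The MC error (>= 0).
#' @export
mc_error <- function(draws, n_batches = 50) {
  n <- length(draws)
  if (n < n_batches) stop("need at least ", n_batches, " draws")
  size <- n %/% n_batches
  bm <- vapply(seq_len(n_batches), function(k) {
    mean(draws[((k - 1) * size + 1):(k * size)])
  }, numeric(1))
  stats::sd(bm) / sqrt(n_batches)
}

# Joint log-likelihood (distances + group sizes + counts) at a single
# parameter set, in R; used for the DIC plug-in deviance and as an
# independent cross-check of the compiled likelihood.
joint_loglik <- function(fit, globals, eps0, eps1, eps2) {
  pn <- fit$param_names
  g <- stats::setNames(as.numeric(globals), pn)
  whale <- fit$species_form == "whale_like"
  dat <- fit$data
  sig <- sigma_from_esw(exp(g["alpha0"] + g["alpha1"] * dat$b +
                              g["alpha2"] * dat$scov + eps0))
  ll_d <- sum(distance_loglik(dat$x, sig))
  if (!is.null(fit$truncation)) {
    ll_d <- ll_d - sum(log(2 * stats::pnorm(fit$truncation / sig) - 1))
  }
  if (whale) {
    ll_s <- sum(stats::dpois(dat$s, g["lambda_s"], log = TRUE))
    if (isTRUE(fit$zero_truncated_sizes)) {
      ll_s <- ll_s - length(dat$s) * log(1 - exp(-g["lambda_s"]))
    }
    M <- g["lambda_s"]
    ms <- g["lambda_s"]
  } else {
    ll_s <- sum(stats::dlnorm(dat$s, g["mu_s"], g["sigma_s"], log = TRUE))
    M <- g["mu_s"] + g["sigma_s"]^2 / 2
    ms <- exp(M)
  }
  w_i <- exp(g["alpha0"] + g["alpha1"] * dat$B + g["alpha2"] * M + eps1)
  a <- dat$A
  d_i <- switch(fit$habitat_form,
    poly2 = density_poly2(g[c("omega0", "omega1", "omega2")], a, eps2),
    poly3 = density_poly3(g[c("theta0", "theta1", "theta2", "theta3")], a,
                          eps2),
    average = density_average(
      g["vartheta"],
      density_poly2(g[c("omega0", "omega1", "omega2")], a, eps2),
      density_poly3(g[c("theta0", "theta1", "theta2", "theta3")], a, eps2)))
  lam <- expected_group_count(w_i, dat$L, d_i, g["g0"], ms)
  ll_n <- sum(suppressWarnings(count_loglik(dat$n, lam)))
  unname(ll_d + ll_s + ll_n)
}

#' Deviance Information Criterion
#'
#' \eqn{DIC = \bar D + p_D} with \eqn{\bar D} the posterior mean deviance
#' and \eqn{p_D = \bar D - D(\bar\vartheta)} the effective number of
#' parameters, where \eqn{D(\bar\vartheta)} is the deviance at the
#' posterior means of all parameters (random effects included).  The
#' deviance uses the full joint likelihood (distances + group sizes +
#' counts), which the habitat variants share, so DIC differences reflect
#' the ecological sub-model.  Lower is preferred.
#'
#' @param fit A fitted [cetadens()] model.
#' @return Named numeric vector: `DIC`, `pD`, `Dbar`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "cetadens"))
  dbar <- mean(fit$deviance)
  gbar <- colMeans(fit$draws)
  e0 <- colMeans(do.call(rbind, lapply(fit$chains, `[[`, "eps0")))
  e1 <- colMeans(do.call(rbind, lapply(fit$chains, `[[`, "eps1")))
  e2 <- colMeans(do.call(rbind, lapply(fit$chains, `[[`, "eps2")))
  dhat <- -2 * joint_loglik(fit, gbar, e0, e1, e2)
  pd <- dbar - dhat
  c(DIC = dbar + pd, pD = pd, Dbar = dbar)
}

#' Posterior predictive Bayesian p-value for the count likelihood
#'
#' For each retained draw m, computes a discrepancy between data and the
#' per-cell Poisson means \eqn{\lambda_i^{(m)}} — by default the
#' Freeman-Tukey sums-of-squares \eqn{T = \sum_i (\sqrt{n_i} -
#' \sqrt{\lambda_i})^2}, stable for small counts — for both the observed
#' counts and a replicated dataset \eqn{n^{rep} \sim Pois(\lambda^{(m)})}.
#' The p-value is the fraction of draws whose replicated discrepancy
#' exceeds the observed one (ties split evenly).  Values near 0.5 indicate
#' adequate fit; values near 0 or 1, misfit.
#'
#' @param fit A fitted [cetadens()] model.
#' @param discrepancy `"freeman_tukey"` or `"squared"`; defaults to the
#'   choice recorded in the fit.
#' @param seed Optional seed for the replicate draws.
#' @return p-value in \[0, 1\].
#' @export
bayesian_pvalue <- function(fit, discrepancy = NULL, seed = NULL) {
  stopifnot(inherits(fit, "cetadens"))
  if (is.null(discrepancy)) discrepancy <- fit$discrepancy
  lam <- fit$lambda
  n_obs <- fit$data$n
  with_seed(seed, {
    M <- nrow(lam)
    I <- ncol(lam)
    disc <- function(n, l) {
      if (discrepancy == "freeman_tukey") rowSums((sqrt(n) - sqrt(l))^2)
      else rowSums((n - l)^2)
    }
    n_mat <- matrix(n_obs, M, I, byrow = TRUE)
    t_obs <- disc(n_mat, lam)
    n_rep <- matrix(stats::rpois(M * I, lam), M, I)
    t_rep <- disc(n_rep, lam)
    mean(t_rep > t_obs) + 0.5 * mean(t_rep == t_obs)
  })
}
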