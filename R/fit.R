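#' MCMC configuration
#'
#' Default protocol: 10,000 iterations, burn-in 2,000, every tenth draw
#' retained, giving a posterior sample of 800 per chain, run as three
#' chains.
#'
#' @param n_iter Total iterations per chain.
#' @param n_burnin Burn-in iterations discarded (must be < `n_iter`).
#' @param thin Thinning interval (>= 1).
#' @param n_chains Number of chains (>= 1; >= 2 needed for R-hat).
#' @param seed Integer seed; chain c uses `seed + c`.
#' @return Object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_iter = 10000, n_burnin = 2000, thin = 10,
                        n_chains = 3, seed = 1L) {
  if (n_burnin >= n_iter) stop("n_burnin must be < n_iter")
  if (thin < 1) stop("thin must be >= 1")
  if (n_chains < 1) stop("n_chains must be >= 1")
  structure(list(n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin),
                 n_chains = as.integer(n_chains),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Retained posterior draws per chain implied by a configuration
#'
#' @param config An [mcmc_config()].
#' @return `(n_iter - n_burnin) / thin`, truncated to integer.
#' @export
retained_per_chain <- function(config) {
  (config$n_iter - config$n_burnin) %/% config$thin
}

param_names <- function(species_form, habitat_form) {
  gs <- if (species_form == "whale_like") "lambda_s" else c("mu_s", "sigma_s")
  hab <- switch(habitat_form,
                poly2 = c("omega0", "omega1", "omega2"),
                poly3 = c("theta0", "theta1", "theta2", "theta3"),
                average = c("omega0", "omega1", "omega2",
                            "theta0", "theta1", "theta2", "theta3",
                            "vartheta"))
  c("alpha0", "alpha1", "alpha2", "sigma_eps0", "sigma_eps1", "sigma_eps2",
    "g0", gs, hab)
}

initial_values <- function(cells, sightings, species_form, habitat_form,
                           g0p, scaled_adt) {
  whale <- species_form == "whale_like"
  sig_hat <- sqrt(mean(sightings$distance_km^2))
  if (sig_hat <= 0) sig_hat <- 0.5
  a0 <- log(esw_from_sigma(sig_hat))
  gs <- if (whale) {
    max(1.01, mean(sightings$group_size))
  } else {
    c(mean(log(sightings$group_size)),
      max(0.1, stats::sd(log(sightings$group_size))))
  }
  ms <- if (whale) gs[1] else exp(gs[1] + gs[2]^2 / 2)
  wbar <- exp(a0)
  om0 <- log(max(sum(cells$n_groups), 0.5) * ms /
               sum(2 * wbar * cells$effort_km * g0p$mean))
  hab <- switch(habitat_form,
                poly2 = c(om0, 0, 0),
                poly3 = c(om0, 0, 0, 0),
                average = c(om0, 0, 0, om0, 0, 0, 0, 0.5))
  c(a0, 0, 0, 0.2, 0.2, 0.2, g0p$mean, gs, hab)
}

proposal_sd_init <- function(species_form, habitat_form) {
  gs <- if (species_form == "whale_like") 0.1 else c(0.1, 0.05)
  hab <- switch(habitat_form,
                poly2 = c(0.1, 0.5, 2),
                poly3 = c(0.1, 0.5, 2, 5),
                average = c(0.1, 0.5, 2, 0.1, 0.5, 2, 5, 0.1))
  c(0.05, 0.02, 0.02, 0.05, 0.05, 0.05, 0.01, gs, hab)
}

#' Fit the hierarchical Bayesian ADT-density model
#'
#' Fits the joint model of the observational process (half-normal
#' perpendicular distances with a log-linear effective strip half-width in
#' Beaufort and group size; Poisson or log-normal group sizes; Poisson
#' group counts per cell corrected by the trackline detection probability
#' g(0) with its informative Beta prior) and the ecological process
#' (population density as a log-polynomial function of rescaled ADT), by
#' adaptive Metropolis-within-Gibbs MCMC.
#'
#' Priors are non-informative except for g(0): Normal(0, 100^2) on all
#' regression coefficients and on \eqn{\mu_{(s)}}, Uniform(0, 10) on
#' residual SDs and \eqn{\sigma_{(s)}}, Uniform(0, 1000) on
#' \eqn{\lambda_{(s)}}, Uniform(0, 1) on the mixing weight
#' \eqn{\vartheta}, and the moment-matched Beta prior of [g0_prior()] on
#' g(0).
#'
#' @param cells Model-ready cell table (see [build_cells()]): columns
#'   `effort_km` (> 0), `beaufort`, `n_groups`, `adt`.
#' @param sightings Sightings table: columns `distance_km`, `group_size`,
#'   `beaufort`; must be non-empty.
#' @param species_form `"whale_like"` or `"dolphin_like"`.
#' @param habitat_form `"poly2"`, `"poly3"` or `"average"`.
#' @param g0_mean,g0_cv Mean and CV of the Beta prior on g(0); defaults are
#'   the published double-observer values for the species form (blue whale
#'   0.921/0.023, short-beaked common dolphin 0.970/0.017).
#' @param config An [mcmc_config()].
#' @param reference_mean ADT centring constant (cm); default is the
#'   effort-weighted mean ADT of `cells`, stored with the fit.
#' @param truncation Optional right-truncation distance (km): sightings
#'   beyond it are discarded and the half-normal likelihood renormalised.
#' @param discrepancy Discrepancy for the posterior predictive check:
#'   `"freeman_tukey"` (sum of squared differences of square roots) or
#'   `"squared"` (raw sums of squares).
#' @param zero_truncated_sizes Whale-like form only: fit group sizes with a
#'   zero-truncated Poisson (default `TRUE`), matching the fact that groups
#'   are only recorded when at least one individual is present.  `FALSE`
#'   uses the plain Poisson likelihood, which is upward-biased for
#'   \eqn{\lambda_{(s)}} on size->=1 data (by about 20% at
#'   \eqn{\lambda \approx 1.8}).
#' @param verbose Print chain progress.
#' @return Object of class `"cetadens"`; see [summary.cetadens()],
#'   [predict.cetadens()], [bayesian_pvalue()], [dic()].
#' @export
cetadens <- function(cells, sightings,
                     species_form = c("whale_like", "dolphin_like"),
                     habitat_form = c("poly2", "poly3", "average"),
                     g0_mean = NULL, g0_cv = NULL,
                     config = mcmc_config(),
                     reference_mean = NULL,
                     truncation = NULL,
                     discrepancy = c("freeman_tukey", "squared"),
                     zero_truncated_sizes = TRUE,
                     verbose = FALSE) {
  species_form <- match.arg(species_form)
  habitat_form <- match.arg(habitat_form)
  discrepancy <- match.arg(discrepancy)
  stopifnot(inherits(config, "mcmc_config"))
  whale <- species_form == "whale_like"

  need_c <- c("effort_km", "beaufort", "n_groups", "adt")
  if (!all(need_c %in% names(cells))) {
    stop("cells must have columns: ", paste(need_c, collapse = ", "))
  }
  cells <- cells[cells$effort_km > 0, , drop = FALSE]
  if (nrow(cells) == 0) stop("no cells with positive effort")
  if (any(!is.finite(cells$adt))) stop("cells have missing ADT values")
  need_s <- c("distance_km", "group_size", "beaufort")
  if (!all(need_s %in% names(sightings))) {
    stop("sightings must have columns: ", paste(need_s, collapse = ", "))
  }
  if (!is.null(truncation)) {
    sightings <- sightings[sightings$distance_km <= truncation, ,
                           drop = FALSE]
  }
  if (nrow(sightings) == 0) stop("sightings table is empty")
  if (whale && any(sightings$group_size != round(sightings$group_size))) {
    stop("whale-like group sizes must be integers")
  }

  if (is.null(g0_mean)) g0_mean <- if (whale) 0.921 else 0.970
  if (is.null(g0_cv)) g0_cv <- if (whale) 0.023 else 0.017
  g0p <- g0_prior(g0_mean, g0_cv)

  if (is.null(reference_mean)) {
    reference_mean <- stats::weighted.mean(cells$adt, cells$effort_km)
  }
  a_sc <- rescale_adt(cells$adt, reference_mean)

  data <- list(L = as.numeric(cells$effort_km),
               B = as.numeric(cells$beaufort),
               A = as.numeric(a_sc),
               n = as.integer(cells$n_groups),
               x = as.numeric(sightings$distance_km),
               b = as.numeric(sightings$beaufort),
               scov = if (whale) as.numeric(sightings$group_size) else
                 log(as.numeric(sightings$group_size)),
               s = as.numeric(sightings$group_size))
  hform <- match(habitat_form, c("poly2", "poly3", "average")) - 1L
  pn <- param_names(species_form, habitat_form)
  init0 <- initial_values(cells, sightings, species_form, habitat_form,
                          g0p, a_sc)
  psd <- proposal_sd_init(species_form, habitat_form)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    jit <- stats::rnorm(length(init0), 0, 0.15)
    jit[c(4:6)] <- abs(jit[c(4:6)]) * 0.5        # keep SDs positive
    init <- init0 + jit
    init[4:6] <- pmin(pmax(init[4:6], 0.01), 5)
    init[7] <- min(max(init0[7] + stats::rnorm(1, 0, g0p$sd / 2), 0.01), 0.99)
    if (whale) init[8] <- max(0.05, init[8])
    if (!whale) init[9] <- min(max(init[9], 0.05), 5)
    if (habitat_form == "average") init[length(init)] <-
        min(max(init[length(init)], 0.05), 0.95)
    if (verbose) message("running chain ", ch)
    chains[[ch]] <- .run_chain(data, whale, whale && zero_truncated_sizes,
                               hform, g0p$a, g0p$b,
                               if (is.null(truncation)) -1 else truncation,
                               init, config$n_iter, config$n_burnin,
                               config$thin, psd, 0.2)
    colnames(chains[[ch]]$globals) <- pn
  }

  pooled <- do.call(rbind, lapply(chains, `[[`, "globals"))
  lambda <- do.call(rbind, lapply(chains, `[[`, "lambda"))
  deviance <- unlist(lapply(chains, `[[`, "deviance"))

  rhat <- if (config$n_chains >= 2) {
    vapply(seq_along(pn), function(k) {
      gelman_rubin(lapply(chains, function(c) c$globals[, k]))
    }, numeric(1))
  } else {
    rep(NA_real_, length(pn))
  }
  names(rhat) <- pn
  mce <- vapply(seq_along(pn), function(k) mc_error(pooled[, k]), numeric(1))
  names(mce) <- pn

  fit <- structure(list(
    chains = chains, draws = pooled, lambda = lambda, deviance = deviance,
    param_names = pn, species_form = species_form,
    habitat_form = habitat_form, g0_prior = g0p,
    reference_mean = reference_mean, cells = cells, sightings = sightings,
    data = data, config = config, truncation = truncation,
    discrepancy = discrepancy,
    zero_truncated_sizes = whale && zero_truncated_sizes,
    diagnostics = list(rhat = rhat, mc_error = mce),
    converged = all(is.na(rhat) | rhat <= 1.1),
    call = match.call()), class = "cetadens")
  fit$dic <- dic(fit)
  fit$pvalue <- bayesian_pvalue(fit, seed = config$seed)
  if (!fit$converged) {
    warning("possible non-convergence: max R-hat = ",
            round(max(rhat, na.rm = TRUE), 3))
  }
  fit
}

#' Pooled posterior draws of the global parameters
#'
#' @param fit A fitted [cetadens()] model.
#' @return Matrix, retained draws (all chains) x parameters.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "cetadens"))
  fit$draws
}

#' @export
print.cetadens <- function(x, ...) {
  cat("Hierarchical Bayesian ADT-density model (", x$species_form, ", ",
      x$habitat_form, ")\n", sep = "")
  cat(sprintf("  %d cells, %d sightings, %d chains x %d retained draws\n",
              nrow(x$cells), nrow(x$sightings), x$config$n_chains,
              retained_per_chain(x$config)))
  cat(sprintf("  DIC %.1f (pD %.1f), Bayesian p-value %.3f, max R-hat %.3f\n",
              x$dic["DIC"], x$dic["pD"], x$pvalue,
              max(x$diagnostics$rhat, na.rm = TRUE)))
  cat("Posterior means:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' Posterior summary table
#'
#' Mean, SD, 2.5%, median and 97.5% quantiles, Monte Carlo error and
#' Gelman-Rubin R-hat for every global parameter.
#'
#' @param object A fitted [cetadens()] model.
#' @param ... Unused.
#' @return Object of class `"summary.cetadens"` with element `table`.
#' @export
summary.cetadens <- function(object, ...) {
  d <- object$draws
  tab <- data.frame(
    mean = colMeans(d),
    sd = apply(d, 2, stats::sd),
    `q2.5` = apply(d, 2, stats::quantile, 0.025),
    median = apply(d, 2, stats::median),
    `q97.5` = apply(d, 2, stats::quantile, 0.975),
    mc_error = object$diagnostics$mc_error,
    rhat = object$diagnostics$rhat,
    check.names = FALSE)
  rownames(tab) <- object$param_names
  structure(list(table = tab, species_form = object$species_form,
                 habitat_form = object$habitat_form, dic = object$dic,
                 pvalue = object$pvalue), class = "summary.cetadens")
}

#' @export
print.summary.cetadens <- function(x, digits = 4, ...) {
  cat("Posterior parameter statistics (", x$species_form, ", ",
      x$habitat_form, ")\n", sep = "")
  print(round(x$table, digits))
  cat(sprintf("DIC %.1f (pD %.1f), Bayesian p-value %.4f\n",
              x$dic["DIC"], x$dic["pD"], x$pvalue))
  invisible(x)
}

#' @export
coef.cetadens <- function(object, ...) {
  colMeans(object$draws)
}

#' Pearson residuals of the group-count model
#'
#' \eqn{(n_i - \bar\lambda_i)/\sqrt{\bar\lambda_i}} with
#' \eqn{\bar\lambda_i} the posterior mean expected count per cell.
#'
#' @param object A fitted [cetadens()] model.
#' @param ... Unused.
#' @return Numeric vector, one residual per cell.
#' @export
residuals.cetadens <- function(object, ...) {
  lam <- colMeans(object$lambda)
  (object$data$n - lam) / sqrt(pmax(lam, 1e-12))
}

#' Posterior predictive replicated group counts
#'
#' Draws replicated per-cell group counts \eqn{n^{rep}_i \sim
#' Pois(\lambda_i^{(m)})} for randomly selected retained posterior draws.
#'
#' @param object A fitted [cetadens()] model.
#' @param nsim Number of replicated datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Integer matrix, cells x `nsim`.
#' @export
simulate.cetadens <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    m <- sample(nrow(object$lambda), nsim, replace = nsim > nrow(object$lambda))
    vapply(m, function(k) stats::rpois(ncol(object$lambda),
                                       object$lambda[k, ]),
           integer(ncol(object$lambda)))
  })
}
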