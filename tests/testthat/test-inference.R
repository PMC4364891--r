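test_that("the default MCMC protocol retains 800 draws per chain", {
  cfg <- mcmc_config()
  expect_equal(cfg$n_iter, 10000L)
  expect_equal(cfg$n_burnin, 2000L)
  expect_equal(cfg$thin, 10L)
  expect_equal(cfg$n_chains, 3L)
  expect_equal(retained_per_chain(cfg), 800L)
  expect_equal(retained_per_chain(mcmc_config(3000, 1000, 4)), 500L)
  expect_error(mcmc_config(1000, 2000), "n_burnin")
  expect_error(mcmc_config(thin = 0), "thin")
})

test_that("Gelman-Rubin statistic separates mixed from unmixed chains", {
  set.seed(51)
  x <- rnorm(5000)
  # identical chains: exactly 1
  # classic estimator gives sqrt((n-1)/n) for identical chains
  expect_equal(gelman_rubin(list(x, x, x)), 1, tolerance = 1e-3)
  # chains from the same distribution: close to 1
  same <- lapply(1:3, function(k) rnorm(10000))
  expect_lt(gelman_rubin(same), 1.01)
  # disjoint supports: far above 1
  apart <- list(rnorm(1000), rnorm(1000) + 50)
  expect_gt(gelman_rubin(apart), 10)
  # invariant under chain order
  expect_equal(gelman_rubin(same), gelman_rubin(rev(same)))
  expect_error(gelman_rubin(list(x)), "2 chains")
})

test_that("batch-means MC error follows the root-n law", {
  expect_equal(mc_error(rep(3.7, 1000)), 0)
  set.seed(52)
  iid <- rnorm(10000, sd = 2)
  expect_equal(mc_error(iid), 2 / sqrt(10000), tolerance = 0.2)
  # never exceeds the posterior SD for stationary chains
  for (k in 1:5) {
    ar <- as.numeric(arima.sim(list(ar = 0.7), 2000))
    expect_lte(mc_error(ar), sd(ar))
  }
  expect_error(mc_error(rnorm(30)), "at least")
})

test_that("fitting returns the Table-1 summary layout with ordered quantiles", {
  fit <- whale_fit_small()
  tab <- summary(fit)$table
  expect_equal(colnames(tab),
               c("mean", "sd", "q2.5", "median", "q97.5", "mc_error",
                 "rhat"))
  expect_setequal(rownames(tab),
                  c("alpha0", "alpha1", "alpha2", "sigma_eps0",
                    "sigma_eps1", "sigma_eps2", "g0", "lambda_s",
                    "omega0", "omega1", "omega2"))
  expect_true(all(tab$`q2.5` <= tab$median & tab$median <= tab$`q97.5`))
  expect_true(all(tab$mc_error >= 0))
  expect_true(all(tab$rhat >= 1 - 1e-3))
  # retained sample accounting
  expect_equal(nrow(fit$chains[[1]]$globals),
               retained_per_chain(fit$config))
  expect_equal(nrow(fit$draws),
               retained_per_chain(fit$config) * fit$config$n_chains)
})

test_that("fits are deterministic given data, config and seed", {
  sim <- whale_sim()
  cfg <- mcmc_config(600, 200, 2, 2, seed = 77)
  f1 <- suppressWarnings(cetadens(sim$cells, sim$sightings, "whale_like",
                                  "poly2", config = cfg))
  f2 <- suppressWarnings(cetadens(sim$cells, sim$sightings, "whale_like",
                                  "poly2", config = cfg))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$pvalue, f2$pvalue)
})

test_that("compiled likelihood agrees with the R reference implementation", {
  fit <- whale_fit_small()
  ch <- fit$chains[[1]]
  for (m in c(1, 57, nrow(ch$globals))) {
    dev_r <- -2 * cetadens:::joint_loglik(fit, ch$globals[m, ],
                                          ch$eps0[m, ], ch$eps1[m, ],
                                          ch$eps2[m, ])
    expect_equal(ch$deviance[m], dev_r, tolerance = 1e-8)
  }
})

test_that("DIC collapses to the plug-in deviance for a degenerate posterior", {
  dfit <- degenerate_fit()
  d <- dic(dfit)
  expect_equal(unname(d["pD"]), 0, tolerance = 1e-8)
  expect_equal(unname(d["DIC"]), unname(d["Dbar"]), tolerance = 1e-8)
  expect_equal(unname(d["Dbar"]), dfit$deviance[1], tolerance = 1e-8)
})

test_that("Bayesian p-value splits ties and flags gross misfit", {
  # lambda identically zero with zero counts: all discrepancies tie at 0
  tie_fit <- structure(list(lambda = matrix(0, 200, 5),
                            data = list(n = rep(0L, 5)),
                            discrepancy = "freeman_tukey"),
                       class = "cetadens")
  expect_equal(bayesian_pvalue(tie_fit, seed = 1), 0.5)
  # overdispersed counts against tight Poisson rates: p near 0
  set.seed(53)
  n_obs <- rpois(60, 2) * c(rep(1, 50), rep(30, 10))
  bad_fit <- structure(list(lambda = matrix(2, 400, 60),
                            data = list(n = n_obs),
                            discrepancy = "freeman_tukey"),
                       class = "cetadens")
  expect_lt(bayesian_pvalue(bad_fit, seed = 2), 0.05)
  # both discrepancy forms are available and bounded
  fit <- whale_fit_small()
  for (d in c("freeman_tukey", "squared")) {
    p <- bayesian_pvalue(fit, discrepancy = d, seed = 3)
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
})

test_that("posterior predictive simulation returns count replicates", {
  fit <- whale_fit_small()
  reps <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(reps), c(nrow(fit$cells), 3))
  expect_true(all(reps >= 0))
  expect_true(all(reps == floor(reps)))
  # Pearson residuals: one per cell, centred near zero for a correct model
  r <- residuals(fit)
  expect_equal(length(r), nrow(fit$cells))
  expect_lt(abs(mean(r)), 0.5)
})

test_that("fit validates its inputs", {
  sim <- whale_sim()
  expect_error(cetadens(sim$cells[0, ], sim$sightings, "whale_like"),
               "positive effort")
  expect_error(cetadens(sim$cells, sim$sightings[0, ], "whale_like"),
               "empty")
  bad <- sim$cells
  bad$adt <- NA
  expect_error(cetadens(bad, sim$sightings, "whale_like"), "ADT")
})
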