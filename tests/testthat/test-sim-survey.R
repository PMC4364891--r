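test_that("simulated effort totals the configured kilometres exactly", {
  sim <- whale_sim()
  cfg <- sim$config
  expect_equal(sum(sim$segments$length_km), cfg$effort_km_total,
               tolerance = 1e-9)
  expect_equal(sum(sim$cells$effort_km), cfg$effort_km_total,
               tolerance = 1e-6)
  # reproducible end to end
  sim2 <- simulate_survey(cfg, simulate_adt_field(cfg))
  expect_identical(sim2$sightings, sim$sightings)
  expect_identical(sim2$cells$n_groups, sim$cells$n_groups)
})

test_that("latent truth is internally consistent with the generative model", {
  sim <- whale_sim()
  cfg <- sim$config
  # per-cell Poisson mean recomputes exactly from the stored latents
  w_i <- esw_cell(cfg$true_detection, sim$cells$beaufort,
                  cfg$true_groupsize$lambda_s, "whale_like",
                  eps1 = sim$truth$eps1)
  d_i <- density_poly2(cfg$true_habitat$omega,
                       rescale_adt(sim$cells$adt, sim$reference_mean),
                       eps2 = sim$truth$eps2)
  lam <- expected_group_count(w_i, sim$cells$effort_km, d_i, cfg$true_g0,
                              cfg$true_groupsize$lambda_s)
  expect_equal(lam, sim$truth$lambda, tolerance = 1e-12)
  # counts match the sighting table cell by cell
  tab <- table(factor(sim$sightings$cell_id, levels = sim$cells$cell_id))
  expect_equal(as.integer(tab), sim$cells$n_groups)
  # sighting-level ESW truths recompute from covariates and residuals
  expect_equal(sim$sightings$true_sigma,
               sigma_from_esw(sim$sightings$true_w), tolerance = 1e-12)
})

test_that("zero density and zero effort degenerate gracefully", {
  cfg0 <- sim_config("whale_like", seed = 11, effort_km_total = 600,
                     true_habitat = habitat_params(
                       omega = c(-60, 0, 0), sigma_eps2 = 0))
  sim0 <- simulate_survey(cfg0, simulate_adt_field(cfg0))
  expect_equal(nrow(sim0$sightings), 0)
  expect_true(all(sim0$cells$n_groups == 0))
  cfg00 <- sim_config("whale_like", seed = 11, effort_km_total = 0)
  sim00 <- simulate_survey(cfg00, simulate_adt_field(cfg00))
  expect_equal(nrow(sim00$sightings), 0)
})

test_that("doubling effort doubles the mean sighting count", {
  # oracle: the expected count is linear in transect length
  n1 <- n2 <- numeric(120)
  for (r in 1:120) {
    c1 <- sim_config("whale_like", seed = 3000 + r, effort_km_total = 300,
                     grid_extent = c(0, 2, 0, 2), n_weeks = 2)
    c2 <- sim_config("whale_like", seed = 3000 + r, effort_km_total = 600,
                     grid_extent = c(0, 2, 0, 2), n_weeks = 2)
    f <- simulate_adt_field(c1)   # same field for both efforts
    n1[r] <- nrow(simulate_survey(c1, f)$sightings)
    n2[r] <- nrow(simulate_survey(c2, f, seed = 9000 + r)$sightings)
  }
  se <- sqrt(var(n2) + 4 * var(n1)) / sqrt(120)
  expect_lt(abs(mean(n2) - 2 * mean(n1)), 3 * se)
})

test_that("perpendicular distances follow the half-normal law", {
  # constant sigma: flat detection model, no residual
  cfg <- sim_config(
    "whale_like", seed = 31, effort_km_total = 4400,
    true_detection = detection_params(1.1, 0, 0, sigma_eps0 = 0,
                                      sigma_eps1 = 0),
    true_habitat = habitat_params(omega = c(-1.3, 0, 0), sigma_eps2 = 0))
  pass <- 0
  for (s in 1:4) {
    cfg$seed <- 30 + s
    sim <- simulate_survey(cfg, simulate_adt_field(cfg))
    x <- sim$sightings$distance_km
    expect_gt(length(x), 3000)
    sigma <- sigma_from_esw(exp(1.1))
    ks <- suppressWarnings(ks.test(x, function(q) 2 * pnorm(q, 0, sigma) - 1))
    if (ks$p.value > 0.01) pass <- pass + 1
  }
  expect_gte(pass, 3)
})

test_that("whale group sizes follow the zero-truncated Poisson law", {
  cfg <- sim_config(
    "whale_like", seed = 33, effort_km_total = 4400,
    true_habitat = habitat_params(omega = c(-1.3, 0, 0), sigma_eps2 = 0))
  sim <- simulate_survey(cfg, simulate_adt_field(cfg))
  s <- sim$sightings$group_size
  expect_gt(length(s), 3000)
  expect_true(all(s >= 1))
  lam <- 1.802
  zt_mean <- lam / (1 - exp(-lam))
  expect_lt(abs(mean(s) - zt_mean), 3 * sd(s) / sqrt(length(s)))
})

test_that("dolphin group sizes are log-normal with the configured mean", {
  cfg <- sim_config(
    "dolphin_like", seed = 34, effort_km_total = 4400,
    true_habitat = habitat_params(omega = c(2.5, 0, 0), sigma_eps2 = 0))
  sim <- simulate_survey(cfg, simulate_adt_field(cfg))
  s <- sim$sightings$group_size
  expect_gt(length(s), 1000)
  gs <- cfg$true_groupsize
  expect_lt(abs(mean(log(s)) - gs$mu_s), 3 * gs$sigma_s / sqrt(length(s)))
  target <- mean_group_size(gs$mu_s, gs$sigma_s)
  expect_lt(abs(mean(s) - target), 3 * sd(s) / sqrt(length(s)))
})
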