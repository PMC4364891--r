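test_that("half-normal scale and ESW are linked by sigma = w*sqrt(2/pi)", {
  expect_equal(sigma_from_esw(1), 0.7978845608, tolerance = 1e-9)
  # oracle: the ESW is the integral of the detection function
  for (w in c(0.5, 1, 2.7, 6)) {
    s <- sigma_from_esw(w)
    integral <- integrate(function(x) exp(-x^2 / (2 * s^2)), 0, Inf)$value
    expect_equal(integral, w, tolerance = 1e-6)
  }
  expect_equal(sigma_from_esw(2), 2 * sigma_from_esw(1))     # linearity
  w <- c(0.3, 1, 3.1, 8)
  expect_equal(esw_from_sigma(sigma_from_esw(w)), w, tolerance = 1e-12)
  expect_error(sigma_from_esw(0), "positive")
  expect_error(esw_from_sigma(-1), "positive")
})

test_that("sighting-level ESW evaluates the log-linear model per species form", {
  p0 <- detection_params(0, 0, 0)
  expect_equal(esw_sighting(p0, 4, 17, "whale_like"), 1)
  expect_equal(esw_sighting(p0, 1, 300, "dolphin_like"), 1)
  # blue whale posterior-mean coefficients, b = 3, s = 2
  pw <- detection_params(1.111, -0.008098, 0.02194)
  expect_equal(esw_sighting(pw, 3, 2, "whale_like"), 3.0974711,
               tolerance = 1e-6)
  # dolphin posterior-mean coefficients, b = 2, s = 100 (log covariate)
  pd <- detection_params(0.1720, -0.1554, 0.2740)
  expect_equal(esw_sighting(pd, 2, 100, "dolphin_like"), 3.0741137,
               tolerance = 1e-6)
  # residual acts on the log scale
  expect_equal(esw_sighting(pw, 3, 2, "whale_like", eps0 = 0.5),
               3.0974711 * exp(0.5), tolerance = 1e-6)
  expect_error(esw_sighting(pw, 3, 0.5, "whale_like"), ">= 1")
  expect_error(esw_sighting(pw, 3, 2, "orca_like"), "form")
})

test_that("cell-level ESW matches the sighting model on shared covariates", {
  pw <- detection_params(1.111, -0.008098, 0.02194)
  expect_equal(esw_cell(pw, 4, 1.802, "whale_like"), 3.0591707,
               tolerance = 1e-6)
  expect_equal(esw_cell(detection_params(0, 0, 0), 2, 5, "dolphin_like"), 1)
  # same formula as the sighting level when covariates coincide
  for (b in 0:5) {
    expect_equal(esw_cell(pw, b, 3, "whale_like", eps1 = 0.2),
                 esw_sighting(pw, b, 3, "whale_like", eps0 = 0.2))
  }
})

test_that("ESW is monotone in Beaufort and group size with signed slopes", {
  p <- detection_params(1, -0.2, 0.1)
  w_b <- esw_sighting(p, 0:5, 2, "whale_like")
  expect_true(all(diff(w_b) < 0))
  w_s <- esw_sighting(p, 2, 1:30, "whale_like")
  expect_true(all(diff(w_s) > 0))
  w_s_d <- esw_sighting(p, 2, c(10, 50, 200, 500), "dolphin_like")
  expect_true(all(diff(w_s_d) > 0))
})

test_that("half-normal distance log-density is correct and normalised", {
  expect_equal(distance_loglik(0, 1), log(0.7978845608), tolerance = 1e-9)
  expect_equal(exp(distance_loglik(1, 1)), 0.7978845608 * exp(-0.5),
               tolerance = 1e-9)
  for (s in c(0.4, 1, 2.5)) {
    total <- integrate(function(x) exp(distance_loglik(x, s)), 0, Inf)$value
    expect_equal(total, 1, tolerance = 1e-7)
  }
  expect_error(distance_loglik(-0.1, 1), "non-negative")
  expect_error(distance_loglik(1, 0), "positive")
})

test_that("ESW equals the numeric integral of the implied detection function", {
  set.seed(71)
  p <- detection_params(0.8, -0.1, 0.05)
  for (k in 1:20) {
    b <- sample(0:5, 1)
    s <- sample(1:20, 1)
    e <- rnorm(1, 0, 0.3)
    w <- esw_sighting(p, b, s, "whale_like", eps0 = e)
    sig <- sigma_from_esw(w)
    expect_equal(integrate(function(x) exp(-x^2 / (2 * sig^2)), 0,
                           Inf)$value,
                 w, tolerance = 1e-6)
  }
})
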