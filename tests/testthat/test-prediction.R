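test_that("prediction surfaces have ordered quantiles and flag extrapolation", {
  fit <- whale_fit_small()
  adt <- seq(20, 120, by = 5)
  surf <- predict(fit, adt)
  expect_s3_class(surf, "density_surface")
  expect_true(all(surf$q025 <= surf$median & surf$median <= surf$q975))
  expect_true(all(surf$q025 >= 0))
  rng <- range(fit$cells$adt)
  expect_equal(surf$extrapolated, adt < rng[1] | adt > rng[2])
})

test_that("a degenerate posterior collapses the three quantile maps", {
  dfit <- degenerate_fit()
  surf <- predict(dfit, c(50, 60, 70))
  expect_equal(surf$q025, surf$median)
  expect_equal(surf$q975, surf$median)
})

test_that("constant rasters give constant surfaces; permutation equivariance", {
  fit <- whale_fit_small()
  const <- predict(fit, rep(65, 7))
  expect_equal(length(unique(const$median)), 1)
  adt <- c(45, 52, 60, 68, 75, 81)
  perm <- c(4, 1, 6, 2, 5, 3)
  s1 <- predict(fit, adt)
  s2 <- predict(fit, adt[perm])
  expect_equal(s2$median, s1$median[perm])
  expect_equal(s2$q975, s1$q975[perm])
})

test_that("the surface median peaks at the posterior-median optimum", {
  fit <- whale_fit_small()
  om <- apply(fit$draws[, c("omega0", "omega1", "omega2")], 2, median)
  opt <- optimum_adt(om, fit$reference_mean)
  grid <- sort(c(opt$optimum_cm, seq(35, 105, length.out = 60)))
  surf <- predict(fit, grid)
  at_opt <- surf$median[which(grid == opt$optimum_cm)]
  expect_true(all(at_opt >= surf$median - 1e-12))
})

test_that("residual-inclusive predictions widen the credible band", {
  fit <- whale_fit_small()
  narrow <- predict(fit, c(55, 65, 75))
  wide <- predict(fit, c(55, 65, 75), include_residual = TRUE, seed = 4)
  expect_true(all(wide$q975 - wide$q025 >= narrow$q975 - narrow$q025))
})

test_that("yearly ENSO surfaces annotate but never alter predictions", {
  fit <- whale_fit_small()
  raster <- data.frame(lon = c(-125, -124), lat = c(12, 12),
                       adt = c(55, 70))
  mei <- simulate_mei(1997:1999, seed = 6,
                      yearly_mean = c(2.1, -1.2, 0.1), monthly_sd = 0)
  surfs <- enso_yearly_surfaces(fit, list(`1997` = raster, `1998` = raster,
                                          `1999` = raster), mei)
  expect_equal(attr(surfs[["1997"]], "enso"), "El Nino")
  expect_equal(attr(surfs[["1998"]], "enso"), "La Nina")
  expect_equal(attr(surfs[["1999"]], "enso"), "neutral")
  # identical rasters -> identical surfaces regardless of ENSO state
  expect_equal(surfs[["1997"]]$median, surfs[["1998"]]$median)
  expect_equal(attr(surfs[["1997"]], "mei_jul_dec"), 2.1)
  # carried-through coordinates survive
  expect_equal(surfs[["1997"]]$lon, raster$lon)
  # missing MEI year: warning, label unknown, surface still produced
  expect_warning(s2 <- enso_yearly_surfaces(fit, list(`2005` = raster), mei),
                 "unknown")
  expect_equal(attr(s2[["2005"]], "enso"), "unknown")
  expect_equal(s2[["2005"]]$median, surfs[["1997"]]$median)
})

test_that("raising ADT uniformly above the optimum lowers density everywhere", {
  fit <- whale_fit_small()
  om <- apply(fit$draws[, c("omega0", "omega1", "omega2")], 2, median)
  opt <- optimum_adt(om, fit$reference_mean)
  base <- predict(fit, opt$optimum_cm + c(5, 10, 15))
  higher <- predict(fit, opt$optimum_cm + c(5, 10, 15) + 8)
  expect_true(all(higher$median < base$median))
})

test_that("the response plot runs and returns the prediction grid", {
  fit <- whale_fit_small()
  pdf(NULL)
  on.exit(dev.off())
  surf <- plot(fit, n_grid = 50)
  expect_s3_class(surf, "density_surface")
  expect_equal(nrow(surf), 50)
})
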