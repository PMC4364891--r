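test_that("effort inside one cell accumulates length and Beaufort verbatim", {
  g <- unit_grid()
  cells <- grid_effort(seg(0.05, 0.05, 0.30, 0.05, beaufort = 3,
                           length_km = 10), g)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$effort_km, 10)
  expect_equal(cells$beaufort, 3)
  expect_equal(cells$lon, 1 / 6)
  # two segments, one cell: effort-weighted Beaufort
  segs <- rbind(seg(0.05, 0.05, 0.30, 0.05, beaufort = 2, length_km = 10),
                seg(0.05, 0.10, 0.30, 0.10, beaufort = 4, length_km = 30))
  cells2 <- grid_effort(segs, g)
  expect_equal(nrow(cells2), 1)
  expect_equal(cells2$effort_km, 40)
  expect_equal(cells2$beaufort, 3.5)
})

test_that("effort is conserved and partitioned across cell boundaries", {
  g <- unit_grid()
  set.seed(21)
  segs <- do.call(rbind, lapply(1:40, function(k) {
    p <- runif(4, 0.01, 1.99)
    seg(p[1], p[2], p[3], p[4], beaufort = sample(0:5, 1))
  }))
  # lengths computed by haversine when not supplied
  total_in <- sum(haversine_km(segs$lon0, segs$lat0, segs$lon1, segs$lat1))
  cells <- grid_effort(segs, g)
  expect_equal(sum(cells$effort_km), total_in, tolerance = 1e-6)
  # with explicit lengths, conservation is exact
  segs$length_km <- runif(40, 1, 30)
  cells2 <- grid_effort(segs, g)
  expect_equal(sum(cells2$effort_km), sum(segs$length_km),
               tolerance = 1e-12)
  # zero-length segments contribute nothing
  segs0 <- segs
  segs0$length_km[1:5] <- 0
  cells3 <- grid_effort(segs0, g)
  expect_equal(sum(cells3$effort_km), sum(segs0$length_km),
               tolerance = 1e-12)
})

test_that("gridding is idempotent: re-gridding the pieces changes nothing", {
  g <- unit_grid()
  set.seed(22)
  segs <- do.call(rbind, lapply(1:20, function(k) {
    p <- runif(4, 0.01, 1.99)
    seg(p[1], p[2], p[3], p[4], beaufort = sample(0:5, 1))
  }))
  cells <- grid_effort(segs, g)
  pieces <- attr(cells, "pieces")
  cells2 <- grid_effort(pieces, g)
  expect_equal(cells2$cell_id, cells$cell_id)
  expect_equal(cells2$effort_km, cells$effort_km, tolerance = 1e-9)
  expect_equal(cells2$beaufort, cells$beaufort, tolerance = 1e-9)
})

test_that("sightings are assigned to exactly one cell, half-open convention", {
  g <- unit_grid()
  empty <- assign_sightings(data.frame(date = as.Date(character()),
                                       lon = numeric(), lat = numeric()), g)
  expect_equal(nrow(empty), 0)
  s3 <- data.frame(date = as.Date("2000-07-05"),
                   lon = c(0.1, 0.2, 0.3), lat = c(0.1, 0.2, 0.3))
  a <- assign_sightings(s3, g)
  expect_equal(unname(table(a$cell_id)[1]), 3L)
  # boundary points: lon = 1/3 belongs to the cell starting at 1/3
  b <- assign_sightings(data.frame(date = as.Date("2000-07-05"),
                                   lon = 1 / 3, lat = 0.1), g)
  expect_equal(b$cell_id, 1L)
  # every sighting maps to exactly one cell
  set.seed(23)
  many <- data.frame(date = as.Date("2000-07-05"),
                     lon = runif(500, 0, 1.999), lat = runif(500, 0, 1.999))
  am <- assign_sightings(many, g)
  expect_equal(nrow(am), 500)
  expect_true(all(am$cell_id >= 0 & am$cell_id < g$nx * g$ny))
  # outside the grid: excluded with a warning
  expect_warning(out <- assign_sightings(
    data.frame(date = as.Date("2000-07-05"), lon = c(0.1, 5), lat = 0.1), g),
    "outside")
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_excluded"), 1L)
})

test_that("weekly ADT is matched verbatim or effort-weighted across weeks", {
  g <- unit_grid()
  weeks <- as.Date(c("2000-07-03", "2000-07-10"))
  field <- constant_field(g, c(60, 80), weeks = weeks)
  # single week: verbatim
  c1 <- match_adt(grid_effort(seg(0.05, 0.05, 0.3, 0.05, 1,
                                  length_km = 10), g), field)
  expect_equal(c1$adt, 60)
  # 10 km in the 60-cm week + 30 km in the 80-cm week -> 75
  segs <- rbind(seg(0.05, 0.05, 0.3, 0.05, 1, 10, as.Date("2000-07-05")),
                seg(0.05, 0.1, 0.3, 0.1, 1, 30, as.Date("2000-07-12")))
  c2 <- match_adt(grid_effort(segs, g), field)
  expect_equal(c2$adt, 75)
  # constant field: every cell gets the constant
  set.seed(24)
  rnd <- do.call(rbind, lapply(1:10, function(k) {
    p <- runif(4, 0.01, 1.99)
    seg(p[1], p[2], p[3], p[4], 1)
  }))
  c3 <- match_adt(grid_effort(rnd, g), constant_field(g, 66))
  expect_equal(c3$adt, rep(66, nrow(c3)), tolerance = 1e-12)
  # no coverage for the survey date -> error naming cells
  late <- seg(0.05, 0.05, 0.3, 0.05, 1, 10, as.Date("2001-01-01"))
  expect_error(match_adt(grid_effort(late, g), field), "no ADT coverage")
})

test_that("build_cells assembles the model-ready table", {
  g <- unit_grid()
  segs <- rbind(seg(0.05, 0.05, 0.3, 0.05, 2, 10),
                seg(0.4, 0.4, 0.6, 0.4, 4, 20))
  sights <- data.frame(date = as.Date("2000-07-05"),
                       lon = c(0.1, 0.12, 0.5), lat = c(0.06, 0.06, 0.4))
  cells <- build_cells(segs, sights, g, constant_field(g, 70))
  expect_equal(sum(cells$n_groups), 3)
  expect_equal(cells$n_groups[cells$cell_id == 0], 2)
  expect_true(all(cells$adt == 70))
  # sum of counts equals number of in-grid sightings
  expect_equal(sum(cells$n_groups), nrow(sights))
})
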