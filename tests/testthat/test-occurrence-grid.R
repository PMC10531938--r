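test_that("hex assignment is a nearest-centre partition", {
  g <- hex_grid(spacing = 100, origin = c(0, 0))
  # neighbouring cell centres are exactly one spacing apart (across flats)
  ctr0 <- hex_center(g, 0, 0)
  ctr1 <- hex_center(g, 0, 1)
  expect_equal(sqrt(sum((ctr1 - ctr0)^2)), 100)

  # random points map to the nearest of the candidate centres
  set.seed(71)
  pts <- data.frame(x = runif(300, -400, 400), y = runif(300, -400, 400))
  cells <- hex_cell_of(g, pts$x, pts$y)
  cand <- expand.grid(q = -8:8, r = -8:8)
  cc <- hex_center(g, cand$q, cand$r)
  for (i in sample(300, 40)) {
    d2 <- (cc[, "x"] - pts$x[i])^2 + (cc[, "y"] - pts$y[i])^2
    j <- which.min(d2)
    expect_equal(c(cells$q[i], cells$r[i]), c(cand$q[j], cand$r[j]),
                 ignore_attr = TRUE)
  }
})

test_that("occurrence aggregation counts records, years and decades per cell", {
  g <- hex_grid(spacing = 1000)
  one <- data.frame(x = 10, y = 20, date = "2001-07-01")
  agg1 <- hex_aggregate_occurrences(one, g)
  expect_identical(nrow(agg1), 1L)
  expect_identical(agg1$n_obs, 1L)

  # years {1990, 1991, 2001} in one cell: 3 years, 2 decades
  occ <- data.frame(x = c(1, 2, 3), y = c(1, 2, 3),
                    date = c("1990-06-01", "1991-07-02", "2001-08-03"))
  agg <- hex_aggregate_occurrences(occ, g)
  expect_identical(agg$n_years, 3L)
  expect_identical(agg$n_decades, 2L)

  # conservation + partition over many cells
  set.seed(72)
  occ2 <- data.frame(x = runif(500, 0, 8000), y = runif(500, 0, 8000),
                     date = sample(1970:2019, 500, replace = TRUE))
  agg2 <- hex_aggregate_occurrences(occ2, g)
  expect_identical(sum(agg2$n_obs), 500L)
  expect_true(all(agg2$n_decades <= agg2$n_years))
  expect_true(all(agg2$n_years <= agg2$n_obs))

  # bad dates are rejected, not silently dropped
  occ3 <- data.frame(x = 1:3, y = 1:3, date = c("1990-01-01", "nope", "2000-01-01"))
  expect_message(agg3 <- hex_aggregate_occurrences(occ3, g), "rejected")
  expect_identical(sum(agg3$n_obs), 2L)
  expect_identical(attr(agg3, "n_rejected"), 1L)

  occ_crs <- occ
  attr(occ_crs, "crs") <- "epsg:4326"
  expect_error(hex_aggregate_occurrences(occ_crs, g), "CRS mismatch")
})

test_that("occurrence edge distances look up the containing pixel", {
  g <- rbind(c(0, 1, 1, 1),
             c(0, 1, 1, 1),
             c(0, 1, 1, 1))
  r <- habitat_raster(g, res = 10)
  d <- signed_edge_distance(r)
  # point on the matrix pixel next to habitat: +10 m
  expect_equal(occurrence_edge_distances(data.frame(x = 5, y = 15), d)[1], 10,
               ignore_attr = TRUE)
  # point in the deepest habitat column: -30 m
  expect_equal(occurrence_edge_distances(data.frame(x = 35, y = 15), d)[1], -30,
               ignore_attr = TRUE)

  # seeded points agree with a per-point oracle lookup
  set.seed(73)
  gg <- random_grid(25, 25, p = 0.4, seed = 73)
  rr <- habitat_raster(gg, res = 10)
  dd <- signed_edge_distance(rr)
  od <- oracle_signed_distance(gg, 10)
  pts <- data.frame(x = runif(50, 0, 250), y = runif(50, 0, 250))
  got <- occurrence_edge_distances(pts, dd)
  rc <- funhab:::raster_rowcol(dd, pts$x, pts$y)
  expect_equal(as.numeric(got), od[rc], tolerance = 1e-12)

  # all points outside -> empty with a warning
  far <- data.frame(x = 1e6, y = 1e6)
  expect_warning(empty <- occurrence_edge_distances(far, dd), "outside")
  expect_length(empty, 0)
})

test_that("Welch comparison matches the textbook formulas", {
  a <- c(1, 2, 3, 4, 5)
  cmp0 <- compare_distance_distributions(a, a)
  expect_equal(cmp0$t, 0)
  expect_equal(cmp0$p, 1)

  set.seed(74)
  x <- rnorm(40, -30, 100)
  y <- rnorm(60, 50, 150)
  cmp <- compare_distance_distributions(x, y)
  orc <- oracle_welch(x, y)
  expect_equal(cmp$t, orc$t, tolerance = 1e-12)
  expect_equal(cmp$df, orc$df, tolerance = 1e-12)
  expect_equal(cmp$p, orc$p, tolerance = 1e-12)
  # antisymmetry
  rev <- compare_distance_distributions(y, x)
  expect_equal(rev$t, -cmp$t)
  expect_equal(rev$p, cmp$p)

  expect_error(compare_distance_distributions(c(1, 1), c(2, 2)), "degenerate")
  expect_error(compare_distance_distributions(1, c(1, 2)), "at least 2")
})

test_that("interquartile interval uses the linear-interpolation convention", {
  expect_equal(interquartile_interval(1:100), c(25.75, 75.25))
  expect_equal(interquartile_interval(rep(7, 10)), c(7, 7))
  expect_error(interquartile_interval(1:3), "at least 4")
})

test_that("cell ranking screens by occurrence record and picks FC extremes", {
  cells <- data.frame(
    cell = c("a", "b", "c", "d", "e"),
    n_obs = c(90, 90, 50, 40, 10),
    n_years = c(5, 9, 3, 2, 1),
    n_decades = c(2, 3, 2, 1, 1),
    fc_mean = c(4, 12, 0.5, 7, 99))
  rk <- rank_sampling_cells(cells, top_k = 3)
  # rank order: b (90 obs, 3 decades), a, c; e never screened despite fc 99
  expect_identical(rk$top$cell, c("b", "a", "c"))
  expect_identical(rk$lowest$cell, "c")
  expect_identical(rk$highest$cell, "b")

  # invariant to input ordering
  rk2 <- rank_sampling_cells(cells[sample(5), ], top_k = 3)
  expect_identical(rk2$lowest$cell, rk$lowest$cell)
  expect_identical(rk2$highest$cell, rk$highest$cell)

  two <- cells[1:2, ]
  rk3 <- rank_sampling_cells(two, top_k = 5)
  expect_setequal(c(rk3$lowest$cell, rk3$highest$cell), c("a", "b"))

  flat <- cells
  flat$fc_mean <- 1
  expect_warning(rank_sampling_cells(flat, top_k = 3), "equal mean connectivity")
  expect_error(rank_sampling_cells(cells, top_k = 1), "at least 2")
})

test_that("random survey points respect the spacing constraint and the seed", {
  g <- matrix(1L, 30, 30)
  region <- habitat_raster(g, res = 10)  # 300 x 300 m of habitat
  pts <- random_survey_points(region, n = 5, min_dist = 60, seed = 75)
  expect_identical(nrow(pts), 5L)
  dm <- as.matrix(dist(pts))
  expect_true(all(dm[upper.tri(dm)] >= 60))

  # bit-identical under the same seed
  pts2 <- random_survey_points(region, n = 5, min_dist = 60, seed = 75)
  expect_identical(pts, pts2)

  # single point always fits; two points cannot fit in one pixel at 200 m
  tiny <- habitat_raster(matrix(1L, 1, 1), res = 10)
  expect_identical(nrow(random_survey_points(tiny, n = 1, seed = 1)), 1L)
  expect_error(random_survey_points(tiny, n = 2, min_dist = 200, seed = 1,
                                    max_iter = 50), "achieved 1")
})
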