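test_that("matrix-edge-core classification matches its definition", {
  # all-habitat 3x3: erosion with depth 1 leaves only the centre as core
  r <- habitat_raster(matrix(1, 3, 3))
  mac <- classify_mac(r, edge_depth_px = 1)
  expect_identical(sum(as.matrix(mac) == 2L), 1L)
  expect_identical(sum(as.matrix(mac) == 1L), 8L)
  expect_identical(as.matrix(mac)[2, 2], 2L)

  expect_error(classify_mac(r, edge_depth_px = 0), "positive integer")
  expect_error(classify_mac(funhab:::fh_raster(matrix(1, 2, 2), res = 10),
                            edge_depth_px = 1), "habitat_raster")
})

test_that("classification agrees with the brute-force erosion oracle", {
  for (seed in c(11, 12, 13)) {
    g <- random_grid(50, 50, p = 0.55, seed = seed)
    r <- habitat_raster(g)
    for (k in c(1, 3)) {
      mac <- as.matrix(classify_mac(r, edge_depth_px = k))
      core <- oracle_core(g, k)
      expect_identical(mac == 2L, core)
      expect_identical(mac >= 1L, g == 1)                 # edge+core = habitat
      expect_identical(sum(mac == 0L) + sum(mac == 1L) + sum(mac == 2L),
                       length(g))                          # MAC partition
    }
  }
})

test_that("NoData propagates and blocks core status of its neighbours", {
  g <- matrix(1L, 5, 5)
  g[3, 3] <- NA
  mac <- as.matrix(classify_mac(habitat_raster(g), edge_depth_px = 1))
  expect_true(is.na(mac[3, 3]))
  expect_true(all(mac[!is.na(mac)] == 1L))  # no pixel has a fully known nbhd
})

test_that("signed edge distance has the right sign and magnitude", {
  r <- habitat_raster(rbind(c(0, 1, 1), c(0, 1, 1)))
  d <- as.matrix(signed_edge_distance(r))
  expect_equal(d[1, 1], 10)    # matrix pixel adjacent to habitat
  expect_equal(d[1, 2], -10)   # habitat pixel adjacent to matrix
  expect_equal(d[1, 3], -20)
  expect_error(signed_edge_distance(habitat_raster(matrix(1, 3, 3))),
               "edge undefined")
})

test_that("signed edge distance equals the all-pairs brute-force scan", {
  for (seed in c(21, 22)) {
    g <- random_grid(40, 40, p = 0.35, seed = seed)
    g[seed %% 7 + 1, 5] <- NA  # some NoData
    d <- as.matrix(signed_edge_distance(habitat_raster(g)))
    expect_equal(d, oracle_signed_distance(g, 10), tolerance = 1e-12)
  }
})

test_that("the functional-habitat band is a closed signed-distance interval", {
  g <- random_grid(30, 30, p = 0.4, seed = 31)
  r <- habitat_raster(g)
  d <- as.matrix(signed_edge_distance(r))

  # interval [-Inf, 0]: all habitat, no matrix (all distances are nonzero)
  efe_all <- as.matrix(extract_efe(r, c(-Inf, 0)))
  expect_identical(efe_all == 1L, g == 1)

  efe <- as.matrix(extract_efe(r, c(-86, 11)))
  expect_identical(efe == 1L, d >= -86 & d <= 11)
  # at 10 m resolution the (-86, 11) band admits interior distances down to
  # -80 m and the +10 m first matrix ring
  expect_true(all(d[efe == 1L] >= -86 & d[efe == 1L] <= 11))
  expect_error(extract_efe(r, c(5, -5)), "inverted")
})

test_that("functional connectivity assigns each cluster its total area", {
  # one 10x10 patch at 10 m resolution = 1.0 ha everywhere on the patch
  g <- matrix(0L, 20, 20)
  g[6:15, 6:15] <- 1L
  efe <- habitat_raster(g)
  fc <- functional_connectivity(efe, crossing_dist = 500)
  expect_equal(unique(as.matrix(fc)[g == 1L]), 1.0)
  expect_true(all(as.matrix(fc)[g == 0L] == 0))

  # two 1.0 ha patches, gap 300 m: merged at 500 m crossing, apart at 200 m
  g2 <- matrix(0L, 10, 70)
  g2[1:10, 1:10] <- 1L
  g2[1:10, 41:50] <- 1L   # centre gap = 31 px = 310 m; edge gap 300 m
  efe2 <- habitat_raster(g2)
  expect_equal(unique(as.matrix(functional_connectivity(efe2, 500))[g2 == 1L]), 2.0)
  expect_equal(unique(as.matrix(functional_connectivity(efe2, 200))[g2 == 1L]), 1.0)

  # crossing 0: each patch keeps its own area
  fc0 <- functional_connectivity(efe2, 0)
  expect_equal(unique(as.matrix(fc0)[g2 == 1L]), 1.0)

  expect_warning(fc_empty <- functional_connectivity(
    habitat_raster(matrix(0L, 5, 5)), 500), "empty")
  expect_true(all(as.matrix(fc_empty) == 0))
})

test_that("gap-crossing clustering matches the patch-graph oracle", {
  crossing <- 100
  res <- 10
  n_checked <- 0
  seed <- 0
  while (n_checked < 8 && seed < 60) {
    seed <- seed + 1
    g <- as.matrix(generate_landscape(50, 50, p = 0.04, f = 0.03,
                                      seed = 400 + seed))
    orc <- oracle_fc_partition(g, crossing, res)
    # skip grids with a gap inside the discretisation band around the threshold
    if (length(orc$gaps) &&
        any(abs(orc$gaps - crossing) <= 1.42 * res)) next
    n_checked <- n_checked + 1
    fc <- functional_connectivity(habitat_raster(g), crossing)
    pc <- attr(fc, "patch_cluster")
    # same patches (package labels are deterministic, oracle order may differ)
    expect_identical(attr(fc, "patch_labels") > 0, orc$labels > 0)
    # identical partition up to label permutation
    expect_identical(length(pc), length(orc$cluster))
    map <- tapply(pc, orc$cluster, function(v) length(unique(v)))
    expect_true(all(map == 1))
    map2 <- tapply(orc$cluster, pc, function(v) length(unique(v)))
    expect_true(all(map2 == 1))
  }
  expect_gte(n_checked, 8)
})

test_that("connectivity values are constant per cluster, monotone in crossing, and conserve area", {
  for (seed in c(51, 52)) {
    g <- random_grid(50, 50, p = 0.15, seed = seed)
    efe <- habitat_raster(g)
    fc1 <- functional_connectivity(efe, 100)
    fc2 <- functional_connectivity(efe, 300)
    m1 <- as.matrix(fc1)
    m2 <- as.matrix(fc2)
    # cluster constancy: value spread within each dilation cluster is exactly 0
    pl <- attr(fc1, "patch_labels")
    pc <- attr(fc1, "patch_cluster")
    vals <- tapply(m1[pl > 0], pc[pl[pl > 0]], function(v) max(v) - min(v))
    expect_true(all(vals == 0))
    # pointwise monotonicity in crossing distance
    expect_true(all(m2 >= m1))
    # area conservation: cluster areas sum to total band area
    areas <- tapply(m1[pl > 0], pc[pl[pl > 0]], unique)
    expect_equal(sum(unlist(areas)), sum(g == 1) * 0.01, tolerance = 1e-12)
  }
})

test_that("temporal summaries compute mean and sample CV with NoData rules", {
  mk <- function(m) funhab:::fh_raster(m, res = 10, layer = "fc", units = "ha")
  a <- mk(matrix(c(2, 0, 1, NA), 2, 2))
  b <- mk(matrix(c(4, 0, 1, 5), 2, 2))
  ts <- temporal_summary(list(a, b))
  expect_equal(as.matrix(ts$mean)[1, 1], 3)
  expect_equal(as.matrix(ts$cv)[1, 1], sqrt(2) / 3)   # sd({2,4}) = sqrt(2)
  expect_true(is.na(as.matrix(ts$cv)[2, 1]))          # mean 0 -> NoData
  expect_equal(as.matrix(ts$cv)[1, 2], 0)             # identical values
  expect_true(is.na(as.matrix(ts$mean)[2, 2]))        # NoData propagates

  # seeded 4-epoch stack equals a direct per-pixel loop
  set.seed(61)
  stack <- lapply(1:4, function(i) mk(matrix(runif(36, 0, 5), 6, 6)))
  ts2 <- temporal_summary(stack)
  for (i in 1:6) for (j in 1:6) {
    v <- sapply(stack, function(r) r$grid[i, j])
    expect_equal(as.matrix(ts2$mean)[i, j], mean(v))
    expect_equal(as.matrix(ts2$cv)[i, j], sd(v) / mean(v))
  }

  expect_error(temporal_summary(list(a)), "at least two")
  expect_error(temporal_summary(list(a, mk(matrix(0, 3, 3)))), "aligned")
})
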