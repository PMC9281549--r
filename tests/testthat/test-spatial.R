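test_that("inverse-distance weights follow 1/d^p with the coincidence floor", {
  w <- build_weights(cbind(c(0, 2), c(0, 0)))
  expect_equal(w$w[1, 2], 0.5)
  expect_equal(unname(diag(w$w)), c(0, 0))
  w3 <- build_weights(cbind(c(0, 1, 2), c(0, 0, 0)))
  expect_equal(w3$w[1, 2], 1)
  expect_equal(w3$w[1, 3], 0.5)
  expect_true(isSymmetric(w3$w))
  # coincident pair gets the distance floor
  wf <- build_weights(rbind(c(0, 0), c(0, 0), c(5, 0)), dist_floor = 0.1)
  expect_equal(wf$w[1, 2], 10)
  expect_error(build_weights(rbind(c(1, 1), c(1, 1))), "coincident")
  # power and cutoff
  wp <- build_weights(cbind(c(0, 2), c(0, 0)), power = 2)
  expect_equal(wp$w[1, 2], 0.25)
  wc <- build_weights(cbind(c(0, 1, 10), c(0, 0, 0)), cutoff = 5)
  expect_equal(wc$w[1, 3], 0)
  wr <- build_weights(cbind(c(0, 1, 2), c(0, 0, 0)), row_standardize = TRUE)
  expect_equal(unname(rowSums(wr$w)), c(1, 1, 1))
})

test_that("Moran's I matches the brute-force double loop and E[I] = -1/(n-1)", {
  set.seed(77)
  for (n in c(5, 10, 25)) {
    coords <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
    x <- rnorm(n)
    w <- build_weights(coords)
    res <- morans_i(x, w)
    expect_equal(res$expected, -1 / (n - 1))
    expect_equal(res$I, moran_brute(x, w$w), tolerance = 1e-12)
  }
})

test_that("checkerboard values are dispersed, clusters autocorrelated", {
  # 4x4 grid, +1/-1 checkerboard: I below the null expectation
  g <- expand.grid(x = 0:3, y = 0:3)
  vals <- ifelse((g$x + g$y) %% 2 == 0, 1, -1)
  w <- build_weights(as.matrix(g))
  res <- morans_i(vals, w)
  expect_lt(res$I, res$expected)

  # two tight clusters of high and low values far apart: I > 0, permutation
  # p significant
  set.seed(99)
  coords <- rbind(cbind(runif(10, 0, 10), runif(10, 0, 10)),
                  cbind(runif(10, 1000, 1010), runif(10, 0, 10)))
  x <- c(rnorm(10, 10, 0.5), rnorm(10, -10, 0.5))
  w2 <- build_weights(coords)
  res2 <- morans_i(x, w2, method = "permutation", n_perm = 499)
  expect_gt(res2$I, 0)
  expect_lt(res2$p, 0.05)
  # randomization test agrees on the direction
  res3 <- morans_i(x, w2)
  expect_gt(res3$Z, 0)
  expect_error(morans_i(rep(1, 20), w2), "constant")
})

test_that("kernel density conserves mass and is linear in the weights", {
  # single point, weight 1, fine grid: mass within 2%
  s <- kernel_density(cbind(0, 0), w = 1, cell_size = 10, bandwidth = 100)
  expect_equal(surface_total(s), 1, tolerance = 0.02)
  expect_true(all(s$z >= 0))
  # doubling weights doubles every cell
  pts <- cbind(c(0, 300), c(0, 100))
  s1 <- kernel_density(pts, w = c(1, 2), cell_size = 25, bandwidth = 120)
  s2 <- kernel_density(pts, w = c(2, 4), cell_size = 25, bandwidth = 120)
  expect_equal(s2$z, 2 * s1$z, tolerance = 1e-12)
  # two identical points == one point with the summed weight
  s3 <- kernel_density(rbind(c(50, 50), c(50, 50)), w = c(1, 1),
                       cell_size = 20, bandwidth = 90)
  s4 <- kernel_density(rbind(c(50, 50)), w = 2, cell_size = 20, bandwidth = 90)
  expect_equal(s3$z, s4$z, tolerance = 1e-12)
  # multi-point mass conservation at fine resolution
  set.seed(5)
  pts2 <- cbind(runif(8, 0, 500), runif(8, 0, 500))
  wts <- runif(8, 1, 10)
  s5 <- kernel_density(pts2, wts, cell_size = 8, bandwidth = 100)
  expect_equal(surface_total(s5), sum(wts), tolerance = 0.02)
  expect_error(kernel_density(cbind(0, 0), 1, bandwidth = -5), "bandwidth")
  expect_error(kernel_density(cbind(0, 0), 1, cell_size = 0), "cell size")
})

test_that("density peak and ASCII export are coherent with the grid", {
  s <- kernel_density(rbind(c(100, 200), c(900, 900)), w = c(5, 1),
                      cell_size = 20, bandwidth = 100)
  pk <- density_peak(s)
  expect_lt(sqrt((pk["x"] - 100)^2 + (pk["y"] - 200)^2), 50)
  f <- tempfile(fileext = ".asc")
  write_surface_asc(s, f)
  hdr <- readLines(f, n = 6)
  expect_match(hdr[1], paste("ncols", s$nx))
  expect_match(hdr[5], "cellsize 20")
  expect_equal(length(readLines(f)), 6 + s$ny)
})

test_that("polygon aggregation conserves totals with a deterministic join", {
  polys <- make_grid_polygons(2, 1, 1000)
  set.seed(31)
  outlets <- data.frame(x = runif(40, 0, 2000), y = runif(40, 0, 1000),
                        category = sample(c("1-2", "1-3"), 40, replace = TRUE),
                        z_TUHII = rnorm(40))
  agg <- aggregate_by_polygon(outlets, polys)
  expect_equal(sum(agg$n), 40L)
  expect_equal(sum(agg$sum_z_TUHII), sum(outlets$z_TUHII), tolerance = 1e-9)
  # one polygon containing everything: the polygon sum is the global sum
  big <- make_grid_polygons(1, 1, 5000)
  agg1 <- aggregate_by_polygon(outlets, big)
  expect_equal(sum(agg1$sum_z_TUHII), sum(outlets$z_TUHII), tolerance = 1e-9)
  expect_true(all(agg1$polygon_id == "P1"))
  # boundary point on the shared edge goes to the first polygon in file order
  edge <- data.frame(x = 1000, y = 500, category = "1-2", z_TUHII = 1)
  expect_equal(assign_polygons(edge[, c("x", "y")], polys), "P1")
  agg_e <- aggregate_by_polygon(edge, polys)
  expect_equal(nrow(agg_e), 1L)
  expect_equal(agg_e$polygon_id, "P1")
  # outside point lands in the unassigned bucket, conserving the total
  far <- rbind(outlets, data.frame(x = 9000, y = 9000, category = "1-2",
                                   z_TUHII = 2))
  expect_warning(agg_f <- aggregate_by_polygon(far, polys), "unassigned")
  expect_equal(sum(agg_f$sum_z_TUHII), sum(far$z_TUHII), tolerance = 1e-9)
  expect_true("unassigned" %in% agg_f$polygon_id)
})

test_that("counting availability covers every polygon and standardizes", {
  polys <- make_grid_polygons(2, 1, 1000)
  outlets <- data.frame(
    x = c(runif(2, 0, 1000), runif(8, 1000.1, 2000)),
    y = runif(10, 0, 1000),
    W = c(rep(1, 3), rep(0.5, 7)))
  cnt <- counting_availability(outlets, polys, "all")
  expect_equal(cnt$count, c(2L, 8L))
  expect_equal(cnt$z_count, c(-1, 1) / sqrt(2))
  ch <- counting_availability(outlets, polys, "healthy")
  cu <- counting_availability(outlets, polys, "unhealthy")
  expect_equal(sum(ch$count), 3L)
  expect_equal(sum(cu$count), 7L)
  expect_equal(ch$count + cu$count, cnt$count)
  # a single polygon cannot be standardized
  expect_warning(c1 <- counting_availability(outlets,
                                             make_grid_polygons(1, 1, 5000)),
                 "degenerate")
  expect_true(is.na(c1$z_count))
})

test_that("method comparison reproduces hand-computed Spearman values", {
  expect_equal(compare_methods(1:8, (1:8) * 3)$rho, 1)
  expect_equal(compare_methods(1:8, rev(1:8))$rho, -1)
  expect_equal(compare_methods(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  expect_error(compare_methods(c(1, 2, 3), c(1, 2, 3)), "four")
  expect_error(compare_methods(c(1, 1, 1, 1), 1:4), "constant")
})
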