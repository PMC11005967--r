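test_that("grid construction follows the ceiling rule and centres the extent", {
  g <- make_grid(c(200, 200, 200), 2)
  expect_identical(g$shape, c(100L, 100L, 100L))
  expect_equal(g$voxel_cc, 0.008)
  g2 <- make_grid(c(10, 10, 10), 3)
  expect_identical(g2$shape, c(4L, 4L, 4L))
  # lattice is centred: voxel centres are symmetric about 0
  expect_equal(overlapdose:::axis_centers(g, 1),
               -rev(overlapdose:::axis_centers(g, 1)))
  expect_error(make_grid(c(-1, 10, 10), 2), "positive")
  expect_error(make_grid(c(10, 10, 10), 0), "positive")
})

test_that("rasterized analytic solids match analytic volumes and converge", {
  g1 <- make_grid(c(64, 64, 64), 1)
  sph <- rasterize_primitive(g1, ellipsoid(c(0, 0, 0), c(25, 25, 25)), "s")
  v_analytic <- 4 / 3 * pi * 25^3 / 1000
  expect_lt(abs(mask_volume(sph) - v_analytic) / v_analytic, 0.02)

  ell <- rasterize_primitive(g1, ellipsoid(c(0, 0, 0), c(30, 20, 20)), "e")
  v_ell <- 4 / 3 * pi * 30 * 20 * 20 / 1000
  expect_lt(abs(mask_volume(ell) - v_ell) / v_ell, 0.02)

  g4 <- make_grid(c(64, 64, 64), 4)
  sph4 <- rasterize_primitive(g4, ellipsoid(c(0, 0, 0), c(25, 25, 25)), "s")
  err4 <- abs(mask_volume(sph4) - v_analytic) / v_analytic
  err1 <- abs(mask_volume(sph) - v_analytic) / v_analytic
  expect_lt(err1, err4)   # error shrinks as spacing is refined

  expect_warning(
    deg <- rasterize_primitive(g1, ellipsoid(c(0, 0, 0), c(10, 10, 0)), "d"),
    "empty")
  expect_equal(mask_volume(deg), 0)
  expect_warning(rasterize_primitive(g1, ellipsoid(c(500, 0, 0), c(5, 5, 5))),
                 "empty")
  expect_error(rasterize_primitive(g1, list(kind = "torus")), "unknown shape")
})

test_that("cylinder rasterization matches the analytic volume", {
  g <- make_grid(c(60, 60, 100), 1)
  cyl <- rasterize_primitive(g, cylinder(c(0, 0, 0), 15, 40, "z"), "c")
  v <- pi * 15^2 * 80 / 1000
  expect_lt(abs(mask_volume(cyl) - v) / v, 0.02)
  # axis choice is honoured: extent along the named axis only
  cylx <- rasterize_primitive(g, cylinder(c(0, 0, 0), 10, 25, "x"), "cx")
  idx <- which(cylx$occupancy, arr.ind = TRUE)
  xs <- overlapdose:::axis_centers(g, 1)[range(idx[, 1])]
  expect_equal(diff(xs), 49)   # centres span just under 2 * half_length
})

test_that("mask volume and overlap equal brute-force counting exactly", {
  g <- tiny_grid()
  set.seed(42)
  for (rep in 1:20) {
    a <- random_mask(g, p = runif(1, 0.1, 0.6))
    b <- random_mask(g, p = runif(1, 0.1, 0.6))
    expect_identical(mask_volume(a), brute_count(a$occupancy) * g$voxel_cc)
    expect_identical(overlap_volume(a, b),
                     brute_overlap_count(a$occupancy, b$occupancy) * g$voxel_cc)
    expect_identical(overlap_volume(a, b), overlap_volume(b, a))
    expect_lte(overlap_volume(a, b), min(mask_volume(a), mask_volume(b)))
  }
  empty <- overlapdose:::new_mask(g, array(FALSE, g$shape), "e")
  expect_equal(mask_volume(empty), 0)
  expect_equal(overlap_volume(empty, empty), 0)
  g2 <- make_grid(c(24, 24, 26), 2)
  expect_error(overlap_volume(random_mask(g), random_mask(g2)), "different grids")
})

test_that("disjoint and identical masks give the expected overlap", {
  g <- make_grid(c(60, 60, 60), 2)
  a <- rasterize_primitive(g, ellipsoid(c(-15, 0, 0), c(8, 8, 8)), "a")
  b <- rasterize_primitive(g, ellipsoid(c(15, 0, 0), c(8, 8, 8)), "b")
  expect_equal(overlap_volume(a, b), 0)
  expect_equal(overlap_volume(a, a), mask_volume(a))
})

test_that("expansion reproduces the analytic margin and is monotone", {
  g <- make_grid(c(64, 64, 64), 2)
  sph <- rasterize_primitive(g, ellipsoid(c(0, 0, 0), c(25, 25, 25)), "s")
  grown <- expand_mask(sph, 5)
  v30 <- 4 / 3 * pi * 30^3 / 1000
  expect_lt(abs(mask_volume(grown) - v30) / v30, 0.02)
  expect_true(all(grown$occupancy[sph$occupancy]))   # contains input
  expect_identical(expand_mask(sph, 0)$occupancy, sph$occupancy)

  # monotone in the margin, on both the analytic and the discrete path
  raw <- overlapdose:::new_mask(g, sph$occupancy, "raw")   # drops primitive
  for (m in list(c(2, 4), c(4, 8))) {
    small_a <- expand_mask(sph, m[1]); big_a <- expand_mask(sph, m[2])
    expect_true(all(big_a$occupancy[small_a$occupancy]))
    small_d <- expand_mask(raw, m[1]); big_d <- expand_mask(raw, m[2])
    expect_true(all(big_d$occupancy[small_d$occupancy]))
    expect_true(all(small_d$occupancy[raw$occupancy]))
  }
  expect_error(expand_mask(overlapdose:::new_mask(g, array(FALSE, g$shape)), 5),
               "empty")
  expect_error(expand_mask(sph, -1), "non-negative")
})

test_that("single-axis margins grow only the requested axis", {
  g <- make_grid(c(80, 80, 80), 2)
  for (mask in list(
    rasterize_primitive(g, ellipsoid(c(0, 0, 0), c(15, 15, 15)), "a"),
    overlapdose:::new_mask(
      g, rasterize_primitive(g, ellipsoid(c(0, 0, 0), c(15, 15, 15)))$occupancy,
      "raw"))) {
    grown <- expand_mask(mask, c(0, 6, 0))
    bbox <- function(m, ax) range(which(m$occupancy, arr.ind = TRUE)[, ax])
    expect_equal(bbox(grown, 1), bbox(mask, 1))
    expect_equal(bbox(grown, 3), bbox(mask, 3))
    expect_equal(bbox(grown, 2), bbox(mask, 2) + c(-3, 3))   # 6 mm = 3 voxels
  }
})

test_that("shifts snap to voxels, conserve volume, and respect bounds", {
  g <- make_grid(c(64, 64, 64), 2)
  sph <- rasterize_primitive(g, ellipsoid(c(0, 0, 0), c(10, 10, 10)), "s")
  expect_identical(shift_mask(sph, c(0, 0, 0))$occupancy, sph$occupancy)
  moved <- shift_mask(sph, c(0, 10, 0))
  expect_identical(mask_volume(moved), mask_volume(sph))
  expect_equal(mask_centroid(moved)[2] - mask_centroid(sph)[2], 10)
  back <- shift_mask(moved, c(0, -10, 0))
  expect_identical(back$occupancy, sph$occupancy)
  expect_error(shift_mask(sph, c(0, 60, 0)), "boundary")
})
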