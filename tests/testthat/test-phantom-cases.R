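# Case generation is deterministic, so the (moderately expensive) families
# are built once per test file and shared across blocks.
grid <- make_grid(c(180, 260, 220), 2)
sim1 <- generate_simulation1_cases(grid)
sim2 <- generate_simulation2_cases(grid)

test_that("the base phantom hits the printed structure volumes", {
  base <- build_base_phantom(grid)
  expect_lt(abs(base$ptv_cc - 162.7) / 162.7, 0.03)
  expect_lt(abs(base$rv_cc - 50) / 50, 0.05)
  expect_lt(abs(base$bv_cc - 165) / 165, 0.05)
  expect_equal(overlap_volume(base$rectum, base$bladder), 0)
  expect_gt(base$rov_cc, 0)
  expect_gt(base$bov_cc, 0)
  # stored overlaps are recomputable from the masks
  expect_identical(base$rov_cc, overlap_volume(base$rectum, base$ptv))
  expect_identical(base$bov_cc, overlap_volume(base$bladder, base$ptv))
})

test_that("overlap solving brackets, converges and reports the achieved volume", {
  g <- make_grid(c(80, 80, 80), 2)
  fixed <- rasterize_primitive(g, ellipsoid(c(0, 0, 0), c(15, 15, 15)), "f")
  moving <- rasterize_primitive(g, ellipsoid(c(0, -34, 0), c(10, 10, 10)), "m")
  expect_equal(overlap_volume(moving, fixed), 0)

  off0 <- solve_shift_for_overlap(moving, fixed, 0, axis = "y", bracket = c(-2, 2))
  expect_equal(as.numeric(off0), 0)
  expect_equal(attr(off0, "achieved_cc"), 0)

  off <- solve_shift_for_overlap(moving, fixed, 1.5, axis = "y", bracket = c(0, 40))
  got <- overlap_volume(attr(off, "mask"), fixed)
  expect_lt(abs(got - 1.5), 0.15)
  expect_identical(got, attr(off, "achieved_cc"))

  expect_error(
    solve_shift_for_overlap(moving, fixed, 2 * mask_volume(moving), axis = "y"),
    "unachievable")
  # masks without a primitive fall back to whole-voxel search
  raw <- overlapdose:::new_mask(g, moving$occupancy, "raw")
  offr <- solve_shift_for_overlap(raw, fixed, 1.5, axis = "y",
                                  bracket = c(0, 30), tol_cc = 2)
  expect_true(abs(as.numeric(offr) %% g$spacing_mm[2]) < 1e-9)
})

test_that("simulation 1 achieves its overlap targets on six cases", {
  expect_length(sim1, 6)
  m <- case_manifest(sim1)
  expect_equal(m$rov_target_cc, rep(c(3.3, 5.3, 7.7), 2))
  expect_true(all(abs(m$rov_cc - m$rov_target_cc) <= 0.15))
  expect_true(all(abs(m$bov_cc - 13.2) <= 0.15))
  expect_true(all(abs(m$rv_cc - 49.9) / 49.9 < 0.05))
  expect_true(all(abs(m$bv_cc - 165) / 165 < 0.05))
  expect_true(all(abs(m$ptv_cc - m$ptv_target_cc) / m$ptv_target_cc < 0.03))
  # achieved overlaps agree with direct voxel counting on the masks
  for (cs in sim1)
    expect_identical(cs$rov_cc, overlap_volume(cs$rectum, cs$ptv))
})

test_that("equal overlap ratios are degenerate for COPP but not for POPP", {
  m <- case_manifest(sim1)
  small <- m[m$ptv_target_cc == 162.7, ]
  large <- m[m$ptv_target_cc == 188.0, ]
  copp_s <- small$rov_cc / small$rv_cc
  copp_l <- large$rov_cc / large$rv_cc
  expect_true(all(abs(copp_s - copp_l) / copp_s < 0.08))
  popp_s <- copp_s * small$ptv_cc / small$rv_cc
  popp_l <- copp_l * large$ptv_cc / large$rv_cc
  # the PTV-volume weighting separates the two arms by ~188.0/162.7
  expect_true(all(abs(popp_l / popp_s - 188.0 / 162.7) < 0.06))
  # arithmetic anchor for the small-PTV, small-overlap corner
  f <- overlap_params(small$rov_cc[1], small$rv_cc[1], small$ptv_cc[1])
  expect_equal(f$copp, small$rov_cc[1] / small$rv_cc[1], tolerance = 1e-12)
  expect_equal(f$copp, 3.3 / 49.9, tolerance = 0.08)
})

test_that("simulation 2 spans the factorial with a fixed PTV", {
  expect_length(sim2, 81)
  m <- case_manifest(sim2)
  expect_equal(length(unique(m$ptv_cc)), 1L)
  expect_lt(abs(m$ptv_cc[1] - 162.7) / 162.7, 0.03)
  expect_identical(
    sort(unique(paste(m$rectum_expand_mm, m$rectum_shift_mm))),
    sort(do.call(paste, expand.grid(c(4, 5, 6), c(10, 12, 14)))))
  rv_target <- c(`4` = 42.5, `5` = 50.0, `6` = 58.2)
  bv_target <- c(`7` = 124.2, `10` = 165.0, `12` = 197.0)
  expect_true(all(abs(m$rv_cc - rv_target[as.character(m$rectum_expand_mm)]) /
                    rv_target[as.character(m$rectum_expand_mm)] < 0.05))
  expect_true(all(abs(m$bv_cc - bv_target[as.character(m$bladder_expand_mm)]) /
                    bv_target[as.character(m$bladder_expand_mm)] < 0.05))
  expect_true(all(vapply(sim2, function(cs)
    overlap_volume(cs$rectum, cs$bladder) == 0, logical(1))))
})

test_that("overlap volumes respond monotonically to expansion and shift", {
  m <- case_manifest(sim2)
  for (s in unique(m$rectum_shift_mm)) {
    sub <- m[m$rectum_shift_mm == s, ]
    rov_by_e <- tapply(sub$rov_cc, sub$rectum_expand_mm, unique)
    expect_true(all(diff(rov_by_e) > 0))
  }
  for (e in unique(m$rectum_expand_mm)) {
    sub <- m[m$rectum_expand_mm == e, ]
    rov_by_s <- tapply(sub$rov_cc, sub$rectum_shift_mm, unique)
    expect_true(all(diff(rov_by_s) < 0))
  }
})

test_that("the cohort overlap ratios match the reference spread", {
  m <- case_manifest(sim2)
  expect_lt(abs(mean(m$rov_cc / m$rv_cc) - 0.11), 0.04)
  expect_lt(abs(mean(m$bov_cc / m$bv_cc) - 0.08), 0.02)
})

test_that("regeneration reproduces identical masks", {
  again <- generate_simulation2_cases(grid)
  for (i in c(1, 41, 81)) {
    expect_identical(sim2[[i]]$rectum$occupancy, again[[i]]$rectum$occupancy)
    expect_identical(sim2[[i]]$bladder$occupancy, again[[i]]$bladder$occupancy)
    expect_identical(sim2[[i]]$ptv$occupancy, again[[i]]$ptv$occupancy)
  }
  s1 <- generate_simulation1_cases(grid)
  expect_identical(case_manifest(s1), case_manifest(sim1))
})
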