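# Independent brute-force oracles and small fixtures shared across tests.

# Count occupied voxels by explicit iteration (independent of sum()).
brute_count <- function(occ) {
  n <- 0L
  for (i in seq_along(occ)) if (occ[i]) n <- n + 1L
  n
}

# Count voxels occupied in both masks by explicit iteration.
brute_overlap_count <- function(a, b) {
  n <- 0L
  for (i in seq_along(a)) if (a[i] && b[i]) n <- n + 1L
  n
}

# Random structure_mask on a given grid (blobby: thresholded smooth noise
# would be nicer, but uniform occupancy is the harsher oracle case).
random_mask <- function(grid, p = 0.3, label = "rand") {
  occ <- array(stats::runif(prod(grid$shape)) < p, grid$shape)
  overlapdose:::new_mask(grid, occ, label)
}

# Small grid used by the mask-pair oracle tests.
tiny_grid <- function(spacing = 2) make_grid(c(24, 24, 24), spacing)

# Dose grid built directly from an array (bypasses the emulator).
manual_dose <- function(grid, arr) {
  structure(list(grid = grid, dose = array(arr, grid$shape)),
            class = "dose_grid")
}

# Ideal conformal plan: exactly rx inside the target, 0 elsewhere.
ideal_plan <- function(case, rx = 75.6) {
  manual_dose(case$ptv$grid, ifelse(case$ptv$occupancy, rx, 0))
}

# One small geometry case (sphere PTV + posterior cylinder + anterior
# ellipsoid) on a compact grid, for dose-engine tests.
small_case <- function(spacing = 2) {
  g <- make_grid(c(120, 160, 140), spacing)
  ptv <- rasterize_primitive(g, ellipsoid(c(0, 0, 0), c(24, 22, 25)), "ptv")
  rectum <- rasterize_primitive(g, cylinder(c(0, -28, 0), 10, 35, "z"), "rectum")
  bladder <- rasterize_primitive(g, ellipsoid(c(0, 30, 25), c(22, 20, 18)), "bladder")
  overlapdose:::new_geometry_case(ptv, rectum, bladder, case_id = "small")
}
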