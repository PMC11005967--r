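#' Dose emulator parameters
#'
#' Parameters of the conformal-dose emulator: a sigmoid falloff of dose with
#' signed distance to the PTV surface, over a far-field background floor,
#' modulated by smooth multiplicative noise and renormalized so that at
#' least 95% of the PTV receives the prescription.
#'
#' The noise-free profile is
#' `dose(v) = rx * (bg + (1 - bg) * plogis((d0 - d(v)) / sigma))`
#' where `d(v)` is the signed Euclidean distance to the PTV surface
#' (negative inside) and `d0 = sigma * qlogis(surface_level)` places the
#' sigmoid midpoint outside the target so that the PTV surface sits at
#' `surface_level` of the falloff.  A sharper `sigma` (the VMAT-like
#' preset) concentrates intermediate dose closer to the target.
#'
#' @param rx_gy prescription dose (Gy).
#' @param falloff_sigma_mm penumbra scale of the sigmoid falloff (mm).
#' @param surface_level fraction of the background-free sigmoid reached at
#'   the PTV surface, in (0, 1); 0.5 puts the midpoint on the surface.
#' @param background_fraction far-field dose floor as a fraction of `rx_gy`.
#' @param noise_amplitude_fraction relative amplitude of the smooth
#'   multiplicative noise (0 disables noise).
#' @param noise_correlation_mm correlation length of the noise field (mm).
#' @param modality label, `"imrt"` or `"vmat"`.
#' @return A list of class `dose_model_params`.
#' @seealso [dose_preset()] for the calibrated modality presets.
#' @export
dose_model_params <- function(rx_gy = 75.6,
                              falloff_sigma_mm = 5,
                              surface_level = 0.88,
                              background_fraction = 0.18,
                              noise_amplitude_fraction = 0.02,
                              noise_correlation_mm = 15,
                              modality = "imrt") {
  stopifnot(rx_gy > 0, falloff_sigma_mm > 0,
            surface_level > 0, surface_level < 1,
            background_fraction >= 0, background_fraction < 1,
            noise_amplitude_fraction >= 0, noise_correlation_mm > 0)
  structure(list(rx_gy = rx_gy, falloff_sigma_mm = falloff_sigma_mm,
                 surface_level = surface_level,
                 background_fraction = background_fraction,
                 noise_amplitude_fraction = noise_amplitude_fraction,
                 noise_correlation_mm = noise_correlation_mm,
                 modality = modality),
            class = "dose_model_params")
}

#' Modality presets for the dose emulator
#'
#' Two falloff presets sharing the 75.6 Gy prescription: the IMRT-like
#' preset uses a broader penumbra (`sigma` = 5 mm) and the VMAT-like preset
#' a sharper one (`sigma` = 4 mm), so the VMAT preset spreads less
#' intermediate dose into the organs at risk.
#'
#' @param modality `"imrt"` or `"vmat"`.
#' @param ... overrides passed on to [dose_model_params()].
#' @return A `dose_model_params` object.
#' @export
dose_preset <- function(modality = c("imrt", "vmat"), ...) {
  modality <- match.arg(modality)
  defaults <- switch(modality,
    imrt = list(falloff_sigma_mm = 5),
    vmat = list(falloff_sigma_mm = 4))
  args <- utils::modifyList(c(defaults, list(modality = modality)), list(...))
  do.call(dose_model_params, args)
}

#' Planning protocol (prescription and dose goals)
#'
#' @param rx_gy prescription dose (Gy).
#' @param coverage_fraction minimum fraction of the PTV receiving `rx_gy`.
#' @param oar_v75_limit_pct,oar_v70_limit_pct organ-at-risk goals: V_75Gy
#'   and V_70Gy must stay strictly below these percentages for the rectum
#'   and the bladder.
#' @return A list of class `planning_protocol`.
#' @export
planning_protocol <- function(rx_gy = 75.6, coverage_fraction = 0.95,
                              oar_v75_limit_pct = 10, oar_v70_limit_pct = 30) {
  structure(list(rx_gy = rx_gy, coverage_fraction = coverage_fraction,
                 oar_v75_limit_pct = oar_v75_limit_pct,
                 oar_v70_limit_pct = oar_v70_limit_pct),
            class = "planning_protocol")
}

#' Signed Euclidean distance field of a structure
#'
#' Per-voxel signed distance in mm: negative inside the structure, positive
#' outside, computed as the difference of the exact Euclidean distance
#' transforms (to occupied and to background voxel centres) with physical
#' spacing.  The zero crossing tracks the surface to within one voxel.
#'
#' @param mask a non-empty `structure_mask`.
#' @return A numeric array of the grid's shape (mm).
#' @export
signed_distance_field <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  occ <- mask$occupancy
  if (!any(occ)) stop("signed distance of an empty mask is undefined")
  g <- mask$grid
  d_out <- sqrt(cpp_edt_sq(as.logical(occ), g$shape, g$spacing_mm))
  d_in <- sqrt(cpp_edt_sq(as.logical(!occ), g$shape, g$spacing_mm))
  out <- d_out - d_in
  dim(out) <- g$shape
  out
}

run_seeded <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

gauss_smooth_axis <- function(arr, sd_vox, axis) {
  d <- dim(arr)
  n <- d[axis]
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) stats::dnorm(i - j, sd = sd_vox))
  K <- K / rowSums(K)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  sm <- K %*% m
  dim(sm) <- dim(a)
  aperm(sm, order(perm))
}

#' Smooth seeded noise field on a grid
#'
#' Zero-mean, unit-variance spatially correlated noise: white Gaussian
#' noise on a coarse lattice, Gaussian-smoothed at the requested
#' correlation length, standardized, clamped at 3.5 sd and trilinearly
#' interpolated to the voxel centres.  Smooth fields emulate plan-to-plan
#' variability without voxel-level speckle.
#'
#' @param grid a `voxel_grid`.
#' @param correlation_mm correlation length (mm).
#' @param seed integer seed; the global RNG state is left untouched.
#' @return A numeric array of the grid's shape.
#' @export
smooth_noise_field <- function(grid, correlation_mm, seed) {
  cs <- max(correlation_mm / 2, max(grid$spacing_mm))
  extent <- grid$shape * grid$spacing_mm
  nc <- as.integer(ceiling(extent / cs)) + 4L
  coarse <- run_seeded(seed, array(stats::rnorm(prod(nc)), dim = nc))
  coarse <- gauss_smooth_axis(coarse, correlation_mm / cs, 1)
  coarse <- gauss_smooth_axis(coarse, correlation_mm / cs, 2)
  coarse <- gauss_smooth_axis(coarse, correlation_mm / cs, 3)
  coarse <- (coarse - mean(coarse)) / stats::sd(coarse)
  coarse <- pmin(pmax(coarse, -3.5), 3.5)

  # trilinear interpolation at voxel centres
  first <- grid$origin_mm - 2 * cs + cs / 2
  w <- vector("list", 3)
  i0 <- vector("list", 3)
  for (ax in 1:3) {
    t <- (axis_centers(grid, ax) - first[ax]) / cs
    lo <- pmin(pmax(floor(t), 0), nc[ax] - 2)
    w[[ax]] <- t - lo
    i0[[ax]] <- as.integer(lo) + 1L
  }
  out <- array(0, grid$shape)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    wx <- if (a == 0) 1 - w[[1]] else w[[1]]
    wy <- if (b == 0) 1 - w[[2]] else w[[2]]
    wz <- if (cc == 0) 1 - w[[3]] else w[[3]]
    vals <- coarse[i0[[1]] + a, i0[[2]] + b, i0[[3]] + cc]
    out <- out + vals * outer(outer(wx, wy), wz)
  }
  out
}

#' Emulate a conformal planned dose for one geometry case
#'
#' Deterministic-plus-noise stand-in for an inverse-optimized conformal
#' plan: sigmoid falloff of dose with signed distance to the PTV (see
#' [dose_model_params()]), multiplied by a smooth seeded noise field, then
#' scaled by the minimal global factor >= 1 such that at least 95% of the
#' PTV volume receives the prescription dose.  If meeting coverage would
#' push any voxel above 1.25 x prescription, the plan fails with an error.
#'
#' @param case a `geometry_case`.
#' @param params a `dose_model_params` (see [dose_preset()]).
#' @param seed integer seed for the noise field.
#' @param sdf optional precomputed [signed_distance_field()] of the case's
#'   PTV (useful when many cases share one PTV).
#' @return A `dose_grid` (fields `grid`, `dose` in Gy) with attributes
#'   `scale_factor`, `params` and `seed`.
#' @export
simulate_plan_dose <- function(case, params = dose_preset("imrt"), seed = 1L,
                               sdf = NULL) {
  stopifnot(inherits(case, "geometry_case"), inherits(params, "dose_model_params"))
  grid <- case$ptv$grid
  if (is.null(sdf)) sdf <- signed_distance_field(case$ptv)
  bg <- params$background_fraction
  d0 <- params$falloff_sigma_mm * stats::qlogis(params$surface_level)
  dose <- bg + (1 - bg) * stats::plogis((d0 - sdf) / params$falloff_sigma_mm)
  dose <- params$rx_gy * dose
  if (params$noise_amplitude_fraction > 0) {
    g <- smooth_noise_field(grid, params$noise_correlation_mm, seed)
    dose <- dose * (1 + params$noise_amplitude_fraction * g)
  }
  pd <- dose[case$ptv$occupancy]
  n <- length(pd)
  k <- n - ceiling(0.95 * n) + 1L
  dk <- sort(pd, partial = k)[k]
  # nudge above the exact ratio so the k-th voxel itself counts as covered
  f <- max(1, params$rx_gy / dk * (1 + 1e-12))
  if (f > 1 && f * max(dose) > 1.25 * params$rx_gy)
    stop("plan failure: coverage unattainable without exceeding 1.25 x prescription")
  dose <- f * dose
  structure(list(grid = grid, dose = array(dose, grid$shape)),
            class = "dose_grid",
            scale_factor = f, params = params, seed = seed)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels | dose %.1f-%.1f Gy\n",
              paste(x$grid$shape, collapse = "x"),
              min(x$dose), max(x$dose)))
  invisible(x)
}

#' Evaluate a plan against the planning protocol
#'
#' Checks PTV coverage (fraction of the PTV at or above the prescription)
#' and the organ-at-risk goals (V_75Gy < 10% and V_70Gy < 30% for rectum
#' and bladder, on relative volumes).
#'
#' @param dose a `dose_grid`.
#' @param case a `geometry_case` on the same grid.
#' @param protocol a [planning_protocol()].
#' @return A list with `goals` (data.frame: goal, structure, value, limit,
#'   pass) and `pass` (TRUE iff every goal passes).
#' @export
check_plan_goals <- function(dose, case, protocol = planning_protocol()) {
  stopifnot(inherits(dose, "dose_grid"), inherits(case, "geometry_case"))
  if (!same_grid(dose$grid, case$ptv$grid)) stop("dose and case are on different grids")
  vx <- function(mask, level) 100 * mean(dose$dose[mask$occupancy] >= level)
  cov <- vx(case$ptv, protocol$rx_gy)
  rows <- rbind(
    data.frame(goal = "ptv_coverage", structure = "ptv", value = cov,
               limit = 100 * protocol$coverage_fraction,
               pass = cov >= 100 * protocol$coverage_fraction),
    data.frame(goal = "v75_lt", structure = "rectum", value = vx(case$rectum, 75),
               limit = protocol$oar_v75_limit_pct,
               pass = vx(case$rectum, 75) < protocol$oar_v75_limit_pct),
    data.frame(goal = "v70_lt", structure = "rectum", value = vx(case$rectum, 70),
               limit = protocol$oar_v70_limit_pct,
               pass = vx(case$rectum, 70) < protocol$oar_v70_limit_pct),
    data.frame(goal = "v75_lt", structure = "bladder", value = vx(case$bladder, 75),
               limit = protocol$oar_v75_limit_pct,
               pass = vx(case$bladder, 75) < protocol$oar_v75_limit_pct),
    data.frame(goal = "v70_lt", structure = "bladder", value = vx(case$bladder, 70),
               limit = protocol$oar_v70_limit_pct,
               pass = vx(case$bladder, 70) < protocol$oar_v70_limit_pct))
  list(goals = rows, pass = all(rows$pass))
}
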