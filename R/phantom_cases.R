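#' Default phantom parameterization
#'
#' Analytic surrogate for a prostate benchmark structure set: the PTV is an
#' ellipsoid, the rectum a circular cylinder along the cranio-caudal axis
#' posterior to the PTV, and the bladder an ellipsoid anterior-superior to
#' the PTV.  Default dimensions are calibrated so that the clinically sized
#' (mid-expansion) structures hit the reference benchmark volumes: PTV 162.7 cc,
#' rectum 50 cc, bladder 165 cc, and so that the systematic geometry
#' variations of [generate_simulation2_cases()] produce cohort mean overlap
#' ratios near 0.11 (rectum) and 0.08 (bladder).
#'
#' @param ptv_semiaxes_mm PTV ellipsoid semi-axes (x, y, z) in mm.
#' @param rectum_radius_mm unexpanded rectum cylinder radius (mm).
#' @param rectum_half_length_mm rectum cylinder half-length (mm).
#' @param rectum_center_mm rectum centre before any shift (mm).
#' @param bladder_semiaxes_mm unexpanded bladder semi-axes (mm).
#' @param bladder_center_mm bladder centre before any shift (mm).
#' @param rectum_margin_mm default clinical expansion of the rectum in the
#'   anterior-posterior and left-right directions (mm).
#' @param bladder_margin_mm default uniform clinical expansion of the
#'   bladder (mm).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(ptv_semiaxes_mm = c(35, 30, 37),
                         rectum_radius_mm = 7.8,
                         rectum_half_length_mm = 48.6,
                         rectum_center_mm = c(0, -21, 0),
                         bladder_semiaxes_mm = c(26, 24, 22),
                         bladder_center_mm = c(0, 31, 32),
                         rectum_margin_mm = 5,
                         bladder_margin_mm = 10) {
  structure(list(ptv_semiaxes_mm = ptv_semiaxes_mm,
                 rectum_radius_mm = rectum_radius_mm,
                 rectum_half_length_mm = rectum_half_length_mm,
                 rectum_center_mm = rectum_center_mm,
                 bladder_semiaxes_mm = bladder_semiaxes_mm,
                 bladder_center_mm = bladder_center_mm,
                 rectum_margin_mm = rectum_margin_mm,
                 bladder_margin_mm = bladder_margin_mm),
            class = "phantom_spec")
}

new_geometry_case <- function(ptv, rectum, bladder, provenance = list(),
                              case_id = "") {
  rov <- overlap_volume(rectum, ptv)
  bov <- overlap_volume(bladder, ptv)
  structure(list(ptv = ptv, rectum = rectum, bladder = bladder,
                 ptv_cc = mask_volume(ptv),
                 rv_cc = mask_volume(rectum),
                 bv_cc = mask_volume(bladder),
                 rov_cc = rov, bov_cc = bov,
                 provenance = provenance, case_id = case_id),
            class = "geometry_case")
}

#' @export
print.geometry_case <- function(x, ...) {
  cat(sprintf(
    "<geometry_case> %s\n  PTV %.1f cc | rectum %.1f cc (ROV %.2f) | bladder %.1f cc (BOV %.2f)\n",
    if (nzchar(x$case_id)) x$case_id else "(unnamed)",
    x$ptv_cc, x$rv_cc, x$rov_cc, x$bv_cc, x$bov_cc))
  invisible(x)
}

#' Build the clinically sized base phantom
#'
#' Rasterizes the default (mid-expansion) structure set on a grid: the PTV
#' ellipsoid, the rectum cylinder at its expanded radius, and the bladder
#' ellipsoid at its expanded semi-axes, each at its unshifted position.
#'
#' @param grid a `voxel_grid` large enough to contain all structures.
#' @param spec a [phantom_spec()].
#' @return A `geometry_case` with PTV near 162.7 cc, rectum near 50 cc and
#'   bladder near 165 cc.
#' @export
build_base_phantom <- function(grid, spec = phantom_spec()) {
  ptv <- rasterize_primitive(grid, ellipsoid(c(0, 0, 0), spec$ptv_semiaxes_mm),
                             label = "ptv")
  rectum <- rasterize_primitive(
    grid,
    cylinder(spec$rectum_center_mm,
             spec$rectum_radius_mm + spec$rectum_margin_mm,
             spec$rectum_half_length_mm, axis = "z"),
    label = "rectum")
  bladder <- rasterize_primitive(
    grid,
    ellipsoid(spec$bladder_center_mm,
              spec$bladder_semiaxes_mm + spec$bladder_margin_mm),
    label = "bladder")
  new_geometry_case(ptv, rectum, bladder,
                    provenance = list(spec = spec, family = "base"),
                    case_id = "base")
}

overlap_at_offset <- function(moving, fixed, offset, axis_idx) {
  p <- attr(moving, "primitive")
  off <- c(0, 0, 0); off[axis_idx] <- offset
  if (!is.null(p)) {
    m <- rasterize_primitive(moving$grid, shift_primitive(p, off), moving$label)
  } else {
    m <- shift_mask(moving, off)
  }
  overlap_volume(m, fixed)
}

#' Solve the axis shift achieving a target overlap volume
#'
#' Finds the offset along one axis at which the moving structure overlaps
#' the fixed structure by a requested volume.  When the moving mask carries
#' its analytic primitive (masks from [rasterize_primitive()] do), the
#' structure is re-rasterized at continuously varied offsets, so the
#' achieved overlap is resolved well below one voxel of travel; otherwise
#' the search is restricted to whole-voxel shifts and the closest achievable
#' overlap is returned (with a warning if it misses the tolerance).
#'
#' @param moving,fixed `structure_mask` objects on the same grid.
#' @param target_cc requested overlap volume (cc), within the range
#'   attainable over the bracket.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param tol_cc acceptance tolerance on the achieved overlap (cc).
#' @param bracket length-2 numeric search interval for the offset (mm).
#'   Overlap must be monotone over the bracket.
#' @return The offset in mm, with attributes `achieved_cc` (the realized
#'   overlap) and `mask` (the moved structure).
#' @export
solve_shift_for_overlap <- function(moving, fixed, target_cc, axis = "y",
                                    tol_cc = 0.15, bracket = c(-60, 60)) {
  stopifnot(inherits(moving, "structure_mask"), inherits(fixed, "structure_mask"))
  if (!same_grid(moving$grid, fixed$grid)) stop("masks are on different grids")
  axis_idx <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  if (target_cc < 0 || target_cc > min(mask_volume(moving), mask_volume(fixed)) + 1e-9)
    stop("unachievable target: overlap target outside [0, min volume]")
  f <- function(o) overlap_at_offset(moving, fixed, o, axis_idx)

  f0 <- f(0)
  if (abs(f0 - target_cc) <= tol_cc && target_cc == 0 && f0 == 0) {
    return(structure(0, achieved_cc = 0, mask = moving))
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  increasing <- fhi >= flo
  rng <- range(flo, fhi)
  if (target_cc < rng[1] - tol_cc || target_cc > rng[2] + tol_cc)
    stop(sprintf(
      "unachievable target: %.2f cc outside attainable range [%.2f, %.2f] over bracket",
      target_cc, rng[1], rng[2]))

  has_primitive <- !is.null(attr(moving, "primitive"))
  if (has_primitive) {
    while (hi - lo > 0.02) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      over <- if (increasing) fm >= target_cc else fm <= target_cc
      if (over) hi <- mid else lo <- mid
    }
    cands <- c(lo, (lo + hi) / 2, hi)
  } else {
    sp <- moving$grid$spacing_mm[axis_idx]
    cands <- seq(ceiling(bracket[1] / sp), floor(bracket[2] / sp)) * sp
    # keep only feasible whole-voxel offsets (no boundary clipping)
    cands <- cands[vapply(cands, function(o) {
      off <- c(0, 0, 0); off[axis_idx] <- o
      !inherits(try(shift_mask(moving, off), silent = TRUE), "try-error")
    }, logical(1))]
  }
  achieved <- vapply(cands, f, numeric(1))
  best <- which.min(abs(achieved - target_cc))
  offset <- cands[best]
  if (abs(achieved[best] - target_cc) > tol_cc)
    warning(sprintf("closest achievable overlap %.3f cc misses target %.3f cc by more than %.2f cc",
                    achieved[best], target_cc, tol_cc))
  off <- c(0, 0, 0); off[axis_idx] <- offset
  p <- attr(moving, "primitive")
  moved <- if (!is.null(p)) {
    rasterize_primitive(moving$grid, shift_primitive(p, off), moving$label)
  } else shift_mask(moving, off)
  structure(offset, achieved_cc = achieved[best], mask = moved)
}

ptv_for_volume <- function(grid, spec, target_cc) {
  s <- spec$ptv_semiaxes_mm
  base_cc <- 4 / 3 * pi * prod(s) / 1000
  scale_xy <- sqrt(target_cc / base_cc)   # scale transverse axes only
  rasterize_primitive(grid, ellipsoid(c(0, 0, 0), c(s[1] * scale_xy, s[2] * scale_xy, s[3])),
                      label = "ptv")
}

#' Generate the two-PTV-size case family
#'
#' Six cases crossing two PTV sizes (162.7 and 188.0 cc) with three rectum
#' overlap volumes (3.3, 5.3 and 7.7 cc).  Rectum (49.9 cc) and bladder
#' (165.0 cc) sizes are held fixed; each ROV level is achieved by solving
#' the rectum's anterior-posterior position, and the bladder overlap is held
#' at 13.2 cc for every case by solving the bladder position.  Because the
#' two PTV arms share each ROV level, COPP is degenerate across PTV size
#' while POPP separates the arms by the PTV volume ratio.
#'
#' @param grid a `voxel_grid`.
#' @param seed reserved for optional surface jitter; generation is fully
#'   deterministic and the default family ignores it.
#' @param spec a [phantom_spec()].
#' @param ptv_targets_cc,rov_targets_cc,bov_target_cc calibration targets (cc).
#' @param tol_cc overlap solve tolerance (cc).
#' @return A list of 6 `geometry_case` objects.
#' @export
generate_simulation1_cases <- function(grid, seed = 1L, spec = phantom_spec(),
                                       ptv_targets_cc = c(162.7, 188.0),
                                       rov_targets_cc = c(3.3, 5.3, 7.7),
                                       bov_target_cc = 13.2,
                                       tol_cc = 0.15) {
  rectum0 <- rasterize_primitive(
    grid, cylinder(c(0, spec$rectum_center_mm[2] - 20, 0),
                   spec$rectum_radius_mm + spec$rectum_margin_mm,
                   spec$rectum_half_length_mm, axis = "z"),
    label = "rectum")
  bladder0 <- rasterize_primitive(
    grid, ellipsoid(spec$bladder_center_mm,
                    spec$bladder_semiaxes_mm + spec$bladder_margin_mm),
    label = "bladder")
  cases <- list()
  i <- 0L
  for (ptv_cc in ptv_targets_cc) {
    ptv <- ptv_for_volume(grid, spec, ptv_cc)
    bl_off <- solve_shift_for_overlap(bladder0, ptv, bov_target_cc,
                                      axis = "y", tol_cc = tol_cc,
                                      bracket = c(-20, 40))
    bladder <- attr(bl_off, "mask")
    for (rov_cc in rov_targets_cc) {
      re_off <- solve_shift_for_overlap(rectum0, ptv, rov_cc,
                                        axis = "y", tol_cc = tol_cc,
                                        bracket = c(-10, 40))
      rectum <- attr(re_off, "mask")
      i <- i + 1L
      cases[[i]] <- new_geometry_case(
        ptv, rectum, bladder,
        provenance = list(family = "simulation1",
                          ptv_target_cc = ptv_cc, rov_target_cc = rov_cc,
                          bov_target_cc = bov_target_cc,
                          rectum_offset_mm = as.numeric(re_off),
                          bladder_offset_mm = as.numeric(bl_off)),
        case_id = sprintf("sim1_ptv%.0f_rov%.1f", ptv_cc, rov_cc))
    }
  }
  cases
}

#' Generate the factorial rectum/bladder geometry family
#'
#' The full 81-case factorial of nine rectum configurations (expansion 4, 5
#' or 6 mm in the anterior-posterior and left-right directions crossed with
#' posterior shifts of 10, 12 or 14 mm) and nine bladder configurations
#' (uniform expansion 7, 10 or 12 mm crossed with anterior shifts of 5, 8
#' or 11 mm).  The PTV (162.7 cc) is fixed across all cases.  Shifts are
#' realized by rasterizing the base primitive at the shifted centre before
#' expansion, so odd-millimetre shifts are honoured at voxel-centre
#' fidelity.  The 81 cases share the 9 + 9 + 1 distinct masks.
#'
#' @inheritParams generate_simulation1_cases
#' @param rectum_expansions_mm,rectum_shifts_mm rectum margin and posterior
#'   shift levels (mm).
#' @param bladder_expansions_mm,bladder_shifts_mm bladder margin and
#'   anterior shift levels (mm).
#' @return A list of 81 `geometry_case` objects, rectum level varying
#'   fastest.
#' @export
generate_simulation2_cases <- function(grid, seed = 1L, spec = phantom_spec(),
                                       rectum_expansions_mm = c(4, 5, 6),
                                       rectum_shifts_mm = c(10, 12, 14),
                                       bladder_expansions_mm = c(7, 10, 12),
                                       bladder_shifts_mm = c(5, 8, 11)) {
  ptv <- rasterize_primitive(grid, ellipsoid(c(0, 0, 0), spec$ptv_semiaxes_mm),
                             label = "ptv")
  rect_cfg <- expand.grid(expand_mm = rectum_expansions_mm,
                          shift_mm = rectum_shifts_mm)
  rectums <- lapply(seq_len(nrow(rect_cfg)), function(i) {
    e <- rect_cfg$expand_mm[i]; s <- rect_cfg$shift_mm[i]
    base <- rasterize_primitive(
      grid, cylinder(spec$rectum_center_mm - c(0, s, 0),
                     spec$rectum_radius_mm, spec$rectum_half_length_mm,
                     axis = "z"),
      label = "rectum")
    expand_mask(base, c(e, e, 0))           # AP and LR only
  })
  blad_cfg <- expand.grid(expand_mm = bladder_expansions_mm,
                          shift_mm = bladder_shifts_mm)
  bladders <- lapply(seq_len(nrow(blad_cfg)), function(i) {
    e <- blad_cfg$expand_mm[i]; s <- blad_cfg$shift_mm[i]
    base <- rasterize_primitive(
      grid, ellipsoid(spec$bladder_center_mm + c(0, s, 0),
                      spec$bladder_semiaxes_mm),
      label = "bladder")
    expand_mask(base, e)                    # uniform
  })
  cases <- vector("list", nrow(rect_cfg) * nrow(blad_cfg))
  k <- 0L
  for (bi in seq_len(nrow(blad_cfg))) {
    for (ri in seq_len(nrow(rect_cfg))) {
      k <- k + 1L
      cases[[k]] <- new_geometry_case(
        ptv, rectums[[ri]], bladders[[bi]],
        provenance = list(family = "simulation2",
                          rectum_expand_mm = rect_cfg$expand_mm[ri],
                          rectum_shift_mm = rect_cfg$shift_mm[ri],
                          bladder_expand_mm = blad_cfg$expand_mm[bi],
                          bladder_shift_mm = blad_cfg$shift_mm[bi]),
        case_id = sprintf("sim2_r%de%d_b%de%d",
                          rect_cfg$shift_mm[ri], rect_cfg$expand_mm[ri],
                          blad_cfg$shift_mm[bi], blad_cfg$expand_mm[bi]))
    }
  }
  cases
}

#' Case manifest table
#'
#' One row per case with identifiers, provenance parameters and achieved
#' volumes; suitable for CSV export and for regenerating cases.
#'
#' @param cases a list of `geometry_case` objects.
#' @return A data.frame.
#' @export
case_manifest <- function(cases) {
  rows <- lapply(cases, function(cs) {
    pv <- cs$provenance
    data.frame(
      case_id = cs$case_id,
      family = if (!is.null(pv$family)) pv$family else NA_character_,
      rectum_expand_mm = pv$rectum_expand_mm %||% NA_real_,
      rectum_shift_mm = pv$rectum_shift_mm %||% NA_real_,
      bladder_expand_mm = pv$bladder_expand_mm %||% NA_real_,
      bladder_shift_mm = pv$bladder_shift_mm %||% NA_real_,
      ptv_target_cc = pv$ptv_target_cc %||% NA_real_,
      rov_target_cc = pv$rov_target_cc %||% NA_real_,
      bov_target_cc = pv$bov_target_cc %||% NA_real_,
      ptv_cc = cs$ptv_cc, rv_cc = cs$rv_cc, bv_cc = cs$bv_cc,
      rov_cc = cs$rov_cc, bov_cc = cs$bov_cc,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
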