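#' Cumulative dose-volume histogram of a structure
#'
#' Relative cumulative DVH over the voxels of one structure.  The exact
#' voxel doses are retained on the object, so volume and dose queries are
#' answered from order statistics and are independent of the display bin
#' width.
#'
#' @param dose a `dose_grid`.
#' @param mask a non-empty `structure_mask` on the same grid.
#' @param bin_gy display bin width in Gy (curve sampling only).
#' @return An object of class `dvh_curve` with fields `label`, `dose_gy`
#'   (ascending edges), `rel_volume` (non-increasing, starts at 1), and
#'   `doses` (sorted voxel doses in Gy).
#' @export
cumulative_dvh <- function(dose, mask, bin_gy = 0.1) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  if (!same_grid(dose$grid, mask$grid)) stop("dose and mask are on different grids")
  if (!any(mask$occupancy)) stop("cannot compute a DVH for an empty mask")
  if (bin_gy <= 0) stop("bin_gy must be positive")
  d <- sort(dose$dose[mask$occupancy])
  edges <- seq(0, max(d) + bin_gy, by = bin_gy)
  n <- length(d)
  # fraction of voxels with dose >= edge
  rel <- (n - findInterval(edges - 1e-12, d)) / n
  structure(list(label = mask$label, dose_gy = edges, rel_volume = rel,
                 doses = d, voxel_cc = mask$grid$voxel_cc),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s | %d voxels | dose %.1f-%.1f Gy\n",
              if (nzchar(x$label)) x$label else "(unnamed)",
              length(x$doses), min(x$doses), max(x$doses)))
  invisible(x)
}

#' Volume receiving at least a dose (V_xGy)
#'
#' Percent of the structure volume receiving at least `threshold_gy`
#' (closed lower bound), computed from the exact voxel doses.
#'
#' @param dvh a `dvh_curve`.
#' @param threshold_gy dose threshold in Gy (>= 0).
#' @param absolute if TRUE return absolute volume in cc instead of percent.
#' @return Percent of structure volume (or cc when `absolute`).
#' @export
volume_at_dose <- function(dvh, threshold_gy, absolute = FALSE) {
  stopifnot(inherits(dvh, "dvh_curve"), threshold_gy >= 0)
  frac <- mean(dvh$doses >= threshold_gy)
  if (absolute) frac * length(dvh$doses) * dvh$voxel_cc else 100 * frac
}

#' Minimum dose covering a volume (D_p)
#'
#' The minimum dose received by the hottest `percent`% of the structure:
#' the largest dose `d` such that at least `percent`% of voxels receive
#' `>= d`.  Computed from exact order statistics, not interpolated bins.
#'
#' @param dvh a `dvh_curve`.
#' @param percent volume percentage in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, percent) {
  stopifnot(inherits(dvh, "dvh_curve"))
  if (percent <= 0 || percent > 100) stop("percent must be in (0, 100]")
  n <- length(dvh$doses)
  k <- ceiling(percent * n / 100)
  dvh$doses[n - k + 1L]
}

#' Mean structure dose
#'
#' @param dose a `dose_grid`.
#' @param mask a non-empty `structure_mask` on the same grid.
#' @return Mean voxel dose in Gy.
#' @export
mean_dose <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  if (!same_grid(dose$grid, mask$grid)) stop("dose and mask are on different grids")
  if (!any(mask$occupancy)) stop("mean dose of an empty mask is undefined")
  mean(dose$dose[mask$occupancy])
}

#' Conformity number
#'
#' `CN = (TV_PIV / TV) * (TV_PIV / PIV)` where `TV` is the target volume,
#' `PIV` the volume (anywhere on the grid) receiving at least the
#' prescription, and `TV_PIV` their intersection.  1 for a perfectly
#' conformal prescription isodose, 0 when nothing reaches prescription.
#'
#' @param dose a `dose_grid`.
#' @param ptv the target `structure_mask`.
#' @param rx_gy prescription dose in Gy.
#' @param inclusive if TRUE (default) "receiving the prescription dose"
#'   means `>= rx_gy`; FALSE uses a strict `>`.
#' @return List with `cn`, `tv_cc`, `piv_cc`, `tv_piv_cc`.
#' @export
conformity_number <- function(dose, ptv, rx_gy, inclusive = TRUE) {
  stopifnot(inherits(dose, "dose_grid"), inherits(ptv, "structure_mask"), rx_gy > 0)
  if (!same_grid(dose$grid, ptv$grid)) stop("dose and mask are on different grids")
  if (!any(ptv$occupancy)) stop("conformity number of an empty target is undefined")
  hot <- if (inclusive) dose$dose >= rx_gy else dose$dose > rx_gy
  vox <- ptv$grid$voxel_cc
  tv <- sum(ptv$occupancy) * vox
  piv <- sum(hot) * vox
  tv_piv <- sum(hot & ptv$occupancy) * vox
  if (piv == 0) {
    warning("no voxel reaches the prescription dose; CN defined as 0")
    cn <- 0
  } else {
    cn <- (tv_piv / tv) * (tv_piv / piv)
  }
  list(cn = cn, tv_cc = tv, piv_cc = piv, tv_piv_cc = tv_piv)
}

#' Homogeneity index
#'
#' `HI = (D_2 - D_98) / D_50` over the target; 0 for a perfectly
#' homogeneous target dose.  Scale-free in the dose.
#'
#' @param dose a `dose_grid`.
#' @param ptv the target `structure_mask`.
#' @return HI (dimensionless scalar >= 0).
#' @export
homogeneity_index <- function(dose, ptv) {
  dvh <- cumulative_dvh(dose, ptv)
  d50 <- dose_at_volume(dvh, 50)
  if (d50 <= 0) stop("undefined metric: D_50 of the target is zero")
  (dose_at_volume(dvh, 2) - dose_at_volume(dvh, 98)) / d50
}

#' Target plan-quality metrics
#'
#' Convenience wrapper combining [conformity_number()] and
#' [homogeneity_index()] with the D_2 / D_50 / D_98 order statistics.
#'
#' @inheritParams conformity_number
#' @return List with `cn`, `hi`, `tv_cc`, `piv_cc`, `tv_piv_cc`, `d2_gy`,
#'   `d50_gy`, `d98_gy`.
#' @export
plan_quality <- function(dose, ptv, rx_gy, inclusive = TRUE) {
  cn <- conformity_number(dose, ptv, rx_gy, inclusive)
  dvh <- cumulative_dvh(dose, ptv)
  d2 <- dose_at_volume(dvh, 2); d50 <- dose_at_volume(dvh, 50)
  d98 <- dose_at_volume(dvh, 98)
  c(cn, list(hi = (d2 - d98) / d50, d2_gy = d2, d50_gy = d50, d98_gy = d98))
}

#' Overlap predictive parameters from volumes
#'
#' The conventional overlap predictive parameter is the overlapped fraction
#' of the organ at risk, `COPP = V_OV / V_OAR`.  The proposed parameter
#' additionally weights by the target-to-organ volume ratio,
#' `POPP = COPP * V_PTV / V_OAR`, so that two geometries with equal overlap
#' fraction but different target sizes are distinguished.
#'
#' @param v_ov_cc overlap volume of OAR and PTV (cc).
#' @param v_oar_cc OAR volume (cc), > 0.
#' @param v_ptv_cc PTV volume (cc).
#' @return A list of class `overlap_features` with fields `v_ov_cc`,
#'   `v_oar_cc`, `v_ptv_cc`, `copp`, `popp`.
#' @examples
#' overlap_params(3.3, 49.9, 162.7)$copp   # 0.0661
#' overlap_params(3.3, 49.9, 188.0)$popp   # 0.2492
#' @export
overlap_params <- function(v_ov_cc, v_oar_cc, v_ptv_cc) {
  if (v_oar_cc <= 0) stop("OAR volume must be positive (division by zero)")
  if (v_ov_cc < 0 || v_ptv_cc < 0) stop("volumes must be non-negative")
  if (v_ov_cc > v_oar_cc + 1e-9) stop("overlap volume cannot exceed the OAR volume")
  copp <- v_ov_cc / v_oar_cc
  structure(list(v_ov_cc = v_ov_cc, v_oar_cc = v_oar_cc, v_ptv_cc = v_ptv_cc,
                 copp = copp, popp = copp * v_ptv_cc / v_oar_cc),
            class = "overlap_features")
}

#' Overlap predictive parameters from structure masks
#'
#' Measures `V_OV`, `V_OAR` and `V_PTV` from the masks and applies
#' [overlap_params()].
#'
#' @param oar a non-empty organ-at-risk `structure_mask`.
#' @param ptv the target `structure_mask` on the same grid.
#' @return An `overlap_features` list.
#' @export
overlap_features <- function(oar, ptv) {
  stopifnot(inherits(oar, "structure_mask"), inherits(ptv, "structure_mask"))
  if (!same_grid(oar$grid, ptv$grid)) stop("masks are on different grids")
  v_oar <- mask_volume(oar)
  if (v_oar == 0) stop("OAR mask is empty (division by zero)")
  overlap_params(overlap_volume(oar, ptv), v_oar, mask_volume(ptv))
}

#' @export
print.overlap_features <- function(x, ...) {
  cat(sprintf("<overlap_features> V_OV %.2f / V_OAR %.2f / V_PTV %.2f cc | COPP %.4f | POPP %.4f\n",
              x$v_ov_cc, x$v_oar_cc, x$v_ptv_cc, x$copp, x$popp))
  invisible(x)
}
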