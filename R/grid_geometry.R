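#' Create an axis-aligned voxel grid
#'
#' The grid is the common frame for all structure masks and dose arrays.
#' Coordinates are patient-style: +x = left, +y = anterior, +z = superior,
#' all in millimetres.  The realized lattice is centred on the origin
#' `(0, 0, 0)`; voxel `i` along an axis has its centre at
#' `origin + (i - 0.5) * spacing`.
#'
#' @param extent_mm length-3 numeric, physical extent of the grid (mm).
#' @param spacing_mm length-3 numeric (or scalar), voxel spacing (mm).
#' @return An object of class `voxel_grid` with fields `origin_mm`,
#'   `spacing_mm`, `shape` and `voxel_cc` (voxel volume in cc).
#' @examples
#' g <- make_grid(c(200, 200, 200), 2)
#' g$shape      # 100 100 100
#' g$voxel_cc   # 0.008
#' @export
make_grid <- function(extent_mm, spacing_mm = 2) {
  extent_mm <- as.numeric(extent_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(extent_mm) != 3L || length(spacing_mm) != 3L)
    stop("extent_mm and spacing_mm must have length 3")
  if (any(!is.finite(extent_mm)) || any(extent_mm <= 0) ||
      any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("extents and spacings must be strictly positive and finite")
  shape <- as.integer(ceiling(extent_mm / spacing_mm - 1e-9))
  origin <- -shape * spacing_mm / 2
  structure(
    list(origin_mm = origin, spacing_mm = spacing_mm, shape = shape,
         voxel_cc = prod(spacing_mm) / 1000),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> shape", paste(x$shape, collapse = " x "),
      "| spacing", paste(x$spacing_mm, collapse = " x "), "mm",
      "| voxel", format(x$voxel_cc), "cc\n")
  invisible(x)
}

#' Voxel-centre coordinates along one axis
#' @param grid a `voxel_grid`.
#' @param axis 1, 2 or 3 (x, y, z).
#' @return Numeric vector of centre coordinates in mm.
#' @keywords internal
axis_centers <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$spacing_mm[axis]
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing_mm, b$spacing_mm)) &&
    isTRUE(all.equal(a$origin_mm, b$origin_mm))
}

new_mask <- function(grid, occ, label = "") {
  dim(occ) <- grid$shape
  structure(list(grid = grid, occupancy = occ, label = label),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat("<structure_mask>", if (nzchar(x$label)) x$label else "(unnamed)",
      "|", format(round(mask_volume(x), 2)), "cc on",
      paste(x$grid$shape, collapse = "x"), "grid\n")
  invisible(x)
}

#' Analytic shape primitives
#'
#' Shape specifications consumed by [rasterize_primitive()].  `ellipsoid()`
#' describes an axis-aligned ellipsoid, `cylinder()` a finite circular
#' cylinder along one grid axis.
#'
#' @param center_mm length-3 numeric centre (mm).
#' @param semiaxes_mm length-3 numeric semi-axes (mm).
#' @param radius_mm cylinder radius (mm).
#' @param half_length_mm half of the cylinder length (mm).
#' @param axis one of `"x"`, `"y"`, `"z"`: the cylinder axis.
#' @return A shape specification list of class `shape_spec`.
#' @export
ellipsoid <- function(center_mm, semiaxes_mm) {
  structure(list(kind = "ellipsoid", center = as.numeric(center_mm),
                 semiaxes = as.numeric(semiaxes_mm)),
            class = "shape_spec")
}

#' @rdname ellipsoid
#' @export
cylinder <- function(center_mm, radius_mm, half_length_mm, axis = "z") {
  axis <- match.arg(axis, c("x", "y", "z"))
  structure(list(kind = "cylinder", center = as.numeric(center_mm),
                 radius = as.numeric(radius_mm),
                 half_length = as.numeric(half_length_mm), axis = axis),
            class = "shape_spec")
}

shift_primitive <- function(primitive, offset_mm) {
  primitive$center <- primitive$center + as.numeric(offset_mm)
  primitive
}

#' Rasterize an analytic primitive onto a grid
#'
#' A voxel is occupied iff its centre lies inside (or on) the analytic
#' surface.  No partial-volume weighting is applied, so rasterized volumes
#' converge to the analytic volume as spacing decreases.
#'
#' @param grid a `voxel_grid`.
#' @param primitive a shape from [ellipsoid()] or [cylinder()].
#' @param label structure name stored on the mask.
#' @return A `structure_mask`.  The primitive is retained as the
#'   `"primitive"` attribute so that downstream solvers can re-rasterize the
#'   structure at sub-voxel offsets.
#' @export
rasterize_primitive <- function(grid, primitive, label = "") {
  if (!inherits(primitive, "shape_spec"))
    stop("unknown shape kind: primitive must be built by ellipsoid() or cylinder()")
  xs <- axis_centers(grid, 1); ys <- axis_centers(grid, 2); zs <- axis_centers(grid, 3)
  if (primitive$kind == "ellipsoid") {
    s <- primitive$semiaxes
    if (any(s <= 0)) {
      occ <- array(FALSE, grid$shape)
    } else {
      dx2 <- ((xs - primitive$center[1]) / s[1])^2
      dy2 <- ((ys - primitive$center[2]) / s[2])^2
      dz2 <- ((zs - primitive$center[3]) / s[3])^2
      occ <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    }
  } else if (primitive$kind == "cylinder") {
    ax <- match(primitive$axis, c("x", "y", "z"))
    rad <- setdiff(1:3, ax)
    cc <- primitive$center
    coords <- list(xs, ys, zs)
    if (primitive$radius <= 0 || primitive$half_length <= 0) {
      occ <- array(FALSE, grid$shape)
    } else {
      d2 <- list()
      d2[[rad[1]]] <- ((coords[[rad[1]]] - cc[rad[1]]) / primitive$radius)^2
      d2[[rad[2]]] <- ((coords[[rad[2]]] - cc[rad[2]]) / primitive$radius)^2
      inside_ax <- abs(coords[[ax]] - cc[ax]) <= primitive$half_length
      d2[[ax]] <- ifelse(inside_ax, 0, Inf)
      occ <- outer(outer(d2[[1]], d2[[2]], `+`), d2[[3]], `+`) <= 1
    }
  } else {
    stop("unknown shape kind: ", primitive$kind)
  }
  if (!any(occ)) warning("primitive does not cover any voxel centre: empty mask")
  m <- new_mask(grid, occ, label)
  attr(m, "primitive") <- primitive
  m
}

#' Structure volume in cc
#'
#' Occupied-voxel count times the voxel volume.
#'
#' @param mask a `structure_mask`.
#' @return Volume in cc (non-negative scalar).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$occupancy) * mask$grid$voxel_cc
}

#' Overlap volume of two structures in cc
#'
#' Volume of the voxelwise conjunction of two masks on the same grid; the
#' quantity `V_OV` entering the overlap predictive parameters.
#'
#' @param a,b `structure_mask` objects on the same grid.
#' @return Overlap volume in cc.
#' @export
overlap_volume <- function(a, b) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  if (!same_grid(a$grid, b$grid)) stop("masks are on different grids")
  sum(a$occupancy & b$occupancy) * a$grid$voxel_cc
}

# Kernel of voxel offsets realizing a (possibly anisotropic, possibly
# asymmetric) margin: offset (i,j,k) is included iff the centre-to-centre
# displacement, scaled per axis by the margin on that side, lies in the
# closed unit ball.  Zero margins admit no displacement on that axis.
margin_kernel <- function(margins, spacing) {
  m <- margins
  nmax <- function(neg, pos, sp) as.integer(floor(max(neg, pos) / sp + 1e-9))
  rx <- nmax(m[1], m[2], spacing[1])
  ry <- nmax(m[3], m[4], spacing[2])
  rz <- nmax(m[5], m[6], spacing[3])
  off <- as.matrix(expand.grid(ix = -rx:rx, iy = -ry:ry, iz = -rz:rz))
  d <- sweep(off, 2, spacing, `*`)
  scl <- function(dv, neg, pos) {
    mm <- ifelse(dv < 0, neg, pos)
    ifelse(dv == 0, 0, ifelse(mm > 0, (dv / mm)^2, Inf))
  }
  r2 <- scl(d[, 1], m[1], m[2]) + scl(d[, 2], m[3], m[4]) +
    scl(d[, 3], m[5], m[6])
  off[r2 <= 1 + 1e-9, , drop = FALSE]
}

# Scaled Euclidean distance (margins as per-axis units) from points u
# (rows, already divided by margins) to the ellipsoid with scaled semiaxes
# A; vectorized bisection on the Lagrange multiplier.  Points inside get 0.
scaled_ellipsoid_distance <- function(u, A) {
  g0 <- (u[, 1] / A[1])^2 + (u[, 2] / A[2])^2 + (u[, 3] / A[3])^2
  out <- numeric(nrow(u))
  ext <- which(g0 > 1)
  if (length(ext) == 0) return(out)
  ue <- u[ext, , drop = FALSE]
  r <- sqrt(rowSums(ue^2))
  Amax <- max(A)
  lo <- numeric(length(ext))
  hi <- Amax * r + Amax^2
  gfun <- function(lam) {
    (A[1]^2 * ue[, 1]^2) / (A[1]^2 + lam)^2 +
      (A[2]^2 * ue[, 2]^2) / (A[2]^2 + lam)^2 +
      (A[3]^2 * ue[, 3]^2) / (A[3]^2 + lam)^2
  }
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    too_far <- gfun(mid) > 1      # constraint > 1 means lambda too small
    lo <- ifelse(too_far, mid, lo)
    hi <- ifelse(too_far, hi, mid)
  }
  lam <- (lo + hi) / 2
  d2 <- (ue[, 1] * lam / (A[1]^2 + lam))^2 +
    (ue[, 2] * lam / (A[2]^2 + lam))^2 +
    (ue[, 3] * lam / (A[3]^2 + lam))^2
  out[ext] <- sqrt(d2)
  out
}

# Analytic Minkowski-margin expansion of a primitive, rasterized by the
# voxel-centre rule.  Supports symmetric margins: any margins for a
# cylinder with equal margins on its two radial axes, and strictly
# positive margins for an ellipsoid.  Returns NULL when not applicable.
analytic_expand <- function(grid, primitive, m3) {
  xs <- axis_centers(grid, 1); ys <- axis_centers(grid, 2); zs <- axis_centers(grid, 3)
  if (primitive$kind == "cylinder") {
    ax <- match(primitive$axis, c("x", "y", "z"))
    rad <- setdiff(1:3, ax)
    if (m3[rad[1]] != m3[rad[2]]) return(NULL)
    mr <- m3[rad[1]]; ma <- m3[ax]
    cc <- primitive$center
    coords <- list(xs, ys, zs)
    d1 <- coords[[rad[1]]] - cc[rad[1]]
    d2 <- coords[[rad[2]]] - cc[rad[2]]
    rho <- sqrt(outer(d1^2, d2^2, `+`))
    gap_r <- pmax(0, rho - primitive$radius)
    gap_a <- pmax(0, abs(coords[[ax]] - cc[ax]) - primitive$half_length)
    gr2 <- if (mr > 0) (gap_r / mr)^2 else ifelse(gap_r == 0, 0, Inf)
    ga2 <- if (ma > 0) (gap_a / ma)^2 else ifelse(gap_a == 0, 0, Inf)
    flat <- outer(as.vector(gr2), ga2, `+`) <= 1 + 1e-12
    # flat has radial-plane voxels varying fastest; reorder to (x, y, z)
    occ <- array(FALSE, grid$shape)
    perm <- c(rad[1], rad[2], ax)
    arr <- array(flat, c(grid$shape[rad[1]], grid$shape[rad[2]], grid$shape[ax]))
    occ <- aperm(arr, order(perm))
    return(occ)
  }
  if (primitive$kind == "ellipsoid") {
    if (any(m3 <= 0)) return(NULL)
    s <- primitive$semiaxes
    if (any(s <= 0)) return(NULL)
    occ <- array(FALSE, grid$shape)
    # candidate box: the Minkowski sum lies inside the per-axis box s + m
    ix <- which(abs(xs - primitive$center[1]) <= s[1] + m3[1])
    iy <- which(abs(ys - primitive$center[2]) <= s[2] + m3[2])
    iz <- which(abs(zs - primitive$center[3]) <= s[3] + m3[3])
    if (!length(ix) || !length(iy) || !length(iz)) return(occ)
    pts <- as.matrix(expand.grid(x = xs[ix], y = ys[iy], z = zs[iz]))
    u <- sweep(sweep(pts, 2, primitive$center, `-`), 2, m3, `/`)
    d <- scaled_ellipsoid_distance(u, s / m3)
    occ[as.matrix(expand.grid(ix, iy, iz))] <- d <= 1 + 1e-12
    return(occ)
  }
  NULL
}

normalize_margins <- function(margins_mm) {
  m <- as.numeric(margins_mm)
  if (length(m) == 1L) m <- rep(m, 6L)
  else if (length(m) == 3L) m <- rep(m, each = 2L)
  else if (length(m) != 6L)
    stop("margins_mm must have length 1 (uniform), 3 (per axis) or 6 (per side)")
  if (any(!is.finite(m)) || any(m < 0))
    stop("margins must be finite and non-negative")
  m
}

#' Expand a structure by anisotropic margins
#'
#' Margin expansion in the sense used by treatment-planning systems: the
#' result contains every voxel whose centre lies within the requested
#' per-axis margin of the structure, i.e. within the unit ball after
#' scaling each axis (and each sign of each axis) by its margin.  Masks
#' carrying their analytic primitive (from [rasterize_primitive()]) with
#' symmetric margins are expanded analytically -- the exact Minkowski
#' margin of the surface, rasterized by the voxel-centre rule -- so their
#' expanded volumes converge to the analytic values with spacing.  Raw
#' masks fall back to binary dilation with the scaled-distance structuring
#' element (a thresholded per-axis-scaled Euclidean distance transform
#' between voxel centres), which localizes the surface only to within
#' about half a voxel.
#'
#' @param mask a non-empty `structure_mask`.
#' @param margins_mm scalar (uniform), length-3 `(x, y, z)` symmetric, or
#'   length-6 `(-x, +x, -y, +y, -z, +z)` margins in mm, all >= 0.
#' @return The expanded `structure_mask` (always contains the input).
#' @export
expand_mask <- function(mask, margins_mm) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!any(mask$occupancy)) stop("cannot expand an empty mask")
  m <- normalize_margins(margins_mm)
  if (all(m == 0)) return(mask)
  occ <- NULL
  p <- attr(mask, "primitive")
  symmetric <- all(m[c(1, 3, 5)] == m[c(2, 4, 6)])
  if (!is.null(p) && symmetric)
    occ <- analytic_expand(mask$grid, p, m[c(1, 3, 5)])
  if (is.null(occ)) {
    off <- margin_kernel(m, mask$grid$spacing_mm)
    occ <- cpp_dilate(as.logical(mask$occupancy), mask$grid$shape, off)
  }
  occ <- occ | mask$occupancy
  out <- new_mask(mask$grid, occ, mask$label)
  attr(out, "expanded_by_mm") <- m
  out
}

#' Translate a structure by a physical offset
#'
#' The offset is snapped to whole voxels (`round(offset / spacing)`), which
#' keeps the volume exactly conserved.  Structures that would be clipped by
#' the grid boundary raise an error rather than being silently truncated.
#'
#' @param mask a `structure_mask`.
#' @param offset_mm length-3 numeric offset in mm (+y anterior, -y posterior).
#' @return The shifted `structure_mask`.
#' @export
shift_mask <- function(mask, offset_mm) {
  stopifnot(inherits(mask, "structure_mask"))
  offset_mm <- as.numeric(offset_mm)
  if (length(offset_mm) != 3L || any(!is.finite(offset_mm)))
    stop("offset_mm must be a finite length-3 vector")
  dv <- as.integer(round(offset_mm / mask$grid$spacing_mm))
  if (all(dv == 0L)) return(mask)
  occ <- mask$occupancy
  idx <- which(occ, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(mask)
  idx <- sweep(idx, 2, dv, `+`)
  if (any(idx < 1L) || any(sweep(idx, 2, mask$grid$shape, `>`)))
    stop("shift pushes structure past the grid boundary")
  out <- array(FALSE, mask$grid$shape)
  out[idx] <- TRUE
  res <- new_mask(mask$grid, out, mask$label)
  p <- attr(mask, "primitive")
  if (!is.null(p)) attr(res, "primitive") <- shift_primitive(p, dv * mask$grid$spacing_mm)
  res
}

#' Centroid of a structure in mm
#' @param mask a non-empty `structure_mask`.
#' @return Length-3 numeric centroid in grid coordinates (mm).
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask$occupancy, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no centroid")
  g <- mask$grid
  ctr <- unname(colMeans(idx))
  g$origin_mm + (ctr - 0.5) * g$spacing_mm
}
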