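#' Experiment configuration
#'
#' A fully serializable description of one end-to-end run: geometry family,
#' dose modality, grid, seeds, sweep range and statistics method.  A run is
#' reproducible from the configuration alone.
#'
#' @param simulation `"simulation1"` (two PTV sizes, fixed overlap ratios)
#'   or `"simulation2"` (81-case factorial of rectum/bladder geometry).
#' @param modality `"imrt"` or `"vmat"` dose preset.
#' @param extent_mm,spacing_mm grid specification (see [make_grid()]).
#' @param seed master integer seed; per-case noise seeds are derived from it.
#' @param sweep_range_gy,sweep_step_gy dose levels of the correlation sweep.
#' @param stats_method method for [compare_correlations()].
#' @param goals_only if TRUE, restrict the regression sweep to plans that
#'   meet the protocol's dose goals (all plans are always simulated and
#'   reported).
#' @param dose_params optional `dose_model_params` overriding the modality
#'   preset.
#' @param output_dir optional directory; when given, result tables are
#'   written there as CSV plus a JSON manifest.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(simulation = c("simulation2", "simulation1"),
                              modality = c("imrt", "vmat"),
                              extent_mm = c(180, 260, 220), spacing_mm = 2,
                              seed = 1L,
                              sweep_range_gy = c(20, 75), sweep_step_gy = 1,
                              stats_method = "williams",
                              goals_only = FALSE,
                              dose_params = NULL,
                              output_dir = NULL) {
  structure(list(simulation = match.arg(simulation),
                 modality = match.arg(modality),
                 extent_mm = extent_mm, spacing_mm = spacing_mm,
                 seed = as.integer(seed),
                 sweep_range_gy = sweep_range_gy,
                 sweep_step_gy = sweep_step_gy,
                 stats_method = stats_method,
                 goals_only = goals_only,
                 dose_params = dose_params,
                 output_dir = output_dir),
            class = "experiment_config")
}

case_seed <- function(master, i, modality) {
  (abs(master) %% 10000L) * 100000L + i * 2L + (modality == "vmat")
}

#' Per-case metrics for one simulated plan
#' @keywords internal
case_metrics <- function(case, dose, protocol, levels_gy) {
  rx <- protocol$rx_gy
  pq <- plan_quality(dose, case$ptv, rx)
  goals <- check_plan_goals(dose, case, protocol)
  feats <- list(rectum = overlap_features(case$rectum, case$ptv),
                bladder = overlap_features(case$bladder, case$ptv))
  oar_row <- function(oar) {
    d <- dose$dose[case[[oar]]$occupancy]
    vx <- vapply(levels_gy, function(x) 100 * mean(d >= x), numeric(1))
    list(dmean = mean(d),
         v70 = 100 * mean(d >= 70), v60 = 100 * mean(d >= 60),
         v375 = 100 * mean(d >= 37.5), vx = vx)
  }
  ptv_d <- dose$dose[case$ptv$occupancy]
  list(coverage_pct = 100 * mean(ptv_d >= rx),
       cn = pq$cn, hi = pq$hi,
       d2_gy = pq$d2_gy, d50_gy = pq$d50_gy, d98_gy = pq$d98_gy,
       feats = feats,
       rectum = oar_row("rectum"), bladder = oar_row("bladder"),
       goals_pass = goals$pass, goals = goals$goals)
}

#' Run a full phantom experiment
#'
#' Generates the configured geometry family, emulates a plan dose for every
#' case, computes overlap parameters and dose-volume metrics, sweeps the
#' COPP/POPP correlations over the configured dose levels for rectum and
#' bladder, compares them, and extracts the threshold dose.  Deterministic
#' given the configuration.
#'
#' @param config an [experiment_config()].
#' @return A list of class `overlap_experiment` with elements `config`,
#'   `cases` (manifest data.frame), `results` (per-case metric table),
#'   `sweeps` (per-OAR `correlation_sweep` with p-values), `dth_gy`
#'   (per-OAR threshold dose), `summary` (cohort mean/sd and correlation
#'   table), and `goal_pass_n`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- make_grid(config$extent_mm, config$spacing_mm)
  cases <- switch(config$simulation,
    simulation1 = generate_simulation1_cases(grid, config$seed),
    simulation2 = generate_simulation2_cases(grid, config$seed))
  params <- config$dose_params
  if (is.null(params)) params <- dose_preset(config$modality)
  protocol <- planning_protocol(rx_gy = params$rx_gy)
  levels_gy <- seq(config$sweep_range_gy[1], config$sweep_range_gy[2],
                   by = config$sweep_step_gy)

  sdf_cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(cases))
  vx_r <- matrix(NA_real_, length(cases), length(levels_gy))
  vx_b <- matrix(NA_real_, length(cases), length(levels_gy))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    key <- sprintf("%s_%d", cs$ptv$label, sum(cs$ptv$occupancy))
    if (is.null(sdf_cache[[key]]))
      sdf_cache[[key]] <- signed_distance_field(cs$ptv)
    dose <- simulate_plan_dose(cs, params,
                               seed = case_seed(config$seed, i, config$modality),
                               sdf = sdf_cache[[key]])
    m <- case_metrics(cs, dose, protocol, levels_gy)
    vx_r[i, ] <- m$rectum$vx
    vx_b[i, ] <- m$bladder$vx
    rows[[i]] <- data.frame(
      case_id = cs$case_id,
      ptv_cc = cs$ptv_cc, rv_cc = cs$rv_cc, bv_cc = cs$bv_cc,
      rov_cc = cs$rov_cc, bov_cc = cs$bov_cc,
      copp_rectum = m$feats$rectum$copp, popp_rectum = m$feats$rectum$popp,
      copp_bladder = m$feats$bladder$copp, popp_bladder = m$feats$bladder$popp,
      coverage_pct = m$coverage_pct, cn = m$cn, hi = m$hi,
      dmean_rectum = m$rectum$dmean, v70_rectum = m$rectum$v70,
      v60_rectum = m$rectum$v60, v375_rectum = m$rectum$v375,
      dmean_bladder = m$bladder$dmean, v70_bladder = m$bladder$v70,
      v60_bladder = m$bladder$v60, v375_bladder = m$bladder$v375,
      goals_pass = m$goals_pass,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  keep <- if (config$goals_only) results$goals_pass else rep(TRUE, nrow(results))
  if (sum(keep) < 3) stop("fewer than 3 cases available for the regression sweep")

  sweeps <- list(
    rectum = compare_correlations(
      sweep_correlations(results$copp_rectum[keep], results$popp_rectum[keep],
                         vx_r[keep, , drop = FALSE], levels_gy),
      method = config$stats_method),
    bladder = compare_correlations(
      sweep_correlations(results$copp_bladder[keep], results$popp_bladder[keep],
                         vx_b[keep, , drop = FALSE], levels_gy),
      method = config$stats_method))
  dth <- vapply(sweeps, function(s) suppressWarnings(threshold_dose(s)), numeric(1))

  out <- structure(
    list(config = config, cases = case_manifest(cases), results = results,
         vx = list(rectum = vx_r, bladder = vx_b, dose_levels_gy = levels_gy),
         sweeps = sweeps, dth_gy = dth,
         summary = summarize_experiment(results),
         goal_pass_n = sum(results$goals_pass)),
    class = "overlap_experiment")
  if (!is.null(config$output_dir)) write_results_table(out, config$output_dir)
  out
}

#' @export
print.overlap_experiment <- function(x, ...) {
  cat(sprintf("<overlap_experiment> %s / %s | %d cases | %d meet dose goals\n",
              x$config$simulation, toupper(x$config$modality),
              nrow(x$results), x$goal_pass_n))
  cat(sprintf("  threshold dose: rectum %.1f Gy, bladder %.1f Gy\n",
              x$dth_gy[["rectum"]], x$dth_gy[["bladder"]]))
  invisible(x)
}

#' Cohort summary table (metric rows by predictor columns)
#'
#' Mean and standard deviation of each dose-volume metric with the Pearson
#' correlation coefficient of COPP and of POPP, per organ at risk.
#'
#' @param results a per-case results table from [run_experiment()].
#' @return A data.frame with one row per OAR x metric.
#' @export
summarize_experiment <- function(results) {
  metric_cols <- list(dmean = "dmean", v70 = "v70", v60 = "v60", v375 = "v375")
  rows <- list()
  for (oar in c("rectum", "bladder")) {
    copp <- results[[paste0("copp_", oar)]]
    popp <- results[[paste0("popp_", oar)]]
    for (mn in names(metric_cols)) {
      y <- results[[paste0(metric_cols[[mn]], "_", oar)]]
      rows[[length(rows) + 1L]] <- data.frame(
        oar = oar, metric = mn, mean = mean(y), sd = stats::sd(y),
        r_copp = safe_cor(copp, y), r_popp = safe_cor(popp, y),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write experiment tables to disk
#'
#' Writes the per-case table, the cohort summary, the per-OAR correlation
#' sweeps and a JSON manifest (configuration and seed) as UTF-8 CSV with
#' '.' decimal separator.
#'
#' @param x an `overlap_experiment`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_results_table <- function(x, dir) {
  stopifnot(inherits(x, "overlap_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(x$results, "cases.csv")
  wr(x$cases, "case_manifest.csv")
  wr(x$summary, "summary.csv")
  for (oar in names(x$sweeps)) {
    sw <- as.data.frame(x$sweeps[[oar]])
    wr(sw, sprintf("sweep_%s.csv", oar))
  }
  cfg <- x$config
  cfg$dose_params <- if (is.null(cfg$dose_params)) NULL else unclass(cfg$dose_params)
  manifest <- list(config = unclass(cfg),
                   dth_gy = as.list(x$dth_gy),
                   goal_pass_n = x$goal_pass_n,
                   n_cases = nrow(x$results),
                   package_version = as.character(utils::packageVersion("overlapdose")))
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

# ---- structure/dose import (plain-text adapters) --------------------------

#' Read a contour table
#'
#' Plain-text exchange format for planar structure contours (one row per
#' polygon vertex): columns `structure`, `z_mm`, `contour` (polygon index
#' within a slice, for multi-polygon slices), `x_mm`, `y_mm`, with vertices
#' in drawing order.
#'
#' @param path CSV file path.
#' @return A data.frame of contour vertices.
#' @export
read_contour_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure", "z_mm", "contour", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("contour table must have columns: ", paste(need, collapse = ", "))
  df
}

# Even-odd (crossing number) point-in-polygon, vectorized over points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize planar contours onto a grid
#'
#' Slice-wise even-odd polygon fill at voxel centres: a voxel is occupied
#' iff its centre lies inside an odd number of the structure's polygons on
#' the nearest contour plane.  Contour planes are snapped to the nearest
#' grid slice.
#'
#' @param grid a `voxel_grid`.
#' @param contours a contour table (see [read_contour_table()]).
#' @param structure structure name to rasterize.
#' @return A `structure_mask`.
#' @export
rasterize_contours <- function(grid, contours, structure) {
  df <- contours[contours$structure == structure, , drop = FALSE]
  if (nrow(df) == 0) stop("structure not found in contour table: ", structure)
  occ <- array(FALSE, grid$shape)
  xs <- axis_centers(grid, 1); ys <- axis_centers(grid, 2); zs <- axis_centers(grid, 3)
  pxy <- expand.grid(x = xs, y = ys)
  for (z in unique(df$z_mm)) {
    k <- which.min(abs(zs - z))
    if (abs(zs[k] - z) > grid$spacing_mm[3]) next
    sl <- df[df$z_mm == z, , drop = FALSE]
    plane <- rep(FALSE, nrow(pxy))
    for (cid in unique(sl$contour)) {
      poly <- sl[sl$contour == cid, , drop = FALSE]
      plane <- xor(plane, points_in_polygon(pxy$x, pxy$y, poly$x_mm, poly$y_mm))
    }
    occ[, , k] <- occ[, , k] | matrix(plane, grid$shape[1], grid$shape[2])
  }
  if (!any(occ)) warning("contours cover no voxel centre: empty mask")
  new_mask(grid, occ, structure)
}

#' Read a dose grid from a long-format table
#'
#' Plain-text exchange format for dose grids: columns `i`, `j`, `k`
#' (1-based voxel indices) and `value`; values are multiplied by
#' `dose_scaling` to obtain Gy (mirroring integer-scaled dose exports).
#'
#' @param path CSV file path.
#' @param grid the `voxel_grid` the dose refers to.
#' @param dose_scaling multiplicative factor from stored values to Gy.
#' @return A `dose_grid`.
#' @export
read_dose_table <- function(path, grid, dose_scaling = 1) {
  df <- utils::read.csv(path)
  need <- c("i", "j", "k", "value")
  if (!all(need %in% names(df)))
    stop("dose table must have columns: ", paste(need, collapse = ", "))
  dose <- array(0, grid$shape)
  dose[cbind(df$i, df$j, df$k)] <- df$value * dose_scaling
  structure(list(grid = grid, dose = dose), class = "dose_grid")
}

#' Write a mask or dose volume as NIfTI
#'
#' Research-format volumetric export (spacing carried in the header).
#' Requires the `RNifti` package.
#'
#' @param x a `structure_mask` or `dose_grid`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume_nifti <- function(x, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  arr <- if (inherits(x, "dose_grid")) x$dose else x$occupancy * 1
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$grid$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
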