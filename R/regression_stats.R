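#' Ordinary least-squares fit of a metric on a predictive parameter
#'
#' @param x predictor values (COPP or POPP), not constant.
#' @param y metric values, same length as `x`, n >= 3.
#' @return A list of class `regression_result` with `slope`, `intercept`,
#'   `pearson_r`, `n` and `residual_sd`.
#' @export
linear_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 observations are required")
  if (stats::sd(x) == 0) stop("degenerate predictor: x is constant")
  fit <- stats::lm.fit(cbind(intercept = 1, x = x), y)
  res <- fit$residuals
  structure(list(slope = unname(fit$coefficients["x"]),
                 intercept = unname(fit$coefficients["intercept"]),
                 pearson_r = stats::cor(x, y),
                 n = length(x),
                 residual_sd = sqrt(sum(res^2) / (length(x) - 2))),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.4g + %.4g x | R = %.3f | n = %d\n",
              x$intercept, x$slope, x$pearson_r, x$n))
  invisible(x)
}

safe_cor <- function(x, y) {
  if (stats::sd(y) == 0 || stats::sd(x) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Correlation sweep over 1-Gy dose levels
#'
#' For every dose level, the Pearson correlation of the cohort's V_xGy
#' values against COPP and against POPP.  Levels at which the metric is
#' constant across the cohort get `NA` correlations.
#'
#' @param copp,popp per-case predictive parameters (length n >= 3).
#' @param vx numeric matrix, n cases x L dose levels, of V_xGy values.
#' @param dose_levels_gy length-L numeric vector of dose levels (Gy).
#' @return A data.frame of class `correlation_sweep` with columns
#'   `dose_gy`, `r_copp`, `r_popp`; the per-case data are retained in
#'   attributes for [compare_correlations()].
#' @export
sweep_correlations <- function(copp, popp, vx, dose_levels_gy) {
  copp <- as.numeric(copp); popp <- as.numeric(popp)
  vx <- as.matrix(vx)
  if (length(copp) < 3) stop("degenerate fit: fewer than 3 cases")
  stopifnot(length(popp) == length(copp), nrow(vx) == length(copp),
            ncol(vx) == length(dose_levels_gy))
  r_copp <- apply(vx, 2, safe_cor, x = copp)
  r_popp <- apply(vx, 2, safe_cor, x = popp)
  out <- data.frame(dose_gy = dose_levels_gy, r_copp = r_copp, r_popp = r_popp)
  class(out) <- c("correlation_sweep", "data.frame")
  attr(out, "copp") <- copp
  attr(out, "popp") <- popp
  attr(out, "vx") <- vx
  out
}

#' Williams test for two dependent overlapping correlations
#'
#' Tests whether two correlations `r12 = cor(y, x2)` and `r13 = cor(y, x3)`
#' sharing the variable `y` differ, given the inter-predictor correlation
#' `r23` (Williams' t, in Steiger's formulation), on `n - 3` degrees of
#' freedom.
#'
#' @param r12,r13 the two correlations sharing a variable.
#' @param r23 correlation between the two predictors.
#' @param n sample size (> 3).
#' @return List with `statistic` (t), `df` and `p_value` (two-sided).
#' @export
williams_r_test <- function(r12, r13, r23, n) {
  if (n <= 3) stop("insufficient data: Williams test needs n > 3")
  if (any(is.na(c(r12, r13, r23)))) {
    return(list(statistic = NA_real_, df = n - 3, p_value = NA_real_))
  }
  if (r12 == r13) return(list(statistic = 0, df = n - 3, p_value = 1))
  # clamp tiny negative determinants arising from near-degenerate triples
  detR <- max(0, 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23)
  rbar <- (r12 + r13) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3
  if (denom <= 0) return(list(statistic = NA_real_, df = n - 3,
                              p_value = NA_real_))
  tval <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  list(statistic = tval, df = n - 3,
       p_value = 2 * stats::pt(-abs(tval), df = n - 3))
}

#' Compare the COPP and POPP correlation series
#'
#' Adds per-level p-values for the difference between the two correlation
#' series of a sweep.  The default method tests, at each dose level, the
#' equality of the two dependent correlations sharing the V_xGy variable
#' (Williams/Steiger construction, using the COPP-POPP inter-correlation).
#' The `"paired-t-window"` alternative runs a paired t-test of the two
#' correlation series over a sliding window of neighbouring 1-Gy levels.
#' A Holm-corrected column is emitted alongside the raw p-values.
#'
#' @param sweep a `correlation_sweep` from [sweep_correlations()].
#' @param method `"williams"` (default) or `"paired-t-window"`.
#' @param window window width in levels for the paired-t variant (odd).
#' @param alpha significance level for the reported ranges.
#' @return The sweep with columns `p_value` and `p_holm` added, plus a
#'   `significant_ranges` attribute (see [significant_ranges()]).
#' @export
compare_correlations <- function(sweep, method = c("williams", "paired-t-window"),
                                 window = 5, alpha = 0.05) {
  stopifnot(inherits(sweep, "correlation_sweep"))
  method <- match.arg(method)
  copp <- attr(sweep, "copp"); popp <- attr(sweep, "popp")
  n <- length(copp)
  if (method == "williams") {
    if (n <= 3) stop("insufficient data for the Williams test (n <= 3)")
    r23 <- stats::cor(copp, popp)
    p <- vapply(seq_len(nrow(sweep)), function(i) {
      williams_r_test(sweep$r_copp[i], sweep$r_popp[i], r23, n)$p_value
    }, numeric(1))
  } else {
    L <- nrow(sweep)
    if (L < window) stop("insufficient data: fewer levels than the window")
    half <- floor(window / 2)
    p <- vapply(seq_len(L), function(i) {
      lo <- max(1, i - half); hi <- min(L, i + half)
      a <- sweep$r_copp[lo:hi]; b <- sweep$r_popp[lo:hi]
      ok <- !is.na(a) & !is.na(b)
      d <- a[ok] - b[ok]
      if (length(d) < 2) return(NA_real_)
      if (all(abs(d) < 1e-12)) return(1)
      if (stats::sd(d) == 0) return(0)
      stats::t.test(d)$p.value
    }, numeric(1))
  }
  sweep$p_value <- p
  sweep$p_holm <- stats::p.adjust(p, method = "holm")
  attr(sweep, "method") <- method
  attr(sweep, "significant_ranges") <-
    significant_ranges(sweep$dose_gy, p, sweep$r_popp - sweep$r_copp, alpha)
  sweep
}

#' Contiguous dose ranges with a significant correlation difference
#'
#' @param dose_gy dose levels (Gy).
#' @param p per-level p-values.
#' @param delta_r per-level `r_popp - r_copp` (sign decides which predictor
#'   leads in the range).
#' @param alpha significance level.
#' @return A data.frame with `from_gy`, `to_gy` and `better` ("popp" or
#'   "copp") per contiguous significant run; zero rows if none.
#' @export
significant_ranges <- function(dose_gy, p, delta_r = NULL, alpha = 0.05) {
  sig <- !is.na(p) & p < alpha
  if (!any(sig)) {
    return(data.frame(from_gy = numeric(0), to_gy = numeric(0),
                      better = character(0)))
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- data.frame(from_gy = dose_gy[starts[keep]], to_gy = dose_gy[ends[keep]])
  out$better <- vapply(keep, function(k) {
    if (is.null(delta_r)) return(NA_character_)
    if (mean(delta_r[starts[k]:ends[k]], na.rm = TRUE) > 0) "popp" else "copp"
  }, character(1))
  out
}

#' Threshold dose where the two predictors are equally informative
#'
#' Scanning upward in dose, the first sign change of
#' `delta_r = r_popp - r_copp` from positive to negative is located by
#' linear interpolation; below the threshold POPP correlates better with
#' V_xGy, above it COPP does.  Absence of a crossing is a valid outcome
#' (`NA`); multiple crossings are reported with a warning and the first is
#' returned.
#'
#' @param sweep a `correlation_sweep`.
#' @return Threshold dose in Gy, or `NA` if `delta_r` never crosses from
#'   positive to negative.
#' @export
threshold_dose <- function(sweep) {
  stopifnot(inherits(sweep, "correlation_sweep"))
  ok <- !is.na(sweep$r_copp) & !is.na(sweep$r_popp)
  lev <- sweep$dose_gy[ok]
  dr <- (sweep$r_popp - sweep$r_copp)[ok]
  if (length(dr) < 2) return(NA_real_)
  crossings <- numeric(0)
  for (i in seq_len(length(dr) - 1)) {
    if (dr[i] == 0) {
      if (i == 1 || dr[i - 1] > 0) crossings <- c(crossings, lev[i])
    } else if (dr[i] > 0 && dr[i + 1] < 0) {
      crossings <- c(crossings,
                     lev[i] + (lev[i + 1] - lev[i]) * dr[i] / (dr[i] - dr[i + 1]))
    }
  }
  if (dr[length(dr)] == 0 && length(dr) > 1 && dr[length(dr) - 1] > 0)
    crossings <- c(crossings, lev[length(dr)])
  crossings <- unique(crossings)
  if (length(crossings) == 0) return(NA_real_)
  if (length(crossings) > 1)
    warning(sprintf("multiple positive-to-negative crossings (%s Gy); returning the first",
                    paste(round(crossings, 2), collapse = ", ")))
  crossings[1]
}
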