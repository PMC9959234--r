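#' Lassen occupancy plot
#'
#' Across-region ordinary least squares of y_r = x_r - b_r on x_r, where
#' x_r is the baseline V_T and b_r the blocking-scan V_T (each divided by
#' its scan's plasma free fraction f_P in `fp_corrected` mode). The slope
#' estimates drug occupancy; the x-intercept estimates the
#' nondisplaceable distribution volume V_ND (in the plotted units, i.e.
#' V_T/f_P units in corrected mode).
#'
#' Regions missing in either condition are dropped pairwise and listed.
#' Points with |studentized residual| > 3 are flagged but never removed.
#' Occupancy outside [0, 1] is reported and flagged, not censored.
#'
#' @param baseline,blocking Named numeric vectors of regional V_T
#'   (mL/cm^3); names are matched, NA allowed.
#' @param fp_base,fp_block Plasma free fractions in (0, 1\] (required in
#'   `fp_corrected` mode).
#' @param mode `"raw_VT"` or `"fp_corrected"`.
#' @return An object of class `occupancy_result` with elements
#'   `occupancy`, `se_occupancy`, `vnd`, `se_vnd`, `r_squared`,
#'   `regions_used`, `regions_dropped`, `outliers`, `mode`, `fit` (the lm)
#'   and `flags`.
#' @export
lassen <- function(baseline, blocking, fp_base = NULL, fp_block = NULL,
                   mode = c("raw_VT", "fp_corrected")) {
  mode <- match.arg(mode)
  if (is.null(names(baseline)) || is.null(names(blocking))) {
    stop("baseline and blocking must be named by region")
  }
  common <- intersect(names(baseline), names(blocking))
  x <- baseline[common]
  b <- blocking[common]
  ok <- is.finite(x) & is.finite(b)
  dropped <- common[!ok]
  x <- x[ok]; b <- b[ok]
  if (length(x) < 3L) {
    stop("insufficient data: at least 3 paired regions required")
  }
  if (any(x <= 0) || any(b <= 0)) stop("V_T values must be > 0")
  if (mode == "fp_corrected") {
    if (is.null(fp_base) || is.null(fp_block)) {
      stop("fp_corrected mode requires fp_base and fp_block")
    }
    if (fp_base <= 0 || fp_base > 1 || fp_block <= 0 || fp_block > 1) {
      stop("free fractions must be in (0, 1]")
    }
    x <- x / fp_base
    b <- b / fp_block
  }
  if (stats::sd(x) < 1e-12 * mean(abs(x))) {
    stop("degenerate design: baseline values have zero variance")
  }
  y <- x - b
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  slope <- unname(co[2L])
  intercept <- unname(co[1L])
  vc <- suppressWarnings(stats::vcov(fit))
  se_slope <- sqrt(vc[2L, 2L])
  flags <- character(0)
  if (abs(slope) < 1e-12) {
    vnd <- NA_real_
    se_vnd <- NA_real_
    flags <- c(flags, "zero_slope_vnd_undefined")
  } else {
    vnd <- -intercept / slope
    # delta method: g = (-1/s, a/s^2) on (intercept, slope)
    g <- c(-1 / slope, intercept / slope^2)
    v <- drop(t(g) %*% vc %*% g)
    se_vnd <- if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  }
  if (is.finite(slope) && (slope < 0 || slope > 1)) {
    flags <- c(flags, "occupancy_outside_unit_interval")
  }
  rs <- suppressWarnings(stats::rstudent(fit))
  outliers <- names(x)[is.finite(rs) & abs(rs) > 3]
  # suppressed: summary.lm warns on an (legitimate) exactly collinear fit
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    occupancy = slope, se_occupancy = se_slope,
    vnd = vnd, se_vnd = se_vnd,
    r_squared = r2,
    regions_used = names(x), regions_dropped = dropped,
    outliers = outliers, mode = mode, fit = fit,
    x = x, y = y, flags = flags
  ), class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf(
    "<occupancy_result> occupancy = %.1f%% (SE %.1f), V_ND = %.3g (SE %.3g), R2 = %.3f [%s, %d regions]\n",
    100 * x$occupancy, 100 * x$se_occupancy, x$vnd, x$se_vnd,
    x$r_squared, x$mode, length(x$regions_used)))
  if (length(x$regions_dropped)) {
    cat("  dropped:", paste(x$regions_dropped, collapse = ", "), "\n")
  }
  if (length(x$outliers)) {
    cat("  flagged outliers:", paste(x$outliers, collapse = ", "), "\n")
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Nondisplaceable binding potential
#'
#' BP_ND = (V_T - V_ND) / V_ND.
#'
#' @param vt Total volume of distribution, mL/cm^3.
#' @param vnd Nondisplaceable volume of distribution, mL/cm^3 (> 0).
#' @return BP_ND (unitless), vectorized over `vt`.
#' @export
bpnd <- function(vt, vnd) {
  if (!is.numeric(vnd) || length(vnd) != 1L || vnd <= 0) {
    stop("vnd must be a single value > 0")
  }
  (vt - vnd) / vnd
}

#' Guo plot: cross-tracer regional V_T regression
#'
#' Ordinary least squares of tracer B's regional V_T on tracer A's, over
#' paired non-missing regions, to compare binding distribution and
#' relative affinity of two tracers.
#'
#' @param vt_tracer_a,vt_tracer_b Named numeric vectors of regional V_T.
#' @return List of class `guo_fit` with `slope`, `intercept`,
#'   `r_squared`, `regions_used`, `regions_dropped` and `fit`.
#' @export
guo_plot <- function(vt_tracer_a, vt_tracer_b) {
  if (is.null(names(vt_tracer_a)) || is.null(names(vt_tracer_b))) {
    stop("V_T vectors must be named by region")
  }
  common <- intersect(names(vt_tracer_a), names(vt_tracer_b))
  a <- vt_tracer_a[common]
  b <- vt_tracer_b[common]
  ok <- is.finite(a) & is.finite(b)
  dropped <- common[!ok]
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) {
    stop("insufficient data: at least 3 paired regions required")
  }
  if (stats::sd(a) < 1e-12 * mean(abs(a))) {
    stop("degenerate design: tracer-A values have zero variance")
  }
  fit <- stats::lm(b ~ a)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    regions_used = names(a), regions_dropped = dropped, fit = fit
  ), class = "guo_fit")
}

#' @export
print.guo_fit <- function(x, ...) {
  cat(sprintf("<guo_fit> slope = %.3f, intercept = %.3f, R2 = %.3f (%d regions)\n",
              x$slope, x$intercept, x$r_squared, length(x$regions_used)))
  invisible(x)
}

#' Absolute V_ND from a free-fraction-normalized estimate
#'
#' Converts a V_ND/f_P estimate (the x-intercept of an fp-corrected Lassen
#' plot) back to absolute units by multiplying with the baseline plasma
#' free fraction.
#'
#' @param vnd_over_fp V_ND / f_P, mL/cm^3.
#' @param fp Plasma free fraction in (0, 1].
#' @return V_ND in mL/cm^3.
#' @export
derive_vnd_absolute <- function(vnd_over_fp, fp) {
  if (any(fp <= 0 | fp > 1)) stop("fp must be in (0, 1]")
  vnd_over_fp * fp
}
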