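#' Frame schedule for a dynamic PET acquisition
#'
#' A frame schedule holds the binning of a dynamic scan into contiguous,
#' non-overlapping frames. All times are minutes from the start of tracer
#' injection.
#'
#' @param start Numeric vector of frame start times (min), strictly
#'   increasing, first frame at 0 or later.
#' @param duration Numeric vector of frame durations (min), all positive.
#'   Frames must be contiguous: `start[i+1] == start[i] + duration[i]`.
#' @return An object of class `frame_schedule` with elements `start`,
#'   `duration`, `mid`, `end` and `n`.
#' @seealso [frame_schedule_nhp120()] for the 33-frame, 120-min preset.
#' @export
frame_schedule <- function(start, duration) {
  start <- as.numeric(start)
  duration <- as.numeric(duration)
  if (length(start) != length(duration) || length(start) == 0L) {
    stop("`start` and `duration` must be non-empty vectors of equal length")
  }
  if (anyNA(start) || anyNA(duration) || !all(is.finite(c(start, duration)))) {
    stop("frame times must be finite")
  }
  if (any(duration <= 0)) stop("all frame durations must be > 0")
  if (any(diff(start) <= 0)) stop("frame starts must be strictly increasing")
  if (start[1L] < 0) stop("first frame must not start before injection (t = 0)")
  gaps <- start[-1L] - (start[-length(start)] + duration[-length(duration)])
  if (any(abs(gaps) > 1e-9)) {
    stop("frames must be contiguous and non-overlapping (gap or overlap found)")
  }
  structure(
    list(
      start = start,
      duration = duration,
      mid = start + duration / 2,
      end = start + duration,
      n = length(start)
    ),
    class = "frame_schedule"
  )
}

#' The 33-frame, 120-min non-human-primate frame schedule
#'
#' Standard binning used throughout this package: 6 x 30 s, 3 x 1 min,
#' 2 x 2 min, 22 x 5 min, totalling 120 min in 33 frames.
#'
#' @return A [frame_schedule()].
#' @export
frame_schedule_nhp120 <- function() {
  dur <- c(rep(0.5, 6), rep(1, 3), rep(2, 2), rep(5, 22))
  frame_schedule(start = cumsum(c(0, dur[-length(dur)])), duration = dur)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf(
    "<frame_schedule> %d frames, 0-%g min (durations %s min)\n",
    x$n, x$end[x$n], paste(unique(x$duration), collapse = "/")
  ))
  invisible(x)
}

#' Sparsely sampled activity curve
#'
#' Holds a measured activity-concentration curve (e.g. arterial plasma or
#' whole blood), decay-corrected to injection time.
#'
#' @param times Sample times in minutes, strictly increasing, all >= 0.
#' @param values Activity concentrations in kBq/mL, finite.
#' @param label Free-text label.
#' @return An object of class `sampled_curve`.
#' @export
sampled_curve <- function(times, values, label = "") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (anyNA(times) || anyNA(values) || !all(is.finite(c(times, values)))) {
    stop("sampled_curve requires finite times and values")
  }
  if (any(diff(times) <= 0)) stop("sample times must be strictly increasing")
  if (any(times < 0)) stop("sample times must be >= 0")
  structure(list(times = times, values = values, label = label),
            class = "sampled_curve")
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("<sampled_curve> '%s': %d samples, %g-%g min\n",
              x$label, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

# Exponential tail with the least-squares log-linear slope of the last
# three samples, anchored at the last sample (continuity). Falls back to
# constant extrapolation when the fitted tail is non-decreasing or any of
# the last samples is non-positive.
curve_tail_model <- function(curve) {
  n <- length(curve$times)
  k <- min(3L, n)
  ti <- curve$times[(n - k + 1L):n]
  vi <- curve$values[(n - k + 1L):n]
  if (k < 2L || any(vi <= 0)) {
    return(list(kind = "constant", value = curve$values[n]))
  }
  fit <- stats::lm.fit(cbind(1, ti), log(vi))
  slope <- fit$coefficients[2L]
  if (!is.finite(slope) || slope >= 0) {
    return(list(kind = "constant", value = curve$values[n]))
  }
  # anchored at the last sample so the curve stays continuous there; for
  # exactly log-linear samples this is identical to the least-squares line
  list(kind = "exp", v_end = curve$values[n], t_end = curve$times[n],
       b = unname(slope))
}

#' Evaluate a sampled curve at arbitrary times
#'
#' Piecewise-linear between samples; zero before the first sample; beyond
#' the last sample a single-exponential tail whose rate is the
#' least-squares log-linear slope of the last three samples, anchored at
#' the last sample so the curve stays continuous (constant extrapolation
#' if the fitted tail is non-decreasing or undefined).
#'
#' @param curve A [sampled_curve()].
#' @param t Evaluation times (min), all >= 0.
#' @return Activity concentrations (kBq/mL) at `t`.
#' @export
evaluate_curve <- function(curve, t) {
  stopifnot(inherits(curve, "sampled_curve"))
  if (length(curve$times) < 2L) {
    stop("unusable curve: at least 2 samples required for evaluation")
  }
  t <- as.numeric(t)
  if (any(t < 0)) stop("evaluation times must be >= 0")
  out <- numeric(length(t))
  tmin <- curve$times[1L]
  tmax <- curve$times[length(curve$times)]
  inside <- t >= tmin & t <= tmax
  if (any(inside)) {
    out[inside] <- stats::approx(curve$times, curve$values,
                                 xout = t[inside], method = "linear")$y
  }
  beyond <- t > tmax
  if (any(beyond)) {
    tail <- curve_tail_model(curve)
    out[beyond] <- if (tail$kind == "exp") {
      tail$v_end * exp(tail$b * (t[beyond] - tail$t_end))
    } else {
      tail$value
    }
  }
  out
}

# Coerce a curve-like object to an evaluable function of time.
as_curve_function <- function(x) {
  if (is.function(x)) return(x)
  if (inherits(x, "sampled_curve")) return(function(t) evaluate_curve(x, t))
  if (inherits(x, "input_function")) return(x$fun)
  stop("cannot evaluate object of class ", paste(class(x), collapse = "/"),
       " as a curve")
}

#' Frame-average a continuous-time curve
#'
#' Frame value i is the mean of the curve over frame i, computed by
#' trapezoidal quadrature on an internal uniform grid of step `step` or
#' finer.
#'
#' @param curve A function of time (min), a [sampled_curve()] or an
#'   input function.
#' @param schedule A [frame_schedule()].
#' @param step Maximum quadrature step in minutes (default 0.05).
#' @return Numeric vector of per-frame mean activities.
#' @export
frame_average <- function(curve, schedule, step = 0.05) {
  stopifnot(inherits(schedule, "frame_schedule"), step > 0)
  f <- as_curve_function(curve)
  vapply(seq_len(schedule$n), function(i) {
    a <- schedule$start[i]
    b <- schedule$end[i]
    m <- max(2L, ceiling((b - a) / step) + 1L)
    tt <- seq(a, b, length.out = m)
    vv <- f(tt)
    h <- tt[2L] - tt[1L]
    (h * (sum(vv) - (vv[1L] + vv[m]) / 2)) / (b - a)
  }, numeric(1L))
}

#' Standardized uptake value
#'
#' SUV normalizes a tissue concentration by injected dose per body weight,
#' assuming tissue density 1 g/mL: kBq/mL divided by injected kBq per gram.
#'
#' @param conc Activity concentration, kBq/mL.
#' @param injected_dose Injected dose, MBq (> 0).
#' @param body_weight Body weight, kg (> 0).
#' @return Dimensionless SUV.
#' @export
to_suv <- function(conc, injected_dose, body_weight) {
  if (!is.numeric(injected_dose) || injected_dose <= 0) {
    stop("injected_dose must be > 0 (MBq)")
  }
  if (!is.numeric(body_weight) || body_weight <= 0) {
    stop("body_weight must be > 0 (kg)")
  }
  conc / (injected_dose * 1000 / (body_weight * 1000))
}

#' Regional time-activity curve
#'
#' @param region Region name (see [roi_names()] for the standard list;
#'   other names are accepted).
#' @param schedule A [frame_schedule()].
#' @param frame_means Per-frame mean activities, kBq/mL (or SUV when
#'   `scale` records the normalization).
#' @param scale Optional list with `injected_dose` (MBq) and
#'   `body_weight` (kg) when `frame_means` are in SUV units.
#' @return An object of class `region_tac`.
#' @export
region_tac <- function(region, schedule, frame_means, scale = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  frame_means <- as.numeric(frame_means)
  if (length(frame_means) != schedule$n) {
    stop("frame_means length must equal the number of frames")
  }
  if (anyNA(frame_means) || !all(is.finite(frame_means))) {
    stop("frame_means must be finite")
  }
  structure(list(region = region, schedule = schedule,
                 frame_means = frame_means, scale = scale),
            class = "region_tac")
}

#' @export
print.region_tac <- function(x, ...) {
  cat(sprintf("<region_tac> %s: %d frames, peak %.3g at %g min\n",
              x$region, x$schedule$n, max(x$frame_means),
              x$schedule$mid[which.max(x$frame_means)]))
  invisible(x)
}
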