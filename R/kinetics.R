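#' Kinetic parameters for a one- or two-tissue compartment model
#'
#' Micro-parameters of the standard plasma-input compartment models:
#' influx K1 (mL cm^-3 min^-1), efflux k2 (min^-1), and for the two-tissue
#' model the specific-binding association/dissociation rates k3, k4
#' (min^-1). `vB` is the fractional blood volume contributing whole-blood
#' signal to the measured TAC; `delay` shifts the input function in time.
#'
#' The total volume of distribution follows from the micro-parameters:
#' V_T = K1/k2 (1T) or (K1/k2) (1 + k3/k4) (2T).
#'
#' @param model `"1T"` or `"2T"`.
#' @param K1 Influx rate, > 0.
#' @param k2 Efflux rate, > 0.
#' @param k3 Association rate, >= 0 (2T only).
#' @param k4 Dissociation rate, > 0 (2T only; irreversible trapping with
#'   k4 = 0 is not supported).
#' @param vB Fractional blood volume in \[0, 1\] (default 0.05).
#' @param delay Input time shift in minutes (default 0).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(model = c("2T", "1T"), K1, k2, k3 = NA_real_,
                           k4 = NA_real_, vB = 0.05, delay = 0) {
  model <- match.arg(model)
  if (!is.numeric(K1) || K1 < 0) stop("K1 must be >= 0")
  if (!is.numeric(k2) || k2 <= 0) stop("k2 must be > 0")
  if (!is.numeric(vB) || vB < 0 || vB > 1) stop("vB must be in [0, 1]")
  if (model == "2T") {
    if (!is.numeric(k3) || is.na(k3) || k3 < 0) stop("2T requires k3 >= 0")
    if (!is.numeric(k4) || is.na(k4) || k4 <= 0) {
      stop("2T requires k4 > 0 (irreversible trapping is out of scope)")
    }
  } else {
    k3 <- NA_real_; k4 <- NA_real_
  }
  structure(list(model = model, K1 = K1, k2 = k2, k3 = k3, k4 = k4,
                 vB = vB, delay = delay),
            class = "kinetic_params")
}

#' Total volume of distribution from kinetic parameters
#'
#' @param params A [kinetic_params()].
#' @return V_T in mL/cm^3: K1/k2 (1T) or (K1/k2)(1 + k3/k4) (2T).
#' @export
vt_from_params <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$model == "1T") params$K1 / params$k2
  else (params$K1 / params$k2) * (1 + params$k3 / params$k4)
}

# Macro-rates of the 2T impulse response:
# alpha_{1,2} = [(k2+k3+k4) -/+ sqrt((k2+k3+k4)^2 - 4 k2 k4)] / 2,
# with 0 < alpha1 <= alpha2.
tcm_alphas <- function(k2, k3, k4) {
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4
  root <- sqrt(max(disc, 0))
  c(a1 = (s - root) / 2, a2 = (s + root) / 2)
}

# Tissue impulse response h(t): 1T: K1 e^{-k2 t};
# 2T: K1/(a2-a1) [(k3+k4-a1) e^{-a1 t} + (a2-k3-k4) e^{-a2 t}],
# with the analytic repeated-root limit when a1 == a2.
irf_eval <- function(params, t) {
  if (params$model == "1T") return(params$K1 * exp(-params$k2 * t))
  a <- tcm_alphas(params$k2, params$k3, params$k4)
  da <- a[2L] - a[1L]
  kk <- params$k3 + params$k4
  if (da <= 1e-10 * (a[1L] + a[2L] + 1e-30)) {
    am <- (a[1L] + a[2L]) / 2
    params$K1 * (1 + (kk - am) * t) * exp(-am * t)
  } else {
    (params$K1 / da) * ((kk - a[1L]) * exp(-a[1L] * t) +
                          (a[2L] - kk) * exp(-a[2L] * t))
  }
}

# Trapezoid-rule convolution of two curves sampled on a shared uniform
# grid of step dt, returned on the same grid (FFT-based).
conv_trapz <- function(x, y, dt) {
  n <- length(x)
  # zero-pad to a highly composite length so the FFT stays O(n log n)
  m <- stats::nextn(2L * n - 1L, c(2L, 3L, 5L))
  X <- stats::fft(c(x, numeric(m - n)))
  Y <- stats::fft(c(y, numeric(m - n)))
  z <- Re(stats::fft(X * Y, inverse = TRUE))[seq_len(n)] / m
  dt * (z - 0.5 * x[1L] * y - 0.5 * x * y[1L])
}

# Uniform quadrature grid from 0 to t_end with step <= step, landing
# exactly on t_end.
make_grid <- function(t_end, step = 0.05) {
  n <- max(1L, ceiling(t_end / step - 1e-9))
  seq(0, t_end, length.out = n + 1L)
}

#' Solve the tissue concentration of a compartment model
#'
#' Computes C_T(t) as the analytic impulse response of the model convolved
#' with the arterial input function, by trapezoidal quadrature on an
#' internal uniform grid. C_T(0) = 0.
#'
#' @param params A [kinetic_params()].
#' @param input An input function (see [make_input_function()]) or a plain
#'   function of time.
#' @param t_grid Times (min) at which to return C_T.
#' @param step Maximum quadrature step in minutes (default 0.05).
#' @return Tissue concentrations (kBq/mL) at `t_grid`.
#' @export
solve_tissue <- function(params, input, t_grid, step = 0.05) {
  stopifnot(inherits(params, "kinetic_params"))
  t_grid <- as.numeric(t_grid)
  if (any(t_grid < 0)) stop("t_grid must be >= 0")
  f <- as_curve_function(input)
  grid <- make_grid(max(t_grid, step), step)
  dt <- grid[2L] - grid[1L]
  cp <- shift_eval(f, grid, params$delay)
  ct <- conv_trapz(irf_eval(params, grid), cp, dt)
  stats::approx(grid, ct, xout = t_grid, rule = 2)$y
}

# Evaluate a curve function at (t - delay), zero before the shifted onset.
shift_eval <- function(f, t, delay = 0) {
  if (is.null(delay) || delay == 0) return(f(t))
  ts <- t - delay
  out <- numeric(length(t))
  ok <- ts >= 0
  if (any(ok)) out[ok] <- f(ts[ok])
  out
}

#' Predicted frame means of a measured TAC
#'
#' The model TAC is `(1 - vB) C_T(t) + vB C_blood(t)` frame-averaged on the
#' schedule, where C_blood is the whole-blood curve when available and the
#' total plasma curve as a surrogate otherwise.
#'
#' @param params A [kinetic_params()] (its `vB` is used).
#' @param input Input function.
#' @param whole_blood Optional whole-blood curve ([sampled_curve()] or
#'   function); defaults to the input's total plasma curve, or the input
#'   itself when no plasma provenance is attached.
#' @param schedule A [frame_schedule()].
#' @param step Quadrature step (min).
#' @return Numeric vector of predicted frame means (kBq/mL).
#' @export
model_tac <- function(params, input, whole_blood = NULL, schedule,
                      step = 0.05) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(schedule, "frame_schedule"))
  ctx <- fit_context(schedule, input, whole_blood, t_end = schedule$end[schedule$n],
                     step = step, delay = params$delay)
  par <- if (params$model == "1T") c(params$K1, params$k2)
         else c(params$K1, params$k2, params$k3, params$k4)
  ctx_frame_means(ctx, par, params$model, params$vB)
}

# ---- fitting internals ------------------------------------------------

# Trapezoid frame-mean weight matrix for frames aligned to a uniform grid;
# NULL when a frame boundary does not land on a grid point.
fw_matrix <- function(schedule, grid) {
  dt <- grid[2L] - grid[1L]
  n <- length(grid)
  W <- matrix(0, nrow = schedule$n, ncol = n)
  for (i in seq_len(schedule$n)) {
    i0 <- schedule$start[i] / dt
    i1 <- schedule$end[i] / dt
    if (abs(i0 - round(i0)) > 1e-6 || abs(i1 - round(i1)) > 1e-6) return(NULL)
    i0 <- as.integer(round(i0)) + 1L
    i1 <- as.integer(round(i1)) + 1L
    if (i1 > n) return(NULL)
    wts <- rep(1, i1 - i0 + 1L)
    wts[c(1L, length(wts))] <- 0.5
    W[i, i0:i1] <- wts * dt / schedule$duration[i]
  }
  W
}

# Precompute everything that does not change across optimizer iterations.
fit_context <- function(schedule, input, whole_blood, t_end, step, delay = 0) {
  grid <- make_grid(t_end, step)
  dt <- grid[2L] - grid[1L]
  f_in <- as_curve_function(input)
  blood <- whole_blood
  if (is.null(blood) && inherits(input, "input_function") &&
      !is.null(input$plasma)) {
    blood <- input$plasma
  }
  if (is.null(blood)) blood <- input
  f_bl <- as_curve_function(blood)
  W <- fw_matrix(schedule, grid)
  if (is.null(W)) {
    stop("frame schedule is not aligned to the quadrature grid; ",
         "choose `step` so frame boundaries are multiples of it")
  }
  list(grid = grid, dt = dt,
       cp = shift_eval(f_in, grid, delay),
       cb = shift_eval(f_bl, grid, delay),
       f_in = f_in, f_bl = f_bl, delay = delay,
       W = W, schedule = schedule)
}

# Frame means for a parameter vector (K1, k2[, k3, k4][, delay]).
ctx_frame_means <- function(ctx, par, model, vB, fit_delay = FALSE) {
  if (fit_delay) {
    delay <- par[length(par)]
    par <- par[-length(par)]
    cp <- shift_eval(ctx$f_in, ctx$grid, delay)
    cb <- shift_eval(ctx$f_bl, ctx$grid, delay)
  } else {
    cp <- ctx$cp
    cb <- ctx$cb
  }
  irf <- if (model == "1T") {
    par[1L] * exp(-par[2L] * ctx$grid)
  } else {
    p <- list(model = "2T", K1 = par[1L], k2 = par[2L], k3 = par[3L],
              k4 = par[4L])
    irf_eval(p, ctx$grid)
  }
  ct <- conv_trapz(irf, cp, ctx$dt)
  as.vector(ctx$W %*% ((1 - vB) * ct + vB * cb))
}

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Fitting options
#'
#' @param weights Residual weighting: `"duration"` (w_i proportional to
#'   frame duration, the default for decay-corrected PET counts) or
#'   `"uniform"`.
#' @param n_starts Number of log-uniform multi-starts (default 10). For 2T
#'   fits one extra deterministic start seeded from a 1T fit (k3 at its
#'   lower boundary) is always added, so the 1T solution is always in the
#'   2T search.
#' @param step Quadrature step in minutes (default 0.05).
#' @param t_end Fit window end (min); NULL fits all frames.
#' @param vB Fixed fractional blood volume (default 0.05).
#' @param fit_delay Fit a global input time-shift (min, bounded
#'   \[-2, 2\])? Default FALSE.
#' @param lower,upper Box bounds for each kinetic rate parameter.
#' @param start_seed Fixed internal seed for the multi-start draws.
#' @return A list of options for [fit_model()].
#' @export
fit_options <- function(weights = c("duration", "uniform"), n_starts = 10L,
                        step = 0.05, t_end = NULL, vB = 0.05,
                        fit_delay = FALSE, lower = 1e-4, upper = 2,
                        start_seed = 76543L) {
  list(weights = match.arg(weights), n_starts = as.integer(n_starts),
       step = step, t_end = t_end, vB = vB, fit_delay = fit_delay,
       lower = lower, upper = upper, start_seed = as.integer(start_seed))
}

#' Fit a compartment model to a regional TAC
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt with box bounds)
#' of the 1T or 2T compartment model to frame-binned data, with
#' multi-start initialization. Reports V_T with a delta-method standard
#' error from the Jacobian-based parameter covariance, the relative
#' standard error rSE = 100 SE(V_T)/V_T, the weighted residual sum of
#' squares, and AIC = n log(RSS/n) + 2k with k free kinetic parameters
#' (vB is fixed).
#'
#' @param tac A [region_tac()].
#' @param input Input function (see [make_input_function()]).
#' @param whole_blood Optional whole-blood curve for the vascular term.
#' @param model `"1T"` or `"2T"`.
#' @param options See [fit_options()].
#' @return An object of class `kinetic_fit`. If no start converges the
#'   result is returned with `converged = FALSE` and diagnostics, never an
#'   exception; `rse` is NA when the covariance is singular.
#' @export
fit_model <- function(tac, input, whole_blood = NULL, model = c("2T", "1T"),
                      options = fit_options()) {
  model <- match.arg(model)
  stopifnot(inherits(tac, "region_tac"))
  schedule <- tac$schedule
  t_end <- if (is.null(options$t_end)) schedule$end[schedule$n] else options$t_end
  use <- schedule$end <= t_end + 1e-9
  if (sum(use) < 3L) stop("fewer than 3 frames inside the fit window")
  sub <- frame_schedule(schedule$start[use], schedule$duration[use])
  y <- tac$frame_means[use]
  w <- if (options$weights == "duration") sub$duration / mean(sub$duration)
       else rep(1, sub$n)
  sw <- sqrt(w)
  ctx <- fit_context(sub, input, whole_blood, t_end = sub$end[sub$n],
                     step = options$step)

  np <- if (model == "1T") 2L else 4L
  lower <- rep(options$lower, np)
  upper <- rep(options$upper, np)
  if (options$fit_delay) { lower <- c(lower, -2); upper <- c(upper, 2) }

  resid_fn <- function(par) {
    sw * (y - ctx_frame_means(ctx, par, model, options$vB,
                              fit_delay = options$fit_delay))
  }

  starts <- with_private_seed(options$start_seed, {
    lapply(seq_len(options$n_starts), function(i) {
      p <- exp(stats::runif(np, log(max(options$lower, 1e-4)),
                            log(options$upper)))
      if (options$fit_delay) p <- c(p, 0)
      p
    })
  })
  if (model == "2T") {
    # nested start: 1T fit carried over with k3 at its lower boundary
    opts1 <- options; opts1$fit_delay <- FALSE; opts1$n_starts <- 4L
    fit1 <- tryCatch(
      fit_model(tac, input, whole_blood, model = "1T", options = opts1),
      error = function(e) NULL
    )
    if (!is.null(fit1)) {
      p <- c(fit1$params$K1, fit1$params$k2, options$lower, 0.05)
      if (options$fit_delay) p <- c(p, 0)
      starts <- c(starts, list(pmin(pmax(p, lower), upper)))
    }
  }

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 150)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }

  n <- sub$n
  k <- np + if (options$fit_delay) 1L else 0L
  if (is.null(best)) {
    params <- kinetic_params(model, K1 = NA_real_, k2 = 1, vB = options$vB)
    return(structure(list(
      params = params, model = model, vt = NA_real_, se_vt = NA_real_,
      rse = NA_real_, rss = NA_real_, aic = NA_real_, n_frames = n,
      converged = FALSE, fit_window = c(0, t_end), region = tac$region,
      weights = w, fitted = rep(NA_real_, n), data = y,
      options = options, message = "all starts failed"
    ), class = "kinetic_fit"))
  }

  par <- best$par
  delay <- if (options$fit_delay) par[length(par)] else 0
  kin <- par[seq_len(np)]
  params <- if (model == "1T") {
    kinetic_params("1T", K1 = kin[1L], k2 = kin[2L], vB = options$vB,
                   delay = delay)
  } else {
    kinetic_params("2T", K1 = kin[1L], k2 = kin[2L], k3 = kin[3L],
                   k4 = kin[4L], vB = options$vB, delay = delay)
  }
  vt <- vt_from_params(params)
  rss <- best$deviance
  # an exact (machine-zero) fit has no finite AIC; -Inf keeps comparisons sane
  aic <- if (rss > 0) aic_rss(n, rss, np) else -Inf

  # delta-method SE of V_T from the weighted Jacobian at the optimum
  se_vt <- NA_real_
  if (n > k) {
    J <- num_jacobian(function(p) {
      ctx_frame_means(ctx, p, model, options$vB,
                      fit_delay = options$fit_delay)
    }, par)
    Jw <- sw * J
    sigma2 <- rss / (n - k)
    covm <- tryCatch(sigma2 * solve(crossprod(Jw)), error = function(e) NULL)
    if (!is.null(covm)) {
      g <- vt_gradient(params)
      if (options$fit_delay) g <- c(g, 0)
      v <- drop(t(g) %*% covm %*% g)
      if (is.finite(v) && v >= 0) se_vt <- sqrt(v)
    }
  }

  structure(list(
    params = params, model = model, vt = vt, se_vt = se_vt,
    rse = if (is.na(se_vt)) NA_real_ else 100 * se_vt / vt,
    rss = rss, aic = aic, n_frames = n,
    converged = best$info %in% 1:4, fit_window = c(0, t_end),
    region = tac$region, weights = w,
    fitted = ctx_frame_means(ctx, par, model, options$vB,
                             fit_delay = options$fit_delay),
    data = y, options = options, message = best$message
  ), class = "kinetic_fit")
}

# Central-difference Jacobian of a vector-valued function.
num_jacobian <- function(f, par, rel = 1e-5) {
  f0 <- f(par)
  J <- matrix(0, nrow = length(f0), ncol = length(par))
  for (j in seq_along(par)) {
    h <- max(abs(par[j]) * rel, 1e-9)
    pp <- par; pp[j] <- par[j] + h
    pm <- par; pm[j] <- par[j] - h
    J[, j] <- (f(pp) - f(pm)) / (2 * h)
  }
  J
}

# Gradient of V_T with respect to the kinetic parameter vector.
vt_gradient <- function(params) {
  if (params$model == "1T") {
    c(1 / params$k2, -params$K1 / params$k2^2)
  } else {
    r <- 1 + params$k3 / params$k4
    c(r / params$k2,
      -params$K1 * r / params$k2^2,
      params$K1 / (params$k2 * params$k4),
      -params$K1 * params$k3 / (params$k2 * params$k4^2))
  }
}

#' Akaike information criterion from a residual sum of squares
#'
#' AIC = n log(RSS/n) + 2k, valid for comparing fits that share the data
#' and weights.
#'
#' @param n Number of fitted frames.
#' @param rss Weighted residual sum of squares (> 0).
#' @param k Number of free parameters.
#' @return AIC (unitless).
#' @export
aic_rss <- function(n, rss, k) {
  if (rss <= 0) stop("AIC undefined for RSS <= 0")
  n * log(rss / n) + 2 * k
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s %s: V_T = %.3f (rSE %.1f%%), AIC = %.2f, %s\n",
              x$region, x$model, x$vt,
              if (is.na(x$rse)) NA else x$rse, x$aic,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Compare two compartment-model fits by AIC
#'
#' @param fit_1t,fit_2t [fit_model()] results for the same data, weights
#'   and fit window.
#' @return List with `preferred` (`"1T"` or `"2T"`) and `delta_aic`
#'   (AIC_2T - AIC_1T). Lower AIC wins; an exact tie goes to the model
#'   with fewer parameters.
#' @export
compare_models <- function(fit_1t, fit_2t) {
  stopifnot(inherits(fit_1t, "kinetic_fit"), inherits(fit_2t, "kinetic_fit"))
  if (fit_1t$model != "1T" || fit_2t$model != "2T") {
    stop("arguments must be a 1T fit and a 2T fit, in that order")
  }
  if (any(abs(fit_1t$fit_window - fit_2t$fit_window) > 1e-9) ||
      fit_1t$n_frames != fit_2t$n_frames) {
    stop("comparison error: fits use different fit windows")
  }
  d <- fit_2t$aic - fit_1t$aic
  # NaN arises when both fits are exact (-Inf AIC): a tie, kept at 1T
  preferred <- if (is.nan(d) || abs(d) < 1e-9) "1T" else if (d < 0) "2T" else "1T"
  list(preferred = preferred, delta_aic = d)
}

#' Scan-truncation stability analysis
#'
#' Refits the same model to progressively truncated data (frames fully
#' contained in \[0, endpoint\]) and reports V_T per endpoint together
#' with the percent change relative to the longest endpoint. A stable
#' tracer shows flat V_T across endpoints; accumulation of brain-penetrant
#' radio-metabolites shows up as V_T increasing with scan length.
#'
#' @param tac A [region_tac()].
#' @param input Input function.
#' @param whole_blood Optional whole-blood curve.
#' @param model `"1T"` or `"2T"`.
#' @param endpoints Truncation endpoints in minutes (each >= 30 and within
#'   the scan); default `seq(30, 120, by = 15)` clipped to the scan end.
#' @param options See [fit_options()].
#' @return A data frame of class `truncation_profile` with columns
#'   `endpoint`, `vt`, `rse`, `n_frames`, `converged`, `flagged` (fewer
#'   than 10 usable frames) and `pct_change` vs the longest endpoint.
#' @export
truncation_analysis <- function(tac, input, whole_blood = NULL,
                                model = c("2T", "1T"), endpoints = NULL,
                                options = fit_options()) {
  model <- match.arg(model)
  scan_end <- tac$schedule$end[tac$schedule$n]
  if (is.null(endpoints)) {
    endpoints <- seq(30, 120, by = 15)
    endpoints <- endpoints[endpoints <= scan_end + 1e-9]
  }
  if (any(endpoints < 30 - 1e-9)) stop("endpoints must be >= 30 min")
  if (any(endpoints > scan_end + 1e-9)) {
    stop("endpoints must not exceed the scan duration")
  }
  endpoints <- sort(endpoints)
  rows <- lapply(endpoints, function(ep) {
    nf <- sum(tac$schedule$end <= ep + 1e-9)
    opts <- options; opts$t_end <- ep
    fit <- fit_model(tac, input, whole_blood, model = model, options = opts)
    data.frame(endpoint = ep, vt = fit$vt, rse = fit$rse, n_frames = nf,
               converged = fit$converged, flagged = nf < 10L)
  })
  out <- do.call(rbind, rows)
  ref <- out$vt[nrow(out)]
  out$pct_change <- 100 * (out$vt - ref) / ref
  class(out) <- c("truncation_profile", class(out))
  out
}
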