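#' Hill-type parent fraction model
#'
#' Fraction of total plasma radioactivity attributable to intact parent
#' radiotracer at time t:
#' \deqn{pf(t) = c + (1 - c) / (1 + (t/t50)^n)}
#' so that pf(0) = 1 by construction, pf is non-increasing, and pf
#' approaches the asymptote `c` at late times.
#'
#' @param c Asymptotic parent fraction, in \[0, 0.99\].
#' @param t50 Time (min, > 0) at which the decaying component is halved.
#' @param n Hill coefficient (> 0).
#' @param rss Optional residual sum of squares from a fit.
#' @param converged Optional convergence flag from a fit.
#' @return An object of class `parent_fraction_model`.
#' @export
parent_fraction_model <- function(c, t50, n, rss = NA_real_, converged = NA) {
  if (!is.numeric(c) || c < 0 || c > 0.99) stop("c must be in [0, 0.99]")
  if (!is.numeric(t50) || t50 <= 0 || t50 > 500) stop("t50 must be in (0, 500]")
  if (!is.numeric(n) || n <= 0 || n > 10) stop("n must be in (0, 10]")
  structure(list(c = unname(c), t50 = unname(t50), n = unname(n),
                 rss = unname(rss), converged = converged),
            class = "parent_fraction_model")
}

#' Evaluate a parent fraction model
#'
#' @param model A [parent_fraction_model()].
#' @param t Times in minutes (>= 0).
#' @return Parent fractions in (c, 1].
#' @export
pf_eval <- function(model, t) {
  stopifnot(inherits(model, "parent_fraction_model"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("times must be >= 0")
  model$c + (1 - model$c) / (1 + (t / model$t50)^model$n)
}

#' @export
print.parent_fraction_model <- function(x, ...) {
  cat(sprintf(
    "<parent_fraction_model> c = %.3g, t50 = %.3g min, n = %.3g (pf(30) = %.3f)\n",
    x$c, x$t50, x$n, pf_eval(x, 30)))
  invisible(x)
}

#' Fit a parent fraction model to measured fractions
#'
#' Least-squares fit of the constrained Hill form to sparse parent-fraction
#' measurements (typically 3, 8, 15, 30, 60, 90 min post-injection).
#' Bounds: c in \[0, 0.99\], t50 in (0, 500\], n in (0, 10\]. Multiple
#' deterministic starts are tried; optimizer non-convergence is flagged on
#' the returned model, not raised.
#'
#' @param times Sample times in minutes, all > 0, at least 3 distinct.
#' @param fractions Measured parent fractions in \[0, 1\].
#' @return A [parent_fraction_model()] with `rss` and `converged` filled in.
#' @export
fit_parent_fraction <- function(times, fractions) {
  times <- as.numeric(times)
  fractions <- as.numeric(fractions)
  if (length(times) != length(fractions)) stop("times/fractions lengths differ")
  keep <- !is.na(times) & !is.na(fractions)
  times <- times[keep]; fractions <- fractions[keep]
  if (length(unique(times)) < 3L) {
    stop("insufficient data: at least 3 parent-fraction samples at distinct times required")
  }
  if (any(times <= 0)) stop("parent-fraction sample times must be > 0")
  if (any(fractions < 0 | fractions > 1)) stop("parent fractions must be in [0, 1]")

  lower <- c(c = 0, t50 = 1e-3, n = 1e-3)
  upper <- c(c = 0.99, t50 = 500, n = 10)
  resid_fn <- function(p) {
    fractions - (p[1L] + (1 - p[1L]) / (1 + (times / p[2L])^p[3L]))
  }
  starts <- list(
    c(c = max(0, min(fractions) * 0.8), t50 = stats::median(times), n = 1.5),
    c(c = 0.01, t50 = 10, n = 2),
    c(c = 0.3, t50 = 30, n = 1),
    c(c = 0.05, t50 = 60, n = 0.8)
  )
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(p0, lower), upper), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    # every start failed: return the first start, flagged
    p <- starts[[1L]]
    return(parent_fraction_model(p[1L], p[2L], p[3L],
                                 rss = sum(resid_fn(p)^2), converged = FALSE))
  }
  p <- best$par
  parent_fraction_model(p[1L], p[2L], p[3L],
                        rss = best$deviance,
                        converged = best$info %in% 1:4)
}

#' Blood data for one scan
#'
#' @param plasma [sampled_curve()] of total plasma activity (kBq/mL).
#' @param whole_blood Optional [sampled_curve()] of whole-blood activity.
#' @param parent_samples Data frame with columns `time_min` and
#'   `parent_fraction` (fractions in \[0, 1\]).
#' @param fp_triplicate Three free-fraction replicate measurements.
#' @return An object of class `blood_data`.
#' @export
blood_data <- function(plasma, whole_blood = NULL, parent_samples,
                       fp_triplicate) {
  stopifnot(inherits(plasma, "sampled_curve"))
  if (!is.null(whole_blood)) stopifnot(inherits(whole_blood, "sampled_curve"))
  stopifnot(is.data.frame(parent_samples),
            all(c("time_min", "parent_fraction") %in% names(parent_samples)))
  if (any(parent_samples$parent_fraction < 0 |
          parent_samples$parent_fraction > 1)) {
    stop("parent fractions must be in [0, 1]")
  }
  structure(list(plasma = plasma, whole_blood = whole_blood,
                 parent_samples = parent_samples,
                 fp_triplicate = as.numeric(fp_triplicate)),
            class = "blood_data")
}

#' Construct a metabolite-corrected arterial input function
#'
#' The input function is the product of the total plasma activity curve and
#' the parent fraction curve, evaluated in continuous time.
#'
#' @param plasma [sampled_curve()] of total plasma activity, or a function
#'   of time.
#' @param pf A [parent_fraction_model()], or NULL for an uncorrected input.
#' @param label Provenance label.
#' @return An object of class `input_function` with elements `fun`
#'   (function of time, kBq/mL), `plasma`, `pf` and `label`.
#' @export
make_input_function <- function(plasma, pf = NULL, label = "") {
  pfun <- as_curve_function(plasma)
  if (is.null(pf)) {
    fun <- pfun
  } else {
    stopifnot(inherits(pf, "parent_fraction_model"))
    fun <- function(t) pfun(t) * pf_eval(pf, t)
  }
  structure(list(fun = fun, plasma = plasma, pf = pf, label = label),
            class = "input_function")
}

#' Evaluate an input function
#'
#' @param input An `input_function` (see [make_input_function()]).
#' @param t Times in minutes.
#' @return Metabolite-corrected parent plasma concentration, kBq/mL.
#' @export
input_eval <- function(input, t) {
  stopifnot(inherits(input, "input_function"))
  input$fun(t)
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("<input_function> '%s'%s\n", x$label,
              if (is.null(x$pf)) " (no metabolite correction)" else
                sprintf(" (Hill pf: c = %.3g, t50 = %.3g, n = %.3g)",
                        x$pf$c, x$pf$t50, x$pf$n)))
  invisible(x)
}

#' Plasma free fraction from an ultrafiltration triplicate
#'
#' The free fraction f_P is the ratio of radioactivity in the ultrafiltrate
#' to that in plasma; it is measured in triplicate and summarized by its
#' mean and standard deviation. Ratios slightly above 1 (up to 1.05) are
#' tolerated as measurement noise and clipped to 1; ratios outside
#' \[0, 1.05\] raise a quality-control error.
#'
#' @param ratios Three ratio measurements, or a 2-column matrix/data.frame
#'   of (filtrate, plasma) raw counts.
#' @return List with `fp` (mean), `sd` and `replicates` (clipped ratios).
#' @export
measure_fp <- function(ratios) {
  if (is.matrix(ratios) || is.data.frame(ratios)) {
    ratios <- as.matrix(ratios)
    if (ncol(ratios) != 2L) stop("count input must have 2 columns (filtrate, plasma)")
    if (any(ratios[, 2L] <= 0)) stop("plasma counts must be > 0")
    ratios <- ratios[, 1L] / ratios[, 2L]
  }
  ratios <- as.numeric(ratios)
  if (any(ratios < 0 | ratios > 1.05)) {
    stop("quality-control error: free-fraction ratio outside [0, 1.05]")
  }
  ratios <- pmin(ratios, 1)
  list(fp = mean(ratios), sd = stats::sd(ratios), replicates = ratios)
}
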