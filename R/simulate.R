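#' Feng-type descriptive arterial input model
#'
#' Smooth parametric form for a parent-plasma curve after a slow bolus:
#' zero up to the onset delay tau, then
#' \deqn{C_p(t) = (A1 (t - tau) - A2 - A3) e^{l1 (t - tau)} +
#'   A2 e^{l2 (t - tau)} + A3 e^{l3 (t - tau)}}
#' with l1 < l2 < l3 <= 0, so C_p(tau) = 0 (continuity at onset).
#'
#' @param tau Onset delay, min (>= 0).
#' @param A1 Linear rise amplitude, kBq/mL/min.
#' @param A2,A3 Exponential amplitudes, kBq/mL.
#' @param l1,l2,l3 Decay rates, min^-1, strictly ordered l1 < l2 < l3 <= 0.
#' @return An object of class `feng_params`.
#' @export
feng_params <- function(tau, A1, A2, A3, l1, l2, l3) {
  if (tau < 0) stop("tau must be >= 0")
  if (!(l1 < l2 && l2 < l3 && l3 <= 0)) {
    stop("decay rates must satisfy l1 < l2 < l3 <= 0")
  }
  structure(list(tau = tau, A1 = A1, A2 = A2, A3 = A3,
                 l1 = l1, l2 = l2, l3 = l3),
            class = "feng_params")
}

#' Evaluate a Feng input model
#'
#' Exact closed-form evaluation (no quadrature).
#'
#' @param params A [feng_params()].
#' @param t Times in minutes.
#' @return Plasma parent concentration, kBq/mL.
#' @export
feng_eval <- function(params, t) {
  stopifnot(inherits(params, "feng_params"))
  u <- as.numeric(t) - params$tau
  out <- numeric(length(u))
  pos <- u > 0
  if (any(pos)) {
    up <- u[pos]
    out[pos] <- (params$A1 * up - params$A2 - params$A3) * exp(params$l1 * up) +
      params$A2 * exp(params$l2 * up) + params$A3 * exp(params$l3 * up)
  }
  out
}

#' The standard 13-region brain ROI set
#'
#' @return Character vector of region names.
#' @export
roi_names <- function() {
  c("frontal_cortex", "temporal_cortex", "occipital_cortex", "cingulate",
    "insula", "caudate", "putamen", "pallidum", "hippocampus", "amygdala",
    "thalamus", "pons", "cerebellum")
}

#' Ground-truth study configuration for the synthetic generator
#'
#' Defines one baseline scan and (optionally) one blocking scan sharing
#' the same input-function shape. Blocking modifies only the
#' specific-binding association rate (k3' = (1 - occupancy) k3) and the
#' plasma free fraction; when `fp_coupling` is TRUE the influx K1 is
#' additionally scaled proportionally to f_P (sensitivity mode modeling
#' the free-fraction increase as a delivery change).
#'
#' @param regions Data frame with columns `region`, `K1`, `k2`, `k3`,
#'   `k4` (true 2T micro-parameters per region; k3 = 0 gives 1T behavior).
#' @param input A [feng_params()] for the parent plasma curve.
#' @param pf A [parent_fraction_model()] for the parent fraction.
#' @param schedule A [frame_schedule()] (default [frame_schedule_nhp120()]).
#' @param vB Fractional blood volume (default 0.05).
#' @param fp_baseline,fp_blocking Plasma free fractions per scan.
#' @param occupancy True blocking occupancy in \[0, 1\]; NA disables the
#'   blocking scan.
#' @param noise_nu Noise scale: per-frame Gaussian SD is
#'   `noise_nu * sqrt(C_i / dt_i)` around the noise-free frame mean C_i;
#'   0 or negative means noise-free.
#' @param contamination NULL, or
#'   `list(K1m = , k2m = , hydrophilic_fraction = )` describing a
#'   brain-penetrant radio-metabolite entering tissue as a 1T response to
#'   the metabolite plasma curve
#'   `total_plasma(t) (1 - pf(t)) hydrophilic_fraction`.
#' @param injected_dose Injected dose, MBq.
#' @param body_weight Body weight, kg.
#' @param wb_ratio Whole-blood to plasma activity ratio.
#' @param fp_coupling Scale K1 with f_P in the blocking scan? Default
#'   FALSE (the f_P shift is plasma-side only).
#' @param seed Integer seed; the study is fully reproducible from it.
#' @param step Internal quadrature step, min.
#' @return An object of class `study_config`.
#' @export
study_config <- function(regions, input, pf,
                         schedule = frame_schedule_nhp120(),
                         vB = 0.05, fp_baseline = 0.03, fp_blocking = NA,
                         occupancy = NA, noise_nu = 0, contamination = NULL,
                         injected_dose = 175, body_weight = 10,
                         wb_ratio = 0.8, fp_coupling = FALSE, seed = 1L,
                         step = 0.05) {
  stopifnot(is.data.frame(regions),
            all(c("region", "K1", "k2", "k3", "k4") %in% names(regions)),
            inherits(input, "feng_params"),
            inherits(pf, "parent_fraction_model"),
            inherits(schedule, "frame_schedule"))
  if (any(regions$K1 <= 0 | regions$k2 <= 0 | regions$k3 < 0 |
          regions$k4 <= 0)) {
    stop("invalid region kinetics: need K1, k2, k4 > 0 and k3 >= 0")
  }
  if (!is.na(occupancy) && (occupancy < 0 || occupancy > 1)) {
    stop("occupancy must be in [0, 1]")
  }
  if (!is.na(occupancy) && is.na(fp_blocking)) {
    stop("blocking scan requires fp_blocking")
  }
  if (!is.null(contamination)) {
    stopifnot(all(c("K1m", "k2m", "hydrophilic_fraction") %in%
                    names(contamination)))
  }
  structure(list(
    regions = regions, input = input, pf = pf, schedule = schedule,
    vB = vB, fp_baseline = fp_baseline, fp_blocking = fp_blocking,
    occupancy = occupancy, noise_nu = max(0, noise_nu),
    contamination = contamination, injected_dose = injected_dose,
    body_weight = body_weight, wb_ratio = wb_ratio,
    fp_coupling = fp_coupling, seed = as.integer(seed), step = step
  ), class = "study_config")
}

# Arterial sampling grid used for the synthetic blood curves: dense manual
# draws through the input peak, sparser afterwards.
blood_sample_times <- function(scan_end = 120) {
  tt <- c(seq(0.25, 3, by = 0.25), 3.5, 4, 5, 6, 8, 10, 12, 15, 20, 25, 30,
          40, 50, 60, 75, 90, 105, 120)
  tt[tt <= scan_end]
}

# Times of the sparse parent-fraction measurements.
parent_sample_times <- function() c(3, 8, 15, 30, 60, 90)

simulate_scan <- function(config, scan = c("baseline", "blocking")) {
  scan <- match.arg(scan)
  sched <- config$schedule
  t_end <- sched$end[sched$n]
  grid <- make_grid(t_end, config$step)
  dt <- grid[2L] - grid[1L]
  W <- fw_matrix(sched, grid)
  if (is.null(W)) stop("frame schedule must align with the quadrature step")

  pf_fun <- function(t) pf_eval(config$pf, t)
  parent_fun <- function(t) feng_eval(config$input, t)
  plasma_fun <- function(t) parent_fun(t) / pf_fun(t)
  wb_fun <- function(t) config$wb_ratio * plasma_fun(t)

  blocking <- scan == "blocking"
  fp <- if (blocking) config$fp_blocking else config$fp_baseline
  reg <- config$regions
  if (blocking) {
    reg$k3 <- (1 - config$occupancy) * reg$k3
    if (config$fp_coupling) {
      reg$K1 <- reg$K1 * config$fp_blocking / config$fp_baseline
    }
  }
  reg$vt_true <- (reg$K1 / reg$k2) * (1 + reg$k3 / reg$k4)

  cp <- parent_fun(grid)
  cwb <- wb_fun(grid)
  ctm <- 0
  if (!is.null(config$contamination)) {
    cm <- config$contamination
    cpm <- plasma_fun(grid) * (1 - pf_fun(grid)) * cm$hydrophilic_fraction
    ctm <- conv_trapz(cm$K1m * exp(-cm$k2m * grid), cpm, dt)
  }

  tacs <- list()
  clean <- list()
  for (i in seq_len(nrow(reg))) {
    p <- list(model = "2T", K1 = reg$K1[i], k2 = reg$k2[i], k3 = reg$k3[i],
              k4 = reg$k4[i])
    ct <- conv_trapz(irf_eval(p, grid), cp, dt)
    mu <- as.vector(W %*% ((1 - config$vB) * (ct + ctm) + config$vB * cwb))
    ybar <- mu
    if (config$noise_nu > 0) {
      sdv <- config$noise_nu * sqrt(pmax(mu, 0) / sched$duration)
      ybar <- mu + stats::rnorm(sched$n, 0, sdv)
    }
    tacs[[reg$region[i]]] <- region_tac(reg$region[i], sched, ybar)
    clean[[reg$region[i]]] <- mu
  }

  bt <- blood_sample_times(t_end)
  fp_trip <- rep(fp, 3)
  if (config$noise_nu > 0) {
    fp_trip <- pmin(pmax(fp * (1 + stats::rnorm(3, 0, 0.02)), 0), 1)
  }
  blood <- blood_data(
    plasma = sampled_curve(bt, plasma_fun(bt), label = paste0(scan, " plasma")),
    whole_blood = sampled_curve(bt, wb_fun(bt),
                                label = paste0(scan, " whole blood")),
    parent_samples = data.frame(time_min = parent_sample_times(),
                                parent_fraction = pf_fun(parent_sample_times())),
    fp_triplicate = fp_trip
  )

  list(name = scan, blood = blood, tacs = tacs, fp = fp,
       params = reg, clean_frame_means = clean,
       input_true = make_input_function(parent_fun, NULL,
                                        label = paste0(scan, " true parent input")),
       whole_blood_true = wb_fun)
}

#' Simulate a synthetic PET study
#'
#' Generates, fully reproducibly from the configured seed, the blood data
#' and frame-binned regional TACs of a baseline scan and (when an
#' occupancy is configured) a blocking scan, with the statistical
#' structure the quantification pipeline assumes: a Feng parent input,
#' Hill parent-fraction decay (total plasma = parent / pf), a constant
#' whole-blood/plasma ratio, an optional brain-penetrant radio-metabolite,
#' a vascular signal fraction, and per-frame Gaussian noise with SD
#' `noise_nu * sqrt(C / dt)`.
#'
#' @param config A [study_config()].
#' @return An object of class `synthetic_study`: `scans` (each with
#'   `blood`, `tacs`, `fp`, the true generating parameters including the
#'   per-region true V_T, the noise-free frame means, and the true parent
#'   input function) plus the `config` as truth ledger.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  with_private_seed(config$seed, {
    scans <- list(baseline = simulate_scan(config, "baseline"))
    if (!is.na(config$occupancy)) {
      scans$blocking <- simulate_scan(config, "blocking")
    }
    structure(list(scans = scans, config = config),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d scan(s), %d regions, seed %d%s\n",
              length(x$scans), nrow(x$config$regions), x$config$seed,
              if (is.na(x$config$occupancy)) "" else
                sprintf(", true occupancy %.2f", x$config$occupancy)))
  invisible(x)
}

# Calibrate the noise scale so the peak-frame coefficient of variation of
# a noise-free grey-matter TAC equals target_cv.
calibrate_noise_nu <- function(config, region = "frontal_cortex",
                               target_cv = 0.05) {
  cfg <- config
  cfg$noise_nu <- 0
  cfg$occupancy <- NA
  scan <- with_private_seed(cfg$seed, simulate_scan(cfg, "baseline"))
  mu <- scan$clean_frame_means[[region]]
  i <- which.max(mu)
  target_cv * sqrt(mu[i] * config$schedule$duration[i])
}

#' Calibrated tracer scenario presets
#'
#' Two documented study configurations emulating the behavior of a
#' fast-metabolizing C-11 tracer and a slower-metabolizing F-18 tracer in
#' adult rhesus macaques:
#'
#' * `"ocm44_like"`: parent fraction below 20% at 30 min, baseline f_P
#'   0.031 rising to 0.085 under blocking, distinguishable 2T kinetics
#'   (K1 0.18-0.47 mL cm^-3 min^-1, true grey-matter V_T about 1.7-2.4
#'   mL/cm^3), peak grey-matter SUV in 2-3, and a brain-penetrant
#'   hydrophilic radio-metabolite (1T uptake with slow washout) that makes
#'   fitted V_T climb with scan duration.
#' * `"ocm50_like"`: about 40% parent remaining at 30 min, f_P 0.006
#'   rising to 0.0145 under blocking, fast-exchange kinetics well
#'   described by a 1T fit (true V_T 0.39-0.87 mL/cm^3), peak SUV in 1-2,
#'   no contamination.
#'
#' Both presets use the 33-frame 120-min schedule, vB = 0.05, a true
#' blocking occupancy of 0.9 (C-11-like) or 0.8 (F-18-like), and a noise
#' scale calibrated so the peak-frame coefficient of variation is 5%.
#'
#' @param name `"ocm44_like"` or `"ocm50_like"`.
#' @param seed Seed stored in the returned config.
#' @return A [study_config()].
#' @export
preset <- function(name = c("ocm44_like", "ocm50_like"), seed = 1L) {
  name <- match.arg(name)
  rois <- roi_names()
  if (name == "ocm44_like") {
    K1 <- c(0.40, 0.35, 0.38, 0.42, 0.33, 0.40, 0.47, 0.18, 0.30, 0.25,
            0.36, 0.28, 0.37)
    vt <- c(2.35, 1.90, 1.92, 2.40, 1.95, 1.93, 1.89, 1.80, 1.96, 1.75,
            1.82, 1.70, 1.84)
    vnd_free <- 0.9   # common K1/k2 across regions (Lassen assumption)
    k4 <- 0.06
    regions <- data.frame(
      region = rois, K1 = K1, k2 = K1 / vnd_free,
      k3 = k4 * (vt / vnd_free - 1), k4 = k4
    )
    cfg <- study_config(
      regions = regions,
      input = feng_params(tau = 0.5, A1 = 315, A2 = 16.5, A3 = 8.2,
                          l1 = -1.4, l2 = -0.25, l3 = -0.012),
      pf = parent_fraction_model(c = 0.03, t50 = 9, n = 1.6),
      fp_baseline = 0.031, fp_blocking = 0.085, occupancy = 0.9,
      contamination = list(K1m = 0.015, k2m = 0.01,
                           hydrophilic_fraction = 0.20),
      injected_dose = 178, body_weight = 10, seed = seed
    )
  } else {
    K1 <- c(0.150, 0.140, 0.210, 0.130, 0.100, 0.095, 0.120, 0.100, 0.120,
            0.083, 0.110, 0.140, 0.130)
    vt <- c(0.87, 0.72, 0.84, 0.71, 0.39, 0.39, 0.54, 0.49, 0.65, 0.45,
            0.52, 0.75, 0.63)
    vnd_free <- 0.20
    k4 <- 1.2
    regions <- data.frame(
      region = rois, K1 = K1, k2 = K1 / vnd_free,
      k3 = k4 * (vt / vnd_free - 1), k4 = k4
    )
    cfg <- study_config(
      regions = regions,
      input = feng_params(tau = 0.5, A1 = 360, A2 = 20, A3 = 12.5,
                          l1 = -1.4, l2 = -0.22, l3 = -0.010),
      pf = parent_fraction_model(c = 0.15, t50 = 18, n = 1.5),
      fp_baseline = 0.006, fp_blocking = 0.0145, occupancy = 0.8,
      contamination = NULL,
      injected_dose = 164, body_weight = 10, seed = seed
    )
  }
  cfg$noise_nu <- calibrate_noise_nu(cfg)
  cfg
}
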