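test_that("the Feng input is zero up to onset and continuous there", {
  p <- feng_params(tau = 0.5, A1 = 230, A2 = 12, A3 = 6,
                   l1 = -1.4, l2 = -0.25, l3 = -0.012)
  expect_equal(feng_eval(p, c(0, 0.2, 0.5)), c(0, 0, 0))
  expect_lt(feng_eval(p, 0.5 + 1e-6), 1e-3)
  expect_error(feng_params(0.5, 230, 12, 6, -0.25, -1.4, -0.012), "l1 < l2")
})

test_that("the Feng integral agrees between closed form and fine-grid quadrature", {
  for (nm in c("ocm44_like", "ocm50_like")) {
    p <- preset(nm)$input
    tt <- seq(0, 120, by = 0.002)
    v <- feng_eval(p, tt)
    quad <- 0.002 * (sum(v) - (v[1] + v[length(v)]) / 2)
    expect_equal(quad, feng_integral_closed(p, 120), tolerance = 5e-4)
  }
})

test_that("preset inputs peak within the first 3 min of injection", {
  for (nm in c("ocm44_like", "ocm50_like")) {
    p <- preset(nm)$input
    tt <- seq(0, 120, by = 0.01)
    expect_lte(tt[which.max(feng_eval(p, tt))], 3)
  }
})

test_that("preset parent fractions match the tracer metabolism they emulate", {
  expect_lt(pf_eval(preset("ocm44_like")$pf, 30), 0.20)
  pf50 <- pf_eval(preset("ocm50_like")$pf, 30)
  expect_gte(pf50, 0.35)
  expect_lte(pf50, 0.45)
})

test_that("presets simulate cleanly and reproducibly from a seed", {
  for (nm in c("ocm44_like", "ocm50_like")) {
    cfg <- preset(nm, seed = 0)
    s1 <- simulate_study(cfg)
    s2 <- simulate_study(cfg)
    expect_identical(s1$scans$baseline$tacs$pons$frame_means,
                     s2$scans$baseline$tacs$pons$frame_means)
    cfg3 <- preset(nm, seed = 1)
    s3 <- simulate_study(cfg3)
    expect_false(identical(s1$scans$baseline$tacs$pons$frame_means,
                           s3$scans$baseline$tacs$pons$frame_means))
    expect_named(s1$scans, c("baseline", "blocking"))
  }
})

test_that("noise-free TACs are non-negative and equal the model prediction", {
  cfg <- preset("ocm50_like")
  cfg$noise_nu <- 0
  st <- simulate_study(cfg)
  sc <- st$scans$baseline
  for (tac in sc$tacs) expect_true(all(tac$frame_means >= 0))
  reg <- sc$params[sc$params$region == "putamen", ]
  p <- kinetic_params("2T", K1 = reg$K1, k2 = reg$k2, k3 = reg$k3,
                      k4 = reg$k4, vB = cfg$vB)
  pred <- model_tac(p, sc$input_true, sc$whole_blood_true, cfg$schedule)
  expect_equal(sc$tacs$putamen$frame_means, pred, tolerance = 1e-10)
})

test_that("frame means conserve the integral of the underlying curve", {
  cfg <- preset("ocm50_like")
  cfg$noise_nu <- 0
  st <- simulate_study(cfg)
  sc <- st$scans$baseline
  reg <- sc$params[sc$params$region == "cerebellum", ]
  p <- kinetic_params("2T", K1 = reg$K1, k2 = reg$k2, k3 = reg$k3,
                      k4 = reg$k4, vB = cfg$vB)
  curve_fun <- function(t) {
    (1 - cfg$vB) * solve_tissue(p, sc$input_true, t) +
      cfg$vB * sc$whole_blood_true(t)
  }
  tt <- seq(0, 120, by = 0.01)
  v <- curve_fun(tt)
  integral <- 0.01 * (sum(v) - (v[1] + v[length(v)]) / 2)
  expect_equal(sum(sc$tacs$cerebellum$frame_means * cfg$schedule$duration),
               integral, tolerance = 1e-4)
})

test_that("peak grey-matter SUV lands in the calibrated tracer-specific band", {
  for (case in list(list(nm = "ocm44_like", lo = 2, hi = 3),
                    list(nm = "ocm50_like", lo = 1, hi = 2))) {
    cfg <- preset(case$nm)
    cfg$noise_nu <- 0
    st <- simulate_study(cfg)
    grey <- c("frontal_cortex", "temporal_cortex", "occipital_cortex",
              "cingulate", "insula", "putamen", "caudate")
    peaks <- vapply(st$scans$baseline$tacs[grey],
                    function(x) max(x$frame_means), numeric(1))
    suv_max <- to_suv(max(peaks), cfg$injected_dose, cfg$body_weight)
    expect_gte(suv_max, case$lo)
    expect_lte(suv_max, case$hi)
  }
})

test_that("blocking scans modify only k3 and f_P (plus K1 when coupling is on)", {
  cfg <- preset("ocm50_like")
  cfg$noise_nu <- 0
  st <- simulate_study(cfg)
  b <- st$scans$baseline$params
  k <- st$scans$blocking$params
  expect_equal(k$k3, (1 - cfg$occupancy) * b$k3)
  expect_equal(k$K1, b$K1)
  expect_equal(k$k2, b$k2)
  expect_equal(k$k4, b$k4)
  expect_equal(st$scans$blocking$fp, cfg$fp_blocking)
  cfg$fp_coupling <- TRUE
  st2 <- simulate_study(cfg)
  expect_equal(st2$scans$blocking$params$K1,
               b$K1 * cfg$fp_blocking / cfg$fp_baseline)
})

test_that("noise-free simulate-fit closes the loop on true V_T", {
  cfg <- preset("ocm50_like")
  cfg$noise_nu <- 0
  cfg$occupancy <- NA
  st <- simulate_study(cfg)
  sc <- st$scans$baseline
  for (rg in c("frontal_cortex", "insula")) {
    fit <- fit_model(sc$tacs[[rg]], sc$input_true, sc$whole_blood_true, "2T",
                     options = quick_opts())
    truth <- sc$params$vt_true[sc$params$region == rg]
    expect_equal(fit$vt, truth, tolerance = 1e-3)
  }
})

test_that("unknown presets and invalid configs are rejected", {
  expect_error(preset("nope"))
  cfg <- preset("ocm50_like")
  bad <- cfg$regions; bad$k2[1] <- -1
  expect_error(study_config(bad, cfg$input, cfg$pf), "invalid region kinetics")
  expect_error(study_config(cfg$regions, cfg$input, cfg$pf, occupancy = 0.5),
               "fp_blocking")
})
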