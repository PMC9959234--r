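test_that("tissue solution vanishes without influx and 2T nests 1T at k3 = 0", {
  f <- test_input_fun()
  tg <- seq(0, 120, 2.5)
  p0 <- kinetic_params("2T", K1 = 0, k2 = 0.1, k3 = 0.05, k4 = 0.03)
  expect_equal(solve_tissue(p0, f, tg), rep(0, length(tg)))
  p1 <- kinetic_params("1T", K1 = 0.3, k2 = 0.15)
  p2 <- kinetic_params("2T", K1 = 0.3, k2 = 0.15, k3 = 0, k4 = 0.03)
  c1 <- solve_tissue(p1, f, tg)
  c2 <- solve_tissue(p2, f, tg)
  expect_equal(c2[-1], c1[-1], tolerance = 1e-6)
  expect_error(kinetic_params("2T", K1 = 0.3, k2 = 0.15, k3 = 0.05, k4 = 0),
               "k4 > 0")
})

test_that("analytic convolution matches direct stiff ODE integration across the parameter grid", {
  f <- test_input_fun()
  mids <- frame_schedule_nhp120()$mid
  for (K1 in c(0.1, 0.3)) for (k2 in c(0.05, 0.2)) {
    for (k3 in c(0, 0.05)) for (k4 in c(0.01, 0.05)) {
      p <- kinetic_params("2T", K1 = K1, k2 = k2, k3 = k3, k4 = k4)
      got <- solve_tissue(p, f, mids, step = 0.01)
      ref <- ode_tissue(K1, k2, k3, k4, f, mids)
      expect_lt(max(abs(got - ref) / pmax(abs(ref), 1e-8)), 1e-3)
    }
  }
})

test_that("the repeated-root 2T impulse response is the analytic limit", {
  f <- test_input_fun()
  tg <- seq(0, 60, 1)
  # k3 = 0 and k2 = k4 collapses the macro-rates to a double root
  p_eq <- kinetic_params("2T", K1 = 0.3, k2 = 0.05, k3 = 0, k4 = 0.05)
  p_near <- kinetic_params("2T", K1 = 0.3, k2 = 0.05, k3 = 1e-9, k4 = 0.05)
  expect_equal(solve_tissue(p_eq, f, tg), solve_tissue(p_near, f, tg),
               tolerance = 1e-6)
})

test_that("long-time equilibrium under constant infusion equals V_T", {
  const_input <- function(t) rep(1, length(t))
  for (p in list(kinetic_params("1T", K1 = 0.3, k2 = 0.15),
                 kinetic_params("2T", K1 = 0.3, k2 = 0.15, k3 = 0.05,
                                k4 = 0.03))) {
    ct <- solve_tissue(p, const_input, 400, step = 0.05)
    expect_equal(ct, vt_from_params(p), tolerance = 0.01)
  }
})

test_that("the model TAC mixes tissue and blood by the vascular fraction", {
  f <- test_input_fun()
  fs <- frame_schedule(seq(0, 50, 10), rep(10, 6))
  p <- kinetic_params("1T", K1 = 0.3, k2 = 0.15, vB = 0)
  expect_equal(model_tac(p, f, NULL, fs),
               frame_average(function(t) solve_tissue(p, f, t), fs),
               tolerance = 1e-8)
  pb <- kinetic_params("1T", K1 = 0, k2 = 0.15, vB = 1)
  expect_equal(model_tac(pb, f, f, fs), frame_average(f, fs),
               tolerance = 1e-10)
  expect_error(kinetic_params("1T", K1 = 0.1, k2 = 0.1, vB = 1.2), "vB")
})

test_that("AIC follows n log(RSS/n) + 2k", {
  expect_equal(aic_rss(33, 3.3, 3), 33 * log(0.1) + 6)
  expect_equal(round(aic_rss(33, 3.3, 3), 2), -69.99)
  expect_error(aic_rss(10, 0, 2), "undefined")
})

test_that("noise-free generated data is refitted to the exact parameters", {
  truth <- kinetic_params("2T", K1 = 0.35, k2 = 0.4, k3 = 0.08, k4 = 0.06)
  f <- test_input_fun()
  fs <- frame_schedule_nhp120()
  y <- model_tac(truth, f, f, fs)
  fit <- fit_model(region_tac("frontal_cortex", fs, y), f, f, "2T",
                   options = quick_opts())
  expect_true(fit$converged)
  expect_equal(fit$params$K1, truth$K1, tolerance = 1e-3)
  expect_equal(fit$params$k2, truth$k2, tolerance = 1e-3)
  expect_equal(fit$params$k3, truth$k3, tolerance = 1e-3)
  expect_equal(fit$params$k4, truth$k4, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-10 * sum(y^2))
})

test_that("the best 2T fit is never worse than the best 1T fit (nesting)", {
  truth <- kinetic_params("1T", K1 = 0.15, k2 = 0.17)
  f <- test_input_fun()
  fs <- frame_schedule_nhp120()
  mu <- model_tac(truth, f, f, fs)
  set.seed(5)
  y <- mu + rnorm(33, 0, 0.02 * max(mu))
  tac <- region_tac("frontal_cortex", fs, y)
  f1 <- fit_model(tac, f, f, "1T", options = quick_opts())
  f2 <- fit_model(tac, f, f, "2T", options = quick_opts())
  expect_lte(f2$rss, f1$rss * (1 + 1e-6))
  cmp <- compare_models(f1, f2)
  expect_true(cmp$preferred %in% c("1T", "2T"))
})

test_that("model comparison prefers lower AIC and breaks ties toward 1T", {
  mk <- function(model, aic) {
    structure(list(model = model, aic = aic, fit_window = c(0, 120),
                   n_frames = 33L), class = "kinetic_fit")
  }
  # equal RSS: the 2-parameter penalty decides
  a1 <- aic_rss(33, 2.2, 2); a2 <- aic_rss(33, 2.2, 4)
  expect_equal(compare_models(mk("1T", a1), mk("2T", a2))$preferred, "1T")
  expect_equal(compare_models(mk("1T", 10), mk("2T", 5))$preferred, "2T")
  expect_equal(compare_models(mk("1T", -Inf), mk("2T", -Inf))$preferred, "1T")
  bad <- mk("2T", 5); bad$fit_window <- c(0, 60)
  expect_error(compare_models(mk("1T", 10), bad), "fit windows")
})

test_that("duration weighting and rSE reporting behave as documented", {
  f <- test_input_fun()
  fs <- frame_schedule_nhp120()
  truth <- kinetic_params("1T", K1 = 0.15, k2 = 0.17)
  mu <- model_tac(truth, f, f, fs)
  set.seed(9)
  y <- mu + rnorm(33, 0, 0.01 * max(mu))
  tac <- region_tac("frontal_cortex", fs, y)
  fit_d <- fit_model(tac, f, f, "1T", options = quick_opts(weights = "duration"))
  fit_u <- fit_model(tac, f, f, "1T", options = quick_opts(weights = "uniform"))
  expect_true(fit_d$converged && fit_u$converged)
  expect_false(isTRUE(all.equal(fit_d$rss, fit_u$rss)))
  expect_gt(fit_d$rse, 0)
  expect_equal(fit_d$rse, 100 * fit_d$se_vt / fit_d$vt)
})

test_that("truncation analysis is stable on clean data and flags short windows", {
  f <- test_input_fun()
  fs <- frame_schedule_nhp120()
  truth <- kinetic_params("1T", K1 = 0.15, k2 = 0.17)
  y <- model_tac(truth, f, f, fs)
  tac <- region_tac("frontal_cortex", fs, y)
  tp <- truncation_analysis(tac, f, f, "1T", endpoints = c(30, 60, 120),
                            options = quick_opts())
  expect_true(all(abs(tp$pct_change) < 2))
  expect_equal(tp$vt[tp$endpoint == 60], tp$vt[tp$endpoint == 120],
               tolerance = 1e-6)
  expect_false(any(tp$flagged))
  # a coarse all-5-min schedule leaves < 10 frames inside 30 min
  fs5 <- frame_schedule(seq(0, 115, 5), rep(5, 24))
  y5 <- model_tac(truth, f, f, fs5)
  tp5 <- truncation_analysis(region_tac("pons", fs5, y5), f, f, "1T",
                             endpoints = c(30, 120), options = quick_opts())
  expect_true(tp5$flagged[tp5$endpoint == 30])
  expect_false(tp5$flagged[tp5$endpoint == 120])
  expect_error(truncation_analysis(tac, f, f, "1T", endpoints = 20), ">= 30")
})
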