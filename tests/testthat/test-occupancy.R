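vs <- c(0.5, 1, 1.5, 2, 3)
regions <- paste0("r", seq_along(vs))
base_exact <- setNames(0.2 + vs, regions)
block_exact <- setNames(0.2 + 0.3 * vs, regions)

test_that("the exact Lassen construction is recovered to machine precision", {
  res <- lassen(base_exact, block_exact)
  expect_equal(res$occupancy, 0.7, tolerance = 1e-12)
  expect_equal(res$vnd, 0.2, tolerance = 1e-10)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_identical(res$regions_dropped, character(0))
})

test_that("identical scans give zero occupancy with undefined V_ND", {
  res <- lassen(base_exact, base_exact)
  expect_equal(res$occupancy, 0, tolerance = 1e-12)
  expect_true(is.na(res$vnd))
  expect_true("zero_slope_vnd_undefined" %in% res$flags)
})

test_that("free-fraction scale invariance holds exactly", {
  fp_b <- 0.03; fp_k <- 0.09
  r1 <- lassen(base_exact, block_exact, fp_b, fp_k, mode = "fp_corrected")
  g <- 3.7
  r2 <- lassen(base_exact, setNames(g * block_exact, regions),
               fp_b, min(g * fp_k, 1), mode = "fp_corrected")
  expect_equal(r2$occupancy, r1$occupancy, tolerance = 1e-12)
  expect_equal(r2$vnd, r1$vnd, tolerance = 1e-9)
})

test_that("raw and fp-corrected modes agree when both scans share one f_P", {
  fp <- 0.031
  raw <- lassen(base_exact, block_exact, mode = "raw_VT")
  cor <- lassen(base_exact, block_exact, fp, fp, mode = "fp_corrected")
  expect_equal(cor$occupancy, raw$occupancy, tolerance = 1e-12)
  expect_equal(cor$vnd, raw$vnd / fp, tolerance = 1e-9)
})

test_that("missing regions are dropped pairwise and reported; small designs error", {
  b2 <- base_exact; b2["r2"] <- NA
  res <- lassen(b2, block_exact)
  expect_identical(res$regions_dropped, "r2")
  expect_equal(length(res$regions_used), 4L)
  expect_error(lassen(b2[1:3], block_exact[1:3]), "insufficient")
  flat <- setNames(rep(1, 5), regions)
  expect_error(lassen(flat, block_exact), "degenerate")
})

test_that("occupancy is robust to 5% noise on V_T", {
  set.seed(17)
  hits <- 0L
  for (i in 1:200) {
    nb <- base_exact * (1 + rnorm(5, 0, 0.05))
    nk <- block_exact * (1 + rnorm(5, 0, 0.05))
    est <- tryCatch(lassen(nb, nk)$occupancy, error = function(e) NA)
    if (!is.na(est) && abs(est - 0.7) <= 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 190L)
})

test_that("binding potential follows (V_T - V_ND)/V_ND", {
  expect_equal(bpnd(0.19, 0.19), 0)
  expect_equal(bpnd(0.38, 0.19), 1)
  expect_equal(round(bpnd(0.87, 0.19), 2), 3.58)
  expect_error(bpnd(1, 0), "> 0")
})

test_that("Guo plots regress one tracer's V_T on the other's", {
  a <- setNames(c(1, 2, 3, 4), paste0("r", 1:4))
  g1 <- guo_plot(a, a)
  expect_equal(g1$slope, 1, tolerance = 1e-12)
  expect_equal(g1$intercept, 0, tolerance = 1e-12)
  expect_equal(g1$r_squared, 1, tolerance = 1e-12)
  g2 <- guo_plot(a, 2 * a)
  expect_equal(g2$slope, 2, tolerance = 1e-12)
  expect_equal(g2$intercept, 0, tolerance = 1e-12)
})

test_that("V_ND in absolute units is the f_P-normalized estimate times f_P", {
  expect_equal(round(derive_vnd_absolute(30.9, 0.006), 2), 0.19)
  expect_equal(round(derive_vnd_absolute(11.5, mean(c(0.031, 0.032))), 2),
               0.36)
  expect_equal(derive_vnd_absolute(4.2, 1), 4.2)
  expect_error(derive_vnd_absolute(1, 0), "fp")
})

test_that("published-table occupancy and Guo fits match an independent OLS oracle", {
  tab <- load_table2_fixture()
  vb <- vt_column(tab, "f18_baseline_a3")
  vk <- vt_column(tab, "f18_block_0.1_a3")
  res <- lassen(vb, vk, 0.006, 0.014, mode = "fp_corrected")
  x <- vb / 0.006
  y <- x - vk / 0.014
  co <- coef(lm(y ~ x))
  expect_equal(res$occupancy, co[[2]], tolerance = 1e-12)
  expect_equal(res$vnd, -co[[1]] / co[[2]], tolerance = 1e-9)
  g <- guo_plot(vt_column(tab, "c11_baseline_a1"), vb)
  co2 <- coef(lm(vb ~ vt_column(tab, "c11_baseline_a1")))
  expect_equal(g$slope, co2[[2]], tolerance = 1e-12)
  expect_equal(g$r_squared, summary(lm(vb ~ vt_column(tab, "c11_baseline_a1")))$r.squared,
               tolerance = 1e-12)
})
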