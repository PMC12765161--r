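test_that("ccf(0) equals the biased Pearson estimator exactly", {
  set.seed(1)
  x <- rnorm(60)
  y <- 0.5 * x + rnorm(60)
  n <- length(x)
  cc <- cross_correlate(x, y, max_lag = 10)
  r0 <- cc$ccf[cc$lag == 0]
  manual <- sum((x - mean(x)) * (y - mean(y))) / (n * sd(x) * sd(y))
  expect_equal(r0, manual, tolerance = 1e-12)
  expect_equal(r0, cor(x, y) * (n - 1) / n, tolerance = 1e-12)
})

test_that("identical series peak at lag 0 with value (n-1)/n", {
  set.seed(2)
  x <- rnorm(40)
  cc <- cross_correlate(x, x)
  expect_equal(cc$best_lag, 0)
  expect_equal(cc$best_ccf, 39 / 40, tolerance = 1e-12)
  expect_true(all(abs(cc$ccf) <= 1 + 1e-12))
  expect_equal(max(abs(cc$lag)), min(20, length(x) - 1))
})

test_that("an index shift is recovered as |lag| = 1 (positive = x leads)", {
  set.seed(3)
  z <- rnorm(80)
  x <- z[2:80]   # x_t = z_{t+1}
  y <- z[1:79]   # y_{t+1} = z_{t+1} = x_t: x leads y by one step
  cc <- cross_correlate(x, y, max_lag = 5)
  expect_equal(cc$best_lag, 1)
  cc_rev <- cross_correlate(y, x, max_lag = 5)
  expect_equal(cc_rev$best_lag, -1)
})

test_that("degenerate coupling inputs raise typed errors", {
  expect_error(cross_correlate(rep(1, 10), rnorm(10)),
               class = "degenerate_series_error")
  expect_error(cross_correlate(1, 2), class = "data_error")
  expect_error(granger_order1(rnorm(3), rnorm(3)), class = "data_error")
  expect_error(granger_order1(rnorm(4), rnorm(4)), class = "data_error")
})

test_that("white-noise cross-correlations stay within sampling bounds", {
  set.seed(42)
  inside <- replicate(500, {
    a <- rnorm(200); b <- rnorm(200)
    max(abs(cross_correlate(a, b, 20)$ccf)) < 3 / sqrt(200)
  })
  # with 41 lags the union exceedance probability is near 8%, so the
  # within-bound frequency sits a little above 0.9
  expect_gte(mean(inside), 0.88)
})

test_that("order-1 Granger equals a from-scratch nested-OLS F test", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(6:60, 1)
    x <- rnorm(n)
    y <- 0.4 * c(0, x[-n]) + rnorm(n)
    ours <- granger_order1(x, y)
    oracle <- granger_F_oracle(x, y)
    expect_equal(ours$F, unname(oracle[, "F"]), tolerance = 1e-10)
    expect_equal(ours$p_value, unname(oracle[, "p"]), tolerance = 1e-10)
  }
})

test_that("Granger p-values match lmtest::grangertest", {
  skip_if_not_installed("lmtest")
  set.seed(6)
  x <- rnorm(50)
  y <- 0.5 * c(0, x[-50]) + rnorm(50)
  ours <- granger_order1(x, y)
  g_xy <- lmtest::grangertest(x = x, y = y, order = 1)
  expect_equal(ours$p_value[1], g_xy$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("swapping the series swaps the two directions exactly", {
  set.seed(7)
  x <- rnorm(30)
  y <- 0.6 * c(0, x[-30]) + rnorm(30, 0, 0.3)
  ab <- granger_order1(x, y)
  ba <- granger_order1(y, x)
  expect_equal(ab$p_value, rev(ba$p_value))
  expect_equal(ab$F, rev(ba$F))
})

test_that("a constructed causal pair is detected in one direction only", {
  set.seed(8)
  x <- rnorm(100)
  y <- 0.9 * c(0, x[-100]) + rnorm(100, 0, 0.1)
  g <- granger_order1(x, y)
  expect_lt(g$p_value[1], 1e-10)
  expect_gt(g$p_value[2], 0.01)
})

test_that("independent series yield nominal Granger type-I error", {
  pairs <- generate_coupled_sections(1000, "none", n_points = 30, seed = 9)
  ps <- vapply(pairs, function(p) granger_order1(p$x, p$y)$p_value, numeric(2))
  expect_gte(mean(ps[1, ] < 0.05), 0.03)
  expect_lte(mean(ps[1, ] < 0.05), 0.07)
  expect_gte(mean(ps[2, ] < 0.05), 0.03)
  expect_lte(mean(ps[2, ] < 0.05), 0.07)
})

test_that("causality tallies follow the threshold arithmetic", {
  expect_equal(tally_causality(tibble::tibble()),
               tibble::tibble(n_xy = 0L, n_yx = 0L, n_none = 0L, n_total = 0L))
  one <- tibble::tibble(section_id = "s", n = 10, best_lag = 0, best_ccf = 0.9,
                        granger_xy_p = 0.0005, granger_yx_p = 0.5)
  expect_equal(tally_causality(one),
               tibble::tibble(n_xy = 1L, n_yx = 0L, n_none = 0L, n_total = 1L))
  short <- one
  short$n <- 2
  expect_equal(tally_causality(short)$n_total, 0L)
})

test_that("constructed lead-lag sections are recovered at high power", {
  pairs <- generate_coupled_sections(100, "x_leads", n_points = 100,
                                     a = 0.9, noise_sd = 0.1, seed = 10)
  res <- coupling_analysis(pairs)
  tl <- tally_causality(res, alpha = 0.001)
  expect_gt(tl$n_xy / tl$n_total, 0.9)
  expect_lt(tl$n_yx / tl$n_total, 0.1)

  shared <- generate_coupled_sections(5, "shared_tempo", n_points = 40,
                                      noise_sd = 0, seed = 11)
  # identical series make the Granger regressors collinear (flagged NA)
  res_s <- suppressWarnings(coupling_analysis(shared))
  expect_true(all(res_s$best_lag == 0))
  expect_true(all(res_s$best_ccf > 0.95))
})

test_that("coupling pairs are built per section and truncated to equal length", {
  corpus <- generate_corpus(synth_config(
    n_calls = 6, pulses_per_call = 20, pant_insertion_prob = 0.8,
    pant_position_profile = "uniform", seed = 12
  ))
  pairs <- coupling_pairs(corpus$events)
  expect_gt(length(pairs), 0)
  for (p in pairs) {
    expect_equal(length(p$x), length(p$y))
    expect_equal(p$n, length(p$x))
    expect_true(all(p$x > 0) && all(p$y > 0))  # interval durations
  }
  res <- coupling_analysis(pairs)
  expect_true(all(abs(res$best_ccf[!is.na(res$best_ccf)]) <= 1 + 1e-12))
})
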