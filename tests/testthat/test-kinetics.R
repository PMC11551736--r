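# Dwell histogramming, background-corrected fitting, decomposition,
# processivity classification and occurrence arithmetic.

test_that("occurrence deltas follow printed-table arithmetic", {
  ev <- data.frame(
    condition = c("control", "c10"), n_total = c(2055, 262),
    n_no_drop = c(1611, 54), n_one_step = c(324, 22),
    n_two_step = c(120, 186), n_rejected = c(0, 0))
  occ <- build_occurrence_table(ev, "control")
  expect_equal(occ$p_two_step, c(5.8, 71.0))
  expect_equal(occ$delta_two_step, c(0, 65.2))
  expect_equal(occ$delta_one_step, c(0, 8.4 - 15.8))
  # identical condition and control: all deltas zero
  ev2 <- ev[c(1, 1), ]; ev2$condition <- c("control", "same")
  occ2 <- build_occurrence_table(ev2, "control")
  expect_true(all(occ2$delta_one_step == 0 & occ2$delta_two_step == 0))
  expect_error(build_occurrence_table(ev, "missing"), "control")
})

test_that("scenario probabilities sum to 100 within rounding", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(50:500, 3)
    ev <- data.frame(condition = "x", n_total = sum(n), n_no_drop = n[1],
                     n_one_step = n[2], n_two_step = n[3], n_rejected = 0)
    occ <- build_occurrence_table(ev, "x")
    expect_lt(abs(occ$p_no_drop + occ$p_one_step + occ$p_two_step - 100),
              0.2)
  }
})

test_that("bin-width selection stabilizes on clean Gaussian dwell samples", {
  set.seed(3)
  x <- rnorm(200, 3.2, 0.8)
  w <- select_bin_width(x)
  f <- fit_plain_gaussian(dwell_histogram(x, w))
  expect_lt(abs(f$mu - 3.2), 0.1)
})

test_that("degenerate and non-stabilizing samples follow the selection rules", {
  expect_equal(select_bin_width(rep(2.5, 50),
                                candidate_widths = c(0.2, 0.5, 1)), 0.2)
  # far-separated bimodal sample: no width stabilizes, Freedman-Diaconis
  set.seed(1)
  x <- c(rnorm(120, 2, 0.3), rnorm(120, 40, 0.3))
  w <- select_bin_width(x, candidate_widths = c(0.2, 0.3, 0.5),
                        stability_tol = 0.2)
  expect_equal(w, 2 * IQR(x) / length(x)^(1 / 3))
  expect_error(select_bin_width(rnorm(10)), "30")
})

test_that("quartic background fits recover known coefficients and masses", {
  mids <- seq(0.5, 19.5, by = 1)
  coefs <- c(40, -3, 0.5, -0.02, 0.0002)
  counts <- round(coefs[1] + coefs[2] * mids + coefs[3] * mids^2 +
                    coefs[4] * mids^3 + coefs[5] * mids^4)
  h <- structure(list(bin_edges = 0:20, mids = mids, counts = counts,
                      n_events = sum(counts), bin_width = 1),
                 class = "dwell_histogram")
  fit <- fit_background(h)
  expect_equal(fit$coeffs, coefs, tolerance = 0.05)
  # flat histogram: constant term only
  h$counts <- rep(25, 20)
  flat <- fit_background(h)
  expect_equal(flat$coeffs[1], 25, tolerance = 1e-6)
  expect_true(all(abs(flat$coeffs[2:5]) < 1e-6))
  h$counts <- c(5, 3, rep(0, 18))
  expect_error(fit_background(h), "nonempty")
})

test_that("fitted bleaching background conserves the event mass", {
  # T2 gaps of independent bleaching at a rate giving good two-drop yield
  photo <- photophysics(noise_sd = 0, k_bleach = 0.02)
  trs <- simulate_many(1600, simulate_bleach_only_trace, photo = photo)
  t2 <- vapply(trs, truth_gap, numeric(1))
  both_in <- vapply(trs, function(tr) all(tr$truth$time <= 100), logical(1))
  t2 <- t2[both_in]
  expect_gt(length(t2), 1000)
  h <- dwell_histogram(t2, 5)
  fit <- fit_background(h)
  mass <- sum(predict(fit, h$mids))
  expect_lt(abs(mass - length(t2)) / length(t2), 0.05)
})

test_that("a pure Gaussian histogram is recovered without background", {
  mids <- seq(0.25, 9.75, by = 0.5)
  counts <- 80 * exp(-(mids - 3.2)^2 / (2 * 0.8^2))
  h <- structure(list(bin_edges = seq(0, 10, 0.5), mids = mids,
                      counts = counts, n_events = round(sum(counts)),
                      bin_width = 0.5), class = "dwell_histogram")
  fit <- fit_gaussian_plus_background(h, NULL, mode = "joint")
  expect_equal(fit$mu, 3.2, tolerance = 1e-3)
  expect_equal(fit$sigma, 0.8, tolerance = 1e-3)
})

test_that("background subtraction recovers the degradation peak in a contaminated pool", {
  # degradation dwells at ~3.26 s over a bleach-derived background
  set.seed(7)
  deg <- rgamma(200, 18, scale = 0.16) + rgamma(200, 4, scale = 0.1)
  photo <- photophysics(noise_sd = 0, k_bleach = 0.02)
  ctrl <- vapply(simulate_many(1600, simulate_bleach_only_trace,
                               photo = photo),
                 truth_gap, numeric(1))
  ctrl <- ctrl[ctrl <= 100]
  contam <- sample(ctrl, 60)
  pool <- c(deg, contam)
  bw <- select_bin_width(pool, candidate_widths = c(0.3, 0.5, 0.75, 1))
  h <- dwell_histogram(pool, bw)
  bg <- fit_background(dwell_histogram(ctrl, bw, t_max = max(pool)))
  fit <- fit_gaussian_plus_background(h, bg, mode = "joint")
  expect_lt(abs(fit$mu - 3.28), 0.3)
  fix <- fit_gaussian_plus_background(h, bg, mode = "fixed_shape")
  expect_lt(abs(fix$mu - 3.28), 0.3)
  expect_error(fit_gaussian_plus_background(h, NULL, mode = "fixed_shape"),
               "control")
})

test_that("the dwell-versus-spacing decomposition matches exact lines", {
  pts <- data.frame(S = c(8, 13, 18, 28), t2_av = 0.5 * c(8, 13, 18, 28) + 1)
  d <- decompose_linear(pts)
  expect_equal(d$slope, 0.5, tolerance = 1e-10)
  expect_equal(d$intercept, 1, tolerance = 1e-10)
  expect_equal(d$rate, 2, tolerance = 1e-10)
  expect_equal(d$r_squared, 1, tolerance = 1e-10)
  expect_equal(d$rate * d$slope, 1)
  expect_equal(d$se_rate, d$se_slope / d$slope^2)
})

test_that("decomposition is equivariant under dwell rescaling", {
  pts <- data.frame(S = c(8, 13, 18, 28), t2_av = c(1.7, 2.5, 3.2, 5.0))
  d1 <- decompose_linear(pts)
  for (k in c(0.5, 2, 10)) {
    pts2 <- pts; pts2$t2_av <- k * pts$t2_av
    d2 <- decompose_linear(pts2)
    expect_equal(d2$slope, k * d1$slope)
    expect_equal(d2$intercept, k * d1$intercept)
    expect_equal(d2$rate, d1$rate / k)
  }
})

test_that("degenerate decompositions error", {
  expect_error(decompose_linear(data.frame(S = c(8, 8, 8),
                                           t2_av = c(1, 2, 3))), "distinct")
  expect_error(decompose_linear(data.frame(S = c(8, 13), t2_av = c(1, 2))),
               "distinct")
  expect_error(decompose_linear(data.frame(S = c(8, 13, 18),
                                           t2_av = c(5, 3, 1))), "slope")
})

test_that("concentration-independent dwells classify as processive", {
  p <- classify_processivity(data.frame(c = c(1, 5, 10),
                                        t2_av = c(3.2, 3.3, 3.2)))
  expect_equal(p$classification, "processive")
  flat <- classify_processivity(data.frame(c = c(1, 5, 10, 50),
                                           t2_av = rep(2.7, 4)))
  expect_equal(flat$classification, "processive")
})

test_that("concentration-dependent dwells classify as distributive", {
  p <- classify_processivity(data.frame(c = c(1, 5, 10, 50),
                                        t2_av = c(21.0, 12.8, 11.3, 9.8)))
  expect_equal(p$classification, "distributive")
  expect_lt(p$slope, 0)
  expect_error(classify_processivity(data.frame(c = c(1, 5),
                                                t2_av = c(2, 2))), "3")
})

test_that("efficiency ratios are simple one-decimal folds", {
  expect_equal(efficiency_ratio(23.2, 12.5), 1.9)
  expect_equal(efficiency_ratio(10, 10), 1.0)
  expect_equal(efficiency_ratio(65.2, 32.6), 2.0)
  expect_error(efficiency_ratio(5, 0), "positive")
})
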