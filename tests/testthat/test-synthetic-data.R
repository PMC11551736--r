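# Monte-Carlo trace generator: event model, censoring, scenario mixtures.

test_that("inactive enzyme, no bleaching, no noise gives a constant two-unit trace", {
  tr <- simulate_processive_trace(sub5p(), enzyme_kinetics("inactive"),
                                  photo_clean(), seed = 1)
  expect_length(tr$intensities, 1000)
  expect_true(all(tr$intensities == 2000))
  expect_true(all(tr$truth$censored))
})

test_that("processive inter-drop times average to S bond times (sum-of-exponentials oracle)", {
  # prebound, n0 = 0, tau_fluor = 0: the gap is a sum of S = 18 exponentials
  # of mean 0.159 s; E = 2.862 s, SE = sqrt(18) * 0.159 / sqrt(n)
  n <- 10000
  enz <- enz_proc(tau_nt = 0.159, tau_fluor = 0, prebound = TRUE)
  gaps <- vapply(simulate_many(n, simulate_processive_trace,
                               substrate = sub5p(S = 18, n0 = 0),
                               enzyme = enz, photo = photo_truth()),
                 truth_gap, numeric(1))
  se <- sqrt(18) * 0.159 / sqrt(n)
  expect_lt(abs(mean(gaps) - 2.862), 3 * se)
})

test_that("processive gap mean matches the dwell model S*tau_nt + tau_fluor", {
  # Fig-1G-style parameters for the 18-nt spacing: expect ~3.28 s mean gap,
  # consistent with a measured dwell of 3.2 +- 0.8 s
  n <- 4000
  enz <- enz_proc(tau_nt = 0.16, tau_fluor = 0.40, prebound = TRUE)
  gaps <- vapply(simulate_many(n, simulate_processive_trace,
                               substrate = sub5p(S = 18, n0 = 0),
                               enzyme = enz, photo = photo_truth()),
                 truth_gap, numeric(1))
  truth_mean <- 18 * 0.16 + 0.40
  expect_lt(abs(mean(gaps) - truth_mean), 4 * sd(gaps) / sqrt(n))
  expect_lt(abs(mean(gaps) - 3.2), 0.8)
})

test_that("distributive gaps are exponential with the per-site rate", {
  n <- 10000
  enz <- enzyme_kinetics("distributive", k_site = 1 / 21)
  gaps <- vapply(simulate_many(n, simulate_distributive_trace,
                               substrate = sub5p(), enzyme = enz,
                               photo = photo_truth()),
                 truth_gap, numeric(1))
  expect_lt(abs(mean(gaps) - 21.0), 3 * 21.0 / sqrt(n))
})

test_that("very fast distributive cleavage darkens the trace immediately", {
  enz <- enzyme_kinetics("distributive", k_site = 1e9)
  tr <- simulate_distributive_trace(sub5p(), enz, photo_clean(), seed = 3)
  expect_true(all(tr$intensities[-1] == 0))
})

test_that("saturating k_site increases with concentration and shortens gaps", {
  enz <- function(c0) enzyme_kinetics("distributive", k_max = 0.2,
                                      c_half = 5, concentration = c0)
  ks <- vapply(c(1, 5, 10, 50), function(c0) site_cleavage_rate(enz(c0)),
               numeric(1))
  expect_true(all(diff(ks) > 0))
  mean_gap <- function(c0) {
    g <- vapply(simulate_many(300, simulate_distributive_trace,
                              substrate = sub5p(), enzyme = enz(c0),
                              photo = photo_truth(), seed0 = 100 * c0),
                truth_gap, numeric(1))
    mean(g)
  }
  gaps <- vapply(c(1, 5, 10, 50), mean_gap, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("bleach-only survival matches the independent-survival product", {
  # per-fluorophore survival 0.9 over the window -> P(no drop) = 0.81
  n <- 10000
  kb <- -log(0.9) / 100
  photo <- photophysics(noise_sd = 0, k_bleach = kb)
  zero_drop <- vapply(simulate_many(n, simulate_bleach_only_trace,
                                    photo = photo),
                      function(tr) all(tr$truth$time > 100), logical(1))
  se <- sqrt(0.81 * 0.19 / n)
  expect_lt(abs(mean(zero_drop) - 0.81), 3 * se)
  expect_equal(mean(zero_drop == 0 | zero_drop == 1), 1)
})

test_that("k_bleach = 0 yields no drops ever", {
  tr <- simulate_bleach_only_trace(photo_clean(), seed = 9)
  expect_true(all(is.infinite(tr$truth$time)))
  expect_true(all(tr$intensities == 2000))
})

test_that("scenario-mixture control reproduces the supplied proportions", {
  n <- 6000
  mix <- c(78.4, 15.8, 5.8)
  photo <- photophysics(noise_sd = 0)
  n_in <- vapply(simulate_many(n, simulate_bleach_only_trace, photo = photo,
                               scenario_mix = mix),
                 function(tr) sum(tr$truth$time <= 100), numeric(1))
  obs <- tabulate(n_in + 1, nbins = 3) / n
  p <- mix / sum(mix)
  for (k in 1:3)
    expect_lt(abs(obs[k] - p[k]), 4 * sqrt(p[k] * (1 - p[k]) / n))
  # all events in a control trace are spontaneous bleaching
  tr <- simulate_bleach_only_trace(photo, 1, scenario_mix = mix)
  expect_true(all(tr$truth$cause == "bleach", na.rm = TRUE))
})

test_that("rendered pre-noise intensity is a non-increasing multiple of the unit", {
  for (seed in 1:20) {
    tr <- simulate_processive_trace(
      sub5p(S = 8, n0 = 2),
      enz_proc(tau_nt = 0.5, tau_fluor = 0.5, prebound = TRUE),
      photophysics(noise_sd = 0, k_bleach = 0.01), seed = seed)
    lev <- tr$intensities / 1000
    expect_true(all(lev %in% c(0, 1, 2)))
    expect_true(all(diff(lev) <= 0))
  }
})

test_that("truth events beyond the window are censored and never rendered", {
  photo <- photophysics(noise_sd = 0, k_bleach = 0.004)
  for (seed in 1:30) {
    tr <- simulate_bleach_only_trace(photo, seed)
    n_drop_rendered <- 2 - tr$intensities[1000] / 1000
    expect_equal(n_drop_rendered, sum(!tr$truth$censored))
    expect_true(all(tr$truth$censored == (tr$truth$time > 100)))
  }
})

test_that("prebound inter-drop intervals are concentration independent (KS)", {
  n <- 1000
  gaps_at <- function(c0, seed0) {
    enz <- enz_proc(concentration = c0, prebound = TRUE)
    vapply(simulate_many(n, simulate_processive_trace, seed0 = seed0,
                         substrate = sub5p(), enzyme = enz,
                         photo = photo_truth()),
           truth_gap, numeric(1))
  }
  g1 <- gaps_at(1, 1); g10 <- gaps_at(10, 50000)
  expect_gt(suppressWarnings(stats::ks.test(g1, g10)$p.value), 0.01)
})

test_that("an inactive enzyme reproduces the bleach-only generator exactly", {
  photo <- photophysics(k_bleach = 0.002)
  for (seed in c(2, 77, 123)) {
    a <- simulate_processive_trace(sub5p(), enzyme_kinetics("inactive"),
                                   photo, seed)
    b <- simulate_bleach_only_trace(photo, seed)
    expect_equal(a$intensities, b$intensities)
    expect_equal(a$truth$time, b$truth$time)
  }
})

test_that("static FRET at E = 0.5 with no noise gives equal channels", {
  ft <- simulate_fret_trace("static", 0.5, photo = photo_clean(), seed = 1)
  expect_equal(ft$donor, ft$acceptor)
})

test_that("unwinding ramp durations average to the configured mean", {
  n <- 10000
  ramps <- vapply(simulate_many(n, simulate_fret_trace, kind = "unwinding",
                                levels = c(0.15, 0.77), t_unwind_mean = 1.4,
                                photo = photo_truth()),
                  function(ft) ft$truth$ramp_duration, numeric(1))
  se <- (1.4 / sqrt(19)) / sqrt(n)
  expect_lt(abs(mean(ramps) - 1.4), 3 * se)
})

test_that("per-frame efficiency of a static high-FRET pair converges to truth", {
  ft <- simulate_fret_trace("static", 0.85, photo = photo_clean(), seed = 4)
  e <- compute_efficiency(ft)
  expect_equal(mean(e$efficiency), 0.85, tolerance = 1e-10)
  ft2 <- simulate_fret_trace("static", 0.85, photo = photophysics(noise_sd = 10),
                             seed = 4)
  expect_equal(mean(compute_efficiency(ft2)$efficiency), 0.85,
               tolerance = 0.005)
})

test_that("parameter validation rejects invalid models", {
  expect_error(substrate_spec(S = 30, n0 = 20, overhang_length = 40),
               "overhang_length")
  expect_error(enzyme_kinetics("processive", tau_nt = -1, tau_fluor = 0),
               "tau_nt")
  expect_error(enzyme_kinetics("distributive"), "k_site")
  expect_error(photophysics(window = 100.05), "whole number")
  expect_error(simulate_fret_trace("unwinding", c(0.8, 0.2),
                                   t_unwind_mean = 1, photo = photo_clean(),
                                   seed = 1))
})
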