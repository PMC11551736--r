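# Step detection, SNR, selection and scenario tabulation.

test_that("SNR is background-subtracted signal over background sd", {
  expect_equal(compute_snr(1100, 100, 50)$snr, 20)
  expect_equal(compute_snr(100, 100, 50)$snr, 0)
  expect_equal(compute_snr(list(signal_mean = 600, background_mean = 100,
                                background_sd = 25))$snr, 20)
  expect_error(compute_snr(1100, 100, 0), "positive")
})

test_that("SNR of a simulated spot matches the generator noise model", {
  # spot of constant intensity over Poisson background: analytic SNR =
  # (mean window signal) / sd(window background sum)
  tr <- list(times = (1:200 - 0.5) * 0.1, intensities = rep(800, 200))
  mv <- simulate_movie(list(new_trace(tr$times, tr$intensities, NULL, NULL)),
                       field_size = 40, psf_sd = 1.2, background = 100,
                       seed = 8)
  ext <- extract_traces_from_movie(mv$stack, detect_threshold = 5,
                                   window_radius = 3)
  expect_length(ext, 1)
  bg_win_sd <- sqrt(49 * 100)             # Poisson background over the window
  snr <- compute_snr(mean(ext[[1]]$intensities), 0, bg_win_sd)$snr
  expect_equal(snr, 800 / bg_win_sd, tolerance = 0.1)
})

test_that("noiseless drops are located exactly and classified two-step", {
  tr <- flat_step_trace(c(100, 400))
  cl <- detect_steps(tr, unit = 1000)
  expect_equal(cl$step_times, c(10, 40))
  expect_equal(cl$scenario, "two_step")
  expect_equal(cl$T2, 30)
  expect_equal(unname(cl$step_magnitudes), c(-1000, -1000))
})

test_that("one-step and no-step traces classify with the right dwells", {
  one <- detect_steps(flat_step_trace(250), unit = 1000)
  expect_equal(one$scenario, "one_step")
  expect_equal(one$T1, 25)
  none <- detect_steps(flat_step_trace(integer(0)), unit = 1000)
  expect_equal(none$scenario, "no_drop")
  zero <- detect_steps(list(times = (1:100 - 0.5) * 0.1,
                            intensities = rep(0, 100)), unit = 1000)
  expect_equal(zero$scenario, "no_drop")
})

test_that("three unit drops are rejected", {
  tr <- flat_step_trace(c(100, 400, 700), levels0 = 3)
  cl <- detect_steps(tr, unit = 1000)
  expect_equal(cl$scenario, "rejected")
})

test_that("detection is idempotent and offset invariant", {
  tr <- flat_step_trace(c(120, 500), noise_sd = 50, seed = 5)
  cl1 <- detect_steps(tr, unit = 1000)
  cl2 <- detect_steps(tr, unit = 1000)
  expect_identical(cl1$step_times, cl2$step_times)
  tr_off <- tr
  tr_off$intensities <- tr$intensities + 12345
  cl3 <- detect_steps(tr_off, unit = 1000)
  expect_equal(cl1$step_times, cl3$step_times)
  expect_equal(cl1$step_magnitudes, cl3$step_magnitudes)
})

test_that("steps at default noise are recovered within two frames", {
  n <- 400
  photo <- photophysics()   # unit 1000, noise 50, bleach 0.0012
  enz <- enz_proc(prebound = TRUE)
  hits <- 0; total <- 0; confused <- 0
  for (i in seq_len(n)) {
    tr <- simulate_processive_trace(sub5p(S = 18, n0 = 3), enz, photo,
                                    seed = 20000 + i)
    cl <- detect_steps(tr, unit = 1000)
    tt <- sort(tr$truth$time[!tr$truth$censored])
    true_scen <- c("no_drop", "one_step", "two_step")[length(tt) + 1]
    if (cl$scenario != true_scen) confused <- confused + 1
    if (length(cl$step_times) && length(tt)) {
      for (st in cl$step_times) {
        total <- total + 1
        if (min(abs(st - tt)) <= 0.2 + 1e-9) hits <- hits + 1
      }
    }
  }
  expect_gt(hits / total, 0.98)
  expect_lt(confused / n, 0.02)
})

test_that("unit intensity is estimated from step candidates", {
  noiseless <- lapply(1:25, function(i) flat_step_trace(c(100 + i, 500)))
  expect_equal(estimate_unit_intensity(noiseless), 1000)
  noisy <- lapply(1:40, function(i)
    flat_step_trace(c(100 + i, 500), noise_sd = 50, seed = i))
  expect_lt(abs(estimate_unit_intensity(noisy) - 1000) / 1000, 0.05)
  expect_equal(estimate_unit_intensity(list(), config_unit = 800), 800)
  expect_error(estimate_unit_intensity(list()), "fallback")
})

test_that("the two-fluorophore intensity criterion selects the right traces", {
  two <- lapply(1:10, function(i) flat_step_trace(c(500)))
  one <- lapply(1:10, function(i) flat_step_trace(c(500), levels0 = 1))
  expect_length(select_traces(two, 1000), 10)
  expect_length(select_traces(one, 1000), 0)
  # engineered mixed population: ~25% dual-labeled
  set.seed(42)
  n <- 2000
  dual <- runif(n) < 0.25
  pop <- lapply(seq_len(n), function(i)
    flat_step_trace(integer(0), levels0 = if (dual[i]) 2 else 1,
                    n = 20, noise_sd = 50, seed = i))
  frac <- length(select_traces(pop, 1000)) / n
  expect_lt(abs(frac - mean(dual)), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("scenario tabulation pools counts and dwells per condition", {
  mk <- function(scen, t1 = NA, t2 = NA, cond = "a")
    structure(list(step_times = numeric(0), step_magnitudes = numeric(0),
                   scenario = scen, T1 = t1, T2 = t2,
                   meta = list(condition = cond)), class = "step_call")
  calls <- c(replicate(10, mk("no_drop"), simplify = FALSE),
             replicate(5, mk("one_step", t1 = 7), simplify = FALSE),
             replicate(5, mk("two_step", t2 = 3), simplify = FALSE))
  et <- classify_and_extract(calls)
  expect_equal(et$events$n_total, 20)
  occ <- build_occurrence_table(et, "a")
  expect_equal(occ$p_no_drop, 50.0)
  expect_equal(occ$p_one_step, 25.0)
  expect_equal(occ$p_two_step, 25.0)
  expect_true(all(et$dwells$dwell_s[et$dwells$dwell_type == "T2"] == 3))
})

test_that("short traces and missing conditions error clearly", {
  expect_error(detect_steps(list(times = 0.05, intensities = 5), unit = 1),
               "min_dwell")
  cl <- detect_steps(flat_step_trace(100), unit = 1000)
  expect_error(classify_and_extract(list(cl)), "condition")
})
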