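# Shared fixtures: quiet photophysics objects and batch simulators.

photo_default <- function(...) photophysics(...)

photo_clean <- function(...) photophysics(noise_sd = 0, k_bleach = 0, ...)

# Short window for generator-truth checks that never look at the rendering.
photo_truth <- function(...) photophysics(noise_sd = 0, k_bleach = 0,
                                          window = 1, ...)

sub5p <- function(S = 18, n0 = 0)
  substrate_spec(S = S, n0 = n0, label_type = "iCy3",
                 overhang_end = "five_prime",
                 overhang_length = max(40, S + n0 + 5))

enz_proc <- function(tau_nt = 0.16, tau_fluor = 0.40, concentration = 10,
                     prebound = FALSE, ...)
  enzyme_kinetics("processive", tau_nt = tau_nt, tau_fluor = tau_fluor,
                  concentration = concentration, prebound = prebound, ...)

# Uncensored inter-drop interval (from the truth log).
truth_gap <- function(tr) abs(diff(tr$truth$time))

simulate_many <- function(n, fun, seed0 = 1000, ...)
  lapply(seq_len(n), function(i) fun(..., seed = seed0 + i))

# Piecewise-constant synthetic trace with drops at given 0-based frames.
flat_step_trace <- function(drop_frames, unit = 1000, n = 1000, dt = 0.1,
                            noise_sd = 0, levels0 = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lev <- rep(levels0, n)
  for (k in drop_frames) lev[(k + 1):n] <- lev[(k + 1):n] - 1
  y <- lev * unit
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  list(times = (seq_len(n) - 0.5) * dt, intensities = y,
       meta = list(frame_interval = dt))
}
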