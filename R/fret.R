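#' Proximity-ratio FRET efficiency series
#'
#' Computes `E = acceptor / (acceptor + donor)` at every frame where the
#' total intensity reaches `floor`; no gamma, leakage or direct-excitation
#' correction is applied. Values are clipped to `[0, 1]`.
#'
#' @param trace a `fret_trace`.
#' @param floor minimum donor+acceptor total (a.u.) for a defined
#'   efficiency; defaults to 20% of the pair's unit intensity when the trace
#'   carries photophysics metadata.
#' @return list of class `efficiency_series`: `times`, `efficiency` (only
#'   frames above the floor).
#' @export
compute_efficiency <- function(trace, floor = NULL) {
  stopifnot(inherits(trace, "fret_trace") ||
              all(c("times", "donor", "acceptor") %in% names(trace)))
  if (is.null(floor)) {
    u <- tryCatch(trace$meta$photo$unit_intensity, error = function(e) NULL)
    floor <- if (is.null(u)) 1 else 0.2 * u
  }
  stopifnot(floor > 0)
  tot <- trace$donor + trace$acceptor
  ok <- is.finite(tot) & tot >= floor
  if (!any(ok))
    stop("compute_efficiency: no frame reaches the intensity floor")
  e <- pmin(pmax(trace$acceptor[ok] / tot[ok], 0), 1)
  structure(list(times = trace$times[ok], efficiency = e),
            class = "efficiency_series")
}

#' @export
print.efficiency_series <- function(x, ...) {
  cat(sprintf("<efficiency_series> %d frames, mean E = %.2f\n",
              length(x$efficiency), mean(x$efficiency)))
  invisible(x)
}

# Local maxima of a histogram profile, tolerating plateaus: a peak is a run
# of equal counts strictly higher than both neighbors (its center is used).
find_hist_peaks <- function(ys) {
  n <- length(ys)
  peaks <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && ys[j + 1] == ys[i]) j <- j + 1
    left <- if (i == 1) -Inf else ys[i - 1]
    right <- if (j == n) -Inf else ys[j + 1]
    if (ys[i] > left && ys[i] > right)
      peaks <- c(peaks, as.integer(floor((i + j) / 2)))
    i <- j + 1
  }
  peaks
}

#' Fit one or two Gaussian components to a pooled FRET-efficiency histogram
#'
#' Pools per-frame efficiencies, bins them on `[0, 1]`, and fits a single
#' Gaussian -- or two Gaussians when a bimodality score exceeds
#' `bimodality_threshold`. The score is the relative dip between the two
#' largest local maxima of the (lightly smoothed) histogram:
#' `(min(peak1, peak2) - valley) / min(peak1, peak2)`.
#'
#' @param efficiencies pooled per-frame efficiencies (>= 100 values), or a
#'   list of `efficiency_series` to pool.
#' @param bin_width histogram bin width (efficiency units).
#' @param bimodality_threshold dip score above which two components are fit.
#' @return data.frame of class `fret_histogram_fit` with one row per
#'   component: `mean`, `sd`, `weight` (fraction of fitted mass).
#' @export
fit_efficiency_histogram <- function(efficiencies, bin_width = 0.02,
                                     bimodality_threshold = 0.5) {
  if (is.list(efficiencies) && !is.numeric(efficiencies))
    efficiencies <- unlist(lapply(efficiencies, function(s) s$efficiency))
  if (length(efficiencies) < 100)
    stop("fit_efficiency_histogram: need at least 100 pooled frames")
  if (stats::sd(efficiencies) < bin_width / 10) {   # degenerate spike
    out <- data.frame(mean = mean(efficiencies), sd = stats::sd(efficiencies),
                      weight = 1)
    class(out) <- c("fret_histogram_fit", "data.frame")
    return(out)
  }
  edges <- seq(0, 1 + bin_width, by = bin_width)
  h <- graphics::hist(pmin(efficiencies, 1), breaks = edges, plot = FALSE)
  d <- data.frame(t = h$mids, y = h$counts)
  ys <- if (length(d$y) >= 5) stats::runmed(d$y, 3) else d$y
  loc_max <- find_hist_peaks(ys)
  two <- FALSE
  if (length(loc_max) >= 2) {
    ord <- loc_max[order(ys[loc_max], decreasing = TRUE)][1:2]
    ord <- sort(ord)
    valley <- min(ys[ord[1]:ord[2]])
    small <- min(ys[ord])
    if (small > 0 && (small - valley) / small > bimodality_threshold &&
        abs(d$t[ord[1]] - d$t[ord[2]]) > 2 * bin_width)
      two <- TRUE
  }
  if (!two) {
    hobj <- list(mids = d$t, counts = d$y, bin_width = bin_width)
    f <- fit_plain_gaussian(hobj)
    if (is.null(f)) stop("fit_efficiency_histogram: fit did not converge")
    out <- data.frame(mean = f$mu, sd = f$sigma, weight = 1)
  } else {
    m1 <- d$t[ord[1]]; m2 <- d$t[ord[2]]
    fit <- try(minpack.lm::nlsLM(
      y ~ A1 * exp(-(t - mu1)^2 / (2 * s1^2)) +
        A2 * exp(-(t - mu2)^2 / (2 * s2^2)),
      data = d,
      start = list(A1 = ys[ord[1]], mu1 = m1, s1 = 0.03,
                   A2 = ys[ord[2]], mu2 = m2, s2 = 0.03),
      lower = c(0, 0, bin_width / 2, 0, 0, bin_width / 2),
      upper = c(Inf, 1, 0.5, Inf, 1, 0.5),
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error"))
      stop("fit_efficiency_histogram: two-component fit did not converge")
    cf <- stats::coef(fit)
    mass <- c(cf[["A1"]] * cf[["s1"]], cf[["A2"]] * cf[["s2"]])
    out <- data.frame(mean = c(cf[["mu1"]], cf[["mu2"]]),
                      sd = c(cf[["s1"]], cf[["s2"]]),
                      weight = mass / sum(mass))
    out <- out[order(out$mean), ]
    rownames(out) <- NULL
  }
  class(out) <- c("fret_histogram_fit", "data.frame")
  out
}

#' Detect a duplex-unwinding transition in a FRET efficiency series
#'
#' An unwinding event is a monotone low-to-high efficiency transit. With
#' band margin `f = enter_frac`, `t_start` is the last time the (smoothed)
#' efficiency is at or below `low + f * (high - low)` before the transition
#' and `t_end` the first subsequent time it reaches `high - f * (high -
#' low)`. Because those crossings span only a fraction `1 - 2f` of a linear
#' ramp, the reported dwell is rescaled by `1 / (1 - 2f)` to estimate the
#' full low-to-high transit time. The call is flagged `paused` when the
#' efficiency lingers at an intermediate level (absolute slope below
#' `pause_slope_tol * (high - low)` per second) for at least `pause_max`
#' seconds; paused calls are excluded from rate aggregation.
#'
#' @param series an [compute_efficiency()] result.
#' @param low_level,high_level the low and high efficiency plateaus.
#' @param enter_frac band margin as a fraction of `high - low`.
#' @param pause_max minimum pause duration (s) that flags the call.
#' @param smooth_frames running-mean width (frames) applied before
#'   thresholding.
#' @param pause_slope_tol pause slope threshold, fraction of the efficiency
#'   span per second.
#' @return object of class `unwinding_call` (`t_start`, `t_end`,
#'   `T_unwinding`, `paused`) or `NULL` when no complete transition occurs.
#' @export
detect_unwinding <- function(series, low_level, high_level, enter_frac = 0.1,
                             pause_max = 0.5, smooth_frames = 5,
                             pause_slope_tol = 0.05) {
  stopifnot(low_level < high_level)
  e <- series$efficiency
  tt <- series$times
  if (length(e) < 2 * smooth_frames) return(NULL)
  k <- max(1, smooth_frames)
  es <- stats::filter(e, rep(1 / k, k), sides = 2)
  es[is.na(es)] <- e[is.na(es)]
  es <- as.numeric(es)
  span <- high_level - low_level
  thr_lo <- low_level + enter_frac * span
  thr_hi <- high_level - enter_frac * span
  j <- which(es >= thr_hi)[1]
  if (is.na(j)) return(NULL)
  before <- which(es[seq_len(j - 1)] <= thr_lo)
  if (!length(before)) return(NULL)
  i <- max(before)
  # sub-frame crossing times by linear interpolation between frames
  interp <- function(k1, k2, thr) {
    if (k2 <= k1 || es[k2] == es[k1]) return(tt[k1])
    tt[k1] + (thr - es[k1]) * (tt[k2] - tt[k1]) / (es[k2] - es[k1])
  }
  t_start <- if (i < j) interp(i, i + 1, thr_lo) else tt[i]
  t_end <- if (j > i) interp(j - 1, j, thr_hi) else tt[j]
  T_raw <- t_end - t_start
  T_unw <- T_raw / (1 - 2 * enter_frac)
  paused <- FALSE
  if (j - i > 2) {
    dt <- stats::median(diff(tt))
    idx <- i:j
    slope <- c(0, diff(es[idx])) / dt
    inter <- es[idx] > thr_lo & es[idx] < thr_hi
    flat <- inter & abs(slope) < pause_slope_tol * span
    r <- rle(flat)
    if (any(r$values & r$lengths * dt >= pause_max)) paused <- TRUE
  }
  structure(list(t_start = t_start, t_end = t_end, T_unwinding = T_unw,
                 paused = paused), class = "unwinding_call")
}

#' @export
print.unwinding_call <- function(x, ...) {
  cat(sprintf("<unwinding_call> %.2f -> %.2f s, T = %.2f s%s\n", x$t_start,
              x$t_end, x$T_unwinding, if (x$paused) " (paused)" else ""))
  invisible(x)
}

#' Aggregate unwinding dwells into a duplex-unwinding rate
#'
#' Pools the unpaused unwinding dwells, fits their histogram with a single
#' Gaussian, and reports `bp_unwound` divided by the fitted mean dwell. The
#' rate uncertainty is propagated from the fitted dwell sd by the delta
#' method (`bp * sigma / mu^2`). Using the fitted mean rather than the mean
#' of per-call rates avoids the heavy right tail of `1/T`.
#'
#' @param calls list of [detect_unwinding()] results (may contain `NULL` and
#'   paused calls, which are dropped). At least 20 unpaused calls required.
#' @param bp_unwound base pairs unwound during one transition.
#' @param bin_width optional dwell histogram bin width (s); selected by
#'   fitted-mean stability when `NULL`.
#' @return list of class `unwinding_rate`: `rate` (bp/s), `sd_rate`,
#'   `mean_dwell`, `sd_dwell`, `n`, `per_call_rates`.
#' @export
unwinding_rate <- function(calls, bp_unwound, bin_width = NULL) {
  calls <- Filter(function(cl) !is.null(cl) && !cl$paused, calls)
  if (length(calls) < 20)
    stop("unwinding_rate: need at least 20 unpaused unwinding calls")
  dwell <- vapply(calls, function(cl) cl$T_unwinding, numeric(1))
  if (stats::sd(dwell) == 0) {
    f <- list(mu = dwell[1], sigma = 0)
  } else {
    if (is.null(bin_width))
      bin_width <- select_bin_width(dwell,
                                    candidate_widths = c(0.05, 0.1, 0.15,
                                                         0.2, 0.3, 0.5),
                                    stability_tol = 0.1)
    f <- fit_plain_gaussian(dwell_histogram(dwell, bin_width))
    if (is.null(f)) stop("unwinding_rate: dwell histogram fit did not converge")
  }
  structure(list(rate = bp_unwound / f$mu,
                 sd_rate = bp_unwound * f$sigma / f$mu^2,
                 mean_dwell = f$mu, sd_dwell = f$sigma, n = length(dwell),
                 per_call_rates = bp_unwound / dwell),
            class = "unwinding_rate")
}

#' @export
print.unwinding_rate <- function(x, ...) {
  cat(sprintf(
    "<unwinding_rate> %.1f +- %.1f bp/s (mean dwell %.2f s, n = %d)\n",
    x$rate, x$sd_rate, x$mean_dwell, x$n))
  invisible(x)
}
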