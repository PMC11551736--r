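#' Signal-to-noise ratio of a detected spot
#'
#' SNR is the background-subtracted mean signal divided by the background
#' standard deviation: `(S - B) / sigma`.
#'
#' @param x either a numeric vector/list with elements `signal_mean`,
#'   `background_mean`, `background_sd`, or the signal mean when the other
#'   two are passed separately.
#' @param background_mean,background_sd background statistics (a.u.).
#' @return list of class `snr_stats`: `signal_mean`, `background_mean`,
#'   `background_sd`, `snr`.
#' @export
#' @examples
#' compute_snr(1100, 100, 50)$snr   # 20
compute_snr <- function(x, background_mean = NULL, background_sd = NULL) {
  if (is.list(x)) {
    background_mean <- x$background_mean
    background_sd <- x$background_sd
    x <- x$signal_mean
  }
  stopifnot(is.numeric(x), is.numeric(background_mean),
            is.numeric(background_sd))
  if (background_sd <= 0)
    stop("compute_snr: background sd must be positive (undefined SNR)")
  structure(list(signal_mean = x, background_mean = background_mean,
                 background_sd = background_sd,
                 snr = (x - background_mean) / background_sd),
            class = "snr_stats")
}

# Robust per-trace noise sd from first differences (steps contribute only
# at the few change points, which MAD ignores).
trace_noise_sd <- function(y) stats::mad(diff(y)) / sqrt(2)

# Penalized binary segmentation of a piecewise-constant signal.
# Returns 0-based indices k such that a new segment starts at frame k.
binseg_changepoints <- function(y, penalty, min_seg) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  seg_rss <- function(l, r) {   # frames l..r, 1-based inclusive
    s <- cs[r + 1] - cs[l]
    q <- cs2[r + 1] - cs2[l]
    q - s^2 / (r - l + 1)
  }
  cps <- integer(0)
  queue <- list(c(1L, n))
  while (length(queue)) {
    seg <- queue[[1]]; queue <- queue[-1]
    l <- seg[1]; r <- seg[2]
    if (r - l + 1 < 2 * min_seg) next
    ks <- (l + min_seg - 1):(r - min_seg)   # last frame of the left part
    if (!length(ks)) next
    left <- cs[ks + 1] - cs[l]
    leftq <- cs2[ks + 1] - cs2[l]
    nl <- ks - l + 1
    right <- cs[r + 1] - cs[ks + 1]
    rightq <- cs2[r + 1] - cs2[ks + 1]
    nr <- r - ks
    rss_split <- (leftq - left^2 / nl) + (rightq - right^2 / nr)
    k <- ks[which.min(rss_split)]
    gain <- seg_rss(l, r) - min(rss_split)
    if (gain > penalty) {
      cps <- c(cps, k)
      queue <- c(queue, list(c(l, k)), list(c(k + 1L, r)))
    }
  }
  sort(cps)
}

#' Detect photodropping steps in an intensity trace
#'
#' Fits a piecewise-constant signal by binary segmentation: the change point
#' minimizing the residual sum of squares is accepted whenever the RSS
#' reduction exceeds a Bayesian-information-style penalty
#' (`penalty_scale * log(n) * sigma^2`, with `sigma` the MAD-based noise
#' estimate), and the two sides are split recursively. Accepted steps are
#' downward level changes with magnitude inside `mag_window * unit` whose
#' flanking segments last at least `min_dwell` frames; when two accepted
#' change points fall within `min_dwell` frames of each other only the
#' larger-magnitude one is kept. Traces are classified by the number of
#' accepted steps: 0 (`no_drop`), 1 (`one_step`, dwell `T1` from acquisition
#' start to the drop), 2 (`two_step`, dwell `T2` between the drops), and
#' more than 2 (`rejected`).
#'
#' @param trace a `nisp_trace` (or any list with `times` and `intensities`).
#' @param unit single-fluorophore unit intensity (a.u.).
#' @param penalty_scale multiplier of the `log(n) * sigma^2` penalty.
#' @param min_dwell minimum segment length (frames).
#' @param mag_window accepted step magnitude as a fraction pair of `unit`.
#' @return An object of class `step_call`: `step_times` (s, time of the first
#'   frame of the new level), `step_magnitudes` (signed, a.u.), `scenario`,
#'   `T1`, `T2`.
#' @export
detect_steps <- function(trace, unit, penalty_scale = 10, min_dwell = 3,
                         mag_window = c(0.5, 1.5)) {
  y <- trace$intensities
  n <- length(y)
  if (n < 2 * min_dwell)
    stop("detect_steps: trace shorter than 2 * min_dwell frames")
  dt <- if (n > 1) trace$times[2] - trace$times[1] else 0.1
  sigma <- trace_noise_sd(y)
  penalty <- penalty_scale * log(n) * sigma^2
  cps <- binseg_changepoints(y, penalty, min_seg = min_dwell)
  bounds <- c(0L, cps, n)
  means <- vapply(seq_len(length(bounds) - 1), function(i)
    mean(y[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
  mags <- diff(means)
  ok <- mags < 0 & abs(mags) >= mag_window[1] * unit &
    abs(mags) <= mag_window[2] * unit
  acc_idx <- cps[ok]
  acc_mag <- mags[ok]
  if (length(acc_idx) > 1) {        # tie-break close pairs: keep larger step
    keep <- rep(TRUE, length(acc_idx))
    for (i in seq_len(length(acc_idx) - 1)) {
      if (!keep[i]) next
      j <- i + 1
      if (acc_idx[j] - acc_idx[i] < min_dwell) {
        if (abs(acc_mag[j]) > abs(acc_mag[i])) keep[i] <- FALSE
        else keep[j] <- FALSE
      }
    }
    acc_idx <- acc_idx[keep]; acc_mag <- acc_mag[keep]
  }
  k <- length(acc_idx)
  scenario <- if (k == 0) "no_drop" else if (k == 1) "one_step"
              else if (k == 2) "two_step" else "rejected"
  st <- acc_idx * dt                # 0-based frame index times frame interval
  structure(list(step_times = st, step_magnitudes = acc_mag,
                 scenario = scenario,
                 T1 = if (k == 1) st[1] else NA_real_,
                 T2 = if (k == 2) st[2] - st[1] else NA_real_,
                 meta = trace$meta),
            class = "step_call")
}

#' @export
print.step_call <- function(x, ...) {
  cat(sprintf("<step_call> %s; steps at %s s\n", x$scenario,
              paste(round(x$step_times, 2), collapse = ", ")))
  invisible(x)
}

#' Estimate the single-fluorophore unit intensity from a trace collection
#'
#' Robust location (median) of candidate downward step magnitudes found by
#' unconstrained binary segmentation. Falls back to `config_unit` when fewer
#' than `min_candidates` candidate steps are found.
#'
#' @param traces list of traces.
#' @param config_unit fallback unit (a.u.) when too few candidates exist.
#' @param penalty_scale,min_dwell segmentation parameters (see
#'   [detect_steps()]).
#' @param min_candidates minimum number of candidate steps.
#' @return unit intensity (a.u.).
#' @export
estimate_unit_intensity <- function(traces, config_unit = NULL,
                                    penalty_scale = 10, min_dwell = 3,
                                    min_candidates = 20) {
  drops <- numeric(0)
  for (tr in traces) {
    y <- tr$intensities
    if (length(y) < 2 * min_dwell) next
    sigma <- trace_noise_sd(y)
    cps <- binseg_changepoints(y, penalty_scale * log(length(y)) * sigma^2,
                               min_seg = min_dwell)
    if (!length(cps)) next
    bounds <- c(0L, cps, length(y))
    means <- vapply(seq_len(length(bounds) - 1), function(i)
      mean(y[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
    d <- diff(means)
    drops <- c(drops, -d[d < 0])
  }
  if (length(drops) >= min_candidates) return(stats::median(drops))
  if (!is.null(config_unit)) return(config_unit)
  stop("estimate_unit_intensity: too few step candidates and no fallback unit")
}

#' Select traces whose initial intensity matches two active fluorophores
#'
#' Keeps traces whose mean intensity over the first 5 frames lies within
#' `[2 * (1 - rel_tol), 2 * (1 + rel_tol)] * unit`, the two-fluorophore
#' selection criterion applied before any kinetic analysis.
#'
#' @param traces list of traces.
#' @param unit single-fluorophore unit intensity (a.u.).
#' @param rel_tol relative tolerance (default 0.25).
#' @return the selected subset of `traces`.
#' @export
select_traces <- function(traces, unit, rel_tol = 0.25) {
  stopifnot(unit > 0)
  keep <- vapply(traces, function(tr) {
    init <- mean(tr$intensities[seq_len(min(5, length(tr$intensities)))])
    init >= 2 * (1 - rel_tol) * unit && init <= 2 * (1 + rel_tol) * unit
  }, logical(1))
  traces[keep]
}

#' Tabulate step calls into a per-condition event table and dwell pool
#'
#' Counts zero-, one- and two-step traces per condition (rejected traces are
#' tabulated but excluded from scenario denominators downstream) and pools
#' the `T1` and `T2` dwell samples.
#'
#' @param calls list of `step_call` objects; each must carry
#'   `meta$condition` (a character label) unless `condition` is given.
#' @param condition optional single condition label applied to all calls.
#' @return list of class `event_table`: `events` (data.frame with columns
#'   condition, n_total, n_no_drop, n_one_step, n_two_step, n_rejected) and
#'   `dwells` (data.frame with columns condition, trace_id, dwell_type,
#'   dwell_s).
#' @export
classify_and_extract <- function(calls, condition = NULL) {
  conds <- vapply(seq_along(calls), function(i) {
    if (!is.null(condition)) condition
    else if (!is.null(calls[[i]]$meta$condition)) calls[[i]]$meta$condition
    else stop("classify_and_extract: calls must carry a condition label")
  }, character(1))
  scen <- vapply(calls, function(cl) cl$scenario, character(1))
  ev <- do.call(rbind, lapply(unique(conds), function(cd) {
    s <- scen[conds == cd]
    data.frame(condition = cd, n_total = length(s),
               n_no_drop = sum(s == "no_drop"),
               n_one_step = sum(s == "one_step"),
               n_two_step = sum(s == "two_step"),
               n_rejected = sum(s == "rejected"),
               stringsAsFactors = FALSE)
  }))
  dw <- do.call(rbind, lapply(seq_along(calls), function(i) {
    cl <- calls[[i]]
    if (cl$scenario == "one_step")
      data.frame(condition = conds[i], trace_id = i, dwell_type = "T1",
                 dwell_s = cl$T1, stringsAsFactors = FALSE)
    else if (cl$scenario == "two_step")
      data.frame(condition = conds[i], trace_id = i, dwell_type = "T2",
                 dwell_s = cl$T2, stringsAsFactors = FALSE)
    else NULL
  }))
  if (is.null(dw))
    dw <- data.frame(condition = character(), trace_id = integer(),
                     dwell_type = character(), dwell_s = numeric())
  structure(list(events = ev, dwells = dw), class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  print(x$events)
  invisible(x)
}
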