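#' Build a uniform dwell-time histogram
#'
#' @param samples dwell times (s).
#' @param bin_width bin width (s).
#' @param t_max optional upper edge; defaults to the sample maximum rounded
#'   up to a whole bin.
#' @return list of class `dwell_histogram`: `bin_edges`, `mids`, `counts`,
#'   `n_events`, `bin_width`.
#' @export
dwell_histogram <- function(samples, bin_width, t_max = NULL) {
  stopifnot(length(samples) > 0, bin_width > 0)
  if (is.null(t_max)) t_max <- max(samples)
  edges <- seq(0, bin_width * ceiling(t_max / bin_width + 1e-9), by = bin_width)
  if (length(edges) < 2) edges <- c(0, bin_width)
  h <- graphics::hist(samples[samples <= max(edges)], breaks = edges,
                      plot = FALSE)
  structure(list(bin_edges = edges, mids = h$mids, counts = h$counts,
                 n_events = sum(h$counts), bin_width = bin_width),
            class = "dwell_histogram")
}

#' @export
print.dwell_histogram <- function(x, ...) {
  cat(sprintf("<dwell_histogram> %d events, %d bins of %.3g s\n",
              x$n_events, length(x$counts), x$bin_width))
  invisible(x)
}

# Least-squares fit of a single Gaussian to histogram counts.
fit_plain_gaussian <- function(hist, mu0 = NULL, sigma0 = NULL) {
  d <- data.frame(t = hist$mids, y = hist$counts)
  rng <- range(d$t)
  if (is.null(mu0)) mu0 <- d$t[which.max(d$y)]
  if (is.null(sigma0)) {
    w <- pmax(d$y, 0)
    sigma0 <- sqrt(stats::weighted.mean((d$t - stats::weighted.mean(d$t, w))^2, w))
    sigma0 <- max(sigma0, hist$bin_width)
  }
  fit <- try(minpack.lm::nlsLM(
    y ~ A * exp(-(t - mu)^2 / (2 * s^2)), data = d,
    start = list(A = max(d$y), mu = mu0, s = sigma0),
    lower = c(0, rng[1], hist$bin_width / 2),
    upper = c(Inf, rng[2], diff(rng) / 2 + hist$bin_width),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  cf <- stats::coef(fit)
  list(amplitude = cf[["A"]], mu = cf[["mu"]], sigma = cf[["s"]],
       rss = sum(stats::resid(fit)^2))
}

#' Select a histogram bin width by fitted-mean stability
#'
#' Fits a plain Gaussian to the dwell histogram at each candidate width
#' (ascending) and returns the smallest width whose fitted mean differs from
#' the next wider width's by less than `stability_tol`. Falls back to the
#' Freedman-Diaconis width when no candidate stabilizes.
#'
#' @param samples dwell times (s), at least 30.
#' @param candidate_widths at least 3 candidate widths (s).
#' @param stability_tol stability tolerance on the fitted mean (s).
#' @return selected bin width (s).
#' @export
select_bin_width <- function(samples, candidate_widths = c(0.2, 0.3, 0.5,
                                                           0.75, 1, 1.5, 2),
                             stability_tol = 0.2) {
  if (length(samples) < 30)
    stop("select_bin_width: need at least 30 dwell samples")
  stopifnot(length(candidate_widths) >= 3)
  ws <- sort(candidate_widths)
  if (stats::sd(samples) == 0) return(ws[1])
  mus <- vapply(ws, function(w) {
    f <- fit_plain_gaussian(dwell_histogram(samples, w))
    if (is.null(f)) NA_real_ else f$mu
  }, numeric(1))
  for (i in seq_len(length(ws) - 1)) {
    if (!is.na(mus[i]) && !is.na(mus[i + 1]) &&
        abs(mus[i] - mus[i + 1]) < stability_tol)
      return(ws[i])
  }
  # Freedman-Diaconis fallback
  fd <- 2 * stats::IQR(samples) / length(samples)^(1 / 3)
  if (fd <= 0) fd <- ws[1]
  fd
}

#' Fit the spontaneous-photobleaching background of a dwell histogram
#'
#' Least-squares quartic polynomial in the bin centers of a no-enzyme
#' control dwell histogram. Predicted counts are clipped at zero.
#'
#' @param hist a [dwell_histogram()] with at least 6 nonempty bins.
#' @return object of class `background_fit`: coefficients `a0..a4`, `rss`
#'   and the fitted range.
#' @export
fit_background <- function(hist) {
  if (sum(hist$counts > 0) < 6)
    stop("fit_background: need at least 6 nonempty bins")
  d <- data.frame(t = hist$mids, y = hist$counts)
  m <- stats::lm(y ~ stats::poly(t, 4, raw = TRUE), data = d)
  cf <- unname(stats::coef(m))
  structure(list(coeffs = cf, rss = sum(stats::resid(m)^2),
                 range = range(d$t), bin_width = hist$bin_width,
                 n_events = hist$n_events),
            class = "background_fit")
}

#' @export
#' @rdname fit_background
#' @param object a `background_fit`.
#' @param t times (s) at which to evaluate the fitted background.
#' @param ... unused.
predict.background_fit <- function(object, t, ...) {
  cf <- object$coeffs
  pmax(cf[1] + cf[2] * t + cf[3] * t^2 + cf[4] * t^3 + cf[5] * t^4, 0)
}

#' Fit a Gaussian degradation peak over a photobleaching background
#'
#' Nonlinear least squares of
#' `A * exp(-(t - mu)^2 / (2 * sigma^2)) + quartic(t)` on the bin counts of a
#' dwell histogram. In `"joint"` mode the quartic coefficients are refit,
#' initialized at the control background fit (scaled to this histogram's
#' event count); in `"fixed_shape"` mode the control quartic is only scaled
#' by a single factor. The Gaussian mean is initialized at the histogram mode
#' after background subtraction and bounded inside the histogram range;
#' `sigma` is bounded in `(bin_width/2, range/2)` and the amplitude is
#' nonnegative. The fitted mean `mu` is the background-corrected average
#' dwell.
#'
#' @param hist a [dwell_histogram()] with at least 8 nonempty bins.
#' @param control_background optional [fit_background()] result from a
#'   matched no-enzyme control; `NULL` initializes the quartic at zero.
#' @param mode `"joint"` or `"fixed_shape"` (the latter requires a control).
#' @param restarts bounded number of jittered restarts on non-convergence.
#' @return object of class `gausspoly_fit`: `mu`, `sigma`, `amplitude`,
#'   `background` (coefficients), `rss`, `mode`.
#' @export
fit_gaussian_plus_background <- function(hist, control_background = NULL,
                                         mode = c("joint", "fixed_shape"),
                                         restarts = 5) {
  mode <- match.arg(mode)
  if (sum(hist$counts > 0) < 8)
    stop("fit_gaussian_plus_background: need at least 8 nonempty bins")
  if (mode == "fixed_shape" && is.null(control_background))
    stop("fit_gaussian_plus_background: fixed_shape mode needs a control background")
  d <- data.frame(t = hist$mids, y = hist$counts)
  rng <- range(d$t)
  bg0 <- if (is.null(control_background)) rep(0, 5) else {
    # rescale control counts-per-bin to this histogram's mass and bin width
    sc <- (hist$n_events / max(control_background$n_events, 1)) *
      (hist$bin_width / control_background$bin_width)
    control_background$coeffs * sc
  }
  resid0 <- pmax(d$y - predict.background_fit(
    structure(list(coeffs = bg0), class = "background_fit"), d$t), 0)
  mu0 <- d$t[which.max(resid0)]
  A0 <- max(resid0)
  if (A0 <= 0) A0 <- max(d$y)
  # seed the peak from a plain Gaussian fit so the background term cannot
  # absorb it; the peak width also caps the sigma search box
  plain <- fit_plain_gaussian(hist, mu0 = mu0)
  s0 <- if (!is.null(plain)) plain$sigma else
    max(hist$bin_width, sqrt(stats::weighted.mean(
      (d$t - stats::weighted.mean(d$t, resid0 + 1e-9))^2, resid0 + 1e-9)) / 2)
  s_max <- min(diff(rng) / 2 + hist$bin_width,
               max(4 * s0, 5 * hist$bin_width))
  one_fit <- function(mu_init, s_init) {
    if (mode == "joint") {
      st <- list(A = A0, mu = mu_init, s = s_init,
                 a0 = bg0[1], a1 = bg0[2], a2 = bg0[3], a3 = bg0[4],
                 a4 = bg0[5])
      try(minpack.lm::nlsLM(
        y ~ A * exp(-(t - mu)^2 / (2 * s^2)) +
          a0 + a1 * t + a2 * t^2 + a3 * t^3 + a4 * t^4,
        data = d, start = st,
        lower = c(0, rng[1], hist$bin_width / 2, rep(-Inf, 5)),
        upper = c(Inf, rng[2], s_max, rep(Inf, 5)),
        control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    } else {
      cfb <- bg0
      try(minpack.lm::nlsLM(
        y ~ A * exp(-(t - mu)^2 / (2 * s^2)) +
          f * (cfb[1] + cfb[2] * t + cfb[3] * t^2 + cfb[4] * t^3 +
                 cfb[5] * t^4),
        data = d, start = list(A = A0, mu = mu_init, s = s_init, f = 1),
        lower = c(0, rng[1], hist$bin_width / 2, 0),
        upper = c(Inf, rng[2], s_max, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    }
  }
  starts <- list(c(mu0, s0))
  if (!is.null(plain)) starts <- c(starts, list(c(plain$mu, plain$sigma)))
  for (k in seq_len(restarts))
    starts <- c(starts, list(c(mu0 * stats::runif(1, 0.7, 1.3),
                               s0 * stats::runif(1, 0.5, 2))))
  fit <- NULL
  best_rss <- Inf
  for (st in starts) {
    f <- one_fit(st[1], min(max(st[2], hist$bin_width / 2 * 1.01),
                            s_max * 0.99))
    if (!inherits(f, "try-error")) {
      rss <- sum(stats::resid(f)^2)
      if (rss < best_rss) { best_rss <- rss; fit <- f }
    }
  }
  if (is.null(fit))
    stop("fit_gaussian_plus_background: fit did not converge after restarts")
  cf <- stats::coef(fit)
  bg <- if (mode == "joint") unname(cf[c("a0", "a1", "a2", "a3", "a4")])
        else bg0 * cf[["f"]]
  structure(list(mu = cf[["mu"]], sigma = cf[["s"]], amplitude = cf[["A"]],
                 background = bg, rss = sum(stats::resid(fit)^2),
                 mode = mode, n_events = hist$n_events),
            class = "gausspoly_fit")
}

#' @export
print.gausspoly_fit <- function(x, ...) {
  cat(sprintf("<gausspoly_fit> mu = %.2f s, sigma = %.2f s (%s background)\n",
              x$mu, x$sigma, x$mode))
  invisible(x)
}

#' Occurrence table of photodropping scenarios with control subtraction
#'
#' Converts per-condition event counts into scenario probabilities (percent,
#' one decimal; rejected traces excluded from the denominator) and, for each
#' enzyme condition, the change in the one- and two-step populations relative
#' to the matched no-enzyme control. Deltas are computed on the one-decimal
#' rounded percentages, matching how such tables are usually reported.
#'
#' @param event_table an [classify_and_extract()] result or its `events`
#'   data.frame.
#' @param control_condition label of the no-enzyme control condition.
#' @return data.frame of class `occurrence_table` with probabilities and
#'   delta columns (`delta_*` is `NA` for the control row).
#' @export
build_occurrence_table <- function(event_table, control_condition) {
  ev <- if (inherits(event_table, "event_table")) event_table$events
        else event_table
  if (!control_condition %in% ev$condition)
    stop("build_occurrence_table: control condition '", control_condition,
         "' not present")
  denom <- ev$n_total - ev$n_rejected
  p <- data.frame(condition = ev$condition,
                  n_used = denom,
                  p_no_drop = round(100 * ev$n_no_drop / denom, 1),
                  p_one_step = round(100 * ev$n_one_step / denom, 1),
                  p_two_step = round(100 * ev$n_two_step / denom, 1),
                  stringsAsFactors = FALSE)
  ctrl <- p[p$condition == control_condition, ]
  p$delta_one_step <- round(p$p_one_step - ctrl$p_one_step, 1)
  p$delta_two_step <- round(p$p_two_step - ctrl$p_two_step, 1)
  p$delta_one_step[p$condition == control_condition] <- 0
  p$delta_two_step[p$condition == control_condition] <- 0
  class(p) <- c("occurrence_table", "data.frame")
  p
}

#' Decompose mean dwell versus fluorophore spacing into a degradation rate
#'
#' Ordinary least squares of the background-corrected mean two-step dwell on
#' the inter-fluorophore spacing `S`. The slope is the mean time to cleave
#' one native scissile bond (s/nt), the intercept the extra time for the
#' fluorophore-conjugated bond (s), and the degradation rate is the inverse
#' slope (nt/s) with its standard error by the delta method.
#'
#' @param points data.frame with columns `S` (nt), `t2_av` (s) and
#'   optionally `se` (s); at least 3 distinct `S` values.
#' @param weighted if `TRUE`, weight by `1/se^2`.
#' @return object of class `kinetic_decomposition`: `slope`, `intercept`,
#'   `rate`, their standard errors, and `r_squared`.
#' @export
#' @examples
#' decompose_linear(data.frame(S = c(8, 13, 18, 28),
#'                             t2_av = c(1.7, 2.5, 3.2, 5.0)))
decompose_linear <- function(points, weighted = FALSE) {
  stopifnot(is.data.frame(points), all(c("S", "t2_av") %in% names(points)))
  if (length(unique(points$S)) < 3)
    stop("decompose_linear: need at least 3 distinct S values")
  if (stats::var(points$S) == 0)
    stop("decompose_linear: zero variance in S")
  w <- if (weighted && "se" %in% names(points)) 1 / points$se^2 else NULL
  m <- stats::lm(t2_av ~ S, data = points, weights = w)
  sm <- suppressWarnings(summary(m))   # exact lines trip the perfect-fit warning
  slope <- unname(stats::coef(m)[2])
  intercept <- unname(stats::coef(m)[1])
  if (slope <= 0)
    stop("decompose_linear: nonpositive slope; dwell must grow with spacing")
  se_slope <- sm$coefficients[2, 2]
  se_intercept <- sm$coefficients[1, 2]
  structure(list(slope = slope, intercept = intercept,
                 rate = 1 / slope,
                 se_slope = se_slope, se_intercept = se_intercept,
                 se_rate = se_slope / slope^2,
                 r_squared = sm$r.squared, n = nrow(points),
                 weighted = weighted),
            class = "kinetic_decomposition")
}

#' @export
print.kinetic_decomposition <- function(x, ...) {
  cat(sprintf(
    "<kinetic_decomposition> slope %.2f +- %.2f s/nt, intercept %.2f +- %.2f s\n",
    x$slope, x$se_slope, x$intercept, x$se_intercept))
  cat(sprintf("  degradation rate %.1f +- %.1f nt/s (R^2 = %.2f, n = %d)\n",
              x$rate, x$se_rate, x$r_squared, x$n))
  invisible(x)
}

#' Classify an enzyme as processive or distributive
#'
#' A processive nuclease completes the inter-fluorophore traversal in a
#' single binding event, so the background-corrected dwell `T2` does not
#' depend on enzyme concentration; a distributive nuclease rebinds between
#' cuts and its `T2` shortens as concentration rises. The dwell means are
#' regressed on log-concentration: the call is `"distributive"` when the
#' slope is negative and exceeds twice its standard error in magnitude,
#' otherwise `"processive"`.
#'
#' @param t2_by_concentration data.frame with columns `c` (nM) and `t2_av`
#'   (s), at least 3 concentrations.
#' @param occurrence_deltas optional occurrence-table deltas reported back
#'   as auxiliary evidence.
#' @return list of class `processivity_call`: `classification`, `slope`,
#'   `se_slope`, `t_stat`.
#' @export
#' @examples
#' classify_processivity(data.frame(c = c(1, 5, 10), t2_av = c(3.2, 3.3, 3.2)))
classify_processivity <- function(t2_by_concentration,
                                  occurrence_deltas = NULL) {
  stopifnot(is.data.frame(t2_by_concentration),
            all(c("c", "t2_av") %in% names(t2_by_concentration)))
  if (nrow(t2_by_concentration) < 3)
    stop("classify_processivity: need at least 3 concentrations")
  m <- stats::lm(t2_av ~ log(c), data = t2_by_concentration)
  sm <- suppressWarnings(summary(m))
  slope <- unname(stats::coef(m)[2])
  se <- sm$coefficients[2, 2]
  cls <- if (slope < 0 && abs(slope) > 2 * se) "distributive" else "processive"
  structure(list(classification = cls, slope = slope, se_slope = se,
                 t_stat = slope / se, occurrence_deltas = occurrence_deltas),
            class = "processivity_call")
}

#' @export
print.processivity_call <- function(x, ...) {
  cat(sprintf("<processivity_call> %s (slope %.3g +- %.3g s per log nM)\n",
              x$classification, x$slope, x$se_slope))
  invisible(x)
}

#' Fold difference between two population-change deltas
#'
#' Ratio of two occurrence deltas (percentage points), the simple measure of
#' relative degradation efficiency between two conditions, reported to one
#' decimal.
#'
#' @param delta_a numerator delta (percentage points).
#' @param delta_b denominator delta (percentage points), must be positive.
#' @return fold change, rounded to one decimal.
#' @export
#' @examples
#' efficiency_ratio(23.2, 12.5)  # 1.9
efficiency_ratio <- function(delta_a, delta_b) {
  if (!is.numeric(delta_b) || delta_b <= 0)
    stop("efficiency_ratio: denominator delta must be positive")
  round(delta_a / delta_b, 1)
}
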