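#' @keywords internal
new_trace <- function(times, intensities, truth, meta) {
  stopifnot(length(times) == length(intensities))
  structure(list(times = times, intensities = intensities,
                 truth = truth, meta = meta), class = "nisp_trace")
}

#' @export
print.nisp_trace <- function(x, ...) {
  nd <- if (is.null(x$truth)) NA_integer_ else sum(!x$truth$censored)
  cat(sprintf("<nisp_trace> %d frames, %d rendered truth events\n",
              length(x$times), nd))
  invisible(x)
}

# Render a two-fluorophore intensity trace from the two removal times.
# Frame k (0-based) covers [k, k+1) * dt and is reported at its midpoint;
# a removal at time t darkens every frame whose midpoint is >= t.
render_two_fluor <- function(drop_times, photo) {
  dt <- photo$frame_interval
  n <- photo$n_frames
  mid <- (seq_len(n) - 0.5) * dt
  level <- rep(2, n)
  if (length(drop_times))
    level <- level - rowSums(outer(mid, drop_times, ">="))
  y <- level * photo$unit_intensity
  if (photo$noise_sd > 0) y <- y + stats::rnorm(n, 0, photo$noise_sd)
  list(times = mid, intensities = y)
}

# Truth log for the two fluorophores: per-fluorophore removal time and cause.
truth_log <- function(times, causes, window) {
  data.frame(fluor = seq_along(times), time = times, cause = causes,
             censored = times > window, stringsAsFactors = FALSE)
}

# Exponential sum helpers tolerating zero means (degenerate at 0).
rexp_mean <- function(n, mean) {
  if (n == 0L || mean == 0) return(0)
  sum(stats::rexp(n, rate = 1 / mean))
}
rerlang_mean <- function(mean, shape) {
  if (mean == 0) return(0)
  stats::rgamma(1, shape = shape, scale = mean / shape)
}

#' Simulate one trace of processive exonucleolytic photodropping
#'
#' The enzyme binds after an exponential waiting time (rate
#' `k_bind_per_nM * concentration`; zero when `prebound`), traverses the `n0`
#' nucleotides before the first label (independent exponential bond times of
#' mean `tau_nt`), removes the first fluorophore (extra Erlang time of mean
#' `tau_fluor`), then traverses the `S` inter-label nucleotides and removes
#' the second fluorophore. Each fluorophore independently photobleaches at
#' rate `k_bleach`; whichever of cleavage or bleaching comes first darkens
#' that fluorophore. Events after the acquisition window are censored (not
#' rendered) but kept in the truth log.
#'
#' @param substrate a [substrate_spec()] (not a blunt duplex).
#' @param enzyme an [enzyme_kinetics()] with `mode = "processive"` or
#'   `"inactive"` (inactive produces bleaching-only traces).
#' @param photo a [photophysics()].
#' @param seed integer seed for this trace.
#' @return A `nisp_trace`: `times` (frame midpoints, s), `intensities`
#'   (a.u.), `truth` (per-fluorophore event time, cause, censoring flag) and
#'   `meta`.
#' @export
simulate_processive_trace <- function(substrate, enzyme, photo, seed) {
  stopifnot(inherits(substrate, "substrate_spec"),
            inherits(enzyme, "enzyme_kinetics"),
            inherits(photo, "photophysics"))
  if (enzyme$mode == "distributive")
    stop("simulate_processive_trace: enzyme mode must be processive or inactive")
  if (enzyme$mode == "processive" && substrate$overhang_end == "blunt_duplex")
    stop("simulate_processive_trace: processive digestion needs a free overhang end")
  set.seed(seed)
  if (enzyme$mode == "inactive") {
    cleave <- c(Inf, Inf)
  } else {
    bind_rate <- enzyme$k_bind_per_nM * enzyme$concentration
    t_b <- if (enzyme$prebound) 0
           else if (bind_rate > 0) stats::rexp(1, bind_rate) else Inf
    t1 <- t_b + rexp_mean(substrate$n0, enzyme$tau_nt) +
      rerlang_mean(enzyme$tau_fluor, enzyme$fluor_shape)
    t2 <- t1 + rexp_mean(substrate$S, enzyme$tau_nt) +
      rerlang_mean(enzyme$tau_fluor, enzyme$fluor_shape)
    cleave <- c(t1, t2)
  }
  bleach <- if (photo$k_bleach > 0) stats::rexp(2, photo$k_bleach) else c(Inf, Inf)
  drop <- pmin(cleave, bleach)
  cause <- ifelse(cleave <= bleach, "cleave", "bleach")
  cause[!is.finite(drop)] <- NA_character_
  r <- render_two_fluor(drop[is.finite(drop) & drop <= photo$window], photo)
  new_trace(r$times, r$intensities,
            truth_log(drop, cause, photo$window),
            list(substrate = substrate, enzyme = enzyme, photo = photo,
                 seed = seed))
}

#' Simulate one trace of distributive endonucleolytic photodropping
#'
#' Each of the two labeled sites is cleaved after an independent exponential
#' time with rate `k_site(concentration)`; by memorylessness the inter-drop
#' interval is itself exponential with that rate, so its mean decreases with
#' enzyme concentration -- the signature that distinguishes a distributive
#' nuclease from a processive one. Bleaching, rendering and censoring follow
#' [simulate_processive_trace()].
#'
#' @inheritParams simulate_processive_trace
#' @return A `nisp_trace`.
#' @export
simulate_distributive_trace <- function(substrate, enzyme, photo, seed) {
  stopifnot(inherits(enzyme, "enzyme_kinetics"))
  if (enzyme$mode != "distributive")
    stop("simulate_distributive_trace: enzyme mode must be distributive")
  set.seed(seed)
  k <- site_cleavage_rate(enzyme)
  cleave <- if (k > 0) stats::rexp(2, k) else c(Inf, Inf)
  bleach <- if (photo$k_bleach > 0) stats::rexp(2, photo$k_bleach) else c(Inf, Inf)
  drop <- pmin(cleave, bleach)
  cause <- ifelse(cleave <= bleach, "cleave", "bleach")
  cause[!is.finite(drop)] <- NA_character_
  r <- render_two_fluor(drop[is.finite(drop) & drop <= photo$window], photo)
  new_trace(r$times, r$intensities, truth_log(drop, cause, photo$window),
            list(substrate = substrate, enzyme = enzyme, photo = photo,
                 seed = seed))
}

#' Simulate a no-enzyme (bleaching only) control trace
#'
#' By default both fluorophores bleach independently at rate `k_bleach`.
#' Alternatively, a three-component `scenario_mix` (probabilities of zero,
#' one and two photodrops inside the window) can be supplied; the scenario is
#' drawn from that mixture and bleach times are then sampled conditionally
#' (truncated exponentials inside/outside the window). The mixture mode
#' reproduces empirical control scenario splits that two independent
#' exponential bleaches cannot produce.
#'
#' @param photo a [photophysics()].
#' @param seed integer seed.
#' @param scenario_mix optional length-3 nonnegative vector, probabilities of
#'   0/1/2 drops; normalized internally.
#' @return A `nisp_trace` whose truth log marks every event as `"bleach"`.
#' @export
simulate_bleach_only_trace <- function(photo, seed, scenario_mix = NULL) {
  stopifnot(inherits(photo, "photophysics"))
  set.seed(seed)
  W <- photo$window
  if (is.null(scenario_mix)) {
    drop <- if (photo$k_bleach > 0) stats::rexp(2, photo$k_bleach) else c(Inf, Inf)
  } else {
    stopifnot(length(scenario_mix) == 3, all(scenario_mix >= 0),
              sum(scenario_mix) > 0)
    p <- scenario_mix / sum(scenario_mix)
    n_drop <- sample(0:2, 1, prob = p)
    kb <- if (photo$k_bleach > 0) photo$k_bleach else 1 / W
    # truncated exponential on (0, W): inverse cdf
    rtrunc_in <- function(m) -log(1 - stats::runif(m) * (1 - exp(-kb * W))) / kb
    rtrunc_out <- function(m) W + stats::rexp(m, kb)
    drop <- c(if (n_drop > 0) rtrunc_in(n_drop),
              if (n_drop < 2) rtrunc_out(2 - n_drop))
  }
  cause <- rep("bleach", 2)
  cause[!is.finite(drop)] <- NA_character_
  r <- render_two_fluor(drop[is.finite(drop) & drop <= W], photo)
  new_trace(r$times, r$intensities, truth_log(drop, cause, W),
            list(substrate = NULL,
                 enzyme = enzyme_kinetics("inactive"), photo = photo,
                 seed = seed, scenario_mix = scenario_mix))
}

#' @keywords internal
new_fret_trace <- function(times, donor, acceptor, truth, meta) {
  stopifnot(length(times) == length(donor), length(donor) == length(acceptor))
  structure(list(times = times, donor = donor, acceptor = acceptor,
                 truth = truth, meta = meta), class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("<fret_trace> %d frames, kind=%s\n", length(x$times),
              x$truth$kind))
  invisible(x)
}

#' Simulate a donor/acceptor FRET trace pair
#'
#' `kind = "static"` holds the true efficiency at `levels[1]` for the whole
#' window. `kind = "unwinding"` holds the low level until a random start time
#' (exponential, mean `t_start_mean`), ramps linearly to the high level over
#' a duration drawn from a Gamma distribution with mean `t_unwind_mean` and
#' shape `k_ramp`, then holds the high level. The duplex is unwound base pair
#' by base pair, so the ramp duration is modeled as a sum of many per-base
#' steps; the default shape 19 (one per base pair of the standard duplex)
#' gives the nearly symmetric unimodal dwell histograms the assay produces.
#' Donor and acceptor are rendered as `total * (1 - E)` and `total * E` plus
#' independent Gaussian noise.
#'
#' @param kind `"static"` or `"unwinding"`.
#' @param levels efficiency value(s) in `[0, 1]`: one value for static, or
#'   `c(low, high)` with `low < high` for unwinding.
#' @param t_unwind_mean mean ramp duration (s), unwinding kind only.
#' @param photo a [photophysics()]; `unit_intensity` is the per-channel unit
#'   and the pair's total intensity is `2 * unit_intensity`.
#' @param seed integer seed.
#' @param k_ramp Gamma shape of the ramp duration.
#' @param t_start_mean mean of the exponential ramp start time (s).
#' @return A `fret_trace` with a truth log (`kind`, levels, `t_start`,
#'   `ramp_duration`).
#' @export
simulate_fret_trace <- function(kind = c("static", "unwinding"), levels,
                                t_unwind_mean = NULL, photo, seed,
                                k_ramp = 19, t_start_mean = 20) {
  kind <- match.arg(kind)
  stopifnot(inherits(photo, "photophysics"), all(levels >= 0), all(levels <= 1))
  if (kind == "unwinding") {
    stopifnot(length(levels) == 2, levels[1] < levels[2],
              is.numeric(t_unwind_mean), t_unwind_mean > 0)
  }
  set.seed(seed)
  dt <- photo$frame_interval
  mid <- (seq_len(photo$n_frames) - 0.5) * dt
  total <- 2 * photo$unit_intensity
  if (kind == "static") {
    E <- rep(levels[1], length(mid))
    truth <- list(kind = kind, levels = levels[1], t_start = NA_real_,
                  ramp_duration = NA_real_)
  } else {
    t_start <- stats::rexp(1, 1 / t_start_mean)
    ramp <- stats::rgamma(1, shape = k_ramp, scale = t_unwind_mean / k_ramp)
    E <- ifelse(mid < t_start, levels[1],
                ifelse(mid < t_start + ramp,
                       levels[1] + (levels[2] - levels[1]) *
                         (mid - t_start) / ramp,
                       levels[2]))
    truth <- list(kind = kind, levels = levels, t_start = t_start,
                  ramp_duration = ramp)
  }
  donor <- total * (1 - E)
  acceptor <- total * E
  if (photo$noise_sd > 0) {
    donor <- donor + stats::rnorm(length(mid), 0, photo$noise_sd)
    acceptor <- acceptor + stats::rnorm(length(mid), 0, photo$noise_sd)
  }
  new_fret_trace(mid, donor, acceptor, truth,
                 list(photo = photo, seed = seed, k_ramp = k_ramp,
                      t_start_mean = t_start_mean))
}
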