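#' Generate a benchmark set of traces with known ground truth
#'
#' Batch wrapper around the single-trace simulators. The configuration lists
#' experimental conditions (enzyme model, substrate, concentration, number of
#' traces); the generator derives one deterministic seed stream per trace
#' from the master seed, so a fixed seed reproduces the set exactly.
#'
#' @param config list with element `conditions`, itself a list of condition
#'   descriptions. Each condition is a list with elements:
#'   \describe{
#'     \item{name}{unique condition label.}
#'     \item{kind}{one of `"processive"`, `"distributive"`, `"bleach_only"`,
#'       `"fret_static"`, `"fret_unwinding"`.}
#'     \item{n_traces}{number of traces to simulate.}
#'     \item{substrate}{arguments for [substrate_spec()] (trace kinds).}
#'     \item{enzyme}{arguments for [enzyme_kinetics()] (enzyme kinds).}
#'     \item{photo}{optional overrides for [photophysics()].}
#'     \item{scenario_mix}{optional 3-vector for `"bleach_only"`.}
#'     \item{fret}{list with `levels`, and for unwinding `t_unwind_mean`,
#'       optionally `k_ramp`, `t_start_mean`.}
#'   }
#' @param seed master integer seed.
#' @return list of class `benchmark_set`: `traces` (named list of trace
#'   lists, one per condition) and `manifest` (one data.frame row per
#'   condition with the ground-truth parameters).
#' @export
generate_benchmark_set <- function(config, seed) {
  conds <- config$conditions
  if (is.null(conds)) conds <- list()
  traces <- list()
  rows <- list()
  for (ci in seq_along(conds)) {
    cd <- conds[[ci]]
    if (is.null(cd$name)) stop("generate_benchmark_set: condition needs a name")
    kind <- cd$kind
    if (is.null(kind) ||
        !kind %in% c("processive", "distributive", "bleach_only",
                     "fret_static", "fret_unwinding"))
      stop("generate_benchmark_set: unknown condition kind '", kind, "'")
    photo <- do.call(photophysics, if (is.null(cd$photo)) list() else cd$photo)
    n <- if (is.null(cd$n_traces)) 0L else cd$n_traces
    base <- derive_seed(seed, ci * 1000003)
    tl <- vector("list", n)
    sub <- NULL; enz <- NULL
    if (kind %in% c("processive", "distributive")) {
      sub <- do.call(substrate_spec, cd$substrate)
      enz <- do.call(enzyme_kinetics, cd$enzyme)
    }
    for (i in seq_len(n)) {
      s_i <- derive_seed(base, i)
      tl[[i]] <- switch(kind,
        processive = simulate_processive_trace(sub, enz, photo, s_i),
        distributive = simulate_distributive_trace(sub, enz, photo, s_i),
        bleach_only = simulate_bleach_only_trace(photo, s_i,
                                                 scenario_mix = cd$scenario_mix),
        fret_static = simulate_fret_trace("static", cd$fret$levels,
                                          photo = photo, seed = s_i),
        fret_unwinding = simulate_fret_trace(
          "unwinding", cd$fret$levels, t_unwind_mean = cd$fret$t_unwind_mean,
          photo = photo, seed = s_i,
          k_ramp = if (is.null(cd$fret$k_ramp)) 19 else cd$fret$k_ramp,
          t_start_mean = if (is.null(cd$fret$t_start_mean)) 20
                         else cd$fret$t_start_mean))
      tl[[i]]$meta$condition <- cd$name
    }
    traces[[cd$name]] <- tl
    rows[[ci]] <- data.frame(
      condition = cd$name, kind = kind, n_traces = n,
      S = if (!is.null(sub)) sub$S else NA_integer_,
      label_type = if (!is.null(sub)) sub$label_type else NA_character_,
      overhang_end = if (!is.null(sub)) sub$overhang_end else NA_character_,
      enzyme_mode = if (!is.null(enz)) enz$mode else NA_character_,
      concentration_nM = if (!is.null(enz)) enz$concentration else NA_real_,
      tau_nt = if (!is.null(enz) && !is.null(enz$tau_nt)) enz$tau_nt
               else NA_real_,
      tau_fluor = if (!is.null(enz) && !is.null(enz$tau_fluor)) enz$tau_fluor
                  else NA_real_,
      k_site = if (!is.null(enz) && enz$mode == "distributive")
                 site_cleavage_rate(enz) else NA_real_,
      k_bleach = photo$k_bleach, unit_intensity = photo$unit_intensity,
      noise_sd = photo$noise_sd, seed = base,
      stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(), kind = character(),
               n_traces = integer())
  structure(list(traces = traces, manifest = manifest),
            class = "benchmark_set")
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat(sprintf("<benchmark_set> %d conditions, %d traces\n",
              nrow(x$manifest), sum(x$manifest$n_traces)))
  invisible(x)
}

#' Condition grid of a processive-exonuclease titration benchmark
#'
#' Convenience builder for the standard benchmark layout: every combination
#' of inter-fluorophore spacing and enzyme concentration, plus a no-enzyme
#' control -- 13 conditions for the default spacings `c(8, 13, 18, 28)` and
#' concentrations `c(1, 5, 10)` nM.
#'
#' @param S_values inter-fluorophore spacings (nt).
#' @param concentrations enzyme concentrations (nM).
#' @param tau_nt,tau_fluor enzyme bond times (s); defaults are the
#'   5'-to-3' values measured for the mitochondrial exonuclease MGME1.
#' @param n_traces traces per condition.
#' @param n_control traces in the no-enzyme control.
#' @param label_type,overhang_end substrate labeling and geometry.
#' @param photo optional [photophysics()] override list.
#' @param scenario_mix optional control scenario mixture (3-vector).
#' @return a config list for [generate_benchmark_set()].
#' @export
processive_benchmark_config <- function(S_values = c(8, 13, 18, 28),
                                        concentrations = c(1, 5, 10),
                                        tau_nt = 0.16, tau_fluor = 0.40,
                                        n_traces = 250, n_control = 1000,
                                        label_type = "iCy3",
                                        overhang_end = "five_prime",
                                        photo = NULL,
                                        scenario_mix = NULL) {
  conds <- list()
  for (S in S_values) for (cc in concentrations)
    conds[[length(conds) + 1]] <- list(
      name = sprintf("S%d_c%g", S, cc), kind = "processive",
      n_traces = n_traces,
      substrate = list(S = S, n0 = 5, label_type = label_type,
                       overhang_end = overhang_end,
                       overhang_length = max(40, S + 10)),
      enzyme = list(mode = "processive", tau_nt = tau_nt,
                    tau_fluor = tau_fluor, concentration = cc),
      photo = photo)
  conds[[length(conds) + 1]] <- list(
    name = "control", kind = "bleach_only", n_traces = n_control,
    photo = photo, scenario_mix = scenario_mix)
  list(conditions = conds)
}
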