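nisp_defaults <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    input_dir = NULL,
    verbose = TRUE,
    simulate = list(conditions = list()),
    analyze = list(
      unit = NULL,               # a.u.; estimated from the data when NULL
      rel_tol = 0.25,            # two-fluorophore selection tolerance
      penalty_scale = 10,        # step-finder penalty multiplier
      min_dwell = 3,             # frames
      mag_window = c(0.5, 1.5),  # accepted step magnitude, units of `unit`
      control_condition = "control",
      candidate_widths = c(0.2, 0.3, 0.5, 0.75, 1, 1.5, 2),  # s
      stability_tol = 0.2,       # s
      background_mode = "joint",
      weighted = FALSE
    ),
    fret = list(
      bin_width = 0.02,
      bimodality_threshold = 0.5,
      bp_unwound = 19,
      enter_frac = 0.1,
      pause_max = 0.5,
      low_level = NULL,          # estimated from the pooled histogram when NULL
      high_level = NULL
    )
  )
}

merge_config <- function(defaults, overrides, path = "config") {
  if (is.null(overrides)) return(defaults)
  for (key in names(overrides)) {
    if (!key %in% names(defaults))
      stop("nisp_config: unknown key '", path, "$", key, "'")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        key != "simulate") {
      defaults[[key]] <- merge_config(defaults[[key]], overrides[[key]],
                                      paste0(path, "$", key))
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  defaults
}

#' Build a resolved run configuration
#'
#' Merges user overrides into the package defaults, rejecting unknown keys.
#' The resolved configuration (defaults + overrides + master seed) is written
#' alongside every output directory so a run can be reproduced exactly.
#'
#' @param overrides named list of overrides (possibly nested), or a path to
#'   a YAML file containing one.
#' @return resolved configuration list of class `nisp_config`.
#' @export
nisp_config <- function(overrides = list()) {
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  cfg <- merge_config(nisp_defaults(), overrides)
  class(cfg) <- "nisp_config"
  cfg
}

write_resolved_config <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(config)
  yaml::write_yaml(cfg, file.path(dir, "config_resolved.yaml"))
}

say <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

#' Simulate a benchmark set from a configuration
#'
#' Runs [generate_benchmark_set()] on `config$simulate` with the master seed
#' and, when `config$output_dir` is set, writes the trace tables, the
#' manifest and the resolved configuration there.
#'
#' @param config a [nisp_config()] (or overrides list passed to it).
#' @return the `benchmark_set`, invisibly when written to disk.
#' @export
run_simulation <- function(config = nisp_config()) {
  if (!inherits(config, "nisp_config")) config <- nisp_config(config)
  bench <- generate_benchmark_set(config$simulate, config$seed)
  say(config, "simulated %d conditions (%d traces), master seed %d",
      nrow(bench$manifest), sum(bench$manifest$n_traces), config$seed)
  if (!is.null(config$output_dir)) {
    write_benchmark_set(bench, config$output_dir)
    write_resolved_config(config, config$output_dir)
    return(invisible(bench))
  }
  bench
}

#' Run the full photodropping analysis on a benchmark set
#'
#' Selection (two-fluorophore intensity criterion), step detection, scenario
#' classification, occurrence table with control subtraction, per-condition
#' background-corrected dwell fitting, and -- when the conditions span at
#' least three fluorophore spacings -- the dwell-versus-spacing
#' decomposition into a degradation rate; when they span at least three
#' concentrations at a fixed spacing, the processive/distributive
#' classification.
#'
#' @param config a [nisp_config()].
#' @param bench optional in-memory `benchmark_set`; read from
#'   `config$input_dir` (or `output_dir`) when `NULL`.
#' @return list of class `nisp_analysis`: `occurrence`, `dwell_fits`
#'   (per-condition `gausspoly_fit`s), `t2_table`, `decomposition`,
#'   `processivity`, `unit`.
#' @export
run_analysis <- function(config = nisp_config(), bench = NULL) {
  if (!inherits(config, "nisp_config")) config <- nisp_config(config)
  an <- config$analyze
  if (is.null(bench)) {
    dir <- if (!is.null(config$input_dir)) config$input_dir else config$output_dir
    if (is.null(dir)) stop("run_analysis: no benchmark set and no input_dir")
    bench <- read_benchmark_set(dir)
  }
  manifest <- bench$manifest
  trace_conds <- manifest$condition[manifest$kind %in%
    c("processive", "distributive", "bleach_only")]
  if (!length(trace_conds)) stop("run_analysis: no intensity-trace conditions")
  all_traces <- unlist(lapply(bench$traces[trace_conds], identity),
                       recursive = FALSE)
  unit <- if (!is.null(an$unit)) an$unit else
    estimate_unit_intensity(all_traces, config_unit = NULL,
                            penalty_scale = an$penalty_scale,
                            min_dwell = an$min_dwell)
  say(config, "unit intensity: %.1f a.u.", unit)
  calls <- list()
  for (cd in trace_conds) {
    trs <- bench$traces[[cd]]
    sel <- select_traces(trs, unit, rel_tol = an$rel_tol)
    say(config, "condition %s: %d traces, %d pass the 2x-intensity criterion",
        cd, length(trs), length(sel))
    calls <- c(calls, lapply(sel, function(tr) {
      cl <- detect_steps(tr, unit, penalty_scale = an$penalty_scale,
                         min_dwell = an$min_dwell, mag_window = an$mag_window)
      cl$meta$condition <- cd
      cl
    }))
  }
  et <- classify_and_extract(calls)
  occ <- if (an$control_condition %in% et$events$condition)
    build_occurrence_table(et, an$control_condition)
  else stop("run_analysis: control condition '", an$control_condition,
            "' missing from the event table")
  # control background from the no-enzyme T2 pool
  ctrl_t2 <- et$dwells$dwell_s[et$dwells$condition == an$control_condition &
                                 et$dwells$dwell_type == "T2"]
  enz_conds <- setdiff(trace_conds, an$control_condition)
  dwell_fits <- list()
  rows <- list()
  for (cd in enz_conds) {
    t2 <- et$dwells$dwell_s[et$dwells$condition == cd &
                              et$dwells$dwell_type == "T2"]
    if (length(t2) < 30) {
      say(config, "condition %s: only %d two-step dwells, skipping fit",
          cd, length(t2))
      next
    }
    bw <- select_bin_width(t2, an$candidate_widths, an$stability_tol)
    hist <- dwell_histogram(t2, bw, t_max = max(c(t2, ctrl_t2)))
    ctrl_bg <- if (length(ctrl_t2) >= 30) {
      ch <- dwell_histogram(ctrl_t2, bw, t_max = max(c(t2, ctrl_t2)))
      tryCatch(fit_background(ch), error = function(e) NULL)
    } else NULL
    fit <- fit_gaussian_plus_background(hist, ctrl_bg,
                                        mode = an$background_mode)
    dwell_fits[[cd]] <- fit
    i <- match(cd, manifest$condition)
    rows[[cd]] <- data.frame(condition = cd, S = manifest$S[i],
                             concentration_nM = manifest$concentration_nM[i],
                             n_events = length(t2), bin_width = bw,
                             t2_av = fit$mu, t2_sd = fit$sigma,
                             stringsAsFactors = FALSE)
    say(config, "condition %s: %d T2 events, T2,av = %.2f +- %.2f s",
        cd, length(t2), fit$mu, fit$sigma)
  }
  t2_table <- if (length(rows)) do.call(rbind, rows) else NULL
  decomposition <- NULL
  processivity <- NULL
  if (!is.null(t2_table)) {
    by_S <- stats::aggregate(t2_av ~ S, data = t2_table, FUN = mean)
    if (nrow(by_S) >= 3)
      decomposition <- decompose_linear(
        data.frame(S = by_S$S, t2_av = by_S$t2_av))
    cc <- t2_table[!is.na(t2_table$concentration_nM) &
                     t2_table$concentration_nM > 0, ]
    smode <- names(sort(table(cc$S), decreasing = TRUE))
    if (length(smode)) {
      cs <- cc[cc$S == as.numeric(smode[1]), ]
      if (nrow(cs) >= 3)
        processivity <- classify_processivity(
          data.frame(c = cs$concentration_nM, t2_av = cs$t2_av))
    }
  }
  res <- structure(list(occurrence = occ, dwell_fits = dwell_fits,
                        t2_table = t2_table, decomposition = decomposition,
                        processivity = processivity, unit = unit),
                   class = "nisp_analysis")
  if (!is.null(config$output_dir)) write_analysis(res, config)
  res
}

write_analysis <- function(res, config) {
  dir <- config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$occurrence, file.path(dir, "occurrence.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$t2_table))
    utils::write.table(res$t2_table, file.path(dir, "t2_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  out <- list(unit = res$unit)
  if (!is.null(res$decomposition))
    out$decomposition <- unclass(res$decomposition)
  if (!is.null(res$processivity))
    out$processivity <- res$processivity[c("classification", "slope",
                                           "se_slope")]
  out$dwell_fits <- lapply(res$dwell_fits, function(f)
    f[c("mu", "sigma", "amplitude", "mode")])
  jsonlite::write_json(out, file.path(dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_resolved_config(config, dir)
  invisible(dir)
}

#' @export
print.nisp_analysis <- function(x, ...) {
  cat("<nisp_analysis>\n")
  print(x$occurrence)
  if (!is.null(x$decomposition)) print(x$decomposition)
  if (!is.null(x$processivity)) print(x$processivity)
  invisible(x)
}

#' Run the FRET branch: efficiency histograms and unwinding kinetics
#'
#' Pools per-frame proximity-ratio efficiencies of every FRET condition and
#' fits the histogram (one or two Gaussian components). For unwinding
#' conditions the low/high levels (from the fitted components unless set in
#' the config) feed [detect_unwinding()], and the unpaused dwells give the
#' duplex-unwinding rate.
#'
#' @param config a [nisp_config()].
#' @param bench optional in-memory `benchmark_set` with FRET conditions.
#' @return list of class `nisp_fret_analysis`: per-condition `histogram`
#'   fits, `unwinding` rate summaries.
#' @export
run_fret_analysis <- function(config = nisp_config(), bench = NULL) {
  if (!inherits(config, "nisp_config")) config <- nisp_config(config)
  fr <- config$fret
  if (is.null(bench)) {
    dir <- if (!is.null(config$input_dir)) config$input_dir else config$output_dir
    if (is.null(dir)) stop("run_fret_analysis: no benchmark set and no input_dir")
    bench <- read_benchmark_set(dir)
  }
  manifest <- bench$manifest
  fret_conds <- manifest$condition[manifest$kind %in%
    c("fret_static", "fret_unwinding")]
  if (!length(fret_conds)) stop("run_fret_analysis: no FRET conditions")
  hist_fits <- list()
  unwinding <- list()
  for (cd in fret_conds) {
    series <- lapply(bench$traces[[cd]], compute_efficiency)
    hist_fits[[cd]] <- fit_efficiency_histogram(
      series, bin_width = fr$bin_width,
      bimodality_threshold = fr$bimodality_threshold)
    kind <- manifest$kind[match(cd, manifest$condition)]
    say(config, "condition %s: %d traces pooled", cd, length(series))
    if (kind == "fret_unwinding") {
      hf <- hist_fits[[cd]]
      low <- if (!is.null(fr$low_level)) fr$low_level else min(hf$mean)
      high <- if (!is.null(fr$high_level)) fr$high_level else max(hf$mean)
      calls <- lapply(series, detect_unwinding, low_level = low,
                      high_level = high, enter_frac = fr$enter_frac,
                      pause_max = fr$pause_max)
      found <- sum(!vapply(calls, is.null, logical(1)))
      say(config, "condition %s: %d/%d complete transitions", cd, found,
          length(calls))
      unwinding[[cd]] <- unwinding_rate(calls, bp_unwound = fr$bp_unwound)
    }
  }
  res <- structure(list(histograms = hist_fits, unwinding = unwinding),
                   class = "nisp_fret_analysis")
  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out <- list(
      histograms = lapply(hist_fits, function(h) as.data.frame(h)),
      unwinding = lapply(unwinding, function(u)
        u[c("rate", "sd_rate", "mean_dwell", "sd_dwell", "n")]))
    jsonlite::write_json(out, file.path(dir, "fret.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_resolved_config(config, dir)
  }
  res
}

#' @export
print.nisp_fret_analysis <- function(x, ...) {
  cat("<nisp_fret_analysis>\n")
  for (cd in names(x$histograms)) {
    cat(sprintf("  %s:\n", cd))
    print(x$histograms[[cd]])
    if (cd %in% names(x$unwinding)) print(x$unwinding[[cd]])
  }
  invisible(x)
}
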