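#' Substrate geometry for a stepwise-photodropping experiment
#'
#' Describes a surface-immobilized DNA molecule carrying two fluorophores on a
#' single-stranded overhang (or on one strand of a blunt duplex). The spacing
#' `S` is the number of nucleotides with scissile phosphodiester bonds between
#' the two labels; `n0` counts the nucleotides between the free overhang end
#' and the first label, which a processive exonuclease must traverse before
#' the first photodrop.
#'
#' @param S integer, nucleotides with scissile bonds between the two labels.
#' @param n0 integer, nucleotides between the free end and the first label.
#' @param label_type `"iCy3"` (backbone-internal) or `"eCy3"` (base-external).
#' @param overhang_end `"five_prime"`, `"three_prime"` or `"blunt_duplex"`.
#' @param overhang_length total overhang length in nt. Must accommodate
#'   `n0 + S + 2` labeled nucleotides unless the substrate is a blunt duplex.
#'
#' @return An object of class `substrate_spec`.
#' @export
#' @examples
#' substrate_spec(S = 18, n0 = 5, label_type = "iCy3",
#'                overhang_end = "five_prime", overhang_length = 40)
substrate_spec <- function(S, n0 = 0, label_type = c("iCy3", "eCy3"),
                           overhang_end = c("five_prime", "three_prime",
                                            "blunt_duplex"),
                           overhang_length = 40L) {
  label_type <- match.arg(label_type)
  overhang_end <- match.arg(overhang_end)
  stopifnot(is.numeric(S), length(S) == 1L, is.finite(S), S >= 0,
            is.numeric(n0), length(n0) == 1L, is.finite(n0), n0 >= 0)
  if (overhang_end != "blunt_duplex" && n0 + S + 2 > overhang_length)
    stop("substrate_spec: overhang_length must be >= n0 + S + 2")
  structure(list(S = as.integer(S), n0 = as.integer(n0),
                 label_type = label_type, overhang_end = overhang_end,
                 overhang_length = as.integer(overhang_length)),
            class = "substrate_spec")
}

#' Enzyme kinetics model for trace simulation
#'
#' Parameterizes the stochastic cleavage clock of a nuclease. A processive
#' enzyme binds once (exponential waiting time with rate
#' `k_bind_per_nM * concentration`, or immediately when `prebound`) and then
#' traverses the overhang bond by bond: each native scissile bond takes an
#' independent exponential time with mean `tau_nt`, and the bond carrying a
#' fluorophore-conjugated nucleotide takes an additional Erlang-distributed
#' time with mean `tau_fluor` (shape `fluor_shape`). A distributive enzyme
#' instead cleaves each labeled site after an independent exponential time
#' with per-site rate `k_site(concentration)`.
#'
#' `tau_nt` is the per-nucleotide bond time (the slope of the dwell-vs-spacing
#' line, s/nt); `tau_fluor` is the extra time charged for removing a
#' fluorophore-conjugated nucleotide (the intercept of that line, s).
#'
#' @param mode `"processive"`, `"distributive"` or `"inactive"`.
#' @param tau_nt mean time to cleave one native scissile bond (s).
#' @param tau_fluor mean extra time for the fluorophore-conjugated bond (s).
#' @param fluor_shape Erlang shape of the fluorophore-bond time; the default 4
#'   makes the labeled-bond dwell moderately peaked rather than exponential,
#'   matching the unimodal dwell histograms the assay produces.
#' @param k_bind_per_nM first-binding rate per unit concentration (1/s/nM).
#'   The default 0.0016 makes roughly a fifth of molecules see no enzyme
#'   within a 100-s window at 10 nM, the occurrence level typical of these
#'   assays; observed binding is sublinear in concentration, so a linear
#'   model calibrated at high concentration understates binding at 1 nM.
#' @param concentration enzyme concentration (nM).
#' @param prebound if `TRUE` the binding time is forced to 0, modeling the
#'   condition where the enzyme is pre-incubated and the reaction is triggered
#'   by adding the catalytic metal ion.
#' @param k_site distributive per-site cleavage rate (1/s) at `concentration`.
#'   Either supply `k_site` directly or `k_max` and `c_half` for the
#'   saturating form `k_site(c) = k_max * c / (c + c_half)`.
#' @param k_max,c_half parameters of the saturating `k_site(c)`.
#'
#' @return An object of class `enzyme_kinetics`.
#' @export
enzyme_kinetics <- function(mode = c("processive", "distributive", "inactive"),
                            tau_nt = NULL, tau_fluor = NULL, fluor_shape = 4,
                            k_bind_per_nM = 0.0016, concentration = 0,
                            prebound = FALSE,
                            k_site = NULL, k_max = NULL, c_half = NULL) {
  mode <- match.arg(mode)
  chk <- function(x, nm, lo = 0, strict = FALSE) {
    if (!is.null(x)) {
      if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
          (strict && x <= lo) || (!strict && x < lo))
        stop(sprintf("enzyme_kinetics: invalid %s", nm))
    }
    x
  }
  if (mode == "processive") {
    chk(tau_nt, "tau_nt", 0, strict = TRUE)
    chk(tau_fluor, "tau_fluor", 0)
    if (is.null(tau_nt) || is.null(tau_fluor))
      stop("enzyme_kinetics: processive mode needs tau_nt and tau_fluor")
  }
  if (mode == "distributive" && is.null(k_site) &&
      (is.null(k_max) || is.null(c_half)))
    stop("enzyme_kinetics: distributive mode needs k_site, or k_max and c_half")
  chk(k_site, "k_site"); chk(k_max, "k_max"); chk(c_half, "c_half")
  chk(k_bind_per_nM, "k_bind_per_nM"); chk(concentration, "concentration")
  chk(fluor_shape, "fluor_shape", 0, strict = TRUE)
  structure(list(mode = mode, tau_nt = tau_nt, tau_fluor = tau_fluor,
                 fluor_shape = fluor_shape, k_bind_per_nM = k_bind_per_nM,
                 concentration = concentration, prebound = isTRUE(prebound),
                 k_site = k_site, k_max = k_max, c_half = c_half),
            class = "enzyme_kinetics")
}

#' Per-site cleavage rate of a distributive enzyme at its concentration
#'
#' Returns `k_site` if given directly, otherwise the saturating form
#' `k_max * c / (c + c_half)`.
#'
#' @param enzyme an [enzyme_kinetics()] object.
#' @param concentration optional concentration (nM) overriding the one stored
#'   in `enzyme`.
#' @return rate in 1/s.
#' @export
site_cleavage_rate <- function(enzyme, concentration = NULL) {
  c0 <- if (is.null(concentration)) enzyme$concentration else concentration
  if (!is.null(enzyme$k_site)) return(enzyme$k_site)
  enzyme$k_max * c0 / (c0 + enzyme$c_half)
}

#' Photophysics of the imaging system
#'
#' Single-fluorophore unit intensity, additive per-frame noise, spontaneous
#' photobleaching rate, and the acquisition raster (frame interval and
#' recording window).
#'
#' @param unit_intensity mean intensity of one fluorophore (a.u.).
#' @param noise_sd additive Gaussian noise sd per frame (a.u.). The default
#'   unit of 1000 a.u. with sd 50 corresponds to a signal-to-noise ratio of
#'   about 20 for a single fluorophore.
#' @param k_bleach per-fluorophore spontaneous photobleaching rate (1/s).
#' @param frame_interval s per frame (default 0.1 s).
#' @param window acquisition length (s, default 100); must be a whole number
#'   of frames.
#'
#' @return An object of class `photophysics`.
#' @export
photophysics <- function(unit_intensity = 1000, noise_sd = 50,
                         k_bleach = 0.0012, frame_interval = 0.1,
                         window = 100) {
  stopifnot(is.numeric(unit_intensity), unit_intensity > 0,
            is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(k_bleach), k_bleach >= 0,
            is.numeric(frame_interval), frame_interval > 0,
            is.numeric(window), window > 0)
  n_frames <- window / frame_interval
  if (abs(n_frames - round(n_frames)) > 1e-8)
    stop("photophysics: window must be a whole number of frames")
  structure(list(unit_intensity = unit_intensity, noise_sd = noise_sd,
                 k_bleach = k_bleach, frame_interval = frame_interval,
                 window = window, n_frames = as.integer(round(n_frames))),
            class = "photophysics")
}

#' @export
print.substrate_spec <- function(x, ...) {
  cat(sprintf("<substrate_spec> S=%d nt, n0=%d nt, %s, %s, overhang %d nt\n",
              x$S, x$n0, x$label_type, x$overhang_end, x$overhang_length))
  invisible(x)
}

#' @export
print.enzyme_kinetics <- function(x, ...) {
  cat(sprintf("<enzyme_kinetics> mode=%s", x$mode))
  if (x$mode == "processive")
    cat(sprintf(", tau_nt=%.3g s, tau_fluor=%.3g s", x$tau_nt, x$tau_fluor))
  if (x$mode == "distributive")
    cat(sprintf(", k_site=%.3g 1/s", site_cleavage_rate(x)))
  cat(sprintf(", %g nM%s\n", x$concentration,
              if (x$prebound) " (prebound)" else ""))
  invisible(x)
}

#' @export
print.photophysics <- function(x, ...) {
  cat(sprintf(
    "<photophysics> unit=%g a.u., noise_sd=%g, k_bleach=%g 1/s, %g s @ %g s/frame\n",
    x$unit_intensity, x$noise_sd, x$k_bleach, x$window, x$frame_interval))
  invisible(x)
}

# Deterministic per-trace seed stream derived from a master seed.
# Simple counter-based multiplicative scheme; keeps values < 2^31.
derive_seed <- function(master, index) {
  m <- 2147483629
  as.integer((((as.numeric(master) %% m) * 48271) %% m + index * 9973) %% m)
}
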