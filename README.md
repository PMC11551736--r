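# nispr

Single-molecule kinetics of DNA-degrading enzymes from stepwise
fluorescence photodropping.

## The problem

Measuring how fast an exo- or endonuclease chews through single-stranded
DNA usually requires labeling or tethering the enzyme, which can distort
the very kinetics being measured. A label-free alternative immobilizes a
DNA substrate carrying **two Cy3 fluorophores** on its single-stranded
overhang and watches the total fluorescence of each molecule under TIRF
illumination. When a nuclease removes the fluorophore-bearing nucleotides
one after the other, the intensity drops in **two discrete steps**; the
time between the drops reports how long the enzyme took to traverse the
nucleotides between the two labels.

Within a 100-s window each molecule shows one of three scenarios: no
photodrop, one step (dwell *T*₁) or two steps (dwell *T*₂). Spontaneous
photobleaching produces the same signatures, so the analysis must subtract
a no-enzyme photobleaching background before interpreting *T*₂.

## The model

For a processive exonuclease, the mean inter-drop dwell is linear in the
label spacing *S* (nucleotides with scissile phosphodiester bonds between
the two fluorophores):

&nbsp;&nbsp;&nbsp;&nbsp;E[*T*₂] = τ_nt · *S* + τ_fluor

where τ_nt (s/nt) is the mean time to cleave one native bond and τ_fluor
(s) the extra time spent on a fluorophore-conjugated nucleotide. Fitting
background-corrected mean dwells against *S* and inverting the slope gives
the **degradation rate in nt/s**, with the label's hindrance isolated in
the intercept. A processive enzyme's *T*₂ is independent of enzyme
concentration (single binding event); a distributive enzyme's *T*₂
shortens with concentration (memoryless per-site cleavage) — the package
classifies the two regimes from a dwell-versus-log-concentration
regression. A FRET branch measures duplex unwinding: the dwell of the
low→high efficiency transit divided into the number of base pairs unwound
gives the unwinding rate in bp/s.

The package provides, per module:

- **Synthetic data** — Monte-Carlo traces (processive, distributive,
  bleach-only controls), FRET donor/acceptor pairs, and TIRF-like image
  stacks, all with ground-truth event logs (`simulate_*`,
  `generate_benchmark_set`).
- **Trace processing** — spot/trace extraction from image stacks, SNR,
  the 2× intensity selection criterion, penalized binary-segmentation step
  detection, and scenario tabulation (`extract_traces_from_movie`,
  `detect_steps`, `classify_and_extract`).
- **Kinetics** — occurrence tables with control subtraction, bin-width
  stability selection, quartic photobleaching background and
  Gaussian-plus-background dwell fits, the *T*₂-vs-*S* decomposition and
  the processive/distributive classifier (`fit_gaussian_plus_background`,
  `decompose_linear`, `classify_processivity`).
- **FRET** — proximity-ratio efficiencies, one/two-component histogram
  fits, unwinding-dwell detection and rate aggregation
  (`compute_efficiency`, `detect_unwinding`, `unwinding_rate`).
- **Pipeline** — YAML-configurable entry points (`run_simulation`,
  `run_analysis`, `run_fret_analysis`) and a thin CLI at
  `inst/cli/nisp.R`.

## Worked example

Simulate a spacing series (S = 8, 13, 18, 28 nt) for a processive
5′→3′ exonuclease with per-bond time 0.16 s/nt and label time 0.40 s at
10 nM, plus a no-enzyme control, then run the full analysis:

```r
library(nispr)
cfg <- nisp_config(list(
  seed = 7, verbose = FALSE,
  simulate = processive_benchmark_config(
    S_values = c(8, 13, 18, 28), concentrations = 10,
    tau_nt = 0.16, tau_fluor = 0.40,
    n_traces = 250, n_control = 1000,
    scenario_mix = c(78.4, 15.8, 5.8))))
bench <- run_simulation(cfg)
res   <- run_analysis(cfg, bench)
res$t2_table[, c("condition", "S", "n_events", "t2_av", "t2_sd")]
#>  condition  S n_events t2_av t2_sd
#>     S8_c10  8      205  1.52 0.511
#>    S13_c10 13      191  2.33 0.552
#>    S18_c10 18      186  3.09 0.588
#>    S28_c10 28      204  4.74 0.825
res$decomposition
#> <kinetic_decomposition> slope 0.16 +- 0.00 s/nt, intercept 0.23 +- 0.03 s
#>   degradation rate 6.2 +- 0.1 nt/s (R^2 = 1.00, n = 4)
```

Reading the output: each row is one substrate; `t2_av` is the
background-corrected Gaussian mean of that condition's *T*₂ histogram.
The dwells grow linearly with the label spacing; the fitted slope
(0.16 s/nt) is the per-nucleotide bond time and its inverse, **6.2 nt/s**,
is the recovered degradation rate — matching the generator truth
(1/0.16 = 6.25 nt/s). The intercept estimates the extra dwell on the
labeled nucleotide. `res$occurrence` holds the scenario probabilities and
their changes against the no-enzyme control.

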