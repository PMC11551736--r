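Package: nispr
Title: Single-Molecule Analysis of Nuclease-Induced Stepwise Photodropping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring single-stranded DNA degradation kinetics of
    exo- and endonucleases from dual-fluorophore single-molecule fluorescence
    time traces. A nuclease removing two Cy3 labels from an immobilized DNA
    substrate produces a two-step decrease in intensity ("stepwise
    photodropping"); the package detects those steps by penalized binary
    segmentation, classifies traces into zero-, one- and two-step scenarios,
    corrects dwell-time histograms for spontaneous photobleaching with a
    Gaussian-plus-quartic-background fit, and decomposes the mean inter-drop
    dwell versus fluorophore spacing into a per-nucleotide degradation rate.
    A companion FRET branch quantifies duplex-unwinding dwell times and rates.
    A Monte-Carlo generator produces intensity traces, donor/acceptor trace
    pairs and TIRF-like image stacks with known ground truth, so the whole
    pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
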