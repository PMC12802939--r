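Package: teloG4
Title: Conformation, Stability, and Repair Analysis of Ribonucleotide-Substituted Telomeric G-Quadruplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the structural and repair consequences of single
    ribonucleotide (rNMP) substitutions in the human telomeric G-quadruplex
    repeat (TTAGGG)4. Parses the lowercase-r substitution notation and maps
    substitution sites to repeat position classes (G1/G2/G3/loop); calls
    G-quadruplex conformations (parallel, antiparallel chair, antiparallel
    basket, 3+1 hybrid) from circular dichroism spectra by spectral-signature
    matching backed by nonnegative basis decomposition; extracts melting
    temperatures from CD melt and anneal ramps as the second-derivative root of
    a fitted third-order polynomial; computes per-frame smFRET efficiency,
    pooled efficiency histograms with Gaussian peak fits, and classifies
    single-molecule traces as static-folded, dynamic, or unfolded with a
    dwell-filtered 0.6-efficiency threshold; and quantifies RNase H2 cleavage
    time courses from gel band intensities with position-class and cation
    summaries. A synthetic-data module generates CD spectra, melting curves,
    two-state Markov FRET trajectories with ground-truth labels, and saturating
    cleavage time courses so the whole workflow is exercisable and testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    pracma,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
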