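# teloG4

Analysis workflow for the structural and repair consequences of single
ribonucleotide (rNMP) substitutions in the human telomeric G-quadruplex
repeat (TTAGGG)₄, written for nucleic-acid biophysicists working with CD
spectroscopy, single-molecule FRET, and RNase H2 cleavage assays.

Telomerase inserts rNMPs into telomeric DNA, and a single ribose can change
which G-quadruplex (G4) conformation forms, how stably it folds, and whether
RNase H2 — the enzyme that initiates ribonucleotide excision repair — can
reach the lesion. The package implements every computational stage of such a
study, plus a synthetic-data module so the whole pipeline runs and is tested
with known ground truth, end to end, without instrument data.

## What it computes

* **Sequence model** — parse/format the lowercase-r substitution notation
  (`TTArGGG…`), and map a substitution at position *p* of the 24-mer to its
  repeat position class via `(p − 1) mod 6` → T, T, loop-A, G1, G2, G3.
* **CD analysis** — buffer subtraction and scan averaging; extrema detection
  with prominence gating; conformation calls against the four topology
  signatures (parallel +265/−240; antiparallel chair +290/−265; antiparallel
  basket +250,+290/−235,−265; 3+1 hybrid +265,+290/−240,−275 nm), with a
  nonnegative basis decomposition arbitrating mixtures; melting temperature
  as the second-derivative root of a fitted cubic, *T*ₘ = −b/(3a), with an
  automatic fit window around the steepest slope; ΔTₘ normalization and
  melt/reanneal refolding checks.
* **smFRET analysis** — per-frame efficiency E = F_A / (F_A + F_D); pooled
  short-movie histograms with single-Gaussian peak fits; trace typing
  (static-folded / dynamic / unfolded) with a 0.6 efficiency threshold and a
  5-frame persistence filter; repeat-level percentage summaries (mean ±
  sample SD).
* **Cleavage analysis** — percent cleavage from gel band intensities,
  triplicate summaries with a not-detected floor, grouping by rNMP position
  class, first-order saturation fits, and Na⁺-vs-K⁺ comparison tables.
* **Synthetic data** — seeded generators for all of the above: Gaussian-band
  CD mixtures, two-state sigmoid (or exact-cubic) melting ramps, two-state
  Markov FRET trajectories with ground-truth labels, and saturating cleavage
  time courses.

Reference tables for the published construct panel (sequences, conformations,
Tm/ΔTm, trace-type percentages, cleavage percentages by cation) are bundled
as tibbles: `telomere_panel()`, `smfret_reference()`, `cleavage_reference()`.

## Worked example

```r
library(teloG4)

s <- parse_telomere_seq("TTAGGGTTArGGGTTAGGGTTAGGG", name = "TELR10")
classify_substitution(s)
#> <substitution_site> position 10, repeat 2, class G1

sp <- gen_cd_spectrum(c(antiparallel_basket = 1), synth_config(seed = 1))
classify_conformation(sp)
#> <conformation_call> antiparallel_basket
#>   extrema scores: parallel=0.00, antiparallel_chair=1.00, antiparallel_basket=1.00, hybrid_3plus1=0.50
#>   decomposition shares: parallel=0.00, antiparallel_chair=0.00, antiparallel_basket=1.00, hybrid_3plus1=0.00

curve <- gen_melting_curve(46.99, synth_config(seed = 1), model = "sigmoid")
res <- fit_cubic_tm(curve, auto_window = TRUE)
res
#> <melt_result> Tm = 46.89 degC (melt, window 31.5-61.5 degC, n = 30)
delta_tm(res$tm, 58.86)
#> [1] -11.97

g <- gen_fret_traces(500, synth_config(seed = 1,
       type_fractions = ref_trace_fractions("TELR10")))
labs <- vapply(g$traces,
               function(tr) classify_trace(compute_fret(tr))$label, character(1))
summarize_dynamics(list(labs), construct = "TELR10")
#> <dynamics_summary TELR10> 500 traces in 1 repeats
#>   static_folded   61.2 +/- NA %
#>   dynamic         31.8 +/- NA %
#>   unfolded         7.0 +/- NA %
mean(labs == g$labels)
#> [1] 0.998
```

Reading the output: the ribo-G at position 10 sits at the G1 position of the
second repeat — the class whose substitution flips the G4 into the
antiparallel basket conformation, which the CD classifier calls from the
spectrum (note the chair signature also fully matches, because its extrema
are a subset of the basket's; the decomposition resolves it). The cubic
inflection recovers the strongly destabilized Tm of this construct
(≈ 47 °C, ΔTₘ ≈ −12 °C against the all-DNA repeat at 58.86 °C), and trace
typing on simulated 3-minute records reproduces the generating
static/dynamic/unfolded mixture with 99.8% per-trace agreement.

## Analysis workflow

Numbered drivers under `analysis/` rerun the full study on synthetic data:

1. `01_simulate.R` — generate all raw inputs (CD spectra, melt/anneal ramps,
   smFRET trace sets, gel triplicates) under `scratch/synthetic/`.
2. `02_cd_conformation_stability.R` — conformation calls (17/17 correct),
   Tm/ΔTm tables, refolding checks → `results/`.
3. `03_smfret_dynamics.R` — pooled histogram + Gaussian fit, trace typing
   across 5 repeats per construct → `results/`.
4. `04_cleavage_by_position.R` — synthetic gel quantification, position-class
   summaries for both cations, Na−K differences → `results/`.

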