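---
title: "Methods: conformation, stability, and repair analysis of rNMP-substituted telomeric G-quadruplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformation, stability, and repair analysis of rNMP-substituted telomeric G-quadruplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teloG4)
```

## The scientific problem

Human telomeres are tandem TTAGGG repeats whose G-rich strand folds into
G-quadruplexes (G4s): stacks of guanine tetrads stabilized by a central
monovalent cation. Telomerase inserts ribonucleotides (rNMPs) into telomeric
DNA at an appreciable rate, and a single ribose — one extra 2'-OH — can
change which G4 conformation forms, how stably it folds, and whether the
repair enzyme RNase H2 can reach the lesion to initiate ribonucleotide
excision repair. This package implements the complete computational workflow
for such a study on the minimal G4-forming telomere (TTAGGG)~4~: sequence
bookkeeping, CD-based conformation calling and melting-temperature
extraction, single-molecule FRET histogram and trace-dynamics analysis, and
gel-based cleavage quantification — together with a synthetic-data module
that generates every input with known ground truth.

## Sequence model

Constructs are written in lowercase-r notation (`TTArGGG...` = ribo-G at
position 4 of the 24-mer); the `r` is a zero-width prefix so that construct
names index the plain base string (TELR4 means position 4). Positions map to
repeat position classes by the offset rule `(position - 1) mod 6`: offsets
0,1 are the two T's, 2 the loop A, and 3,4,5 the G1, G2, G3 tetrad guanines.
Two conventions are worth making explicit:

* position 3 — the A of the leading TTA, which is a 5'-flank rather than an
  inter-tetrad loop in the folded structure — is grouped with the loop-A
  class, matching how the construct panel is grouped in practice;
* positions at T offsets are labelled `T` and accepted rather than rejected,
  because the generator may legitimately produce them even though no
  T-substituted construct was studied.

## CD analysis

**Conformation signatures.** The four intramolecular G4 topologies carry
characteristic CD extrema: parallel (max ~265 nm, min ~240 nm), antiparallel
2+2 chair (max ~290, min ~265), antiparallel 2+2 basket (maxima ~250/~290,
minima ~235/~265), and 3+1 hybrid (maxima ~265/~290, minima ~240/~275).
Observed extrema are matched to signature positions within a tolerance of
8 nm — positions are nominal ("~") and drift several nm between sequence
variants — and each signature is scored by the fraction of its required
extrema matched (calling threshold 0.75).

**Why extrema matching alone cannot call all mixtures.** The basis spectra
are sums of unit-amplitude Gaussian bands at the signature positions. In a
50/50 parallel + chair mixture the parallel +265 band and the chair −265
band cancel exactly, leaving only a 290-nm maximum and a 240-nm minimum:
every signature then scores 0.5 and nothing passes the threshold, although
the mixture is real (and is exactly the call reported for one of the
G1-substituted constructs). More generally, no extrema-only rule can
simultaneously require a maximum at 265 (parallel) and a minimum at 265
(chair) from one spectrum. The default `"combined"` method therefore backs
the extrema scores with a nonnegative least-squares decomposition of the
spectrum onto the four basis spectra. Because Gaussians at distinct centers
are linearly independent, the decomposition of any zero-noise mixture is
unique and exact; a conformation is supported when its weight share is at
least 0.2. Calls are the extrema-passing signatures confirmed by the
decomposition, with a fallback to the decomposition alone when nothing
passes. The subset-specificity tie rule (a pure basket spectrum also fully
matches the chair signature; a pure hybrid also fully matches parallel) only
drops the nested signature when the decomposition lends it no independent
support, so genuine basket+chair and hybrid+parallel mixtures keep both
components. `method = "extrema"` is available as the literal
signature-matching procedure with its hybrid-superset tie rules.

**Melting temperatures.** Ramps run 25–95 °C at 1 °C steps; the monitored
wavelength is the ellipticity argmax of the pre-melt spectrum (with an
override for mixture constructs melted at a conformation-specific
wavelength; such constructs get one independent fit per wavelength, never a
joint fit). Tm is the root of the second derivative of a least-squares
third-order polynomial, Tm = −b/(3a). Numerical choices:

* the cubic is fitted on centered temperatures and back-transformed, which
  keeps the normal equations well conditioned on a 25–95 grid;
* a fit whose cubic term contributes less than about 10^-6^ of the signal
  range over the window is rejected as degenerate (a straight line has no
  inflection), and a root falling outside the fit window is an error that
  reports the root;
* the default window is the full ramp; `auto_window = TRUE` restricts the
  fit to ±15 °C around the steepest-slope temperature. A cubic fitted to a
  sigmoid over a symmetric window recovers the inflection essentially
  exactly, while shifting the window pulls the estimate monotonically toward
  the window center — the automatic window exists to remove that asymmetry
  bias, and the residual error from the discrete slope estimate is about
  0.1 °C;
* Tm values are reported to 0.01 °C.

Mixed-population melting is summarized by one Tm per curve — no
deconvolution — and melt/reanneal integrity is checked as the Pearson
similarity of pre- and post-melt spectra over 230–320 nm.

A note on the bundled reference table: both its Tm and ΔTm columns are
replicate means independently rounded to 0.01 °C, so recomputing a
difference from the rounded Tm columns can disagree with the printed
difference by one unit in the last digit. The accessor documentation records
this; the tests assert agreement at that precision.

## smFRET analysis

Per-frame efficiency is `E = acceptor / (acceptor + donor)` — raw signals
under donor excitation, no crosstalk or gamma correction, matching the
uncorrected form used with this instrument geometry. Frames with nonpositive
total intensity are dropped, not zero-filled. Pooled histograms span
[−0.2, 1.2] at bin width 0.02, which puts ~14 bins across ±1σ of a
0.14-wide folded peak; the peak is summarized by a least-squares single
Gaussian initialized at the mode. The reported half-width is the fitted
Gaussian σ — the fit's native scale parameter; multiply by 1.177 for HWHM —
because the convention behind the published "half-width" column is not
stated.

Traces are typed against a 0.6 efficiency threshold (≥ 0.6 counts as
folded): static-folded stays above throughout the 3-min record, unfolded
stays below, everything else is dynamic. Applied literally, frame-wise
thresholding would label nearly every trace dynamic at realistic per-frame
noise, whereas the original categorization was done by eye. The explicit
surrogate for that judgment is a persistence filter: a state change is
accepted only when the new state lasts at least `min_dwell = 5` frames
(0.5 s at 100 ms/frame). The filter absorbs isolated sub-dwell excursions
into the surrounding state and — because acceptance requires persistence —
scattered noise frames can never accumulate into a spurious excursion.
Repeat-level percentages use the sample SD (n−1): repeats are a sample of
experiments.

## Cleavage analysis

Percent cleavage is cleaved band intensity over total (cleaved + uncleaved),
a scale-invariant ratio. Replicate summaries report per-timepoint mean ±
sample SD on the fixed default grid {1, 5, 15, 30, 60, 120} min; a
replicate-mean below 0.1% is flagged not-detected, mirroring the assay's
detection floor. Class summaries group constructs solely by their
substitution-site class; not-detected cells default to 0 in class means
(`nd_as_zero = TRUE`) because an invisible product band means ~0 cleavage,
and excluding such cells can only bias class means upward (the two rules
bracket each other, which is tested). Cells missing outright are always
excluded. A descriptive first-order fit
`F(t) = burst + (plateau − burst)(1 − e^{−kt})` with fractions bounded to
[0, 1] summarizes each time course; flat series short-circuit to
`burst = plateau = value, k = 0`, and the bounded solver falls back to an
unbounded fit clamped into range on exactly-saturating data where the
bounded solver's gradient check fails. The cation comparison is a plain
Na-minus-K difference table per class and timepoint — the underlying tables
are descriptive means, so no hypothesis test is attached.

## The synthetic-data module

The generators define the study conditions and carry ground truth:

* **CD spectra**: weighted sums of the four Gaussian-band basis spectra on
  220–340 nm plus iid Gaussian noise. Band σ defaults to 12 nm — wide
  enough to look like real G4 CD bands, narrow enough that the adjacent
  265/290 bands remain resolvable by the extrema finder. Zero-noise spectra
  are exactly linear in the weights.
* **Melting curves**: two-state sigmoids
  `f(T) = 1/(1 + exp((T − Tm)/w))` with width `w = 4` °C (a 10–90%
  transition of ~17 °C, typical of intramolecular telomeric G4 melts),
  between folded/unfolded baselines of 10 and 1 mdeg; the anneal direction
  reverses temperature order only. An exact-cubic mode generates a
  polynomial whose inflection is placed analytically, as an oracle for the
  Tm procedure.
* **FRET traces**: types drawn from `type_fractions`; static molecules emit
  0.67 (the pooled-histogram peak center) plus noise, unfolded molecules
  0.4 (the unfolded-state histogram center established for this construct
  family), per-frame noise SD 0.05. Dynamic molecules follow a two-state
  discrete-time Markov chain with per-frame switch probability
  `1 − exp(−k·Δt)`, rates 0.2/s (folded→unfolded) and 0.4/s
  (unfolded→folded), i.e. dwells of 5 s and 2.5 s — no dwell times were
  published, so these sit where multiple transitions occur within a 3-min
  record while dwells stay an order of magnitude above the 0.5-s filter.
  Donor/acceptor channels are reconstructed as `scale·E` and `scale·(1−E)`
  so `compute_fret()` inverts the simulation exactly.
* **Cleavage time courses**: saturating first-order fractions with defaults
  rate 0.01 /min, plateau 0.295, burst 0 — the parameters that pass the
  first-order form through the strongest potassium G1 time course (13.4% at
  60 min, 20.7% at 120 min) — with fraction noise SD 0.04 truncated so both
  band intensities stay nonnegative.

Every generator is deterministic given (seed, parameters).

**What the generators do not emulate** — and hence what passing tests do not
establish about instrument data: photobleaching, blinking, shot noise and
camera offsets in FRET channels; three-state folding intermediates and
intermolecular G4 species; wavelength-correlated CD baseline drift;
gel-loading variation beyond iid fraction noise. Recovery results on
synthetic data validate the estimators under the stated statistical model,
not the instruments.

## Problem sizes

The test suite exercises the estimators at the scales the workflow is meant
for, chosen to characterize the statistics well: histogram fits on 6000
molecules × 20 frames; trace typing on 1000 three-minute traces (1800
frames); classifier noise-recovery over 100 seeded replicates; label-fraction
convergence at n = 10^4^; Tm recovery across the 40–80 °C range. The
analysis drivers under `analysis/` run the same estimators over a full
simulated construct panel (5 repeats × 200 traces per construct).

## Known limitations

* The conformation caller shares its basis model with the generator; on real
  spectra the Gaussian-band basis is an approximation, and decomposition
  shares should be read as support indicators, not molar fractions.
* One Tm per curve: genuinely biphasic melts of conformational mixtures are
  summarized by a single inflection unless melted per-wavelength.
* The dwell filter is an explicit surrogate for manual trace categorization;
  its 0.5-s default is a judgment parameter exposed in the configuration,
  and agreement rates near the dwell boundary depend on it.
* Reference tables are rounded published summaries; replicate-level
  instrument data are not available, so exact replication of those tables is
  limited to arithmetic over the printed values.
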