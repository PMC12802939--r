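#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs every later stage consumes.
#
# Emulated conditions: CD spectra (220-340 nm) for each conformation named in
# the construct panel, sigmoid melt/anneal ramps (25-95 degC) centered on each
# construct's reference Tm, 3-min smFRET trace sets and 2-s histogram movies
# at each construct's reference type fractions, and triplicate cleavage time
# courses on the 1-120 min grid. Everything is seeded and written as plain
# text under scratch/synthetic/ (bulky raw inputs; the stage scripts that
# follow write their summary tables under results/).

suppressPackageStartupMessages({
  library(teloG4)
  library(dplyr)
})

cfg <- run_config(overrides = list(seed = 20260925))
out <- file.path("scratch", "synthetic")
dir.create(file.path(out, "cd"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "melt"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "fret"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "cleavage"), recursive = TRUE, showWarnings = FALSE)
provenance_record(cfg, file.path(out, "provenance.json"))

panel <- telomere_panel()
constructs <- panel[!duplicated(panel$construct), ]

message("simulating CD spectra for ", nrow(constructs), " constructs")
for (i in seq_len(nrow(constructs))) {
  confs <- strsplit(constructs$conformation[i], ",")[[1]]
  weights <- stats::setNames(rep(1 / length(confs), length(confs)), confs)
  sp <- gen_cd_spectrum(weights, synth_config(seed = cfg$seed + i,
                                              cd_noise_sd = 0.02))
  sp$name <- constructs$construct[i]
  sp$cation <- "K"
  write_cd_spectrum_csv(sp, file.path(out, "cd",
                                      paste0(constructs$construct[i], ".csv")))
}

message("simulating melt/anneal ramps for every panel row")
for (i in seq_len(nrow(panel))) {
  tag <- if (is.na(panel$wavelength_nm[i])) panel$construct[i]
         else sprintf("%s_%gnm", panel$construct[i], panel$wavelength_nm[i])
  for (dir_ in c("melt", "anneal")) {
    mc <- gen_melting_curve(panel$tm[i],
                            synth_config(seed = cfg$seed + 100 + i,
                                         melt_noise_sd = 0.05),
                            direction = dir_, model = "sigmoid")
    mc$wavelength <- panel$wavelength_nm[i]
    write_melting_curve_csv(mc, file.path(out, "melt",
                                          sprintf("%s_%s.csv", tag, dir_)))
  }
}

message("simulating smFRET trace sets (5 repeats x 200 traces per construct)")
fret_constructs <- smfret_reference()$construct
fret_constructs <- fret_constructs[fret_constructs != "TEL-TTAG"]
labels_all <- list()
for (cn in fret_constructs) {
  p <- ref_trace_fractions(cn)
  for (r in 1:5) {
    g <- gen_fret_traces(200, synth_config(seed = cfg$seed + 7919L * r +
                                             match(cn, fret_constructs),
                                           type_fractions = p))
    write_fret_traces_tsv(g$traces,
                          file.path(out, "fret", sprintf("%s_rep%d.tsv", cn, r)))
    labels_all[[sprintf("%s_rep%d", cn, r)]] <-
      tibble(construct = cn, repeat_id = r,
             molecule_id = vapply(g$traces, `[[`, "", "molecule_id"),
             label = g$labels)
  }
}
write.table(bind_rows(labels_all),
            file.path(out, "fret", "ground_truth_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("simulating cleavage triplicates (saturating first-order shape)")
tc <- gen_cleavage_timecourse(synth_config(seed = cfg$seed + 5000),
                              replicates = 3, construct = "TELR22", cation = "K")
write_cleavage_tsv(tc, file.path(out, "cleavage", "TELR22_K.tsv"))

message("done; inputs under ", out)
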