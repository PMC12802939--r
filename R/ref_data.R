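#' Reference panel of rNMP-substituted telomeric constructs
#'
#' Published reference measurements for the (TTAGGG)4 construct panel: each
#' construct carries at most one ribonucleotide substitution (lowercase-r
#' notation), its CD-called conformation(s), and the melting temperature (Tm,
#' degC) extracted from CD melt ramps as the second-derivative root of a fitted
#' cubic, together with the Tm difference relative to the all-DNA TEL
#' construct. Two constructs (TELR4, TELR16) formed conformational mixtures
#' and were melted at two wavelengths, giving one row per monitored
#' wavelength, hence 19 rows for 17 constructs.
#'
#' Both the Tm and delta-Tm columns are replicate means rounded independently
#' to 0.01 degC, so recomputing the difference from the rounded Tm columns can
#' disagree with the printed difference by one unit in the last digit.
#'
#' @return A tibble with columns `construct`, `sequence`, `conformation`
#'   (comma-separated labels), `wavelength_nm` (monitored melt wavelength;
#'   `NA` when a single wavelength was used), `tm`, and `delta_tm`.
#' @export
telomere_panel <- function() {
  tibble::tribble(
    ~construct, ~sequence,                      ~conformation,                          ~wavelength_nm, ~tm,   ~delta_tm,
    "TEL",      "TTAGGGTTAGGGTTAGGGTTAGGG",     "hybrid_3plus1",                        NA,             58.86,  0.00,
    "TELR3",    "TTrAGGGTTAGGGTTAGGGTTAGGG",    "hybrid_3plus1",                        NA,             61.17,  2.31,
    "TELR4",    "TTArGGGTTAGGGTTAGGGTTAGGG",    "antiparallel_basket,hybrid_3plus1",    290,            55.69, -3.16,
    "TELR4",    "TTArGGGTTAGGGTTAGGGTTAGGG",    "antiparallel_basket,hybrid_3plus1",    275,            59.33,  0.48,
    "TELR5",    "TTAGrGGTTAGGGTTAGGGTTAGGG",    "hybrid_3plus1",                        NA,             57.35, -1.51,
    "TELR6",    "TTAGGrGTTAGGGTTAGGGTTAGGG",    "hybrid_3plus1",                        NA,             59.86,  1.01,
    "TELR9",    "TTAGGGTTrAGGGTTAGGGTTAGGG",    "hybrid_3plus1",                        NA,             60.77,  1.92,
    "TELR10",   "TTAGGGTTArGGGTTAGGGTTAGGG",    "antiparallel_basket",                  NA,             46.99, -11.87,
    "TELR11",   "TTAGGGTTAGrGGTTAGGGTTAGGG",    "hybrid_3plus1",                        NA,             57.16, -1.70,
    "TELR12",   "TTAGGGTTAGGrGTTAGGGTTAGGG",    "hybrid_3plus1",                        NA,             61.42,  2.56,
    "TELR15",   "TTAGGGTTAGGGTTrAGGGTTAGGG",    "hybrid_3plus1",                        NA,             60.34,  1.48,
    "TELR16",   "TTAGGGTTAGGGTTArGGGTTAGGG",    "parallel,antiparallel_chair",          270,            58.33, -0.53,
    "TELR16",   "TTAGGGTTAGGGTTArGGGTTAGGG",    "parallel,antiparallel_chair",          295,            57.95, -0.91,
    "TELR17",   "TTAGGGTTAGGGTTAGrGGTTAGGG",    "hybrid_3plus1",                        NA,             57.49, -1.37,
    "TELR18",   "TTAGGGTTAGGGTTAGGrGTTAGGG",    "hybrid_3plus1",                        NA,             61.38,  2.52,
    "TELR21",   "TTAGGGTTAGGGTTAGGGTTrAGGG",    "hybrid_3plus1",                        NA,             61.26,  2.40,
    "TELR22",   "TTAGGGTTAGGGTTAGGGTTArGGG",    "hybrid_3plus1,parallel",               NA,             58.37, -0.49,
    "TELR23",   "TTAGGGTTAGGGTTAGGGTTAGrGG",    "hybrid_3plus1",                        NA,             59.12,  0.27,
    "TELR24",   "TTAGGGTTAGGGTTAGGGTTAGGrG",    "hybrid_3plus1",                        NA,             59.40,  0.54
  )
}

#' Reference smFRET trace-type percentages and histogram peaks
#'
#' Published single-molecule reference values for the constructs studied by
#' smFRET: mean +/- SD percentage of traces classified static-folded,
#' dynamic, and unfolded across >= 5 experimental repeats (>= 900 traces per
#' construct), and the fitted Gaussian peak center and half-width of the
#' pooled FRET-efficiency histogram.
#'
#' @return A tibble with columns `construct`, `folded`, `folded_sd`,
#'   `dynamic`, `dynamic_sd`, `unfolded`, `unfolded_sd`, `peak_center`,
#'   `peak_center_sd`, `half_width`, `half_width_sd`.
#' @export
smfret_reference <- function() {
  tibble::tribble(
    ~construct, ~folded, ~folded_sd, ~dynamic, ~dynamic_sd, ~unfolded, ~unfolded_sd, ~peak_center, ~peak_center_sd, ~half_width, ~half_width_sd,
    "TELR9",    73.1, 9.43, 19.6, 2.88, 7.28, 5.28, 0.68,  0.01,  0.14, 0.01,
    "TELR10",   58.8, 4.87, 34.6, 4.87, 6.19, 3.11, 0.68,  0.02,  0.15, 0.01,
    "TELR11",   56.0, 3.87, 38.9, 2.96, 5.05, 2.68, 0.67,  0.01,  0.14, 0.01,
    "TELR12",   65.2, 3.05, 29.0, 4.57, 5.74, 3.75, 0.67,  0.01,  0.15, 0.01,
    "TELR21",   71.8, 3.45, 25.8, 2.70, 2.48, 1.41, 0.66,  0.01,  0.13, 0.01,
    "TELR22",   66.8, 2.79, 29.2, 2.79, 3.99, 1.84, 0.664, 0.012, 0.14, 0.01,
    "TELR23",   54.9, 2.48, 39.6, 1.95, 5.51, 1.27, 0.65,  0.01,  0.14, 0.01,
    "TELR24",   48.2, 4.87, 46.1, 2.36, 5.72, 4.16, 0.68,  0.01,  0.16, 0.01,
    "TEL",      74.3, 2.50, 17.8, 5.13, 7.89, 3.29, 0.67,  0.01,  0.14, 0.01,
    "TEL-TTAG", 67.9, 1.74, 29.6, 1.24, 2.25, 0.69, 0.65,  0.01,  0.12, 0.02
  )
}

#' Reference trace-type fractions for a construct, normalized to sum to 1
#'
#' Convenience accessor over [smfret_reference()] returning the
#' static/dynamic/unfolded percentages of one construct as fractions usable
#' as generator `type_fractions`.
#'
#' @param construct Construct name, e.g. `"TEL"` or `"TELR24"`.
#' @return Named numeric vector `c(static, dynamic, unfolded)` summing to 1.
#' @export
ref_trace_fractions <- function(construct) {
  ref <- smfret_reference()
  row <- ref[ref$construct == construct, ]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown construct '%s'", construct), call. = FALSE)
  }
  p <- c(static = row$folded, dynamic = row$dynamic, unfolded = row$unfolded)
  p / sum(p)
}

#' Reference RNase H2 cleavage percentages by cation
#'
#' Published percent-cleavage time courses (mean +/- SD over triplicates) for
#' each construct at 1, 5, 15, 30, 60, and 120 min in potassium or sodium
#' reaction buffer. Values below the assay's detection floor are recorded as
#' not detected (`detected = FALSE`, `mean_percent = NA`). The duplex control
#' (dsTELR10) was a single confirmation reaction (`sd_percent = NA`); three
#' sodium cells for TELR12 were likewise printed as single-replicate values,
#' and three sodium cells for TELR18 are missing entirely (`NA` mean with
#' `detected = NA`).
#'
#' @param cation `"K"` or `"Na"`.
#' @return A long tibble with columns `construct`, `cation`, `time_min`,
#'   `mean_percent`, `sd_percent`, `detected`.
#' @export
cleavage_reference <- function(cation = c("K", "Na")) {
  cation <- match.arg(cation)
  times <- c(1, 5, 15, 30, 60, 120)
  # one row per construct: list(mean vector, sd vector); NA mean = N.D.
  if (cation == "K") {
    cells <- list(
      dsTELR10 = list(m = c(96, 98, 99, 99, 99, 99),        s = rep(NA, 6)),
      TELR3    = list(m = rep(NA, 6),                       s = rep(NA, 6)),
      TELR4    = list(m = rep(NA, 6),                       s = rep(NA, 6)),
      TELR5    = list(m = rep(NA, 6),                       s = rep(NA, 6)),
      TELR6    = list(m = rep(NA, 6),                       s = rep(NA, 6)),
      TELR9    = list(m = c(6.5, 7, 6.8, 6.7, 7.6, 7.4),    s = c(1.1, 1.8, 1.1, 1, 2.7, 2.1)),
      TELR10   = list(m = c(2.4, 2.9, 3.8, 4.5, 6.3, 9.8),  s = c(0.7, 0.5, 0.3, 0.6, 0.3, 0.3)),
      TELR11   = list(m = c(1.9, 1.9, 1.4, 2.1, 2.1, 2.1),  s = c(1.2, 1.1, 0.7, 1.2, 1.1, 1.2)),
      TELR12   = list(m = c(0.6, 0.8, 0.7, 0.6, 1, 0.7),    s = c(1, 1.1, 1, 1, 1.4, 1.1)),
      TELR15   = list(m = c(6, 6.1, 6.6, 6.9, 8, 9.4),      s = c(0.1, 0.2, 0.3, 0.3, 0.4, 0.5)),
      TELR16   = list(m = c(2.3, 2.5, 3.3, 4, 5.4, 7.2),    s = c(1.2, 1.2, 1.6, 1.9, 2.4, 2.8)),
      TELR17   = list(m = c(1.8, 1.7, 1.9, 2.1, 2.3, 2.7),  s = c(1.1, 1, 1, 1.4, 1.4, 1.4)),
      TELR18   = list(m = c(0.2, NA, NA, NA, 0.2, 0.2),     s = c(0.3, NA, NA, NA, 0.3, 0.4)),
      TELR21   = list(m = c(4.6, 4.7, 4.7, 4.9, 5.2, 5.5),  s = c(2.2, 2, 2.3, 2.2, 2.2, 2.2)),
      TELR22   = list(m = c(1.8, 2.9, 5.2, 8.6, 13.4, 20.7), s = c(1.3, 1.8, 3, 2.9, 4.4, 4)),
      TELR23   = list(m = c(1.4, 1.4, 2.1, 1.1, 1.1, 1.2),  s = c(2.3, 1.9, 3, 1.5, 1.9, 2)),
      TELR24   = list(m = rep(NA, 6),                       s = rep(NA, 6))
    )
    missing_cells <- NULL
  } else {
    cells <- list(
      dsTELR10 = list(m = c(97, 98, 98, 99, 99, 99),            s = rep(NA, 6)),
      TELR3    = list(m = c(5.3, 9.4, 21.4, 29.2, 42.9, 58.5),  s = c(8.2, 4.6, 2.6, 2.3, 1, 0.6)),
      TELR4    = list(m = c(7.2, 10.4, 18.1, 26.2, 39.5, 54.1), s = c(6.4, 9, 4, 2.7, 1.4, 5.2)),
      TELR5    = list(m = rep(NA, 6),                           s = rep(NA, 6)),
      TELR6    = list(m = rep(NA, 6),                           s = rep(NA, 6)),
      TELR9    = list(m = c(13.5, 15.5, 20.6, 25.7, 33.5, 42.1), s = c(5.7, 6, 6.4, 5.5, 4.5, 4.4)),
      TELR10   = list(m = c(7.4, 20.9, 43.6, 63.4, 81.4, 92.6), s = c(3.9, 3, 1.4, 1, 3.3, 2.9)),
      TELR11   = list(m = c(3.8, 3.5, 3.8, 12.9, 10.6, 10.3),   s = c(5.2, 4.4, 4.3, 12.8, 9.4, 7.9)),
      TELR12   = list(m = c(7.5, 0.3, 0.6, 0.6, 9, 6.6),        s = c(6.6, NA, NA, NA, 7.2, 4.6)),
      TELR15   = list(m = c(14.8, 19.7, 30.9, 44.7, 61.2, 75.7), s = c(6.5, 5.1, 3.4, 1.4, 0.6, 1.8)),
      TELR16   = list(m = c(4.4, 8.1, 14.6, 19.4, 26.6, 38.4),  s = c(3, 2.9, 3.2, 3.7, 3.8, 5.8)),
      TELR17   = list(m = c(3.3, 3.8, 3.8, 4.7, 6.5, 9),        s = c(3.7, 4.1, 3.6, 3.6, 3.3, 3.2)),
      TELR18   = list(m = c(11.1, NA, NA, NA, 13.3, 9.3),       s = c(9.6, NA, NA, NA, 12.4, 8.1)),
      TELR21   = list(m = c(13.4, 16.7, 12.6, 15.7, 20.7, 22.9), s = c(10.4, 10.4, 5.6, 5.1, 5.6, 12.9)),
      TELR22   = list(m = c(12.4, 51.4, 87.9, 99.3, 99.9, 99.3), s = c(3.9, 1.5, 4.1, 0.6, 0.1, 1.1)),
      TELR23   = list(m = rep(NA, 6),                           s = rep(NA, 6)),
      TELR24   = list(m = rep(NA, 6),                           s = rep(NA, 6))
    )
    # blank (not N.D.) sodium cells: TELR18 at 5, 15, 30 min
    missing_cells <- data.frame(construct = "TELR18", time_min = c(5, 15, 30))
  }
  out <- dplyr::bind_rows(lapply(names(cells), function(cn) {
    tibble::tibble(
      construct = cn, cation = cation, time_min = times,
      mean_percent = as.numeric(cells[[cn]]$m),
      sd_percent = as.numeric(cells[[cn]]$s),
      detected = !is.na(cells[[cn]]$m)
    )
  }))
  if (!is.null(missing_cells)) {
    hit <- out$construct %in% missing_cells$construct &
      out$time_min %in% missing_cells$time_min
    out$detected[hit] <- NA
  }
  out
}
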