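# shared fixtures, built in code

conformations <- c("parallel", "antiparallel_chair", "antiparallel_basket",
                   "hybrid_3plus1")

quiet_cfg <- function(seed = 1L, ...) {
  synth_config(seed = seed, cd_noise_sd = 0, melt_noise_sd = 0,
               emission_noise_sd = 0, cleavage_noise_sd = 0, ...)
}

# independent extrema oracle: sign changes of the discrete first difference,
# no smoothing, no prominence gating
oracle_extrema <- function(wavelengths, y) {
  s <- sign(diff(y))
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(diff(s) != 0) + 1L
  data.frame(wavelength = wavelengths[idx],
             kind = ifelse(s[idx] < s[idx - 1L], "max", "min"))
}

# build a melting curve directly from arbitrary cubic coefficients
cubic_curve <- function(a, b, c_, d, temps = 25:95) {
  melting_curve(temps, a * temps^3 + b * temps^2 + c_ * temps + d)
}

label_vector <- function(traces, ...) {
  vapply(traces, function(tr) classify_trace(compute_fret(tr), ...)$label,
         character(1))
}
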