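#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the generators with the study's default
#' conditions: 220-340 nm CD spectra, 25-95 degC melting ramps, 100 ms/frame
#' smFRET records of 180 s (3 min) for trace typing or 2 s for histogram
#' movies, a folded-state efficiency of 0.67 (the pooled-histogram peak
#' center), an unfolded-state efficiency of 0.4, and saturating cleavage
#' kinetics whose defaults solve the first-order form through the strongest
#' potassium time course (13.4% at 60 min, 20.7% at 120 min).
#'
#' @param seed Integer seed; every generator is deterministic given
#'   (seed, parameters).
#' @param cd_noise_sd Per-wavelength Gaussian noise SD on CD spectra (mdeg).
#' @param cd_band_width Gaussian band sigma of the basis spectra (nm).
#' @param melt_width Sigmoid transition steepness (degC).
#' @param melt_noise_sd Noise SD on melting curves (mdeg).
#' @param theta_folded,theta_unfolded Ellipticity of the folded/unfolded
#'   baselines (mdeg).
#' @param fret_frame_interval Camera frame interval (s).
#' @param fret_duration Record length (s): 180 for trace records, 2 for
#'   histogram movies.
#' @param folded_mean,unfolded_mean State-mean FRET efficiencies.
#' @param emission_noise_sd Per-frame efficiency noise SD.
#' @param switch_rates Named rates per second,
#'   `c(fold_to_unfold = ..., unfold_to_fold = ...)`, for dynamic molecules.
#' @param type_fractions Probabilities `c(static, dynamic, unfolded)`;
#'   must be nonnegative and sum to 1 within 1e-9.
#' @param cleavage_rate First-order cleavage rate (per minute).
#' @param cleavage_plateau,burst_fraction Cleaved-fraction plateau and burst.
#' @param cleavage_noise_sd Noise SD on the cleaved fraction.
#' @param intensity_scale Arbitrary-unit scale for reconstructed
#'   donor/acceptor signals and gel band intensities.
#' @param detection_threshold Percent floor below which a replicate-mean
#'   cleavage value is reported as not detected.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         cd_noise_sd = 0,
                         cd_band_width = 12,
                         melt_width = 4,
                         melt_noise_sd = 0,
                         theta_folded = 10,
                         theta_unfolded = 1,
                         fret_frame_interval = 0.1,
                         fret_duration = 180,
                         folded_mean = 0.67,
                         unfolded_mean = 0.4,
                         emission_noise_sd = 0.05,
                         switch_rates = c(fold_to_unfold = 0.2,
                                          unfold_to_fold = 0.4),
                         type_fractions = c(static = 0.743,
                                            dynamic = 0.178,
                                            unfolded = 0.079),
                         cleavage_rate = 0.01,
                         cleavage_plateau = 0.295,
                         burst_fraction = 0,
                         cleavage_noise_sd = 0.04,
                         intensity_scale = 1000,
                         detection_threshold = 0.1) {
  type_fractions <- type_fractions / sum(type_fractions)
  cfg <- as.list(environment())
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, is.finite(cfg$seed))
  if (cfg$fret_frame_interval <= 0) {
    stop("fret_frame_interval must be > 0", call. = FALSE)
  }
  sds <- c(cfg$cd_noise_sd, cfg$melt_noise_sd, cfg$emission_noise_sd,
           cfg$cleavage_noise_sd)
  if (any(sds < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  tf <- cfg$type_fractions
  if (length(tf) != 3L || any(tf < 0) || abs(sum(tf) - 1) > 1e-9) {
    stop("type_fractions must be 3 nonnegative values summing to 1",
         call. = FALSE)
  }
  if (any(cfg$switch_rates <= 0) || length(cfg$switch_rates) != 2L) {
    stop("switch_rates must be two positive rates per second", call. = FALSE)
  }
  if (cfg$cleavage_plateau < 0 || cfg$cleavage_plateau > 1 ||
      cfg$burst_fraction < 0 || cfg$burst_fraction > 1) {
    stop("cleavage plateau and burst fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$cleavage_rate < 0) stop("cleavage_rate must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Generate a synthetic CD spectrum as a weighted conformational mixture
#'
#' The spectrum on the 220-340 nm grid (1 nm pitch) is the weighted sum of
#' the four Gaussian-band basis spectra ([cd_basis_matrix()]) plus zero-mean
#' Gaussian noise of SD `cd_noise_sd`. Zero noise makes the generator exactly
#' linear in the weights.
#'
#' @param weights Named nonnegative weights over `parallel`,
#'   `antiparallel_chair`, `antiparallel_basket`, `hybrid_3plus1` (missing
#'   names default to 0); at least one must be positive.
#' @param config A [synth_config()].
#' @param wavelengths Wavelength grid (nm).
#' @return A `cd_spectrum`.
#' @export
gen_cd_spectrum <- function(weights, config = synth_config(),
                            wavelengths = 220:340) {
  sigs <- g4_signatures()
  w <- stats::setNames(numeric(length(sigs)), names(sigs))
  if (is.null(names(weights)) && length(weights) == length(sigs)) {
    names(weights) <- names(sigs)
  }
  unknown <- setdiff(names(weights), names(sigs))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown conformation(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  w[names(weights)] <- weights
  if (any(w < 0)) stop("conformation weights must be nonnegative", call. = FALSE)
  if (all(w == 0)) stop("at least one conformation weight must be positive",
                        call. = FALSE)
  basis <- cd_basis_matrix(wavelengths, sigs, config$cd_band_width)
  set.seed(config$seed)
  y <- drop(basis %*% w) + stats::rnorm(length(wavelengths), 0, config$cd_noise_sd)
  cd_spectrum(wavelengths, y)
}

#' Generate a synthetic melting or annealing curve
#'
#' `model = "sigmoid"`: folded fraction `f(T) = 1 / (1 + exp((T - tm) /
#' melt_width))`, ellipticity `theta_unfolded + (theta_folded -
#' theta_unfolded) * f(T)` plus noise, sampled 25-95 degC at 1 degC. The
#' anneal direction reverses the temperature order only. `model = "cubic"`:
#' an exact third-order polynomial whose inflection point equals `tm`
#' (nonzero leading coefficient, no noise), for validating the
#' second-derivative-root extraction against a known answer.
#'
#' @param tm Target melting temperature (degC); must lie in \[25, 95\] for
#'   the sigmoid model.
#' @param config A [synth_config()].
#' @param direction `"melt"` or `"anneal"`.
#' @param model `"sigmoid"` or `"cubic"`.
#' @return A `melting_curve`.
#' @export
gen_melting_curve <- function(tm, config = synth_config(),
                              direction = c("melt", "anneal"),
                              model = c("sigmoid", "cubic")) {
  direction <- match.arg(direction)
  model <- match.arg(model)
  temps <- 25:95
  if (model == "sigmoid") {
    if (tm < 25 || tm > 95) stop("tm must lie in [25, 95] degC", call. = FALSE)
    if (config$melt_width <= 0) stop("melt_width must be > 0", call. = FALSE)
    f <- 1 / (1 + exp((temps - tm) / config$melt_width))
    set.seed(config$seed)
    y <- config$theta_unfolded +
      (config$theta_folded - config$theta_unfolded) * f +
      stats::rnorm(length(temps), 0, config$melt_noise_sd)
  } else {
    a <- -8e-4
    b <- -3 * a * tm
    c_ <- 3 * a * tm^2 - 0.25  # slope -0.25 mdeg/degC at the inflection
    d <- 5 - (a * tm^3 + b * tm^2 + c_ * tm)
    y <- a * temps^3 + b * temps^2 + c_ * temps + d
  }
  if (direction == "anneal") {
    temps <- rev(temps)
    y <- rev(y)
  }
  melting_curve(temps, y, wavelength = NA_real_, direction = direction)
}

#' Simulate single-molecule FRET trajectories with ground-truth labels
#'
#' Each molecule draws a behavioural type from `type_fractions`. Static
#' molecules emit `folded_mean` plus per-frame Gaussian noise; unfolded
#' molecules emit `unfolded_mean` plus noise; dynamic molecules follow a
#' two-state discrete-time Markov chain (per-frame switch probability
#' `1 - exp(-k * dt)`, initial state from the stationary distribution) with
#' state-dependent means. Per-frame donor and acceptor intensities are
#' reconstructed as `acceptor = intensity_scale * E` and `donor =
#' intensity_scale * (1 - E)` so that [compute_fret()] inverts them exactly.
#'
#' @param n Number of molecules (>= 1).
#' @param config A [synth_config()]; `fret_duration` / `fret_frame_interval`
#'   set the number of frames.
#' @return List with `traces` (list of `fret_trace`) and `labels` (character
#'   vector of ground-truth types: `"static_folded"`, `"dynamic"`,
#'   `"unfolded"`).
#' @export
gen_fret_traces <- function(n, config = synth_config()) {
  stopifnot(n >= 1)
  validate_synth_config(config)
  n_frames <- as.integer(round(config$fret_duration / config$fret_frame_interval))
  stopifnot(n_frames >= 1L)
  set.seed(config$seed)
  types <- sample(c("static_folded", "dynamic", "unfolded"), n, replace = TRUE,
                  prob = config$type_fractions)
  k_fu <- config$switch_rates[["fold_to_unfold"]]
  k_uf <- config$switch_rates[["unfold_to_fold"]]
  p_fu <- 1 - exp(-k_fu * config$fret_frame_interval)
  p_uf <- 1 - exp(-k_uf * config$fret_frame_interval)

  # state means per molecule per frame (TRUE = folded)
  folded <- matrix(TRUE, nrow = n_frames, ncol = n)
  folded[, types == "unfolded"] <- FALSE
  dyn <- which(types == "dynamic")
  if (length(dyn) > 0L) {
    p_stat <- k_uf / (k_uf + k_fu)  # stationary P(folded)
    state <- stats::runif(length(dyn)) < p_stat
    folded[1L, dyn] <- state
    for (f in seq_len(n_frames - 1L)) {
      u <- stats::runif(length(dyn))
      state <- ifelse(state, u >= p_fu, u < p_uf)
      folded[f + 1L, dyn] <- state
    }
  }
  e_true <- ifelse(folded, config$folded_mean, config$unfolded_mean)
  e_noisy <- e_true + matrix(stats::rnorm(n_frames * n, 0, config$emission_noise_sd),
                             nrow = n_frames)
  traces <- lapply(seq_len(n), function(i) {
    fret_trace(molecule_id = sprintf("mol%05d", i),
               donor = config$intensity_scale * (1 - e_noisy[, i]),
               acceptor = config$intensity_scale * e_noisy[, i],
               frame_interval = config$fret_frame_interval)
  })
  list(traces = traces, labels = types)
}

#' Simulate saturating RNase H2 cleavage time courses
#'
#' The true cleaved fraction follows `F(t) = burst + (plateau - burst) *
#' (1 - exp(-rate * t))`, clipped to \[0, 1\]. Per replicate and timepoint,
#' Gaussian noise of SD `cleavage_noise_sd` is added to the fraction
#' (truncated to \[0, 1\] so both band intensities stay nonnegative) and band
#' intensities are reconstructed as `cleaved = intensity_scale * F` and
#' `uncleaved = intensity_scale * (1 - F)`.
#'
#' @param config A [synth_config()].
#' @param timepoints Positive increasing times in minutes.
#' @param replicates Number of replicates (default 3).
#' @param construct,cation Metadata carried on the result.
#' @return List of `cleavage_timecourse` objects, one per replicate.
#' @export
gen_cleavage_timecourse <- function(config = synth_config(),
                                    timepoints = c(1, 5, 15, 30, 60, 120),
                                    replicates = 3,
                                    construct = "synthetic", cation = "K") {
  validate_synth_config(config)
  if (any(timepoints <= 0) || any(diff(timepoints) <= 0)) {
    stop("timepoints must be positive and increasing", call. = FALSE)
  }
  f_true <- config$burst_fraction +
    (config$cleavage_plateau - config$burst_fraction) *
    (1 - exp(-config$cleavage_rate * timepoints))
  f_true <- pmin(pmax(f_true, 0), 1)
  set.seed(config$seed)
  lapply(seq_len(replicates), function(r) {
    f <- f_true + stats::rnorm(length(timepoints), 0, config$cleavage_noise_sd)
    f <- pmin(pmax(f, 0), 1)
    cleavage_timecourse(
      construct = construct, cation = cation, replicate = r,
      time_min = timepoints,
      intensity_cleaved = config$intensity_scale * f,
      intensity_uncleaved = config$intensity_scale * (1 - f)
    )
  })
}
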