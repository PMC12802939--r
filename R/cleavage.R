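#' Fraction of substrate cleaved from gel band intensities
#'
#' Cleaved band intensity over total DNA content (cleaved plus uncleaved).
#' Scale-invariant: multiplying both intensities by any positive constant
#' leaves the fraction unchanged.
#'
#' @param intensity_cleaved,intensity_uncleaved Nonnegative band intensities
#'   (arbitrary units), vectorized.
#' @return Cleaved fraction(s) in \[0, 1\].
#' @export
percent_cleaved <- function(intensity_cleaved, intensity_uncleaved) {
  stopifnot(length(intensity_cleaved) == length(intensity_uncleaved))
  if (any(intensity_cleaved < 0) || any(intensity_uncleaved < 0)) {
    stop("band intensities must be nonnegative", call. = FALSE)
  }
  total <- intensity_cleaved + intensity_uncleaved
  if (any(total <= 0)) {
    stop("zero total intensity: cleaved fraction undefined", call. = FALSE)
  }
  intensity_cleaved / total
}

#' Construct a cleavage time course for one replicate
#'
#' @param construct Construct name.
#' @param cation `"K"` or `"Na"`.
#' @param replicate Replicate identifier.
#' @param time_min Strictly increasing times in minutes.
#' @param intensity_cleaved,intensity_uncleaved Band intensities per
#'   timepoint.
#' @return A `cleavage_timecourse`: tibble of measurements with the derived
#'   `percent` column, plus metadata attributes.
#' @export
cleavage_timecourse <- function(construct, cation, replicate, time_min,
                                intensity_cleaved, intensity_uncleaved) {
  stopifnot(cation %in% c("K", "Na"))
  if (any(diff(time_min) <= 0)) {
    stop("times must be strictly increasing within a replicate", call. = FALSE)
  }
  m <- tibble::tibble(
    time_min = time_min,
    intensity_cleaved = intensity_cleaved,
    intensity_uncleaved = intensity_uncleaved,
    percent = 100 * percent_cleaved(intensity_cleaved, intensity_uncleaved)
  )
  structure(m, class = c("cleavage_timecourse", class(m)),
            construct = construct, cation = cation, replicate = replicate)
}

#' Per-timepoint mean and SD of percent cleavage across replicates
#'
#' Replicates must share one time grid. Timepoints whose replicate-mean
#' percent falls below `detection_threshold` are reported as not detected
#' (`detected = FALSE`, mirroring gel assays where no product band is
#' visible), with the computed values retained.
#'
#' @param replicates List of `cleavage_timecourse` objects.
#' @param detection_threshold Percent floor for the not-detected flag
#'   (default 0.1).
#' @return Tibble with `time_min`, `mean_percent`, `sd_percent` (sample SD,
#'   n-1 denominator), `n`, `detected`.
#' @export
summarize_timecourse <- function(replicates, detection_threshold = 0.1) {
  stopifnot(length(replicates) >= 1L)
  grid <- replicates[[1]]$time_min
  same <- vapply(replicates, function(r) {
    length(r$time_min) == length(grid) && all(r$time_min == grid)
  }, logical(1))
  if (!all(same)) stop("replicates must share one time grid", call. = FALSE)
  pct <- vapply(replicates, function(r) r$percent, numeric(length(grid)))
  pct <- matrix(pct, nrow = length(grid))
  m <- rowMeans(pct)
  s <- apply(pct, 1, stats::sd)
  tibble::tibble(time_min = grid, mean_percent = m, sd_percent = s,
                 n = length(replicates), detected = m >= detection_threshold)
}

#' Group per-construct cleavage summaries by rNMP position class
#'
#' Constructs are grouped solely by the position class of their substitution
#' site ([classify_substitution()]); per class and timepoint, the mean over
#' member constructs is reported. Not-detected entries are treated as 0 when
#' `nd_as_zero` (no detectable product implies ~0 cleavage; excluding them
#' would bias class means upward) or excluded otherwise; the choice is
#' recorded in the output. Cells that are missing outright (`detected = NA`)
#' are always excluded.
#'
#' @param summaries Long tibble with columns `construct`, `time_min`,
#'   `mean_percent`, `detected` (e.g. from [summarize_timecourse()] rows
#'   bound per construct, or [cleavage_reference()]).
#' @param sites Named list of `substitution_site` objects (or a character
#'   vector of position classes), one per construct in `summaries`.
#' @param nd_as_zero Treat not-detected as 0 (default `TRUE`).
#' @return Tibble with `position_class`, `time_min`, `mean_percent`,
#'   `n_constructs`, `nd_rule`.
#' @export
group_by_position_class <- function(summaries, sites, nd_as_zero = TRUE) {
  class_of <- function(s) {
    if (inherits(s, "substitution_site")) s$position_class else as.character(s)
  }
  missing_sites <- setdiff(unique(summaries$construct), names(sites))
  if (length(missing_sites) > 0L) {
    stop(sprintf("no substitution site supplied for construct(s): %s",
                 paste(missing_sites, collapse = ", ")), call. = FALSE)
  }
  cls <- vapply(sites, class_of, character(1))
  df <- summaries
  df$position_class <- cls[df$construct]
  df$value <- df$mean_percent
  nd <- !is.na(df$detected) & !df$detected
  if (nd_as_zero) {
    df$value[nd] <- 0
  } else {
    df <- df[!nd, ]
  }
  df <- df[!is.na(df$value), ]
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$position_class, .data$time_min),
    mean_percent = mean(.data$value),
    n_constructs = dplyr::n_distinct(.data$construct),
    .groups = "drop"
  )
  out$nd_rule <- if (nd_as_zero) "nd_as_zero" else "nd_excluded"
  out
}

#' First-order saturation fit to a cleavage time course
#'
#' Least-squares fit of `F(t) = burst + (plateau - burst) * (1 - exp(-k t))`
#' to per-timepoint mean cleaved fractions, with `k >= 0` and both fractions
#' bounded to \[0, 1\]. A descriptive fit: it summarizes the shape of a time
#' course in three interpretable numbers.
#'
#' @param summary Tibble with `time_min` and `mean_percent` columns (>= 4
#'   timepoints), as from [summarize_timecourse()].
#' @return Named list with `rate` (per minute), `plateau`, `burst`
#'   (fractions).
#' @export
fit_first_order <- function(summary) {
  stopifnot(all(c("time_min", "mean_percent") %in% names(summary)))
  t <- summary$time_min
  f <- summary$mean_percent / 100
  keep <- !is.na(f)
  t <- t[keep]; f <- f[keep]
  if (length(t) < 4L) stop("need at least 4 timepoints", call. = FALSE)
  if (all(f == f[1])) {
    # flat series: saturated from the start (or flat zero)
    return(list(rate = 0, plateau = f[1], burst = f[1]))
  }
  dat <- data.frame(t = t, f = f)
  start <- list(burst = max(0, min(f)), plateau = max(f),
                k = 1 / stats::median(t))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12, ptol = 1e-12)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ burst + (plateau - burst) * (1 - exp(-k * t)), data = dat,
      start = start,
      lower = c(burst = 0, plateau = 0, k = 0),
      upper = c(burst = 1, plateau = 1, k = Inf),
      control = ctrl
    ),
    # the bounded solver can fail on exactly-saturating (zero-residual) data;
    # refit unbounded and clamp into the physical range
    error = function(e) {
      tryCatch(
        minpack.lm::nlsLM(
          f ~ burst + (plateau - burst) * (1 - exp(-k * t)), data = dat,
          start = start, control = ctrl
        ),
        error = function(e2) {
          stop(sprintf("first-order fit failed to converge: %s",
                       conditionMessage(e2)), call. = FALSE)
        }
      )
    }
  )
  cf <- stats::coef(fit)
  clamp01 <- function(x) min(max(x, 0), 1)
  list(rate = max(cf[["k"]], 0), plateau = clamp01(cf[["plateau"]]),
       burst = clamp01(cf[["burst"]]))
}

#' Sodium-minus-potassium cleavage differences by position class
#'
#' Pairs class summaries obtained in sodium and potassium and reports the
#' per-class, per-timepoint difference in mean percent cleavage (descriptive;
#' no hypothesis test).
#'
#' @param k_summary,na_summary Class-summary tibbles from
#'   [group_by_position_class()] with matching classes and time grids.
#' @return Tibble with `position_class`, `time_min`, `k_percent`,
#'   `na_percent`, `difference` (Na minus K).
#' @export
compare_cations <- function(k_summary, na_summary) {
  if (nrow(k_summary) == 0L || nrow(na_summary) == 0L) {
    stop("empty class summary", call. = FALSE)
  }
  k <- dplyr::select(k_summary, "position_class", "time_min",
                     k_percent = "mean_percent")
  na <- dplyr::select(na_summary, "position_class", "time_min",
                      na_percent = "mean_percent")
  only_k <- dplyr::anti_join(k, na, by = c("position_class", "time_min"))
  only_na <- dplyr::anti_join(na, k, by = c("position_class", "time_min"))
  if (nrow(only_k) > 0L || nrow(only_na) > 0L) {
    stop("class/timepoint sets do not match between cations", call. = FALSE)
  }
  out <- dplyr::inner_join(k, na, by = c("position_class", "time_min"))
  out$difference <- out$na_percent - out$k_percent
  out
}
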