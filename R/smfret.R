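#' Construct a single-molecule FRET trace
#'
#' @param molecule_id Identifier.
#' @param donor,acceptor Per-frame donor emission and acceptor emission under
#'   donor excitation (arbitrary units), equal length >= 1.
#' @param frame_interval Frame interval in seconds (default 0.1, i.e. 100 ms).
#' @return A `fret_trace` object.
#' @export
fret_trace <- function(molecule_id, donor, acceptor, frame_interval = 0.1) {
  stopifnot(length(donor) == length(acceptor), length(donor) >= 1L,
            frame_interval > 0)
  structure(list(molecule_id = molecule_id,
                 donor = as.numeric(donor), acceptor = as.numeric(acceptor),
                 frame_interval = frame_interval),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("<fret_trace %s> %d frames at %g s/frame\n",
              x$molecule_id, length(x$donor), x$frame_interval))
  invisible(x)
}

#' Per-frame FRET efficiency
#'
#' `E = acceptor / (acceptor + donor)`, the acceptor signal under donor
#' excitation over the total emission, with no crosstalk or gamma
#' correction. Frames with nonpositive total intensity are invalid and
#' returned as `NA` (they are dropped, not zero-filled, downstream).
#'
#' @param trace A `fret_trace`.
#' @return Numeric efficiency vector, `NA` at invalid frames.
#' @export
compute_fret <- function(trace) {
  stopifnot(inherits(trace, "fret_trace"))
  total <- trace$donor + trace$acceptor
  e <- ifelse(total > 0, trace$acceptor / total, NA_real_)
  if (all(is.na(e))) {
    stop(sprintf("trace %s has no valid frame (nonpositive total intensity throughout)",
                 trace$molecule_id), call. = FALSE)
  }
  e
}

#' Pool short-movie traces into a FRET-efficiency histogram
#'
#' All valid frames of all molecules across all movies are pooled into
#' fixed-width bins spanning `range`.
#'
#' @param movies A list of movies, each a list of `fret_trace` objects
#'   (a flat list of traces is treated as a single movie).
#' @param bin_width Bin width in efficiency units (default 0.02).
#' @param range Histogram support (default `c(-0.2, 1.2)`).
#' @return A `fret_histogram`: list with `bin_edges`, `counts`,
#'   `n_molecules`, `n_movies`. Frames outside `range` are excluded.
#' @export
build_histogram <- function(movies, bin_width = 0.02, range = c(-0.2, 1.2)) {
  if (bin_width <= 0) stop("bin width must be positive", call. = FALSE)
  if (length(movies) >= 1L && inherits(movies[[1]], "fret_trace")) {
    movies <- list(movies)
  }
  stopifnot(length(movies) >= 1L)
  traces <- unlist(movies, recursive = FALSE)
  e <- unlist(lapply(traces, compute_fret))
  e <- e[!is.na(e) & e >= range[1] & e <= range[2]]
  edges <- seq(range[1], range[2] + bin_width, by = bin_width)
  counts <- as.integer(table(cut(e, breaks = edges, right = FALSE,
                                 include.lowest = FALSE)))
  structure(list(bin_edges = edges, counts = counts,
                 n_molecules = length(traces), n_movies = length(movies)),
            class = "fret_histogram")
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat(sprintf("<fret_histogram> %d frames from %d molecules in %d movies, %d bins\n",
              sum(x$counts), x$n_molecules, x$n_movies, length(x$counts)))
  invisible(x)
}

#' Fit a single Gaussian to a FRET-efficiency histogram
#'
#' Least-squares fit of `A * exp(-(x - center)^2 / (2 * half_width^2))` to
#' bin centers vs counts, initialized at the histogram mode. The reported
#' half-width is the fitted Gaussian sigma (the fit's native scale
#' parameter; multiply by 1.177 for HWHM).
#'
#' @param hist A `fret_histogram` with at least 5 nonzero bins.
#' @return A `gaussian_peak`: list with `center`, `half_width`, `amplitude`.
#' @export
fit_gaussian_peak <- function(hist) {
  stopifnot(inherits(hist, "fret_histogram"))
  if (sum(hist$counts > 0) < 5L) {
    stop("need at least 5 nonzero bins to fit a peak", call. = FALSE)
  }
  mids <- (hist$bin_edges[-1] + hist$bin_edges[-length(hist$bin_edges)]) / 2
  counts <- hist$counts
  i0 <- which.max(counts)
  dat <- data.frame(x = mids, y = counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)), data = dat,
      start = list(A = counts[i0], mu = mids[i0], sigma = 0.1),
      lower = c(A = 0, mu = min(mids), sigma = 1e-4),
      upper = c(A = Inf, mu = max(mids), sigma = diff(range(mids))),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop(sprintf("Gaussian peak fit failed to converge: %s (mode at %.3f, %d nonzero bins)",
                   conditionMessage(e), mids[i0], sum(counts > 0)), call. = FALSE)
    }
  )
  cf <- stats::coef(fit)
  structure(list(center = cf[["mu"]], half_width = cf[["sigma"]],
                 amplitude = cf[["A"]]),
            class = "gaussian_peak")
}

#' @export
print.gaussian_peak <- function(x, ...) {
  cat(sprintf("<gaussian_peak> center %.3f, half-width (sigma) %.3f, amplitude %.1f\n",
              x$center, x$half_width, x$amplitude))
  invisible(x)
}

# persistence filter: a state change is accepted only when the new state
# lasts at least min_dwell frames, so sub-dwell noise runs are absorbed into
# the surrounding state instead of accumulating into spurious excursions
filter_excursions <- function(above, min_dwell) {
  r <- rle(above)
  if (length(r$lengths) <= 1L) return(above)
  long <- which(r$lengths >= min_dwell)
  if (length(long) == 0L) {
    # no persistent run at all: treat the whole trace as its majority state
    return(rep(mean(above) >= 0.5, length(above)))
  }
  state <- r$values[long[1]]  # runs before the first persistent run join it
  out_states <- logical(length(r$lengths))
  for (i in seq_along(r$lengths)) {
    if (r$lengths[i] >= min_dwell) state <- r$values[i]
    out_states[i] <- state
  }
  out_states[seq_len(long[1])] <- r$values[long[1]]
  inverse.rle(list(lengths = r$lengths, values = out_states))
}

#' Classify a FRET trace as static-folded, dynamic, or unfolded
#'
#' Frames are binarized at `threshold` (efficiency >= threshold counts as
#' folded); runs shorter than `min_dwell` frames are absorbed into the
#' surrounding state, emulating the noise tolerance of manual trace
#' categorization. After filtering: all frames above -> `static_folded`, all
#' below -> `unfolded`, otherwise `dynamic`.
#'
#' @param efficiency Per-frame efficiency series (`NA` frames are dropped).
#' @param threshold Folded/unfolded cutoff (default 0.6).
#' @param min_dwell Minimum dwell in frames (default 5, i.e. 0.5 s at
#'   100 ms/frame).
#' @return A `trace_classification`: list with `label`, `n_excursions`
#'   (state changes after filtering), `fraction_above`.
#' @export
classify_trace <- function(efficiency, threshold = 0.6, min_dwell = 5) {
  e <- efficiency[!is.na(efficiency)]
  if (length(e) == 0L) stop("empty efficiency series", call. = FALSE)
  above <- e >= threshold
  above <- filter_excursions(above, min_dwell)
  n_exc <- sum(diff(above) != 0)
  frac <- mean(above)
  label <- if (all(above)) "static_folded"
  else if (!any(above)) "unfolded"
  else "dynamic"
  structure(list(label = label, n_excursions = n_exc, fraction_above = frac),
            class = "trace_classification")
}

#' @export
print.trace_classification <- function(x, ...) {
  cat(sprintf("<trace_classification> %s (%d excursions, %.1f%% of frames above threshold)\n",
              x$label, x$n_excursions, 100 * x$fraction_above))
  invisible(x)
}

#' Aggregate trace classifications across experimental repeats
#'
#' @param classified List of repeats, each a list of `trace_classification`
#'   objects or a character vector of labels.
#' @param construct Construct name carried on the result.
#' @return A `dynamics_summary`: list with `construct`, `per_repeat`
#'   (percentage matrix, repeats x labels), `summary` (tibble of label,
#'   mean_pct, sd_pct with sample SD, n-1 denominator), and `n_traces`.
#' @export
summarize_dynamics <- function(classified, construct = NA_character_) {
  stopifnot(length(classified) >= 1L)
  labels <- c("static_folded", "dynamic", "unfolded")
  per_repeat <- t(vapply(seq_along(classified), function(r) {
    rep_r <- classified[[r]]
    lab <- if (is.character(rep_r)) rep_r
    else vapply(rep_r, function(x) x$label, character(1))
    if (length(lab) == 0L) {
      stop(sprintf("repeat %d contains no traces", r), call. = FALSE)
    }
    bad <- setdiff(unique(lab), labels)
    if (length(bad) > 0L) {
      stop(sprintf("repeat %d has unknown label(s): %s", r,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    100 * vapply(labels, function(l) mean(lab == l), numeric(1))
  }, numeric(3)))
  colnames(per_repeat) <- labels
  n_traces <- sum(vapply(classified, length, integer(1)))
  summary <- tibble::tibble(
    label = labels,
    mean_pct = unname(apply(per_repeat, 2, mean)),
    sd_pct = unname(apply(per_repeat, 2, stats::sd))
  )
  structure(list(construct = construct, per_repeat = per_repeat,
                 summary = summary, n_traces = n_traces),
            class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf("<dynamics_summary%s> %d traces in %d repeats\n",
              if (is.na(x$construct)) "" else paste0(" ", x$construct),
              x$n_traces, nrow(x$per_repeat)))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-14s %5.1f +/- %.2f %%\n", x$summary$label[i],
                x$summary$mean_pct[i], x$summary$sd_pct[i]))
  }
  invisible(x)
}
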