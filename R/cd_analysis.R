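#' Construct a CD spectrum object
#'
#' @param wavelengths Strictly increasing wavelength grid (nm), typically
#'   220-340 at 1 nm pitch.
#' @param ellipticity Ellipticity (mdeg), one value per wavelength.
#' @param name,cation,temperature Optional metadata (`cation` is `"K"` or
#'   `"Na"`, `temperature` in degC).
#' @return A `cd_spectrum` object.
#' @export
cd_spectrum <- function(wavelengths, ellipticity, name = NULL,
                        cation = NULL, temperature = NULL) {
  stopifnot(is.numeric(wavelengths), is.numeric(ellipticity))
  if (length(wavelengths) != length(ellipticity)) {
    stop("wavelengths and ellipticity must have equal length", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (!is.null(cation)) stopifnot(cation %in% c("K", "Na"))
  structure(
    list(wavelengths = wavelengths, ellipticity = as.numeric(ellipticity),
         name = name, cation = cation, temperature = temperature),
    class = "cd_spectrum"
  )
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<cd_spectrum%s> %d points, %g-%g nm, range [%.3g, %.3g] mdeg\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              min(x$ellipticity), max(x$ellipticity)))
  invisible(x)
}

#' Spectral signatures of the four intramolecular G-quadruplex conformations
#'
#' Characteristic CD extrema (nm) used both to synthesize basis spectra and
#' to call conformations: parallel (max ~265, min ~240), antiparallel 2+2
#' chair (max ~290, min ~265), antiparallel 2+2 basket (maxima ~250 and ~290,
#' minima ~235 and ~265), and 3+1 hybrid (maxima ~265 and ~290, minima ~240
#' and ~275).
#'
#' @param tolerance Matching tolerance in nm applied when comparing observed
#'   extrema to signature positions (default 8; the "~" positions drift
#'   several nm between variants).
#' @return Named list of signatures, each a list with `label`, `maxima`,
#'   `minima`, `tolerance`.
#' @export
g4_signatures <- function(tolerance = 8) {
  sig <- function(label, maxima, minima) {
    list(label = label, maxima = maxima, minima = minima, tolerance = tolerance)
  }
  list(
    parallel            = sig("parallel",            265,          240),
    antiparallel_chair  = sig("antiparallel_chair",  290,          265),
    antiparallel_basket = sig("antiparallel_basket", c(250, 290),  c(235, 265)),
    hybrid_3plus1       = sig("hybrid_3plus1",       c(265, 290),  c(240, 275))
  )
}

#' Gaussian-band basis spectra for the four conformations
#'
#' Each basis spectrum is a sum of unit-amplitude Gaussian bands centered at
#' the signature's maxima (+1) and minima (-1), with a common band-width
#' parameter (Gaussian sigma, nm).
#'
#' @param wavelengths Wavelength grid (nm).
#' @param signatures Signature list from [g4_signatures()].
#' @param band_width Gaussian band sigma in nm (default 12).
#' @return Numeric matrix, one column per conformation.
#' @export
cd_basis_matrix <- function(wavelengths, signatures = g4_signatures(),
                            band_width = 12) {
  stopifnot(band_width > 0)
  band_sum <- function(centers, sign) {
    if (length(centers) == 0L) return(numeric(length(wavelengths)))
    rowSums(vapply(centers, function(c0) {
      sign * exp(-(wavelengths - c0)^2 / (2 * band_width^2))
    }, numeric(length(wavelengths))))
  }
  basis <- vapply(signatures, function(s) {
    band_sum(s$maxima, +1) + band_sum(s$minima, -1)
  }, numeric(length(wavelengths)))
  colnames(basis) <- names(signatures)
  basis
}

#' Average replicate scans and subtract the buffer baseline
#'
#' @param sample_scans,buffer_scans Lists of `cd_spectrum` objects sharing
#'   one wavelength grid. `buffer_scans` may be an empty list.
#' @return A `cd_spectrum`: pointwise mean of the sample scans minus
#'   pointwise mean of the buffer scans.
#' @export
average_and_subtract <- function(sample_scans, buffer_scans = list()) {
  stopifnot(length(sample_scans) >= 1L)
  scans <- c(sample_scans, buffer_scans)
  grid <- sample_scans[[1]]$wavelengths
  ok <- vapply(scans, function(s) {
    length(s$wavelengths) == length(grid) && all(s$wavelengths == grid)
  }, logical(1))
  if (!all(ok)) {
    stop("all scans must share one wavelength grid", call. = FALSE)
  }
  mean_of <- function(lst) {
    if (length(lst) == 0L) return(numeric(length(grid)))
    rowMeans(vapply(lst, function(s) s$ellipticity, numeric(length(grid))))
  }
  cd_spectrum(grid, mean_of(sample_scans) - mean_of(buffer_scans),
              name = sample_scans[[1]]$name, cation = sample_scans[[1]]$cation,
              temperature = sample_scans[[1]]$temperature)
}

moving_average <- function(y, k) {
  if (k <= 1L) return(y)
  n <- length(y)
  out <- numeric(n)
  h <- k %/% 2L
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- mean(y[lo:hi])
  }
  out
}

# prominence of the extremum at index i: height above the higher of the two
# base levels, where each base is the lowest point between the peak and the
# nearest higher point (or the boundary) on that side; minima via negation
peak_prominence <- function(y, i) {
  n <- length(y)
  base_side <- function(idx_range) {
    if (length(idx_range) == 0L) return(y[i])
    higher <- which(y[idx_range] > y[i])
    if (length(higher) > 0L) {
      # restrict to the stretch up to the nearest higher point
      idx_range <- idx_range[seq_len(min(higher) - 1L)]
      if (length(idx_range) == 0L) return(y[i])
    }
    min(y[idx_range])
  }
  left <- base_side(rev(seq_len(i - 1L)))
  right <- base_side(if (i < n) (i + 1L):n else integer(0))
  y[i] - max(left, right)
}

#' Locate local extrema of a CD spectrum
#'
#' Finds local maxima and minima of the (optionally moving-average smoothed)
#' ellipticity whose topographic prominence reaches `min_prominence`.
#'
#' @param spectrum A `cd_spectrum` whose grid covers at least 230-300 nm.
#' @param smooth_window Moving-average window in nm (0 = no smoothing, the
#'   default: averaged 1-nm-pitch scans are already smooth).
#' @param min_prominence Minimum prominence in mdeg; default 5% of the
#'   spectrum's maximum absolute ellipticity.
#' @return Tibble with columns `wavelength`, `ellipticity`, `kind`
#'   (`"max"`/`"min"`), sorted by wavelength; zero rows when no extremum
#'   qualifies.
#' @export
find_extrema <- function(spectrum, smooth_window = 0, min_prominence = NULL) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  wl <- spectrum$wavelengths
  if (min(wl) > 230 || max(wl) < 300) {
    stop("wavelength grid must cover at least 230-300 nm", call. = FALSE)
  }
  pitch <- stats::median(diff(wl))
  k <- max(1L, as.integer(round(smooth_window / pitch)))
  if (smooth_window > diff(range(wl))) {
    stop("smoothing window larger than the wavelength grid", call. = FALSE)
  }
  y <- moving_average(spectrum$ellipticity, k)
  if (is.null(min_prominence)) {
    min_prominence <- 0.05 * max(abs(y))
  }
  n <- length(y)
  if (n < 3L || all(y == y[1])) {
    return(tibble::tibble(wavelength = numeric(0), ellipticity = numeric(0),
                          kind = character(0)))
  }
  # sign of the first difference, carrying the last nonzero sign over plateaus
  s <- sign(diff(y))
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  idx <- which(diff(s) != 0) + 1L
  rows <- lapply(idx, function(i) {
    kind <- if (s[i] < s[i - 1L]) "max" else "min"
    prom <- if (kind == "max") peak_prominence(y, i) else peak_prominence(-y, i)
    if (prom >= min_prominence) {
      tibble::tibble(wavelength = wl[i], ellipticity = y[i], kind = kind)
    } else NULL
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(wavelength = numeric(0), ellipticity = numeric(0),
                          kind = character(0)))
  }
  dplyr::arrange(out, .data$wavelength)
}

signature_score <- function(signature, extrema) {
  hit <- function(positions, kind) {
    if (length(positions) == 0L) return(logical(0))
    obs <- extrema$wavelength[extrema$kind == kind]
    vapply(positions, function(p) {
      length(obs) > 0L && min(abs(obs - p)) <= signature$tolerance
    }, logical(1))
  }
  hits <- c(hit(signature$maxima, "max"), hit(signature$minima, "min"))
  mean(hits)
}

has_extremum <- function(extrema, kind, position, tolerance) {
  obs <- extrema$wavelength[extrema$kind == kind]
  length(obs) > 0L && min(abs(obs - position)) <= tolerance
}

# TRUE when s1's required extrema are a subset of s2's (positions compared
# within tolerance)
signature_subset <- function(s1, s2) {
  within <- function(a, b) {
    all(vapply(a, function(p) any(abs(b - p) <= s1$tolerance), logical(1)))
  }
  length(s1$maxima) + length(s1$minima) <
    length(s2$maxima) + length(s2$minima) &&
    within(s1$maxima, s2$maxima) && within(s1$minima, s2$minima)
}

#' Call G-quadruplex conformation(s) from a CD spectrum
#'
#' Two complementary readouts are combined. (1) Signature matching: each
#' conformation is scored by the fraction of its required extrema matched by
#' an observed extremum of the correct kind within the signature tolerance;
#' signatures with score >= `threshold` are candidates, with tie rules
#' preferring the more specific signature (e.g. hybrid over its parallel
#' sub-signature) when the dropped signature has no independent support.
#' (2) Nonnegative least-squares decomposition of the spectrum onto the four
#' Gaussian-band basis spectra; conformations with weight share >=
#' `share_min` are supported. The default `"combined"` method calls the
#' extrema candidates confirmed by decomposition, falling back to the
#' decomposition alone when no signature passes the extrema threshold (as
#' happens for mixtures whose overlapping bands of opposite sign cancel, e.g.
#' parallel + antiparallel chair around 265 nm). `"extrema"` uses signature
#' matching only, with the tie rules: an observed superset of the hybrid
#' signature is called hybrid; 265/290 maxima with a 265 minimum but no 275
#' minimum are called parallel + chair.
#'
#' @param spectrum A `cd_spectrum`.
#' @param signatures Signature list, see [g4_signatures()].
#' @param threshold Extrema-score calling threshold (default 0.75).
#' @param share_min Minimum decomposition weight share (default 0.2).
#' @param band_width Basis band sigma (nm) for the decomposition.
#' @param method `"combined"` (default) or `"extrema"`.
#' @param ... Passed to [find_extrema()].
#' @return A `conformation_call`: list with `called` (character vector, empty
#'   if unclassifiable), `scores` (extrema match fraction per signature),
#'   `shares` (decomposition weight shares; `NA` for `method = "extrema"`),
#'   `mixture_flag`, and `unclassifiable`.
#' @export
classify_conformation <- function(spectrum, signatures = g4_signatures(),
                                  threshold = 0.75, share_min = 0.2,
                                  band_width = 12,
                                  method = c("combined", "extrema"), ...) {
  method <- match.arg(method)
  extrema <- find_extrema(spectrum, ...)
  scores <- vapply(signatures, signature_score, numeric(1), extrema = extrema)
  result <- function(called, shares = rep(NA_real_, length(signatures))) {
    names(shares) <- names(signatures)
    structure(list(called = called, scores = scores, shares = shares,
                   mixture_flag = length(called) > 1L,
                   unclassifiable = length(called) == 0L),
              class = "conformation_call")
  }
  if (nrow(extrema) == 0L) {
    return(result(character(0)))
  }

  passing <- names(signatures)[scores >= threshold]

  if (method == "extrema") {
    tol <- signatures[[1]]$tolerance
    # parallel + chair pattern: 265/290 maxima, 265 minimum, no 275 minimum
    if (!("hybrid_3plus1" %in% passing) &&
        has_extremum(extrema, "max", 265, tol) &&
        has_extremum(extrema, "max", 290, tol) &&
        has_extremum(extrema, "min", 265, tol) &&
        !has_extremum(extrema, "min", 275, tol)) {
      return(result(c("parallel", "antiparallel_chair")))
    }
    keep <- vapply(passing, function(nm) {
      !any(vapply(setdiff(passing, nm), function(other) {
        signature_subset(signatures[[nm]], signatures[[other]])
      }, logical(1)))
    }, logical(1))
    return(result(passing[keep]))
  }

  # combined: decomposition shares arbitrate
  basis <- cd_basis_matrix(spectrum$wavelengths, signatures, band_width)
  w <- pracma::lsqnonneg(basis, spectrum$ellipticity)$x
  shares <- if (sum(w) > 0) w / sum(w) else rep(0, length(w))
  names(shares) <- names(signatures)

  supported <- names(signatures)[shares >= share_min]
  if (length(passing) > 0L) {
    # drop a passing signature nested in another passing one only when the
    # decomposition lends it no independent support
    keep <- vapply(passing, function(nm) {
      nested <- any(vapply(setdiff(passing, nm), function(other) {
        signature_subset(signatures[[nm]], signatures[[other]])
      }, logical(1)))
      !nested || shares[nm] >= share_min
    }, logical(1))
    called <- intersect(passing[keep], supported)
    if (length(called) > 0L) {
      return(result(called, shares))
    }
  }
  result(supported, shares)
}

#' @export
print.conformation_call <- function(x, ...) {
  if (x$unclassifiable) {
    cat("<conformation_call> unclassifiable\n")
  } else {
    cat(sprintf("<conformation_call> %s%s\n", paste(x$called, collapse = " + "),
                if (x$mixture_flag) " (mixture)" else ""))
  }
  cat("  extrema scores:", paste(sprintf("%s=%.2f", names(x$scores), x$scores),
                                 collapse = ", "), "\n")
  if (!all(is.na(x$shares))) {
    cat("  decomposition shares:",
        paste(sprintf("%s=%.2f", names(x$shares), x$shares), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Choose the wavelength at which to monitor a melting ramp
#'
#' The melt is monitored at the wavelength of maximum ellipticity, unless an
#' explicit override is given (used for mixture constructs melted at a
#' conformation-specific wavelength).
#'
#' @param spectrum A `cd_spectrum`.
#' @param override Optional wavelength (nm) returned as-is.
#' @return Wavelength in nm.
#' @export
pick_melt_wavelength <- function(spectrum, override = NULL) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  if (!is.null(override)) return(override)
  spectrum$wavelengths[which.max(spectrum$ellipticity)]
}

#' Construct a melting (or annealing) curve object
#'
#' @param temperatures Temperatures in degC, monotone increasing for
#'   `direction = "melt"` and decreasing for `"anneal"`.
#' @param ellipticity Ellipticity (mdeg) at the monitored wavelength.
#' @param wavelength Monitored wavelength (nm).
#' @param direction `"melt"` or `"anneal"`.
#' @return A `melting_curve` object.
#' @export
melting_curve <- function(temperatures, ellipticity, wavelength = NA_real_,
                          direction = c("melt", "anneal")) {
  direction <- match.arg(direction)
  stopifnot(length(temperatures) == length(ellipticity))
  d <- diff(temperatures)
  if (direction == "melt" && any(d <= 0)) {
    stop("melt temperatures must be strictly increasing", call. = FALSE)
  }
  if (direction == "anneal" && any(d >= 0)) {
    stop("anneal temperatures must be strictly decreasing", call. = FALSE)
  }
  structure(list(temperatures = temperatures,
                 ellipticity = as.numeric(ellipticity),
                 wavelength = wavelength, direction = direction),
            class = "melting_curve")
}

#' Melting temperature as the second-derivative root of a fitted cubic
#'
#' Fits a third-order polynomial `a*T^3 + b*T^2 + c*T + d` to ellipticity vs
#' temperature by least squares (internally on centered temperatures for
#' conditioning, reported in raw coordinates) and returns the unique root of
#' its second derivative, Tm = -b / (3a).
#'
#' @param curve A `melting_curve`.
#' @param window Optional `c(lo, hi)` temperature window (degC) restricting
#'   the fit; default is the full recorded ramp.
#' @param auto_window If `TRUE`, fit within `window_halfwidth` degC of the
#'   steepest-slope temperature; reduces the asymmetry bias of a cubic fitted
#'   to a sigmoid whose transition sits off-center in the ramp.
#' @param window_halfwidth Half-width of the automatic window (default 15).
#' @return A `melt_result`: list with `tm`, `coefficients` (a, b, c, d),
#'   `wavelength`, `direction`, `window`, `n_points`.
#' @export
fit_cubic_tm <- function(curve, window = NULL, auto_window = FALSE,
                         window_halfwidth = 15) {
  stopifnot(inherits(curve, "melting_curve"))
  temp <- curve$temperatures
  y <- curve$ellipticity
  ord <- order(temp)
  temp <- temp[ord]; y <- y[ord]
  if (auto_window && is.null(window)) {
    slope <- diff(y) / diff(temp)
    slope <- moving_average(slope, 5L)
    mid <- (temp[-1] + temp[-length(temp)]) / 2
    t_star <- mid[which.max(abs(slope))]
    window <- c(t_star - window_halfwidth, t_star + window_halfwidth)
  }
  if (!is.null(window)) {
    keep <- temp >= window[1] & temp <= window[2]
    temp <- temp[keep]; y <- y[keep]
  } else {
    window <- range(temp)
  }
  if (length(temp) < 8L) {
    stop("need at least 8 points in the fit window", call. = FALSE)
  }
  if (diff(range(temp)) < 20) {
    stop("fit window must span at least 20 degC", call. = FALSE)
  }
  m <- mean(temp)
  t_c <- temp - m
  fit <- stats::lm(y ~ t_c + I(t_c^2) + I(t_c^3))
  cf <- stats::coef(fit)  # (delta, gamma, beta, alpha) in centered coords
  alpha <- cf[[4]]; beta <- cf[[3]]; gamma <- cf[[2]]; delta <- cf[[1]]
  span <- diff(range(temp))
  if (abs(alpha) * span^3 < 1e-6 * max(1, diff(range(y)))) {
    stop("degenerate fit: no cubic curvature in the melting curve", call. = FALSE)
  }
  tm <- m - beta / (3 * alpha)
  # back-transform to raw-temperature coefficients
  a <- alpha
  b <- beta - 3 * alpha * m
  c_ <- gamma - 2 * beta * m + 3 * alpha * m^2
  d <- delta - gamma * m + beta * m^2 - alpha * m^3
  if (tm < window[1] || tm > window[2]) {
    stop(sprintf("inflection root %.2f degC lies outside the fit window [%.1f, %.1f]",
                 tm, window[1], window[2]), call. = FALSE)
  }
  structure(list(tm = tm, coefficients = c(a = a, b = b, c = c_, d = d),
                 wavelength = curve$wavelength, direction = curve$direction,
                 window = window, n_points = length(temp)),
            class = "melt_result")
}

#' @export
print.melt_result <- function(x, ...) {
  cat(sprintf("<melt_result> Tm = %.2f degC (%s%s, window %.1f-%.1f degC, n = %d)\n",
              x$tm, x$direction,
              if (is.na(x$wavelength)) "" else sprintf(" at %g nm", x$wavelength),
              x$window[1], x$window[2], x$n_points))
  invisible(x)
}

#' Melting-temperature difference relative to a reference construct
#'
#' @param sample,reference `melt_result` objects (or bare Tm values in degC)
#'   obtained in the same ramp direction.
#' @return `sample` Tm minus `reference` Tm, in degC.
#' @export
delta_tm <- function(sample, reference) {
  tm_of <- function(x) if (inherits(x, "melt_result")) x$tm else as.numeric(x)
  if (inherits(sample, "melt_result") && inherits(reference, "melt_result") &&
      sample$direction != reference$direction) {
    stop("sample and reference were fitted in different ramp directions",
         call. = FALSE)
  }
  tm_of(sample) - tm_of(reference)
}

#' Pre- vs post-melt refolding similarity
#'
#' Product-moment similarity (Pearson correlation) of two ellipticity vectors
#' over 230-320 nm, used to confirm that the original conformation reformed
#' after a melt/reanneal cycle.
#'
#' @param pre_melt,post_melt `cd_spectrum` objects on a shared grid.
#' @param range Wavelength window used for the comparison.
#' @return Similarity score in \[-1, 1\].
#' @export
check_refold <- function(pre_melt, post_melt, range = c(230, 320)) {
  stopifnot(inherits(pre_melt, "cd_spectrum"), inherits(post_melt, "cd_spectrum"))
  if (length(pre_melt$wavelengths) != length(post_melt$wavelengths) ||
      any(pre_melt$wavelengths != post_melt$wavelengths)) {
    stop("spectra must share one wavelength grid", call. = FALSE)
  }
  keep <- pre_melt$wavelengths >= range[1] & pre_melt$wavelengths <= range[2]
  a <- pre_melt$ellipticity[keep]
  b <- post_melt$ellipticity[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined similarity: zero-variance spectrum in comparison window",
         call. = FALSE)
  }
  stats::cor(a, b)
}
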