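test_that("FRET efficiency is acceptor over total with invalid-frame guards", {
  tr <- fret_trace("m1", donor = c(50, 33, 0, 10), acceptor = c(50, 67, 0, -10))
  e <- compute_fret(tr)
  expect_equal(e[1], 0.5)
  expect_equal(e[2], 0.67)
  expect_true(is.na(e[3]))  # zero total
  expect_true(is.na(e[4]))  # nonpositive total
  dead <- fret_trace("m2", donor = c(0, 0), acceptor = c(0, 0))
  expect_error(compute_fret(dead), "no valid frame")
})

test_that("efficiency stays within [0, 1] for nonnegative signals", {
  set.seed(3)
  for (i in 1:50) {
    d <- stats::runif(20, 0, 100)
    a <- stats::runif(20, 0, 100)
    e <- compute_fret(fret_trace("m", d, a))
    e <- e[!is.na(e)]
    expect_true(all(e >= 0 & e <= 1))
  }
})

test_that("histograms pool all valid frames and conserve counts", {
  one <- fret_trace("m", donor = rep(50, 20), acceptor = rep(50, 20))
  h <- build_histogram(list(list(one)), bin_width = 0.05)
  expect_equal(sum(h$counts), 20L)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(h$n_molecules, 1L)

  g <- gen_fret_traces(50, synth_config(seed = 2, fret_duration = 2,
                                        emission_noise_sd = 0.05))
  h2 <- build_histogram(list(g$traces))
  n_valid <- sum(vapply(g$traces, function(tr) sum(!is.na(compute_fret(tr))),
                        integer(1)))
  expect_equal(sum(h2$counts), n_valid)
  expect_error(build_histogram(list(g$traces), bin_width = 0), "positive")
})

test_that("the histogram mode bin contains the folded-state mean", {
  cfg <- synth_config(seed = 21, fret_duration = 2, type_fractions = c(1, 0, 0))
  g <- gen_fret_traces(6000, cfg)
  h <- build_histogram(list(g$traces))
  mode_bin <- which.max(h$counts)
  expect_lte(h$bin_edges[mode_bin], 0.67)
  expect_gt(h$bin_edges[mode_bin + 1], 0.67)
})

test_that("Gaussian peak fitting recovers known parameters", {
  # law of large numbers on generated samples
  set.seed(31)
  e <- stats::rnorm(1e5, 0.67, 0.05)
  traces <- list(fret_trace("m", donor = 1000 * (1 - e), acceptor = 1000 * e))
  pk <- fit_gaussian_peak(build_histogram(list(traces)))
  expect_lt(abs(pk$center - 0.67), 3 * 0.05 / sqrt(1e5) + 1e-3)
  expect_lt(abs(pk$half_width - 0.05), 0.005)

  # symmetric histogram: center at its midpoint
  mids <- seq(0.3, 0.7, 0.02)
  counts <- round(100 * exp(-(mids - 0.5)^2 / (2 * 0.06^2)))
  h <- list(bin_edges = c(mids - 0.01, max(mids) + 0.01), counts = counts,
            n_molecules = 1L, n_movies = 1L)
  class(h) <- "fret_histogram"
  expect_equal(fit_gaussian_peak(h)$center, 0.5, tolerance = 1e-3)

  expect_error(fit_gaussian_peak(build_histogram(list(list(
    fret_trace("m", rep(50, 3), rep(50, 3)))))), "nonzero bins")
})

test_that("with two separated modes the fit follows the taller one", {
  mids <- seq(-0.19, 1.19, 0.02)
  counts <- round(100 * exp(-(mids - 0.3)^2 / (2 * 0.05^2)) +
                  60 * exp(-(mids - 0.8)^2 / (2 * 0.05^2)))
  h <- structure(list(bin_edges = c(mids - 0.01, 1.21), counts = counts,
                      n_molecules = 1L, n_movies = 1L), class = "fret_histogram")
  pk <- fit_gaussian_peak(h)
  # coarse grid-search oracle over (center, sigma) with closed-form amplitude
  grid <- expand.grid(mu = seq(0, 1, 0.01), sigma = seq(0.02, 0.3, 0.005))
  sse <- apply(grid, 1, function(p) {
    g <- exp(-(mids - p[1])^2 / (2 * p[2]^2))
    A <- sum(counts * g) / sum(g^2)
    sum((counts - A * g)^2)
  })
  oracle_mu <- grid$mu[which.min(sse)]
  expect_lt(abs(oracle_mu - 0.3), 0.02)
  expect_lt(abs(pk$center - oracle_mu), 0.02)
})

test_that("trace typing follows the dwell-filtered 0.6 threshold", {
  expect_equal(classify_trace(rep(0.7, 1800))$label, "static_folded")
  expect_equal(classify_trace(rep(0.3, 1800))$label, "unfolded")
  # exactly at threshold counts as folded
  expect_equal(classify_trace(rep(0.6, 100))$label, "static_folded")

  two_state <- classify_trace(c(rep(0.75, 900), rep(0.35, 900)))
  expect_equal(two_state$label, "dynamic")
  expect_equal(two_state$n_excursions, 1L)
  expect_equal(two_state$fraction_above, 0.5)

  # a single sub-dwell dip is absorbed
  dip <- rep(0.7, 1800); dip[900] <- 0.5
  res <- classify_trace(dip, min_dwell = 5)
  expect_equal(res$label, "static_folded")
  expect_equal(res$fraction_above, 1)

  # scattered sub-dwell noise never accumulates into an excursion
  noisy <- rep(0.7, 100); noisy[c(40, 41, 43, 44)] <- 0.5
  expect_equal(classify_trace(noisy, min_dwell = 5)$label, "static_folded")
})

test_that("after filtering, no internal run is shorter than the dwell minimum", {
  set.seed(8)
  for (i in 1:50) {
    e <- stats::runif(200, 0.3, 0.9)
    cl <- classify_trace(e, min_dwell = 5)
    # reconstruct the filtered state sequence the way the classifier defines it
    above <- e >= 0.6
    filtered <- teloG4:::filter_excursions(above, 5)
    r <- rle(filtered)
    if (length(r$lengths) > 1) expect_true(all(r$lengths >= 5))
    expect_equal(cl$n_excursions, sum(diff(filtered) != 0))
  }
})

test_that("trace typing is stable under extension and threshold monotonicity", {
  e <- c(rep(0.75, 50), rep(0.3, 50), rep(0.8, 60))
  base <- classify_trace(e)
  extended <- classify_trace(c(e, rep(0.8, 40)))
  expect_equal(extended$label, base$label)
  expect_equal(extended$n_excursions, base$n_excursions)

  # raising the threshold can never turn an unfolded trace static-folded
  set.seed(9)
  for (i in 1:20) {
    tr <- stats::runif(100, 0, 1)
    labs <- vapply(c(0.4, 0.6, 0.8),
                   function(th) classify_trace(tr, threshold = th)$label,
                   character(1))
    was_unfolded <- which(labs == "unfolded")
    if (length(was_unfolded) > 0) {
      expect_false(any(labs[seq(min(was_unfolded), 3)] == "static_folded"))
    }
  }
})

test_that("generated traces are classified to match ground truth", {
  cfg <- synth_config(seed = 14, type_fractions = ref_trace_fractions("TEL"))
  g <- gen_fret_traces(1000, cfg)
  labs <- label_vector(g$traces)
  expect_gte(mean(labs == g$labels), 0.95)
  # mismatches only ever involve the dynamic boundary, not static<->unfolded
  flips <- labs != g$labels
  expect_false(any(labs[flips] == "unfolded" & g$labels[flips] == "static_folded"))
  expect_false(any(labs[flips] == "static_folded" & g$labels[flips] == "unfolded"))
})

test_that("dynamics summaries aggregate per-repeat percentages with sample SD", {
  # five identical repeats: means equal the common value, SDs zero
  rep1 <- c(rep("static_folded", 743), rep("dynamic", 178), rep("unfolded", 79))
  s <- summarize_dynamics(rep(list(rep1), 5), construct = "TEL")
  expect_equal(s$summary$mean_pct, c(74.3, 17.8, 7.9))
  expect_equal(s$summary$sd_pct, c(0, 0, 0))
  expect_equal(s$n_traces, 5000L)
  expect_true(all(abs(rowSums(s$per_repeat) - 100) < 0.1))

  # counting: S,S,D,U -> 50/25/25
  s2 <- summarize_dynamics(list(c("static_folded", "static_folded",
                                  "dynamic", "unfolded")))
  expect_equal(s2$summary$mean_pct, c(50, 25, 25))

  # hand arithmetic for the SD
  s3 <- summarize_dynamics(list(c("dynamic"), c("static_folded"),
                                c("static_folded")))
  expect_equal(s3$summary$mean_pct[1], 200 / 3)
  expect_equal(s3$summary$sd_pct[2], stats::sd(c(100, 0, 0)))

  expect_error(summarize_dynamics(list(character(0))), "repeat 1")
  expect_error(summarize_dynamics(list(c("banana"))), "unknown label")
})

test_that("simulated repeats recover the generating fractions within 3 SE", {
  p <- ref_trace_fractions("TEL")
  reps <- lapply(1:5, function(r) {
    g <- gen_fret_traces(200, synth_config(seed = 100 + r, type_fractions = p))
    label_vector(g$traces)
  })
  s <- summarize_dynamics(reps, construct = "TEL")
  se <- 100 * sqrt(p * (1 - p) / 1000)
  expect_true(all(abs(s$summary$mean_pct - 100 * p) <= 3 * se))
})
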