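test_that("cleaved fraction is intensity bookkeeping with guards", {
  expect_equal(percent_cleaved(50, 50), 0.5)
  expect_equal(percent_cleaved(0, 100), 0)
  expect_error(percent_cleaved(0, 0), "zero total")
  expect_error(percent_cleaved(-1, 2), "nonnegative")
  # scale invariance
  set.seed(4)
  a <- stats::runif(20, 0, 10); b <- stats::runif(20, 0, 10)
  for (k in c(0.01, 3, 1e6)) {
    expect_equal(percent_cleaved(k * a, k * b), percent_cleaved(a, b))
  }
  # generator ground truth, zero noise
  tc <- gen_cleavage_timecourse(quiet_cfg(cleavage_rate = 0, burst_fraction = 0.2,
                                          cleavage_plateau = 0.2),
                                timepoints = c(5, 10), replicates = 1)[[1]]
  expect_equal(percent_cleaved(tc$intensity_cleaved, tc$intensity_uncleaved),
               c(0.2, 0.2), tolerance = 1e-12)
})

test_that("timecourse summaries compute per-timepoint mean and sample SD", {
  mk <- function(r, pct) cleavage_timecourse("X", "K", r, c(10, 30),
                                             intensity_cleaved = pct,
                                             intensity_uncleaved = 100 - pct)
  reps <- list(mk(1, c(10, 1)), mk(2, c(10, 2)), mk(3, c(10, 3)))
  s <- summarize_timecourse(reps)
  expect_equal(s$mean_percent, c(10, 2))
  expect_equal(s$sd_percent, c(0, 1))
  expect_true(all(s$detected))

  # permutation invariance over replicates
  s2 <- summarize_timecourse(reps[c(3, 1, 2)])
  expect_equal(s2$mean_percent, s$mean_percent)
  expect_equal(s2$sd_percent, s$sd_percent)

  # mismatched grids are an error
  bad <- cleavage_timecourse("X", "K", 4, c(10, 60), c(1, 2), c(99, 98))
  expect_error(summarize_timecourse(list(reps[[1]], bad)), "time grid")

  # sub-threshold means flag as not detected
  nd <- summarize_timecourse(list(mk(1, c(0.01, 5)), mk(2, c(0.03, 5))))
  expect_equal(nd$detected, c(FALSE, TRUE))
})

test_that("synthetic triplicates recover the generating fraction within 3 SE", {
  cfg <- synth_config(seed = 6, cleavage_rate = 0.0101, cleavage_plateau = 0.2945,
                      burst_fraction = 0, cleavage_noise_sd = 0.04)
  s <- summarize_timecourse(gen_cleavage_timecourse(cfg))
  f60 <- 100 * 0.2945 * (1 - exp(-0.0101 * 60))
  expect_lt(abs(s$mean_percent[s$time_min == 60] - f60), 3 * 100 * 0.04 / sqrt(3))
})

test_that("position-class grouping applies the N.D. rule over the reference table", {
  ref <- cleavage_reference("K")
  constructs <- setdiff(unique(ref$construct), "dsTELR10")
  panel <- telomere_panel()
  sites <- lapply(constructs, function(cn) {
    classify_substitution(parse_telomere_seq(panel$sequence[panel$construct == cn][1]))
  })
  names(sites) <- constructs
  grouped <- group_by_position_class(ref[ref$construct != "dsTELR10", ], sites,
                                     nd_as_zero = TRUE)
  g1_120 <- grouped$mean_percent[grouped$position_class == "G1" &
                                 grouped$time_min == 120]
  # members TELR4 (N.D. -> 0), TELR10 9.8, TELR16 7.2, TELR22 20.7
  expect_equal(g1_120, mean(c(0, 9.8, 7.2, 20.7)))
  expect_equal(g1_120, 9.425)

  # excluding N.D. can only raise (or preserve) a class mean
  excl <- group_by_position_class(ref[ref$construct != "dsTELR10", ], sites,
                                  nd_as_zero = FALSE)
  both <- dplyr::inner_join(grouped, excl, by = c("position_class", "time_min"),
                            suffix = c("_zero", "_excl"))
  expect_true(all(both$mean_percent_excl >= both$mean_percent_zero))

  # single-member class equals that member; all-N.D. class is zero
  one <- tibble::tibble(construct = "TELR10", time_min = 120,
                        mean_percent = 9.8, detected = TRUE)
  g <- group_by_position_class(one, sites["TELR10"])
  expect_equal(g$mean_percent, 9.8)
  allnd <- tibble::tibble(construct = c("TELR5", "TELR23"), time_min = 120,
                          mean_percent = NA_real_, detected = FALSE)
  g0 <- group_by_position_class(allnd, sites[c("TELR5", "TELR23")])
  expect_equal(g0$mean_percent, 0)

  expect_error(group_by_position_class(one, sites["TELR22"]), "TELR10")
})

test_that("first-order fits recover generating parameters on clean data", {
  t <- c(1, 5, 15, 30, 60, 120)
  exact <- data.frame(time_min = t, mean_percent = 100 * (1 - exp(-0.03 * t)))
  fit <- fit_first_order(exact)
  expect_equal(fit$rate, 0.03, tolerance = 1e-6)
  expect_equal(fit$plateau, 1, tolerance = 1e-6)
  expect_equal(fit$burst, 0, tolerance = 1e-6)

  with_burst <- data.frame(
    time_min = t,
    mean_percent = 100 * (0.1 + 0.5 * (1 - exp(-0.05 * t)))
  )
  fit2 <- fit_first_order(with_burst)
  expect_equal(fit2$rate, 0.05, tolerance = 1e-6)
  expect_equal(fit2$plateau, 0.6, tolerance = 1e-6)
  expect_equal(fit2$burst, 0.1, tolerance = 1e-6)

  zeros <- data.frame(time_min = t, mean_percent = rep(0, 6))
  expect_equal(fit_first_order(zeros)$rate, 0)
  expect_equal(fit_first_order(zeros)$plateau, 0)
  flat <- data.frame(time_min = t, mean_percent = rep(50, 6))
  f3 <- fit_first_order(flat)
  expect_equal(f3$burst, 0.5)
  expect_equal(f3$plateau, 0.5)
  expect_error(fit_first_order(data.frame(time_min = 1:3, mean_percent = 1:3)),
               "4 timepoints")
})

test_that("cation comparison reports Na-minus-K differences per class", {
  k <- tibble::tibble(position_class = c("G1", "G1"), time_min = c(60, 120),
                      mean_percent = c(13.4, 20.7))
  na <- tibble::tibble(position_class = c("G1", "G1"), time_min = c(60, 120),
                       mean_percent = c(99.9, 99.3))
  cmp <- compare_cations(k, na)
  expect_equal(cmp$difference[cmp$time_min == 120], 99.3 - 20.7)
  expect_equal(cmp$difference[cmp$time_min == 120], 78.6)

  expect_equal(compare_cations(k, k)$difference, c(0, 0))
  expect_error(compare_cations(k[0, ], na), "empty")
  na_missing <- na[na$time_min == 60, ]
  expect_error(compare_cations(k, na_missing), "do not match")
})
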