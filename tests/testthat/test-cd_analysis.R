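test_that("scan averaging and buffer subtraction are pointwise means", {
  wl <- 220:340
  mk <- function(y) cd_spectrum(wl, y)
  scan <- gen_cd_spectrum(c(hybrid_3plus1 = 1), quiet_cfg())

  avg <- average_and_subtract(rep(list(scan), 10))
  expect_equal(avg$ellipticity, scan$ellipticity)

  zero <- average_and_subtract(list(scan), list(scan))
  expect_equal(zero$ellipticity, rep(0, length(wl)))

  pm <- average_and_subtract(list(mk(rep(1, length(wl))), mk(rep(-1, length(wl)))))
  expect_equal(pm$ellipticity, rep(0, length(wl)))

  expect_error(average_and_subtract(list(scan), list(cd_spectrum(230:340, rep(0, 111)))),
               "grid")
})

test_that("extrema finder matches the sign-change oracle on basis spectra", {
  for (conf in c("parallel", "hybrid_3plus1", "antiparallel_basket")) {
    sp <- gen_cd_spectrum(stats::setNames(1, conf), quiet_cfg())
    found <- find_extrema(sp)
    oracle <- oracle_extrema(sp$wavelengths, sp$ellipticity)
    expect_equal(nrow(found), nrow(oracle), label = conf)
    expect_true(all(abs(found$wavelength - oracle$wavelength) <= 2), label = conf)
    expect_identical(found$kind, oracle$kind, label = conf)
  }
  # band centers are recovered within a couple of nm despite band overlap
  par <- find_extrema(gen_cd_spectrum(c(parallel = 1), quiet_cfg()))
  expect_lt(abs(par$wavelength[par$kind == "max"] - 265), 2.5)
  expect_lt(abs(par$wavelength[par$kind == "min"] - 240), 2.5)
})

test_that("extrema finder handles flat input, prominence, and bad windows", {
  flat <- cd_spectrum(220:340, rep(2, 121))
  expect_equal(nrow(find_extrema(flat)), 0L)
  sp <- gen_cd_spectrum(c(parallel = 1), quiet_cfg())
  expect_error(find_extrema(sp, smooth_window = 500), "window")
  expect_error(find_extrema(cd_spectrum(240:300, rep(0, 61))), "230-300")
  # a huge prominence floor silences everything
  expect_equal(nrow(find_extrema(sp, min_prominence = 100)), 0L)
})

test_that("each pure zero-noise basis spectrum is called as exactly itself", {
  for (conf in conformations) {
    sp <- gen_cd_spectrum(stats::setNames(1, conf), quiet_cfg())
    call <- classify_conformation(sp)
    expect_identical(call$called, conf, label = conf)
    expect_false(call$mixture_flag)
    expect_gte(call$scores[[conf]], 0.75)
  }
})

test_that("50/50 mixtures are called as both components with the mixture flag", {
  pairs <- list(c("parallel", "antiparallel_chair"),
                c("antiparallel_basket", "hybrid_3plus1"),
                c("hybrid_3plus1", "parallel"),
                c("antiparallel_basket", "antiparallel_chair"))
  for (pr in pairs) {
    w <- stats::setNames(c(0.5, 0.5), pr)
    call <- classify_conformation(gen_cd_spectrum(w, quiet_cfg()))
    expect_setequal(call$called, pr)
    expect_true(call$mixture_flag)
  }
})

test_that("classification survives noise at 10% of peak amplitude", {
  n_ok <- 0L
  for (conf in conformations) {
    peak <- max(abs(gen_cd_spectrum(stats::setNames(1, conf), quiet_cfg())$ellipticity))
    for (seed in 1:25) {
      cfg <- synth_config(seed = seed, cd_noise_sd = 0.1 * peak)
      call <- classify_conformation(gen_cd_spectrum(stats::setNames(1, conf), cfg))
      if (identical(call$called, conf)) n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok, 95L)
})

test_that("an extrema-free spectrum yields an explicit unclassifiable call", {
  call <- classify_conformation(cd_spectrum(220:340, rep(0.001, 121)))
  expect_true(call$unclassifiable)
  expect_length(call$called, 0)
})

test_that("the literal extrema method applies the hybrid-superset tie rule", {
  hy <- gen_cd_spectrum(c(hybrid_3plus1 = 1), quiet_cfg())
  call <- classify_conformation(hy, method = "extrema")
  expect_identical(call$called, "hybrid_3plus1")
  # parallel also matches both of its extrema here but is the less specific set
  expect_gte(call$scores[["parallel"]], 0.75)
})

test_that("melt wavelength is the ellipticity argmax unless overridden", {
  sp <- gen_cd_spectrum(c(parallel = 1), quiet_cfg())
  expect_equal(pick_melt_wavelength(sp, override = 290), 290)
  expect_lt(abs(pick_melt_wavelength(sp) - 265), 2.5)
  neg <- cd_spectrum(220:340, -(1:121))
  expect_equal(pick_melt_wavelength(neg), 220)  # least-negative value
})

test_that("cubic Tm extraction equals the analytic inflection of any exact cubic", {
  set.seed(17)
  for (i in 1:20) {
    a <- stats::runif(1, -5e-3, 5e-3)
    if (abs(a) < 1e-4) a <- 1e-3
    b <- stats::runif(1, -1, 1)
    tm_true <- -b / (3 * a)
    # keep the inflection inside the ramp
    if (tm_true < 30 || tm_true > 90) { b <- -3 * a * 60; tm_true <- 60 }
    curve <- cubic_curve(a, b, stats::runif(1, -2, 2), stats::runif(1, -5, 5))
    res <- fit_cubic_tm(curve)
    expect_equal(res$tm, tm_true, tolerance = 1e-8)
    expect_equal(unname(res$coefficients["a"]), a, tolerance = 1e-6)
    expect_equal(res$tm, -res$coefficients[["b"]] / (3 * res$coefficients[["a"]]),
                 tolerance = 1e-10)
  }
})

test_that("cubic fit guards degenerate and out-of-window roots", {
  line <- melting_curve(25:95, 2 - 0.05 * (25:95))
  expect_error(fit_cubic_tm(line), "degenerate")
  expect_error(fit_cubic_tm(melting_curve(25:31, rnorm(7))), "at least 8 points")
  expect_error(fit_cubic_tm(melting_curve(seq(25, 40, 1), rnorm(16))), "20 degC")
  # window excluding the true inflection: root reported as out of range
  s <- gen_melting_curve(60, quiet_cfg(), model = "cubic")
  expect_error(fit_cubic_tm(s, window = c(25, 50)), "outside the fit window")
})

test_that("sigmoid Tm is recovered within 1 degC with the automatic window", {
  for (tm in c(45, 60, 75)) {
    curve <- gen_melting_curve(tm, quiet_cfg(), model = "sigmoid")
    res <- fit_cubic_tm(curve, auto_window = TRUE)
    expect_lt(abs(res$tm - tm), 1.0)
    # steepest-slope oracle on a fine grid
    tt <- seq(25, 95, 0.01)
    f <- 1 / (1 + exp((tt - tm) / 4))
    oracle <- tt[which.max(abs(diff(f)))]
    expect_lt(abs(res$tm - oracle), 1.0)
  }
})

test_that("window shifts pull the sigmoid estimate toward the window center", {
  curve <- gen_melting_curve(60, quiet_cfg(), model = "sigmoid")
  est <- vapply(c(57, 60, 63),
                function(ctr) fit_cubic_tm(curve, window = c(ctr - 15, ctr + 15))$tm,
                numeric(1))
  expect_true(all(diff(est) > 0))
  expect_lt(est[1], 60)
  expect_gt(est[3], 60)
  expect_equal(est[2], 60, tolerance = 1e-6)
})

test_that("delta Tm is a plain difference, antisymmetric, zero on self", {
  expect_equal(delta_tm(46.99, 58.86), -11.87)
  expect_equal(delta_tm(61.17, 58.86), 2.31)
  expect_equal(delta_tm(58.86, 58.86), 0)
  expect_equal(delta_tm(46.99, 58.86), -delta_tm(58.86, 46.99))
  m1 <- fit_cubic_tm(gen_melting_curve(60, quiet_cfg(), model = "cubic"))
  m2 <- fit_cubic_tm(gen_melting_curve(55, quiet_cfg(), model = "cubic"))
  expect_equal(delta_tm(m1, m2), 5, tolerance = 1e-9)
  a1 <- fit_cubic_tm(gen_melting_curve(60, quiet_cfg(), "anneal", "cubic"))
  expect_error(delta_tm(a1, m2), "direction")
})

test_that("refolding similarity is 1 on identity, -1 on negation, low across bases", {
  sp <- gen_cd_spectrum(c(hybrid_3plus1 = 1), quiet_cfg())
  expect_equal(check_refold(sp, sp), 1.0)
  neg <- cd_spectrum(sp$wavelengths, -sp$ellipticity)
  expect_equal(check_refold(sp, neg), -1.0)
  basket <- gen_cd_spectrum(c(antiparallel_basket = 1), quiet_cfg())
  expect_lt(check_refold(sp, basket), 0.9)
  flat <- cd_spectrum(sp$wavelengths, rep(1, length(sp$wavelengths)))
  expect_error(check_refold(sp, flat), "zero-variance")
})
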