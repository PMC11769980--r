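test_that("time-domain indices match hand arithmetic", {
  td <- time_domain(c(800, 810, 790, 810))
  expect_equal(td$rmssd, sqrt(900 / 3), tolerance = 1e-12) # 17.3205

  td2 <- time_domain(c(800, 860, 870, 800))
  expect_equal(td2$pnn50, 100 * 2 / 3, tolerance = 1e-12) # 66.667 %

  td3 <- time_domain(rep(800, 50))
  expect_equal(td3$rmssd, 0)
  expect_equal(td3$pnn50, 0)
  expect_equal(td3$hr, 75)
  expect_equal(td3$hr, 60000 / td3$mean_rr)

  expect_error(time_domain(800), class = "cardioresp_error_input")
})

test_that("stress index follows the Baevsky convention with 0-anchored bins", {
  # 60 intervals in the modal bin [800, 850), 40 spread outside it over
  # [650, 950]: Mo = 0.825 s, AMo = 60 %, MxDMn = 0.3 s
  rr <- c(rep(820, 60), seq(650, 790, length.out = 20),
          seq(860, 950, length.out = 20))
  si <- stress_index(rr)
  expect_equal(si$mo, 0.825)
  expect_equal(si$amo, 60)
  expect_equal(si$mxdmn, 0.3)
  expect_equal(si$si, 60 / (2 * 0.825 * 0.3), tolerance = 1e-12)

  # proportions, not counts: doubling every interval leaves SI unchanged
  expect_equal(stress_index(rep(rr, 2))$si, si$si)

  # spreading the histogram strictly decreases SI
  wider <- c(rep(820, 40), seq(600, 1000, length.out = 60))
  expect_lt(stress_index(wider)$si, si$si)

  expect_error(stress_index(rep(800, 30)), "undefined",
               class = "cardioresp_error_input")
})

test_that("resampling interpolates, detrends and validates", {
  t <- cumsum(rep(0.8, 150))
  out <- resample_tachogram(t, rep(5, 150))
  expect_equal(diff(out$t), rep(0.25, length(out$t) - 1))
  expect_true(all(abs(out$value) < 1e-9)) # constant -> 0 after detrend

  ramp <- resample_tachogram(t, 2 * t)
  expect_true(all(abs(ramp$value) < 1e-6)) # linear trend removed

  # a 0.1 Hz oscillation survives resampling with < 1% amplitude error
  y <- 20 * sin(2 * pi * 0.1 * t)
  res <- resample_tachogram(t, y)
  expect_equal(var(res$value), 200, tolerance = 0.02)

  expect_error(resample_tachogram(t[1:20], rep(5, 20)),
               class = "cardioresp_error_input")
  expect_error(resample_tachogram(t[1:40] / 3, rep(5, 40)),
               class = "cardioresp_error_input") # span < 60 s
})

test_that("band powers localize sinusoids and satisfy Parseval", {
  lone <- band_powers(sine_series(0.1, 20))
  expect_equal(lone$lf, 200, tolerance = 0.05)
  expect_lt(lone$hf, 2)
  expect_equal(lone$lfn + lone$hfn, 100, tolerance = 1e-9)

  # a single oscillation puts >= 95% of its power into its own band
  for (f in c(0.02, 0.08, 0.12, 0.3)) {
    bp <- band_powers(sine_series(f, 10, phase = 1))
    band <- dplyr::case_when(f < 0.04 ~ "vlf", f < 0.15 ~ "lf",
                             TRUE ~ "hf")
    expect_gt(bp[[band]] / bp$tp, 0.95)
  }

  # Parseval on the estimator: full-range Welch integral equals the
  # variance of white noise
  x <- withr::with_seed(1, rnorm(1201, 0, 5))
  spec <- cardioresp:::welch_psd(x, fs = 4)
  expect_equal(sum(spec$psd) * diff(spec$freq[1:2]), var(x),
               tolerance = 0.05)

  # broadband in-band input: 30 tones spread over the analysis range carry
  # total power sum(A^2/2); tp recovers it within 10%
  t <- seq(0, 300, 0.25)
  freqs <- seq(0.015, 0.385, length.out = 30)
  phases <- withr::with_seed(2, runif(30, 0, 2 * pi))
  y <- rowSums(sapply(seq_along(freqs),
                      function(i) 3 * sin(2 * pi * freqs[i] * t + phases[i])))
  bp <- band_powers(tibble::tibble(t = t, value = y))
  expect_equal(bp$tp, 30 * 9 / 2, tolerance = 0.10)
  expect_equal(bp$vlf + bp$lf + bp$hf, bp$tp, tolerance = 0.02)

  expect_error(band_powers(sine_series(0.1, 20, duration = 30)),
               class = "cardioresp_error_input")
  irregular <- tibble::tibble(t = cumsum(runif(300, 0.2, 0.3)) * 2,
                              value = rnorm(300))
  expect_error(band_powers(irregular), class = "cardioresp_error_input")
})

test_that("spectral operations are pure", {
  s <- sine_series(0.1, 20)
  expect_identical(band_powers(s), band_powers(s))
})
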