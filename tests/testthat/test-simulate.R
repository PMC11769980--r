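test_that("paced phases produce exactly periodic breaths", {
  p <- make_preset("I")
  proto <- default_protocol()
  cr6 <- generate_breathing(proto[2, ], p, seed = 1)
  expect_equal(nrow(cr6), 12) # 120 s / 10 s
  expect_true(all(cr6$ti_s == 5) && all(cr6$te_s == 5))

  cr15 <- generate_breathing(proto[3, ], p, seed = 1)
  expect_equal(nrow(cr15), 30) # 120 s / 4 s
  expect_true(all(cr15$ti_s == 2) && all(cr15$te_s == 2))

  expect_error(
    generate_breathing(list(label = "CR6", duration = -5, t_insp = 5,
                            t_exp = 5), p, seed = 1),
    class = "cardioresp_error_protocol"
  )
})

test_that("spontaneous breathing covers the phase and VE = VT x RR holds", {
  p <- make_preset("III")
  sr <- generate_breathing(default_protocol()[1, ], p, seed = 7)
  ends <- sr$breath_start_s + sr$ti_s + sr$te_s
  expect_equal(max(ends), 120)
  expect_true(all(diff(sr$breath_start_s) > 0))
  # per-minute normalization: minute ventilation is exactly mean VT times
  # the count-based rate
  rate <- nrow(sr) / 2
  ve <- mean(sr$vt_l) * rate
  expect_equal(ve, mean(sr$vt_l) * nrow(sr) / 2)
})

test_that("a single oscillation realizes its band power and pressure gain", {
  p <- make_preset("I")
  p$target_lf <- 200
  p$target_vlf <- 1e-8
  p$target_hf <- 1e-8
  p$alpha_lf <- 10
  p$rsa_shape <- 0
  p$noise_sd <- 0
  p$noise_sd_sbp <- 0
  resp <- generate_breathing(default_protocol()[1, ], p, seed = 1)
  beats <- generate_beats(p, resp, seed = 2)
  # sinusoid of amplitude A = sqrt(2 * 200) carries power A^2 / 2 = 200 ms^2
  expect_equal(var(beats$rr_ms), 200, tolerance = 0.05)
  # SBP oscillation amplitude is A / alpha = 2 mmHg -> variance 2 mmHg^2
  expect_equal(var(beats$sbp_mmhg), 2, tolerance = 0.05)
})

test_that("noise-free records realize their band-power targets", {
  proto <- default_protocol()[1, ]
  for (ty in c("I", "III", "IV")) {
    p <- make_preset(ty, noise_sd = 0, noise_sd_sbp = 0)
    # saturated waveforms (types I/II) shed a few percent of carrier power
    # into harmonics; near-sinusoidal types hold a tighter band
    tol <- if (ty %in% c("I", "II")) 0.20 else 0.15
    for (s in c(2, 9)) {
      pan <- analyze_recording(generate_recording(p, proto, seed = s))
      expect_equal(pan$lf, p$target_lf, tolerance = tol, info = ty)
      expect_equal(pan$hf, p$target_hf, tolerance = tol, info = ty)
    }
  }
})

test_that("generation is deterministic under a fixed seed", {
  p <- make_preset("II")
  r1 <- generate_recording(p, seed = 11)
  r2 <- generate_recording(p, seed = 11)
  expect_identical(r1$beats, r2$beats)
  expect_identical(r1$breaths, r2$breaths)
  r3 <- generate_recording(p, seed = 12)
  expect_false(identical(r1$beats, r3$beats))
})

test_that("recordings follow the three-phase maneuver layout", {
  rec <- generate_recording(make_preset("IV"), seed = 3)
  expect_equal(rec$phases$label, c("SR", "CR6", "CR15"))
  expect_equal(rec$phases$end - rec$phases$start, rep(120, 3))
  expect_gte(max(rec$beats$t_s) - min(rec$beats$t_s), 355)
  expect_error(generate_recording(make_preset("I"),
                                  protocol = default_protocol()[0, ],
                                  seed = 1),
               class = "cardioresp_error_protocol")
})

test_that("cohorts have the requested composition and derived seeds", {
  cohort <- make_cohort(sizes = c(I = 2, II = 1, IV = 1), seed = 5)
  expect_equal(nrow(cohort), 4)
  expect_equal(table(cohort$type)[c("I", "II", "IV")],
               table(rep(c("I", "II", "IV"), c(2, 1, 1))))
  expect_equal(length(unique(cohort$seed)), 4)
  cohort2 <- make_cohort(sizes = c(I = 2, II = 1, IV = 1), seed = 5)
  expect_identical(cohort$recording[[3]]$beats, cohort2$recording[[3]]$beats)
  expect_error(make_cohort(sizes = integer(0)),
               class = "cardioresp_error_input")
})
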