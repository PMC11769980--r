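test_that("phase panels are internally consistent", {
  p <- make_preset("I", noise_sd = 0, noise_sd_sbp = 0)
  rec <- generate_recording(p, seed = 6)
  pan <- analyze_recording(rec)
  expect_equal(nrow(pan), 3)
  expect_equal(pan$phase, c("SR", "CR6", "CR15"))

  # exact internal identities
  expect_equal(pan$hi, pan$hr / pan$rr_resp, tolerance = 1e-12)
  expect_equal(pan$vsi, pan$co / pan$ve, tolerance = 1e-12)
  expect_equal(pan$ve, pan$vt * pan$rr_resp, tolerance = 1e-12)
  expect_equal(pan$lfn + pan$hfn, rep(100, 3), tolerance = 1e-9)

  # paced design: CR15 respiratory rate is 15 per minute
  expect_equal(pan$rr_resp[pan$phase == "CR15"], 15, tolerance = 0.1 / 15)
  expect_equal(pan$rr_resp[pan$phase == "CR6"], 6, tolerance = 0.1 / 6)

  # spontaneous phase reproduces the preset frequency ratio
  sr <- pan[pan$phase == "SR", ]
  expect_equal(sr$hi, (60000 / p$mean_rr) / p$resp_rate_sr,
               tolerance = 0.05)
})

test_that("increments are CR minus SR and antisymmetric", {
  pan <- analyze_recording(generate_recording(make_preset("II"), seed = 2))
  pan$subject_id <- "A"
  sr <- pan[pan$phase == "SR", ]
  cr6 <- pan[pan$phase == "CR6", ]

  d <- panel_deltas(sr, cr6)
  expect_equal(d$condition, "CR6")
  expect_equal(d$delta_hi, cr6$hi - sr$hi)
  expect_equal(d$delta_br_lf, cr6$br_lf - sr$br_lf)

  # hand check of the subtraction convention
  a <- sr; a$hi <- 4.5
  b <- cr6; b$hi <- 11.0
  expect_equal(panel_deltas(a, b)$delta_hi, 6.5)

  rev <- panel_deltas(cr6, sr)
  expect_equal(rev$delta_hi, -d$delta_hi)

  expect_error(panel_deltas(sr, sr), class = "cardioresp_error_input")
})

test_that("identical panels give zero increments", {
  pan <- analyze_recording(generate_recording(make_preset("I"), seed = 3))
  sr <- pan[pan$phase == "SR", ]
  fake_cr <- sr
  fake_cr$phase <- "CR6"
  d <- panel_deltas(sr, fake_cr)
  expect_true(all(abs(dplyr::select(d, dplyr::starts_with("delta_"))) < 1e-12))
})

test_that("cohort summaries use type-7 quantiles and ignore order", {
  df <- tibble::tibble(type = c("I", "I", "I", "I"), x = c(1, 2, 3, 4))
  s <- cohort_summary(df, x, type)
  expect_equal(s$median, 2.5)
  expect_equal(s$q1, quantile(1:4, 0.25, type = 7, names = FALSE))

  one <- cohort_summary(tibble::tibble(type = "II", x = 7), x, type)
  expect_equal(c(one$q1, one$median, one$q3), c(7, 7, 7))

  shuffled <- df[c(3, 1, 4, 2), ]
  expect_equal(cohort_summary(shuffled, x, type), s)
})

test_that("the cohort pipeline assembles panels, classes and deltas", {
  cohort <- make_cohort(sizes = c(I = 2, IV = 1), seed = 21,
                        dispersion = FALSE)
  res <- analyze_cohort(cohort)
  expect_s3_class(res, "cr_cohort_analysis")
  expect_equal(nrow(res$panels), 9) # 3 subjects x 3 phases
  expect_equal(nrow(res$deltas), 6) # 3 subjects x 2 paced conditions
  expect_true(all(c("hrr_class", "type") %in% names(res$panels)))
  expect_equal(nrow(res$qc), 3)

  g <- glance(res)
  expect_equal(g$n_subjects, 3L)
  # without dispersion every subject classifies to its generating type
  expect_equal(g$class_agreement, 1)

  td <- tidy(res)
  expect_identical(td, res$panels)
})
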