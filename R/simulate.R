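#' The standard three-phase breathing-maneuver protocol
#'
#' Two minutes of spontaneous breathing (SR), two minutes paced at 6
#' breaths/min (CR6: 5 s inhalation, 5 s exhalation, 0.1 Hz), two minutes
#' paced at 15 breaths/min (CR15: 2 s inhalation, 2 s exhalation, 0.25 Hz).
#'
#' @param phase_duration Duration of each phase in seconds.
#' @return A tibble with columns `label`, `duration` (s), `t_insp`, `t_exp`
#'   (s; `NA` for spontaneous breathing).
#' @export
#' @examples
#' default_protocol()
default_protocol <- function(phase_duration = 120) {
  tibble::tibble(
    label = c("SR", "CR6", "CR15"),
    duration = phase_duration,
    t_insp = c(NA, 5, 2),
    t_exp = c(NA, 5, 2)
  )
}

validate_protocol <- function(protocol) {
  if (!is.data.frame(protocol) || nrow(protocol) == 0) {
    cr_abort("protocol must be a non-empty data frame of phases",
             class = "cardioresp_error_protocol")
  }
  need <- c("label", "duration", "t_insp", "t_exp")
  if (!all(need %in% names(protocol))) {
    cr_abort(paste("protocol lacks columns:",
                   paste(setdiff(need, names(protocol)), collapse = ", ")),
             class = "cardioresp_error_protocol")
  }
  if (any(protocol$duration <= 0)) {
    cr_abort("phase durations must be positive",
             class = "cardioresp_error_protocol")
  }
  bad6 <- protocol$label == "CR6" &
    (protocol$t_insp != 5 | protocol$t_exp != 5)
  bad15 <- protocol$label == "CR15" &
    (protocol$t_insp != 2 | protocol$t_exp != 2)
  if (any(bad6, na.rm = TRUE) || any(bad15, na.rm = TRUE)) {
    cr_abort("CR6 phases must be paced 5 s / 5 s and CR15 phases 2 s / 2 s",
             class = "cardioresp_error_protocol")
  }
  invisible(protocol)
}

#' Generate a breath-by-breath series for one maneuver phase
#'
#' Paced phases (CR6, CR15) produce strictly periodic breaths with the
#' prescribed inspiratory/expiratory durations; spontaneous phases draw
#' cycle lengths and tidal volumes with mild lognormal jitter (5% coefficient
#' of variation) around the preset respiratory rate and tidal volume. Tidal
#' volume in paced phases is the preset volume times the preset phase gain
#' (deep slow breathing at CR6, moderate hyperventilation at CR15).
#'
#' @param phase One-row data frame (or list) with `label`, `duration`,
#'   `t_insp`, `t_exp` -- see [default_protocol()].
#' @param preset A [make_preset()] object supplying the spontaneous rate and
#'   tidal volume.
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @param start Phase start time in seconds.
#' @return A tibble with columns `breath_start_s`, `ti_s`, `te_s`, `vt_l`.
#' @export
#' @examples
#' proto <- default_protocol()
#' generate_breathing(proto[2, ], make_preset("I"), seed = 1)
generate_breathing <- function(phase, preset, seed, start = 0) {
  phase <- as.list(phase)
  if (is.null(phase$duration) || phase$duration <= 0) {
    cr_abort("phase duration must be positive",
             class = "cardioresp_error_protocol")
  }
  paced <- !is.na(phase$t_insp) && !is.na(phase$t_exp)
  withr::with_seed(seed, {
    if (paced) {
      cycle <- phase$t_insp + phase$t_exp
      if (phase$duration < cycle) {
        cr_abort("phase shorter than one breath cycle",
                 class = "cardioresp_error_protocol")
      }
      n <- floor(phase$duration / cycle)
      vt_gain <- switch(phase$label,
                        CR6 = preset$vt_gain_cr6,
                        CR15 = preset$vt_gain_cr15,
                        1)
      breaths <- tibble::tibble(
        breath_start_s = start + (seq_len(n) - 1) * cycle,
        ti_s = phase$t_insp,
        te_s = phase$t_exp,
        vt_l = preset$vt * vt_gain
      )
    } else {
      mean_cycle <- 60 / preset$resp_rate_sr
      if (phase$duration < mean_cycle) {
        cr_abort("phase shorter than one breath cycle",
                 class = "cardioresp_error_protocol")
      }
      # draw generously, then keep breaths starting inside the phase
      n_max <- ceiling(phase$duration / mean_cycle * 1.6) + 4
      cycles <- mean_cycle * exp(rnorm(n_max, 0, 0.05))
      starts <- start + cumsum(c(0, cycles[-n_max]))
      keep <- starts - start + cycles <= phase$duration + 1e-9
      cycles <- cycles[keep]
      starts <- starts[keep]
      te <- 0.55 * cycles
      # stretch the final expiration so the series covers the phase exactly
      n <- length(starts)
      te[n] <- start + phase$duration - starts[n] - 0.45 * cycles[n]
      breaths <- tibble::tibble(
        breath_start_s = starts,
        ti_s = 0.45 * cycles,
        te_s = te,
        vt_l = preset$vt * exp(rnorm(n, 0, 0.05))
      )
    }
    breaths
  })
}

# Draw the oscillator component table (amplitudes, phase offsets) for one
# subject. VLF is one slow component at 0.013 Hz carrying the whole VLF
# target: concentrating VLF keeps the RR histogram compact, which is what
# gives sympathotonic records their high stress index; spreading the same
# power over several VLF lines Gaussianizes the marginal and caps the
# stress index well below the published type-I/II medians. LF is a single
# 0.1 Hz Mayer-wave component; the respiratory (RSA) component rides the
# instantaneous breathing frequency and is handled separately.
draw_components <- function(preset, seed) {
  withr::with_seed(seed, {
    list(
      vlf_freq = 0.013,
      vlf_amp = sqrt(2 * preset$target_vlf),
      vlf_phi = runif(1, 0, 2 * pi),
      lf_freq = 0.1,
      lf_amp = sqrt(2 * preset$target_lf),
      lf_phi = runif(1, 0, 2 * pi),
      hf_amp = sqrt(2 * preset$target_hf),
      hf_phi = runif(1, 0, 2 * pi)
    )
  })
}

# Oscillation waveform: a saturated (flat-topped) sine,
# tanh(kappa * sin(theta)) normalized to the mean-square of a unit sine, so
# an amplitude A carries total power A^2/2 regardless of shape. kappa = 0
# degenerates to the pure sine. Flat-topped oscillations concentrate the RR
# histogram at the plateaus and shrink its range per unit power -- the
# compact, peaked short-record geometry seen with sympathetic predominance;
# odd harmonics (3f, 5f, ...) of the respiratory component fall above the
# analyzed bands for spontaneous breathing rates.
clip_wave <- function(kappa) {
  if (kappa <= 0) {
    return(function(theta) sin(theta))
  }
  th <- seq(0, 2 * pi, length.out = 2048)
  rms <- sqrt(mean(tanh(kappa * sin(th))^2))
  scale <- sqrt(0.5) / rms
  function(theta) scale * tanh(kappa * sin(theta))
}

# Continuous respiratory phase (radians) as a function of time: each breath
# advances the phase by exactly 2*pi, linearly within the breath, so the RSA
# oscillation is phase-continuous across rate changes.
resp_phase_fun <- function(breaths) {
  n <- nrow(breaths)
  cycle <- breaths$ti_s + breaths$te_s
  knots_t <- c(breaths$breath_start_s, breaths$breath_start_s[n] + cycle[n])
  knots_phi <- 2 * pi * (0:n)
  stats::approxfun(knots_t, knots_phi, rule = 2)
}

#' Generate a baroreflex-coupled beat series over one phase window
#'
#' Beats are laid down iteratively (`t[k+1] = t[k] + RR(t[k]) / 1000`,
#' an integrate-to-next-beat rule) from an RR-interval process built as
#' additive oscillations plus white noise: one slow (0.013 Hz) component
#' carrying the VLF power target, one 0.1 Hz component carrying the LF
#' target, and a respiratory sinus arrhythmia component at the instantaneous
#' breathing frequency carrying the HF target (times `rsa_gain`). All
#' oscillations use the preset's saturated-sine waveform (`rsa_shape`),
#' which shapes the RR histogram without moving band power. Systolic
#' pressure mirrors the oscillations scaled down by the preset baroreflex
#' gains (`alpha_lf` for the VLF/LF components -- with `sbp_lf_gain`
#' amplifying the 0.1 Hz pressure wave, `alpha_hf` for the respiratory
#' component, unscaled by `rsa_gain`), so the spectral alpha-coefficient of
#' the generated record recovers the preset gains. Diastolic pressure is
#' systolic minus a fixed 40 mmHg pulse pressure plus noise; stroke volume
#' is constant.
#'
#' @param preset A [make_preset()] object.
#' @param resp Breath series covering the window, as from
#'   [generate_breathing()].
#' @param seed Integer seed for the per-beat noise.
#' @param start,end Window in seconds; defaults to the span of `resp`.
#' @param rsa_gain Multiplier on the cardiac respiratory-arrhythmia
#'   amplitude for this phase.
#' @param sbp_lf_gain Multiplier on the systolic 0.1 Hz pressure amplitude
#'   for this phase.
#' @param components Oscillator table from an earlier draw, to keep
#'   component phases continuous across maneuver phases; drawn from `seed`
#'   when `NULL`.
#' @return A tibble with columns `t_s`, `rr_ms`, `sbp_mmhg`, `dbp_mmhg`,
#'   `sv_ml`.
#' @export
#' @examples
#' p <- make_preset("I")
#' resp <- generate_breathing(default_protocol()[1, ], p, seed = 1)
#' beats <- generate_beats(p, resp, seed = 2)
generate_beats <- function(preset, resp, seed, start = NULL, end = NULL,
                           rsa_gain = 1, sbp_lf_gain = 1,
                           components = NULL) {
  if (nrow(resp) == 0) {
    cr_abort("respiration series is empty", class = "cardioresp_error_input")
  }
  if (is.null(start)) start <- resp$breath_start_s[1]
  if (is.null(end)) {
    n <- nrow(resp)
    end <- resp$breath_start_s[n] + resp$ti_s[n] + resp$te_s[n]
  }
  last_cover <- resp$breath_start_s[nrow(resp)] +
    resp$ti_s[nrow(resp)] + resp$te_s[nrow(resp)]
  if (last_cover < end - 1e-6) {
    cr_abort("respiration series does not cover the requested window",
             class = "cardioresp_error_input")
  }
  if (is.null(components)) components <- draw_components(preset, seed)
  phi_resp <- resp_phase_fun(resp)
  co <- components

  wave <- clip_wave(preset$rsa_shape)

  n_guess <- ceiling((end - start) / (preset$mean_rr / 1000) * 1.5) + 10
  withr::with_seed(seed, {
    eps_rr <- rnorm(n_guess, 0, preset$noise_sd)
    eps_sbp <- rnorm(n_guess, 0, preset$noise_sd_sbp)
    eps_dbp <- rnorm(n_guess, 0, preset$noise_sd_sbp)
  })

  t_k <- start
  ts <- numeric(n_guess)
  rrs <- numeric(n_guess)
  sbps <- numeric(n_guess)
  k <- 0L
  while (t_k < end && k < n_guess) {
    k <- k + 1L
    vlf <- sum(co$vlf_amp * wave(2 * pi * co$vlf_freq * t_k + co$vlf_phi))
    lf <- co$lf_amp * wave(2 * pi * co$lf_freq * t_k + co$lf_phi)
    rsa <- wave(phi_resp(t_k) + co$hf_phi)
    rr <- preset$mean_rr + vlf + lf +
      rsa_gain * co$hf_amp * rsa + eps_rr[k]
    rr <- max(rr, 250) # physiological floor, guards the time step
    sbp <- preset$sbp0 + vlf / preset$alpha_lf +
      sbp_lf_gain * lf / preset$alpha_lf +
      co$hf_amp / preset$alpha_hf * rsa + eps_sbp[k]
    ts[k] <- t_k
    rrs[k] <- rr
    sbps[k] <- sbp
    t_k <- t_k + rr / 1000
  }
  idx <- seq_len(k)
  tibble::tibble(
    t_s = ts[idx],
    rr_ms = rrs[idx],
    sbp_mmhg = sbps[idx],
    dbp_mmhg = sbps[idx] - 40 + eps_dbp[idx],
    sv_ml = preset$sv
  )
}

#' Generate a complete maneuver recording for one synthetic subject
#'
#' Concatenates per-phase breath and beat generation over the protocol with
#' continuous time and a single subject-level oscillator draw, so component
#' phases are continuous across the maneuver. Phase annotations are attached
#' to the returned recording.
#'
#' @param preset A [make_preset()] object.
#' @param protocol Phase table as from [default_protocol()].
#' @param seed Integer master seed for this subject; per-phase child seeds
#'   are derived deterministically.
#' @param subject_id Identifier stored in the recording.
#' @return A `cr_recording` object: list with `subject_id`, `beats`,
#'   `breaths` (tibbles in the [read_beats()] / [read_breaths()] dialects)
#'   and `phases` (tibble `label`, `start`, `end`).
#' @export
#' @examples
#' rec <- generate_recording(make_preset("III"), seed = 42)
#' rec$phases
generate_recording <- function(preset, protocol = default_protocol(),
                               seed = 1, subject_id = "S1") {
  validate_protocol(protocol)
  components <- draw_components(preset, child_seed(seed, 0))
  starts <- cumsum(c(0, protocol$duration[-nrow(protocol)]))
  ends <- starts + protocol$duration

  breaths <- purrr::map(seq_len(nrow(protocol)), function(i) {
    generate_breathing(protocol[i, ], preset,
                       seed = child_seed(seed, i), start = starts[i])
  })
  beats <- purrr::map(seq_len(nrow(protocol)), function(i) {
    label <- protocol$label[i]
    generate_beats(
      preset, breaths[[i]], seed = child_seed(seed, 100 + i),
      start = starts[i], end = ends[i],
      rsa_gain = switch(label, CR6 = preset$rsa_gain_cr6,
                        CR15 = preset$rsa_gain_cr15, 1),
      sbp_lf_gain = switch(label, CR15 = preset$sbp_lf_gain_cr15, 1),
      components = components
    )
  })

  new_recording(
    subject_id = subject_id,
    beats = dplyr::bind_rows(beats),
    breaths = dplyr::bind_rows(breaths),
    phases = tibble::tibble(label = protocol$label,
                            start = starts, end = ends)
  )
}

#' Generate a synthetic cohort of maneuver recordings
#'
#' One recording per subject, with subject-level dispersion applied to the
#' type preset: band-power targets, baroreflex gains and mean heart rate are
#' jittered lognormally with spreads sized from the published inter-quartile
#' ranges of each type (sigma = log(Q3/Q1) / (2 * qnorm(0.75))), and stroke
#' volume, resting pressure, spontaneous rate and tidal volume with mild
#' fixed spreads. The default group sizes are the cohort composition of the
#' source study (53/29/85/16 for types I--IV).
#'
#' @param sizes Named integer vector of subjects per HRR type.
#' @param seed Integer master seed; subject seeds are derived
#'   deterministically from it.
#' @param protocol Phase table as from [default_protocol()].
#' @param dispersion Logical; `FALSE` generates every subject from the exact
#'   type preset (useful for calibration checks).
#' @param noise_sd,noise_sd_sbp Per-beat noise levels passed to
#'   [make_preset()].
#' @return A tibble with one row per subject: `subject_id`, `type`, `seed`
#'   and a `recording` list-column of `cr_recording` objects.
#' @export
#' @examples
#' cohort <- make_cohort(sizes = c(I = 2, III = 2), seed = 7)
#' cohort$subject_id
make_cohort <- function(sizes = c(I = 53, II = 29, III = 85, IV = 16),
                        seed = 1, protocol = default_protocol(),
                        dispersion = TRUE, noise_sd = 3, noise_sd_sbp = 1) {
  if (length(sizes) == 0 || any(sizes < 0) || sum(sizes) == 0) {
    cr_abort("cohort sizes must be a non-empty set of non-negative counts",
             class = "cardioresp_error_input")
  }
  types <- rep(names(sizes), times = sizes)
  iqr_sigma <- function(q1, q3) log(q3 / q1) / (2 * stats::qnorm(0.75))
  quart <- hrr_type_quartiles()

  rows <- purrr::map(seq_along(types), function(i) {
    type <- types[i]
    preset <- make_preset(type, noise_sd = noise_sd,
                          noise_sd_sbp = noise_sd_sbp)
    if (dispersion) {
      q <- quart[quart$type == type, ]
      preset <- withr::with_seed(child_seed(seed, 1000 + i), {
        jit <- function(x, sigma) x * exp(rnorm(1, 0, sigma))
        preset$target_vlf <- jit(preset$target_vlf,
                                 iqr_sigma(q$vlf_q1, q$vlf_q3))
        preset$target_lf <- jit(preset$target_lf,
                                iqr_sigma(q$lf_q1, q$lf_q3))
        preset$target_hf <- jit(preset$target_hf,
                                iqr_sigma(q$hf_q1, q$hf_q3))
        alpha_fac <- exp(rnorm(1, 0, iqr_sigma(q$br_lf_q1, q$br_lf_q3)))
        preset$alpha_lf <- preset$alpha_lf * alpha_fac
        preset$alpha_hf <- preset$alpha_hf * alpha_fac
        preset$mean_rr <- jit(preset$mean_rr, iqr_sigma(q$hr_q1, q$hr_q3))
        preset$sv <- jit(preset$sv, 0.08)
        preset$sbp0 <- jit(preset$sbp0, 0.05)
        preset$resp_rate_sr <-
          min(30, max(4, jit(preset$resp_rate_sr, 0.10)))
        preset$vt <- jit(preset$vt, 0.10)
        preset
      })
    }
    sid <- sprintf("S%03d", i)
    tibble::tibble(
      subject_id = sid,
      type = type,
      seed = child_seed(seed, 2000 + i),
      recording = list(generate_recording(preset, protocol,
                                          seed = child_seed(seed, 2000 + i),
                                          subject_id = sid))
    )
  })
  dplyr::bind_rows(rows)
}

#' Inject artificial ectopic (premature) beats into a recording
#'
#' Quality-control helper: replaces `n` randomly chosen RR intervals (away
#' from the record edges) with intervals shortened to 45% of their value,
#' emulating premature beats, so rhythm screening can be exercised on
#' synthetic data.
#'
#' @param recording A `cr_recording`.
#' @param n Number of spikes to inject.
#' @param seed Integer seed.
#' @return The recording with modified `beats`.
#' @export
inject_ectopics <- function(recording, n = 3, seed = 1) {
  beats <- recording$beats
  if (nrow(beats) < n + 12) {
    cr_abort("too few beats to inject ectopics",
             class = "cardioresp_error_input")
  }
  idx <- withr::with_seed(seed, {
    sample(seq(7, nrow(beats) - 6), n)
  })
  beats$rr_ms[idx] <- beats$rr_ms[idx] * 0.45
  recording$beats <- beats
  recording
}
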