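#' Group-median profiles of the four heart-rhythm-regulation types
#'
#' Resting (spontaneous breathing) group medians for athletes of
#' heart-rhythm-regulation (HRR) types I--IV, as reported in a cohort study of
#' 183 athletes classified by the Shlyk criteria. These medians serve two
#' roles: as the reference triples for classifier checks, and as the
#' generation targets behind [make_preset()].
#'
#' Columns: `type` (I--IV), heart rate `hr` (min^-1), `sbp`/`dbp` (mmHg),
#' RR spectral powers `tp`, `vlf`, `lf`, `hf` (ms^2), stress index `si`
#' (c.u.), SBP spectral powers `lf_sbp`, `hf_sbp` (mmHg^2), cardiac output
#' `co` (dm^3 min^-1), respiratory rate `rr_resp` (min^-1), minute
#' ventilation `ve` (L min^-1), `rmssd` (ms), `pnn50` (%), `vsi`
#' (dm^3 L^-1), Hildebrandt index `hi` (c.u.), baroreflex sensitivity
#' `br_lf`, `br_hf` (ms mmHg^-1), and group size `n`.
#'
#' @return A tibble with one row per HRR type.
#' @export
#' @examples
#' hrr_type_profiles()
hrr_type_profiles <- function() {
  tibble::tribble(
    ~type, ~n,  ~hr,  ~sbp, ~dbp, ~tp,   ~vlf, ~lf,  ~hf,  ~si,   ~lf_sbp, ~hf_sbp, ~co, ~rr_resp, ~ve, ~rmssd, ~pnn50, ~vsi,  ~hi,  ~br_lf, ~br_hf,
    "I",   53L, 74.1, 114,  74,   2704,  581,  924,  1089, 172.1, 6.8,     5.3,     4.8, 15.7,     8.5, 33.6,   11.11,  0.548, 4.52, 11.29,  14.85,
    "II",  29L, 74.8, 118,  76,   1823,  169,  557,  1129, 210.0, 7.3,     5.3,     4.7, 14.7,     8.6, 31.8,   11.11,  0.572, 4.85, 9.03,   12.00,
    "III", 85L, 65.1, 114,  70,   5314,  538,  1640, 2642, 59.7,  6.3,     4.8,     4.4, 13.4,     7.6, 57.7,   13.16,  0.591, 4.82, 16.49,  21.54,
    "IV",  16L, 62.2, 110,  68,   13833, 1024, 4487, 5789, 24.9,  9.0,     4.9,     4.3, 12.9,     7.1, 110.8,  27.31,  0.648, 5.05, 25.18,  32.03
  )
}

# Inter-quartile spans used to size cohort dispersion (see make_cohort):
# lognormal sigma per variable derived from the published (Q1; Q3) spread,
# sigma = log(q3/q1) / (2 * qnorm(0.75)).
hrr_type_quartiles <- function() {
  tibble::tribble(
    ~type, ~tp_q1, ~tp_q3, ~vlf_q1, ~vlf_q3, ~lf_q1, ~lf_q3, ~hf_q1, ~hf_q3, ~br_lf_q1, ~br_lf_q3, ~hr_q1, ~hr_q3,
    "I",   2285,   4651,   335,     894,     557,    1892,   661,    1665,   8.88,      17.65,     65.1,   80.8,
    "II",  1475,   2652,   104,     207,     331,    824,    600,    1756,   8.14,      11.14,     65.4,   81.2,
    "III", 3881,   7674,   286,     882,     1018,   3352,   1282,   3931,   13.12,     21.97,     61.4,   70.8,
    "IV",  10491,  18376,  764,     1513,    3177,   9220,   2942,   11182,  20.05,     31.65,     57.5,   66.5
  )
}

#' Build a synthetic-subject preset for one HRR type
#'
#' Translates the group medians of [hrr_type_profiles()] into the parameter
#' set that drives the beat/breath generator: mean RR interval, per-band RR
#' power targets, resting pressures, baroreflex gains (the published median
#' alpha-coefficients), stroke volume (from median cardiac output and heart
#' rate), spontaneous respiratory rate and tidal volume (from median minute
#' ventilation), and the maneuver response gains.
#'
#' The maneuver gains are generator choices, not published values:
#' `rsa_gain_cr6 = 2` amplifies respiratory sinus arrhythmia under slow
#' 0.1 Hz breathing (vagal resonance), `rsa_gain_cr15 = 0.6` attenuates it
#' under mild hyperventilation, and `sbp_lf_gain_cr15 = 2` amplifies the
#' Mayer-wave component of systolic pressure at CR15 (sympathetic
#' activation), which lowers low-frequency baroreflex sensitivity there.
#'
#' @param type_label HRR type label, one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param noise_sd Standard deviation of per-beat white RR noise, ms.
#' @param noise_sd_sbp Standard deviation of per-beat SBP noise, mmHg.
#' @return A list of class `cr_preset` with fields `name`, `mean_rr` (ms),
#'   `target_vlf`, `target_lf`, `target_hf` (ms^2), `sbp0`, `dbp0` (mmHg),
#'   `alpha_lf`, `alpha_hf` (ms mmHg^-1), `sv` (ml), `resp_rate_sr`
#'   (min^-1), `vt` (L), `rsa_gain_cr6`, `rsa_gain_cr15`,
#'   `sbp_lf_gain_cr15`, `vt_gain_cr6`, `vt_gain_cr15` (tidal-volume
#'   multipliers for the paced phases), `rsa_shape` (waveform saturation;
#'   flat-topped oscillations give the compact high-stress-index histograms
#'   of sympathotonic records), `noise_sd`, `noise_sd_sbp`.
#' @export
#' @examples
#' p <- make_preset("IV")
#' p$target_lf # 4487 ms^2
make_preset <- function(type_label, noise_sd = 3, noise_sd_sbp = 1) {
  prof <- hrr_type_profiles()
  if (!is.character(type_label) || length(type_label) != 1 ||
      !type_label %in% prof$type) {
    cr_abort(
      sprintf("unknown HRR type label %s; must be one of I, II, III, IV",
              deparse(substitute(type_label))),
      class = "cardioresp_error_preset"
    )
  }
  row <- prof[prof$type == type_label, ]
  preset <- list(
    name = type_label,
    mean_rr = 60000 / row$hr,
    target_vlf = row$vlf,
    target_lf = row$lf,
    target_hf = row$hf,
    sbp0 = row$sbp,
    dbp0 = row$dbp,
    alpha_lf = row$br_lf,
    alpha_hf = row$br_hf,
    sv = 1000 * row$co / row$hr,
    resp_rate_sr = row$rr_resp,
    vt = row$ve / row$rr_resp,
    rsa_gain_cr6 = 2.0,
    rsa_gain_cr15 = 0.6,
    sbp_lf_gain_cr15 = 2.0,
    vt_gain_cr6 = 3.2,
    vt_gain_cr15 = 1.7,
    rsa_shape = rsa_shape_default(type_label),
    noise_sd = noise_sd,
    noise_sd_sbp = noise_sd_sbp
  )
  validate_preset(preset)
  structure(preset, class = "cr_preset")
}

# RSA waveform saturation per type: sympathotonic records show compact,
# flat-topped respiratory oscillations (high Baevsky stress index at a given
# total power); vagotonic records show large smooth quasi-sinusoidal RSA.
# Values sized so generated spontaneous-breathing stress indices approach
# the type medians.
rsa_shape_default <- function(type_label) {
  c(I = 3, II = 3, III = 0.5, IV = 0)[[type_label]]
}

validate_preset <- function(p) {
  stopifnot(
    p$target_vlf > 0, p$target_lf > 0, p$target_hf > 0,
    p$alpha_lf > 0, p$alpha_hf > 0,
    p$vt > 0, p$vt < 5,
    p$resp_rate_sr >= 4, p$resp_rate_sr <= 30,
    p$mean_rr > 0, p$sbp0 > p$dbp0, p$dbp0 > 0,
    p$sv > 0, p$noise_sd >= 0, p$noise_sd_sbp >= 0
  )
  invisible(p)
}

#' @export
print.cr_preset <- function(x, ...) {
  cat(sprintf("<cr_preset> HRR type %s\n", x$name))
  cat(sprintf("  mean RR %.1f ms (HR %.1f min^-1), SBP/DBP %g/%g mmHg\n",
              x$mean_rr, 60000 / x$mean_rr, x$sbp0, x$dbp0))
  cat(sprintf("  band targets VLF/LF/HF %g/%g/%g ms^2\n",
              x$target_vlf, x$target_lf, x$target_hf))
  cat(sprintf("  baroreflex alpha LF/HF %.2f/%.2f ms.mmHg^-1, SV %.1f ml\n",
              x$alpha_lf, x$alpha_hf, x$sv))
  cat(sprintf("  spontaneous breathing %.1f min^-1, VT %.2f L\n",
              x$resp_rate_sr, x$vt))
  invisible(x)
}
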