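#' Classify heart-rhythm-regulation type by the Shlyk criteria
#'
#' Assigns HRR type I--IV from the resting stress index (SI), very-low-
#' frequency power (VLF) and total power (TP):
#' type I when SI > 100 and VLF > 240; type II when SI > 100 and VLF <= 240;
#' type III when 30 <= SI <= 100 and VLF > 240; type IV when SI < 30,
#' VLF > 500 and TP > 8000. Triples covered by none of the published rules
#' (e.g. moderate SI with low VLF) return `"UNCLASSIFIED"` with a rationale
#' naming the gap rather than being forced to a nearest type. Boundary
#' conventions (inclusive 30--100, strict > 100, TP threshold at the lower
#' printed bound 8000) are overridable through `thresholds`.
#'
#' @param si Stress index, c.u. (non-negative; vectorized).
#' @param vlf VLF power, ms^2.
#' @param tp Total power, ms^2.
#' @param thresholds Named list overriding `si_hi` (100), `si_lo` (30),
#'   `vlf_split` (240), `vlf_iv` (500), `tp_iv` (8000).
#' @return A tibble with columns `label` (`"I"`, `"II"`, `"III"`, `"IV"`,
#'   `"UNCLASSIFIED"`) and `rationale` (the rule fired).
#' @export
#' @examples
#' classify_hrr(172.1, 581, 2704)  # type I
#' classify_hrr(24.9, 1024, 13833) # type IV
classify_hrr <- function(si, vlf, tp, thresholds = list()) {
  if (any(si < 0) || any(vlf < 0) || any(tp < 0)) {
    cr_abort("classification inputs must be non-negative",
             class = "cardioresp_error_input")
  }
  th <- utils::modifyList(
    list(si_hi = 100, si_lo = 30, vlf_split = 240, vlf_iv = 500,
         tp_iv = 8000),
    thresholds
  )
  one <- function(si, vlf, tp) {
    if (si > th$si_hi && vlf > th$vlf_split) {
      c("I", sprintf("SI %.4g > %g and VLF %.4g > %g", si, th$si_hi,
                     vlf, th$vlf_split))
    } else if (si > th$si_hi) {
      c("II", sprintf("SI %.4g > %g and VLF %.4g <= %g", si, th$si_hi,
                      vlf, th$vlf_split))
    } else if (si >= th$si_lo && si <= th$si_hi && vlf > th$vlf_split) {
      c("III", sprintf("SI %.4g in [%g, %g] and VLF %.4g > %g", si,
                       th$si_lo, th$si_hi, vlf, th$vlf_split))
    } else if (si < th$si_lo && vlf > th$vlf_iv && tp > th$tp_iv) {
      c("IV", sprintf("SI %.4g < %g, VLF %.4g > %g, TP %.4g > %g", si,
                      th$si_lo, vlf, th$vlf_iv, tp, th$tp_iv))
    } else {
      c("UNCLASSIFIED",
        sprintf(paste("no rule covers SI %.4g, VLF %.4g, TP %.4g:",
                      "published criteria leave this region undefined"),
                si, vlf, tp))
    }
  }
  res <- purrr::pmap(list(si, vlf, tp), function(s, v, p) one(s, v, p))
  tibble::tibble(label = purrr::map_chr(res, 1),
                 rationale = purrr::map_chr(res, 2))
}
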