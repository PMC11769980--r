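#' Spectral baroreflex sensitivity (alpha-coefficient)
#'
#' The alpha-coefficient relates RR-interval and systolic-pressure spectral
#' powers within one band. The default `"sqrt"` formula returns
#' `sqrt(p_rr / p_bp)` in ms/mmHg -- the standard spectral BRS estimator,
#' and the only formula whose output carries baroreflex-gain units. The
#' plain `"ratio"` (`p_rr / p_bp`, in ms^2/mmHg^2) is retained as an option
#' with a warning since it appears in some method descriptions but yields
#' values an order of magnitude or more away from published gains.
#'
#' @param p_rr RR band power, ms^2.
#' @param p_bp SBP band power in the same band, mmHg^2 (positive).
#' @param formula `"sqrt"` (default) or `"ratio"`.
#' @return Baroreflex sensitivity (scalar or vectorized over inputs).
#' @export
#' @examples
#' brs_alpha(924, 6.8) # 11.66 ms/mmHg
brs_alpha <- function(p_rr, p_bp, formula = c("sqrt", "ratio")) {
  formula <- match.arg(formula)
  if (any(p_bp <= 0)) {
    cr_abort("BRS undefined: pressure band power must be positive",
             class = "cardioresp_error_input")
  }
  if (formula == "ratio") {
    warn(paste("un-rooted power ratio requested: result is in ms^2/mmHg^2,",
               "not baroreflex-gain units"))
    p_rr / p_bp
  } else {
    sqrt(p_rr / p_bp)
  }
}

#' Hildebrandt index (frequency synchronization)
#'
#' Heart rate divided by respiratory rate, both per minute; a conventional
#' unit index of cardiorespiratory frequency coupling, around 4--5 at rest.
#'
#' @param hr Heart rate, min^-1.
#' @param rr_resp Respiratory rate, min^-1 (positive).
#' @return HI in conventional units (exact quotient).
#' @export
#' @examples
#' hildebrandt(74.1, 15.7)
hildebrandt <- function(hr, rr_resp) {
  if (any(rr_resp <= 0)) {
    cr_abort("Hildebrandt index undefined: respiratory rate must be positive",
             class = "cardioresp_error_input")
  }
  hr / rr_resp
}

#' Volume synchronization index
#'
#' Cardiac output (dm^3/min) divided by minute ventilation (L/min): the
#' volumetric counterpart of the Hildebrandt index, tied to oxygen
#' transport.
#'
#' @param co Cardiac output, dm^3/min.
#' @param ve Minute ventilation, L/min (positive).
#' @return VSI in dm^3/L (exact quotient).
#' @export
#' @examples
#' vsi(4.8, 8.5)
vsi <- function(co, ve) {
  if (any(ve <= 0)) {
    cr_abort("VSI undefined: minute ventilation must be positive",
             class = "cardioresp_error_input")
  }
  co / ve
}

#' Cardiac output from stroke volume and heart rate
#'
#' @param sv Stroke volume, ml (positive).
#' @param hr Heart rate, min^-1 (positive).
#' @return Cardiac output in dm^3/min (`sv * hr / 1000`).
#' @export
#' @examples
#' cardiac_output(70, 60) # 4.2
cardiac_output <- function(sv, hr) {
  if (any(is.na(sv)) || any(sv <= 0) || any(hr <= 0)) {
    cr_abort("CO unavailable: needs positive stroke volume and heart rate",
             class = "cardioresp_error_input")
  }
  sv * hr / 1000
}
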