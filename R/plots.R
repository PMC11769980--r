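#' Plot a maneuver recording
#'
#' Tachogram, beat-to-beat systolic pressure and breath-by-breath tidal
#' volume over time, with the maneuver phase boundaries marked.
#'
#' @param object A `cr_recording`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cr_recording <- function(object, ...) {
  beats <- object$beats
  long <- dplyr::bind_rows(
    tibble::tibble(t = beats$t_s, value = beats$rr_ms,
                   panel = "RR interval (ms)"),
    tibble::tibble(t = beats$t_s, value = beats$sbp_mmhg,
                   panel = "SBP (mmHg)"),
    tibble::tibble(t = object$breaths$breath_start_s,
                   value = object$breaths$vt_l,
                   panel = "Tidal volume (L)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$phases$start[-1],
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL,
                  title = sprintf("Recording %s", object$subject_id)) +
    ggplot2::theme_minimal()
}

#' Plot maneuver increments by HRR type and paced condition
#'
#' Boxplots of a chosen `delta_*` column across HRR types, split by paced
#' condition (CR6 / CR15), with the zero line for orientation.
#'
#' @param deltas Delta tibble from [analyze_cohort()]'s `deltas` element
#'   (needs `type`, `condition` and the chosen column).
#' @param index Name of the delta column to plot.
#' @return A ggplot object.
#' @export
plot_delta_summary <- function(deltas, index = "delta_hi") {
  ggplot2::ggplot(deltas,
                  ggplot2::aes(x = .data$type, y = .data[[index]],
                               fill = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "HRR type", y = index,
                  title = "Maneuver increments by regulation type") +
    ggplot2::theme_minimal()
}

#' Plot the Welch spectrum of a phase's tachogram
#'
#' @param phase_record One element of [segment_phases()] output.
#' @param bands Band edges drawn as shaded regions.
#' @return A ggplot object.
#' @export
plot_phase_spectrum <- function(phase_record, bands = default_bands()) {
  tach <- resample_tachogram(phase_record$beats$t_s,
                             phase_record$beats$rr_ms)
  spec <- welch_psd(tach$value, fs = 1 / diff(tach$t[1:2]))
  band_df <- tibble::tibble(
    band = names(bands),
    lo = purrr::map_dbl(bands, 1),
    hi = purrr::map_dbl(bands, 2)
  )
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = band_df,
                       ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                    ymin = 0, ymax = Inf,
                                    fill = .data$band), alpha = 0.15) +
    ggplot2::geom_line(data = dplyr::filter(spec, .data$freq <= 0.5),
                       ggplot2::aes(x = .data$freq, y = .data$psd)) +
    ggplot2::labs(x = "Frequency (Hz)", y = "PSD (ms²/Hz)",
                  title = sprintf("Phase %s", phase_record$label)) +
    ggplot2::theme_minimal()
}
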