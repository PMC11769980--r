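#' Compute the full index panel for one maneuver phase
#'
#' Runs every analysis on the beats and breaths of a single phase window:
#' time-domain HRV, Baevsky geometric indices, Welch band powers of the RR,
#' SBP and DBP beat-to-beat series, respiration parameters (count-based
#' respiratory rate over the window, mean tidal volume, minute ventilation
#' as their exact product), cardiac output from per-beat stroke volume, and
#' the coupling indices (spectral baroreflex sensitivity in the LF and HF
#' bands, Hildebrandt index, volume synchronization index).
#'
#' @param phase_record One element of [segment_phases()] output: a list with
#'   `label`, `beats`, `breaths`, `start`, `end`.
#' @param bands Spectral band edges, see [default_bands()].
#' @param brs_formula Passed to [brs_alpha()].
#' @return A one-row tibble with the phase label and all indices; SBP/DBP
#'   spectral columns carry `_sbp` / `_dbp` suffixes.
#' @export
phase_panel <- function(phase_record, bands = default_bands(),
                        brs_formula = "sqrt") {
  pr <- phase_record
  panel <- tryCatch({
    td <- time_domain(pr$beats$rr_ms)
    geo <- stress_index(pr$beats$rr_ms)
    rr_bands <- band_powers(
      resample_tachogram(pr$beats$t_s, pr$beats$rr_ms), bands)
    sbp_bands <- band_powers(
      resample_tachogram(pr$beats$t_s, pr$beats$sbp_mmhg), bands)
    dbp_bands <- band_powers(
      resample_tachogram(pr$beats$t_s, pr$beats$dbp_mmhg), bands)

    minutes <- (pr$end - pr$start) / 60
    rr_resp <- nrow(pr$breaths) / minutes
    vt <- mean(pr$breaths$vt_l)
    ve <- vt * rr_resp
    co <- cardiac_output(mean(pr$beats$sv_ml), td$hr)

    dplyr::bind_cols(
      tibble::tibble(phase = pr$label, n_beats = nrow(pr$beats)),
      td, geo, rr_bands,
      dplyr::rename_with(sbp_bands, ~ paste0(.x, "_sbp")),
      dplyr::rename_with(dbp_bands, ~ paste0(.x, "_dbp")),
      tibble::tibble(
        rr_resp = rr_resp, vt = vt, ve = ve, co = co,
        hi = hildebrandt(td$hr, rr_resp),
        vsi = vsi(co, ve),
        br_lf = brs_alpha(rr_bands$lf, sbp_bands$lf, brs_formula),
        br_hf = brs_alpha(rr_bands$hf, sbp_bands$hf, brs_formula)
      )
    )
  }, cardioresp_error = function(e) {
    cr_abort(sprintf("phase %s: %s", pr$label, conditionMessage(e)),
             class = "cardioresp_error_phase", parent = e)
  })
  panel
}

#' Analyze one recording into per-phase index panels
#'
#' Segments the recording by its phase annotations (or a supplied protocol)
#' and computes [phase_panel()] for every phase.
#'
#' @param recording A `cr_recording`.
#' @inheritParams segment_phases
#' @inheritParams phase_panel
#' @return A tibble with one row per phase, prefixed by `subject_id`.
#' @export
#' @examples
#' rec <- generate_recording(make_preset("I"), seed = 1)
#' analyze_recording(rec)
analyze_recording <- function(recording, protocol = NULL, min_beats = 30,
                              bands = default_bands(),
                              brs_formula = "sqrt") {
  segs <- segment_phases(recording, protocol, min_beats = min_beats)
  panels <- purrr::map(segs, phase_panel, bands = bands,
                       brs_formula = brs_formula)
  dplyr::bind_cols(
    tibble::tibble(subject_id = recording$subject_id),
    dplyr::bind_rows(panels)
  )
}

#' Per-subject maneuver increments between paced and spontaneous phases
#'
#' For two panels of the same subject, the increment of every shared numeric
#' index is paced-phase value minus spontaneous value (CR - SR). Positive
#' increments therefore mean the index rose under paced breathing.
#'
#' @param panel_sr One-row panel for the spontaneous (SR) phase.
#' @param panel_cr One-row panel for a paced (CR6 or CR15) phase of the same
#'   subject.
#' @return A one-row tibble with `subject_id`, `condition` (the paced phase
#'   label) and `delta_*` columns for every shared numeric index.
#' @export
panel_deltas <- function(panel_sr, panel_cr) {
  if (!identical(panel_sr$subject_id, panel_cr$subject_id) &&
      !is.null(panel_sr$subject_id)) {
    cr_abort("increments need two panels from the same subject",
             class = "cardioresp_error_input")
  }
  if (identical(panel_sr$phase, panel_cr$phase)) {
    cr_abort("increments need one spontaneous and one paced phase panel",
             class = "cardioresp_error_input")
  }
  num <- intersect(names(panel_sr)[purrr::map_lgl(panel_sr, is.numeric)],
                   names(panel_cr)[purrr::map_lgl(panel_cr, is.numeric)])
  d <- purrr::map(num, ~ panel_cr[[.x]] - panel_sr[[.x]])
  names(d) <- paste0("delta_", num)
  dplyr::bind_cols(
    tibble::tibble(subject_id = panel_sr$subject_id %||% NA_character_,
                   condition = panel_cr$phase),
    tibble::as_tibble(d)
  )
}

#' Maneuver increments for a table of per-phase panels
#'
#' Computes CR6 - SR and CR15 - SR increments per subject from a panel
#' table as returned by [analyze_recording()] (stacked over subjects).
#' Subjects missing any of the three phases are dropped (complete-case).
#'
#' @param panels Panel tibble with `subject_id` and `phase` columns.
#' @return A tibble with one row per subject x paced condition and
#'   `delta_*` columns.
#' @export
maneuver_deltas <- function(panels) {
  panels |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_split() |>
    purrr::keep(~ all(c("SR", "CR6", "CR15") %in% .x$phase)) |>
    purrr::map(function(p) {
      sr <- p[p$phase == "SR", ]
      dplyr::bind_rows(
        panel_deltas(sr, p[p$phase == "CR6", ]),
        panel_deltas(sr, p[p$phase == "CR15", ])
      )
    }) |>
    dplyr::bind_rows()
}

#' Group medians and quartiles of panel or delta tables
#'
#' Per-group median and 25%/75% quartiles (linear-interpolation, quantile
#' type 7) for every requested column -- the summary layout used for cohort
#' tables.
#'
#' @param data Panel or delta tibble.
#' @param cols Tidy-select of columns to summarize.
#' @param ... Grouping columns (tidy-select), e.g. `type`, `condition`.
#' @return A long tibble with `variable`, grouping columns, `n`, `q1`,
#'   `median`, `q3`.
#' @export
#' @examples
#' df <- tibble::tibble(type = c("I", "I", "II"), x = c(1, 3, 5))
#' cohort_summary(df, x, type)
cohort_summary <- function(data, cols, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(data, ..., {{ cols }}),
    cols = {{ cols }}, names_to = "variable", values_to = "value"
  )
  grouped <- dplyr::group_by(long, .data$variable,
                             dplyr::across(dplyr::all_of(
                               setdiff(names(long), c("variable", "value")))))
  empty <- dplyr::filter(dplyr::summarise(grouped, n = sum(!is.na(.data$value)),
                                          .groups = "drop"), n == 0)
  if (nrow(empty) > 0) {
    warn(sprintf("%d empty group(s) omitted from summary", nrow(empty)))
  }
  grouped |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1 = quantile(.data$value, 0.25, type = 7, names = FALSE),
      median = median(.data$value),
      q3 = quantile(.data$value, 0.75, type = 7, names = FALSE),
      .groups = "drop"
    )
}

#' Run the full analysis pipeline over a cohort
#'
#' Per subject: rhythm screening, phase segmentation, per-phase index
#' panels, HRR classification from the spontaneous-breathing panel (SI,
#' VLF, TP), and maneuver increments. Screening verdicts are always
#' reported; with `qc = TRUE` subjects with any flagged beat are dropped
#' before analysis, mirroring whole-record exclusion practice. The gate is
#' off by default because the local-median rule of [screen_rhythm()] also
#' fires on genuine high-amplitude respiratory arrhythmia -- in particular
#' the protocol-induced deep-breathing swings at CR6 and the large vagal
#' oscillations of type-IV athletes -- so excluding on it indiscriminately
#' would remove healthy high-variability subjects; in practice rhythm
#' exclusion is a manual preliminary-analysis decision. Failures in
#' individual subjects are logged and skipped; the pipeline continues.
#'
#' @param cohort Cohort tibble from [make_cohort()] or [read_cohort()].
#' @param qc Logical: drop subjects whose screening verdict is `"exclude"`.
#' @param qc_threshold Relative-deviation threshold for [screen_rhythm()].
#' @inheritParams phase_panel
#' @return A list of class `cr_cohort_analysis` with elements `panels`
#'   (subject x phase rows with generating `type` and assigned
#'   `hrr_class`), `deltas` (subject x paced-condition increments with
#'   `type`), and `qc` (per-subject screening verdicts).
#' @export
#' @examples
#' cohort <- make_cohort(sizes = c(I = 2, IV = 2), seed = 3)
#' res <- analyze_cohort(cohort)
#' res$deltas
analyze_cohort <- function(cohort, qc = FALSE, qc_threshold = 0.2,
                           bands = default_bands(), brs_formula = "sqrt") {
  qc_tab <- purrr::map(seq_len(nrow(cohort)), function(i) {
    rep <- screen_rhythm(cohort$recording[[i]]$beats,
                         threshold = qc_threshold)
    dplyr::bind_cols(tibble::tibble(subject_id = cohort$subject_id[i],
                                    type = cohort$type[i]), rep)
  }) |> dplyr::bind_rows()

  keep <- if (qc) qc_tab$verdict == "accept" else rep(TRUE, nrow(cohort))
  panels <- purrr::map(which(keep), function(i) {
    tryCatch(
      dplyr::bind_cols(
        analyze_recording(cohort$recording[[i]], bands = bands,
                          brs_formula = brs_formula),
        tibble::tibble(type = cohort$type[i])
      ),
      cardioresp_error = function(e) {
        warn(sprintf("subject %s skipped: %s", cohort$subject_id[i],
                     conditionMessage(e)))
        NULL
      }
    )
  }) |> dplyr::bind_rows()

  sr <- dplyr::filter(panels, .data$phase == "SR")
  cls <- classify_hrr(sr$si, sr$vlf, sr$tp)
  panels <- dplyr::left_join(
    panels,
    tibble::tibble(subject_id = sr$subject_id, hrr_class = cls$label),
    by = "subject_id"
  )

  deltas <- maneuver_deltas(panels) |>
    dplyr::left_join(dplyr::distinct(panels, .data$subject_id, .data$type),
                     by = "subject_id")

  structure(list(panels = panels, deltas = deltas, qc = qc_tab),
            class = "cr_cohort_analysis")
}

#' @export
print.cr_cohort_analysis <- function(x, ...) {
  cat(sprintf(
    "<cr_cohort_analysis> %d subjects analyzed (%d screened out), %d phases\n",
    dplyr::n_distinct(x$panels$subject_id),
    sum(x$qc$verdict == "exclude"),
    nrow(x$panels)
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
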