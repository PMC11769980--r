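#' Construct a maneuver recording
#'
#' Bundles a beat-by-beat series, a breath-by-breath series and the phase
#' annotations of one subject, validating the container invariants: strictly
#' increasing beat times, positive RR, SBP > DBP > 0, ordered non-overlapping
#' breaths and phase windows inside the data span.
#'
#' @param subject_id Subject identifier.
#' @param beats Tibble with columns `t_s`, `rr_ms`, `sbp_mmhg`, `dbp_mmhg`
#'   and optionally `sv_ml`.
#' @param breaths Tibble with columns `breath_start_s`, `ti_s`, `te_s`,
#'   `vt_l`.
#' @param phases Tibble with columns `label`, `start`, `end` (seconds).
#' @return A `cr_recording` object.
#' @export
new_recording <- function(subject_id, beats, breaths, phases) {
  validate_beats(beats)
  validate_breaths(breaths)
  if (nrow(phases) > 0) {
    if (any(phases$end <= phases$start) ||
        is.unsorted(phases$start, strictly = TRUE) ||
        any(phases$start[-1] < phases$end[-nrow(phases)])) {
      cr_abort("phase windows must be ordered and non-overlapping",
               class = "cardioresp_error_input")
    }
  }
  structure(
    list(subject_id = subject_id, beats = beats,
         breaths = breaths, phases = phases),
    class = "cr_recording"
  )
}

#' @export
print.cr_recording <- function(x, ...) {
  cat(sprintf("<cr_recording> subject %s: %d beats, %d breaths, %d phases\n",
              x$subject_id, nrow(x$beats), nrow(x$breaths), nrow(x$phases)))
  if (nrow(x$phases)) {
    cat(sprintf("  phases: %s\n",
                paste(sprintf("%s [%g, %g)", x$phases$label,
                              x$phases$start, x$phases$end),
                      collapse = ", ")))
  }
  invisible(x)
}

validate_beats <- function(beats) {
  need <- c("t_s", "rr_ms", "sbp_mmhg", "dbp_mmhg")
  missing <- setdiff(need, names(beats))
  if (length(missing)) {
    cr_abort(paste("beat series lacks column(s):",
                   paste(missing, collapse = ", ")),
             class = "cardioresp_error_parse")
  }
  bad <- which(diff(beats$t_s) <= 0)
  if (length(bad)) {
    cr_abort(sprintf("beat times not strictly increasing at row %d", bad[1] + 1),
             class = "cardioresp_error_parse")
  }
  bad <- which(beats$rr_ms <= 0)
  if (length(bad)) {
    cr_abort(sprintf("non-positive RR interval at row %d", bad[1]),
             class = "cardioresp_error_parse")
  }
  bad <- which(!(beats$sbp_mmhg > beats$dbp_mmhg & beats$dbp_mmhg > 0))
  if (length(bad)) {
    cr_abort(sprintf("pressure invariant SBP > DBP > 0 violated at row %d",
                     bad[1]),
             class = "cardioresp_error_parse")
  }
  invisible(beats)
}

validate_breaths <- function(breaths) {
  need <- c("breath_start_s", "ti_s", "te_s", "vt_l")
  missing <- setdiff(need, names(breaths))
  if (length(missing)) {
    cr_abort(paste("breath series lacks column(s):",
                   paste(missing, collapse = ", ")),
             class = "cardioresp_error_parse")
  }
  bad <- which(breaths$ti_s <= 0 | breaths$te_s <= 0 | breaths$vt_l <= 0)
  if (length(bad)) {
    cr_abort(sprintf("non-positive breath duration or volume at row %d", bad[1]),
             class = "cardioresp_error_parse")
  }
  if (nrow(breaths) > 1) {
    ends <- breaths$breath_start_s + breaths$ti_s + breaths$te_s
    # 1e-4 s slack: written series are rounded to 6 decimals
    if (is.unsorted(breaths$breath_start_s, strictly = TRUE) ||
        any(breaths$breath_start_s[-1] < ends[-nrow(breaths)] - 1e-4)) {
      cr_abort("breaths must be ordered and non-overlapping",
               class = "cardioresp_error_parse")
    }
  }
  invisible(breaths)
}

#' Read and write beat-by-beat series
#'
#' The beat CSV dialect has header `t_s,rr_ms,sbp_mmhg,dbp_mmhg` with an
#' optional `sv_ml` column, decimal point, UTF-8. A write/read round trip is
#' lossless to 6 decimal places. Parse errors name the offending row.
#'
#' @param path File path.
#' @return `read_beats()` returns the beat tibble; `write_beats()` returns
#'   `path` invisibly.
#' @export
read_beats <- function(path) {
  beats <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_double()))
  validate_beats(beats)
  beats
}

#' @rdname read_beats
#' @param beats Beat tibble as returned by [read_beats()] or
#'   [generate_beats()].
#' @export
write_beats <- function(beats, path) {
  validate_beats(beats)
  readr::write_csv(dplyr::mutate(beats, dplyr::across(
    dplyr::everything(), ~ round(.x, 6))), path)
  invisible(path)
}

#' Read and write breath-by-breath series
#'
#' The breath CSV dialect has header `breath_start_s,ti_s,te_s,vt_l`.
#'
#' @param path File path.
#' @return `read_breaths()` returns the breath tibble; `write_breaths()`
#'   returns `path` invisibly.
#' @export
read_breaths <- function(path) {
  breaths <- readr::read_csv(path, show_col_types = FALSE,
                             col_types = readr::cols(.default = readr::col_double()))
  validate_breaths(breaths)
  breaths
}

#' @rdname read_breaths
#' @param breaths Breath tibble.
#' @export
write_breaths <- function(breaths, path) {
  validate_breaths(breaths)
  readr::write_csv(dplyr::mutate(breaths, dplyr::across(
    dplyr::everything(), ~ round(.x, 6))), path)
  invisible(path)
}

#' Split a recording into per-phase records
#'
#' Beats are assigned to a phase iff the beat time lies in `[start, end)`
#' (half-open, so boundary beats are never double counted); breaths iff the
#' breath start lies in the window. Every phase must retain at least
#' `min_beats` beats to be analyzable.
#'
#' @param recording A `cr_recording`.
#' @param protocol Optional phase table ([default_protocol()] layout); by
#'   default the recording's own phase annotations are used.
#' @param min_beats Minimum beats per phase below which an error is raised.
#' @return A named list of per-phase records, each a list with `label`,
#'   `beats`, `breaths`, `start`, `end`.
#' @export
segment_phases <- function(recording, protocol = NULL, min_beats = 30) {
  phases <- if (is.null(protocol)) {
    recording$phases
  } else {
    starts <- cumsum(c(0, protocol$duration[-nrow(protocol)]))
    tibble::tibble(label = protocol$label, start = starts,
                   end = starts + protocol$duration)
  }
  # the final beat precedes the window end by up to one RR interval, so
  # allow a 2 s shortfall before declaring the recording too short
  span <- range(recording$beats$t_s)
  if (span[2] < max(phases$end) - 2 || min(phases$start) < span[1] - 1e-9) {
    cr_abort("recording is shorter than the protocol span",
             class = "cardioresp_error_input")
  }
  out <- purrr::map(seq_len(nrow(phases)), function(i) {
    lo <- phases$start[i]
    hi <- phases$end[i]
    beats <- dplyr::filter(recording$beats, .data$t_s >= lo, .data$t_s < hi)
    breaths <- dplyr::filter(recording$breaths,
                             .data$breath_start_s >= lo,
                             .data$breath_start_s < hi)
    if (nrow(beats) < min_beats) {
      cr_abort(sprintf("phase %s has < %d beats", phases$label[i], min_beats),
               class = "cardioresp_error_qc")
    }
    list(label = phases$label[i], beats = beats, breaths = breaths,
         start = lo, end = hi)
  })
  stats::setNames(out, phases$label)
}

#' Screen a beat series for ectopic beats
#'
#' A beat is flagged ectopic when its RR interval deviates from the local
#' median (window of 11 beats, truncated at the record edges) by more than
#' `threshold` times that median. Any flagged beat yields the verdict
#' `"exclude"`, mirroring whole-record exclusion of rhythm disturbances.
#'
#' @param beats Beat tibble (needs `rr_ms`; at least 10 beats).
#' @param threshold Relative deviation from the local median that flags a
#'   beat; default 0.2.
#' @return A tibble (one row) with `n_beats`, `ectopic_fraction`, `verdict`.
#' @export
#' @examples
#' rec <- generate_recording(make_preset("I"), seed = 1)
#' screen_rhythm(rec$beats)
screen_rhythm <- function(beats, threshold = 0.2) {
  rr <- beats$rr_ms
  if (length(rr) < 10) {
    cr_abort("rhythm screening needs at least 10 beats",
             class = "cardioresp_error_qc")
  }
  med <- runmed(rr, k = 11, endrule = "median")
  flag <- abs(rr - med) > threshold * med
  tibble::tibble(
    n_beats = length(rr),
    ectopic_fraction = mean(flag),
    verdict = if (any(flag)) "exclude" else "accept"
  )
}

#' Write and read a cohort as per-subject CSV files plus a JSON manifest
#'
#' Each subject gets a beat CSV and a breath CSV in the [read_beats()] /
#' [read_breaths()] dialects; the manifest records subject id, HRR type,
#' seed, phase annotations and file paths.
#'
#' @param cohort Cohort tibble from [make_cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns the manifest path invisibly;
#'   `read_cohort()` returns a cohort tibble.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- purrr::map(seq_len(nrow(cohort)), function(i) {
    rec <- cohort$recording[[i]]
    sid <- cohort$subject_id[i]
    beats_file <- file.path(dir, paste0(sid, "_beats.csv"))
    breaths_file <- file.path(dir, paste0(sid, "_breaths.csv"))
    write_beats(rec$beats, beats_file)
    write_breaths(rec$breaths, breaths_file)
    list(subject_id = sid, type = cohort$type[i], seed = cohort$seed[i],
         beats = basename(beats_file), breaths = basename(breaths_file),
         phases = rec$phases)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(manifest)
}

#' @rdname write_cohort
#' @param manifest Path to a manifest written by [write_cohort()].
#' @export
read_cohort <- function(manifest) {
  entries <- jsonlite::read_json(manifest, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  dir <- dirname(manifest)
  rows <- purrr::map(entries, function(e) {
    phases <- tibble::as_tibble(e$phases)
    rec <- new_recording(
      subject_id = e$subject_id,
      beats = read_beats(file.path(dir, e$beats)),
      breaths = read_breaths(file.path(dir, e$breaths)),
      phases = phases
    )
    tibble::tibble(subject_id = e$subject_id, type = e$type,
                   seed = e$seed, recording = list(rec))
  })
  dplyr::bind_rows(rows)
}
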