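Package: cardioresp
Title: Combined Cardiorespiratory Variability Analysis for Paced-Breathing Maneuvers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of combined beat-to-beat cardiovascular and
    breath-by-breath respiratory recordings across a three-phase breathing
    maneuver (spontaneous breathing, paced breathing at 6 and 15 breaths per
    minute). Computes time-domain and spectral heart rate variability,
    blood-pressure variability, spectral baroreflex sensitivity
    (alpha-coefficient), Baevsky stress index, the Shlyk heart-rhythm-regulation
    typology, and frequency (Hildebrandt) and volume synchronization indices;
    derives per-subject maneuver increments and cohort summaries with Wilcoxon
    matched-pairs, rank-sum and unbalanced sequential two-way ANOVA statistics.
    Includes a baroreflex-coupled synthetic-cohort generator with presets for
    the four heart-rhythm-regulation types so the full pipeline is testable
    without physiological hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
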