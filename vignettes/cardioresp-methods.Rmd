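---
title: "Methods: combined cardiorespiratory analysis of a paced-breathing maneuver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined cardiorespiratory analysis of a paced-breathing maneuver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioresp)
```

## The measurement and the question

A combined cardiorespiratory examination records, beat by beat, the RR
interval, systolic and diastolic finger pressure and stroke volume, and,
breath by breath, inspiratory/expiratory durations and tidal volume, over a
6-minute protocol: 2 minutes of spontaneous breathing (SR), 2 minutes paced
at 6 breaths/min (CR6; 5 s in, 5 s out, 0.1 Hz) and 2 minutes paced at
15 breaths/min (CR15; 2 s in, 2 s out, 0.25 Hz). CR6 is a vagal
(baroreflex-resonant) stimulus; CR15 imposes a non-physiological 1:1
timing ratio that produces mild hyperventilation and sympathetic
activation. The analysis question is how indices of cardiovascular coupling
(spectral baroreflex sensitivity) and cardiorespiratory coupling
(Hildebrandt index, volume synchronization index) move between phases, and
how those movements differ across the four Shlyk
heart-rhythm-regulation (HRR) types.

## Indices

For every phase the package computes:

* **Time domain** — mean RR, HR = 60000/RR, RMSSD (root mean square of
  successive differences, ms), pNN50 (% of successive differences over
  50 ms).
* **Baevsky geometric** — RR histogram with 50 ms bins anchored at zero;
  Mo = modal-bin midpoint (s), AMo = % of intervals in the modal bin,
  MxDMn = interval range (s), stress index SI = AMo / (2 · Mo · MxDMn)
  (c.u.). The 50 ms bin and the second/percent unit mix are the only
  convention under which the classical SI bands (30, 100 c.u.) make
  dimensional sense.
* **Spectral** — the beat series is cubic-spline resampled to 4 Hz,
  linearly detrended, and Welch-estimated (Hann window, segments of
  min(100 s, record), 50% overlap). Band powers integrate the one-sided
  density over VLF 0.0033–0.04, LF 0.04–0.15, HF 0.15–0.40 Hz; TP is the
  integral over the union. The same path is applied to systolic and
  diastolic series in mmHg². VLF from a 2-minute segment has coarse
  resolution and is reported as-is; it is used only against generous
  thresholds (240/500 ms²), not as a precise power.
* **Coupling** — baroreflex sensitivity by the spectral alpha-coefficient
  `sqrt(P_RR / P_SBP)` per band (BR~LF~, BR~HF~, ms·mmHg⁻¹); Hildebrandt
  index HI = HR/RR (heart beats per breath); cardiac output CO = SV·HR/1000;
  minute ventilation V~E~ = V~T~·RR (exactly, with the count-based
  per-minute respiratory rate); volume synchronization index VSI = CO/V~E~.

The square root in the alpha-coefficient is deliberate: applied to the
published per-type group medians it reproduces the published median BR~LF~
within 3–12% for all four types, whereas the plain power ratio is off by
roughly an order of magnitude and carries the wrong units (ms²/mmHg²). The
plain ratio remains available behind a warning.

## Classification

HRR types follow the Shlyk criteria on resting (SR) values: type I
(SI > 100, VLF > 240), II (SI > 100, VLF ≤ 240), III (30 ≤ SI ≤ 100,
VLF > 240), IV (SI < 30, VLF > 500, TP > 8000). The published rules do not
cover the whole (SI, VLF, TP) space; uncovered triples return
`UNCLASSIFIED` with a rationale string rather than a forced nearest type.
Boundary conventions (inclusive 30–100; strict >100; the TP bound at the
lower printed value 8000) are explicit choices and overridable.

## Maneuver increments and group statistics

Increments are per subject, paced phase minus spontaneous (CR − SR), for
every numeric index; subjects missing a phase are dropped whole
(complete-case), mirroring whole-record exclusion. Note the sign: published
increment tables head their columns "SR—CR" yet report positive values for
indices that rise under paced breathing, which forces the CR − SR reading.

Cohort tables report medians with 25–75% quartiles (linear-interpolation,
type-7 quantiles). Paired phase comparisons use the Wilcoxon signed-rank
test: exact (tie-aware generating-function distribution) up to 20 non-zero
pairs, tie- and continuity-corrected normal approximation above, |z|
reported. Between-group comparisons use the Mann–Whitney rank-sum test —
the conventional companion of a fully nonparametric design; the source
tables never name their between-group test, so this is an assumption and is
labelled as such.

The two-way ANOVA of increments uses **sequential (Type I) sums of
squares** — condition (CR6/CR15) first, then HRR type, then the
interaction — fitted by least squares. Sequential projections are
orthogonal, so the components add up exactly to the total SS even with
heavily unbalanced groups (53/29/85/16); that additivity is visible in the
published tables and is what Type III decompositions would not satisfy.
With 183 subjects × 2 conditions the design yields the characteristic
df pattern (1, 3, 3, 358). `assemble_anova_table()` finishes a printed
SS/df decomposition into MS, F and p, which is how the shipped reference
decompositions are checked.

## The synthetic cohort

No raw data accompany the study, so the package carries a generator whose
defaults *are* the study conditions: the three-phase protocol above and the
published per-type medians as targets — band powers (e.g. type IV:
VLF 1024, LF 4487, HF 5789 ms²), baroreflex gains (the median BR~LF~ and
BR~HF~ as `alpha_lf`, `alpha_hf`), heart rate, pressures, stroke volume
(from median CO and HR), spontaneous respiratory rate and tidal volume
(from median V~E~), and cohort composition 53/29/85/16.

Beats are laid down by an integrate-to-next-beat rule
(t~k+1~ = t~k~ + RR(t~k~)/1000) over an RR process of additive
oscillations plus white noise (default 3 ms): one slow VLF component at
0.013 Hz, a 0.1 Hz Mayer-wave component, and a respiratory component
riding the phase-continuous instantaneous breathing frequency, so its
energy lands in HF during spontaneous and CR15 breathing and moves into
the LF band at CR6 — the mechanism behind the maneuver's delta patterns.
Systolic pressure mirrors the oscillations scaled by 1/alpha, so the
spectral alpha-coefficient of a generated record recovers the preset gain;
diastolic pressure is systolic minus a fixed 40 mmHg pulse pressure plus
noise (produced, not calibrated); stroke volume is constant.

Three generator choices deserve justification:

* **Waveform shape.** A sum of several comparable sinusoids has a
  near-Gaussian marginal, and at the published type-I total power such a
  record cannot exceed SI ≈ 90 — the classifier would never assign type I.
  Real sympathotonic records are compact and peaked. The generator
  therefore uses saturated sines, `tanh(k·sin)` normalized to sine power,
  with per-type k (I/II: 3, III: 0.5, IV: 0), and one concentrated VLF
  component rather than several: flat-topped oscillations concentrate the
  histogram and shrink its range per unit power, lifting generated type-I
  SI to ~105–130 while keeping median LF/HF estimates within ~6% of
  targets (worst single noise-free record ~16%, the cost of harmonic
  spill). Saturation harmonics of spontaneous-rate breathing fall above
  0.4 Hz and leave the analyzed bands clean.
* **Maneuver response gains.** RSA amplitude is multiplied by 2.0 at CR6
  (vagal resonance) and 0.6 at CR15, on the cardiac side only; the
  pressure-side respiratory component keeps its resting scale. At CR15 the
  systolic 0.1 Hz Mayer component is additionally doubled
  (hyperventilation-driven sympathetic activation). Together these produce
  the observed sign structure: BR~LF~ rises at CR6 and falls at CR15,
  BR~HF~ falls at CR15. Tidal volume is multiplied by 3.2 at CR6 (deep
  slow breathing, V~E~ ≈ 10 L/min) and 1.7 at CR15 (mild hyperventilation,
  V~E~ ≈ 14 L/min, within the described range), which makes VSI fall in
  both paced phases. These are calibration knobs of the generator, chosen
  once from the described physiology, not published claims.
* **Dispersion.** The study reports only medians and quartiles, so
  subject-level spread is modelled as lognormal jitter with
  sigma = log(Q3/Q1)/(2·qnorm(0.75)) per type for band powers, gains and
  heart rate, and mild fixed spreads (5–10%) elsewhere. This preserves the
  published central tendency and inter-quartile geometry but invents the
  tail behaviour.

Seeding: one master seed; every subject, phase and noise stream uses a
deterministically derived child seed (`(s·48271 + i·7919) mod (2³¹−1)`), so
cohorts are bit-reproducible.

What passing simulator-based tests shows — and does not. They show the
analysis chain is self-consistent: it recovers known powers and gains,
classifies generated types back (≥ 96% over 50 seeds per type), and
reproduces the qualitative maneuver structure (median δHI > 0 at CR6
everywhere, |median δHI| < 1 at CR15 for types III/IV, median δBR~LF~ < 0
at CR15 everywhere, df pattern 1/3/3/358). They do not validate the
generator against real physiology: real RR series have broadband fractal
structure, ectopy, drifting respiratory rates and baroreflex nonlinearity
that the model omits, and published subject-level magnitudes are not
reproducible without the raw data.

## Quality screening

`screen_rhythm()` flags beats deviating from an 11-beat local median by
more than 20% of it — a standard premature-beat heuristic. On
low-variability records it is selective (tests reproduce a 3-of-17
exclusion batch). It is reported but not used as an automatic gate in
`analyze_cohort()`: measured on clean synthetic cohorts, protocol-induced
deep-breathing swings and the large vagal oscillations of type-IV athletes
deviate by up to 170% of the local median, far beyond any spike threshold,
so gating on the rule would discard healthy high-variability subjects. In
the source setting, rhythm exclusion was a manual preliminary-analysis
decision (11 records of 194).

## Numerical conventions and degenerate inputs

Half-open phase windows [start, end) prevent double-counting boundary
beats. Phases need ≥ 30 beats, spectral analysis ≥ 60 s and ≥ 30 points.
SI is undefined (error) for constant series; BRS for zero pressure power;
HI/VSI for non-positive denominators. The Wilcoxon exact/approximate
switch sits at n = 20 (configurable); both branches agree within 0.01
there. CSV round trips are exact to 6 decimals. All errors carry the
`cardioresp_error` condition class.

## Problem sizes

The shipped tests and the acceptance script run, per invocation: one full
synthetic cohort (183 subjects × 3 phases), 200 single-phase recordings
for type recovery (50 seeds × 4 types), and 80 noise-free recordings for
calibration (20 seeds × 4 types) — a few minutes end to end, scaled so the
whole evidence chain reruns routinely.

## Known limitations

Open-loop generator (no closed baroreflex feedback, unlike DeBoer-type
models); no ectopic simulation beyond the uniform spike injector; VLF on
2-minute segments is a coarse estimate; DBP variability uncalibrated;
between-group test identity assumed; published cohort proportions are not
a reproduction target.
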