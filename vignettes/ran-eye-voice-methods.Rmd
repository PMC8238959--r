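---
title: "Methods: eye-voice coordination analysis for rapid automatized naming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eye-voice coordination analysis for rapid automatized naming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ranevs)
```

## The task and the measurements

In a rapid automatized naming (RAN) task a participant names a grid of 36
highly familiar items (colored circles, simple objects, digits, or letters)
as fast and accurately as possible, left to right within each row and top to
bottom across rows. Number and letter runs form the *symbolic* condition,
color and object runs the *non-symbolic* condition; each stimulus type is
administered twice, giving eight runs per participant. Two synchronized
streams are recorded on a common run-relative clock: gaze samples from an
eye tracker (nominally 60 Hz, binocular, screen pixels) and per-item
articulation intervals from a forced aligner, with error annotations added
by human coders. `ranevs` turns those two streams into per-run measures of
eye-voice coordination and fits the group-level models for a two-diagnosis
by two-culture design.

The per-run measures are:

* **Naming time** — offset of the last articulation minus onset of the
  first, errors included.
* **Errors** — the sum of all annotations (repetition, omission,
  substitution, self-correction); an event carrying two tags counts twice.
* **Eye-voice span (EVS)** — at the onset of each item's articulation, the
  signed number of items by which the currently fixated item leads the item
  being spoken; the run value is the mean over eligible onsets. Units are
  items, typically 1-1.6 in fluent naming.
* **Total fixations** — raw count of retained-item fixations, before any
  pooling of repeats.
* **Perseverations** — consecutively repeated fixations within one item's
  area of interest (AOI); a block of *m* repeats contributes *m − 1*.
* **Regressions** — backward eye movements landing on a previously visited
  lower-index item.
* **Refixations** — perseverations plus regressions.

## AOI geometry

`build_array_layout()` places the 36 items on a uniform grid (default 4 rows
by 9 columns, the shape implied by practice rows of nine symbols; both are
configurable) and tiles the surrounding region with axis-aligned AOI
rectangles whose shared boundaries bisect the distance between adjacent item
centers. Edge AOIs extend outward by the same half-spacing rather than to
the screen edge, so gaze parked far off the array is recognized as
off-array instead of being absorbed by a border item. Rectangles are
half-open (`[left, right) × [top, bottom)`), which removes boundary
ambiguity: every in-grid point belongs to exactly one AOI, a property the
test suite checks by dense lattice sampling. Coordinates are screen pixels
with the origin top-left and serial indices 0-based in reading order.

The physical item spacing and glyph size of real stimulus cards are not
modeled; the default grid spreads centers uniformly with one half-spacing of
margin, which is all the AOI logic consumes.

## From gaze samples to fixations

Gaze is reduced to a cyclopean point by a *strict* binocular average: the
mean of the two eyes when both are valid, and no point at all otherwise.
One tracked eye is not enough; this is deliberately conservative for
populations with frequent partial track loss, and the per-run invalid
fraction doubles as the track-loss QC statistic.

Pixel displacements convert to visual angle by planar trigonometry through
the physical pixel pitch and viewing distance (`screen_geometry()`,
defaults 1280 × 1024 px on a 41.6 × 33.3 cm panel at 57 cm — the midpoint
of a typical 50-60 cm seating range; override per dataset).

`ivt_classify()` implements velocity-threshold (I-VT) classification with
the parameter set standard for this task family
(`ivt_params()`):

| parameter | default | role |
|---|---|---|
| `velocity_threshold_deg_s` | 35 | fixation samples are strictly below |
| `merge_max_gap_ms` | 100 | max gap between merging candidates |
| `merge_max_angle_deg` | 0.5 | max centroid separation for merging |
| `min_fixation_ms` | 100 | minimum retained fixation duration |

Numerical choices worth knowing:

* Velocity at sample *i* is the central difference over `(i − 1, i + 1)`
  when both neighbors carry valid points, one-sided when only one does, and
  undefined (the sample is unclassifiable and breaks candidate runs) when
  neither does. Invalid stretches are never interpolated across; the merge
  step is what bridges short dropouts, and only when the gap and angle
  rules both hold.
* A sample at exactly the threshold velocity is a saccade sample (the
  threshold is exclusive for fixations). All threshold comparisons carry a
  1e-9 absolute tolerance so constructed boundary cases land
  deterministically on the documented side despite floating-point error in
  the pixel-angle trigonometry.
* A fixation's end time is its last member sample plus one sample period,
  so an *n*-sample fixation at a uniform rate has duration *n* periods and
  gaps between clusters equal the blanked wall-clock time.
* Gap samples never contribute to a merged centroid (there are none: only
  fixation samples are members).
* No gap-filling of short invalid windows is performed before
  classification; whether vendor filters do so is generally undocumented,
  and the merge rule covers the same ground transparently.

## Aligning eyes and voice

Both streams use seconds from run onset, so alignment is translation-free.
`fixated_item_at()` resolves the gaze state at a vocal onset by containment
in a fixation's `[start, end)` interval; an onset falling in a saccade or
dropout resolves to the most recent preceding AOI-bearing fixation
(carry-forward), and onsets before any fixation yield no sample. EVS is
computed against the *intended* serial position, so a substituted word
still anchors to its array slot, and omissions contribute no EVS sample.
Carry-forward is the simplest deterministic rule for mid-saccade onsets;
alternatives (e.g. nearest fixation in time) are not implemented.

## Quality control and aggregation

`evaluate_run_qc()` applies three run-level rules, accumulating every
failing reason rather than short-circuiting: more than 35% of samples
without a valid binocular point (`track_loss`); any fixation-free interval
longer than 10 s, including the run's edges (`fixation_gap`); and a
detected-fixation count outside 15-50 for symbolic or 20-55 for
non-symbolic runs (`fixation_count`, bounds inclusive). The track-loss rule
is operationalized on the invalid-sample fraction of the run — the natural
reading of a sample-level dropout criterion — and the fraction is
configurable if a duration-weighted variant is preferred.

Eye movements on the first two and last four items of each array are
excluded from analysis (`positional_exclusion_mask()`, 30 retained items of
36): edge items attract long return sweeps and mistargeting. The exclusion
applies to the scanpath metrics and to EVS onset eligibility, but not to
naming time or errors, which are defined over all 36 items.

`aggregate_conditions()` averages passing runs in two stages — over the (up
to two) runs of each stimulus type, then over the two types of each
condition — which equals the simple mean when all four runs survive and
otherwise weights the two stimulus types equally. Participants keep a
condition summary as long as one run survives; only all-excluded conditions
drop out. `exclusion_accounting()` tallies excluded fractions per
diagnosis-by-culture group for the exclusion-rate comparison
(`chisq_counts()`).

## Group-level inference

`fit_group_model()` regresses one metric, separately per condition, on
culture, diagnosis, and their interaction, with sex and age as control
covariates and IQ added for the naming-performance metrics only. With
repeated rows per participant (e.g. run-level data) it fits a linear mixed
model with a random by-participant intercept (REML, Satterthwaite degrees
of freedom via `lmerTest`); with one row per participant — the usual
condition-summary case — the random intercept is unidentifiable and the
same fixed-effects model is fitted by ordinary least squares. A
likelihood-ratio comparison of models with and without the interaction is
reported alongside, but inference always proceeds with the interaction
retained.

Factor coding is treatment coding with **ASD and HK as reference levels**,
so the reported `diagnosis` estimate is control − ASD and `culture` is
US − HK: a *negative* estimate means the ASD (or HK) cell is higher. This
matches the sign convention of the cross-cultural reports this design
mirrors; flip the factor levels before fitting if the opposite orientation
is wanted. Covariates enter on their raw scales (no centering), which
affects the intercept only, not the reported terms.

Families of p-values are adjusted with Benjamini-Hochberg (`bh_adjust()`),
conventionally read against a false-discovery rate of 0.10 — a deliberately
permissive level for modest samples. Significant models are followed by
Tukey-adjusted least-square-means contrasts of the four cells
(`pairwise_contrasts()`, via `emmeans`). Skewed error counts get
`mann_whitney()` (exact by enumeration for untied samples with
n1 + n2 ≤ 12, tie-corrected normal approximation otherwise), and
symptom-severity correlates use `partial_pearson()` (residualize on the
covariates, correlate, t-transform with df = n − 2 − k). Whether a
self-corrected substitution should count once or twice is a coding-manual
question; the counters here count tags, so it counts twice.

## The synthetic generator

No public gaze/voice corpus accompanies this design, so validation rests on
`simulate_run()`: a generative model whose ground truth the pipeline must
recover. The voice names items serially with lognormal durations
(mean 0.45 s, CV 0.25, clamped at 0.32 s, 50 ms pauses — an ~18 s run,
between typical symbolic and non-symbolic naming times). Gaze occupies item
`i + round(lead)` (default lead 1) during item *i*'s articulation, jumping
80 ms before each onset (eyes lead the voice at saccade initiation, and the
anticipation keeps the new fixation established by onset even if a couple
of boundary samples are lost). On eligible items — gaze target inside the
retained range, window long enough for an extra 0.18 s fixation — a
perseveration is injected with probability 0.2 (a repeat fixation displaced
2.2° vertically within the same AOI: far enough above the 1.17° step that
corresponds to the 35°/s threshold at 60 Hz that centroid noise cannot fuse
the pair, yet well inside the ~3.3° AOI half-height) and a regression with
probability 0.1 (a fixation on a previously visited retained item at most 3
back, drawn uniformly). Fixation centroids get 0.2° Gaussian noise and each
sample is invalidated independently with probability 0.05. Every injected
event, trial, per-onset lead, naming time, and error tag is recorded as
ground truth, and the whole run is reproducible from its seed.

Default event rates put expected refixations near 9 per run and detected
fixation counts in the high 30s-40s, inside the QC bounds; naming errors
are injected as substitution/self-correction *tags* (3% of items) so the
timing ground truth stays exact, while omissions and repetitions are
exercised through the readers and counters rather than generated.

What the generator does **not** emulate: within-fixation oculomotor noise
(samples are constant within a scripted fixation, so I-VT recovers segment
boundaries essentially exactly), smooth pursuit, saccade kinematics
(position jumps are instantaneous between samples), calibration drift,
blink dynamics (loss is independent per sample, not bursty), and any
coupling between speech errors and gaze behavior. Passing recovery tests
therefore certifies the *measurement* pipeline — detection, assignment,
alignment, counting, exclusion, aggregation, inference — not robustness to
every oculomotor artifact of real recordings.

`simulate_cohort()` builds diagnosis-by-culture cohorts at two levels.
`level = "samples"` synthesizes full traces and scores them through the
real pipeline. `level = "metrics"` draws run metrics directly from the same
generative quantities — binomial event counts over the nominal 30/29
retained-item trials with a participant-level logit-normal rate shift
(SD 0.3), lognormal naming times with a participant speed factor, the
injected lead plus small resolution jitter — which is the right tool for
replicated power and null studies of the model layer: the sample-to-metric
equivalence is pinned separately by the full-pipeline recovery checks, so
the replications need not pay for gaze synthesis. Demographic covariates
(age ~ N(19, 6) clamped to 10-35, IQ ~ N(108, 14) clamped to 80-145, ~60%
male, ADOS severity ~ N(5.8, 2.4) clamped to 1-10 for ASD groups — ranges
typical of adolescent/adult cross-cultural ASD cohorts) are generated as
pure nuisance: they carry no effect, so covariate-adjustment code paths are
exercised without confounding the injected group effects.

## Validation summary

The test suite (and `scripts/acceptance.R`, which recomputes everything
from scratch) checks four things at fixed problem sizes chosen to keep the
full run in minutes on one CPU:

1. **Boundary fidelity** — parameter sweeps with exactly-constructed traces
   locate every classifier and QC boundary at its stated value: 35°/s,
   100 ms minimum duration, 100 ms / 0.5° merge rules, 35% track loss,
   10 s fixation-free gap, 15-50 and 20-55 fixation bounds.
2. **Oracle equivalence** — AOI assignment, perseveration/regression
   counts, BH adjustment, exact Mann-Whitney p, and chi-squared agree with
   independent brute-force recomputations on ≥ 1000 random instances each.
3. **Parameter recovery** — over 100 simulated runs at default noise, the
   mean recovered EVS sits within 0.1 items of the injected lead and the
   event probabilities within 0.02 of their injected values; an injected
   ASD excess of 0.05 in regression probability yields a negative diagnosis
   estimate in ≥ 95% of 200 cohort replicates at 40 per group; with no
   injected effects the diagnosis test rejects at a rate inside the
   binomial 95% interval around 0.05 over 1000 replicates at 15 per group.
4. **Determinism** — a fixed seed reproduces byte-identical metric tables
   through the entire pipeline.

## Known limitations

* The carry-forward EVS rule and the non-gap-filling I-VT variant are
  documented defaults, not reconstructions of any vendor's or prior
  study's exact code path; both are single-switch choices a re-analysis
  could flip.
* The track-loss criterion uses the sample fraction; a fixation-duration-
  weighted reading would need only a different statistic in
  `evaluate_run_qc()`.
* Whether "total fixations" should be counted before or after pooling
  repeats is ambiguous in the field; the raw (pre-pooling) count is
  primary here, and the pooled count is recoverable as
  `total_fixations - perseverations`.
* TextGrid support covers the long interval-tier format with a `word`
  tier; omissions cannot be represented there and require the delimited
  table format.
* The group model assumes approximately normal metric distributions;
  error counts are the documented exception and get the rank test.
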