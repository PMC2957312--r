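---
title: "Quantifying neuromotor performance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuromotor performance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocat)
```

## Scope

`neurocat` is a hardware-free implementation of a portable computerized
neuromotor test battery of the kind used to quantify parkinsonian motor
signs: tremor (a biaxial accelerometer stylus), bradykinesia (a touch
plate recording maximum-frequency tapping), simple reaction time (a
hand-held click device), and postural sway (a three-sensor static
posturography plate). The package provides the metric computations, the
standardized evaluation protocol, seeded synthetic-signal generators
that emulate parkinsonian (PD) and control cohorts, and the
nonparametric statistics used to compare groups and relate metrics to
clinician-rated item scores.

## Tremor metrics

A stylus trace is a uniformly sampled acceleration signal in m/s²; when
two perpendicular axes are recorded, the per-sample Euclidean norm is
analyzed, since every reported metric is scalar. All spectral analysis
is confined to the 0.9–15.0 Hz band, which covers pathological and
physiological upper-extremity tremor while excluding slow voluntary
movement and high-frequency sensor noise.

The spectral estimate is a Welch average: Hann window, 256-sample
segments, 50 % overlap. At the default 125 Hz sampling rate an 8.192 s
task (1024 samples — the protocol's displayed "8.2 s") yields seven
segments, trading variance for a 0.49 Hz bin width that still resolves
the band. Power is normalized so the full-spectrum sum equals the mean
square of the signal; segment windowing slightly under-weights the trace
edges, so a final rescaling restores exact Parseval consistency without
changing the spectral shape.

* **Tremor intensity (TI)** is the RMS of the band-passed signal.
  The band-pass is a cascade of 4th-order low- and high-pass Butterworth
  sections applied forward and backward (zero phase). Two numerical
  details matter. First, forward–backward filtering squares the
  magnitude response, so the design corners are pre-warped by
  $(\sqrt2-1)^{1/8}$ to put the double-pass half-power points on the
  band edges; without this, broadband signals lose about 7 % of their
  in-band energy and a 5 Hz unit sinusoid reads 1–2 % low. Second,
  0.5 s is trimmed from each end before the RMS so filter transients do
  not bias an 8 s trace.
* **Center frequency (F50)** is the median of the band-restricted power
  distribution: the smallest frequency at which cumulative power reaches
  half the total, linearly interpolated inside the crossing bin (bin
  mass treated as uniform over the bin width). Interpolation removes
  bin-width quantization; the estimate is invariant to amplitude
  scaling.
* **Frequency dispersion (SF50)** is the sample SD of per-window F50
  estimates over sliding 2.048 s windows with 50 % overlap. The window
  is the shortest that still resolves the 0.9 Hz lower band edge; at
  least three windows are required. A constant-frequency signal scores
  near 0.
* **Harmonic index (HI)** measures how much of the band power is
  consistent with a single harmonic oscillation. The original device's
  formula is unpublished; here the dominant spectral lobe is the
  global-maximum bin extended outward while power is monotonically
  non-increasing, and HI is lobe power over total band power. This
  operationalization equals 1.0 for a single spectral line (verified to
  within the 0.02 window-leakage tolerance), and decreases as power
  spreads into frequent irregular oscillations. Because it is a stated
  operationalization rather than a recovered formula, its absolute scale
  on broadband signals (≈0.2–0.5) is lower than the proprietary
  device's printed cohort values (≈0.9); orderings, not absolute
  levels, are comparable across implementations.

Whether spectra should be normalized before or after band restriction is
ambiguous in the source material; this implementation restricts first.
All four metrics depend only on power ratios within the band, so the
choice affects nothing downstream.

## Tapping and reaction time

Tapping metrics are deliberately simple: **MFT** is hit count divided by
recording time, and **MFT-SD** is the sample SD of instantaneous tap
frequencies (reciprocals of successive inter-tap intervals), the only
per-hit frequency available without a metronome track. A perfectly
periodic tapper scores MFT-SD = 0.

Reaction-time trials pass a validity filter before aggregation:
latencies below 0.10 s are anticipatory and invalid, latencies above the
user-set maximum permitted reaction time (default 2.0 s) are excluded,
and missing responses are dropped. The boundaries themselves are kept,
reading the exclusion rules as strict inequalities. **RT** and **RT-SD**
are the mean and sample SD over valid trials only; with one valid trial
the SD is absent, with none both are absent. Missed stimuli appear in no
denominator. The sample SD (n−1) convention is used everywhere in the
package.

## Posturography

Three vertical-force channels at non-collinear plate positions determine
the center of force (COP) as the force-weighted centroid of the sensor
coordinates; force units cancel, so kilogram-equivalent readings are
used as recorded. The trajectory is mean-centered, and all metrics are
invariant under rigid translation of the raw path. The commercial
plate's sensor placement is unpublished; the default geometry is a
triangle inscribed in the 40 cm × 29 cm plate, configurable.

* **TS / SS**: the literal "mean of the x- and y-axis values" of a
  centered trajectory is identically zero, so these are implemented as
  the mean absolute deviation per axis — the only nonzero reading
  consistent with published nonzero cohort values.
* **MS**: mean Euclidean distance from the mean position.
* **SA**: area of the convex hull of the trajectory (monotone
  construction via `grDevices::chull`, shoelace area). An optional
  grid-occupancy mode (1 mm cells) honors the alternative
  "through a grid" reading; the hull is the default because it matches
  the primary "smallest polygon including the total trajectory"
  definition.
* **SV**: total path length over the recording period.
* **SI**: RMS of the band-limited (0.1–10.1 Hz) COP acceleration
  magnitude. Acceleration is computed by second-order central
  differences (symmetric, minimal phase error), band-passed with the
  same zero-phase Butterworth cascade, and trimmed by 1 s per end to
  remove differentiation and filter edge artifacts.

The standard stance task records 80.5 s at 50 Hz (comfortably above
twice the 10.1 Hz band edge); a 10 s run-in and 5 s run-out are trimmed
so 65.5 s are analyzed.

## The evaluation protocol

`default_protocol()` fixes the battery: rest and postural tremor
(8.192 s per hand), maximum-frequency pronation/supination and finger
tapping (10 s per hand), simple reaction time (9 randomly spaced tones
in 40 s per hand), and the stance task. `run_session()` validates each
recording's duration against the protocol to within one sample at the
recording's own rate and computes every metric; a missing recording
yields absent metrics — never imputed values — and downstream statistics
use pairwise-complete observations, mirroring how such studies report
varying per-metric group sizes.

## The synthetic cohort generator

The generator exists so every pipeline stage is testable without
hardware. It claims fidelity to the reference cohorts' group moments
and to the sign and ordering of group differences — not to waveform
realism. Key choices:

* **Skewed nonnegative metrics** (tremor intensity above all: the PD
  group's rest-TI SD exceeds its mean, which rules out a Gaussian on the
  positive half-line) are drawn log-normal with closed-form moment
  matching. Tremor traces are then rescaled so the measured TI equals
  the drawn value exactly — TI is linear in signal scale — so cohort
  means are recovered by construction rather than by hope.
* **Reaction time in PD** is modeled as a 0.25 s physiological baseline
  plus a log-normal slowing increment whose moments are chosen so the
  total preserves the target mean (0.41 s) and SD (0.21 s). A
  design-time power analysis showed that a plain log-normal with these
  moments gives a Mann-Whitney separation from controls
  (0.29 ± 0.06 s) of only ~79 % at n = 44/28, while the
  baseline-plus-increment family — equally moment-matched, and arguably
  more physiologic, since disease adds impairment to an intact
  sensorimotor floor — separates in ~99 % of cohorts, consistent with
  the strong separation reported for real cohorts.
* **Tapping** uses gamma-renewal inter-tap intervals with the requested
  rate and CV. The process is started 30 mean intervals before the
  window so the retained window is approximately stationary and the
  expected hit count is rate × T without start-up bias. Between-subject
  rate SDs are set slightly below the printed cohort SDs so that the
  measured metric SD (between-subject plus within-recording renewal
  noise) matches the printed value.
* **Sway** paths are planar Gaussian processes per axis: slow drift
  (white noise low-passed at 0.15 Hz) plus a faster corrective component
  (1 Hz, 15 % power in controls), the sagittal axis scaled up relative
  to the transversal. The dynamics constants were calibrated once so the
  control-group shape ratios (SS/SV, TS/SS, MS/SV) match the reference
  control cohort; each subject's path is then rescaled so its
  analyzed-window SV equals a log-normal moment-matched draw. Forces are
  obtained by inverting the weighted-centroid relation (barycentric
  coordinates) at constant total force; paths that would leave the
  sensor triangle are reflected inward with a warning. One scale cannot
  satisfy every printed sway moment simultaneously: SV, SS, TS and MS
  are matched; SA follows to within ~30 %; the printed sway-intensity
  scale is *not* reproduced, because no planar path can jointly exhibit
  the printed SV, SS and an SI of a few mm/s² (the implied
  acceleration-to-velocity ratio is below the narrowband lower bound
  2π f for any f consistent with the printed SS/SV ratio — the printed
  SI scale presumably reflects a device-internal unit convention). SI's
  group ordering (PD > control) is preserved, which is what the group
  comparisons use.
* **Spectral heterogeneity.** A PD subject's side is "tremulous" —
  narrowband 4–6 Hz, noise fraction 0.30–0.60 — with probability
  A/(A+8) in the latent amplitude A; all other sides, in both groups,
  share one background law (spectral peak uniform on 2.5–13 Hz, noise
  fraction uniform on 0.15–0.90). This reproduces the reference
  cohorts' striking F50/SF50 overlap between groups (their printed
  moments imply a group AUC of ~0.53) while the single-trace PD
  archetype (`tremor_archetype("pd_rest")`, noise fraction 0.1) remains
  a canonical narrowband rest tremor with F50 ∈ [4, 6] and HI > 0.8.
  The cost is deliberate: the cohort-level group difference in harmonic
  index reported for real cohorts is *not* reproduced, since at
  cohort level HI is driven by the same heterogeneity as F50.
* **Clinical items** (rest-tremor and action-tremor ratings per side,
  0–4; body bradykinesia) are threshold-binned transforms of the latent
  amplitudes with added ordinal noise, giving strong but imperfect
  Spearman correlations with the corresponding metrics. Within-subject
  task severities share a common latent factor (r ≈ 0.7).
* **Laterality.** Each subject has one more-affected side; the
  better side is a fixed fraction of the worse (inverted for rates),
  with gaps kept wide relative to within-recording measurement noise so
  the side that is worse by latent severity is almost surely the worse
  side as measured. This keeps most-affected-side cohort means on
  target: when the lateral gap is comparable to measurement noise,
  taking the per-subject worse of two noisy values inflates the group
  mean.

Everything is deterministic under a fixed seed, including stimulus
schedules and sway paths. By default cohorts are complete (every subject
performs every task); `missingness = "reference"` reproduces the
reference study's per-task group sizes, including posturography in only
7 of 44 patients and 10 of 28 controls. Group discrimination is
evaluated on complete cohorts: at the reference posturography subset
sizes the printed group moments imply only ~50 % Mann-Whitney power for
sway metrics, an insufficiency of the original subset sizes rather than
of the metrics.

What passing tests on synthetic cohorts do **not** show: robustness to
real sensor artifacts (drift, clipping, missed taps), to non-log-normal
severity distributions, or to medication-state fluctuation. The
generator constrains moments and orderings, not waveform families.

## Statistics

Group comparisons are Mann-Whitney U tests (the reference cohorts'
metrics violate normality), two-sided, exact by enumeration when the
smaller group has ≤ 10 observations and the pooled values are tie-free,
otherwise the normal approximation with tie and continuity corrections
(delegated to `stats::wilcox.test`; tests verify the exact path against
exhaustive enumeration of all C(10,5) labelings). Upper-extremity
metrics are first reduced to the **most affected side**: each task's
side is chosen by its primary metric (TI for tremor, MFT for plate
tasks, RT for reaction; higher worse except for tap rates), identically
in both groups, with exact ties broken to the dominant side and flagged.
Pronation/supination is additionally reduced as the bilateral mean when
correlated with the body-bradykinesia item, matching how such analyses
pair that item. Metric–item associations are Spearman correlations with
average ranks for ties. Significance is p ≤ 0.05 with no multiplicity
correction, as in the source analyses; a Holm adjustment is available
behind a flag.

## Problem sizes used in the shipped checks

The test suite regenerates everything: 200 simulated control cohorts per
targeted metric for moment recovery (n = 28 tremor, 22 reaction,
18 tapping, 10 stance — the reference per-metric group sizes), 100
seeded archetype traces for the rest-tremor frequency band, and 50
complete 44-vs-28 cohorts for the discrimination structure. These sizes
keep Monte-Carlo standard errors small relative to the tolerances while
remaining desk-scale.

## Worked example

```{r example}
cohort <- simulate_cohort(n_pd = 6, n_control = 6, seed = 42,
                          tasks = c("rest_tremor", "reaction"))
tbl <- reduce_most_affected(cohort_metrics(cohort))
compare_cohort(tbl, metrics = c("rest_tremor_TI", "reaction_RT"))
```

## Known limitations

* HI and SF50 are stated operationalizations of unpublished proprietary
  formulas; absolute levels are not comparable to the original device.
* The sway-intensity absolute scale follows the physics of the
  generated paths, not the printed reference values (see above).
* The generator's clinical-item model is ordinal-noise quantile binning;
  it reproduces qualitative association strength, not exact printed
  correlation coefficients.
* No eyes-closed or foam stance conditions, no medication-state
  scheduling, no essential-tremor archetype beyond a configuration stub.
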