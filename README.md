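# neurocat

Hardware-free R implementation of a portable computerized neuromotor
test battery of the kind used in movement-disorder and
occupational-neurotoxicology research to quantify parkinsonian motor
signs. The battery has four instruments — an accelerometer tremor
stylus, a touch plate for maximum-frequency tapping, a reaction-time
handle, and a three-sensor static posturography plate — and `neurocat`
implements their metric computations, the standardized evaluation
protocol, seeded synthetic-signal generators emulating Parkinson's
disease (PD) and control cohorts, and the nonparametric statistics used
to compare groups.

## The metrics

**Tremor** (from an acceleration trace, analyzed on the 0.9–15.0 Hz
band of a Welch spectrum):

- *TI*, tremor intensity: RMS of the band-passed acceleration (m/s²),
  `TI = sqrt(mean(a_band(t)^2))`;
- *F50*, center frequency: median of the band-restricted power
  distribution (Hz), with in-bin linear interpolation;
- *SF50*, frequency dispersion: SD of per-window F50 over sliding
  2.048 s windows (Hz);
- *HI*, harmonic index: fraction of band power in the dominant spectral
  lobe; 1.0 for a single harmonic oscillation.

**Motor speed**: *MFT* = taps / recording time (events/s); *MFT-SD* =
SD of instantaneous inter-tap frequencies; *RT*, *RT-SD* = mean and SD
of valid reaction times, where latencies < 0.10 s (anticipations) and
> max RT (default 2.0 s) are excluded.

**Postural sway** (from the center-of-force trajectory, the
force-weighted centroid of three vertical-force sensors, mean-centered):
transversal and sagittal sway *TS*/*SS* (mean |x|, |y|, mm), mean sway
*MS* (mean distance from center, mm), sway area *SA* (convex hull,
mm²), sway velocity *SV* (path length / time, mm/s), and sway intensity
*SI* (RMS of 0.1–10.1 Hz band-passed COP acceleration, mm/s²). The
standard stance task records 80.5 s; a 10 s run-in and 5 s run-out
leave 65.5 s analyzed.

Group comparisons use Mann-Whitney U tests on the most affected side
(the worse side per task: higher TI/RT, lower tap rate), and
metric–clinical-item associations use Spearman rank correlations.

## Worked example

```r
library(neurocat)

# one canonical parkinsonian rest-tremor trace
tr <- simulate_tremor_trace(seed = 7)
tremor_metrics(tr)
#> TI 1.0000 m/s^2 | F50 5.78 Hz | SF50 0.02 Hz | HI 0.918
```

TI equals the requested amplitude (the generator rescales exactly);
F50 falls in the classic 4–6 Hz parkinsonian rest-tremor band; SF50
near 0 and HI near 1 say the tremor is narrowband and almost a pure
harmonic oscillation.

```r
# a small synthetic cohort, reduced to the most affected side
cohort <- simulate_cohort(n_pd = 6, n_control = 6, seed = 42,
                          tasks = c("rest_tremor", "reaction"))
tbl <- reduce_most_affected(cohort_metrics(cohort))
compare_cohort(tbl, metrics = c("rest_tremor_TI", "reaction_RT"))
#>           metric  U           p n_pd n_control   mean_pd mean_control
#> 1 rest_tremor_TI 35 0.004329004    6         6 0.8409658   0.07791746
#> 2    reaction_RT 32 0.025974026    6         6 0.4417425   0.30232274
#> ...  direction significant
#> ...  pd_higher        TRUE
#> ...  pd_higher        TRUE
```

Even at n = 6 per group the PD cohort's rest tremor intensity
(0.84 m/s² vs 0.08 m/s²) and reaction time (0.44 s vs 0.30 s) separate
cleanly; the exact two-sided p values come from full enumeration since
both groups have ≤ 10 tie-free observations.

```r
# a stance recording through the posturography pipeline
sway_metrics(simulate_sway(seed = 1))
#> TS 2.96 SS 3.31 MS 4.88 mm | SA 258.4 mm^2 | SV 7.24 mm/s | SI 47.77 mm/s^2 (65.5 s)
```

Sagittal sway exceeds transversal sway, as in standing subjects, and SV
equals the generator's control-cohort target exactly on the 65.5 s
analyzed window.

## Command line

```sh
Rscript inst/cli/neurocat.R simulate --n-pd 44 --n-control 28 --seed 17 --out cohort/
Rscript inst/cli/neurocat.R analyze  --cohort cohort/cohort.json --out metrics.csv
Rscript inst/cli/neurocat.R compare  --metrics metrics.csv --alpha 0.05
Rscript inst/cli/neurocat.R sway     --forces forces.csv --run-in 10 --run-out 5
```

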