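# senphys

Quantification pipeline for head-fixed sensorimotor physiology experiments
that pair a whisker-based Go/NoGo discrimination task with whole-cell
electrophysiology, fiber photometry of axonal calcium, and pupillometry.
It is written for experimenters who record these modalities together and
need one tested code path from raw traces and marker tables to
per-session metrics — plus ground-truthed synthetic data so every stage
can be validated without touching real recordings.

## What it computes

**Behavior.** Trials are scored by the task's grace-period rule (licks in
the first 500 ms of the 2 s presentation window never trigger outcomes);
sessions are summarized by signal detection theory,

    d' = Z(HR) − Z(FA),    bias = ½ (Z(HR) + Z(FA)),

with HR = Hit/(Hit+Miss), FA = FA/(FA+CR), Z the standard-normal quantile,
and extreme rates clamped to 1/(2N). A subject is Expert at the second of
the first two consecutive sessions with HR ≥ 0.80 and FA ≤ 0.30.

**Photometry.** Both channels are detrended (line or exponential), scaled
by the robust z-score ZMAD(x) = (x − median x)/MAD(x) with a raw MAD, and
the isosbestic channel is subtracted from the activity channel to cancel
shared motion artifacts.

**Calcium statistics.** Trial-aligned windows anchored on the texture
arrival TTL; sliding-window auROC against the pooled pre-task baseline
(rank-based, ties = ½, so identical distributions give exactly 0.50);
per-trial maxima in the ±2 s target window; calcium events kept when their
height reaches the session's 90th peak-height percentile with prominence
≥ 2; activity split around the grand-average reaction time; pupil–calcium
cross-correlation lag.

**Pupillometry.** Direct least-squares ellipse fits on eight pupil
markers, blink removal above 450 px² with interpolation, rational-fraction
resampling onto the photometry grid, percentage normalization.

**Electrophysiology.** Evoked PSP amplitude and latency from averaged,
zero-baselined sweeps; per-pulse amplitudes of paired-pulse (5 × 50 ms)
and train (30 × 64.2 ms) protocols by iterative exponential decay
subtraction; paired-pulse ratio A2/A1 and train ratio mean(A5..A15)/A1;
spike threshold (dV/dt criterion), peak, half-height width, 10–90% rise
time, AHP depth and maximal rate at the +350 pA step.

**Synthetic data.** Generators for trial schedules, two-channel photometry
(bleach + shared artifacts + trial-locked transients), pupil marker frames
with blinks, piezo lick voltage, PSP sweeps under resource-depletion
synaptic depression, and current steps with stereotyped spikes — each
returning the ground truth the analysis is supposed to recover.

## Worked example

Simulate a paired-pulse experiment at recording noise, run the full
quantification chain, and compare with the generator's truth:

```r
library(senphys)

syn <- synapse_model_params()            # a1 = 7 mV, U tuned near PPR 0.73
sim <- simulate_psp_sweeps("PPR", syn, seed = 1)
qc  <- qc_baseline(sim$sweeps)           # holding range -80 +/- 2 mV
avg <- average_sweeps(baseline_subtract(sim$sweeps), include = qc$include)
pa  <- pulse_amplitudes(avg, sim$sweeps$stim_times_s)

cat("recovered:", paste(round(pa$amplitudes_mv, 2), collapse = " "), "\n")
cat("true     :", paste(round(sim$truth$amplitudes_mv, 2), collapse = " "), "\n")
cat("PPR =", round(ppr(pa), 3), "\n")
```

```
recovered: 6.95 5.1 3.85 2.97 2.38
true     : 7 5.14 3.86 2.98 2.39
PPR = 0.734
```

The five per-pulse amplitudes show the depression profile (each pulse
depletes ~28% of the available resource), the recovered values sit within
a percent of truth despite 0.2 mV sweep noise, and the paired-pulse ratio
below 1 quantifies the short-term depression.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end, writing their
tables under `results/` (regenerated on each run, not shipped):

1. `01_simulate_study.R` — seven-session synthetic learning study, saved
   as plain-text session bundles.
2. `02_behavior.R` — lick detection, outcome scoring, d'/bias, expert
   classification.
3. `03_photometry_calcium.R` — isosbestic correction, trial-max
   amplitudes, sliding auROC, event capture, RT-aligned averages.
4. `04_pupil.R` — ellipse areas, blink cleaning, resampling,
   pupil–calcium lag.
5. `05_ephys.R` — SP/PPR/TRAIN quantification and intrinsic features.

`run_pipeline(pipeline_config(seed = 1))` performs steps 1–4 in memory and
returns the per-session metric table; repeated runs are byte-identical.

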