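---
title: "Models and numerical choices in senphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in senphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senphys)
```

senphys quantifies head-fixed whisker-based Go/NoGo experiments that combine
whole-cell electrophysiology of optogenetically evoked synaptic responses,
fiber photometry of axonal calcium, pupillometry, and behavior. This
vignette documents the models behind each stage, the tunable parameters and
their defaults, what the synthetic generators emulate, and the numerical
decisions taken where the underlying procedures are conventionally
under-specified.

## Behavior: outcomes and signal-detection metrics

Each trial presents one of two textures. A 1 s pre-task interval precedes a
100 ms cue; the texture then travels into the whisker field, and its arrival
(PT start, the TTL synchronization flag) opens a 2 s presentation-time
window. The first 500 ms of that window is a grace period: licks there never
trigger outcomes. The first lick after the grace period and before the
window closes triggers a Hit (Go texture, rewarded) or a False Alarm (NoGo,
12 s timeout); otherwise the trial is a Miss or a Correct Rejection. A lick
falling exactly on the grace boundary counts as post-grace (the interval is
open on the left): the grace period is defined as the first 500 ms, so only
strictly interior licks are exempt. Responded trials end at the triggering
lick, because the texture retreats immediately; downstream trace extraction
uses the truncated window end.

Session metrics follow signal detection theory with hit rate
$HR = \mathrm{Hit}/(\mathrm{Hit}+\mathrm{Miss})$ and false-alarm rate
$FA = \mathrm{FA}/(\mathrm{FA}+\mathrm{CR})$:

$$d' = Z(HR) - Z(FA), \qquad \mathrm{bias} = \tfrac12\,(Z(HR) + Z(FA)),$$

with $Z = \Phi^{-1}$ the standard-normal quantile. Two conventions needed
fixing:

* **Extreme rates.** $Z(0)$ and $Z(1)$ are infinite. Rates of exactly 0 or
  1 are clamped to $1/(2N)$ and $1-1/(2N)$, $N$ the number of trials of
  that type — the standard correction that needs no added constant
  elsewhere.
* **Bias parenthesization.** The one-half is applied to the whole sum of
  quantiles. `sdt_metrics(..., bias_half_sum = FALSE)` gives the other
  reading, $0.5\,Z(HR) + Z(FA)$. Note the classical criterion
  $c = -\tfrac12 (Z(HR)+Z(FA))$ is the negative of the bias reported here.

The expert criterion is $HR \ge 0.80$ and $FA \le 0.30$ on two consecutive
non-Shaping sessions; the expert index is the second session of the first
qualifying pair. Phase labels assign Early Learning to the first two
Learning-phase sessions and Late Learning to the last two before the expert
session; in degenerate short sequences where those overlap, the later label
wins.

## Photometry: detrend, ZMAD, isosbestic subtraction

The correction chain is per-channel detrending, robust z-scoring, and
channel subtraction:

$$\mathrm{ZMAD}(x) = \frac{x - \mathrm{median}(x)}
{\mathrm{median}\,|x - \mathrm{median}(x)|}, \qquad
\mathrm{corrected} = \mathrm{ZMAD}(\mathrm{act}) - \mathrm{ZMAD}(\mathrm{iso}).$$

* The MAD carries **no Gaussian consistency constant** by default (the
  quantity is a plain median absolute deviation); `consistency = 1.4826`
  restores the Gaussian-consistent scale if wanted.
* **Subtraction direction** is activity minus isosbestic, so calcium
  transients stay positive-going; a `flip_sign` flag provides the reverse.
* **Detrending** fits the whole session (not per-trial segments) with a
  line by default; a single decaying exponential plus offset is available
  and is the better match when bleaching is strong relative to the noise.
  The exponential is fitted by profiling the linear coefficients out and
  minimizing the residual sum of squares over $\log\tau$ with 1-D
  optimization — robust even on noise-free exponentials, where
  Gauss-Newton solvers fail on the zero-residual problem. No low-pass
  filtering is applied anywhere in the chain.

ZMAD units are trace-relative: the scale is the session's own MAD, which
trial-locked transients inflate above the noise-only value. Recovery tests
therefore express the generator's ground-truth amplitudes on the corrected
trace's scale using the MAD recorded in the trace provenance; the same
inflation means artifact cancellation degrades when strong transients sit
in only one channel, which is a property of the method itself, not of this
implementation.

## Trial alignment and lick detection

All continuous streams are cut into per-trial windows anchored at PT start
(cue-anchored alignment is available). Off-grid event times round to the
nearest sample, so alignment is exact on-grid and at worst half a sample
period off; no sub-sample interpolation is performed. Licks are detected as
crossings of an upper or lower piezo voltage threshold; crossings within
30 ms of the previous lick merge into it. The 30 ms refractory window sits
well below the ~100–150 ms minimum inter-lick interval of rodent licking,
so it merges the biphasic deflection of one spout contact without fusing
distinct licks. A sustained crossing rate above 20 events/s flags
thresholds that sit inside the noise floor.

## Calcium statistics

`auroc(baseline, window)` is the probability that a window sample exceeds a
baseline sample with ties counted one-half — the Mann–Whitney statistic
normalized by $nm$, computed from midranks. Identical sets give exactly
0.50. The sliding variant pools baseline samples across trials from the
pre-task second (aligned time $[-2, -1]$ s with the default trial
geometry), slides a 0.5 s window in steps of one sample (the pipeline
driver uses two samples), and reports the curve and its maximum. Window
length, step, and baseline interval are unstated in the source procedure;
these defaults are exposed as arguments. auROC is rank-based, hence
invariant under any strictly monotone transform of the pooled samples.

Event filtering measures all local maxima of the session trace, then keeps
peaks whose height reaches the **90th percentile of detected peak heights**
(type-7 quantile; the percentile is over peaks, not over all samples) and
whose topographic prominence is at least 2 ZMAD units. Captured events are
the maximum retained peak per trial inside the control window (trial start
to cue, 1 s) and the target window (2 s before to 2 s after PT start, 4 s
total), averaged over the session where present.

Pupil–calcium coupling is summarized by the lag maximizing the Pearson
correlation over the overlapping segment at each integer-sample lag
(positive lag = second trace follows the first). The reported lag between
corrected calcium and pupil area combines the physiological delay with the
low-pass character of the pupil response, so it exceeds the generator's
pure delay parameter; the pure delay is recoverable against the low-passed
drive, and the tests check exactly that.

## Evoked PSP quantification

Sweeps are zero-baselined by subtracting the mean of the first 10,000
samples (0.5 s at 20 kHz) per sweep. Quality control excludes sweeps whose
raw baseline leaves the −80 ± 2 mV holding range and flags the whole cell
when a single-pulse sweep contains an evoked action potential. Amplitudes
are measured on the average of the included sweeps (20 for SP and PPR, 5
for trains), not per sweep.

For multi-pulse protocols, each PSP's decay is fitted with a single
exponential and subtracted from everything that follows before the next
pulse's amplitude is read — measured as the residual maximum in the pulse's
response window relative to the residual level just before the pulse.
Numerical choices:

* **Response window**: 1 ms after the pulse to the next pulse onset or
  +60 ms, whichever is first. **Decay segment**: from 80% of the peak on
  the falling phase to the next pulse onset; fitted on the log scale when
  positive, refined by nonlinear least squares, with a constant-level
  fallback (flagged per pulse) when no usable fit exists.
* **Measurement smoothing**: a 2 ms centered boxcar is applied before peak
  reading. Reading maxima off a noisy average is positively biased; the
  boxcar suppresses that bias while attenuating a 2/20 ms
  double-exponential kernel peak by under 0.5%, and it cancels entirely in
  amplitude ratios. `smooth_ms = 0` disables it.
* **Train timing**: the 30-pulse train uses the 64.2 ms inter-pulse
  interval as ground truth (15.6 Hz); the conventional "15 Hz" label is
  kept as protocol metadata only. The train summary is
  $\mathrm{mean}(A_5..A_{15})/A_1$, and the paired-pulse ratio is
  $A_2/A_1$.

Intrinsic features are computed at the +350 pA step of the −300..+400 pA,
50 pA, 500 ms protocol. The spike threshold uses a derivative criterion of
**10 mV/ms** by default; a literal 10 mV/s criterion (which fires on
recording noise at 20 kHz) can be requested explicitly. The threshold
sample is found by walking back from each spike peak through the sustained
suprathreshold rise to the last sub-criterion sample, which is immune to
isolated noise crossings earlier in the sweep. Peak height is threshold to
maximum; half-height width and 10–90% rise time are interpolated linearly
between samples; AHP depth is threshold value minus the post-spike minimum;
features are averaged across all spikes in the sweep and the maximum firing
rate is the reciprocal of the smallest inter-spike interval.

## Pupillometry

Eight markers circumscribe the pupil; the area estimate is an ellipse fit.
The fit is the numerically stable direct least-squares conic formulation
constrained to ellipses (with optional likelihood weighting, off by
default), exact to numerical precision on noise-free points from any
rotated ellipse, and failing explicitly on collinear or non-elliptical
configurations. Blink frames are those whose fitted area exceeds 450 px² —
the threshold is interpreted as an area, since area is the thresholded
quantity — and are replaced by linear interpolation between the nearest
valid frames (edge runs take the nearest valid value). Cleaning is
idempotent and never alters unmasked frames.

Rate conversion to the photometry grid uses the best rational
approximation $p/q$ of the rate ratio with $q \le 1000$, a polyphase FIR
resampler, edge-replicate padding against end ringing, and per-phase DC
gain normalization so constants resample exactly. Percentage normalization
offers both plausible references — session maximum (default) and a
pre-trial baseline — since the reference behind "area as a percentage" is
conventionally left unstated.

## The synthetic study

Every stage is validated against generators that emit ground truth for each
latent quantity later estimated. Defaults define a seven-session study:
one Shaping session (Go probability 0.75), five Learning sessions whose
target rates improve until the last two meet the expert criterion, and one
Reward session in which no lick triggers an outcome and water arrives
automatically at PT end. Sessions have 150 trials; Go probability is 0.5
during learning with at most three consecutive presentations of one
texture.

* **Photometry** (20 Hz): activity = exponential bleach + shared motion
  artifacts (Gaussian bumps, Poisson times, identical in both channels) +
  trial-locked double-exponential transients (rise 0.1 s, decay 0.4 s,
  peak at PT start, per-trial amplitude $\mathcal N(a, 0.1a)$ truncated at
  zero) + white noise (sd 0.5, giving transient signal-to-noise in the
  2–6 range typical of ZMAD-scaled recordings); isosbestic = its own
  bleach + the same artifacts + noise, no transients. Stage amplitudes
  grow 0.5 → 2.0 across learning and fall back to 0.5 at Reward.
* **Pupil** (20 fps): latent area = 200 px² baseline + 150 px² × the
  low-passed (τ = 0.5 s) arousal drive delayed by 250 ms; markers sit on
  an ellipse of that area (session-fixed axis ratio ≤ 1.2) with 0.2 px
  coordinate jitter, matching the sub-pixel test error of a well-trained
  pose estimator; blinks overwrite markers with a wide eyelid
  configuration whose fitted area exceeds 450 px².
* **Licking**: responded trials get a reaction time from a truncated
  normal on (grace, 2 s] with stage-dependent mean (0.95 s early → 0.80 s
  expert) and a ~7 Hz consumption train; impulsive licks are placed at a
  stage-dependent rate where they cannot trigger outcomes. Published lick
  statistics for this task are shown as rasters rather than numbers, so
  these parameters are qualitative matches. A piezo voltage trace with a
  biphasic deflection per lick feeds the lick detector.
* **Synapses**: per-pulse amplitudes follow resource depletion
  ($A_k = a_1 R_k$, a fraction $U$ consumed per pulse, recovery toward 1
  with τ = 1 s) — deliberately simpler than a full facilitation/depression
  model because only the measurement pipeline is under test here, not a
  synapse model. Defaults give $A_2/A_1 \approx 0.73$ at the 50 ms
  interval; `depression_u_for_ppr()` inverts the two-pulse recurrence.
  Kernels are double-exponential (2/20 ms); sweeps add 0.2 mV noise on a
  −80 mV baseline with a stimulus-free first 0.5 s.
* **Current steps**: subthreshold sweeps follow an RC charge (80 MΩ,
  20 ms); suprathreshold steps insert stereotyped spikes (threshold
  −45 mV, peak +20 mV, linear 0.4 ms rise and 1.0 ms fall to a −55 mV AHP,
  exponential recovery to a fixed depolarized plateau) at known, evenly
  spaced times, so width and AHP have closed-form true values.

What the generators do **not** emulate — and what passing tests therefore
do not certify on real data: photon shot noise and hemodynamic
contamination, whisking and movement covariates, clock drift between
acquisition systems (all synthetic streams share one clock; drift
correction is an extension point), eyelid occlusion short of a full blink,
non-exponential bleaching, synaptic facilitation, and any biological
variability across cells or subjects. The detrending stage is nonetheless
never told the generator's bleach form, and the test suite exercises both
detrend models.

## Determinism and problem sizes

Every generator is a pure function of its parameters and a seed (the
caller's RNG state is saved and restored); the study driver derives
per-session substreams from one study seed, so any session can be
regenerated in isolation. The full default study — seven sessions of 150
trials with photometry at 20 Hz, pupil at 20 fps, piezo at 1 kHz, roughly
1,000–1,600 s per session — runs through the complete pipeline in about a
minute on one core, and repeated runs produce byte-identical reports.
Electrophysiology simulations use the protocol sweep counts at the full
20 kHz rate. Serialization uses plain-text bundles (CSV for traces and
tables, JSON for parameters and the schema-versioned manifest) with 17
significant digits, which round-trips IEEE doubles bit-exactly.

## Known limitations

* The artifact-cancellation guarantee is scale-matched: when transients
  occupy a large fraction of the session at high amplitude, the activity
  channel's MAD inflates and shared artifacts cancel less completely.
* The pupil lag reported by the pipeline is the empirical cross-correlation
  peak, not the generative delay; interpreting it requires the low-pass
  caveat above.
* `classify_expert` assumes sessions arrive in chronological order and
  that Shaping/Reward flags are supplied by the experimenter.
* Proprietary acquisition formats are out of scope; ingest starts from the
  marker CSV and the plain-text session bundles.
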