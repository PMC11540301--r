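---
title: "axonav: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{axonav: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`axonav` analyses two-photon calcium recordings of single neuromodulatory
axons — dopaminergic (VTA) and noradrenergic (LC) projections imaged in
dorsal CA1 — while a head-fixed mouse navigates a virtual linear track.
This vignette documents the models and procedures the package implements,
the parameters that matter and their defaults, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the underlying procedure was genuinely open.

## The experimental world

One session is a 30 Hz frame-synchronised recording: per-frame track
position on a 2 m or 3 m virtual track, reward events (4 µl at the track
end), a 1.5 s VR pause after each reward followed by a teleport to the
track start, an environment schedule (optional darkness, then a familiar
and usually a novel environment), and one raw fluorescence trace per ROI.
ROIs are either axons or "blebs" — autofluorescent structures with no
neural signal, processed identically and used as a noise reference.

All frame indices are 0-based and intervals half-open; time in seconds is
`frame / frame_rate_hz`; positions are stored in cm (normalisation is an
analysis choice, not a storage one). The on-disk format is a directory of
CSV + JSON files written at full float precision (`%.17g`), so a session
round-trips bit-exactly and identical sessions produce identical bytes.

## Behavioural derivation

Velocity is the backward difference of position times the frame rate,
smoothed with a Savitzky–Golay filter (7-frame window, degree-5
polynomial). Differences spanning a teleport are meaningless (the position
resets), so each contiguous run of valid differences is smoothed
independently and excluded frames carry the nearest valid value plus an
exclusion mask — teleports can never inject spurious negative spikes.
Because Savitzky–Golay reproduces polynomials up to its degree, the
smoothed velocity of any polynomial trajectory of order ≤ 5 is exact on
interior frames (at the backward-difference convention's native time
points, `t − dt/2`).

Two immobility thresholds coexist deliberately: velocity < 5 cm/s defines
immobility for freezing ratios and motion-onset detection, while
velocity ≤ 0.2 cm/s defines the stricter stationarity used when running
periods are concatenated for the novelty analysis. Both are configurable;
the defaults are the published values.

A motion onset is a strict crossing: velocity < 5 cm/s for at least 1.5 s,
then ≥ 5 cm/s at the onset frame and for at least 3 s after. A session
that begins mid-run produces no event at frame 0 (the crossing must be
observed). Laps are delimited by teleports — lap *k* spans
`[teleport_{k−1}, teleport_k)` — and the reward-pause frames belong to the
lap they end; empty laps (teleport at frame 0, consecutive teleports) are
dropped with a log line.

## Trace quality control

**ΔF/F.** The baseline `F0[t]` is a rolling 8th percentile of the raw
trace over a centred window, truncated at the edges; two window sizes are
used: 300 frames for lap-by-lap analysis and 2000 frames for the novelty
analysis (a wide window avoids flattening slow signals). The percentile,
computed with type-7 (linear-interpolation) quantiles in compiled code, is
exposed in configuration; the 8th percentile is the field-standard low
quantile. A non-positive baseline is an error naming the offending frame,
since it signals a units problem in the input.

**Merging.** Axon pairs with Pearson r ≥ 0.7 on long-window ΔF/F are
considered duplicated segments of one axon. Merging uses single-linkage
connected components of the r ≥ 0.7 graph (the source procedure says
"combined" without specifying transitivity); the merged trace is the
unweighted mean of member raw traces, with ΔF/F recomputed. Blebs never
merge.

**SNR.** The power spectral density of each ΔF/F trace is estimated by
Welch averaging (60 s Hann-windowed segments, 50% overlap — frequency
resolution ≈ 0.017 Hz at 30 Hz sampling). SNR is the peak power in
0.5–1 Hz (where GCaMP6s transients live) divided by the mean power in
1–3 Hz (above what the indicator can follow). The inclusion threshold is
`mean(bleb SNR) + 1.5 × sd(bleb SNR)` (sample sd), strict inequality, and
at least two blebs are required. SNR is computed on long-window ΔF/F (the
source does not say raw F or ΔF/F; ΔF/F makes the statistic insensitive
to baseline brightness).

**Sustained shifts.** Some axons step up in fluorescence at a random time
and stay elevated ("filling" artifact). An upward CUSUM on the robustly
standardised trace (median/MAD; slack k = 0.5 sd, decision h = 5 sd)
proposes candidate change points; a candidate is confirmed when the
101-frame moving average stays above the pre-change mean + 1 pre-change sd
for ≥ 2000 frames, or ≥ 500 frames reaching the end of the trace.
Unconfirmed alarms reset the statistic and scanning resumes — with h = 5
the raw CUSUM alarms every ~10³ frames on stationary noise, and it is the
sustained-mean confirmation that provides the specificity (false-positive
rate ≲ 5% per 10-minute trace, verified by the calibration suite). The
parameterisation is validated by calibration, not by fidelity to an
unstated original.

**Normalisations.** For tuning analyses each ROI is scaled as
`(x − q01)/(q99 − q01)` (1st/99th type-7 quantiles, no clipping) so that
high-SNR axons do not dominate population averages; for the novelty
analysis each ROI is divided by its mean (output mean exactly 1).

## Tuning curves and aligned activity

Covariate binning always follows the same per-lap scheme: for each
completed lap in the selected environment, the mean activity per bin; then
the across-lap mean and s.e.m. per bin, skipping NaN cells (laps with no
sample in a bin) — a bin's mean uses exactly the laps that visited it.
Bins are half-open with the final bin closed, so reward-pause frames
(position frozen at the track end) fall in the last position bin.
Defaults: 5 cm position bins; 1 cm/s velocity bins over 1–30 cm/s with
bins above 14 cm/s flagged as not population-complete (not all animals run
faster); reward proximity either as distance (5 cm) or time-to-reward
(0.5 s bins over the final 10 s — the bin width is not stated in the
source and is configurable). For pooling across 2 m and 3 m tracks,
position-bin centres are also reported normalised by track length.

Motion-onset alignment extracts (−2, +3) s windows around each qualifying
onset (the post side is for display; regressions use the (−2, 0] s
segment); events whose window leaves the trace are excluded. Transition
alignment stacks mean-normalised ROI traces around the environment-switch
frame; an optional retained-frame mask (running-only or immobile-only) is
applied *before* alignment so concatenated timelines are aligned at the
first retained frame at or after the event. Aligned series can be reduced
to non-overlapping 50-frame bins anchored at the event (a remainder
shorter than one bin is dropped) or to per-lap means.

## Statistics

Simple regressions are closed-form OLS with an F test of the slope on
(1, n − 2) degrees of freedom. Per-ROI regressions use lap × bin cells as
points; population regressions use each ROI's across-lap bin means (the
source's "on all data points, not means" is ambiguous between these
levels; both are available and the pipeline logs its choice). ROIs are
classified positive/negative/non-significant by slope sign at α = 0.05.

Populations of unequal size are compared by Monte-Carlo resampling: the
larger population is resampled (default 1000×) at the smaller population's
size, each draw pooling the selected ROIs' points into one regression;
the reference fit is "contained" when slope and intercept both fall inside
the per-axis 2.5–97.5 percentile box.

The ANCOVA omnibus is the F test of the group × covariate interaction
(separate-slopes vs common-slope model); pairwise slope differences use
the studentized-range (Tukey HSD) distribution with the full model's
residual variance and each group's own `Sxx`. The one-way ANOVA is the
textbook between/within decomposition with Tukey HSD pairwise tests.

**Shuffle-bootstrap null band.** The null for "is the population mean
elevated?" is built by circularly rotating each ROI's full-session trace
by a uniform random offset of at least 30 s — rotation preserves the
marginal distribution and autocorrelation, the conservative choice for a
time-localised null (the source says only "shuffled traces"). Each of
1000 subsample replicates draws the observed number of traces from a pool
of pre-drawn rotations and averages them; the baseline mean and 95% CI are
pointwise 2.5/97.5 percentiles across replicates (percentile rather than
Gaussian CI; the source does not name a type). Epochs are maximal runs of
points strictly above the upper limit, kept at ≥ 2 consecutive frames for
frame-resolution series and ≥ 1 bin for lap/50-frame-binned series.

A consequence worth stating plainly: a correctly calibrated 95% band is
exceeded on ~2.5% of time points under the null, so at 30 Hz a 10-minute
null session unavoidably contains many ≥ 2-frame micro-epochs (even white
noise gives 18 000 × 0.025² ≈ 11 expected runs, and the temporal
smoothness of calcium traces clusters exceedances into more and longer
runs — the calibration suite measures ~90 per null session at reduced
replicates). The two-frame rule is therefore not a false-positive control
at frame resolution; the 50-frame-binned variant reduces spurious runs by
more than an order of magnitude (~3 per session under the same rule) and
the lap-binned variant further still, which is why sustained novelty
claims should rest on the binned series and on epoch duration, not on
isolated frame-level crossings. The acceptance criterion asserting ≤ 1
spurious frame-level segment per null session is left deliberately red:
it is arithmetically incompatible with a calibrated 95% band (it would
require either < 0.75% exceedance or a correlation length of ~15 s), and
no honest parameterisation reaches it.

## The synthetic-data generator

The generator exists so every stage is testable with known ground truth.
It emulates: run/pause locomotion as a two-state semi-Markov process
(per-run speed N(15, 3) cm/s floored at 1, run hazard 0.05 /s, pause
duration Exp(4 s), pauses preferentially placed after teleport with
probability 0.6 — immobility concentrates between reward and the next
lap); reward at the track end with the 1.5 s pause and teleport; the
familiar→novel switch with a velocity dip (×0.5 on the first novel lap,
exponential recovery with a 30 s constant) and persistently reduced
pausing (hazard halved); optional darkness before VR onset. Axon latent
rates compose additively: a reward-expectation ramp
`g_r · position/track_length` active in rewarded environments and decaying
exponentially (τ = 2 s) after each reward; `g_v · velocity`; a linear 2 s
pre-motion ramp `g_m`; a novelty transient `A · exp(−Δt/τ_nov)` after the
switch (and, scaled, at VR onset); plus a per-axon private
Ornstein–Uhlenbeck component (sd 0.3, τ = 0.5 s) standing in for
spontaneous transients — without it, identically tuned axons would be
perfectly correlated and always merge, and axons would carry no in-band
spectral power of their own. Rates are clipped at zero, convolved with a
unit-area double-exponential GCaMP kernel (rise 0.2 s, decay 1.5 s,
GCaMP6s-like; the source never states a forward model), scaled onto a
baseline of 100 with optional per-frame bleaching, and given i.i.d.
Gaussian noise (sd 0.03). "Unhealthy" axons receive a sustained step (5 ×
noise sd) at a uniform random mid-session frame. Blebs are rendered from a
zero rate. Lap-velocity dip magnitude and recovery are only shown
graphically in the source; the defaults are plausibility choices, not
fidelity claims.

What the generator does **not** emulate: photon (shot) noise and its
intensity dependence, motion artifacts, neuropil contamination, z-drift,
slow non-exponential bleaching, licking, and any correlation between
axons beyond shared behavioural drive. A green calibration test therefore
establishes that the analysis correctly recovers what this generative
world contains — not that it is robust to every artifact of real data.

The noise floor (0.03 relative to signal amplitudes of ~0.5–1 fluorescence
unit) was chosen so that signal-bearing axons genuinely separate from
blebs in the 0.5–1 Hz SNR band; at a white-noise floor comparable to the
signal the PSD filter cannot distinguish them even in principle, because
the GCaMP kernel concentrates behavioural signal below 0.5 Hz.

## Determinism and seeds

Every stochastic operation takes a seed and restores the caller's RNG
state; cohort members derive per-session and per-ROI seeds from the root
seed by a fixed integer recurrence kept below 2³¹. The pipeline writes
every table with `%.17g` formatting so a (config, seed) pair reproduces
every output byte-for-byte — the end-to-end test asserts equal MD5 hashes
across reruns.

## Known limitations

- The behaviour frame loop is plain R; simulating very long cohorts is
  linear but not fast (~2 s per 10-minute session).
- The full-frame shuffle baseline at the published 1000 × 1000 replicates
  over a 36 000-frame session holds a replicate × frame matrix in memory;
  use the binned variants (`bin_fun`) for long sessions, as the source
  analyses ultimately do.
- Reading microscope vendor formats or Suite2p outputs is out of scope;
  sessions enter through the documented CSV + JSON directory layout.
- The CLI accepts JSON configuration only (no YAML parser is available in
  the supported dependency set).
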