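---
title: "Artifact suppression by logarithmic piecewise-linear interpolation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artifact suppression by logarithmic piecewise-linear interpolation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loglira)
```

## The problem

Intracortical microstimulation (ICMS) injects current pulses orders of
magnitude larger than extracellular spikes. Each pulse leaves a stimulation
artifact in the recording: a fast transient, often saturating the amplifier,
followed by a slow decay that can last tens of milliseconds. Spikes evoked
within the first milliseconds after the pulse — the short-latency,
potentially monosynaptic response — sit right on top of this artifact, and
naive blanking of a fixed post-stimulus window destroys exactly the signal
of interest.

This package suppresses such artifacts one stimulus at a time, making no
assumption that consecutive artifacts share a shape, and ships the
semisynthetic benchmark machinery needed to evaluate any suppressor of this
kind against a known ground truth.

## The per-trial model

A channel with `K` stimulus onsets is split into `K` trials, trial `i`
covering the half-open interval from onset `i` to onset `i+1` (the last
trial runs to the end of the recording; samples before the first onset are
never touched). Within a trial the algorithm proceeds in four steps.

**Transient detection.** Two windows of `transient_window` (5 ms) are
compared, one immediately before the onset and one immediately after the
default blanking period `beta0` (1 ms). When their means differ by no more
than `mean_k` (2) pre-window standard deviations and their SD ratio lies in
`sd_ratio_range` ([0.5, 2]), the trial is declared transient-free and only
`beta0` is discarded. The original description requires the statistics to be
"similar enough" without quantifying it; these two scale-free criteria are
this package's calibration, exposed in `loglira_config()`.

**Dynamic blanking.** Saturation is any sample at or beyond `sat_fraction`
(95%) of the amplifier operating limit, or of the channel-wide maximum
absolute voltage when the limit is unknown (a channel-wide rather than
per-trial maximum, so artifact-free trials cannot misfire). Saturated
stretches are concatenated; the recovery start `n_s` follows the last one,
or `beta0` when none extends past it. The actual blanking `beta = n_s` (in
ms) is reported per trial. The transient end `n_e` is the first
post-blanking sample at which a centered 5 ms moving average (edge-truncated,
so no phase lag biases the estimate) enters a `steady_tol` (1 uV) band
around the median steady-state value, computed from samples after
`settling_time` (40 ms); trials shorter than the settling time use their
last sample.

**Artifact estimation.** Interpolation times follow

    t_j = 10^(j/(P-1) * log10(T)) - 1,   j = 0, ..., P-1

with `P = 42` points spanning 0 to `T - 1 = 49` ms, converted to samples by
`round(t_j * 1e-3 * fs)` so behaviour is identical across sampling rates,
shifted right by the blanking interval, truncated at `n_e`, and de-duplicated
after rounding. Each node value is the mean of the signal in a neighbourhood
whose width tracks the local grid pitch (half the span between the flanking
nodes, capped at `eps_cap` times the local spacing, one-sided at the
endpoints, clipped to the recovery region) — denser and narrower right after
the stimulus where the artifact changes fastest, wider in the slow tail where
averaging suppresses spikes and noise. The piecewise-linear interpolant
through these node means is the artifact estimate; the blanked portion is
pasted unmodified and the estimate is zero beyond `n_e`.

**Subtraction and bridging.** After subtraction, a straight line from the
sample preceding the onset to the sample following `n_e` is superimposed on
the recovered segment, so the output is continuous at both ends and the
blanked stretch carries the line rather than a hard step (steps would ring
after bandpass filtering and masquerade as spikes). When no sample precedes
the onset the line is anchored flat at its right endpoint.

## Secondary-artifact mitigation

Piecewise-linear interpolation leaves a deterministic residual where the
signal still bends quickly just after blanking. Because the procedure is
deterministic, this residual is nearly identical across trials with similar
artifacts, while neural activity is not aligned across trials. The 2 ms
(`secondary_window`) stretch following each trial's own blanking interval is
therefore collected across all `K` trials, embedded in two dimensions, and
clustered by density; each cluster with at least `theta = 20` members
contributes its mean waveform, which is subtracted from its member trials.
Fewer than `theta` trials, or no sufficiently large cluster, makes this
stage the identity. Stereotyped short-latency evoked spikes can be partially
attenuated by this averaging; that trade-off is accepted rather than
corrected, and windows from transient-free trials are included by default
(`include_no_transient`) where they form their own low-energy cluster.

Two implementation choices here are this package's own. The two-dimensional
embedding is classical multidimensional scaling (principal coordinates) of
the correlation distance `1 - r` between windows: it preserves the stated
metric (correlation, hence scale-invariant — windows enter raw), is exactly
reproducible, and needs no stochastic optimisation; zero-variance windows,
for which correlation is undefined, are pinned at the origin and excluded
from density estimation. The density-based clustering is kernel-density
mode-merging: a bivariate KDE on a 64 x 64 grid (normal-reference
bandwidths), hill-climbing assignment of every grid cell to its local
density mode, and merging of modes whose separating saddle exceeds
`saddle_ratio` (0.5) of the lower peak. It requires no preset cluster count
and discards small groups, which is the contract this stage depends on.
Because the principal-coordinate embedding preserves the absolute scale of
the correlation distance, a set of windows whose pairwise embedded
distances all fall below `same_shape_tol` (0.1 — mutual correlations near
one) is treated as a single waveform family outright: estimating a density
there would only resolve sampling noise into spurious modes and split what
is by construction one family.

## The semisynthetic benchmark

Evaluating a suppressor requires data where the truth is known. The
benchmark superimposes two independently generated components, so the
ground truth is exact by construction:

* **Basal activity** (`gen_basal()`): Gaussian background noise bandpassed
  to 300-6000 Hz (default SD 4 uV) plus biphasic/triphasic spike waveforms
  of about 1 ms, peak amplitudes uniform in 30-120 uV, inserted at
  gamma-distributed inter-spike intervals (shape 2) with a 2 ms refractory
  period. Draws are repeated until the realised mean firing rate is within
  0.5 Hz of the target (targets 5-25 Hz). Spike times are reported
  peak-aligned. The gamma ISI model avoids the implausibly short Poisson
  intervals that would confound jitter-matched scoring.
* **Artifact templates** (`gen_templates()`): a sharp biphasic onset pulse
  followed by a bi-exponential decay (defaults 0.3 and 8 ms), with the
  polarity and decay constants spread deterministically across the set so a
  channel carries genuinely distinct families, plus per-template jitter.
  Saturated variants clip exactly at the amplifier limit for a stated
  plateau. Scales are declared, not fitted: no amplitude statistics of the
  original recordings are available, and only ratios matter for the test
  suite.
* **Stimulus trains** (`gen_stim_onsets()`): log-normal inter-artifact
  intervals (IAIs), rescaled so the mean artifact rate `MAR = 1/median(IAI)`
  lands within 0.1 Hz of the target (targets 2-20 Hz).

Dictionaries of artifact templates are learned per channel
(`build_dictionary()`): all artifact waveforms, cut to the minimum IAI, are
embedded and density-clustered as above; clusters of at least 100 members
contribute a template — the per-sample median smoothed by a zero-phase FIR
lowpass at ~2 kHz. For saturated clusters the raw median and the smoothed
version are merged at the last time point where their difference exceeds
2.5 times its median, preserving the onset transient and clip edges.

Snippets (`synthesize_snippet()`) resample the dictionary channel's IAIs to
a target MAR: a constant rightward shift when lowering the rate; iterative
removal of the largest 2% of IAIs when raising it, keeping the minimum in
place. Because removing discrete values rarely lands the median exactly
inside the 0.1 Hz tolerance on small desk-scale sets, the trimming loop
finishes with an affine shrink toward the minimum (which stays fixed) that
puts the median exactly on target. A Gaussian KDE (Silverman's rule) of the
adjusted set is then sampled, truncated to its range, until the intervals
cover the snippet duration, redrawing (bounded retries) until the realised
rate is inside tolerance. Templates are drawn uniformly per onset,
truncated at the next onset when they would overlap, and multiplied by the
decaying half of a Blackman window raised to a per-insertion exponent in
[0.5, 2]. A full symmetric window would null the onset transient that the
suppressors are tested on, so only the decaying half is used: weight one at
the onset, exactly zero at the end, with the random exponent providing the
documented window-shape variability. The snippet stores its basal component
alongside the artifact track, so `signal = basal_signal + artifact_track`
holds bit-exactly.

`build_benchmark()` produces one snippet per (MFR, MAR) cell per subset —
the full default grid is 5 x 10 = 50 per subset — with every cell's seed
recorded in the manifest.

## Evaluation

Suppressor outputs and the ground-truth basal signal go through the same
processing: a forward-backward 4th-order Butterworth bandpass (300-7000 Hz),
then SWTTEO spike detection. The detector computes stationary wavelet
transform detail coefficients (an a-trous scheme with sym4 filters,
implemented here directly since no wavelet package is available in R),
applies the Teager energy operator `y[n]^2 - y[n-1]y[n+1]` per level,
smooths with a 1 ms Hamming window, sums levels, and picks peaks above
`5 * median(|feature|)/0.6745` with a 1 ms dead time. It is fully
deterministic, so a perfectly recovered snippet reproduces the ground-truth
train exactly. The per-signal detection parameters live in the harness and
are applied identically to ground truth and output, which is the property
the comparison depends on.

Scores per snippet and suppressor: RMSE between the filtered signals;
false positives and negatives from greedy one-to-one matching within a
±0.2 ms jitter window, as percentages of the ground-truth count (not capped
at 100); the zero-lag cross-correlation

    C0 = (1 / sqrt(Nx * Ny)) * #{coincidences within ±0.2 ms}

clipped to [0, 1] (identical non-empty trains score exactly 1, either train
empty scores 0, both inclusive window bounds at sample resolution); the
per-artifact wall time; and the blanking distribution. PSTHs with 0.25 ms
bins are available for qualitative latency analysis. Timing is reported but
hardware-dependent, so it carries no acceptance weight.

## Numerical and design choices

* Durations are configured in milliseconds and converted by
  `round(ms * 1e-3 * fs)`; sample indices are 1-based as is natural in R,
  with trial landmarks stored as counts from the trial start so the
  recovery region `(n_s, n_e]` matches the half-open interval of the design.
* Duplicate grid nodes after rounding are merged; node spacing is
  non-decreasing on the millisecond grid and within one sample of
  non-decreasing after integer rounding.
* The transient-free path and the saturation scan are ordered so the
  95%-of-maximum fallback threshold cannot misfire on artifact-free
  channels: saturation-based blanking extension applies only once a
  transient is detected.
* Degenerate inputs resolve conservatively: a fully saturated trial is
  blanked whole and flagged; an empty grid or a transient end at or before
  the recovery start falls back to blanking-only treatment; per-trial
  failures warn and leave that trial unmodified rather than aborting the
  channel.
* Baseline suppressors: dynamic averaging subtracts the mean of the 10
  temporally nearest trials (excluding the current one; a global average
  when `K <= n_neighbors`) and blanks 1 ms; global polynomial fitting
  subtracts an order-8 least-squares polynomial over 10 ms and blanks
  0.5 ms. The original parameterisations are not published in detail, so
  these defaults are declared as reasonable choices and exposed in full.
  These baselines exist for ordering comparisons, not as faithful
  reproductions.

## Desk-scale study conditions

The test suite and the reproduction script run everything from scratch, so
problem sizes are chosen at desk scale as the package's own conditions:
snippets of 5-10 s at 20 kHz instead of 150 s, ten snippets at MAR 10 Hz
and MFR 10 Hz with non-saturating templates for the blanking-distribution
summary, and a 2 x 3 (MFR x MAR) grid for the suppressor-ordering
comparison. The full 5 x 10 x 3-subset grid is exercised in
duration-reduced form to verify the combinatorics.

## What passing tests do and do not show

The generator emulates the statistical structure the method depends on —
heavy-tailed stimulus timing, diverse per-channel artifact families with
fast transients, slow decays and optional saturation plateaus, spikes of
realistic amplitude over band-limited noise — but not everything about real
recordings: no electrode drift or movement artifacts, no true evoked
responses locked to the stimulus in the benchmark proper (the optional
`gen_evoked_spikes()` mode inserts spikes at 1-5 ms post-onset latencies
with per-trial jitter to probe that scenario qualitatively, and the partial
attenuation of stereotyped evoked spikes by cluster-mean subtraction is a
known, accepted limitation), no
amplifier nonlinearities beyond hard clipping, and spike waveforms from a
three-prototype bank rather than real units. Passing the suite shows the
algorithm implements its specification and beats the reference baselines
under these conditions; it does not certify performance on any particular
real preparation.

## Known limitations

* Single-channel processing only; high-density probes with correlated
  artifacts across channels are out of scope.
* Not suitable for online use: the secondary stage needs the full set of
  trials (at least `theta`, in practice a few hundred) before it can act.
* The embedding cost grows quadratically with `K` (a K x K distance matrix);
  channels with many thousands of stimuli pay a noticeable one-off cost in
  the mitigation stage.
* Very short inter-stimulus intervals leave little steady-state signal for
  the median used by the transient-end scan, pushing `n_e` toward the trial
  end and widening the interpolated region.

```{r example, eval = FALSE}
# end-to-end sketch
fs <- 20000
dict <- synthetic_dictionary(fs = fs, seed = 1)
bench <- build_benchmark(list(dict), mfr_grid = c(10, 20),
                         mar_grid = c(4, 10, 16), duration = 10,
                         fs = fs, seed = 5)
report <- run_benchmark(bench, methods = c("loglira", "dynavg", "polyfit"))
glance(report)
```
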