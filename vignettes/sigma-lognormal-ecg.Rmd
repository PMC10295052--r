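---
title: "Sigma-lognormal modeling of the PQRST complex: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sigma-lognormal modeling of the PQRST complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecglognorm)
```

## The model

Each heartbeat's PQRST complex is modeled as a sum of six time-shifted,
scaled lognormal density functions — one per physiological wave: P
(atrial depolarization), Q, R, S (ventricular depolarization), and a T
wave represented by the difference of a positive (`Tp`) and a negative
(`Tm`) lognormal to capture its negative skew. A component contributes

$$D_j \, \Lambda(t;\mu_j,\sigma_j,t_{0j}), \qquad
\Lambda(t) = \frac{1}{\sigma (t-t_0)\sqrt{2\pi}}
\exp\!\left[-\frac{(\ln(t-t_0)-\mu)^2}{2\sigma^2}\right],\; t > t_0,$$

and exactly 0 for $t \le t_0$ (causal support; this is a deliberate
convention, not NaN). $t_0$ is the initiation time of the underlying
depolarization/repolarization avalanche, $\mu$ and $\sigma$ are its
log-scale delay and spread, and $D$ (signed, µV · time unit) is the
time-integral of the wave: positive for P, R, Tp and negative for Q, S,
Tm, a sign that is part of each wave's physiological meaning and is
never allowed to flip. All logarithms are natural; the profile-
invariance property of the denormalization map below holds exactly only
under that convention.

The mode of a component sits at $t_p = t_0 + e^{\mu-\sigma^2}$, and the
six modes must stay strictly ordered P < Q < R < S < Tp < Tm. Ties are
rejected as degenerate: two coincident peaks make the decomposition
unidentifiable.

Beats are compared on a duration-normalized axis: 500 samples across
$[-1, 1)$ with the R peak at 0, the previous R at $-1$, the next R at
$+1$ (each half interpolated from its own RR interval — a
piecewise-linear warp). Fitted parameters are mapped back to seconds
with $\{\mu,\sigma,t_0,D\} \mapsto \{\mu+\log\alpha,\ \sigma,\
\alpha t_0,\ \alpha D\}$ where $\alpha = (t_3-t_1)/2$ is half the
previous-R-to-next-R span; this map preserves the waveform amplitude
numerically, which is also how the package tests it.

## Prototype, bounds, envelopes

Fitting starts from a hand-fitted prototype (packaged CSV) and is
confined to a box: for $\mu, \sigma, t_0$ the box is
$\theta \pm 0.2\,|\theta|$; amplitude intervals are clamped to 0 on the
zero-adjacent side so a wave can vanish but never invert. The packaged
bounds table widens the Tp amplitude ceiling to 204 µV (the ±20% rule
gives 180, the narrative derivation of the widened rule 210; the
package ships the printed table and exposes the raw rule via
`derive_bounds(tp_D_upper = NULL)` rather than guessing which was
intended). The box midpoint is the reference point: the initial
estimate of every fit.

For any such box the package provides closed-form pointwise envelopes
of the unit-amplitude density (exact piecewise suprema/infima over the
box, 10 branches for the upper envelope with a constant plateau between
the two extreme mode abscissae), and their signed sums over the six
components. Every waveform synthesizable from in-box parameters lies
between the two model envelopes; the test suite verifies this by Monte
Carlo and checks tightness of the upper envelope against a
corner/grid/optimizer search to 0.1%. Branch intervals are
left-open/right-closed as printed; the interior-supremum branches use
$\sigma^* = \mu_- - \ln(t-t_{0-})$ (rising flank), $\mu^* =
\ln(t-t_{0+})$ (crest), $\sigma^* = \ln(t-t_{0+}) - \mu_+$ (falling
flank). The construction assumes $\sigma < 1$, amply true of the
packaged box.

A 24-dimensional box is mostly corners: `box_geometry_check(24)` ≈
1.15e-10 is the volume fraction of the inscribed ball, the package's
reminder that box constraints are a crude prior in high dimension.

## Quality control

Segment quality uses the classic power-ratio SNR in dB of the mean beat
against per-beat residuals, averaged across beats (`snr_bar`); segments
below 5 dB are rejected (exactly 5.0 is kept), as are segments with
fewer than 20 detected beats. The SNR is capped at +120 dB for
(near-)zero residuals so averages stay finite. Note the dB convention:
20 dB means noise *power* 100× below signal power (amplitude 10×
below); prose that reads 20 dB as "amplitude 10² smaller" conflates the
two conventions — the implementation follows the formula.

## The fitting environment

Fitting is phrased as an episodic decision process so any
policy-optimization backend can drive it:

* **State / observation**: the current 24-parameter estimate (affinely
  mapped from the box onto $[-1,1]^{24}$) and the residual on the 250
  grid points with normalized time in $[-0.3, 0.7)$ (indices 176–425;
  the rest of the beat carries little wave information), min-max
  normalized per point into $[-1,1]$. The residual bounds default to
  1.5× the envelope-implied extremes at the initial estimate — a
  corpus-free bound with the same 1.5× convention as the corpus-based
  `error_obs_bounds_from_beats()`, which is computed per point (not
  globally).
* **Action**: $a \in [-0.01, 0.01]^{24}$, applied as $\hat\theta
  \leftarrow \hat\theta + a \circ \theta_{\mathrm{ref}}$ (Hadamard
  product with the reference point — each parameter steps in proportion
  to its typical magnitude; any other reading of the update rule is
  dimensionally incoherent). A component whose 4-parameter sub-update
  would invert its peak order with either neighbor is cancelled
  (reverted whole); the result is clipped into the box and the
  cancellation re-checked (≤6 passes, with full revert as the
  fallback). Constraining actions, rather than penalizing the reward,
  categorically excludes biologically meaningless states.
* **Reward**: the change in fitting SNR, so rewards telescope to final
  minus initial SNR over any episode — an identity the tests verify on
  random rollouts.
* **Termination**: step cap (1000 training / 2000 extraction) or no new
  best SNR for a patience of 100 / 200 steps. "Improvement" means
  strictly exceeding the best seen; extraction returns the best-seen
  estimate, not the last.

**Where the fitting SNR is scored.** The fitting SNR (reward, episode
bookkeeping, reported fit quality, and the 5 dB beat exclusion) is
computed on the fitting window $[-0.3, 0.7)$, not on the full
500-sample epoch. This is a deliberate deviation with a measured
justification: R-to-R epochs contain the neighboring beats' R
complexes at their edges by construction, and those samples are not
representable by the six-component model of the central beat. On
synthetic data rendered from the packaged prototype, even the
ground-truth parameters score only ≈3 dB on the full epoch (≈85% of
the residual power sits at the edges) — a strict 5 dB exclusion would
then discard essentially every beat, which is inconsistent with the
published analysis retaining the large majority of beats. Scoring on
the informative window, which is also exactly what the environment
observes, resolves the inconsistency. Segment quality keeps the
full-epoch definition, where the edge R peaks are consistent across
beats and count as signal.

## Training and the baseline optimizer

The published pipeline trains a deep policy with an off-the-shelf
proximal-policy-optimization implementation (default
hyperparameters — its authors report that tuning attempts did not
improve on them). No reinforcement-learning backend exists in this R
stack, so the package substitutes a transparent policy search with the
same environment contract: a linear policy $a = 0.01\,\tanh(W f)$ over
the observation ($f$ = intercept + 250 residual points + 24 normalized
parameters), initialized at a damped Gauss-Newton linearization of the
forward model at the reference point (`gauss_newton_policy()`: the
least-squares direction is a linear map of the residual, so it lives
inside this policy class) and refined by antithetic evolution
strategies with rank-normalized updates and validation-based elitism.
`total_steps` counts environment steps; the desk-scale default is 1e5
(the published budget, 3e6, is a flag away but not a test-time
setting). Training is single-threaded and seed-reproducible.
`total_steps = 0` returns the untrained policy, whose action rule is
random exploration — the documented fallback.

The deterministic `baseline_fit()` is both a floor for policy quality
and the testing oracle for the environment: greedy coordinate search
with a seeded coordinate order, a ladder of step magnitudes and a line
search along improving directions, run under exactly the same
constrained-update contract (so it can never leave the box or break
the peak order). On noiseless in-box beats it reaches ≥15 dB in ≥90%
of seeded trials and recovers parameters with a median box-scaled
absolute error ≈0.13; the residual error reflects genuine partial
non-identifiability (overlapping components trade µ/σ/D against each
other at equal waveform fit), not optimizer failure.

## The synthetic world

The generator emulates a longitudinal infant ECG sample: 8 age levels
(1–15 months) with the recording design {9, 13, 19, 21, 14, 19, 17, 9}
(121 recordings, 40 subjects assigned round-robin so subjects repeat
across ages), mean RR 0.43 s (≈140 bpm, a typical infant heart rate)
with 0.02 s jitter, between-subject parameter offsets at 5% of box
width, between-beat jitter at 2%, all draws clipped into the box and
rejected until order-valid. Age enters as per-parameter linear drifts.
Noise is white Gaussian plus a 0.3 Hz baseline-wander sinusoid (70/30
power split) — chosen to exercise both the SNR filter and the
observation window; the scale of a single fixed noise realization is
calibrated by root finding so the epoched segment SNR hits its target
almost exactly (landing a hair above, never below). The generator does
**not** emulate respiratory sinus arrhythmia, electrode artifacts,
ectopic beats, or non-lognormal wave shapes — a green test establishes
correct mechanics of the pipeline on a world where the model is true,
not clinical validity.

Beats are rendered through the same piecewise-linear warp that
epoching inverts; a single symmetric per-beat scale would make the
round-trip test fail whenever consecutive RR intervals differ, through
no fault of the epoching code. The symmetric $\alpha$ remains what the
analysis pipeline uses for denormalization, faithfully reproducing the
published procedure (and its small warp-asymmetry approximation).

## Statistical stage

Fitted parameters are averaged in two stages (beats within segments,
segment means within recordings — not a pooled-beat mean), only from
beats at or above the 5 dB fitting SNR; age levels with fewer than 8
distinct participants are dropped; each of the 24 seconds-basis
parameters is tested against age with the Kendall rank correlation
(tau-b — the variant is not pinned down by the published description,
and tau-b is the standard choice under the heavy ties of discrete age
levels), Bonferroni-corrected ×24 and flagged at corrected p < 0.01.
All recordings enter the correlation, including repeated subjects — a
faithful reproduction of the published analysis that carries the usual
repeated-measures caveat. Amplitude parameters are written to output
CSVs in µV·s × 1e6 for readability.

The simulation test for this stage plants 10 strong slopes (≈50% of
box width across the age span) and 14 nulls, with slope signs chosen
so drifting parameters move neighboring peaks apart (slopes that drive
peaks together make order-valid draws impossible at extreme ages). The
stage must find ≥8 of 10 with ≤1 false positive. The test feeds the
stage from generator ground truth with a fixed α: with per-beat α, the
µ, t₀ and D slopes measured in seconds confound parameter drift with
RR variability, which is a property of the denormalization, not an
error of the statistical stage under test.

## Numerical choices

* Support convention: exactly 0 at and before $t_0$.
* Closed (inclusive) box: a clipped-to-bound state is valid; strict
  inequality only for peak ordering.
* Epoch halves are half-open so the shared R sample appears once
  (grid index 251, normalized time 0); the error window is half-open
  at 0.7 so exactly 250 points are selected.
* SNR cap 120 dB; residual power below 1e-12 of signal power counts
  as exact.
* Resampling to 1024 Hz is Fourier-domain zero-insertion (ideal
  lowpass interpolation) for the integer factors 2× and 8×.
* The R-peak detector thresholds the squared 5–30 Hz bandpassed
  signal at 0.35× the median of its 2 s block maxima; a low-percentile
  threshold (first tried) sat below residual T-wave energy and noise
  maxima in flat spans and produced systematic false peaks.
* Patience counts strictly-non-improving steps (no new best); ties do
  not reset it.

## Known limitations

* The policy-search trainer is a stand-in for the published
  deep-RL optimizer; it improves clearly over the initial estimate and
  the untrained policy at desk scale, but the deterministic baseline
  optimizer remains the stronger extractor and is the pipeline default.
* Only CSV traces are read (no EDF reader in the supported stack).
* The published headline numbers (82.7% of 751,510 beats retained,
  10/24 significant parameters with |τ| in 0.27–0.51) belong to an
  unavailable infant dataset; the package mirrors them structurally on
  synthetic data and makes no claim to reproduce them numerically.
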