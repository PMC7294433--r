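---
title: "Remote PRV measurement: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remote PRV measurement: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and their assumptions, every tunable parameter with its default
and rationale, what the synthetic generator does and does not emulate, and
the numerical decisions taken where the design was genuinely open.

## 1. The measurement problem

Remote photoplethysmography (rPPG) observes the cardiac blood volume pulse
(BVP) as a minute color variation of facial skin in video. Mean heart rate
survives heavy averaging, but *pulse rate variability* (PRV) — the
beat-to-beat fluctuation of inter-beat intervals (IBIs) — requires every
individual systolic peak to be located in a signal that is noisy and
sampled at camera frame rates (~25 Hz, versus 250–1000 Hz for contact
PPG). `pvmprv` implements the post-video part of such a pipeline: the
input is the spatially averaged RGB trace; its output is a PRV series with
time- and frequency-domain features, plus a complete error report against
a ground-truth (contact-sensor style) peak annotation.

## 2. Periodic variance maximization (PVM)

PVM assumes the pulse is the most *self-similar-at-lag* linear combination
of the three color channels. For the centered, detrended trace $x(i)$ and
candidate lag $\tau$ (samples):

$$C_x = \frac{1}{N}\sum_{i=1}^{N} x(i)x(i)^\top,\qquad
  P_x = \frac{1}{N-\tau}\sum_{i=1}^{N-\tau} x(i)x(i+\tau)^\top,$$

with $P_x$ symmetrized as $(P_x+P_x^\top)/2$ so the generalized
eigenvalues are real. Solving $W^\top P_x W = D$, $W^\top C_x W = I$ and
taking the top eigenvector $w$ gives the projection $y(i)=w^\top x(i)$
with maximal periodicity
$\rho(\tau) = (w^\top P_x w)/(w^\top C_x w) \le 1$, with equality exactly
for a fully periodic component at its true period. The lag scan covers
all integer lags in the heart-rate band and the best lag $\tau^*$ defines
the extracted BVP.

Numerical choices:

* **Truncated, renormalized lagged sum.** The lagged products only exist
  for $i \le N-\tau$; normalizing by $N-\tau$ (not $N$) keeps $P_x$
  unbiased and avoids out-of-range indices.
* **Integer lags only.** The covariances are defined on sample indices;
  at 25 Hz the implied heart-rate quantization (e.g. 21 vs 22 samples
  ≈ 71.4 vs 68.2 bpm) is accepted and visible in `tau_star_s`. No
  fractional-lag interpolation is attempted.
* **Ridge.** Facial RGB channels are near-collinear, so $C_x$ is often
  ill-conditioned. A relative ridge `ridge * mean(diag(Cx))` (default
  `ridge = 1e-8`) is added before the Cholesky factorization, and $\rho$
  is evaluated against the *ridged* covariance. The latter matters: on a
  noise-free rank-deficient trace the top generalized eigenvector can lie
  in the null space of $C_x$, where the unridged ratio is 0/0. The ridge
  bias on $\rho$ is $O(10^{-8})$, far below any decision threshold.
* **GEVD solver.** Cholesky whitening plus a symmetric eigendecomposition
  (base `chol`/`eigen`); the constraints $W^\top C_x W = I$ and
  $W^\top P_x W = D$ hold to ~1e-14 on well-conditioned input and are
  property-tested at 1e-8.
* **Tie-break.** Equal $\rho$ resolves to the smallest lag
  (`which.max`), making the scan deterministic.
* **Sign.** Eigenvectors have arbitrary sign; `fix_sign()` orients the
  output so its sample skewness is non-negative (systolic upstrokes are
  sharp and upward), flipping only when skewness is negative beyond float
  noise (`< -1e-12`) so symmetric signals are left alone.
* **Band endpoints.** The "human heart rate range" is taken as
  40–240 bpm by default and is configurable; results in the test
  batteries are insensitive to the endpoints as long as the band contains
  the pulse.
* **Whole record vs windows.** The default applies PVM once to the whole
  record — the covariances are whole-record statistics and the synthetic
  conditions are stationary. A windowed mode (`window_s`, hop of half a
  window, sign-aligned on overlaps, center-concatenated) is provided for
  long or non-stationary recordings, and is checked against whole-record
  extraction on stationary traces.

A `low_periodicity` flag marks records whose best $\rho$ falls below 0.3.
The threshold comes from the null behavior of the scan: on i.i.d. noise
traces of a few thousand samples the maximum $\rho$ over the band stays
well under 0.3, while even badly degraded pulse mixtures exceed it.

## 3. Preprocessing

Centering is per-channel over the whole record (the covariances above are
whole-record moments). Two detrenders are provided because the drift
remover is genuinely a free choice:

* `smoothness_prior` (default): regularized least squares with a
  second-difference penalty,
  $\hat z = (I + \lambda^2 D_2^\top D_2)^{-1} y$, the standard HRV drift
  remover, solved on sparse banded matrices. Its effective high-pass
  corner is $f_c \approx f_s/(2\pi\sqrt{\lambda})$, so the package
  parameterizes by `cutoff_hz` (default **0.1 Hz**) and derives
  $\lambda = (f_s/2\pi f_c)^2$ (≈ 1.6×10³ at 25 Hz). This removes
  illumination drift (≲0.1 Hz) while passing the slowest plausible pulse
  (40 bpm = 0.67 Hz) essentially untouched. A fixed small $\lambda$
  independent of $f_s$ would put the corner *inside* the pulse band —
  at $\lambda = 10$, $f_c \approx 1.3$ Hz at 25 Hz — and destroy the
  signal, which is why the corner, not $\lambda$, is the exposed knob.
* `linear`: ordinary least-squares line removal, an exact projection and
  therefore exactly idempotent. The smoothing detrender is a linear
  *filter*, not a projection: a second pass attenuates components near
  the corner again ($h$ vs $h^2$), so idempotence holds only
  approximately for in-band signals. Tests assert exact idempotence for
  the projection method and document this distinction.

## 4. The three detectors

All three operate on the detrended, sign-fixed BVP and use only
*relative* thresholds, so all are invariant to positive rescaling
(property-tested).

**Adaptive two-window.** Beat window $W_b(i) = 1/F_b(i)$, where $F_b(i)$
is the dominant in-band frequency of a Hann-windowed **10 s** segment
centered on sample $i$, zero-padded ×4 (native resolution 0.1 Hz is too
coarse to set a window length; padded, ~0.025 Hz). Edge samples closer
than half a window to a record end reuse the nearest full-window
estimate — short asymmetric windows are unstable. The peak window is
$W_p(i) = 0.25\,W_b(i)$: peaks live in the positive half of the detrended
beat, and the systolic crest occupies about half of that. Both windows
are converted to odd sample counts (`round`, then +1 if even) so the
moving averages are symmetric about $i$; edge windows shrink to the valid
range. Candidate blocks are maximal runs with $MA_p(i) > MA_b(i)$
(strict; boundary equality is "not a block"), the width threshold THR2 is
the mean of $W_p$ in samples over all in-block samples of the record
(record-global and deterministic), blocks narrower than THR2 are
discarded, and each survivor yields one peak at its signal maximum
(earliest sample on ties).

**Slope sum function.** $SSF(i)=\sum_{k=i-w+1}^{i}\Delta y_k^+$ with
window $w$ = **0.4 s** of samples and $SSF(i)=0$ for $i\le w$. The
trailing-window reading of the summation limits follows the transform's
standard definition. Peaks are strict local maxima of the *detrended* SSF
above **0.175 ×** its mean absolute value, with the **0.24 s** minimum
distance. The transform reshapes the waveform, so SSF peak *locations*
carry a systematic shift relative to the raw apexes; no correction is
applied — interval sequences are largely shift-invariant, and the
evaluation treats SSF location error accordingly.

**Local maximum.** Strict local maxima filtered by height ≥ **0.75 ×**
and topographic prominence ≥ **0.3 ×** the mean absolute amplitude, with
the same 0.24 s spacing rule. Prominence is the standard definition: peak
height minus the higher of the two lowest valleys separating it from the
nearest higher terrain, with record boundaries counting as lower terrain;
it is pinned by an exhaustive $O(n^2)$ valley-search oracle.

Minimum-distance conflicts (SSF and local-max) are resolved by sorting
candidates by height (ties to the earlier index) and keeping greedily —
deterministic and the common practice. The fixed-height rule is the
local-max detector's documented weakness: a beat whose amplitude collapses
below 0.75×mean is missed regardless of tuning, while the two-window
comparison is local on both sides of the inequality and survives
amplitude collapse. The degraded benchmark condition exists to expose
exactly this mechanism.

## 5. PRV construction and features

IBIs anchor at the later peak of each pair (the usual event-time
convention; only sub-interval alignment depends on it). The event series
is interpolated to a uniform **200 Hz** grid — natural cubic spline by
default (smooth at this oversampling), linear selectable, automatic
linear fallback below 4 intervals. The interpolant passes exactly through
anchors (interpolation, not smoothing; tested at 1e-9).

Spectral features use a Welch PSD of the mean-removed PRV series: Hann
window, 50% overlap, segment length `min(duration/2, 60 s)` — short
records need the variance reduction, and 60 s segments give ~0.017 Hz
resolution, adequate for the LF band. The estimator is written on base
`fft` (no installed Welch routine exists here) and is validated against
Parseval's identity. Band powers integrate the PSD by the trapezoid rule
over LF = 0.04–0.15 Hz and HF = 0.15–0.4 Hz; the LF/HF ratio is flagged
`NA` when HF is exactly zero. The PSD is computed directly on the 200 Hz
series without decimation. Short records cannot support the LF band
(a 20 s record holds less than one LF cycle), so spectral fields are `NA`
below 10 s of PRV support and LF claims on short records are out of
scope.

Dispersion features: `std_ibi` uses the sample (n−1) standard deviation;
`rmssd` is $\sqrt{\tfrac{1}{N-1}\sum (IBI_{i+1}-IBI_i)^2}$.

## 6. Evaluation metrics

Matching is one-to-one within ±**0.2 s** (absorbing contact-to-face pulse
transit delay; no constant-offset pre-alignment is applied), built
greedily by ascending $|\Delta t|$ — deterministic, and verified to agree
with exhaustive optimal assignment on every instance of a seeded battery
of realistic (jittered, dropped, inserted) peak sets up to 12 peaks.
%CP, %MP and %IP all use the number of ground-truth peaks as denominator,
so %CP + %MP = 100 identically and %IP can exceed 100 in pathological
cases (documented rather than clamped). IBI errors compare only intervals
whose bounding peaks are adjacent in *both* series: a missed or inserted
beat breaks the comparison chain instead of polluting neighboring
intervals. PRV errors compare the two interpolated 200 Hz series on their
overlapping support; %PRVer normalizes by the mean ground-truth PRV on
that support. Cohort aggregation reports per-metric means with Student-t
95% half-widths ($t_{0.975,n-1}\,s/\sqrt n$; the t rather than normal
quantile, labeled as such, since cohorts are small).

## 7. The synthetic generator: what it emulates, what it does not

The generator exists so every stage is testable without access to any
video corpus. It emulates the *signal-level* structure of a
webcam-plus-contact-sensor recording:

* **Beat timing.** An instantaneous rate modulated at a respiratory
  frequency (default 0.25 Hz) and a low frequency (default 0.1 Hz) is
  integrated to a cumulative phase on a 1 ms grid; beats fall at integer
  phase crossings (linearly interpolated). Integrating the *rate* makes
  the programmed modulation frequencies appear at the programmed Hz in
  the IBI spectrum. Depths are specified in seconds of IBI swing and
  converted to relative frequency modulation internally. Defaults:
  72 bpm, RSA depth 0.03 s, LF depth 0.02 s.
* **Waveform.** Each beat is two Gaussian bumps — systolic (σ = 0.13 s)
  plus a dicrotic bump (relative amplitude 0.3, delay 0.3 s) — rather
  than a physiological template library: simple, differentiable, and with
  an analytically known apex. The σ reflects what a 25 Hz rPPG signal
  looks like after the optical and averaging chain: broad, near-sinusoidal
  beats with the dicrotic wave reduced to a shoulder. Ground-truth apex
  times are refined per beat by numerical maximization of the clean
  waveform, so neighboring-bump interference is included in the truth.
* **Degradations.** White Gaussian noise at a target SNR (a pink-noise
  switch is deliberately absent — simplicity over realism), sinusoidal
  baseline drift (amplitude relative to the AC RMS, default 0.05 Hz),
  and per-beat amplitude collapse (probability, factor) reproducing the
  low-beat failure mode that defeats fixed-height rules.
* **RGB embedding.** Outer product of the clean BVP with a fixed mixing
  vector (default (0.3, 1, 0.5), strongest in green), then per-channel
  independent drift phases and noise.
* **Contact/remote pairs.** One beat sequence rendered clean at 1000 Hz
  (contact) and corrupted at 25 Hz with a pulse-transit delay
  (|delay| < 0.2 s) for the remote trace.
* **Edges.** Beats are kept ≥ ~0.7 beat periods clear of the record
  boundaries, so every ground-truth beat is fully rendered and outside
  the zone where centered-window statistics are edge-biased — the
  synthetic analogue of trimming record boundaries before scoring.

What it does **not** emulate: motion artifacts, illumination transients,
compression noise, skin-tone-dependent mixing changes, non-stationary
heart-rate trends, or any video-level effect. Passing the clean and
degraded batteries therefore demonstrates the algorithms' correctness and
their relative robustness mechanisms — not field performance on real
video, whose error levels are substantially higher.

The generator is seeded (`withr::with_seed`, R's default Mersenne
Twister), bitwise reproducible, and never touches the caller's RNG state.

## 8. Study conditions and problem sizes used by the test suite

The packaged batteries run 50 seeded recordings per condition, 30 s at
25 Hz, heart rates drawn uniformly in 55–95 bpm: the **clean** condition
at 20 dB SNR with drift, and the **degraded** condition at 5 dB SNR with
per-beat collapse (probability 0.2, factor 0.25). Lag-scan recovery uses
50 recordings of 60 s at 5 dB SNR with heart rates in 50–150 bpm.
Feature-recovery checks use 120 s records against an independent
high-resolution (250 Hz grid) beat-time integrator; spectral concentration
checks use 300 s of ground-truth IBI so the LF band holds many modulation
cycles. On these conditions the clean battery yields %CP = 100 for all
three detectors, and the degraded battery reproduces the ordering
two-window ≥ SSF ≥ local-max with the two-window vs local-max gap
significant under a paired one-sided t-test.

## 9. Known limitations

* Integer-lag quantization bounds the precision of `tau_star_s` at low
  sampling rates; the scan does not interpolate the $\rho$ curve.
* The two-window FFT rate estimate assumes one dominant in-band
  component; polyrhythmic interference (e.g. strong drift harmonics
  inside the band) can mislead $W_b$ locally.
* SSF peak locations carry their systematic shape shift; only
  interval-domain quantities should be compared across detectors without
  correction.
* The evaluation assumes the ground truth itself is noiseless; annotation
  jitter is not modeled.
* Welch band powers on records near the 10 s minimum are dominated by a
  single segment and should be treated as qualitative.
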