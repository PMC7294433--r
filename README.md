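# pvmprv

Remote pulse-rate-variability (PRV) measurement from camera-derived color
traces: blood-volume-pulse (BVP) extraction by **Periodic Variance
Maximization (PVM)**, systolic peak detection with an **adaptive two-window**
method (plus slope-sum-function and rule-based local-maximum baselines),
PRV construction with time- and frequency-domain features, and a full
evaluation-metric suite — all exercisable end to end on a bundled,
seeded synthetic-signal generator.

## Who this is for

Remote photoplethysmography (rPPG) pipelines recover the cardiac pulse from
skin-color variation in face video. Estimating mean heart rate this way is
routine; estimating *beat-to-beat* variability is much harder, because it
requires locating every individual systolic peak in a noisy,
low-frame-rate signal. This package implements the signal-processing core
of such a pipeline — everything downstream of the video frontend. Its input
is the spatially averaged RGB time series (`time,r,g,b` CSV); face
detection, tracking and skin masking are out of scope.

## The methods

**PVM extraction.** Let x(i) be the centered, detrended 3-channel trace.
For a candidate lag τ define the covariance pair

    Cx = (1/N) Σ x(i) x(i)ᵀ ,   Px = 1/(N−τ) Σ x(i) x(i+τ)ᵀ ,

with Px symmetrized as (Px + Pxᵀ)/2. The generalized eigenvalue problem
W ᵀ Px W = D, W ᵀ Cx W = I yields the weight vector w (top eigenvector)
whose projection y(i) = wᵀ x(i) is maximally self-similar at lag τ; its
periodicity is ρ(τ) = (wᵀ Px w)/(wᵀ Cx w), which equals 1 for a fully
periodic signal at its true period. Scanning integer lags over the human
heart-rate band (default 40–240 bpm) gives the optimal period τ\* and the
extracted BVP.

**Adaptive two-window detection.** Two centered moving averages are
compared per sample: MAb over one beat period Wb(i) (estimated from a
sliding 10 s FFT) and MAp over the systolic-peak window Wp(i) = 0.25·Wb(i).
Runs where MAp > MAb form blocks of interest; blocks narrower than the
mean peak-window width are discarded as noise; each surviving block
contributes one peak at its maximum. All thresholds are relative, so the
detector needs no amplitude tuning.

**Baselines.** A slope-sum-function detector (trailing 0.4 s sum of
positive increments, threshold 0.175×mean |SSF|) and a `findpeaks`-style
local-maximum detector (height 0.75×, prominence 0.3× the mean absolute
amplitude, 0.24 s minimum distance).

**PRV.** Inter-beat intervals from successive peaks are interpolated to a
uniform 200 Hz series (natural cubic spline); features are the interval
standard deviation, RMSSD, and Welch-PSD band powers in LF (0.04–0.15 Hz)
and HF (0.15–0.4 Hz).

**Evaluation.** Detected peaks are matched one-to-one to ground-truth
peaks within ±0.2 s; the report contains peak location error (PLE),
correct/missing/incorrect detection percentages (%CP, %MP, %IP), interval
and PRV-series errors (IBIer, PRVer, %PRVer) and feature errors (STDer,
RMSSDer), with Student-t cohort aggregation.

## Worked example

Simulate a synchronized contact/remote pair (72 bpm pulse mixed into RGB
at 10 dB SNR with drift and a 50 ms pulse-transit delay), extract, detect
and evaluate:

```r
library(pvmprv)
pair <- simulate_pair(pulse_model(mean_hr = 72),
                      corruption_model(snr_db = 10, drift_amp = 0.5),
                      duration = 30, delay = 0.05, seed = 1)
trace <- center_detrend(pair$remote$trace)
pvm <- extract_bvp(trace)
pvm
#> <pvm_result> tau* = 21 samples (0.840 s, 71.4 bpm), rho* = 0.9008
#>   w = (3.8902, 1.1116, 1.9511)
peaks <- detect_peaks(pvm$bvp, "two_window")
report <- evaluate_detection(peaks, peak_series(pair$contact$truth$peak_times))
report
#> <evaluation_report>
#>   PLE = 0.0513 s   %CP = 100.00   %MP = 0.00   %IP = 2.86
#>   IBIer = 0.0411 s   PRVer = 0.0346 s   %PRVer = 4.15
#>   STDer = 0.0332 s   RMSSDer = 0.0652 s
```

The scan found the pulse period at 21 samples (the programmed 72 bpm is
25·60/72 ≈ 20.8 samples) with periodicity 0.90; every ground-truth beat
was matched within the 0.2 s window (%CP = 100), the mean matched-peak
location error is ~51 ms (dominated by the programmed 50 ms transit
delay), and the PRV series differs from the contact reference by 4.2% on
average.

A shell interface wrapping the same functions is installed as `exec/pvmprv`:

```sh
pvmprv simulate --kind pair --duration 30 --seed 9 --out-prefix sim
pvmprv pipeline --in sim_remote.csv --truth sim_contact_truth.csv --report report.json
```

`benchmark_detectors()` runs seeded 50-recording batteries (clean and
degraded study conditions) comparing the three detectors; see the methods
vignette (`vignettes/pvm-prv-methods.Rmd`) for what the generator does and
does not emulate.

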