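---
title: "Estimating the knee angle from sEMG with time-advanced RMS features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the knee angle from sEMG with time-advanced RMS features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The estimation problem

During walking, the electrical activation of the lower-limb muscles precedes
the knee motion it produces by an electromechanical delay of roughly
20–200 ms. A decoder that pairs each sEMG feature window with the
*simultaneous* angle sample therefore throws away the predictive lead that
makes sEMG useful for exoskeleton control in the first place. `rrtaf`
estimates the continuous knee angle from eight muscles' sEMG while modelling
that lead explicitly.

The recording regime assumed throughout is dual-rate: sEMG at
`f_EMG` = 1200 Hz and the knee angle at `f_angle` = 120 Hz, with `f_EMG` an
integer multiple of `f_angle`.

## Pipeline

**Preprocessing.** Raw sEMG is notch-filtered at 50 Hz (power-line
interference; constrained biquad, default Q = 30, i.e. a −3 dB width of
about 1.7 Hz) and band-passed with a 4th-order Butterworth at 10–500 Hz,
the band holding essentially all sEMG energy. Both filters run zero-phase
(forward–backward) by default: this is an offline decoder, and a causal
pass would add a frequency-dependent group delay that corrupts the
time-advance bookkeeping below. A causal mode is available behind
`filter_spec(zero_phase = FALSE)` for real-time emulation. Note that the
forward–backward pass squares the magnitude response, so the quoted design
orders understate the attenuation actually applied.

**Time-advance arithmetic.** For an advance time `Δt` (seconds),

* `l = ceil(Δt · f_angle)` is the number of samples the angle sequence is
  lagged, and
* `k = l · f_EMG / f_angle` the number of samples the *concurrent* sEMG
  stream is lagged;

`k` must come out integral, which holds whenever `f_EMG` is a multiple of
`f_angle`. With the defaults (`Δt` = 0.2 s, 120/1200 Hz): `l` = 24,
`k` = 240. The default advance of 0.2 s sits at the top of the physiological
range, and the supported range is 0.02–0.2 s.

**Features.** Each muscle contributes two series of non-overlapping
window-RMS values (window width = increment = 20 sEMG samples, so the
feature rate is 1200/20 = 60 Hz):

* *concurrent RMS*, windows offset by `k` samples — synchronous with the
  lagged angle;
* *time-advanced RMS*, windows from the raw origin — leading the lagged
  angle by `Δt`.

Window `h` covers samples `(h−1)·20 + offset + 1 … h·20 + offset`, 1-based
inclusive. Raw RMS curves vibrate acutely, so both series are smoothed with
a 2nd-order Butterworth low-pass at 5 Hz (zero-phase, again to preserve
alignment); gait content lives below ~3 Hz and is untouched. The angle is
brought to the 60 Hz feature rate by pairwise averaging, lagged by `l`
before averaging. Because the three streams (concurrent, advanced, angle)
lose different amounts of length to their shifts, all are right-trimmed to
the common length; at `Δt` = 0.2 s a `d`-second recording yields
`T = 60·d − 12` aligned steps. Columns are interleaved per muscle
(`RF_rms, RF_rmstaf, BF_rms, BF_rmstaf, …`), giving the 16-input RRTAF set;
`concurrent_only()` produces the 8-column RMS-only baseline.

**Normalization.** Min–max to [−1, 1], fitted on the training split only;
the test split reuses the training extremes and may leave [−1, 1]. Values
are deliberately *not* clipped: clipping would make the angle inversion
(back to degrees) lossy and would hide distribution shift rather than
expose it.

**LSTM regressor.** A single recurrent layer of gated cells
(`f, i, o = σ(W h + U x + b)`, `c' = tanh(·)`, `c_t = f∘c_{t−1} + i∘c'`,
`h_t = o∘tanh(c_t)`) with a linear readout per time step, trained by full
backpropagation-through-time with Adam on the mean squared error. The
reference recipe is 200 hidden units, unroll length 100, learning rate
0.0005, 200 epochs, mini-batches of 50 windows, dropout 0.5. A "100-layer"
description of such a network is read here as the *unroll depth in time*
of one recurrent layer, not 100 stacked layers: the latter is untrainable
with this recipe and contradicts the readout-per-step topology. A
`stacked_layers` argument is reserved should stacking ever be worth a
sensitivity check.

Choices the recipe leaves open, fixed as follows: weights initialized
uniformly in ±1/√fan-in from the seeded generator; training windows cut
non-overlapping in temporal order, shuffled at the window level each epoch;
hidden state reset per window; dropout applied to the cell output before
the readout (the only non-recurrent site in a single-layer model), with
inverted scaling so prediction needs no rescaling. Prediction unrolls
statefully over the whole sequence with dropout off.

**BPNN baseline.** A 16–`n_hidden`–1 network, tansig hidden layer
(`2/(1+e^{−2z})−1`), trained by full-batch gradient descent with momentum
(default coefficient 0.9, the conventional value) at learning rate 0.1,
stopping at a training MSE of 0.01 (normalized units) or 50,000 epochs.
The network equation is implemented exactly as its printed form, in which
the output node applies a logistic function before the output bias; the
accompanying prose calls the output layer `purelin`, so a `"linear"`
output option provides the conventional affine readout. The logistic form
constrains the output span to a unit-wide band, which contributes to this
baseline's larger errors on targets spanning [−1, 1] — consistent with its
role as the weaker comparator. Hidden-layer sizing follows the empirical
rules `floor(sqrt(n+m)) + a, a ∈ 1..10` (5–14 for 16 inputs) and
`log2(n)` (= 4); because empirically selected optima can fall outside that
union (18 in the reference setting), `hidden_unit_candidates()` widens the
default scan to 4–26, and `select_hidden_units()` picks the validation-MSE
minimizer, ties going to the smaller network.

**Evaluation.** RMSE in degrees — implemented as the standard
`sqrt(mean((est − act)²))`; the printed formula it follows omits the square
and root typographically but names the metric RMSE and reports degrees
consistent with the standard reading — and the zero-lag Pearson correlation
ρ. `summarize_methods()` adds the cross-method arithmetic: per-method mean
and spread, percent reductions (RMSE) and increases (ρ) of column means,
and per-subject maxima. Two conventions matter when reproducing published
comparison tables of this kind and are therefore explicit arguments:

* **Spread.** The shipped five-subject table's "±" values follow the
  population (divide-by-n) convention in seven of eight cells
  (e.g. 2.2334 = 2.4971·√(4/5)); one cell (BPNN-RRTAF RMSE ± 1.8886)
  matches neither convention and is treated as an erratum. The default is
  therefore `sd_convention = "population"`, which also keeps the
  single-subject edge case defined (sd = 0); `"sample"` is available.
* **Rounding.** Percent changes are computed from unrounded column means by
  default. Exactly one published figure (the 18.35 % ρ increase of
  LSTM-RRTAF over BPNN-RMS) only reproduces when the means are first
  rounded to 4 decimal places as printed; `round_means = 4` reproduces that
  convention, and the tests document which figure needs it.

One published per-subject maximum (the 20.46 % ρ increase attributed to
subject 1 for BPNN-RRTAF over BPNN-RMS) is internally inconsistent with its
own table, which yields a larger value for subject 4 (≈21.0 %); it is not
asserted anywhere.

## The synthetic gait simulator

No public recording of this acquisition regime exists, so the package ships
a simulator whose point is a *known* electromechanical delay, not
physiological realism.

* **Angle**: a 3-harmonic Fourier series of the stride phase
  (default period 1.2 s, matching ~1.0 m/s treadmill walking), coefficients
  chosen once to give a biphasic knee-flexion pattern spanning roughly
  0.8–68.5°: a small stance-phase flexion wave and a dominant swing-phase
  peak. These defaults are stand-ins — they are *not* fitted to any
  subject's waveform.
* **Envelopes**: per muscle `m`, the standardized angle and standardized
  angular velocity, both evaluated at `t + delay_s`, are mixed with phase
  `ψ_m = 2π(m−1)/8` and half-wave rectified. This is the simplest
  construction that makes the eight channels distinct, nonnegative, and
  delay-bearing; muscle 1 (ψ = 0) is a pure rectified-angle channel, which
  is what makes the delay exactly recoverable by cross-correlation.
* **sEMG**: envelope × band-limited (10–500 Hz) unit-variance Gaussian
  carrier, plus `interference_amp`·sin(2π·50·t) (default 0.1) and white
  measurement noise (default sd 0.05). A single seeded generator draws, in
  documented order, each muscle's carrier then each muscle's noise, so
  recordings are bitwise reproducible.
* A degenerate `envelope = "constant"` mode reduces each channel to its
  carrier, for stationarity checks.

What passing tests on this simulator do **not** show: robustness to
electrode shift, fatigue, crosstalk, within- and between-subject
variability, non-stationary cadence, or motion artifact — none of which the
generator emulates. Results on synthetic gait bound the pipeline's
correctness, not its field performance.

## Numerical choices

* **Zero-phase filtering** uses odd-reflection padding at both ends plus
  steady-state initial conditions, so constants pass exactly and edge
  transients die in the padding rather than the data.
* **Notch design**: constrained biquad with unit gain at DC and Nyquist and
  a zero at 50 Hz; `filter_response()` exposes the analytic magnitude
  response of every designed filter, squared when it will be applied
  forward–backward.
* **Degenerate inputs** fail fast: constant feature columns reject
  normalization; zero-variance inputs to ρ signal an error rather than
  returning 0; mismatched feature layouts (permuted columns) are refused at
  prediction time.
* **Tie-breaks**: hidden-unit selection prefers fewer units at equal MSE.
* **Problem sizes.** The tests and the acceptance script run the stochastic
  checks at a scale a desk machine handles comfortably: 60 s recordings,
  unroll length 100, 30 epochs, and — because 60 s of gait yields only 28
  training windows, which the reference batch size of 50 would collapse
  into a single optimizer step per epoch — a scaled training configuration
  of 48 hidden units, batch 7, learning rate 0.005, dropout 0.2. The
  full-scale recipe remains the package default for real-length recordings.
* The method-ordering property (RRTAF ≤ RMS-only test RMSE for the LSTM) is
  asserted over 10 seeded replicates with a ≥7/10 criterion, reflecting
  that it is a stochastic ordering, not a per-run guarantee.

## Known limitations

* The BPNN's printed logistic output form limits its representable range;
  use `output_activation = "linear"` for a conventional regression readout.
* Training is plain R (BLAS matrix products); the full reference recipe
  (200 hidden units, 200 epochs, minutes of data) is feasible but slow —
  expect hours, not seconds, on one core.
* The simulator's delay is constant per recording; time-varying delays
  (speed changes, fatigue) are out of scope.
* `Δt` is a single global advance; per-muscle delays are not modelled.
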