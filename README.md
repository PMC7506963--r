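# rrtaf

Continuous knee-joint angle estimation from multichannel surface
electromyography (sEMG) during gait, built around a **time-advanced RMS
feature**.

## The problem

Exoskeleton and rehabilitation-robotics controllers need the knee angle
*before* it happens. Surface EMG is the natural control signal for that:
muscle electrical activity precedes the mechanical motion it produces by an
electromechanical delay of roughly 20–200 ms. Most angle decoders ignore
this lead and pair each sEMG window with the simultaneous angle sample,
discarding exactly the predictive information that makes sEMG attractive.

`rrtaf` implements a decoding pipeline that exploits the lead explicitly.
For an advance time Δt, the shift arithmetic

```
l = ceil(Δt · f_angle)        (angle samples to lag)
k = l · f_EMG / f_angle       (sEMG samples to lag)
```

pairs each lagged angle sample with **two** RMS features per muscle,
extracted with non-overlapping windows of N = 20 samples:

```
RMS(j)  = sqrt( 1/N · Σ_{i=(j−1)N+k+1}^{jN+k}  emg²(i) )   (concurrent)
RMS(h)  = sqrt( 1/N · Σ_{i=(h−1)N+1}^{hN}      emg²(i) )   (time-advanced)
```

The concurrent series is synchronous with the lagged angle; the
time-advanced series leads it by Δt. With eight lower-limb muscles (RF, BF,
ST, GC, SM, SR, MG, TA) this gives the 16-column **RRTAF** feature set, the
input of an LSTM sequence regressor (gated cell `f, i, o = σ(·)`,
`c' = tanh(·)`, `c_t = f∘c_{t−1} + i∘c'`, `h_t = o∘tanh(c_t)`, trained
from scratch with BPTT + Adam). A three-layer back-propagation network
(tansig hidden layer, momentum training, empirical hidden-unit selection)
serves as the baseline, and predictions are scored by RMSE (degrees) and
the zero-lag Pearson correlation ρ.

The package also contains:

* preprocessing exactly as the acquisition demands: 50 Hz power-line notch
  (Q = 30 biquad) followed by a 4th-order Butterworth band-pass, 10–500 Hz,
  zero-phase by default;
* leakage-safe min–max normalization to [−1, 1] (parameters fitted on the
  training split only, test values deliberately unclipped);
* a synthetic gait/sEMG simulator with a *known* electromechanical delay —
  periodic biphasic knee trajectory, per-muscle activation envelopes leading
  the angle, band-limited Gaussian carriers, 50 Hz interference — so every
  stage is testable without subject data;
* cross-method summary arithmetic (per-method averages, percent
  reductions/increases, per-subject maxima) with the published five-subject
  comparison table shipped as a worked example (`example_method_table()`).

## Worked example

Simulate a minute of treadmill gait with a 0.2 s electromechanical delay,
then run the full pipeline (preprocess → featurize at Δt = 0.2 s → 80/20
temporal split → normalize → LSTM → evaluate):

```r
library(rrtaf)
cfg <- pipeline_config(
  out_dir = file.path(tempdir(), "demo"),
  sim = gait_sim_config(duration_s = 60, delay_s = 0.2, seed = 42),
  model = "lstm",
  model_cfg = lstm_config(input_size = 16, hidden_size = 48, seq_len = 100,
                          learning_rate = 0.005, epochs = 30, batch_size = 7,
                          dropout_p = 0.2, seed = 42),
  seed = 42)
rep <- run_pipeline(cfg)
print(rep)
```

```
[rrtaf] simulate: 60.0 s, delay 0.200 s, seed 42
[rrtaf] preprocess: notch 50 Hz (Q 30), band-pass 10-500 Hz order 4, zero-phase
[rrtaf] featurize: window 20, delta_t 0.2 s (l = 24, k = 240)
[rrtaf] train lstm: hidden 48, seq_len 100, 30 epochs, seed 42
[rrtaf] evaluate: RMSE 0.9768 deg, rho 0.9987 on 718 test steps
<pipeline_report> lstm using rrtaf: RMSE 0.9768 deg, rho 0.9987 (n_test = 718)
```

The held-out 12 s of gait are reconstructed to within about one degree RMS
with ρ ≈ 0.999. Dropping the time-advanced columns
(`features = "rms"`) degrades the same run — the package's central,
test-enforced property. Artifacts (recording CSVs, feature matrix + sidecar,
JSON model checkpoint, predictions, report) land in `out_dir` and every
stage is re-loadable from them.

A thin command-line front end (`exec/rrtaf`) exposes `simulate`, `run`
(YAML-configured pipeline), `evaluate` and `report` subcommands.

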