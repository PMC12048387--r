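# kneetorque

Piezoelectric wearable knee-torque monitoring, from raw voltage trace to
safety alert — plus the inverse design of the auxetic patch the sensor is
cut from.

Excessive knee torque drives ligament and meniscus injuries, but torque is
normally measured with lab-bound dynamometry or motion capture. A flexible
piezoelectric film worn over the knee produces voltage pulses during
flexion whose amplitude and spectral content reflect the load and joint
angle; a small neural network can map those signals to torque in real
time. `kneetorque` implements that analysis as a tested R pipeline:

* **Synthetic signal generation** (`generator_calibration`,
  `simulate_standard_test`, `simulate_session`, `build_dataset`) — 1000 Hz
  piezoelectric traces calibrated to the film's bench characterization
  (0.50 V/N sensitivity; 5.76 V at 2 Hz falling to 3.89 V at 10 Hz under
  the 11.5 N standard load), with physiological and mechanical noise and
  labelled knee-flexion events every 3 s. Torque labels follow the
  lever-arm model τ = F·L·sin(θ) with the foot weight taken as 1.4% of
  body weight.
* **Feature extraction** (`featurize`, `stft_spectrogram`,
  `suppress_artefacts`, `mean_spectrum_features`) — zero-phase high-pass
  artefact suppression, 256-point Hann STFT with 50% overlap, and the
  per-bin time-averaged magnitude (129 features per 3 s segment).
* **Torque/angle/load estimation** (`torque_net`, `decode_weighted`,
  `evaluate`, `fine_tune`, `model_footprint`) — a two-hidden-layer ReLU
  network with a softmax or regression head, Adam training on a 7:1:2
  split, probability-weighted continuous decoding, user-specific
  fine-tuning, and exact parameter/FLOP accounting.
* **Real-time monitoring** (`stream_state`, `buffer_push`,
  `step_inference`, `run_stream`) — a 3000-sample circular buffer, one
  inference every 3 s of stream, CSV logging, and alerts exactly when the
  decoded torque exceeds 30 Nm.
* **Device metrics** (`tensile_modulus`, `toughness`, `power_density`,
  `estimate_sensitivity`) — the bench formulas: E = σ/ε over the initial
  20% strain window, T = ∫σ dε, P = V²/(A·R), and the force–voltage slope.
* **Auxetic inverse design** (`build_patch`, `solve_stretch`,
  `structural_poisson`, `design_objective`, `optimize_design`,
  `export_cut_path`) — rotating-square kirigami geometry (square edge a,
  joint width b, angle θ), a plane-stress quadratic-triangle finite
  element solver with incremental geometric stepping, the structural
  Poisson's ratio μ = −((W_t−W_i)/W_i)/((L_t−L_i)/L_i), and Nelder–Mead
  minimization of f = μ + 1 (+10 penalty when max von Mises stress exceeds
  0.5 MPa), with SVG cut-path export.

## Worked example

```r
library(kneetorque)

# 1. Study conditions and labelled synthetic dataset (9 x 100 + 100 rest)
cond <- motion_conditions()
head(cond, 3)
#>   load angle   torque class
#> 1  0.0    20 1.765029     0
#> 2  9.8    20 3.340374     1
#> 3  0.0    60 4.469211     2
ds <- build_dataset(cond, n_per_condition = 100, seed = 42)
fz <- featurize_dataset(ds)

# 2. Train the 9+1-class torque classifier and evaluate on the test split
fit <- torque_net(fz$features, fz$labels$torque, epochs = 100, seed = 7)
evaluate(fit)
#> Held-out evaluation (n = 200 )
#>   accuracy: 1.0000
#>   RMSE: 0.0004
#>   Pearson r: 1.0000

# 3. Stream a synthetic session and log threshold alerts
ses <- simulate_session(subject_params(),
                        regular_schedule(cond, 20, start = 0.5),
                        duration = 60, seed = 21)
log <- run_stream(ses$waveform, stream_state(fit, threshold = 30))
table(log$alert)
#> FALSE  TRUE
#>    18     2
log[log$alert, ]
#>    t_s   class torque_Nm alert
#> 9   27 32.7966   32.7966  TRUE
#> 18  54 32.7966   32.7966  TRUE
# alerts fire only on the 32.8 Nm (58.8 N, 90 deg) condition windows

# 4. Rebuild the optimized auxetic patch and verify its mechanics
patch <- build_patch(auxetic_params(10, 3, 175), grid = c(5, 5))
resp <- solve_stretch(patch, displacement = 10, step = 0.5)
resp
#> Stretch response: 10 mm axial displacement
#>   W: 52.133 -> 59.606 mm, L: 52.133 -> 62.133 mm
#>   structural Poisson's ratio: -0.7472 at full stretch, -0.9068 sweep mean
#>   max von Mises: 0.3818 MPa
```

The held-out accuracy of 1.0 reflects the synthetic generator's clean
class structure; see the methods vignette
(`vignettes/kneetorque-methods.Rmd`) for what that does and does not say
about real recordings. The patch response shows the auxetic behaviour: the
patch *widens* by 7.5 mm while being stretched 10 mm, a sweep-mean
structural Poisson's ratio of −0.91, with the stress constraint (≤ 0.5
MPa) satisfied.

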