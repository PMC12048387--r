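---
title: "Methods: synthetic piezoelectric knee-torque monitoring and auxetic patch design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic piezoelectric knee-torque monitoring and auxetic patch design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kneetorque` implements, end to end, the analysis behind a piezoelectric
wearable that monitors knee-joint torque: a calibrated synthetic signal
generator, a spectral feature pipeline, a lightweight neural estimator with
probability-weighted decoding, a streaming alert harness, bench-test
characterization formulas, and the inverse design of the rotating-square
auxetic patch the sensor is cut from. This vignette explains the models, the
defaults and their units, the numerical choices, and what the synthetic data
can and cannot tell you.

## The torque label model

Seated knee flexion against gravity is summarized by the lever-arm model

$$\tau = F \, L \, \sin\theta,$$

where $F$ (N) is the combined weight of the foot and any external load, $L$
(m) the knee-to-ankle distance, and $\theta$ the angle of the lower leg from
vertical. Defaults: the foot weight is 1.4% of body weight (10.98 N for the
default subject) and $L = 0.47$ m. The default study grid crosses loads
$\{0, 9.8, 58.8\}$ N with angles $\{20^\circ, 60^\circ, 90^\circ\}$, giving
nine distinct torque levels from 1.77 to 32.80 Nm; `motion_conditions()`
refuses grids whose torques collide, because the class map of the
classifier would be ill-defined.

```{r}
library(kneetorque)
motion_conditions()
```

## The synthetic signal generator

No public dataset accompanies the device, so the generator is the package's
study population. It is phenomenological: it reproduces the *printed
outputs* of the film, not its electromechanics.

* **Sensitivity.** 0.50 V/N, chosen as $5.76/11.5$ so the standard 2 Hz,
  11.5 N compression test peaks at exactly 5.76 V.
* **Frequency attenuation.** Relative amplitude 1 at 2 Hz falling to
  $3.89/5.76 \approx 0.675$ at 10 Hz, interpolated linearly through the
  four tabulated bench frequencies (2, 5, 8, 10 Hz) and clamped outside.
* **Pulse shape.** Loading/unloading is a biphasic lobe pair (one period of
  a sine over the pulse width) so the voltage rises with load and returns
  exactly to baseline after unloading. The bench pulse occupies a duty
  fraction 0.4 of each cycle.
* **Angle encoding.** The paper does not state how knee angle shapes the
  waveform. Three mechanisms are used, all motivated by the "small
  motion-related features" visible in the published traces: pulse duration
  shrinks with angle, a second harmonic grows with angle, and each flexion
  event carries a Hann-enveloped vibrational burst at an angle-dependent
  carrier ($10 + \theta/3$ Hz, i.e. 16.7/30/40 Hz at the three study
  angles). The carrier matters: at the 3.9 Hz bin resolution of the
  spectral features, duration differences alone live almost entirely in the
  two lowest bins, where they are both attenuated by the artefact filter
  and swamped by event-timing jitter. A spectrally localized component
  makes angle recoverable regardless of where the event sits in its window.
* **Noise.** White ($\sigma = 0.05$ V), cardiac (1.2 Hz, 0.05 V),
  respiratory (0.3 Hz, 0.08 V) sinusoids with random phase, and Poisson
  mechanical transients (rate 0.05 s$^{-1}$, 0.5 V, 20 ms). The paper names
  these sources without magnitudes; the defaults are chosen so the stated
  filtering suppresses them.
* **Randomness.** One seeded generator per call; the same seed reproduces a
  session bit for bit, different seeds change only the noise realization.
  Event-onset jitter (default $\pm 0.1$ s inside each segment for
  datasets) emulates imperfect exercise timing.

Datasets built by `build_dataset()` follow the study protocol: 3 s segments
at 1000 Hz (3000 samples), 100 repetitions per condition by default, plus
rest-state segments (zero torque, pure baseline noise) at a 1:9 ratio so a
deployed classifier can recognize inactivity.

**What the generator does not emulate.** There is no piezoelectric tensor,
charge transport, electrode physics, hysteresis, drift, or inter-subject
biomechanical variability, and the angle encoding is a modelling choice,
not a measured property. Consequently the estimator accuracies reported on
synthetic data certify the *pipeline* (features, training, decoding,
streaming) under the stated noise model — they do not predict accuracy on
human recordings, which the original study measured separately.

## Feature pipeline

Each 3000-sample segment passes through:

1. **Artefact suppression** — zero-phase 4th-order Butterworth high-pass at
   1.5 Hz (`signal::filtfilt`, applied forwards and backwards). The
   physiological band (0.3–2 Hz) lies almost entirely inside the DC bin at
   the 1000/256 = 3.9 Hz STFT resolution, so per-bin spectral masking
   cannot isolate it; a time-domain high-pass honours the intent of
   removing low-frequency artefacts. Measured response: a 0.3 Hz tone is
   attenuated by more than 20 dB, a 5 Hz tone is within 1 dB.
2. **STFT** — 256-sample periodic Hann window with 50% overlap, no zero
   padding: $\lfloor(3000-256)/128\rfloor + 1 = 22$ frames of
   $256/2 + 1 = 129$ magnitude bins. The 50% overlap is the canonical
   constant-overlap-add configuration for a Hann window.
3. **Mean-spectrum features** — the per-bin mean of the magnitude across
   frames ("mean frequency components"), one 129-vector per segment, with
   the DC bin zeroed. The alternative reading of a single spectral-centroid
   scalar could not feed a 9-class network meaningfully and was rejected.

The magnitude mean is homogeneous of degree one, so feature vectors scale
linearly with signal amplitude — this is what lets the network read load
from the spectrum.

## The estimator

`torque_net()` fits the two-hidden-layer ReLU network (defaults 256 and 64
units) with either a softmax head over the distinct label values (sparse
categorical cross-entropy) or a single linear output (mean squared error),
trained with Adam (learning rate $10^{-3}$) for 100 epochs on a seeded
7:1:2 train/validation/test split. No early stopping is used; the history
is retained for overfitting inspection. All randomness derives from one
seed, so a fit is reproducible on a single thread.

Two numerical choices deserve mention:

* **Normalization.** Features are centred per bin but scaled by a single
  pooled training-set standard deviation. Per-bin whitening would inflate
  the ~120 signal-free bins to the same variance as the informative ones,
  and the network then overfits noise (held-out accuracy drops from 1.00
  to 0.72 on the default dataset). The study states that normalization was
  applied without giving a method; preserving relative bin magnitudes is
  the package's choice.
* **Hidden widths.** The published parameter count (75,017) does not
  determine the layer widths given the ambiguous input dimension, so the
  defaults (129-256-64-K) are the package's own; `model_footprint()`
  reports the exact parameter count (50,378 for K = 10) and a FLOP
  estimate (2 per weight, 1 per bias, 1 per ReLU unit, 3 per softmax
  class), which is roughly twice the parameter count.

Continuous torque from the classifier uses probability-weighted decoding,
$\hat\tau = \sum_k p_k \tau_k$, which is bounded by the class-value range.
`evaluate()` reports accuracy, the confusion matrix, RMSE of the decoded or
regressed value, and the Pearson correlation. `fine_tune()` continues Adam
from the fitted weights on a small user-specific calibration set without
touching the architecture or scaling, matching the deployment story of
adapting to a new wearer.

## Streaming inference

`stream_state()` + `run_stream()` form a headless stand-in for the original
GUI: a circular buffer of 3000 samples (~3 s at 1000 Hz), one inference per
3 s of ingested samples (cadence counted in samples, not wall-clock, so
runs are reproducible), and an alert exactly when the decoded torque
exceeds the 30 Nm safety threshold — no hysteresis. Stream windows are
cadence-aligned rather than event-aligned, since a live system cannot see
event onsets; this is why the deployed classifier must include a rest
class. Streaming predictions on aligned windows are identical to the batch
pipeline, which the tests assert directly.

## Bench characterization

`tensile_modulus()` uses the least-squares slope within 20% of the maximum
strain (identical to the point ratio on an exact line but robust to
noise); `toughness()` is the trapezoidal area under the engineering
stress–strain curve (MPa × strain = MJ m$^{-3}$ = J cm$^{-3}$);
`power_density()` is $V^2/(AR)$; `estimate_sensitivity()` fits peak voltage
against peak force with an intercept (the study does not state a
through-origin fit) and returns the slope with its standard error.

## Auxetic patch: geometry, FEM, inverse design

The sensor patch is a rotating-square kirigami: squares of edge $a$
connected by ligaments of width $b$, pre-opened to an inter-square angle
$\theta$ (180° = closed sheet). On an $R \times C$ cell grid, each internal
cell edge carries a straight slit of length $a - b$ leaving the ligament at
alternating ends — the parity pattern that lets alternate squares
counter-rotate. Zero-width slits are realized by node duplication on a
structured tensor grid whose lines include the exact ligament offsets $b$
and $a-b$ inside every cell, so the joint width is exact rather than
snapped to the mesh pitch. Pre-opening applies the rigid rotating-square
kinematic map (rotation $\pm(180^\circ-\theta)/2$, lattice factor
$\cos\varphi + \sin\varphi$).

The solver is plane-stress linear elasticity on 6-node quadratic triangles
(3-point Gauss rule, sparse Cholesky through `Matrix`), with the bottom
edge fixed axially (one node pinned laterally), the top edge displaced
along the length, and lateral edges free — clamp conditions matching a
tensile stage. Default material: $E = 0.63$ MPa, $\nu = 0.20$, thickness
0.30 mm.

**Finite rotations.** A single linear solve at the full 10 mm stretch
(~19% strain, square rotations approaching 15°) linearly extrapolates the
rotation mechanism and overshoots the lateral expansion
($\mu \approx -1.14$ at the optimum). `solve_stretch()` therefore applies
the stretch in 0.5 mm increments, updating the geometry between steps;
each step is a linear solve. Under this protocol $\mu$ genuinely depends
on the stretch, falling from about $-1.08$ at 2 mm to $-0.75$ at 10 mm at
the optimized parameters, and the design is summarized by `mu_sweep`, the
mean secant ratio over the 2–10 mm displacement sweep — the same sweep the
original optimization was characterized with. Incremental stresses are
accumulated component-wise (rotation of stress axes within a step is
neglected), and the maximum von Mises stress is taken over element Gauss
points.

**Stress protocol.** The re-entrant slit tips are singular in linear
elasticity, so a raw stress maximum is mesh-dependent. The package
evaluates $\sigma_{\max}$ on a fixed documented mesh density — element
edges at most $b/4$ at the joints, quadratic elements, sharp corners (no
fillet, since rounding would alter the auxetic response) — and reports the
protocol with the value. At the optimized parameters a refinement step
changes the sweep ratio by less than 0.01 (asserted in the tests at
reduced scale).

**Inverse design.** `optimize_design()` minimizes the piecewise objective

$$f(\mu, \sigma) = \begin{cases}\mu + 1 & \sigma \le 0.5\ \text{MPa}\\
\mu + 11 & \sigma > 0.5\ \text{MPa}\end{cases}$$

over $(a, b, \theta)$ with an in-package Nelder–Mead simplex: the
judgement condition stops the search when the objective spread across the
simplex falls below $\delta = 0.01$ (40-iteration budget), iterates are
clamped to the box bounds ($a \in [5, 15]$ mm, $b \in [1, 5]$ mm,
$\theta \in [150^\circ, 179^\circ]$ by default — the published ranges are
in an unavailable supplement), and every evaluation is recorded in a
trace. Infeasible geometries receive a large finite penalty. A 5×5 cell
grid is the default patch extent (the cell count is not stated in the
source study).

```{r}
patch <- build_patch(auxetic_params(10, 3, 175), grid = c(5, 5))
resp <- solve_stretch(patch, displacement = 10, step = 0.5)
resp$mu_sweep   # about -0.91 at the printed optimum
resp$sigma_max  # about 0.38 MPa, inside the 0.5 MPa constraint
```

`export_cut_path()` writes the closed-configuration slit skeleton as an
SVG in millimetre units for the laser cutter.

## Problem sizes and determinism

The default study conditions are used throughout: 9 conditions × 100
segments plus 100 rest segments (1000 × 3000 samples), 129-dimensional
features, 100 training epochs; the acceptance analysis solves the full
5×5-cell patch (about 20,700 nodes, 9,800 quadratic triangles) in twenty
0.5 mm increments. Unit tests exercise the same code paths on smaller
grids, coarser meshes and fewer epochs. Every stochastic step takes an
explicit seed; FEM, features and decoding are deterministic.

## Known limitations

* The generator is calibrated to printed scalar outputs; its angle
  encoding and noise magnitudes are modelling choices, so synthetic
  accuracies bound the pipeline, not the device.
* The FEM is two-dimensional plane stress with a linear elastic material;
  finite rotations are handled by geometric stepping but strains within a
  step are small-strain, stress accumulation ignores within-step axis
  rotation, and self-contact of closing slits is not modelled (relevant
  only near $\theta = 180^\circ$ or in compression).
* $\sigma_{\max}$ is protocol-defined (fixed mesh density at a stress
  singularity), suitable for comparing designs under the same protocol,
  not as a pointwise material stress.
* The streaming harness processes recorded or synthetic traces; no
  hardware ingestion or timing guarantees are provided.
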