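---
title: "Methods: sEMG-driven elbow force estimation and mirror-assist simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sEMG-driven elbow force estimation and mirror-assist simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In bilateral rehabilitation of post-stroke hemiplegia, the non-paretic arm
guides the paretic one: both limbs press isometrically on force sensors, and
a robot assists the affected side to track the healthy side's force. Two
quantities must be produced in real time: (i) an estimate of the *active*
force the affected limb itself generates — measured force alone cannot
separate the patient's contribution from the robot's — and (ii) the motor
command that closes the force-tracking loop. `semgforce` implements both: an
sEMG-to-force estimator (conditioning → sliding-window time-domain features
→ a small backpropagation network) and a closed-loop simulation of the
assist on a series-elastic elbow actuator, plus a seeded synthetic
generator so the complete three-phase protocol (offline learning, online
validation, real-time assist) runs without hardware or subjects.

# The synthetic world

Surface EMG at moderate contraction levels is well described as
amplitude-modulated, band-limited Gaussian noise. The generator takes that
model literally:

$$ s(t) = \big[A_\mathrm{rest} + (A_\mathrm{mvc}-A_\mathrm{rest})\,
   a_\mathrm{ch}(t)\big]\, w(t) + A_\mathrm{mains}\sin(2\pi\,50\,t), $$

where $a(t)\in[0,1]$ is the activation profile (default: one trapezoidal
effort — 40 % linear rise, 20 % hold, 40 % fall), $w(t)$ is zero-mean,
unit-RMS Gaussian noise band-limited to 20–450 Hz by FFT masking, and the
biceps uses $a_\mathrm{ch}=a$ while the triceps uses
$a_\mathrm{ch}=0.15\,a$ (elbow flexion against a sensor is
biceps-dominated; the antagonist shows only weak co-contraction). Force is
a mild power law with sensor noise,
$F(t) = F_\mathrm{max}\,a(t)^{1.2} + \varepsilon(t)$, clamped at zero.

Parameter defaults and their reasons:

| parameter | default | unit | rationale |
|---|---|---|---|
| `fs` | 1000 | Hz | acquisition rate of the emulated device |
| `A_rest`, `A_mvc` | 0.2, 0.6 | mV | resting vs maximal envelope of biceps sEMG in this task |
| `emg_band` | 20–450 | Hz | inside the 10–500 Hz analysis band; typical surface-EMG energy |
| `cocontraction` | 0.15 | — | weak antagonist activity during flexion |
| `F_max` | 30 | N | a comfortable maximal isometric fingertip force |
| `force_noise_sd` | 0.5 | N | thin-film force-sensor noise scale |
| `mains_amp` | 0.05 | mV | small residual power-line pickup, so the notch stage is exercised end to end |
| `nonlinearity_p` | 1.2 | — | mildly supralinear EMG-to-force map, so the estimator's nonlinear capacity matters |
| `duration_s` | 10 | s | one rest–max–rest effort |

The 0.2–0.6 mV range is interpreted as *envelope RMS*; whether it denotes
RMS, peak, or envelope amplitude in the emulated acquisition is not
determinable, and nothing downstream depends on the choice because MVC
normalization removes the absolute scale. Per-trial seeds are
`master seed + trial index`, so any trial is regenerable in isolation, and
within a trial draws happen in a fixed order (biceps, triceps, force).

What the generator does **not** emulate: motor-unit recruitment structure,
fatigue-induced spectral compression, electrode lift/shift artifacts,
cross-talk between channels, or the human's reaction to visual feedback. A
green estimation test therefore establishes that the pipeline recovers
force from signals *obeying the stated statistical model* at realistic
noise levels — not that it would survive every artifact of a clinical
recording.

# Conditioning chain

Stages, in order: mean subtraction (DC offset), a 50 Hz biquad notch, a
4th-order (prototype) Butterworth band-pass at 10–500 Hz, full-wave
rectification, and MVC normalization. Numerical choices:

* **The 500 Hz edge.** At 1000 Hz sampling the printed upper cut equals
  Nyquist and no digital band-pass can realize it; the edge is clamped to
  $0.99\times f_s/2$ = 495 Hz and a message logs the clamp. This is the
  closest realizable design to the nominal specification.
* **Notch Q.** No quality factor is specified for the notch; Q = 30
  (≈1.7 Hz bandwidth) rejects 50 Hz by far more than the 20 dB contract
  while passing 100 Hz within 10 %. The contract, not the coefficients, is
  what the tests pin down.
* **Causality.** Filters run forward-only by default (the estimator is a
  real-time component); a `zero_phase` flag runs forward–backward for
  offline analysis. All stages preserve sample count.
* **Design implementation.** No filter-design library ships in the target
  R environment, so the classical design path (analog Butterworth
  prototype, low-pass→band-pass transform, bilinear transform with
  pre-warping, second-order sections) is implemented in the package and
  verified against an independently coded magnitude-response oracle in the
  tests.
* **Which signal feeds the features.** MAV and RMS are invariant to
  rectification; DASDV and WL are not, and clamping a rectified signal to
  [0, 1] would destroy the waveform they measure. The default feature
  input is therefore the *signed* band-passed signal divided by MVC
  (`scaled`), with the rectified clamped envelope (`normalized`) available
  behind a switch. The MVC reference itself is the maximum of the
  0.2 s-smoothed rectified conditioned signal from the first (maximal
  effort) trial, mirroring a single MVC test before a session.

# Features and windows

Per 0.2 s window and channel: MAV $\frac1n\sum|x_i|$, RMS
$\sqrt{\frac1n\sum x_i^2}$, DASDV
$\sqrt{\frac1{n-1}\sum(x_{i+1}-x_i)^2}$, WL $\sum|x_{i+1}-x_i|$ — eight
inputs in the frozen ordering biceps[MAV, RMS, DASDV, WL],
triceps[MAV, RMS, DASDV, WL], serialized with the model so trained models
stay portable. The step defaults to 0.1 s (half overlap): the real-time
budget bounds per-window computation below one window, implying update
intervals of that order; the step is configurable because overlap is an
open protocol choice. Window timestamps are window-end (causal semantics),
and each window's force label is the window-mean force (no pairing rule is
otherwise defined; the mean is the minimum-variance choice under
within-window stationarity).

# The estimator

Topology follows $N_\mathrm{hidden} = \lceil \log_2 N_\mathrm{input}
\rceil$: eight inputs give three hidden units (the ceiling extends the rule
to non-powers of two). Hidden units compute the symmetric sigmoid
$h_j = 2/(1+e^{-2z_j})-1 = \tanh(z_j)$ of $z_j = \sum_i w_{ji}x_i - t_j$;
the output neuron is linear, and its value is anti-normalized from the
min–max target scale back to newtons. The symmetric form is used because
the complete input-to-output expression is only given in that expanded
algebra; a logistic hidden layer differs only by an affine reparameterization
the linear output layer absorbs.

Training is plain batch gradient descent on the MSE of normalized targets,
with min–max feature normalization fitted on the training split, weight
initialization U(−0.5, 0.5), early stopping on a validation share, and
restoration of the best-validation weights. Defaults: learning rate 0.2,
at most 5000 epochs, patience 200. These were set by a convergence
criterion, not by chasing any benchmark: at lr 0.05 / 2000 epochs training
always terminated at the epoch cap while still underfitting a linear
least-squares baseline on the same split — an unconverged fit, since a
tanh network with a linear output strictly contains linear maps. At the
chosen defaults training either early-stops or matches/exceeds that
baseline. The split defaults to 70/15/15 (train/validation/test),
stratified by trial so every trial contributes held-out windows; a literal
70/30 two-way split is available, in which case the validation share
doubles as the held-out set. Everything is deterministic given the seed.

The online validation phase is a safety gate, not a benchmark: a fresh
trial is streamed through the full pipeline and the model is accepted only
if its per-trial squared correlation reaches the threshold (default 0.90);
rejected models are to be retrained.

# The assist loop

Under the isometric constraint the output link (forearm cuff) is frozen at
the joint angle $\theta_j$, so the plant reduces to the motor-driven
mainframe winding the joint spring (stiffness $K$ = 118.49 N·m/rad, the
high-stiffness mode — the only mode modeled):

$$ J_1\ddot\theta_1 + B_1\dot\theta_1 + K(\theta_1-\theta_j)/\gamma
   = k_{m1} i, \qquad
   F_\mathrm{aff} = \max\!\Big(0,\;
   \frac{K(\theta_1-\theta_j) + \tau_\mathrm{human}
         - mgl\cos\theta_j}{\ell}\Big). $$

The gravity moment of forearm + device appears in the sensor balance and
is cancelled by a feed-forward current $mgl\cos\theta_j/(\gamma k_{m1})$;
this is the reading under which a zero reference with zero human torque is
an exact equilibrium (zero measured force, feed-forward current only). The
PID controller acts on $F_\mathrm{err} = F_\mathrm{ref} - F_\mathrm{aff}$
with a trapezoid integral (no area until a second sample exists), a
backward-difference derivative, output clamping to $\pm i_\mathrm{max}$,
and conditional anti-windup (integration frozen while the output is
saturated in the error's direction).

Numeric plant defaults ($J_1 = 5\times10^{-4}$ kg·m², $B_1 = 0.2$,
$\gamma = 10$, $k_{m1} = 0.1$ N·m/A, $\ell = 0.25$ m, $mgl = 1.5$ N·m,
$i_\mathrm{max} = 6$ A) are design values of this simulation, not measured
device constants, and all are config-exposed. They were chosen jointly so
that (i) actuator authority $\gamma k_{m1} i_\mathrm{max} = 6$ N·m covers a
10 N tracking task plus the gravity preload with headroom, and (ii) the
reflected-spring resonance ($\omega_n = \sqrt{K/(\gamma J_1)} \approx
154$ rad/s) is well damped ($\zeta \approx 1.3$), as a geared drive with
friction is in practice — an underdamped setting would make the
deliberately simple low-gain PID (kp = 0.5 A/N, ki = 2 A/(N·s), kd = 0,
mirroring a safety-first clinical tuning) marginally unstable. Integration
is semi-implicit Euler at 1 ms; the tests hold its trajectory within 1 %
RMS of an RK4 reference under recorded currents and of a 10× finer-step
rerun of the whole closed loop. With a 30 N-peak reference the current
saturates and tracking degrades gracefully — the expected behavior of a
soft-tuned assist, not a fault.

In the simulated assist phase the affected limb is emulated as an
`impairment`-scaled healthy effort (default 0.3: envelope excursion and
force both scaled), contributing $\tau_\mathrm{human} = \ell\,
F_\mathrm{affected,true}$, while its sEMG is streamed through the validated
estimator to produce the participation overlay. The overlay is computed
regardless of assist authority — assessment and assist are deliberately
decoupled.

# Evaluation

Per trial: RMSE $\sqrt{\frac1N\sum(F_E-F_A)^2}$ and the squared Pearson
correlation $R^2$ between estimated and measured force (reported as a
fraction or as a percentage, $100\,R^2$), plus mean/min/max aggregation
across trials and the bilateral mean absolute error
$\overline{|F_\mathrm{health}-F_\mathrm{affected}|}$ for condition
comparisons.

# Known limitations

* The generator's stationarity-within-window assumption makes window
  features nearly sufficient statistics; real sEMG is less cooperative.
* Only the high-stiffness actuator mode is modeled; compliant
  (variable-stiffness) control, cable elasticity, and contact dynamics are
  out of scope.
* The estimator is subject- and session-specific by construction (MVC and
  feature normalization are fitted per session); no cross-subject transfer
  is attempted.
* "Real time" is replay-mode simulation on the recorded clock; no
  scheduling guarantees are made, though per-window feature cost is tested
  to sit far below the window length.
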