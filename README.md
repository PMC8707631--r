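# semgforce

Estimation of isometric elbow-joint force from two-channel surface EMG
(biceps, triceps) and closed-loop simulation of a mirror bilateral assist
on a series-elastic elbow actuator.

## Who this is for

In bilateral rehabilitation after stroke, the healthy arm's isometric force
is the reference the robot helps the paretic arm track. Because the robot
supplies part of the measured force, the patient's *active* contribution
must be estimated independently — from the muscle's electrical activity.
This package is for rehabilitation-engineering and biosignal work that
needs a complete, testable implementation of that pipeline, with a seeded
synthetic sEMG/force generator so every stage runs and can be validated
without hardware or subjects.

## What it computes

1. **Conditioning** — DC removal, 50 Hz notch (Q = 30), 4th-order
   Butterworth band-pass 10–500 Hz (upper edge clamped to 0.99 × Nyquist =
   495 Hz at fs = 1000 Hz), full-wave rectification, MVC normalization to
   [0, 1].
2. **Features** — per 0.2 s sliding window (0.1 s step) and channel:

   MAV = (1/n) Σ|xᵢ|, RMS = √((1/n) Σxᵢ²),
   DASDV = √((1/(n−1)) Σ(xᵢ₊₁−xᵢ)²), WL = Σ|xᵢ₊₁−xᵢ|

   giving the 8-dimensional input (two muscles × four features).
3. **Estimator** — an 8–3–1 backpropagation network
   (N_hidden = ⌈log₂ N_input⌉): hidden units hⱼ = tanh(Σᵢ wⱼᵢxᵢ − tⱼ),
   linear output anti-normalized to newtons; batch gradient descent with
   early stopping, 70/15/15 trial-stratified split.
4. **Assist loop** — PID force tracking (trapezoid integral,
   anti-windup, current saturation) of a healthy-side reference on a
   variable-stiffness elbow joint (K = 118.49 N·m/rad, isometric
   constraint), integrated by semi-implicit Euler at 1 ms.
5. **Evaluation** — per-trial RMSE = √((1/N) Σ(F_E−F_A)²) and squared
   Pearson correlation R², with mean/min/max aggregation.

## Worked example

```r
library(semgforce)

cfg <- run_config(out_dir = "run", seed = 42)   # 5 trials, all defaults
res <- offline_phase(cfg)                       # train + persist model.json
res$metrics$per_trial
#>   trial  n     rmse        r2
#> 1     1 15 2.086837 0.9690465
#> 2     2 15 1.553299 0.9698439
#> 3     3 15 2.175255 0.9637981
#> 4     4 15 2.435557 0.9337017
#> 5     5 15 1.909113 0.9590361

val <- online_phase(cfg)                        # fresh trial through the gate
#> online validation: accept=TRUE  R2=0.9622  RMSE=2.02 N

out <- assist_phase(cfg)                        # simulated mirror assist
out$sim
#> <assist_sim> 10000 steps (10.00 s); final-20% |F_err|: mean 0.747 N, max 3.2 N
#>   current: max |i| = 6 A (limit 6 A)
r_squared(out$overlay$est_active_n, out$overlay$true_active_n)
#> [1] 0.864
```

Reading the numbers: each training trial's held-out windows are estimated
with R² ≈ 0.93–0.97 and RMSE ≈ 1.6–2.4 N on a 0–30 N force range; the
online gate accepts the model (R² = 0.96 ≥ 0.90); in the assist phase the
low-gain, saturation-limited controller tracks a 30 N-peak effort with a
sub-newton mean error once settled, and the sEMG overlay recovers the
impaired limb's active force (R² = 0.86 against ground truth — the
affected side's envelope excursion is 0.3× the healthy one, so its
estimation problem is genuinely harder).

The same protocol is scriptable from the shell:

```sh
Rscript -e 'semgforce::force_cli()' simulate-data --out data/ --seed 42 --trials 5
Rscript -e 'semgforce::force_cli()' train      --data data/ --out run/ --seed 42
Rscript -e 'semgforce::force_cli()' validate   --out run/ --seed 42
Rscript -e 'semgforce::force_cli()' assist-sim --out run/ --seed 42
```

## Layout

- `R/` — generator (`synth.R`), conditioning (`preprocess.R`), features,
  estimator (`bpnn.R`), assist simulation (`control.R`), metrics,
  three-phase pipeline + CLI.
- `src/` — small Rcpp kernels (IIR second-order sections, moving average).
- `vignettes/semgforce-methods.Rmd` — the model, assumptions, parameter
  rationale, and known limitations.
- `tests/testthat/` — unit, property, and acceptance tests (independent
  oracles in `helper-oracles.R`).
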