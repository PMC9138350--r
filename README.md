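# hillexo

EMG-driven musculoskeletal simulation of a single-joint (knee)
exoskeleton, with analytical adjoint gradients for calibrating the
per-muscle parameters of a Hill-type model.

## Who this is for

Researchers in computational biomechanics and assistive robotics who
need a *differentiable* forward model from surface EMG to joint motion:
to predict the wearer's intended trajectory, to estimate the
unmeasurable human muscle torque, or to calibrate subject-specific
muscle parameters from a motion recording instead of cadaver tables.

## The model

Surface EMG is band-pass filtered (20–450 Hz), rectified, low-pass
filtered (8 Hz) and MVC-normalized into an envelope e(t); neural
activation follows the recursion
`u(t) = α e(t−d) − β₁u(t−1) − β₂u(t−2)` and muscle activation the
nonlinearity `a = (e^{Au} − 1)/(e^A − 1)`, A ∈ (−3, 0).  Each of the
eight knee muscle–tendon units (RF; three vastus heads on the VM
channel; semimembranosus + semitendinosus on ST; two biceps femoris
heads on BF) is a Hill-type model — Gaussian active force–length
`f_l(l) = exp(−(l−1)²/γ)`, exponential passive element, exponential-toe
/ linear tendon, force–velocity
`v = (0.25 + 0.75a) V_max (f_ce − a f_l)/b` — and the joint obeys

    J θ̈ + B θ̇ + K(θ − θr) + τg sin(θ − θr) = τe + τh,
    τh = Σⱼ rⱼ F_mt⁽ʲ⁾

integrated by an adaptive Runge–Kutta–Fehlberg 4(5) scheme.

Calibration minimizes the velocity-trajectory loss
`ℓ = ∫ ‖ż − θ̇_meas‖² dt` over ω = {L\*, F_max, l_slack} per muscle
(24 parameters).  The gradient is computed by the continuous adjoint
method — backward integration of
`λ̇ = −(∂f/∂x)ᵀ λ` with measurement jumps, then
`∂ℓ/∂ω = ∫ λᵀ ∂f/∂ω dt` — so every iteration costs exactly **2**
loss-grade evaluations (one forward, one backward solve) regardless of
the parameter count, versus 25 for two-point finite differences.
Nelder–Mead (plain and adaptive) and finite-difference baselines with
exact evaluation accounting are included, as are inertial-parameter
identification (K static, J/B dynamic with Fourier smoothing), a
saturated discrete PID assist controller, and a synthetic-experiment
generator so everything runs without recorded data.

## Worked example

Calibrate the eight-muscle model against a synthetic 45°-class
flexion–extension recording, starting from length parameters perturbed
by ±3 cm:

```r
library(hillexo)

fix  <- make_experiment(t_span = c(0, 2), rate_hz = 0.5,
                        encoder_noise_sd_deg = 0, seed = 1)
prob <- fit_problem(fix$trajectory, fix$activations, fix$true_muscles,
                    fix$exo, state0 = fix$state0,
                    rtol = 1e-6, atol = 1e-8)

set.seed(3)
start <- omega_get(fix$true_muscles)
len   <- sort(c(seq(1, 24, 3), seq(3, 24, 3)))
start[len] <- pmax(start[len] + runif(16, -0.03, 0.03), 0.005)

fit <- fit_parameters(hillexo:::fit_problem_restart(prob, start),
                      max_iter = 80, lr = 0.02)
print(fit)
```

```
<experiment_fixture> 8 muscles, 2.0 s at 0.5 Hz movement, seed 1
  theta range: [82.3, 114.1] deg
<fit_result> 80 iterations (max_iter), loss 9.187 -> 0.01506,
             2 loss-grade evaluations/iteration
final velocity RMS error: 0.0851 rad/s (signal RMS 0.568 rad/s)
fitted vastus lateralis: L* = 10.30 cm (true 9.60), l_slack = 13.60 cm (true 12.90)
```

The loss falls by ~600× in 80 iterations at 2 evaluations per
iteration; the fitted trajectory tracks the reference to ~15% velocity
RMS, and the fitted lengths move toward (not exactly onto) the truth —
with a single-DOF recording the 24 parameters are only partially
identifiable, which is precisely why the across-start *spread* of the
analytic method versus gradient-free baselines is the interesting
comparison (see the methods vignette).

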