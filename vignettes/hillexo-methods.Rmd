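---
title: "EMG-driven musculoskeletal simulation with adjoint-based calibration"
author: "hillexo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMG-driven musculoskeletal simulation with adjoint-based calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A single-joint knee exoskeleton should assist, not replace, the wearer's
own muscle torque.  Doing that well requires a forward model that maps
surface EMG to joint motion: EMG to muscle activation, activation to
muscle-tendon force through a Hill-type model, force to joint angular
acceleration through the rigid-body motion equation of the
leg-plus-exoskeleton.  The model has per-subject parameters — for each
muscle an optimal fiber length $L^\*$, a maximum isometric force
$F_{max}$ and a tendon slack length $l_{slack}$ — that must be calibrated
from recorded trajectories.  `hillexo` implements this pipeline and, at
its core, the *continuous adjoint method* that turns the calibration into
gradient-based optimization with exactly one forward and one backward ODE
solve per iteration, independent of the number of parameters (24 for the
eight-muscle knee model).

## Signal chain

Raw EMG (1 kHz) is band-pass filtered (Butterworth, 20–450 Hz, 4-pole),
full-wave rectified, low-pass filtered (2nd order, 8 Hz) and normalized
by the muscle's maximum voluntary contraction, giving an envelope
$e(t) \in [0,1]$.  Both filters are applied forward–backward (zero
phase): the electromechanical lag is modeled explicitly by the delay $d$
below, so the filters should not add phase delay of their own.

Neural activation follows the damped second-order recursion
$$u(t) = \alpha\, e(t-d) - \beta_1 u(t-1) - \beta_2 u(t-2),$$
parameterized by its poles $c_1, c_2$ ($\beta_1 = -(c_1+c_2)$,
$\beta_2 = c_1 c_2$, $|c_i| < 1$ for stability).  We enforce unit
steady-state gain, $\alpha = 1 + \beta_1 + \beta_2$, so that a sustained
envelope level maps to the same activation level; without this constraint
the recursion rescales the envelope arbitrarily.  (Parts of the
activation-dynamics literature print the constraint with the opposite
sign convention on the $\beta$s; for the recursion exactly as written
above, unit DC gain requires $\alpha = 1+\beta_1+\beta_2$.)  The default
delay is $d = 40$ samples (40 ms at 1 kHz), a typical electromechanical
delay; it is configurable because no canonical value exists.

Muscle activation applies the motor-unit nonlinearity
$a(u) = (e^{Au}-1)/(e^{A}-1)$ with shape factor $A \in (-3, 0)$
(default $-1.5$): a strictly increasing bijection of $[0,1]$ with
$a(u) \ge u$.

## Muscle-tendon model

Each of the eight knee muscle-tendon units (rectus femoris; the three
vastus heads sharing the VM electrode; semimembranosus and semitendinosus
sharing the ST electrode; the two biceps femoris heads) is a Hill-type
model with contractile (CE), parallel-elastic (PE) and series-elastic
(tendon, SE) elements:

* active force–length: $f_l(l) = \exp(-(l-1)^2/\gamma)$, $l = L/L^\*$;
* passive force–length: $f_{pe}(l) = (e^{k(l-1)/\varepsilon_{pe}}-1)/(e^k-1)$,
  kept in its raw exponential form (slightly negative below optimal
  length) so the curve is smooth where fibers operate;
* tendon force–strain: exponential toe region up to
  $\varepsilon_{toe} = 0.02$, linear above, zero for negative strain
  (slack tendon).  Strain is $(l_t - l_{slack})/l_{slack}$, i.e. zero at
  slack length — the only definition under which zero strain gives zero
  force.  The linear slope $k_{lin}$ is set so the curve is $C^1$ at the
  toe boundary, which the adaptive integrator and the adjoint both
  appreciate;
* force–velocity, inverted to give the fiber velocity
  $v = (0.25 + 0.75a)\, V_{max} (f_{ce} - a f_l(l)) / b$.

Series equilibrium closes the algebra: the tendon length is
$l_t = l_{mt} - L^\* l \cos\alpha_p$ (pennation $\alpha_p$), the tendon
curve gives $f_{se}$, and $f_{ce} = f_{se}/\cos\alpha_p - f_{pe}(l)$,
clamped at zero because contractile elements cannot push.  The
muscle–tendon force transmitted to the joint is $F_{mt} = f_{se} F_{max}$.

Two closures are deliberate modeling choices rather than published
values.  First, the joint torque is $\tau_h = \sum_j r_j F_{mt}^{(j)}$
with a constant signed moment arm per muscle (+0.04 m for the extensor
group, −0.035 m for the flexors): summing forces directly into a torque
is not dimensionally possible, and a constant moment arm is the simplest
closure consistent with virtual work.  Second, the muscle–tendon path
length is affine, $l_{mt}(\theta) = l_{mt0} - r(\theta - \theta_r)$, with
$l_{mt0} = l_{slack} + L^\*\cos\alpha_p$ by default, which makes the rest
pose (optimal fiber length, just-slack tendon) an exact passive
equilibrium.  The curve-shape constants
($\gamma = 0.45$, $k_{pe} = 5$, $\varepsilon_{pe} = 0.6$,
$f_{toe} = 0.33$, $k_{toe} = 3$, $\varepsilon_{toe} = 0.02$,
$V_{max} = 10\,L^\*/s$, $b = 0.25$) are standard-magnitude fixture
values, configurable per muscle.

## Joint dynamics and integration

The exoskeleton joint obeys
$$J\ddot\theta + B\dot\theta + K(\theta-\theta_r)
  + \tau_g \sin(\theta-\theta_r) = \tau_e + \tau_h,$$
with $\tau_g = m g r_{cm}$, rest angle $\theta_r = \pi/2$, and the
identified constants $J = 0.07$ kg m², $B = 1.5$, $K = 1.27$,
$m = 5.5$ kg, $r_{cm} = 0.16$ m bundled as defaults.  The coupled state
(per-muscle normalized fiber lengths, $\theta$, $\dot\theta$) is
integrated with an adaptive Runge–Kutta–Fehlberg 4(5) scheme implemented
in C++ with cubic-Hermite dense output on accepted steps.  Defaults
`rtol = 1e-6`, `atol = 1e-8`; the method is named by the source material
but tolerances are ours.  Fiber states are initialized at the passive
isometric equilibrium (or a caller-fixed state) to avoid startup
transients.  The integrator is cross-checked in the test suite against
`deSolve`'s independent `rk45f` implementation running on a pure-R
composition of the muscle-module operations.

The contraction dynamics are moderately stiff (the series-elastic
coupling gives local rates of several hundred per second), so accepted
steps are stability-limited to a few milliseconds; a 2-second
eight-muscle solve costs a few tens of milliseconds.

## Inertial identification

$K$ comes from static holds (120° to 0° in 15° steps): with
$\dot\theta = \ddot\theta = 0$, the motion equation is linear in $K$ and
the estimate is the closed-form regression-through-origin slope.  $J$ and
$B$ come from dynamic sweeps (0.01–0.5 Hz): after subtracting the known
gravity and stiffness terms, the residual is linear in $(J, B)$ and is
solved by least squares (a Levenberg–Marquardt path via `minpack.lm` is
retained for parity with nonlinear workflows; the optimum is identical
because the problem is linear).  Encoder noise is handled by fitting a
truncated Fourier series to the angle record and differentiating the
series analytically; 8 harmonics by default, base period taken from the
commanded movement.

## The adjoint gradient

Calibration minimizes the trajectory loss
$\ell = \int \lVert \dot z(t) - \dot\theta_{meas}(t)\rVert^2 dt$
(a maximum-a-posteriori estimate with a flat torque prior), evaluated by
trapezoidal quadrature on the measurement grid.  The gradient with
respect to all $3m$ muscle parameters is computed by the continuous
adjoint method: the adjoint state $\lambda(t)$ spans the full ODE state
(fiber lengths included — the fiber dynamics couple into the torque), is
integrated backward from $\lambda(T) = 0$ with
$\dot\lambda = -(\partial f/\partial x)^\top \lambda$, and receives a
jump $2 w_i (\dot z_i - \dot\theta_i)$ in its angular-velocity component
at each measurement time, $w_i$ being the trapezoid weight.  Treating
the running cost as per-sample impulses makes the adjoint differentiate
*exactly* the discrete loss the forward pass computes, which is what
allows finite-difference agreement at the $10^{-3}$ relative level.  The
gradient accumulates $\lambda^\top \partial f/\partial \omega$ by
quadrature along the backward solve.  All Jacobians are analytic
(hand-derived from the curve formulas) and evaluated on the cached dense
forward solution rather than re-integrating the state backward, which
would be unstable against the stiff fiber equilibrium.

One gradient therefore costs one forward and one backward solve — 2
loss-grade evaluations per iteration, against $n+1 = 25$ for two-point
finite differences on the 24-parameter problem.

Parameter updates run in log-space (positivity for free, one learning
rate across meters and newtons) with Adam (default `lr = 1e-2`,
$\beta = (0.9, 0.999)$, optional per-iteration decay) or plain gradient
descent.  The initial ODE state is part of the problem and held fixed
across candidate parameters, so the loss depends on $\omega$ only
through the dynamics and the adjoint needs no initial-condition term.

Numerical notes: where the tendon goes slack or the contractile force
clamps at zero the dynamics are continuous but have kinked derivatives;
the loss remains differentiable (the kink set has measure zero in time)
and both the adjoint and finite differences converge, but finite
differences converge slowly near regime boundaries.  The gradient-oracle
tests therefore use a co-contracted fixture in which every tendon stays
taut — it isolates the property being tested (adjoint = true gradient)
from fixture roughness.  The finite-difference oracle itself takes the
median of central differences over three relative steps
($3\times10^{-4}$, $10^{-4}$, $3\times10^{-5}$) at solver tolerances of
$10^{-11}$: single-step quotients are occasionally corrupted either by
adaptive-step noise (small steps, near-zero-gradient components) or by
truncation near slack/taut boundaries (large steps), and the median
rejects the corrupted value without biasing smooth components.

## Baselines and the benchmark harness

The comparison methods are the standard Nelder–Mead simplex and its
dimension-adaptive variant (hand-implemented so that per-simplex-update
evaluation counts are exact), and the two-point forward-difference
gradient plugged into the same Adam loop.  The harness perturbs the true
lengths ($L^\*$ and $l_{slack}$) of every muscle with uniform
$\pm 5$ cm noise — 10 shared sets × 24 parameters = 240 perturbed values
— runs every method from the same starts, and reports per-iteration loss
curves, exact evaluations per iteration, and the across-start spread
(max − min) of every fitted parameter.  $F_{max}$ perturbation
($\pm 20\%$ multiplicative) is available but off by default, since the
stated bounds are lengths.

## What the synthetic generator emulates — and what it does not

`make_experiment` produces reciprocal extensor/flexor activation
profiles at a chosen movement frequency (0.01–0.5 Hz) around a
co-contraction baseline, with the flexor drive scaled by 2.4 to balance
the much stronger extensor group; the default amplitude (0.022) was
chosen so the default experiment spans about 45° of knee motion, the
flexion–extension protocol the hardware study used.  Ground-truth
trajectories are exact forward solutions of the bundled
subject-calibrated muscle table; encoder noise defaults to
$\sigma = 0.5°$ and raw EMG is emulated by amplitude-modulating a
band-limited Gaussian carrier (normalized so the chain's
rectify-and-smooth step recovers the designed envelope) at 20 dB SNR.
These noise levels are documented fixture choices, not measured values.

Real surface EMG differs in ways the generator does not model:
motor-unit structure, electrode crosstalk, movement artifact below 20 Hz,
fatigue and activation-dependent spectral shifts.  Passing round-trip
tests therefore show the processing chain is self-consistent, not that it
is robust to every physiological artifact.  Likewise the synthetic
trajectories come from the same model family being fitted, so parameter
recovery on them demonstrates the optimizer and gradient machinery, not
model adequacy for a real limb.

## Problem sizes used in tests

The test suite and the acceptance script run scaled-down experiments
chosen to exercise every claim at comfortable margins: single-muscle
problems over 1–2 s for gradient checks and fitting behavior, the full
eight-muscle model over 2–4 s windows at 100 Hz sampling for the
benchmark and spread analyses (up to 200 optimizer iterations, 10
perturbed starts), and 20 random draws for the gradient-oracle
comparisons.  The identification module runs at its natural full size.
The convergence-spread experiment uses a 4-s amplitude-modulated
reciprocal movement — richer excitation than a single sinusoid — because
parameter identifiability, not optimizer behavior, is the binding
constraint on how fast different starts collapse to the same optimum.

## Known limitations

* Constant moment arms and affine path lengths; no wrapping geometry.
* Constant pennation; no fatigue or history dependence.
* Single joint; the assist torque model is a saturated discrete PID
  (100 Hz, derivative-on-measurement with a 10 Hz filter), not a motor
  model.
* The three calibrated parameters per muscle are only partially
  identifiable from a single-DOF trajectory; different starts converge
  to a low-loss manifold and the across-start spread contracts slowly
  for weakly observed parameters (notably flexor slack lengths: within
  the shared ST channel the two muscles have identical activation and
  moment arm, so only their force sum is well constrained).  Whether the
  spread of a given parameter contracts within a 200-iteration budget
  also depends on the particular perturbed start set — runs that begin
  with a deeply slack tendon see near-zero gradient in that coordinate
  until the rest of the model adjusts.
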