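---
title: "Methods: delayed-feedback control of muscle-actuated standing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delayed-feedback control of muscle-actuated standing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stancesim)
```

## The model

stancesim simulates quiet human standing as a planar (sagittal-plane)
musculoskeletal control problem. Three coupled subsystems are integrated
together with fixed-step RK4:

**Skeleton.** A kinematic tree of rigid segments connected by 1-DoF
revolute joints, over an optional 3-DoF floating base. The equations of
motion are formed in generalized coordinates — the mass matrix is assembled
from point Jacobians each step and `M(q) vdot = f(q, v, tau, F_ext)` is
solved directly — so joint constraints are satisfied exactly and there is
no drift. Reduced fixtures pin the root (foot) segment to the ground
instead of simulating foot contact dynamically.

**Muscles.** Hill-type muscular-tendon actuators: a contractile fiber
(active force-length, force-velocity, passive elastic curve) in series
with a compliant tendon. Excitation-to-activation dynamics are first
order with asymmetric time constants,

$$\dot a = \frac{u(t-\tau_{trans}) - a}{\delta(a, u)},\qquad
\delta = \begin{cases} t_{act}(0.5 + 1.5a) & u > a\\
t_{dact}/(0.5+1.5a) & u \le a \end{cases}$$

with `t_act` = 20 ms and `t_dact` = 40 ms. Muscle paths use constant
signed moment arms, a good approximation over the few degrees of motion of
quiet stance, so the muscular-tendon length is affine in the joint angles.

**Contact.** Compliant normal force `R_y = E h^{3/2} (1 + 1.5 b hdot)`
(clamped at zero, no adhesion) with stiffness `E = 1e8 N m^-1.5` and
dissipation `b = 0.5 s/m`, and a smooth velocity-dependent friction
coefficient built from static/dynamic/viscous terms
(`mu_s = mu_d = 0.9`, `mu_v = 0.6`, transition speed 0.1 m/s). Contact
spheres are treated as points; the sphere radius is folded into the
attachment position. For pinned-base fixtures the heel/toe loads are
recovered from a whole-body momentum balance (the ground wrench must
balance gravity and the rate of change of momentum), which yields the CoP
and the heel/toe force split without simulating the stiff contact ODE.

**Controller.** Each muscle receives a constant feed-forward activation
plus delayed PD feedback on its own muscular-tendon length and velocity,

$$u_i = \mathrm{clamp}\Big(c_i + k_{p,i}\frac{L^{MT}_i(t-\tau_{fb}) -
L^{MT}_{0,i}}{L^{MT}_{0,i}} + k_{d,i}\frac{\dot L^{MT}_i(t-\tau_{fb})}
{V^{max}_i},\; 0, 1\Big)$$

with a 40-ms feedback delay and a 40-ms transmission delay: together with
the activation dynamics the loop carries up to 120 ms of neurological
latency. Normalizing the length error by the objective-posture length and
the velocity by the maximal fiber speed makes both gains dimensionless, so
one `(kp, kd)` pair can be shared by each of nine functional muscle
groups (lumbar/hip/knee/ankle x extensor/flexor, plus biarticular).
Feedback is sampled at a 1-ms control step with zero-order hold; delays
are therefore exact integer sample shifts, and the delay buffers are
pre-filled with the initial sensor values so the first 40 ms run on the
initial-posture signals rather than on an artificial startup transient.
The clamp of `u` to [0, 1] is applied before the transmission delay, since
the activation rate law presumes excitations in that range.

## The design pipeline

The controller has 53 free variables in the full model (35 bilaterally
symmetric feed-forward activations plus 18 group gains). They are designed
in two stages:

1. **Objective posture.** CMA-ES tunes the free coordinates to minimize
   `J_pos = w_static[(CoM_x - BoS_x)^2 + (CoP_x - BoS_x)^2] +
   w_Omega * sum(Omega_n^2)` with `w_static = 10000` and
   `w_Omega = 0.1`: a statically stable posture (CoM projection and
   initial CoP at the base-of-support centre) that can be held with
   minimal joint torque. For a pinned base the static CoP is the CoM
   projection; for a free base it comes from a short (0.2 s) servo-held
   passive settle on the compliant contact, since the static CoP of a
   free-standing posture is otherwise indeterminate.
2. **Feed-forward harvest (grid search).** With both transport delays at
   zero (activation dynamics retained), a shared-gain controller —
   extensors `(P, D)`, flexors scaled by 0.5, biarticular by 0.2 — is
   swept over a `(P, D)` grid (0-2, step 0.1 at full scale). Each trial
   starts at the objective posture with zero activations and runs 60 s;
   if the model stands throughout, the time-averaged activations over
   [3 s, 5 s] are recorded as a feed-forward candidate `u_ff`, tagged
   with its Euclidean norm (the active stiffness level).
3. **Gain optimization.** For a selected candidate, CMA-ES minimizes
   `J = w_fail J_fail + w_stability J_stability` on 5-s trials under the
   full delays, with `J_fail = (T_simu - T_fail)/T_fail` and
   `J_stability = sum_n int |q_n(t) - q_n(0)| dt`
   (`w_fail = 5e5`, `w_stability = 50`; a term whose square falls below
   1e-6 is zeroed — the floor is applied to the squares, the literal
   reading of the rule, with the raw-value alternative switchable).
   Trials start from the stable posture maintained by the candidate, with
   activations initialized to `u_ff`, and the feedback references are
   recomputed at that posture (the stable posture effectively becomes the
   objective posture of the gain stage). The failure monitor ends a trial
   when the CoM height drops below 0.4 m or a heel or toe normal force
   reaches zero (metatarsal points are not part of the trigger);
   detection is at control-step resolution, with `T_fail` the first
   violating sample.

Two design choices here deviate from obvious defaults and deserve their
rationale. First, the CMA-ES start point for the gain stage is the
`(P, D)`-derived gain set of the selected candidate rather than a small
random vector: the zero-delay stage has already located the feasible gain
region, and for the reduced fixtures that region sits at gains of order 1,
which a `[0, 0.3]` random start with a 0.005 step size cannot reach within
a modest iteration budget. Second, the step size is quoted in gain units
and should scale with the fixture's gain magnitude; the single-link
pipeline uses `sigma = 0.1`. The configuration default remains 0.005,
appropriate for gains of order 0.1.

## Fixtures: what the synthetic plants emulate

`make_single_link_ankle()` is the classic ankle-strategy abstraction: the
body above the ankle lumped into one 70-kg link with its CoM 1 m above
the joint, on a grounded foot spanning heel x = -0.05 m to toe
x = +0.15 m, driven by one lumped plantarflexor and one dorsiflexor with
0.05-m moment arms. Its linearization is closed form (toppling time
constant `sqrt(I/mgd)` = 0.35 s), which anchors several tests. The lumped
maximal forces (1e5 / 8e4 N) are deliberately bilateral-equivalent
aggregates, not single-muscle values: with length-normalized feedback
through a 0.05-m moment arm, the linearized feedback stiffness per muscle
is `kp F0 r^2 / L0` and must exceed `mgd` (about 690 N m/rad) for gains
inside the 0-2 search grid — that inequality, evaluated before any
simulation, sizes `F0`.

`make_three_link_sagittal()` adds knee and hip (six muscles, six gain
groups) for the multi-joint statics and dynamics cross-checks.
`make_full_sagittal_meta()` carries the full topology — 8 segments,
7 joints in the order lumbar, right hip/knee/ankle, left hip/knee/ankle,
70 muscles in 35 bilateral symmetry classes covering all nine groups,
four contact spheres per foot — with plausible, deterministic stand-in
parameters. It exercises counts, symmetry, gain sharing, configuration
round-trips and the free-base contact physics (a drop-and-settle run must
carry the body weight).

What the fixtures do **not** emulate: anatomical muscle routing (wrapping,
posture-dependent moment arms), 3-D and frontal-plane mechanics, sensory
noise, and real anthropometry. A passing suite therefore demonstrates the
correctness of the mechanics, the delay handling and the design pipeline —
not fidelity to any particular human subject.

## Numerical choices

- **Integrator**: fixed-step explicit RK4, default `dt = 1e-4 s`,
  controller sampled every 1 ms (the dynamics substep the control step).
  Determinism was preferred over adaptive stepping because delay buffers
  and reproducibility demand a fixed grid. Energy drift on passive
  conservative runs is below 1e-5 relative over 10 s; halving the step
  changes a 60-s closed-loop CoM trajectory by less than 1 mm.
- **Fiber state**: integrated as a continuous state with a
  damped-equilibrium rate law (the normalized fiber velocity solves
  `a f_L f_V(v) + beta v = f_T - f_PE`, `beta = 0.1`) rather than an
  algebraic root-solve per step; this stays well-posed as activation
  approaches zero. The solve is a safeguarded Newton iteration on a
  monotone function.
- **Curves**: Gaussian active force-length (width 0.45), exponential
  passive curve normalized to 1 at 1.7 optimal lengths, quadratic-toe /
  linear tendon reaching its reference force at 4.9% strain, and a
  rational force-velocity law with eccentric plateau 1.4 whose two
  branches meet with matched slope at zero velocity. All shape constants
  are configurable; they are standard published shapes, not fitted values.
- **Pennation** is zero by default (planar model).
- **Degenerate inputs**: non-finite states abort a trial as a failure at
  that time, flagged separately from mechanical failures; a candidate
  posture that cannot settle on the ground receives a large finite
  penalty; `T_fail = 0` maps to a large finite failure surrogate rather
  than infinity so the optimizer ranks it worst without poisoning the
  covariance update.
- **Angle units**: radians everywhere internally; degrees only in config
  files, reports and the recorded `q_deg` trajectories.

## Problem sizes used by the test suite

The full-scale protocol (21 x 21 grid, 60-s trials, lambda = 20, up to
750 CMA-ES iterations) is exposed through the configuration objects, and
the test suite runs the same code paths at reduced sizes chosen as the
package's own test protocol: an 11 x 11 grid with `dt = 5e-4 s` for the
stabilization-existence check (five gain-stage seeds, CMA-ES lambda = 8,
at most 40 iterations, 60-s validation), a 4 x 3 grid with 20-s trials
for the re-simulation consistency check, and 100 random 1-3 link states
for the dynamics oracle. The single-link stable region and the delay
margins do not depend on these budgets; only wall-clock time does.

## Known limitations

- Only proprioceptive (muscular-tendon length/velocity) feedback is
  modeled; no visual or vestibular channels, no sensory noise, no
  intermittent control.
- Constant moment arms restrict validity to small excursions about the
  reference posture.
- The contact model is planar and point-based; no torsional friction or
  deformable ground.
- CMA-ES here is the standard algorithm with default parameterisation; no
  restarts or bound-constrained variants.
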