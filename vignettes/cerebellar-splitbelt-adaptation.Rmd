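---
title: "Cerebellar adaptation of reflex-based gait on a split-belt treadmill"
author: "splitbeltsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cerebellar adaptation of reflex-based gait on a split-belt treadmill}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitbeltsim)
```

## The model

When people walk on a split-belt treadmill with one belt faster than the
other (here 1.0 vs 0.5 m/s, a 2:1 ratio), their gait is initially
asymmetric and then adapts over minutes toward symmetry. A long-standing
account attributes this to the cerebellum acting as a forward model: it
predicts the sensory outcome of the current motor program, compares the
prediction with the observed outcome, and uses the mismatch -- the sensory
prediction error -- to adjust both the prediction and the motor commands.

`splitbeltsim` implements that account as a layered controller:

* **Spinal layer** (`controller_state()`, `advance_phase()`,
  `muscle_excitations()`): a reflex controller in the Geyer tradition. Each
  leg runs a five-phase state machine -- early stance (ES), mid-stance
  (MS), pre-swing (PS), swing (SW), landing preparation (LP) -- that gates
  force (F), length (L), constant (C), and pelvis-PD control laws onto
  seven muscle groups per leg (HAM, GLU, IL, VAS, GAS, SOL, TA), through
  sensory channels delayed by 5--20 ms. The MS→PS transition is a *timed*
  swing-initiation trigger: it fires when the time since the leg's own heel
  strike exceeds a threshold $t$. This replaces the classical
  contralateral-heel-strike trigger, which pins the double-support duration
  and cannot express changes in interlimb timing.

* **Cerebellar layer** (`cerebellar_state()`, `on_heel_strike()`): the
  error signal is the step velocity asymmetry
  $\mathrm{SVA} = (SV_f - SV_s)/(SV_f + SV_s)$ with $SV = l/d$ (step
  length over step time per leg). The internal prediction $p$ and the two
  thresholds are updated by gradient descent on
  $e = \tfrac12 (p - \mathrm{SVA})^2$ shortly after every heel strike:

  $$p \leftarrow p - \alpha\,(p - \mathrm{SVA}), \qquad
    t_{s/f} \leftarrow t_{s/f} - \beta\,\frac{\partial e}{\partial SV_{s/f}}.$$

  $\alpha$ (learning rate, dimensionless) sets how fast the prediction
  tracks the observation; $\beta$ (adaptation rate, s per unit gradient)
  sets how strongly the motor timing is corrected. Adaptation stops when
  the prediction matches the observation -- a "new normal" -- not
  necessarily at zero asymmetry.

* **Surrogate plant** (`plant_parameters()`, `run_closed_loop()`): a
  reduced-order event-driven walker that closes the loop at desk scale
  (see below).

The analysis layer (`sla()`, `step_lengths_and_times()`,
`center_of_oscillation_difference()`, `limb_phasing()`,
`fit_exponential()`, `ncc()`, `rmse()`) reproduces the standard
split-belt readouts: step length asymmetry (SLA), the spatial component
(center-of-oscillation difference, degrees), the temporal component (limb
phasing: normalized lag at the peak circular cross-correlation of the
limb-angle traces, 0.5 = perfect alternation), and exponential
adaptation-curve fits $y = a - b e^{-s/c}$ over stride number $s$, where
$c$ is the adaptation rate and $|b|$ the amount of adaptation.

## Gradient conventions and the sign question

Writing $f = SV_f$, $s = SV_s$, the chain rule through the asymmetry gives

$$\frac{\partial e}{\partial f} = (\mathrm{SVA} - p)\,\frac{2s}{(f+s)^2},
\qquad
\frac{\partial e}{\partial s} = -(\mathrm{SVA} - p)\,\frac{2f}{(f+s)^2}.$$

A published closed form of these derivatives circulates with the *same*
leading sign on both legs ($-2\,SV_{\mathrm{other}}\,[\dots]$); it equals
the chain rule for the fast leg and its negative for the slow leg. Both
conventions are implemented (`error_gradients(..., convention =)`) and the
choice is recorded in the per-heel-strike diagnostics. Following the
functional requirement that adaptation must *reduce* the error, the
default is the analytic chain-rule convention with the unit sensitivity
factor $\partial SV/\partial t = +1$ exactly as the update rule is
written: on the shipped surrogate this is the only configuration in which
the closed loop converges while the printed-sign variant diverges.
`cerebellar_state()` also exposes a signed per-leg `sensitivity` factor
for plants whose true $\partial SV/\partial t$ sign differs.

## The surrogate plant: what it is and is not

The full model this package abstracts is a 9-DOF planar musculoskeletal
simulation (pelvis-trunk plus two three-segment legs, seven Hill-type
muscle-tendon units per leg, nonlinear foot--belt contact). Running such a
simulation is out of scope here; instead `surrogate_plant` keeps only the
causal chain the cerebellum exploits:

threshold $t$ → stance duration → trailing-foot excursion under the belt →
step length and step time at heel strike → SVA.

Each leg lifts off $t_{leg} + d_{PS}$ after its own heel strike and lands
$d_{SW}$ later at its anterior placement offset $a_{leg}$; the stance foot
is carried backward at its belt speed; step length at a heel strike is the
leading placement minus the trailing stance-foot position; step time is
the interval since the contralateral heel strike. With the defaults
($a_f - a_s = 0.06$ m, $d_{PS} = 0.15$ s, $d_{SW} = 0.40$ s, $t = 0.35$ s,
belts 1.0/0.5 m/s) the open-loop steady state is $d_f = d_s = 0.45$ s,
$l_f = 0.285$ m, $l_s = 0.39$ m, SLA $= -0.156$ -- an operating point
near the early-adaptation asymmetry of about $-0.17$ reported for the
full model, chosen once and not revisited.

**Phase entrainment.** The literal event map above makes the relative
phase of the two heel-strike trains a pure integrator: each stride,
$d_s$ grows by $(t_s - t_f)$. Since adaptation necessarily drives the two
thresholds apart, every convention/sign combination collapses the walker
(a step time crosses the 0.1 s floor) within tens of strides -- the map as
stated cannot support an 80-stride adaptation run. Real walkers do not
have this failure mode because foot--ground contact re-entrains the legs.
The plant therefore adds one term: the slow (reference) leg's landing
phase-locks to the fast leg's heel-strike train with gain
`phase_gain` $\kappa$ (default 0.5),

$$S_{k+1} = (1-\kappa)\,(S_k + c_s) + \kappa\,(F_k + c_f/2),$$

where $c_{leg} = t_{leg} + d_{PS} + d_{SW}$ is a leg's cycle duration.
The fast-leg cycle stays rigid, so the conservation law
$d_f + d_s = t_f + d_{PS} + d_{SW}$ holds *exactly*, and the correction
vanishes identically whenever the thresholds are equal (all symmetric
baselines and the open-loop steady state are untouched; setting
`phase_gain = 0` recovers the literal map, which the unit tests use for
the exact sensitivity checks). $\kappa = 0.5$ was fixed from a one-time
analysis: weaker coupling lets the gait develop step-time asymmetry that
makes the SLA curve overshoot and backtrack; at 0.5 the closed loop rises
monotonically to a plateau and the rate-interplay orderings below hold.

**What the surrogate does not claim.** No joint kinetics, muscle forces,
ground-reaction forces, balance, or falls; the mapping from SVA to SLA at
the adapted state is quantitatively different from the full dynamics (the
adapted SLA plateau here overshoots zero, whereas the full model plateaus
near $-0.03$). Green closed-loop tests therefore establish the *mechanism*
-- error-driven threshold adaptation converging the prediction loop with
the reported qualitative rate interplay -- not the published trajectories.

## What a closed loop run shows

```{r closed-loop}
plant <- plant_parameters()
sim <- run_closed_loop(plant, cerebellar_state(alpha = 0.002, beta = 0.02),
                       n_strides = 80, seed = 1)
r <- sim$records
round(c(sla_start = r$sla[1], sla_end = r$sla[80],
        err_stride2 = r$error[2], err_stride80 = r$error[80]), 4)
```

With the rates fixed at their standard initial values
($\alpha = 0.002$, $\beta = 0.02$) the error at stride 80 is orders of
magnitude below its stride-2 value and SLA rises monotonically (on a
5-stride moving average) from $-0.156$ toward a plateau. With
$\alpha = \beta = 0$ the loop is the reflex-only analogue: thresholds and
SLA stay frozen. The four-cell rate grid
($\beta \in \{0.01, 0.04\} \times \alpha \in \{0.01, 0.05\}$) reproduces
the qualitative interplay: higher $\beta$ changes SLA more over the first
five strides (speed of adaptation), and lower $\alpha$ plateaus at a more
positive SLA (the prediction stays nearer its symmetric prior, so the
motor system is pulled further).

## Numerical choices

* **Thresholds** are clipped to [0.05, 1] s (prevents degenerate stance
  phases; no published bounds exist). Both thresholds are updated at every
  heel strike of either leg, from the same pre-update state as the
  prediction; updates latch into the plant at the next stride.
* **Warm-up**: the very first heel strike of a run cannot form a complete
  two-leg observation and is a flagged no-op.
* **Exponential fits** multi-start over $c \in \{2, 5, 10, 20, 40\}$ with
  endpoint-derived $a, b$ starts, `nls` (port, $c > 0$) with a
  Nelder--Mead fallback, reporting `converged = FALSE` rather than
  erroring.
* **Limb phasing** uses circular lags over one stride on mean-removed
  traces (periodic gait makes circular treatment natural); resolution is
  one sample period (1 ms waveform sampling by default).
* **Delays** are zero-order-hold shifts with the first sample held before
  the stream starts; a 1 ns knot guard keeps exact-multiple delays on
  their sample.
* **Objective**: the station-keeping drift is taken in absolute value (a
  signed drift cost would reward backward drift); the upper-body "penalty
  of 100" is integrated as a penalty *rate* over the violation time; the
  metabolic term uses the *mean* rate (integrated energy vs mean rate is
  not settled; the choice is flagged here); the default energy model is an
  activation-squared proxy clearly labeled as such, with the real
  muscle-energetics model out of scope. Knee limit torque is an input
  signal (the surrogate has no knee-ligament model) defaulting to zero.
* **CMA-ES** is implemented in-package (no CMA-ES library ships with the
  supported environment) in the standard tutorial formulation; the
  harness owns the stopping rules: a generation budget, and a
  500-generation moving-average improvement below $10^{-4}$.
* **Parameter registry**: the published total of 64 spinal parameters (62
  reflex gains/offsets plus the two thresholds; 66 with $\alpha, \beta$)
  is reproduced by a shipped 31-scalar-per-leg law enumeration. The
  per-law breakdown is not published in the main text; the shipped
  enumeration and its default values are documented placeholders in
  `default_controller_config()`, editable without changing the counts'
  provenance. Bounds default to one order of magnitude around each gain,
  [0, 1] s for thresholds, and [$10^{-5}$, 1] for the rates.

## Known limitations

* No after-effect/washout phase and no reflex-gain adaptation (both held
  out deliberately).
* Whether the slow-leg step length decreases slightly during adaptation
  (as reported for the full model) is not asserted for the surrogate;
  treated as exploratory.
* Per-leg updates occur at *every* heel strike rather than only at the
  leg's own; the alternative is not specified anywhere and the chosen
  semantics is the simplest consistent one.
* The PD set-points and per-law offsets of the trunk controller are
  placeholders pending a published enumeration.
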