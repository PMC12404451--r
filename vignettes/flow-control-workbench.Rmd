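---
title: "A desk-scale workbench for ventilator flow control: PID versus fuzzy logic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale workbench for ventilator flow control: PID versus fuzzy logic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ventbench reproduces, entirely in software, the experimental structure of a
flow-control comparison on an electropneumatic ventilator bench: a
proportional valve delivers inspiratory flow to a test lung, a flow sensor
closes the loop, and either a discrete PID controller or a Mamdani
fuzzy-logic controller (FLC) regulates the flow against step setpoints,
disturbances and changing lung mechanics. Around the control loop sit the
analysis tools such a study needs: ARX identification of discrete transfer
functions, Jury and Nyquist stability analysis, step-response metrics, and
the agreement/repeatability statistics (Bland–Altman, Fisher variance test,
finite-population sample size).

This vignette documents the modelling choices, their rationale, and what the
synthetic experiments can and cannot say about real hardware.

## The synthetic plant

No plant equations were available for the hardware this emulates, so the
simulator is the minimal structure exhibiting every nonlinearity such a
bench presents:

* **Valve static map with backlash.** The command $u \in [0,1]$ passes
  through a play (backlash) operator of half-width $w$,
  $h_k = \min(u_k + w,\, \max(u_k - w,\, h_{k-1}))$, and a power law,
  $Q_\mathrm{valve} = Q_\mathrm{max}\, h^{\gamma}$. Defaults: $w = 0.02$,
  $\gamma = 1.4$, $Q_\mathrm{max} = 80$ L/min. The backlash gives the
  direction-dependent hysteresis of real proportional valves; $\gamma > 1$
  gives the progressive opening characteristic.
* **Actuator lag.** The opening tracks the command through a first-order
  filter with time constant 5 ms (the valve class is specified to respond in
  under 5 ms).
* **Single-compartment lung with back-pressure.** Lung volume integrates the
  delivered flow; elastic recoil pressure $V/C + \mathrm{PEEP}$ pushes back
  through the supply path, subtracting $(V/C + \mathrm{PEEP})/R$ (in L/s)
  from the valve flow. $R$ here is the *supply-path impedance* seen by the
  recoil — a pressure-regulated source behind a proportional valve is a
  stiff flow source, so the default (200 cmH2O/(L/s)) is deliberately above
  airway-only values; compliance defaults to 50 mL/cmH2O, an adult
  test-lung setting. The linear form keeps the idealized plant
  (no backlash, $\gamma = 1$, no noise) exactly linear time-invariant, which
  the test suite exploits through a superposition check.
* **Sensor path.** A pure transport delay of `round(lag_time/dt)` samples
  (default 5 ms) plus i.i.d. Gaussian noise (default sd 0.25 L/min,
  consistent with a ±5% instrument class at mid-scale). All noise derives
  from the scenario seed; seeded runs are bit-identical.
* **Disturbances.** A cough is an additive half-sine flow pulse; a leak is a
  constant subtractive flow while active. These are the simplest shapes
  matching the phenomena they stand for.

Time advances in fixed 1 ms steps — small enough to resolve the 5 ms valve —
and volume integrates trapezoidally. Units are fixed: flow L/min at module
boundaries (L/s internally), volume mL, pressure cmH2O, time s.

### Breath cycling

Scenarios model *sustained* ventilation, not an isolated inspiration: each
breath is an inspiration (constant flow setpoint) followed by a passive
expiration (setpoint zero, lung vents with a 0.3 s time constant, the
proportional valve shut). During expiration the flow controller is paused
with its state held — the standard phase sequencing of flow-targeted
ventilators, where an expiratory solenoid takes over. This matters
quantitatively: on a cold start the PID integrator must wind up to the
steady valve command, and that wind-up costs exactly $u_{ss}/K_i$ of
flow-time (tens of mL) out of the delivered volume. On the warmed-up second
breath of a cycle both controllers deliver 99–100% of the 500/700/900 mL
targets; the shipped presets (`scenario_preset("v500")` etc., 1 s
inspiration, 2 s expiration, two breaths) therefore evaluate breath two via
`breath_trace()`.

## The PID controller

The discrete PID is the parallel form with rectangular integration (the
integral includes the current sample), a backward-difference derivative
smoothed by a first-order filter of time constant $10\,dt$ (an unfiltered
derivative would amplify sensor noise at the 1 kHz loop rate), and
conditional-integration anti-windup: the integral freezes whenever the
unclipped output already saturates in the direction of the current error.

The tuned gains ($K_p = 5.7$, $K_i = 87.3$ s$^{-1}$, $K_d = 0.05$ s) are
dimensionally meaningful only in the physical units of the bench they came
from: flow error in L/s in, valve drive voltage on a 0–10 V input out.
`pid_controller()` applies exactly those scalings (`error_scale = 1/60`,
`output_scale = 1/10`) and saturates at the voltage limits. Mapping the
output directly onto the 0–1 command fraction would multiply the loop gain
by ten and destabilize it under any realistic loop delay.

`zn_tune()` implements the classic ultimate-cycle rule
($K_p = 0.6 K_c$, $T_i = T_u/2$, $T_d = T_u/8$), and `estimate_kc_tu()`
finds the critical point experimentally: a proportional-only gain sweep,
declaring sustained oscillation when successive peak amplitudes of the
mean-centred error stay within ±5% of each other. The centring matters —
P-only loops oscillate about a nonzero offset. The adaptive gain refinement
the original bench alluded to is not specified anywhere and is deliberately
out of scope.

## The fuzzy controller

A Mamdani controller on flow error (universe ±20 L/min) and error rate
(±200 L/min/s), five symmetric triangular terms per variable with apexes
evenly spaced and 50% overlap, minimum AND, max aggregation of clipped
consequents, centroid defuzzification. The output variable is a *command
increment* (±0.1 per 5 ms reference interval, scaled by $dt$): Table-style
action phrasings ("reduce valve opening") are changes, so the controller is
incremental (velocity form), which also gives it integral action and hence
offset-free tracking.

Only five anchor rules of the 5×5 base were given; the shipped default
completes the matrix as an antisymmetric PD-type map: with error index $s$
and rate index $r$ in $\{-2..2\}$, the consequent index is
$\mathrm{clip}(s + \mathrm{trunc}(r/2))$, with the zero-error row pinned to
*NoChange* for every rate. This honours four of the five anchors (zero-error
row; large-positive & increasing → open fast; small-negative & decreasing →
reduce; large-negative & rapid-decreasing → close fast). The fifth anchor
(small-positive & constant → maintain) is deliberately replaced by *open
slowly*: honouring it would zero the control action over the entire inner
half of the error universe at steady rates, a structural deadband that stalls
tracking several L/min short of the setpoint. The full matrix ships as data
(`default_rule_base()`) and is user-overridable; configurations serialize to
JSON (`write_flc_config()`).

Two numerical choices are worth noting. The output grid spans the *full
supports* of the consequent terms, not just the universe: truncating the
outermost triangles at the universe bound makes their centroid drift with
the clip level and breaks monotonicity of the control surface. And the
default 1201-point grid places every default apex exactly on a grid point,
so symmetric aggregates defuzzify to exactly zero. The resulting surface is
antisymmetric, monotone non-decreasing in error for every fixed rate, and
bounded by the output universe — all property-tested.

## Identification and stability analysis

`fit_arx()` estimates
$y_k = \sum_{i=0}^{4} b_i u_{k-i} - \sum_{j=1}^{4} a_j y_{k-j}$
by least squares via the SVD; the minimum-norm solution handles exactly
representable rank-deficient cases (the identity system), while inputs that
cannot explain the output (constant excitation) raise an error asking for a
richer input. On noise-free data the generating coefficients are recovered
to below $10^{-6}$, which the tests assert against the shipped reference
loops.

Two fourth-order discrete transfer functions ship as JSON fixtures
(`reference_tf("pid")`, `reference_tf("fuzzy")`) — closed-loop models of the
PID- and fuzzy-controlled flow loops of the bench this package emulates.
Their sample time is not specified, so frequency axes are reported in
rad/sample.

`jury_test()` implements the classical array: $P(1) > 0$,
$(-1)^n P(-1) > 0$, $|a_n| < a_0$, then successive derived rows
$b_k = c_0 c_k - c_m c_{m-k}$ each requiring $|b_0| > |b_{m-1}|$, down to a
three-element row; degree ≤ 2 is decided by the basic conditions alone. The
implementation is validated against a `polyroot` modulus oracle on thousands
of random polynomials.

`margins()` treats a transfer function as the loop gain of a unity
negative-feedback system. Phase crossovers are located as sign changes of
$\mathrm{Im}\,G(e^{i\omega})$ with $\mathrm{Re}\,G < 0$ on a hybrid
log+linear grid of $10^5$ points, refined by bisection to $10^{-10}$ rad;
the endpoints $z = \pm 1$, where the response is exactly real, are included
as crossover candidates when the response is negative there. The gain margin
is the *minimum* of $-20\log_{10}|G|$ over all phase crossovers (worst
case). This convention is load-bearing: the PID reference loop has an
interior crossover at $\omega \approx 1.08$ rad/sample (16.2 dB) and a
second one at $z = -1$ where $G(-1) = -0.1663$, i.e. 15.58 dB — the binding
margin. Margins are `Inf` when the corresponding crossover does not exist,
which is how the fuzzy reference loop reports both margins (its response
never reaches the negative real axis and stays below unit magnitude).

`nyquist_encirclements()` counts the winding of $G(e^{i\omega})$ about
$(-1, 0)$ by summed wrapped angle increments over the full circle, with
recursive refinement wherever an increment exceeds 0.5 rad; a pole on the
unit circle raises an error (the winding number is indeterminate). The test
suite checks it against the argument principle by root counting.
`min_distance_to_critical()` reports the closest approach to the critical
point — larger for the fuzzy loop than for the PID loop, the robustness
ordering the workbench is designed to exhibit.

## Agreement and repeatability statistics

`bland_altman()` uses the classical estimators: mean difference, sd with
$n-1$, limits of agreement $\bar d \pm 1.96 s$, and standard errors
$s/\sqrt{n}$ for the mean and $s\sqrt{3/n}$ for both limits. These formulas
were chosen because they are internally consistent with the published
agreement table this workbench mirrors (sd back-derived from the limits
reproduces the printed standard errors to rounding). The difference
direction is fixed as device − reference.

`fisher_variance_test()` computes $F = s_x^2 / s_y^2$ with an upper-tail
one-sided p-value and critical value $F_{1-\alpha}(n_x-1, n_y-1)$, rejecting
equality of variances when $F > F_\mathrm{crit}$ — the standard convention
(one published description inverts the inequality in prose while clearly
using the standard convention in its conclusions; the standard one is
implemented). Degrees of freedom for the reference critical values
(≈1.487/1.485) are not published; the record counts implied by the
sample-size calculation (72 and 71) give $F_{0.95}(71,70) = 1.484$, within
0.003 of the printed value — consistent, but an inference, so the package
always computes the critical value from the data's own degrees of freedom.

`sample_size()` is the finite-population formula
$n = N Z^2 p q / (e^2 (N-1) + Z^2 p q)$. The success probability $p$ is not
printed in the source material; $p = 0.05$ is the unique standard choice
reproducing the published 71.70 for $N = 4000$ (for the analyzer population
of 2000 it yields 70.45 against a printed 70.40 — a discrepancy we report
rather than force).

## What the synthetic experiments show — and what they don't

Passing tests demonstrate that the *methods* behave correctly on a plant
with the right nonlinearity structure: volume delivery within ±5% on all
presets for both controllers, disturbance recovery, exact seeded
reproducibility, coefficient-exact identification, stability verdicts that
match root-finding, and statistics that match their closed forms. They do
not reproduce hardware-specific numbers: experimental settling times, the
measured Bland–Altman biases and the published F statistics depend on
unshared recordings, and the plant parameters here are fabricated working
values (labelled as such in the documentation). Time-domain numbers from
the simulator describe the simulator.

Problem sizes are chosen for a laptop-class machine: 1 kHz loops over a few
breaths (thousands of plant steps per run), $10^5$-point frequency grids,
$10^4$-pair synthetic agreement samples, and 1000-polynomial stability
cross-checks; the full suite runs in well under a minute.

## Known limitations

* Pressure- or patient-triggered ventilation modes, multi-compartment lungs
  and neonatal scenarios are out of scope.
* The expiratory side is a passive first-order vent, adequate only for
  resetting the lung between inspirations.
* Whether the reference transfer functions model open or closed loops is
  unspecified upstream; they are analyzed as loop transfer functions, as
  their published margins imply.
* The fuzzy controller's fifth printed anchor rule is intentionally not
  honoured (see above); users who want the literal rule can pass their own
  matrix to `flc_config()`.
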