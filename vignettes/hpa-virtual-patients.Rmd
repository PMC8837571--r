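---
title: "Virtual patients of the HPA stress axis: model, cohorts, triage, bifurcations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual patients of the HPA stress axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpaxis)
```

## The model

The hypothalamic–pituitary–adrenal (HPA) axis is modelled as a
sigmoidal-network ODE system in four dimensionless activities
$X_i \in (0,1)$ for CRH, ACTH, cortisol (COR) and the glucocorticoid
receptor (GR):

$$
\frac{dX_i}{dt} = k_i\,(F_i - X_i), \qquad
F_i = \frac{1}{1 + e^{-\sigma W_i}}, \qquad
W_i = R_0^i + \sum_j R_j^i X_j + c_i \cdot \mathit{Stress}.
$$

Each species relaxes at rate $k_i$ toward a pseudo-steady-state activity
$F_i$, a logistic function of the weighted input $W_i$; $R_0^i$ is a basal
weight, $R_j^i$ the signed influence of species $j$ on species $i$, and
$c_i$ couples the external stress input into $W_i$. The shipped wiring
(`default_hpa_spec()`, mirrored by the config file
`inst/extdata/hpa_model.yaml`) implements the canonical axis: stress
activates CRH; CRH → ACTH → COR → GR; GR represses CRH and ACTH (negative
feedback); CRH and GR carry positive self-feedback. Stress enters only the
CRH input ($c = (1,0,0,0)$).

**Steepness.** A single global $\sigma$ applies to all species, fixed at
$\sigma = 1$. Two considerations fix this choice. First, in a one-species
self-activation loop $x = F(R_0 + R x + s)$ the fold condition
$\sigma R\,F(1-F) = 1$ with $F(1-F) \le 1/4$ means bistability requires
$R > 4/\sigma$; with $\sigma = 1$ the switching threshold on a
self-feedback weight sits at 4, in the interior of the sampling range
$[0, 8]$, so a sampled cohort contains both monostable and bistable
individuals. Second, the decision-tree threshold the triage discovers on
the CRH self-weight (≈ 4.5–5) then falls just above that theoretical onset,
which is the behaviour the workflow is designed to expose.

**Stress protocol.** The input is a transient pulse: constant baseline 0.1
up to $t = 10$, exponential rise $0.1\,e^{0.6(t-10)}$ to the peak
$0.1\,e^{3} \approx 2.009$ at $t = 15$, then exponential decay at the same
rate, clamped from below at the baseline. The decay is implemented with a
*negative* exponent and with the exact rise value (not its rounded value 2)
as prefactor, so the signal is continuous at the peak and genuinely
decreasing — the only formulation consistent with a transient stressor.

## Simulating a patient and labelling the response

`run_stress_protocol()` finds the pre-stress steady state, integrates
through the pulse (deSolve's `lsoda` with the analytic Jacobian; the
relaxation rates make the system moderately stiff), continues at baseline
until the post-stress steady state, and labels the patient by comparing
cortisol before and after:

```{r label}
pr <- stress_protocol()
run_stress_protocol(hpa_example_vp("VP1"), pr)
run_stress_protocol(hpa_example_vp("VP3"), pr)
```

*higher* means post-stress cortisol exceeds the pre-stress level by more
than the equality tolerance, *lower* the reverse, *control* equality within
tolerance. The tolerance defaults to $10^{-3}$ in cortisol units: a
monostable patient returns to the identical equilibrium, so the tolerance
only has to absorb solver error, while a patient that switched attractors
typically moves by $10^{-1}$; the classification is therefore insensitive
to the exact value over several orders of magnitude. It is exposed as
`label_tol` because the population split ultimately depends on it.

**Pre-stress initial condition.** The pre-stress relaxation starts from the
all-zero rest state: the axis begins with all hormone levels low, as an
unstimulated physiological baseline. For bistable patients this
deterministically selects the attractor whose basin contains the rest
state — for a CRH switch the low branch, for a GR latch the unlatched
state. A mid-range start (all components at 0.5) was considered and
rejected: with a strong GR self-feedback the mid state already lies in the
latch's basin, so the latch engages *before* stress and the lower response
class — whose mechanism is precisely the stress-triggered latch — almost
never occurs. The initial state remains an argument (`x0`) for users who
want a different convention.

**Steady-state detection.** Relaxation runs in chunks of 25 time units; at
each chunk end a damped Newton solve is attempted from the trajectory
endpoint and accepted only if (i) the polished residual satisfies
$\|dX/dt\|_\infty < 10^{-9}$ (default), (ii) the equilibrium is linearly
stable, and (iii) the endpoint is within $10^{-4}$ of it, i.e. the flow has
actually approached the state it reports. A hard cap of 500 time units
applies; a limit-cycle attractor (as in the oscillatory patient VP5 at
elevated stress) therefore raises a distinct `vpaxis_no_steady_state`
condition rather than returning a spurious average.

## Virtual cohorts

`build_population()` draws each named parameter uniformly from its range,
simulates the protocol and rejection-samples until each class (higher,
lower, control) holds its quota; each draw uses a seed derived
deterministically from the master seed, so cohorts reproduce exactly and
individual draws can be replayed. The shipped ranges
(`default_ranges()`) are: relaxation rates $[1, 10]$, basal weights
$[-4, 0]$, activating and self-feedback weights $[0, 8]$, repressive
weights $[-8, 0]$. They are a documented reconstruction, chosen so the
cohort contains all three classes; under them roughly 5% of draws are
higher, 1% lower, the rest control, so quota filling is dominated by the
lower class.

What the generator emulates: heterogeneous patients as parameter draws
around one shared network. What it does not emulate: measurement noise,
intra-patient variability over time, non-uniform (data-calibrated)
parameter distributions, or any pruning toward clinical plausibility.
Passing tests therefore demonstrate the *workflow* — that the triage
recovers mechanistically causal parameters and that the dynamical analysis
explains the classes — on a population whose ground truth is known, not
agreement with any clinical cohort.

## Machine-learning triage

Two two-class comparisons are run (higher vs control, lower vs control),
mirroring a divide-and-conquer strategy:

* `rf_importance()` — random forest (500 trees,
  $\lfloor\sqrt{p}\rfloor$ features per split) scored by *unscaled*
  out-of-bag permutation importance, i.e. the mean accuracy drop when one
  feature is shuffled; negative drops are permutation noise and are floored
  at zero, then scores are min–max normalized so the top feature reads 100
  and the bottom 0.
* `fit_tree()` — a depth-limited classification tree (Gini impurity,
  thresholds at midpoints of adjacent observed values; depth 3 by default,
  matching the depth at which printed trees stay readable). The fitted
  structure is re-expressed as explicit nodes with class counts, majority
  fractions (reported as nearest-integer percent) and printable thresholds.
* `svm_train()` — a two-feature soft-margin SVM, radial kernel with unit
  bandwidth after standardization (`gamma = 0.5`); two features because the
  triage's purpose is a *plottable* boundary in the plane of the two most
  important parameters, and a radial kernel because the class boundary
  induced by a fold condition is curved, not linear.
* `cross_validate()` — stratified $k$-fold (default 10) accuracy for any
  of the above.

On regenerated cohorts the higher-vs-control comparison ranks the CRH
self-weight first by a wide margin with the basal CRH weight in the top
three, and the tree's root threshold on the self-weight lands just above
the bistability onset — the triage rediscovers the switch condition. For
lower vs control the triage ranks the GR self-weight and basal GR weight
on top: under the shipped ranges the lower class is created by the GR
positive-feedback latch, so those are the causally correct answers for
*this* generator, and the cross-check against the dynamical analysis below
closes the loop.

## Bifurcation analysis

The continuation layer is written in-package:

* `newton_equilibrium()` / `equilibria_scan()` — damped Newton with the
  analytic Jacobian; the scan multi-starts from a regular grid (default
  $5^n$) and deduplicates, serving as branch seeding and as a brute-force
  cross-check of the continuation.
* `continue_branch()` — pseudo-arclength predictor–corrector in
  $(X, \mathit{Stress})$: secant predictor, Newton corrector orthogonal to
  the secant, step halving on corrector failure and growth on easy
  convergence (initial step 0.01, bounds $[10^{-5}, 0.05]$). Arclength
  parameterization lets the trace *round* saddle-node turning points, which
  natural-parameter stepping cannot. Eigenvalues of the $4\times4$ Jacobian
  are computed at every accepted point; a point is stable when all real
  parts are below $-10^{-8}$, and real parts within that margin are flagged
  `marginal` rather than silently stable.
* `detect_folds()` — folds are bracketed where the stress coordinate's
  arclength derivative changes sign and refined by bisection *on the
  curve* (each probe is a corrected point, so refinement never leaves the
  equilibrium manifold) to a stress tolerance of $10^{-4}$; each fold must
  exhibit a near-zero eigenvalue ($<10^{-3}$).
* `detect_hopf()` — sign changes of the leading complex pair's real part,
  refined the same way; a reported point must have $|\mathrm{Re}\,\lambda| <
  10^{-4}$ with $|\mathrm{Im}\,\lambda| > 10^{-3}$.
* `bistable_interval()` — stress windows where at least two *distinct*
  stable states coexist, counted on a fine grid with state-space
  deduplication (two traces covering the same curve are not double
  counted); window ends snap to detected folds.
* `continue_fold()` — two-parameter fold following of the augmented system
  $\{f = 0,\ J v = 0,\ \|v\|^2 = 1\}$ in (stress, second parameter), with a
  finite-difference Jacobian of the augmented system (the model Jacobian
  itself stays analytic) and clean termination with a recorded reason when
  the parameter window is left, the corrector fails at the minimum step, or
  the zero eigenvalue stops being simple.

```{r bif}
vp1 <- hpa_example_vp("VP1")
summ <- bifurcation_summary(vp1, c(0, 2))
summ$folds
summ$bistable
```

The higher patient VP1 is an S-shaped CRH switch: bistable from near zero
stress up to the upper saddle-node at 0.7, with the resting baseline 0.1
inside the window. A transient pulse that exceeds the fold carries the
state to the high branch, and after the pulse the system stays there — the
pathological attractor. Removing it (VP2, lower CRH self-weight) makes the
same pulse reversible.

## The representative patients

`hpa_example_vp("VP1")` … `"VP5"` are five *synthetic* parameter sets
(also in `inst/extdata/vp_examples_synthetic.yaml`) that realize the
workflow's illustrative phenotypes:

| patient | phenotype | mechanism |
|---|---|---|
| VP1 | higher | CRH self-activation switch, baseline in the bistable window |
| VP2 | control | VP1 with the CRH self-weight reduced below the switch onset |
| VP3 | lower | GR self-activation latch engaged by the pulse, repressing CRH/ACTH/COR |
| VP4 | control (spurious) | VP3 with the basal ACTH weight reduced: resting cortisol already low |
| VP5 | control, oscillatory | VP3 with the GR self-weight reduced: latch gone, negative loop oscillates at elevated stress |

They are reconstructions, not data fits: the wiring realizes the intended
mechanism and two scalar landmarks were calibrated to the documented
diagrams (VP1's basal CRH weight so the upper fold sits at stress 0.700;
VP5's GR self-weight so the Hopf onset sits at 0.400). All other values
are round numbers inside the sampling ranges. VP4's edited basal weight
(−7) lies outside the sampling range, which is deliberate: it is a designed
intervention on an existing patient, not a sampled one, and the spurious
"cure" it illustrates — control only because cortisol is already
pathologically low before stress, with the pathological attractor still
present — requires saturating ACTH off.

## Numerical choices and degenerate inputs

* Integration tolerances: `atol = 1e-10`, `rtol = 1e-8` for trajectories;
  the self-convergence of endpoints under tolerance halving is tested.
* `soft_switch()` saturates to values strictly inside $(0,1)$ for extreme
  inputs instead of returning 0, 1 or NaN; the forward invariance of the
  unit box follows and is asserted on simulated trajectories.
* Ties and degenerate cases fail loudly: single-class tables for the
  forest/SVM raise a degenerate-labels condition, identical points with
  conflicting labels are rejected before SVM training, an empty rule
  selection reports an explicit empty result rather than dividing by zero,
  and unsatisfiable class quotas raise a quota failure carrying per-class
  counts.
* The quasi-static hysteresis argument (bistable window containing the
  baseline + pulse peak above the fold ⇒ non-control) holds when the pulse
  actually completes the crossing. Because escape slows down near a
  saddle-node without bound, a pulse that exceeds the fold only briefly —
  the peak within ~10–15% of the fold, giving well under one relaxation
  time above it — can fail to switch and leaves a control label; one such
  marginal case occurs among the sampled panel in the test suite and is a
  real property of the dynamics, not a solver artifact. Likewise the
  argument presupposes that the coexisting attractor differs visibly in
  cortisol and that the rest state sits on the branch that folds; both
  preconditions are computed, not assumed, in the tests.

## Problem sizes used in the checks

The shipped checks run cohorts of 50 patients per class (the workflow
scales to thousands per class unchanged; quota filling is linear in the
rarest class's incidence), 500-tree forests, continuation windows of
stress ∈ [0, 2] at up to 5000 points per branch, and grid scans of $5^4$
Newton starts at 50 stress slices. These sizes were chosen to make every
statistical margin in the checks comfortable while keeping a full run on
one core in minutes.

## Known limitations

* Periodic orbits are observed by simulation only; limit-cycle
  continuation past Hopf points and codimension-2 classification (cusp,
  Bogdanov–Takens) are out of scope.
* The sampled-parameter set, ranges and representative patients are
  reconstructions; quantities that depend on the exact published cohort
  (printed node purities, the lower-class importance ordering) are
  reproduced in *shape* but not numerically.
* Stress enters only through CRH; per-species steepness is not supported
  (one global $\sigma$).
* The two-parameter fold curve is continued with a finite-difference
  augmented Jacobian; very sharp sigmoids ($\sigma \gg 1$) would warrant
  analytic second derivatives.
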