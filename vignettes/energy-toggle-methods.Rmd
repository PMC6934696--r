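---
title: "Methods: energy-dependent decision-making in a two-gene toggle switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy-dependent decision-making in a two-gene toggle switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(energytoggle)
```

## The model

`energytoggle` analyses a deterministic ODE model of a canonical cell-fate
decision motif: two genes whose protein products $x_1, x_2$ each activate
their own conditional promoter and repress the other gene's constitutive
promoter, with all production scaled by the cell's energy budget:

$$
\frac{dx_i}{dt} \;=\;
\lambda(A^*)\, a_i \frac{x_i^n}{\theta_{a_i}^n + x_i^n}
\;+\; \lambda(A^*)\, b_i \frac{\theta_{b_i}^n}{\theta_{b_i}^n + x_j^n}
\;-\; k_i x_i,
\qquad j \neq i .
$$

The additive terms are, left to right: Hill-type self-activation saturating
at $a_i$, cross-repression down from the basal rate $b_i$, and first-order
degradation at rate $k_i$. $\theta_{a}$ and $\theta_{b}$ are the
dissociation constants of the activator and inhibitor to their promoter
sites; $n \ge 1$ is the binding cooperativity. The model deliberately
coarse-grains gene expression to the protein level — there is no explicit
mRNA stage — and degradation is taken as energy-independent, since protein
turnover is a smaller ATP sink than transcription plus translation.

Stable steady states of this system are **attractors**, read as the cell
fates the circuit supports; the set of initial conditions converging to an
attractor is its **basin**. The package's central question is how the
number, geometry and accessibility of these fates change with the energy
budget.

### Energy scaling

Transcription and translation consume ATP, so both production terms carry a
factor $\lambda(A^*)$, where $A^* \in [0, 1]$ is the cell's free-energy
availability scaled by its maximum. Three forms are provided
(`energy_model()`):

* **sigmoid** (default): $\lambda = 1/(1 + e^{-(s_1 A^* + s_2)})$ with
  $s_1 = 16$, $s_2 = -8$, matching the empirically observed sigmoidal
  dependence of total transcription rate on ATP. With these defaults
  $\lambda(0.5) = 0.5$ exactly, and $0 < \lambda < 1$ everywhere.
* **linear**: $\lambda = A^*$ clamped to $[0,1]$. The literature states only
  that a linear choice leaves the qualitative picture unchanged, without a
  formula; the identity map is the minimal such choice, and the package's
  sweeps confirm the qualitative agreement.
* **shifted**: $\mathrm{floor} + (\mathrm{ceiling} - \mathrm{floor})\,
  \sigma(s_1 A^* + s_2)$, modelling uptake of external ATP: expression
  capacity is nonzero even at $A^* = 0$ and may exceed the closed-cell
  maximum. The exact published form of this variant is not available, so an
  affine rescale of the same sigmoid is used, with demonstration values
  floor $= 0.1$, ceiling $= 1.2$ exposed as parameters.

`map_atp_to_astar()` places real concentrations on this axis via a linear
map of the observed E. coli range (320--2760 uM); concentrations below the
lower bound map to negative $A^*$ and are flagged sub-critical (non-viable).

### Parameters at a glance

| parameter | meaning | units | default |
|---|---|---|---|
| $a_i$ | max conditional-promoter rate | conc/time | 1 |
| $b_i$ | basal constitutive-promoter rate | conc/time | 1 |
| $k_i$ | degradation rate | 1/time | 1 |
| $\theta_{a_i}$ | activator dissociation constant | conc | 0.5 |
| $\theta_{b_i}$ | inhibitor dissociation constant | conc | 0.5 |
| $n$ | Hill coefficient | — | 4 |
| $s_1, s_2$ | sigmoid steepness/offset | — | 16, −8 |

The default set is the standard example parameterisation for this motif and
is tristable at full energy. All analyses in the package are exact in these
dimensionless units; conclusions are qualitative (counts, orderings,
geometry), not quantitative rate predictions.

## Steady states and stability

`find_steady_states()` locates roots by damped Newton iteration started
from every node of a grid covering $[0, 1.2\,x_{\max}]^2$, where
$x_{\max} = \max_i \lambda (a_i + b_i)/k_i$ bounds every steady state
(production is bounded by $\lambda(a_i + b_i)$). The iteration runs
vectorised across all starts simultaneously, solving the $2\times 2$ Newton
system in closed form, projecting iterates onto the non-negative quadrant
(roots with $x_i = 0$ exist when $b = 0$ or $\lambda = 0$), and halving any
step that fails to reduce the residual. Starts that stall are discarded;
accepted roots must satisfy $\lVert f \rVert < 10^{-9}$. The default start
grid is $25 \times 25$ ($15 \times 15$ for landscape sweeps) — far denser
than the at-most-nine roots this planar system can possess, and the count
invariance under grid offsets is tested explicitly. An independent
Levenberg–Marquardt solver (minpack.lm) reproduces the same root sets in
the test suite.

Duplicate roots from different starts are merged greedily: candidates are
visited in order of increasing residual and kept only if farther than
$10^{-5}$ from every kept root, so each cluster is represented by its most
accurate member.

Stability is read from the analytic Jacobian (closed-form eigenvalues of
the $2\times2$ matrix; the analytic entries are verified against central
finite differences on seeded random draws). A root is **stable** iff the
largest eigenvalue real part is below $-10^{-8}$. Marginal roots — leading
real part within $\pm 10^{-8}$ of zero — are labelled *unstable*: a
marginally stable state cannot hold a fate against arbitrarily small
expression noise, so only robustly attracting states count as decisions.
This "functionally unstable" convention also makes classification exactly
at a bifurcation point deterministic. Complex eigenvalue pairs are handled
through their real part; no oscillatory attractors arise in this model
class, and the trajectory-oracle test would expose them if they did.

## Trajectories and basins

`settle()` integrates batches of initial conditions with fixed-step RK4
($dt = 0.05$, $t_{\max} = 500$ time units), freezing each trajectory once
$\lVert f \rVert < 10^{-8}$. The dynamics are non-stiff with rates of order
one (Jacobian norms stay well below $10/\text{time}$ over the studied
ranges), so the step size sits comfortably inside RK4's stability region;
the batched integrator is cross-checked against an adaptive stiff solver
(deSolve's lsoda) in the tests. Batching is what makes basin maps cheap:
all grid cells advance through vectorised arithmetic at once.

`basin_map()` labels each cell of a regular grid with the stable attractor
its trajectory reaches (matched within $10^{-3}$). Two kinds of cell get no
label: **boundary** cells whose trajectory converges onto a separatrix —
e.g. the exact diagonal of a symmetric bistable switch, which relaxes to
the saddle — and **undetermined** cells that fail to converge at all.
Boundary cells are legitimate measure-zero starts and are simply excluded
from basin geometry; more than 1% undetermined cells raises an error, since
that indicates inadequate integrator settings rather than geometry.

## Bifurcation sweeps and landscapes

`sweep_energy()` solves every energy level independently (step $5\times
10^{-3}$ for the canonical fine sweep): no continuation, so each stable
count is self-contained and count changes cannot be artefacts of branch
tracking. `count_sequence()` run-length-encodes the counts and flags
**re-entrance** — a count value recurring in non-adjacent runs, the
signature of a fate that exists only in an intermediate energy window.
`attractor_count_grid()` tiles a parameter plane (constitutive rate $b$,
binding strengths, cooperativity, or energy) with such counts;
`monostability_threshold()` extracts, per parameter value, the energy below
which only a single fate exists.

Default landscape resolutions are $31 \times 26$ nodes for the
$b \times A^*$ plane (and the same grids in the acceptance analyses); the
distinct-count category set is insensitive to resolution well below this,
which the tests exploit with coarser grids. Attractor counting is exact at
each node, so grids are embarrassingly parallel in structure and
deterministic by construction.

## Transition distances

Fate switching is quantified geometrically: the minimum Euclidean
perturbation in $(x_1, x_2)$ that moves the system from one extreme
attractor into the basin of the other. `assign_roles()` names the extreme
attractors `high_x1` / `high_x2` (argmax of $x_1 - x_2$ and its mirror,
ties broken towards larger $x_1$), a `near_zero` attractor when the
smallest attractor satisfies $x_1 + x_2 < 0.05\, x_{\max}$, and
`intermediate` otherwise. `transition_distance()` returns the minimum of

* the **direct** route: shortest distance from the `high_x1` point into the
  `high_x2` basin, and
* the **indirect** route: into a non-extreme basin, relaxing to that
  attractor point, then from there into the `high_x2` basin, minimised over
  all non-extreme attractors (both `intermediate` and `near_zero` qualify
  as stepping stones; an optional flag also scores two-hop routes in
  four-attractor landscapes).

Point-to-basin distances are first taken over labelled basin-map cells
(overestimating by at most one cell diagonal), then refined by bisection
along the segment to the best cell, localising the basin boundary to
$10^{-4}$; the tests verify the refined distance never exceeds the cell
minimum and lies within a diagonal of it. The metric is undefined for
monostable landscapes — a single-fate system cannot transition — and the
functions refuse rather than return a default.

## Scenarios as synthetic study conditions

`builtin_scenarios()` encodes the canonical parameter regimes: the default
tristable fine sweep, the $b \times A^*$ landscape at $a = 1$, the panel
series over conditional-promoter activity $a \in \{0.25, 0.5, 1, 1.5, 2,
3\}$, cooperativity $n = 1 \ldots 4$, binding-strength scans, the shifted
external-ATP variant, the high-$a$ re-entrance scan over
$a \in \{1.5, 2, 2.5, 3\}$, and transition-difficulty grids. Where the
literature prints exact values (the default parameter set, the sigmoid
constants, the axis ranges, the $5\times10^{-3}$ sweep step) the scenarios
use them; where it does not (the panel $a$ values, $\theta$ scan ranges,
the shifted-model floor/ceiling), representative values are fixed once and
the scenario's provenance note says `"guessed"`, so downstream analyses can
never silently depend on a guess. `random_params()` supplies seeded
log-uniform parameter draws spanning the studied ranges ($a, b \in [0.1,
3]$, $k \in [0.2, 2]$, $\theta \in [0.1, 1.5]$, $n \in \{1,\dots,4\}$) for
property tests.

What this synthetic setting emulates is the deterministic skeleton of the
decision landscape: counts, basins and distances of the mean-field ODE
model. What it does **not** emulate: stochastic gene-expression noise (no
fluctuation-driven switching, no residence times), mRNA-level dynamics,
energy-dependent degradation, or interactions beyond the two-gene motif.
Passing tests therefore certify the geometry of the deterministic model,
not quantitative behaviour of any particular biological cell.

## Numerical choices and degenerate inputs

* Residual acceptance $10^{-9}$; Newton works to $10^{-11}$ internally.
* Dedup tolerance $10^{-5}$, attractor matching $10^{-3}$ — separated by
  orders of magnitude from both root accuracy ($\sim 10^{-11}$) and
  attractor spacing ($\gtrsim 10^{-1}$), so no plausible perturbation flips
  a classification.
* Hill activation at $x = 0$ is defined as its limit 0 for every
  $n \ge 1$; its derivative there is 0 for $n > 1$ and $a/\theta_a$ for
  $n = 1$, removing the $0/0$ ambiguity.
* $\lambda = 0$ collapses the dynamics to pure decay; the solver and
  integrator handle it (single attractor at the origin, eigenvalues
  $-k_i$).
* Exactly at a fold bifurcation a root is marginal; the
  stability-threshold rule labels it unstable, deterministically.
* Ties in role assignment break towards larger $x_1$; degenerate geometry
  (extremes coinciding with $\ge 2$ attractors) raises an error rather
  than guessing.

## Known limitations

* Counts at a grid node are exact, but a category occupying a region
  thinner than the grid spacing can be missed between nodes; the canonical
  resolutions were chosen so the reported category sets are stable under
  refinement.
* The basin-cell + bisection transition distance refines only along the
  segment to the best cell; for extremely convoluted basins the true
  nearest boundary point could be off-segment, bounded in error by one
  cell diagonal.
* The multistart solver offers no formal completeness guarantee for root
  sets (no interval arithmetic); the trajectory-limit oracle test guards
  against missed stable roots across random parameter draws.
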