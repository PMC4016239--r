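---
title: "Predicting mutant fluxes from the near-optimal growth region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mutant fluxes from the near-optimal growth region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoflux)
```

## The model and its assumptions

Constraint-based metabolic modelling treats a cell's metabolism as a flux
vector $f$ over the reactions of a stoichiometric reconstruction. At steady
state every internal metabolite is balanced, $S f = 0$, and each flux is
boxed by thermodynamic and media constraints, $b_L \le f \le b_U$
(mmol·gDW⁻¹·hr⁻¹ throughout). Flux balance analysis (FBA) predicts behaviour
by maximising the biomass flux $f_{\mathrm{GROWTH}}$ over this polytope;
minimisation of metabolic adjustment (MOMA) predicts a knockout's behaviour
as the Euclidean projection of a wild-type flux vector onto the mutant's
polytope.

Both baselines pin the wild type to a *single* flux vector, although the
growth optimum of a genome-scale model is massively degenerate: many flux
configurations support the same, or nearly the same, growth. This package's
central objective instead represents the wild type by its **near-optimal
region**

$$
P(\alpha) = \{\, p : S p = 0,\; b_L \le p \le b_U,\;
             p_{\mathrm{GROWTH}} \ge \alpha \, \hat f_{\mathrm{GROWTH}} \,\},
$$

all flux vectors supporting at least a fraction $\alpha$ of the maximal
growth $\hat f_{\mathrm{GROWTH}}$, and predicts the mutant flux vector $q$
as the point of the mutant polytope $Q$ (the same constraints plus the
knockout bounds $b'_L \le q_{\mathrm{MUT}} \le b'_U$, intersected with the
base bounds) closest to that region:

$$
\min_{p \in P(\alpha),\, q \in Q} \; \lVert p - q \rVert .
$$

Both polytopes are convex and the objective is convex, so the minimum is
global. A minimum distance of zero is *diagnostic*: it occurs exactly when
the mutant's own growth optimum still clears the threshold
$\alpha \hat f_{\mathrm{GROWTH}}$, i.e. the polytopes intersect.
`pseudo()` detects this case with an exact linear-programming test on the
mutant optimum before any quadratic solve; `overlap_check = FALSE` forces
the full solve, which the test-suite uses to confirm the two routes agree.

The biological reading: regulation steers fluxes toward the near-optimal
cloud but tolerates free variation inside it. The knockout prediction is
then the *smallest* adjustment that returns the perturbed network to the
boundary of that cloud — not to one arbitrary optimal vertex.

## Two formulations, one optimum

Stacking $z = (p, q)$ turns the squared objective into
$z^\top \bigl[\begin{smallmatrix} I & -I \\ -I & I \end{smallmatrix}\bigr] z$,
a positive-semidefinite quadratic form whose eigenvalues are only 0 and 2
(the test-suite checks this numerically), over block-diagonal mass-balance
equalities. Alternatively, introducing $x = p - q$ and a scalar
$z_{\mathrm{DIST}}$ constrained to the quadratic cone
$z_{\mathrm{DIST}} \ge \lVert x \rVert$ yields a second-order-cone program
whose optimum *is* the distance, square-root free. `pseudo()` exposes both
(`formulation = "qp"` or `"socp"`); they must and do agree — the acceptance
suite requires $10^{-6}$ relative agreement on every fixture. The threshold
$\alpha$ is one parameter shared by both formulations.

## Solver design

The three problem classes sit behind a small backend
(`solve_lp()`, `solve_qp()`, `solve_socp()`) so the science modules never
depend on a particular solver.

* **Quadratic programs** are solved by a proximal-point outer loop around a
  dual active-set inner solver. Each prox step minimises the strictly
  convex $x^\top Q x + c^\top x + \rho\lVert x - x_k\rVert^2$; the fixed
  points of that map are exactly the minimisers of the original program,
  so the loop converges for the singular distance matrix as well as for
  strictly convex projections. $\rho$ (default $10^{-6}\times$ the
  spectral scale) escalates tenfold whenever the inner solver rejects a
  degenerate face; any positive value is correct, larger values merely
  condition better.
* **Linear programs** use the same machinery: for a polyhedral objective
  the proximal iteration — project $x_k - t\,c$ back onto the feasible
  polytope — terminates at an exact optimum in finitely many steps. The
  step $t$ adapts downward when projecting from far away lands on a
  degenerate face. Infeasibility is declared only after projections from
  several distinct starts fail.
* **The conic form** is solved as a smooth epigraph problem (minimise $z$
  subject to $\lVert p - q\rVert - z \le 0$ plus the linear constraints)
  with sequential least-squares quadratic programming. The cone gradient
  is smooth wherever $p \ne q$; the overlapping case never reaches this
  solver because the LP pre-check catches it.
* Variables pinned by their bounds (knockouts, the maintenance flux) are
  substituted out before every solve; this keeps the active-set inner
  solver away from zero-width intervals, its one systematic weakness.

Numerical guards worth knowing: growth floors derived from an LP optimum
are backed off by a relative $10^{-9}$ (the optimum itself carries a
$\sim 10^{-12}$ constraint residual, so "at least 100% of optimal" would
otherwise be empty); the parsimonious pass retries its growth pin across
the same ladder; `overlap_epsilon` ($10^{-6}$ distance units, the solver
tolerance scale) decides when a computed distance counts as overlap.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.90 | fraction $\alpha$ of maximal growth defining the near-optimal region |
| `default_bound` | 1000 | magnitude for otherwise unbounded fluxes; keeps every polytope bounded |
| `overlap_epsilon` | 1e-6 | distance below which the degenerate overlap case is declared |
| lethality cutoff | 0.05 | growth fraction below which a knockout is called lethal |
| `n_samples` | 3000 | points drawn from the near-optimal region |
| `target_mixed_fraction` | 0.53 | mixing diagnostic at which collection starts |

The 0.90 threshold is the headline default: reported growth variability of
metabolic mutants suggests real metabolism tolerates roughly this much
slack, and `threshold_sweep()` shows predictions are stable across
0.80–0.99 (distance is monotone in the threshold — nested regions — which
the sweep checks). Thresholds at or above 0.999 draw a warning: the region
collapses toward the optimal face and becomes numerically hostile.

The bundled `media_iaf1260_glucose()` preset carries the standard aerobic
minimal-glucose configuration for the iAF1260 *E. coli* reconstruction:
glucose uptake 8, oxygen 18.5, non-growth ATP maintenance 8.39 (all
mmol·gDW⁻¹·hr⁻¹) and growth-associated ATP 59.81 mmol·gDW⁻¹ (metadata; it
enters through the biomass equation). Other nutrients stay "available in
excess", i.e. at the default bound.

## Wild-type reference and secondary objectives

FBA and MOMA conventionally receive a 1-norm secondary pass:
`parsimonious_pass()` minimises $\sum_i |f_i|$ at fixed growth, encoded
exactly as an LP by splitting each flux into non-negative parts. This
removes futile-cycle flux and picks a reproducible representative from the
optimal face; the MOMA reference defaults to this parsimonious FBA vector.
No secondary objective is applied to the polytope-distance solution: its
$(p, q)$ pair can itself be non-unique at the same distance (the
`distance_degenerate_possible` flag, available via
`detect_degenerate = TRUE`, re-solves from a second start to probe this),
and the package deliberately reports the solver's point rather than
imposing an undocumented tie-break.

## Sampling the near-optimal region

`achr_sample()` draws approximately uniform points from $P(\alpha)$ with
artificially-centered hit-and-run. Warmup points are LP optima of random
unit directions — extreme vertices of the region. Chains then move along
directions of the form (random stored point − running centre), stepping
uniformly on the feasible chord. Two implementation choices matter:

* Chains live in *chart coordinates*: an anchor point plus an orthonormal
  basis of directions that keep both $S x$ and every pinned flux
  invariant. Every reconstructed sample is mass-balanced to machine
  precision by construction, with no projection/clamping feedback that
  could accumulate drift.
* Convergence is monitored with the **mixed fraction**: warmup points are
  split at the median of a flux with genuine spread (vertex clusters that
  sit exactly on the median are split mid-range instead, otherwise
  floating-point noise would assign their sides), and the fraction of
  chains now on the opposite side of their starting label approaches 1/2
  at equilibrium. Collection starts once it reaches 0.53.

Defaults: 50 warmup chains (or twice the null-space dimension if larger),
3000 samples, `thin = 1`. Consecutive sweeps are autocorrelated; analyses
that assume independent draws (e.g. two-sample distribution tests) should
thin (`thin = 5` in the test-suite) or use batch-means standard errors, as
the test-suite does for its moment checks. Per-flux summaries report the
coefficient of variation CV = σ/mean, left `NA` where |mean| is below
`cv_epsilon` rather than dividing by noise.

## Carbon accounting

`carbon_partition()` traces consumed carbon (uptaking exchanges weighted
by the carbon count of their metabolite, parsed from Hill-style formulas)
into three fates: biomass (growth flux × net carbon consumed by the
biomass equation), CO₂ (exchanges of metabolites with formula `CO2`;
the set is overridable, e.g. to count bicarbonate), and secreted organic
carbon (all other positive carbon-carrying exchanges). On a
carbon-balanced model the three fates sum to consumption — the acceptance
suite demands a $10^{-6}$ relative residual. The secreted-metabolite
profile applies a floor of $10^{-6}$ mmol·gDW⁻¹·hr⁻¹ so solver dust does
not inflate the count of secreted species; the floor is a parameter.

## Comparison statistics

`compare_predictions()` evaluates several prediction methods against one
measured flux table: Pearson and Spearman correlations with Fisher-z
standard errors $1/\sqrt{n-3}$; the Meng–Rosenthal–Rubin Z-test for two
dependent correlations sharing the measured variable (the variant for one
shared variable, with the redundancy correction capped at 1 — validated
against an independently coded oracle to $10^{-10}$); and seeded
percentile-bootstrap confidence intervals for the mean signed prediction
error (bias) and the mean absolute error, resampling flux rows. Coverage
of the 95% intervals is checked empirically over 200 synthetic replicates
in the acceptance suite.

## What the synthetic networks do and do not show

`make_toy_model()` builds carbon-balanced networks — glucose enters, $k$
parallel pathways convert it to a one-carbon biomass precursor plus CO₂ at
configurable yields, with optional secretion routes and futile cycles — for
which the growth optimum ($\text{uptake} \times \max \text{yield}$),
variability ranges, and knockout classes (neutral / yield-reducing /
lethal) are known in closed form. The test-suite validates every solver
against enumeration oracles on these fixtures (vertex enumeration for
growth; brute-force active-set projection and alternating exact
projections for the distances), at sizes of at most 8 reactions, where
enumeration is exact and fast.

These networks emulate the *geometry* that matters to the method —
degenerate optima, redundant pathways, secretion trade-offs, threshold
overlap — but not the scale, the cofactor/energy coupling, or the
gene-to-reaction complexity of a genome-scale reconstruction. Passing
tests therefore certify the optimisation and sampling machinery, not the
biological accuracy of any particular reconstruction; applying the package
to a real model (e.g. iAF1260 in SBML or COBRA JSON, with the bundled
media preset, parsimonious reference and threshold 0.90) exercises exactly
the same code paths but larger problem instances.

## Known limitations

* The interior solvers are dense; they are comfortable at the tested
  scale and at the few-thousand-reaction scale will be slow. The backend
  contract is the extension point for a sparse or compiled solver.
* Hit-and-run convergence is *monitored*, not proven; the mixed fraction
  is a practical diagnostic and the step cap errs loudly rather than
  returning an unmixed sample.
* Gene knockouts require gene–protein–reaction rules; models without them
  accept only reaction-level mutations, and the boolean-evaluation
  convention (and = all required, or = alternatives, all listed deletions
  absent jointly) is this package's choice.
* Growth ordering (MOMA ≤ distance-prediction ≤ FBA) is tested across the
  whole fixture suite but not asserted as a theorem.
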