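---
title: "Complex-balanced flux prediction: model, algorithms, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complex-balanced flux prediction: model, algorithms, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbfba)
```

## The model

A metabolic network with $m$ metabolites and $r$ irreversible reactions is
described by its stoichiometric matrix $S \in \mathbb{R}^{m \times r}$.
Steady-state flux distributions are the vectors $v$ with $S v = 0$ and
$v_{\min} \le v \le v_{\max}$; bounds come from thermodynamics, capacity
caps, and measured uptake/secretion/growth rates.

Chemical reaction network theory views the same network through its
*complexes*: the left- and right-hand sides of reactions, each a
non-negative combination of metabolites. Every reaction is then a directed
edge from its substrate complex to its product complex, and $S$ factors as

$$ S = Y A, $$

where $Y \in \mathbb{R}_{\ge 0}^{m \times c}$ holds the stoichiometry with
which metabolites enter the $c$ complexes and
$A \in \{-1, 0, 1\}^{c \times r}$ is the incidence matrix of the complex
graph (one $-1$ and one $+1$ per column). `decompose()` constructs this
factorization by scanning reaction columns: negative entries form the
substrate complex, positive entries the product complex, and identical
sides are shared between reactions. All exchange reactions meet in a single
*empty* complex, the environment node `O`. A reaction whose two sides
coincide carries no net transformation; it is excluded from the complex
graph with a warning (its incidence column is zero, so $S = YA$ still holds).

The *activity* of complex $i$ under a flux distribution $v$ is
$A_{i\cdot} v$: total influx minus total outflux at that node of the
complex graph. A complex is *balanced* when its activity is zero — either
for one particular distribution (`balanced_in_distribution()`), or across a
whole flux space (`balanced_over_space()`, which bounds each activity with
two LPs). Because $S v = Y (A v)$, metabolite balance is implied by complex
balance; balanced complexes encode dependencies that tie several reactions
together beyond what single metabolite balances require.

Two structural facts the package exploits and tests:

* a metabolite occurring in exactly one complex forces that complex's
  activity to equal the metabolite's steady-state balance, hence the
  complex is balanced in *every* steady state (the basis of
  `planted_balanced_network()`);
* a complex with only incoming or only outgoing reactions can never be
  balanced in a strictly positive flux distribution
  (`structurally_never_balanced()`).

## Objectives

Two L1 objectives over the same steady-state box are implemented:

* **cbFBA** (`solve_cbfba()`) minimizes the total absolute complex
  activity $\sum_{i=1}^{c} |A_{i\cdot} v|$. Zero terms in this sum are
  balanced complexes, so the minimization is a convex surrogate for
  maximizing their number (the exact count is an $\ell_0$ objective and not
  tractable as an LP).
* **pFBA** (`solve_pfba()`) minimizes total flux $\sum_j |v_j|$, the
  parsimony baseline. On split networks all fluxes are non-negative, so the
  objective is a plain sum.

Absolute values are linearized with auxiliary variables
($t_i \ge \pm A_{i\cdot} v$, objective $\sum_i t_i$), keeping every stage a
linear program; minimization drives $t_i$ to $|A_{i\cdot} v|$ at the
optimum. The growth phenotype is *constrained from data* (scenario tables),
not maximized: both objectives are asked which flux routing supports an
observed phenotype, and they answer differently. On the bundled toy network
the demand can be met either by a short high-activity route or by a longer
routing whose complex activities cancel entirely; pFBA picks the first,
cbFBA the second, which is exactly the behavioural contrast the fixture is
designed to exhibit.

## Preprocessing

`split_reversible()` replaces each reversible reaction by a forward and a
reverse irreversible copy (net flux = forward − reverse;
`merge_split_fluxes()` inverts the map). `apply_scenario()` intersects
model bounds with measured bounds; `prune()` then iterates two reductions
to a fixed point for that scenario: dead-end metabolites (no producer or no
consumer) leave together with their reactions, and blocked reactions
(maximum attainable flux below the activity threshold, one LP each) are
dropped. Reactions with strictly positive lower bounds encode measurements
and are never pruned. Pruning is per scenario because blocked status
depends on the bounds in force.

## Fixed-optimum variability and sampling

With the optimal budget $z$ in hand, `fva()` computes per-reaction flux
ranges subject to the objective held at its optimum, and `sample_fluxes()`
draws flux distributions from the optimal face: each sample is the
Euclidean projection (a convex QP) of a componentwise-uniform random point
in the flux box onto the constraint set. The "budget" constraint is
implemented as $\le z(1+\tau)$ rather than $= z$: the optimum is the
minimum of the constraint set, so the lower side is automatic, and exact
equality is numerically brittle. When $z$ is indistinguishable from zero
the budget is imposed instead as the exact equality $A v = 0$, which is
both tighter and better conditioned than an empty-interior inequality.

All draws for a sample set are generated up front from one integer seed,
so results do not depend on the order in which projections are solved and
identical seeds give bitwise-identical sample sets. The uniform law on the
box is a deliberate, simple choice; the draw distribution only shapes how
the optimal face is explored, and any density supported on the box could be
substituted.

## Evaluation statistics

Given experimentally estimated fluxes with confidence intervals (e.g. from
carbon-13 metabolic flux analysis), the package computes the comparison
surface that a prediction-vs-measurement study needs: active/blocked
concordance with sensitivity, specificity and accuracy
(`classify_active()`, `confusion_metrics()`); closed-interval overlap of
predicted and measured ranges (`range_overlap()`); a taxonomy of how pFBA
ranges relate to cbFBA ranges (`categorize_ranges()`); Pearson correlation
of log10 fluxes over jointly active reactions (`log_flux_correlation()`);
a per-reaction location test of sampled fluxes against the measured mean
with Benjamini–Hochberg adjustment (`mean_difference_test()`); regression
outliers in log-log space flagged at twice the residual scale
$s = \sqrt{\sum (\hat y - y)^2 / (n-2)}$ (`detect_outliers()`); and the
Euclidean metabolic-adjustment distance between paired sample sets
(`metabolic_adjustment()`), the quantity behind
minimization-of-metabolic-adjustment arguments. `subsystem_summary()`
aggregates range widths per pathway label; it deliberately stops at
grouping and computes no enrichment p-values.

The location test is one design decision among several defensible ones: a
one-sample two-sided t-test per reaction, BH-adjusted across reactions,
with zero-variance sampling distributions compared by absolute tolerance
instead and flagged as degenerate. Rank-based alternatives would also be
reasonable; the t-test was chosen because sampled flux distributions are
bounded and well-behaved, and the test is calibrated in the suite against
null simulations.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `epsilon` | 1e-6 | mmol gDW⁻¹ h⁻¹ | activity threshold for calling a complex balanced |
| `blocked_tol` / `threshold` | 1e-6 | mmol gDW⁻¹ h⁻¹ | flux below this is "blocked"; same scale as `epsilon` so balance and activity classifications cannot drift apart |
| `tau` | 1e-6 | relative | slack on the optimal budget in FVA/sampling |
| `default_bound` / `cap_bound` | 1000 | mmol gDW⁻¹ h⁻¹ | finite cap for missing/unbounded fluxes; the sampler needs a finite box to draw from |
| `n` | 1000 | — | flux samples per condition |
| `fdr_level` | 0.05 | — | BH level for the mean-difference test |
| `trim` | 0.05 (distances), 0 (fluxes) | — | trimmed-mean fraction for robust means |

## Numerical choices

Every optimization stage is a small dense LP or QP. LPs are solved with
`pracma::linprog` and audited (equalities, bounds, and inequality residuals
re-checked on the returned point); when that solver's big-M path fails —
which happens on degenerate instances where many absolute-value
linearization rows are active at zero — the package falls back to its own
two-phase primal simplex (`R/simplex.R`) with Dantzig pricing and an
automatic switch to Bland's rule to rule out cycling. The fallback exists
because no robust LP interface is otherwise available to the package, and
it is exercised directly by the test suite against an exhaustive
enumeration oracle and by fuzzing against the primary solver.

Projections eliminate the equality constraints first (null-space
parameterization, with fixed variables promoted to equality rows and
redundant rows dropped by QR rank detection) and hand `quadprog` a strictly
positive-definite reduced Hessian; inequality rows whose normal vanishes in
the reduced space are checked for consistency and dropped. Auxiliary
absolute-value variables enter the quadratic objective only through a
1e-8 ridge so the Hessian stays positive definite without noticeably
perturbing the projection.

Complex identity during decomposition uses exact coefficient comparison
with relative tolerance 1e-9, so integer stoichiometries decompose exactly
while fractional (biomass-style) coefficients still merge correctly. Range
category ties use 1e-9. Steady-state feasibility is accepted at
$\|S v\|_\infty \le$ 1e-6 for user-supplied vectors and achieved at
better than 1e-9 by the solvers themselves.

## The synthetic generator

`random_network()` builds networks that are feasible by construction:
metabolites are partitioned into complexes (plus extra complexes that
re-use already-placed metabolites, plus the empty environment complex), and
reactions are laid down as one closed walk through the complex pool. The
all-ones flux vector is then an exact steady-state witness, and small
integer stoichiometry keeps the decomposition exact. The extra overlapping
complexes matter: if complexes partition the metabolites, the null space of
$S$ equals that of $A$, every steady state is a circulation of the complex
graph, and the minimal total activity is trivially zero. Shared metabolites
couple complex activities the way real networks do and give the cbFBA
objective something to trade off.

What the generator does *not* emulate: genome-scale degree distributions,
cofactor coupling, compartments, or biomass-style reactions with hundreds
of fractional coefficients. Passing tests on these networks therefore
demonstrates correctness of the algorithms (decomposition, optimization,
classification, sampling) — not that cbFBA's biological premise holds on
any particular organism; that question needs real models and measured
fluxes, which the evaluation module is built to consume.

`planted_balanced_network()` plants ground truth for the balance screen:
chain intermediates occur in exactly one singleton complex each (balanced
over the whole cone, by the structural argument above), and one branch
produces a two-metabolite complex with only incoming reactions (never
balanced in a positive distribution). Recovery of the planted set with zero
structural false positives is part of the acceptance battery.

## Problem sizes in the test and acceptance suites

The suites run on the nine-reaction toy fixture, on 100 random networks of
4–9 metabolites and 6–10 reactions for the decomposition properties, on
twelve networks of at most 8 reactions for the enumeration oracle (the
oracle is exponential in the degrees of freedom, which caps its reach), on
50 planted-structure seeds, on 1000 sampler projections, and on 1000 null
reactions (25 replicates × 40 reactions) for the false-discovery
calibration. These sizes were chosen so that each property is exercised
well past its edge cases while the whole battery stays interactive.

## Known limitations

* Dense linear algebra throughout: genome-scale models (thousands of
  reactions) are outside the intended envelope of the bundled solvers.
  The module boundaries (solver layer vs. formulations) are drawn so a
  sparse LP/QP backend could be substituted without touching the science.
* The SBML layer covers the constraint-based subset (species, reactions,
  stoichiometry, fbc or COBRA-style bounds, subsystem notes); gene
  associations, compartment semantics, and unit definitions are ignored.
* `balanced_over_space()` certifies balance with two LPs per complex at
  tolerance `epsilon`; complexes whose activity range straddles zero but
  exceeds `epsilon` on either side are correctly reported unbalanced, but
  no attempt is made to distinguish "identically zero" from "zero-crossing"
  ranges.
* The mean-difference procedure tests location only; shape differences
  between sampled and measured flux distributions are not assessed.
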