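---
title: "Chance-constrained strain design under flux-capacity uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chance-constrained strain design under flux-capacity uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainopt)
```

## The model

Constraint-based strain design works on a stoichiometric network: `N`
internal metabolites, `M` reactions, the matrix `S` of stoichiometric
coefficients, and the steady-state assumption `S v = 0`. Reversible
reactions are split into irreversible forward/backward components before
any optimization (`split_reversible()`), so all fluxes are nonnegative;
the forward component keeps the original identifier and the backward
component gets the suffix `_b`.

An engineering intervention — up- or down-regulating the gene behind a
reaction — changes that reaction's flux *capacity*, the upper bound its
enzyme level imposes. The package's central assumption is that this change
is a random event: the realized fold-change in enzyme activity follows a
distribution, and so does the resulting capacity. A design should therefore
be judged not by a single predicted flux but by the probability of reaching
it.

Writing `y_j^u, y_j^d ∈ {0,1}` for the decision to up-/down-regulate
reaction `j`, the capacity constraint becomes a chance constraint: the flux
must respect the (random) modified bound with probability at least
`1 − ε`. Because each constraint involves exactly one random variable at a
time (`y_j^u + y_j^d ≤ 1`), each chance constraint has an exact
deterministic equivalent obtained by replacing the random capacity with its
`ε`-quantile. The full program CCOpt then maximizes
`v_target − α Σ (y^u + y^d)` subject to steady state, a minimal-biomass
viability constraint (`v_biomass ≥ f · v_biomass^max`, default `f = 0.01`,
skipped when no biomass reaction is designated), quantile-substituted
capacity bounds, reference lower bounds `v_j ≥ SSL_j (1 − y_j^d)`, the
intervention budget `L`, per-reaction up/down exclusivity, and split-pair
exclusivity (a reversible reaction's two components may not both be
up-regulated, nor both down-regulated). DetOpt is the same program at
`ε = 0`; MCOpt replaces the quantiles with independent draws and repeats;
MCEval fixes the intervention set and repeats plain FBA under draws.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `eps` | confidence parameter; each capacity bound holds with probability ≥ 1 − eps | 0.1 | conservative; 0.25 is a common relaxed choice |
| `L` | maximum number of interventions | 1 | smallest nontrivial budget |
| `alpha` | per-intervention objective penalty (flux units) | `1e-4 ×` wild-type target optimum (or 1 if that is 0) | keeps the penalty well below any flux improvement of interest while still breaking ties toward smaller sets; must satisfy `alpha · L <` smallest improvement you care about |
| `biomass_fraction` | viability floor as a fraction of the wild-type maximal biomass flux | 0.01 | minimal-viability convention |
| up fold-change `mu`, `delta` | mean and spread (`= 6σ`) of the enzyme activity fold-change after over-expression (dimensionless) | 6 and 8 | typical mammalian over-expression magnitudes; the spread keeps the worst case `mu − delta/2 = 2` above 1, so an up-regulated enzyme never lands below its unmodified activity |
| down fold-change `mu`, `delta` | as above, after knockdown | 0.5 and 1 | support `[0, 1]`: a knockdown at worst abolishes and at best preserves activity |
| `h` | power-law exponent linking enzyme fold-change to mode-coefficient scaling in ECF | 1 | the linear case; exposed because the power-law family is the modeling assumption, not a fitted value |

## Distributions and their numerics

Fold-change distributions are normals truncated to
`[mu − delta/2, mu + delta/2]` and renormalized, with `sigma = delta/6`.
Truncation is a deliberate modeling decision, not a numerical convenience:
the worst-case optimizer DetOpt needs the capacity's *minimum* to exist,
which an unbounded normal does not provide, and a bounded fold-change is
also the physically sensible reading of "spread". With `delta → 0` the
distribution degenerates to a point mass (handled explicitly; quantiles and
draws all return `mu`).

Kinetic capacities scale the fold-change by `v_max`, so capacity quantiles
are closed-form compositions of the normal CDF/quantile. Quantiles at 0 and
1 return the exact support endpoints. Empirical capacities (from ECF) use
linear interpolation of the empirical CDF across order statistics with the
endpoints pinned to the sample minimum/maximum — again so that `ε = 0` is
well defined. A configurable floor (default 100) rejects samples too small
to drive an optimization.

One asymmetric rule: a *down*-quantile (or down-draw) larger than the
unmodified bound `SSU_j` is capped at `SSU_j`, in CCOpt, MCOpt and MCEval
alike. A down-regulation models a knockdown; whatever the sampled
fold-change, it must not *raise* the capacity above the unmodified state.
Up-quantiles are not capped: at small `ε` an up-regulation whose worst case
sits below `SSU_j` genuinely lowers the bound, and the optimizer correctly
learns to leave such reactions alone.

## Reference state and v_max completion

`estimate_reference_state()` computes `SSU_j`/`SSL_j` as the LP maximum and
minimum of each flux over `{S v = 0, 0 ≤ v ≤ v_max, v_k = measured_k}`
(flux variability analysis with measurements pinned). A relative
`measurement_tol` (default 0, i.e. exact equality) is exposed because real
exchange measurements can be slightly inconsistent with exact mass balance.
The wild-type biomass maximum is computed *without* the measurement
constraints: the viability floor refers to the theoretical capability of
the unmodified network, not to the observed operating point.
`complete_vmax()` fills in missing maximal velocities as the largest flux
the known `v_max` set permits through each unannotated reaction, and errors
by name when no known cap reaches a reaction (an unbounded completion would
silently disable that capacity constraint).

## Elementary modes and the ECF capacity estimator

For stoichiometric models without kinetic data, capacities come from
elementary flux modes. `enumerate_ems()` implements the double-description
(tableau) method on the irreversible cone: starting from the identity rays,
each mass-balance row is processed in turn, keeping rays in its null space
and combining adjacent positive/negative pairs (adjacency tested via
zero-set inclusion). Modes are normalized to maximum entry 1,
deduplicated, ordered lexicographically by support, and futile two-cycles
supported exactly on a forward/backward split pair are removed.

The reference data constrain the elementary-mode coefficients `λ` to the
polytope `{λ ≥ 0, SSL ≤ E λ ≤ SSU, (E λ)_k = measured_k}`. This problem is
underdetermined in general, so flux questions are answered as LP ranges
over the polytope. **A design note worth flagging prominently:** the
enzyme-control-flux literature describes an iterative scheme for choosing
reference mode coefficients. This package does not reproduce any specific
iteration; it replaces that step with the explicit LP-over-polytope
formulation above, which directly realizes the range-of-flux semantics the
method needs and is exact for the maximal-flux question the capacity
estimator asks. The power-law adjustment then rescales, by `a^h`, the
coefficient of every mode whose support contains the modified reaction
(`a` the sampled fold-change), leaving other modes untouched, and the
capacity draw is the adjusted maximal flux of the modified reaction.
Modifications are applied one enzyme at a time, matching the per-reaction
repetition of the estimation procedure; simultaneous multi-enzyme
adjustment would require assumptions about interaction that the power-law
model does not supply.

## Solving the MILP

No linear-programming package is available in this environment's R stack,
so `R/lp.R` carries a dense two-phase primal simplex (Dantzig pricing with
a Bland's-rule fallback engaged after a stall, explicit infeasible and
unbounded statuses, feasibility/optimality tolerance `1e-9`, values below
`1e-9` reported as 0). The MILP over the binary `y` variables is solved by
depth-first branch-and-bound on the LP relaxation: branch on the most
fractional binary, explore the `y = 1` child first (interventions that look
useful fractionally usually are), prune on the relaxation bound, accept
integral solutions at tolerance `1e-6`, and after the search re-verify the
rounded binaries against every bound constraint. The search returns a
single global optimum; when several intervention sets tie, which one is
returned depends on search order, so tests compare objectives rather than
sets except on fixtures constructed to have a provably unique optimum.

Monte-Carlo reproducibility follows one regime everywhere: a master seed
spawns one RNG substream per sample, and within a sample draws are ordered
by reaction id (up before down). Results are therefore independent of the
iteration order of the eligible set, and any single sample can be replayed
from its substream seed.

MCEval counts infeasible samples (possible when an extreme down-draw
starves the viability constraint) and excludes them from percentiles while
reporting the count — silently dropping them would bias the summary
invisibly. Percentiles use the below/above counting rule — the lower
percentile is the smallest sample value with at least 5% of the data at or
below it, the upper the largest with at least 5% at or above — rather than
interpolation, so a degenerate distribution reports identical 5th and 95th
percentiles, which is the informative answer when every draw hits the same
bottleneck.

## What the synthetic fixtures do and do not show

The generators build three families: linear chains with one planted
bottleneck (`make_linear_fixture()`; the three-reaction instance with
bounds (30, 5, 30) recurs throughout the tests because every quantity on
it is computable by hand), branched networks whose target branch has two
reactions in series so that no single intervention can help
(`make_branched_fixture()`), and randomized small networks mixing chains,
drains, reversible splits, positive lower bounds and optional biomass
designations (`make_random_fixture()`). Chains and branches are
deterministic given their arguments — the planted algebra must be exact —
while the random family is fully determined by its seed.

These fixtures exercise every constraint type of the MILP and make
exhaustive enumeration (`brute_force_optimum()`) feasible, which is the
package's strongest correctness evidence: the branch-and-bound agrees with
enumeration over all valid intervention sets, LP by LP. What passing these
tests does *not* show: behavior on genome-scale networks (the fixtures
have at most ~8 reactions; elementary-mode enumeration in particular is
exponential and intended for models up to roughly a hundred reactions),
realistic kinetic structure (capacities here are linear in `v_max` by
construction), or correlated uncertainties — capacities are sampled
independently per reaction and direction, as the underlying model assumes.

Problem sizes in the shipped tests and acceptance script (20 random
fixtures for oracle agreement; 10^4 evaluation samples; 10^3 sampling
optimizations) were chosen so the distributional checks are stable to
about a percentile point while the whole suite stays fast to run.

## Known limitations

- Elementary-mode enumeration is exact but exponential; genome-scale
  models need the kinetic route (possibly with `complete_vmax()` over
  FBA-derived caps) instead.
- Interventions are reaction-level; gene–protein–reaction mappings,
  isozymes and operon effects are out of scope.
- The optimizer returns one global optimum, not the set of alternate
  optima; enumeration of ties would need integer cuts.
- The split-pair exclusivity constraint forbids up+up and down+down on a
  forward/backward pair, as specified; up-regulating one component while
  down-regulating the other remains permissible, a deliberate reading of
  the constraint as stated.
- The biomass viability constraint is a floor, not a coupled objective; a
  growth-coupled (bi-level) formulation is intentionally not provided.
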