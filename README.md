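# strainopt

Strain-design optimization for constraint-based metabolic models when the
outcome of an enzyme modification is uncertain.

## The problem

Computational strain design picks a small set of reactions whose enzymes
should be up- or down-regulated so that a target flux (a secreted product, a
biosynthetic rate) is maximized while the cell stays viable. In practice a
gene-expression modification never lands exactly on its intended level:
over-expression of an enzyme might raise its activity 4-fold in one clone
and 9-fold in the next. The flux *capacity* of the modified reaction — the
upper bound its enzyme level imposes — is therefore better described as a
probability distribution than as a number.

`strainopt` treats each capacity as a random variable and offers three
optimizers over the same mixed-integer program plus an evaluation
framework:

- **CCOpt** — chance-constrained optimization. Each capacity constraint
  `v_j ≤ Cap_j` must hold with probability at least `1 − ε`; the chance
  constraint is converted to its deterministic equivalent through the
  ε-quantile `F_j⁻¹(ε)` of the capacity distribution, and the resulting
  MILP is solved to global optimality.
- **DetOpt** — the worst case, `ε = 0`: fluxes must stay below the
  *smallest* value the capacity can take.
- **MCOpt** — Monte-Carlo optimization: capacities are sampled, the
  deterministic MILP is solved per sample, and intervention sets are
  tabulated by selection frequency.
- **MCEval** — Monte-Carlo evaluation: for a *fixed* intervention set,
  repeated flux balance analysis under sampled capacities yields the
  distribution of achievable target fluxes and its probable
  (5th–95th percentile) range.

The program solved by CCOpt, for a network of `N` metabolites and `M`
irreversible reactions (reversible reactions are split into forward and
backward components first), is

```
max  v_target − α Σ_j (y_j^u + y_j^d)
s.t. Σ_j S_ij v_j = 0                                   (steady state)
     v_biomass ≥ f · v_biomass^max                      (viability, f = 0.01)
     v_j ≤ SSU_j + y_j^u (F_{j,u}⁻¹(ε) − SSU_j)
                + y_j^d (F_{j,d}⁻¹(ε) − SSU_j)          (capacity)
     v_j ≥ SSL_j (1 − y_j^d)                            (reference lower bound)
     Σ_j (y_j^u + y_j^d) ≤ L                            (intervention budget)
     y_j^u + y_j^d ≤ 1, split-pair exclusivity, y ∈ {0,1}
```

where `SSU_j`/`SSL_j` are the reference (unmodified) steady-state bounds and
`y_j^u`, `y_j^d` decide up-/down-regulation of reaction `j`.

Capacity distributions come from one of two estimators:

- **kinetic route** — when maximal velocities `v_max` are known (or
  completed by LP from a known subset, `complete_vmax()`), the capacity is
  `v_max` times a truncated-normal enzyme fold-change distribution
  (defaults: up-regulation mean 6, spread `δ = 6σ = 8`, support `[2, 10]`;
  down-regulation mean 0.5, spread 1, support `[0, 1]`);
- **elementary-mode route** — for purely stoichiometric models, all
  elementary flux modes are enumerated (`enumerate_ems()`), the reference
  data constrain the mode coefficients to a polytope, and sampled
  fold-changes are pushed through a power-law enzyme-control-flux
  adjustment to give an empirical capacity sample
  (`ecf_capacity_distribution()`).

## Worked example

A three-reaction chain (uptake → conversion → export) with flux bounds
(30, 5, 30): the middle reaction R2 is the planted bottleneck
(`v_max = 5`), carries up/down capacity distributions, and the export R3 is
the target.

```r
library(strainopt)

fx <- make_linear_fixture(3)
settings <- optimization_settings(eps = 0.25, L = 1, alpha = 0.01)

ccopt_solve(fx$model, fx$ref, fx$caps, settings)
#> optimization_result [optimal]
#>   interventions: up:{R2} down:{}
#>   v_target = 25.51755, objective = 25.50755

detopt_solve(fx$model, fx$ref, fx$caps, settings)
#> optimization_result [optimal]
#>   interventions: up:{R2} down:{}
#>   v_target = 10, objective = 9.99
```

Both methods up-regulate the bottleneck, but they promise different fluxes.
DetOpt assumes the worst outcome — a 2-fold activity gain, capacity
`2 × 5 = 10`. CCOpt at `ε = 0.25` uses the 25% quantile of the capacity
distribution (`≈ 5.10 × 5 = 25.5`): a flux it expects to reach with 75%
probability. Evaluating the design under sampled capacities shows which
promise is realistic:

```r
ev <- mceval_run(fx$model, fx$ref, fx$caps,
                 intervention_set(up = "R2"), n_samples = 10000, seed = 1)
ev
#> eval_distribution: 10000 feasible samples (0 infeasible)
#>   probable range [p05, p95] = [19.14004, 30]
```

The CCOpt prediction (25.5) sits inside the probable range; the DetOpt
prediction (10) falls below its 5th percentile — the worst-case design
systematically understates what the strain will deliver.

The same workflow runs from the shell via the installed `strainopt` script:

```sh
strainopt make-fixture --kind linear --out fx/
strainopt ccopt --model fx/model.json --refstate fx/refstate.tsv \
  --capacities fx/capacities.tsv --epsilon 0.25 --max-interventions 1 \
  --alpha 0.01 --out result.json
strainopt mceval --model fx/model.json --refstate fx/refstate.tsv \
  --capacities fx/capacities.tsv --interventions result.json \
  --samples 10000 --seed 1 --out eval.json
```

## Package layout

- `R/model_io.R` — canonical JSON/TSV/SBML model input, reversible-reaction
  splitting
- `R/capacity.R` — fold-change and capacity distributions, reference-state
  estimation (`SSU`/`SSL` by flux variability analysis), `v_max` completion
- `R/em_ecf.R` — elementary-mode enumeration, enzyme-control-flux capacity
  distributions
- `R/optimize.R` — CCOpt / DetOpt / MCOpt (branch-and-bound MILP)
- `R/evaluate.R` — MCEval, percentile and frequency summaries
- `R/fixtures.R` — synthetic bottleneck networks and the enumeration oracle
- `R/lp.R` — the dense two-phase simplex backing every LP above
- `R/cli.R`, `exec/strainopt` — command-line interface
- `vignettes/chance-constrained-strain-design.Rmd` — methods and design
  notes
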