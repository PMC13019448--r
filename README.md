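# bstkit

Construction, simulation, and global sensitivity analysis of power-law
(S-system) models of biochemical networks — the Biochemical Systems Theory
(BST) formalism — in R.

BST represents every flux in a metabolic or regulatory network as a product
of power-law functions of the species concentrations. `bstkit` uses the
generalized matrix form of that formalism: a network of *n* dynamic
species, *m* static species (enzymes, fixed pools), and *p* reactions
evolves as

    dx/dt = S · r(x, xs) + u(t),      r_k = α_k · Π_j X_j^G[j,k]

with stoichiometric matrix **S** (n × p), kinetic-order matrix **G**
((n+m) × p), non-negative rate constants **α**, and an optional external
input **u(t)**. Kinetic orders encode regulation directly: positive =
activation, negative = inhibition, zero = no dependence. The classical
two-term S-system (one aggregate production and one consumption term per
species) is the subclass whose steady state is solvable as a linear system
in log coordinates.

The package is aimed at systems-biology and metabolic-engineering users
who want to go from a declarative pathway description to dynamic
trajectories, steady states, and parameter-importance rankings without
writing ODE code:

* **Model construction** — declarative reaction/kinetics records compiled
  to `S` and `G` (`assemble_matrices()`, `model_from_records()`), read
  from a documented TOML dialect or a plain-text BST dialect
  (`build_model()`), and serialized to a lossless JSON archive
  (`save_model()` / `load_model()`).
* **Simulation** — adaptive stiff-capable ODE integration (via `deSolve`,
  with a compiled power-law right-hand side) with square-pulse input
  schedules handled by exact restarts at pulse edges (`evaluate()`).
* **Steady states** — dynamic settling with explicit tolerances and a
  typed non-convergence error (`steadystate()`), plus the exact
  log-linear solution for classical S-systems (`solve_loglinear()`).
* **Global sensitivity analysis** — native Morris elementary-effects
  screening and Saltelli/Jansen Sobol indices on a scrambled Sobol'
  low-discrepancy design, over any mapped set of model parameters
  (`morris()`, `sobol()`, `parameter_map()`, `gsa_objective()`).
* **Command line** — `exec/bstkit` exposes `build`, `simulate`,
  `steadystate`, `morris`, and `sobol` subcommands over the same API.

## Worked example

The package ships a five-species feedback-inhibited pathway: X1 → X2 → X3
→ X4 with a branch X3 → X5, enzymes E1–E3 catalyzing the conversions, and
product feedback — X4 inhibits the first reaction with kinetic order −0.5.
The source flux into X1 is a pulsed external input (baseline 1, a high
pulse of 10 on t ∈ [5, 15), a medium pulse of 5 on t ∈ [25, 35)).

```r
library(bstkit)

fx <- feedback_pathway_model()
fx$model
#> <bst_model> 5 dynamic + 3 static species, 6 reactions
#>   dynamic: X1, X2, X3, X4, X5
#>   static:  E1=1, E2=1, E3=1
#>   alpha:   r0=0, r1=10, r2=10, r3=10, r4=3, r5=0.1

traj <- evaluate(fx$model, c(0, 50), fx$input)
max(traj$states[, "X4"])
#> [1] 3.30033
```

X4 peaks near 3.3 at the end of the high pulse — the feedback loop caps
the response, and during the medium pulse the peaks are roughly halved.
The byproduct X5, which has no degradation reaction, ratchets up to ~1.9
by t = 50.

Steady-state flux partitioning at a branch point (second shipped example:
C is consumed by two competing enzyme-catalyzed reactions):

```r
ss <- steadystate(branched_pathway_model(E3 = 5))  # E4 = 1
round(ss, 3)
#>     A     B     C     D     E
#> 0.408 0.913 0.167 0.833 0.167
```

With the branch enzyme E3 at five-fold excess, five sixths of the flux
leaves through the D branch — exactly `E3/(E3+E4)` for this model's unit
rate constants.

Which parameters control the cumulative product exposure
J = ∫₀²⁰ X4 dt? Screen seven of them (rate constants at ±50%, the source
gain, and the feedback order over [−2, 0]):

```r
g <- feedback_gsa_problem()
res <- sobol(g$f, g$lower, g$upper, N = 1024, seed = 1)
round(res$S1[c("alpha_r4", "alpha_r0")], 2)
#> alpha_r4 alpha_r0
#>     0.54     0.42
round(res$ST[c("alpha_r4", "alpha_r0")], 2)
#> alpha_r4 alpha_r0
#>     0.58     0.46
```

The product degradation rate (`alpha_r4`) and the source gain
(`alpha_r0`) together explain nearly all of the output variance — the
intermediate conversion steps and even the feedback order barely matter —
and the S1 < ST gaps indicate mild interactions from the multiplicative
kinetics. `morris(g$f, g$lower, g$upper, r = 500, seed = 1)` reaches the
same ranking at a fraction of the cost.

## Further documentation

The methods vignette (`vignettes/bst-modeling.Rmd`) describes the model
formalism, the file dialects, every numerical choice (concentration
floor, tolerances, pulse segmentation, settling schedule), the
sensitivity estimators, and the package's limitations.
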