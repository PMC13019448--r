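---
title: "Power-law modeling of biochemical networks with bstkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-law modeling of biochemical networks with bstkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bstkit)
```

## The model class

Biochemical Systems Theory (BST) approximates the net flux of every process
in a reaction network by a product of power-law functions of the species
concentrations. `bstkit` works with the generalized matrix form of that
formalism: a network of `n` dynamic species, `m` static species (enzymes or
other externally fixed concentrations), and `p` reactions evolves as

$$\frac{dx}{dt} = S\,r(x, x_s) + u(t), \qquad
  r_k = \alpha_k \prod_{j=1}^{n+m} X_j^{G_{jk}},$$

where `S` (n x p) is the stoichiometric matrix, `G` ((n+m) x p) the
kinetic-order matrix, `alpha` the non-negative rate constants, and `u(t)` an
optional external input with one channel per dynamic species. A kinetic
order is the exponent of a species in a rate law: positive values are
activation, negative values inhibition, zero no dependence. The matrix form
separates network structure (`S`) from kinetics (`G`, `alpha`) and contains
the classical two-term S-system — one aggregate production and one
aggregate consumption term per species,

$$\frac{dX_i}{dt} = \alpha_i \prod_j X_j^{g_{ij}}
                  - \beta_i \prod_j X_j^{h_{ij}},$$

as the subclass in which every species has exactly one producing and one
consuming reaction of unit stoichiometry (`classical_from_model()` performs
the reduction and refuses anything else, e.g. branch points).

Models are compiled from declarative records: reaction records give
connectivity (`reactants`, `products`, with positive coefficients on each
side), kinetics records give the rate-law dependencies. The compiler writes
`S[i, k]` as products minus reactants and `G[j, k]` from the kinetics
records, with rows of `G` ordered dynamic species first, then static
species, both in model order — a convention the rest of the package (and
any hand-indexing into `G`) relies on. Stoichiometry overrides replace the
computed entry verbatim; a zero override is deliberate and allowed, so a
species can shape a rate without participating in mass flow. Kinetic orders
are always explicit in the records; only the file readers supply the
default order of 1, which keeps the in-memory core unambiguous.

## Model files

Two text dialects are supported, plus a JSON archive:

* **TOML dialect** — `[metadata]` (free-form strings), `[model]` with
  `dynamic_species`, `static_species`, `reactions`
  (`"r1::A + 2*B --> C"`, empty side written `[]`), `kinetics`
  (`"r1::A, E1, X4^-0.5"`, exponent defaulting to 1), optional
  `stoichiometry` overrides (`"X2::r1::2.0"`), and the numeric tables
  `[model.alpha]`, `[model.initial]`, `[model.static_values]`. Missing
  initial conditions default to 0, missing static values to 1; a missing
  rate constant is an error. The canonical reaction arrow is `-->`; the
  en-dash variant `–>` that some document pipelines produce is accepted on
  input.
* **BST dialect** — the same record grammar inside
  `#section::start` / `#section::end` blocks (`dynamic`, `static`,
  `reactions`, `kinetics`, `stoichiometry`, `alpha`, `initial`,
  `staticvalues`), with `//` comments.
* **JSON archive** — `save_model()` / `load_model()`, with an explicit
  `schema_version`. Every floating-point number is stored as a
  17-significant-digit decimal string, which round-trips IEEE doubles
  bit-exactly; the test suite checks losslessness across all three formats
  on 100 randomized models.

`build_model()` dispatches on the extension (`.toml`, `.bst`, `.json`) and
always returns a validated model; `validate_model()` itself returns
diagnostics rather than throwing, so it can be used to lint hand-edited
models.

## Numerical choices

**Concentration floor.** Negative kinetic orders (feedback inhibition) make
the rate law singular at zero concentration, and trajectories are routinely
started near zero. Inside the rate evaluation only, concentrations are
floored at `eps = 1e-8` before exponentiation; the state itself is never
clamped. Species with a zero kinetic order contribute a factor of exactly 1
even at zero concentration. The floor is a property of the rate law
evaluation, visible in `rates()`, the plain-R `bst_rhs()`, and the
compiled derivative routine alike.

**Integration.** `evaluate()` integrates with `deSolve::lsoda` (adaptive
step, automatic stiff/non-stiff switching) at `rtol = 1e-8`,
`atol = 1e-10`. Pulsed inputs are square waves, and an adaptive integrator
stepping blindly across a ten-fold input discontinuity loses accuracy, so
the integration is segmented: the solver is restarted exactly at every
pulse edge with the input held constant within each segment. Pulses are
half-open intervals `[start, stop)` and may not overlap within a channel;
the pulse value replaces the baseline rather than adding to it. The
derivative is implemented both in C (used by default; the whole model is
passed to the compiled routine once per segment) and in plain R (the
reference implementation, `compiled = FALSE`); a test pins the two paths
together.

**Steady states.** `steadystate()` settles dynamically: it integrates in
geometrically growing blocks and stops when
`||dx/dt||_inf < tau_abs + tau_rel ||x||_inf` (defaults `1e-8`, `1e-6`),
giving up at `t_max = 1e6` with a typed `bst_nonconvergence` error that
carries the last state and residual — the signature of sustained
oscillation or divergence, which a longer horizon would not cure. For
classical S-systems, `solve_loglinear()` instead solves the steady-state
condition exactly: equating the two power-law terms and taking logarithms
yields the linear system `(G - H) y = log(beta/alpha) - (G - H)_s log(xs)`
in `y = log x`. The two routes are checked against each other on dozens of
randomized well-conditioned classical systems to `1e-5` relative error;
the settling route is the general-purpose tool, the log-linear route the
oracle (and the faster choice when it applies). Systems whose
kinetic-order difference matrix is singular have no isolated steady state
in log space and are reported as degenerate rather than solved.

## Global sensitivity analysis

Both screening methods are implemented in the package itself and operate
on an arbitrary scalar function of a parameter vector, typically built
with `gsa_objective()`, which applies a `parameter_map()` to a deep copy
of the model per evaluation (evaluations are pure; nothing shared is
mutated).

**Morris elementary effects** uses the classic trajectory design on a
`p = 4`-level grid with step `Delta = p / (2(p-1)) = 2/3` of the unit
hypercube: each trajectory starts at a random grid point and perturbs
every parameter once, in random order and direction, yielding one
elementary effect per parameter per trajectory. Effects are measured per
unit of *normalized* parameter span, so parameters with very different
natural scales are comparable. We report the signed mean `mu`, the mean
absolute value `mu*` (the screening statistic used for ranking), and the
variance `sigma^2` (nonlinearity/interaction indicator).

**Sobol indices** use the Saltelli design: two base matrices `A` and `B`
drawn from a Sobol' low-discrepancy sequence of dimension `2d` (split in
half), plus the `d` cross matrices, for `N(d+2)` model evaluations. The
sequence uses the published Joe–Kuo direction numbers (dimensions up to
32) and is randomized by a seeded digital shift, which preserves its
equidistribution; the unscrambled sequence is pinned against reference
values in the tests. First-order indices use the Saltelli (2010)
estimator, total-order indices the Jansen estimator, both applied to
mean-centered outputs (centering makes the estimators invariant to
additive shifts of the objective at finite sample size). Confidence
intervals come from a bootstrap over sample rows — a pragmatic choice that
treats the quasi-random rows as exchangeable and therefore tends to be
conservative. Zero output variance is reported as all-zero indices with a
flag rather than as `0/0`. Evaluations that fail (ODE blow-ups at extreme
parameter corners) are retried once — with tighter tolerances when the
objective was built by `gsa_objective()` — then dropped; more than 1%
missing aborts the analysis rather than silently biasing it.

## The example systems

`feedback_pathway_model()` is a five-species linear pathway
X1 → X2 → X3 → X4 with a branch X3 → X5, enzymes E1–E3 = 1 catalyzing
r1–r3, rate constants `(r1, r2, r3, r5, r4) = (10, 10, 10, 0.1, 3)`, and
feedback inhibition of r1 by the product X4 with kinetic order −0.5. The
source reaction r0 carries a rate constant of zero: the source flux is
delivered through the input channel `u1(t)` instead (baseline 1, a high
pulse of 10 on `[5, 15)`, a medium pulse of 5 on `[25, 35)`), which
exercises the feedback under two loading conditions. Initial conditions
are fixed at 0.1 for all five species — strictly positive (the feedback
order is negative), and small relative to the responses of order 1–3, a
concrete reading of "near zero".

For the sensitivity study on this pathway, the output is the cumulative
product exposure `J = integral of X4 over [0, 20]` under the pulsed input
(the window contains the first pulse), and the seven parameters are the
rate constants of r1–r5 at ±50% of nominal, the feedback order on
`[-2, 0]`, and — because the source enters through `u(t)`, not through a
reaction — a multiplicative *gain* on the input channel, labelled
`alpha_r0`, nominal 1, bounds `[0.5, 1.5]`. Treating the source magnitude
as a gain keeps "±50% of the nominal source rate" meaningful for a source
that is a time-varying input.

`branched_pathway_model()` is a biosynthetic branch point: source → A → B
→ C, then C → D (r3, enzyme E3) competing with C → E (r4, enzyme E4),
first-order degradation of D and E, and dual feedback (E inhibits r1, D
inhibits r2, orders −0.5). Its rate constants default to 1.0; the
behavior of interest — flux redistribution as E3 is swept against fixed
E4 — is qualitative and, with unit rate constants, analytically
transparent: at steady state every flux equals the source flux, so
`D = E3/(E3+E4)` and `E = E4/(E3+E4)` exactly, the two branches crossing
exactly once at `E3 = E4`. The tests use this closed form as the oracle
for the sweep.

`random_model()` and `random_classical_ssystem()` generate seeded models
for property tests. The classical generator draws rate constants from
`[0.5, 5]`, self-consumption orders from `[0.5, 1.5]`, and sparse
off-diagonal production orders from `[-0.4, 0.4]` — keeping `G - H`
diagonally dominant, hence nonsingular, well conditioned, and dynamically
stable, so the settling/log-linear cross-check is meaningful on every
draw. These generators emulate the *structure* of small metabolic models
(connected topology, moderate orders, positive states); they do not
emulate stiff time-scale separation, conservation cycles, or measurement
noise, so passing property tests says nothing about parameter
*estimation* on real data — estimation is out of scope altogether.

## Problem sizes used in the checks

The shipped checks run the pulse simulation on a 1001-point grid over
`[0, 50]`; the Sobol analysis at base `N = 1024` (9216 ODE solves) and the
Morris screening at `r = 500` trajectories (4000 solves), matching the
scale of the published analyses; the settling/log-linear cross-check on 50
random classical systems; and the round-trip property on 100 random
models. On a single CPU the full suite completes in a few minutes, most of
it in the Sobol evaluations.

## Limitations

Only the S-system representation is supported — no Generalized Mass
Action form with several independent production terms per species, no
reversible-reaction expansion. There is no local sensitivity analysis or
logarithmic-gain computation, no parameter estimation, no stochastic
simulation, and no SBML import/export. Events beyond piecewise-constant
pulse schedules (ramps, state-dependent events) are not handled. The
Sobol' sequence implementation carries direction numbers for 32
dimensions, i.e. up to 16 simultaneous Sobol parameters; Morris has no
such limit. Sensitivity evaluations are sequential; they are pure by
construction, so a parallel map would be a drop-in change, but none is
shipped.
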