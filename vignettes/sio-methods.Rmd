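---
title: "Structural identifiability and observability of tumour growth models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural identifiability and observability of tumour growth models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncosio)
```

## The question the package answers

A mechanistic tumour model `dx/dt = f(u, x, θ)`, `y = h(u, x, θ)` is only as
useful as our ability to pin down its unknowns from data. Two *structural*
properties decide this before any experiment is run: a parameter is
**structurally locally identifiable** if, for generic parameter values, its
true value can be distinguished from every other value in a neighbourhood
using ideal noise-free output data; a state is **observable** if its time
course can be inferred from the outputs. When these fail, infinitely many
parameter sets reproduce the same measurements, and both calibration and
prediction of hidden states become meaningless — no amount of data quality can
fix it, only a different measurement set-up can.

These are local, generic properties: verdicts hold for every parameter value
outside a measure-zero set. Practical (noise- and design-dependent)
identifiability is a separate question and out of scope here, as is global
identifiability.

## The rank test

The analysis is the differential-geometric one. States and parameters are
joined into the augmented state `x̃ = (x, θ)` (parameters have trivial
dynamics `θ̇ = 0`; initial conditions are thereby unknowns on the same footing
as parameters — the package has no known-initial-condition mechanism). The
observability–identifiability (OI) matrix stacks the Jacobians of successive
Lie derivatives of the output,

* `L⁰h = h`,
* `L^{i} h = ∂(L^{i-1}h)/∂x̃ · f + Σ_j ∂(L^{i-1}h)/∂u^{(j)} · u^{(j+1)}`,

for orders `0 … nx+nθ−1`. Full generic rank `nx + nθ` means everything is
identifiable and observable. Below full rank, each augmented symbol is
classified by the **column-removal test**: removing an identifiable symbol's
column destroys an independent direction (rank drops); removing an
unidentifiable one does not. A state that is itself a measured output is
observable by definition and short-circuited accordingly.

In practice the matrix is grown one Lie order at a time and stops early once
an additional order leaves the rank unchanged (the observability filtration
stalls and stays stalled), at full rank, or at the order cap.

## Exact rank decisions

Generic rank is a yes/no algebraic property, but the singular values of OI
matrices of the larger catalogue models genuinely span more than sixteen
orders of magnitude, so no double-precision cutoff can separate "tiny but
nonzero" from "zero". The package therefore decides rank *exactly*: matrix
entries are evaluated at seeded random points of the prime field GF(p),
p = 2147483629, and ranked by modular Gaussian elimination. By the
Schwartz–Zippel argument the rank at a random field point equals the
structural rank except with probability O(degree/p); the package takes the
maximum over 3 independent points (an unlucky point can only lower the rank,
never raise it).

Two care points make this sound for non-polynomial models:

* subterms `a^b`, `tanh(z)`, `sqrt(a)` are rewritten to single `exp`/`log`
  normal forms *before* any differentiation, so each transcendental value
  appears once and consistently;
* `exp`, `log` and `tanh` values are algebraically independent of the rational
  point (transcendence over the rational function field), so they are assigned
  independent random field elements, while `1/e` auxiliaries get honest
  modular inverses.

A floating SVD rank with the usual relative-tolerance-plus-gap policy
(`numeric_rank()`, default rtol 1e-6, minimum gap 1e3, ambiguous verdicts
raised as a condition rather than guessed) is retained for inspecting
timepoint sensitivity matrices and for estimating nullspaces, where actual
directions, not just dimensions, are needed.

## Two engines, one matrix

**Symbolic Lie engine** (`build_oi()`, `saturated_oi()`). Raw expression-tree
differentiation swells exponentially with Lie order, so every entry is kept as
a canonical sparse multivariate polynomial over the model symbols plus
auxiliary symbols for `1/e`, `exp(e)`, `log(e)`, `tanh(e)`, each carrying a
chain-rule partial that is again polynomial in the extended symbol set.
Differentiation and multiplication collapse terms instead of nesting them. A
configurable per-entry term budget (default 5e5) guards against blow-up; under
automatic backend choice an over-budget model is routed to the numeric engine.

**Numeric jet engine** (used for `nx + nθ ≥ 12`). The k-th row block of the OI
matrix equals the k-th Taylor coefficient (scaled by k!) of the output
sensitivity trajectory. The engine propagates truncated Taylor series of the
state together with the forward variational system
`dS/dt = (∂f/∂x) S + [0 | ∂f/∂θ]`, `S(0) = [I | 0]`, entirely in field
arithmetic, and stacks the coefficients of `(∂h/∂x)S + [0 | ∂h/∂θ]`. This
produces the exact OI matrix at the point without any symbolic object ever
being formed. The backend threshold (12) routes the four immunotherapy models
and the cancer–immunity cycle model to the jet engine and everything else to
the symbolic one.

The two engines are independent implementations of the same mathematical
object, and their ranks are required to agree on every model small enough to
run both — this backend-agreement property is part of the test suite.

The timepoint-sampled sensitivity matrix (`build_sensitivity_matrix()`)
integrates the same variational system with a stiff solver and stacks rows at
sample times; it is the workhorse for nullspace estimation, witness
refinement, and inspection/export, but its floating rank is reliable only for
small, well-conditioned models.

## Generic points and the synthetic-data generator

Floating-point work (simulation oracles, witnesses, noisy datasets) samples
generic points as rationals `k/7` with `k = 8…21` — strictly above 1 to avoid
accidental cancellations and poles at zero, small enough that the stiffest
catalogue models stay finite and positive over their horizons. Symbols the
models themselves bound in (0,1) (the power-law and von Bertalanffy exponents
with `0 < γ < 1`; the cell fractions and the T-cell activity level of the
cancer–immunity cycle model) are drawn from rationals `k/71`, `k = 8…63`.
Points where any model denominator vanishes are rejected and resampled. Exact
rank work samples uniform field elements instead; conditioning is irrelevant
there.

Each catalogue model carries a simulation horizon (in the model's abstract
time units — the analyses are unit-free) chosen once so that trajectories
remain finite at generic points: 1 for the benign growth laws, down to 0.02
for the fastest-moving treatment models. `generate_dataset()` adds i.i.d.
Gaussian noise to the outputs for downstream demonstrations; the structural
analysis itself is by definition noise-free, so passing tests say nothing
about practical identifiability under realistic noise — that is the main
sense in which the synthetic data is easier than real data.

Integration uses `lsoda` with tight tolerances (1e-10/1e-12 by default,
1e-11/1e-13 where witness equality claims depend on them), because a witness
pair's "identical outputs" claim is only as strong as the integrator.

## Catalogue encoding choices

The twenty shipped models follow the published equations, with these encoding
decisions where the sources leave room (or conflict):

* **Impulsive treatments.** Radiotherapy fraction trains and drug injections
  appear in the sources as Dirac impulse sums. The analysis framework needs
  smooth inputs, so impulses are replaced by known treatment-intensity
  inputs. A *constant* known input is not enough for the radiotherapy models:
  with constant `u` the growth rate and the dose term merge into the single
  lump `λ − (αd+βd²)u`, which would (wrongly, per the published verdicts)
  make `λ` unidentifiable. A known input with one nonzero time derivative —
  realised in simulation as `u(t) = u(0) + u̇(0)·t` — separates the pathways
  and reproduces the published radiotherapy classifications. The same
  convention is applied to the chemotherapy/vitamin inputs of the CICV model,
  where a constant vitamin rate would be absorbed into the unknown baseline
  immune production (an exact affine symmetry making `α1`, `δ` and the immune
  state unrecoverable from tumour measurements alone); time-varying intake
  breaks it. Purely saturating controls (CYCLE, CYTO2) stay constant.
* **Gompertz, decaying-rate form (GOM1).** The printed dynamics
  `a·exp(−bt)·N` depend explicitly on time; the rank framework needs an
  autonomous system. The growth rate is carried as an auxiliary state `g`
  with `ġ = −bg`, `g(0) = a` — the same solutions, with the initial rate `a`
  becoming an unknown initial condition (matching the source's listing of
  `N0` among the unknowns).
* **CYCLE.** The instantaneous-growth-rate symbol `αG` is kept as a free
  unknown constant (as in the published parameter list) rather than
  substituted by its defining expression; the measured outputs are the cancer
  cell fraction `x2` together with the tumour volume `V`, the source's stated
  output set. With `V` alone the volume equation would decouple entirely from
  the replicator subsystem and the published verdicts could not hold.
* **CRS.** The macrophage activation rate uses the four-argument form
  containing the antigen-negative kill contribution `g0·TN` (the
  three-argument header in the source is taken as a typo), and the
  antigen-negative tumour equation takes a minus sign before its kill term,
  consistent with the description of `g0` as reduced cytotoxicity.
* **LEUK.** The interaction functions `e, f, h, g` are encoded as unknown
  scalar constants, per the source's parameter table; the derived functional
  forms are documentation, not analysed dynamics.
* **NECR, viable volume measured.** As printed, the necrotic compartment
  never feeds back into the viable volume or its measurement, so neither the
  necrotic state nor its decay rate can possibly be inferred from `Vt`, and
  the growth/necrosis/capacity parameters enter only through two lumps. The
  package asserts what the equations support (the radiotherapy kill rate
  identifiable, `Vt` observable) and marks the remaining published cells as
  not asserted. The necrotic-volume measurement reproduces in full.
* **RAD2.** Only `α` is asserted unidentifiable (as published); `β` and `d`
  enter solely through the lump `αd + βd²`, so their verdicts are recorded
  but not asserted.
* **IMRAD.** Best-effort encoding: the delayed arguments are replaced by
  current-time values (making the two delays structurally absent, hence
  unidentifiable by construction), damaged cells are pooled into a single
  compartment, and impulse trains are constant known inputs. The source's
  text and its summary table disagree about this model, so it is excluded
  from strict comparison.
* **Measured-state rows.** Where a source table reports "all states
  unobservable" for a scenario whose output *is* a state (CRS, HCART), the
  package reads this as "all unmeasured states" and leaves the measured
  state's cell unasserted (the rank test, and first principles, make a
  measured state observable).

## Witness pairs

For every scenario classified below full rank, `make_witness()` produces an
explicit pair of augmented points with indistinguishable outputs: a direction
in the numerical nullspace of the OI matrix (support projected onto the
symbols the exact classification marked unidentifiable/unobservable) is
followed in a few short steps with direction refresh, and the endpoint is
projected back onto the indistinguishability manifold by Gauss–Newton
iterations using the timepoint sensitivity matrix as Jacobian (singular
directions truncated, so the correction never moves along the symmetry).
Positivity of all coordinates is enforced, with step-halving retries. For two
scenarios the symmetry is catalogued in closed form and applied exactly: the
radiotherapy dose lump `αd + βd²` (RAD1) and the scaling symmetry
`(VR, K_R, γ_R, γ_S) → (cVR, cK_R, γ_R/c, cγ_S)` of the partially observed
Lotka–Volterra model. Witnesses are checked on a 100-point output grid
(sup-discrepancy below 1e-6) while the unidentifiable coordinates move by a
Euclidean distance above 0.01.

`local_distinguishability_check()` is the converse diagnostic for full-rank
scenarios — twenty random perturbations must all change the output — and
doubles as a negative control when forced along a known symmetry direction.

## Numerical choices and degenerate inputs

* Backend threshold `nx + nθ < 12` symbolic, else numeric; symbolic term
  budget 5e5 per entry, with automatic fallback to the jet engine.
* Exact rank: 3 field points per decision, maximum taken; pole points
  (vanishing denominators) rejected and resampled; sampling failure after all
  trials is an error, never a silent verdict.
* Floating rank policy: rtol 1e-6 after row and column normalisation, gap
  factor 1e3, ambiguity raised as a typed condition.
* Ties/degeneracies: models with zero-valued rates are legitimate inputs to
  simulation (equilibria are tested) but generic points never sample them;
  verdicts are only claimed for generic values.
* Problem sizes: the shipped analyses run the full 24-scenario catalogue,
  50-point closed-form comparison grids at 5 seeded points per closed-form
  model, 3 rank trials per decision, and 100-point witness grids.

## Known limitations

* Verdicts are local: a locally identifiable parameter may still admit
  finitely many indistinguishable mirror values (e.g. the cytostatic and
  cytotoxic rates of CYTO2 swap under `a ↔ b`); no global analysis is
  attempted.
* Identifiable *combinations* (the lumped reparameterisations themselves) are
  not derived; only per-symbol verdicts are reported.
* No delay-differential, stochastic or spatial models; the IMRAD delays are
  approximated away as described.
* The witness walk certifies unidentifiability empirically; failure to find a
  witness is not a proof of identifiability (the distinguishability check is
  supporting evidence only).
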