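---
title: "Forecasting production in two-strain consortia: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting production in two-strain consortia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofactory)
```

## The scientific problem

Engineered two-strain *E. coli* consortia split a biosynthesis route across
an upstream strain, which converts the carbon source into an exchanged
intermediate, and a downstream strain, which converts that intermediate into
the final product. Predicting the product titer of such a consortium from
genome-scale models is hard because each strain balances two conflicting
objectives: growing as fast as it can, and expressing a heterologous pathway
that diverts carbon, enzyme capacity, and thermodynamic driving force away
from growth.

`cofactory` models that conflict explicitly through a single scalar per
strain, the **biosynthesis-pathway expression degree**

$$ d = \frac{\bar v_{bio}^{nfeg} - \bar v_{bio}^{feg}}{\bar v_{bio}^{nfeg}}, $$

the fractional growth-rate loss caused by forced pathway expression
(`nfeg` = no forced expression genes; `feg` = forced). A small $d$ means
biosynthesis and growth coexist; $d$ near 1 means they conflict. The degree
enters the flux simulation as a growth lower bound: production is maximized
subject to $\bar v_{bio} \ge (1-d)\,\bar v_{bio}^{nfeg}$.

## The constraint stack

Mono-culture mean fluxes are simulated by linear programming over the
steady-state flux cone, with up to three constraint layers:

1. **FBA** — $S\,v = 0$ with flux bounds; the objective is growth
   ($\max \bar v_{bio}$) or, in forced-expression mode, production
   ($\max \bar v_{production}$).
2. **Enzyme pool (kinetic)** — $\sum_i v_i\, \mathrm{MW}_i / k_{cat,i} \le$
   pool, a linear cap representing finite catalytic protein. The default
   pool is 0.227 g/gDW, the standard *E. coli* total-enzyme budget used by
   enzyme-constrained FBA; both the pool and the per-reaction
   $k_{cat}$/MW annotations are user-supplied.
3. **Thermodynamic (max–min driving force)** — every *pathway* reaction
   $i$ that carries flux must admit a positive driving force
   $Df_i = -(\Delta_r G'^0_i + RT\, S_i^T \ln C) \ge Df_{min}$ at some
   metabolite concentration vector $C$ inside a physiological box
   (default $10^{-6}$–$10^{-2}$ M). A binary $z_i$ per pathway reaction
   couples flux to feasibility ($v_i \le z_i\,UB_i$;
   $Df_i + (1-z_i)K \ge Df_{min}$ with $K$ large). Only the biosynthesis
   pathway is thermodynamically constrained — the rest of the network keeps
   plain FBA bounds.

After the primary objective is optimized, a second lexicographic stage
maximizes the common driving-force margin $B$ ($Df_i \ge B$ for all active
pathway reactions) with the primary objective fixed to within a relative
tolerance of $10^{-6}$. This treats the two stated objectives — biological
optimum and "as spontaneous as possible" — as a strict priority order, which
is the only reading under which both can be reported from one solution.

Constants: $R = 8.314\times10^{-3}$ kJ/(mol·K), $T = 310.15$ K (*E. coli*
culture), $K = 1000$ kJ/mol, $Df_{min} = 0$. The concentration box and the
water/proton exclusion (their activities are absorbed into
$\Delta_r G'^0$) follow the standard MDF conventions. All are overridable
via `thermo_config()` and per-metabolite fields.

## MDF analysis and shadow prices

`pathway_mdf()` maximizes $B$ over the concentration box with every listed
reaction forced active, and reports the per-reaction driving forces and the
**bottlenecks** (reactions with $Df_i = B$, tolerance $10^{-6}$ kJ/mol).
A structural consequence worth knowing: if a pathway contains a reaction
*and its exact reverse* (negated $\Delta_r G'^0$), then
$Df_{fwd} = -Df_{rev}$ at every concentration, so forcing both active pins
$B$ at exactly 0 — no concentration engineering can help such a pathway.

```{r reversible}
m <- toy_model(toy_spec(include_reverse_pair = TRUE))
pathway_mdf(m, c("atoDA", "atoDA_reverse"), shadow = FALSE)
```

**Shadow prices** quantify how the optimal $B$ responds to a metabolite's
allowed concentration (both bounds shifted together in log space); positive
means raising that metabolite's concentration promotes the pathway.
Two routes are computed: the dual values of the MDF linear program
(obtained by solving the explicit dual with the same simplex kernel), and
central finite differences on the bounds (step $10^{-3}$ on
$\ln C$ — small against the 9.21 width of the default box, and exact for a
piecewise-linear $B$ away from breakpoints). Where they disagree by more
than $10^{-4}$ kJ/mol the optimum is degenerate (multiple dual solutions —
the reversible-pair case is the canonical example); the finite-difference
value is then reported and the metabolite flagged. On non-degenerate toys
the two agree and bottleneck substrates come out positive, bottleneck
products negative.

## Calibration

`calibrate_degree()` inverts the forward simulator: it computes
$\bar v_{bio}^{nfeg}$, scans $d$ over $[0,1]$, simulates the titer at each
candidate (mean production flux × culture duration × biomass density), and
keeps the $d$ minimizing the absolute titer error. The scan is a coarse
pass at $10^{-2}$ refined to $10^{-4}$ around the best coarse point —
$10^{-4}$ being the precision at which degrees are conventionally reported
— with ties broken toward smaller $d$ (the least-burden explanation of the
data). Absolute rather than relative error is used because a single scalar
titer is fitted; the choice only matters under ties.

When no mono-culture data exist, `calibrate_from_coculture()` estimates
both degrees jointly from co-culture observations at two or more distinct
inoculum ratios, minimizing the summed relative error across datasets
(relative, because the datasets may sit at different titer scales; an
absolute option is exposed). The grid is three-staged
($10^{-2} \to 10^{-3} \to 10^{-4}$) with per-strain caching of production
solutions, and ties break lexicographically toward the smaller pair.

Identifiability deserves a note: with a single ratio the two degrees are
confounded (many $(d_{up}, d_{down})$ pairs explain one titer). Two ratios
suffice when the intermediate supply regime differs between them — e.g.
supply exceeding downstream demand at one ratio and limiting it at the
other — which is exactly how the bundled synthetic consortium is shaped
(upstream uptake bound 20, downstream 10 mmol/gDW/h).

## From mono-culture means to co-culture dynamics

Mean mono-culture fluxes are mapped to instantaneous co-culture fluxes by a
single constant $k$: per strain, $k_j$ is the ratio of the initial
carbon-source concentration to its time-averaged concentration (trapezoid
rule over the recorded depletion curve), and $k = \sum_j k_j\,icr_j$ with
inoculum fractions $icr_j$. Production is then integrated over the horizon
in `tp` discrete steps of length $\Delta t$ (default 60 steps, the grid
used for a 6-h exchange-culture horizon; both configurable):
at each step every strain contributes its instantaneous production flux
$k\,\bar v_{production,j}$, weighted by $icr_j$, times $\Delta t$ and the
biomass density.

Two interpretive decisions are made explicit here because the discrete
scheme does not fully determine them:

* **Inoculum weighting.** The per-step sum over strains weights each
  strain by its (constant) inoculum fraction. Without this weighting the
  prediction would not depend on the strain ratio at all, contradicting the
  observed ratio–titer trends; with it, the ratio dependence emerges
  naturally while no biomass dynamics need to be tracked.
* **Cross-feeding.** The exchanged intermediate is tracked as an explicit
  pool: producer secretion adds to it each step, consumer uptake draws from
  it, and uptake is capped at availability, scaling the consumer's fluxes
  proportionally in that step. This is the largest modelling commitment in
  the package — the alternative (no coupling) would let the downstream
  strain produce from an intermediate that was never made. A diagnostic
  mode (`cap_uptake = FALSE`) disables the cap and reports the first step
  at which a pool would go negative.

Fluxes (mmol/gDW/h) are converted to concentrations via a constant biomass
density (default 1 gDW/L); an optional total-substrate budget truncates the
integration, with the final step scaled to land exactly on the budget.

## Sensitivity analysis

`evaluate_feature()` re-runs the pipeline with one feature perturbed by a
relative step $\delta$ (default 0.1) and reports
$puf = (C^* - C)/(x^* - x)$ and $Rpuf = puf/C$. Degree features re-solve
the production LP at the perturbed $d$; mapping-constant features
re-integrate only. Because the toy integrator is linear in $k$, the
$k$-lever satisfies $Rpuf = 1/k$ exactly, which the tests use as a
closed-form check. `rank_strategies()` sorts features by $Rpuf$, labelled
IBPE/DBPE (increase/decrease of a pathway expression degree) and ICSU
(increased carbon-source utilization, implemented as raising the mapping
multiplier).

## Numerical choices

* **LP kernel.** All programs are solved by a two-phase dense simplex with
  Bland's anti-cycling rule, written for this package: the problems are
  small (tens of variables) but structurally degenerate (reversible pairs
  force $B$ to a vertex shared by many bases), and Bland's rule guarantees
  termination there. Feasibility tolerance $10^{-9}$; invariant checks in
  the tests use $10^{-6}$.
* **Binaries.** The thermodynamic binaries are solved by exact enumeration
  over pathway reactions (reactions with a positive flux lower bound are
  pinned active). This is exact and deterministic for the pathway sizes the
  package targets; beyond 12 free binaries the solver refuses and asks for
  explicit activity fixing. In the pure MDF program (no flux coupling),
  non-required reactions are optimally inactive, so the program reduces to
  a single LP.
* **Degenerate inputs.** Equal-bound metabolites, zero-variance titers,
  instantly-depleted substrate records, and zero-denominator sensitivity
  steps all raise informative errors rather than propagating NaN.

## What the synthetic data do and do not show

The generators emulate the study conditions the method was built for:
mono-culture titers at a small expression degree (default $d = 0.0011$, the
magnitude calibrated for a tyrosol-synthesis strain under FBA), 6-h/60-step
horizons, multiplicative lognormal noise on titers (positive, scale
proportional to magnitude), substrate depletion curves averaged on the
integrator's own grid, and co-culture observations at 1:4 and 1:9 inoculum
ratios with generating degrees (0.035, 0.011). Passing the recovery tests
shows the calibration inverts the package's own forward model exactly and
degrades gracefully under noise — it does not show that a genome-scale
model of a real strain is correctly parameterized, that biomass density is
constant in a real fermenter, or that cross-feeding in a real consortium is
uptake-capped per step. Those remain modelling assumptions to be validated
against experimental titers via `fit_metrics()` (MRE, $R^2$, and a paired
two-sided t-test P value where high P means simulated ≈ experimental; a
TOST-style equivalence test was deliberately not made the default because
the reported convention is "larger is more similar").

## Problem sizes

The bundled toys use chains of 1–3 reactions (2–4 thermodynamically tracked
metabolites), 60-step integrations, and calibration grids of ~100 coarse ×
~200 refined points; the full test-suite (including a 20-seed noise study
and the joint two-degree calibration) completes in well under a minute on
one core. These sizes were chosen so every optimum has a closed form or a
brute-force oracle; the algorithms themselves are size-agnostic, but the
dense simplex and binary enumeration are not intended for genome-scale
models, for which a production MILP solver should back the same interfaces.

## Known limitations

* Two strains only; the mapping constant is defined for a two-membered sum.
* One mean flux solution per strain is scaled through the whole horizon
  (the single-constant mapping); a per-step re-solve mode is the natural
  extension but is not the default, since the mapping constant already
  absorbs the time-averaged depletion profile.
* Alternate optima of the flux LP are not enumerated; the reported mean
  fluxes are one optimal vertex.
* No pH/ionic-strength transforms of $\Delta_r G'^0$ and no group
  contribution estimation — energies are taken as supplied.
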