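---
title: "Constraint-based modelling of a weak Crabtree positive yeast network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modelling of a weak Crabtree positive yeast network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lkcbm)
```

## The model and its assumptions

Everything in this package rests on the steady-state constraint-based
model of metabolism: a network of `n` reactions over `m` metabolites is
summarized by its stoichiometric matrix `S` (m × n), and a flux state is a
vector `v` (mmol/gdw/h) satisfying

* mass balance, `S v = 0` — internal metabolite pools neither accumulate
  nor deplete on the timescale of growth;
* capacity bounds, `lb ≤ v ≤ ub` — thermodynamic direction and transport
  or enzyme limits, with the conventional "unconstrained" magnitude of
  1000 mmol/gdw/h;
* an objective — flux balance analysis (FBA) maximizes the flux of a
  biomass pseudo-reaction, whose value is the specific growth rate μ
  (h⁻¹).

Exchange reactions are single-metabolite boundary reactions; uptake is
negative flux and secretion positive, so a growth medium is just a named
set of exchange lower bounds (`medium()`, `apply_medium()`). This sign
convention makes the dynamic-FBA update equations below literally correct
as written.

FBA returns one optimal vertex of a generally degenerate optimum. Any
claim about an *individual* flux at optimality therefore goes through flux
variability analysis (FVA: per-reaction min/max subject to the objective
retaining a fraction of its optimum), never through the single returned
vector.

## The linear-programming core

No LP solver package is available to depend on in this toolchain, so the
package carries its own dense bounded-variable two-phase primal simplex
(`solve_lp()`). Design choices:

* bounds are handled natively (variables nonbasic at either bound), which
  keeps the basis at the number of balance rows;
* the basis is refactorized from scratch at every iteration — at a few
  dozen variables the robustness is worth far more than the speed;
* Dantzig pricing with a switch to Bland's rule after `4(n+m)` iterations
  guards against degenerate cycling;
* redundant balance rows (conserved moieties create them routinely) keep
  their phase-1 artificial basic at zero, frozen for phase 2, so no row
  preprocessing is needed.

The suite validates this engine against brute-force vertex enumeration and
against `boot::simplex` (an independently implemented tableau method) on
randomized problems. MOMA's quadratic program is solved by `quadprog`
after rescaling variables into the unit box and normalizing balance rows —
the dual active-set method mislabels the raw 1000-magnitude problem
infeasible.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| unconstrained bound | 1000 | mmol/gdw/h | conventional "no limit" magnitude |
| flux tolerance `LK_FLUX_TOL` | 1e-6 | mmol/gdw/h | above double-precision LP noise; used for "blocked", "viable", "significant flux" |
| essentiality cutoff | 0.01 | μ_KO/μ_WT | a knockout below 1% of wild-type growth is lethal for practical purposes |
| FVA `fraction_of_optimum` | 1.0 | — | interrogate the optimal face unless relaxed |
| GIMME threshold percentile | 25 | — | the conventional low-expression quartile |
| GIMME objective fraction | 0.9 | — | a context model must keep 90% of the parent optimum |
| differential-flux FVA fraction | 0.9 | — | see below |
| aerobic / anaerobic O2 uptake | 1000 / 0.25 | mmol/gdw/h | unconstrained vs trace oxygen; semi-aerobic screens use ~2–3 |

The differential-flux comparison deliberately runs its FVA at the same
0.9 fraction the contexts were extracted at. At fraction 1.0 every
interval collapses to a point on the optimal face, and under the
degenerate-interval convention (below) any two numerically distinct points
have Jaccard index 0 — every reaction would be "differential". At 0.9 the
shared machinery overlaps broadly and only genuinely shifted routes (the
nitrogen assimilation path, here) are flagged.

## Numerical choices and conventions

* **Degenerate Jaccard intervals.** Two identical point-intervals give
  J = 1; a point against anything it does not overlap gives 0. This
  preserves "J = 0 ⇔ no overlap" as the differential criterion. Interval
  endpoints below the flux tolerance are snapped to exactly zero before
  comparison so that a blocked reaction is a true point at 0 rather than
  an LP-noise sliver.
* **Loopless FVA.** Loop-capable reactions are the support of the
  nullspace of the internal (non-exchange) stoichiometric submatrix.
  For each sign pattern over that set, a pattern is thermodynamically
  admissible iff a Gibbs-energy-like potential `G` exists with
  `N'G = 0` and each `G_i` sign-opposed to the pattern; the loopless
  interval is the union of the sign-restricted LP ranges over admissible
  patterns. This enumerates exactly the branches of the usual
  mixed-integer loopless formulation and is exact; the enumeration is
  capped (default 12 loop reactions) and errors loudly rather than
  returning unresolved intervals. Reactions outside the loop set keep
  their plain FVA interval — subtracting a cycle component never changes
  them.
* **MCC.** The Matthews correlation coefficient uses the standard
  square-rooted denominator `√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; the
  unrooted variant sometimes seen in print cannot reach 1 for a perfect
  prediction.
* **Growth from OD.** `estimate_growth_rate()` uses
  `μ = ln(OD(t_f)/OD(t_i))/(t_f − t_i)` — the ratio oriented so that
  growth gives positive μ — with the natural logarithm, consistent with
  the exponential model underlying the batch updates.
* **Currency metabolites in precursor checks.** A biomass substrate whose
  formula carries a lumped pseudo-element (the ATP lump, written in P/X
  moieties) is a conserved moiety; a plain sink demand on it is
  unsatisfiable by construction. `check_biomass_precursors()` detects
  this and checks *turnover* instead, returning the moiety through the
  biomass reaction's own products (ATP → ADP + Pi) — the energetic
  question the check is actually asking.
* **Dynamic FBA.** Updates are
  `X' = X e^{μΔt}` and `C' = C + v_EX (M/1000) X (e^{μΔt}−1)/μ`, with the
  analytic μ → 0 limit `C + v_EX (M/1000) X Δt`. Fluxes are mmol/gdw/h
  and concentrations g/L, hence the molar-mass/1000 conversion. Uptake in
  each interval is capped by `availability_bound()` (the pool divided by
  the linearized draw), so substrate exhaustion is resolved within one
  sampling interval and refining Δt barely moves the final biomass; any
  residual overshoot is clamped at zero and flagged in the trajectory.
  Product re-uptake (diauxie) opens only after the primary substrate is
  exhausted — sequential, not simultaneous, utilization.

## What the synthetic generator emulates — and what it does not

`make_toy_model()` builds a ~44-reaction, two-compartment network designed
so every pipeline stage has a known answer:

* lumped glycolysis (2 ATP + 2 NADH per glucose), a respiratory branch
  (TCA lump + oxidative phosphorylation at P/O = 2, 28 ATP per glucose
  fully respired) and a fermentative branch (2 ATP per glucose), so
  growth is ATP-limited and oxygen availability reproduces the
  respiro-fermentative switch of a weak Crabtree positive yeast;
* a biomass drain of 6.5 mmol glucose skeletons + 1 mmol ammonium +
  130 mmol ATP per gdw. These defaults were chosen once so that the
  aerobic optimum at a realistic glucose uptake of 2.28 mmol/gdw/h is
  μ = 0.205 h⁻¹ (a yield of ≈0.5 g/g) — and they give closed forms
  μ_aer = 28g/(130 + 28·6.5) and μ_O2-limited = (2g + 13w/3)/(130 + 2·6.5)
  that the engines are tested against;
* an ethyl acetate branch (acetate-forming aldehyde dehydrogenase + AAT
  condensation + exporter) producible only when both precursors carry
  flux, hence never in the anaerobic optimum;
* an optional uracil catabolism branch (uracil → urea +
  3-hydroxypropionate; urea → 2 ammonium + CO2) enabling uracil as sole
  nitrogen source, plus gluconeogenesis so non-sugar carbon sources can
  feed the biomass skeletons;
* a lactate "decoy" branch that is never needed and whose ATP-coupled
  exporter keeps the fermentative optimum uniquely ethanol — the target
  the expression-driven extraction is supposed to remove;
* GPRs spanning single genes, AND complexes and OR isozyme pairs; real
  molecular formulas throughout, so balance checks and g/g yields are
  meaningful (cofactor pairs are lumped with pseudo-elements, balanced by
  construction; charges are uniformly zero in the toy).

Expression profiles are log-normal (multiplicative noise respects
positivity): baseline around 10, condition-specific silenced sets around
1, far below the 25th percentile of the scored-reaction distribution.
Under the ammonium condition the URC genes and the decoy are silenced;
under the uracil condition the decoy plus the respiratory genes are low —
the latter are flux-forced, so extraction must retain them and removes
exactly the decoy. Condition tables and OD series perturb the model's own
predictions with multiplicative Gaussian noise.

What the toy does **not** emulate: genome-scale redundancy (dozens of
isozymes and alternative routes that make real essentiality calls noisy),
compartment-specific cofactor pools, maintenance ATP, protons and charge
as a real electrochemical balance, regulatory effects on expression, and
the measurement structure of real microarrays. Passing tests on the toy
therefore demonstrate the *correctness of the algorithms* against known
ground truth — not that a particular genome-scale reconstruction is
accurate.

## Problem sizes

The shipped analyses run at toy scale: ~44 reactions, 22 genes, batch
simulations of 100–200 FBA steps, essentiality screens over all genes and
four media, loopless FVA with ≤3 loop-capable reactions, and randomized
property checks at a few hundred LPs each. These sizes make every result
checkable against enumeration or closed forms; the algorithms themselves
are written for correctness first and accept any model the container
validates, but the dense simplex is not intended for genome-scale FVA
sweeps in tight loops.

## Known limitations

* The simplex refactorizes every iteration: robust, but O(m³) per step —
  fine for toys and single genome-scale solves, slow for large FVA sweeps.
* Loopless FVA is exact but exponential in the number of loop-capable
  reactions (capped, with a loud error).
* MOMA relies on `quadprog`'s dual active-set method; severely
  ill-conditioned genome-scale problems may still defeat the rescaling.
* The SBML reader covers the fbc subset emitted by mainstream
  constraint-based toolchains (bound parameters, gene-product
  associations, one maximization objective); it is not a general SBML
  implementation.
* Dynamic FBA assumes uptake kinetics constant within a sampling interval
  and no Michaelis–Menten saturation, pH or temperature effects.
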