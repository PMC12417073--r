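---
title: "Ranking metabolic engineering targets by flux-span overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking metabolic engineering targets by flux-span overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retap)
```

## The model and its assumptions

`retap` works entirely inside the constraint-based (stoichiometric) view of
metabolism: a network of reactions with flux bounds, assumed to operate at
steady state, so every feasible flux vector $v$ satisfies $S v = 0$ and
$lb \le v \le ub$. Everything the method knows about a strain is encoded in
that polytope. The core assumption is that engineering targets reveal
themselves geometrically: if the polytope's shadow on one reaction's axis
(its feasible flux interval, or *flux span*) must move when production is
enforced, that reaction has to behave differently in a producer strain.

The method deliberately ignores kinetics, regulation, and product toxicity
— it inherits both the power and the blind spots of flux balance analysis.
Its output is a ranked hypothesis list for a design–build–test–learn cycle,
not a prediction of realized fluxes.

## The procedure

For a product reaction $p$, biomass reaction $b$ and carbon exchange $c$:

1. Fix the medium: the carbon exchange's lower bound is set to
   $-\text{uptake}$ (negative flux = uptake).
2. Maximize $v_b$ → `max_growth`. With $v_b \ge
   \beta \cdot \text{max\_growth}$ (the *biomass floor*, $\beta$ =
   `biomass_min_fraction`), maximize $v_p$ → the maximum theoretical yield
   (MTY). Computing the MTY *under* the floor guarantees that the last scan
   step is feasible by construction.
3. For each fraction $f$ in the scan grid, set $v_p \ge f \cdot
   \text{MTY}$ (a floor — the upper bound is untouched, matching the
   enforced-objective-flux family of scans) and record every reaction's FVA
   interval $[v^{min}_r(f),\, v^{max}_r(f)]$.
4. Summarize the two smallest fractions as the low-production state and
   the two largest as the high-production state of each reaction, each as a
   gaussian: $\mu$ = mean of the four interval endpoints, $\sigma$ =
   overall spread (largest max − smallest min across the two fractions).
5. Score by inverse overlap: $\eta = \int \min(\varphi_{low},
   \varphi_{high})\,dx \in [0,1]$, score $= \min(1/\eta,\,
   \text{score\_cap})$.
6. Classify: $\mu$ rising → overexpress; falling → downregulate; falling
   *and* span at $f = 1$ pinned at zero → knockout. Filter and rank.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `uptake_rate` | 10 | mmol/gDW/h | carbon availability; sets the flux scale |
| `biomass_min_fraction` | 0.1 | — | growth retained during the scan; 10% keeps both toy and genome-scale models feasible while still freeing most carbon |
| `n_fractions` | 10 | — | grid 0.1…1.0; four is the minimum (two per state) |
| `flux_diff_cutoff` | 1e-4 | mmol/gDW/h | smallest mean shift treated as a signal |
| `score_cutoff` | 1.0 | — | keep anything with less-than-total overlap |
| `sigma_floor` | 1e-6 | mmol/gDW/h | proper densities for fixed-flux (degenerate) spans |
| `knockout_eps` | 1e-6 | mmol/gDW/h | numerical zero for the knockout test |
| `score_cap` | 1e6 | — | finite, sortable stand-in for 1/0 |

Raising `score_cutoff` or `flux_diff_cutoff` is a pure filter on a fixed
scored set, so the number of returned targets is non-increasing in either —
a property the test suite asserts exactly.

## Design choices

**Fraction grid.** Ten equally spaced fractions starting at 0.1. The
lowest fractions with the product bound barely raised already describe a
near-baseline state; a literal 0% point adds nothing but an LP solve. The
grid is configurable down to the minimum of four.

**State means.** "Average of the FVA range over two fractions" is read as
the arithmetic mean of the four interval endpoints — equivalently the mean
of the two midpoints. A mean of span *widths* cannot serve as a location
parameter, so the endpoint reading is the only self-consistent one.

**Knockout calls use the full-enforcement span, not the high-state mean.**
A knockout is warranted when the reaction *cannot carry flux at all* in the
high-production state. The two-fraction high-state mean is the wrong
statistic for that test: $v^{max}_r(f)$ is concave in $f$, so for any
reaction active at baseline, $v^{max}_r(0.9) \ge 0.1\, v^{max}_r(0)$, and
the high-state mean retains a strictly positive residual from the
penultimate fraction — a mean-based test at any tight epsilon would never
fire. `rank_targets` therefore calls a knockout when the mean shift is
negative and the span at $f = 1$ lies within `knockout_eps` of zero.
`classify_intervention` without span evidence falls back to comparing the
high-state mean itself against `knockout_eps`.

**Exclusions.** The product, biomass and carbon reactions are enforced or
trivially correlated with enforcement, so they are never reported;
exchanges are excluded by default (they are transport artifacts, not
enzyme-level levers). Both lists are configurable.

**GPR handling.** Rules are validated as boolean expressions and flattened
to a deduplicated, sorted gene list; no isozyme-versus-complex reasoning is
attempted. The verbatim rule is reported alongside so a curator can make
that call.

## Numerical choices

* **LP backend.** All FBA/FVA problems are solved with a dense simplex
  (`pracma::linprog`) after shifting fluxes to the nonnegative orthant.
  Feasibility tolerance 1e-9, optimality 1e-6 relative. Infinite bounds are
  replaced by a ±1e6 envelope; an optimum pressed against the envelope
  along a direction the model leaves free is reported as `unbounded`. The
  backend breaks degenerate pivot ties through R's global RNG, so each
  solve pins the RNG to a fixed constant and restores the caller's stream —
  making scans bit-reproducible, an invariant the tests check.
* **Overlap integral.** Evaluated analytically via the crossing points of
  the two normal densities: one crossing for equal $\sigma$ (closed form
  $2\Phi(-|\Delta\mu|/2\sigma)$), up to two otherwise, each piece a
  difference of normal CDFs. The quadrature fallback integrates the
  pointwise minimum over the intersection of the two 9σ windows (outside
  it the minimum is negligible by construction), which keeps the integrand
  well scaled even for near-disjoint densities.
* **Degenerate inputs.** Fixed-flux spans get `sigma_floor`; overlap below
  `1/score_cap` maps to the cap rather than infinity; exact score ties are
  broken by larger absolute mean shift, then lexicographic reaction id, so
  reports are deterministic.

## What the synthetic models emulate — and what they do not

`build_branched_toy()` generates the smallest network with a planted
answer: a carbon source, a linear trunk, a product branch competing with a
biomass branch at a hub, an optional cofactor drain coupled to production,
and a two-reaction internal cycle as a decoy whose span never responds to
enforcement. Stoichiometric consistency at the hub (carbon in = product +
biomass carbon out) makes the optima analytic: with uptake 10 and a 10%
growth floor, `max_growth` = 10, MTY = 9, and at full enforcement the
product branch is pinned at [9, 9] and the competing branch at [1, 1].
Seeded variants jitter only decoy bounds, never the planted pathway, so
the ground truth stays exact across the recovery suite.

These fixtures exercise the algorithm's logic, not its scale: they have no
alternative routes of differing yield, no cofactor balancing across
compartments, no redundant isozymes, and a fraction of the degeneracy of a
genome-scale model. Passing the recovery suite shows the scoring machinery
is correct, not that any particular organism's model will yield fruitful
targets; on real models the ranked list is a prioritization, with expected
false positives from the missing regulation and kinetics.

## Problem sizes used in validation

The shipped validation uses 8-reaction fixtures throughout: the
flux-polytope vertex-enumeration oracle checks every FVA bound on 20 seeded
models, the recovery suite runs the full pipeline on the default fixture
plus 10 seeded variants, and the overlap oracle compares 1,000 random
gaussian pairs against dense quadrature. These sizes keep the entire suite
under half a minute while covering every code path; the dense simplex
backend is comfortable into the hundreds of reactions, and the scan's cost
grows linearly in reactions × fractions (two LPs each).

## Known limitations

* The dense simplex backend makes genome-scale scans (thousands of
  reactions) slow compared to sparse interior-point solvers; the method's
  logic is solver-agnostic, and the LP layer is isolated behind
  `optimize_flux()`/`flux_variability()` for substitution.
* Reversible reactions are treated as signed net fluxes and not split; a
  reaction whose span is symmetric around zero in both states can hide a
  directional shift.
* Plain FVA is used — no loopless correction — so thermodynamically
  infeasible cycles (like the fixture's decoy) retain wide spans; they are
  harmless to the ranking because their spans do not respond to
  enforcement, but they can inflate span widths in real models.
* SBML support is Level 3 FBC v2 only; earlier encodings are rejected with
  a clear message rather than half-parsed.
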