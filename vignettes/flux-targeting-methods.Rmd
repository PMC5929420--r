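---
title: "Transcriptome-constrained flux analysis and selective target discovery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-constrained flux analysis and selective target discovery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxwindow)
```

## The model

A genome-scale metabolic model (GSMM) is a stoichiometric matrix $S$
(metabolites $\times$ reactions) together with flux bounds
$l_r \le v_r \le u_r$ (mmol gDW$^{-1}$ h$^{-1}$) and gene–protein–reaction
links. Under the steady-state assumption $S v = 0$, flux balance analysis
(FBA) predicts a flux distribution by maximizing the flux of a biomass
pseudo-reaction, whose value is the predicted growth rate (h$^{-1}$).

`fluxwindow` implements a pipeline around that core:

1. **Expression constraining** (`fullConstrain`). Each gene-associated
   reaction receives a capacity ceiling $B = k \cdot E$, where $E$ is the RPKM
   of its highest-expressed associated gene rounded *up* to the next multiple
   of the granularity (default 10), and $k = 0.0027$
   mmol gDW$^{-1}$ h$^{-1}$ per RPKM. Forward reactions are bounded to
   $[0, \min(u, B)]$, backward ones to $[\max(l, -B), 0]$, and reversible ones
   to $[\max(l,-B), \min(u, B)]$. Gene-less reactions (exchanges, spontaneous
   steps) are left untouched; a reaction whose genes are all unexpressed is
   closed. The constant $k$ is phenomenological — it is calibrated so the
   constrained model reproduces a measured growth rate (`calibrateK` performs
   this inversion by bisection, valid because growth is non-decreasing in
   $k$: larger $k$ only widens bounds).

2. **Flux estimation** (`pfba`). Fluxes are point-estimated parsimoniously:
   first maximize biomass ($z^\*$), then fix the biomass flux at
   $\ge (1-\varepsilon) z^\*$ and minimize $\sum_r |v_r|$ via the standard
   split into non-negative forward/backward components. The inequality (rather
   than equality) fixation is a numerical-robustness choice; with the default
   tolerance $\varepsilon = 10^{-7}$ the growth loss is negligible, and the
   parsimonious stage zeroes futile cycles.

3. **Alternative optima** (`sampleAlternativeOptima`). The FBA optimum is
   typically a face, not a point, of the flux polytope. The sampler fixes the
   objective at its optimum and repeatedly maximizes a random linear objective
   with i.i.d. standard-normal coefficients, collecting vertex solutions of
   the optimal face. Per-reaction means and standard deviations summarise how
   determined each flux is. The scheme is seeded and bit-reproducible; it
   characterises the *extreme points* of the face rather than sampling it
   uniformly (a hit-and-run sampler would do the latter; the summary
   statistics of interest — spread vs. no spread, conserved totals — do not
   depend on that distinction, and the vertex scheme needs no burn-in or
   mixing diagnostics).

4. **Throttling** (`blockReactions`). The growth effect of inhibiting a
   reaction set is scored by capping each member at a fraction (default 0.1)
   of its baseline parsimonious flux and re-solving; the score is the ratio of
   blocked to baseline growth. The fraction is deliberately non-zero: real
   inhibition is partial, and essential reactions can often be strongly
   reduced before growth collapses proportionally. A ratio equal to the
   fraction means full coupling; 1 means full compensation through
   alternative routes. When every bound brackets zero, scaling the baseline
   solution by the fraction stays feasible, so the ratio can never fall below
   the fraction — this is asserted as a test invariant on the fixtures.

5. **Selective target search** (`findTargetSet`). Given a target and a
   reference model (same network, different expression constraints), the
   greedy heuristic ranks reactions by $|v^{target}| - |v^{reference}|$
   (descending) and walks the ranking, tentatively throttling each candidate
   in *both* models on top of previously kept constraints. A candidate is kept
   iff the target's cumulative relative growth drops below 0.9 **and** the
   reference's exceeds the target's by more than 0.05; the search stops when
   the target's relative growth reaches 0.5. The output records the accepted
   set, a full decision trace, and whether the stop was reached.

6. **Differential statistics** (`differentialUse`, `welchT`, `bhFDR`,
   `hallmarks`). Reactions whose fluxes differ between sample groups
   ("differentially used") are called per-feature by a two-sample t-test with
   Benjamini–Hochberg correction at FDR 0.01; hallmark reactions are the
   significant reactions backed by at least one significant associated gene.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `k` | 0.0027 | mmol gDW$^{-1}$h$^{-1}$ per RPKM | expression-to-capacity scale; calibrate per dataset |
| `granularity` | 10 | RPKM | discretisation of expression before scaling; avoids LP noise |
| `blockFraction` | 0.1 | — | residual flux under inhibition |
| `singleThreshold` | 0.9 | — | minimum target growth impairment to keep a candidate |
| `selectivityMargin` | 0.05 | — | required reference-minus-target growth gap |
| `stopRatio` | 0.5 | — | target growth at which the search stops (cytostatic goal) |
| `fdrLevel` | 0.01 | — | differential-call significance |
| `solverTolerance` | $10^{-7}$ | — | LP feasibility/optimality slack |

The invariant $0 <$ `blockFraction` $<$ `stopRatio` $<$ `singleThreshold`
$< 1$ is enforced at construction.

## Design choices where the design was open

- **GPR flattening.** Because constraining uses only the *highest expressed*
  associated gene, AND/OR association structure is collapsed to a flat gene
  list at read time. A complex whose limiting subunit is lowly expressed is
  therefore bounded optimistically; a min-over-AND-members semantics is a
  possible refinement that the data model deliberately does not guess at.
- **Genes absent from the profile count as unexpressed** (bound 0), with a
  counted warning. Leaving them unconstrained would silently keep
  non-expressed pathways open, which is exactly what expression constraining
  is meant to prevent. Zero RPKM rounds to 0, not to the granularity, for the
  same reason.
- **Reversible reactions are capped on both sides** at $\pm B$: the enzyme's
  capacity limits catalysis in either direction.
- **Ranking by flux magnitudes.** The candidate ranking uses
  $|v^{t}| - |v^{r}|$ so that reversible reactions rank by usage regardless of
  sign; `rankSigned = TRUE` switches to the signed difference. Ties break
  lexicographically by reaction id for cross-platform determinism.
- **"Original flux" is the initial baseline.** Inside the greedy search the
  throttle for a candidate always refers to its flux in the *initial*
  parsimonious solution of each model, not one recomputed after each
  acceptance; the procedure stays order-dependent but deterministic.
  Zero-flux-in-both-models candidates are skipped — closing an unused
  reaction cannot change either ratio.
- **LP backend.** Problems of this package's size (tens of reactions on the
  fixtures) are solved by a dense bounded-variable two-phase primal simplex
  with Bland's anti-cycling rule, behind a single internal
  `solve(c, S, lb, ub)` contract so a different backend can be swapped in.
  Every fixture solve is cross-checked in the test suite against an
  exhaustive vertex-enumeration oracle, which on networks this small is a
  complete search of all basic solutions.

## The fixtures: what they emulate, and what they do not

The generator (`makeFixtureModel` / `makeFixtureProfiles`) produces the
smallest networks exhibiting each regime the method must distinguish:

- `CHAIN3` — full coupling: one substrate, one enzyme (gene `g1`, 37 RPKM so
  that the capacity is $0.0027 \times 40 = 0.108$), one biomass drain.
- `PARALLEL` — compensation and degenerate optima: a second route (gene `g2`).
  Both route genes are set to 5000 RPKM so that substrate *uptake* (bound
  $-10$) is limiting rather than enzyme capacity: each route alone can carry
  the whole optimum, which is what makes single-route throttling fully
  compensated and gives the sampler a genuinely degenerate optimal face.
- `SELECTIVE` — the therapeutic-window mechanism: biomass needs B and C; C is
  importable (transporter `T`, gene `gT`) or synthesisable (`S`, gene `gS`).
  The target profile lacks `gT` (as a cell lacking a transporter gene), the
  reference expresses it. Synthesis consumes two substrate units per product,
  so a cell with the choice imports — this keeps the reference's parsimonious
  solution off the synthesis route, as a real cell would be, and makes the
  synthesis reaction the top-ranked, uniquely selective candidate.
- `CYCLE` — a balanced futile cycle that parsimony must silence.
- `RANDOM` — seeded sparse networks with a planted chain guaranteeing
  feasibility, used for property tests (bound contracts, round trips).

All fixture bounds bracket zero: no forced maintenance fluxes. What the
fixtures do **not** emulate: compartments, cofactor coupling, biomass
equations with realistic precursor proportions, thousands of reactions, or
noisy expression data. Tests passing on them validate the *mechanics* of the
method (LP correctness, bound arithmetic, search logic, statistical
calibration), not biological predictions on real genome-scale models, which
additionally depend on model curation and expression normalisation.

## Numerical choices and degenerate inputs

- Objective fixation uses $\ge (1-\varepsilon)z^\*$; tests therefore compare
  parsimonious totals to the oracle at tolerance $10^{-4}$ rather than
  machine precision.
- Rounding up to a granularity is implemented with an exact post-correction so
  that exact multiples are their own ceiling even when the floating-point
  quotient lands marginally above an integer.
- Infeasible and unbounded models are reported through the `status` slot of
  `FluxDistribution`; only contract violations (e.g. searching targets on a
  model with no growth) raise classed errors.
- Two constant, equal groups give $t = 0, p = 1$; constant but different
  groups give $p = 0$ flagged `degenerate`. Zero-variance features in
  `differentialUse` inherit these rules.
- Welch's unequal-variance test is the default (`pooled = TRUE` restores
  Student's); the multiple-testing correction is Benjamini–Hochberg, isolated
  behind `bhFDR` so a different procedure could be substituted.

## Problem sizes used in tests

The test suite and the acceptance script run entirely on the fixtures: vertex
enumeration up to 6-reaction networks, 200 seeded random model/profile pairs
(8 reactions each) for the constraining contract, 50 random throttle pairs
for monotonicity, 100 sampler draws, and a 20-replicate, 1000-feature null
for FDR calibration. These sizes exercise every code path while keeping the
whole suite in the tens of seconds on one CPU; all statistical checks are
seeded.

## Known limitations

- No AND-aware (complex-limited) gene association semantics, by design (see
  above).
- The sampler characterises vertices of the optimal face, not its uniform
  measure.
- The greedy search is a heuristic: it returns *a* small selective set along
  its ranking, not a provably minimal cut set; on the fixtures its result is
  verified minimal by brute force, which is not feasible at genome scale.
- No thermodynamic (loopless) constraints; parsimony suppresses futile cycles
  in the reported point estimate but does not forbid them in the feasible set.
- SBML support covers Level 3 + fbc and the legacy Level 2 COBRA dialect;
  SBML writing is out of scope.
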