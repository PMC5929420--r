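# fluxwindow

Constraint-based prediction of selective metabolic drug targets from RNA-seq.

## The problem

Cancer cells rewire metabolism to proliferate, and that rewiring is, in
principle, druggable — but a useful metabolic target must impair the tumour's
growth while sparing healthy tissue. Measuring fluxes directly (e.g. by
¹³C labelling) covers only central carbon metabolism; RNA-seq is cheap and
genome-wide. `fluxwindow` is for computational/systems biologists who want to
go from a genome-scale metabolic model (GSMM) plus per-sample RPKM tables to
(i) putative flux distributions per cell type and (ii) small reaction sets
predicted to *selectively* halt a target cell's growth — a personalised
"therapeutic window".

## The method

With stoichiometric matrix $S$, flux bounds $l \le v \le u$ and a biomass
objective, the pipeline is:

1. **Expression constraining** — every gene-associated reaction gets the
   capacity cap $B = k \cdot \lceil E \rceil_{10}$, where $E$ is the RPKM of
   its highest-expressed gene, $\lceil\cdot\rceil_{10}$ rounds up to the next
   multiple of 10, and $k = 0.0027$ mmol gDW⁻¹h⁻¹ per RPKM (calibrated
   against a measured growth rate; `calibrateK` re-derives it by bisection).
   Gene-less reactions stay unconstrained; unexpressed reactions close.
2. **Parsimonious FBA** — maximize biomass $z^*$ subject to $Sv = 0$ and the
   bounds, then minimize $\sum_r |v_r|$ with biomass fixed at
   $\ge(1-\varepsilon)z^*$.
3. **Throttling** — cap a candidate reaction set at 10% of its baseline flux
   and report the ratio of blocked to baseline growth (0.1 = fully coupled,
   1 = fully compensated).
4. **Greedy window search** — rank reactions by
   $|v^{\mathrm{target}}| - |v^{\mathrm{reference}}|$, throttle candidates in
   both models, keep those with target relative growth $< 0.9$ and a
   reference−target gap $> 0.05$, stop when the target's growth halves.
5. **Cohort statistics** — Welch t-tests with Benjamini–Hochberg correction
   (FDR 0.01) call differentially used reactions and differentially expressed
   genes; reactions significant on both levels are metabolic hallmarks.

Alternative optimal flux distributions (the optimal face of the polytope) are
characterised by seeded random-objective vertex sampling
(`sampleAlternativeOptima`).

## Worked example

The built-in `SELECTIVE` toy network has a biomass reaction consuming two
precursors; the second precursor can be imported (transporter `T`, gene `gT`)
or synthesised at double substrate cost (`S`, gene `gS`). The target cell
does not express the transporter gene; the reference does.

```r
library(fluxwindow)

model     <- makeFixtureModel("SELECTIVE")
profiles  <- makeFixtureProfiles("SELECTIVE")
target    <- fullConstrain(model, profiles$target)
reference <- fullConstrain(model, profiles$reference)

objectiveValue(pfba(target))
#> [1] 0.135
objectiveValue(pfba(reference))
#> [1] 0.135

ts <- findTargetSet(target, reference)
ts
#> TargetSet: 1 accepted reaction(s) [S]
#>   target growth ratio 0.1, reference 1, converged: TRUE
decisionTrace(ts)
#>   reaction_id target_ratio_after reference_ratio_after accepted
#> 1        EX_A         0.09999999            0.09999999    FALSE
#> 2           S         0.09999999            1.00000000     TRUE
```

Both cells initially grow at 0.135 h⁻¹ (their enzyme capacities are
0.0027 × 50-RPKM-rounded-to-50 = 0.135). The search first tries the substrate
uptake `EX_A` — it cripples both cells equally (ratios 0.10 vs 0.10), so it
is rejected for lack of selectivity. Throttling the synthesis reaction `S`
to 10% of its baseline flux drops the transporter-less target to 10% of its
growth while the reference reroutes through import and keeps 100%: `S` is
accepted, the target's relative growth (0.1) is below the 0.5 stopping
threshold, and the search converges with a one-reaction target set.

The same pipeline is scriptable from a shell via the thin wrapper in
`inst/scripts/fluxwindow` (subcommands `constrain`, `flux`, `sample`,
`block`, `screen`, `personal`, `diffuse`, `hallmarks`, `fixture`,
`calibrate`), which writes a `*.manifest.json` (config snapshot + input
digests) next to every output.

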