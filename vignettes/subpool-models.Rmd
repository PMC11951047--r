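---
title: "Modeling promiscuous enzyme activity with per-reaction subpools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling promiscuous enzyme activity with per-reaction subpools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coral)
```

## The problem

In a GECKO-style protein-constrained model, every enzyme is a
pseudometabolite consumed by the reactions it catalyses at MW/kcat per unit
flux, and enzyme supply is drawn from a finite protein pool. This couples
flux to enzyme investment, but it treats a promiscuous enzyme — one
catalysing two or more reactions — as a single undifferentiated resource:
there is no way to ask how much of the enzyme serves its main reaction
versus its side (underground) activities, and no way to disable the main
activity while leaving the side activities available. Gene knockouts
cannot do it either, because a knockout removes *all* reactions the gene
product catalyses.

This package restructures the model so each promiscuous enzyme's pool is
split into per-reaction **subpools**. Catalysed reactions are ranked within
each enzyme by their specific enzyme cost MW/kcat: rank 1 — the largest
kcat, the cheapest activity — is the main reaction, higher ranks are side
reactions. The subpool of rank *i* is the share of the enzyme dedicated to
that one activity, and defects can be introduced at the level of a single
activity by zeroing a single subpool.

## Wiring and units

Fluxes are mmol/gDW/h, molecular weights g/mmol, turnover numbers 1/h
(per-second inputs are converted at read time), enzyme usages mmol/gDW.
The pool layer is wired in mass units:

- a total-protein pseudometabolite with an exchange bounded by
  E~tot~ = P~tot~·σ·f, defaults P~tot~ = 0.61 g protein/gDW (measured total
  protein content of *E. coli*), σ = 0.5 (average saturation), f = 0.5
  (fraction of proteome in the model);
- one pool pseudometabolite and supply pseudoreaction per enzyme (1:1 in
  mass), so the supply flux is the enzyme's mass investment;
- one subpool pseudometabolite and pool-draw pseudoreaction per catalysed
  (reaction, direction); the catalysed reaction consumes its subpool with
  the pseudo-stoichiometric coefficient MW/kcat.

Steady state of the pseudometabolites then enforces, exactly: usage equals
flux/kcat per subpool, subpool draws sum to the enzyme pool, and total
enzyme mass stays within the budget. A reversible catalysed reaction is
split into forward and reverse copies, each with its own kcat and its own
subpool — the two directions are distinct catalytic activities (the
reverse mode of ATP synthase is the motivating example). Reactions whose
GPR genes have no enzyme record carry no protein cost, the usual GECKO
convention.

GPR simplification precedes the enzyme layer: OR branches (isozymes)
become duplicate reactions with one catalyst each; an AND conjunction of
k enzymes becomes k partial reactions chained through k−1 linking
pseudometabolites, so all partials carry the same flux and each has
exactly one catalyst. Chaining couples the subunits' usages through that
common flux; subunit stoichiometry inside a complex is taken as 1:1
unless data say otherwise. Whether partial fluxes should instead be left
independent is not observable from the outside behaviour of the model we
reproduce; coupling is the stricter, mass-conserving choice and is what
the chain construction gives naturally.

## Ordering constraints

Biologically, enzymes are mostly occupied by their native substrate, so
resource allocation should favour the catalytically efficient activity.
The package expresses this as linear rows over subpool draws,
kcat~i+1~·E~s,i+1~ ≤ kcat~i~·E~s,i~ along consecutive ranks (`"chain"`,
the default, reading the prioritisation as a succession over the ordered
kcats). Because usage is tied to flux, this says a side reaction can never
run faster than the activity one rank above it. Alternative topologies are
available: `"vs_main"` compares every side subpool to the main one only,
`"equality"` forces equal maximal velocities across ranks (the reading
under which allocation ratios are exactly reciprocal kcat ratios — a
strong assumption worth relaxing, which is why it is optional here), and
`"off"` disables the rows.

With ties in MW/kcat (identical kcats and one MW), ranks are assigned by
lexicographic reaction id. This is deterministic, and the feasible region
is invariant under the tie order, which the test suite checks with the
independent oracle.

**Interaction with blocking.** Blocking a subpool means zeroing its draw.
Under the chain topology a zeroed main subpool would propagate
kcat~2~·E~s,2~ ≤ kcat~1~·E~s,1~ = 0 down the whole hierarchy and forbid any
redistribution — precisely the compensation the defect analyses exist to
measure, and incompatible with redistribution to deep ranks through
intermediate subpools that carry no flux. The package therefore releases
*all* ordering rows of a blocked enzyme, the same way all of its subpools
are released from the wild-type band; other enzymes keep their
hierarchies. This is the only reading we found under which
deep-rank rescue (pool moving to rank 3 while a dead-end rank 2 stays at
zero) is feasible.

## The analyses

- `fva_flux()` / `fva_subpools()`: per-target minimum and maximum under the
  shared constraints; scenarios toggle underground reactions (blocked =
  both bounds zero on every reaction derived from an underground reaction)
  and a fixed growth rate (the chemostat condition, growth pinned to the
  dilution rate). Targets are solved independently, so results are
  order-free and trivially parallelisable.
- `pfba_subpools()`: minimum total molar enzyme usage at fixed growth — the
  parsimonious wild-type reference. The objective value is unique;
  individual usages inherit whatever degeneracy the network has.
- `wt_reference()` + `block_main_single()` / `screen_single_blocks()`:
  re-optimize growth with one main subpool zeroed, all other enzymes held
  to the wild type within a flexibility band (default 5%), and the blocked
  enzyme fully released. Band placement is per subpool draw by default; a
  `band_level = "pool"` switch bands per-enzyme totals instead — the
  equation the band comes from is ambiguous between the two, and the
  subpool reading is the one that makes redistribution analysis
  meaningful. Subpools unused in the wild type get the band [0, 1e-8]
  rather than a proportional one; otherwise no idle subpool could ever
  activate, and observed redistribution is precisely idle subpools
  activating.
- `block_main_pairs()` / `block_side_pairs()`: pairwise blocks at rank 1
  (or a side rank k = 2..5; enzymes lacking rank k are skipped) without
  the wild-type band, reporting growth ratios, the 1% impact threshold,
  and each pair's promiscuity status (an enzyme is promiscuous when its
  registry has K ≥ 2 subpools).
- `double_gene_knockout()`: the conventional contrast — GPR-boolean
  knockouts on the unrestructured model, which remove side activities
  along with the main one.
- `flux_sums()` / `flux_sum_delta()`: metabolite turnover
  φ~i~ = ½·Σ~j~ |S~ij~·v~j~| and wild-type-vs-defect differences.
  Pseudometabolites (pools, subpools, linking metabolites) are accounting
  devices and are excluded by default.

Choosing the wild-type growth rate matters: at the protein-limited batch
optimum the budget has no slack, the band pins all fluxes near wild type,
and almost every main-reaction block is lethal because side activities
need more enzyme mass per unit flux. A chemostat-like rate below the
optimum (the scripts use half of it) leaves slack and makes the
compensation structure visible.

`block_main_pairs()` compares growth ratios against the unblocked optimum
by default, which guarantees ratios ≤ 1 on any model; passing
`mu_wt = 0.1` reproduces the conventional fixed-reference setup, and the
CLI uses that as its default.

## Numerical choices

LPs are assembled sparsely and solved in batches by HiGHS through
`scipy.optimize.linprog` in a `python` subprocess; one batch per screen, so
interpreter start-up is paid once per analysis. Solver defaults are used
(primal/dual feasibility 1e-7 in HiGHS); downstream checks use an absolute
1e-8 "carries flux / subpool in use" threshold and solutions are verified
in tests to residuals ≤ 1e-6. Infeasible blocks are reported as lethal
outcomes, not errors; unbounded problems are surfaced as such, since they
signal a missing budget or bound. "Non-lethal" means optimal status with
growth above 1e-6 1/h. All computations are deterministic: the only
randomness in the package is the fixture generator's seed, and rebuilding
or re-screening with the same inputs is byte-identical.

## What the synthetic fixtures do and do not show

The generator (`make_fixture()`) builds a linear backbone pathway with a
substrate uptake of 10 mmol/gDW/h feeding a biomass sink, one enzyme per
leading step with a configurable number of side reactions — productive
ones duplicate the main conversion, the rest are dead ends — plus optional
isozyme and complex steps and underground reactions attached as extra
low-kcat activities of existing promiscuous enzymes. kcats are drawn
log-uniformly over 1e2–1e4 1/h (the bulk of measured turnover ranges), MWs
uniformly over 10–50 g/mmol, and the protein-pool defaults are the ones
above, so budgets genuinely bind at high growth. The canonical
`fixture_suite()` isolates single structural features: a near-equal-kcat
direct-transfer enzyme, a deep-rank rescuer behind a dead-end rank 2, a
non-promiscuous essential pair, isozyme-backed redundancy, an AND complex,
an OR pair, and tied kcats.

These fixtures have the promiscuity *structure* of a real network but not
its scale, loops, cofactor coupling or biomass composition. Tests passing
on them demonstrate that the formulation and algorithms are correct — the
subpool split is a pure refinement, conservation holds, screens match an
independent dense-LP assembly — not that any biological conclusion
transfers to a particular organism; that requires a curated genome-scale
model and measured or predicted kcats as inputs, which the readers
(`read_gem()`, `read_enzyme_table()`, `read_underground_table()`) accept
in community formats. The problem sizes used throughout the tests and the
acceptance script (backbones of 4–6 steps, up to ~35 reactions and ~12
subpools after restructuring, 20 random replicates) were chosen so the
whole battery of LP screens stays comfortably interactive.

## Known limitations

- The ordering rows encode prioritisation through velocities, inheriting
  the equal-V~max~ flavour of the underlying assumption; enzymes whose side
  activities have higher V~max~ than a slower main activity are not
  representable without switching the topology off.
- Usage equals flux/kcat by construction, so "allocated but idle" enzyme
  exists only as pool-exchange slack, not per subpool.
- Complex subunit stoichiometry is 1:1; kcat inference and tuning are out
  of scope (kcats are inputs).
- The duplicate-reaction screen compares stoichiometric columns by cosine
  similarity only; it reports (or on request removes) pairs, it does not
  merge annotations.
- The dense oracle is a correctness tool and refuses models beyond ~200
  network reactions; the main path has no such limit but toy-scale models
  are the intended regime for the bundled analyses.
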