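---
title: "Range-evolution models on island arcs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range-evolution models on island arcs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decarc)
```

## The model

decarc implements the Dispersal-Extinction-Cladogenesis (DEC) family of
historical-biogeography models.  The state of a lineage is its
*geographic range*: a non-empty subset of `A` discrete areas, capped at
`max_range_size` areas.  With 12 areas and a cap of 3 the space holds
`choose(12,1) + choose(12,2) + choose(12,3) = 298` ranges; an empty
(null) range is carried internally as an absorbing state reached by the
extinction of a single-area range, but it is never valid data and is not
counted.

Two processes act on ranges:

* **Anagenesis** (along branches) is a continuous-time Markov chain.
  Range expansion adds one area `b` to range `R` at rate
  `d * sum(a in R) m[a,b] * dist[a,b]^x`, where `m` is a dispersal
  multiplier matrix (hard constraints are 0, soft constraints values
  such as 0.5) and `dist^x` is the distance modifier; contraction
  removes one area at rate `e` per occupied area.  `d` and `e` are in
  events/Myr; `x` is dimensionless and expected non-positive, so that
  farther targets receive lower rates.

* **Cladogenesis** (at nodes) distributes the parent range over the two
  daughters.  A single-area parent copies itself (weight 1).  A
  widespread parent undergoes subset sympatry (one daughter inherits one
  area, the other the full range; weight 1 per member area) or narrow
  vicariance (one member area versus the rest; weight 1 per member).
  The `+J` extension adds founder-event jumps: a daughter starts in a
  single *outside* area `b` with weight `j * mod(R, b)`, where `mod` is
  the same multiplier-and-distance modifier (the mean over the parent's
  member areas).  Weights are normalized per parent, so cladogenesis
  probabilities are time-free.

The four family members — DEC, DEC+J, DEC+x, DEC+J+x — carry 2, 3, 3 and
4 free parameters: the sympatry/subset/vicariance weights stay fixed at
1 and only `d`, `e`, and optionally `j` and `x` are estimated.

### Time stratification

Geography changes over geological time, so a scenario is an ordered list
of epochs, each with its own distance matrix, multiplier matrix and set
of available areas (ages in Ma, present = 0).  Branch segments are cut
at epoch boundaries, per-segment transition matrices are multiplied in
old-to-young order, and on entry into an epoch the probability mass of
any state containing an area that does not exist there is zeroed
*without renormalization*: a lineage that would have had to occupy a
non-existent area is simply an impossible history.  Cladogenesis at a
node uses the table of the epoch the node's age falls in.

### Likelihood, fitting, ancestral ranges

Tip ranges are indicator vectors over the state space; Felsenstein
pruning propagates conditional likelihoods up each branch with the
(epoch-aware) transition matrices and combines daughters through the
cladogenesis table.  The root likelihood averages over all non-null
states available at the root age (a uniform root prior, the convention
of the standard implementations of this model family).

Fitting maximizes the log-likelihood with bounded `L-BFGS-B` from a
deterministic multi-start grid; `d`, `e`, `j` are searched on the log
scale (bounds `[1e-12, 5]` for the rates, `[0, 3]` for `j`) and `x`
linearly in `[-10, 2]`.  Because `+J` surfaces are often multi-modal,
the `(d, e)` grid `{(0.01, 0.01), (0.1, 0.01), (0.01, 0.1)}` is crossed
with starts for the extra parameters; for DEC+J+x we pair `(j, x)` as
`(1e-9, 0)` (the j boundary, which guarantees the nested DEC optimum is
always reachable and nesting inequalities hold at convergence),
`(0.01, 0)` (weak effects) and `(0.5, -1)` (strong effects) rather than
taking the full four-way cross — profiling showed the paired corners
reach the same optima at half the cost.  Fits are fully deterministic.

Per-node ancestral-range marginals (the node pie charts of
biogeography figures) come from the up-down algorithm: rootward partial
likelihoods times tipward conditionals, normalized per node.  They refer
to the state *at* the node, immediately before cladogenesis.  Published
analyses of this kind occasionally override individual node ranges on
biological grounds; no such heuristic is applied here — the marginals
are reported as computed.

### Model comparison

`AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)` with `n` the number of tips.
Evidence ratios are `exp(-(AICc - min AICc)/2)` (best model 1), and
normalizing them gives relative model probabilities, rendered as rounded
percentages.  DEC-type models are nested in their `+J` counterparts, so
pairs are also compared by a likelihood-ratio test with one degree of
freedom.  The bundled reference table (`inst/extdata/
sunda_weevil_models.tsv`) carries the published log-likelihoods of 24
such fits for a 191-tip weevil radiation across the Indo-Australian
Archipelago; the test suite and the acceptance script recompute its
AICc, evidence-ratio and percent columns from the `lnL`/`k` columns
alone.

### Numerical choices

* Transition matrices are matrix exponentials.  The engine
  eigendecomposes each epoch's generator once per parameter set and
  propagates by `V exp(Lambda t) V^-1`; if the decomposition fails to
  reproduce `Q` to 1e-9 (near-defective generators arise at `e = 0`,
  where eigenvalues repeat) it falls back to uniformization, switching
  to a Padé exponential when `rate * t > 60` keeps the series short.
  The structural parts of `Q` and of the cladogenesis table are
  precomputed once per scenario and refilled per parameter set; the test
  suite checks the filled objects against the plain reference builders.
* Conditional-likelihood vectors are rescaled at every node to avoid
  underflow on large trees.
* Distances enter raw (km); rescaling all distances by `c` is absorbed
  exactly by `d -> d c^(-x)` (and `j -> j c^(-x)` when jumps carry the
  distance modifier), so the distance *unit* is immaterial.  The
  sentinel distance 9999 km marks geologically implausible pairs:
  under negative `x` dispersal stays possible but negligible, which is
  the intended "soft exclusion".
* Whether the distance modifier also applies to jump weights is a
  documented switch (`jump_distance` in `dec_model()`, default on, the
  convention of the software this model family comes from).
* Ultrametricity is enforced within 1e-6 Myr; adjacency between areas
  is always explicit user input (it encodes geology, not metric
  proximity).

## Parsimony reconstruction

As an assumption-free cross-check, `fitch_asr()` reconstructs ancestral
areas by uniform-cost Fitch/Sankoff parsimony on the topology alone
(every tip must occupy exactly one area).  The Sankoff dynamic program
is used throughout, so arbitrary cost matrices remain available, and the
up-pass reports the full set of states attained by some
most-parsimonious reconstruction.  Event counting resolves the
reconstruction with DELTRAN (ties keep the parent's state, delaying
changes tipward; ACCTRAN is available) — any such resolution is itself
most parsimonious, so the total equals the Fitch minimum and is reported
as the "at least N events" lower bound alongside the per-pair counts,
whose split between pairs does depend on the rule.  Per-area
lineage-accumulation curves count branches crossing each bin boundary
(default 2 Myr bins); a branch whose ends disagree is assigned the
ancestral area on its older half (change at the branch midpoint — the
unbiased placement absent any information about where on the branch the
change happened).

## The synthetic-data generator

No machine-readable empirical dataset ships with the package; the
simulator stands in for one and makes every stage testable.

* `arc_distances()` builds a linear arc of 8 areas (defaults) with fixed
  nearest-neighbour gaps of 100-300 km — the geometry of a volcanic
  island chain; `arc_scenario()` removes the two westernmost areas in
  the old epoch, mimicking islands that emerged late.  Distances are
  rescaled to a maximum of 1 by default: the likelihood is invariant to
  the unit, and on the rescaled scale default parameter magnitudes like
  `d = 0.02` produce realistic event densities.
* `sim_bd_tree()` draws constant-rate birth-death trees conditioned on
  the number of extant tips (via `ape::rphylo`), ages in Ma.
* `sim_range_history()` runs the exact model forward: Gillespie
  simulation of the anagenetic chain along branches (rates switching at
  epoch boundaries, areas dropped when they cease to exist) and
  cladogenetic draws at nodes, with a complete event log that replays to
  the tip ranges bit-exactly.  Because nearly all real tips in such
  systems are microendemics, the default collapses any multi-area tip
  range to a single area at the present (`tip_singleton = "contract"`);
  this can be switched to rejection sampling or off.
* `recovery_experiment()` simulates, refits, and tabulates bias, RMSE
  and median relative error, plus AICc selection frequencies.  It
  simulates with `tip_singleton = "none"` so the fitted model is
  exactly the generating model: forcing tips to single areas
  misspecifies the fit and exposes the known founder-event degeneracy
  (`d, e -> 0` with jumps absorbing everything), under which `d` is not
  identifiable — a caveat worth remembering when interpreting `+J` fits
  to microendemic data.

What passing simulations do *not* show: real datasets carry dating
error, incomplete sampling, range polymorphism and geological
uncertainty that the generator does not emulate; recovery results bound
estimation error under the model, not under reality.

## Problem sizes used in the shipped checks

The test suite exercises enumeration oracles on trees of 2-4 tips over
2-3 areas (200 random parameter draws), parameter recovery on 25
replicates of 200-tip trees over a 6-area arc
(`d = 0.02, e = 0.005, j = 0.2, x = -1`), and a full 24-model pipeline
(12 variants, stratified and not) on a 50-tip, 8-area synthetic
dataset.  The acceptance script repeats the pipeline at 40 tips and the
recovery at 10 replicates.

## Known limitations

* Only the DEC family: no DIVA- or BAYAREA-like cladogenesis, no
  estimation of the fixed cladogenetic weights, no widespread-widespread
  vicariance.
* Marginal (not joint) ancestral states; no stochastic mapping.
* Tips must be single ranges known without error; no range
  polymorphism or detection uncertainty.
* The founder-event degeneracy above is a property of the model family,
  not of this implementation; compare `+J` fits against DEC and the
  parsimony reconstruction before leaning on them.
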