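---
title: "Growth-thresholded expression integration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-thresholded expression integration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemflux)
```

## The model and its assumptions

`gemflux` treats a genome-scale metabolic model as a linear system: a
stoichiometric matrix S (metabolites × reactions), per-reaction flux bounds
in mmol/gDW/h, and a biomass pseudo-reaction in g/gDW/h whose flux is the
predicted growth rate. Flux balance analysis maximises biomass flux subject
to S·v = 0 and the bounds. Three assumptions follow the standard
constraint-based canon and one is specific to this method:

* **steady state** — internal metabolite pools neither accumulate nor
  deplete over the simulated interval;
* **biomass objective** — proliferating cells allocate flux to maximise
  growth, a defensible objective for tumour cell lines though not for
  differentiated tissue;
* **expression as capacity** — a transcript abundance of E (log2(TPM+1))
  is read as an upper flux capacity of E mmol/gDW/h for the catalysed
  reaction. The units are incommensurable in principle; the method treats
  the mapping as an ansatz and relies on the growth threshold (below) to
  absorb its worst failures;
* **growth-rate/doubling-time duality** — with biomass in g/gDW/h the
  predicted doubling time is the reciprocal of the predicted growth rate,
  so an experimentally measured doubling time T defines a floor 1/T on
  admissible predicted growth.

The integration loop applies expression-derived bounds one reaction at a
time and keeps each constraint only if FBA still attains the floor. This is
deliberately asymmetric: constraints only ever tighten the model (the FBA
optimum is non-increasing across kept constraints), and any constraint whose
addition breaks the floor is rolled back in full. Reopened reactions are
therefore exactly the places where the transcriptome is inconsistent with
the observed growth phenotype — a diagnostic, not just a repair.

## Bound formulas per rule category

Gene-protein-reaction rules are classified by their operator content:
`one-gene`, `or` (isoenzymes), `and` (complex subunits), `andor` (both
operators), `none`. The first three are integrable: a single gene's
expression is used directly; isoenzyme expression is summed, on the view
that catalytic capacity is cumulative across alternative enzymes; subunit
expression enters as the minimum, since a complex cannot exceed its
scarcest subunit. Reversible reactions get the mirrored negative lower
bound; irreversible reactions keep 0. Mixed `andor` rules are skipped —
they are a small minority of annotated reactions and no single scalar
summary of a mixed rule is defensible; the disposition `andor_skipped`
makes the omission visible per reaction.

Two readings were left open by the scheme and resolved as follows:

* **missing genes** — a reaction is only constrained when *all* its rule
  genes are present in the profile (disposition `genes_missing`
  otherwise). Partial `or` sums would silently understate capacity where
  coverage is low; the conservative reading leaves the reaction at its
  prior bounds.
* **no cap on isoenzyme sums** — the `or` sum is not clipped at the
  default bound magnitude (1000 mmol/gDW/h). At log2 scale a sum exceeding
  1000 is unreachable in practice, and clipping would add a hidden
  discontinuity.

## The sequential loop and its order

The loop visits reactions in SBML document order, which is fixed as the
canonical order throughout the package (`order = "id"` gives a sorted
alternative). The procedure is order-sensitive — an early kept constraint
can change whether a later one violates the floor — so determinism requires
pinning the order; document order is the only order every SBML consumer
agrees on. Two further loop-semantics decisions:

* **relaxation scope** — only the currently provisional constraint is
  rolled back when the floor is violated; previously kept constraints are
  never revisited. A global re-optimisation of which constraint set to keep
  would be a different (combinatorial) problem.
* **essentiality is re-evaluated against the current, partially
  constrained model**, not the media-only model: the test (`closing the
  reaction drops the optimum below essential_fraction × current optimum`)
  protects the loop from constraining a reaction that has *become*
  load-bearing as earlier constraints accumulated.

`essential_fraction` defaults to 0.01: a reaction whose closure removes
more than 99 % of attainable growth is locked. At 0 the test degenerates to
"knockout optimum numerically zero", which is the boundary behaviour the
tests pin down.

If the requested floor exceeds what the media-constrained model can attain
at all, the loop warns and uses the attainable optimum as the effective
floor — integration then preserves the best reachable growth rather than
reopening everything.

## Media and serum estimation

A medium is a dictionary of exchange-reaction bounds. Applying it sets the
listed bounds verbatim, closes uptake (lower bound 0) on every unlisted
exchange, and leaves secretion open. The closure rule is not optional: a
medium that only *opened* reactions would constrain nothing. Uptake is
negative flux (COBRA sign convention).

Sera such as FBS are chemically under-defined, so a named-ingredient medium
can starve the model. `estimate_serum_components()` reconstructs plausible
missing components greedily: while growth is below the floor, every closed
candidate exchange is temporarily restored to default bounds, and the one
with the largest optimum gain is permanently reopened (ties broken by
document order). This is a reproducible reconstruction of what is, in
practice, a manual curation step; the per-step growth bookkeeping is
returned so the choice can be audited, and an unreachable floor yields a
partial estimate flagged `satisfied = FALSE` rather than an error.

## Numerical choices

* **LP solver** — an in-package dense two-phase primal simplex with
  Bland's rule. FBA equality systems (S·v = 0) are maximally degenerate,
  which defeats pivoting heuristics that are not cycling-safe; Bland's rule
  trades speed for guaranteed termination, an acceptable trade at the
  problem sizes this package targets (tens to a few hundred reactions; the
  test suite runs models of 5–30 reactions). The solver sits behind a
  single internal entry point (`solve_lp`) so a faster backend can be
  swapped in without touching any module.
* **parsimonious FBA** — flux *vectors* (used by the differential-flux
  module) default to pFBA: total absolute flux is minimised at the fixed
  optimum, choosing a reproducible representative among alternate optima.
  The optimum is pinned with a `≥ optimum − 1e-9` row rather than an exact
  equality, which keeps the phase-1 system non-degenerate. The integration
  loop itself uses plain FBA — only the optimum matters there.
* **tolerances** — objective comparisons against the growth floor use an
  absolute 1e-9; "non-zero flux" and the sign-change test use 1e-6
  mmol/gDW/h; knockout ratios tolerate 1e-6 above 1 before the invariant
  check fails.
* **degenerate inputs** — an infeasible model returns a `flux_solution`
  with `status = "infeasible"` rather than raising; a zero-growth baseline
  defines the knockout ratio as 1 when the knockout optimum is also zero;
  a correlation on fewer than 3 points or zero variance is an error naming
  the condition.

## Differential-flux criteria

Two groups of flux vectors are compared per reaction by three quantities:
relative change of the group means, `|m₁ − m₂| / max(|m₁|, |m₂|)` (0 when
both are 0); a magnitude condition, some sample flux in either group with
|flux| ≥ 0.5 mmol/gDW/h; and a direction change of the means beyond the
zero tolerance. A reaction is flagged when (relative change ≥ 0.10 AND
magnitude) OR direction change. Three readings were fixed here: the
denominator of "10 % change" is the larger absolute mean (the criterion is
then symmetric under group swap); the magnitude test is sample-level, not
mean-level (a single strong observation qualifies); and the reversible-flux
clause is an absolute-value test. All three intermediate quantities are
emitted per reaction so alternative combinations can be audited after the
fact. Raising either threshold provably shrinks the flagged set, and label
swap leaves it unchanged — both are asserted as properties in the tests.

## Validation statistics

The dependency-based validation works on CRISPR dependency scores in
[0, 1]. Group deltas are differences of group means per gene; the top-N
selection (default N = 250) sorts by delta with a lexicographic tie-break
and reports whether the cut fell inside a tie. Because a rank cut and a
score cut answer subtly different questions, both are exposed — `top_n`
here, and any score threshold by filtering the delta vector directly —
rather than conflating them.

Over-representation uses the hypergeometric upper tail within a
user-supplied reference universe, BH-adjusted across sets; the enrichment
ratio is observed over expected overlap. Gene-set collections come from GMT
files; no pathway database is bundled (versions drift and licences vary),
and inputs must share a gene namespace — unmapped genes are reported, not
silently dropped. The knockout-vs-dependency check is a Pearson correlation
restricted to genes with a predicted growth effect (ratio < 1), with the
p-value from the t transform on n − 2 degrees of freedom; the expected
direction is negative.

## What the synthetic fixtures do and do not show

`make_toy_gem()` builds parallel linear chains — one uptake exchange, a few
conversions, a shared biomass precursor — because that topology makes the
FBA optimum analytic (the sum over chains of each chain's minimum
capacity), giving exact oracles for every downstream module. Planted
essential genes ride on a funnel reaction every chain must pass; planted
expression lows sit below chain demand so their constraints provably bind;
planted dependency contrasts use clipped Gaussians at 0.9 vs 0.1. All
randomness flows through one seed per generator call, so fixtures are
byte-stable.

What this emulates: the bound-mapping arithmetic, the order-sensitive
constrain/check/relax dynamics, knockout logic over every rule category,
and the recovery of planted group contrasts. What it does not: loops,
cofactor coupling, compartmentalisation, alternate-optimum structure at
scale, or the correlation structure of real transcriptomes. A green test
suite therefore certifies the algorithmic contracts, not predictive
accuracy on real cell lines — the latter depends on a curated genome-scale
reconstruction and measured media, which are inputs, not part of this
package.

## Known limitations

* `andor` rules are never integrated; their flux is constrained only by
  media and network context.
* The expression-to-flux unit identification is heuristic; the growth
  threshold bounds its damage but does not remove it.
* Plain FBA returns one optimum among possibly many; differential-flux
  conclusions inherit pFBA's particular representative. Flux variability
  or sampling approaches would characterise the solution space more
  honestly and are out of scope here.
* The serum estimator is greedy and single-best; it finds *a* minimal-ish
  rescuing set under its ordering, not the global minimum set.
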