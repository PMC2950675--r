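---
title: "Context-specific organ models and perturbation phenotypes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-specific organ models and perturbation phenotypes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organfba)
```

This vignette is the package's own account of its models and numerical
choices: what is computed, under which assumptions, which parameters matter,
and where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The modeling problem

An organ's metabolic job is summarized as an **objective**: a curated list
of metabolites it secretes (synthesized internally, exported to one
biofluid) and reabsorbs (taken up from the circulation, consumed or
converted internally). Given a compartmentalized stoichiometric network with
gene–protein–reaction (GPR) rules, expression data from the organ, and
metabolite-detection evidence for the relevant biofluids, the package
derives the sub-network that can perform those functions and predicts how
gene deficiencies and drug off-target inhibitions degrade each one.

All flux computations are flux balance analysis: linear programs over
steady-state mass balance `S v = 0` with box bounds on every reaction flux.
Flux units are dimensionless and capped at `Vmax = 1000` in magnitude; a
flux is treated as nonzero above `1e-9`, and all optimality/balance
tolerances are `1e-6`. Only optimal *objective values* are contractual;
flux vectors at degenerate optima are solver-dependent and are never used as
a result surface.

## The LP core

No robust linear-programming backend is assumed; the package carries its own
bounded-variable two-phase primal simplex (`solve_lp()`). Nonbasic variables
sit at a bound, the basis inverse is maintained by pivot updates with
refactorization every 80 pivots, and Dantzig pricing switches permanently to
Bland's rule after 40 consecutive degenerate pivots, which guarantees
termination. Phase 1 minimizes artificial residuals from a bound-feasible
start; a residual above `1e-7` (scaled by the right-hand side) is reported
as infeasible. Because all variable bounds are finite, unboundedness cannot
occur. Follow-up solves on the same constraint matrix (flux variability,
GIMME activity probes) reuse the previous optimal basis as a warm start and
skip phase 1 when that basis is still primal-feasible. The test suite
fuzzes this solver against a brute-force vertex-enumeration oracle on
hundreds of random networks; agreement is required to `1e-6`.

## Expression processing

Two background-subtracted replicate probe tables are combined as follows:

* **Global normalization** multiplies replicate 2 by
  `sum(rep1) / sum(rep2)`, making totals match exactly.
* **Lowess smoothing** regresses the log-ratio `M = log2(r1/r2)` on the
  log-average `A` over shared, positive probesets (`stats::lowess`,
  span 0.3, one robustness iteration — the span is a free parameter of
  `smooth_replicates()`) and subtracts the full fitted trend symmetrically.
  Whether such smoothing is applied per-array against a pseudo-reference or
  in MA space is not uniquely determined by the procedure this package
  follows; MA-space trend removal was chosen as the standard two-array
  normalization, with the consequence that proportional replicates (which
  become identical after global normalization) pass through unchanged.
* **Averaging** takes per-probeset means; probesets present in only one
  replicate pass through at their own value (a warning notes how many),
  maximizing gene coverage.
* **Gene values** are the max over a gene's probesets; genes with no
  probeset are *absent*, and reactions whose GPR has no measured gene score
  `NA` ("no data") — they are never penalized downstream.
* The **significance threshold** fits a Gaussian to the gene values by
  moments and returns the smallest observed value whose upper tail
  `1 − Φ((x−μ̂)/σ̂)` does not exceed the target `p = 0.05`. It is an observed
  data value, not the analytic quantile; on large unimodal samples the two
  coincide closely (the acceptance script verifies the z-location ≈ 1.645 on
  100,000 normal draws), while on strongly bimodal data the returned value
  snaps up to the lower edge of the expressed mode. The whole pipeline is
  scale-covariant: rescaling both replicates rescales gene values and
  threshold alike.

## Exchange constraints and the objective

`derive_exchange_bounds()` encodes the evidence rules: blood ∧ tissue (or a
curated free-exchange flag) opens uptake and efflux; urine ∧ tissue opens
efflux only; no evidence closes the exchange. Secretion-objective
metabolites never take up their product (the organ must synthesize what it
secretes). Every allowed efflux is capped at the **system boundary flux
constraint** (`sbfc`, default 13.5 flux units): a common cap that lets all
candidate routes operate concurrently without favoring any of them. Every
bound carries a rule tag, and the build stage writes this table as the
constraint-provenance log.

`assemble_objective()` adds one boundary reaction per function — an efflux
exchange for secretions, a cytosolic demand for reabsorptions (enabling
direct reabsorption next to indirect, catabolize-then-reabsorb routes) — and
one combined objective reaction consuming every component with unit weights
plus an ATP maintenance term (1 ATP + 1 H2O → 1 ADP + 1 Pi + 1 H, weight 1;
the stoichiometry is a convention, as only flux activity matters at this
stage). Components that cannot carry positive flux even with all exchanges
opened are reported incompatible and excluded. The combined reaction exists
*only* to drive model extraction; simulations always optimize single
functions with it closed, because unit weights make its flux magnitude
biologically meaningless.

## GIMME extraction and reduction

`run_gimme()` solves `min Σ w_i |v_i|`, `w_i = max(0, threshold − score_i)`,
subject to mass balance, bounds and `v_obj ≥ 0.9 · v_obj_max` (the
`required_fraction` parameter). Absolute values are linearized by splitting
every reaction into nonnegative forward/backward halves. Scored-above and
no-data reactions have `w = 0` (the latter reported "unpenalized-active").
Activity of a penalized reaction is decided against *all* alternative
optima, not one LP vertex: each below-threshold reaction is re-maximized
subject to the total penalty staying within `1e-6` of its minimum, and
called inactive when its attainable flux stays below `1e-6`. The flux cutoff
for this probe is deliberately `1e-6` rather than the generic `1e-9`: with
weights of the order of an expression threshold, the `1e-6` penalty slack
permits leakage fluxes of order `1e-9` through penalized reactions, and the
cutoff must sit between that leakage and a real route flux. A reaction
scoring marginally below threshold (tiny `w`) could in principle leak more;
on data with a clear expressed/silent separation the weights are large and
the classification is unambiguous.

`reduce_model()` keeps the union, over objective components, of reactions
that can carry flux while the component's boundary reaction is anchored at
`ε = 1e-6` in its functional direction (efflux for secretions, uptake for
reabsorptions). The anchor is ε-positive rather than 90 %-of-max because the
goal is every *possible* supporting route, not only optimal ones. Since no
flux-capable supporting reaction is removed, each component's optimum is
identical in full and reduced models (verified to `1e-6` on every build and
in the acceptance checks). Connectivity of the reaction–metabolite bipartite
graph is verified afterwards; disconnected islands are retained with a
warning — on an extracted model the functional sub-network is connected
through shared currency metabolites and the combined objective, whereas
reducing an unextracted model legitimately yields islands.

## Perturbation simulations

`simulate_component()` maximizes one function at a time. Secretions maximize
the component's efflux exchange; reabsorptions maximize the uptake magnitude
of the component's blood exchange while every *other* allowed uptake is
capped at `sbfc` — this keeps alternative direct and indirect reabsorption
routes concurrently active in a single simulation instead of requiring
enumeration of alternate optima. In both directions the optimized boundary
flux itself is freed to `Vmax`: the boundary cap applies to everything
*except* the flux being measured, which is what makes a total-loss
phenotype of a single-route function invariant across the entire `sbfc`
range, including 0.

Phenotypes are ratios of perturbed to matched-context unperturbed optima,
clamped only within `1e-6` of the ends of `[0, 1]`. A dead reference
(`0/0`) is defined as ratio 1 — no *additional* disorder — so the statistic
is total. Gene deletions close exactly the reactions whose GPR rule
evaluates false; drug targets scale their reactions' bounds by the
remaining-activity fraction (`inhibition_fraction`, default 0 = complete
inhibition), with an `ALL` row for the cumulative effect of every target.
Gene-deletion ratios in the drug-treated context divide by the drug-treated
normal model (the denominator of the cryptic-factor definition); drug-target
rows divide by the untreated normal model. A **cryptic risk factor** is a
(gene, function) pair with untreated ratio ≥ 1 − 1e-6 and treated ratio
below that.

**Sensitivity.** For a parameter grid (defaults: `sbfc` over
{0, 13.5, 50, 100, 200, 400, 600, 800, 1000}, inhibition fraction over
{0, 0.1, …, 1}), each ratio `r` is re-computed — for `sbfc` sweeps the
standing efflux caps are re-derived at each grid value — and reported as the
normalized sensitivity coefficient `NSC = (r − r_base)/max(r_base, 1 −
r_base)`. A phrasing of this coefficient as a quotient of percent
differences leaves it undefined when `r_base = 0`; the absolute-deviation
form used here is the only total interpretation, is bounded in `[−1, 1]`,
and is zero at the base grid point by construction.

## Validation

`roc_analysis()` sweeps the disorder threshold over all observed ratios plus
the endpoints (an exact step-function ROC with no discretization error),
calls a disorder on strict `ratio < t`, and integrates TPR vs FPR by the
trapezoidal rule; with distinct ratios this equals the Mann–Whitney rank
statistic, which the tests assert to `1e-9`. The mean true positive rate is
reported both over the whole sweep and with the two endpoint thresholds
excluded, since either convention is defensible. `permutation_null()`
shuffles ratio values across all cells (a per-gene-row variant is available
behind `granularity`; the global pool is the default because cell identities
are exchangeable under the null) and compares the observed AROC to the null
by a one-sample left-tailed t-test; a degenerate null distribution short-
circuits to p ∈ {0, 1}.

`crossval_recall()` holds out the expression data of the top-expressed 20 %
of network-associated genes, split across 5 folds, rebuilds threshold,
scores and extraction per fold, and measures recall of held-out genes among
predicted-active genes — a gene is predicted active when it is the
expression-limiting gene of a non-inactive reaction or is associated with
one while having no data (held-out genes necessarily enter by the second
route). Significance is the hypergeometric upper tail over network genes,
Bonferroni-multiplied by the fold count.

## What the synthetic generator emulates — and what it does not

`generate_toy_organ()` builds a three-compartment (blood/cytosol/urine)
organ with four objective functions and planted ground truth:

| plant | motif | expected signal |
|---|---|---|
| total loss | secretion with a unique synthesis route | ratio 0 for every route gene |
| partial loss | reabsorption with direct (10) + indirect (5) routes | ratios 1/3 and 2/3 exactly |
| no phenotype | isozyme pairs inside GPRs | ratio exactly 1 |
| cryptic pair | primary/backup isozymes, drug hits the primary | silent alone, 0 under treatment |
| boundary-sensitive | co-substrate bypass needing 2 uptakes per unit | ratio `min(10, sbfc/2)/10` |
| extraction-inactive | low-expression side routes, a dead-end branch | inactivated by GIMME / dropped by FVA |

Default sizes (~70 metabolites, ~80 reactions, ~70 genes plus 150
background array genes) keep exhaustive oracle checks fast while leaving
room for random filler pathways (count, redundancy and depth are
parameters). Expression defaults — expressed genes at `N(2000, 100²)`,
silent at `N(400, 100²)`, two probesets per gene, replicate-2 scale 0.6 with
an intensity-dependent bias exponent 0.15, 5 % probeset dropout, truncation
at zero — produce the clearly bimodal present/absent structure of a
background-subtracted array in which the Gaussian threshold cleanly
separates the expressed mode. What the generator does **not** emulate:
realistic organ topology (no shared cofactor economy across routes beyond
the ATP module), heavy-tailed or probe-level correlated microarray noise,
partial-detection evidence errors, or benchmark label noise. Passing the
planted-recovery suite therefore demonstrates correctness of the machinery
under known ground truth, not predictive performance on real organs. Note
that dropout can remove all probesets of a planted low-expression gene, in
which case its reaction is legitimately unpenalized ("no data") rather than
inactivated; recovery checks on extraction plants are conditioned on the
gene being measured.

## Degenerate inputs and tie-breaking

Empty GPR rules evaluate true for knockouts and `NA` for expression. Ties in
limiting-gene evaluation return all tied genes. Ties in ROC ratios are
merged per unique threshold before integration. Equal lowess `x` values are
aggregated (`ties = "ordered"`). `0/0` phenotype ratios are 1 (see above).
Components infeasible at reduction time are skipped and reported. Benchmark
tables must contain both outcome classes; duplicated (gene, function) pairs
are rejected.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on generated data:
LP-oracle equivalence on 200 random networks of ≤ 8 reactions, GPR-oracle
equivalence on 1000 random rules, reduction preservation on 20 generated
organs, planted-phenotype recovery on 50 generator seeds (25 in the
acceptance script, which additionally rebuilds the full context model once),
and permutation nulls at 100 and 1000 trials. These sizes were chosen so the
exhaustive oracles — vertex enumeration scales combinatorially — remain
exact, and the complete suite runs in a few minutes on one CPU.

## Known limitations

* The simplex is dense; genome-scale networks (thousands of reactions) would
  need a sparse factorized backend behind the same `solve_lp()` contract.
* GIMME activity probing at `penalty ≤ min + 1e-6` can misjudge reactions
  whose score is within ~`1e-6 / Vmax` of the threshold (see above).
* The combined objective's unit stoichiometry makes its flux value
  meaningless as a physiological quantity; it is used strictly as an
  extraction anchor.
* Only single-gene deletions and target-set inhibitions are simulated; no
  double-deletion epistasis, kinetics, or regulation.
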