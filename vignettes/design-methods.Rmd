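---
title: "Designing stable synthetic communities from niche indices and metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing stable synthetic communities from niche indices and metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecom)
```

`nichecom` supports a bottom-up design loop for synthetic microbial
communities: quantify each candidate strain's resource-utilization niche,
simulate every candidate consortium's cooperative potential and
competitive pressure with constraint-based models, rank, and probe the
winners. This vignette documents the models behind each stage, the
defaults and why they were chosen, and what the synthetic-data tests do
and do not demonstrate about real data.

## Niche indices from utilization panels

A utilization panel is a strains × resources matrix of respiration
signals (phenotype microarray units) or binary growth calls. A resource
counts as utilized when its signal **strictly exceeds** the cutoff
(default 50, the conventional respiration threshold; ties at the cutoff
are non-utilization). Utilization proportions are computed by zeroing
sub-threshold signals and renormalizing the rest to sum to one.

Levins' width `W = 1/sum(P_i^2)` is then the *effective* number of
resources used: `W = k` for uniform use of `k` resources, `W = 1` for a
single resource, and `1 <= W <= k` in between, invariant to uniform
rescaling of the signal. Pianka's overlap is the cosine similarity of
two proportion vectors, clamped to `[0, 1]` against floating-point
error.

Two conventions deserve explicit mention:

* **Raw vs. renormalized proportions.** Whether sub-threshold signal
  should contribute to `P_i` is genuinely ambiguous for thresholded
  respiration data. The default zeroes it (the cutoff defines
  utilization, and the index should not reward noise below it); the
  `renormalize = FALSE` escape hatch computes proportions over the raw
  row for sensitivity analysis.
* **Binary panels.** Growth-call panels get uniform proportions over
  the utilized substrates, which collapses Levins' width onto the
  simplified count-based width — the appropriate simplification when
  only presence/absence is measured.

Strains utilizing nothing are retained with a warning and excluded from
width/overlap statistics; erroring the whole panel for one dead strain
would be worse. The NSR/BSR classification cuts the width distribution
at ≤ 7 and ≥ 29 utilizable compounds by default, the tail cutoffs used
for plant-associated strain collections.

## Flux balance analysis and the built-in solver

Metabolic models follow the standard constraint-based conventions:
steady-state mass balance `S v = 0`, finite flux bounds (±1000
mmol·gDW⁻¹·h⁻¹ internally; an opened uptake defaults to 10), exchange
reactions written as `1 met_e ↔ ∅` with negative flux meaning uptake,
and a biomass reaction as objective. SBML Level 3 with the fbc v2
extension is the interchange format; a JSON dialect covers toy models.

FBA runs on the package's own dense two-phase primal simplex with
Bland's anti-cycling rule. Owning the solver keeps the stack free of
external dependencies and — more importantly for a design tool — makes
every solve deterministic and bit-stable: identical inputs give
identical fluxes, media and scores. Feasibility and pivot tolerances are
1e-9, and producibility calls count a metabolite as producible when its
demand flux exceeds 1e-6. The test suite cross-checks the solver against
an independent textbook implementation (`boot::simplex`) on random
instances and against exhaustive vertex enumeration on every toy model,
to 1e-6.

The problem sizes this package targets — toy and reduced models with
tens of reactions, communities of two to six members — are solved in
milliseconds. It is not engineered for full genome-scale
reconstructions with thousands of reactions; plugging those in will work
but will be slow.

## Minimal media as a mixed-integer program

The minimal medium of a model is the minimum-cardinality set of
environmental metabolites whose uptake sustains growth at a threshold.
Each candidate metabolite gets a binary indicator `y` coupled to its
uptake by `v_ex >= -U * y`; minimizing `sum(y)` subject to `S v = 0`,
bounds and `v_biomass >= threshold` is solved by depth-first branch and
bound on the LP relaxation, branching on the most fractional indicator
(lowest index on ties) and exploring the `y = 0` branch first — a
deterministic search. Alternate optima are enumerated with integer
cuts; the single-solution call returns the lexicographically smallest
set (by sorted metabolite id), so ties never depend on solver state.

Defaults and their rationale:

* **Growth threshold**: 10% of the model's maximum growth on the full
  medium. A fraction-of-maximum threshold adapts to models of very
  different absolute growth yields; an absolute override is available.
* **Free list**: optionally, ubiquitous inorganic components (water,
  protons, phosphate, ammonium, metal ions) can be declared always
  present and excluded from the cardinality count, since they are
  environmentally sourced rather than cross-fed. Off by default:
  the toy models have no such species, and silently discounting
  metabolites is the kind of default that surprises.

## Community scores: MIP and MRO

Members are merged with namespaced internal compartments. In the
*interacting* regime all extracellular metabolites share one pool with a
single community exchange per compound, so anything secreted is
available to everyone. In the *non-interacting* regime each member keeps
a private environment copy; one indicator still gates all private copies
of the same compound, so the medium counts *distinct* compounds — a
shared environment supplies each nutrient once, not once per member.
Community growth means every member reaches its own threshold
simultaneously; there is no abundance weighting, matching the
minimal-media framing rather than a flux-sharing simulation.

* `MIP = |medium, non-interacting| − |medium, interacting|` — the
  number of environmental nutrients spared through exchange. It is a
  non-negative integer; a tiny negative difference from solver noise is
  clamped to 0 with a warning.
* `MRO = mean(|M_i ∩ M_j| over pairs) / mean(|M_i|)` over the members'
  *individual* minimal media, 0 for disjoint requirements, 1 for
  identical ones. By default each member contributes its single
  deterministic medium; `average_alternates = TRUE` averages over
  enumerated alternate optima instead, for models with many equivalent
  nutrient choices.

These two formulas are fixed as this package's operational definitions
of the widely used cooperation/competition scores; other
implementations differ in detail (alternate-media averaging,
abundance weighting, SMETANA's flux-coupling variants), so absolute
values are comparable only within one implementation. Rankings sort by
MIP descending, then MRO ascending, then member set — deterministic end
to end. Dropout scans rescore every leave-one-out subset and report
ΔMIP/ΔMRO per dropped member, the in-silico analogue of strain-dropout
stability experiments.

## Producibility metric

For a target metabolite, every exchangeable compound is included in a
random environment independently with probability `P_in`; FBA on an
appended demand sink decides producibility; the Monte-Carlo estimate of
`P_out` over a grid of `P_in` values yields a curve whose half-point
`P_in,0.5` gives `PM = 1 − P_in,0.5`.

Choices the estimator makes:

* **Grid and sampling**: 21 evenly spaced `P_in` points with 500
  samples each by default — enough that the binomial half-width
  (≈ 0.044 at the curve's steepest point) matches the grid resolution;
  both are configurable. Repeated environments are memoized, so sparse
  exchange sets cost far fewer than `21 × 500` LP solves.
* **Monotonization**: `P_out` is non-decreasing in `P_in` in
  expectation (supersets of media can only help), so isotonic
  regression is applied before interpolating the half-point; this
  removes Monte-Carlo jitter without biasing the crossing.
* **Conventions**: a curve entirely at or above 0.5 has `P_in,0.5 = 0`
  (PM 1, producible from almost nothing); entirely below, `P_in,0.5 =
  1` (PM 0, never producible). Ionic targets that only occur inside
  larger compounds are scored as the species itself — their low PM
  reflects external sourcing, not a biosynthesis defect.
* **Seeding**: panels derive one seed per strain × metabolite cell
  from the master seed by counter hashing, so any sub-panel is
  reproducible in isolation and a full panel is bit-identical across
  runs.

Analytic fixtures pin the estimator: a target needing one essential
nutrient has `P_out = p` (PM 0.5); `k` interchangeable nutrients give
`P_out = 1 − (1−p)^k`; two jointly essential nutrients give
`P_out = p²` (PM `1 − sqrt(0.5) ≈ 0.293`).

## Statistical layer

Width↔score relations use ordinary least squares with the two-sided
F-test p-value and a 95% confidence band; R² equals the squared Pearson
correlation to machine precision, which the tests assert. Width
distributions are fit by nonlinear least squares of a Gaussian to the
histogram (Freedman–Diaconis bins by default, Levenberg–Marquardt via
`minpack.lm`); the fit's R² against the counts is returned as
`goodness`, and clearly non-Gaussian (e.g. bimodal) samples surface as
low goodness rather than a hard failure. Distance-binned correlations
partition strain pairs by patristic distance (summed branch lengths,
when a tree rather than a matrix is supplied) and refit per bin; bins
with fewer than three pairs are reported as empty, never silently
dropped, and a single all-covering bin reproduces the global fit
exactly. PM panels are clustered with average-linkage hierarchical
clustering on Euclidean distances after sorting labels, so the
dendrogram is invariant to input order.

## What the synthetic data does — and does not — show

The generators exist so that every pipeline stage has a ground truth:

* `make_crossfeeding_panel()` builds toy organisms on one shared carbon
  source with engineered auxotrophies and carbon-costing
  synthesis/secretion routes. The number of engineered exchanges inside
  a member subset *is* its true MIP, and the package recovers it
  exactly for communities of two to five members (verified against
  brute-force media search).
* `make_profile_panel()` inverts the Levins formula analytically
  (a two-level proportion profile over `ceiling(w)` resources), so
  requested widths are recovered to 1e-9.
* `make_mixed_panel()` couples the two layers the way the design
  hypothesis expects: narrow strains form the cross-feeding cycle,
  broad strains are self-sufficient. On such panels pairwise MIP falls
  and MRO rises with mean width in every seeded replicate.

That last construction deserves honesty: the width→cross-feeding
association is *built in*, so these tests demonstrate that the scoring
machinery transmits the association to the indices with the right signs
— they do not, and cannot, re-demonstrate the empirical finding that
real narrow-spectrum strains are cross-feeders. Likewise the toy models
omit most features of genome-scale reconstructions (redundant pathways,
maintenance reactions, cofactor coupling, thermodynamic limits), so
absolute MIP/MRO values from real CarveMe-style models will differ from
any toy expectation; only the machinery, not the biology, is certified
by the tests. Reproducing published absolute scores additionally
requires the original reconstruction pipeline and database versions.

Problem sizes throughout the test-suite and the acceptance script —
communities of up to six members, panels of up to 58 resources, 20
seeded replicate panels, 500 Monte-Carlo samples per grid point,
n = 3001 width samples — were chosen as the smallest scales at which
every property is sharply testable; all are parameters, not limits.

## Known limitations

* The MILP enumerates alternate media up to a cap (default 32); models
  with astronomically many equivalent minimal media will be truncated
  (deterministically).
* `MRO` uses minimal-media intersections, not quantitative flux
  overlap; two strains sharing one nutrient at very different uptake
  rates still count as overlapping.
* The SBML reader covers the fbc v2 subset used by standard
  reconstruction tools (species, compartments, formulas, bound
  parameters, flux objectives); exotic constructs (gene-product
  associations, annotations) are ignored on read and not written.
* `run_full()` is a pure function of its inputs and configuration;
  anything nondeterministic (e.g. parallel schedulers) is deliberately
  absent.
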