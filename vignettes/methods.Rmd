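---
title: "Methods: constraint-based repertoire analysis of isolate collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repertoire)
```

This vignette is the package's own account of its models, parameters,
numerical choices and limitations. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The constraint-based model

A `MetabolicModel` is a stoichiometric network: metabolites in a cytosolic
(`c`) and an extracellular (`e`) compartment, reactions with flux bounds
in mmol/gDW/h, exchange pseudo-reactions moving a single `e`-metabolite
across the system boundary (negative flux = uptake, the COBRA
convention), and exactly one biomass reaction whose flux is the specific
growth rate in 1/h. Flux balance analysis assumes steady state
(S·v = 0) and optimizes growth by linear programming; flux variability
analysis brackets each reaction's flux subject to an optional growth
floor. These are standard assumptions: no kinetics, no regulation, no
thermodynamic (loopless) constraints — futile cycles are therefore
*reported* (FVA with all exchanges closed) but not repaired.

Media are maps from extracellular metabolite to a maximum uptake rate.
Applying a medium sets matching exchange lower bounds to −limit and
closes all other uptake; secretion bounds are untouched, so a "minimal"
medium still lets the cell vent byproducts.

### Screens built on the LP core

* **Utilizability**: a carbon source is utilizable iff the *minimal* flux
  of its exchange (with the source added to the medium at 10 mmol/gDW/h)
  is below −tol. Whether such a screen should also demand growth is
  genuinely open; we default to no growth constraint, because the
  criterion asks whether the network *can consume* the compound, and the
  growth-coupled variant is one flag away (`growthFraction`). The two
  modes differ exactly on compounds a network can absorb but not grow on.
* **Byproducts**: producible iff the maximal exchange flux exceeds +tol.
* **Auxotrophies**: per biomass precursor, a temporary demand reaction is
  maximized on the minimal medium; max ≤ tol means the precursor cannot
  be synthesized — an auxotrophy.
* **Gap-filling**: minimize the summed absolute flux through candidate
  pool reactions subject to growth ≥ threshold, then prune greedily in
  lexicographic id order. The prune step guarantees subset minimality and
  determinism; the LP stage keeps the search linear (no MILP dependency).
  The test suite verifies returned sets against exhaustive subset
  enumeration on pools of up to 12 reactions.

Numerical choices: all flux tolerances default to `1e-6` (solver
precision); the LP itself is a dense bounded-variable two-phase primal
simplex with Dantzig pricing and a Bland's-rule fallback for degenerate
bases, solving basis systems by LAPACK factorization each iteration.
Problem sizes here are tens to a few hundred variables, where this is
fast and numerically transparent; it is not meant for genome-scale
models with thousands of reactions.

## Pairwise community growth and interaction labels

Two models are joined over a shared extracellular pool ("one common
compartment for exchanged metabolites"): member internals are namespaced,
`e`-metabolites merged by id, and a single community exchange created per
pooled metabolite. Every member internal reaction *v* carries coupling
constraints −c·μ ≤ v ≤ c·μ against its owner's growth, preventing flux
that benefits only the partner while the producer does not grow. The
coupling coefficient is not a measured quantity; we default to c = 400,
the customary value in the coupling literature, and the label assignments
on all planted scenarios are verified to be identical across
c ∈ {100, 400, 1000}.

The community objective maximizes μ₁ + μ₂. That optimum is usually
degenerate in how growth is split, so a second stage fixes the optimal
sum and maximizes min(μ₁, μ₂) — a deterministic, maximally even
tie-break. Monoculture references are computed under the same coupling
structure (a one-member community), so j and s are strictly comparable.

Labels compare joint with single rates: mutualism (j₁>s₁, j₂>s₂),
competition (both down), parasitism (one up, one down), commensalism
(one up, one equal), amensalism (one down, one equal), neutral (both
equal). Amensalism and neutral complete the partition for combinations
the classical four names leave out. Equality uses
|j−s| ≤ max(eps·s, floor) with eps = 1e-6 and floor = 1e-9; the floor
keeps zero-growth comparisons from degenerating to exact float equality.

A caveat worth knowing: with the sum objective, a pair of members with
*unequal* yields on one shared resource resolves winner-take-all — the
better converter gets the whole pool, so the loser reads as amensal
rather than competitive. The planted competition fixtures therefore use
equal yields, where stage 2 splits evenly and both members lose relative
to monoculture.

## Dynamic co-culture

The dFBA simulator is deliberately well-mixed: biomasses (gDW/L) and pool
concentrations (mM) advance by explicit Euler with dt = 0.05 h. Per step,
each member's uptake bound for pool metabolite m is
min(vmax, conc_m/(X_total·dt)) — a hard cap (vmax = 10 mmol/gDW/h, a
pseudo-Monod stand-in) combined with availability rationing that makes
pool overdraw impossible by construction; residual negative
concentrations from floating-point noise are clamped and counted.
Extracellular enzymes are independent catalytic species with fixed
abundance and a single conversion at rate k·abundance capped by substrate
availability; there is no enzyme synthesis or decay, the simplest faithful
reading of "an enzyme as an independent species". A spatial lattice with
stochastic cell placement would add realism for colony-scale questions
but is orthogonal to the qualitative claim the simulator supports (the
secreted-enzyme co-growth rescue), so the simulator is deterministic:
seeds play no role. Carbon conservation is auditable on fixtures whose
metabolites carry carbon counts (`carbonBalance`); the suite requires
drift below 1% per run, and the shipped fixtures conserve to machine
precision because every toy reaction is exactly carbon-balanced. Kinetic
parameters in the invertase scenario are ours, not measured; only
qualitative orderings (who grows when) are asserted.

## Pathway inference thresholds

Reaction presence from homology hits is inclusive at bitscore ≥ 50
(conservative layer ≥ 150) and coverage ≥ 0.75; pathway presence is
strict: completeness > 0.75, or > 0.66 with key enzymes present. The
operators follow the conventions of homology-based reconstruction
("≥ 50", "75% minimum", "> 75%", "> 66%") literally, and the boundary
cases (completeness exactly 0.75 → absent) are pinned by tests. "Key
enzymes present" is read as *all* key enzymes (`keyMode = "all"`), the
stricter reading; `"any"` is selectable. Conservative calls imply
standard calls by monotonicity, which the suite checks on 1000 random
fixtures. BLAST itself is never run — hit tables are inputs — keeping
the module free of databases.

## Similarity, correlation and clustering

16S identity is global pairwise alignment (match +1, mismatch −1, gap
open −2, extend −0.5 — fixed package defaults, since alignment-parameter
choice is not the object of study) with identity = matches / alignment
columns including gaps (the alternative denominator is selectable).
"Metabolic identity" between binary pathway repertoires is the simple
matching coefficient — a stand-in, since no formal definition of a
percent metabolic identity exists; Euclidean distance drives the
clustering. Matrix association uses Spearman rank correlation over upper
triangles with a Mantel permutation p (rows and columns of one matrix
permuted together): pairwise entries are not exchangeable, whole-id
permutation preserves the dependence structure. The p-value uses the
add-one convention, so it is never zero. Dendrogram support is the plain
bootstrap proportion over resampled pathway columns rather than
multiscale (AU) bootstrapping: AU's multi-scale resampling machinery is
peripheral to what the support is used for here, and the plain
proportion is directly interpretable; AU p-values are generally higher,
so our supports are conservative.

## BIOLOG analysis

The substrate statistic is the endpoint fold change
(OD_t46 − OD_t0)/OD_t0 minus the *fold change* of the water control, and
replicates are averaged. Subtracting the water fold change (not the raw
control OD) keeps the statistic dimensionless and exactly zero for a
well that behaves like water; the literal raw-OD variant is available
via `background = "raw_od"`. Binarization for model agreement defaults
to FC ≥ 1.0 — an unmeasured convention, exposed as a parameter — and
agreement is (TP+TN)/total over the shared substrate universe, symmetric
in its arguments. Substrate k-means uses k = 7 and 1000 restarts by
default; strain dendrograms use Ward (ward.D2) linkage with 100
bootstrap resamples.

## Adaptive strategy scoring

Cohort-relative scoring: a criterion point is earned when the isolate
falls in the strategy-favourable quartile (growth rate: above/below the
cohort mean, the one stated exception). "Quantile" is read as quartile
(25%/75%), the cited convention, with inclusive boundaries (≤ Q1, ≥ Q3)
so the scoring is rank-based and invariant under positive rescaling of
any trait. Scores divide by criteria per strategy (C: 4, S: 4, R: 3);
assignment is argmax with exact ties — two- or three-way — reported as
"mixed". Because scores are cohort-relative, adding or removing isolates
can change individual assignments; that is a property of the method, not
a bug.

## Association testing

Per binary trait, Spearman correlation against the phenotype with an
empirical null of prevalence-preserving permutations of the trait column
("randomly generated features" is not formally defined; permutation
preserves exactly the trait's marginal, and a Bernoulli-with-matched-
prevalence mode is provided). p = (1 + #{|ρ₀| ≥ |ρ|})/(n+1), then
Benjamini–Hochberg across traits. The default n = 100 random features
gives coarse granularity (minimum p ≈ 0.0099, and with 20 traits a
minimum q ≈ 0.2); the documentation and the acceptance script use 999
where a q < 0.05 decision is actually needed.

## What the synthetic generators emulate — and what they do not

The generators plant ground truth for every stage: chain models with
closed-form optima (growth = yield × uptake); interaction scenarios
constructed so the LP provably yields each label (equal-yield
competitors; obligate vitamin cross-feeders; a cofactor-dependent
glucose exploiter; an acetate-overflow commensal); a six-member
community whose labels flip between a rich four-carbon medium and a
glucose minimal medium; hit tables with planted pathway presence
(including exact-boundary cases); plates with planted substrate usage;
trait cohorts drawn from three archetype distributions (at zero noise
each archetype scores 1.0 on its own strategy and recovery is exact by
construction; the suite requires ≥ 90% at 15% relative noise);
phenotypes with planted trait effects; and 16S/pathway pairs evolved on
one random phylogeny, where the fraction of tree-coupled pathway columns
is chosen from a monotone map calibrated once (anchors at target ρ = 0,
0.3, 0.6, 0.9, 1 → coupled fractions 0, 0.13, 0.30, 0.88, 1 at n = 30
isolates, 800 bp sequences, 400 pathways, trait flip rate 3 per unit
branch length, tree depth 0.15 substitutions/site) so the realized
matrix correlation lands near the target; full coupling tops out near
ρ ≈ 0.92 because finite sequences and finite pathway universes add
irreducible sampling noise.

What passing these tests does *not* show: real genomes have database-
and annotation-version-dependent pathway calls, models with thousands of
reactions, non-binary trait structure, and media whose composition is
only partially known. The package's correctness claims are about the
*methods* — implemented faithfully and verified against closed forms,
exhaustive enumeration, independent reference implementations
(`p.adjust`, `wilcox.test`, `vegan::mantel`) and planted-truth recovery —
not about any particular biological dataset.

## Problem sizes

The default test and acceptance runs use: toy models of 3–25 reactions;
50 random models for FVA/monotonicity properties; gap-fill pools of ≤ 12
candidates (exhaustive oracle); 6-member × 2-media interaction screens
(15 pairs each); dFBA runs of 200 Euler steps; 1000 random pathway-rule
fixtures; cohorts of 40 isolates over 5 seeds; 500 null replicates for
type-I calibration; and 10 seeds × 30 isolates for matrix-correlation
recovery. These sizes make every property check exact or tightly
concentrated while keeping a full run in minutes on one core.

## Known limitations

No thermodynamic/loopless FBA; no MILP gap-filling; communities larger
than two members are screened pairwise, not as one LP; no community FVA;
no spatial structure in dFBA; the SBML reader is a deliberately small
subset (species, reactions, bounds via parameters), not full FBC
round-tripping; identifier namespaces are opaque strings and no mapping
between reaction databases is attempted.
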