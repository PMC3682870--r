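---
title: "Models and methods in mtphylogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mtphylogeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtphylogeo)
```

mtphylogeo analyses geocoded alignments of intraspecific sequence data —
typically mitochondrial markers from a species whose range is subdivided
into parapatric maternal lineages. This vignette documents the models the
package implements, the parameters that matter, the numerical conventions,
and the boundaries of what the bundled simulator can and cannot tell you
about real data.

## Diversity statistics and missing data

All sequence statistics operate on equal-length alignments over
`A/C/G/T/N/-` plus IUPAC ambiguity codes. Only `A/C/G/T` count as
resolved. Two deletion rules are available everywhere:

- **complete** (default): every site carrying a gap, `N` or ambiguity code
  in *any* sequence is dropped before anything is computed. This is the
  convention most desktop population-genetics programs default to, and it
  makes the identity `k̄ = π · L_used` exact.
- **pairwise**: unresolved sites are dropped per sequence pair; the
  per-pair number of compared sites is retained in the distance object.

The choice changes S, π and every downstream statistic, which is why it is
an explicit argument rather than a hidden convention, and why the
per-pair site counts are kept for audit. Segregating sites are columns
with at least two distinct *resolved* alleles. Haplotype diversity uses
the small-sample correction `Hd = n/(n-1) (1 - Σ pᵢ²)`, so a fully
distinct sample scores exactly 1 and a monomorphic one exactly 0.
Haplotype collapse is strict sequence equality by default; an optional
wildcard mode lets `N`/`-` match any base, merging greedily in input
order (deterministic, but order-dependent — which is why it is off by
default).

## Neutrality tests and their null distribution

Tajima's D, Fu's Fs and the Ramos-Onsins & Rozas R2 statistic are
computed from the sufficient summaries (n, S, k̄, number of distinct
haplotypes, per-sequence singleton counts). Three conventions deserve
note:

- **Fu's Fs** needs `Pr(K ≥ h)` under the Ewens sampling distribution at
  θ̂ = k̄. The unsigned-Stirling-number recurrence is evaluated in log
  space and cached per n; the distribution sums to 1 to better than 1e-9
  for n up to at least 200 (this is tested).
- **Singletons for R2** are defined on the folded spectrum: a resolved
  base observed in exactly one sequence at a polymorphic site scores for
  its carrier. This requires no outgroup and applies identically to
  observed alignments and simulated genealogies.
- **Degenerate inputs raise typed errors** — S = 0 has no defined D or
  R2, and a monomorphic sample has no defined Fs. Returning a sentinel 0
  would silently look like neutrality, so we refuse instead.

Significance is assessed by simulation: `reps` (default 1000)
constant-size coalescent genealogies for n tips, conditioned on the
observed S by placing exactly S mutations uniformly on the total branch
length (the fixed-S scheme). p-values are one-tailed lower
(`p = (#{sim ≤ obs} + 1)/(reps + 1)`), the direction produced by
population expansion, for all three statistics. Fixed-S ignores the size
bias of genealogies given S, and simulating instead with a point estimate
of θ is a defensible alternative; we fixed the fixed-S scheme because in
our calibration experiments (type-I error at the 5% level, 500 null
datasets, n = 30) it stays within the binomial noise band around the
nominal level, while θ̂-conditioned simulation ran visibly
anti-conservative under the same conditions. The acceptance suite re-runs
this calibration.

## AMOVA and the Mantel test

The one-level AMOVA follows the classical sums-of-squared-distances
decomposition: `SSD_total = Σ δ²ᵢⱼ / 2N`, within-group terms weighted by
group size, variance components from the mean squares with
`n' = (N - Σ n_g²/N)/(G-1)`, and `Φ_ST = σ²_a/(σ²_a + σ²_b)`. Distances
supplied as pairwise difference counts are **squared by default**
(`square = TRUE`); pass `square = FALSE` to treat entries as already
being squared distances (the convention in which a difference count *is*
the squared Euclidean distance between haplotypes). The flag is recorded
in the result. A negative among-group component is reported as-is, but
the percentage of variation clamps it at zero — percentages are what get
quoted, and a negative percentage is never meaningful. Significance
permutes individuals among groups (default 1000 permutations).

The Mantel test correlates strictly-lower-triangle entries of two
conforming distance matrices and permutes rows and columns of the second
jointly (default 999 permutations, one-tailed for positive association).
Both tests take explicit seeds and reproduce bit-for-bit.

## Spatial diversity and barrier detection

**Moving windows.** Local diversity at each sampling location pools all
sequences within a radius of 1.0 (degrees by default, since "about 100
km" windows in mid-latitudes are most naturally expressed in degrees; a
km mode is available). Windows with fewer than 3 sequences are skipped —
"more than two samples" is read strictly. By default only sequences of
the focal sample's lineage enter the window: where divergent lineages
meet in secondary contact, pooled windows would score the contact zone
itself as the most diverse place, which is a statement about lineage
divergence, not standing local diversity. A location hosting several
lineages yields one window per lineage present. Turning the filter off
reproduces the pooled behaviour for comparison.

**Surfaces.** Gridding uses inverse-distance weighting with power 2
within a search radius, on an explicit grid (origin, cell size, extent),
so outputs are exactly reproducible. IDW is deterministic, exact at data
points, and never overshoots the input range — properties the tests
assert. Kriging and any geostatistical model fitting are deliberately out
of scope.

**Barriers.** Monmonier's Maximum Difference algorithm runs on a Delaunay
triangulation of the sampling sites (via deldir; exact duplicate
coordinates are jittered by a seeded epsilon ≤ 1e-6 degrees so each
sample keeps its own vertex and its own distances). The barrier seeds at
the midpoint of the edge with the greatest genetic distance and extends
in both directions, always crossing the adjacent triangle's
larger-distance edge, stopping at the convex hull or on revisiting an
edge. Ties break toward the lexicographically smaller id pair, making the
trace fully deterministic. Raw genetic distances are used; residual
(IBD-corrected) barrier runs are not implemented.

## Genealogies, parsimony and the clock surrogate

Haplotype networks are built by collapsing a phylogenetic tree (supplied
as newick, or an NJ tree of haplotype representatives): branch lengths ×
alignment length give expected substitutions; branches below 0.5 expected
substitutions (i.e. "less than one mutation" under round-half-up) are
contracted, and a surviving branch of m ≥ 2 steps is subdivided by m − 1
unsampled intermediates. The 0.5 threshold is configurable because the
exact collapse rule of interactive genealogy viewers is unpublished
detail; what matters is that the rule is stated and fixed.

Ancestral-state parsimony uses Hartigan's generalization of Fitch's
two-pass algorithm, so multifurcating trees are handled and the change
count is the true minimum (verified against exhaustive enumeration over
all internal labelings for small trees). The down-pass fixes one optimal
labeling — ties resolved toward the lexicographically smallest state —
and reports the branches forced to change. Translation defaults to the
vertebrate mitochondrial code (`TGA` = Trp, `ATA` = Met), which is the
correct table for cytochrome *b*; the table choice is visible in the
function's documentation because it changes stop-codon diagnostics.

`clockTmrca()` is deliberately the simplest possible dating device: a
calibration pair fixes `rate = d_split/(2 t_split)` and the target
distance converts as `t = d_target/(2 rate)`. It exists so that pipelines
have a rough time axis; it is *not* a substitute for Bayesian
relaxed-clock dating, makes no attempt at uncertainty quantification, and
its output should never be compared to published posterior estimates.

## What the simulator emulates — and what it does not

`defaultSimulationConfig()` encodes the study conditions the package is
designed around: 134 samples in four parapatric lineages (A1/A2/B1/B2
with n = 48/16/29/41), per-locus θ of 5.3/2.4/3.6/0.6 chosen as
per-lineage π × L for L = 1482 — one order of magnitude between the
high-diversity refugium lineage (A1) and the near-monomorphic,
recently-expanded one (B2). A1 and B2 coalesce on star genealogies
(post-expansion shape); A2 and B1 on constant-size coalescents. Mutations
follow the infinite-sites model, mapped to distinct uniformly chosen
sites, so within-lineage S equals the realized mutation count and the
generator refuses configurations that would exhaust the alignment.
Geography is an annular ring (radius 1.8–2.6 degrees around 41.8°N,
3.5°W) in four quadrant sectors, group A occupying the west half and
group B the east, which produces exactly two narrow A/B contact zones;
eight basin wedges, offset by half a wedge, cross-cut the lineage
sectors so that basin grouping is correlated with, but distinct from,
lineage structure. Biparental loci are low-variability biallelic markers:
a variant arises in one home lineage and, with migration enabled, may
also segregate at low frequency in a ring-adjacent lineage, emulating
sparse cross-lineage allele sharing; genotypes are Hardy–Weinberg draws
within lineages.

The lineage tree carries Poisson-distributed fixed differences with mean
`interLineageSteps = 8` per branch. This is deeper than the shallow
divergence a real mid-Pleistocene split typically shows, and the reason
is a property of the generator, not of nature: coordinates are uniform
within each sector, so the simulator has **no within-lineage isolation by
distance**. In real data, geographic neighbours are genetically similar,
which keeps within-lineage triangulation-edge distances far below the
contact-zone distances even when overall divergence is shallow. In the
simulator that cushion is absent, so the between-group offset must stand
clear of the within-lineage pairwise-difference tail for the group split
to be identifiable from a single maximum-difference trace. With the
default settings, one simulated dataset supports the full recovery
suite: lineage-AMOVA far above basin-AMOVA, a barrier confined to
inter-group edges, and (in most realizations — the θ contrast between A1
and B1 is only ~1.5-fold, so single draws can deviate) a diversity
surface peaking in the refugium sector.

Beyond IBD, the simulator also omits recombination, selection, recurrent
mutation, spatially explicit migration and real coastline geometry.
Passing the recovery tests therefore demonstrates that the estimators and
trace algorithms recover *this* generative structure; it does not
demonstrate robustness to the correlations real data add.

## Numerical and reproducibility conventions

- Every Monte-Carlo operation takes an explicit seed and restores the
  caller's RNG state; the simulator requires one. Equal seeds give
  byte-identical outputs, which the tests assert, and permutation
  p-values always use the `(count + 1)/(N + 1)` form.
- Distance matrices are symmetrized against floating-point asymmetry and
  validated (zero diagonal, symmetry to 1e-12, finiteness) at
  construction; the `kind` tag prevents, e.g., feeding kilometres into an
  AMOVA.
- NJ branch lengths below zero are clamped to 0 with the total deficit
  recorded as an attribute rather than silently discarded.
- Coordinates are WGS84 decimal degrees throughout; great-circle
  distances use the haversine formula at Earth radius 6371.0088 km; no
  projection is ever applied implicitly.
- Test problem sizes are chosen to keep the full suite at a few minutes:
  oracle equivalence uses n ≤ 12 instances, estimator calibration uses
  2000 coalescent replicates per condition (θ ∈ {1, 5} × n ∈ {10, 30}),
  the p-value calibration uses 500 null datasets of n = 30 with 199 null
  replicates each, and full-pipeline recovery runs one default-sized
  (134-sample) dataset.

## Known limitations

- Real-data reproduction of published per-lineage tables requires the
  original accessioned sequences and groupings, which the package does
  not download; the deletion-rule convention of any given desktop program
  is a further source of ±1-site differences in S and small differences
  in π.
- The fixed-S null is mildly conservative for some statistics at small
  θ; where exact conditional inference matters, users should treat
  borderline p-values with care.
- Monmonier tracing assumes the triangulation is in general position;
  heavily gridded coordinates with exact cocircularities may produce
  triangulation-dependent barriers (the seeded jitter mitigates exact
  duplicates only).
- The wildcard haplotype-matching mode is order-dependent by design
  (greedy transitive merge); use strict matching when order invariance
  matters.
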