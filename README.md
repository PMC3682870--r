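# mtphylogeo

Spatial population genetics of geocoded, aligned sequence data — built for
mitochondrial phylogeography studies of the kind where a species' range is
structured into a handful of parapatric maternal lineages by glacial
refugia, and the questions are: how is diversity partitioned, where are the
genetic breaks, and which regions look like refugia versus recent
expansions.

The package takes an alignment (FASTA; one or more loci per individual,
e.g. a complete cytochrome *b* gene plus a D-loop fragment) and a sample
table (TSV: id, latitude, longitude, lineage, drainage-basin group, sample
type) and provides:

- **Diversity and neutrality statistics** per sample partition: n, S, h,
  haplotype diversity `Hd = n/(n-1) (1 - Σ pᵢ²)`, nucleotide diversity π,
  mean pairwise differences k̄; Tajima's
  `D = (k̄ - S/a₁)/√(e₁S + e₂S(S-1))`, Fu's `Fs = ln(P/(1-P))` with
  `P = Pr(K ≥ h)` under the Ewens sampling distribution at θ̂ = k̄, and the
  Ramos-Onsins & Rozas `R₂ = √(Σᵢ(Uᵢ - k̄/2)²/n)/S`. One-tailed p-values
  come from constant-size coalescent simulation conditional on the
  observed number of segregating sites.
- **Structure tests**: one-level AMOVA (Excoffier variance components,
  Φ_ST, permutation p) over any grouping, and the Mantel test of genetic
  against geographic distance (isolation by distance).
- **Spatial analyses**: moving-window nucleotide diversity around each
  sampling location (1-degree radius by default, lineage-filtered to
  avoid contact-zone inflation), inverse-distance-weighted diversity
  surfaces, and Monmonier's Maximum Difference barrier traced across a
  Delaunay triangulation of the sampling sites.
- **Genealogies**: neighbor-joining trees, Haploviewer-style collapse of a
  phylogenetic tree into a haplotype network with unsampled
  single-mutation intermediates, Fitch/Hartigan parsimony with per-branch
  change attribution (for amino-acid rooting arguments), translation under
  the vertebrate mitochondrial code, and a strict-clock TMRCA
  back-of-envelope calculator.
- **A refugial-expansion simulator** producing datasets with the full
  structure the analyses assume — parapatric lineages on a ring with
  narrow contact zones, unequal within-lineage diversity, star (expansion)
  versus constant genealogies, cross-cutting basin labels and
  low-variability biparental loci — so every stage is testable end to end
  without any downloads.

Sampling-design helpers are included, e.g. `dedupFeces()` implements the
rule that fecal samples count as distinct individuals only if collected at
least 1 km apart or carrying different haplotypes.

## Worked example

Simulate the default four-lineage dataset (A1/A2/B1/B2, group A west /
group B east, A1 the high-diversity refugium lineage) and run the core
analyses:

```r
library(mtphylogeo)

ds   <- simulateDataset(defaultSimulationConfig(seed = 42))
writeDataset(ds, "demo")                      # FASTA + TSV + truth.json
al   <- readFasta("demo/alignment.fasta")
meta <- readSampleMetadata("demo/metadata.tsv")

basicDiversity(al)
#> DiversitySummary (complete deletion): n=134 S=211 h=72 Hd=0.9458
#>   pi=0.01542 kbar=22.8596 (L_used=1482.0)

neutralityTests(al[meta$lineage == "A1"], reps = 1000, seed = 42)
#> NeutralityResult:
#>   Tajima's D: -2.9358 (p=0.0010)
#>   Fu's Fs:    -50.0978 (p=0.0010)
#>   R2:         0.0163 (p=0.0010)

d <- pairwiseDifferences(al)
amovaOneLevel(d, setNames(meta$group, meta$id), perms = 1000, seed = 42)
#> One-level AMOVA
#>   Among groups:  df=7 SS=39442.2900 sigma2=334.301731
#>   Within groups: df=126 SS=11669.7697 sigma2=92.617220
#>   Phi_ST=0.7831  %among=78.31  p=0.000999 (1000 perms)

mantelTest(d, geoDistanceMatrix(meta, "km"), perms = 999, seed = 42)
#> Mantel test: r = 0.6277, p = 0.001 (999 permutations)

monmonierBarrier(delaunayEdges(meta, seed = 42), d)
#> GeneticBarrier: 22 vertices, first crossed edge A1_23-B1_21 (d=40)
```

Reading the output: the sample is diverse (72 haplotypes, Hd 0.95) and
most of that variation separates the configured lineages; the A1 lineage
shows the classic expansion signature (strongly negative Fu's Fs, tiny
R2, both significant); basin grouping still captures a sizeable share of
variance because basins correlate with geography; isolation by distance
is strong (r = 0.63); and the barrier seeds on an edge joining an A1 and
a B1 sample in the north-west contact zone — the deepest genetic break —
rather than anywhere within a group.

The whole pipeline (diversity table, neutrality TSV, AMOVA/Mantel
reports, surface grid, barrier polyline and GeoJSON, network TSVs, plus a
hashed run manifest) runs from one config:

```r
runPipeline(pipelineConfig(outDir = "run1", simulate = TRUE, seed = 42))
```

or from the shell via `inst/scripts/mtphylogeo-cli.R` with the verbs
`simulate`, `diversity`, `neutrality`, `amova`, `mantel`, `surface`,
`barrier`, `genealogy`, `run-all`.

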