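Package: mtphylogeo
Title: Mitochondrial Phylogeography and Spatial Population Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phylogeographic analysis of geocoded, aligned
    mitochondrial (and low-variability nuclear) sequence data: diversity
    summaries and neutrality statistics (Tajima's D, Fu's Fs, R2) with
    coalescent-simulation p-values, one-level AMOVA and Mantel
    isolation-by-distance tests, Monmonier maximum-difference barrier
    detection on a Delaunay triangulation, lineage-aware moving-window
    nucleotide-diversity surfaces, haplotype genealogy collapse from
    phylogenetic trees, Fitch/Hartigan parsimony for character rooting, a
    strict-clock TMRCA calculator, and a coalescent simulator of
    multi-lineage refugial-expansion datasets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    deldir,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
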