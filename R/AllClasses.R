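#' @import methods
NULL

#' Pairwise distance matrix with provenance
#'
#' A labelled, symmetric, zero-diagonal distance matrix shared by the
#' AMOVA, Mantel, Monmonier and tree-building machinery. The `kind` slot
#' records what the entries are (`"diff_count"`, `"p_distance"`, `"km"` or
#' `"degrees"`) so downstream methods can refuse category errors. For
#' sequence-derived matrices computed under pairwise deletion, `lused`
#' holds the per-pair number of sites actually compared.
#'
#' @slot ids character vector of sample labels (row/column order).
#' @slot values numeric symmetric matrix, zero diagonal.
#' @slot kind one of `"diff_count"`, `"p_distance"`, `"km"`, `"degrees"`.
#' @slot lused `NULL`, or an integer matrix of per-pair site counts.
#' @exportClass DistMatrix
setClass("DistMatrix",
  representation(ids = "character", values = "matrix", kind = "character",
                 lused = "ANY"),
  prototype(lused = NULL))

setValidity("DistMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (nrow(v) != ncol(v)) return("values must be square")
  if (length(object@ids) != nrow(v)) return("ids length must match matrix")
  if (anyDuplicated(object@ids)) return("duplicate ids")
  if (!all(is.finite(v))) return("non-finite distances")
  if (any(abs(diag(v)) > 1e-12)) return("diagonal must be zero")
  if (max(abs(v - t(v))) > 1e-12) return("matrix must be symmetric")
  if (any(v < -1e-12)) return("negative distances")
  if (!object@kind %in% c("diff_count", "p_distance", "km", "degrees"))
    return("unknown kind")
  TRUE
})

#' Haplotype table
#'
#' Equivalence classes of identical sequences in an alignment, with the
#' matching rule used (strict equality, or wildcard matching where N and
#' gaps match any base).
#'
#' @slot sequences character vector of representative sequences, one per
#'   haplotype (the first member seen, in input order).
#' @slot counts integer vector of member counts per haplotype.
#' @slot members list of character vectors of member sample ids.
#' @slot assignment named integer vector mapping sample id to haplotype
#'   index.
#' @slot rule `"strict"` or `"wildcard"`.
#' @exportClass HaplotypeTable
setClass("HaplotypeTable",
  representation(sequences = "character", counts = "integer",
                 members = "list", assignment = "integer", rule = "character"))

setValidity("HaplotypeTable", function(object) {
  if (length(object@sequences) != length(object@counts)) return("length mismatch")
  if (length(object@members) != length(object@counts)) return("length mismatch")
  if (sum(object@counts) != length(object@assignment))
    return("counts must sum to the number of samples")
  if (!identical(unname(vapply(object@members, length, 0L)),
                 unname(object@counts)))
    return("member lists inconsistent with counts")
  TRUE
})

#' Per-sample diversity summary
#'
#' The standard single-population summary of an alignment: sample size,
#' segregating sites, haplotype count and diversity, per-site nucleotide
#' diversity and mean pairwise differences, plus the number of sites used
#' after the active deletion rule.
#'
#' @slot n,S,h integers: sequences, segregating sites, haplotypes.
#' @slot Hd haplotype diversity in [0, 1] (sample-size corrected).
#' @slot pi nucleotide diversity per site.
#' @slot kbar mean number of pairwise differences.
#' @slot Lused sites retained by the deletion rule (complete deletion) or
#'   the mean per-pair count (pairwise deletion).
#' @slot deletion `"complete"` or `"pairwise"`.
#' @exportClass DiversitySummary
setClass("DiversitySummary",
  representation(n = "integer", S = "integer", h = "integer", Hd = "numeric",
                 pi = "numeric", kbar = "numeric", Lused = "numeric",
                 deletion = "character"))

setValidity("DiversitySummary", function(object) {
  if (object@Hd < -1e-12 || object@Hd > 1 + 1e-12) return("Hd outside [0,1]")
  if (object@pi < 0) return("pi must be non-negative")
  if (object@h > object@n) return("h cannot exceed n")
  TRUE
})

#' Neutrality test result
#'
#' Tajima's D, Fu's Fs and the Ramos-Onsins & Rozas R2 statistic for one
#' sample, with coalescent-simulation p-values when computed.
#'
#' @slot D,Fs,R2 the three statistics (NA when undefined).
#' @slot pD,pFs,pR2 one-tailed simulation p-values in (0, 1], or NA.
#' @slot reps simulation replicates used for the p-values (0 if none).
#' @slot seed RNG seed used for the simulation (NA if none).
#' @exportClass NeutralityResult
setClass("NeutralityResult",
  representation(D = "numeric", Fs = "numeric", R2 = "numeric",
                 pD = "numeric", pFs = "numeric", pR2 = "numeric",
                 reps = "integer", seed = "integer"))

#' One-level AMOVA result
#'
#' Variance decomposition of squared inter-individual distances into
#' among-group and within-group components (Excoffier-style), with a
#' permutation p-value for Phi-ST.
#'
#' @slot ssAmong,ssWithin sums of squared deviations.
#' @slot dfAmong,dfWithin degrees of freedom (G-1 and N-G).
#' @slot sigma2Among,sigma2Within variance components; the among-group
#'   component is reported unclamped.
#' @slot phiST Phi-ST fixation index.
#' @slot pctAmong percentage of variance among groups, computed after
#'   clamping a negative among-group component at zero.
#' @slot pPerm permutation p-value; @slot perms permutations; @slot seed RNG seed.
#' @slot squared whether supplied distances were squared before use.
#' @exportClass AmovaResult
setClass("AmovaResult",
  representation(ssAmong = "numeric", ssWithin = "numeric",
                 dfAmong = "integer", dfWithin = "integer",
                 sigma2Among = "numeric", sigma2Within = "numeric",
                 phiST = "numeric", pctAmong = "numeric",
                 pPerm = "numeric", perms = "integer", seed = "integer",
                 squared = "logical"))

#' Mantel test result
#'
#' @slot r matrix correlation over strictly-lower-triangle entries.
#' @slot pPerm one-tailed (positive association) permutation p-value.
#' @slot perms permutations used; @slot seed RNG seed.
#' @exportClass MantelResult
setClass("MantelResult",
  representation(r = "numeric", pPerm = "numeric", perms = "integer",
                 seed = "integer"))

setValidity("MantelResult", function(object) {
  if (abs(object@r) > 1 + 1e-12) return("r outside [-1,1]")
  TRUE
})

#' Interpolated diversity surface
#'
#' A regular lat/lon grid of interpolated nucleotide-diversity values.
#' `values[i, j]` is the cell centred at latitude `latMin + (i-1)*cellSize`
#' and longitude `lonMin + (j-1)*cellSize`; cells with no supporting data
#' are NA.
#'
#' @slot latMin,lonMin coordinates of the first cell centre (decimal degrees).
#' @slot cellSize cell edge in decimal degrees (> 0).
#' @slot values numeric matrix (nrow latitudes x ncol longitudes).
#' @exportClass DiversitySurface
setClass("DiversitySurface",
  representation(latMin = "numeric", lonMin = "numeric", cellSize = "numeric",
                 values = "matrix"))

setValidity("DiversitySurface", function(object) {
  if (object@cellSize <= 0) return("cellSize must be positive")
  v <- object@values[!is.na(object@values)]
  if (length(v) && any(v < 0)) return("negative diversity values")
  TRUE
})

#' Monmonier genetic barrier
#'
#' The polyline traced across a Delaunay triangulation of sampling sites
#' by repeatedly crossing the adjacent edge of largest genetic distance.
#'
#' @slot vertices two-column matrix (lat, lon) of crossed-edge midpoints,
#'   in barrier order.
#' @slot crossedEdges data.frame with columns `id1`, `id2`, `distance`:
#'   the triangulation edges crossed, in the same order as `vertices`.
#' @exportClass GeneticBarrier
setClass("GeneticBarrier",
  representation(vertices = "matrix", crossedEdges = "data.frame"))

#' Haplotype genealogy network
#'
#' A haplotype network obtained by collapsing short branches of a
#' phylogenetic tree: sampled haplotypes (with their abundances) and
#' unsampled single-mutation intermediates, joined by single-step edges.
#'
#' @slot nodes data.frame with columns `node` (id), `count` (individuals;
#'   0 for intermediates), `sampled` (logical), `haplotypes`
#'   (comma-separated haplotype labels; "" for intermediates).
#' @slot edges data.frame with columns `from`, `to` (node ids).
#' @exportClass HaplotypeNetwork
setClass("HaplotypeNetwork",
  representation(nodes = "data.frame", edges = "data.frame"))

#' Strict-clock TMRCA estimate
#'
#' @slot rate substitutions/site/Myr from the calibration split.
#' @slot tmrca time to MRCA in Myr for the target divergence.
#' @slot splitDistance,splitAge the calibration pair (distance, Myr).
#' @exportClass ClockEstimate
setClass("ClockEstimate",
  representation(rate = "numeric", tmrca = "numeric",
                 splitDistance = "numeric", splitAge = "numeric"))

setValidity("ClockEstimate", function(object) {
  if (object@rate <= 0) return("rate must be positive")
  if (object@tmrca < 0) return("tmrca must be non-negative")
  TRUE
})

#' Synthetic phylogeographic dataset
#'
#' Output of the refugial-expansion simulator: a FASTA-writable alignment,
#' geocoded per-sample metadata, diploid nuclear genotype calls and the
#' full generating truth (configuration, seed, realized per-lineage
#' genealogy summaries) for recovery tests.
#'
#' @slot alignment a [Biostrings::DNAStringSet] of equal-width sequences.
#' @slot meta data.frame with columns id, lat, lon, lineage, group,
#'   sample_type.
#' @slot nuclear data.frame of genotype calls (sample, locus, allele1,
#'   allele2) or an empty data.frame.
#' @slot truth list holding the SimulationConfig and realized quantities.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(alignment = "ANY", meta = "data.frame", nuclear = "data.frame",
                 truth = "list"))

setValidity("SyntheticDataset", function(object) {
  if (!identical(names(object@alignment), object@meta$id))
    return("metadata ids must match alignment ids, in order")
  TRUE
})
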