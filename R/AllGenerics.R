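#' Sample identifiers of an object
#' @param x a DistMatrix, HaplotypeTable or SyntheticDataset.
#' @return character vector of ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Kind of a distance matrix
#' @param x a DistMatrix.
#' @return one of "diff_count", "p_distance", "km", "degrees".
#' @export
setGeneric("distKind", function(x) standardGeneric("distKind"))

#' Number of haplotypes
#' @param x a HaplotypeTable.
#' @return integer.
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' Haplotype counts
#' @param x a HaplotypeTable.
#' @return integer vector of member counts.
#' @export
setGeneric("haplotypeCounts", function(x) standardGeneric("haplotypeCounts"))

#' Haplotype assignment
#' @param x a HaplotypeTable.
#' @return named integer vector mapping sample id to haplotype index.
#' @export
setGeneric("haplotypeAssignment",
           function(x) standardGeneric("haplotypeAssignment"))

#' @describeIn sampleIds ids of a distance matrix
#' @export
setMethod("sampleIds", "DistMatrix", function(x) x@ids)

#' @describeIn sampleIds sample ids of a haplotype table
#' @export
setMethod("sampleIds", "HaplotypeTable", function(x) names(x@assignment))

#' @describeIn sampleIds sample ids of a synthetic dataset
#' @export
setMethod("sampleIds", "SyntheticDataset", function(x) x@meta$id)

#' @describeIn distKind kind accessor
#' @export
setMethod("distKind", "DistMatrix", function(x) x@kind)

#' @describeIn nHaplotypes haplotype count accessor
#' @export
setMethod("nHaplotypes", "HaplotypeTable", function(x) length(x@counts))

#' @describeIn haplotypeCounts counts accessor
#' @export
setMethod("haplotypeCounts", "HaplotypeTable", function(x) x@counts)

#' @describeIn haplotypeAssignment assignment accessor
#' @export
setMethod("haplotypeAssignment", "HaplotypeTable", function(x) x@assignment)

#' Coerce a DistMatrix to a plain labelled matrix
#' @param x a DistMatrix.
#' @param ... unused.
#' @return numeric matrix with ids as dimnames.
#' @export
setMethod("as.matrix", "DistMatrix", function(x, ...) {
  m <- x@values
  dimnames(m) <- list(x@ids, x@ids)
  m
})

setMethod("show", "DistMatrix", function(object) {
  cat(sprintf("DistMatrix [%s] of %d samples\n", object@kind,
              length(object@ids)))
  lt <- object@values[lower.tri(object@values)]
  if (length(lt))
    cat(sprintf("  range %.6g .. %.6g, mean %.6g\n", min(lt), max(lt),
                mean(lt)))
})

setMethod("show", "HaplotypeTable", function(object) {
  cat(sprintf("HaplotypeTable: %d haplotypes over %d samples (%s matching)\n",
              length(object@counts), length(object@assignment), object@rule))
  cat("  counts:", paste(sort(object@counts, decreasing = TRUE),
                         collapse = " "), "\n")
})

setMethod("show", "DiversitySummary", function(object) {
  cat(sprintf(paste0("DiversitySummary (%s deletion): n=%d S=%d h=%d ",
                     "Hd=%.4f pi=%.5f kbar=%.4f (L_used=%.1f)\n"),
              object@deletion, object@n, object@S, object@h, object@Hd,
              object@pi, object@kbar, object@Lused))
})

setMethod("show", "NeutralityResult", function(object) {
  fmt <- function(v, p) {
    if (is.na(v)) return("NA")
    if (is.na(p)) sprintf("%.4f", v) else sprintf("%.4f (p=%.4f)", v, p)
  }
  cat("NeutralityResult:\n")
  cat("  Tajima's D:", fmt(object@D, object@pD), "\n")
  cat("  Fu's Fs:   ", fmt(object@Fs, object@pFs), "\n")
  cat("  R2:        ", fmt(object@R2, object@pR2), "\n")
  if (object@reps > 0)
    cat(sprintf("  (%d coalescent replicates, seed %d)\n", object@reps,
                object@seed))
})

setMethod("show", "AmovaResult", function(object) {
  cat("One-level AMOVA\n")
  cat(sprintf("  Among groups:  df=%d SS=%.4f sigma2=%.6f\n",
              object@dfAmong, object@ssAmong, object@sigma2Among))
  cat(sprintf("  Within groups: df=%d SS=%.4f sigma2=%.6f\n",
              object@dfWithin, object@ssWithin, object@sigma2Within))
  cat(sprintf("  Phi_ST=%.4f  %%among=%.2f  p=%.4g (%d perms)\n",
              object@phiST, object@pctAmong, object@pPerm, object@perms))
})

setMethod("show", "MantelResult", function(object) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations)\n",
              object@r, object@pPerm, object@perms))
})

setMethod("show", "DiversitySurface", function(object) {
  v <- object@values
  cat(sprintf("DiversitySurface: %d x %d cells of %.3g deg from (%.3f, %.3f)\n",
              nrow(v), ncol(v), object@cellSize, object@latMin, object@lonMin))
  cat(sprintf("  %d cells with values, range %.5g .. %.5g\n",
              sum(!is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
})

setMethod("show", "GeneticBarrier", function(object) {
  cat(sprintf("GeneticBarrier: %d vertices, first crossed edge %s-%s (d=%.4g)\n",
              nrow(object@vertices), object@crossedEdges$id1[1],
              object@crossedEdges$id2[1], object@crossedEdges$distance[1]))
})

setMethod("show", "HaplotypeNetwork", function(object) {
  cat(sprintf("HaplotypeNetwork: %d sampled + %d intermediate nodes, %d edges\n",
              sum(object@nodes$sampled), sum(!object@nodes$sampled),
              nrow(object@edges)))
})

setMethod("show", "ClockEstimate", function(object) {
  cat(sprintf(paste0("ClockEstimate: rate=%.5g subst/site/Myr, ",
                     "TMRCA=%.4g Myr (calibration d=%.4g at %.4g Myr)\n"),
              object@rate, object@tmrca, object@splitDistance,
              object@splitAge))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d samples x %d bp, %d lineages, seed %d\n",
              length(object@alignment),
              if (length(object@alignment)) Biostrings::width(object@alignment)[1] else 0L,
              length(unique(object@meta$lineage)),
              object@truth$config$seed))
})
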