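#' Read an aligned FASTA file
#'
#' Reads a multi-record FASTA (wrapped or unwrapped) into a
#' [Biostrings::DNAStringSet], uppercased, and enforces the alignment
#' invariants: unique non-empty ids and equal sequence lengths. The name of
#' the offending record is reported on failure.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet` of equal-width sequences.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  al <- Biostrings::readDNAStringSet(path)
  names(al) <- sub("\\s.*$", "", names(al))   # id = first token of header
  .asAlignment(Biostrings::DNAStringSet(toupper(as.character(al))))
}

#' Write an alignment to FASTA
#'
#' @param al alignment (named `DNAStringSet` or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(al, path) {
  al <- .asAlignment(al)
  Biostrings::writeXStringSet(al, path, width = 70L)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with header `id lat lon lineage group sample_type`.
#' Coordinates are WGS84 decimal degrees; `lineage` and `group` may be
#' empty strings when the consuming analysis does not need them.
#'
#' @param path path to the TSV.
#' @return data.frame with the six columns, ids as character.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("id", "lat", "lon", "lineage", "group", "sample_type")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  meta$lat <- as.numeric(meta$lat)
  meta$lon <- as.numeric(meta$lon)
  .checkMeta(meta)
  meta[, need]
}

#' Write a sample metadata table
#' @param meta metadata data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeSampleMetadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Concatenate loci sharing a sample set
#'
#' Joins per-sample sequences across loci in the given order (e.g. a
#' complete cytochrome b gene of 1140 bp plus a 342 bp D-loop fragment
#' giving 1482 bp per individual). All loci must cover exactly the same
#' ids; the output keeps the id order of the first locus.
#'
#' @param alignments list of alignments (each a named `DNAStringSet` or
#'   named character vector) over the same id set.
#' @return a single `DNAStringSet` of width `sum(L_i)`.
#' @export
concatenateLoci <- function(alignments) {
  if (!length(alignments)) stop("no alignments supplied")
  als <- lapply(alignments, .asAlignment)
  ids <- names(als[[1]])
  for (k in seq_along(als)) {
    miss <- setdiff(ids, names(als[[k]]))
    extra <- setdiff(names(als[[k]]), ids)
    if (length(miss) || length(extra))
      stop("locus ", k, " id mismatch; missing: ",
           paste(miss, collapse = ", "), "; unexpected: ",
           paste(extra, collapse = ", "))
  }
  parts <- lapply(als, function(a) as.character(a)[ids])
  out <- do.call(paste0, parts)
  names(out) <- ids
  .asAlignment(out)
}

#' Collapse an alignment into haplotypes
#'
#' Strict mode groups sequences by exact equality. Wildcard mode lets `N`
#' and `-` match any base, merging greedily in input order: each sequence
#' joins the first existing haplotype whose representative it is compatible
#' with (site-wise equal, or either side a wildcard); otherwise it founds a
#' new haplotype represented by itself. Other IUPAC ambiguity codes match
#' only themselves.
#'
#' @param al alignment.
#' @param wildcardMissing logical; `FALSE` (strict) by default.
#' @return a [HaplotypeTable-class].
#' @export
collapseHaplotypes <- function(al, wildcardMissing = FALSE) {
  m <- .charMatrix(al)
  ids <- rownames(m)
  n <- nrow(m)
  assignment <- integer(n)
  if (!wildcardMissing) {
    seqs <- apply(m, 1, paste, collapse = "")
    assignment <- match(seqs, unique(seqs))
    repIdx <- match(seq_len(max(assignment)), assignment)
  } else {
    wild <- m == "N" | m == "-"
    repIdx <- integer(0)
    for (i in seq_len(n)) {
      hit <- 0L
      for (k in seq_along(repIdx)) {
        r <- repIdx[k]
        ok <- all(m[i, ] == m[r, ] | wild[i, ] | wild[r, ])
        if (ok) { hit <- k; break }
      }
      if (hit == 0L) { repIdx <- c(repIdx, i); hit <- length(repIdx) }
      assignment[i] <- hit
    }
  }
  names(assignment) <- ids
  members <- split(ids, assignment)[as.character(seq_along(repIdx))]
  methods::new("HaplotypeTable",
    sequences = apply(m[repIdx, , drop = FALSE], 1, paste, collapse = ""),
    counts = unname(vapply(members, length, 0L)),
    members = unname(members),
    assignment = assignment,
    rule = if (wildcardMissing) "wildcard" else "strict")
}

#' Pairwise difference matrix
#'
#' Counts, for every sequence pair, the sites at which both carry resolved
#' (A/C/G/T) bases that differ. `deletion = "complete"` first drops every
#' site holding a gap, N or ambiguity code in any sequence; `"pairwise"`
#' drops such sites per pair. The per-pair number of sites compared is
#' kept in the result's `lused` slot.
#'
#' @param al alignment of n >= 2 sequences.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return a [DistMatrix-class] of kind `"diff_count"`.
#' @export
pairwiseDifferences <- function(al, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- .charMatrix(al)
  if (nrow(m) < 2) stop("need at least 2 sequences")
  if (deletion == "complete") {
    keep <- .resolvedColumns(m)
    if (!any(keep))
      stop("no fully resolved sites left under complete deletion")
    m <- m[, keep, drop = FALSE]
  }
  pd <- .pairDiffMatrices(m)
  off <- pd$lused[lower.tri(pd$lused)]
  if (any(off == 0)) stop("some sequence pair shares no resolved site")
  d <- .newDistMatrix(rownames(m), pd$diffs, "diff_count",
                      lused = pd$lused)
  d
}

#' Pairwise p-distance matrix
#'
#' Proportion of differing sites per pair: the pairwise-difference count
#' divided by the per-pair number of compared sites.
#'
#' @inheritParams pairwiseDifferences
#' @return a [DistMatrix-class] of kind `"p_distance"`.
#' @export
pDistanceMatrix <- function(al, deletion = c("complete", "pairwise")) {
  d <- pairwiseDifferences(al, deletion)
  vals <- d@values / d@lused
  diag(vals) <- 0
  .newDistMatrix(d@ids, vals, "p_distance", lused = d@lused)
}

#' Mean between-group p-distance
#'
#' Average p-distance over all pairs with one member in each of two groups
#' (e.g. the mean divergence between mitochondrial phylogroups).
#'
#' @param d a p-distance [DistMatrix-class].
#' @param groups named vector mapping id to group label.
#' @param g1,g2 the two group labels.
#' @return mean p-distance, a scalar.
#' @export
meanGroupDistance <- function(d, groups, g1, g2) {
  m <- as.matrix(d)
  i <- d@ids[groups[d@ids] == g1]
  j <- d@ids[groups[d@ids] == g2]
  if (!length(i) || !length(j)) stop("empty group")
  mean(m[i, j, drop = FALSE])
}

#' Geographic distance matrix
#'
#' `kind = "km"` gives great-circle (haversine) distances at Earth radius
#' 6371.0088 km; `kind = "degrees"` gives plain Euclidean distances in
#' decimal-degree space (the working unit of the 1-degree moving window).
#'
#' @param meta metadata data.frame with id, lat, lon.
#' @param kind `"km"` (default) or `"degrees"`.
#' @return a [DistMatrix-class].
#' @export
geoDistanceMatrix <- function(meta, kind = c("km", "degrees")) {
  kind <- match.arg(kind)
  .checkMeta(meta)
  if (kind == "km") {
    v <- geosphere::distm(cbind(meta$lon, meta$lat),
                          fun = function(p1, p2)
                            geosphere::distHaversine(p1, p2, r = 6371008.8))
    v <- v / 1000
  } else {
    v <- as.matrix(stats::dist(cbind(meta$lat, meta$lon)))
  }
  .newDistMatrix(meta$id, v, kind)
}

#' Haversine great-circle distance
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return distance in km at Earth radius 6371.0088 km.
#' @export
haversineKm <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371008.8) / 1000
}

#' Deduplicate fecal samples by distance and haplotype
#'
#' Implements the sampling rule that fecal samples must come from distinct
#' individuals: scanning in input order, a feces sample is dropped iff an
#' already-retained feces sample lies closer than `minKm` (great-circle)
#' and carries the same haplotype. Samples within that distance but with
#' different haplotypes are kept, as are all tissue and museum samples.
#'
#' @param meta metadata data.frame (id, lat, lon, sample_type).
#' @param assignment named integer vector (sample id -> haplotype index),
#'   e.g. from [collapseHaplotypes()].
#' @param minKm exclusion radius in km (default 1).
#' @return character vector of retained ids, in input order.
#' @export
dedupFeces <- function(meta, assignment, minKm = 1.0) {
  .checkMeta(meta, need = "sample_type")
  if (anyNA(assignment[meta$id]))
    stop("missing haplotype assignment for: ",
         paste(meta$id[is.na(assignment[meta$id])], collapse = ", "))
  keep <- logical(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    if (meta$sample_type[i] != "feces") { keep[i] <- TRUE; next }
    prior <- which(keep & meta$sample_type == "feces")
    drop <- FALSE
    if (length(prior)) {
      dkm <- haversineKm(meta$lat[i], meta$lon[i],
                         meta$lat[prior], meta$lon[prior])
      same <- assignment[meta$id[prior]] == assignment[meta$id[i]]
      drop <- any(dkm < minKm & same)
    }
    keep[i] <- !drop
  }
  meta$id[keep]
}

#' Write a distance matrix as square TSV
#'
#' Square layout with an id header row and id first column.
#'
#' @param d a [DistMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDistMatrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square TSV distance matrix
#' @param path path written by [writeDistMatrix()].
#' @param kind the distance kind to stamp on the result.
#' @return a [DistMatrix-class].
#' @export
readDistMatrix <- function(path, kind = "diff_count") {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(id = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  .newDistMatrix(df$id, m, kind)
}
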