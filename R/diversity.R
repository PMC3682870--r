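#' Basic diversity summary of an alignment
#'
#' The standard single-population summary: sample size n, segregating
#' sites S, haplotype count h, haplotype diversity
#' \eqn{Hd = \frac{n}{n-1}(1 - \sum_i p_i^2)} over haplotype frequencies,
#' per-site nucleotide diversity \eqn{\pi} (mean pairwise p-distance) and
#' the mean number of pairwise differences \eqn{\bar k}.
#'
#' Under complete deletion every statistic is computed on the sites free
#' of gaps/ambiguities in all sequences, so \eqn{\bar k = \pi \cdot
#' L_{used}} exactly. Under pairwise deletion, sites are dropped per pair;
#' S counts sites with at least two distinct resolved bases among the
#' resolved entries, haplotypes are collapsed on full sequences, and
#' `Lused` reports the mean per-pair site count.
#'
#' @param al alignment (named `DNAStringSet` or character vector), n >= 2.
#' @param deletion `"complete"` (default, the usual DnaSP-style
#'   convention) or `"pairwise"`.
#' @return a [DiversitySummary-class].
#' @export
basicDiversity <- function(al, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- .charMatrix(al)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 sequences")
  if (deletion == "complete") {
    keep <- .resolvedColumns(m)
    if (!any(keep)) stop("no fully resolved sites under complete deletion")
    mm <- m[, keep, drop = FALSE]
    S <- sum(apply(mm, 2, function(col) length(unique(col))) >= 2)
    pd <- .pairDiffMatrices(mm)
    kbar <- mean(.lowerTri(pd$diffs))
    Lused <- ncol(mm)
    pi <- kbar / Lused
    hap <- collapseHaplotypes(apply(mm, 1, paste, collapse = ""))
  } else {
    S <- .countSegSites(m)
    pd <- .pairDiffMatrices(m)
    kbar <- mean(.lowerTri(pd$diffs))
    pi <- mean(.lowerTri(pd$diffs) / .lowerTri(pd$lused))
    Lused <- mean(.lowerTri(pd$lused))
    hap <- collapseHaplotypes(apply(m, 1, paste, collapse = ""))
  }
  h <- nHaplotypes(hap)
  p <- haplotypeCounts(hap) / n
  Hd <- if (n > 1) n / (n - 1) * (1 - sum(p^2)) else 0
  methods::new("DiversitySummary", n = n, S = as.integer(S),
               h = as.integer(h), Hd = Hd, pi = pi, kbar = kbar,
               Lused = as.numeric(Lused), deletion = deletion)
}

## Segregating sites among resolved entries (pairwise-deletion sense).
.countSegSites <- function(m) {
  sum(apply(m, 2, function(col) {
    col <- col[col %in% RESOLVED_BASES]
    length(unique(col)) >= 2
  }))
}

#' Observed heterozygosity from genotype calls
#'
#' Counts heterozygous locus-by-individual calls. Input mirrors the TSV
#' interface `sample locus allele1 allele2`: one row per sequenced locus
#' per individual.
#'
#' @param calls data.frame with columns `sample`, `locus`, `allele1`,
#'   `allele2`.
#' @return list with `n_sequenced`, `n_het` and `het` (= n_het /
#'   n_sequenced, also carried rounded to 3 decimals as `het3`).
#' @export
observedHeterozygosity <- function(calls) {
  need <- c("sample", "locus", "allele1", "allele2")
  if (!all(need %in% names(calls)))
    stop("calls need columns: ", paste(need, collapse = ", "))
  if (!nrow(calls)) stop("no genotype calls")
  nh <- sum(calls$allele1 != calls$allele2)
  list(n_sequenced = nrow(calls), n_het = nh, het = nh / nrow(calls),
       het3 = round(nh / nrow(calls), 3))
}

#' Diversity and neutrality table over sample partitions
#'
#' One row per level of each partitioning column (e.g. lineage,
#' sample_type) plus a whole-sample row, mirroring the usual per-lineage
#' summary-table layout (N, S, h, Hd, pi, Tajima's D, R2, Fu's Fs).
#' Partition cells with fewer than 2 samples are flagged and their
#' statistics left NA; neutrality statistics that are undefined for a cell
#' (no segregating sites, monomorphic) are NA.
#'
#' @param al alignment.
#' @param meta metadata data.frame with `id` plus the partition columns.
#' @param partitions character vector of metadata column names
#'   (default `"lineage"`).
#' @param deletion deletion rule passed to [basicDiversity()].
#' @return data.frame with columns partition, level, n, S, h, Hd, pi,
#'   kbar, D, R2, Fs, flagged.
#' @export
diversityTable <- function(al, meta, partitions = "lineage",
                           deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  al <- .asAlignment(al)
  if (!all(names(al) %in% meta$id))
    stop("metadata missing for: ",
         paste(setdiff(names(al), meta$id), collapse = ", "))
  meta <- meta[match(names(al), meta$id), , drop = FALSE]
  rowFor <- function(partition, level, idx) {
    out <- data.frame(partition = partition, level = level,
                      n = length(idx), S = NA_integer_, h = NA_integer_,
                      Hd = NA_real_, pi = NA_real_, kbar = NA_real_,
                      D = NA_real_, R2 = NA_real_, Fs = NA_real_,
                      flagged = FALSE, stringsAsFactors = FALSE)
    if (length(idx) < 2) { out$flagged <- TRUE; return(out) }
    sub <- al[idx]
    ds <- basicDiversity(sub, deletion)
    out$S <- ds@S; out$h <- ds@h; out$Hd <- ds@Hd
    out$pi <- ds@pi; out$kbar <- ds@kbar
    out$D <- tryCatch(tajimasD(sub, deletion), error = function(e) NA_real_)
    out$R2 <- tryCatch(r2Statistic(sub, deletion), error = function(e) NA_real_)
    out$Fs <- tryCatch(fusFs(sub, deletion), error = function(e) NA_real_)
    out
  }
  rows <- list(rowFor("whole", "whole", seq_along(al)))
  for (p in partitions) {
    if (!p %in% names(meta)) stop("no metadata column '", p, "'")
    for (lev in unique(meta[[p]][nzchar(meta[[p]])])) {
      rows[[length(rows) + 1L]] <- rowFor(p, lev, which(meta[[p]] == lev))
    }
  }
  do.call(rbind, rows)
}

#' Write a diversity table as TSV
#' @param tab data.frame from [diversityTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDiversityTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
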