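## Internal helpers shared across modules.

RESOLVED_BASES <- c("A", "C", "G", "T")

## Run code with a fixed RNG seed without clobbering the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("seed must be a single integer")
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## Alignment (DNAStringSet or character vector) -> uppercase character matrix,
## one row per sequence, one column per site.
.charMatrix <- function(al) {
  al <- .asAlignment(al)
  s <- toupper(as.character(al))
  m <- do.call(rbind, strsplit(s, "", fixed = TRUE))
  rownames(m) <- names(al)
  m
}

## Accept a named DNAStringSet or named character vector; enforce the
## alignment invariants (unique non-empty ids, equal lengths >= 1).
.asAlignment <- function(al) {
  if (is.character(al)) {
    if (is.null(names(al)) || any(!nzchar(names(al))))
      stop("alignment sequences must be named")
    al <- Biostrings::DNAStringSet(toupper(al))
  }
  if (!methods::is(al, "DNAStringSet"))
    stop("alignment must be a DNAStringSet or named character vector")
  if (length(al) == 0) stop("empty alignment")
  if (is.null(names(al)) || any(!nzchar(names(al))))
    stop("alignment sequences must be named")
  if (anyDuplicated(names(al)))
    stop("duplicate sequence ids: ",
         paste(unique(names(al)[duplicated(names(al))]), collapse = ", "))
  w <- Biostrings::width(al)
  if (any(w != w[1])) {
    bad <- names(al)[which(w != w[1])[1]]
    stop("unequal sequence lengths: '", bad, "' has ", w[which(w != w[1])[1]],
         " sites, expected ", w[1])
  }
  if (w[1] < 1) stop("alignment length must be >= 1")
  al
}

## Deletion handling: site columns free of anything but A/C/G/T in all rows.
.resolvedColumns <- function(m) {
  apply(m, 2, function(col) all(col %in% RESOLVED_BASES))
}

## Pairwise difference and per-pair used-site matrices via one-hot algebra:
## for base b let I_b be the n x L indicator of a *resolved* b; then
## matches = sum_b I_b I_b^T and pairL = R R^T with R = sum_b I_b.
.pairDiffMatrices <- function(m) {
  n <- nrow(m)
  L <- ncol(m)
  matches <- matrix(0, n, n)
  resolved <- matrix(0, n, L)
  for (b in RESOLVED_BASES) {
    ib <- (m == b) * 1
    matches <- matches + tcrossprod(ib)
    resolved <- resolved + ib
  }
  pairL <- tcrossprod(resolved)
  list(diffs = pairL - matches, lused = pairL)
}

.lowerTri <- function(m) m[lower.tri(m)]

.newDistMatrix <- function(ids, values, kind, lused = NULL) {
  values <- (values + t(values)) / 2     # kill fp asymmetry
  diag(values) <- 0
  methods::new("DistMatrix", ids = as.character(ids), values = values,
               kind = kind, lused = lused)
}

## Reorder / subset a DistMatrix by id.
.subsetDist <- function(d, ids) {
  idx <- match(ids, d@ids)
  if (anyNA(idx))
    stop("ids missing from distance matrix: ",
         paste(ids[is.na(idx)], collapse = ", "))
  .newDistMatrix(ids, d@values[idx, idx, drop = FALSE], d@kind,
                 if (!is.null(d@lused)) d@lused[idx, idx, drop = FALSE])
}

## md5 of an arbitrary R object, via a serialized temp file (tools::md5sum).
.objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

.checkMeta <- function(meta, need = character()) {
  req <- c("id", "lat", "lon")
  miss <- setdiff(c(req, need), names(meta))
  if (length(miss))
    stop("metadata lacks required columns: ", paste(miss, collapse = ", "))
  if (anyNA(meta$lat) || anyNA(meta$lon))
    stop("missing coordinates for: ",
         paste(meta$id[is.na(meta$lat) | is.na(meta$lon)], collapse = ", "))
  if (any(meta$lat < -90 | meta$lat > 90)) stop("latitude outside [-90, 90]")
  if (any(meta$lon < -180 | meta$lon > 180)) stop("longitude outside [-180, 180]")
  invisible(meta)
}
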