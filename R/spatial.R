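#' Moving-window local nucleotide diversity
#'
#' For each sampling location, pools all sequences collected within
#' `radius` of it (1 degree by default, roughly 100 km at these
#' latitudes) and estimates nucleotide diversity of the window. To avoid
#' inflating diversity where divergent lineages meet in secondary
#' contact, `sameLineageOnly = TRUE` (default) restricts each window to
#' sequences sharing the focal sample's lineage; a location hosting
#' samples of two lineages yields one window per lineage present.
#' Windows with fewer than 3 sequences (i.e. not "more than two") are
#' skipped.
#'
#' @param al alignment.
#' @param meta metadata data.frame (id, lat, lon and, if filtering,
#'   lineage).
#' @param radius neighborhood radius (default 1.0).
#' @param sameLineageOnly restrict windows to the focal lineage.
#' @param unit `"degrees"` (Euclidean in decimal degrees, the default
#'   working unit) or `"km"` (great-circle).
#' @param deletion deletion rule for [basicDiversity()].
#' @return data.frame with columns lat, lon, lineage (`"mixed"` when not
#'   filtering), n_local, pi_local; one row per emitted window.
#' @export
localDiversity <- function(al, meta, radius = 1.0, sameLineageOnly = TRUE,
                           unit = c("degrees", "km"),
                           deletion = c("complete", "pairwise")) {
  unit <- match.arg(unit)
  deletion <- match.arg(deletion)
  al <- .asAlignment(al)
  .checkMeta(meta, need = if (sameLineageOnly) "lineage" else character())
  meta <- meta[match(names(al), meta$id), , drop = FALSE]
  if (anyNA(meta$id)) stop("metadata missing for some sequences")
  locKey <- paste(meta$lat, meta$lon)
  out <- list()
  for (key in unique(locKey)) {
    at <- which(locKey == key)
    lat0 <- meta$lat[at[1]]; lon0 <- meta$lon[at[1]]
    dists <- if (unit == "degrees")
      sqrt((meta$lat - lat0)^2 + (meta$lon - lon0)^2)
    else haversineKm(lat0, lon0, meta$lat, meta$lon)
    inWin <- which(dists <= radius)
    focal <- if (sameLineageOnly) unique(meta$lineage[at]) else "mixed"
    for (lin in focal) {
      idx <- if (sameLineageOnly) inWin[meta$lineage[inWin] == lin] else inWin
      if (length(idx) < 3) next
      pi <- basicDiversity(al[idx], deletion)@pi
      out[[length(out) + 1L]] <- data.frame(
        lat = lat0, lon = lon0, lineage = lin,
        n_local = length(idx), pi_local = pi, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(lat = numeric(0), lon = numeric(0),
                      lineage = character(0), n_local = integer(0),
                      pi_local = numeric(0)))
  do.call(rbind, out)
}

#' Interpolate a regular diversity surface
#'
#' Inverse-distance-weighted (power `power`) gridding of local-diversity
#' points onto a regular lat/lon grid: each cell value is the IDW average
#' of the points within `maxRadius` (degrees) of the cell centre; a cell
#' coincident with a data point takes that point's value exactly (the
#' mean, if several points coincide); cells with no point in range are
#' NA. IDW never overshoots the input range.
#'
#' @param points data.frame from [localDiversity()] (needs lat, lon,
#'   pi_local).
#' @param cellSize grid cell edge in degrees.
#' @param latMin,lonMin,nrow,ncol grid spec; defaults snap to the point
#'   bounding box.
#' @param power IDW exponent (default 2).
#' @param maxRadius search radius in degrees (default Inf).
#' @return a [DiversitySurface-class].
#' @export
interpolateSurface <- function(points, cellSize = 0.25, latMin = NULL,
                               lonMin = NULL, nrow = NULL, ncol = NULL,
                               power = 2, maxRadius = Inf) {
  if (!nrow(points)) stop("no input points")
  if (!is.numeric(cellSize) || cellSize <= 0) stop("cellSize must be > 0")
  if (is.null(latMin)) latMin <- min(points$lat)
  if (is.null(lonMin)) lonMin <- min(points$lon)
  if (is.null(nrow))
    nrow <- max(1L, ceiling((max(points$lat) - latMin) / cellSize) + 1L)
  if (is.null(ncol))
    ncol <- max(1L, ceiling((max(points$lon) - lonMin) / cellSize) + 1L)
  if (nrow < 1 || ncol < 1) stop("degenerate grid spec")
  vals <- matrix(NA_real_, nrow, ncol)
  for (i in seq_len(nrow)) {
    lat <- latMin + (i - 1) * cellSize
    for (j in seq_len(ncol)) {
      lon <- lonMin + (j - 1) * cellSize
      d <- sqrt((points$lat - lat)^2 + (points$lon - lon)^2)
      hit <- d < 1e-9
      if (any(hit)) { vals[i, j] <- mean(points$pi_local[hit]); next }
      use <- which(d <= maxRadius)
      if (!length(use)) next
      w <- 1 / d[use]^power
      vals[i, j] <- sum(w * points$pi_local[use]) / sum(w)
    }
  }
  methods::new("DiversitySurface", latMin = latMin, lonMin = lonMin,
               cellSize = cellSize, values = vals)
}

#' Export a diversity surface as ESRI ASCII grid
#'
#' @param surface a [DiversitySurface-class].
#' @param path output path.
#' @param nodata NODATA sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
writeSurfaceAsciiGrid <- function(surface, path, nodata = -9999) {
  v <- surface@values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", surface@lonMin - surface@cellSize / 2),
    paste("yllcorner", surface@latMin - surface@cellSize / 2),
    paste("cellsize", surface@cellSize),
    paste("NODATA_value", nodata)), con)
  for (i in rev(seq_len(nrow(v)))) {        # north row first
    row <- v[i, ]
    row[is.na(row)] <- nodata
    writeLines(paste(format(row, trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Export a diversity surface as long-format TSV (lat, lon, pi)
#' @param surface a [DiversitySurface-class].
#' @param path output path.
#' @param dropNA omit empty cells (default TRUE).
#' @return `path`, invisibly.
#' @export
writeSurfaceTSV <- function(surface, path, dropNA = TRUE) {
  v <- surface@values
  df <- expand.grid(i = seq_len(nrow(v)), j = seq_len(ncol(v)))
  df <- data.frame(
    lat = surface@latMin + (df$i - 1) * surface@cellSize,
    lon = surface@lonMin + (df$j - 1) * surface@cellSize,
    pi = v[cbind(df$i, df$j)])
  if (dropNA) df <- df[!is.na(df$pi), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Delaunay triangulation of sampling sites
#'
#' Triangulates sample coordinates (lon as x, lat as y) and returns the
#' edge list with triangle membership, the substrate of the Monmonier
#' barrier trace. Exactly duplicated coordinates are jittered by a seeded
#' epsilon (<= 1e-6 degrees) so every sample keeps its own vertex.
#'
#' @param meta metadata data.frame (id, lat, lon) of >= 3 points, not all
#'   collinear.
#' @param seed seed for the duplicate jitter.
#' @return list with `ids`, `coords` (lat/lon used, post-jitter),
#'   `edges` (data.frame id1, id2 with id1 < id2), `triangles` (matrix of
#'   vertex indices, one row per triangle) and `edgeTriangles` (list
#'   mapping each edge to the adjacent triangle row indices; hull edges
#'   have one).
#' @export
delaunayEdges <- function(meta, seed = 1) {
  .checkMeta(meta)
  if (nrow(meta) < 3) stop("need at least 3 points")
  x <- meta$lon; y <- meta$lat
  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    jit <- withSeed(seed, matrix(stats::runif(2 * sum(dup), -1e-6, 1e-6), ncol = 2))
    x[dup] <- x[dup] + jit[, 1]
    y[dup] <- y[dup] + jit[, 2]
  }
  if (qr(cbind(1, x, y))$rank < 3) stop("all points are collinear")
  dd <- deldir::deldir(x, y, suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  if (!length(tl)) stop("triangulation produced no triangles")
  triangles <- t(vapply(tl, function(tr) sort(tr$ptNum), integer(3)))
  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  edgeMap <- list()
  for (t in seq_len(nrow(triangles))) {
    v <- triangles[t, ]
    for (pair in list(v[c(1, 2)], v[c(1, 3)], v[c(2, 3)])) {
      k <- ekey(pair[1], pair[2])
      edgeMap[[k]] <- c(edgeMap[[k]], t)
    }
  }
  keys <- names(edgeMap)
  ij <- do.call(rbind, strsplit(keys, " "))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  edges <- data.frame(id1 = meta$id[i], id2 = meta$id[j],
                      i = i, j = j, stringsAsFactors = FALSE)
  ## canonical order: id1 < id2 lexicographically
  flip <- edges$id1 > edges$id2
  tmp <- edges$id1[flip]; edges$id1[flip] <- edges$id2[flip]
  edges$id2[flip] <- tmp
  tmp <- edges$i[flip]; edges$i[flip] <- edges$j[flip]; edges$j[flip] <- tmp
  list(ids = meta$id, coords = data.frame(lat = y, lon = x),
       edges = edges, triangles = triangles,
       edgeTriangles = unname(edgeMap), edgeKeys = keys)
}

#' Monmonier maximum-difference barrier
#'
#' Traces a genetic barrier across the Delaunay triangulation: the
#' barrier seeds at the midpoint of the triangulation edge with the
#' greatest genetic distance between its endpoints, then extends
#' independently in both directions, at each step moving into the
#' adjacent triangle and crossing whichever of its two other edges has
#' the larger genetic distance, stopping on reaching the convex hull or
#' an already-crossed edge. Ties break toward the lexicographically
#' smaller id pair.
#'
#' @param tri triangulation from [delaunayEdges()].
#' @param d a [DistMatrix-class] covering all triangulation ids
#'   (typically raw pairwise differences of the concatenated
#'   mitochondrial data).
#' @param nBarriers number of successive barriers (default 1; later
#'   barriers seed at the strongest edge not yet crossed).
#' @return a [GeneticBarrier-class], or a list of them if `nBarriers > 1`.
#' @export
monmonierBarrier <- function(tri, d, nBarriers = 1) {
  if (!methods::is(d, "DistMatrix")) stop("d must be a DistMatrix")
  miss <- setdiff(tri$ids, d@ids)
  if (length(miss))
    stop("distance matrix lacks ids: ", paste(miss, collapse = ", "))
  dm <- as.matrix(d)
  ed <- tri$edges
  ed$distance <- dm[cbind(ed$id1, ed$id2)]
  ## deterministic edge priority: distance desc, then id pair asc
  ord <- order(-ed$distance, ed$id1, ed$id2)
  crossedGlobal <- logical(nrow(ed))
  midpoint <- function(e) {
    c(lat = mean(tri$coords$lat[c(ed$i[e], ed$j[e])]),
      lon = mean(tri$coords$lon[c(ed$i[e], ed$j[e])]))
  }
  edgeOfTriangle <- function(t, e) {
    ## row indices of the edges of triangle t other than edge e
    v <- tri$triangles[t, ]
    cand <- which((ed$i %in% v) & (ed$j %in% v))
    setdiff(cand, e)
  }
  barriers <- list()
  for (b in seq_len(nBarriers)) {
    seedE <- ord[which(!crossedGlobal[ord])[1]]
    if (is.na(seedE)) break
    crossed <- seedE
    crossedGlobal[seedE] <- TRUE
    walk <- function(startTri) {
      path <- integer(0)
      curE <- seedE
      curT <- startTri
      repeat {
        others <- edgeOfTriangle(curT, curE)
        oo <- others[order(-ed$distance[others], ed$id1[others],
                           ed$id2[others])]
        nxt <- oo[1]
        if (crossedGlobal[nxt]) break
        path <- c(path, nxt)
        crossedGlobal[nxt] <<- TRUE
        adj <- setdiff(tri$edgeTriangles[[nxt]], curT)
        if (!length(adj)) break             # reached the convex hull
        curT <- adj[1]
        curE <- nxt
      }
      path
    }
    adjSeed <- tri$edgeTriangles[[seedE]]
    dir1 <- if (length(adjSeed) >= 1) walk(adjSeed[1]) else integer(0)
    dir2 <- if (length(adjSeed) >= 2) walk(adjSeed[2]) else integer(0)
    orderE <- c(rev(dir2), seedE, dir1)
    verts <- t(vapply(orderE, midpoint, numeric(2)))
    colnames(verts) <- c("lat", "lon")
    barriers[[b]] <- methods::new("GeneticBarrier",
      vertices = verts,
      crossedEdges = data.frame(id1 = ed$id1[orderE], id2 = ed$id2[orderE],
                                distance = ed$distance[orderE],
                                seed = orderE == seedE,
                                stringsAsFactors = FALSE))
  }
  if (nBarriers == 1) barriers[[1]] else barriers
}

#' Export a barrier polyline as two-column TSV (lat, lon)
#' @param barrier a [GeneticBarrier-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBarrierTSV <- function(barrier, path) {
  utils::write.table(as.data.frame(barrier@vertices), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a barrier as a GeoJSON LineString
#' @param barrier a [GeneticBarrier-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBarrierGeoJSON <- function(barrier, path) {
  coords <- lapply(seq_len(nrow(barrier@vertices)), function(i)
    c(barrier@vertices[i, "lon"], barrier@vertices[i, "lat"]))
  obj <- list(type = "Feature",
              geometry = list(type = "LineString", coordinates = coords),
              properties = list(n_crossed = nrow(barrier@crossedEdges)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
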