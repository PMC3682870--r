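test_that("moving-window diversity follows the window and lineage rules", {
  ## three identical sequences at one spot -> pi_local = 0
  al <- c(a = "ACGT", b = "ACGT", c = "ACGT")
  meta <- toyMeta(names(al), lat = c(42, 42.1, 42.2), lon = -3,
                  lineage = "L1")
  pts <- localDiversity(al, meta)
  expect_true(all(pts$pi_local == 0))
  expect_true(all(pts$n_local == 3))
  ## a window with only 2 same-lineage members emits no point
  meta2 <- meta; meta2$lineage <- c("L1", "L1", "L2")
  pts2 <- localDiversity(al, meta2)
  expect_equal(nrow(pts2), 0)
  ## filter off pools across lineages
  pts3 <- localDiversity(al, meta2, sameLineageOnly = FALSE)
  expect_true(all(pts3$lineage == "mixed"))
  expect_true(all(pts3$n_local == 3))
})

test_that("lineage filtering never raises local diversity in contact zones", {
  set.seed(83)
  ds <- simulateDataset(defaultSimulationConfig(83))
  on <- localDiversity(ds@alignment, ds@meta, sameLineageOnly = TRUE)
  off <- localDiversity(ds@alignment, ds@meta, sameLineageOnly = FALSE)
  key <- function(p) paste(p$lat, p$lon)
  shared <- intersect(key(on), key(off))
  expect_gt(length(shared), 50)
  onv <- tapply(on$pi_local, key(on), max)[shared]
  offv <- tapply(off$pi_local, key(off), max)[shared]
  expect_true(all(offv >= onv - 1e-12))
  ## mixed windows near the contact zones show the inflation
  expect_gt(max(offv - onv), 0)
})

test_that("IDW interpolation is exact at points, bounded, symmetric", {
  ## one point: every in-range cell equals its value
  p1 <- data.frame(lat = 42, lon = -3, pi_local = 0.004)
  s1 <- interpolateSurface(p1, cellSize = 0.5, latMin = 41, lonMin = -4,
                           nrow = 5, ncol = 5, maxRadius = 10)
  expect_true(all(abs(s1@values - 0.004) < 1e-15))
  ## midpoint of two points averages them
  p2 <- data.frame(lat = c(42, 42), lon = c(-4, -2), pi_local = c(0, 0.01))
  s2 <- interpolateSurface(p2, cellSize = 1, latMin = 42, lonMin = -3,
                           nrow = 1, ncol = 1, maxRadius = 10)
  expect_equal(s2@values[1, 1], 0.005)
  ## coincident cell takes the point value exactly
  s3 <- interpolateSurface(p2, cellSize = 2, latMin = 42, lonMin = -4,
                           nrow = 1, ncol = 2, maxRadius = 10)
  expect_equal(s3@values[1, 1], 0)
  ## no overshoot of the input range
  set.seed(91)
  pts <- data.frame(lat = runif(20, 40, 44), lon = runif(20, -6, 0),
                    pi_local = runif(20, 0, 0.01))
  s4 <- interpolateSurface(pts, cellSize = 0.5, maxRadius = 3)
  v <- s4@values[!is.na(s4@values)]
  expect_true(all(v >= min(pts$pi_local) - 1e-12))
  expect_true(all(v <= max(pts$pi_local) + 1e-12))
  ## out-of-range cells are missing
  s5 <- interpolateSurface(p1, cellSize = 1, latMin = 10, lonMin = 10,
                           nrow = 2, ncol = 2, maxRadius = 1)
  expect_true(all(is.na(s5@values)))
  expect_error(interpolateSurface(p1, cellSize = -1), "cellSize")
})

test_that("a west-high gradient yields decreasing column means", {
  lon <- seq(-8, 0, by = 0.5)
  pts <- data.frame(lat = 42, lon = lon,
                    pi_local = seq(0.01, 0.001, length.out = length(lon)))
  s <- interpolateSurface(pts, cellSize = 0.5, maxRadius = 1.2)
  cm <- colMeans(s@values, na.rm = TRUE)
  expect_true(all(diff(cm) < 1e-9))
})

test_that("surface exports round-trip through TSV and ESRI ASCII", {
  p <- data.frame(lat = c(41, 42), lon = c(-3, -2),
                  pi_local = c(0.002, 0.006))
  s <- interpolateSurface(p, cellSize = 0.5, maxRadius = 5)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".asc")
  writeSurfaceTSV(s, f1)
  tab <- read.delim(f1)
  expect_true(all(tab$pi >= 0.002 - 1e-12 & tab$pi <= 0.006 + 1e-12))
  writeSurfaceAsciiGrid(s, f2)
  hdr <- readLines(f2, n = 6)
  expect_match(hdr[1], "^ncols")
  expect_equal(length(readLines(f2)) - 6, nrow(s@values))
})

test_that("Delaunay triangulation matches planar counts and the circumcircle oracle", {
  ## 3 points: 3 edges, 1 triangle
  m3 <- toyMeta(c("a", "b", "c"), lat = c(0, 1, 0), lon = c(0, 0, 1))
  t3 <- delaunayEdges(m3)
  expect_equal(nrow(t3$edges), 3)
  expect_equal(nrow(t3$triangles), 1)
  ## 4 points in convex position: 5 edges, 2 triangles
  m4 <- toyMeta(letters[1:4], lat = c(0, 0, 1, 1), lon = c(0, 1, 1.2, -0.2))
  t4 <- delaunayEdges(m4)
  expect_equal(nrow(t4$edges), 5)
  expect_equal(nrow(t4$triangles), 2)
  ## random instances vs the O(n^4) empty-circumcircle oracle
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    meta <- toyMeta(paste0("p", 1:n), lat = runif(n), lon = runif(n))
    tri <- delaunayEdges(meta)
    got <- sort(paste(pmin(tri$edges$i, tri$edges$j),
                      pmax(tri$edges$i, tri$edges$j)))
    want <- oracleDelaunayEdges(meta$lon, meta$lat)
    ## oracle works in (x, y) = (lon, lat) with the same indexing
    expect_identical(got, want)
  }
  ## degenerate inputs
  expect_error(delaunayEdges(m3[1:2, ]), "at least 3")
  mc <- toyMeta(c("a", "b", "c"), lat = c(0, 1, 2), lon = c(0, 1, 2))
  expect_error(delaunayEdges(mc), "collinear")
  ## duplicate coordinates are jittered, not merged
  md <- toyMeta(c("a", "b", "c", "d"), lat = c(0, 0, 1, 0),
                lon = c(0, 0, 0.5, 1))
  td <- delaunayEdges(md, seed = 3)
  expect_equal(length(td$ids), 4)
  expect_false(any(duplicated(td$coords)))
})

test_that("Monmonier barrier separates two divergent clusters", {
  ## two tight geographic clusters with a fixed genetic difference
  al <- c(w1 = "AAAAAA", w2 = "AAAAAT", w3 = "AAAAAA",
          e1 = "TTTTAA", e2 = "TTTTAT", e3 = "TTTTAA")
  meta <- toyMeta(names(al),
                  lat = c(42.0, 42.3, 41.8, 42.0, 42.3, 41.8),
                  lon = c(-5, -5.1, -4.9, -1, -1.1, -0.9))
  d <- pairwiseDifferences(al)
  tri <- delaunayEdges(meta)
  bar <- monmonierBarrier(tri, d)
  side <- substr(bar@crossedEdges$id1, 1, 1) != substr(bar@crossedEdges$id2, 1, 1)
  expect_true(all(side))            # every crossed edge joins w to e
  ## first crossed edge carries the global maximum edge distance
  dm <- as.matrix(d)
  edgeD <- dm[cbind(tri$edges$id1, tri$edges$id2)]
  seedRow <- which(bar@crossedEdges$seed)
  expect_equal(bar@crossedEdges$distance[seedRow], max(edgeD))
  ## barrier vertices are midpoints: between the clusters
  expect_true(all(bar@vertices[, "lon"] > -5 & bar@vertices[, "lon"] < -0.9))
})

test_that("Monmonier under uniform distances is deterministic via tie-breaks", {
  al <- c(a = "AAAA", b = "AAAT", c = "AATA", d = "ATAA", e = "TAAA")
  ## all pairwise distances equal 2 except identical
  meta <- toyMeta(names(al), lat = c(0, 0, 1, 1, 0.5),
                  lon = c(0, 1, 0, 1, 0.5))
  d <- pairwiseDifferences(al)
  tri <- delaunayEdges(meta)
  b1 <- monmonierBarrier(tri, d)
  b2 <- monmonierBarrier(tri, d)
  expect_identical(b1@crossedEdges, b2@crossedEdges)
  ## the seed edge is the lexicographically smallest maximal pair
  dm <- as.matrix(d)
  edgeD <- dm[cbind(tri$edges$id1, tri$edges$id2)]
  mx <- max(edgeD)
  cand <- tri$edges[edgeD == mx, ]
  cand <- cand[order(cand$id1, cand$id2), ]
  seedRow <- which(b1@crossedEdges$seed)
  expect_identical(b1@crossedEdges$id1[seedRow], cand$id1[1])
  expect_identical(b1@crossedEdges$id2[seedRow], cand$id2[1])
})

test_that("barrier exports emit a polyline TSV and GeoJSON LineString", {
  al <- c(a = "AAAA", b = "TTTT", c = "AATT", d = "TTAA")
  meta <- toyMeta(names(al), lat = c(0, 1, 0, 1), lon = c(0, 0, 1, 1.2))
  bar <- monmonierBarrier(delaunayEdges(meta), pairwiseDifferences(al))
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".geojson")
  writeBarrierTSV(bar, f1)
  expect_equal(nrow(read.delim(f1)), nrow(bar@vertices))
  writeBarrierGeoJSON(bar, f2)
  gj <- jsonlite::read_json(f2)
  expect_equal(gj$geometry$type, "LineString")
  expect_equal(length(gj$geometry$coordinates), nrow(bar@vertices))
})
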