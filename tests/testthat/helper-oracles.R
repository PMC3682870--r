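## Independent brute-force oracles and small fixture builders. These
## deliberately avoid the package's own code paths (direct loops, exact
## integer arithmetic) so they can serve as cross-checks.

## random alignment: ancestral sequence plus nMut random single-site
## variants spread over random subsets of sequences
randomAlignment <- function(n, L, nMut = max(1, L %/% 3)) {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(anc, n), nrow = n, byrow = TRUE)
  for (k in seq_len(nMut)) {
    s <- sample(L, 1)
    carriers <- sample(n, sample(n - 1, 1))
    m[carriers, s] <- sample(setdiff(c("A", "C", "G", "T"), anc[s]), 1)
  }
  out <- apply(m, 1, paste, collapse = "")
  names(out) <- paste0("s", seq_len(n))
  out
}

charMat <- function(al) {
  m <- do.call(rbind, strsplit(unname(al), ""))
  rownames(m) <- names(al)
  m
}

## direct-formula Tajima's D evaluated from scratch (complete-deletion
## alignments assumed clean here)
oracleTajimaD <- function(al) {
  m <- charMat(al)
  n <- nrow(m)
  S <- sum(apply(m, 2, function(col) length(unique(col)) >= 2))
  ks <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    ks <- c(ks, sum(m[i, ] != m[j, ]))
  kbar <- mean(ks)
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

## exact unsigned Stirling numbers of the first kind, row n (plain
## doubles, adequate for the small n used in tests)
exactStirlingRow <- function(n) {
  row <- 1
  if (n == 1) return(row)
  for (m in 1:(n - 1)) row <- c(m * row, 0) + c(0, row)
  row
}

## Fu's Fs by direct summation of the Ewens distribution
oracleFuFs <- function(n, h, theta) {
  s1 <- exactStirlingRow(n)
  denom <- prod(theta + 0:(n - 1))
  pk <- s1 * theta^seq_len(n) / denom
  P <- sum(pk[h:n])
  log(P / (1 - P))
}

## R2 from hand-counted singletons
oracleR2 <- function(al) {
  m <- charMat(al)
  n <- nrow(m)
  U <- numeric(n)
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    if (length(tab) < 2) next
    for (b in names(tab)[tab == 1]) U[m[, j] == b] <- U[m[, j] == b] + 1
  }
  ks <- c()
  for (i in 1:(n - 1)) for (jj in (i + 1):n)
    ks <- c(ks, sum(m[i, ] != m[jj, ]))
  kbar <- mean(ks)
  S <- sum(apply(m, 2, function(col) length(unique(col)) >= 2))
  sqrt(mean((U - kbar / 2)^2)) / S
}

## AMOVA variance components by explicit loops over a squared-distance
## matrix
oracleAmova <- function(d2, g) {
  N <- nrow(d2)
  ug <- unique(g)
  G <- length(ug)
  ssTot <- 0
  for (i in 1:N) for (j in 1:N) ssTot <- ssTot + d2[i, j]
  ssTot <- ssTot / (2 * N)
  ssW <- 0
  ng <- numeric(G)
  for (k in 1:G) {
    idx <- which(g == ug[k])
    ng[k] <- length(idx)
    acc <- 0
    for (i in idx) for (j in idx) acc <- acc + d2[i, j]
    ssW <- ssW + acc / (2 * ng[k])
  }
  ssA <- ssTot - ssW
  msdA <- ssA / (G - 1)
  msdW <- ssW / (N - G)
  nprime <- (N - sum(ng^2) / N) / (G - 1)
  s2w <- msdW
  s2a <- (msdA - s2w) / nprime
  list(ssAmong = ssA, ssWithin = ssW, sigma2Among = s2a,
       sigma2Within = s2w, phiST = s2a / (s2a + s2w))
}

## Pearson correlation over strictly-lower triangles, from the sum
## formulas
oracleMantelR <- function(mA, mB) {
  x <- c(); y <- c()
  n <- nrow(mA)
  for (i in 2:n) for (j in 1:(i - 1)) {
    x <- c(x, mA[i, j]); y <- c(y, mB[i, j])
  }
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

## brute-force Delaunay edge set: (i,j) is an edge iff some circumcircle
## through i, j and a third point contains no other point
oracleDelaunayEdges <- function(x, y) {
  n <- length(x)
  circum <- function(i, j, k) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  edges <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    found <- FALSE
    for (k in setdiff(1:n, c(i, j))) {
      cc <- circum(i, j, k)
      if (is.null(cc)) next
      others <- setdiff(1:n, c(i, j, k))
      dd <- sqrt((x[others] - cc[1])^2 + (y[others] - cc[2])^2)
      if (all(dd > cc[3] - 1e-9)) { found <- TRUE; break }
    }
    if (found) edges <- c(edges, paste(i, j))
  }
  sort(edges)
}

## exhaustive minimum-change count over all internal labelings
bruteFitch <- function(tree, tipStates) {
  nTip <- length(tree$tip.label)
  states <- sort(unique(unname(tipStates)))
  nInt <- tree$Nnode
  grid <- do.call(expand.grid,
                  c(rep(list(states), nInt), stringsAsFactors = FALSE))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- c(tipStates[tree$tip.label], unlist(grid[r, ]))
    cost <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, cost)
  }
  best
}

## simple BFS connectivity check for a haplotype network
netConnected <- function(net) {
  nodes <- net@nodes$node
  if (length(nodes) <= 1) return(TRUE)
  adj <- lapply(setNames(nm = nodes), function(x) character(0))
  for (e in seq_len(nrow(net@edges))) {
    a <- net@edges$from[e]; b <- net@edges$to[e]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- nodes[1]
  queue <- nodes[1]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- setdiff(adj[[v]], seen)
    seen <- c(seen, nb); queue <- c(queue, nb)
  }
  length(seen) == length(nodes)
}

## metadata builder
toyMeta <- function(ids, lat, lon, lineage = "", group = "",
                    sample_type = "tissue") {
  data.frame(id = ids, lat = lat, lon = lon, lineage = lineage,
             group = group, sample_type = sample_type,
             stringsAsFactors = FALSE)
}
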