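## Neutrality statistics: Tajima's D, Fu's Fs, Ramos-Onsins & Rozas R2,
## with coalescent-simulation p-values. The core formulas operate on the
## sufficient summaries (n, S, kbar, h, per-sequence singleton counts) so
## that observed data and simulated genealogies share one code path.

.tajimaConstants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

.tajimaDStat <- function(n, S, kbar) {
  k <- .tajimaConstants(n)
  (kbar - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

## Row of log unsigned Stirling numbers of the first kind, |s(n, 1..n)|,
## via the recurrence |s(n+1,k)| = n|s(n,k)| + |s(n,k-1)| in log space.
## Rows are cached per n: the simulation p-values reuse one n thousands
## of times.
.stirlingCache <- new.env(parent = emptyenv())

.logStirlingFirstRow <- function(n) {
  key <- as.character(n)
  hit <- .stirlingCache[[key]]
  if (!is.null(hit)) return(hit)
  row <- 0                           # |s(1,1)| = 1
  if (n > 1) {
    for (m in 1:(n - 1)) {           # row for m+1 from row for m
      t1 <- c(log(m) + row, -Inf)    # n|s(m,k)| term, k = 1..m+1
      t2 <- c(-Inf, row)             # |s(m,k-1)| term
      hi <- pmax(t1, t2)
      row <- hi + log(exp(t1 - hi) + exp(t2 - hi))
      row[is.nan(row)] <- -Inf
    }
  }
  .stirlingCache[[key]] <- row
  row
}

## log Pr(K = k) for k = 1..n under the Ewens sampling distribution at theta.
.ewensLogProbs <- function(n, theta) {
  ls1 <- .logStirlingFirstRow(n)
  k <- seq_len(n)
  ls1 + k * log(theta) - sum(log(theta + 0:(n - 1)))
}

.fuFsStat <- function(n, h, kbar) {
  if (kbar <= 0) stop("monomorphic sample: Fu's Fs undefined (kbar = 0)")
  lp <- .ewensLogProbs(n, kbar)
  idx <- h:n
  m <- max(lp[idx])
  logP <- m + log(sum(exp(lp[idx] - m)))
  P <- exp(logP)
  if (P >= 1) P <- 1 - 1e-15       # guard; exact only in degenerate h = 1
  log(P / (1 - P))
}

.r2Stat <- function(n, U, kbar, S) {
  sqrt(mean((U - kbar / 2)^2)) / S
}

## Sufficient summaries of an alignment under a deletion rule:
## n, S, kbar, h (haplotypes over the analyzed sites) and U (per-sequence
## count of singleton mutations: a resolved base seen exactly once at a
## polymorphic column scores for its carrier).
.neutralitySummaries <- function(al, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- .charMatrix(al)
  n <- nrow(m)
  if (deletion == "complete") {
    keep <- .resolvedColumns(m)
    if (!any(keep)) stop("no fully resolved sites under complete deletion")
    m <- m[, keep, drop = FALSE]
  }
  pd <- .pairDiffMatrices(m)
  kbar <- mean(.lowerTri(pd$diffs))
  S <- .countSegSites(m)
  hap <- collapseHaplotypes(apply(m, 1, paste, collapse = ""))
  U <- numeric(n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    res <- col %in% RESOLVED_BASES
    tab <- table(col[res])
    if (length(tab) < 2) next
    ones <- names(tab)[tab == 1]
    for (b in ones) U[which(res & col == b)] <- U[which(res & col == b)] + 1
  }
  list(n = n, S = S, kbar = kbar, h = nHaplotypes(hap), U = U)
}

#' Tajima's D
#'
#' Normalized difference between the pairwise (\eqn{\bar k}) and
#' Watterson (\eqn{S/a_1}) estimators of the population mutation rate;
#' negative values indicate an excess of rare variants as produced by
#' population expansion or purifying selection.
#'
#' @param al alignment of n >= 4 sequences with S >= 1.
#' @param deletion deletion rule (see [basicDiversity()]).
#' @return Tajima's D, a finite scalar.
#' @export
tajimasD <- function(al, deletion = c("complete", "pairwise")) {
  s <- .neutralitySummaries(al, deletion)
  if (s$n < 4) stop("Tajima's D needs at least 4 sequences")
  if (s$S == 0) stop("no segregating sites: Tajima's D undefined")
  .tajimaDStat(s$n, s$S, s$kbar)
}

#' Fu's Fs
#'
#' Log-odds of observing at least the sampled number of distinct
#' haplotypes under the Ewens sampling distribution with
#' \eqn{\hat\theta = \bar k}: \eqn{F_s = \ln(P/(1-P))} with
#' \eqn{P = \Pr(K \ge h_{obs})}. The Stirling-number recurrence is
#' evaluated in log space and remains stable well beyond n = 200.
#' Strongly negative values indicate an excess of alleles, as after an
#' expansion.
#'
#' @param al alignment with \eqn{\bar k > 0}.
#' @param deletion deletion rule.
#' @return Fu's Fs, a finite scalar.
#' @export
fusFs <- function(al, deletion = c("complete", "pairwise")) {
  s <- .neutralitySummaries(al, deletion)
  .fuFsStat(s$n, s$h, s$kbar)
}

#' Ramos-Onsins & Rozas R2
#'
#' Contrasts per-sequence singleton counts \eqn{U_i} with half the mean
#' pairwise difference: \eqn{R_2 = \sqrt{\frac{1}{n}\sum_i (U_i - \bar
#' k/2)^2} / S}. Small values indicate a star-like genealogy (population
#' expansion). A singleton is a resolved base observed in exactly one
#' sequence at a polymorphic site, under the active deletion rule.
#'
#' @param al alignment with S >= 1.
#' @param deletion deletion rule.
#' @return R2, a non-negative scalar.
#' @export
r2Statistic <- function(al, deletion = c("complete", "pairwise")) {
  s <- .neutralitySummaries(al, deletion)
  if (s$S == 0) stop("no segregating sites: R2 undefined")
  .r2Stat(s$n, s$U, s$kbar, s$S)
}

## Summaries of one simulated genealogy from a binary incidence matrix
## (n x S, entry 1 = sequence carries the mutation). Folded singleton
## rule matches the observed-data path.
.statsFromIncidence <- function(inc) {
  n <- nrow(inc)
  S <- ncol(inc)
  if (S == 0) return(list(n = n, S = 0L, kbar = 0, h = 1L, U = numeric(n)))
  r <- rowSums(inc)
  diffs <- outer(r, r, "+") - 2 * tcrossprod(inc)
  kbar <- mean(diffs[lower.tri(diffs)])
  h <- nrow(unique(inc))
  cs <- colSums(inc)
  U <- numeric(n)
  for (j in which(cs == 1)) U[which(inc[, j] == 1)] <- U[which(inc[, j] == 1)] + 1
  for (j in which(cs == n - 1)) U[which(inc[, j] == 0)] <- U[which(inc[, j] == 0)] + 1
  list(n = n, S = as.integer(S), kbar = kbar, h = as.integer(h), U = U)
}

## One constant-size coalescent genealogy conditional on S segregating
## sites: mutations placed uniformly on total branch length (fixed-S
## scheme). Returns the incidence matrix.
.simulateFixedS <- function(n, S) {
  g <- .coalescentBranches(n, mode = "constant")
  probs <- g$lengths / sum(g$lengths)
  counts <- as.vector(stats::rmultinom(1, S, probs))
  cols <- rep(seq_along(counts), counts)
  inc <- matrix(0L, n, length(cols))
  for (k in seq_along(cols)) inc[g$tipsets[[cols[k]]], k] <- 1L
  inc
}

#' Coalescent-simulation p-values for the neutrality statistics
#'
#' Simulates `reps` constant-size coalescent genealogies for `n` tips
#' conditional on the observed number of segregating sites (Hudson
#' fixed-S scheme: mutations placed uniformly on the total branch
#' length), recomputes each statistic, and reports one-tailed (lower
#' tail) p-values \eqn{p = (\#\{sim \le obs\} + 1)/(reps + 1)}. D, Fs and
#' R2 are all tested against their lower tail, the direction produced by
#' population expansion.
#'
#' @param n sample size.
#' @param S observed segregating sites (>= 1).
#' @param D,Fs,R2 observed statistics (any may be NA to skip).
#' @param reps simulation replicates (>= 100; default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @return list with `pD`, `pFs`, `pR2` (NA where the observed statistic
#'   was NA) and `reps`.
#' @export
neutralityPvalues <- function(n, S, D = NA, Fs = NA, R2 = NA,
                              reps = 1000, seed = 1) {
  if (reps < 100) stop("reps must be >= 100")
  if (S < 1) stop("need S >= 1")
  withSeed(seed, {
    simD <- simFs <- simR2 <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      st <- .statsFromIncidence(.simulateFixedS(n, S))
      simD[r] <- if (st$S > 0) .tajimaDStat(st$n, st$S, st$kbar) else NA
      simFs[r] <- if (st$kbar > 0) .fuFsStat(st$n, st$h, st$kbar) else NA
      simR2[r] <- if (st$S > 0) .r2Stat(st$n, st$U, st$kbar, st$S) else NA
    }
    lowerP <- function(obs, sim) {
      if (is.na(obs)) return(NA_real_)
      (sum(sim <= obs, na.rm = TRUE) + 1) / (reps + 1)
    }
    list(pD = lowerP(D, simD), pFs = lowerP(Fs, simFs),
         pR2 = lowerP(R2, simR2), reps = as.integer(reps))
  })
}

#' All three neutrality statistics, optionally with p-values
#'
#' Convenience wrapper computing Tajima's D, Fu's Fs and R2 for one
#' alignment and, when `reps > 0`, their fixed-S coalescent p-values.
#' Statistics undefined for the input (S = 0, monomorphic) are NA.
#'
#' @param al alignment.
#' @param deletion deletion rule.
#' @param reps simulation replicates (0 = no p-values).
#' @param seed RNG seed for the simulation.
#' @return a [NeutralityResult-class].
#' @export
neutralityTests <- function(al, deletion = c("complete", "pairwise"),
                            reps = 1000, seed = 1) {
  deletion <- match.arg(deletion)
  s <- .neutralitySummaries(al, deletion)
  D <- if (s$n >= 4 && s$S >= 1) .tajimaDStat(s$n, s$S, s$kbar) else NA_real_
  Fs <- if (s$kbar > 0) .fuFsStat(s$n, s$h, s$kbar) else NA_real_
  R2 <- if (s$S >= 1) .r2Stat(s$n, s$U, s$kbar, s$S) else NA_real_
  p <- list(pD = NA_real_, pFs = NA_real_, pR2 = NA_real_)
  if (reps > 0 && s$S >= 1)
    p <- neutralityPvalues(s$n, s$S, D, Fs, R2, reps = reps, seed = seed)
  methods::new("NeutralityResult", D = D, Fs = Fs, R2 = R2,
               pD = p$pD, pFs = p$pFs, pR2 = p$pR2,
               reps = as.integer(if (reps > 0 && s$S >= 1) reps else 0),
               seed = as.integer(seed))
}
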