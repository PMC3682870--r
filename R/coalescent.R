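## Constant-size and star coalescent genealogies. Branch lengths are in
## coalescent units (2N generations); with mutations Poisson(theta/2 x
## length) the closed forms E[pi] = theta and E[S] = theta * a1 hold.

## Genealogy as a flat branch list: for every non-root lineage, its length
## and the set of tips below it.
.coalescentBranches <- function(n, mode = c("constant", "star"),
                                starDepth = 1) {
  mode <- match.arg(mode)
  if (n < 2) stop("need n >= 2")
  if (mode == "star") {
    return(list(lengths = rep(starDepth, n),
                tipsets = as.list(seq_len(n))))
  }
  tipsets <- as.list(seq_len(n))
  age <- rep(0, n)                  # time since lineage birth
  outLen <- numeric(0)
  outSet <- list()
  k <- n
  while (k > 1) {
    t <- stats::rexp(1, rate = k * (k - 1) / 2)
    age <- age + t
    pair <- sample.int(k, 2)
    i <- min(pair); j <- max(pair)
    outLen <- c(outLen, age[i], age[j])
    outSet <- c(outSet, tipsets[i], tipsets[j])
    merged <- c(tipsets[[i]], tipsets[[j]])
    tipsets[[i]] <- merged
    age[i] <- 0
    tipsets[[j]] <- NULL
    age <- age[-j]
    k <- k - 1
  }
  list(lengths = outLen, tipsets = outSet)
}

#' Simulate a coalescent genealogy with mutations
#'
#' Constant mode draws inter-coalescence times \eqn{T_k \sim
#' Exp(k(k-1)/2)} (coalescent units) and merges uniformly random pairs;
#' star mode coalesces all lineages simultaneously at depth `starDepth`,
#' emulating a post-bottleneck expansion genealogy. Mutations are Poisson
#' with mean \eqn{(\theta/2) \times} branch length.
#'
#' @param n number of tips (>= 2).
#' @param theta population-scaled mutation rate per locus (>= 0).
#' @param mode `"constant"` or `"star"`.
#' @param seed RNG seed.
#' @param starDepth depth of the star genealogy in coalescent units.
#' @return list with `lengths` (branch lengths), `tipsets` (tips below
#'   each branch), `mutations` (mutation count per branch), `S` (total)
#'   and `incidence` (n x S binary matrix of mutation carriage).
#' @export
simulateCoalescent <- function(n, theta, mode = c("constant", "star"),
                               seed = 1, starDepth = 1) {
  mode <- match.arg(mode)
  if (theta < 0) stop("theta must be >= 0")
  withSeed(seed, {
    g <- .coalescentBranches(n, mode, starDepth)
    muts <- stats::rpois(length(g$lengths), theta / 2 * g$lengths)
    S <- sum(muts)
    inc <- matrix(0L, n, S)
    col <- 0L
    for (b in seq_along(muts)) {
      if (muts[b] == 0) next
      for (k in seq_len(muts[b])) {
        col <- col + 1L
        inc[g$tipsets[[b]], col] <- 1L
      }
    }
    list(lengths = g$lengths, tipsets = g$tipsets, mutations = muts,
         S = S, incidence = inc)
  })
}
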