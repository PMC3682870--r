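#' One-level analysis of molecular variance (AMOVA)
#'
#' Partitions squared inter-individual distances into among-group and
#' within-group variance components (Excoffier et al. 1992 scheme):
#' \deqn{SSD_{tot} = \frac{1}{2N}\sum_{i,j}\delta^2_{ij}, \quad
#'       SSD_{within} = \sum_g \frac{1}{2n_g}\sum_{i,j \in g}\delta^2_{ij}}
#' with \eqn{MSD = SSD/df}, \eqn{\sigma^2_b = MSD_{within}},
#' \eqn{\sigma^2_a = (MSD_{among} - \sigma^2_b)/n'} where
#' \eqn{n' = (N - \sum_g n_g^2/N)/(G-1)}, and
#' \eqn{\Phi_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_b)}.
#'
#' By default the supplied distances are squared to give \eqn{\delta^2}
#' (`square = TRUE`); pass `square = FALSE` to treat the entries
#' themselves as squared distances (the Arlequin "pairwise difference"
#' reading). A negative among-group component is reported unclamped, but
#' the percentage of variation among groups clamps it at zero.
#' Significance comes from permuting individuals among groups.
#'
#' @param d a [DistMatrix-class] (typically kind `"diff_count"`).
#' @param groups named vector mapping every id in `d` to a group label.
#' @param perms permutations for the p-value (default 1000).
#' @param seed RNG seed.
#' @param square square the distances before use (default TRUE).
#' @return an [AmovaResult-class].
#' @export
amovaOneLevel <- function(d, groups, perms = 1000, seed = 1, square = TRUE) {
  if (!methods::is(d, "DistMatrix")) stop("d must be a DistMatrix")
  ids <- d@ids
  g <- as.character(groups[ids])
  if (anyNA(g) || any(!nzchar(g)))
    stop("group label missing for: ",
         paste(ids[is.na(g) | !nzchar(g)], collapse = ", "))
  if (length(unique(g)) < 2) stop("need at least 2 groups")
  d2 <- d@values
  if (square) d2 <- d2^2
  obs <- .amovaComponents(d2, g)
  if (any(table(g) == 0)) stop("empty group")
  pPerm <- withSeed(seed, {
    cnt <- 0L
    for (p in seq_len(perms)) {
      phi <- .amovaComponents(d2, sample(g))$phiST
      if (phi >= obs$phiST - 1e-12) cnt <- cnt + 1L
    }
    (cnt + 1) / (perms + 1)
  })
  methods::new("AmovaResult",
    ssAmong = obs$ssAmong, ssWithin = obs$ssWithin,
    dfAmong = obs$dfAmong, dfWithin = obs$dfWithin,
    sigma2Among = obs$sigma2Among, sigma2Within = obs$sigma2Within,
    phiST = obs$phiST, pctAmong = obs$pctAmong,
    pPerm = pPerm, perms = as.integer(perms), seed = as.integer(seed),
    squared = square)
}

.amovaComponents <- function(d2, g) {
  N <- nrow(d2)
  ug <- unique(g)
  G <- length(ug)
  ssTotal <- sum(d2) / (2 * N)
  ssWithin <- 0
  ng <- integer(G)
  for (k in seq_len(G)) {
    idx <- which(g == ug[k])
    ng[k] <- length(idx)
    ssWithin <- ssWithin + sum(d2[idx, idx]) / (2 * ng[k])
  }
  ssAmong <- ssTotal - ssWithin
  dfAmong <- G - 1L
  dfWithin <- N - G
  msdAmong <- ssAmong / dfAmong
  msdWithin <- ssWithin / dfWithin
  nprime <- (N - sum(ng^2) / N) / (G - 1)
  s2w <- msdWithin
  s2a <- (msdAmong - s2w) / nprime
  phi <- s2a / (s2a + s2w)
  s2aClamp <- max(s2a, 0)
  pct <- if (s2aClamp + s2w > 0) 100 * s2aClamp / (s2aClamp + s2w) else 0
  list(ssAmong = ssAmong, ssWithin = ssWithin,
       dfAmong = dfAmong, dfWithin = as.integer(dfWithin),
       sigma2Among = s2a, sigma2Within = s2w, phiST = phi, pctAmong = pct)
}

#' Write an AMOVA report as TSV
#'
#' Source-of-variation rows (among groups / within groups) with df, sum
#' of squares, variance component and percentage of variation.
#'
#' @param x an [AmovaResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAmovaReport <- function(x, path) {
  s2a <- max(x@sigma2Among, 0)
  tot <- s2a + x@sigma2Within
  df <- data.frame(
    source = c("among_groups", "within_groups"),
    df = c(x@dfAmong, x@dfWithin),
    SS = c(x@ssAmong, x@ssWithin),
    variance_component = c(x@sigma2Among, x@sigma2Within),
    pct = c(x@pctAmong, if (tot > 0) 100 * x@sigma2Within / tot else 100),
    phi_ST = c(x@phiST, NA),
    p = c(x@pPerm, NA))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the strictly-lower-triangle entries of two
#' conforming distance matrices (typically genetic vs geographic
#' distance, diagnosing isolation by distance). The null distribution is
#' obtained by jointly permuting rows and columns of the second matrix;
#' the p-value is one-tailed for positive association,
#' \eqn{p = (\#\{r_{perm} \ge r_{obs}\} + 1)/(perms + 1)}.
#'
#' @param dA,dB [DistMatrix-class] objects with identical id order, n >= 4.
#' @param perms permutations (default 999).
#' @param seed RNG seed.
#' @return a [MantelResult-class].
#' @export
mantelTest <- function(dA, dB, perms = 999, seed = 1) {
  if (!methods::is(dA, "DistMatrix") || !methods::is(dB, "DistMatrix"))
    stop("dA and dB must be DistMatrix objects")
  if (!identical(dA@ids, dB@ids))
    stop("dA and dB must share the same ids in the same order")
  n <- length(dA@ids)
  if (n < 4) stop("need at least 4 samples")
  a <- .lowerTri(dA@values)
  if (stats::sd(a) == 0 || stats::sd(.lowerTri(dB@values)) == 0)
    stop("zero variance in a distance matrix")
  rObs <- stats::cor(a, .lowerTri(dB@values))
  pPerm <- withSeed(seed, {
    cnt <- 0L
    for (p in seq_len(perms)) {
      ord <- sample.int(n)
      rp <- stats::cor(a, .lowerTri(dB@values[ord, ord]))
      if (rp >= rObs - 1e-12) cnt <- cnt + 1L
    }
    (cnt + 1) / (perms + 1)
  })
  methods::new("MantelResult", r = rObs, pPerm = pPerm,
               perms = as.integer(perms), seed = as.integer(seed))
}
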