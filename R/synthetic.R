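#' Lineage specification for the simulator
#'
#' One parapatric mitochondrial lineage: sample size, per-locus
#' population-scaled mutation rate theta, an angular sector of the
#' sampling ring with a radial band, and the genealogy mode (`"constant"`
#' population size, or `"star"` for a post-bottleneck expansion).
#'
#' @param name lineage label.
#' @param n samples (>= 2).
#' @param theta per-locus theta (>= 0).
#' @param sectorStart,sectorEnd angular range in degrees (counterclockwise
#'   from east; `sectorEnd` may exceed 360 to wrap).
#' @param rInner,rOuter radial band in degrees.
#' @param growth `"constant"` or `"star"`.
#' @return a list usable in [simulationConfig()].
#' @export
lineageSpec <- function(name, n, theta, sectorStart, sectorEnd,
                        rInner = 1.8, rOuter = 2.6,
                        growth = c("constant", "star")) {
  growth <- match.arg(growth)
  if (n < 2) stop("n must be >= 2")
  if (theta < 0) stop("theta must be >= 0")
  list(name = name, n = as.integer(n), theta = theta,
       sectorStart = sectorStart, sectorEnd = sectorEnd,
       rInner = rInner, rOuter = rOuter, growth = growth)
}

#' Simulation configuration
#'
#' Bundles the lineage specs with the global parameters: alignment length
#' L, the expected number of fixed differences per branch of the lineage
#' tree, the basin (drainage) wedge layout that cross-cuts the lineage
#' sectors, the nuclear-locus model and the mandatory seed.
#'
#' @param lineages list of [lineageSpec()] entries.
#' @param L sites per sequence.
#' @param interLineageSteps expected fixed differences per lineage-tree
#'   branch (Poisson).
#' @param nBasins number of radial basin wedges.
#' @param basinOffset angular offset of the first wedge boundary
#'   (degrees), so wedges cross-cut lineage sectors.
#' @param centerLat,centerLon ring centre.
#' @param nuclear list(nLoci, theta, migration): count of biparental
#'   loci, per-locus theta controlling how often a locus is variable, and
#'   whether a variant may leak into an adjacent lineage (cross-lineage
#'   allele sharing).
#' @param seed mandatory RNG seed governing genealogies, mutation
#'   placement and coordinates.
#' @return a config list for [simulateDataset()].
#' @export
simulationConfig <- function(lineages, L = 1482, interLineageSteps = 8,
                             nBasins = 8, basinOffset = 22.5,
                             centerLat = 41.8, centerLon = -3.5,
                             nuclear = list(nLoci = 8, theta = 0.4,
                                            migration = TRUE),
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (L < 1) stop("L must be >= 1")
  list(lineages = lineages, L = as.integer(L),
       interLineageSteps = interLineageSteps, nBasins = as.integer(nBasins),
       basinOffset = basinOffset, centerLat = centerLat,
       centerLon = centerLon, nuclear = nuclear, seed = as.integer(seed))
}

#' Default four-lineage refugial-expansion configuration
#'
#' The study conditions the simulator emulates: four parapatric
#' mitochondrial lineages named A1/A2/B1/B2 with sample sizes 48, 16, 29
#' and 41 and per-locus thetas 5.3, 2.4, 3.6 and 0.6 (i.e. Table-style
#' per-lineage diversity, one order of magnitude between the
#' high-diversity refugium lineage A1 and the near-monomorphic B2).
#' A1 and B2 use star genealogies (expansion); the ring of radius
#' 1.8-2.6 degrees around (41.8, -3.5) is split into four quadrant
#' sectors with group A occupying the west half and group B the east
#' half, giving two narrow A/B contact zones; 8 basin wedges offset by
#' half a wedge cross-cut the lineage sectors. The lineage tree carries 8
#' expected fixed differences per branch: because coordinates are uniform
#' within each sector (no within-lineage isolation by distance), the
#' between-group divergence must stand clear of the within-lineage
#' pairwise-difference tail for the group split to be identifiable from a
#' single maximum-difference barrier trace.
#'
#' @param seed mandatory RNG seed.
#' @return a config list.
#' @export
defaultSimulationConfig <- function(seed) {
  simulationConfig(
    lineages = list(
      lineageSpec("A1", 48, 5.3, 135, 225, growth = "star"),
      lineageSpec("A2", 16, 2.4, 225, 315, growth = "constant"),
      lineageSpec("B1", 29, 3.6, 45, 135, growth = "constant"),
      lineageSpec("B2", 41, 0.6, -45, 45, growth = "star")),
    seed = seed)
}

## allocate k unused sites, or fail loudly
.takeSites <- function(pool, k) {
  if (k > length(pool$free))
    stop("infinite-sites mapping exhausted the alignment; increase L")
  idx <- if (length(pool$free) == 1) pool$free else sample(pool$free, k)
  idx <- idx[seq_len(k)]
  pool$free <- setdiff(pool$free, idx)
  idx
}

#' Simulate a multi-lineage phylogeographic dataset
#'
#' Generates, from one seed: (1) a random ancestral sequence of length L;
#' (2) fixed inter-lineage differences along a lineage tree (a balanced
#' ((1,2),(3,4)) topology for four lineages, a star otherwise), Poisson
#' per branch; (3) per lineage, a coalescent sample (constant or star
#' genealogy) with infinite-sites mutations mapped to distinct unused
#' sites, so S equals the realized mutation count; (4) uniform
#' coordinates within each lineage's ring sector, basin labels from the
#' cross-cutting radial wedges and a feces/tissue/museum sample type; (5)
#' low-variability biparental loci in which a variant arises in one home
#' lineage and, when migration is enabled, may also segregate at low
#' frequency in an adjacent lineage.
#'
#' @param cfg configuration from [simulationConfig()] or
#'   [defaultSimulationConfig()].
#' @return a [SyntheticDataset-class]; `truth` holds the config and the
#'   realized genealogy summaries.
#' @export
simulateDataset <- function(cfg) {
  L <- cfg$L
  specs <- cfg$lineages
  nl <- length(specs)
  withSeed(cfg$seed, {
    anc <- sample(RESOLVED_BASES, L, replace = TRUE)
    pool <- new.env()
    pool$free <- seq_len(L)
    ## lineage tree: fixed differences per branch
    branchOf <- function() {
      k <- stats::rpois(1, cfg$interLineageSteps)
      sites <- .takeSites(pool, k)
      bases <- vapply(sites, function(s)
        sample(setdiff(RESOLVED_BASES, anc[s]), 1), "")
      list(sites = sites, bases = bases)
    }
    lineageMuts <- vector("list", nl)   # per lineage: accumulated fixed muts
    if (nl == 4) {
      bA <- branchOf(); bB <- branchOf()
      stems <- lapply(seq_len(4), function(i) branchOf())
      groupMut <- list(bA, bA, bB, bB)
      for (i in seq_len(4))
        lineageMuts[[i]] <- list(
          sites = c(groupMut[[i]]$sites, stems[[i]]$sites),
          bases = c(groupMut[[i]]$bases, stems[[i]]$bases))
    } else {
      for (i in seq_len(nl)) lineageMuts[[i]] <- branchOf()
    }
    seqs <- character(0)
    meta <- list()
    realized <- list()
    for (i in seq_len(nl)) {
      sp <- specs[[i]]
      lanc <- anc
      lanc[lineageMuts[[i]]$sites] <- lineageMuts[[i]]$bases
      g <- .coalescentBranches(sp$n, sp$growth, starDepth = 1)
      muts <- stats::rpois(length(g$lengths), sp$theta / 2 * g$lengths)
      m <- matrix(rep(lanc, sp$n), nrow = sp$n, byrow = TRUE)
      for (b in seq_along(muts)) {
        if (muts[b] == 0) next
        sites <- .takeSites(pool, muts[b])
        for (k in seq_along(sites)) {
          s <- sites[k]
          newBase <- sample(setdiff(RESOLVED_BASES, lanc[s]), 1)
          m[g$tipsets[[b]], s] <- newBase
        }
      }
      ids <- sprintf("%s_%02d", sp$name, seq_len(sp$n))
      seqsL <- apply(m, 1, paste, collapse = "")
      names(seqsL) <- ids
      seqs <- c(seqs, seqsL)
      angle <- (stats::runif(sp$n, sp$sectorStart, sp$sectorEnd)) %% 360
      r <- stats::runif(sp$n, sp$rInner, sp$rOuter)
      lat <- cfg$centerLat + r * sin(angle * pi / 180)
      lon <- cfg$centerLon + r * cos(angle * pi / 180)
      basin <- sprintf("basin%d",
                       1 + floor(((angle - cfg$basinOffset) %% 360) /
                                 (360 / cfg$nBasins)))
      stype <- sample(c("feces", "tissue", "museum"), sp$n, replace = TRUE,
                      prob = c(0.515, 0.47, 0.015))
      meta[[i]] <- data.frame(id = ids, lat = lat, lon = lon,
                              lineage = sp$name, group = basin,
                              sample_type = stype, stringsAsFactors = FALSE)
      realized[[sp$name]] <- list(S = sum(muts),
                                  fixedSites = length(lineageMuts[[i]]$sites))
    }
    meta <- do.call(rbind, meta)
    nuclear <- .simulateNuclear(cfg, meta)
    methods::new("SyntheticDataset",
      alignment = Biostrings::DNAStringSet(seqs),
      meta = meta, nuclear = nuclear,
      truth = list(config = cfg, realized = realized,
                   sitesUsed = L - length(pool$free)))
  })
}

## Low-variability biparental loci. Each locus: variable with probability
## 1 - exp(-theta); if variable, a derived allele arises in a "home"
## lineage (chosen proportional to lineage theta) at a uniform frequency,
## and with migration enabled it may also segregate at low frequency in
## one ring-adjacent lineage (cross-lineage allele sharing). Genotypes
## are Hardy-Weinberg draws; alleles are reported as bases.
.simulateNuclear <- function(cfg, meta) {
  nuc <- cfg$nuclear
  if (is.null(nuc) || nuc$nLoci == 0)
    return(data.frame(sample = character(0), locus = character(0),
                      allele1 = character(0), allele2 = character(0),
                      stringsAsFactors = FALSE))
  specs <- cfg$lineages
  lnames <- vapply(specs, `[[`, "", "name")
  thetas <- vapply(specs, `[[`, 0, "theta")
  ## ring adjacency by sector midpoint order
  mid <- vapply(specs, function(sp)
    ((sp$sectorStart + sp$sectorEnd) / 2) %% 360, 0)
  ringOrder <- order(mid)
  adjacentOf <- function(i) {
    pos <- which(ringOrder == i)
    nb <- c(ringOrder[(pos %% length(ringOrder)) + 1],
            ringOrder[((pos - 2) %% length(ringOrder)) + 1])
    unique(nb)
  }
  out <- list()
  for (l in seq_len(nuc$nLoci)) {
    locus <- sprintf("locus%02d", l)
    ancA <- sample(RESOLVED_BASES, 1)
    derA <- sample(setdiff(RESOLVED_BASES, ancA), 1)
    freq <- stats::setNames(rep(0, length(lnames)), lnames)
    if (stats::runif(1) < 1 - exp(-nuc$theta)) {
      home <- sample(seq_along(lnames), 1, prob = thetas + 1e-6)
      freq[home] <- stats::runif(1, 0.1, 0.5)
      if (isTRUE(nuc$migration) && stats::runif(1) < 0.5) {
        nb <- sample(adjacentOf(home), 1)
        freq[nb] <- stats::runif(1, 0.05, 0.2)
      }
    }
    q <- freq[meta$lineage]
    a1 <- ifelse(stats::runif(nrow(meta)) < q, derA, ancA)
    a2 <- ifelse(stats::runif(nrow(meta)) < q, derA, ancA)
    out[[l]] <- data.frame(sample = meta$id, locus = locus,
                           allele1 = a1, allele2 = a2,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the formats the readers consume: `alignment.fasta`,
#' `metadata.tsv`, `nuclear.tsv` (genotype calls) and `truth.json` (the
#' generating config, seed included, plus realized summaries). Equal
#' seeds give byte-identical output.
#'
#' @param ds a [SyntheticDataset-class].
#' @param outDir output directory (created if absent).
#' @return named character vector of the paths written.
#' @export
writeDataset <- function(ds, outDir) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", outDir)
  paths <- c(
    fasta = file.path(outDir, "alignment.fasta"),
    meta = file.path(outDir, "metadata.tsv"),
    nuclear = file.path(outDir, "nuclear.tsv"),
    truth = file.path(outDir, "truth.json"))
  writeFasta(ds@alignment, paths[["fasta"]])
  writeSampleMetadata(ds@meta, paths[["meta"]])
  utils::write.table(ds@nuclear, paths[["nuclear"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ds@truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
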