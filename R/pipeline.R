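#' Default pipeline configuration
#'
#' @param outDir output directory.
#' @param fasta character vector of locus FASTA paths (concatenated in
#'   order), or NULL when `simulate = TRUE`.
#' @param metadata metadata TSV path, or NULL when simulating.
#' @param newick optional newick tree for the genealogy stage (an NJ tree
#'   of haplotype representatives is built when absent).
#' @param simulate generate the input dataset with
#'   [defaultSimulationConfig()] first.
#' @param stages stages to run, in order.
#' @param deletion deletion rule for sequence statistics.
#' @param radius moving-window radius (degrees).
#' @param cellSize surface grid cell (degrees).
#' @param maxRadius IDW search radius (degrees).
#' @param amovaPerms,mantelPerms,neutralityReps Monte-Carlo sizes.
#' @param seed seed for every stochastic stage (and the simulator).
#' @return a config list for [runPipeline()].
#' @export
pipelineConfig <- function(outDir, fasta = NULL, metadata = NULL,
                           newick = NULL, simulate = is.null(fasta),
                           stages = c("diversity", "neutrality", "amova",
                                      "mantel", "surface", "barrier",
                                      "genealogy"),
                           deletion = "complete", radius = 1.0,
                           cellSize = 0.25, maxRadius = 2.0,
                           amovaPerms = 1000, mantelPerms = 999,
                           neutralityReps = 1000, seed = 1) {
  list(outDir = outDir, fasta = fasta, metadata = metadata, newick = newick,
       simulate = simulate, stages = stages, deletion = deletion,
       radius = radius, cellSize = cellSize, maxRadius = maxRadius,
       amovaPerms = amovaPerms, mantelPerms = mantelPerms,
       neutralityReps = neutralityReps, seed = as.integer(seed))
}

#' Run the phylogeographic pipeline end-to-end
#'
#' Orchestrates the stages over one config: (optional) synthetic-data
#' generation, diversity table, neutrality tests with p-values, AMOVA by
#' the metadata `group` column, Mantel isolation-by-distance, the
#' moving-window diversity surface, the Monmonier barrier and the
#' haplotype genealogy. Every artifact lands in `outDir` alongside a
#' machine-readable `manifest.json` (input hashes, parameters, seeds,
#' package version). A stage failure writes a `FAILED` marker naming the
#' stage and rethrows; partial outputs are retained.
#'
#' @param config list from [pipelineConfig()], or the path of a YAML file
#'   with the same keys.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- do.call(pipelineConfig, config[!vapply(config, is.null, TRUE)])
  out <- cfg$outDir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE))
    stop("cannot create output directory: ", out)
  log <- function(...) message("[mtphylogeo] ", ...)
  stage <- function(name, expr) {
    log("stage ", name)
    tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage", name, ":", conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  unlink(file.path(out, "FAILED"))
  artifacts <- character(0)
  if (isTRUE(cfg$simulate)) {
    stage("simulate", {
      ds <- simulateDataset(defaultSimulationConfig(cfg$seed))
      paths <- writeDataset(ds, file.path(out, "data"))
      cfg$fasta <- paths[["fasta"]]
      cfg$metadata <- paths[["meta"]]
      artifacts <- c(artifacts, paths)
    })
  }
  if (is.null(cfg$fasta) || is.null(cfg$metadata))
    stop("config must provide fasta and metadata (or simulate = TRUE)")
  al <- stage("read", concatenateLoci(lapply(cfg$fasta, readFasta)))
  meta <- stage("read", readSampleMetadata(cfg$metadata))
  if (!all(names(al) %in% meta$id))
    stop("stage 'read' failed: metadata missing for some sequences")
  meta <- meta[match(names(al), meta$id), ]
  dDiff <- pairwiseDifferences(al, cfg$deletion)
  run <- function(s) s %in% cfg$stages
  emit <- function(path) artifacts <<- c(artifacts, path)
  if (run("diversity")) stage("diversity", {
    tab <- diversityTable(al, meta, partitions = c("lineage", "sample_type"),
                          deletion = cfg$deletion)
    emit(writeDiversityTable(tab, file.path(out, "diversity_table.tsv")))
  })
  if (run("neutrality")) stage("neutrality", {
    lev <- c(list(whole = seq_along(al)),
             split(seq_along(al), meta$lineage))
    rows <- lapply(names(lev), function(nm) {
      idx <- lev[[nm]]
      if (length(idx) < 4)
        return(data.frame(level = nm, n = length(idx), D = NA, pD = NA,
                          Fs = NA, pFs = NA, R2 = NA, pR2 = NA))
      r <- neutralityTests(al[idx], cfg$deletion,
                           reps = cfg$neutralityReps, seed = cfg$seed)
      data.frame(level = nm, n = length(idx), D = r@D, pD = r@pD,
                 Fs = r@Fs, pFs = r@pFs, R2 = r@R2, pR2 = r@pR2)
    })
    tab <- do.call(rbind, rows)
    f <- file.path(out, "neutrality.tsv")
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(f)
  })
  if (run("amova")) stage("amova", {
    if (any(!nzchar(meta$group)))
      stop("metadata 'group' column required for AMOVA")
    groups <- stats::setNames(meta$group, meta$id)
    res <- amovaOneLevel(dDiff, groups, perms = cfg$amovaPerms,
                         seed = cfg$seed)
    emit(writeAmovaReport(res, file.path(out, "amova.tsv")))
  })
  if (run("mantel")) stage("mantel", {
    dGeo <- geoDistanceMatrix(meta, "km")
    res <- mantelTest(dDiff, dGeo, perms = cfg$mantelPerms, seed = cfg$seed)
    f <- file.path(out, "mantel.tsv")
    utils::write.table(
      data.frame(r = res@r, p = res@pPerm, perms = res@perms,
                 seed = res@seed),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(f)
  })
  if (run("surface")) stage("surface", {
    pts <- localDiversity(al, meta, radius = cfg$radius,
                          sameLineageOnly = TRUE, deletion = cfg$deletion)
    surf <- interpolateSurface(pts, cellSize = cfg$cellSize,
                               maxRadius = cfg$maxRadius)
    emit(writeSurfaceAsciiGrid(surf, file.path(out, "surface.asc")))
    emit(writeSurfaceTSV(surf, file.path(out, "surface.tsv")))
  })
  if (run("barrier")) stage("barrier", {
    tri <- delaunayEdges(meta, seed = cfg$seed)
    bar <- monmonierBarrier(tri, dDiff)
    emit(writeBarrierTSV(bar, file.path(out, "barrier.tsv")))
    emit(writeBarrierGeoJSON(bar, file.path(out, "barrier.geojson")))
  })
  if (run("genealogy")) stage("genealogy", {
    haps <- collapseHaplotypes(al)
    reps <- vapply(haps@members, `[[`, "", 1)
    tree <- if (!is.null(cfg$newick)) readNewick(cfg$newick)
            else njTree(pDistanceMatrix(al[reps], cfg$deletion))
    net <- haplotypeGenealogy(tree, haps,
                              L = Biostrings::width(al)[1])
    emit(writeNetworkTSV(net, file.path(out, "network_nodes.tsv"),
                         file.path(out, "network_edges.tsv")))
  })
  manifest <- list(
    package = "mtphylogeo",
    version = as.character(utils::packageVersion("mtphylogeo")),
    inputs = lapply(stats::setNames(nm = unique(c(cfg$fasta, cfg$metadata,
                                                  cfg$newick))),
                    function(p) unname(tools::md5sum(p))),
    parameters = cfg[c("deletion", "radius", "cellSize", "maxRadius",
                       "amovaPerms", "mantelPerms", "neutralityReps",
                       "stages", "simulate")],
    seed = cfg$seed,
    artifacts = unname(artifacts),
    artifact_md5 = lapply(stats::setNames(nm = unname(artifacts)),
                          function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
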