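#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining (via ape), used as the distance-tree
#' substrate when no externally inferred newick is supplied. Negative
#' branch lengths are clamped to zero; the total clamped deficit is kept
#' in the `"clampedDeficit"` attribute.
#'
#' @param d a [DistMatrix-class] of n >= 3 samples.
#' @return an [ape::phylo] tree.
#' @export
njTree <- function(d) {
  if (!methods::is(d, "DistMatrix")) stop("d must be a DistMatrix")
  if (length(d@ids) < 3) stop("need at least 3 samples")
  tr <- ape::nj(as.matrix(d))
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clampedDeficit") <- deficit
  tr
}

#' Read a newick tree
#'
#' Wraps [ape::read.tree] with a bracket-balance pre-check that reports
#' the byte offset of an unbalanced parenthesis.
#'
#' @param path path to a newick file.
#' @return an [ape::phylo] tree.
#' @export
readNewick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") {
      depth <- depth - 1L
      if (depth < 0) stop("malformed newick: unbalanced ')' at offset ", k)
    }
  }
  if (depth != 0)
    stop("malformed newick: ", depth, " unclosed '(' at end of input")
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("malformed newick in ", path)
  tr
}

#' Write a newick tree
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Collapse a phylogenetic tree into a haplotype genealogy
#'
#' Haploviewer-style network construction: branch lengths (in
#' substitutions/site) are scaled by the alignment length to expected
#' substitution counts; branches carrying fewer than `collapseBelow`
#' expected substitutions (default 0.5, i.e. "less than one mutation"
#' under round-half-up) are contracted, merging their endpoints; every
#' remaining branch of rounded step count \eqn{m \ge 2} is subdivided by
#' \eqn{m-1} unsampled intermediate nodes (the "black dots"). Sampled
#' node sizes are the haplotype abundances.
#'
#' @param tree an [ape::phylo] tree whose tip labels are haplotype
#'   representatives present in `haps` (e.g. the first member id of each
#'   haplotype).
#' @param haps a [HaplotypeTable-class].
#' @param L alignment length in sites.
#' @param collapseBelow contraction threshold in expected substitutions.
#' @return a [HaplotypeNetwork-class].
#' @export
haplotypeGenealogy <- function(tree, haps, L, collapseBelow = 0.5) {
  assignment <- haplotypeAssignment(haps)
  miss <- setdiff(tree$tip.label, names(assignment))
  if (length(miss))
    stop("tree tips absent from haplotype table: ",
         paste(miss, collapse = ", "))
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  ## union-find over tree nodes
  parent <- seq_len(nNode)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  exp <- tree$edge.length * L
  steps <- ifelse(exp < collapseBelow, 0L, pmax(1L, floor(exp + 0.5)))
  for (e in seq_len(nrow(tree$edge)))
    if (steps[e] == 0) {
      ra <- find(tree$edge[e, 1]); rb <- find(tree$edge[e, 2])
      if (ra != rb) parent[rb] <- ra
    }
  roots <- vapply(seq_len(nNode), find, 0L)
  groups <- unique(roots)
  gIdx <- match(roots, groups)
  ## node bookkeeping per group
  labels <- counts <- character(0)
  nodes <- data.frame(node = character(0), count = integer(0),
                      sampled = logical(0), haplotypes = character(0),
                      stringsAsFactors = FALSE)
  for (k in seq_along(groups)) {
    tips <- which(gIdx[seq_len(nTip)] == k)
    if (length(tips)) {
      labs <- tree$tip.label[tips]
      cnt <- sum(haplotypeCounts(haps)[assignment[labs]])
      nodes <- rbind(nodes, data.frame(
        node = labs[1], count = as.integer(cnt), sampled = TRUE,
        haplotypes = paste(labs, collapse = ","), stringsAsFactors = FALSE))
    } else {
      nodes <- rbind(nodes, data.frame(
        node = sprintf("node%d", k), count = 0L, sampled = FALSE,
        haplotypes = "", stringsAsFactors = FALSE))
    }
  }
  edges <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  interm <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    if (steps[e] == 0) next
    a <- nodes$node[gIdx[tree$edge[e, 1]]]
    b <- nodes$node[gIdx[tree$edge[e, 2]]]
    chain <- a
    if (steps[e] >= 2) {
      for (s in seq_len(steps[e] - 1L)) {
        interm <- interm + 1L
        mid <- sprintf("mv%d", interm)
        nodes <- rbind(nodes, data.frame(
          node = mid, count = 0L, sampled = FALSE, haplotypes = "",
          stringsAsFactors = FALSE))
        chain <- c(chain, mid)
      }
    }
    chain <- c(chain, b)
    edges <- rbind(edges, data.frame(from = chain[-length(chain)],
                                     to = chain[-1],
                                     stringsAsFactors = FALSE))
  }
  methods::new("HaplotypeNetwork", nodes = nodes, edges = edges)
}

#' Write a haplotype network as node and edge TSVs
#' @param net a [HaplotypeNetwork-class].
#' @param nodePath,edgePath output paths.
#' @return invisibly, c(nodePath, edgePath).
#' @export
writeNetworkTSV <- function(net, nodePath, edgePath) {
  utils::write.table(net@nodes, nodePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net@edges, edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nodePath, edgePath))
}

#' Minimum-change (Fitch/Hartigan) ancestral reconstruction
#'
#' Two-pass parsimony on a rooted tree with one discrete character (e.g.
#' the amino acid at one cytochrome b codon): the up-pass computes the
#' minimal number of state changes (Hartigan's generalization, so
#' multifurcations are allowed); the down-pass fixes one optimal
#' labeling (ties resolved toward the lexicographically smallest state)
#' and reports the branches on which a change is forced.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @param tipStates named character vector mapping every tip label to a
#'   state.
#' @return list with `changes` (minimal change count), `nodeStates`
#'   (assigned state per node, tips first in `tree$tip.label` order,
#'   then internal nodes), `stateSets` (the up-pass state sets) and
#'   `changedBranches` (data.frame parent, child, from, to).
#' @export
fitchChanges <- function(tree, tipStates) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  miss <- setdiff(tree$tip.label, names(tipStates))
  if (length(miss))
    stop("missing tip state for: ", paste(miss, collapse = ", "))
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  children <- vector("list", nNode)
  for (e in seq_len(nrow(tree$edge)))
    children[[tree$edge[e, 1]]] <- c(children[[tree$edge[e, 1]]],
                                     tree$edge[e, 2])
  sets <- vector("list", nNode)
  for (t in seq_len(nTip)) sets[[t]] <- tipStates[[tree$tip.label[t]]]
  changes <- 0L
  ## process internal nodes children-first
  done <- c(rep(TRUE, nTip), rep(FALSE, tree$Nnode))
  while (any(!done)) {
    for (v in (nTip + 1):nNode) {
      if (done[v] || !all(done[children[[v]]])) next
      allStates <- unique(unlist(sets[children[[v]]]))
      k <- vapply(allStates, function(s)
        sum(vapply(children[[v]], function(ch) s %in% sets[[ch]], TRUE)),
        0L)
      K <- max(k)
      sets[[v]] <- sort(allStates[k == K])
      changes <- changes + length(children[[v]]) - K
      done[v] <- TRUE
    }
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  states <- character(nNode)
  states[root] <- sort(sets[[root]])[1]
  changed <- data.frame(parent = integer(0), child = integer(0),
                        from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  ## preorder down-pass
  stack <- root
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    for (ch in children[[v]]) {
      if (states[v] %in% sets[[ch]]) {
        states[ch] <- states[v]
      } else {
        states[ch] <- sort(sets[[ch]])[1]
        changed <- rbind(changed, data.frame(
          parent = v, child = ch, from = states[v], to = states[ch],
          stringsAsFactors = FALSE))
      }
      if (ch > nTip) stack <- c(stack, ch)
    }
  }
  list(changes = as.integer(changes), nodeStates = states,
       stateSets = sets, changedBranches = changed)
}

#' Translate mitochondrial DNA to protein
#'
#' Translation under the vertebrate mitochondrial genetic code (so ATA is
#' Met and TGA is Trp, unlike the standard code). A premature internal
#' stop raises a warning naming the codon index.
#'
#' @param dna DNA string (character or [Biostrings::DNAString]); length
#'   must be divisible by 3 unless `trim = TRUE`, which drops the
#'   trailing partial codon.
#' @param trim drop a trailing partial codon instead of erroring.
#' @return the protein as a character string.
#' @export
translateMtdna <- function(dna, trim = FALSE) {
  s <- toupper(as.character(dna))
  if (nchar(s) %% 3 != 0) {
    if (!trim) stop("length not divisible by 3 (use trim = TRUE)")
    s <- substr(s, 1, nchar(s) - nchar(s) %% 3)
  }
  if (!nchar(s)) stop("empty sequence")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(s),
    genetic.code = Biostrings::getGeneticCode("2"),
    if.fuzzy.codon = "X"))
  stops <- which(strsplit(aa, "")[[1]] == "*")
  internal <- stops[stops < nchar(aa)]
  if (length(internal))
    warning("internal stop codon at codon index ",
            paste(internal, collapse = ", "))
  aa
}

#' Jukes-Cantor distance correction
#'
#' @param p raw p-distance(s) in [0, 0.75).
#' @return JC69-corrected distance \eqn{-\frac{3}{4}\ln(1 - \frac{4}{3}p)}.
#' @export
jcDistance <- function(p) {
  if (any(p < 0 | p >= 0.75)) stop("p must lie in [0, 0.75)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Strict-clock TMRCA from a calibration split
#'
#' The simplest distance-clock calculation: a calibration pair at known
#' divergence time fixes the rate, \eqn{r = d_{split}/(2 t_{split})}, and
#' a within-species distance converts to a coalescence time
#' \eqn{t = d_{target}/(2r)}. This deliberately replaces full Bayesian
#' relaxed-clock dating; treat its output as a back-of-envelope figure.
#'
#' @param dSplit distance between the calibration taxa
#'   (substitutions/site; p- or JC-corrected, use the same scale as
#'   `dTarget`).
#' @param tSplit age of the calibration split in Myr.
#' @param dTarget within-species distance to date.
#' @return a [ClockEstimate-class].
#' @export
clockTmrca <- function(dSplit, tSplit, dTarget) {
  if (any(c(dSplit, tSplit, dTarget) <= 0))
    stop("all inputs must be positive")
  rate <- dSplit / (2 * tSplit)
  methods::new("ClockEstimate", rate = rate, tmrca = dTarget / (2 * rate),
               splitDistance = dSplit, splitAge = tSplit)
}
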