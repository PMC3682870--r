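test_that("NJ recovers additive distances exactly", {
  ## additive 4-taxon matrix from a known tree:
  ## ((a:1,b:2):1,(c:3,d:1):1); path lengths below
  ids <- c("a", "b", "c", "d")
  m <- matrix(c(0, 3, 6, 4,
                3, 0, 7, 5,
                6, 7, 0, 4,
                4, 5, 4, 0), 4, 4, dimnames = list(ids, ids))
  d <- new("DistMatrix", ids = ids, values = m * 1.0, kind = "diff_count",
           lused = NULL)
  tr <- njTree(d)
  pd <- ape::cophenetic.phylo(tr)[ids, ids]
  expect_equal(unname(pd), unname(m), tolerance = 1e-9)
  ## 3 taxa: closed-form star lengths
  m3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(ids[1:3], ids[1:3]))
  d3 <- new("DistMatrix", ids = ids[1:3], values = m3 * 1.0,
            kind = "diff_count", lused = NULL)
  t3 <- njTree(d3)
  len <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(len[["a"]], 1)
  expect_equal(len[["b"]], 1)
  expect_equal(len[["c"]], 3)
  ## random matrices: NJ tree distances approximate input (least squares)
  set.seed(111)
  for (rep in 1:5) {
    al <- randomAlignment(8, 60, nMut = 20)
    d8 <- pDistanceMatrix(al)
    tr8 <- njTree(d8)
    pd8 <- ape::cophenetic.phylo(tr8)[names(al), names(al)]
    expect_lt(max(abs(pd8 - as.matrix(d8))), 0.25)
  }
})

test_that("newick IO round-trips and reports malformed input positions", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(length(t2$tip.label), 2)
  set.seed(121)
  tr <- ape::rtree(50)
  f <- tempfile(fileext = ".nwk")
  writeNewick(tr, f)
  back <- readNewick(f)
  expect_identical(back$tip.label, tr$tip.label)
  expect_equal(back$edge, tr$edge)
  expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-10)
  writeLines("((A:1,B:1);", f)
  expect_error(readNewick(f), "unclosed")
  writeLines("(A:1,B:1));", f)
  expect_error(readNewick(f), "offset 10")
})

test_that("haplotype genealogy collapses, subdivides and conserves counts", {
  ## 3 haplotypes one step from a common ancestor (L = 10)
  tr <- ape::read.tree(text = "(h1:0.1,h2:0.1,h3:0.1);")
  al <- c(h1 = "TAAAAAAAAA", h2 = "ATAAAAAAAA", h3 = "AATAAAAAAA",
          x1 = "TAAAAAAAAA", x2 = "ATAAAAAAAA")
  haps <- collapseHaplotypes(al)
  net <- haplotypeGenealogy(tr, haps, L = 10)
  expect_equal(sum(net@nodes$count), 5)      # sampled counts sum to n
  expect_true(netConnected(net))
  expect_equal(nrow(net@edges), 3)           # single-step star edges
  expect_equal(sum(!net@nodes$sampled), 1)   # the unsampled hub
  ## an edge of expected length 3.2 becomes 3 steps, 2 intermediates
  tr2 <- ape::read.tree(text = "(h1:0.16,h2:0.16);")  # 0.32 x L(10) = 3.2 total
  al2 <- c(h1 = "TTTAAAAAAA", h2 = "AAAAAAAAAA")
  net2 <- haplotypeGenealogy(tr2, collapseHaplotypes(al2), L = 10)
  ## both tree branches round to 2 steps (1.6 -> 2): total 4 edges here;
  ## use a single pendant branch for the hand-evaluated rule instead
  tr3 <- ape::rtree(2)
  tr3$tip.label <- c("h1", "h2")
  tr3$edge.length <- c(0.32, 0)              # one 3.2-step branch, one zero
  net3 <- haplotypeGenealogy(tr3, collapseHaplotypes(al2), L = 10)
  expect_equal(sum(!net3@nodes$sampled), 2)  # two intermediate black dots
  expect_equal(nrow(net3@edges), 3)          # 3 single-mutation steps
  expect_true(netConnected(net3))
  ## zero-length internal branches collapse into a multifurcation
  tr4 <- ape::read.tree(text = "((h1:0.1,h2:0.1):0.0001,h3:0.1);")
  al4 <- al[1:3]
  net4 <- haplotypeGenealogy(tr4, collapseHaplotypes(al4), L = 10)
  expect_equal(sum(!net4@nodes$sampled), 1)  # root/internal merged to one hub
  expect_equal(nrow(net4@edges), 3)
  ## tip absent from the table errors
  expect_error(haplotypeGenealogy(tr, collapseHaplotypes(al2), L = 10),
               "absent")
})

test_that("haplotype genealogy stays connected on random trees", {
  set.seed(131)
  for (rep in 1:10) {
    nh <- sample(4:10, 1)
    tr <- ape::rtree(nh)
    tr$tip.label <- paste0("h", seq_len(nh))
    tr$edge.length <- runif(nrow(tr$edge), 0, 0.4)
    seqs <- randomAlignment(nh, 12)
    names(seqs) <- tr$tip.label
    haps <- collapseHaplotypes(seqs)
    reps <- vapply(haps@members, `[[`, "", 1)
    keep <- ape::keep.tip(tr, intersect(tr$tip.label, reps))
    net <- haplotypeGenealogy(keep, haps, L = 12)
    expect_true(netConnected(net))
    expect_equal(sum(net@nodes$count),
                 sum(haplotypeCounts(haps)[haps@assignment[keep$tip.label]]))
  }
})

test_that("parsimony counts match brute force and phangorn", {
  ## all tips identical: zero changes
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(fitchChanges(tr, c(a = "A", b = "A", c = "A", d = "A"))$changes,
               0L)
  ## random binary trees, binary states: exhaustive minimum
  set.seed(141)
  for (rep in 1:15) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n)
    st <- setNames(sample(c("A", "T"), n, TRUE), tr$tip.label)
    got <- fitchChanges(tr, st)
    expect_equal(got$changes, bruteFitch(tr, st))
    expect_equal(nrow(got$changedBranches), got$changes)
    ## independent reference implementation
    pd <- phangorn::phyDat(matrix(st[tr$tip.label], ncol = 1,
                                  dimnames = list(tr$tip.label, NULL)),
                           type = "USER", levels = c("A", "T"))
    expect_equal(got$changes, phangorn::fitch(tr, pd, site = "pscore"))
  }
  ## multistate multifurcating case
  tr2 <- ape::read.tree(text = "((a:1,b:1,c:1):1,(d:1,e:1):1);")
  st2 <- c(a = "A", b = "S", c = "T", d = "A", e = "A")
  expect_equal(fitchChanges(tr2, st2)$changes, bruteFitch(tr2, st2))
  expect_error(fitchChanges(tr2, st2[-1]), "missing tip state")
})

test_that("the codon-329 configuration needs exactly two changes", {
  tree <- readNewick(system.file("extdata",
                                 "talpid_cytb329_synthetic_tree.nwk",
                                 package = "mtphylogeo"))
  st <- read.delim(system.file("extdata",
                               "talpid_cytb329_synthetic_states.tsv",
                               package = "mtphylogeo"))
  states <- setNames(st$state, st$tip)
  res <- fitchChanges(tree, states)
  expect_equal(res$changes, 2L)
  ## one change lies on the branch subtending the two A-lineages
  a12 <- ape::getMRCA(tree, c("GalemysA1", "GalemysA2"))
  expect_true(a12 %in% res$changedBranches$child)
  chg <- res$changedBranches[res$changedBranches$child == a12, ]
  expect_equal(chg$to, "T")
})

test_that("mitochondrial translation uses the vertebrate mito code", {
  expect_equal(translateMtdna("ATGGCC"), "MA")
  expect_equal(translateMtdna("ATA"), "M")    # Ile in the standard code
  expect_equal(translateMtdna("TGA"), "W")    # stop in the standard code
  expect_equal(translateMtdna("AGA"), "*")    # mito-specific stop
  expect_warning(translateMtdna("ATGTAAATG"), "codon index 2")
  expect_error(translateMtdna("ATGG"), "divisible")
  expect_equal(translateMtdna("ATGG", trim = TRUE), "M")
})

test_that("strict-clock TMRCA arithmetic and the JC convexity property", {
  ce <- clockTmrca(dSplit = 0.2, tSplit = 10, dTarget = 0.01)
  expect_equal(ce@rate, 0.01)
  expect_equal(ce@tmrca, 0.5)
  ## identity: dating the calibration distance returns the calibration age
  expect_equal(clockTmrca(0.2, 10, 0.2)@tmrca, 10)
  expect_error(clockTmrca(0, 10, 0.1), "positive")
  ## JC correction is convex: corrected times dominate raw times
  p <- 0.3
  rawT <- clockTmrca(0.2, 10, p)@tmrca
  jcT <- clockTmrca(jcDistance(0.2), 10, jcDistance(p))@tmrca
  expect_gte(jcT, rawT)
  expect_error(jcDistance(0.8), "0.75")
})
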