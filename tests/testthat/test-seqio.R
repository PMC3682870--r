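test_that("FASTA round trip preserves sequences and enforces invariants", {
  al <- c(s1 = "ACGTACGTAC", s2 = "ACGTTCGTAC")
  f <- tempfile(fileext = ".fasta")
  writeFasta(al, f)
  back <- readFasta(f)
  expect_identical(as.character(back), al)
  expect_identical(names(back), names(al))
  ## unequal lengths name the offending record
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), f)
  expect_error(readFasta(f), "'b'")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(readFasta(f), "duplicate")
})

test_that("locus concatenation joins per-id and checks id sets", {
  set.seed(1)
  ids <- paste0("ind", 1:5)
  cytb <- setNames(replicate(5, paste(sample(c("A", "C", "G", "T"), 1140,
                                             TRUE), collapse = "")), ids)
  dloop <- setNames(replicate(5, paste(sample(c("A", "C", "G", "T"), 342,
                                              TRUE), collapse = "")),
                    rev(ids))  # order must not matter
  cat12 <- concatenateLoci(list(cytb, dloop))
  expect_equal(unique(Biostrings::width(cat12)), 1140 + 342)
  expect_equal(Biostrings::width(cat12)[1], 1482)
  expect_identical(substr(as.character(cat12)[["ind3"]], 1, 1140),
                   cytb[["ind3"]])
  expect_identical(substr(as.character(cat12)[["ind3"]], 1141, 1482),
                   dloop[["ind3"]])
  ## single alignment is the identity
  expect_identical(as.character(concatenateLoci(list(cytb))), cytb)
  ## mismatched id sets error, listing the missing id
  expect_error(concatenateLoci(list(cytb, dloop[1:4])), "ind1")
})

test_that("haplotype collapse counts classes under both matching rules", {
  al <- c(a = "ACGT", b = "ACGT", c = "AGGT")
  ht <- collapseHaplotypes(al)
  expect_equal(nHaplotypes(ht), 2L)
  expect_equal(sort(haplotypeCounts(ht), decreasing = TRUE), c(2L, 1L))
  expect_equal(haplotypeAssignment(ht)[["b"]], haplotypeAssignment(ht)[["a"]])
  ## all distinct -> h = n
  al2 <- c(a = "AAAA", b = "AAAT", c = "AATT")
  expect_equal(nHaplotypes(collapseHaplotypes(al2)), 3L)
  ## wildcard rule: N matches any base
  al3 <- c(a = "ACGT", b = "ACGN")
  expect_equal(nHaplotypes(collapseHaplotypes(al3, wildcardMissing = TRUE)), 1L)
  expect_equal(nHaplotypes(collapseHaplotypes(al3, wildcardMissing = FALSE)), 2L)
  ## counts always sum to n (property over random inputs)
  set.seed(7)
  for (rep in 1:20) {
    al <- randomAlignment(sample(3:10, 1), 12)
    for (w in c(TRUE, FALSE))
      expect_equal(sum(haplotypeCounts(collapseHaplotypes(al, w))),
                   length(al))
  }
})

test_that("pairwise differences honor complete and pairwise deletion", {
  al <- c(a = "AAAA", b = "AAAT", c = "AATT")
  d <- pairwiseDifferences(al)
  m <- as.matrix(d)
  expect_equal(unname(m[c("b", "c"), "a"]), c(1, 2))
  expect_equal(unname(m["c", "b"]), 1)
  expect_equal(distKind(d), "diff_count")
  ## identical sequences -> all-zero
  expect_true(all(as.matrix(pairwiseDifferences(c(a = "ACGT", b = "ACGT"))) == 0))
  ## pairwise deletion drops unresolved sites per pair
  al2 <- c(a = "AANA", b = "AATA")
  d2 <- pairwiseDifferences(al2, deletion = "pairwise")
  expect_equal(unname(as.matrix(d2)["b", "a"]), 0)
  expect_equal(d2@lused[2, 1], 3)
  ## complete deletion drops the N column for everyone
  d3 <- pairwiseDifferences(c(a = "AANA", b = "AATA", c = "ATTA"),
                            deletion = "complete")
  expect_equal(unname(as.matrix(d3)["c", "a"]), 1)
})

test_that("p-distance equals differences over sites used, exactly", {
  al <- c(a = paste(rep("A", 100), collapse = ""),
          b = paste(c(rep("A", 99), "T"), collapse = ""))
  expect_equal(unname(as.matrix(pDistanceMatrix(al))[2, 1]), 0.01)
  set.seed(11)
  for (rep in 1:10) {
    al <- randomAlignment(5, 20)
    dd <- pairwiseDifferences(al, "pairwise")
    pp <- pDistanceMatrix(al, "pairwise")
    expect_equal(pp@values, dd@values / dd@lused, tolerance = 1e-15)
  }
})

test_that("mean between-group p-distance averages the cross block", {
  al <- c(a1 = "AAAA", a2 = "AAAT", b1 = "TTAA", b2 = "TTAT")
  d <- pDistanceMatrix(al)
  g <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  expect_equal(meanGroupDistance(d, g, "A", "B"), mean(c(2, 3, 3, 2) / 4))
})

test_that("geographic distances: haversine at the stated radius, degrees", {
  m <- toyMeta(c("p", "q"), lat = c(0, 0), lon = c(0, 1))
  expect_equal(unname(as.matrix(geoDistanceMatrix(m, "km"))[2, 1]),
               111.1951, tolerance = 1e-4)
  m2 <- toyMeta(c("p", "q"), lat = c(42, 43), lon = c(-3, -3))
  expect_equal(unname(as.matrix(geoDistanceMatrix(m2, "degrees"))[2, 1]), 1.0)
  expect_equal(haversineKm(10, 20, 10, 20), 0)
  ## symmetry and triangle inequality on random triples
  set.seed(3)
  for (rep in 1:25) {
    la <- runif(3, -60, 60); lo <- runif(3, -170, 170)
    ab <- haversineKm(la[1], lo[1], la[2], lo[2])
    ba <- haversineKm(la[2], lo[2], la[1], lo[1])
    bc <- haversineKm(la[2], lo[2], la[3], lo[3])
    ac <- haversineKm(la[1], lo[1], la[3], lo[3])
    expect_equal(ab, ba)
    expect_lte(ac, ab + bc + 1e-9)
  }
})

test_that("feces deduplication drops only same-haplotype close feces", {
  ## ~0.5 km apart: 0.0045 degrees of latitude
  meta <- toyMeta(c("f1", "f2", "f3", "t1"),
                  lat = c(42, 42.0045, 42.2, 42.0045),
                  lon = c(-3, -3, -3, -3),
                  sample_type = c("feces", "feces", "feces", "tissue"))
  sameHap <- setNames(c(1L, 1L, 1L, 1L), meta$id)
  diffHap <- setNames(c(1L, 2L, 1L, 1L), meta$id)
  ## same haplotype within 1 km -> second dropped; 2 km apart kept
  expect_identical(dedupFeces(meta, sameHap), c("f1", "f3", "t1"))
  ## different haplotypes within 1 km -> both kept
  expect_identical(dedupFeces(meta, diffHap), meta$id)
  ## tissue never dropped even at 0 distance
  meta2 <- meta; meta2$sample_type <- c("feces", "tissue", "feces", "tissue")
  expect_identical(dedupFeces(meta2, sameHap), meta2$id)
  ## idempotence
  kept <- dedupFeces(meta, sameHap)
  meta3 <- meta[meta$id %in% kept, ]
  expect_identical(dedupFeces(meta3, sameHap), kept)
})

test_that("metadata and distance-matrix TSV round trips", {
  meta <- toyMeta(c("x", "y"), c(41.5, 42.5), c(-3, -2),
                  lineage = c("A1", "B2"), group = c("g1", "g2"))
  f <- tempfile(fileext = ".tsv")
  writeSampleMetadata(meta, f)
  expect_equal(readSampleMetadata(f), meta)
  d <- pairwiseDifferences(c(x = "AAAA", y = "ATAT"))
  f2 <- tempfile(fileext = ".tsv")
  writeDistMatrix(d, f2)
  back <- readDistMatrix(f2)
  expect_equal(as.matrix(back), as.matrix(d))
})
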