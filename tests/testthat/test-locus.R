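# locus anchoring, island extraction, annotation and status calls, mostly
# on small generated genomes with known implant coordinates

test_that("findAnchors recovers the implanted anchor pair exactly", {
  coh <- generateCohort(small_config(21, nStrainsPerType = c(III = 1L),
                                     nFgiMinus = 0L, divergence = 0))
  g <- coh$genomes[[1]]
  pair <- findAnchors(g, defaultAnchorSet())
  ft <- features(g)
  expect_equal(S4Vectors::mcols(pair$flaA2)$gene, "flaA2")
  expect_equal(S4Vectors::mcols(pair$flaG)$gene, "flaG")
  truthA2 <- ft[S4Vectors::mcols(ft)$gene == "flaA2"]
  expect_equal(start(pair$flaA2), start(truthA2))
  expect_equal(end(pair$flaA2), end(truthA2))
})

test_that("findAnchors tolerates anchors mutated to ~80% identity", {
  coh <- generateCohort(small_config(22, nStrainsPerType = c(I = 1L),
                                     nFgiMinus = 0L, divergence = 0.2))
  g <- coh$genomes[[1]]
  pair <- findAnchors(g, defaultAnchorSet())
  expect_equal(S4Vectors::mcols(pair$flaA2)$gene, "flaA2")
  expect_equal(S4Vectors::mcols(pair$flaG)$gene, "flaG")
  ## the anchors really are diverged (verified through the aligner)
  anc <- defaultAnchorSet()
  idG <- alignGlobal(S4Vectors::mcols(pair$flaG)$protein,
                     as.character(anc@proteins[["flaG"]]))@identityPct
  expect_lt(idG, 100)
  expect_gt(idG, 60)
})

test_that("a genome without flaG raises an anchors-not-found error", {
  coh <- generateCohort(small_config(23, nStrainsPerType = c(II = 1L),
                                     nFgiMinus = 0L))
  g <- coh$genomes[[1]]
  keep <- S4Vectors::mcols(features(g))$gene != "flaG"
  g2 <- Genome(strainId(g), contigs(g), features(g)[keep])
  expect_error(findAnchors(g2, defaultAnchorSet()), "anchors not found")
})

test_that("extractIsland excises the intergenic span with its metrics", {
  coh <- generateCohort(small_config(24, nStrainsPerType = c(IV = 1L),
                                     nFgiMinus = 0L, pTruncate = 0,
                                     pDisrupt = 0))
  g <- coh$genomes[[1]]
  tr <- coh$truth[[1]]
  pair <- findAnchors(g, defaultAnchorSet())
  rec <- extractIsland(g, pair$flaA2, pair$flaG)
  expect_equal(rec@start, tr$island_interval[1])
  expect_equal(rec@end, tr$island_interval[2])
  expect_equal(rec@nCds, length(tr$families))
  expect_equal(rec@sizeKb, (rec@end - rec@start + 1) / 1000)
  ## interval disjoint from both anchor CDSs
  expect_gt(rec@start, end(pair$flaA2))
  expect_lt(rec@end, start(pair$flaG))
  ## deviation identity before rounding
  expect_equal(rec@gcDeviation, rec@islandGC - rec@genomeGC,
               tolerance = 1e-9)
  expect_equal(rec@genomeGC, genomeGC(g))
})

test_that("an empty intergap yields a valid record with NA composition", {
  dna <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  gr <- GenomicRanges::GRanges("c1",
                               IRanges::IRanges(c(101, 401), c(400, 700)),
                               strand = "+")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    feature_id = c("fa2", "fg"), type = "CDS", gene = c("flaA2", "flaG"),
    product = "", protein = c("MAAA", "MCCC"))
  g <- Genome("empty-gap", c(c1 = dna), gr)
  ft <- features(g)
  rec <- extractIsland(g, ft[1], ft[2])
  expect_equal(rec@nCds, 0L)
  expect_true(is.na(rec@islandGC))
  expect_true(is.na(rec@gcDeviation))
  expect_equal(rec@end - rec@start + 1L, 0L)
  ## and overlapping/reversed anchors are malformed
  expect_error(extractIsland(g, ft[2], ft[1]), "malformed")
})

test_that("annotateIsland applies the identity and coverage rules", {
  refdb <- defaultReferenceDb()
  coh <- generateCohort(small_config(25, nStrainsPerType = c(V = 1L),
                                     nFgiMinus = 0L, divergence = 0,
                                     pTruncate = 0, pDisrupt = 0))
  g <- coh$genomes[[1]]
  pair <- findAnchors(g, defaultAnchorSet())
  rec <- annotateIsland(extractIsland(g, pair$flaA2, pair$flaG), refdb)
  ft <- cdsFeatures(rec)
  genes <- S4Vectors::mcols(ft)$gene
  cat_labels <- S4Vectors::mcols(refdb)$label[match(genes, names(refdb))]
  expect_equal(unname(islandAnnotations(rec)[S4Vectors::mcols(ft)$feature_id]),
               unname(cat_labels))

  ## below the identity threshold: hypothetical
  set.seed(1)
  lowRec <- rec
  lowRec@cds <- rec@cds[1]
  S4Vectors::mcols(lowRec@cds)$protein <- random_seq(200)
  lowRec@nCds <- 1L
  lowRec <- annotateIsland(lowRec, refdb)
  expect_equal(unname(islandAnnotations(lowRec)), "hypothetical")

  ## passes identity but covers only half the reference: hypothetical
  halfRec <- rec
  halfRec@cds <- rec@cds[1]
  full <- as.character(refdb[[genes[1]]])
  S4Vectors::mcols(halfRec@cds)$protein <-
    substring(full, 1, floor(nchar(full) / 2))
  halfRec@nCds <- 1L
  halfRec <- annotateIsland(halfRec, refdb)
  expect_equal(unname(islandAnnotations(halfRec)), "hypothetical")

  expect_error(annotateIsland(rec, refdb[0]), "empty reference")
})

test_that("classifyIsland calls FGI status from GT/maf content", {
  mk <- function(labels) {
    rec <- new("IslandRecord", strainId = "s", contigId = "c1",
               start = 1L, end = 0L, sizeKb = 0, islandGC = NA_real_,
               genomeGC = 50, gcDeviation = NA_real_,
               cds = GenomicRanges::GRanges(), nCds = 0L,
               fgiStatus = NA_character_,
               annotations = stats::setNames(labels, if (length(labels))
                 paste0("f", seq_along(labels)) else character()))
    fgiStatus(classifyIsland(rec))
  }
  expect_equal(mk(c("glycosyltransferase", "hypothetical")), "FGI+")
  expect_equal(mk(c("maf", "biosynthesis:pse")), "FGI+")
  expect_equal(mk(c("endonuclease", "hypothetical")), "FGI-")
  expect_equal(mk(character()), "FGI-")
})

test_that("status truth is recovered on a mutated cohort", {
  coh <- generateCohort(small_config(26,
                                     nStrainsPerType = c(I = 1L, V = 1L),
                                     nFgiMinus = 2L, divergence = 0.15))
  refdb <- coh$refdb
  for (sid in names(coh$genomes)) {
    pair <- findAnchors(coh$genomes[[sid]], defaultAnchorSet())
    rec <- classifyIsland(annotateIsland(
      extractIsland(coh$genomes[[sid]], pair$flaA2, pair$flaG), refdb))
    expect_equal(fgiStatus(rec), coh$truth[[sid]]$fgi_status)
  }
})
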