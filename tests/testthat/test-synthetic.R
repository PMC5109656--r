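test_that("identical configurations give byte-identical cohorts", {
  cfg <- small_config(41, nStrainsPerType = c(I = 1L, II = 1L),
                      nFgiMinus = 1L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- generateCohort(cfg, outDir = d1)
  c2 <- generateCohort(cfg, outDir = d2)
  for (sid in names(c1$genomes)) {
    expect_identical(as.character(contigs(c1$genomes[[sid]])),
                     as.character(contigs(c2$genomes[[sid]])))
    f1 <- file.path(d1, paste0(sid, ".gbk"))
    f2 <- file.path(d2, paste0(sid, ".gbk"))
    expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  }
  expect_identical(c1$truth, c2$truth)
})

test_that("a seed change rewrites the sequences but not the design", {
  cfg1 <- small_config(42, nStrainsPerType = c(III = 1L), nFgiMinus = 1L)
  cfg2 <- small_config(43, nStrainsPerType = c(III = 1L), nFgiMinus = 1L)
  c1 <- generateCohort(cfg1)
  c2 <- generateCohort(cfg2)
  expect_identical(names(c1$genomes), names(c2$genomes))
  expect_identical(vapply(c1$truth, `[[`, "", "fgi_status"),
                   vapply(c2$truth, `[[`, "", "fgi_status"))
  expect_false(identical(as.character(contigs(c1$genomes[[1]])),
                         as.character(contigs(c2$genomes[[1]]))))
})

test_that("the family pool is deterministic, distinct and length-bounded", {
  p1 <- generateFamilyPool(fgiSimConfig(seed = 1))
  p2 <- generateFamilyPool(fgiSimConfig(seed = 999))
  expect_identical(as.character(p1), as.character(p2))  # seed-independent
  expect_false(anyDuplicated(as.character(p1)) > 0)
  expect_true(all(Biostrings::width(p1) >= 120 &
                    Biostrings::width(p1) <= 400))
  expect_true(all(c("glycosyltransferase", "maf", "hypothetical",
                    "endonuclease") %in% S4Vectors::mcols(p1)$label))
  ## the five type profiles are pairwise distinct
  profs <- lapply(c("I", "II", "III", "IV", "V"), function(tp)
    sort(names(p1)[vapply(strsplit(S4Vectors::mcols(p1)$types, ","),
                          function(x) tp %in% x, TRUE)]))
  expect_equal(length(unique(profs)), 5L)
})

test_that("FGI-negative strains carry no glycosyltransferase or maf genes", {
  coh <- generateCohort(small_config(44, nStrainsPerType = c(I = 0L),
                                     nFgiMinus = 4L))
  pool <- generateFamilyPool(fgiSimConfig())
  for (tr in coh$truth) {
    expect_equal(tr$fgi_status, "FGI-")
    labs <- S4Vectors::mcols(pool)$label[match(tr$families, names(pool))]
    expect_false(any(labs %in% c("glycosyltransferase", "maf")))
  }
})

test_that("a forced truncation is scored absent downstream", {
  ## pTruncate = 1: every island gene except the protected status gene is
  ## truncated below half length
  coh <- generateCohort(small_config(45, nStrainsPerType = c(I = 1L),
                                     nFgiMinus = 0L, pTruncate = 1,
                                     pDisrupt = 0))
  tr <- coh$truth[[1]]
  expect_true(sum(unlist(tr$intact)) == 1L)  # only the protected GT/maf
  g <- coh$genomes[[1]]
  pair <- findAnchors(g, defaultAnchorSet())
  rec <- extractIsland(g, pair$flaA2, pair$flaG)
  prots <- islandProteins(rec)
  pool <- generateFamilyPool(fgiSimConfig())
  truncated <- names(which(!unlist(tr$intact)))
  full <- Biostrings::width(pool[truncated])
  got <- nchar(as.character(prots))[match(
    truncated, S4Vectors::mcols(cdsFeatures(rec))$gene)]
  expect_true(all(got < 0.5 * full))
})

test_that("transposon disruption splits a gene around a transposase CDS", {
  coh <- generateCohort(small_config(46, nStrainsPerType = c(IV = 1L),
                                     nFgiMinus = 0L, pTruncate = 0,
                                     pDisrupt = 1))
  g <- coh$genomes[[1]]
  tr <- coh$truth[[1]]
  pair <- findAnchors(g, defaultAnchorSet())
  rec <- extractIsland(g, pair$flaA2, pair$flaG)
  genes <- S4Vectors::mcols(cdsFeatures(rec))$gene
  expect_true("tnp1" %in% genes)
  ## each disrupted family contributes two fragments flanking a transposase
  disrupted <- names(which(!unlist(tr$intact)))
  expect_gt(length(disrupted), 0L)
  for (d in disrupted) {
    idx <- which(genes == d)
    expect_length(idx, 2L)
    expect_equal(genes[idx[1] + 1L], "tnp1")
  }
})

test_that("divergence zero reproduces the pan-pool families exactly", {
  coh <- generateCohort(small_config(47,
                                     nStrainsPerType = c(I = 1L, II = 1L,
                                                         III = 1L, IV = 1L,
                                                         V = 1L),
                                     nFgiMinus = 0L, divergence = 0,
                                     pTruncate = 0, pDisrupt = 0))
  recs <- lapply(coh$genomes, function(g) {
    pair <- findAnchors(g, defaultAnchorSet())
    extractIsland(g, pair$flaA2, pair$flaG)
  })
  prots <- lapply(recs, islandProteins)
  fams <- clusterOrthologs(prots)
  panPool <- unique(unlist(lapply(coh$truth, `[[`, "families")))
  expect_equal(length(fams), length(panPool))
})

test_that("realized island G+C tracks the configured target", {
  ## a type III island (~15 genes) on a 60 kb backbone
  cfg <- fgiSimConfig(seed = 48, nStrainsPerType = c(III = 1L),
                      nFgiMinus = 0L, hostLength = 60000L)
  coh <- generateCohort(cfg)
  g <- coh$genomes[[1]]
  tr <- coh$truth[[1]]
  isl <- Biostrings::subseq(contigs(g)[[1]], tr$island_interval[1],
                            tr$island_interval[2])
  expect_gt(length(isl), 10000L)
  expect_lt(abs(100 * gcContent(isl) - 100 * tr$configured_island_gc), 1.5)
})
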