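test_that("gcContent follows the unambiguous-base rule", {
  expect_equal(gcContent("GCGC"), 1)
  expect_equal(gcContent("ATAT"), 0)
  expect_equal(gcContent("ATGNN"), 1 / 3)  # Ns excluded from both sides
  expect_equal(gcContent("atgc"), 0.5)
  expect_error(gcContent(""), "empty")
  expect_error(gcContent("NNNN"), "undefined")
})

test_that("gcContent is invariant under case change and reverse complement", {
  set.seed(42)
  for (k in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 200, TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(gcContent(tolower(s)), gcContent(s))
    expect_equal(gcContent(rc), gcContent(s))
  }
})

test_that("Genome caches a genome G+C consistent with its contigs", {
  coh <- generateCohort(small_config(5, nStrainsPerType = c(I = 1L),
                                     nFgiMinus = 1L))
  for (g in coh$genomes) {
    expect_equal(genomeGC(g),
                 100 * gcContent(unlist(contigs(g))), tolerance = 1e-12)
  }
})

test_that("GenBank files round-trip through the reader", {
  coh <- generateCohort(small_config(7, nStrainsPerType = c(II = 1L),
                                     nFgiMinus = 0L))
  g <- coh$genomes[[1]]
  f <- withr::local_tempfile(fileext = ".gbk")
  writeGenBank(g, f)
  g2 <- readGenome(f, format = "genbank")
  expect_equal(strainId(g2), strainId(g))
  expect_equal(as.character(contigs(g2)), as.character(contigs(g)))
  expect_equal(start(features(g2)), start(features(g)))
  expect_equal(end(features(g2)), end(features(g)))
  expect_equal(as.character(GenomicRanges::strand(features(g2))),
               as.character(GenomicRanges::strand(features(g))))
  expect_equal(S4Vectors::mcols(features(g2))$protein,
               S4Vectors::mcols(features(g))$protein)
})

test_that("GenBank reader sorts features and translates minus-strand CDSs", {
  ## protein of 99 aa on the minus strand spanning 300 nt (101..400)
  prot <- random_seq(99)
  cds <- paste0(vapply(strsplit(prot, "")[[1]], function(a) {
    names(which(Biostrings::GENETIC_CODE == a))[1]
  }, ""), collapse = "")
  cds <- paste0(cds, "TAA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  seq <- paste0(strrep("A", 100), rc, strrep("T", 100))
  lines <- c(
    sprintf("LOCUS       ctg %d bp    DNA     linear   BCT", nchar(seq)),
    "DEFINITION  toy",
    "FEATURES             Location/Qualifiers",
    "     CDS             complement(101..400)",
    "                     /locus_tag=\"b\"",
    "     CDS             450..470",
    "                     /locus_tag=\"c\"",
    "                     /translation=\"MNN\"",
    "     CDS             10..30",
    "                     /locus_tag=\"a\"",
    "                     /translation=\"MKK\"",
    "ORIGIN",
    vapply(seq(1, nchar(seq), 60), function(p)
      sprintf("%9d %s", p, tolower(substring(seq, p,
                                             min(p + 59, nchar(seq))))), ""),
    "//")
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(lines, f)
  g <- readGenome(f, format = "genbank")
  ft <- features(g)
  expect_equal(S4Vectors::mcols(ft)$feature_id, c("a", "b", "c"))  # sorted
  expect_equal(nchar(S4Vectors::mcols(ft)$protein[2]), 99L)
  expect_equal(S4Vectors::mcols(ft)$protein[2], prot)
})

test_that("truncated GenBank files raise a format error", {
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       ctg 100 bp", "DEFINITION  x", "ORIGIN",
               "        1 acgt"), f)  # no record terminator
  expect_error(readGenome(f, format = "genbank"), "truncated|terminator")
})

test_that("FASTA + GFF3 input matches the GenBank path", {
  coh <- generateCohort(small_config(9, nStrainsPerType = c(IV = 1L),
                                     nFgiMinus = 0L))
  g <- coh$genomes[[1]]
  fa <- withr::local_tempfile(fileext = ".fna")
  gff <- withr::local_tempfile(fileext = ".gff3")
  Biostrings::writeXStringSet(contigs(g), fa)
  gr <- features(g)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = S4Vectors::mcols(gr)$type,
    ID = S4Vectors::mcols(gr)$feature_id,
    gene = S4Vectors::mcols(gr)$gene,
    product = S4Vectors::mcols(gr)$product,
    phase = 0L)
  rtracklayer::export(gr, gff, format = "gff3")
  g2 <- readGenome(fa, format = "gff3", gff = gff,
                   strainId = strainId(g))
  expect_equal(length(features(g2)), length(features(g)))
  expect_equal(S4Vectors::mcols(features(g2))$protein,
               S4Vectors::mcols(features(g))$protein)
})

test_that("the packaged island metrics fixture has the survey cohort shape", {
  tab <- loadIslandTable(system.file("extdata", "island_metrics_table.csv",
                                     package = "fgiTyper"))
  expect_equal(nrow(tab), 36L)
  expect_equal(sum(is.na(tab$fgi_type)), 18L)
  expect_true(all(tab$fgi_type[!is.na(tab$fgi_type)] %in%
                    c("I", "II", "III", "IV", "V")))
  r1 <- tab[tab$strain_id == "G. thermodenitrificans DSM465T", ]
  expect_equal(r1$genome_gc_pct, 49.05)
  expect_equal(r1$island_gc_pct, 45.08)
  expect_equal(r1$gc_deviation_pct, -3.97)
  expect_equal(r1$size_kb, 0.9)
  expect_equal(r1$n_cds, 0L)
  expect_true(is.na(r1$fgi_type))
  r2 <- tab[tab$strain_id == "Geobacillus sp. C56-T2", ]
  expect_equal(r2$fgi_type, "III")
  expect_equal(r2$size_kb, 30.4)
  expect_equal(r2$n_cds, 23L)
})

test_that("island table writer round-trips and the loader validates", {
  tab <- loadIslandTable(system.file("extdata", "island_metrics_table.csv",
                                     package = "fgiTyper"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeIslandTable(tab, f)
  tab2 <- loadIslandTable(f)
  expect_equal(tab2, tab)
  ## header-only output for an empty row list
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeIslandTable(tab[0, ], f2)
  expect_equal(length(readLines(f2)), 1L)
  ## a row whose deviation is off by 1.0 must be rejected by strain name
  bad <- tab
  bad$gc_deviation_pct[3] <- bad$gc_deviation_pct[3] + 1.0
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(transform(bad, fgi_type = ifelse(is.na(fgi_type), "-",
                                                    fgi_type)),
                   f3, row.names = FALSE)
  expect_error(loadIslandTable(f3), bad$strain_id[3], fixed = TRUE)
})

test_that("protein FASTA writing skips empty sequences with a warning", {
  p <- Biostrings::AAStringSet(c(a = "MKV", b = "", c = "MV"))
  f <- withr::local_tempfile(fileext = ".faa")
  expect_warning(writeProteinFasta(p, f), "b")
  back <- Biostrings::readAAStringSet(f)
  expect_equal(names(back), c("a", "c"))
  expect_equal(as.character(back), c(a = "MKV", c = "MV"))
})

test_that("labelled reference databases round-trip with their labels", {
  db <- defaultReferenceDb()
  f <- withr::local_tempfile(fileext = ".faa")
  writeReferenceDb(db, f)
  db2 <- readReferenceDb(f)
  expect_equal(names(db2), names(db))
  expect_equal(S4Vectors::mcols(db2)$label, S4Vectors::mcols(db)$label)
  expect_equal(as.character(db2), as.character(db))
})
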