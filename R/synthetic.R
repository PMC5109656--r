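# Synthetic annotated genomes with implanted flagellin glycosylation
# islands of known status, type, composition and gene intactness.
#
# All ancestral material (locus proteins, anchor proteins, the island
# family pool, the reference database) derives from a FIXED internal
# seed, independent of the user-facing cohort seed, so that any cohort —
# whatever its seed — can be analysed with defaultAnchorSet() and
# defaultReferenceDb().  The cohort seed drives only per-strain
# mutation, assembly and event sampling.

.ANCESTOR_SEED <- 104729L

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")

## evaluate `code` under a temporary RNG state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

.random_protein <- function(len) {
  paste(c("M", sample(.AA20, len - 1L, replace = TRUE)), collapse = "")
}

.mutate_protein <- function(seq, rate, protectTermini = 0L) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  eligible <- setdiff(seq_len(n), c(1L,
    if (protectTermini > 0L) c(seq_len(min(protectTermini, n)),
                               seq(max(1L, n - protectTermini + 1L), n))))
  hit <- eligible[stats::runif(length(eligible)) < rate]
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(a)
      sample(setdiff(.AA20, a), 1L), "")
  }
  paste(ch, collapse = "")
}

## termini mutated at a low fixed rate, the centre at `centralRate`:
## the flagellin conservation structure (conserved N-/C-termini,
## variable surface-exposed centre)
.mutate_flagellin <- function(seq, centralRate, termLen = 60L,
                              termRate = 0.01) {
  n <- nchar(seq)
  nterm <- substring(seq, 1L, termLen)
  centre <- substring(seq, termLen + 1L, n - termLen)
  cterm <- substring(seq, n - termLen + 1L, n)
  paste0(.mutate_protein(nterm, termRate),
         .mutate_protein(centre, centralRate),
         .mutate_protein(cterm, termRate))
}

# ---------------------------------------------------------------------------
# codon machinery: reverse translation with a G+C dial
# ---------------------------------------------------------------------------

.codon_tables <- function() {
  if (is.null(.fgi_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    aa <- unname(gc)
    frac <- vapply(strsplit(codons, "", fixed = TRUE),
                   function(x) sum(x %in% c("G", "C")), 0L) / 3
    lo <- hi <- loF <- hiF <- stats::setNames(character(0), character(0))
    for (a in setdiff(unique(aa), "*")) {
      cs <- codons[aa == a]
      fs <- frac[aa == a]
      o <- order(fs, cs)
      lo[a] <- cs[o[1]]
      hi[a] <- cs[o[length(o)]]
    }
    .fgi_cache$codons <- list(
      lo = lo, hi = hi,
      loGC = vapply(strsplit(lo, "", fixed = TRUE),
                    function(x) sum(x %in% c("G", "C")), 0L) / 3,
      hiGC = vapply(strsplit(hi, "", fixed = TRUE),
                    function(x) sum(x %in% c("G", "C")), 0L) / 3)
  }
  .fgi_cache$codons
}

## mixing weight toward the high-G+C synonymous codon such that the
## expected coding G+C (stop codons included) equals targetGC
.solve_lambda <- function(proteins, targetGC) {
  ct <- .codon_tables()
  res <- strsplit(paste(proteins, collapse = ""), "", fixed = TRUE)[[1]]
  nstop <- length(proteins)  # one TAA per gene, G+C 0
  ntot <- length(res) + nstop
  e0 <- (sum(ct$loGC[res])) / ntot
  e1 <- (sum(ct$hiGC[res])) / ntot
  if (targetGC < e0 - 1e-9 || targetGC > e1 + 1e-9)
    stop(sprintf(paste0("target G+C %.3f not achievable with the codon ",
                        "table for these proteins (range %.3f-%.3f)"),
                 targetGC, e0, e1))
  min(1, max(0, (targetGC - e0) / (e1 - e0)))
}

.encode_protein <- function(protein, lambda) {
  ct <- .codon_tables()
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  pickHi <- stats::runif(length(res)) < lambda
  paste0(paste(ifelse(pickHi, ct$hi[res], ct$lo[res]), collapse = ""),
         "TAA")
}

.random_dna <- function(len, gc) {
  if (len <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# ---------------------------------------------------------------------------
# ancestral material
# ---------------------------------------------------------------------------

## island family catalog: name, functional label, and the island types
## whose gene complement contains the family (emulating the five
## type-specific presence/absence profiles); "minus" families are the
## endonuclease/hypothetical filler found in FGI-negative intergaps
.family_catalog <- function() {
  e <- function(name, label, types) data.frame(name = name, label = label,
                                               types = types)
  rbind(
    e("neuA", "biosynthesis:neu", "I"), e("neuB", "biosynthesis:neu", "I"),
    e("neuC", "biosynthesis:neu", "I"), e("neuD", "biosynthesis:neu", "I"),
    e("arnA", "biosynthesis:neu", "I"), e("degT", "biosynthesis:neu", "I"),
    e("ntp", "biosynthesis:neu", "I"),
    e("maf1", "maf", "I"), e("maf2", "maf", "II,III"),
    e("maf3", "maf", "II,III"), e("maf4", "maf", "IV"),
    e("gtr1", "glycosyltransferase", "I"),
    e("gtr2", "glycosyltransferase", "I"),
    e("gtr3", "glycosyltransferase", "II"),
    e("gtr4", "glycosyltransferase", "II"),
    e("gtr5", "glycosyltransferase", "III"),
    e("gtr6", "glycosyltransferase", "III"),
    e("gtr7", "glycosyltransferase", "III"),
    e("gtr8", "glycosyltransferase", "IV"),
    e("gtr9", "glycosyltransferase", "IV"),
    e("gtr10", "glycosyltransferase", "V"),
    e("pseB", "biosynthesis:pse", "II,III"),
    e("pseC", "biosynthesis:pse", "II,III,IV"),
    e("pseF", "biosynthesis:pse", "II,III,IV"),
    e("pseG", "biosynthesis:pse", "II,III,IV"),
    e("pseI", "biosynthesis:pse", "II,III,IV"),
    e("pen", "biosynthesis:pse", "IV"), e("pal", "biosynthesis:pse", "IV"),
    e("rmlA", "biosynthesis:rml", "V"), e("rmlB", "biosynthesis:rml", "V"),
    e("rmlC", "biosynthesis:rml", "V"), e("rmlD", "biosynthesis:rml", "V"),
    e("fdtB", "biosynthesis:fdt", "II"), e("fdtC", "biosynthesis:fdt", "II"),
    e("glf", "biosynthesis:glf", "III,IV"),
    e("sam1", "modification:methyl", "I"),
    e("sam2", "modification:methyl", "IV"),
    e("sam3", "modification:methyl", "V"),
    e("fkbM1", "modification:methyl", "III"),
    e("fmt1", "modification:formyl", "I"),
    e("fmt2", "modification:formyl", "III"),
    e("fmt3", "modification:formyl", "V"),
    e("hyp1", "hypothetical", "I"), e("hyp2", "hypothetical", "II"),
    e("hyp3", "hypothetical", "III"), e("hyp4", "hypothetical", "IV"),
    e("hyp5", "hypothetical", "V"),
    e("edn1", "endonuclease", "minus"), e("edn2", "endonuclease", "minus"),
    e("appr1p", "hypothetical", "minus"),
    e("hyp6", "hypothetical", "minus"), e("hyp7", "hypothetical", "minus"),
    e("hyp8", "hypothetical", "minus"))
}

.LOCUS_LENGTHS <- c(comFA = 450L, flgN = 140L, flgM = 90L, flgK = 500L,
                    flgL = 300L, fliD = 470L, fliS = 130L, fliS2 = 135L,
                    fliT = 100L, flaG = 120L, raiA = 180L, tnp1 = 280L)
.FLA_TERM <- 60L
.FLA_CENTRE <- c(flaA1 = 400L, flaA2 = 280L, flaA3 = 145L)

## fixed-seed ancestral proteins, keyed by the island gene length range
.ancestral <- function(islandGeneLen = c(120L, 400L)) {
  key <- paste0("anc_", islandGeneLen[1], "_", islandGeneLen[2])
  if (is.null(.fgi_cache[[key]])) {
    .fgi_cache[[key]] <- .with_seed(.ANCESTOR_SEED, {
      locus <- vapply(names(.LOCUS_LENGTHS), function(g)
        .random_protein(.LOCUS_LENGTHS[[g]]), "")
      termN <- paste(c("M", sample(.AA20, .FLA_TERM - 1L, TRUE)),
                     collapse = "")
      termC <- paste(sample(.AA20, .FLA_TERM, TRUE), collapse = "")
      fla <- vapply(names(.FLA_CENTRE), function(g)
        paste0(termN, paste(sample(.AA20, .FLA_CENTRE[[g]], TRUE),
                            collapse = ""), termC), "")
      cat_ <- .family_catalog()
      lens <- sample(seq(islandGeneLen[1], islandGeneLen[2]),
                     nrow(cat_), replace = TRUE)
      pool <- vapply(lens, .random_protein, "")
      names(pool) <- cat_$name
      list(locus = locus, fla = fla, pool = pool, catalog = cat_)
    })
  }
  .fgi_cache[[key]]
}

#' Default anchor protein set
#'
#' The bundled anchor proteins for the inner (flaA2, flaG) and outer
#' (comFA, raiA) anchors of the flagellar biosynthetic locus.  These are
#' synthetic reference sequences generated from a fixed internal seed —
#' they are the ancestors the synthetic-genome generator mutates, so any
#' generated cohort is analysable with this set; for real genomes supply
#' organism-appropriate anchors via [readReferenceDb()]-style FASTA and
#' the [AnchorSet-class] constructor.
#'
#' @return an [AnchorSet-class].
#' @export
defaultAnchorSet <- function() {
  anc <- .ancestral()
  new("AnchorSet", proteins = AAStringSet(c(
    flaA2 = anc$fla[["flaA2"]], flaG = anc$locus[["flaG"]],
    comFA = anc$locus[["comFA"]], raiA = anc$locus[["raiA"]])))
}

#' Default labelled reference protein database
#'
#' The synthetic ancestral island proteins with their functional labels
#' (glycosyltransferase, maf, biosynthesis pathways, modification
#' enzymes, endonuclease, transposase, hypothetical) plus the three
#' flagellin classes.  Generated from a fixed internal seed; see
#' [defaultAnchorSet()] for the rationale.
#'
#' @param islandGeneLen island gene length range (amino acids) the pool
#'   was built for; must match the generator configuration.
#' @return labelled \link[Biostrings]{AAStringSet} (metadata column
#'   \code{label}).
#' @export
defaultReferenceDb <- function(islandGeneLen = c(120L, 400L)) {
  anc <- .ancestral(islandGeneLen)
  seqs <- c(anc$pool, tnp1 = anc$locus[["tnp1"]], anc$fla)
  labels <- c(anc$catalog$label, "transposase",
              rep("flagellin", length(anc$fla)))
  db <- AAStringSet(seqs)
  mcols(db)$label <- labels
  db
}

#' Synthetic cohort configuration
#'
#' The study conditions of the simulated cohort.  Defaults: five island
#' types with three strains each plus five FGI-negative strains; host
#' backbone at 52\% G+C with islands implanted at 38\% (46\% for the
#' small FGI-negative filler intergaps), emulating the compositional
#' depression of horizontally acquired loci; 5\% amino-acid divergence
#' within ortholog families; 5\% per-gene truncation and
#' transposon-disruption rates; a 250 kb host backbone, large enough
#' that the island does not drag the genome-wide G+C mean.
#'
#' @param seed integer cohort seed (all cohort-level randomness).
#' @param nStrainsPerType named integer vector, strains per island type.
#' @param nFgiMinus number of FGI-negative strains.
#' @param hostGC,islandGC,minusIslandGC target G+C fractions.
#' @param divergence expected amino-acid substitution fraction within an
#'   island gene family.
#' @param pTruncate,pDisrupt per-island-gene probabilities of truncation
#'   (to below half length) and of transposon disruption.
#' @param islandGeneLen island gene length range in amino acids.
#' @param hostLength host backbone length in nucleotides.
#' @param flagellinCentralDivergence per-class substitution rate of the
#'   variable flagellin centre (termini are held nearly constant).
#' @param spacerLen intergenic spacer length range in nucleotides.
#' @param minusCdsRange CDS count range of FGI-negative intergaps.
#' @return a list of class \code{FgiSimConfig}.
#' @seealso [generateCohort()]
#' @export
fgiSimConfig <- function(seed = 1L,
                         nStrainsPerType = c(I = 3L, II = 3L, III = 3L,
                                             IV = 3L, V = 3L),
                         nFgiMinus = 5L,
                         hostGC = 0.52, islandGC = 0.38,
                         minusIslandGC = 0.46,
                         divergence = 0.05,
                         pTruncate = 0.05, pDisrupt = 0.05,
                         islandGeneLen = c(120L, 400L),
                         hostLength = 250000L,
                         flagellinCentralDivergence = c(flaA1 = 0.30,
                                                        flaA2 = 0.30,
                                                        flaA3 = 0.05),
                         spacerLen = c(80L, 200L),
                         minusCdsRange = c(0L, 6L)) {
  stopifnot(all(c(pTruncate, pDisrupt) >= 0),
            all(c(pTruncate, pDisrupt) <= 1),
            hostGC > 0, hostGC < 1, islandGC > 0, islandGC < 1,
            divergence >= 0, divergence <= 1,
            all(names(nStrainsPerType) %in% c("I", "II", "III", "IV", "V")))
  structure(list(seed = as.integer(seed),
                 nStrainsPerType = nStrainsPerType,
                 nFgiMinus = as.integer(nFgiMinus), hostGC = hostGC,
                 islandGC = islandGC, minusIslandGC = minusIslandGC,
                 divergence = divergence, pTruncate = pTruncate,
                 pDisrupt = pDisrupt, islandGeneLen = islandGeneLen,
                 hostLength = as.integer(hostLength),
                 flagellinCentralDivergence = flagellinCentralDivergence,
                 spacerLen = spacerLen, minusCdsRange = minusCdsRange),
            class = "FgiSimConfig")
}

#' Ancestral island family pool
#'
#' The per-family ancestral proteins (deterministic for a given
#' configuration) from which island genes are derived by mutation.
#'
#' @param config an \code{FgiSimConfig}.
#' @return \link[Biostrings]{AAStringSet} named by family, with metadata
#'   columns \code{label} and \code{types}.
#' @export
generateFamilyPool <- function(config = fgiSimConfig()) {
  anc <- .ancestral(config$islandGeneLen)
  pool <- AAStringSet(anc$pool)
  mcols(pool)$label <- anc$catalog$label
  mcols(pool)$types <- anc$catalog$types
  pool
}

.type_profile <- function(catalog, type) {
  sel <- vapply(strsplit(catalog$types, ","), function(t) type %in% t, TRUE)
  catalog$name[sel]
}

## one gene as a list of CDS feature stubs (a disrupted gene yields two
## fragments with a transposase CDS between them)
.render_gene <- function(name, protein, event, anc) {
  if (event == "truncate") {
    keep <- max(10L, floor(stats::runif(1, 0.25, 0.45) * nchar(protein)))
    return(list(list(gene = name, protein = substring(protein, 1L, keep),
                     intact = FALSE)))
  }
  if (event == "disrupt") {
    k <- floor(stats::runif(1, 0.3, 0.7) * nchar(protein))
    tnp <- .mutate_protein(anc$locus[["tnp1"]], 0.05)
    return(list(
      list(gene = name, protein = substring(protein, 1L, k), intact = FALSE),
      list(gene = "tnp1", protein = tnp, intact = TRUE),
      list(gene = name, protein = paste0("M", substring(protein, k + 1L)),
           intact = FALSE)))
  }
  list(list(gene = name, protein = protein, intact = TRUE))
}

#' Generate one synthetic genome
#'
#' Builds a single-contig genome: a host backbone at the host G+C with
#' the conserved flagellar locus (comFA ... flaA2 [island] flaG ... raiA,
#' one to three flagellin copies), and an implanted intergenic island
#' whose genes are drawn from the type's family profile, mutated at the
#' configured divergence, reverse-translated with codons biased so the
#' island's expected G+C equals the configured target, and occasionally
#' truncated or split by a transposase insertion.  FGI-negative strains
#' receive only endonuclease/hypothetical filler.  Sampling uses the
#' current RNG state; seed via [generateCohort()] for reproducibility.
#'
#' @param config an \code{FgiSimConfig}.
#' @param strainId strain identifier.
#' @param type island type \code{"I"}..\code{"V"}, or \code{NA} for an
#'   FGI-negative strain.
#' @param copies number of flagellin genes (1-3); 3 implies flaA3.
#' @return list with elements \code{genome} (a [Genome-class]) and
#'   \code{truth} (status, type, implanted families, per-gene intact
#'   flags, island interval, configured G+C).
#' @export
generateGenome <- function(config, strainId, type = NA_character_,
                           copies = 2L) {
  anc <- .ancestral(config$islandGeneLen)
  fgiPlus <- !is.na(type)
  islGC <- if (fgiPlus) config$islandGC else config$minusIslandGC

  ## island gene plan
  if (fgiPlus) {
    famNames <- .type_profile(anc$catalog, type)
    u <- stats::runif(length(famNames))
    event <- ifelse(u < config$pTruncate, "truncate",
                    ifelse(u < config$pTruncate + config$pDisrupt,
                           "disrupt", "keep"))
    ## never knock out the last intact status-carrying (GT/maf) gene
    lab <- anc$catalog$label[match(famNames, anc$catalog$name)]
    statusGene <- lab %in% c("glycosyltransferase", "maf")
    if (all(event[statusGene] != "keep"))
      event[which(statusGene)[1]] <- "keep"
  } else {
    nfill <- sample(seq(config$minusCdsRange[1], config$minusCdsRange[2]),
                    1L)
    minusPool <- anc$catalog$name[anc$catalog$types == "minus"]
    famNames <- if (nfill > 0L) sample(minusPool, nfill) else character()
    event <- rep("keep", length(famNames))
  }
  mutProt <- vapply(famNames, function(f)
    .mutate_protein(anc$pool[[f]], config$divergence), "")
  genes <- list()
  intact <- stats::setNames(logical(length(famNames)), famNames)
  for (i in seq_along(famNames)) {
    parts <- .render_gene(famNames[i], mutProt[[i]], event[i], anc)
    intact[i] <- all(vapply(parts, `[[`, TRUE, "intact")[
      vapply(parts, `[[`, "", "gene") == famNames[i]])
    genes <- c(genes, parts)
  }

  ## flagellins for this strain
  fdiv <- config$flagellinCentralDivergence
  flaA1 <- if (copies >= 2L)
    .mutate_flagellin(anc$fla[["flaA1"]], fdiv[["flaA1"]]) else NULL
  flaA2 <- .mutate_flagellin(anc$fla[["flaA2"]], fdiv[["flaA2"]])
  flaA3 <- if (copies >= 3L && fgiPlus)
    .mutate_flagellin(anc$fla[["flaA3"]], fdiv[["flaA3"]]) else NULL

  ## locus gene order: (gene name, protein, strand); island in the middle
  host <- function(g) list(gene = g,
                           protein = .mutate_protein(anc$locus[[g]],
                                                     config$divergence),
                           strand = "+")
  pre <- list(host("comFA"), host("flgN"),
              modifyList(host("flgM"), list(strand = "-")),
              host("flgK"), host("flgL"), host("fliD"))
  if (!is.null(flaA1))
    pre <- c(pre, list(host("fliS2"),
                       list(gene = "flaA1", protein = flaA1, strand = "+")))
  pre <- c(pre, list(list(gene = "flaA2", protein = flaA2, strand = "+")))
  post <- list(list(gene = "flaG", protein = host("flaG")$protein,
                    strand = "+"))
  if (!is.null(flaA3))
    post <- c(post, list(list(gene = "flaA3", protein = flaA3,
                              strand = "+")))
  post <- c(post, list(host("fliS"), host("fliT"),
                       modifyList(host("raiA"), list(strand = "-"))))

  ## assemble the contig
  lamHost <- .solve_lambda(vapply(c(pre, post), `[[`, "", "protein"),
                           config$hostGC)
  lamIsl <- if (length(genes))
    .solve_lambda(vapply(genes, `[[`, "", "protein"), islGC) else NA_real_
  spacer <- function(gc) .random_dna(
    sample(seq(config$spacerLen[1], config$spacerLen[2]), 1L), gc)

  segs <- character(); feats <- list(); pos <- 0L; fcount <- 0L
  addSeg <- function(s) { segs[[length(segs) + 1L]] <<- s
                          pos <<- pos + nchar(s) }
  addGene <- function(gene, protein, strand, lambda, type = "CDS",
                      product = "") {
    dna <- .encode_protein(protein, lambda)
    if (strand == "-")
      dna <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(dna)))
    fcount <<- fcount + 1L
    feats[[length(feats) + 1L]] <<- list(
      contig = "contig1", start = pos + 1L, end = pos + nchar(dna),
      strand = strand,
      feature_id = sprintf("%s_%04d", strainId, fcount),
      gene = gene, product = product, protein = protein)
    addSeg(dna)
  }

  left <- floor(config$hostLength * 0.55)
  right <- config$hostLength - left
  addSeg(.random_dna(left, config$hostGC))
  for (g in pre) {
    addSeg(spacer(config$hostGC))
    addGene(g$gene, g$protein, g$strand, lamHost)
  }
  ## the island: everything between end(flaA2 CDS) and start(flaG CDS)
  islandStart <- pos + 1L
  if (!fgiPlus) addSeg(.random_dna(sample(500:1100, 1L), islGC))
  for (g in genes) {
    addSeg(spacer(islGC))
    addGene(g$gene, g$protein, "+", lamIsl)
  }
  addSeg(spacer(islGC))
  islandEnd <- pos
  for (g in post) {
    addGene(g$gene, g$protein, g$strand, lamHost)
    addSeg(spacer(config$hostGC))
  }
  addSeg(.random_dna(right, config$hostGC))

  contig <- DNAStringSet(paste(segs, collapse = ""))
  names(contig) <- "contig1"
  genome <- Genome(strainId, contig, .features_granges(feats))
  truth <- list(strain_id = strainId,
                fgi_status = if (fgiPlus) "FGI+" else "FGI-",
                type = type, families = famNames,
                intact = as.list(intact),
                island_interval = c(islandStart, islandEnd),
                configured_island_gc = islGC, copies = copies)
  list(genome = genome, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Generates one genome per strain under the configuration (typed strains
#' first, then FGI-negative strains), together with the per-strain ground
#' truth and the labelled reference database matching the pool.  With an
#' output directory, genomes are written as GenBank flat files, the
#' reference set as labelled FASTA and the truth as JSON.  The whole
#' cohort is a deterministic function of the configuration: the same
#' config yields byte-identical files.
#'
#' @param config an \code{FgiSimConfig} (see [fgiSimConfig()]).
#' @param outDir optional output directory.
#' @return list with \code{genomes} (named list of [Genome-class]),
#'   \code{truth} (named list, one entry per strain), \code{refdb}
#'   (labelled \link[Biostrings]{AAStringSet}) and \code{config}.
#' @examples
#' \donttest{
#' cfg <- fgiSimConfig(seed = 7, hostLength = 20000L)
#' coh <- generateCohort(cfg)
#' length(coh$genomes)
#' }
#' @export
generateCohort <- function(config = fgiSimConfig(), outDir = NULL) {
  specs <- list()
  for (tp in names(config$nStrainsPerType)) {
    n <- config$nStrainsPerType[[tp]]
    if (n > 0L) for (i in seq_len(n))
      specs[[length(specs) + 1L]] <- list(type = tp)
  }
  if (config$nFgiMinus > 0L) for (i in seq_len(config$nFgiMinus))
    specs[[length(specs) + 1L]] <- list(type = NA_character_)

  out <- .with_seed(config$seed, {
    genomes <- list(); truth <- list()
    for (i in seq_along(specs)) {
      sid <- sprintf("SIM%02d", i)
      fgiPlus <- !is.na(specs[[i]]$type)
      copies <- if (fgiPlus)
        sample(1:3, 1L, prob = c(0.1, 0.7, 0.2)) else
        sample(1:2, 1L, prob = c(0.15, 0.85))
      g <- generateGenome(config, sid, specs[[i]]$type, copies)
      genomes[[sid]] <- g$genome
      truth[[sid]] <- g$truth
    }
    list(genomes = genomes, truth = truth)
  })
  refdb <- defaultReferenceDb(config$islandGeneLen)
  res <- list(genomes = out$genomes, truth = out$truth, refdb = refdb,
              config = config)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(res$genomes))
      writeGenBank(res$genomes[[sid]], file.path(outDir,
                                                 paste0(sid, ".gbk")))
    writeReferenceDb(refdb, file.path(outDir, "reference_db.faa"))
    jsonlite::write_json(res$truth, file.path(outDir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
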