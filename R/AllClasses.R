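#' @import methods
#' @importClassesFrom Biostrings DNAStringSet AAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges start end width strand seqnames
#' @importFrom GenomeInfoDb seqlengths seqlevels
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet AAStringSet AAString
#' @importFrom Rcpp sourceCpp
#' @useDynLib fgiTyper, .registration = TRUE
NULL

#' Annotated bacterial genome
#'
#' Container for one (possibly draft) genome: its contig sequences, an
#' ordered table of gene features, and the cached genome-wide G+C content.
#' Features are stored as a \link[GenomicRanges]{GRanges} (1-based, closed
#' intervals, the Bioconductor convention) whose metadata columns carry
#' \code{feature_id}, \code{type} (\code{"CDS"} or other), \code{gene},
#' \code{product} and \code{protein} (amino-acid sequence, empty for
#' non-CDS features).
#'
#' @slot strainId single non-empty strain identifier.
#' @slot contigs \link[Biostrings]{DNAStringSet} of contig sequences,
#'   named by contig id.
#' @slot features \link[GenomicRanges]{GRanges} of gene features, sorted by
#'   (contig, start).
#' @slot genomeGC cached genome G+C content in percent, computed over the
#'   concatenation of all contigs (ambiguous bases excluded).
#'
#' @seealso [readGenome()], [genomeGC()], [gcContent()]
#' @export
setClass("Genome",
  representation(strainId = "character", contigs = "DNAStringSet",
                 features = "GRanges", genomeGC = "numeric"))

setValidity("Genome", function(object) {
  msg <- character()
  if (length(object@strainId) != 1L || is.na(object@strainId) ||
      !nzchar(object@strainId))
    msg <- c(msg, "strainId must be a single non-empty string")
  if (is.null(names(object@contigs)) || anyDuplicated(names(object@contigs)))
    msg <- c(msg, "contigs must have unique names")
  ft <- object@features
  if (length(ft)) {
    needed <- c("feature_id", "type", "gene", "product", "protein")
    if (!all(needed %in% colnames(mcols(ft))))
      msg <- c(msg, paste("features must carry metadata columns:",
                          paste(needed, collapse = ", ")))
    bad <- !(as.character(seqnames(ft)) %in% names(object@contigs))
    if (any(bad)) {
      msg <- c(msg, "feature contig not present in contigs")
    } else {
      len <- width(object@contigs)[match(as.character(seqnames(ft)),
                                         names(object@contigs))]
      if (any(start(ft) < 1L | end(ft) > len))
        msg <- c(msg, "feature coordinates outside contig bounds")
    }
  }
  if (length(object@genomeGC) == 1L && !is.na(object@genomeGC)) {
    gc <- 100 * gcContent(unlist(object@contigs))
    if (abs(gc - object@genomeGC) > 1e-9)
      msg <- c(msg, "cached genomeGC does not match contigs")
  }
  if (length(msg)) msg else TRUE
})

#' Extracted flagellin glycosylation island for one strain
#'
#' Per-strain record of the intergenic span between the \emph{flaA2} and
#' \emph{flaG} coding sequences: its coordinates, size, compositional
#' metrics, member CDS features, functional annotations and FGI status.
#' An empty intergap is permitted; its G+C content and deviation are
#' \code{NA}.
#'
#' @slot strainId strain identifier.
#' @slot contigId contig carrying the locus.
#' @slot start,end 1-based closed interval of the intergenic span
#'   (\code{end == start - 1} for an empty island).
#' @slot sizeKb island length in kilobases (unrounded).
#' @slot islandGC,genomeGC,gcDeviation island and genome G+C in percent
#'   and their signed difference (island minus genome; negative values
#'   indicate the compositional depression typical of horizontally
#'   acquired DNA).
#' @slot cds \link[GenomicRanges]{GRanges} of CDS features fully contained
#'   in the interval.
#' @slot nCds number of island CDSs.
#' @slot fgiStatus \code{"FGI+"}, \code{"FGI-"}, or \code{NA} before
#'   classification.
#' @slot annotations named character vector, feature id to functional label.
#'
#' @seealso [extractIsland()], [annotateIsland()], [classifyIsland()]
#' @export
setClass("IslandRecord",
  representation(strainId = "character", contigId = "character",
                 start = "integer", end = "integer", sizeKb = "numeric",
                 islandGC = "numeric", genomeGC = "numeric",
                 gcDeviation = "numeric", cds = "GRanges", nCds = "integer",
                 fgiStatus = "character", annotations = "character"))

setValidity("IslandRecord", function(object) {
  msg <- character()
  if (object@end - object@start + 1L < 0L)
    msg <- c(msg, "negative island width")
  if (abs(object@sizeKb - (object@end - object@start + 1L) / 1000) > 0.05)
    msg <- c(msg, "sizeKb inconsistent with interval length")
  if (object@nCds != length(object@cds))
    msg <- c(msg, "nCds != length(cds)")
  if (!is.na(object@fgiStatus) && !object@fgiStatus %in% c("FGI+", "FGI-"))
    msg <- c(msg, "fgiStatus must be 'FGI+', 'FGI-' or NA")
  if (!is.na(object@islandGC) && !is.na(object@genomeGC) &&
      !is.na(object@gcDeviation) &&
      abs(object@gcDeviation - (object@islandGC - object@genomeGC)) > 1e-6)
    msg <- c(msg, "gcDeviation != islandGC - genomeGC")
  if (length(msg)) msg else TRUE
})

#' Pipeline thresholds
#'
#' The identity/coverage and clustering thresholds used throughout the
#' pipeline, with the defaults used for the \emph{Geobacillus} analysis:
#' functional annotation requires >50\% amino-acid identity over at least
#' 70\% of the reference protein length; orthology between island proteins
#' requires >70\% identity over at least 70\% of both protein lengths;
#' island types are separated at 50\% profile similarity; and a family
#' member shorter than 50\% of the family's median length is scored as
#' truncated.
#'
#' @slot annotIdPct,annotCovPct annotation identity (strict >) and
#'   reference-coverage (>=) thresholds in percent.
#' @slot orthoIdPct,orthoCovPct orthology identity (strict >) and mutual
#'   coverage (>=) thresholds in percent.
#' @slot typeCutoffPct similarity cutoff for typing, percent.
#' @slot truncationFrac fraction of the family median length below which
#'   a member is scored truncated.
#'
#' @seealso [fgiThresholds()]
#' @export
setClass("FgiThresholds",
  representation(annotIdPct = "numeric", annotCovPct = "numeric",
                 orthoIdPct = "numeric", orthoCovPct = "numeric",
                 typeCutoffPct = "numeric", truncationFrac = "numeric"))

setValidity("FgiThresholds", function(object) {
  v <- c(object@annotIdPct, object@annotCovPct, object@orthoIdPct,
         object@orthoCovPct, object@typeCutoffPct)
  if (any(v <= 0 | v > 100)) return("percent thresholds must lie in (0, 100]")
  if (object@truncationFrac <= 0 || object@truncationFrac >= 1)
    return("truncationFrac must lie in (0, 1)")
  TRUE
})

#' Anchor proteins for locating the flagellar locus
#'
#' Reference amino-acid sequences for the two inner anchors (the flagellin
#' FlaA2 and the downstream FlaG) that delimit the island, and the two
#' outer anchors (ComFA and RaiA) that flank the whole flagellar
#' biosynthetic locus and are used as a fallback search window when
#' flagellin paralogs make the inner anchors ambiguous.
#'
#' @slot proteins \link[Biostrings]{AAStringSet} named
#'   \code{flaA2, flaG, comFA, raiA}.
#' @seealso [defaultAnchorSet()], [findAnchors()]
#' @export
setClass("AnchorSet", representation(proteins = "AAStringSet"))

setValidity("AnchorSet", function(object) {
  need <- c("flaA2", "flaG", "comFA", "raiA")
  if (!all(need %in% names(object@proteins)))
    return(paste("anchor proteins must include:", paste(need, collapse = ", ")))
  if (any(width(object@proteins) == 0L)) return("empty anchor sequence")
  if (anyDuplicated(names(object@proteins))) return("duplicated anchor names")
  TRUE
})

#' Binary ortholog presence/absence matrix
#'
#' Strain-by-family binary matrix in which a cell is 1 iff the strain has
#' at least one intact member of the ortholog family; truncated and
#' transposon-disrupted members score 0.  The parallel provenance matrix
#' records why each cell has its value (\code{"present"}, \code{"absent"},
#' \code{"truncated"} or \code{"disrupted"}).
#'
#' @slot cells integer 0/1 matrix, strains in rows, families in columns.
#' @slot provenance character matrix of identical dimensions.
#' @seealso [scoreMatrix()], [pearsonSimilarity()]
#' @export
setClass("PresenceAbsenceMatrix",
  representation(cells = "matrix", provenance = "matrix"))

setValidity("PresenceAbsenceMatrix", function(object) {
  if (!all(object@cells %in% c(0L, 1L))) return("cells must be 0/1")
  if (!identical(dim(object@cells), dim(object@provenance)))
    return("cells and provenance dimensions differ")
  ok <- c("present", "absent", "truncated", "disrupted")
  if (!all(object@provenance %in% ok))
    return("invalid provenance value")
  if ((!all(object@cells[object@provenance == "present"] == 1L)) ||
      (!all(object@cells[object@provenance != "present"] == 0L)))
    return("cells inconsistent with provenance")
  TRUE
})

#' UPGMA dendrogram of island profiles
#'
#' Ultrametric tree produced by average-linkage (UPGMA) clustering of the
#' profile distance matrix d = 100 - similarity.  Stored both as an
#' \code{\link[stats]{hclust}}-compatible structure (heights in full
#' distance units, i.e. the merge distance) and as an \link[ape]{ape}
#' \code{phylo} tree whose branch lengths place each merge at height
#' d/2, so that leaf-to-leaf path lengths reproduce the merge distances.
#'
#' @slot hclust the \code{hclust}-style list (merge, height, labels, order).
#' @slot phylo the equivalent \code{phylo} tree.
#' @seealso [upgma()], [assignTypes()], [writeNewick()]
#' @export
setClass("UpgmaTree", representation(hclust = "ANY", phylo = "ANY"))

#' Island typing result
#'
#' The Pearson similarity matrix, the UPGMA dendrogram, and the type
#' partition obtained by cutting the dendrogram at the similarity cutoff.
#' Types are labelled with Roman numerals by decreasing member count
#' (ties broken by the lexicographically first strain id).
#'
#' @slot similarity symmetric strain-by-strain similarity matrix
#'   (Pearson r x 100, diagonal 100).
#' @slot tree [UpgmaTree-class] dendrogram.
#' @slot cutoffPct similarity cutoff in percent.
#' @slot typeOf named character vector, strain id to type label.
#' @slot nTypes number of types at the cutoff.
#' @seealso [assignTypes()]
#' @export
setClass("TypingResult",
  representation(similarity = "matrix", tree = "UpgmaTree",
                 cutoffPct = "numeric", typeOf = "character",
                 nTypes = "integer"))

#' Flagellin paralog set
#'
#' The members of one flagellin class (flaA1, flaA2 or flaA3) across
#' strains, with their length range and average pairwise identity.
#'
#' @slot geneClass one of \code{"flaA1"}, \code{"flaA2"}, \code{"flaA3"}.
#' @slot members \link[Biostrings]{AAStringSet} named by strain id.
#' @slot lengthRange integer (min, max) member length in amino acids.
#' @slot avgPairwiseIdentity mean global-alignment identity over all
#'   unordered member pairs, percent (\code{NA} with fewer than 2 members).
#' @seealso [classifyFlagellins()], [averagePairwiseIdentity()]
#' @export
setClass("FlagellinSet",
  representation(geneClass = "character", members = "AAStringSet",
                 lengthRange = "integer", avgPairwiseIdentity = "numeric"))

#' Cohort summary of island metrics
#'
#' Aggregate statistics over a table of per-strain island metrics:
#' FGI+/FGI- counts, per-status group means (island G+C, mean absolute
#' G+C deviation) and ranges (size in kb, CDS count), the number of
#' distinct types and per-type strain counts.  Percentages are rounded to
#' two decimals and sizes to one, matching the reporting precision of the
#' per-strain table.
#'
#' @slot nStrains,nFgiPlus,nFgiMinus strain counts.
#' @slot nTypes number of distinct island types among FGI+ strains.
#' @slot typeCounts named integer vector of strains per type.
#' @slot groupStats data.frame with one row per status group
#'   (\code{FGI+}, \code{FGI-}): \code{n}, \code{mean_island_gc_pct},
#'   \code{mean_abs_gc_deviation_pct}, \code{min_size_kb},
#'   \code{max_size_kb}, \code{min_n_cds}, \code{max_n_cds}.
#' @slot notes character vector of validation notes.
#' @seealso [summarizeIslands()]
#' @export
setClass("CohortSummary",
  representation(nStrains = "integer", nFgiPlus = "integer",
                 nFgiMinus = "integer", nTypes = "integer",
                 typeCounts = "integer", groupStats = "data.frame",
                 notes = "character"))

#' Full pipeline result
#'
#' Everything [runPipeline()] computes for a cohort: the per-strain island
#' records, the per-strain metrics table, the ortholog families, the
#' presence/absence matrix, the typing result (or \code{NULL} when fewer
#' than two FGI+ strains are present) and the cohort summary.
#'
#' @slot records list of [IslandRecord-class], named by strain.
#' @slot table per-strain metrics data.frame (the island table schema).
#' @slot families list of ortholog families (see [clusterOrthologs()]).
#' @slot pam [PresenceAbsenceMatrix-class] or \code{NULL}.
#' @slot typing [TypingResult-class] or \code{NULL}.
#' @slot summary [CohortSummary-class].
#' @slot failures named character vector of strains excluded because
#'   anchor detection failed, with the error messages.
#' @export
setClass("FgiCohortResult",
  representation(records = "list", table = "data.frame", families = "list",
                 pam = "ANY", typing = "ANY", summary = "CohortSummary",
                 failures = "character"))
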