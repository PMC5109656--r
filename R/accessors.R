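#' @rdname Genome-class
#' @param object,x a package object.
#' @export
setGeneric("strainId", function(x) standardGeneric("strainId"))

#' @rdname Genome-class
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname Genome-class
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname Genome-class
#' @export
setGeneric("genomeGC", function(x) standardGeneric("genomeGC"))

#' @rdname IslandRecord-class
#' @export
setGeneric("fgiStatus", function(x) standardGeneric("fgiStatus"))

#' @rdname IslandRecord-class
#' @export
setGeneric("islandAnnotations", function(x) standardGeneric("islandAnnotations"))

#' @rdname TypingResult-class
#' @export
setGeneric("typeOf", function(x) standardGeneric("typeOf"))

#' @rdname TypingResult-class
#' @export
setGeneric("nTypes", function(x) standardGeneric("nTypes"))

#' @export
#' @rdname Genome-class
setMethod("strainId", "Genome", function(x) x@strainId)
#' @export
#' @rdname IslandRecord-class
#' @aliases strainId,IslandRecord-method
setMethod("strainId", "IslandRecord", function(x) x@strainId)
#' @export
#' @rdname Genome-class
setMethod("contigs", "Genome", function(x) x@contigs)
#' @export
#' @rdname Genome-class
setMethod("features", "Genome", function(x) x@features)
#' @export
#' @rdname Genome-class
setMethod("genomeGC", "Genome", function(x) x@genomeGC)
#' @export
#' @rdname IslandRecord-class
setMethod("fgiStatus", "IslandRecord", function(x) x@fgiStatus)
#' @export
#' @rdname IslandRecord-class
setMethod("islandAnnotations", "IslandRecord", function(x) x@annotations)
#' @export
#' @rdname TypingResult-class
setMethod("typeOf", "TypingResult", function(x) x@typeOf)
#' @export
#' @rdname TypingResult-class
setMethod("nTypes", "TypingResult", function(x) x@nTypes)

#' CDS features of a genome or island
#'
#' @param x a [Genome-class] or [IslandRecord-class].
#' @return a \link[GenomicRanges]{GRanges} of CDS features.
#' @export
setGeneric("cdsFeatures", function(x) standardGeneric("cdsFeatures"))

#' @rdname cdsFeatures
#' @export
setMethod("cdsFeatures", "Genome", function(x) {
  ft <- x@features
  ft[mcols(ft)$type == "CDS"]
})

#' @rdname cdsFeatures
#' @export
setMethod("cdsFeatures", "IslandRecord", function(x) x@cds)

#' Island CDS proteins
#'
#' @param x an [IslandRecord-class].
#' @return an \link[Biostrings]{AAStringSet} named by feature id.
#' @export
islandProteins <- function(x) {
  stopifnot(is(x, "IslandRecord"))
  p <- AAStringSet(mcols(x@cds)$protein)
  names(p) <- mcols(x@cds)$feature_id
  p
}

setMethod("show", "Genome", function(object) {
  cat("Genome:", object@strainId, "\n")
  cat(" ", length(object@contigs), "contig(s),",
      sum(width(object@contigs)), "bp, G+C",
      sprintf("%.2f%%", object@genomeGC), "\n")
  cat(" ", length(object@features), "feature(s),",
      sum(mcols(object@features)$type == "CDS"), "CDS\n")
})

setMethod("show", "IslandRecord", function(object) {
  cat("IslandRecord:", object@strainId,
      if (!is.na(object@fgiStatus)) paste0("[", object@fgiStatus, "]"), "\n")
  cat(sprintf("  %s:%d-%d  %.1f kb, %d CDS\n", object@contigId,
              object@start, object@end, object@sizeKb, object@nCds))
  if (!is.na(object@islandGC))
    cat(sprintf("  island G+C %.2f%%, genome %.2f%%, deviation %+.2f\n",
                object@islandGC, object@genomeGC, object@gcDeviation))
})

setMethod("show", "PresenceAbsenceMatrix", function(object) {
  cat("PresenceAbsenceMatrix:", nrow(object@cells), "strains x",
      ncol(object@cells), "families;",
      sum(object@cells), "present cells\n")
})

setMethod("show", "TypingResult", function(object) {
  cat("TypingResult:", length(object@typeOf), "strains,",
      object@nTypes, "type(s) at", object@cutoffPct, "% similarity\n")
  print(table(type = object@typeOf))
})

setMethod("show", "UpgmaTree", function(object) {
  cat("UpgmaTree with", length(object@hclust$labels), "leaves\n")
})

setMethod("show", "FlagellinSet", function(object) {
  cat(sprintf("FlagellinSet %s: %d member(s), length %d-%d aa",
              object@geneClass, length(object@members),
              object@lengthRange[1], object@lengthRange[2]))
  if (!is.na(object@avgPairwiseIdentity))
    cat(sprintf(", avg pairwise identity %.2f%%", object@avgPairwiseIdentity))
  cat("\n")
})

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary:", object@nStrains, "strains;",
      object@nFgiPlus, "FGI+ /", object@nFgiMinus, "FGI-;",
      object@nTypes, "island type(s)\n")
  if (length(object@typeCounts)) {
    cat("  strains per type:",
        paste(names(object@typeCounts), object@typeCounts,
              sep = ":", collapse = "  "), "\n")
  }
  print(object@groupStats, row.names = FALSE)
  if (length(object@notes)) cat("  note:", object@notes, sep = "\n  ")
})

setMethod("show", "FgiCohortResult", function(object) {
  cat("FgiCohortResult\n")
  show(object@summary)
  if (length(object@failures))
    cat("  excluded strains:", paste(names(object@failures), collapse = ", "),
        "\n")
})

setMethod("show", "AnchorSet", function(object) {
  cat("AnchorSet:", paste(names(object@proteins), collapse = ", "), "\n")
})

setMethod("show", "FgiThresholds", function(object) {
  cat(sprintf(paste0("FgiThresholds: annotation >%g%% id / >=%g%% cov; ",
                     "orthology >%g%% id / >=%g%% cov; type cutoff %g%%; ",
                     "truncation < %g x median\n"),
              object@annotIdPct, object@annotCovPct, object@orthoIdPct,
              object@orthoCovPct, object@typeCutoffPct,
              object@truncationFrac))
})

#' Construct the threshold set
#'
#' @param annotIdPct,annotCovPct annotation identity / reference coverage
#'   thresholds (percent).  Identity is compared strictly (>), coverage
#'   inclusively (>=).
#' @param orthoIdPct,orthoCovPct orthology identity / mutual coverage
#'   thresholds (percent).
#' @param typeCutoffPct similarity cutoff separating island types.
#' @param truncationFrac fraction of the family median length below which
#'   a member is scored truncated.
#' @return an [FgiThresholds-class] object.
#' @examples
#' fgiThresholds()
#' @export
fgiThresholds <- function(annotIdPct = 50, annotCovPct = 70,
                          orthoIdPct = 70, orthoCovPct = 70,
                          typeCutoffPct = 50, truncationFrac = 0.5) {
  new("FgiThresholds", annotIdPct = annotIdPct, annotCovPct = annotCovPct,
      orthoIdPct = orthoIdPct, orthoCovPct = orthoCovPct,
      typeCutoffPct = typeCutoffPct, truncationFrac = truncationFrac)
}
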