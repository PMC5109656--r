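#' Locate the flaA2/flaG anchor pair in a genome
#'
#' Scans the CDS proteins for the two inner anchors delimiting the
#' island: a CDS qualifies as an anchor when it exceeds the annotation
#' identity threshold over at least the annotation coverage fraction of
#' the reference protein's length.  When several flagellin-like CDSs
#' qualify as flaA2 (the flaA1/flaA3 paralogs), the qualifying CDS
#' nearest to flaG on its 5' side is chosen; the outer anchors
#' (comFA/raiA) bound the search window as a fallback when the inner
#' pair is still ambiguous.
#'
#' @param genome a [Genome-class].
#' @param anchors an [AnchorSet-class].
#' @param thresholds an [FgiThresholds-class].
#' @return list with elements \code{flaA2} and \code{flaG}, each a
#'   one-row \link[GenomicRanges]{GRanges} feature.
#' @seealso [extractIsland()]
#' @export
findAnchors <- function(genome, anchors = defaultAnchorSet(),
                        thresholds = fgiThresholds()) {
  cds <- cdsFeatures(genome)
  cds <- cds[nzchar(mcols(cds)$protein)]
  if (!length(cds)) stop("findAnchors: genome has no CDS with proteins")
  prots <- mcols(cds)$protein

  hit_tab <- function(anchorName) {
    ref <- as.character(anchors@proteins[[anchorName]])
    .reference_hits(prots, ref, thresholds@annotIdPct,
                    thresholds@annotCovPct)
  }
  h2 <- hit_tab("flaA2")
  hG <- hit_tab("flaG")
  cand2 <- which(h2$qualifies)
  candG <- which(hG$qualifies)

  if (!length(cand2) || !length(candG)) {
    near <- function(h) {
      if (all(is.na(h$identity))) "no alignment candidate" else
        sprintf("best identity %.1f%% / reference coverage %.1f%%",
                max(h$identity, na.rm = TRUE),
                h$coverage[which.max(h$identity)])
    }
    stop("anchors not found in ", genome@strainId,
         if (!length(cand2)) paste0(" [flaA2: ", near(h2), "]"),
         if (!length(candG)) paste0(" [flaG: ", near(hG), "]"))
  }

  ## restrict to the comFA..raiA window when the inner anchors are
  ## ambiguous (flagellin paralogs) and the outer anchors are present
  if (length(cand2) > 1L) {
    hC <- hit_tab("comFA"); hR <- hit_tab("raiA")
    ci <- which(hC$qualifies); ri <- which(hR$qualifies)
    if (length(ci) == 1L && length(ri) == 1L &&
        as.character(seqnames(cds))[ci] ==
          as.character(seqnames(cds))[ri]) {
      win <- range(c(start(cds)[c(ci, ri)], end(cds)[c(ci, ri)]))
      ctg <- as.character(seqnames(cds))[ci]
      inwin <- function(idx) as.character(seqnames(cds))[idx] == ctg &
        start(cds)[idx] >= win[1] & end(cds)[idx] <= win[2]
      if (any(inwin(cand2))) cand2 <- cand2[inwin(cand2)]
      if (any(inwin(candG))) candG <- candG[inwin(candG)]
    }
  }

  ## pair every flaG candidate with the nearest upstream flaA2 candidate
  ## on the same contig; keep the tightest pair
  best <- NULL
  for (g in candG[order(start(cds)[candG])]) {
    same <- cand2[as.character(seqnames(cds))[cand2] ==
                    as.character(seqnames(cds))[g]]
    up <- same[end(cds)[same] < start(cds)[g]]
    if (!length(up)) next
    a2 <- up[which.max(end(cds)[up])]
    gap <- start(cds)[g] - end(cds)[a2]
    if (is.null(best) || gap < best$gap) best <- list(a2 = a2, g = g,
                                                     gap = gap)
  }
  if (is.null(best)) {
    ovl <- any(vapply(candG, function(g) any(
      as.character(seqnames(cds))[cand2] == as.character(seqnames(cds))[g] &
        start(cds)[cand2] <= end(cds)[g] & end(cds)[cand2] >= start(cds)[g]),
      TRUE))
    if (ovl) stop("malformed locus in ", genome@strainId,
                  ": anchor CDSs overlap")
    stop("anchors not found in ", genome@strainId,
         ": no flaA2 upstream of flaG on a single contig")
  }
  list(flaA2 = cds[best$a2], flaG = cds[best$g])
}

## identity / reference-coverage of every protein against one reference;
## coverage is measured over the reference length (the fixed
## interpretation of "70% of the protein length")
.reference_hits <- function(prots, ref, idPct, covPct, prefilter = TRUE) {
  n <- length(prots)
  identity <- rep(NA_real_, n)
  coverage <- rep(NA_real_, n)
  alncols <- rep(NA_real_, n)
  cand <- seq_len(n)
  if (prefilter && n > 0L) {
    refk <- .kmer_strings(ref)[[1]]
    pk <- .kmer_strings(prots)
    cand <- which(vapply(seq_len(n), function(i)
      sum(pk[[i]] %in% refk) >= 2L, TRUE))
  }
  for (i in cand) {
    res <- alignGlobal(prots[i], ref)
    identity[i] <- res@identityPct
    coverage[i] <- res@coverageBPct
    alncols[i] <- nchar(res@alignedA)
  }
  data.frame(identity = identity, coverage = coverage, alncols = alncols,
             qualifies = !is.na(identity) & identity > idPct &
               coverage >= covPct)
}

#' Excise the flaA2-flaG intergenic island
#'
#' The island is the intergenic span between the end of the flaA2 CDS and
#' the start of the flaG CDS (anchor genes excluded, so they never
#' inflate the island G+C).  CDS membership requires full containment in
#' the interval.  An empty intergap is a valid (FGI-negative-looking)
#' record whose G+C content and deviation are \code{NA}.
#'
#' @param genome a [Genome-class].
#' @param flaA2,flaG the anchor features from [findAnchors()].
#' @return an [IslandRecord-class] without status or annotations.
#' @export
extractIsland <- function(genome, flaA2, flaG) {
  ctg <- as.character(seqnames(flaA2))
  if (ctg != as.character(seqnames(flaG)))
    stop("malformed locus: anchors on different contigs")
  if (end(flaA2) >= start(flaG))
    stop("malformed locus: flaA2 does not end before flaG starts")
  istart <- end(flaA2) + 1L
  iend <- start(flaG) - 1L
  w <- iend - istart + 1L
  cds <- cdsFeatures(genome)
  inside <- as.character(seqnames(cds)) == ctg &
    start(cds) >= istart & end(cds) <= iend
  cds <- cds[inside]
  islGC <- NA_real_
  if (w > 0L)
    islGC <- 100 * gcContent(Biostrings::subseq(genome@contigs[[ctg]],
                                                istart, iend))
  dev <- if (is.na(islGC)) NA_real_ else islGC - genome@genomeGC
  new("IslandRecord", strainId = genome@strainId, contigId = ctg,
      start = istart, end = iend, sizeKb = w / 1000,
      islandGC = islGC, genomeGC = genome@genomeGC, gcDeviation = dev,
      cds = cds, nCds = length(cds), fgiStatus = NA_character_,
      annotations = stats::setNames(character(), character()))
}

#' Functionally annotate island CDSs against a labelled reference set
#'
#' Each island CDS receives the label of its best qualifying reference
#' hit: identity above the annotation threshold over at least the
#' annotation coverage fraction of the reference protein's length.  The
#' best hit is the qualifying hit of highest identity; ties are broken by
#' longer aligned length, then lexicographic reference name.  A CDS with
#' no qualifying hit — including a truncated gene fragment whose hit
#' passes identity but falls short of the reference coverage — is
#' \code{"hypothetical"}.
#'
#' @param island an [IslandRecord-class].
#' @param refdb labelled \link[Biostrings]{AAStringSet}
#'   (see [readReferenceDb()]).
#' @param thresholds an [FgiThresholds-class].
#' @param prefilter skip alignments ruled out by the shared-5-mer screen.
#' @return the island record with the \code{annotations} slot filled.
#' @seealso [classifyIsland()]
#' @export
annotateIsland <- function(island, refdb, thresholds = fgiThresholds(),
                           prefilter = TRUE) {
  if (is.null(refdb) || !length(refdb))
    stop("annotateIsland: empty reference database")
  prots <- islandProteins(island)
  labels <- stats::setNames(rep("hypothetical", length(prots)),
                            names(prots))
  reflabels <- mcols(refdb)$label
  refnames <- names(refdb)
  refseq <- as.character(refdb)
  refK <- if (prefilter) .kmer_strings(refseq) else NULL
  for (i in seq_along(prots)) {
    p <- as.character(prots[[i]])
    if (!nzchar(p)) next
    cand <- seq_along(refseq)
    if (prefilter) {
      pk <- .kmer_strings(p)[[1]]
      cand <- which(vapply(refK, function(rk) sum(pk %in% rk) >= 2L, TRUE))
    }
    if (!length(cand)) next
    identity <- numeric(length(cand)); refcov <- numeric(length(cand))
    cols <- numeric(length(cand))
    for (j in seq_along(cand)) {
      res <- alignGlobal(p, refseq[cand[j]])
      identity[j] <- res@identityPct
      refcov[j] <- res@coverageBPct
      cols[j] <- nchar(res@alignedA)
    }
    full <- identity > thresholds@annotIdPct &
      refcov >= thresholds@annotCovPct
    if (any(full)) {
      o <- order(-identity[full], -cols[full], refnames[cand[full]])
      labels[i] <- reflabels[cand[full][o[1]]]
    }
  }
  island@annotations <- labels
  island
}

#' Call FGI status from island annotations
#'
#' An island is FGI-positive iff at least one of its CDSs is annotated as
#' a glycosyltransferase or a motility-associated factor (Maf); islands
#' with only endonuclease/hypothetical content — or no CDSs at all — are
#' FGI-negative.
#'
#' @param island an annotated [IslandRecord-class].
#' @return the record with \code{fgiStatus} set.
#' @export
classifyIsland <- function(island) {
  plus <- any(island@annotations %in% c("glycosyltransferase", "maf"))
  island@fgiStatus <- if (plus) "FGI+" else "FGI-"
  island
}
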