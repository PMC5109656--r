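#' Average pairwise global-alignment identity
#'
#' Mean identity of [alignGlobal()] over all unordered pairs — the
#' statistic used to summarise within-class flagellin conservation.
#'
#' @param proteins \link[Biostrings]{AAStringSet} or character vector of
#'   at least two sequences.
#' @return mean identity in percent.
#' @examples
#' averagePairwiseIdentity(c("MKLV", "MKLV", "MALV"))
#' @export
averagePairwiseIdentity <- function(proteins) {
  p <- as.character(proteins)
  if (length(p) < 2L)
    stop("averagePairwiseIdentity: need at least two proteins")
  ids <- utils::combn(length(p), 2L, function(ij)
    alignGlobal(p[ij[1]], p[ij[2]])@identityPct)
  mean(ids)
}

#' Center-star multiple sequence alignment
#'
#' Deterministic progressive alignment: the center is the sequence
#' maximising its summed pairwise identity to all others (ties: first in
#' input order); every other sequence is aligned to the center by global
#' pairwise alignment and the pairwise gap patterns are merged under
#' "once a gap, always a gap".  The result is a conventional gapped
#' alignment suitable for column-conservation profiling; externally
#' produced alignments (aligned FASTA) can be used instead wherever an
#' alignment is consumed.
#'
#' @param proteins named \link[Biostrings]{AAStringSet} or character
#'   vector (>= 2 sequences).
#' @return \link[Biostrings]{AAStringSet} of gapped sequences of equal
#'   length, in input order.
#' @seealso [conservationProfile()]
#' @export
buildMsa <- function(proteins) {
  nm <- names(proteins)
  p <- as.character(proteins)
  n <- length(p)
  if (n < 2L) stop("buildMsa: need at least two sequences")
  if (any(!nzchar(p))) stop("buildMsa: empty sequence")
  if (is.null(nm)) nm <- paste0("seq", seq_len(n))

  ## pick the center
  idsum <- numeric(n)
  alns <- vector("list", n)  # pairwise alignments to the eventual center
  pairId <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- alignGlobal(p[i], p[j])
    pairId[i, j] <- pairId[j, i] <- r@identityPct
  }
  center <- which.max(rowSums(pairId))

  others <- setdiff(seq_len(n), center)
  for (j in others) alns[[j]] <- alignGlobal(p[center], p[j])

  ## merge gap patterns: gaps(i, k) = gaps inserted in the center before
  ## center residue k+1 (k = 0 .. len) in alignment i
  clen <- nchar(p[center])
  gapCount <- function(alignedCenter) {
    ac <- strsplit(alignedCenter, "", fixed = TRUE)[[1]]
    cnt <- integer(clen + 1L)
    k <- 0L
    for (ch in ac) {
      if (ch == "-") cnt[k + 1L] <- cnt[k + 1L] + 1L else k <- k + 1L
    }
    cnt
  }
  counts <- lapply(others, function(j) gapCount(alns[[j]]@alignedA))
  maxGaps <- if (length(counts)) do.call(pmax, counts) else
    integer(clen + 1L)

  expandRow <- function(alignedCenter, alignedSeq) {
    ac <- strsplit(alignedCenter, "", fixed = TRUE)[[1]]
    as_ <- strsplit(alignedSeq, "", fixed = TRUE)[[1]]
    flush <- function(seg, slot) {
      pad <- maxGaps[slot] - length(seg)
      c(seg, rep("-", pad))
    }
    res <- character(0)
    seg <- character(0)
    k <- 0L
    for (idx in seq_along(ac)) {
      if (ac[idx] == "-") {
        seg <- c(seg, as_[idx])
      } else {
        res <- c(res, flush(seg, k + 1L), as_[idx])
        seg <- character(0)
        k <- k + 1L
      }
    }
    res <- c(res, flush(seg, clen + 1L))
    paste(res, collapse = "")
  }

  centerRow <- {
    cc <- strsplit(p[center], "", fixed = TRUE)[[1]]
    res <- character(0)
    for (k in 0:clen) {
      res <- c(res, rep("-", maxGaps[k + 1L]),
               if (k < clen) cc[k + 1L])
    }
    paste(res, collapse = "")
  }

  out <- character(n)
  out[center] <- centerRow
  for (j in others) {
    a <- alns[[j]]
    out[j] <- expandRow(a@alignedA, a@alignedB)
  }
  msa <- AAStringSet(out)
  names(msa) <- nm
  msa
}

#' Per-column conservation of an alignment
#'
#' For each alignment column, the fraction of sequences carrying the
#' modal non-gap residue, in percent.  Gaps count in the denominator
#' (a column with one residue in three sequences is 33.3\% conserved);
#' set \code{excludeGaps = TRUE} for gap-excluded denominators.
#'
#' @param alignment \link[Biostrings]{AAStringSet} (or character vector)
#'   of gapped sequences of equal length, >= 2 sequences.
#' @param excludeGaps drop gapped sequences from a column's denominator.
#' @return numeric vector of per-column conservation percentages.
#' @seealso [buildMsa()], [writeConservationTsv()]
#' @export
conservationProfile <- function(alignment, excludeGaps = FALSE) {
  a <- as.character(alignment)
  if (length(a) < 2L) stop("conservationProfile: need >= 2 sequences")
  if (length(unique(nchar(a))) != 1L)
    stop("conservationProfile: ragged alignment")
  m <- do.call(rbind, strsplit(a, "", fixed = TRUE))
  apply(m, 2L, function(col) {
    res <- col[col != "-"]
    if (!length(res)) return(0)
    den <- if (excludeGaps) length(res) else length(col)
    100 * max(table(res)) / den
  })
}

#' @rdname conservationProfile
#' @param profile numeric vector from \code{conservationProfile}.
#' @param path output TSV (\code{column, conservation_pct}).
#' @export
writeConservationTsv <- function(profile, path) {
  utils::write.table(
    data.frame(column = seq_along(profile), conservation_pct = profile),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify flagellin paralogs around the island
#'
#' Identifies flagellin-like CDSs (annotation criterion against the
#' flagellin references in the labelled reference set) in each genome and
#' assigns them to classes by position relative to the locus: the anchor
#' at the island's 5' boundary is flaA2; a flagellin upstream of flaA2
#' (next to the second fliS copy) is flaA1; an additional copy within the
#' island or 3' of flaG is flaA3.  A flagellin that fits no positional
#' rule falls back to the class of its highest-identity reference.
#'
#' @param genomes list of [Genome-class] objects.
#' @param anchors an [AnchorSet-class].
#' @param refdb labelled reference set containing \code{flaA1},
#'   \code{flaA2}, \code{flaA3} entries with label \code{"flagellin"}.
#' @param thresholds an [FgiThresholds-class].
#' @return named list of [FlagellinSet-class] objects (classes with no
#'   members are dropped; a warning is raised if no flagellin is found at
#'   all).
#' @export
classifyFlagellins <- function(genomes, anchors = defaultAnchorSet(),
                               refdb = defaultReferenceDb(),
                               thresholds = fgiThresholds()) {
  flaRefs <- refdb[mcols(refdb)$label == "flagellin"]
  if (!length(flaRefs))
    stop("classifyFlagellins: reference set has no flagellin entries")
  members <- list(flaA1 = character(), flaA2 = character(),
                  flaA3 = character())
  for (g in genomes) {
    pair <- try(findAnchors(g, anchors, thresholds), silent = TRUE)
    if (inherits(pair, "try-error")) next
    cds <- cdsFeatures(g)
    cds <- cds[nzchar(mcols(cds)$protein)]
    prots <- mcols(cds)$protein
    ## flagellin-like CDSs: qualify against any flagellin reference
    hitId <- matrix(NA_real_, length(prots), length(flaRefs))
    qual <- rep(FALSE, length(prots))
    for (r in seq_along(flaRefs)) {
      h <- .reference_hits(prots, as.character(flaRefs[[r]]),
                           thresholds@annotIdPct, thresholds@annotCovPct)
      hitId[, r] <- h$identity
      qual <- qual | h$qualifies
    }
    idx <- which(qual)
    a2id <- mcols(pair$flaA2)$feature_id
    for (i in idx) {
      fid <- mcols(cds)$feature_id[i]
      cls <- if (fid == a2id) {
        "flaA2"
      } else if (end(cds)[i] <= start(pair$flaA2) &&
                 as.character(seqnames(cds))[i] ==
                   as.character(seqnames(pair$flaA2))) {
        "flaA1"
      } else if (start(cds)[i] >= end(pair$flaA2) &&
                 as.character(seqnames(cds))[i] ==
                   as.character(seqnames(pair$flaA2))) {
        "flaA3"
      } else {
        best <- names(flaRefs)[which.max(hitId[i, ])]
        if (best %in% c("flaA1", "flaA2", "flaA3")) best else "flaA2"
      }
      if (!g@strainId %in% names(members[[cls]]))
        members[[cls]][g@strainId] <- prots[i]
    }
  }
  if (!sum(lengths(members)))
    warning("no flagellin CDS found in any genome")
  sets <- lapply(names(members), function(cls) {
    m <- members[[cls]]
    if (!length(m)) return(NULL)
    aa <- AAStringSet(m)
    new("FlagellinSet", geneClass = cls, members = aa,
        lengthRange = range(width(aa)),
        avgPairwiseIdentity = if (length(aa) >= 2L)
          averagePairwiseIdentity(aa) else NA_real_)
  })
  names(sets) <- names(members)
  sets[!vapply(sets, is.null, TRUE)]
}
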