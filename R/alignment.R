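#' Pairwise global protein alignment result
#'
#' Result of a Needleman-Wunsch global alignment under BLOSUM62 with
#' affine gap penalties.  Identity is the fraction of alignment columns in
#' which both sequences carry the same residue; coverage of a sequence is
#' the fraction of its residues aligned to a residue (not a gap) of the
#' other sequence — the quantity behind the orthology criterion
#' "identity over 70\% of the protein length".
#'
#' @slot alignedA,alignedB gapped sequences (equal length; removing the
#'   gaps recovers the inputs).
#' @slot identityPct matching columns / alignment columns x 100.
#' @slot coverageAPct,coverageBPct residue-to-residue columns / sequence
#'   length x 100.
#' @slot score alignment score (substitution matrix + affine gaps).
#' @seealso [alignGlobal()], [qualifies()]
#' @export
setClass("AlignmentResult",
  representation(alignedA = "character", alignedB = "character",
                 identityPct = "numeric", coverageAPct = "numeric",
                 coverageBPct = "numeric", score = "numeric"))

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf(
    "AlignmentResult: score %g, identity %.2f%%, coverage %.1f%%/%.1f%%\n",
    object@score, object@identityPct, object@coverageAPct,
    object@coverageBPct))
})

.fgi_cache <- new.env(parent = emptyenv())

## BLOSUM62 with X (and any unknown residue) scored 0 against everything
.blosum62x <- function() {
  if (is.null(.fgi_cache$blosum62x)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["X", ] <- 0L
    m[, "X"] <- 0L
    storage.mode(m) <- "integer"
    .fgi_cache$blosum62x <- m
  }
  .fgi_cache$blosum62x
}

.aa_index <- function(s, alphabet) {
  idx <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], alphabet)
  idx[is.na(idx)] <- match("X", alphabet)
  idx
}

#' Global protein alignment with affine gaps
#'
#' Optimal global (Needleman-Wunsch) alignment under BLOSUM62 with affine
#' gap penalties: a gap of length L costs \code{gapOpen + L * gapExt}
#' (11 + L with the defaults).  Unknown residues, including X, score 0
#' against everything.  The traceback is deterministic: score ties are
#' resolved diagonal > up > left, so identical inputs always produce the
#' identical alignment.
#'
#' @param a,b protein sequences (character or \link[Biostrings]{AAString}).
#' @param gapOpen,gapExt affine gap parameters.
#' @param substitutionMatrix optional integer substitution matrix with
#'   single-letter row/column names; defaults to BLOSUM62 with X scored 0.
#' @return an [AlignmentResult-class].
#' @examples
#' alignGlobal("MKLV", "MALV")
#' @export
alignGlobal <- function(a, b, gapOpen = 11, gapExt = 1,
                        substitutionMatrix = NULL) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != 1L || length(b) != 1L || is.na(a) || is.na(b) ||
      !nzchar(a) || !nzchar(b))
    stop("alignGlobal: sequences must be single non-empty strings")
  smat <- if (is.null(substitutionMatrix)) .blosum62x() else {
    m <- substitutionMatrix; storage.mode(m) <- "integer"; m
  }
  alphabet <- rownames(smat)
  ai <- .aa_index(a, alphabet)
  bi <- .aa_index(b, alphabet)
  res <- .gotoh_align(ai, bi, smat, as.integer(gapOpen), as.integer(gapExt))
  achars <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bchars <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  ga <- ifelse(res$a_pos == 0L, "-", achars[pmax(res$a_pos, 1L)])
  gb <- ifelse(res$b_pos == 0L, "-", bchars[pmax(res$b_pos, 1L)])
  ncol <- length(ga)
  both <- res$a_pos > 0L & res$b_pos > 0L
  matches <- sum(both & ga == gb)
  new("AlignmentResult",
      alignedA = paste(ga, collapse = ""),
      alignedB = paste(gb, collapse = ""),
      identityPct = 100 * matches / ncol,
      coverageAPct = 100 * sum(both) / length(achars),
      coverageBPct = 100 * sum(both) / length(bchars),
      score = as.numeric(res$score))
}

#' Alignment identity under alternative denominators
#'
#' The default identity of [alignGlobal()] uses alignment columns as the
#' denominator (BLAST-like).  This helper recomputes identity over the
#' shorter or longer input for sensitivity analyses.
#'
#' @param result an [AlignmentResult-class].
#' @param denominator \code{"columns"}, \code{"shorter"} or
#'   \code{"longer"}.
#' @return identity in percent.
#' @export
alignmentIdentity <- function(result,
                              denominator = c("columns", "shorter",
                                              "longer")) {
  denominator <- match.arg(denominator)
  ga <- strsplit(result@alignedA, "", fixed = TRUE)[[1]]
  gb <- strsplit(result@alignedB, "", fixed = TRUE)[[1]]
  matches <- sum(ga != "-" & gb != "-" & ga == gb)
  la <- sum(ga != "-"); lb <- sum(gb != "-")
  den <- switch(denominator, columns = length(ga),
                shorter = min(la, lb), longer = max(la, lb))
  100 * matches / den
}

#' Orthology decision for one alignment
#'
#' TRUE iff identity exceeds the identity threshold (strictly, per the
#' ">" criterion) and both coverages reach the coverage threshold.
#'
#' @param result an [AlignmentResult-class].
#' @param idThresh identity threshold in percent (strict >).
#' @param covThresh coverage threshold in percent (>=), applied to
#'   \code{min(coverageA, coverageB)}.
#' @return logical flag.
#' @examples
#' r <- alignGlobal("MKLVA", "MKLVA")
#' qualifies(r, 70, 70)
#' @export
qualifies <- function(result, idThresh, covThresh) {
  result@identityPct > idThresh &&
    min(result@coverageAPct, result@coverageBPct) >= covThresh
}

# ---------------------------------------------------------------------------
# k-mer prefilter: candidate pair generation.  Sequences below the
# identity/coverage thresholds share almost no 5-mers, so pairs with
# fewer than `minShared` shared distinct 5-mers (or a length ratio that
# makes the mutual coverage threshold unreachable) are skipped without
# alignment.  This only skips alignments; alignGlobal itself is exact.
# ---------------------------------------------------------------------------

.kmer_strings <- function(seqs, k = 5L) {
  lapply(as.character(seqs), function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
}

.candidate_pairs <- function(seqs, covThresh, prefilter = TRUE,
                             minShared = 2L) {
  n <- length(seqs)
  if (n < 2L) return(matrix(integer(), ncol = 2L))
  len <- nchar(as.character(seqs))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[, c(2L, 1L), drop = FALSE]  # (i < j)
  ratio <- pmin(len[pairs[, 1]], len[pairs[, 2]]) /
    pmax(len[pairs[, 1]], len[pairs[, 2]])
  pairs <- pairs[ratio >= covThresh / 100, , drop = FALSE]
  if (prefilter && nrow(pairs)) {
    km <- .kmer_strings(seqs)
    keep <- vapply(seq_len(nrow(pairs)), function(r) {
      shared <- sum(km[[pairs[r, 1]]] %in% km[[pairs[r, 2]]])
      shared >= minShared
    }, TRUE)
    pairs <- pairs[keep, , drop = FALSE]
  }
  pairs
}

# ---------------------------------------------------------------------------
# Ortholog families
# ---------------------------------------------------------------------------

#' Cluster island proteins into ortholog families
#'
#' Builds the qualifying-pair graph over all island CDS proteins of all
#' strains (identity > \code{orthoIdPct} over >= \code{orthoCovPct} of
#' both protein lengths) and returns its single-linkage connected
#' components as ortholog families.  Families are ordered by their
#' first-seen member, strains taken in sorted order, so the family list is
#' invariant to the order in which strains are supplied.
#'
#' @details
#' Truncated or transposon-split genes rarely reach the mutual 70\%
#' coverage that full-length orthologs satisfy, yet they are still
#' recognisable copies of their family and the downstream scoring rules
#' expect to see (and zero) them.  After the strict clustering, each
#' leftover singleton is therefore recruited into the family it matches
#' with identity above the orthology threshold over its aligned region
#' and coverage of its own (shorter) length of at least the coverage
#' threshold; recruitment never merges two multi-member families.
#'
#' @param proteins named list, strain id to \link[Biostrings]{AAStringSet}
#'   of island CDS proteins (names are feature ids, unique per strain).
#' @param thresholds an [FgiThresholds-class].
#' @param prefilter skip alignments that a shared-5-mer/length screen
#'   shows cannot qualify (default TRUE; set FALSE to force every
#'   alignment).
#' @param recruitFragments attach left-over fragment singletons to the
#'   family they derive from (see Details).
#' @return list of families; each family is a list with elements
#'   \code{id} (e.g. \code{"FAM003"}) and \code{members}, a data.frame
#'   with columns \code{strain_id}, \code{feature_id}, \code{length}.
#' @seealso [scoreMatrix()]
#' @export
clusterOrthologs <- function(proteins, thresholds = fgiThresholds(),
                             prefilter = TRUE, recruitFragments = TRUE) {
  stopifnot(length(proteins) >= 1L)
  strains <- sort(names(proteins))
  flat_strain <- character(); flat_id <- character(); flat_seq <- character()
  for (s in strains) {
    p <- proteins[[s]]
    flat_strain <- c(flat_strain, rep(s, length(p)))
    flat_id <- c(flat_id, names(p))
    flat_seq <- c(flat_seq, as.character(p))
  }
  n <- length(flat_seq)
  if (n == 0L) return(list())
  pairs <- .candidate_pairs(flat_seq, thresholds@orthoCovPct, prefilter)
  edges <- integer()
  if (nrow(pairs)) {
    hit <- vapply(seq_len(nrow(pairs)), function(r) {
      res <- alignGlobal(flat_seq[pairs[r, 1]], flat_seq[pairs[r, 2]])
      qualifies(res, thresholds@orthoIdPct, thresholds@orthoCovPct)
    }, TRUE)
    edges <- t(pairs[hit, , drop = FALSE])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, as.vector(edges))
  comp <- igraph::components(g)$membership
  fams <- split(seq_len(n), comp)

  if (recruitFragments && length(fams) > 1L) {
    singles <- which(lengths(fams) == 1L)
    multis <- which(lengths(fams) > 1L)
    if (length(singles) && length(multis)) {
      km <- .kmer_strings(flat_seq)
      ## representative of each multi-member family: its longest member
      reps <- vapply(multis, function(m)
        fams[[m]][which.max(nchar(flat_seq[fams[[m]]]))], 0L)
      for (s in singles) {
        i <- fams[[s]][1]
        bestFam <- 0L; bestId <- -Inf
        for (mi in seq_along(multis)) {
          j <- reps[mi]
          if (prefilter && sum(km[[i]] %in% km[[j]]) < 2L) next
          res <- alignGlobal(flat_seq[i], flat_seq[j])
          ga <- strsplit(res@alignedA, "", fixed = TRUE)[[1]]
          gb <- strsplit(res@alignedB, "", fixed = TRUE)[[1]]
          both <- ga != "-" & gb != "-"
          if (!any(both)) next
          idAligned <- 100 * sum(both & ga == gb) / sum(both)
          covShorter <- 100 * sum(both) /
            min(nchar(flat_seq[i]), nchar(flat_seq[j]))
          if (idAligned > thresholds@orthoIdPct &&
              covShorter >= thresholds@orthoCovPct &&
              idAligned > bestId) {
            bestId <- idAligned; bestFam <- multis[mi]
          }
        }
        if (bestFam > 0L) {
          fams[[bestFam]] <- c(fams[[bestFam]], i)
          fams[[s]] <- integer()
        }
      }
      fams <- fams[lengths(fams) > 0L]
    }
  }

  ## order families by smallest member index (first-seen strain, then gene)
  fams <- fams[order(vapply(fams, min, 0L))]
  lapply(seq_along(fams), function(k) {
    idx <- sort(fams[[k]])
    list(id = sprintf("FAM%03d", k),
         members = data.frame(strain_id = flat_strain[idx],
                              feature_id = flat_id[idx],
                              length = nchar(flat_seq[idx]),
                              stringsAsFactors = FALSE))
  })
}

#' Score the binary presence/absence matrix
#'
#' A strain scores 1 for a family iff it has at least one member that is
#' neither truncated (shorter than \code{truncationFrac} times the family
#' median length) nor transposon-disrupted; truncated and disrupted
#' members score 0, with the reason kept in the provenance matrix.
#'
#' @param families family list from [clusterOrthologs()].
#' @param strains character vector of strain ids (matrix rows, in order).
#' @param truncationFrac truncation threshold as a fraction of the family
#'   median member length.
#' @param disrupted character vector of feature ids flagged as
#'   transposon-disrupted ([runPipeline()] flags island CDSs adjacent to
#'   a transposase-annotated CDS); a flagged member is treated as
#'   disrupted only when it is also shorter than the family median, so
#'   an intact gene that merely neighbours a mobile element keeps its 1.
#' @return a [PresenceAbsenceMatrix-class].
#' @export
scoreMatrix <- function(families, strains, truncationFrac = 0.5,
                        disrupted = character()) {
  nf <- length(families)
  cells <- matrix(0L, nrow = length(strains), ncol = nf,
                  dimnames = list(strains,
                                  vapply(families, `[[`, "", "id")))
  prov <- matrix("absent", nrow = length(strains), ncol = nf,
                 dimnames = dimnames(cells))
  for (k in seq_len(nf)) {
    mem <- families[[k]]$members
    med <- stats::median(mem$length)
    for (s in unique(mem$strain_id)) {
      if (!s %in% strains) next
      ms <- mem[mem$strain_id == s, , drop = FALSE]
      is_disr <- ms$feature_id %in% disrupted & ms$length < med
      is_trunc <- ms$length < truncationFrac * med
      intact <- !is_disr & !is_trunc
      if (any(intact)) {
        cells[s, k] <- 1L
        prov[s, k] <- "present"
      } else {
        prov[s, k] <- if (any(is_disr)) "disrupted" else "truncated"
      }
    }
  }
  new("PresenceAbsenceMatrix", cells = cells, provenance = prov)
}

#' Export a presence/absence matrix
#'
#' Writes the binary matrix as CSV (strains in rows, family ids in the
#' header) and, optionally, a long-format TSV with per-cell provenance.
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param path output CSV.
#' @param longPath optional long-format TSV
#'   (\code{strain_id, family_id, present, provenance}).
#' @return \code{path}, invisibly.
#' @export
writePresenceAbsence <- function(pam, path, longPath = NULL) {
  utils::write.csv(as.data.frame(pam@cells), path, row.names = TRUE)
  if (!is.null(longPath)) {
    long <- data.frame(
      strain_id = rep(rownames(pam@cells), ncol(pam@cells)),
      family_id = rep(colnames(pam@cells), each = nrow(pam@cells)),
      present = as.vector(pam@cells),
      provenance = as.vector(pam@provenance), stringsAsFactors = FALSE)
    utils::write.table(long, longPath, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
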