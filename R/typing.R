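#' Pearson similarity of presence/absence profiles
#'
#' Entry (i, j) is the Pearson correlation of the binary family profiles
#' of strains i and j, scaled to [-100, 100].  A pair in which either
#' profile has zero variance (all families present or all absent) is
#' defined as 100 when the two profiles are identical and 0 otherwise.
#'
#' @param pam a [PresenceAbsenceMatrix-class] (or a plain 0/1 matrix with
#'   strain rownames).
#' @return symmetric numeric matrix with unit diagonal scaled to 100.
#' @seealso [upgma()], [assignTypes()]
#' @export
pearsonSimilarity <- function(pam) {
  m <- if (is(pam, "PresenceAbsenceMatrix")) pam@cells else as.matrix(pam)
  if (nrow(m) < 2L)
    stop("pearsonSimilarity: need at least two strains")
  if (ncol(m) < 1L)
    stop("pearsonSimilarity: need at least one family")
  n <- nrow(m)
  sims <- diag(100, n)
  dimnames(sims) <- list(rownames(m), rownames(m))
  v <- apply(m, 1L, stats::var)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- if (v[i] == 0 || v[j] == 0) {
        if (all(m[i, ] == m[j, ])) 100 else 0
      } else {
        100 * stats::cor(m[i, ], m[j, ])
      }
      sims[i, j] <- sims[j, i] <- s
    }
  }
  sims
}

#' UPGMA clustering of a similarity matrix
#'
#' Standard unweighted pair-group average clustering of the distance
#' matrix d = 100 - similarity: at each step the pair of clusters with
#' the minimal average distance is merged, and distances to the new
#' cluster are size-weighted arithmetic means of the distances to its two
#' parts.  Ties are broken by the lowest (row, column) index pair, with
#' merged clusters occupying the position of their lower-indexed part, so
#' the tree is fully deterministic.  Each merge is recorded at height
#' d_min; on the [ape]-style tree the merge node sits at depth d_min/2,
#' making the tree ultrametric.
#'
#' @param similarity symmetric similarity matrix with strain dimnames
#'   (diagonal 100), e.g. from [pearsonSimilarity()]; alternatively a
#'   distance matrix via \code{isDistance = TRUE}.
#' @param isDistance interpret the input as distances directly.
#' @return an [UpgmaTree-class].
#' @examples
#' s <- matrix(c(100, 90, 100, 90, 100, 90, 100, 90,
#'               90, 100, 90, 90), 4, 4)  # toy
#' @export
upgma <- function(similarity, isDistance = FALSE) {
  m <- as.matrix(similarity)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-9)
    stop("upgma: input must be a symmetric matrix")
  n <- nrow(m)
  if (n < 2L) stop("upgma: need at least two leaves")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))
  d <- if (isDistance) m else 100 - m
  diag(d) <- 0

  ## active clusters: id (negative leaf / positive merge step), size
  id <- -seq_len(n)
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(id)
    ## lowest (i, j) among minima: column-major which() on the upper
    ## triangle scanned row-by-row
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (d[i, j] < best - 1e-12) { best <- d[i, j]; bi <- i; bj <- j }
      }
    }
    merge[step, ] <- c(id[bi], id[bj])
    height[step] <- best
    ## Lance-Williams size-weighted average update
    newrow <- (size[bi] * d[bi, ] + size[bj] * d[bj, ]) /
      (size[bi] + size[bj])
    d[bi, ] <- newrow; d[, bi] <- newrow; d[bi, bi] <- 0
    keep <- setdiff(seq_len(k), bj)
    d <- d[keep, keep, drop = FALSE]
    size[bi] <- size[bi] + size[bj]
    id[bi] <- step
    id <- id[keep]; size <- size[keep]
  }
  ## UPGMA merge heights are monotone in exact arithmetic; the weighted
  ## average updates can drift by ~1e-14 on tied merges, which cutree
  ## rejects.  Clamp numerical drift only.
  if (n > 2L) for (s in 2:(n - 1L)) {
    if (height[s] < height[s - 1L]) {
      if (height[s - 1L] - height[s] > 1e-8)
        stop("upgma: non-monotone merge heights")  # should be impossible
      height[s] <- height[s - 1L]
    }
  }
  hc <- list(merge = merge, height = height, order = .hclust_order(merge),
             labels = labels, method = "average",
             call = match.call(), dist.method = "profile")
  class(hc) <- "hclust"
  new("UpgmaTree", hclust = hc, phylo = ape::as.phylo(hc))
}

.hclust_order <- function(merge) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' Assign island types by cutting the UPGMA dendrogram
#'
#' Cuts the dendrogram at the similarity cutoff (i.e. at merge distance
#' 100 - cutoff, which is twice the node height on the ultrametric tree);
#' each resulting subtree is a type.  Types are labelled I, II, ... by
#' decreasing member count, ties broken by the lexicographically first
#' strain id, so labels are reproducible.
#'
#' @param tree an [UpgmaTree-class] from [upgma()].
#' @param cutoffPct similarity cutoff in percent.
#' @param similarity the similarity matrix the tree was built from
#'   (stored in the result for reporting; optional).
#' @return a [TypingResult-class].
#' @export
assignTypes <- function(tree, cutoffPct = 50, similarity = NULL) {
  stopifnot(is(tree, "UpgmaTree"))
  if (cutoffPct <= -100 || cutoffPct > 100)
    stop("cutoffPct must lie in (-100, 100]")
  hc <- tree@hclust
  cl <- stats::cutree(hc, h = 100 - cutoffPct + 1e-9)
  labels <- hc$labels
  sizes <- table(cl)
  firsts <- vapply(split(labels, cl), function(x) sort(x)[1], "")
  ord <- order(-as.integer(sizes), firsts)
  relabel <- stats::setNames(as.character(utils::as.roman(
    seq_along(ord))), names(sizes)[ord])
  typeOf <- stats::setNames(unname(relabel[as.character(cl)]), labels)
  if (is.null(similarity)) similarity <- matrix(numeric(), 0, 0)
  new("TypingResult", similarity = similarity, tree = tree,
      cutoffPct = cutoffPct, typeOf = typeOf,
      nTypes = length(unique(typeOf)))
}

#' Write / read a typing dendrogram in Newick format
#'
#' Branch lengths are in half-distance units (node height d/2), so the
#' file round-trips through any Newick reader preserving topology and
#' heights.
#'
#' @param tree an [UpgmaTree-class].
#' @param path output file.
#' @return \code{path} invisibly; \code{readNewick} returns an
#'   \link[ape]{ape} \code{phylo} tree.
#' @examples
#' tr <- upgma(matrix(c(100, 90, 90, 100), 2, 2,
#'             dimnames = list(c("A", "B"), c("A", "B"))))
#' f <- tempfile(fileext = ".nwk")
#' writeNewick(tr, f)
#' readLines(f)  # "(A:5,B:5);"
#' @export
writeNewick <- function(tree, path) {
  stopifnot(is(tree, "UpgmaTree"))
  ok <- try(ape::write.tree(tree@phylo, file = path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write to ", path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)
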