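# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the alignment oracle enumerates every global
# alignment; the UPGMA oracle recomputes all cluster averages from the
# original matrix at every step.

## BLOSUM62 with X scored 0, constructed here from the Biostrings data set
oracle_blosum62x <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["X", ] <- 0L
  m[, "X"] <- 0L
  m
})

## Exhaustive enumeration of all global alignments of a and b under an
## affine gap cost of gapOpen + L * gapExt per gap of length L.  Returns
## the optimal score and the identities (matches / columns * 100) of every
## optimal alignment.
enum_align <- function(a, b, smat = oracle_blosum62x, gapOpen = 11,
                       gapExt = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(A); nb <- length(B)
  best <- -Inf
  ids <- numeric(0)
  rec <- function(i, j, score, last, matches, cols) {
    if (i > na && j > nb) {
      if (score > best) { best <<- score; ids <<- numeric(0) }
      if (score == best) ids <<- c(ids, 100 * matches / cols)
      return(invisible(NULL))
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, score + smat[A[i], B[j]], "D",
          matches + (A[i] == B[j]), cols + 1L)
    if (i <= na)
      rec(i + 1L, j, score - gapExt - if (identical(last, "U")) 0 else
        gapOpen, "U", matches, cols + 1L)
    if (j <= nb)
      rec(i, j + 1L, score - gapExt - if (identical(last, "L")) 0 else
        gapOpen, "L", matches, cols + 1L)
  }
  rec(1L, 1L, 0, "", 0L, 0L)
  list(score = best, identities = unique(ids))
}

## independent rescoring of a gapped alignment under the same cost model
score_alignment <- function(alignedA, alignedB, smat = oracle_blosum62x,
                            gapOpen = 11, gapExt = 1) {
  ga <- strsplit(alignedA, "", fixed = TRUE)[[1]]
  gb <- strsplit(alignedB, "", fixed = TRUE)[[1]]
  stopifnot(length(ga) == length(gb))
  s <- 0
  lastA <- lastB <- FALSE
  for (k in seq_along(ga)) {
    if (ga[k] == "-") {
      s <- s - gapExt - if (lastA) 0 else gapOpen
      lastA <- TRUE; lastB <- FALSE
    } else if (gb[k] == "-") {
      s <- s - gapExt - if (lastB) 0 else gapOpen
      lastB <- TRUE; lastA <- FALSE
    } else {
      s <- s + smat[ga[k], gb[k]]
      lastA <- lastB <- FALSE
    }
  }
  s
}

random_protein_pair <- function(maxLen = 8L) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  lens <- sample(seq_len(maxLen), 2L, replace = TRUE)
  c(paste(sample(aa, lens[1], TRUE), collapse = ""),
    paste(sample(aa, lens[2], TRUE), collapse = ""))
}

## brute-force UPGMA: recompute every inter-cluster average from the
## ORIGINAL distance matrix at each step; same tie rule (lowest index
## pair, merged cluster keeps the lower slot).  Returns the cophenetic
## matrix in full distance units and the merge heights.
bf_upgma <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      avg <- mean(D[clusters[[i]], clusters[[j]]])
      if (avg < best - 1e-12) { best <- avg; bi <- i; bj <- j }
    }
    coph[clusters[[bi]], clusters[[bj]]] <- best
    coph[clusters[[bj]], clusters[[bi]]] <- best
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  list(cophenetic = coph, heights = heights)
}

## random ultrametric distance matrix from random sequential merges
random_ultrametric <- function(n) {
  clusters <- lapply(seq_len(n), identity)
  D <- matrix(0, n, n)
  h <- 0
  while (length(clusters) > 1L) {
    h <- h + stats::runif(1, 0.5, 2)
    pick <- sort(sample(length(clusters), 2L))
    D[clusters[[pick[1]]], clusters[[pick[2]]]] <- h
    D[clusters[[pick[2]]], clusters[[pick[1]]]] <- h
    clusters[[pick[1]]] <- c(clusters[[pick[1]]], clusters[[pick[2]]])
    clusters[[pick[2]]] <- NULL
  }
  dimnames(D) <- list(paste0("L", seq_len(n)), paste0("L", seq_len(n)))
  D
}

## cophenetic matrix (full distance units) of an UpgmaTree
tree_cophenetic <- function(tree) {
  ph <- tree@phylo
  m <- ape::cophenetic.phylo(ph)
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

## point substitutions at a fixed rate, first residue kept
mutate_seq <- function(seq, rate) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_along(ch)[-1]) {
    if (stats::runif(1) < rate) ch[i] <- sample(setdiff(aa, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

random_seq <- function(len) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(c("M", sample(aa, len - 1L, TRUE)), collapse = "")
}

## a small, quick cohort configuration for unit tests (short backbone;
## compositional criteria are exercised on full-size cohorts elsewhere)
small_config <- function(seed, ...) {
  fgiSimConfig(seed = seed, hostLength = 12000L, ...)
}
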