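test_that("pearsonSimilarity reproduces hand-computed correlations", {
  m <- rbind(s1 = c(1, 0, 1, 1), s2 = c(1, 0, 1, 1))
  expect_equal(unname(pearsonSimilarity(m)[1, 2]), 100)
  m2 <- rbind(s1 = c(1, 0, 1, 0), s2 = c(0, 1, 0, 1))
  expect_equal(unname(pearsonSimilarity(m2)[1, 2]), -100)
  m3 <- rbind(s1 = c(1, 1, 0, 0), s2 = c(1, 0, 1, 0))
  expect_equal(unname(pearsonSimilarity(m3)[1, 2]), 0)  # phi = 0
  ## zero-variance profiles: identical -> 100, otherwise 0
  m4 <- rbind(s1 = c(1, 1, 1), s2 = c(1, 1, 1), s3 = c(1, 0, 1))
  s <- pearsonSimilarity(m4)
  expect_equal(unname(s[1, 2]), 100)
  expect_equal(unname(s[1, 3]), 0)
  expect_error(pearsonSimilarity(m[1, , drop = FALSE]), "two strains")
})

test_that("upgma reproduces hand-worked dendrograms and Newick output", {
  d2 <- matrix(c(0, 10, 10, 0), 2, 2, dimnames = list(c("A", "B"),
                                                      c("A", "B")))
  t2 <- upgma(d2, isDistance = TRUE)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(t2, f)
  expect_equal(readLines(f), "(A:5,B:5);")

  d3 <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3, isDistance = TRUE)
  writeNewick(t3, f)
  expect_equal(readLines(f), "((A:1,B:1):3,C:4);")
  expect_equal(t3@hclust$height, c(2, 8))
})

test_that("upgma matches the from-scratch oracle on random matrices", {
  set.seed(303)
  for (k in 1:30) {
    n <- sample(3:7, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2, 1, 100)
    D <- D + t(D)
    dimnames(D) <- list(paste0("L", 1:n), paste0("L", 1:n))
    tr <- upgma(D, isDistance = TRUE)
    oracle <- bf_upgma(D)
    expect_equal(tree_cophenetic(tr), oracle$cophenetic[order(rownames(D)),
                                                       order(rownames(D))],
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(sort(tr@hclust$height), sort(oracle$heights),
                 tolerance = 1e-9)
  }
})

test_that("upgma agrees with hclust average linkage on tie-free input", {
  set.seed(404)
  n <- 6
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2, 1, 100)
  D <- D + t(D)
  dimnames(D) <- list(paste0("L", 1:n), paste0("L", 1:n))
  tr <- upgma(D, isDistance = TRUE)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  expect_equal(sort(tr@hclust$height), sort(hc$height), tolerance = 1e-9)
  expect_equal(stats::cutree(tr@hclust, k = 3)[hc$labels],
               stats::cutree(tr@hclust, k = 3)[hc$labels])
  co <- stats::cophenetic(hc)
  expect_equal(tree_cophenetic(tr),
               as.matrix(co)[sort(rownames(D)), sort(rownames(D))],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("upgma reproduces ultrametric inputs exactly", {
  set.seed(505)
  for (k in 1:10) {
    n <- sample(3:7, 1)
    D <- random_ultrametric(n)
    tr <- upgma(D, isDistance = TRUE)
    expect_equal(tree_cophenetic(tr), D[order(rownames(D)),
                                        order(rownames(D))],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("upgma rejects asymmetric input and single leaves", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(upgma(bad, isDistance = TRUE), "symmetric")
  expect_error(upgma(matrix(0, 1, 1), isDistance = TRUE), "two leaves")
})

test_that("assignTypes partitions at the similarity cutoff", {
  ## two blocks of identical profiles, dissimilar across blocks
  m <- rbind(a1 = c(1, 1, 1, 0, 0, 0), a2 = c(1, 1, 1, 0, 0, 0),
             a3 = c(1, 1, 1, 0, 0, 0), a4 = c(1, 1, 1, 0, 0, 0),
             b1 = c(0, 0, 0, 1, 1, 1), b2 = c(0, 0, 0, 1, 1, 1))
  s <- pearsonSimilarity(m)
  expect_lt(s["a1", "b1"], 50)
  ty <- assignTypes(upgma(s), 50, s)
  expect_equal(nTypes(ty), 2L)
  ## labels by decreasing size: the 4-strain block is type I
  expect_equal(unname(typeOf(ty)[c("a1", "b1")]), c("I", "II"))
  expect_equal(unname(table(typeOf(ty))[["I"]]), 4L)

  ## all profiles identical: a single type
  m1 <- matrix(1, 3, 4, dimnames = list(c("x", "y", "z"), NULL))
  s1 <- pearsonSimilarity(m1)
  ty1 <- assignTypes(upgma(s1), 50)
  expect_equal(nTypes(ty1), 1L)
})

test_that("raising the cutoff never decreases the number of types", {
  set.seed(606)
  n <- 8
  m <- matrix(rbinom(n * 12, 1, 0.5), n, 12,
              dimnames = list(paste0("s", 1:n), NULL))
  s <- pearsonSimilarity(m)
  tr <- upgma(s)
  nt <- vapply(c(-50, 0, 25, 50, 75, 95),
               function(ct) nTypes(assignTypes(tr, ct)), 0L)
  expect_true(all(diff(nt) >= 0))
})

test_that("the type partition is invariant to strain order", {
  set.seed(707)
  prof <- rbind(matrix(rep(c(1, 1, 0, 0, 1, 0), 3), 3, byrow = TRUE),
                matrix(rep(c(0, 0, 1, 1, 0, 1), 2), 2, byrow = TRUE))
  rownames(prof) <- paste0("s", 1:5)
  perm <- sample(5)
  ty1 <- assignTypes(upgma(pearsonSimilarity(prof)), 50)
  ty2 <- assignTypes(upgma(pearsonSimilarity(prof[perm, ])), 50)
  expect_equal(typeOf(ty1)[rownames(prof)], typeOf(ty2)[rownames(prof)])
})

test_that("Newick output round-trips topology and heights", {
  set.seed(808)
  for (k in 1:10) {
    n <- sample(3:8, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2, 1, 100)
    D <- D + t(D)
    dimnames(D) <- list(paste0("L", 1:n), paste0("L", 1:n))
    tr <- upgma(D, isDistance = TRUE)
    f <- withr::local_tempfile(fileext = ".nwk")
    writeNewick(tr, f)
    ph <- readNewick(f)
    co <- ape::cophenetic.phylo(ph)
    expect_equal(co[sort(rownames(co)), sort(rownames(co))],
                 tree_cophenetic(tr), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})
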