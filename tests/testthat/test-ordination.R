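test_that("similarity transforms to distance and rejects bad input", {
  S <- matrix(c(1, 0.6, 0.6, 1), 2, 2,
              dimnames = list(c("m1", "m2"), c("m1", "m2")))
  D <- similarity_to_distance(S)
  expect_equal(D["m1", "m2"], 0.4)
  expect_true(all(diag(D) == 0))
  Ds <- similarity_to_distance(S, transform = "sqrt")
  expect_equal(Ds["m1", "m2"], sqrt(0.4))

  ones <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(similarity_to_distance(ones) == 0))

  bad <- S; bad[1, 2] <- bad[2, 1] <- 1.4
  expect_error(similarity_to_distance(bad), class = "input_error")
})

test_that("PCoA recovers planar configurations to 1e-8", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4), c(1, 1))
  rownames(pts) <- sprintf("p%d", 1:4)
  D <- as.matrix(dist(pts))
  res <- pcoa(D)
  expect_s3_class(res, "pcoa_result")
  rec <- as.matrix(dist(res$points))
  expect_lt(max(abs(rec - D)), 1e-8)
  ## spectral identity: eigenvalue sum = trace of the Gower-centred matrix
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  expect_equal(sum(res$eigenvalues), sum(diag(B)), tolerance = 1e-10)
  ## proportions over the positive spectrum sum to one, descending axes
  expect_equal(sum(res$proportion_explained), 1)
  expect_true(all(diff(res$positive_eigenvalues) <= 1e-12))
  ## cross-check against an independent implementation
  ref <- ape::pcoa(D)
  expect_equal(sort(abs(res$points[, 1])),
               sort(abs(ref$vectors[, 1])), tolerance = 1e-8)
})

test_that("degenerate and invalid ordinations are handled", {
  Dz <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  res <- pcoa(Dz)
  expect_equal(ncol(res$points), 0L)
  expect_true(all(abs(res$eigenvalues) < 1e-12))

  D2 <- dist_fixture(c("a", "b"), 0.3)
  expect_error(pcoa(D2), class = "ordination_error")
})

test_that("eigen-sum/trace identity holds on random symmetric matrices", {
  set.seed(181)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    D <- dist_fixture(sprintf("x%d", seq_len(n)),
                      runif(n * (n - 1) / 2, 0, 1))
    res <- pcoa(D)
    J <- diag(n) - matrix(1 / n, n, n)
    B <- -0.5 * J %*% (D^2) %*% J
    expect_equal(sum(res$eigenvalues), sum(diag(B)), tolerance = 1e-9)
  }
})

test_that("PCoA is invariant to point order up to axis sign", {
  set.seed(191)
  D <- dist_fixture(sprintf("m%d", 1:5), runif(10, 0.1, 0.9))
  r1 <- pcoa(D)
  perm <- sample(rownames(D))
  r2 <- pcoa(D[perm, perm])
  expect_equal(r1$eigenvalues, r2$eigenvalues, tolerance = 1e-9)
  d1 <- as.matrix(dist(r1$points))
  d2 <- as.matrix(dist(r2$points))[rownames(d1), colnames(d1)]
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("method ordination separates identical-partition pairs", {
  p1 <- as_partition(c(a = "1", b = "1", c = "2", d = "2"))
  p2 <- p1
  p3 <- as_partition(c(a = "x", b = "y", c = "y", d = "z"))
  p4 <- p3
  res <- ordinate_methods(list(A = p1, B = p2, C = p3, D = p4))
  expect_equal(nrow(res$points), 4L)
  ## coincident pairs, separated on axis 1
  expect_equal(res$points["A", 1], res$points["B", 1])
  expect_equal(res$points["C", 1], res$points["D", 1])
  expect_gt(abs(res$points["A", 1] - res$points["C", 1]), 0)

  ## identical partitions everywhere collapse to the origin
  res0 <- ordinate_methods(list(A = p1, B = p1, C = p1))
  expect_equal(ncol(res0$points), 0L)

  ## full-dimensional distances preserve the 1 - s ordering
  set.seed(201)
  ids <- sprintf("s%d", 1:8)
  parts <- lapply(1:5, function(i) random_partition(ids, 3))
  names(parts) <- sprintf("m%d", 1:5)
  S <- pairwise_similarity(parts)
  ord <- ordinate_methods(parts)
  if (ncol(ord$points) > 0 && ord$negative_magnitude < 1e-12) {
    emb <- as.matrix(dist(ord$points))
    for (i in 1:4) for (j in (i + 1):5)
      expect_equal(emb[i, j], 1 - S[i, j], tolerance = 1e-6)
  }
})
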