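test_that("Pearson distances behave at the extremes and match the textbook formula", {
  v <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  rownames(v) <- sprintf("g%d", 1:4)
  d <- pearson_distance_matrix(v)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  withr::with_seed(81, {
    for (i in 1:20) {
      x <- rnorm(50); y <- rnorm(50)
      m <- cbind(s1 = x, s2 = y)
      rownames(m) <- sprintf("g%02d", 1:50)
      expect_equal(pearson_distance_matrix(m)["s1", "s2"],
                   1 - oracle_pearson(x, y), tolerance = 1e-10)
    }
  })
  vz <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  rownames(vz) <- sprintf("g%d", 1:3)
  expect_error(pearson_distance_matrix(vz), "zero-variance sample\\(s\\): a")
})

test_that("complete linkage follows the max-rule on a hand-traced case", {
  d <- matrix(c(0, 1, 5,
                1, 0, 6,
                5, 6, 0), 3, 3, dimnames = list(c("p1", "p2", "p3"),
                                                c("p1", "p2", "p3")))
  hc <- hclust_complete(d)
  expect_equal(sort(hc$height), c(1, 6))  # {p1,p2} at 1, then join p3 at max(5,6)
  first <- hc$merge[1, ]
  expect_setequal(first, c(-1, -2))
  # n = 2: a single merge at the pairwise distance
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  hc2 <- hclust_complete(d2)
  expect_equal(hc2$height, 0.3)
  asym <- d; asym[1, 3] <- 99
  expect_error(hclust_complete(asym), "symmetric")
})

test_that("trees equal brute-force agglomeration for small n", {
  withr::with_seed(82, {
    for (n in 4:8) {
      for (rep in 1:4) {
        x <- matrix(rnorm(n * 5), 5, n,
                    dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:n)))
        d <- as.matrix(dist(t(x)))
        hc <- hclust_complete(d)
        expect_equal(as.matrix(cophenetic(hc))[colnames(d), colnames(d)],
                     oracle_complete_linkage_cophenetic(d), tolerance = 1e-12)
      }
    }
  })
})

test_that("complete-linkage merge heights are non-decreasing", {
  withr::with_seed(83, {
    for (i in 1:1000) {
      x <- matrix(rnorm(6 * 4), 4, 6)
      colnames(x) <- sprintf("s%d", 1:6)
      hc <- hclust_complete(as.matrix(dist(t(x))))
      expect_true(all(diff(hc$height) >= -1e-12))
    }
  })
})

test_that("PCA recovers exact low-rank structure and matches the eigen oracle", {
  # samples on an exact line: one component carries all variance
  t_ <- seq(-2, 2, length.out = 6)
  line <- outer(c(1, 2, -1, 0.5), t_)
  dimnames(line) <- list(sprintf("g%d", 1:4), sprintf("s%d", 1:6))
  p <- pca_samples(line, n_components = 2)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-9)

  m <- rand_expr_matrix(40, 8, seed = 84)
  p <- pca_samples(m, n_components = 3)
  # oracle: eigendecomposition of the sample covariance of centered samples
  xc <- t(scale(t(unclass(m)), center = TRUE, scale = FALSE))
  ev <- eigen(cov(t(xc)))
  expect_equal(p$explained_variance,
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-8)
  for (k in 1:3)
    expect_equal(abs(ev$vectors[, k]), abs(unname(p$loadings[, k])),
                 tolerance = 1e-8)
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # gene reordering permutes loadings but leaves scores intact (up to sign)
  perm <- withr::with_seed(85, sample(nrow(m)))
  p2 <- pca_samples(m[perm, ], n_components = 3)
  for (k in 1:3)
    expect_equal(abs(p2$scores[, k]), abs(p$scores[, k]), tolerance = 1e-8)
  expect_error(pca_samples(m, n_components = 8), "n_components")
})

test_that("lineage assignment votes among the query's nearest subtree", {
  # query identical to an mDC sample joins the myeloid branch at height ~0
  v <- cbind(mdc1 = c(5, 1, 2, 8), mdc2 = c(5.1, 1.1, 2, 8),
             pdc1 = c(1, 6, 7, 2), pdc2 = c(1.2, 6, 7, 2.2))
  v <- v + 0
  rownames(v) <- sprintf("g%d", 1:4)
  q <- v[, "mdc1", drop = FALSE] + 0.01
  colnames(q) <- "query"
  m <- cbind(v, q)
  d <- pearson_distance_matrix(m)
  hc <- hclust_complete(d)
  labels <- c(mdc1 = "myeloid", mdc2 = "myeloid", pdc1 = "pDC", pdc2 = "pDC")
  res <- assign_lineage(hc, "query", labels, d)
  expect_equal(res$branch, "myeloid")
  expect_true(all(res$sibling_samples %in% c("mdc1", "mdc2")))
  # two-sample tree: assigned the other sample's branch
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("q", "ref"), c("q", "ref")))
  res2 <- assign_lineage(hclust_complete(d2), "q", c(ref = "lymphoid"), d2)
  expect_equal(res2$branch, "lymphoid")
  expect_error(assign_lineage(hc, "nope", labels), "not in the dendrogram")
})

test_that("assignment walks past unlabelled siblings", {
  # two near-identical queries merge with each other first; the vote must
  # come from the next merge up
  v <- cbind(mdc1 = c(5, 1, 2, 8), mdc2 = c(5.1, 1.1, 2, 8),
             pdc1 = c(1, 6, 7, 2), pdc2 = c(1.2, 6, 7, 2.2),
             qA = c(5.05, 1.02, 2.1, 7.9), qB = c(5.06, 1.03, 2.1, 7.9))
  rownames(v) <- sprintf("g%d", 1:4)
  d <- pearson_distance_matrix(v)
  hc <- hclust_complete(d)
  labels <- c(mdc1 = "myeloid", mdc2 = "myeloid", pdc1 = "pDC", pdc2 = "pDC")
  res <- assign_lineage(hc, "qA", labels, d)
  expect_equal(res$branch, "myeloid")
})

test_that("gene-wise z-scoring centers, scales, and zeroes flat genes", {
  m <- rand_expr_matrix(30, 5, seed = 86)
  mm <- unclass(m)
  mm[3, ] <- 7  # constant gene
  z <- zscore_genes(mm)
  expect_equal(unname(rowMeans(z)), rep(0, 30), tolerance = 1e-12)
  expect_equal(unname(apply(z[-3, ], 1, sd)), rep(1, 29), tolerance = 1e-12)
  expect_equal(unname(z[3, ]), rep(0, 5))
})
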