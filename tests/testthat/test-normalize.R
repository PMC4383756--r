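test_that("rank-invariant selection keeps genes with stable ranks", {
  withr::with_seed(1, x <- rnorm(500, 7, 1.5))
  names(x) <- sprintf("g%03d", seq_along(x))
  # identical vectors: everything survives in one round
  ri <- rank_invariant_genes(x, x)
  expect_length(ri$genes, 500)
  expect_equal(ri$iterations_used, 1L)
  expect_true(ri$converged)
  # a monotone transform preserves all ranks
  ri <- rank_invariant_genes(2^x, x + 100)
  expect_length(ri$genes, 500)
  expect_error(rank_invariant_genes(x[1:5], x[1:5]), "at least 10")
  expect_error(rank_invariant_genes(x, rev(x), rank_tol = 0.001), "rank_tol")
})

test_that("rank-invariant selection separates permuted from stable genes", {
  kept_stable <- c(); kept_perm <- c()
  for (seed in 201:220) {
    withr::with_seed(seed, {
      ref <- rnorm(1000, 7, 1.5)
      names(ref) <- sprintf("g%04d", 1:1000)
      target <- ref
      perm <- sample(1000, 100)
      target[perm] <- target[sample(perm)]
    })
    ri <- rank_invariant_genes(target, ref, rank_tol = 0.05)
    kept_stable <- c(kept_stable, mean(names(ref)[-perm] %in% ri$genes))
    kept_perm <- c(kept_perm, mean(names(ref)[perm] %in% ri$genes))
  }
  expect_gte(mean(kept_stable), 0.8)
  expect_lte(mean(kept_perm), 0.2)
})

test_that("selection is symmetric in target and reference", {
  withr::with_seed(33, {
    a <- rnorm(300); b <- a + rnorm(300, 0, 0.5)
    names(a) <- names(b) <- sprintf("g%03d", 1:300)
  })
  expect_setequal(rank_invariant_genes(a, b)$genes,
                  rank_invariant_genes(b, a)$genes)
})

test_that("normalization recovers an additive shift and is monotone", {
  withr::with_seed(7, ref <- rnorm(2000, 7, 1.5))
  names(ref) <- sprintf("g%04d", seq_along(ref))
  shifted <- ref + 1.5
  nf <- normalize_to_reference(shifted, ref)
  expect_lt(max(abs(nf$normalized - ref)), 0.05)
  # identity on the reference itself
  nf0 <- normalize_to_reference(ref, ref)
  expect_lt(max(abs(nf0$normalized - ref)), 1e-6)
  # knots are monotone in both coordinates and the map preserves order
  k <- nf$fit$mapping_knots
  expect_true(all(diff(k$target_value) > 0))
  expect_true(all(diff(k$reference_value) >= 0))
  withr::with_seed(8, y <- rnorm(2000, 5, 2))
  names(y) <- names(ref)
  nfy <- normalize_to_reference(y, ref)
  expect_true(all(diff(nfy$normalized[order(y)]) >= -1e-12))
  expect_error(normalize_to_reference(rep(1, 20), rep(1, 20) ,
                                      invariant_genes = as.character(1:20)),
               "2 knots")
})

test_that("merging platforms with no offset is a near-identity", {
  # samples sharing a gene-wise baseline (replicate-like panel, no platform
  # distortion): normalization should change nothing beyond curve noise,
  # and the duplicate of the reference sample must come back exactly
  withr::with_seed(10, {
    base <- rnorm(400, 7, 1.5)
    v <- base + matrix(rnorm(400 * 4, 0, 0.1), 400, 4)
    dimnames(v) <- list(sprintf("g%04d", 1:400), sprintf("s%02d", 1:4))
  })
  arr <- expr_matrix(v, unit = "log2_intensity", platform = "array")
  rn <- expr_matrix(v, unit = "log2_rpkm", platform = "rnaseq")
  colnames(rn) <- paste0("q_", colnames(rn))
  m <- merge_platforms(rn, arr)
  expect_equal(nrow(m$matrix), 400L)
  expect_equal(em_unit(m$matrix), "normalized")
  dup_ref <- paste0("q_", m$reference_sample)
  expect_lt(max(abs(unclass(m$matrix)[, dup_ref] -
                      unclass(arr)[, m$reference_sample])), 1e-6)
  for (j in colnames(rn))
    expect_lt(median(abs(unclass(m$matrix)[, j] -
                           unclass(rn)[, j])), 0.1)
  # normalization never reorders a sample
  inputs <- cbind(unclass(rn), unclass(arr))
  for (j in colnames(m$matrix)) {
    x <- unclass(m$matrix)[, j]
    expect_true(all(diff(x[order(inputs[, j])]) >= -1e-12))
  }
  # shared genes are the intersection
  rn2 <- rn[1:250, ]
  m2 <- merge_platforms(rn2, arr)
  expect_equal(nrow(m2$matrix), 250L)
  expect_error(merge_platforms(rn2[0, ], arr), "shared genes")
})

test_that("normalization reference sample is passed through untouched", {
  arr <- rand_expr_matrix(300, 5, seed = 44)
  rn <- expr_matrix(unclass(arr)[, 1:2] + 2, unit = "log2_rpkm",
                    platform = "rnaseq")
  colnames(rn) <- c("q1", "q2")
  m <- merge_platforms(rn, arr)
  expect_true(m$reference_sample %in% colnames(arr))
  expect_equal(unclass(m$matrix)[, m$reference_sample],
               unclass(arr)[, m$reference_sample])
  expect_equal(unname(m$platforms[c("q1", "s01")]), c("rnaseq", "array"))
})

test_that("cross-platform normalization raises within-population correlation", {
  gains <- c()
  for (seed in 221:240) {
    cfg <- small_sim_config(seed = seed)
    arr <- simulate_reference_arrays(cfg)
    sim <- simulate_query_rnaseq(cfg)
    q <- quantify_reads(sim$reads, sim$gene_models)
    logq <- log_transform(q$rpkm)
    shared <- intersect(rownames(logq), rownames(arr$matrix))
    pdc <- arr$meta$sample_id[arr$meta$population == "pDC"]
    before <- mean(cor(unclass(logq)[shared, "CD56neg_1"],
                       unclass(arr$matrix)[shared, pdc]))
    m <- merge_platforms(logq, arr$matrix)
    after <- mean(cor(unclass(m$matrix)[, "CD56neg_1"],
                      unclass(m$matrix)[, pdc]))
    gains <- c(gains, after - before)
  }
  expect_gt(mean(gains), 0)
})
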