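test_that("generators are pure functions of the config seed", {
  cfg <- small_sim_config(seed = 21)
  a1 <- simulate_reference_arrays(cfg)
  a2 <- simulate_reference_arrays(cfg)
  expect_identical(unclass(a1$matrix)[, ], unclass(a2$matrix)[, ])
  q1 <- simulate_query_rnaseq(cfg)
  q2 <- simulate_query_rnaseq(cfg)
  expect_identical(q1$reads, q2$reads)
  expect_identical(unclass(q1$counts)[, ], unclass(q2$counts)[, ])
  b1 <- simulate_bpdcn_arrays(cfg)
  b2 <- simulate_bpdcn_arrays(cfg)
  expect_identical(unclass(b1$matrix)[, ], unclass(b2$matrix)[, ])
  # a different seed changes the data
  a3 <- simulate_reference_arrays(small_sim_config(seed = 22))
  expect_false(identical(unclass(a1$matrix)[, ], unclass(a3$matrix)[, ]))
})

test_that("noise-free arrays give identical replicates", {
  cfg <- small_sim_config(seed = 3, array_noise_sd = 0)
  arr <- simulate_reference_arrays(cfg)
  pdc <- arr$meta$sample_id[arr$meta$population == "pDC"]
  expect_equal(unclass(arr$matrix)[, pdc[1]], unclass(arr$matrix)[, pdc[2]])
  bp <- simulate_bpdcn_arrays(cfg)
  expect_equal(ncol(bp$matrix), 6L)
  for (j in 2:6) expect_equal(unclass(bp$matrix)[, 1], unclass(bp$matrix)[, j],
                              ignore_attr = TRUE)
})

test_that("within-branch correlation exceeds between-branch correlation", {
  within <- c(); between <- c()
  for (seed in 101:120) {
    arr <- simulate_reference_arrays(small_sim_config(seed = seed))
    v <- unclass(arr$matrix)
    br <- dclineage:::branch_of(arr$meta$population, default_lineage_tree())
    r <- cor(v)
    same <- outer(br, br, "==") & upper.tri(r)
    diff <- outer(br, br, "!=") & upper.tri(r)
    within <- c(within, r[same])
    between <- c(between, r[diff])
  }
  expect_gt(mean(within), mean(between))
})

test_that("read counts approach Poisson as dispersion vanishes", {
  ratios <- c()
  for (seed in 131:133) {
    cfg <- sim_config(n_genes = 200L, module_sizes = c(pdc = 15L, mdc = 15L),
                      n_de_up = 30L, n_de_down = 30L, library_size = 40000L,
                      seq_dispersion = 1e-8, seed = seed)
    sim <- simulate_query_rnaseq(cfg)
    mu <- dclineage:::expected_counts(cfg)$CD56neg_1
    x <- unclass(sim$counts)[names(mu), "CD56neg_1"]
    ratios <- c(ratios, (x - mu)^2 / mu)
  }
  expect_gt(mean(ratios), 0.8)
  expect_lt(mean(ratios), 1.3)
})

test_that("overdispersed counts exceed Poisson variance", {
  ratios <- c()
  for (seed in 141:143) {
    cfg <- sim_config(n_genes = 200L, module_sizes = c(pdc = 15L, mdc = 15L),
                      n_de_up = 30L, n_de_down = 30L, library_size = 40000L,
                      seq_dispersion = 0.2, seed = seed)
    sim <- simulate_query_rnaseq(cfg)
    mu <- dclineage:::expected_counts(cfg)$CD56neg_1
    x <- unclass(sim$counts)[names(mu), "CD56neg_1"]
    ratios <- c(ratios, (x - mu)^2 / mu)
  }
  expect_gt(mean(ratios), 2)
})

test_that("all reads fall outside probe regions when frac_reads_off_probe is 1", {
  cfg <- small_sim_config(seed = 8, frac_reads_off_probe = 1)
  sim <- simulate_query_rnaseq(cfg)
  q <- quantify_reads(sim$reads, sim$gene_models, restrict_to_probes = TRUE)
  expect_true(all(q$counts == 0L))
  # the same reads do land in exons
  q2 <- quantify_reads(sim$reads, sim$gene_models, restrict_to_probes = FALSE)
  expect_gt(sum(q2$counts), 0L)
})

test_that("BPDCN tracks the planted CD56+ profile, not the pDC profile", {
  for (seed in 151:170) {
    cfg <- small_sim_config(seed = seed)
    sc <- dclineage:::sim_scenario(cfg)
    bp <- rowMeans(unclass(simulate_bpdcn_arrays(cfg)$matrix))
    expect_gt(cor(bp, sc$cd56pos), cor(bp, sc$cd56neg))
  }
})

test_that("planted truth is internally consistent", {
  cfg <- small_sim_config(seed = 12, planted_concordance = 0.6)
  sim <- simulate_query_rnaseq(cfg)
  tr <- sim$truth
  expect_length(intersect(tr$de_up_genes, tr$de_down_genes), 0)
  fr_up <- mean(tr$concordant_flags[tr$de_up_genes])
  fr_down <- mean(tr$concordant_flags[tr$de_down_genes])
  expect_lt(abs(fr_up - 0.6), 1 / length(tr$de_up_genes) + 1e-9)
  expect_lt(abs(fr_down - 0.6), 1 / length(tr$de_down_genes) + 1e-9)
  expect_error(simulate_query_rnaseq(small_sim_config(seed = 1, library_size = 100L)),
               "library_size")
})

test_that("simulation artifacts round-trip through disk", {
  cfg <- sim_config(n_genes = 60L, module_sizes = c(pdc = 5L, mdc = 5L),
                    n_de_up = 10L, n_de_down = 10L, library_size = 6000L,
                    seed = 4)
  sim <- simulate_query_rnaseq(cfg)
  arr <- simulate_reference_arrays(cfg)
  outdir <- withr::local_tempdir()
  paths <- write_simulation(sim, arr, outdir)
  expect_true(all(file.exists(paths)))
  counts <- read_matrix(paths[["counts"]], unit = "count", platform = "rnaseq")
  expect_equal(unclass(counts)[, ], unclass(sim$counts)[, ])
  reads <- read_bed(paths[["reads_CD56neg_1"]])
  expect_equal(nrow(reads), nrow(sim$reads$CD56neg_1))
  exons <- read_bed(paths[["exons"]])
  expect_equal(sort(unique(exons$name)), sort(names(sim$gene_models)))
})
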