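test_that("counting_region restricts merged exons to probe targets", {
  gm <- gene_model("G1", exons = genomic_intervals("chr1", 0, 100),
                   probe_regions = genomic_intervals("chr1", 50, 150))
  r <- counting_region(gm, restrict_to_probes = TRUE)
  expect_equal(cbind(r$start, r$end), cbind(50L, 100L))
  r <- counting_region(gm, restrict_to_probes = FALSE)
  expect_equal(cbind(r$start, r$end), cbind(0L, 100L))
  gm2 <- gene_model("G2", exons = genomic_intervals("chr1", 0, 100),
                    probe_regions = genomic_intervals("chr1", 200, 300))
  expect_equal(nrow(counting_region(gm2, TRUE)), 0L)
  gm3 <- gene_model("G3", exons = genomic_intervals("chr1", 0, 100))
  expect_equal(nrow(counting_region(gm3, TRUE)), 0L)
})

test_that("count_reads honours the one-base-overlap half-open rule", {
  region <- genomic_intervals("chr1", 50, 100)
  rd <- function(s, e, chrom = "chr1", uniq = TRUE) {
    data.frame(read_id = "r", chrom = chrom, start = s, end = e, strand = "+",
               uniquely_mapped = uniq, stringsAsFactors = FALSE)
  }
  expect_equal(count_reads(rd(95, 105), region), 1L)   # 5-base overlap
  expect_equal(count_reads(rd(100, 110), region), 0L)  # zero overlap at boundary
  expect_equal(count_reads(rd(45, 51), region), 1L)    # 1-base overlap
  expect_equal(count_reads(rd(45, 50), region), 0L)
  expect_equal(count_reads(rd(60, 70, chrom = "chr2"), region), 0L)
  expect_equal(count_reads(rd(60, 70, uniq = FALSE), region), 0L)
  # a read spanning two region intervals is counted once
  two <- genomic_intervals("chr1", c(0, 80), c(60, 120))
  expect_equal(count_reads(rd(50, 90), two), 1L)
})

test_that("read counting matches the per-base brute-force oracle", {
  withr::with_seed(77, {
    for (rep in 1:5) {
      k <- sample(2:4, 1)
      s <- sort(sample(0:900, k))
      region <- merge_intervals(genomic_intervals("chr1", s, s + sample(20:120, k,
                                                                        replace = TRUE)))
      n <- 200
      rs <- sample(0:1000, n, replace = TRUE)
      reads <- data.frame(read_id = sprintf("r%03d", 1:n),
                          chrom = sample(c("chr1", "chr2"), n, TRUE, c(.9, .1)),
                          start = rs, end = rs + sample(10:60, n, TRUE),
                          strand = "+",
                          uniquely_mapped = runif(n) < 0.9,
                          stringsAsFactors = FALSE)
      expect_equal(count_reads(reads, region), oracle_count_reads(reads, region))
    }
  })
})

test_that("rpkm follows its defining arithmetic and invariances", {
  expect_equal(unname(rpkm(data.frame(gene_id = "g", count = 100,
                                      effective_length_bp = 1000), 1e6)), 100)
  expect_equal(unname(rpkm(data.frame(gene_id = "g", count = 250,
                                      effective_length_bp = 2500), 5e6)), 20)
  df <- data.frame(gene_id = c("a", "b"), count = c(10, 30),
                   effective_length_bp = c(500, 1500))
  base <- rpkm(df, 2e6)
  df2 <- df; df2$count <- df2$count * 2
  expect_equal(rpkm(df2, 4e6), base)            # library-scaling invariance
  df3 <- df; df3$count <- df3$count * 3
  expect_equal(rpkm(df3, 2e6), base * 3)        # linear in counts
  dfz <- rbind(df, data.frame(gene_id = "z", count = 5, effective_length_bp = 0))
  expect_message(rz <- rpkm(dfz, 2e6), "missing")
  expect_named(rz, c("a", "b"))                 # missing, not zero
  expect_error(rpkm(df, 0), "total_mapped_reads")
})

test_that("probe restriction never increases counts and lengths are consistent", {
  cfg <- small_sim_config(seed = 31)
  sim <- simulate_query_rnaseq(cfg)
  qr <- quantify_reads(sim$reads, sim$gene_models, restrict_to_probes = TRUE)
  qf <- quantify_reads(sim$reads, sim$gene_models, restrict_to_probes = FALSE)
  shared <- intersect(rownames(qr$counts), rownames(qf$counts))
  expect_true(all(qr$counts[shared, ] <= qf$counts[shared, ]))
  # restricted effective length equals the exon-probe intersection per gene
  gm <- sim$gene_models[[shared[1]]]
  reg <- counting_region(gm, restrict_to_probes = TRUE)
  expect_equal(unname(qr$effective_length[gm$gene_id]),
               as.integer(total_bases(reg)))
  ex <- counting_region(gm, restrict_to_probes = FALSE)
  expect_equal(unname(qf$effective_length[gm$gene_id]),
               as.integer(total_bases(ex)))
  # totals are pre-restriction uniquely mapped read counts in both modes
  expect_equal(qr$total_mapped_reads, qf$total_mapped_reads)
  expect_equal(unname(qr$total_mapped_reads["CD56neg_1"]),
               sum(sim$reads$CD56neg_1$uniquely_mapped))
})

test_that("bulk quantification agrees with per-gene count_reads", {
  cfg <- sim_config(n_genes = 40L, module_sizes = c(pdc = 4L, mdc = 4L),
                    n_de_up = 6L, n_de_down = 6L, library_size = 4000L, seed = 19)
  sim <- simulate_query_rnaseq(cfg)
  q <- quantify_reads(sim$reads, sim$gene_models, restrict_to_probes = TRUE)
  for (g in sample(rownames(q$counts), 8)) {
    reg <- counting_region(sim$gene_models[[g]], restrict_to_probes = TRUE)
    expect_equal(q$counts[g, "CD56pos_1"],
                 count_reads(sim$reads$CD56pos_1, reg),
                 ignore_attr = TRUE)
  }
})
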