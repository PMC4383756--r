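# Synthetic two-platform data with planted ground truth.
#
# The generator emulates the study design the pipeline is built for: a
# reference panel of immune lineages on a microarray platform, a pair of
# query populations on RNA-seq (a pDC-like CD56- sample and an mDC-like
# CD56+ sample carrying a pDC-module overlay), and a BPDCN-like tumor panel.
# Everything downstream can then be checked against the planted truth.

.ref_populations <- c("pDC", "BDCA1_mDC", "BDCA3_mDC", "monocyte",
                      "neutrophil", "NK", "B", "T")

#' Default lineage tree of the reference panel
#'
#' Three branches: the pDC branch (plasmacytoid DCs), the myeloid branch
#' (BDCA1/BDCA3 mDCs, monocytes, neutrophils) and the lymphoid branch
#' (NK, B, T cells).
#'
#' @return named list mapping branch -> population labels.
#' @export
default_lineage_tree <- function() {
  list(pDC = "pDC",
       myeloid = c("BDCA1_mDC", "BDCA3_mDC", "monocyte", "neutrophil"),
       lymphoid = c("NK", "B", "T"))
}

#' Default sample panel
#'
#' Two replicates per reference array population, one replicate per RNA-seq
#' query (the CD56- query is a pDC by population; its platform distinguishes
#' it), and six BPDCN tumor arrays.
#'
#' @return data.frame with columns `population`, `platform`, `replicates`,
#'   `role` (`reference`, `query`, `tumor`).
#' @export
default_populations <- function() {
  data.frame(
    population = c(.ref_populations, "pDC", "CD56posDC", "BPDCN"),
    platform = c(rep("array", 8L), "rnaseq", "rnaseq", "array"),
    replicates = c(rep(2L, 8L), 1L, 1L, 6L),
    role = c(rep("reference", 8L), "query", "query", "tumor"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defines the planted structure of a synthetic two-platform dataset. The
#' defaults are the study conditions used throughout the package's
#' validation: log2 effect size 1, array noise SD 0.5, planted concordance
#' 0.75 over differential sets of 400 genes each.
#'
#' @param n_genes number of genes.
#' @param populations sample panel as in [default_populations()].
#' @param lineage_tree branch structure as in [default_lineage_tree()].
#' @param module_sizes named integer vector `c(pdc = ..., mdc = ...)`:
#'   sizes of the pDC-specific and mDC-specific expression modules.
#' @param n_de_up,n_de_down sizes of the planted CD56+ vs CD56- up/down
#'   gene sets.
#' @param effect_size_log2 SD of branch effects and magnitude of planted
#'   differential effects, log2 units (> 0).
#' @param array_noise_sd SD of log-scale array replicate noise (>= 0).
#' @param seq_dispersion negative-binomial overdispersion of read counts
#'   (> 0; values near 0 approach Poisson sampling).
#' @param library_size expected uniquely mapped reads per RNA-seq sample.
#' @param frac_reads_off_probe fraction of reads placed within exons but
#'   outside probe target regions, in `[0, 1]`.
#' @param planted_concordance fraction of each planted differential set
#'   whose reference mDC-vs-pDC direction agrees with the query direction,
#'   in `[0, 1]`.
#' @param overlay_weight weight of the pDC profile in the CD56+ sample's
#'   pDC-module overlay (0.5 = midpoint of the mDC and pDC levels).
#' @param tumor_shift_sd SD of the gene-wise tumor shift shared by all
#'   BPDCN replicates.
#' @param bpdcn_like population the BPDCN profile copies before the tumor
#'   shift: `"CD56posDC"` (default) or `"pDC"` (null configuration).
#' @param read_length simulated read length in bases.
#' @param seed integer root seed; every random draw in the generators flows
#'   from it through fixed stream offsets.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L,
                       populations = default_populations(),
                       lineage_tree = default_lineage_tree(),
                       module_sizes = c(pdc = 100L, mdc = 100L),
                       n_de_up = 400L, n_de_down = 400L,
                       effect_size_log2 = 1,
                       array_noise_sd = 0.5,
                       seq_dispersion = 0.1,
                       library_size = 200000L,
                       frac_reads_off_probe = 0.2,
                       planted_concordance = 0.75,
                       overlay_weight = 0.5,
                       tumor_shift_sd = 0.3,
                       bpdcn_like = c("CD56posDC", "pDC"),
                       read_length = 50L,
                       seed = 1L) {
  bpdcn_like <- match.arg(bpdcn_like)
  cfg <- list(n_genes = as.integer(n_genes), populations = populations,
              lineage_tree = lineage_tree,
              module_sizes = c(pdc = as.integer(module_sizes[["pdc"]]),
                               mdc = as.integer(module_sizes[["mdc"]])),
              n_de_up = as.integer(n_de_up), n_de_down = as.integer(n_de_down),
              effect_size_log2 = effect_size_log2,
              array_noise_sd = array_noise_sd,
              seq_dispersion = seq_dispersion,
              library_size = as.integer(library_size),
              frac_reads_off_probe = frac_reads_off_probe,
              planted_concordance = planted_concordance,
              overlay_weight = overlay_weight,
              tumor_shift_sd = tumor_shift_sd,
              bpdcn_like = bpdcn_like,
              read_length = as.integer(read_length),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 20L) stop_config("n_genes must be at least 20")
    if (sum(module_sizes) + n_de_up + n_de_down > n_genes)
      stop_config("module sizes plus differential set sizes exceed n_genes")
    if (effect_size_log2 <= 0) stop_config("effect_size_log2 must be > 0")
    if (array_noise_sd < 0) stop_config("array_noise_sd must be >= 0")
    if (seq_dispersion <= 0) stop_config("seq_dispersion must be > 0")
    for (p in c("frac_reads_off_probe", "planted_concordance", "overlay_weight"))
      if (cfg[[p]] < 0 || cfg[[p]] > 1)
        stop_config("%s must lie in [0, 1]", p)
    if (any(populations$replicates < 1L))
      stop_config("every population needs at least 1 replicate")
    need <- c("population", "platform", "replicates", "role")
    if (!all(need %in% names(populations)))
      stop_config("populations needs columns: %s", paste(need, collapse = ", "))
  })
  invisible(cfg)
}

branch_of <- function(pops, tree) {
  map <- unlist(lapply(names(tree), function(b) setNames(rep(b, length(tree[[b]])),
                                                         tree[[b]])))
  unname(map[pops])
}

# Saturating microarray response: maps log2 expression onto the log2
# intensity scale with compression at both extremes (slope ~1 mid-range).
array_response <- function(x) 3 + 10 * plogis((x - 7) / 2.5)

# The deterministic heart of the generator: per-gene baselines, branch and
# population effects, module memberships, planted differential sets with
# concordance flags, and the noise-free expression profile of every
# population. Pure function of the config (stream offset 1 of cfg$seed).
sim_scenario <- function(cfg) {
  n <- cfg$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  eff <- cfg$effect_size_log2
  branches <- names(cfg$lineage_tree)
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    baseline <- rnorm(n, mean = 7, sd = 1.5)
    ord <- sample.int(n)
    i_pdc_mod <- ord[seq_len(cfg$module_sizes[["pdc"]])]
    i_mdc_mod <- ord[cfg$module_sizes[["pdc"]] + seq_len(cfg$module_sizes[["mdc"]])]
    off <- sum(cfg$module_sizes)
    i_up <- ord[off + seq_len(cfg$n_de_up)]
    i_down <- ord[off + cfg$n_de_up + seq_len(cfg$n_de_down)]
    i_branch <- ord[-seq_len(off + cfg$n_de_up + cfg$n_de_down)]

    branch_eff <- matrix(0, n, length(branches), dimnames = list(NULL, branches))
    branch_eff[i_branch, ] <- rnorm(length(i_branch) * length(branches), 0, eff)
    pop_eff <- matrix(0, n, length(.ref_populations),
                      dimnames = list(NULL, .ref_populations))
    pop_eff[i_branch, ] <- rnorm(length(i_branch) * length(.ref_populations),
                                 0, eff / 4)

    flags_up <- rep(FALSE, cfg$n_de_up)
    flags_up[sample.int(cfg$n_de_up, round(cfg$planted_concordance * cfg$n_de_up))] <- TRUE
    flags_down <- rep(FALSE, cfg$n_de_down)
    flags_down[sample.int(cfg$n_de_down, round(cfg$planted_concordance * cfg$n_de_down))] <- TRUE

    tumor_shift <- rnorm(n, 0, cfg$tumor_shift_sd)
  })

  ref_profile <- baseline + branch_eff[, branch_of(.ref_populations, cfg$lineage_tree)] +
    pop_eff
  colnames(ref_profile) <- .ref_populations
  ref_profile[i_pdc_mod, "pDC"] <- ref_profile[i_pdc_mod, "pDC"] + 2 * eff
  mdc_cols <- c("BDCA1_mDC", "BDCA3_mDC")
  ref_profile[i_mdc_mod, mdc_cols] <- ref_profile[i_mdc_mod, mdc_cols] + 2 * eff

  # Planted differential genes carry no branch/population structure in the
  # reference; their mDC-vs-pDC sign encodes the concordance flag.
  i_de <- c(i_up, i_down)
  ref_profile[i_de, ] <- baseline[i_de]
  sign_up <- ifelse(flags_up, 1, -1)     # concordant up-gene: higher in mDC
  sign_down <- ifelse(flags_down, -1, 1) # concordant down-gene: lower in mDC
  for (col in mdc_cols) {
    ref_profile[i_up, col] <- baseline[i_up] + sign_up * eff
    ref_profile[i_down, col] <- baseline[i_down] + sign_down * eff
  }
  ref_profile[i_up, "pDC"] <- baseline[i_up] - sign_up * eff
  ref_profile[i_down, "pDC"] <- baseline[i_down] - sign_down * eff

  # Query profiles: CD56- follows the pDC profile; CD56+ follows the mean
  # mDC profile with the pDC module raised to an intermediate overlay level.
  # Planted differential genes sit at baseline +/- the effect in CD56+ and
  # at baseline in CD56-, so the query contrast is exactly +/- eff.
  mdc_mean <- rowMeans(ref_profile[, mdc_cols])
  cd56neg <- ref_profile[, "pDC"]
  cd56neg[i_de] <- baseline[i_de]
  cd56pos <- mdc_mean
  w <- cfg$overlay_weight
  cd56pos[i_pdc_mod] <- (1 - w) * mdc_mean[i_pdc_mod] + w * ref_profile[i_pdc_mod, "pDC"]
  cd56pos[i_up] <- baseline[i_up] + eff
  cd56pos[i_down] <- baseline[i_down] - eff

  # null configuration copies the pDC array population profile exactly
  bpdcn <- if (cfg$bpdcn_like == "CD56posDC") cd56pos else ref_profile[, "pDC"]
  bpdcn <- bpdcn + tumor_shift

  truth <- list(
    planted_lineage = c(CD56posDC = "myeloid", pDC = "pDC"),
    de_up_genes = gene_ids[i_up],
    de_down_genes = gene_ids[i_down],
    concordant_flags = setNames(c(flags_up, flags_down), gene_ids[c(i_up, i_down)]),
    pdc_module_genes = gene_ids[i_pdc_mod],
    mdc_module_genes = gene_ids[i_mdc_mod],
    planted_concordance = cfg$planted_concordance,
    query_replicates_assumed = 1L,
    seed = cfg$seed)

  list(gene_ids = gene_ids, baseline = baseline, ref_profile = ref_profile,
       cd56neg = cd56neg, cd56pos = cd56pos, bpdcn = bpdcn, truth = truth)
}

#' Simulate the reference lineage array panel
#'
#' Draws, for every reference population in the panel, `replicates` array
#' samples around the population's noise-free log2 profile with Gaussian
#' noise of SD `array_noise_sd`. Within-branch profiles share branch
#' effects, so within-branch correlation exceeds between-branch correlation.
#' Deterministic for a fixed config seed.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (an `expr_matrix`, unit `log2_intensity`,
#'   platform `array`), `meta` (a `sample_meta`) and `truth`.
#' @export
simulate_reference_arrays <- function(config) {
  validate_sim_config(config)
  sc <- sim_scenario(config)
  pops <- config$populations
  refs <- pops[pops$role == "reference" & pops$platform == "array", ]
  cols <- list(); ids <- character(); pop_lab <- character()
  for (i in seq_len(nrow(refs))) {
    p <- refs$population[i]
    for (r in seq_len(refs$replicates[i])) {
      sid <- sprintf("%s_a%d", p, r)
      withr::with_seed(derive_seed(config$seed, 100L + 10L * i + r), {
        cols[[sid]] <- array_response(sc$ref_profile[, p]) +
          rnorm(config$n_genes, 0, config$array_noise_sd)
      })
      ids <- c(ids, sid); pop_lab <- c(pop_lab, p)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- sc$gene_ids
  list(matrix = expr_matrix(m, unit = "log2_intensity", platform = "array"),
       meta = sample_meta(ids, pop_lab, "array"),
       truth = sc$truth)
}

# Random exon layout: 1-3 exons per gene laid sequentially on chr1; the
# 3' half of every exon is its probe target region (both halves always
# leave room for a full read).
make_gene_models <- function(n_genes, read_length) {
  ks <- sample(1:3, n_genes, replace = TRUE)
  m <- sum(ks)
  w <- sample(200:800, m, replace = TRUE)
  gaps <- sample(100:500, m, replace = TRUE)
  first <- cumsum(c(1L, ks[-n_genes]))  # index of each gene's first exon
  gaps[first] <- 1000L
  starts <- cumsum(gaps) + c(0L, cumsum(w)[-m])
  gene_idx <- rep.int(seq_len(n_genes), ks)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  exons <- data.frame(gene_id = gene_ids[gene_idx], chrom = "chr1",
                      start = starts, end = starts + w, stringsAsFactors = FALSE)
  probes <- data.frame(gene_id = gene_ids[gene_idx], chrom = "chr1",
                       start = starts + w %/% 2L, end = starts + w,
                       stringsAsFactors = FALSE)
  rows_of <- split(seq_len(m), gene_idx)
  models <- lapply(seq_len(n_genes), function(i) {
    rows <- rows_of[[i]]
    structure(list(
      gene_id = gene_ids[i], symbol = gene_ids[i],
      exons = new_intervals("chr1", exons$start[rows], exons$end[rows],
                            name = gene_ids[i]),
      probe_regions = new_intervals("chr1", probes$start[rows],
                                    probes$end[rows], name = gene_ids[i])),
      class = "gene_model")
  })
  names(models) <- gene_ids
  attr(models, "flattened") <- list(exons = exons, probes = probes)
  models
}

# Per-gene placement slots for on-probe / off-probe read starts, computed
# generically from exon/probe interval algebra (gene id as the "space").
read_placement_segments <- function(flat, read_length) {
  lv <- unique(c(flat$exons$gene_id, flat$probes$gene_id))
  gr <- function(df) GenomicRanges::GRanges(factor(df$gene_id, levels = lv),
                                            IRanges::IRanges(df$start + 1L, df$end))
  ex <- gr(flat$exons)
  pr <- gr(flat$probes)
  seg_table <- function(g) {
    if (length(g) == 0L)
      return(data.frame(gene_id = character(), start = integer(),
                        avail = integer()))
    avail <- IRanges::width(g) - read_length + 1L
    keep <- avail >= 1L
    data.frame(gene_id = as.character(GenomicRanges::seqnames(g))[keep],
               start = GenomicRanges::start(g)[keep] - 1L,
               avail = avail[keep], stringsAsFactors = FALSE)
  }
  chrom_of <- setNames(flat$exons$chrom, flat$exons$gene_id)
  list(on = seg_table(GenomicRanges::intersect(ex, pr)),
       off = seg_table(GenomicRanges::setdiff(ex, pr)),
       chrom_of = chrom_of[!duplicated(names(chrom_of))])
}

# Draw start positions for `k` reads of given genes within a segment table.
# Returns NA start for genes absent from the table (no room in category).
draw_read_starts <- function(genes, segs) {
  out <- rep(NA_integer_, length(genes))
  if (length(genes) == 0L || nrow(segs) == 0L) return(out)
  segs <- segs[order(segs$gene_id), , drop = FALSE]
  tot <- tapply(segs$avail, segs$gene_id, sum)
  seg_left <- cumsum(as.numeric(segs$avail)) - segs$avail  # global slot offset
  gene_left <- setNames(seg_left[!duplicated(segs$gene_id)],
                        segs$gene_id[!duplicated(segs$gene_id)])
  ok <- genes %in% names(tot)
  if (!any(ok)) return(out)
  g <- genes[ok]
  u <- floor(runif(length(g)) * as.numeric(tot[g]))   # 0-based slot in gene
  gu <- gene_left[g] + u                               # global slot
  idx <- findInterval(gu, seg_left)
  out[ok] <- as.integer(segs$start[idx] + (gu - seg_left[idx]))
  out
}

place_reads <- function(counts, segs, cfg, sample_id) {
  gene_ids <- names(counts)
  reads_gene <- rep.int(gene_ids, counts)
  k <- length(reads_gene)
  if (k == 0L)
    return(data.frame(read_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      uniquely_mapped = logical(), stringsAsFactors = FALSE))
  off <- runif(k) < cfg$frac_reads_off_probe
  start <- rep(NA_integer_, k)
  start[off] <- draw_read_starts(reads_gene[off], segs$off)
  start[!off] <- draw_read_starts(reads_gene[!off], segs$on)
  # genes with no room in the requested category fall back to the other one
  miss <- which(is.na(start))
  if (length(miss)) {
    start[miss] <- draw_read_starts(reads_gene[miss], segs$on)
    miss2 <- miss[is.na(start[miss])]
    if (length(miss2))
      start[miss2] <- draw_read_starts(reads_gene[miss2], segs$off)
  }
  keep <- !is.na(start)
  reads_gene <- reads_gene[keep]; start <- start[keep]
  data.frame(read_id = sprintf("%s_r%07d", sample_id, seq_along(start)),
             chrom = unname(segs$chrom_of[reads_gene]),
             start = start, end = start + cfg$read_length,
             strand = "+", uniquely_mapped = TRUE, stringsAsFactors = FALSE)
}

# Noise-free expected read counts per gene for each query sample (used by
# calibration tests; deterministic given the config).
expected_counts <- function(config) {
  sc <- sim_scenario(config)
  models <- withr::with_seed(derive_seed(config$seed, 50L),
                             make_gene_models(config$n_genes, config$read_length))
  flat <- attr(models, "flattened")
  len_bp <- tapply(flat$exons$end - flat$exons$start, flat$exons$gene_id, sum)
  len_bp <- as.numeric(len_bp[sc$gene_ids])
  mu_of <- function(profile) {
    w <- 2^profile * len_bp
    setNames(config$library_size * w / sum(w), sc$gene_ids)
  }
  list(CD56neg_1 = mu_of(sc$cd56neg), CD56pos_1 = mu_of(sc$cd56pos),
       effective_length = setNames(len_bp, sc$gene_ids))
}

#' Simulate the query RNA-seq samples
#'
#' Generates gene models (exons plus probe target regions), draws
#' negative-binomial read counts per gene with mean proportional to
#' expression times merged exon length, and expands each count into that
#' many uniform-start read intervals over the exons; a fraction
#' `frac_reads_off_probe` of reads is placed inside exons but with zero
#' overlap with probe regions. The CD56- sample follows the pDC profile,
#' the CD56+ sample the mDC profile with the pDC-module overlay; planted
#' differential genes differ by exactly `effect_size_log2` between them.
#'
#' @param config a [sim_config()].
#' @return list with `reads` (named list of read-alignment data frames, one
#'   per sample: columns `read_id`, `chrom`, `start`, `end`, `strand`,
#'   `uniquely_mapped`), `gene_models` (named list of [gene_model()]s),
#'   `counts` (an `expr_matrix`, unit `count`), `meta` and `truth`.
#' @export
simulate_query_rnaseq <- function(config) {
  validate_sim_config(config)
  if (config$library_size < config$n_genes)
    stop_config("library_size (%d) must be at least n_genes (%d)",
                config$library_size, config$n_genes)
  sc <- sim_scenario(config)
  models <- withr::with_seed(derive_seed(config$seed, 50L),
                             make_gene_models(config$n_genes, config$read_length))
  flat <- attr(models, "flattened")
  segs <- read_placement_segments(flat, config$read_length)
  len_bp <- tapply(flat$exons$end - flat$exons$start, flat$exons$gene_id, sum)
  len_bp <- as.numeric(len_bp[sc$gene_ids])

  pops <- config$populations
  queries <- pops[pops$role == "query", ]
  profiles <- list(pDC = sc$cd56neg, CD56posDC = sc$cd56pos)
  prefix <- c(pDC = "CD56neg", CD56posDC = "CD56pos")
  reads <- list(); count_cols <- list(); ids <- character(); pop_lab <- character()
  k <- 0L
  for (i in seq_len(nrow(queries))) {
    p <- queries$population[i]
    for (r in seq_len(queries$replicates[i])) {
      k <- k + 1L
      sid <- sprintf("%s_%d", prefix[[p]], r)
      withr::with_seed(derive_seed(config$seed, 300L + k), {
        w <- 2^profiles[[p]] * len_bp
        mu <- config$library_size * w / sum(w)
        counts <- rnbinom(config$n_genes, mu = mu, size = 1 / config$seq_dispersion)
        names(counts) <- sc$gene_ids
        reads[[sid]] <- place_reads(counts, segs, config, sid)
      })
      count_cols[[sid]] <- counts
      ids <- c(ids, sid); pop_lab <- c(pop_lab, p)
    }
  }
  cm <- do.call(cbind, count_cols)
  rownames(cm) <- sc$gene_ids
  list(reads = reads, gene_models = models,
       counts = expr_matrix(cm, unit = "count", platform = "rnaseq"),
       meta = sample_meta(ids, pop_lab, "rnaseq"),
       truth = sc$truth)
}

#' Simulate the BPDCN tumor array panel
#'
#' The BPDCN profile copies the CD56+ query profile (or the pDC profile in
#' the null configuration `bpdcn_like = "pDC"`), adds a gene-wise tumor
#' shift shared by all replicates, and draws array replicates around it.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (`expr_matrix`, unit `log2_intensity`),
#'   `meta`, and `truth`.
#' @export
simulate_bpdcn_arrays <- function(config) {
  validate_sim_config(config)
  sc <- sim_scenario(config)
  pops <- config$populations
  reps <- pops$replicates[pops$role == "tumor"][1]
  if (is.na(reps) || reps < 1L) stop_config("BPDCN panel needs at least 1 replicate")
  cols <- list()
  for (r in seq_len(reps)) {
    withr::with_seed(derive_seed(config$seed, 500L + r), {
      cols[[sprintf("BPDCN_t%d", r)]] <- array_response(sc$bpdcn) +
        rnorm(config$n_genes, 0, config$array_noise_sd)
    })
  }
  m <- do.call(cbind, cols)
  rownames(m) <- sc$gene_ids
  list(matrix = expr_matrix(m, unit = "log2_intensity", platform = "array"),
       meta = sample_meta(colnames(m), "BPDCN", "array"),
       truth = sc$truth)
}

#' Write a simulated dataset to disk
#'
#' Emits reads as BED (one file per sample), exon and probe annotations as
#' BED, count/array matrices and sample metadata as TSV, and the planted
#' truth as JSON.
#'
#' @param sim result of [simulate_query_rnaseq()].
#' @param arrays result of [simulate_reference_arrays()].
#' @param outdir output directory (created if needed).
#' @param bpdcn optional result of [simulate_bpdcn_arrays()].
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, arrays, outdir, bpdcn = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  flat <- attr(sim$gene_models, "flattened") %||% flatten_gene_models(sim$gene_models)
  paths <- c()
  p <- file.path(outdir, "exons.bed")
  write_bed(genomic_intervals(flat$exons$chrom, flat$exons$start,
                              flat$exons$end, name = flat$exons$gene_id), p)
  paths["exons"] <- p
  p <- file.path(outdir, "probes.bed")
  write_bed(genomic_intervals(flat$probes$chrom, flat$probes$start,
                              flat$probes$end, name = flat$probes$gene_id), p)
  paths["probes"] <- p
  for (sid in names(sim$reads)) {
    rd <- sim$reads[[sid]]
    p <- file.path(outdir, sprintf("reads_%s.bed", sid))
    write_bed(genomic_intervals(rd$chrom, rd$start, rd$end, name = rd$read_id,
                                strand = rd$strand), p)
    paths[paste0("reads_", sid)] <- p
  }
  p <- file.path(outdir, "query_counts.tsv")
  write_matrix(sim$counts, p); paths["counts"] <- p
  p <- file.path(outdir, "reference_arrays.tsv")
  write_matrix(arrays$matrix, p); paths["arrays"] <- p
  meta <- rbind(as.data.frame(arrays$meta), as.data.frame(sim$meta))
  if (!is.null(bpdcn)) {
    p <- file.path(outdir, "bpdcn_arrays.tsv")
    write_matrix(bpdcn$matrix, p); paths["bpdcn"] <- p
    meta <- rbind(meta, as.data.frame(bpdcn$meta))
  }
  p <- file.path(outdir, "sample_meta.tsv")
  write_sample_meta(sample_meta(meta$sample_id, meta$population, meta$platform), p)
  paths["meta"] <- p
  p <- file.path(outdir, "truth.json")
  jsonlite::write_json(sim$truth, p, auto_unbox = TRUE, digits = NA)
  paths["truth"] <- p
  invisible(paths)
}
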