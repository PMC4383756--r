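# End-to-end orchestration: simulate -> quantify -> filter -> normalize ->
# differential sets -> concordance -> cluster/PCA -> lineage assignment,
# with a machine-readable report. Fully deterministic under a fixed seed.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] describing the synthetic dataset (the
#'   pipeline's input source).
#' @param fc_threshold fold-change threshold for the query differential
#'   sets (default 2).
#' @param min_rpkm RPKM expression filter threshold (default 10); a gene is
#'   kept when its maximum across the query samples reaches it.
#' @param alpha BH-adjusted significance level for the moderated-t stage
#'   (default 0.05).
#' @param rank_tol rank-invariant normalization tolerance (default 0.05).
#' @param metric clustering distance: `"pearson"` (default) or
#'   `"euclidean"`.
#' @param zscore gene-wise z-scoring before clustering/PCA (default `TRUE`).
#' @param restrict_to_probes probe-restricted read counting (default `TRUE`).
#' @param length_mode RPKM length convention, `"restricted"` or `"exon"`.
#' @param pseudocount pseudocount for the RPKM log transform (default 1).
#' @param include_bpdcn run the BPDCN arm (default `TRUE`).
#' @param seed overrides the simulation seed when non-NULL.
#' @param outdir optional directory for intermediate artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), fc_threshold = 2,
                            min_rpkm = 10, alpha = 0.05, rank_tol = 0.05,
                            metric = c("pearson", "euclidean"),
                            zscore = TRUE, restrict_to_probes = TRUE,
                            length_mode = c("restricted", "exon"),
                            pseudocount = 1, include_bpdcn = TRUE,
                            seed = NULL, outdir = NULL) {
  metric <- match.arg(metric)
  length_mode <- match.arg(length_mode)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  stopifnot(fc_threshold >= 1, min_rpkm >= 0, alpha > 0, alpha < 1)
  structure(list(sim = sim, fc_threshold = fc_threshold, min_rpkm = min_rpkm,
                 alpha = alpha, rank_tol = rank_tol, metric = metric,
                 zscore = zscore, restrict_to_probes = restrict_to_probes,
                 length_mode = length_mode, pseudocount = pseudocount,
                 include_bpdcn = include_bpdcn, seed = sim$seed,
                 outdir = outdir),
            class = "pipeline_config")
}

query_groups <- function(meta) {
  list(pos = meta$sample_id[meta$population == "CD56posDC"],
       neg = meta$sample_id[meta$population == "pDC" & meta$platform == "rnaseq"])
}

#' Run the full cross-platform lineage analysis
#'
#' Executes, in order: simulation of the reference array panel, query
#' RNA-seq samples and (optionally) BPDCN arrays; probe-restricted RPKM
#' quantification from the read intervals; the minimum-RPKM filter; log
#' transform; fold-change differential sets between the CD56+ and CD56-
#' queries; directional concordance of both sets against the pooled
#' mDC-vs-pDC array contrast (also per mDC subset, and for the planted
#' truth sets); rank-invariant merging of the two platforms; complete-
#' linkage clustering, PCA and lineage assignment of both queries; and the
#' BPDCN moderated-t arm. Any stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return an `analysis_report` list; when `config$outdir` is set, all
#'   intermediate artifacts are written there and their MD5 checksums
#'   recorded in the report.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) stop_config("expected a pipeline_config")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_data("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  log <- list()

  arrays <- stage("simulate_reference_arrays", simulate_reference_arrays(config$sim))
  sim <- stage("simulate_query_rnaseq", simulate_query_rnaseq(config$sim))
  bpdcn <- if (config$include_bpdcn)
    stage("simulate_bpdcn_arrays", simulate_bpdcn_arrays(config$sim)) else NULL
  truth <- sim$truth
  log$simulate <- list(n_genes = config$sim$n_genes,
                       n_array_samples = ncol(arrays$matrix),
                       n_query_samples = ncol(sim$counts),
                       n_reads = vapply(sim$reads, nrow, integer(1)))

  quant <- stage("quantify", quantify_reads(
    sim$reads, sim$gene_models, restrict_to_probes = config$restrict_to_probes,
    length_mode = config$length_mode))
  log$quantify <- list(genes_quantified = nrow(quant$rpkm),
                       total_mapped_reads = quant$total_mapped_reads)

  expressed <- stage("expression_filter",
                     expression_filter(quant$rpkm, min_rpkm = config$min_rpkm))
  log$filter <- list(min_rpkm = config$min_rpkm, genes_in = nrow(quant$rpkm),
                     genes_out = length(expressed))

  logq <- stage("log_transform",
                log_transform(quant$rpkm[expressed, , drop = FALSE],
                              pseudocount = config$pseudocount))

  qg <- query_groups(sim$meta)
  de <- stage("fold_change_sets",
              fold_change_sets(logq, qg$pos, qg$neg,
                               fc_threshold = config$fc_threshold))
  log$de <- list(fc_threshold = config$fc_threshold,
                 n_up = length(de$up), n_down = length(de$down))

  mdc <- arrays$meta$sample_id[arrays$meta$population %in% c("BDCA1_mDC", "BDCA3_mDC")]
  pdc <- arrays$meta$sample_id[arrays$meta$population == "pDC"]
  conc <- stage("concordance", list(
    up = directional_concordance(de$up, "up", arrays$matrix, mdc, pdc),
    down = directional_concordance(de$down, "down", arrays$matrix, mdc, pdc)))
  conc_subset <- stage("concordance_per_subset", {
    out <- list()
    for (sub in c("BDCA1_mDC", "BDCA3_mDC")) {
      ss <- arrays$meta$sample_id[arrays$meta$population == sub]
      out[[sub]] <- list(
        up = directional_concordance(de$up, "up", arrays$matrix, ss, pdc),
        down = directional_concordance(de$down, "down", arrays$matrix, ss, pdc))
    }
    out
  })
  conc_planted <- stage("concordance_planted", list(
    up = directional_concordance(truth$de_up_genes, "up", arrays$matrix, mdc, pdc),
    down = directional_concordance(truth$de_down_genes, "down", arrays$matrix, mdc, pdc)))

  merged <- stage("merge_platforms",
                  merge_platforms(logq, arrays$matrix, rank_tol = config$rank_tol))
  log$merge <- list(shared_genes = nrow(merged$matrix),
                    reference_sample = merged$reference_sample)

  clust <- stage("cluster", {
    m <- if (config$zscore) zscore_genes(merged$matrix) else unclass(merged$matrix)
    d <- if (config$metric == "pearson") pearson_distance_matrix(m)
         else as.matrix(dist(t(m)))
    hc <- hclust_complete(d)
    pca <- pca_samples(m, n_components = min(2L, ncol(m) - 1L))
    list(dist = d, hclust = hc, pca = pca)
  })
  ref_branches <- setNames(branch_of(arrays$meta$population, config$sim$lineage_tree),
                           arrays$meta$sample_id)
  assignments <- stage("assign_lineage", {
    out <- list()
    for (q in c(qg$pos, qg$neg))
      out[[q]] <- assign_lineage(clust$hclust, q, ref_branches, clust$dist)
    out
  })
  log$cluster <- list(metric = config$metric, zscore = config$zscore,
                      assignments = vapply(assignments, `[[`, "", "branch"))

  bp <- NULL
  if (config$include_bpdcn) {
    pdc_arrays <- arrays$matrix[, pdc, drop = FALSE]
    bp <- stage("bpdcn_analysis",
                bpdcn_analysis(bpdcn$matrix, pdc_arrays, quant$rpkm,
                               alpha = config$alpha, min_rpkm = config$min_rpkm,
                               rank_tol = config$rank_tol,
                               group_pos = qg$pos, group_neg = qg$neg,
                               pseudocount = config$pseudocount))
  }

  report <- structure(list(
    package_version = as.character(utils::packageVersion("dclineage")),
    seed = config$sim$seed,
    parameters = config[c("fc_threshold", "min_rpkm", "alpha", "rank_tol",
                          "metric", "zscore", "restrict_to_probes",
                          "length_mode", "pseudocount")],
    stages = log,
    de_sets = de[c("up", "down")],
    concordance = conc,
    concordance_per_subset = conc_subset,
    concordance_planted = conc_planted,
    assignments = assignments,
    bpdcn = bp,
    truth = truth), class = "analysis_report")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- write_simulation(sim, arrays, config$outdir, bpdcn = bpdcn)
    p <- file.path(config$outdir, "query_rpkm.tsv")
    write_matrix(quant$rpkm, p); paths["rpkm"] <- p
    p <- file.path(config$outdir, "merged_normalized.tsv")
    write_matrix(merged$matrix, p); paths["merged"] <- p
    p <- file.path(config$outdir, "dendrogram.nwk")
    ape::write.tree(ape::as.phylo(clust$hclust), file = p); paths["dendrogram"] <- p
    p <- file.path(config$outdir, "pca_scores.tsv")
    utils::write.table(clust$pca$scores, p, sep = "\t", quote = FALSE,
                       col.names = NA); paths["pca"] <- p
    report$input_checksums <- as.list(tools::md5sum(unname(paths)))
    p <- file.path(config$outdir, "report.json")
    jsonlite::write_json(report_to_json(report), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    report$outputs <- as.list(paths)
  }
  report
}

# Strip non-serializable bulk (per-gene flag vectors stay; tables coerced).
report_to_json <- function(report) {
  simplify <- function(x) {
    if (inherits(x, "concordance_result"))
      return(x[c("n_query_set", "n_matched", "n_concordant",
                 "percent_concordant", "percent_rounded", "direction_tested")])
    if (is.table(x)) return(as.list(x))
    if (is.list(x)) return(lapply(x, simplify))
    x
  }
  simplify(unclass(report))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> seed %d\n", x$seed))
  cat(sprintf("  query DE sets: %d up / %d down (fold-change >= %g)\n",
              length(x$de_sets$up), length(x$de_sets$down),
              x$parameters$fc_threshold))
  up <- x$concordance$up; dn <- x$concordance$down
  cat(sprintf("  concordance with mDC-vs-pDC: up %d/%d (%d%%), down %d/%d (%d%%)\n",
              up$n_concordant, up$n_matched, up$percent_rounded,
              dn$n_concordant, dn$n_matched, dn$percent_rounded))
  for (q in names(x$assignments))
    cat(sprintf("  lineage of %s: %s\n", q, x$assignments[[q]]$branch))
  if (!is.null(x$bpdcn)) {
    bu <- x$bpdcn$concordance$high; bd <- x$bpdcn$concordance$low
    cat(sprintf("  BPDCN-high vs CD56+ contrast: %d/%d (%d%%); BPDCN-low: %d/%d (%d%%)\n",
                bu$n_concordant, bu$n_matched, bu$percent_rounded,
                bd$n_concordant, bd$n_matched, bd$percent_rounded))
  }
  invisible(x)
}

#' BPDCN arm: moderated-t differential sets scored against the query contrast
#'
#' Normalizes the BPDCN and pDC array samples together (rank-invariant, to
#' the median array sample), calls the moderated t with BH adjustment at
#' `alpha`, drops genes below `min_rpkm` in every query RNA-seq sample, and
#' scores the BPDCN-high set (direction up) and BPDCN-low set (direction
#' down) against the CD56+ vs CD56- contrast in the query RNA-seq data.
#'
#' @param bpdcn `expr_matrix` of BPDCN arrays (log scale).
#' @param pdc_ref `expr_matrix` of pDC arrays (log scale, same genes).
#' @param query_rpkm `expr_matrix` of query RPKM (unit `rpkm`), used both
#'   for the expression filter and (log-transformed) as the concordance
#'   reference.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param min_rpkm expression filter threshold (default 10).
#' @param rank_tol rank-invariant tolerance (default 0.05).
#' @param group_pos,group_neg CD56+ / CD56- query sample ids; default: the
#'   columns named `CD56pos*` / `CD56neg*`.
#' @param pseudocount for the query log transform.
#' @return list with `de` (the full moderated-t table), `high`/`low` gene
#'   sets (after the RPKM filter), and `concordance` (`high`, `low`
#'   `concordance_result`s against the query contrast).
#' @export
bpdcn_analysis <- function(bpdcn, pdc_ref, query_rpkm, alpha = 0.05,
                           min_rpkm = 10, rank_tol = 0.05,
                           group_pos = NULL, group_neg = NULL,
                           pseudocount = 1) {
  shared <- intersect(rownames(bpdcn), rownames(pdc_ref))
  if (length(shared) < 10L)
    stop_data("BPDCN and pDC arrays share too few genes (%d)", length(shared))
  combined <- expr_matrix(cbind(unclass(bpdcn)[shared, , drop = FALSE],
                                unclass(pdc_ref)[shared, , drop = FALSE]),
                          unit = "log2_intensity", platform = "array")
  meds <- apply(unclass(combined), 2, median)
  ref_sample <- colnames(combined)[order(meds)][ceiling(ncol(combined) / 2)]
  norm <- combined
  for (sid in colnames(combined)) {
    if (sid == ref_sample) next
    norm[, sid] <- normalize_to_reference(unclass(combined)[, sid],
                                          unclass(combined)[, ref_sample],
                                          rank_tol = rank_tol)$normalized
  }
  norm <- expr_matrix(unclass(norm), unit = "normalized", platform = "array")
  de <- moderated_t(norm, colnames(bpdcn), colnames(pdc_ref), alpha = alpha)
  expressed <- expression_filter(query_rpkm, min_rpkm = min_rpkm)
  high <- intersect(de$gene_id[de$direction == "up"], expressed)
  low <- intersect(de$gene_id[de$direction == "down"], expressed)
  logq <- log_transform(query_rpkm, pseudocount = pseudocount)
  group_pos <- group_pos %||% grep("^CD56pos", colnames(logq), value = TRUE)
  group_neg <- group_neg %||% grep("^CD56neg", colnames(logq), value = TRUE)
  list(de = de, high = high, low = low,
       n_tested = nrow(de),
       concordance = list(
         high = directional_concordance(high, "up", logq, group_pos, group_neg),
         low = directional_concordance(low, "down", logq, group_pos, group_neg)))
}
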