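# Probe-region-restricted RPKM quantification: only reads with at least one
# base of overlap with the regions targeted by microarray probes are counted,
# so RNA-seq expression is measured over the same gene regions the array
# interrogates.

#' Counting region of a gene
#'
#' The merged exons of the gene, optionally intersected with its probe
#' target regions. The restricted region may be empty (a gene without
#' probes), which is a legal result: such genes are reported as missing,
#' not zero, by [rpkm()].
#'
#' @param gene a [gene_model()].
#' @param restrict_to_probes if `TRUE` (the pipeline default), intersect
#'   merged exons with merged probe regions.
#' @return merged, sorted `genomic_intervals`.
#' @export
counting_region <- function(gene, restrict_to_probes = TRUE) {
  if (!inherits(gene, "gene_model")) stop_data("counting_region expects a gene_model")
  ex <- merge_intervals(gene$exons)
  if (!restrict_to_probes) return(ex)
  if (nrow(gene$probe_regions) == 0L)
    return(genomic_intervals(character(), integer(), integer()))
  intersect_intervals(ex, merge_intervals(gene$probe_regions))
}

#' Count uniquely mapped reads overlapping a region
#'
#' A read is counted when it is uniquely mapped and shares at least one
#' base with the region (half-open coordinates: a read starting exactly at
#' the region end has zero overlap). Each read is counted at most once,
#' however many region intervals it touches.
#'
#' @param reads read alignments: a data.frame with columns `chrom`, `start`,
#'   `end` and logical `uniquely_mapped` (e.g. from [simulate_query_rnaseq()]
#'   or [as_read_alignments()]).
#' @param region `genomic_intervals`, typically from [counting_region()].
#' @return integer read count.
#' @export
count_reads <- function(reads, region) {
  if (nrow(region) == 0L || nrow(reads) == 0L) return(0L)
  u <- reads[reads$uniquely_mapped, , drop = FALSE]
  if (nrow(u) == 0L) return(0L)
  lv <- union(unique(u$chrom), unique(region$chrom))
  rgr <- GenomicRanges::GRanges(factor(u$chrom, levels = lv),
                                IRanges::IRanges(u$start + 1L, u$end))
  ggr <- GenomicRanges::GRanges(factor(region$chrom, levels = lv),
                                as_iranges(region))
  hits <- GenomicRanges::findOverlaps(rgr, ggr, minoverlap = 1L)
  length(unique(S4Vectors::queryHits(hits)))
}

#' Tag a set of intervals as read alignments
#'
#' Convenience for BED-backed reads (the plain-text stand-in for BAM): every
#' interval becomes one read, with its `name` as the read id.
#'
#' @param intervals `genomic_intervals` (e.g. from [read_bed()]).
#' @param uniquely_mapped logical, recycled across reads (default `TRUE`).
#' @return a read-alignment data.frame.
#' @export
as_read_alignments <- function(intervals, uniquely_mapped = TRUE) {
  data.frame(read_id = intervals$name, chrom = intervals$chrom,
             start = intervals$start, end = intervals$end,
             strand = intervals$strand,
             uniquely_mapped = rep_len(uniquely_mapped, nrow(intervals)),
             stringsAsFactors = FALSE)
}

#' RPKM from gene counts
#'
#' RPKM = reads per kilobase of counting region per million mappable
#' (uniquely mapped) reads:
#' `count / (effective_length_bp / 1000) / (total_mapped_reads / 1e6)`.
#' Genes with zero effective length are dropped from the result (missing,
#' not zero) with a message.
#'
#' @param counts data.frame with columns `gene_id`, `count`,
#'   `effective_length_bp`.
#' @param total_mapped_reads total uniquely mapped reads in the sample
#'   (before any probe restriction), > 0.
#' @return named numeric vector of RPKM values.
#' @export
rpkm <- function(counts, total_mapped_reads) {
  if (total_mapped_reads <= 0) stop_data("total_mapped_reads must be > 0")
  need <- c("gene_id", "count", "effective_length_bp")
  if (!all(need %in% names(counts)))
    stop_data("counts needs columns: %s", paste(need, collapse = ", "))
  zero <- counts$effective_length_bp <= 0
  if (any(zero)) {
    message(sprintf("%d gene(s) with zero effective length reported as missing",
                    sum(zero)))
    counts <- counts[!zero, , drop = FALSE]
  }
  setNames(counts$count / (counts$effective_length_bp / 1000) /
             (total_mapped_reads / 1e6),
           counts$gene_id)
}

# Bulk counting: per-gene restricted (or full-exon) regions as one flat
# GRanges, one findOverlaps call for all genes of a sample.
gene_regions_granges <- function(models, restrict_to_probes) {
  flat <- attr(models, "flattened") %||% flatten_gene_models(models)
  lv <- unique(flat$exons$gene_id)
  gr <- function(df) GenomicRanges::GRanges(factor(df$gene_id, levels = lv),
                                            IRanges::IRanges(df$start + 1L, df$end))
  ex <- GenomicRanges::reduce(gr(flat$exons))
  reg <- if (restrict_to_probes) {
    if (is.null(flat$probes) || nrow(flat$probes) == 0L) ex[0]
    else GenomicRanges::intersect(ex, gr(flat$probes))
  } else ex
  chrom_of <- setNames(flat$exons$chrom, flat$exons$gene_id)
  chrom_of <- chrom_of[!duplicated(names(chrom_of))]
  gene <- as.character(GenomicRanges::seqnames(reg))
  list(gene = gene, chrom = unname(chrom_of[gene]),
       start1 = GenomicRanges::start(reg), end = GenomicRanges::end(reg),
       gene_ids = lv,
       full_exon_gr = ex)
}

region_lengths <- function(reg_gr, gene_ids) {
  w <- tapply(reg_gr$end - reg_gr$start1 + 1L, factor(reg_gr$gene, levels = gene_ids),
              sum)
  ifelse(is.na(w), 0L, as.integer(w))
}

#' Quantify RNA-seq samples as probe-restricted RPKM
#'
#' Counts, for every gene and sample, the uniquely mapped reads with at
#' least one base of overlap with the gene's counting region, and converts
#' counts to RPKM. With `length_mode = "restricted"` (default) the RPKM
#' denominator uses the length of the exon-by-probe intersection, keeping
#' numerator and denominator over the same bases; `"exon"` uses the full
#' merged exon length (the literal per-kilobase-of-exon reading).
#'
#' @param reads named list of read-alignment data frames, one per sample.
#' @param models named list of [gene_model()]s.
#' @param restrict_to_probes count only reads overlapping probe target
#'   regions (default `TRUE`).
#' @param length_mode `"restricted"` or `"exon"`.
#' @param total_mapped_reads optional named vector of per-sample totals;
#'   defaults to each sample's number of uniquely mapped reads before any
#'   restriction ("per million mappable reads").
#' @return list with `rpkm` (an `expr_matrix`), `counts` (integer matrix),
#'   `effective_length` (named vector) and `total_mapped_reads`. Genes whose
#'   counting region is empty are absent from the matrices.
#' @export
quantify_reads <- function(reads, models,
                           restrict_to_probes = TRUE,
                           length_mode = c("restricted", "exon"),
                           total_mapped_reads = NULL) {
  length_mode <- match.arg(length_mode)
  if (!restrict_to_probes && length_mode == "restricted") length_mode <- "exon"
  reg <- gene_regions_granges(models, restrict_to_probes)
  gene_ids <- reg$gene_ids
  len <- if (length_mode == "restricted") {
    setNames(region_lengths(reg, gene_ids), gene_ids)
  } else {
    ex <- reg$full_exon_gr
    w <- tapply(GenomicRanges::width(ex),
                factor(as.character(GenomicRanges::seqnames(ex)), levels = gene_ids),
                sum)
    setNames(ifelse(is.na(w), 0L, as.integer(w)), gene_ids)
  }
  reg_gr <- GenomicRanges::GRanges(reg$chrom, IRanges::IRanges(reg$start1, reg$end))
  counts <- matrix(0L, length(gene_ids), length(reads),
                   dimnames = list(gene_ids, names(reads)))
  totals <- setNames(numeric(length(reads)), names(reads))
  for (sid in names(reads)) {
    rd <- reads[[sid]]
    rd <- rd[rd$uniquely_mapped, , drop = FALSE]
    totals[sid] <- nrow(rd)
    if (nrow(rd) == 0L || length(reg_gr) == 0L) next
    rgr <- GenomicRanges::GRanges(rd$chrom, IRanges::IRanges(rd$start + 1L, rd$end))
    hits <- GenomicRanges::findOverlaps(rgr, reg_gr, minoverlap = 1L)
    gidx <- match(reg$gene[S4Vectors::subjectHits(hits)], gene_ids)
    key <- (as.numeric(S4Vectors::queryHits(hits)) - 1) * length(gene_ids) + gidx
    gidx <- gidx[!duplicated(key)]   # each read counted once per gene
    counts[, sid] <- tabulate(gidx, nbins = length(gene_ids))
  }
  if (!is.null(total_mapped_reads)) totals[names(total_mapped_reads)] <- total_mapped_reads
  keep <- len > 0L
  rp <- sapply(names(reads), function(sid) {
    rpkm(data.frame(gene_id = gene_ids[keep], count = counts[keep, sid],
                    effective_length_bp = len[keep]),
         totals[sid])
  })
  if (is.null(dim(rp))) rp <- matrix(rp, ncol = length(reads),
                                     dimnames = list(gene_ids[keep], names(reads)))
  list(rpkm = expr_matrix(rp, unit = "rpkm", platform = "rnaseq"),
       counts = counts[keep, , drop = FALSE],
       effective_length = len[keep],
       total_mapped_reads = totals)
}
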