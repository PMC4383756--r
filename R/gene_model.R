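# Gene models: per-gene exon intervals plus the microarray probe target
# regions used to restrict read counting.

#' Construct a gene model
#'
#' A gene model holds the exon intervals of a gene and, optionally, the
#' genomic regions targeted by its microarray probes. All intervals of one
#' gene must share a chromosome; exons must cover at least one base.
#'
#' @param gene_id gene identifier (string).
#' @param symbol display symbol; defaults to `gene_id`.
#' @param exons `genomic_intervals` of the exons (non-empty).
#' @param probe_regions `genomic_intervals` of probe target regions; may be
#'   empty (a gene without probes yields an empty probe-restricted counting
#'   region).
#' @return a `gene_model` list.
#' @export
gene_model <- function(gene_id, exons, probe_regions = NULL, symbol = gene_id) {
  if (is.null(probe_regions))
    probe_regions <- genomic_intervals(character(), integer(), integer())
  if (!inherits(exons, "genomic_intervals") ||
      !inherits(probe_regions, "genomic_intervals"))
    stop_data("exons and probe_regions must be genomic_intervals")
  if (nrow(exons) == 0L) stop_data("gene %s has no exons", gene_id)
  chroms <- unique(c(exons$chrom, probe_regions$chrom))
  if (length(chroms) > 1L)
    stop_data("gene %s has intervals on multiple chromosomes: %s", gene_id,
              paste(chroms, collapse = ", "))
  if (sum(exons$end - exons$start) <= 0L)
    stop_data("gene %s has zero merged exon length", gene_id)
  structure(list(gene_id = as.character(gene_id), symbol = as.character(symbol),
                 exons = exons, probe_regions = probe_regions),
            class = "gene_model")
}

#' Build gene models from exon and probe BED annotations
#'
#' The BED name column associates intervals with genes: every exon line must
#' carry a gene id; probe lines whose gene id has no exon line are dropped
#' with a warning.
#'
#' @param exons `genomic_intervals` with `name` = gene id (e.g. from
#'   [read_bed()]).
#' @param probes optional `genomic_intervals` with `name` = gene id.
#' @return named list of `gene_model` objects, in order of first appearance.
#' @export
gene_models_from_intervals <- function(exons, probes = NULL) {
  if (anyNA(exons$name))
    stop_data("every exon interval needs a gene id in the name column")
  ids <- unique(exons$name)
  exon_split <- split(seq_len(nrow(exons)), factor(exons$name, levels = ids))
  probe_split <- if (!is.null(probes) && nrow(probes) > 0) {
    if (anyNA(probes$name))
      stop_data("every probe interval needs a gene id in the name column")
    orphan <- setdiff(unique(probes$name), ids)
    if (length(orphan))
      warning(sprintf("dropping probe regions for %d gene id(s) with no exons",
                      length(orphan)))
    split(seq_len(nrow(probes)), factor(probes$name, levels = ids))
  } else NULL
  out <- lapply(ids, function(g) {
    ex <- exons[exon_split[[g]], , drop = FALSE]
    class(ex) <- c("genomic_intervals", "data.frame")
    pr <- if (!is.null(probe_split) && length(probe_split[[g]])) {
      p <- probes[probe_split[[g]], , drop = FALSE]
      class(p) <- c("genomic_intervals", "data.frame")
      p
    } else NULL
    gene_model(g, exons = ex, probe_regions = pr)
  })
  names(out) <- ids
  out
}

# Flatten a list of gene models into exon/probe data.frames with a gene
# column (fast path used by quantification and the simulator).
flatten_gene_models <- function(models) {
  stopifnot(is.list(models))
  ex <- do.call(rbind, lapply(models, function(m) {
    data.frame(gene_id = m$gene_id, chrom = m$exons$chrom,
               start = m$exons$start, end = m$exons$end,
               stringsAsFactors = FALSE)
  }))
  pr <- do.call(rbind, lapply(models, function(m) {
    if (nrow(m$probe_regions) == 0L) return(NULL)
    data.frame(gene_id = m$gene_id, chrom = m$probe_regions$chrom,
               start = m$probe_regions$start, end = m$probe_regions$end,
               stringsAsFactors = FALSE)
  }))
  list(exons = ex, probes = pr)
}
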