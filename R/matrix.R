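# Expression matrices: genes x samples, tagged with a unit and a platform so
# stages can refuse inputs on the wrong scale.

.em_units <- c("count", "rpkm", "log2_intensity", "log2_rpkm", "normalized")
.em_platforms <- c("rnaseq", "array")

#' Construct an expression matrix
#'
#' A dense genes-by-samples matrix carrying a `unit` tag (`count`, `rpkm`,
#' `log2_intensity`, `log2_rpkm`, `normalized`) and a `platform` tag
#' (`rnaseq`, `array`). Gene ids (rownames) and sample ids (colnames) must be
#' unique; `count` matrices must be integer-valued and non-negative.
#'
#' @param values numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param unit expression unit tag.
#' @param platform measurement platform tag.
#' @return an `expr_matrix`.
#' @export
expr_matrix <- function(values, unit, platform) {
  unit <- match.arg(unit, .em_units)
  platform <- match.arg(platform, .em_platforms)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_data("expression matrix needs gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop_data("duplicated gene id: %s", rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop_data("duplicated sample id: %s", colnames(values)[duplicated(colnames(values))][1])
  if (!is.numeric(values)) stop_data("expression values must be numeric")
  if (unit %in% c("count", "rpkm") && any(values < 0, na.rm = TRUE))
    stop_data("'%s' values must be non-negative", unit)
  if (unit == "count" && any(values != round(values), na.rm = TRUE))
    stop_data("'count' values must be integer-valued")
  structure(values, unit = unit, platform = platform,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "unit") <- attr(x, "unit")
    attr(out, "platform") <- attr(x, "platform")
    class(out) <- class(x)
  }
  out
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
em_unit <- function(x) attr(x, "unit")

#' @rdname expr_matrix
#' @export
em_platform <- function(x) attr(x, "platform")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [unit=%s, platform=%s]\n",
              nrow(x), ncol(x), em_unit(x), em_platform(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE]))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Duplicate gene ids and ragged rows are errors. Round-trips bit-exactly
#' with [write_matrix()] for finite values.
#'
#' @param path TSV path.
#' @param unit,platform tags recorded on the result (the file itself is
#'   unit-agnostic).
#' @return an `expr_matrix`.
#' @export
read_matrix <- function(path, unit, platform) {
  if (!file.exists(path)) stop_data("matrix file not found: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop_data("ragged matrix file: line %d has %d fields, expected %d",
              which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1])
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids))
    stop_data("duplicated gene id in %s: %s", path, gene_ids[duplicated(gene_ids)][1])
  chars <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(chars), nrow = nrow(chars),
                                  dimnames = dimnames(chars)))
  if (any(is.na(vals) & !(chars %in% c("NA", "NaN"))))
    stop_data("non-numeric value in matrix file %s", path)
  rownames(vals) <- gene_ids
  expr_matrix(vals, unit = unit, platform = platform)
}

#' Write an expression matrix as TSV
#'
#' First column `gene_id`, then one column per sample; values are printed
#' with 17 significant digits so finite values survive a read/write
#' round trip exactly.
#'
#' @param x `expr_matrix` (or plain numeric matrix with dimnames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  header <- paste(c("gene_id", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, useBytes = TRUE)
  invisible(path)
}

.populations <- c("pDC", "CD56posDC", "BDCA1_mDC", "BDCA3_mDC", "monocyte",
                  "neutrophil", "NK", "B", "T", "BPDCN")

#' Construct, read and write sample metadata
#'
#' Sample metadata maps sample ids to a cell population and a platform.
#' Populations are restricted to the panel handled by the pipeline
#' (pDC, CD56posDC, BDCA1_mDC, BDCA3_mDC, monocyte, neutrophil, NK, B, T,
#' BPDCN).
#'
#' @param sample_id character sample ids (unique).
#' @param population population labels from the supported panel.
#' @param platform `"rnaseq"` or `"array"` per sample.
#' @return a `data.frame` of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, population, platform) {
  x <- data.frame(sample_id = as.character(sample_id),
                  population = as.character(population),
                  platform = as.character(platform),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(x$sample_id))
    stop_data("duplicated sample id: %s", x$sample_id[duplicated(x$sample_id)][1])
  bad <- setdiff(unique(x$population), .populations)
  if (length(bad))
    stop_data("unknown population label(s): %s", paste(bad, collapse = ", "))
  if (!all(x$platform %in% .em_platforms))
    stop_data("platform must be one of: %s", paste(.em_platforms, collapse = ", "))
  class(x) <- c("sample_meta", "data.frame")
  x
}

#' @rdname sample_meta
#' @param path TSV path with columns `sample_id`, `population`, `platform`.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "platform")
  if (!all(need %in% names(df)))
    stop_data("sample metadata must have columns: %s", paste(need, collapse = ", "))
  sample_meta(df$sample_id, df$population, df$platform)
}

#' @rdname sample_meta
#' @param x a `sample_meta` data frame.
#' @export
write_sample_meta <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("sample_id\tpopulation\tplatform",
               sprintf("%s\t%s\t%s", x$sample_id, x$population, x$platform)),
             con, useBytes = TRUE)
  invisible(path)
}

#' Log-transform an RPKM matrix
#'
#' Applies `log2(v + pseudocount)` elementwise and updates the unit tag to
#' `log2_rpkm`. Array intensities in this package are generated/stored on the
#' log2 scale already and need no transform.
#'
#' @param x `expr_matrix` with unit `rpkm`.
#' @param pseudocount positive offset added before taking logs (default 1).
#' @return `expr_matrix` with unit `log2_rpkm`.
#' @export
log_transform <- function(x, pseudocount = 1) {
  if (!inherits(x, "expr_matrix")) stop_data("log_transform expects an expr_matrix")
  if (em_unit(x) != "rpkm")
    stop_data("log_transform expects unit 'rpkm', got '%s'", em_unit(x))
  if (pseudocount <= 0) stop_data("pseudocount must be > 0")
  if (any(x < 0)) stop_data("negative values cannot be log-transformed")
  expr_matrix(log2(unclass(x) + pseudocount), unit = "log2_rpkm",
              platform = em_platform(x))
}
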