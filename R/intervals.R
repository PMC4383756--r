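# Genomic intervals: 0-based half-open coordinates (BED convention)
# throughout. Strand is carried but never consulted by overlap computations.

#' Construct a set of genomic intervals
#'
#' Intervals use the BED convention: `start` is 0-based inclusive, `end` is
#' exclusive, so an interval covers `end - start` bases.
#'
#' @param chrom character chromosome names.
#' @param start integer 0-based inclusive starts, `>= 0`.
#' @param end integer exclusive ends, `> start`.
#' @param name optional feature names (gene ids, read ids); `NA` if absent.
#' @param strand one of `"+"`, `"-"`, `"*"` (unspecified).
#' @return a `data.frame` of class `genomic_intervals` with columns
#'   `chrom`, `start`, `end`, `name`, `strand`.
#' @examples
#' genomic_intervals("chr1", 100, 200, name = "G1")
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              strand = "*") {
  n <- max(length(chrom), length(start), length(end))
  if (length(start) == 0L || length(end) == 0L) {
    n <- 0L
    chrom <- character()
  }
  x <- data.frame(chrom = rep_len(as.character(chrom), n),
                  start = rep_len(as.integer(start), n),
                  end = rep_len(as.integer(end), n),
                  name = rep_len(as.character(name), n),
                  strand = rep_len(as.character(strand), n),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  class(x) <- c("genomic_intervals", "data.frame")
  x
}

validate_intervals <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (anyNA(x$start) || anyNA(x$end))
    stop_data("interval coordinates must be non-missing integers")
  if (any(x$start < 0L))
    stop_data("interval start must be >= 0 (0-based convention)")
  bad <- which(x$end <= x$start)
  if (length(bad))
    stop_data("interval end must exceed start (half-open convention); first offender: %s:%d-%d",
              x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]])
  if (!all(x$strand %in% c("+", "-", "*")))
    stop_data("strand must be one of '+', '-', '*'")
  invisible(x)
}

# Fast path for intervals already known to be valid (internal generators).
new_intervals <- function(chrom, start, end, name = NA_character_,
                          strand = "*") {
  n <- length(start)
  structure(list(chrom = rep_len(chrom, n), start = as.integer(start),
                 end = as.integer(end), name = rep_len(name, n),
                 strand = rep_len(strand, n)),
            class = c("genomic_intervals", "data.frame"),
            row.names = .set_row_names(n))
}

# IRanges uses 1-based closed coordinates; shift on the way in and out.
as_iranges <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

from_iranges <- function(ir, chrom, name = NA_character_, strand = "*") {
  genomic_intervals(chrom, IRanges::start(ir) - 1L, IRanges::end(ir),
                    name = name, strand = strand)
}

as_granges <- function(x) {
  GenomicRanges::GRanges(seqnames = x$chrom, ranges = as_iranges(x))
}

#' Total bases covered by a set of intervals
#'
#' @param x `genomic_intervals`.
#' @param merged if `FALSE` (default), sums raw widths; if `TRUE`, merges
#'   overlapping intervals first so each base is counted once.
#' @return integer base count.
#' @export
total_bases <- function(x, merged = FALSE) {
  if (nrow(x) == 0L) return(0L)
  if (merged) {
    sum(vapply(split(x, x$chrom),
               function(ch) sum(IRanges::width(IRanges::reduce(as_iranges(ch)))),
               integer(1)))
  } else {
    sum(x$end - x$start)
  }
}

#' Merge overlapping or abutting intervals on one chromosome
#'
#' Under the half-open convention, abutting intervals (`end == next start`)
#' merge into one. The result is sorted, pairwise disjoint, and covers
#' exactly the union of input bases.
#'
#' @param x `genomic_intervals`, all on one chromosome.
#' @return merged `genomic_intervals` (names are dropped).
#' @examples
#' merge_intervals(genomic_intervals("chr1", c(0, 5), c(10, 15)))
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(genomic_intervals(character(), integer(), integer()))
  chroms <- unique(x$chrom)
  if (length(chroms) > 1L)
    stop_data("merge_intervals requires a single chromosome; got: %s",
              paste(chroms, collapse = ", "))
  r <- IRanges::reduce(as_iranges(x))
  from_iranges(r, chroms)
}

#' Intersect two interval sets on one chromosome
#'
#' Returns the merged set of bases present in both inputs; may be empty.
#'
#' @param x,y `genomic_intervals` on the same single chromosome.
#' @return `genomic_intervals` covering the intersection.
#' @export
intersect_intervals <- function(x, y) {
  if (nrow(x) == 0L || nrow(y) == 0L)
    return(genomic_intervals(character(), integer(), integer()))
  chroms <- unique(c(x$chrom, y$chrom))
  if (length(chroms) > 1L)
    stop_data("intersect_intervals requires both sets on one chromosome; got: %s",
              paste(chroms, collapse = ", "))
  r <- IRanges::intersect(as_iranges(x), as_iranges(y))
  from_iranges(r, chroms)
}

#' Read a BED3+ file of genomic intervals
#'
#' Accepts BED with at least three tab-separated columns; column 4 (name) is
#' kept as the feature/gene association and column 6 (strand) is honoured
#' when present. Coordinates are taken as 0-based half-open, unchanged.
#'
#' @param path path to a BED file; an empty file yields zero intervals.
#' @return `genomic_intervals`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_data("BED file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(genomic_intervals(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop_data("malformed BED line %d: fewer than 3 tab-separated columns",
              which(nf < 3L)[1])
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop_data("malformed BED line %d: non-integer coordinate",
              which(is.na(start) | is.na(end))[1])
  bad <- which(end <= start)
  if (length(bad))
    stop_data("invalid interval on BED line %d: end (%d) <= start (%d)",
              bad[1], end[bad[1]], start[bad[1]])
  chrom <- vapply(fields, `[`, "", 1L)
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[4] %||% NA_character_, ""),
                 NA_character_)
  name[name == "."] <- NA_character_
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[6] %||% "*", ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  genomic_intervals(chrom, start, end, name = name, strand = strand)
}

#' Write genomic intervals as BED
#'
#' Emits BED6 (chrom, start, end, name, score 0, strand), UTF-8,
#' newline-terminated; round-trips with [read_bed()].
#'
#' @param x `genomic_intervals`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- ifelse(is.na(x$name), ".", x$name)
  strand <- ifelse(x$strand %in% c("+", "-"), x$strand, ".")
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", x$chrom, x$start, x$end, name, strand)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
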