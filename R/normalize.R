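# Cross-platform harmonization: rank-invariant gene selection and a
# monotone running-median mapping of each sample onto a reference sample,
# so RNA-seq RPKM and array intensities become directly comparable.

#' Select rank-invariant genes between a target and a reference sample
#'
#' Iterative selection: starting from all shared genes, each round keeps the
#' genes whose rank differs between target and reference by less than
#' `rank_tol` of the current set size (ranks are recomputed within the
#' surviving set each round), until a fixed point or `max_iter`.
#'
#' @param target,reference numeric vectors aligned on the same genes
#'   (log scale); names are used as gene ids when present.
#' @param rank_tol relative rank tolerance in (0, 1); default 0.05.
#' @param max_iter maximum refinement rounds; default 20.
#' @return list with `genes` (surviving gene ids, or indices when unnamed),
#'   `iterations_used`, `converged`.
#' @export
rank_invariant_genes <- function(target, reference, rank_tol = 0.05,
                                 max_iter = 20L) {
  if (length(target) != length(reference))
    stop_data("target and reference must be aligned on the same genes")
  if (length(target) < 10L) stop_data("need at least 10 shared genes")
  if (rank_tol <= 0 || rank_tol >= 1) stop_data("rank_tol must lie in (0, 1)")
  ids <- names(target) %||% as.character(seq_along(target))
  keep <- seq_along(target)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    n <- length(keep)
    rt <- rank(target[keep], ties.method = "average")
    rr <- rank(reference[keep], ties.method = "average")
    surv <- abs(rt - rr) / n < rank_tol
    if (sum(surv) < 10L)
      stop_data("rank-invariant set collapsed below 10 genes; increase rank_tol (used %g)",
                rank_tol)
    if (all(surv)) { converged <- TRUE; break }
    keep <- keep[surv]
  }
  list(genes = ids[keep], iterations_used = it, converged = converged)
}

# Strictly-increasing knot sequence from running medians of the invariant
# (target, reference) pairs, sorted by target. Window = max(9, N/100),
# forced odd. Reference knots are made non-decreasing (cummax), duplicate
# target values collapsed by averaging.
normalization_knots <- function(t_inv, r_inv, window = NULL) {
  ord <- order(t_inv)
  ts <- t_inv[ord]; rs <- r_inv[ord]
  n <- length(ts)
  w <- window %||% max(9L, as.integer(n / 100))
  w <- min(w, if (n %% 2L == 1L) n else n - 1L)
  if (w %% 2L == 0L) w <- w + 1L
  if (n >= 3L && w >= 3L) {
    ts <- stats::runmed(ts, w, endrule = "median")
    rs <- stats::runmed(rs, w, endrule = "median")
  }
  xs <- as.numeric(tapply(ts, ts, mean))  # collapse duplicate target values
  ys <- as.numeric(tapply(rs, ts, mean))
  ys <- cummax(ys)
  keep <- !duplicated(xs)
  data.frame(target_value = xs[keep], reference_value = ys[keep])
}

piecewise_linear_map <- function(x, knots) {
  xs <- knots$target_value; ys <- knots$reference_value
  m <- length(xs)
  if (m < 2L) stop_data("normalization mapping needs at least 2 knots")
  y <- approx(xs, ys, xout = pmin(pmax(x, xs[1]), xs[m]), ties = "ordered")$y
  slope_lo <- (ys[2] - ys[1]) / (xs[2] - xs[1])
  slope_hi <- (ys[m] - ys[m - 1]) / (xs[m] - xs[m - 1])
  below <- x < xs[1]; above <- x > xs[m]
  y[below] <- ys[1] + slope_lo * (x[below] - xs[1])
  y[above] <- ys[m] + slope_hi * (x[above] - xs[m])
  y
}

#' Normalize a sample onto a reference via a rank-invariant monotone curve
#'
#' Fits a monotone mapping through the invariant-gene (target, reference)
#' pairs -- a running median over sorted target values, linearly
#' interpolated between knots and linearly extrapolated beyond them -- and
#' applies it to all target values. The mapping never reorders the target
#' sample (ties allowed), and normalizing a sample to itself is the
#' identity to within numerical tolerance.
#'
#' @param target,reference aligned numeric vectors (log scale).
#' @param rank_tol,max_iter passed to [rank_invariant_genes()].
#' @param invariant_genes optionally, a precomputed invariant gene set
#'   (names into `target`).
#' @param window running-median window override (odd integer).
#' @return list with `normalized` (numeric vector, same names/order as
#'   `target`) and `fit` (invariant gene set, knots, iterations, convergence).
#' @export
normalize_to_reference <- function(target, reference, rank_tol = 0.05,
                                   max_iter = 20L, invariant_genes = NULL,
                                   window = NULL) {
  ids <- names(target) %||% as.character(seq_along(target))
  if (is.null(invariant_genes)) {
    ri <- rank_invariant_genes(setNames(target, ids), setNames(reference, ids),
                               rank_tol = rank_tol, max_iter = max_iter)
    invariant_genes <- ri$genes
    iterations <- ri$iterations_used; converged <- ri$converged
  } else {
    iterations <- 0L; converged <- NA
  }
  sel <- match(invariant_genes, ids)
  knots <- normalization_knots(target[sel], reference[sel], window = window)
  normalized <- setNames(piecewise_linear_map(target, knots), ids)
  list(normalized = normalized,
       fit = list(invariant_genes = invariant_genes, mapping_knots = knots,
                  iterations_used = iterations, converged = converged))
}

#' Merge RNA-seq and array matrices into one normalized expression matrix
#'
#' Restricts both platforms to their shared genes and normalizes every
#' sample onto a single reference sample with [normalize_to_reference()].
#' The default reference is the array sample whose median expression is the
#' median among array samples (an internal-reference-array convention); the
#' reference sample itself is passed through unchanged.
#'
#' @param rnaseq `expr_matrix` on the log scale (unit `log2_rpkm`).
#' @param array `expr_matrix` on the log scale (unit `log2_intensity` or
#'   `normalized`).
#' @param reference_sample sample id of the normalization reference;
#'   default picks the median-expression array sample.
#' @param rank_tol,max_iter passed to [rank_invariant_genes()].
#' @return list with `matrix` (an `expr_matrix`, unit `normalized`; RNA-seq
#'   columns first), `platforms` (named vector sample -> platform),
#'   `reference_sample`, and `fits` (per-sample normalization fits).
#' @export
merge_platforms <- function(rnaseq, array, reference_sample = NULL,
                            rank_tol = 0.05, max_iter = 20L) {
  for (m in list(rnaseq, array)) {
    if (!inherits(m, "expr_matrix")) stop_data("merge_platforms expects expr_matrix inputs")
    if (!em_unit(m) %in% c("log2_rpkm", "log2_intensity", "normalized"))
      stop_data("merge_platforms needs log-scale inputs; got unit '%s'", em_unit(m))
  }
  shared <- intersect(rownames(rnaseq), rownames(array))
  if (length(shared) == 0L) stop_data("no shared genes between the platforms")
  if (length(shared) < 10L)
    stop_data("only %d shared genes between platforms; need at least 10",
              length(shared))
  rn <- unclass(rnaseq)[shared, , drop = FALSE]
  ar <- unclass(array)[shared, , drop = FALSE]
  if (is.null(reference_sample)) {
    meds <- apply(ar, 2, median)
    reference_sample <- colnames(ar)[order(meds)][ceiling(ncol(ar) / 2)]
  }
  all_cols <- cbind(rn, ar)
  if (!reference_sample %in% colnames(all_cols))
    stop_data("reference sample '%s' not found", reference_sample)
  ref <- all_cols[, reference_sample]
  fits <- list()
  out <- all_cols
  for (sid in colnames(all_cols)) {
    if (sid == reference_sample) next
    nf <- normalize_to_reference(all_cols[, sid], ref, rank_tol = rank_tol,
                                 max_iter = max_iter)
    out[, sid] <- nf$normalized
    fits[[sid]] <- nf$fit
  }
  platforms <- setNames(c(rep("rnaseq", ncol(rn)), rep("array", ncol(ar))),
                        colnames(all_cols))
  list(matrix = expr_matrix(out, unit = "normalized", platform = "array"),
       platforms = platforms, reference_sample = reference_sample,
       fits = fits)
}
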