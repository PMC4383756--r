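# Directional concordance: the fraction of a query-derived gene set whose
# direction of change agrees with an independent reference contrast
# (typically mDC vs pDC on the array panel).

#' Match a query gene set to a reference matrix
#'
#' @param query_set character gene ids.
#' @param reference `expr_matrix` (or any matrix with gene rownames).
#' @return the genes of `query_set` present in the reference, in query order.
#' @export
match_to_reference <- function(query_set, reference) {
  query_set[query_set %in% rownames(reference)]
}

#' Directional concordance of a gene set with a reference contrast
#'
#' For every matched gene, computes the mean over `group_high` minus the
#' mean over `group_low` in the reference (log scale). With
#' `direction = "up"`, genes with a positive difference are concordant;
#' with `"down"`, genes with a negative difference. A zero difference is
#' never concordant. The percentage is reported exactly and rounded to the
#' nearest integer; with no matched genes it is absent (`NA`).
#'
#' @param query_set character gene ids (e.g. an up- or down-regulated set
#'   from [fold_change_sets()] or [moderated_t()]).
#' @param direction `"up"` or `"down"`: the direction the query set had in
#'   the query contrast.
#' @param reference log-scale `expr_matrix` of the reference panel.
#' @param group_high,group_low disjoint, non-empty sample-id sets defining
#'   the reference contrast (e.g. pooled mDC samples vs pDC samples).
#' @return a `concordance_result` list: `n_query_set`, `n_matched`,
#'   `n_concordant`, `percent_concordant` (exact), `percent_rounded`,
#'   `direction_tested`, `contrast`, and the per-gene logical
#'   `concordant_flags`.
#' @export
directional_concordance <- function(query_set, direction = c("up", "down"),
                                    reference, group_high, group_low) {
  direction <- match.arg(direction)
  if (length(group_high) == 0L || length(group_low) == 0L)
    stop_data("both contrast groups must be non-empty")
  if (length(intersect(group_high, group_low)))
    stop_data("contrast groups must be disjoint")
  missing <- setdiff(c(group_high, group_low), colnames(reference))
  if (length(missing))
    stop_data("sample(s) not in reference: %s", paste(missing, collapse = ", "))
  matched <- match_to_reference(query_set, reference)
  v <- unclass(reference)
  diffs <- rowMeans(v[matched, group_high, drop = FALSE]) -
    rowMeans(v[matched, group_low, drop = FALSE])
  conc <- if (direction == "up") diffs > 0 else diffs < 0
  n_matched <- length(matched)
  n_conc <- sum(conc)
  pct <- if (n_matched > 0) 100 * n_conc / n_matched else NA_real_
  structure(list(n_query_set = length(query_set), n_matched = n_matched,
                 n_concordant = n_conc, percent_concordant = pct,
                 percent_rounded = if (is.na(pct)) NA_integer_ else as.integer(round(pct)),
                 direction_tested = direction,
                 contrast = c(high = paste(group_high, collapse = ","),
                              low = paste(group_low, collapse = ",")),
                 concordant_flags = setNames(as.logical(conc), matched)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Directional concordance (%s-set): %d/%d matched genes concordant",
              x$direction_tested, x$n_concordant, x$n_matched))
  if (!is.na(x$percent_concordant))
    cat(sprintf(" = %.1f%% (%d%%)", x$percent_concordant, x$percent_rounded))
  cat(sprintf("\n  query set: %d genes, %d present in reference\n",
              x$n_query_set, x$n_matched))
  invisible(x)
}
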