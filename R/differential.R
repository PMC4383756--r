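# Differential expression, two ways: plain fold-change thresholding (for
# unreplicated designs) and an empirical-Bayes moderated t-statistic with
# Benjamini-Hochberg adjustment (for replicated array panels), plus the
# RPKM expression filter applied before matching gene sets across platforms.

#' Filter genes by minimum RPKM
#'
#' Keeps genes whose maximum RPKM across samples reaches `min_rpkm`
#' (default 10); genes below the threshold in every sample are deleted.
#'
#' @param matrix `expr_matrix` with unit `rpkm`.
#' @param min_rpkm threshold (default 10).
#' @return character vector of retained gene ids.
#' @export
expression_filter <- function(matrix, min_rpkm = 10) {
  if (!inherits(matrix, "expr_matrix") || em_unit(matrix) != "rpkm")
    stop_data("expression_filter expects an expr_matrix with unit 'rpkm'")
  mx <- apply(unclass(matrix), 1, max)
  rownames(matrix)[mx >= min_rpkm]
}

#' Fold-change differential gene sets
#'
#' Splits genes into up/down sets by the difference of group means on the
#' log scale: `up` genes satisfy `mean(A) - mean(B) >= log2(fc_threshold)`,
#' `down` genes the reverse. With `mode = "linear_ratio"` the threshold is
#' instead applied to the ratio of linear-scale group means.
#'
#' @param matrix log-scale `expr_matrix`.
#' @param groupA,groupB disjoint, non-empty sample-id sets.
#' @param fc_threshold fold-change threshold `>= 1` (default 2).
#' @param mode `"log_difference"` (default) or `"linear_ratio"`.
#' @return list with character vectors `up` and `down` (disjoint) and the
#'   per-gene `log2_fold_change` (A minus B).
#' @export
fold_change_sets <- function(matrix, groupA, groupB, fc_threshold = 2,
                             mode = c("log_difference", "linear_ratio")) {
  mode <- match.arg(mode)
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop_data("both groups must be non-empty")
  if (length(intersect(groupA, groupB)))
    stop_data("groups must be disjoint")
  missing <- setdiff(c(groupA, groupB), colnames(matrix))
  if (length(missing))
    stop_data("sample(s) not in matrix: %s", paste(missing, collapse = ", "))
  if (fc_threshold < 1) stop_data("fc_threshold must be >= 1")
  v <- unclass(matrix)
  mA <- rowMeans(v[, groupA, drop = FALSE])
  mB <- rowMeans(v[, groupB, drop = FALSE])
  if (mode == "log_difference") {
    lfc <- mA - mB
  } else {
    lfc <- log2(rowMeans(2^v[, groupA, drop = FALSE]) /
                  rowMeans(2^v[, groupB, drop = FALSE]))
  }
  thr <- log2(fc_threshold)
  list(up = rownames(matrix)[lfc >= thr],
       down = rownames(matrix)[lfc <= -thr],
       log2_fold_change = setNames(lfc, rownames(matrix)))
}

# Newton inversion of the trigamma function (monotone decreasing on (0,
# Inf)); used by the method-of-moments fit of the variance prior.
trigamma_inverse <- function(x) {
  out <- x
  lo <- x < 1e-6; hi <- x > 1e7
  out[lo] <- 1 / sqrt(x[lo])
  out[hi] <- 1 / x[hi]
  mid <- which(!lo & !hi)
  y <- 0.5 + 1 / x[mid]
  for (i in seq_len(50)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-8) break
  }
  out[mid] <- y
  out
}

# Method-of-moments fit of the scaled-F model for gene-wise sample
# variances: log(s^2) has a shifted log-F distribution whose mean and
# variance identify the prior degrees of freedom d0 and prior variance s0^2.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    warning("degenerate gene-wise variances; falling back to prior_df = 4")
    return(list(d0 = 4, s0_sq = max(median(s2), 1e-8)))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (!is.finite(evar)) {
    warning("degenerate gene-wise variances; falling back to prior_df = 4")
    return(list(d0 = 4, s0_sq = exp(emean)))
  }
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread in log s^2 beyond chi-square sampling noise: the
    # prior absorbs everything and s0^2 is the mean sample variance
    d0 <- Inf
    s0_sq <- mean(s2[ok])
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated t-test between two groups
#'
#' Per gene, an ordinary two-group linear-model variance `s_g^2` with
#' residual df `n_A + n_B - 2` is shrunk toward a prior variance `s_0^2`
#' estimated, together with the prior df `d_0`, by method-of-moments on
#' `log s_g^2`:
#' `s~_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)`.
#' The moderated t is the mean difference over `s~_g sqrt(1/n_A + 1/n_B)`,
#' with two-sided p-values on `d_0 + d_g` degrees of freedom, BH-adjusted.
#'
#' @param matrix log-scale `expr_matrix`.
#' @param groupA,groupB disjoint sample-id sets, each with at least 2
#'   samples (use [fold_change_sets()] for unreplicated designs).
#' @param prior_df optional override of the estimated `d_0`: `0` gives the
#'   ordinary pooled t-test, `Inf` full shrinkage to the prior variance.
#' @param alpha significance level for the `direction` call (default 0.05).
#' @return data.frame with columns `gene_id`, `log2_fold_change` (A minus
#'   B), `t_moderated`, `p_value`, `adj_p_value`, `direction` (`up`, `down`,
#'   `ns`), carrying the prior fit as attribute `ebayes`
#'   (`d0`, `s0_sq`, `df_residual`, `sg_sq`, `s_tilde_sq`).
#' @export
moderated_t <- function(matrix, groupA, groupB, prior_df = NULL, alpha = 0.05) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop_data("each group needs >= 2 samples for a variance estimate; use fold_change_sets for unreplicated designs")
  if (length(intersect(groupA, groupB))) stop_data("groups must be disjoint")
  missing <- setdiff(c(groupA, groupB), colnames(matrix))
  if (length(missing))
    stop_data("sample(s) not in matrix: %s", paste(missing, collapse = ", "))
  v <- unclass(matrix)
  a <- v[, groupA, drop = FALSE]; b <- v[, groupB, drop = FALSE]
  nA <- ncol(a); nB <- ncol(b)
  dg <- nA + nB - 2L
  mA <- rowMeans(a); mB <- rowMeans(b)
  ssA <- rowSums((a - mA)^2); ssB <- rowSums((b - mB)^2)
  sg_sq <- (ssA + ssB) / dg
  prior <- fit_variance_prior(sg_sq, dg)
  d0 <- prior_df %||% prior$d0
  s0_sq <- prior$s0_sq
  s_tilde_sq <- if (is.infinite(d0)) rep(s0_sq, length(sg_sq)) else
    (d0 * s0_sq + dg * sg_sq) / (d0 + dg)
  lfc <- mA - mB
  tmod <- lfc / sqrt(s_tilde_sq * (1 / nA + 1 / nB))
  df_total <- d0 + dg
  p <- 2 * pt(-abs(tmod), df = df_total)
  adj <- bh_adjust(p)
  dir <- ifelse(adj < alpha, ifelse(lfc > 0, "up", "down"), "ns")
  res <- data.frame(gene_id = rownames(matrix), log2_fold_change = lfc,
                    t_moderated = tmod, p_value = p, adj_p_value = adj,
                    direction = dir, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(res, "ebayes") <- list(d0 = d0, s0_sq = s0_sq, df_residual = dg,
                              sg_sq = sg_sq, s_tilde_sq = s_tilde_sq)
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: sorted ascending,
#' `q_i = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order. Delegates to `stats::p.adjust(method = "BH")` after validation.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop_data("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}
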