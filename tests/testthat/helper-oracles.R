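# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles deliberately use naive formulations (per-base loops,
# from-scratch agglomeration, literal definitions) so they share no code
# path with the implementation they check.

# Per-base membership read counting: a read counts if any of its bases lies
# inside any region interval on the same chromosome.
oracle_count_reads <- function(reads, region) {
  cnt <- 0L
  for (i in seq_len(nrow(reads))) {
    if (!reads$uniquely_mapped[i]) next
    bases <- seq.int(reads$start[i], reads$end[i] - 1L)
    hit <- FALSE
    for (j in seq_len(nrow(region))) {
      if (region$chrom[j] == reads$chrom[i] &&
          any(bases >= region$start[j] & bases < region$end[j])) {
        hit <- TRUE
        break
      }
    }
    cnt <- cnt + hit
  }
  cnt
}

# Greedy complete-linkage agglomeration from the definition: at each step
# merge the two clusters whose maximum pairwise member distance is
# smallest; record that height as the cophenetic distance of all
# cross-cluster pairs.
oracle_complete_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL
    bh <- Inf
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < bh) {
          bh <- h
          best <- c(i, j)
        }
      }
    }
    a <- clusters[[best[1]]]
    b <- clusters[[best[2]]]
    coph[a, b] <- bh
    coph[b, a] <- bh
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(sorted[i:m] * m / (i:m))
  res <- numeric(m)
  res[o] <- pmin(q, 1)
  res
}

# Ordinary two-sample pooled-variance t-statistic, coded from the formula.
oracle_pooled_t <- function(a, b) {
  nA <- ncol(a); nB <- ncol(b)
  mA <- rowMeans(a); mB <- rowMeans(b)
  sp2 <- (rowSums((a - mA)^2) + rowSums((b - mB)^2)) / (nA + nB - 2)
  (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
}

# Textbook direct-summation Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

rand_expr_matrix <- function(n_genes, n_samples, unit = "log2_intensity",
                             platform = "array", seed = 1) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n_genes * n_samples, 7, 1.5), n_genes, n_samples,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
  })
  expr_matrix(v, unit = unit, platform = platform)
}

# Small-but-structured simulation config used where full scale is not needed.
small_sim_config <- function(seed, n_genes = 400L, ...) {
  sim_config(n_genes = n_genes, module_sizes = c(pdc = 30L, mdc = 30L),
             n_de_up = 60L, n_de_down = 60L, library_size = 50000L,
             seed = seed, ...)
}
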