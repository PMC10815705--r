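# fixture builders shared across test files

# study from explicit log2(TPM + 1) values per group: each element of
# `groups` is a genotype -> matrix of log2 values (genes x replicates)
study_from_log2 <- function(groups, pseudocount = 1) {
  mats <- lapply(names(groups), function(g) {
    m <- groups[[g]]
    tpm <- 2^m - pseudocount
    colnames(tpm) <- paste(g, seq_len(ncol(tpm)), sep = "_")
    tpm
  })
  tpm <- do.call(cbind, mats)
  rownames(tpm) <- sprintf("g%03d", seq_len(nrow(tpm)))
  genotype <- rep(names(groups), vapply(groups, ncol, integer(1)))
  design <- data.frame(
    sample = colnames(tpm), genotype = genotype,
    replicate = unlist(lapply(groups, function(m) seq_len(ncol(m)))),
    stringsAsFactors = FALSE)
  expression_study(tpm, design)
}

# minimal study: per-genotype mean TPM vectors, constant across replicates
# plus tiny deterministic jitter so variances are non-zero
study_from_means <- function(means_by_genotype, n_rep = 4, jitter = 0.01) {
  genes <- rownames(means_by_genotype) %||%
    sprintf("g%03d", seq_len(nrow(means_by_genotype)))
  cols <- list()
  for (g in colnames(means_by_genotype)) {
    for (r in seq_len(n_rep)) {
      cols[[paste(g, r, sep = "_")]] <-
        means_by_genotype[, g] * (1 + jitter * (r - (n_rep + 1) / 2))
    }
  }
  tpm <- do.call(cbind, cols)
  rownames(tpm) <- genes
  design <- data.frame(
    sample = colnames(tpm),
    genotype = rep(colnames(means_by_genotype), each = n_rep),
    replicate = rep(seq_len(n_rep), times = ncol(means_by_genotype)),
    stringsAsFactors = FALSE)
  expression_study(tpm, design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# long contrast table straight from fc/p values, with DEG flags derived
# from the stated thresholds
mk_contrasts <- function(df, fc_threshold = 1.5, p_threshold = 0.05) {
  df$deg_up <- !is.na(df$fc) & !is.na(df$p) &
    df$fc > fc_threshold & df$p < p_threshold
  df$deg_down <- !is.na(df$fc) & !is.na(df$p) &
    df$fc < 1 / fc_threshold & df$p < p_threshold
  df
}

# exhaustive upper-tail hypergeometric oracle from binomial coefficients
# (independent of phyper)
hyper_tail_oracle <- function(k, K, n, N) {
  j <- max(0, k):min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# brute-force Benjamini-Hochberg, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
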