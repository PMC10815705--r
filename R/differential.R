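# expression filtering, knockout-vs-WT contrasts, comparative-Ct qPCR

#' Keep the top expression quantile of genes
#'
#' Retains exactly `floor(quantile * n_genes)` genes with the highest mean
#' TPM across all samples — the "significantly detected" filter applied
#' before DEG calling (upper 25% by default). Ties at the cutoff are broken
#' by gene-id lexicographic order so the result is reproducible; gene and
#' sample order of the input are preserved in the output.
#'
#' @param study An [expression_study()].
#' @param quantile Fraction of genes to keep, in (0, 1].
#' @return A filtered [expression_study()].
#' @export
filter_expressed <- function(study, quantile = 0.25) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (nrow(study$tpm) == 0L) stop("empty TPM matrix", call. = FALSE)
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile > 1) {
    stop("quantile must lie in (0, 1]", call. = FALSE)
  }
  n_keep <- floor(quantile * nrow(study$tpm))
  if (n_keep == 0L) {
    warning("quantile keeps zero genes", call. = FALSE)
  }
  means <- rowMeans(study$tpm)
  ord <- order(-means, rownames(study$tpm), method = "radix")
  keep <- rownames(study$tpm)[ord][seq_len(n_keep)]
  tpm <- study$tpm[rownames(study$tpm) %in% keep, , drop = FALSE]
  expression_study(tpm, study$design)
}

#' Differential expression of one knockout genotype versus WT
#'
#' Per gene: fold change as the ratio of mean TPM (mutant over WT, on the
#' raw scale so it is independent of the pseudocount), and a two-sided
#' Student's t-test on `log2(TPM + pseudocount)` with pooled variance and
#' `df = n1 + n2 - 2` (Welch's correction available via `var_equal = FALSE`).
#' DEG flags use strict inequalities: `deg_up` iff `fc > fc_threshold` and
#' `p < p_threshold`; `deg_down` iff `fc < 1/fc_threshold` and
#' `p < p_threshold` (one fold-change criterion applied symmetrically in
#' both directions). No multiple-testing correction enters the flags —
#' BH-adjusted q-values are emitted as an extra column for users.
#'
#' Degenerate genes are handled explicitly: zero within-group variance in
#' both groups with equal means gives p = 1; zero variance with unequal
#' means gives p = 0 with `degenerate = TRUE`; a 0/0 fold change is `NaN`
#' with `fc_undefined = TRUE` and never flagged.
#'
#' @param study An [expression_study()] containing WT and the requested
#'   genotype with >= 2 replicates each.
#' @param genotype One of `"N1KO"`, `"N2KO"`, `"NDKO"`.
#' @param fc_threshold Primary fold-change threshold (default 1.5).
#' @param p_threshold p-value threshold (default 0.05).
#' @param pseudocount Added to TPM before the log2 transform (default 1).
#' @param var_equal Pooled-variance Student's t if `TRUE` (default), Welch
#'   otherwise.
#' @return Data frame with one row per gene: `gene`, `genotype`, `mean_wt`,
#'   `mean_mut`, `fc`, `log2fc`, `t`, `p`, `q`, `deg_up`, `deg_down`,
#'   `fc_undefined`, `degenerate`.
#' @export
contrast <- function(study, genotype, fc_threshold = 1.5,
                     p_threshold = 0.05, pseudocount = 1,
                     var_equal = TRUE) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (!genotype %in% MUTANT_GENOTYPES) {
    stop("genotype must be one of ", paste(MUTANT_GENOTYPES, collapse = ", "),
         call. = FALSE)
  }
  wt_samples <- study$design$sample[study$design$genotype == "WT"]
  mu_samples <- study$design$sample[study$design$genotype == genotype]
  if (length(mu_samples) == 0L) {
    stop("genotype ", genotype, " absent from design", call. = FALSE)
  }
  if (length(wt_samples) < 2L || length(mu_samples) < 2L) {
    stop("need >= 2 replicates in WT and ", genotype, call. = FALSE)
  }
  X <- study$tpm[, wt_samples, drop = FALSE]
  Y <- study$tpm[, mu_samples, drop = FALSE]
  n1 <- ncol(X)
  n2 <- ncol(Y)

  mean_wt <- rowMeans(X)
  mean_mut <- rowMeans(Y)
  fc <- mean_mut / mean_wt
  fc_undefined <- is.nan(fc)
  log2fc <- log2(fc)

  L1 <- log2(X + pseudocount)
  L2 <- log2(Y + pseudocount)
  m1 <- rowMeans(L1)
  m2 <- rowMeans(L2)
  v1 <- rowSums((L1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((L2 - m2)^2) / (n2 - 1)

  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(tstat), df)

  zero_se <- se == 0
  eq_means <- abs(m2 - m1) <= 1e-12 * (1 + abs(m1) + abs(m2))
  degenerate <- zero_se & !eq_means
  p[zero_se & eq_means] <- 1
  tstat[zero_se & eq_means] <- 0
  p[degenerate] <- 0
  tstat[degenerate] <- sign(m2 - m1)[degenerate] * Inf

  q <- stats::p.adjust(p, method = "BH")
  deg_up <- !is.na(fc) & !is.na(p) & fc > fc_threshold & p < p_threshold
  deg_down <- !is.na(fc) & !is.na(p) & fc < 1 / fc_threshold & p < p_threshold

  data.frame(gene = rownames(study$tpm), genotype = genotype,
             mean_wt = mean_wt, mean_mut = mean_mut, fc = fc,
             log2fc = log2fc, t = tstat, p = p, q = q,
             deg_up = deg_up, deg_down = deg_down,
             fc_undefined = fc_undefined, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Contrasts of all mutant genotypes against WT
#'
#' Convenience wrapper running [contrast()] for each mutant genotype present
#' in the design and row-binding the results.
#'
#' @inheritParams contrast
#' @param genotypes Mutant genotypes to test (default all three).
#' @return Long data frame, one row per gene x genotype.
#' @export
contrast_all <- function(study, genotypes = MUTANT_GENOTYPES,
                         fc_threshold = 1.5, p_threshold = 0.05,
                         pseudocount = 1, var_equal = TRUE) {
  out <- lapply(genotypes, function(g) {
    contrast(study, g, fc_threshold = fc_threshold,
             p_threshold = p_threshold, pseudocount = pseudocount,
             var_equal = var_equal)
  })
  do.call(rbind, out)
}

#' Comparative-Ct (delta-delta-Ct) relative quantification
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; `ddCt = dCt - mean(dCt)`
#' over the control group; relative expression `= 2^(-ddCt)`, so the
#' control-group mean of `-ddCt` is 0 and its geometric-mean expression is 1.
#' Samples with missing Ct values are dropped with a warning.
#'
#' @param qpcr Data frame with columns `sample`, `group`, `ct_target`,
#'   `ct_reference` (threshold cycles).
#' @param control_group Group label whose mean dCt is the calibrator.
#' @return The input rows (minus any skipped samples) with added columns
#'   `dct`, `ddct`, `rel_expr`.
#' @examples
#' q <- data.frame(sample = c("c1", "t1"), group = c("WT", "KO"),
#'                 ct_target = c(20, 19), ct_reference = c(15, 15))
#' ddct(q, "WT")$rel_expr # 1, 2
#' @export
ddct <- function(qpcr, control_group) {
  need <- c("sample", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(qpcr))) {
    stop("qpcr table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- is.na(qpcr$ct_target) | is.na(qpcr$ct_reference)
  if (any(bad)) {
    warning("skipping sample(s) with missing Ct: ",
            paste(qpcr$sample[bad], collapse = ", "), call. = FALSE)
    qpcr <- qpcr[!bad, , drop = FALSE]
  }
  ctrl <- qpcr$group == control_group
  if (!any(ctrl)) {
    stop("control group '", control_group, "' empty or absent",
         call. = FALSE)
  }
  qpcr$dct <- qpcr$ct_target - qpcr$ct_reference
  qpcr$ddct <- qpcr$dct - mean(qpcr$dct[ctrl])
  qpcr$rel_expr <- 2^(-qpcr$ddct)
  rownames(qpcr) <- NULL
  qpcr
}
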