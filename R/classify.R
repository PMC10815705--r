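# partition double-knockout DEGs into redundant vs isoform-dominant classes

#' Classify double-knockout DEGs by isoform dominance
#'
#' Every gene flagged as a DEG in the NDKO-vs-WT contrast receives exactly
#' one class per direction:
#' \describe{
#'   \item{alpha_dominant}{also a same-direction DEG in N1KO, while N2KO
#'     changes less than `fc_secondary`-fold (up: `fc_N2 < fc_secondary`;
#'     down: `fc_N2 > 1/fc_secondary`) — evidence that the first paralog
#'     carries the regulation.}
#'   \item{beta_dominant}{the mirror image (DEG in N2KO, N1KO below the
#'     secondary bound).}
#'   \item{ndko_exclusive}{a DEG in neither single knockout — redundant or
#'     compensatory regulation revealed only by the double knockout.}
#'   \item{shared}{everything else: significant in one or both single
#'     knockouts but failing a dominance criterion (e.g. the other single
#'     mutant exceeds the secondary bound).}
#'   \item{ambiguous}{qualifies as both alpha- and beta-dominant, possible
#'     only under conflicting threshold settings.}
#' }
#' The secondary criterion is a fold-change bound only — no p-value
#' requirement on the other single mutant. The down-direction secondary
#' bound is the reciprocal of the up-direction one, i.e. "less than a
#' 1.3-fold decrease".
#'
#' @param contrasts Long contrast table from [contrast_all()]; must contain
#'   rows for all three mutant genotypes for every gene.
#' @param fc_secondary Secondary fold-change bound on the non-dominant
#'   single knockout (default 1.3).
#' @return Data frame with one row per NDKO DEG: `gene`, `direction`
#'   (`"up"`/`"down"`), `class`, and the supporting `fc_N1`, `p_N1`,
#'   `fc_N2`, `p_N2`, `fc_ND`, `p_ND`.
#' @export
classify_isoforms <- function(contrasts, fc_secondary = 1.3) {
  w <- widen_contrasts(contrasts)
  out <- lapply(c("up", "down"), function(direction) {
    if (direction == "up") {
      nd_deg <- w$deg_up_ND
      deg1 <- w$deg_up_N1
      deg2 <- w$deg_up_N2
      sec1 <- w$fc_N1 < fc_secondary      # N1 below bound (for beta)
      sec2 <- w$fc_N2 < fc_secondary      # N2 below bound (for alpha)
    } else {
      nd_deg <- w$deg_down_ND
      deg1 <- w$deg_down_N1
      deg2 <- w$deg_down_N2
      sec1 <- w$fc_N1 > 1 / fc_secondary
      sec2 <- w$fc_N2 > 1 / fc_secondary
    }
    sec1[is.na(sec1)] <- FALSE
    sec2[is.na(sec2)] <- FALSE
    keep <- which(nd_deg)
    if (length(keep) == 0L) return(NULL)
    a <- deg1[keep] & sec2[keep]
    b <- deg2[keep] & sec1[keep]
    cls <- ifelse(a & b, "ambiguous",
           ifelse(a, "alpha_dominant",
           ifelse(b, "beta_dominant",
           ifelse(!deg1[keep] & !deg2[keep], "ndko_exclusive", "shared"))))
    data.frame(gene = w$gene[keep], direction = direction, class = cls,
               fc_N1 = w$fc_N1[keep], p_N1 = w$p_N1[keep],
               fc_N2 = w$fc_N2[keep], p_N2 = w$p_N2[keep],
               fc_ND = w$fc_ND[keep], p_ND = w$p_ND[keep],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene = character(), direction = character(),
                      class = character(), fc_N1 = numeric(),
                      p_N1 = numeric(), fc_N2 = numeric(), p_N2 = numeric(),
                      fc_ND = numeric(), p_ND = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

# reshape the long contrast table to one row per gene with per-genotype
# columns; errors name the first gene missing a genotype row
widen_contrasts <- function(contrasts) {
  need <- c("gene", "genotype", "fc", "p", "deg_up", "deg_down")
  if (!all(need %in% names(contrasts))) {
    stop("contrast table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  genes <- unique(contrasts$gene)
  short <- c(N1KO = "N1", N2KO = "N2", NDKO = "ND")
  w <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (g in MUTANT_GENOTYPES) {
    rows <- contrasts[contrasts$genotype == g, , drop = FALSE]
    idx <- match(genes, rows$gene)
    if (anyNA(idx)) {
      stop("gene '", genes[which(is.na(idx))[1L]],
           "' has no contrast row for genotype ", g, call. = FALSE)
    }
    w[[paste0("fc_", short[[g]])]] <- rows$fc[idx]
    w[[paste0("p_", short[[g]])]] <- rows$p[idx]
    w[[paste0("deg_up_", short[[g]])]] <- rows$deg_up[idx]
    w[[paste0("deg_down_", short[[g]])]] <- rows$deg_down[idx]
  }
  w
}

#' Venn summary of DEG sets across mutant genotypes
#'
#' For each direction, tabulates the per-genotype DEG sets, all seven
#' intersection cells of the three-way Venn diagram, and the
#' NDKO-exclusive fraction `100 * |NDKO only| / |NDKO|` (the headline
#' measure of redundant regulation), rounded to two decimals via
#' [exclusive_fraction()]. An empty NDKO set yields `NA` for the fraction.
#'
#' @inheritParams classify_isoforms
#' @return Data frame with one row per direction: totals `n_N1`, `n_N2`,
#'   `n_ND`; cells `n1_only`, `n2_only`, `nd_only`, `n1_n2`, `n1_nd`,
#'   `n2_nd`, `all3` (cells are disjoint and sum to the union); and
#'   `ndko_exclusive_pct`.
#' @export
venn_summary <- function(contrasts) {
  w <- widen_contrasts(contrasts)
  rows <- lapply(c("up", "down"), function(direction) {
    flag <- if (direction == "up") "deg_up_" else "deg_down_"
    in1 <- w[[paste0(flag, "N1")]]
    in2 <- w[[paste0(flag, "N2")]]
    ind <- w[[paste0(flag, "ND")]]
    data.frame(direction = direction,
               n_N1 = sum(in1), n_N2 = sum(in2), n_ND = sum(ind),
               n1_only = sum(in1 & !in2 & !ind),
               n2_only = sum(!in1 & in2 & !ind),
               nd_only = sum(!in1 & !in2 & ind),
               n1_n2 = sum(in1 & in2 & !ind),
               n1_nd = sum(in1 & !in2 & ind),
               n2_nd = sum(!in1 & in2 & ind),
               all3 = sum(in1 & in2 & ind),
               ndko_exclusive_pct =
                 exclusive_fraction(sum(!in1 & !in2 & ind), sum(ind)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' NDKO-exclusive fraction from Venn counts
#'
#' `round(100 * n_exclusive / n_total, 2)` — the percentage of
#' double-knockout DEGs not significant in either single knockout, reported
#' to two decimals. Vectorised; `n_total = 0` yields `NA` (not applicable).
#'
#' @param n_exclusive Count of DEGs exclusive to the double knockout.
#' @param n_total Total double-knockout DEG count.
#' @return Numeric percentage(s) in \[0, 100\].
#' @examples
#' exclusive_fraction(757, 1033) # 73.28
#' exclusive_fraction(955, 1495) # 63.88
#' @export
exclusive_fraction <- function(n_exclusive, n_total) {
  out <- ifelse(n_total > 0, round(100 * n_exclusive / n_total, 2), NA_real_)
  as.numeric(out)
}
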