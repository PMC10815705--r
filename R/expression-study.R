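# ExpressionStudy: a TPM matrix tied to a genotype/replicate design

#' Construct an ExpressionStudy
#'
#' Bundles a genes-by-samples TPM matrix with its design table. TPM
#' (transcripts per million) is a within-sample normalised expression unit;
#' all downstream differential-expression operations start from this
#' container.
#'
#' @param tpm Numeric matrix of non-negative TPM values, genes in rows
#'   (rownames are gene ids), samples in columns (colnames are sample ids).
#' @param design Data frame with columns `sample`, `genotype` (one of
#'   [GENOTYPES]) and `replicate` (integer index within genotype).
#'
#' @return An object of class `ExpressionStudy`: a list with elements
#'   `tpm` and `design`.
#' @examples
#' tpm <- matrix(c(10, 20, 12, 22), nrow = 2,
#'               dimnames = list(c("A", "B"), c("WT_1", "WT_2")))
#' design <- data.frame(sample = c("WT_1", "WT_2"),
#'                      genotype = "WT", replicate = 1:2)
#' expression_study(tpm, design)
#' @export
expression_study <- function(tpm, design) {
  if (!is.matrix(tpm) || !is.numeric(tpm)) {
    stop("`tpm` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(tpm)) || is.null(colnames(tpm))) {
    stop("`tpm` must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(tpm))) {
    stop("duplicate gene ids in TPM matrix", call. = FALSE)
  }
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be >= 0", call. = FALSE)
  need <- c("sample", "genotype", "replicate")
  if (!all(need %in% names(design))) {
    stop("design must have columns sample, genotype, replicate", call. = FALSE)
  }
  design <- design[need]
  design$sample <- as.character(design$sample)
  design$genotype <- as.character(design$genotype)
  bad <- setdiff(unique(design$genotype), GENOTYPES)
  if (length(bad) > 0L) {
    stop("unknown genotype(s) in design: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  missing_in_matrix <- setdiff(design$sample, colnames(tpm))
  if (length(missing_in_matrix) > 0L) {
    stop("design sample(s) absent from matrix: ",
         paste(missing_in_matrix, collapse = ", "), call. = FALSE)
  }
  missing_in_design <- setdiff(colnames(tpm), design$sample)
  if (length(missing_in_design) > 0L) {
    stop("sample(s) in matrix but not in design: ",
         paste(missing_in_design, collapse = ", "), call. = FALSE)
  }
  # keep design in matrix column order
  design <- design[match(colnames(tpm), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(tpm = tpm, design = design), class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf("ExpressionStudy: %d genes x %d samples\n",
              nrow(x$tpm), ncol(x$tpm)))
  tab <- table(factor(x$design$genotype, levels = GENOTYPES))
  cat("samples per genotype:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read an ExpressionStudy from TSV files
#'
#' Reads the TPM matrix (first column gene id, remaining columns one per
#' sample) and the design table (`sample`, `genotype`, `replicate`) in the
#' dialect written by [write_expression()]. Malformed inputs are rejected
#' with errors naming the offending file line or sample.
#'
#' @param matrix_path Path to the TPM TSV.
#' @param design_path Path to the design TSV.
#' @return An [expression_study()].
#' @export
read_expression <- function(matrix_path, design_path) {
  mat_df <- read_tsv(matrix_path)
  if (ncol(mat_df) < 2L) {
    stop("TPM matrix needs a gene-id column plus at least one sample column",
         call. = FALSE)
  }
  offset <- n_comment_lines(matrix_path) + 1L # metadata lines + header
  gene <- as.character(mat_df[[1L]])
  dup <- which(duplicated(gene))
  if (length(dup) > 0L) {
    stop(sprintf("duplicate gene id '%s' on line %d of %s",
                 gene[dup[1L]], dup[1L] + offset, matrix_path), call. = FALSE)
  }
  tpm <- as.matrix(mat_df[, -1L, drop = FALSE])
  storage.mode(tpm) <- "double"
  rownames(tpm) <- gene

  des_df <- read_tsv(design_path)
  need <- c("sample", "genotype", "replicate")
  if (!all(need %in% names(des_df))) {
    stop("design file must have columns sample, genotype, replicate",
         call. = FALSE)
  }
  d_offset <- n_comment_lines(design_path) + 1L
  bad <- which(!(des_df$genotype %in% GENOTYPES))
  if (length(bad) > 0L) {
    stop(sprintf("unknown genotype '%s' on line %d of %s",
                 des_df$genotype[bad[1L]], bad[1L] + d_offset, design_path),
         call. = FALSE)
  }
  expression_study(tpm, des_df)
}

#' Write an ExpressionStudy to TSV files
#'
#' @param study An [expression_study()].
#' @param matrix_path,design_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(study, matrix_path, design_path) {
  stopifnot(inherits(study, "ExpressionStudy"))
  mat_df <- data.frame(gene_id = rownames(study$tpm), study$tpm,
                       check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(mat_df, matrix_path)
  write_tsv(study$design, design_path)
  invisible(c(matrix_path, design_path))
}
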