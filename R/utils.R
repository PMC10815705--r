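# shared helpers and the fixed genotype vocabulary

#' Genotype vocabulary
#'
#' The four genotypes of the wild-type / single-knockout / double-knockout
#' design: `WT`, `N1KO` (first paralog ablated), `N2KO` (second paralog
#' ablated), `NDKO` (both). The classifier's semantics are tied to this
#' single/single/double structure, so the vocabulary is fixed; map other
#' naming schemes onto it when constructing the design table.
#'
#' @format Character vectors.
#' @export
GENOTYPES <- c("WT", "N1KO", "N2KO", "NDKO")

#' @rdname GENOTYPES
#' @export
MUTANT_GENOTYPES <- c("N1KO", "N2KO", "NDKO")

`%||%` <- function(a, b) if (is.null(a)) b else a

# TSV with '#'-prefixed metadata lines; all pipeline tables go through these
# so byte-identical re-runs are achievable.
write_tsv <- function(df, path, meta = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta) > 0L) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# count leading '#' metadata lines so parse errors can name file lines
n_comment_lines <- function(path) {
  n <- 0L
  con <- file(path, open = "rt")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || !startsWith(ln, "#")) break
    n <- n + 1L
  }
  n
}

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
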