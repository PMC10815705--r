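# Fisher's-exact (hypergeometric) gene-set overrepresentation against GMT
# libraries; the statistic behind web overrepresentation tools, computed
# locally so it can be audited and tested

#' Read a GMT gene-set library
#'
#' Standard GMT: one term per line, `term<TAB>description<TAB>gene1<TAB>...`.
#' Parsing is delegated to [fgsea::gmtPathways()]; empty sets are dropped
#' with a warning and duplicate term names rejected.
#'
#' @param path Path to a `.gmt` file.
#' @param toupper Upper-case all gene symbols (gene matching everywhere in
#'   this package is case-sensitive, so harmonise case at read time if your
#'   sources disagree).
#' @return Named list of character vectors (term -> gene symbols).
#' @export
read_gmt <- function(path, toupper = FALSE) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) {
    stop("duplicate term names in ", path, call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(g[nzchar(g)]))
  if (toupper) sets <- lapply(sets, base::toupper)
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) {
    warning("dropping empty term(s): ",
            paste(names(sets)[empty], collapse = ", "), call. = FALSE)
    sets <- sets[!empty]
  }
  sets
}

#' Upper-tail hypergeometric overrepresentation p-value
#'
#' `P(X >= k)` for `X ~ Hypergeom(N, K, n)`: the probability that a random
#' query of size `n` drawn from a universe of `N` genes, of which `K` belong
#' to the term, overlaps the term in at least `k` genes. One-sided by
#' construction (overrepresentation only), identical to the one-sided
#' Fisher's exact test on the 2x2 overlap table. Vectorised over all
#' arguments; numerically stable up to `N` of at least 1e5.
#'
#' @param k Observed overlap count.
#' @param K Term size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return p-value(s) in (0, 1]; `k = 0` gives exactly 1.
#' @export
overrep_p <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Overrepresentation test of one query set against one term
#'
#' Query and term are intersected with the universe before counting, then
#' the upper-tail hypergeometric probability [overrep_p()] is computed.
#'
#' @param query Character vector of query gene symbols.
#' @param term Character vector of term gene symbols.
#' @param universe Character vector: the background gene set (typically the
#'   expressed genes after [filter_expressed()], not the whole genome).
#' @return List with elements `k`, `K`, `n`, `N`, `p`.
#' @examples
#' u <- sprintf("g%02d", 1:20)
#' fisher_overrep(u[1:5], u[1:5], u)$p # 1 / choose(20, 5)
#' @export
fisher_overrep <- function(query, term, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  q <- intersect(unique(query), universe)
  s <- intersect(unique(term), universe)
  k <- length(intersect(q, s))
  if (length(q) == 0L) {
    warning("query empty after universe intersection", call. = FALSE)
    return(list(k = 0L, K = length(s), n = 0L, N = length(universe), p = 1))
  }
  list(k = k, K = length(s), n = length(q), N = length(universe),
       p = overrep_p(k, length(s), length(q), length(universe)))
}

#' Overrepresentation of a query list against a whole GMT library
#'
#' One row per term with at least `min_term_size` genes inside the universe.
#' p-values are BH-adjusted across the tested terms of this library only
#' (libraries are queried independently, so each gets its own correction).
#' Rows are sorted by ascending p, ties by descending `overlap_pct`
#' (`100 * k / K`, the fraction of the term covered) then term name.
#'
#' @inheritParams fisher_overrep
#' @param library Named list of gene sets, as from [read_gmt()].
#' @param min_term_size Minimum term size within the universe (default 3).
#' @return Data frame: `term`, `k`, `K`, `n`, `N`, `overlap_pct`,
#'   `query_frac` (`k / n`), `p`, `q`.
#' @export
enrich <- function(query, library, universe, min_term_size = 3) {
  if (length(library) == 0L) stop("empty gene-set library", call. = FALSE)
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) < length(query)) {
    stop("universe smaller than query", call. = FALSE)
  }
  q <- intersect(query, universe)
  if (length(q) == 0L && length(query) > 0L) {
    warning("query empty after universe intersection", call. = FALSE)
  }
  N <- length(universe)
  n <- length(q)
  K <- vapply(library, function(s) length(intersect(unique(s), universe)),
              integer(1))
  keep <- K >= min_term_size
  library <- library[keep]
  K <- K[keep]
  if (length(library) == 0L) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), overlap_pct = numeric(),
                      query_frac = numeric(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  k <- vapply(library, function(s) length(intersect(q, s)), integer(1))
  p <- overrep_p(k, K, n, N)
  qv <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = names(library), k = k, K = K, n = n, N = N,
                    overlap_pct = 100 * k / K,
                    query_frac = if (n > 0) k / n else NA_real_,
                    p = p, q = qv,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, -out$overlap_pct, out$term, method = "radix"), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
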