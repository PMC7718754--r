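# Functional-term enrichment among TE-adjacent genes: one-sided (upper
# tail) hypergeometric test per term over a flat gene-to-term table, with
# Benjamini-Hochberg FDR control.  The background universe is the gene set
# used for the proximity analysis, not the whole genome.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment `q_(i) = min_{j >= i} (m p_(j) / j)`, mapped back to
#' the input order and capped at 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    rs_abort("p-values must be in [0, 1]", "invalid_argument")
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric term enrichment
#'
#' For each term with at least `min_term` background genes, tests
#' over-representation of the term among the query genes: with `N`
#' background genes, `K` of them in the term, a query of size `n` and `k`
#' query genes in the term,
#' `p = sum_{i = k}^{min(K, n)} C(K, i) C(N-K, n-i) / C(N, n)`.
#' BH q-values are computed over the tested terms and results are sorted
#' by q, then p.
#'
#' @param query Character vector of gene ids (must be a subset of
#'   `background`).
#' @param background Character vector: the gene universe.
#' @param terms Data frame with columns `term_id`, `term_name`, `gene_id`
#'   (one gene per row), as from [simulate_term_mapping()] or a TSV; term
#'   genes outside the background are ignored.
#' @param min_term Minimum term size within the background (default 5).
#' @return Data frame `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p`,
#'   `q`, sorted by `q` then `p`.
#' @export
hypergeom_enrich <- function(query, background, terms, min_term = 5) {
  query <- unique(query); background <- unique(background)
  stray <- setdiff(query, background)
  if (length(stray) > 0)
    rs_abort(paste0("query genes not in background: ",
                    paste(utils::head(stray, 10), collapse = ", ")),
             "invalid_argument")
  N <- length(background)
  n <- length(query)
  term_genes <- split(terms$gene_id, terms$term_id)
  term_name <- terms$term_name[!duplicated(terms$term_id)]
  names(term_name) <- terms$term_id[!duplicated(terms$term_id)]
  rows <- list()
  for (tid in names(term_genes)) {
    genes <- intersect(unique(term_genes[[tid]]), background)
    K <- length(genes)
    if (K < min_term) next
    k <- length(intersect(genes, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[tid]] <- data.frame(term_id = tid,
                              term_name = unname(term_name[tid]),
                              k = k, K = K, n = n, N = N, p = p,
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$q, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
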