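# hypergeometric upper tail: P(X >= a) with a successes observed, `k_term`
# term genes among `n_bg` background genes, `n_query` drawn. This is the
# one-sided (over-representation) Fisher exact p.
hypergeom_tail_p <- function(a, k_term, n_bg, n_query) {
  stats::phyper(a - 1, k_term, n_bg - k_term, n_query, lower.tail = FALSE)
}

#' Gene-set over-representation by Fisher's exact test
#'
#' Builds the 2x2 table of query membership against term membership over an
#' explicit background (the background is always supplied, never a whole
#' annotation universe: in the cancer analysis it is the downregulated gene
#' set). The default alternative is one-sided over-representation; a
#' two-sided variant is available for representation-style questions.
#'
#' @param query Character vector of genes to test (must lie inside
#'   `background`).
#' @param term_genes Character vector: the gene set; intersected with the
#'   background before testing.
#' @param background Character vector: the reference universe.
#' @param alternative `"greater"` (over-representation, hypergeometric upper
#'   tail) or `"two.sided"` (Fisher's exact).
#' @return One-row tibble with `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`,
#'   `degenerate`; `a` counts genes in both the query and the term. An empty
#'   term-background intersection returns `p_value = 1` with
#'   `degenerate = TRUE`.
#' @export
fisher_enrichment_test <- function(query, term_genes, background,
                                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  query <- unique(query)
  background <- unique(background)
  if (!all(query %in% background)) {
    stop("`query` must be a subset of `background`", call. = FALSE)
  }
  term <- intersect(unique(term_genes), background)
  a <- length(intersect(query, term))
  b <- length(query) - a
  c_ <- length(term) - a
  d <- length(background) - a - b - c_
  if (length(term) == 0) {
    return(tibble::tibble(a = a, b = b, c = c_, d = d,
                          odds_ratio = NaN, p_value = 1, degenerate = TRUE))
  }
  out <- contingency_test(a, b, c_, d, alternative = "two.sided")
  if (alternative == "greater") {
    out$p_value <- hypergeom_tail_p(a, length(term), length(background),
                                    length(query))
  }
  out
}

#' Enrichment p-value matrix over seed lists and a gene-set collection
#'
#' One one-sided enrichment p-value per (seed, term) cell, where each seed
#' contributes its gene list (differential-coexpression partners or
#' trans-scan targets of a TSG) as the query. The Bonferroni threshold for
#' the whole matrix is `alpha / (n_seeds * n_terms)`.
#'
#' @param seed_lists Named list: seed identifier -> character vector of
#'   query genes (each a subset of `background`). Empty lists give a row of
#'   1s with a message.
#' @param collection Named list of gene sets (e.g. from [read_gmt()] or
#'   [simulate_gene_sets()]).
#' @param background Character vector: the reference universe.
#' @param alpha Family-wise level for the matrix-wide Bonferroni threshold.
#' @return Numeric matrix (seeds x terms) of p-values with attribute
#'   `bonferroni`.
#' @export
enrichment_matrix <- function(seed_lists, collection, background,
                              alpha = 0.05) {
  stopifnot(is.list(seed_lists), !is.null(names(seed_lists)),
            is.list(collection), !is.null(names(collection)))
  background <- unique(background)
  n_bg <- length(background)
  terms <- purrr::map(collection, ~ intersect(unique(.x), background))
  k_term <- lengths(terms)
  pm <- matrix(1, nrow = length(seed_lists), ncol = length(collection),
               dimnames = list(names(seed_lists), names(collection)))
  n_empty <- 0L
  for (i in seq_along(seed_lists)) {
    q <- unique(seed_lists[[i]])
    if (!all(q %in% background)) {
      stop("seed list `", names(seed_lists)[i],
           "` is not a subset of the background", call. = FALSE)
    }
    if (length(q) == 0) {
      n_empty <- n_empty + 1L
      next
    }
    a <- purrr::map_int(terms, ~ length(intersect(q, .x)))
    p <- hypergeom_tail_p(a, k_term, n_bg, length(q))
    p[k_term == 0] <- 1
    pm[i, ] <- p
  }
  if (n_empty > 0) message(n_empty, " empty seed list(s): row of 1s")
  structure(pm, bonferroni = bonferroni_threshold(alpha, length(pm)))
}
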