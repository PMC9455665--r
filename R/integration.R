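#' Integrate enrichment evidence across omics layers per TSG-term pair
#'
#' The final step of the pipeline: for each (TSG, term) cell, the three
#' enrichment p-values — from the differential-coexpression partner list,
#' the CNA-to-methylation trans-target list and the CNA-to-expression
#' trans-target list — are combined with the Empirical Brown method. The
#' three layers reuse the same underlying tumor data, so their p-values are
#' dependent; the Brown covariance is estimated jointly across all cells
#' (three long columns), which is far better conditioned than a per-TSG fit
#' on three values. Cells missing from a source matrix are imputed as p = 1
#' and flagged, so a missing layer can only weaken, never strengthen, a
#' cell.
#'
#' @param pm_dcg,pm_meth,pm_expr Seed-by-term p-value matrices (e.g. from
#'   [enrichment_matrix()]). Any of the three may be `NULL`, in which case
#'   the combination degrades to the remaining sources with a warning.
#' @param alpha Family-wise level for the Bonferroni flag over all cells.
#' @return A `tsg_integration` tibble sorted by ascending `p_combined`:
#'   `tsg`, `term`, `p_dcg`, `p_meth`, `p_expr`, `p_combined`, `imputed`,
#'   `significant`. Attributes: `brown_model`, `bonferroni`.
#' @export
integrate_tsg_go <- function(pm_dcg, pm_meth, pm_expr, alpha = 0.05) {
  sources <- list(dcg = pm_dcg, meth = pm_meth, expr = pm_expr)
  present <- !purrr::map_lgl(sources, is.null)
  if (sum(present) < 2) stop("need at least two source matrices", call. = FALSE)
  if (any(!present)) {
    warning("source matrix entirely missing (",
            paste(names(sources)[!present], collapse = ", "),
            "); degrading to a ", sum(present), "-source combination")
  }
  avail <- sources[present]
  tsgs <- sort(unique(unlist(purrr::map(avail, rownames))))
  terms <- sort(unique(unlist(purrr::map(avail, colnames))))
  aligned <- purrr::map(sources, function(pm) {
    full <- matrix(NA_real_, length(tsgs), length(terms),
                   dimnames = list(tsgs, terms))
    if (!is.null(pm)) full[rownames(pm), colnames(pm)] <- pm
    full
  })
  long <- purrr::map(aligned, as.vector)
  imputed <- Reduce(`|`, purrr::map(long[present], is.na))
  pm <- do.call(cbind, purrr::map(long[present], ~ ifelse(is.na(.x), 1, .x)))
  fit <- empirical_brown(pm)
  out <- tibble::tibble(
    tsg = rep(tsgs, times = length(terms)),
    term = rep(terms, each = length(tsgs)),
    p_dcg = ifelse(is.na(long$dcg) & present["dcg"], 1, long$dcg),
    p_meth = ifelse(is.na(long$meth) & present["meth"], 1, long$meth),
    p_expr = ifelse(is.na(long$expr) & present["expr"], 1, long$expr),
    p_combined = fit$p_combined,
    imputed = imputed
  )
  threshold <- bonferroni_threshold(alpha, nrow(out))
  out$significant <- out$p_combined < threshold
  out <- dplyr::arrange(out, .data$p_combined, .data$tsg, .data$term)
  structure(out, class = c("tsg_integration", class(out)),
            brown_model = fit$model, bonferroni = threshold)
}

#' Export the ranked TSG-term network as an edge list
#'
#' Takes the top `top_k` integrated records and emits a plain edge list
#' (`tsg`, `term`, `weight = -log10(p_combined)`) compatible with common
#' graph viewers, plus a bipartite node table (attribute `nodes`, column
#' `kind` distinguishing TSG nodes from term nodes). When `path` is given
#' the edges are written as TSV to `path` and the nodes to
#' `<path>.nodes.tsv`.
#'
#' @param records A `tsg_integration` tibble (already sorted by
#'   `p_combined`).
#' @param top_k Number of edges to keep; capped at the record count.
#' @param path Optional output TSV path.
#' @return Edge tibble with attribute `nodes`.
#' @export
export_network <- function(records, top_k = 50, path = NULL) {
  top_k <- min(top_k, nrow(records))
  edges <- dplyr::mutate(
    utils::head(dplyr::arrange(tibble::as_tibble(records), .data$p_combined), top_k),
    weight = -log10(.data$p_combined),
    .keep = "unused"
  )[, c("tsg", "term", "weight")]
  nodes <- dplyr::bind_rows(
    tibble::tibble(node = unique(edges$tsg), kind = "tsg"),
    tibble::tibble(node = unique(edges$term), kind = "term")
  )
  if (!is.null(path)) {
    readr::write_tsv(edges, path)
    readr::write_tsv(nodes, paste0(path, ".nodes.tsv"))
  }
  structure(edges, nodes = nodes)
}
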