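#' Restrict expression matrices to their common genes
#'
#' All matrices are cut down to the sorted intersection of their gene sets,
#' with identical gene order across outputs, so downstream per-gene tests see
#' aligned rows.
#'
#' @param matrices List of at least two gene-by-sample matrices.
#' @return List of matrices restricted to the common genes.
#' @export
intersect_common_genes <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 2)
  purrr::walk(matrices, assert_matrix, name = "matrices[[i]]", finite = FALSE)
  common <- sort(Reduce(intersect, purrr::map(matrices, rownames)))
  if (length(common) == 0) stop("no common genes across matrices", call. = FALSE)
  purrr::map(matrices, ~ .x[common, , drop = FALSE])
}

#' Within-sample rank transformation
#'
#' Each sample (column) is replaced by the ascending ranks of its expression
#' values; higher expression gets a higher rank, ties receive midranks. Ranks
#' are invariant to any strictly increasing per-sample distortion, which is
#' what makes the downstream differential-expression test batch robust.
#'
#' @param matrix Gene-by-sample numeric matrix; all values must be finite.
#' @return Matrix of the same shape holding within-sample midranks; each
#'   column sums to `G * (G + 1) / 2`.
#' @export
rank_transform <- function(matrix) {
  assert_matrix(matrix, name = "matrix", finite = TRUE)
  out <- apply(matrix, 2, rank, ties.method = "average")
  dimnames(out) <- dimnames(matrix)
  set_condition(out, condition_of(matrix))
}

#' Differential expression on rank-transformed values
#'
#' Per gene, a two-sided Wilcoxon rank-sum test compares the within-sample
#' ranks between the normal samples and the pooled cancer samples. Small
#' groups without ties are tested by exact enumeration, larger ones by the
#' normal approximation with tie and continuity corrections (the
#' `stats::wilcox.test()` default). Significance is Bonferroni at
#' `alpha / G`; the direction comes from the median-rank ratio, not the test:
#' a significant gene is `down` when the cancer/normal median-rank ratio is
#' below 1 and `up` when above.
#'
#' @param normal Rank matrix for the normal condition.
#' @param cancers A rank matrix or list of rank matrices for the cancer
#'   condition(s); columns are pooled into one group.
#' @param alpha Family-wise error level for the Bonferroni threshold.
#' @return A `tsg_deg` tibble with columns `gene`, `p_value`,
#'   `median_rank_normal`, `median_rank_cancer`, `ratio`, `direction`,
#'   `significant`, and attributes `n_tests` and `bonferroni`.
#' @export
wilcoxon_deg <- function(normal, cancers, alpha = 0.05) {
  if (is.matrix(cancers)) cancers <- list(cancers)
  stopifnot(length(cancers) >= 1)
  aligned <- intersect_common_genes(c(list(normal), cancers))
  normal <- aligned[[1]]
  cancer <- do.call(cbind, aligned[-1])
  if (ncol(normal) < 2 || ncol(cancer) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  genes <- rownames(normal)
  g <- length(genes)
  threshold <- bonferroni_threshold(alpha, g)
  # ties trigger the approximate path with tie correction; the accompanying
  # warning is expected on midrank data and carries no information
  p <- vapply(seq_len(g), function(i) {
    suppressWarnings(stats::wilcox.test(normal[i, ], cancer[i, ])$p.value)
  }, numeric(1))
  med_n <- unname(apply(normal, 1, median))
  med_c <- unname(apply(cancer, 1, median))
  ratio <- med_c / med_n
  significant <- p < threshold
  direction <- dplyr::case_when(
    significant & ratio < 1 ~ "down",
    significant & ratio > 1 ~ "up",
    .default = "flat"
  )
  out <- tibble::tibble(
    gene = genes, p_value = p,
    median_rank_normal = med_n, median_rank_cancer = med_c,
    ratio = ratio, direction = direction, significant = significant
  )
  structure(out, class = c("tsg_deg", class(out)),
            n_tests = g, bonferroni = threshold)
}

#' Two-by-two table with sample odds ratio and Fisher's exact p
#'
#' Shared backbone of every contingency decision in the pipeline. The odds
#' ratio reported is the sample value `(a * d) / (b * c)` (not the
#' conditional-MLE estimate); the p-value comes from Fisher's exact test. A
#' zero in `b * c` yields an infinite odds ratio with `degenerate = TRUE`;
#' the p-value is still computed.
#'
#' @param a,b,c,d Non-negative cell counts, laid out row-wise as
#'   (row1: a, b; row2: c, d).
#' @param alternative Passed to [stats::fisher.test()].
#' @return One-row tibble: `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`,
#'   `degenerate`.
#' @export
contingency_test <- function(a, b, c, d, alternative = "two.sided") {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0) stop("empty contingency table", call. = FALSE)
  degenerate <- (b * c) == 0 || (a * d) == 0
  or <- if ((b * c) == 0) {
    if ((a * d) == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  p <- stats::fisher.test(matrix(counts, 2, byrow = TRUE),
                          alternative = alternative)$p.value
  tibble::tibble(a = a, b = b, c = c, d = d,
                 odds_ratio = or, p_value = p, degenerate = degenerate)
}

#' Are strongly downregulated genes depleted of TSGs?
#'
#' Among downregulated genes, cross-tabulates the TSG label against whether
#' the median-rank ratio falls below `ratio_threshold` (default 0.5, i.e. the
#' cancer median rank at most half the normal one) and tests the association
#' with Fisher's exact test. In the breast cohorts this association is
#' negative: the most strongly downregulated genes are enriched in non-TSGs.
#'
#' @param records A `tsg_deg` tibble (only rows with `direction == "down"`
#'   are used).
#' @param tsg_labels Character vector of TSG identifiers.
#' @param ratio_threshold Ratio cutoff in (0, 1).
#' @return One-row tibble from [contingency_test()]; rows are
#'   (TSG, non-TSG), columns are (ratio below threshold, not).
#' @export
strong_down_enrichment <- function(records, tsg_labels, ratio_threshold = 0.5) {
  stopifnot(ratio_threshold > 0, ratio_threshold < 1)
  down <- dplyr::filter(records, .data$direction == "down")
  is_tsg <- down$gene %in% tsg_labels
  low <- down$ratio < ratio_threshold
  contingency_test(
    a = sum(is_tsg & low), b = sum(is_tsg & !low),
    c = sum(!is_tsg & low), d = sum(!is_tsg & !low)
  )
}
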