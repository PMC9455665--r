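# internal validation helpers

`%||%` <- rlang::`%||%`

assert_matrix <- function(x, name = deparse(substitute(x)), finite = TRUE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`", name, "` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x))) {
    stop("`", name, "` must have gene identifiers as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("`", name, "` has duplicate gene identifiers", call. = FALSE)
  }
  if (finite && !all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop("non-finite value in `", name, "` for gene ", rownames(x)[bad[1]],
         ", sample ", colnames(x)[bad[2]] %||% bad[2], call. = FALSE)
  }
  invisible(x)
}

#' Bonferroni family-wise threshold
#'
#' The per-test significance level `alpha / n_tests` used throughout the
#' pipeline (DEG genes, candidate pairs, scan genes, enrichment cells).
#'
#' @param alpha Family-wise error level in (0, 1].
#' @param n_tests Number of tests in the family.
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha <= 1, n_tests >= 1)
  alpha / n_tests
}

condition_of <- function(mat) attr(mat, "condition") %||% NA_character_

set_condition <- function(mat, condition) {
  attr(mat, "condition") <- condition
  mat
}
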