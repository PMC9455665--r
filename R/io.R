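#' Read and write gene-by-sample matrices as TSV
#'
#' Matrices are stored with genes as rows and samples as columns, a header row
#' of sample identifiers and a leading `gene` column of row labels — the layout
#' shared by the expression, copy-number and methylation tables the pipeline
#' consumes.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path File path.
#' @param condition Optional condition label (`"normal"` or `"cancer-<name>"`)
#'   attached to the matrix as an attribute on read.
#' @return `read_matrix_tsv()` returns a numeric matrix; `write_matrix_tsv()`
#'   returns `path` invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  assert_matrix(mat, finite = FALSE)
  df <- tibble::as_tibble(mat, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, condition = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  if (!is.null(condition)) mat <- set_condition(mat, condition)
  mat
}

#' Read and write gene sets in GMT format
#'
#' Standard tab-delimited GMT: one gene set per line, fields `term`,
#' `description`, then member genes.
#'
#' @param sets Named list of character vectors (members per term).
#' @param path File path.
#' @param descriptions Optional character vector of term descriptions,
#'   recycled from term names when missing.
#' @return `read_gmt()` returns a named list of character vectors with a
#'   `descriptions` attribute; `write_gmt()` returns `path` invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (anyDuplicated(names(sets))) stop("duplicate term identifiers", call. = FALSE)
  if (any(lengths(sets) == 0)) stop("gene sets must be non-empty", call. = FALSE)
  descriptions <- descriptions %||% attr(sets, "descriptions") %||% names(sets)
  lines <- purrr::map_chr(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- purrr::map(fields, ~ unique(.x[-(1:2)]))
  names(sets) <- purrr::map_chr(fields, 1)
  attr(sets, "descriptions") <- purrr::map_chr(fields, 2)
  sets
}

#' Write and read the simulation ground truth as a JSON sidecar
#'
#' @param truth A `sim_truth` object from [simulate_expression()] or
#'   [simulate_multiomics()].
#' @param path File path.
#' @return `read_sim_truth()` returns a `sim_truth` list; `write_sim_truth()`
#'   returns `path` invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  out <- truth
  out$flipped_pairs <- as.data.frame(truth$flipped_pairs)
  out$cis_effect_genes <- as.data.frame(truth$cis_effect_genes)
  out <- unclass(out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$flipped_pairs <- tibble::as_tibble(raw$flipped_pairs)
  raw$cis_effect_genes <- tibble::as_tibble(raw$cis_effect_genes)
  raw$trans_targets <- purrr::map(raw$trans_targets, unlist)
  structure(raw, class = "sim_truth")
}
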