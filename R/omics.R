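# Vectorised simple linear regression of each row of `y` on the matching row
# of `x` (shared columns). Missing values are dropped pairwise per fit.
# Returns slope, t, two-sided p and n per row; rows with a constant predictor
# or n < 3 come back as NA with a reason.
row_ols <- function(x, y) {
  stopifnot(identical(dim(x), dim(y)))
  ok <- !is.na(x) & !is.na(y)
  n <- rowSums(ok)
  x0 <- ifelse(ok, x, 0)
  y0 <- ifelse(ok, y, 0)
  sx <- rowSums(x0); sy <- rowSums(y0)
  sxx <- rowSums(x0 * x0); syy <- rowSums(y0 * y0); sxy <- rowSums(x0 * y0)
  ssx <- sxx - sx^2 / n
  ssy <- syy - sy^2 / n
  sxy_c <- sxy - sx * sy / n
  slope <- sxy_c / ssx
  rss <- pmax(ssy - slope * sxy_c, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / ssx)
  t <- slope / se
  p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  reason <- rep(NA_character_, length(n))
  bad_n <- n < 3
  bad_const <- !bad_n & (ssx <= 0)
  reason[bad_n] <- "fewer than 3 complete samples"
  reason[bad_const] <- "constant predictor"
  bad <- bad_n | bad_const
  slope[bad] <- t[bad] <- p[bad] <- NA_real_
  tibble::tibble(slope = unname(slope), t_stat = unname(t),
                 p_value = unname(p), n = unname(n), reason = reason)
}

align_omics <- function(cna, response) {
  genes <- sort(intersect(rownames(cna), rownames(response)))
  samples <- intersect(colnames(cna), colnames(response))
  if (length(genes) == 0) stop("no shared genes", call. = FALSE)
  if (length(samples) < 3) stop("need at least 3 shared samples", call. = FALSE)
  list(cna = cna[genes, samples, drop = FALSE],
       response = response[genes, samples, drop = FALSE])
}

#' Cis scan: regress each gene's methylation or expression on its own CNA
#'
#' Ordinary least squares of the response (methylation beta or expression) on
#' the same gene's copy-number level treated as a numeric covariate (-2..2).
#' Bonferroni correction is over the genes scanned. Genes whose CNA is
#' constant across samples are skipped with a reason.
#'
#' @param cna Gene-by-sample integer matrix with levels in -2..2.
#' @param response Gene-by-sample methylation or expression matrix sharing
#'   genes and samples with `cna`.
#' @param layer `"expression"` or `"methylation"` (recorded in the output).
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @return Tibble with `predictor_gene`, `response_gene`, `layer`, `slope`,
#'   `t_stat`, `p_value`, `n`, `significant`; skipped genes are dropped and
#'   counted in attribute `n_skipped`. Attributes `n_scanned` (fits kept,
#'   the Bonferroni denominator) and `bonferroni`.
#' @export
cis_scan <- function(cna, response, layer = c("expression", "methylation"),
                     alpha = 0.05) {
  layer <- match.arg(layer)
  al <- align_omics(cna, response)
  fits <- row_ols(al$cna, al$response)
  out <- tibble::tibble(
    predictor_gene = rownames(al$cna), response_gene = rownames(al$cna),
    layer = layer, fits[, c("slope", "t_stat", "p_value", "n")]
  )
  skipped <- !is.na(fits$reason)
  if (any(skipped)) {
    message(sum(skipped), " gene(s) skipped: ",
            paste(unique(fits$reason[skipped]), collapse = "; "))
  }
  out <- out[!skipped, ]
  threshold <- bonferroni_threshold(alpha, max(nrow(out), 1))
  out$significant <- out$p_value < threshold
  structure(out, n_scanned = nrow(out), n_skipped = sum(skipped),
            bonferroni = threshold)
}

#' Trans scan: regress every gene's response on one gene's CNA
#'
#' For a single predictor gene (typically a TSG), fits the response of every
#' gene on the predictor's copy-number level. Bonferroni correction is over
#' the response genes tested for this predictor.
#'
#' @param cna_gene Identifier of the predictor gene (must be in `cna`).
#' @inheritParams cis_scan
#' @return Tibble as in [cis_scan()] with `predictor_gene = cna_gene`; empty
#'   (with a message) when the predictor CNA has zero variance.
#' @export
trans_scan <- function(cna_gene, cna, response,
                       layer = c("expression", "methylation"), alpha = 0.05) {
  layer <- match.arg(layer)
  if (!cna_gene %in% rownames(cna)) {
    stop("predictor gene not in the CNA matrix: ", cna_gene, call. = FALSE)
  }
  samples <- intersect(colnames(cna), colnames(response))
  x <- cna[cna_gene, samples]
  if (stats::var(x, na.rm = TRUE) == 0 || length(samples) < 3) {
    message("predictor ", cna_gene, " has zero variance; empty scan")
    return(structure(
      tibble::tibble(predictor_gene = character(), response_gene = character(),
                     layer = character(), slope = numeric(), t_stat = numeric(),
                     p_value = numeric(), n = integer(), significant = logical()),
      n_scanned = 0L, bonferroni = NA_real_
    ))
  }
  resp <- response[, samples, drop = FALSE]
  xmat <- matrix(x, nrow = nrow(resp), ncol = length(samples), byrow = TRUE)
  fits <- row_ols(xmat, resp)
  out <- tibble::tibble(
    predictor_gene = cna_gene, response_gene = rownames(resp),
    layer = layer, fits[, c("slope", "t_stat", "p_value", "n")]
  )
  out <- out[is.na(fits$reason), ]
  threshold <- bonferroni_threshold(alpha, max(nrow(out), 1))
  out$significant <- out$p_value < threshold
  structure(out, n_scanned = nrow(out), bonferroni = threshold)
}

#' Pick the methylation probe most anti-correlated with expression
#'
#' When several array probes map to one gene, the probe whose beta values
#' have the most negative Pearson correlation with the gene's expression is
#' used as that gene's degree of methylation. Ties break by probe identifier
#' order; genes with no candidate probes are dropped with a message.
#'
#' @param meth Probe-by-sample beta matrix.
#' @param expr Gene-by-sample expression matrix sharing samples with `meth`.
#' @param mapping Named list: gene -> character vector of candidate probes.
#' @return Tibble with `gene`, `probe`, `correlation`.
#' @export
select_probe_for_gene <- function(meth, expr, mapping) {
  samples <- intersect(colnames(meth), colnames(expr))
  if (length(samples) < 3) stop("need at least 3 shared samples", call. = FALSE)
  rows <- purrr::imap(mapping, function(probes, gene) {
    probes <- sort(intersect(probes, rownames(meth)))
    if (length(probes) == 0 || !gene %in% rownames(expr)) return(NULL)
    r <- vapply(probes, function(pr) {
      stats::cor(meth[pr, samples], expr[gene, samples])
    }, numeric(1))
    best <- which.min(r)  # most anti-correlated; first probe id wins ties
    tibble::tibble(gene = gene, probe = probes[best], correlation = r[best])
  })
  dropped <- sum(purrr::map_lgl(rows, is.null))
  if (dropped > 0) message(dropped, " gene(s) without candidate probes dropped")
  dplyr::bind_rows(rows)
}

#' TSG representation among significant scan hits
#'
#' Cross-tabulates membership in the significant set against the TSG label
#' over the scanned universe and reports the sample odds ratio with a
#' two-sided Fisher's exact p-value. Values above 1 mean TSGs are
#' over-represented among significant copy-number effects.
#'
#' @param significant Character vector of significant genes (subset of
#'   `universe`).
#' @param universe Character vector: all genes scanned.
#' @param tsg_labels Character vector of TSG identifiers (subset of
#'   `universe`).
#' @return One-row tibble from [contingency_test()]: rows are (significant,
#'   not), columns are (TSG, non-TSG). Degenerate layouts (empty or
#'   exhaustive significant set) are flagged via `degenerate`.
#' @export
tsg_representation_test <- function(significant, universe, tsg_labels) {
  significant <- unique(significant)
  tsg_labels <- unique(intersect(tsg_labels, universe))
  if (!all(significant %in% universe)) {
    stop("`significant` must be a subset of `universe`", call. = FALSE)
  }
  a <- length(intersect(significant, tsg_labels))
  b <- length(significant) - a
  c_ <- length(tsg_labels) - a
  d <- length(universe) - a - b - c_
  if (length(significant) == 0) {
    # nothing significant: association is vacuous, reported as OR 0, p 1
    return(tibble::tibble(a = a, b = b, c = c_, d = d,
                          odds_ratio = 0, p_value = 1, degenerate = TRUE))
  }
  contingency_test(a, b, c_, d)
}

#' Compare scan p-value distributions between TSGs and non-TSGs
#'
#' Wilcoxon rank-sum test of the linear-model p-values of TSG genes against
#' those of non-TSG genes — lower p-values among TSGs indicate stronger
#' copy-number coupling of the label class.
#'
#' @param fits A scan tibble from [cis_scan()] or [trans_scan()].
#' @param tsg_labels Character vector of TSG identifiers.
#' @return List with `p_value` (of the rank-sum comparison), `n_tsg`,
#'   `n_other`, and the median scan p in each group.
#' @export
compare_pvalue_distributions <- function(fits, tsg_labels) {
  is_tsg <- fits$response_gene %in% tsg_labels
  if (!any(is_tsg) || all(is_tsg)) stop("both groups must be non-empty", call. = FALSE)
  ht <- stats::wilcox.test(fits$p_value[is_tsg], fits$p_value[!is_tsg])
  list(p_value = ht$p.value, n_tsg = sum(is_tsg), n_other = sum(!is_tsg),
       median_p_tsg = median(fits$p_value[is_tsg]),
       median_p_other = median(fits$p_value[!is_tsg]))
}
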