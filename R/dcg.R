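#' Pearson correlation and its t-test p-value
#'
#' `pearson_cc()` is the plain product-moment correlation of two expression
#' vectors. `pcc_pvalue()` converts a correlation into a two-sided p-value
#' via `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to the t distribution
#' with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (at least 2), neither constant.
#' @param r Correlation(s) in \[-1, 1\].
#' @param n Sample count(s), at least 3.
#' @return `pearson_cc()`: a correlation. `pcc_pvalue()`: two-sided
#'   p-value(s); `|r| = 1` returns 0 (t-statistic diverges).
#' @export
pearson_cc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' @rdname pearson_cc
#' @export
pcc_pvalue <- function(r, n) {
  stopifnot(all(n >= 3), all(abs(r) <= 1))
  t <- abs(r) * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
  p[abs(r) == 1] <- 0
  p
}

#' Fisher z-transformation of a correlation
#'
#' `z = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing map used by
#' the coexpression difference test. Correlations at (or numerically beyond)
#' `|r| = 1` are clipped to `1 - 1e-15` in magnitude with a warning.
#'
#' @param r Correlation(s).
#' @return z-value(s); antisymmetric in `r`.
#' @export
fisher_z <- function(r) {
  lim <- 1 - 1e-15
  if (any(abs(r) >= lim)) {
    warning("|r| at or beyond 1; clipped to +/- (1 - 1e-15)")
    r <- pmin(pmax(r, -lim), lim)
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Difference test for two correlations (Fisher z)
#'
#' Tests whether two correlations estimated from independent groups differ:
#' `dz = (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))`, referred to the
#' standard normal, two-sided.
#'
#' @param r1,r2 Correlations in the two conditions.
#' @param n1,n2 Sample counts (at least 4, so `n - 3 > 0`).
#' @return Tibble with columns `dz` and `p_value` (vectorized).
#' @export
delta_z_test <- function(r1, n1, r2, n2) {
  stopifnot(all(n1 >= 4), all(n2 >= 4))
  dz <- (fisher_z(r1) - fisher_z(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(dz = dz, p_value = 2 * stats::pnorm(abs(dz), lower.tail = FALSE))
}

# correlation + screen p-value matrices for one dataset, candidates ordered
screen_one_dataset <- function(mat, candidates, counts) {
  m <- mat[candidates, , drop = FALSE]
  if (counts) m <- log(m + 1)
  r <- stats::cor(t(m))
  list(r = r, n = ncol(m))
}

#' Differential-coexpression screen between normal and cancer datasets
#'
#' For every unordered pair of candidate genes the screen (i) computes the
#' Pearson correlation in the normal and in each cancer dataset, (ii) keeps
#' pairs whose correlation is significant in *every* dataset at the Bonferroni
#' level `alpha / choose(m, 2)` (m = number of candidates) *and* whose normal
#' correlation exceeds `abs_r_threshold` in magnitude (hard thresholding),
#' (iii) computes one Fisher z-difference p-value per cancer dataset (normal
#' vs that cancer), and (iv) combines those dependent p-values with the
#' Empirical Brown method (the cancer comparisons share the normal data, so
#' plain Fisher summation would be anti-conservative). Pairs are flagged
#' significant at Bonferroni over the combined tests.
#'
#' @param normal Gene-by-sample matrix for the normal condition.
#' @param cancers Named list of cancer matrices.
#' @param candidate_genes Genes to screen (must be present in all matrices);
#'   defaults to the common genes.
#' @param abs_r_threshold Minimum `|r|` in the normal dataset (strict).
#' @param alpha Family-wise level for both Bonferroni corrections.
#' @param counts If `TRUE`, all matrices get `log(x + 1)` before correlation
#'   (count inputs); normalized inputs are used as-is.
#' @return A `tsg_dcg` tibble with one row per retained pair: `gene_a` <
#'   `gene_b` lexicographically, `r_normal`, per-dataset `r_<name>`,
#'   `dz_<name>`, `p_dz_<name>`, `p_combined`, `significant`. Attributes:
#'   `n_candidates`, `n_pairs`, `screen_alpha`, `combine_alpha`,
#'   `brown_model` (NULL when fewer than 10 pairs survive and Fisher's
#'   method is used instead), `n_excluded_constant`.
#' @export
dcg_screen <- function(normal, cancers, candidate_genes = NULL,
                       abs_r_threshold = 0.3, alpha = 0.05, counts = FALSE) {
  if (is.matrix(cancers)) cancers <- list(cancer1 = cancers)
  if (is.null(names(cancers))) names(cancers) <- sprintf("cancer%d", seq_along(cancers))
  mats <- intersect_common_genes(c(list(normal = normal), cancers))
  candidates <- sort(candidate_genes %||% rownames(mats[[1]]))
  missing <- setdiff(candidates, rownames(mats[[1]]))
  if (length(missing)) {
    stop("candidate genes absent from all matrices: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  empty <- tibble::tibble(gene_a = character(), gene_b = character(),
                          r_normal = numeric(), p_combined = numeric(),
                          significant = logical())
  if (length(candidates) < 2) {
    warning("fewer than 2 candidate genes; empty screen")
    return(structure(empty, class = c("tsg_dcg", class(empty))))
  }

  scr <- purrr::map(mats, screen_one_dataset, candidates = candidates,
                    counts = counts)
  m <- length(candidates)
  n_pairs <- choose(m, 2)
  screen_alpha <- bonferroni_threshold(alpha, n_pairs)

  ut <- upper.tri(scr[[1]]$r)
  idx <- which(ut, arr.ind = TRUE)
  r_mat <- purrr::map(scr, ~ .x$r[ut])
  n_vec <- purrr::map_dbl(scr, "n")

  constant_bad <- Reduce(`|`, purrr::map(r_mat, is.na))
  n_excluded <- sum(constant_bad)
  if (n_excluded > 0) {
    message(n_excluded, " pair(s) excluded: constant expression vector")
  }

  keep <- !constant_bad & abs(r_mat[[1]]) > abs_r_threshold
  for (d in seq_along(r_mat)) {
    p_d <- pcc_pvalue(r_mat[[d]][!is.na(r_mat[[d]])], n_vec[d])
    pd_full <- rep(NA_real_, length(r_mat[[d]]))
    pd_full[!is.na(r_mat[[d]])] <- p_d
    keep <- keep & !is.na(pd_full) & pd_full < screen_alpha
  }

  if (!any(keep)) {
    out <- structure(empty, class = c("tsg_dcg", class(empty)),
                     n_candidates = m, n_pairs = n_pairs,
                     screen_alpha = screen_alpha,
                     n_excluded_constant = n_excluded)
    return(out)
  }

  ga <- candidates[idx[keep, 1]]
  gb <- candidates[idx[keep, 2]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp

  out <- tibble::tibble(gene_a = ga, gene_b = gb,
                        r_normal = r_mat[[1]][keep])
  cancer_names <- names(mats)[-1]
  p_dz <- matrix(NA_real_, nrow = sum(keep), ncol = length(cancer_names))
  for (d in seq_along(cancer_names)) {
    rc <- r_mat[[d + 1]][keep]
    dz <- delta_z_test(out$r_normal, n_vec[1], rc, n_vec[d + 1])
    out[[paste0("r_", cancer_names[d])]] <- rc
    out[[paste0("dz_", cancer_names[d])]] <- dz$dz
    out[[paste0("p_dz_", cancer_names[d])]] <- dz$p_value
    p_dz[, d] <- dz$p_value
  }

  model <- NULL
  if (nrow(p_dz) >= 10 && ncol(p_dz) >= 2) {
    model <- brown_fit(p_dz)
    out$p_combined <- brown_combine(p_dz, model)
  } else if (ncol(p_dz) >= 2) {
    message("fewer than 10 retained pairs; combining with Fisher's method")
    out$p_combined <- fisher_combine_rows(p_dz)$p_value
  } else {
    out$p_combined <- p_dz[, 1]
  }
  combine_alpha <- bonferroni_threshold(alpha, nrow(out))
  out$significant <- out$p_combined < combine_alpha
  out <- dplyr::arrange(out, .data$gene_a, .data$gene_b)
  structure(out, class = c("tsg_dcg", class(out)),
            n_candidates = m, n_pairs = n_pairs,
            screen_alpha = screen_alpha, combine_alpha = combine_alpha,
            brown_model = model, n_excluded_constant = n_excluded)
}

#' Per-gene partner statistics: are a gene's partners enriched in TSGs?
#'
#' For each gene with at least one significant differential-coexpression
#' partner, cross-tabulates partner membership against the TSG label over the
#' background universe (the gene itself excluded) and applies a two-sided
#' Fisher's exact test with Bonferroni correction over the genes tested. A
#' significantly high odds ratio marks a gene whose rewiring preferentially
#' involves TSGs — a candidate core regulator.
#'
#' @param records A `tsg_dcg` tibble; only rows with `significant == TRUE`
#'   are used.
#' @param tsg_labels Character vector of TSG identifiers.
#' @param background Character vector: the gene universe for the table.
#' @param alpha Family-wise level for the Bonferroni correction over genes.
#' @return Tibble with `gene`, `n_partners`, `n_tsg_partners`, `odds_ratio`,
#'   `p_value`, `significant`; attributes `bonferroni`, `n_zero_partner`
#'   (genes in the background with no partners, excluded), and
#'   `mean_partner_count`.
#' @export
per_gene_partner_stats <- function(records, tsg_labels, background,
                                   alpha = 0.05) {
  sig <- dplyr::filter(records, .data$significant)
  partners <- split(
    c(sig$gene_b, sig$gene_a),
    factor(c(sig$gene_a, sig$gene_b), levels = sort(unique(c(sig$gene_a, sig$gene_b))))
  )
  n_zero <- length(setdiff(background, names(partners)))
  if (n_zero > 0) {
    message(n_zero, " background gene(s) with no partners excluded")
  }
  genes <- names(partners)
  threshold <- bonferroni_threshold(alpha, length(genes))
  rows <- purrr::map(genes, function(g) {
    p_set <- unique(partners[[g]])
    bg <- setdiff(background, g)
    tsg <- intersect(tsg_labels, bg)
    a <- length(intersect(p_set, tsg))
    b <- length(setdiff(p_set, tsg))
    c_ <- length(setdiff(tsg, p_set))
    d <- length(bg) - a - b - c_
    ct <- contingency_test(a, b, c_, d)
    tibble::tibble(gene = g, n_partners = length(p_set), n_tsg_partners = a,
                   odds_ratio = ct$odds_ratio, p_value = ct$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p_value < threshold
  # mean degree over the whole background: 2 * edges / background size
  structure(out, bonferroni = threshold, n_zero_partner = n_zero,
            mean_partner_count = 2 * nrow(sig) / length(background))
}
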