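#' Fisher's p-value combination
#'
#' `chi2 = -2 * sum(log(p_i))` referred to a chi-square distribution with
#' `2k` degrees of freedom. Valid for independent p-values; dependent vectors
#' inflate the statistic and should go through [brown_combine()] instead.
#'
#' @param p Vector of p-values in (0, 1]; zeros are floored at `eps` with a
#'   warning.
#' @param eps Floor applied to zero p-values.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
fisher_combine <- function(p, eps = 1e-300) {
  p <- floor_pvalues(p, eps)
  stat <- -2 * sum(log(p))
  list(statistic = stat, df = 2 * length(p),
       p_value = stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE))
}

#' @rdname fisher_combine
#' @param pm Matrix of p-values, one combination per row (columns = studies).
#' @return `fisher_combine_rows()`: tibble with `statistic` and `p_value`
#'   per row.
#' @export
fisher_combine_rows <- function(pm, eps = 1e-300) {
  pm <- floor_pvalues(as.matrix(pm), eps)
  stat <- -2 * rowSums(log(pm))
  tibble::tibble(
    statistic = stat,
    p_value = stats::pchisq(stat, df = 2 * ncol(pm), lower.tail = FALSE)
  )
}

floor_pvalues <- function(p, eps = 1e-300) {
  stopifnot(all(p >= 0, na.rm = TRUE), all(p <= 1, na.rm = TRUE))
  if (any(p < eps, na.rm = TRUE)) {
    warning("p-values at or below ", eps, " floored")
    p <- pmax(p, eps)
  }
  p
}

#' Right-sided empirical survival transform
#'
#' `w_j = -2 * log(S(x_j))` where `S(x) = #\{x_i >= x\} / n` is the empirical
#' survival function of the vector evaluated at its own entries. Because the
#' comparison is `>=`, `S >= 1/n` everywhere and the transform never hits
#' `log(0)`. Applied per study column to `x = -log(p)`, it turns each column
#' into an approximately chi-square(2) sample whose empirical covariances
#' calibrate the Brown model.
#'
#' @param x Numeric vector of length at least 2.
#' @return Vector `w` of the same length, all finite and non-negative.
#' @export
survival_transform <- function(x) {
  stopifnot(length(x) >= 2)
  n <- length(x)
  # #\{x_i >= x_j\} = n - rank_min(x_j) + 1
  s <- (n - rank(x, ties.method = "min") + 1) / n
  -2 * log(s)
}

#' Fit the Empirical Brown model for dependent p-value columns
#'
#' Fisher's statistic `psi = -2 * sum_i log(p_i)` over `k` dependent studies
#' is referred to a rescaled chi-square `c * chisq(f)` with
#' `E = 2k`, `var = 4k + 2 * sum_{i<j} cov(w_i, w_j)`,
#' `c = var / (2 E)` and `f = 2 E^2 / var`, where `w_i` is the
#' survival-transformed `-log(p)` column of study `i` and the covariances are
#' estimated empirically across rows. Independent columns give `c = 1`,
#' `f = 2k` (Fisher's method); duplicated columns give `c = 2`, `f = 2`
#' (the single-column test), so dependence can only cost, never manufacture,
#' significance.
#'
#' @param pm Matrix of p-values: rows are tests (gene pairs, term cells),
#'   columns are studies. At least 2 columns and 10 rows (the covariance
#'   needs replication across rows).
#' @param eps Floor applied to zero p-values.
#' @param k_min The fitted degrees of freedom `f` are floored at `2 * k_min`.
#' @return A `brown_model`: list with `k`, `expected`, `variance`, `scale_c`,
#'   `df_f`, `cov` (the k-by-k covariance of the transformed columns).
#' @export
brown_fit <- function(pm, eps = 1e-300, k_min = 1) {
  pm <- as.matrix(pm)
  if (ncol(pm) < 2) stop("need at least 2 study columns", call. = FALSE)
  if (nrow(pm) < 10) stop("need at least 10 rows to estimate covariances", call. = FALSE)
  if (anyNA(pm)) stop("missing p-values in rows submitted for combination", call. = FALSE)
  pm <- floor_pvalues(pm, eps)
  w <- apply(-log(pm), 2, survival_transform)
  covm <- stats::cov(w)
  k <- ncol(pm)
  expected <- 2 * k
  variance <- 4 * k + 2 * sum(covm[upper.tri(covm)])
  structure(
    list(k = k, expected = expected, variance = variance,
         scale_c = variance / (2 * expected),
         df_f = max(2 * expected^2 / variance, 2 * k_min),
         cov = covm),
    class = "brown_model"
  )
}

#' @rdname brown_fit
#' @param model A fitted `brown_model`; refitted from `pm` when `NULL`. If
#'   the fitted variance is non-positive the combination falls back to
#'   Fisher's method with a warning.
#' @return `brown_combine()`: vector of combined p-values in (0, 1], one per
#'   row of `pm`.
#' @export
brown_combine <- function(pm, model = NULL, eps = 1e-300) {
  pm <- floor_pvalues(as.matrix(pm), eps)
  model <- model %||% brown_fit(pm, eps)
  if (!inherits(model, "brown_model")) stop("`model` must be a brown_model", call. = FALSE)
  if (model$variance <= 0) {
    warning("non-positive Brown variance; falling back to Fisher's method")
    return(pmax(fisher_combine_rows(pm, eps)$p_value, eps))
  }
  psi <- -2 * rowSums(log(pm))
  p <- stats::pchisq(psi / model$scale_c, df = model$df_f, lower.tail = FALSE)
  pmax(p, eps)
}

#' @rdname brown_fit
#' @return `empirical_brown()`: list with `model` and `p_combined`.
#' @export
empirical_brown <- function(pm, eps = 1e-300, k_min = 1) {
  model <- brown_fit(pm, eps, k_min)
  list(model = model, p_combined = brown_combine(pm, model, eps))
}

#' @export
print.brown_model <- function(x, ...) {
  cat("Empirical Brown model:", x$k, "studies\n")
  cat(sprintf("  E[psi] = %g, var[psi] = %.4f\n", x$expected, x$variance))
  cat(sprintf("  scale c = %.4f, df f = %.4f\n", x$scale_c, x$df_f))
  invisible(x)
}

#' Tidiers for the Empirical Brown model
#'
#' `tidy()` returns the pairwise covariances of the survival-transformed
#' study columns; `glance()` returns the model constants.
#'
#' @param x A `brown_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.brown_model <- function(x, ...) {
  idx <- which(upper.tri(x$cov, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    study_i = rownames(x$cov)[idx[, 1]] %||% idx[, 1],
    study_j = colnames(x$cov)[idx[, 2]] %||% idx[, 2],
    covariance = x$cov[idx]
  )
}

#' @rdname tidy.brown_model
#' @exportS3Method generics::glance
glance.brown_model <- function(x, ...) {
  tibble::tibble(k = x$k, expected = x$expected, variance = x$variance,
                 scale_c = x$scale_c, df_f = x$df_f)
}
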