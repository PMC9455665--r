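#' Assemble the per-gene feature table for TSG prediction
#'
#' Three functional-genomics features per candidate gene: `f_dcg`, the mean
#' of `-log10(combined differential-coexpression p)` over the gene's pairs
#' (genes in no pair get a missing value); `f_tmeth` and `f_texpr`, the
#' signed cis t-statistics of the methylation and expression scans (signed,
#' so the direction of the copy-number coupling is kept). Genes absent from
#' a platform get missing values for that feature.
#'
#' @param dcg A `tsg_dcg` tibble (pass the screened pairs; all rows are
#'   used).
#' @param cis_meth,cis_expr Scan tibbles from [cis_scan()] (may be `NULL`).
#' @param labels Character vector of TSG identifiers (non-empty).
#' @param genes Candidate gene universe; defaults to every gene seen in the
#'   inputs.
#' @return Tibble with `gene`, `f_dcg`, `f_tmeth`, `f_texpr`, `label`
#'   (logical).
#' @export
build_feature_table <- function(dcg, cis_meth, cis_expr, labels,
                                genes = NULL) {
  if (length(labels) == 0) stop("empty TSG label set", call. = FALSE)
  genes <- genes %||% sort(unique(c(dcg$gene_a, dcg$gene_b,
                                    cis_meth$response_gene,
                                    cis_expr$response_gene)))
  neglog <- -log10(pmax(dcg$p_combined, 1e-300))
  per_gene <- tapply(c(neglog, neglog), c(dcg$gene_a, dcg$gene_b), mean)
  f_dcg <- unname(per_gene[genes])
  lookup_t <- function(fits) {
    if (is.null(fits) || nrow(fits) == 0) return(rep(NA_real_, length(genes)))
    fits$t_stat[match(genes, fits$response_gene)]
  }
  tibble::tibble(
    gene = genes,
    f_dcg = as.numeric(f_dcg),
    f_tmeth = lookup_t(cis_meth),
    f_texpr = lookup_t(cis_expr),
    label = genes %in% labels
  )
}

feature_cols <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, logical(1))], "label")
}

#' k-nearest-neighbour imputation of missing feature cells
#'
#' Each missing cell is replaced by the mean of that feature over the `k`
#' nearest rows, with distances computed as root-mean-square differences of
#' the standardized features observed in both rows; donors must have the
#' target feature observed. Observed cells are never altered. Rows with all
#' features missing are dropped with a message. Standardization (and donor
#' pool, via `donors`) can come from a training table so that
#' cross-validation never leaks test information.
#'
#' @param table Feature tibble from [build_feature_table()].
#' @param k Number of neighbours; every feature column must have at least
#'   `k` complete donor rows.
#' @param donors Optional tibble supplying the donor rows and the
#'   standardization constants (defaults to `table` itself).
#' @return The table with missing cells filled in.
#' @export
knn_impute <- function(table, k = 5, donors = NULL) {
  donors <- donors %||% table
  cols <- feature_cols(table)
  stopifnot(identical(cols, feature_cols(donors)))
  dm <- as.matrix(donors[, cols])
  tm <- as.matrix(table[, cols])
  n_complete <- colSums(!is.na(dm))
  if (any(n_complete < k)) {
    stop("every feature needs at least k = ", k, " complete donor rows",
         call. = FALSE)
  }
  all_missing <- rowSums(!is.na(tm)) == 0
  if (any(all_missing)) {
    message(sum(all_missing), " row(s) with all features missing dropped")
    table <- table[!all_missing, ]
    tm <- tm[!all_missing, , drop = FALSE]
  }
  mu <- colMeans(dm, na.rm = TRUE)
  sdev <- apply(dm, 2, sd, na.rm = TRUE)
  sdev[sdev == 0] <- 1
  dz <- sweep(sweep(dm, 2, mu), 2, sdev, `/`)
  tz <- sweep(sweep(tm, 2, mu), 2, sdev, `/`)
  out <- tm
  for (i in which(rowSums(is.na(tm)) > 0)) {
    obs <- !is.na(tz[i, ])
    for (j in which(is.na(tm[i, ]))) {
      ok <- !is.na(dz[, j])
      if (any(obs)) {
        diff2 <- sweep(dz[ok, obs, drop = FALSE], 2, tz[i, obs], `-`)^2
        d <- sqrt(rowMeans(diff2, na.rm = TRUE))
        d[is.nan(d)] <- Inf  # donor shares no observed feature
      } else {
        d <- rep(0, sum(ok))
      }
      nearest <- order(d)[seq_len(k)]
      out[i, j] <- mean(dm[ok, j][nearest])
    }
  }
  table[, cols] <- tibble::as_tibble(out)
  table
}

# Neyman-Pearson umbrella order index: the smallest k such that
# P(Binom(n, 1 - alpha) >= k) <= delta; classifying above the k-th order
# statistic of n held-out null scores then bounds the population type-I
# error at alpha with probability >= 1 - delta.
np_order_index <- function(n, alpha, delta) {
  tail <- stats::pbinom(seq_len(n) - 1, n, 1 - alpha, lower.tail = FALSE)
  k <- which(tail <= delta)[1]
  if (is.na(k)) {
    n_min <- ceiling(log(delta) / log(1 - alpha))
    stop("too few null scores for the NP guarantee: need at least ",
         n_min, ", got ", n, call. = FALSE)
  }
  k
}

#' Neyman-Pearson classifier with a type-I error guarantee
#'
#' Fits a base scorer (linear discriminant on the features, oriented so that
#' TSGs score higher) on the positive class plus part of the null class, and
#' sets the decision threshold on the held-out null scores by the NP
#' umbrella rule: the threshold is the k-th smallest held-out null score,
#' with k the smallest order index whose binomial tail
#' `P(Binom(n, 1 - alpha) >= k)` is at most `delta`. This guarantees
#' population type-I error at most `alpha` with probability at least
#' `1 - delta`, while the scorer minimizes type-II error.
#'
#' @param table Complete feature tibble (impute first; see [knn_impute()]).
#' @param alpha Type-I error bound.
#' @param delta Allowed probability of violating the bound.
#' @param split_frac Fraction of null rows held out for threshold
#'   calibration.
#' @return An `np_classifier` with the fitted discriminant, threshold,
#'   orientation and calibration constants. Use `predict(object, newdata,
#'   type = "score"|"class")`.
#' @export
np_classify <- function(table, alpha = 0.05, delta = 0.05, split_frac = 0.5) {
  cols <- feature_cols(table)
  if (anyNA(table[, cols])) stop("impute missing features first", call. = FALSE)
  y <- table$label
  if (!any(y) || all(y)) stop("both classes must be present", call. = FALSE)
  null_idx <- which(!y)
  n_cal <- max(1L, round(split_frac * length(null_idx)))
  cal_idx <- sample(null_idx, n_cal)
  fit_rows <- setdiff(seq_len(nrow(table)), cal_idx)
  x <- as.matrix(table[, cols])
  lda_fit <- MASS::lda(x[fit_rows, , drop = FALSE],
                       grouping = factor(y[fit_rows], levels = c(FALSE, TRUE)))
  score_all <- as.numeric(stats::predict(lda_fit, x)$x[, 1])
  sign_flip <- if (mean(score_all[y]) >= mean(score_all[!y])) 1 else -1
  score_all <- sign_flip * score_all
  null_scores <- sort(score_all[cal_idx])
  k <- np_order_index(length(null_scores), alpha, delta)
  structure(
    list(lda = lda_fit, sign = sign_flip, features = cols,
         threshold = null_scores[k], order_index = k,
         n_null_calibration = length(null_scores),
         alpha = alpha, delta = delta),
    class = "np_classifier"
  )
}

#' @rdname np_classify
#' @param object A fitted `np_classifier`.
#' @param newdata Feature tibble with the same feature columns, complete.
#' @param type `"class"` for thresholded TSG calls, `"score"` for the raw
#'   discriminant score.
#' @param ... Unused.
#' @export
predict.np_classifier <- function(object, newdata, type = c("class", "score"),
                                  ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[, object$features])
  score <- object$sign * as.numeric(stats::predict(object$lda, x)$x[, 1])
  if (type == "score") score else score > object$threshold
}

#' @export
print.np_classifier <- function(x, ...) {
  cat("Neyman-Pearson classifier (LDA base scorer)\n")
  cat(sprintf("  alpha = %g, delta = %g, threshold = %.4f (order index %d of %d)\n",
              x$alpha, x$delta, x$threshold, x$order_index,
              x$n_null_calibration))
  invisible(x)
}

#' @rdname np_classify
#' @param x An `np_classifier`.
#' @exportS3Method generics::tidy
tidy.np_classifier <- function(x, ...) {
  tibble::tibble(feature = rownames(x$lda$scaling),
                 coefficient = x$sign * x$lda$scaling[, 1])
}

#' @rdname np_classify
#' @exportS3Method generics::glance
glance.np_classifier <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, delta = x$delta, threshold = x$threshold,
                 order_index = x$order_index,
                 n_null_calibration = x$n_null_calibration)
}

#' Stratified cross-validated evaluation of the NP classifier
#'
#' Splits genes into `folds` label-stratified folds (the TSG class is rare,
#' about 7-10% of genes, so stratification keeps positives in every fold).
#' Within each training fold the feature table is imputed using training
#' donors only, the classifier is fitted, and held-out genes — imputed with
#' the training donors, never with themselves — are scored. Reported per
#' fold: AUC of the score, accuracy and sensitivity of the NP decisions.
#'
#' @param table Feature tibble (may contain missing cells).
#' @param folds Number of folds, at least 2.
#' @param alpha,delta NP guarantee parameters, see [np_classify()].
#' @param k_impute Neighbours for [knn_impute()].
#' @param seed Seed controlling fold assignment and the null calibration
#'   split.
#' @return A `tsg_cv` tibble with one row per fold (`fold`, `auc`,
#'   `accuracy`, `sensitivity`); `glance()` gives mean and sd of each
#'   metric.
#' @export
evaluate_cv <- function(table, folds = 5, alpha = 0.05, delta = 0.05,
                        k_impute = 5, seed = 1) {
  stopifnot(folds >= 2)
  withr::with_seed(seed, {
    y <- table$label
    fold_id <- integer(nrow(table))
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(y == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    if (any(tapply(y, fold_id, sum) == 0)) {
      stop("a fold has no positive genes; reduce `folds`", call. = FALSE)
    }
    rows <- purrr::map(seq_len(folds), function(f) {
      train <- table[fold_id != f, ]
      test <- table[fold_id == f, ]
      train_imp <- knn_impute(train, k = k_impute)
      test_imp <- knn_impute(test, k = k_impute, donors = train_imp)
      clf <- np_classify(train_imp, alpha = alpha, delta = delta)
      score <- predict(clf, test_imp, type = "score")
      call <- predict(clf, test_imp, type = "class")
      truth <- test_imp$label
      auc <- as.numeric(pROC::auc(
        response = factor(truth, levels = c(FALSE, TRUE)),
        predictor = score, direction = "<", quiet = TRUE
      ))
      tibble::tibble(
        fold = f, auc = auc,
        accuracy = mean(call == truth),
        sensitivity = sum(call & truth) / sum(truth)
      )
    })
    out <- dplyr::bind_rows(rows)
    structure(out, class = c("tsg_cv", class(out)),
              alpha = alpha, delta = delta, folds = folds)
  })
}

#' @rdname evaluate_cv
#' @param x A `tsg_cv` tibble.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.tsg_cv <- function(x, ...) {
  tibble::tibble(
    folds = nrow(x),
    auc = mean(x$auc), auc_sd = sd(x$auc),
    accuracy = mean(x$accuracy), accuracy_sd = sd(x$accuracy),
    sensitivity = mean(x$sensitivity), sensitivity_sd = sd(x$sensitivity)
  )
}
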