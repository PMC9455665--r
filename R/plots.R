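#' Plot methods for pipeline result tables
#'
#' `autoplot()` methods give quick diagnostic views: the DEG table as a
#' median-rank-ratio versus significance scatter, the differential
#' coexpression table as normal-versus-cancer correlations, the integrated
#' TSG-term network as ranked edge weights, and cross-validation metrics as
#' per-fold points.
#'
#' @param object A `tsg_deg`, `tsg_dcg`, `tsg_integration` or `tsg_cv`
#'   object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name tsgnet-autoplot
NULL

#' @rdname tsgnet-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.tsg_deg <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = log2(.data$ratio), y = -log10(pmax(.data$p_value, 1e-300)),
    colour = .data$direction
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "bonferroni")),
                        linetype = "dashed") +
    ggplot2::labs(x = "log2 median-rank ratio (cancer / normal)",
                  y = "-log10 p (Wilcoxon on ranks)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname tsgnet-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.tsg_dcg <- function(object, ...) {
  r_cancer_cols <- grep("^r_cancer", names(object), value = TRUE)
  df <- dplyr::mutate(tibble::as_tibble(object),
                      r_cancer_mean = rowMeans(object[, r_cancer_cols, drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_normal, y = .data$r_cancer_mean,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "r (normal)", y = "mean r (cancer)",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' @rdname tsgnet-autoplot
#' @param top_k Number of top-ranked TSG-term pairs to show.
#' @exportS3Method ggplot2::autoplot
autoplot.tsg_integration <- function(object, top_k = 25, ...) {
  df <- utils::head(tibble::as_tibble(object), top_k)
  df$pair <- factor(paste(df$tsg, df$term, sep = " — "),
                    levels = rev(paste(df$tsg, df$term, sep = " — ")))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(pmax(.data$p_combined, 1e-300)), y = .data$pair
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10 combined p", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname tsgnet-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.tsg_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("auc", "accuracy", "sensitivity"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.05),
                        alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "held-out value") +
    ggplot2::theme_minimal()
}
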