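#' Primary versus secondary alignment score scatter
#'
#' Reads on the diagonal match several library entries equally well and
#' are discarded as ambiguous under the default thresholds; reads
#' without a secondary score are shown on the baseline.
#'
#' @param classified output of [classify_reads].
#' @return A ggplot.
#' @export
plot_score_scatter <- function(classified) {
  df <- dplyr::mutate(classified,
                      secondary_plot = dplyr::coalesce(.data$secondary_score,
                                                       0L))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$secondary_plot,
                                   y = .data$primary_score,
                                   colour = .data$category)) +
    ggplot2::geom_jitter(width = 0.3, height = 0.3, alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "secondary alignment score",
                  y = "primary alignment score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Mean-variance plot of a dispersion model
#'
#' Per-sgRNA control means against sample variances with the fitted
#' quadratic variance law and the Poisson diagonal.
#'
#' @param object a `dispersion_model`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.dispersion_model <- function(object, ...) {
  df <- object$sgrnas[object$sgrnas$mu > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mu, y = .data$var)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$model_var), colour = "red") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "control mean", y = "control variance",
                  title = sprintf("sigma^2 = mu + %.3g mu^2", object$D)) +
    ggplot2::theme_minimal()
}

#' Gene ranking overview
#'
#' Score (-log10 rho) by rank, coloured by FDR significance.
#'
#' @param object a `gene_ranking` from [arra_ranking].
#' @param fdr_level significance level to colour by (default 0.05).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.gene_ranking <- function(object, fdr_level = 0.05, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      significant = .data$fdr < fdr_level)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                   y = .data$neg_log10_rho,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "gene rank", y = "-log10 alpha-RRA score",
                  colour = sprintf("FDR < %g", fdr_level)) +
    ggplot2::theme_minimal()
}

#' Per-sample count distribution boxplot
#'
#' @param m a (normalized) count matrix.
#' @return A ggplot of log10(count + 1) per sample.
#' @export
plot_count_distributions <- function(m) {
  long <- tidyr::pivot_longer(tibble::as_tibble(m),
                              cols = dplyr::all_of(sample_cols(m)),
                              names_to = "sample_id", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = log10(.data$count + 1))) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "log10(normalized count + 1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
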