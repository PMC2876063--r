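#' Scatter plot of one regulator-target pair
#'
#' Plots microRNA against mRNA expression per sample, colored by condition —
#' the per-pair view used to judge whether anti-correlation holds within
#' each class and overall.
#'
#' @param mirna_x,mrna_x Expression tables.
#' @param metadata Sample metadata.
#' @param mirna_id,gene_id The pair to plot.
#' @return A ggplot object.
#' @export
plot_pair <- function(mirna_x, mrna_x, metadata, mirna_id, gene_id) {
  meta <- align_metadata(mirna_x, metadata)
  df <- tibble(
    sample_id = meta$sample_id,
    condition = meta$condition,
    mirna = expr_matrix(mirna_x)[mirna_id, meta$sample_id],
    mrna = expr_matrix(mrna_x)[gene_id, meta$sample_id])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mirna, y = .data$mrna,
      colour = .data$condition)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      linewidth = 0.4) +
    ggplot2::labs(x = paste(mirna_id, "expression (log2)"),
      y = paste(gene_id, "expression (log2)"),
      colour = NULL,
      title = paste0(mirna_id, " vs ", gene_id)) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of a DE table
#'
#' @param de DE tibble from [call_de_mirna()] or [call_de_mrna()].
#' @return A ggplot object.
#' @export
plot_de <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2_fold_change,
      y = -log10(.data$p_value), colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
      `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (tumor - normal)",
      y = "-log10 permutation p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Overview plot of a finished screen
#'
#' Screening correlation against permutation significance for every
#' candidate pair, with the correlation cutoff and the passing pairs marked.
#'
#' @param object A `mirdirect_screen` from [run_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mirdirect_screen <- function(object, ...) {
  pairs <- as_tibble(object$pairs)
  if (nrow(pairs) == 0) {
    return(ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0, label = "no candidate pairs") +
      ggplot2::theme_void())
  }
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$screen_r,
      y = -log10(.data$perm_p), colour = .data$passes,
      shape = .data$pair_class)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_vline(xintercept = object$config$P0, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
      `TRUE` = "firebrick")) +
    ggplot2::labs(x = "screening Pearson correlation",
      y = "-log10 permutation p", colour = "passes", shape = "pair class") +
    ggplot2::theme_minimal()
}
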