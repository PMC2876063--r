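#' Collapse qPCR replicates to per-sample mean Ct
#'
#' Averages the present replicates of each (feature, sample) cell. Every
#' feature/sample combination implied by the table must have at least one
#' replicate present.
#'
#' @param ct A Ct table (see [ct_table()] / [read_ct_table()]).
#' @return An expression table of mean Ct values (`scale_tag = "ct"`), feature
#'   and sample order following first appearance in the input.
#' @export
collapse_replicates <- function(ct) {
  ct <- ct_table(ct)
  features <- unique(ct$feature_id)
  samples <- unique(ct$sample_id)
  means <- ct |>
    group_by(.data$feature_id, .data$sample_id) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  grid <- tidyr::expand_grid(feature_id = features, sample_id = samples)
  missing <- anti_join(grid, means, by = c("feature_id", "sample_id"))
  if (nrow(missing) > 0) {
    mirdirect_abort(
      paste0("no replicate present for (", missing$feature_id[1], ", ",
        missing$sample_id[1], ")",
        if (nrow(missing) > 1) paste0(" and ", nrow(missing) - 1, " more cell(s)")),
      class = "mirdirect_error_ct")
  }
  wide <- tidyr::pivot_wider(means, names_from = "sample_id", values_from = "ct")
  wide <- wide[match(features, wide$feature_id), c("feature_id", samples)]
  expression_table(wide, scale_tag = "ct")
}

#' Select a housekeeping microRNA for comparative-Ct normalization
#'
#' Identifies the feature whose level is most unchanged between tumor and
#' normal samples, to serve as the per-sample reference in
#' [comparative_ct_normalize()]. Three notions of "most unchanged" are
#' provided:
#'
#' * `"snr"` (default): minimum absolute signal-to-noise statistic between
#'   conditions ([snr_statistic()]);
#' * `"variance"`: minimum overall variance across all samples;
#' * `"delta_mean"`: minimum absolute difference of condition means.
#'
#' Ties are broken by smaller overall variance, then lexicographically by
#' feature ID, so selection is deterministic.
#'
#' @param ct_matrix Expression table of (collapsed) Ct values.
#' @param metadata Sample metadata.
#' @param method Stability criterion, see above.
#' @return A `normalization_report` object: list with `housekeeping_id`,
#'   `method`, and a `stability_scores` tibble. [tidy()] returns the scores.
#' @export
select_housekeeping <- function(ct_matrix, metadata,
    method = c("snr", "variance", "delta_mean")) {
  method <- rlang::arg_match(method)
  meta <- align_metadata(ct_matrix, metadata)
  m <- expr_matrix(ct_matrix)
  tum <- m[, meta$condition == "tumor", drop = FALSE]
  nor <- m[, meta$condition == "normal", drop = FALSE]
  if (ncol(tum) < 2 || ncol(nor) < 2) {
    mirdirect_abort("housekeeping selection needs >= 2 samples per condition",
      class = "mirdirect_error_groupsize")
  }
  score <- switch(method,
    snr = abs(snr_rows(tum, nor)),
    variance = apply(m, 1, var),
    delta_mean = abs(rowMeans(tum) - rowMeans(nor)))
  overall_var <- apply(m, 1, var)
  ord <- order(score, overall_var, rownames(m))
  scores <- tibble(feature_id = rownames(m), score = unname(score),
    overall_variance = unname(overall_var))
  structure(list(
    housekeeping_id = rownames(m)[ord[1]],
    method = method,
    stability_scores = arrange(scores, .data$score, .data$overall_variance,
      .data$feature_id)),
    class = "normalization_report")
}

#' @export
print.normalization_report <- function(x, ...) {
  cat("Comparative-Ct normalization report\n")
  cat("  housekeeping feature:", x$housekeeping_id, "\n")
  cat("  stability method:    ", x$method, "\n")
  cat("  features scored:     ", nrow(x$stability_scores), "\n")
  invisible(x)
}

#' @rdname select_housekeeping
#' @param x A `normalization_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.normalization_report <- function(x, ...) x$stability_scores

#' Comparative-Ct (delta-Ct) normalization
#'
#' Expresses each feature's abundance relative to a housekeeping feature
#' measured in the same sample: relative expression
#' \eqn{2^{-(Ct_{feature} - Ct_{hk})}}, or on the log2 scale
#' \eqn{-(Ct_{feature} - Ct_{hk})}. No calibrator sample is involved; this is
#' per-sample delta-Ct relative quantification.
#'
#' @param ct_matrix Expression table of (collapsed) Ct values.
#' @param housekeeping_id Feature to normalize against (e.g. from
#'   [select_housekeeping()]).
#' @param log2 If `TRUE`, return log2 relative expression (recommended input
#'   scale for the differential-expression statistics); otherwise linear
#'   relative expression.
#' @return An expression table with `scale_tag` `"log2"` or
#'   `"linear_relative"`.
#' @export
#' @examples
#' ct <- expression_table(
#'   matrix(c(25, 26, 20, 20), 2, byrow = TRUE,
#'     dimnames = list(c("miR-x", "hk"), c("s1", "s2"))),
#'   scale_tag = "ct")
#' comparative_ct_normalize(ct, "hk")
comparative_ct_normalize <- function(ct_matrix, housekeeping_id, log2 = FALSE) {
  m <- expr_matrix(ct_matrix)
  if (!housekeeping_id %in% rownames(m)) {
    mirdirect_abort(paste0("housekeeping feature `", housekeeping_id,
      "` not present in Ct matrix"), class = "mirdirect_error_ct")
  }
  delta <- sweep(m, 2, m[housekeeping_id, ])
  out <- if (log2) -delta else 2^(-delta)
  expression_table(out, scale_tag = if (log2) "log2" else "linear_relative")
}

#' Binarize expression against training-set midpoint thresholds
#'
#' For each feature, the threshold is the midpoint of the two condition means
#' computed on the training samples only; values strictly greater than the
#' threshold map to 1, all others (including exact equality) to 0. This is the
#' front end of the weighted-voting classifier.
#'
#' @param x Expression table.
#' @param metadata Sample metadata.
#' @param train_sample_ids Samples the thresholds may be learned from; all
#'   columns of `x` are binarized, but only these inform the thresholds.
#' @return An expression table of 0/1 values (`scale_tag = "binary"`) with a
#'   `thresholds` attribute (tibble `feature_id`, `threshold`).
#' @export
binarize_expression <- function(x, metadata, train_sample_ids = NULL) {
  meta <- align_metadata(x, metadata)
  train_sample_ids <- train_sample_ids %||% meta$sample_id
  thr <- binarize_thresholds(x, meta, train_sample_ids)
  m <- expr_matrix(x)
  bin <- (m > thr$threshold[match(rownames(m), thr$feature_id)]) + 0
  out <- expression_table(bin, scale_tag = "binary")
  attr(out, "thresholds") <- thr
  out
}

binarize_thresholds <- function(x, meta, train_sample_ids) {
  train <- meta[meta$sample_id %in% train_sample_ids, ]
  if (!all(CONDITIONS %in% train$condition)) {
    mirdirect_abort("both conditions must be present among training samples",
      class = "mirdirect_error_groupsize")
  }
  m <- expr_matrix(x)
  tum <- rowMeans(m[, train$sample_id[train$condition == "tumor"], drop = FALSE])
  nor <- rowMeans(m[, train$sample_id[train$condition == "normal"], drop = FALSE])
  tibble(feature_id = rownames(m), threshold = unname((tum + nor) / 2))
}
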