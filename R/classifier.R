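#' Fit a weighted-voting two-class model
#'
#' The classical SNR-weighted voting classifier: each feature gets a weight
#' `w = snr_statistic(tumor, normal)` and a decision boundary `b` at the
#' midpoint of the two training class means. With `binarize_first = TRUE`,
#' expression is first binarized against training-set midpoint thresholds
#' ([binarize_expression()]) and the votes operate on the 0/1 values.
#'
#' @param x Expression table.
#' @param metadata Sample metadata; only samples listed here train the model.
#' @param feature_ids Panel of features to vote with (default: all).
#' @param binarize_first Binarize expression before fitting/voting.
#' @return A `voting_model`: weights/boundaries tibble plus the binarization
#'   thresholds when used. [tidy()] returns per-feature parameters;
#'   [glance()] a one-row summary.
#' @export
fit_voting <- function(x, metadata, feature_ids = NULL, binarize_first = FALSE) {
  meta <- sample_metadata(metadata)
  feature_ids <- feature_ids %||% x$feature_id
  missing <- setdiff(feature_ids, x$feature_id)
  if (length(missing) > 0) {
    mirdirect_abort(paste0("panel feature(s) absent from expression: ",
      paste(missing, collapse = ", ")), class = "mirdirect_error_expression")
  }
  x <- x[match(feature_ids, x$feature_id), c("feature_id", meta$sample_id)]
  if (sum(meta$condition == "tumor") < 2 || sum(meta$condition == "normal") < 2) {
    mirdirect_abort("voting model needs >= 2 training samples per class",
      class = "mirdirect_error_groupsize")
  }
  thresholds <- NULL
  if (binarize_first) {
    thresholds <- binarize_thresholds(x, meta, meta$sample_id)
    x <- apply_binarization(x, thresholds)
  }
  m <- expr_matrix(x)
  tum <- m[, meta$condition == "tumor", drop = FALSE]
  nor <- m[, meta$condition == "normal", drop = FALSE]
  w <- snr_rows(tum, nor)
  b <- (rowMeans(tum) + rowMeans(nor)) / 2
  structure(list(
    features = tibble(feature_id = rownames(m), weight = unname(w),
      boundary = unname(b)),
    binarize_first = binarize_first,
    thresholds = thresholds,
    class_labels = c(positive = "tumor", negative = "normal")),
    class = "voting_model")
}

apply_binarization <- function(x, thresholds) {
  m <- expr_matrix(x)
  bin <- (m > thresholds$threshold[match(rownames(m), thresholds$feature_id)]) + 0
  expression_table(bin, scale_tag = "binary")
}

#' @export
print.voting_model <- function(x, ...) {
  cat("Weighted-voting classifier:", nrow(x$features), "feature(s)",
    if (x$binarize_first) "(binarized votes)" else "(continuous votes)", "\n")
  invisible(x)
}

#' @rdname fit_voting
#' @param x A `voting_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.voting_model <- function(x, ...) x$features

#' @rdname fit_voting
#' @exportS3Method generics::glance
glance.voting_model <- function(x, ...) {
  tibble(n_features = nrow(x$features), binarized = x$binarize_first,
    mean_abs_weight = mean(abs(x$features$weight)))
}

#' Predict a sample's class by weighted voting
#'
#' Each feature casts the vote `w * (x - b)`; the sample is called tumor when
#' the vote sum is positive, normal otherwise. An exact tie (sum of 0, as
#' happens when every weight is zero) is resolved to normal with a warning so
#' the rule stays deterministic.
#'
#' @param model A `voting_model`.
#' @param sample_vector Named numeric vector covering the model's features
#'   (raw expression; binarization, if the model uses it, is applied here with
#'   the training thresholds).
#' @return A list with `class` (`"tumor"`/`"normal"`) and `vote_margin` (the
#'   signed vote sum).
#' @export
predict_voting <- function(model, sample_vector) {
  feats <- model$features$feature_id
  missing <- setdiff(feats, names(sample_vector))
  if (length(missing) > 0) {
    mirdirect_abort(paste0("sample vector is missing feature(s): ",
      paste(missing, collapse = ", ")), class = "mirdirect_error_expression")
  }
  v <- sample_vector[feats]
  if (model$binarize_first) {
    thr <- model$thresholds$threshold[match(feats, model$thresholds$feature_id)]
    v <- (v > thr) + 0
  }
  votes <- model$features$weight * (v - model$features$boundary)
  total <- sum(votes)
  if (total == 0) {
    warn("vote sum is exactly zero; resolving tie to `normal`")
  }
  list(class = if (total > 0) "tumor" else "normal", vote_margin = total)
}

#' Leave-one-out cross-validated accuracy of weighted voting
#'
#' Each sample in turn is held out; the model — including the binarization
#' thresholds when `binarize_first` — is refit on the remaining samples and
#' used to predict the held-out sample, so no information leaks from the test
#' sample into its fold's model.
#'
#' @inheritParams fit_voting
#' @return Fraction of samples classified correctly, in \[0, 1\], with a
#'   `predictions` attribute (per-sample tibble).
#' @export
loo_accuracy <- function(x, metadata, feature_ids = NULL,
    binarize_first = FALSE) {
  meta <- align_metadata(x, metadata)
  if (nrow(meta) < 3) {
    mirdirect_abort("leave-one-out needs >= 3 samples",
      class = "mirdirect_error_groupsize")
  }
  preds <- purrr::map(seq_len(nrow(meta)), function(i) {
    train_meta <- meta[-i, ]
    model <- fit_voting(x, train_meta, feature_ids = feature_ids,
      binarize_first = binarize_first)
    held <- expr_matrix(x)[, meta$sample_id[i]]
    pred <- predict_voting(model, held)
    tibble(sample_id = meta$sample_id[i], truth = meta$condition[i],
      predicted = pred$class, vote_margin = pred$vote_margin)
  })
  preds <- bind_rows(preds)
  acc <- mean(preds$predicted == preds$truth)
  attr(acc, "predictions") <- preds
  acc
}
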