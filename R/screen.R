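#' Sample Pearson correlation with screening preconditions
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be constant
#'   (the correlation is undefined there, and callers skip such pairs).
#' @return The Pearson correlation coefficient in \[-1, 1\].
#' @export
#' @examples
#' pearson_cor(c(1, 2, 3), c(3, 2, 1)) # -1
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) {
    mirdirect_abort("vectors must have equal length", class = "mirdirect_error_pearson")
  }
  if (length(x) < 3) {
    mirdirect_abort("Pearson correlation needs >= 3 paired observations",
      class = "mirdirect_error_pearson")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    mirdirect_abort("correlation undefined for a constant vector",
      class = "mirdirect_error_constant")
  }
  cor(x, y)
}

#' Build candidate regulator-target pairs from the DE and conservation filters
#'
#' Candidates are the pairs the anti-correlation screen will examine: every
#' (significantly up-regulated microRNA, significantly down-regulated mRNA)
#' combination and every (down-regulated microRNA, up-regulated mRNA)
#' combination that is also present in the conserved target list.
#'
#' @param de_mirna DE table from [call_de_mirna()].
#' @param de_mrna DE table from [call_de_mrna()].
#' @param targets Conserved target tibble from [conserved_targets()] or
#'   [targets_from_annotation()]; rows with `conserved == FALSE` are ignored.
#' @return Tibble of candidate skeletons: `mirna_id`, `gene_id`, `pair_class`
#'   (`upMiR_downMRNA` or `downMiR_upMRNA`).
#' @export
build_candidates <- function(de_mirna, de_mrna, targets) {
  if ("conserved" %in% names(targets)) {
    targets <- targets[targets$conserved, ]
  }
  sig_mir <- de_mirna[de_mirna$significant, c("feature_id", "direction")]
  sig_rna <- de_mrna[de_mrna$significant, c("feature_id", "direction")]
  pairs <- inner_join(
    rename(sig_mir, mirna_id = "feature_id", mir_direction = "direction"),
    tibble(mirna_id = targets$mirna_id, gene_id = targets$gene_id),
    by = "mirna_id", relationship = "many-to-many")
  pairs <- inner_join(pairs,
    rename(sig_rna, gene_id = "feature_id", mrna_direction = "direction"),
    by = "gene_id", relationship = "many-to-many")
  pairs <- pairs |>
    filter(.data$mir_direction != .data$mrna_direction) |>
    mutate(pair_class = ifelse(.data$mir_direction == "up_in_tumor",
      "upMiR_downMRNA", "downMiR_upMRNA")) |>
    select("mirna_id", "gene_id", "pair_class") |>
    distinct()
  arrange(pairs, .data$mirna_id, .data$gene_id)
}

# Sample IDs whose expression vectors a pair's screening correlation uses.
screen_samples <- function(meta, pair_class, mode) {
  if (mode == "combined") return(meta$sample_id)
  cls <- if (pair_class == "upMiR_downMRNA") "tumor" else "normal"
  meta$sample_id[meta$condition == cls]
}

#' Per-class Pearson anti-correlation screen
#'
#' For each candidate pair the microRNA and mRNA expression vectors are
#' correlated within tumor samples, within normal samples, and over all
#' samples. The decision correlation `screen_r` depends on `mode`:
#'
#' * `"per_class"` (default): pairs of up-regulated microRNA with
#'   down-regulated mRNA are screened in tumor samples; pairs of
#'   down-regulated microRNA with up-regulated mRNA in normal samples —
#'   i.e. the class where the regulator is abundant and presumed active.
#' * `"combined"`: all samples together (the mode used when validating pairs
#'   on noisier array data).
#'
#' A pair passes when `screen_r < P0` (default -0.95, the strict cutoff
#' appropriate for low-noise qPCR data). Pairs whose expression vector is
#' constant over the screening samples have no defined correlation and are
#' skipped with a message; they are returned in the `skipped` attribute.
#'
#' @param candidates Candidate pairs from [build_candidates()].
#' @param mirna_x,mrna_x Expression tables for the two modalities (shared
#'   samples per `metadata`).
#' @param metadata Sample metadata.
#' @param P0 Anti-correlation cutoff in \[-1, 0).
#' @param mode `"per_class"` or `"combined"`.
#' @return The candidate tibble with `r_tumor`, `r_normal`, `r_combined`,
#'   `screen_r`, `passes` columns.
#' @export
screen_pairs <- function(candidates, mirna_x, mrna_x, metadata,
    P0 = -0.95, mode = c("per_class", "combined")) {
  mode <- rlang::arg_match(mode)
  if (!(P0 >= -1 && P0 < 0)) {
    mirdirect_abort("P0 must lie in [-1, 0)", class = "mirdirect_error_config")
  }
  meta <- align_metadata(mirna_x, metadata)
  align_metadata(mrna_x, metadata)
  mir <- expr_matrix(mirna_x)
  rna <- expr_matrix(mrna_x)
  tum <- meta$sample_id[meta$condition == "tumor"]
  nor <- meta$sample_id[meta$condition == "normal"]

  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }
  res <- purrr::pmap(candidates[c("mirna_id", "gene_id", "pair_class")],
    function(mirna_id, gene_id, pair_class) {
      xv <- mir[mirna_id, ]
      yv <- rna[gene_id, ]
      r_t <- safe_cor(xv[tum], yv[tum])
      r_n <- safe_cor(xv[nor], yv[nor])
      r_c <- safe_cor(xv, yv)
      ids <- screen_samples(meta, pair_class, mode)
      screen_r <- safe_cor(xv[ids], yv[ids])
      tibble(mirna_id = mirna_id, gene_id = gene_id, pair_class = pair_class,
        r_tumor = r_t, r_normal = r_n, r_combined = r_c, screen_r = screen_r)
    })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(mirna_id = character(), gene_id = character(),
      pair_class = character(), r_tumor = numeric(), r_normal = numeric(),
      r_combined = numeric(), screen_r = numeric())
  }
  skipped <- out[is.na(out$screen_r), ]
  if (nrow(skipped) > 0) {
    inform(paste0("skipping ", nrow(skipped),
      " pair(s) with constant expression over the screening samples"))
    out <- out[!is.na(out$screen_r), ]
  }
  out <- mutate(out, passes = .data$screen_r < P0)
  attr(out, "skipped") <- skipped
  attr(out, "P0") <- P0
  attr(out, "mode") <- mode
  out
}

# All permutations of 1..n as an n x n! index matrix (n <= 7 in practice).
all_orderings <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_orderings(n - 1L)
  cols <- lapply(seq_len(n), function(pos) {
    rbind_insert(sub, n, pos)
  })
  do.call(cbind, cols)
}

rbind_insert <- function(sub, value, pos) {
  n <- nrow(sub) + 1L
  out <- matrix(0L, n, ncol(sub))
  if (pos > 1) out[seq_len(pos - 1L), ] <- sub[seq_len(pos - 1L), , drop = FALSE]
  out[pos, ] <- value
  if (pos < n) out[(pos + 1L):n, ] <- sub[pos:(n - 1L), , drop = FALSE]
  out
}

# One-sided (toward anti-correlation) permutation p-value for a single
# correlation: permute the order of x relative to y.
cor_perm_pvalue <- function(x, y, B = 999, seed = NULL,
    mode = c("auto", "monte_carlo", "exhaustive"), exhaustive_max_n = 6) {
  mode <- rlang::arg_match(mode)
  n <- length(x)
  r_obs <- cor(x, y)
  if (mode == "auto") {
    mode <- if (n <= exhaustive_max_n) "exhaustive" else "monte_carlo"
  }
  if (mode == "exhaustive") {
    if (n > exhaustive_max_n) {
      mirdirect_abort(paste0("exhaustive correlation null infeasible for n = ", n),
        class = "mirdirect_error_permutation")
    }
    perms <- all_orderings(n)
    r_star <- cor(y, matrix(x[perms], nrow = n))[1, ]
    mean(r_star <= r_obs + 1e-12)  # identity ordering is enumerated
  } else {
    if (is.null(seed)) {
      mirdirect_abort("seed required in monte_carlo mode",
        class = "mirdirect_error_seed")
    }
    perm_idx <- with_seed(seed, {
      vapply(seq_len(B), function(i) sample.int(n), integer(n))
    })
    r_star <- cor(y, matrix(x[perm_idx], nrow = n))[1, ]
    (sum(r_star <= r_obs + 1e-12) + 1) / (B + 1)
  }
}

#' Permutation significance of pair anti-correlations
#'
#' For each screened pair, the null distribution of the correlation is
#' obtained by permuting the sample order of the microRNA vector relative to
#' the mRNA vector, within the same sample class the screening correlation
#' used. The p-value is one-sided toward anti-correlation:
#' p = (#\{r* <= r_obs\} + 1) / (B + 1) in Monte-Carlo mode, or the exact
#' proportion over all n! orderings when n <= `exhaustive_max_n`.
#'
#' @param pairs Screened pairs from [screen_pairs()].
#' @param mirna_x,mrna_x Expression tables.
#' @param metadata Sample metadata.
#' @param B Monte-Carlo permutation count.
#' @param seed RNG seed (required unless every pair is enumerated
#'   exhaustively).
#' @param mode `"auto"` (exhaustive when feasible), `"monte_carlo"`, or
#'   `"exhaustive"`.
#' @param exhaustive_max_n Largest class size enumerated exhaustively.
#' @return `pairs` with a `perm_p` column.
#' @export
pair_permutation_significance <- function(pairs, mirna_x, mrna_x, metadata,
    B = 999, seed = NULL, mode = "auto", exhaustive_max_n = 6) {
  meta <- align_metadata(mirna_x, metadata)
  mir <- expr_matrix(mirna_x)
  rna <- expr_matrix(mrna_x)
  screen_mode <- attr(pairs, "mode") %||% "per_class"
  if (nrow(pairs) == 0) {
    return(mutate(pairs, perm_p = numeric(0)))
  }
  seeds <- if (!is.null(seed)) derive_seeds(seed, nrow(pairs)) else
    rep(list(NULL), nrow(pairs))
  perm_p <- purrr::pmap_dbl(
    list(pairs$mirna_id, pairs$gene_id, pairs$pair_class, seq_len(nrow(pairs))),
    function(mirna_id, gene_id, pair_class, i) {
      ids <- screen_samples(meta, pair_class, screen_mode)
      cor_perm_pvalue(mir[mirna_id, ids], rna[gene_id, ids], B = B,
        seed = seeds[[i]], mode = mode, exhaustive_max_n = exhaustive_max_n)
    })
  out <- mutate(pairs, perm_p = perm_p)
  attr(out, "P0") <- attr(pairs, "P0")
  attr(out, "mode") <- screen_mode
  out
}

#' Finalize the anti-correlation screen
#'
#' A pair is retained when it clears all three hurdles: the strict
#' correlation cutoff (`screen_r < P0`, carried over from [screen_pairs()]),
#' permutation significance (`perm_p < p_threshold`, default 0.01), and a
#' BH false-discovery rate over the whole candidate family
#' (`fdr_q < fdr_threshold`, default 0.2).
#'
#' @param pairs Pairs with `perm_p` from [pair_permutation_significance()].
#' @param p_threshold Permutation p-value threshold.
#' @param fdr_threshold BH FDR threshold across the pair family.
#' @return `pairs` with `fdr_q` and the final `passes` flag.
#' @export
finalize_screen <- function(pairs, p_threshold = 0.01, fdr_threshold = 0.2) {
  if (!"perm_p" %in% names(pairs)) {
    mirdirect_abort("pairs must carry `perm_p`; run pair_permutation_significance()",
      class = "mirdirect_error_screen")
  }
  out <- pairs |>
    mutate(fdr_q = bh_fdr(.data$perm_p),
      passes = .data$passes & .data$perm_p < p_threshold &
        .data$fdr_q < fdr_threshold)
  attr(out, "P0") <- attr(pairs, "P0")
  attr(out, "mode") <- attr(pairs, "mode")
  out
}
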