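#' Signal-to-noise class-separation statistic
#'
#' The SNR statistic for two groups is
#' \deqn{s = \frac{\bar{x}_a - \bar{x}_b}{\sigma_a + \sigma_b}}
#' with sample (n-1) standard deviations. To guard against degenerate
#' variances, each standard deviation is floored at
#' `max(sd_floor_frac * |group mean|, sd_floor_abs)`, the convention
#' historically used with this statistic in expression profiling. Set
#' `sd_floor_frac = 0` to remove the floor.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2. In the
#'   tumor-vs-normal screens, `group_a` is tumor so positive values mean
#'   up-in-tumor.
#' @param sd_floor_frac Fraction of the absolute group mean used as an sd
#'   floor (default 0.2).
#' @param sd_floor_abs Absolute sd floor (default 1e-8).
#' @return The SNR statistic (unitless scalar).
#' @export
#' @examples
#' snr_statistic(c(3, 5), c(1, 3)) # 2 / (2 * sqrt(2)) = 0.7071
snr_statistic <- function(group_a, group_b, sd_floor_frac = 0.2,
    sd_floor_abs = 1e-8) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    mirdirect_abort("each group needs >= 2 values for the SNR statistic",
      class = "mirdirect_error_groupsize")
  }
  snr_rows(matrix(group_a, nrow = 1), matrix(group_b, nrow = 1),
    sd_floor_frac, sd_floor_abs)[1]
}

# Row-wise SNR over two matrices sharing rows (features x group samples).
snr_rows <- function(a, b, sd_floor_frac = 0.2, sd_floor_abs = 1e-8) {
  ma <- rowMeans(a); mb <- rowMeans(b)
  sda <- floor_sd(apply(a, 1, sd), ma, sd_floor_frac, sd_floor_abs)
  sdb <- floor_sd(apply(b, 1, sd), mb, sd_floor_frac, sd_floor_abs)
  (ma - mb) / (sda + sdb)
}

floor_sd <- function(s, m, frac, abs_floor) {
  pmax(s, frac * abs(m), abs_floor)
}

# SNR statistics for every feature under every column of the 0/1 tumor
# assignment matrix A (n_samples x n_perm). Vectorised: group sums via
# matrix products, variances from sums of squares.
perm_snr_matrix <- function(m, A, sd_floor_frac = 0.2, sd_floor_abs = 1e-8) {
  na <- colSums(A)[1]
  nb <- nrow(A) - na
  S1a <- m %*% A
  S2a <- (m^2) %*% A
  mean_a <- S1a / na
  var_a <- pmax((S2a - na * mean_a^2) / (na - 1), 0)
  S1b <- rowSums(m) - S1a
  S2b <- rowSums(m^2) - S2a
  mean_b <- S1b / nb
  var_b <- pmax((S2b - nb * mean_b^2) / (nb - 1), 0)
  sda <- pmax(sqrt(var_a), sd_floor_frac * abs(mean_a), sd_floor_abs)
  sdb <- pmax(sqrt(var_b), sd_floor_frac * abs(mean_b), sd_floor_abs)
  (mean_a - mean_b) / (sda + sdb)
}

# Tumor-assignment matrices for the permutation null.
# scheme "labels": unrestricted relabeling of condition labels.
# scheme "paired_signflip": within-patient label swaps (matched design).
perm_assignments <- function(meta, B, mode, seed, exhaustive_bound,
    scheme = c("labels", "paired_signflip")) {
  scheme <- rlang::arg_match(scheme)
  n <- nrow(meta)
  tumor <- meta$condition == "tumor"
  na <- sum(tumor)
  if (scheme == "labels") {
    n_distinct <- choose(n, na)
    mode <- resolve_perm_mode(mode, n_distinct, exhaustive_bound)
    if (mode == "exhaustive") {
      sets <- combn(n, na)
      A <- matrix(0, n, ncol(sets))
      A[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = na))] <- 1
    } else {
      A <- with_seed(seed, {
        vapply(seq_len(B), function(i) {
          a <- numeric(n); a[sample.int(n, na)] <- 1; a
        }, numeric(n))
      })
    }
  } else {
    patients <- unique(meta$patient_id)
    P <- length(patients)
    base <- as.numeric(tumor)
    pair_idx <- lapply(patients, function(p) which(meta$patient_id == p))
    flip_to_assignment <- function(flips) {
      a <- base
      for (k in which(flips)) a[pair_idx[[k]]] <- 1 - a[pair_idx[[k]]]
      a
    }
    n_distinct <- 2^P
    mode <- resolve_perm_mode(mode, n_distinct, exhaustive_bound)
    if (mode == "exhaustive") {
      grid <- expand.grid(rep(list(c(FALSE, TRUE)), P))
      A <- vapply(seq_len(nrow(grid)), function(i) {
        flip_to_assignment(unlist(grid[i, ]))
      }, numeric(n))
    } else {
      A <- with_seed(seed, {
        vapply(seq_len(B), function(i) {
          flip_to_assignment(runif(P) < 0.5)
        }, numeric(n))
      })
    }
  }
  list(A = A, mode = mode)
}

resolve_perm_mode <- function(mode, n_distinct, exhaustive_bound) {
  if (mode == "auto") {
    if (n_distinct <= exhaustive_bound) "exhaustive" else "monte_carlo"
  } else if (mode == "exhaustive" && n_distinct > exhaustive_bound) {
    mirdirect_abort(paste0("exhaustive mode requested but ", n_distinct,
      " distinct relabelings exceed the bound ", exhaustive_bound),
      class = "mirdirect_error_permutation")
  } else {
    mode
  }
}

# Shared permutation engine: observed SNR and two-sided permutation p-value
# for every feature of an expression table.
de_permutation <- function(x, metadata, B = 1000,
    mode = c("auto", "monte_carlo", "exhaustive"), seed = NULL,
    exhaustive_bound = 20000, scheme = "labels",
    sd_floor_frac = 0.2, sd_floor_abs = 1e-8) {
  mode <- rlang::arg_match(mode)
  meta <- align_metadata(x, metadata)
  if (sum(meta$condition == "tumor") < 2 || sum(meta$condition == "normal") < 2) {
    mirdirect_abort("permutation testing needs >= 2 samples per condition",
      class = "mirdirect_error_groupsize")
  }
  m <- expr_matrix(x)
  obs_A <- matrix(as.numeric(meta$condition == "tumor"), ncol = 1)
  s_obs <- perm_snr_matrix(m, obs_A, sd_floor_frac, sd_floor_abs)[, 1]
  perms <- perm_assignments(meta, B, mode, seed, exhaustive_bound, scheme)
  if (perms$mode == "monte_carlo" && is.null(seed)) {
    mirdirect_abort("seed required in monte_carlo mode",
      class = "mirdirect_error_seed")
  }
  S <- perm_snr_matrix(m, perms$A, sd_floor_frac, sd_floor_abs)
  hits <- rowSums(abs(S) >= abs(s_obs) - 1e-12)
  p <- if (perms$mode == "exhaustive") {
    hits / ncol(perms$A)  # observed labeling is one of the enumerated columns
  } else {
    (hits + 1) / (ncol(perms$A) + 1)
  }
  tibble(feature_id = rownames(m), statistic = unname(s_obs),
    p_value = unname(p), perm_mode = perms$mode, n_perm = ncol(perms$A))
}

#' Permutation p-value for one feature's class separation
#'
#' Two-sided empirical p-value of the SNR statistic under permutation of the
#' condition labels. In `monte_carlo` mode the estimator includes the observed
#' labeling, p = (#\{|s*| >= |s_obs|\} + 1) / (B + 1), so p >= 1/(B+1) > 0. In
#' `exhaustive` mode all distinct relabelings are enumerated and the exact
#' proportion is returned (the observed labeling is among them). `auto`
#' (the default elsewhere in the package) enumerates exactly whenever the
#' number of distinct relabelings is at most `exhaustive_bound`.
#'
#' @param x Expression table.
#' @param metadata Sample metadata.
#' @param feature_id Feature to test.
#' @param B Number of Monte-Carlo permutations.
#' @param mode `"auto"`, `"monte_carlo"` or `"exhaustive"`.
#' @param seed RNG seed (required in Monte-Carlo mode).
#' @param exhaustive_bound Largest number of distinct relabelings enumerated.
#' @param scheme `"labels"` for unrestricted label permutation (default), or
#'   `"paired_signflip"` for within-patient label swaps honouring the matched
#'   design.
#' @return The p-value (scalar).
#' @export
permutation_pvalue <- function(x, metadata, feature_id, B = 1000,
    mode = "monte_carlo", seed = NULL, exhaustive_bound = 20000,
    scheme = "labels") {
  if (!feature_id %in% x$feature_id) {
    mirdirect_abort(paste0("unknown feature `", feature_id, "`"),
      class = "mirdirect_error_expression")
  }
  res <- de_permutation(x[x$feature_id == feature_id, ], metadata, B = B,
    mode = mode, seed = seed, exhaustive_bound = exhaustive_bound,
    scheme = scheme)
  res$p_value[1]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; a thin, validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    mirdirect_abort("p-values must lie in [0, 1]", class = "mirdirect_error_pvalues")
  }
  p.adjust(p_values, method = "BH")
}

#' Storey q-values
#'
#' Estimates the null proportion \eqn{\hat\pi_0} from the distribution of
#' p-values above a grid of lambda thresholds,
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))}, smoothed
#' with a cubic spline and evaluated at the largest lambda, then computes
#' \deqn{q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)} / j .}
#' With fewer than `min_n` p-values the smoother is unreliable and
#' \eqn{\hat\pi_0} falls back to 1, making the q-values equal to
#' Benjamini-Hochberg adjusted values.
#'
#' @param p_values Numeric vector of p-values.
#' @param lambda Grid for the \eqn{\pi_0} smoother.
#' @param min_n Minimum number of p-values before the smoother is trusted.
#' @param pi0 Optionally force a null proportion (e.g. `1` reduces to BH).
#' @return q-values in input order.
#' @export
storey_qvalues <- function(p_values, lambda = seq(0.05, 0.95, by = 0.05),
    min_n = 100, pi0 = NULL) {
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    mirdirect_abort("p-values must lie in [0, 1]", class = "mirdirect_error_pvalues")
  }
  if (is.null(pi0)) {
    pi0 <- if (m < min_n) 1 else estimate_pi0(p_values, lambda)
  }
  ord <- order(p_values, decreasing = TRUE)
  q <- pi0 * m * p_values[ord] / (m - seq_len(m) + 1)
  q <- pmin(cummin(pmin(q, 1)), 1)
  q[order(ord)]
}

estimate_pi0 <- function(p, lambda) {
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  fit <- smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  min(max(pi0, 1e-8), 1)
}

#' Call differentially expressed microRNA
#'
#' Screen Step 1: each microRNA is scored with the SNR statistic between
#' tumor and normal samples and assigned a two-sided permutation p-value;
#' features with p below `alpha` (default 0.001) are flagged significant.
#' BH-adjusted values (`fdr_q`) and Storey q-values (`q_value`) are reported
#' alongside the raw permutation p the threshold applies to.
#'
#' @param x Expression table on a log scale (log2 relative expression from
#'   [comparative_ct_normalize()] recommended).
#' @param metadata Sample metadata.
#' @param alpha Significance threshold on the permutation p-value.
#' @inheritParams permutation_pvalue
#' @return A tibble with one row per feature: `feature_id`, `statistic`,
#'   `log2_fold_change` (tumor - normal), `p_value`, `fdr_q`, `q_value`,
#'   `direction` (`up_in_tumor`/`down_in_tumor`), `significant`, `perm_mode`,
#'   `n_perm`.
#' @export
call_de_mirna <- function(x, metadata, alpha = 0.001, B = 1000,
    mode = "auto", seed = NULL, exhaustive_bound = 20000, scheme = "labels") {
  res <- de_permutation(x, metadata, B = B, mode = mode, seed = seed,
    exhaustive_bound = exhaustive_bound, scheme = scheme)
  annotate_de(res, x, metadata) |>
    mutate(significant = .data$p_value < alpha)
}

#' Call differentially expressed mRNA
#'
#' Screen Step 2: a gene is called significant when it clears a fold-change
#' cutoff (default two-fold on the log2 scale) and its permutation-based
#' BH false-discovery rate is at or below `fdr_target` (default 0.1). This is
#' the fold-plus-permutation-FDR conjunction; no moderated variance (SAM
#' fudge factor) is applied.
#'
#' @param x Log2 expression table.
#' @param metadata Sample metadata.
#' @param fold_cutoff Linear fold-change cutoff (default 2).
#' @param fdr_target FDR threshold on `fdr_q` (default 0.1).
#' @inheritParams permutation_pvalue
#' @return A tibble as in [call_de_mirna()].
#' @export
call_de_mrna <- function(x, metadata, fold_cutoff = 2, fdr_target = 0.1,
    B = 100, mode = "auto", seed = NULL, exhaustive_bound = 20000,
    scheme = "labels") {
  res <- de_permutation(x, metadata, B = B, mode = mode, seed = seed,
    exhaustive_bound = exhaustive_bound, scheme = scheme)
  annotate_de(res, x, metadata) |>
    mutate(significant = abs(.data$log2_fold_change) >= log2(fold_cutoff) &
      .data$fdr_q <= fdr_target)
}

annotate_de <- function(res, x, metadata) {
  meta <- align_metadata(x, metadata)
  m <- expr_matrix(x)
  lfc <- rowMeans(m[, meta$condition == "tumor", drop = FALSE]) -
    rowMeans(m[, meta$condition == "normal", drop = FALSE])
  res |>
    mutate(
      log2_fold_change = unname(lfc[.data$feature_id]),
      fdr_q = bh_fdr(.data$p_value),
      q_value = storey_qvalues(.data$p_value),
      direction = ifelse(.data$statistic >= 0, "up_in_tumor", "down_in_tumor")) |>
    select("feature_id", "statistic", "log2_fold_change", "p_value",
      "fdr_q", "q_value", "direction", dplyr::everything())
}
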