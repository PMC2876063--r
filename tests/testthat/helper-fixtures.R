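# Shared fixtures and independent oracles. Oracles are written from the
# definitions (brute-force loops, naive substring comparison, exhaustive
# enumeration) so they stay independent of the package's vectorised paths.

make_meta <- function(n_pairs = 8) {
  pid <- sprintf("P%02d", seq_len(n_pairs))
  tibble::tibble(
    sample_id = c(paste0(pid, "_T"), paste0(pid, "_N")),
    condition = rep(c("tumor", "normal"), each = n_pairs),
    patient_id = rep(pid, 2))
}

rand_expr <- function(n_features, meta, seed, mean = 0, sd = 1,
    scale_tag = "log2") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_features * nrow(meta), mean, sd), n_features,
      dimnames = list(sprintf("f%03d", seq_len(n_features)), meta$sample_id))
    expression_table(m, scale_tag = scale_tag)
  })
}

# Brute-force Benjamini-Hochberg: adj_i = min_{p_j >= p_i} min(1, m p_j / rank_j)
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranks <- seq_len(m)
  raw <- pmin(1, m * p[ord] / ranks)
  adj <- vapply(seq_len(m), function(i) min(raw[i:m]), numeric(1))
  adj[order(ord)]
}

# Reference SNR written out from the definition.
snr_ref <- function(a, b, frac = 0.2, floor = 1e-8) {
  sa <- max(sd(a), frac * abs(mean(a)), floor)
  sb <- max(sd(b), frac * abs(mean(b)), floor)
  (mean(a) - mean(b)) / (sa + sb)
}

# All permutations of 1..n by lexicographic successor (independent of the
# package's recursive generator).
perms_lexico <- function(n) {
  p <- seq_len(n)
  out <- list(p)
  repeat {
    i <- n - 1L
    while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (p[j] <= p[i]) j <- j - 1L
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
    p[(i + 1L):n] <- rev(p[(i + 1L):n])
    out[[length(out) + 1L]] <- p
  }
  do.call(cbind, out)
}

# Naive all-positions substring comparison; 0-based starts.
naive_scan <- function(utr, pattern) {
  n <- nchar(utr); m <- nchar(pattern)
  if (n < m) return(integer(0))
  starts <- seq_len(n - m + 1L)
  hits <- substring(utr, starts, starts + m - 1L) == pattern
  starts[hits] - 1L
}

# Reverse complement written with chartr on reversed characters.
revcomp_ref <- function(seq) {
  chars <- rev(strsplit(seq, "")[[1]])
  paste(chartr("ACGU", "UGCA", chars), collapse = "")
}

random_rna_str <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
    collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# p-values from the package's shared DE permutation engine.
de_perm <- function(x, meta, ...) {
  mirdirect:::de_permutation(x, meta, ...)$p_value
}
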