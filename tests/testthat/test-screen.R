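test_that("Pearson correlation matches hand computation and its preconditions", {
  expect_identical(pearson_cor(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_cor(1:5, 1:5), 1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8,
    tolerance = 1e-12)
  expect_error(pearson_cor(c(1, 2), c(3, 4)), class = "mirdirect_error_pearson")
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)),
    class = "mirdirect_error_constant")
})

make_screen_fixture <- function(n_pairs = 8, n_edges = 5, n_null = 95,
    rho = -0.995, seed = 1) {
  meta <- make_meta(n_pairs)
  withr::with_seed(seed, {
    n <- 2 * n_pairs
    n_feat <- n_edges + n_null
    mir <- matrix(rnorm(n_feat * n), n_feat,
      dimnames = list(sprintf("miR-%03d", seq_len(n_feat)), meta$sample_id))
    rna <- matrix(rnorm(n_feat * n), n_feat,
      dimnames = list(sprintf("G%03d", seq_len(n_feat)), meta$sample_id))
    tum <- meta$condition == "tumor"
    for (e in seq_len(n_edges)) {
      z1 <- rnorm(n_pairs); z2 <- rnorm(n_pairs)
      mir[e, tum] <- z1
      rna[e, tum] <- rho * z1 + sqrt(1 - rho^2) * z2
    }
  })
  cand <- tibble::tibble(
    mirna_id = rownames(mir), gene_id = rownames(rna),
    pair_class = "upMiR_downMRNA")
  list(meta = meta, mir = expression_table(mir), rna = expression_table(rna),
    cand = cand, edges = cand[seq_len(n_edges), ])
}

test_that("the screen's pass set equals brute-force correlation enumeration", {
  fx <- make_screen_fixture()
  out <- screen_pairs(fx$cand, fx$mir, fx$rna, fx$meta, P0 = -0.95)
  tum <- fx$meta$sample_id[fx$meta$condition == "tumor"]
  mirm <- expr_matrix(fx$mir); rnam <- expr_matrix(fx$rna)
  oracle <- vapply(seq_len(nrow(fx$cand)), function(i) {
    cor(mirm[fx$cand$mirna_id[i], tum], rnam[fx$cand$gene_id[i], tum]) < -0.95
  }, logical(1))
  expect_equal(out$passes,
    oracle[match(paste(out$mirna_id, out$gene_id),
      paste(fx$cand$mirna_id, fx$cand$gene_id))])
  expect_true(all(out$screen_r >= -1 & out$screen_r <= 1))
  expect_true(all(out$r_combined >= -1 & out$r_combined <= 1))
})

test_that("per-class screening uses the class named by the pair class", {
  fx <- make_screen_fixture(n_edges = 2, n_null = 2)
  cand_norm <- dplyr::mutate(fx$cand, pair_class = "downMiR_upMRNA")
  out_t <- screen_pairs(fx$cand, fx$mir, fx$rna, fx$meta)
  out_n <- screen_pairs(cand_norm, fx$mir, fx$rna, fx$meta)
  expect_equal(out_t$screen_r, out_t$r_tumor)
  expect_equal(out_n$screen_r, out_n$r_normal)
  out_c <- screen_pairs(fx$cand, fx$mir, fx$rna, fx$meta, mode = "combined")
  expect_equal(out_c$screen_r, out_c$r_combined)
})

test_that("tightening P0 never grows the passing set; duplication leaves r unchanged", {
  fx <- make_screen_fixture(seed = 3)
  loose <- screen_pairs(fx$cand, fx$mir, fx$rna, fx$meta, P0 = -0.9)
  tight <- screen_pairs(fx$cand, fx$mir, fx$rna, fx$meta, P0 = -0.98)
  expect_true(all(which(tight$passes) %in% which(loose$passes)))
  # P0 = -1 can pass only exact -1, never for generic noisy data
  atmin <- screen_pairs(fx$cand, fx$mir, fx$rna, fx$meta, P0 = -1 + 1e-12)
  expect_equal(sum(atmin$passes), 0)

  # duplicating every sample leaves all correlations unchanged
  meta2 <- fx$meta
  dup <- dplyr::mutate(fx$meta, sample_id = paste0(sample_id, "_b"),
    patient_id = paste0(patient_id, "b"))
  meta2 <- dplyr::bind_rows(fx$meta, dup)
  dup_expr <- function(x) {
    m <- expr_matrix(x)
    m2 <- cbind(m, m)
    colnames(m2) <- meta2$sample_id
    expression_table(m2)
  }
  out1 <- screen_pairs(fx$cand, fx$mir, fx$rna, fx$meta)
  out2 <- screen_pairs(fx$cand, dup_expr(fx$mir), dup_expr(fx$rna), meta2)
  expect_equal(out2$screen_r, out1$screen_r, tolerance = 1e-12)
  expect_equal(out2$passes, out1$passes)
})

test_that("constant-expression pairs are skipped, not fatal", {
  fx <- make_screen_fixture(n_edges = 1, n_null = 2)
  m <- expr_matrix(fx$mir)
  m["miR-002", ] <- 7
  expect_message(
    out <- screen_pairs(fx$cand, expression_table(m), fx$rna, fx$meta),
    "constant")
  expect_false("miR-002" %in% out$mirna_id)
  expect_equal(attr(out, "skipped")$mirna_id, "miR-002")
})

test_that("candidate construction is the conserved DE cross product", {
  de_mir <- tibble::tibble(
    feature_id = c("m1", "m2", "m3"),
    direction = c("up_in_tumor", "down_in_tumor", "up_in_tumor"),
    significant = c(TRUE, TRUE, FALSE))
  de_rna <- tibble::tibble(
    feature_id = c("g1", "g2", "g3", "g4"),
    direction = c("down_in_tumor", "down_in_tumor", "up_in_tumor",
      "down_in_tumor"),
    significant = c(TRUE, TRUE, TRUE, FALSE))
  targets <- tibble::tibble(
    mirna_id = c("m1", "m1", "m2", "m3", "m1"),
    gene_id = c("g1", "g2", "g3", "g1", "g4"),
    conserved = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  got <- build_candidates(de_mir, de_rna, targets)
  # m1 (up) x its conserved down targets g1, g2; m2 (down) x up target g3;
  # m3 not significant; g4 not significant
  expect_equal(paste(got$mirna_id, got$gene_id), c("m1 g1", "m1 g2", "m2 g3"))
  expect_equal(got$pair_class,
    c("upMiR_downMRNA", "upMiR_downMRNA", "downMiR_upMRNA"))

  # no significant features -> empty
  de_mir0 <- dplyr::mutate(de_mir, significant = FALSE)
  expect_equal(nrow(build_candidates(de_mir0, de_rna, targets)), 0)

  # random fixture vs brute-force double loop
  withr::with_seed(17, {
    de_mir_r <- tibble::tibble(feature_id = sprintf("m%02d", 1:10),
      direction = sample(c("up_in_tumor", "down_in_tumor"), 10, TRUE),
      significant = sample(c(TRUE, FALSE), 10, TRUE))
    de_rna_r <- tibble::tibble(feature_id = sprintf("g%02d", 1:20),
      direction = sample(c("up_in_tumor", "down_in_tumor"), 20, TRUE),
      significant = sample(c(TRUE, FALSE), 20, TRUE))
    tg_r <- tibble::tibble(
      mirna_id = sample(de_mir_r$feature_id, 40, replace = TRUE),
      gene_id = sample(de_rna_r$feature_id, 40, replace = TRUE),
      conserved = sample(c(TRUE, FALSE), 40, TRUE)) |> dplyr::distinct()
  })
  got_r <- build_candidates(de_mir_r, de_rna_r, tg_r)
  oracle <- character(0)
  for (i in seq_len(nrow(de_mir_r))) {
    for (j in seq_len(nrow(de_rna_r))) {
      mi <- de_mir_r[i, ]; gj <- de_rna_r[j, ]
      in_targets <- any(tg_r$mirna_id == mi$feature_id &
        tg_r$gene_id == gj$feature_id & tg_r$conserved)
      if (mi$significant && gj$significant && in_targets &&
          mi$direction != gj$direction) {
        oracle <- c(oracle, paste(mi$feature_id, gj$feature_id))
      }
    }
  }
  expect_setequal(paste(got_r$mirna_id, got_r$gene_id), oracle)
})

test_that("pair permutation p equals exhaustive enumeration for n = 5", {
  withr::with_seed(23, {
    x <- rnorm(5); y <- rnorm(5)
  })
  p_pkg <- mirdirect:::cor_perm_pvalue(x, y, mode = "exhaustive")
  perms <- perms_lexico(5)
  r_obs <- cor(x, y)
  r_all <- apply(perms, 2, function(idx) cor(x[idx], y))
  expect_equal(p_pkg, mean(r_all <= r_obs + 1e-12))
  expect_equal(ncol(perms), 120)
})

test_that("pair permutation p-values are extreme for perfect anti-correlation", {
  fx <- make_screen_fixture(n_edges = 1, n_null = 0, rho = -1, seed = 31)
  out <- screen_pairs(fx$cand, fx$mir, fx$rna, fx$meta)
  sig <- pair_permutation_significance(out, fx$mir, fx$rna, fx$meta,
    B = 999, seed = 7)
  expect_lte(sig$perm_p[1], 2 / 1000)
})

test_that("pair permutation p-values are calibrated under independence", {
  meta <- make_meta(8)
  B <- 199
  withr::with_seed(41, {
    p <- vapply(1:200, function(i) {
      mirdirect:::cor_perm_pvalue(rnorm(8), rnorm(8), B = B,
        seed = sample.int(1e6, 1), mode = "monte_carlo")
    }, numeric(1))
  })
  frac <- mean(p <= 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 1 / (B + 1))
})

test_that("finalize applies the three-hurdle conjunction", {
  fx <- make_screen_fixture(seed = 51)
  out <- screen_pairs(fx$cand, fx$mir, fx$rna, fx$meta)
  sig <- pair_permutation_significance(out, fx$mir, fx$rna, fx$meta,
    B = 199, seed = 8)
  fin <- finalize_screen(sig)
  oracle <- sig$passes & sig$perm_p < 0.01 & bh_brute(sig$perm_p) < 0.2
  expect_equal(fin$passes, oracle)
  # degenerate thresholds reduce to the correlation cutoff alone
  fin_all <- finalize_screen(sig, p_threshold = 1, fdr_threshold = 1)
  expect_equal(fin_all$passes, sig$passes &
    sig$perm_p < 1 & bh_brute(sig$perm_p) < 1)
  # a single mediocre pair fails
  one <- sig[1, ]
  one$perm_p <- 0.5
  expect_false(finalize_screen(one)$passes)
  expect_error(finalize_screen(out), class = "mirdirect_error_screen")
})

test_that("planted anti-correlated pairs are detected with high sensitivity", {
  # population r = -0.99 with 8 samples per class at P0 = -0.95
  hits <- vapply(1:60, function(i) {
    withr::with_seed(1000 + i, {
      z1 <- rnorm(8); z2 <- rnorm(8)
      cor(z1, -0.99 * z1 + sqrt(1 - 0.99^2) * z2) < -0.95
    })
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
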