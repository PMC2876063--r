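test_that("seed extraction slices the documented mature positions", {
  # the miR-141/200a* family seed, printed from its mature sequence
  expect_equal(extract_seed("UAACACUGUCUGGUAAAGAUGG", "6mer"), "AACACU")
  expect_equal(extract_seed("UAACACUGUCUGGUAAAGAUGG", "7mer_m8"), "AACACUG")
  expect_error(extract_seed("ACGUACGU", "7mer_m8"),
    class = "mirdirect_error_seed")

  withr::with_seed(5, {
    for (i in 1:10) {
      mat <- random_rna_str(22)
      expect_equal(extract_seed(mat, "6mer"),
        paste(strsplit(mat, "")[[1]][2:7], collapse = ""))
      expect_equal(extract_seed(mat, "8mer"),
        paste(strsplit(mat, "")[[1]][2:8], collapse = ""))
    }
  })
})

test_that("site patterns are seed reverse complements with site-type A anchors", {
  expect_equal(site_pattern("AACACU", "6mer"), "AGUGUU")
  expect_equal(site_pattern("AAUACU", "6mer"), "AGUAUU") # miR-200b/200c/429 family
  expect_equal(site_pattern("AACACU", "7mer_1A"), "AGUGUUA")
  expect_equal(site_pattern("AACACUG", "8mer"), "CAGUGUUA")

  withr::with_seed(6, {
    for (i in 1:10) {
      seed <- random_rna_str(7)
      expect_equal(site_pattern(seed, "7mer_m8"), revcomp_ref(seed))
      # involution: pattern of the pattern's reverse complement is the seed
      expect_equal(revcomp_ref(site_pattern(seed, "7mer_m8")), seed)
    }
  })
})

test_that("UTR scanning finds exactly the naive-oracle hit set", {
  expect_equal(scan_utr("", "AGUGUU"), integer(0))
  expect_equal(scan_utr("ACG", "AGUGUU"), integer(0))

  # constructed containment: X + pattern + Y with pattern-free flanks
  x_flank <- strrep("AC", 15)
  y_flank <- strrep("GA", 10)
  utr <- paste0(x_flank, "AGUGUU", y_flank)
  expect_equal(scan_utr(utr, "AGUGUU"), nchar(x_flank))

  # overlapping occurrences are all reported
  expect_equal(scan_utr("AAAAAA", "AAAA"), c(0L, 1L, 2L))

  withr::with_seed(7, {
    for (i in 1:40) {
      utr <- random_rna_str(500)
      pat <- random_rna_str(sample(4:8, 1))
      expect_identical(scan_utr(utr, pat), as.integer(naive_scan(utr, pat)))
    }
  })
})

test_that("scan starts shift exactly with a pattern-free prefix", {
  withr::with_seed(8, utr <- random_rna_str(300))
  pat <- "AGUGUU"
  prefix <- strrep("C", 37) # cannot contain the pattern
  base_hits <- scan_utr(utr, pat)
  shifted <- scan_utr(paste0(prefix, utr), pat)
  expect_equal(shifted, base_hits + 37L)
})

test_that("conservation requires a site in every required species", {
  species <- c("human", "mouse", "rat", "dog")
  mature <- tibble::tibble(mirna_id = c("miR-A", "miR-B"),
    mature_sequence = c("UAACACUGUCUGGUAAAGAUGG", "UGGAAUGUAAAGAAGUAUGUAU"))
  seeds <- mirna_seeds(mature, "7mer_m8")
  flank <- strrep("AC", 40)
  with_site <- function(pat) paste0(flank, pat, flank)
  utrs <- dplyr::bind_rows(
    # g1 carries miR-A's site in all four species
    tibble::tibble(species = species, gene_id = "g1",
      sequence = with_site(seeds$pattern[1])),
    # g2 carries miR-B's site in only three species
    tibble::tibble(species = c("human", "mouse", "rat"), gene_id = "g2",
      sequence = with_site(seeds$pattern[2])),
    tibble::tibble(species = "dog", gene_id = "g2", sequence = flank))
  ct <- conserved_targets(seeds, utrs, species)
  expect_true(ct$conserved[ct$mirna_id == "miR-A" & ct$gene_id == "g1"])
  expect_false(ct$conserved[ct$mirna_id == "miR-B" & ct$gene_id == "g2"])
  expect_setequal(ct$species_with_site[ct$gene_id == "g2"][[1]],
    c("human", "mouse", "rat"))

  # single-species requirement reduces to the per-species scan
  ct_h <- conserved_targets(seeds, utrs, "human")
  expect_true(all(ct_h$conserved))
  expect_error(conserved_targets(seeds, utrs, c(species, "chicken")),
    class = "mirdirect_error_species")
})

test_that("conserved set equals a brute-force per-species intersection", {
  d <- generate_paired_expression(n_mirna = 10, n_mrna = 50, n_edges = 3,
    seed = 301)
  u <- generate_utr_universe(d$truth, utr_length = 200, n_decoys = 3,
    seed = 302)
  seeds <- mirna_seeds(u$mature)
  species <- c("human", "mouse", "rat", "dog")
  got <- conserved_targets(seeds, u$utrs, species)
  got_pairs <- paste(got$mirna_id[got$conserved], got$gene_id[got$conserved])

  # oracle: naive substring scan per (mirna, gene, species), set intersection
  oracle_pairs <- character(0)
  for (mi in seq_len(nrow(seeds))) {
    for (g in unique(u$utrs$gene_id)) {
      present <- vapply(species, function(sp) {
        s <- u$utrs$sequence[u$utrs$species == sp & u$utrs$gene_id == g]
        length(naive_scan(s, seeds$pattern[mi])) > 0
      }, logical(1))
      if (all(present)) {
        oracle_pairs <- c(oracle_pairs, paste(seeds$mirna_id[mi], g))
      }
    }
  }
  expect_setequal(got_pairs, oracle_pairs)
  # every truth edge is conserved; no decoy is
  expect_true(all(paste(d$truth$edges$mirna_id, d$truth$edges$gene_id) %in%
    got_pairs))
  expect_false(any(paste(u$decoys$mirna_id, u$decoys$gene_id) %in% got_pairs))
})

test_that("annotation filtering keeps exactly the species-covering entries", {
  ann <- tibble::tibble(
    mirna_id = c("m1", "m2", "m3"),
    gene_id = c("g1", "g2", "g3"),
    species_set = list(c("dog", "human", "mouse", "rat"), "human",
      c("human", "mouse", "rat")))
  kept <- targets_from_annotation(ann)
  expect_equal(kept$mirna_id, "m1")
  kept2 <- targets_from_annotation(ann, c("human", "mouse"))
  expect_setequal(kept2$mirna_id, c("m1", "m3"))

  # random annotation vs predicate oracle
  withr::with_seed(9, {
    species <- c("human", "mouse", "rat", "dog")
    rnd <- tibble::tibble(
      mirna_id = sprintf("m%02d", 1:50), gene_id = sprintf("g%02d", 1:50),
      species_set = lapply(1:50, function(i)
        sample(species, sample(1:4, 1))))
  })
  got <- targets_from_annotation(rnd, species)
  oracle <- vapply(rnd$species_set, function(s) all(species %in% s),
    logical(1))
  expect_setequal(got$mirna_id, rnd$mirna_id[oracle])
})

test_that("annotation path and de novo path agree on a planted universe", {
  d <- generate_paired_expression(n_mirna = 8, n_mrna = 30, n_edges = 2,
    seed = 401)
  u <- generate_utr_universe(d$truth, utr_length = 150, seed = 402)
  species <- c("human", "mouse", "rat", "dog")
  de_novo <- conserved_targets(mirna_seeds(u$mature), u$utrs, species)
  from_ann <- targets_from_annotation(u$annotation, species)
  expect_setequal(
    paste(de_novo$mirna_id[de_novo$conserved], de_novo$gene_id[de_novo$conserved]),
    paste(from_ann$mirna_id, from_ann$gene_id))
})

test_that("microRNAs sharing a seed collapse into one family", {
  mature <- tibble::tibble(
    mirna_id = c("miR-x", "miR-y", "miR-z"),
    mature_sequence = c("UAACACUGUCUGGUAAAGAUGG", "CAACACUGCCUGGUAAAGAUGG",
      "UGGAAUGUAAAGAAGUAUGUAU"))
  fams <- mirna_families(mirna_seeds(mature, "6mer"))
  expect_equal(fams$family_id[fams$mirna_id == "miR-x"], "miR-x/miR-y")
  expect_equal(fams$family_id[fams$mirna_id == "miR-z"], "miR-z")
})
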