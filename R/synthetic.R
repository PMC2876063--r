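#' Generate patient-matched two-modality expression with planted structure
#'
#' Simulates the study design the screen targets: `n_patients` patients each
#' contributing one tumor and one normal sample, profiled for microRNA and
#' mRNA on a log2 scale. Most features are independent Gaussian noise around
#' a feature-specific baseline. A subset is differentially expressed, with a
#' condition mean shift of `effect_size` log2 units. `n_edges` of the DE
#' features form regulator-target pairs: the microRNA and its target gene are
#' drawn from a bivariate Gaussian with population correlation `rho` within
#' the class where the regulator is abundant — tumor for up-regulated
#' microRNA (paired with a down-regulated target), normal for down-regulated
#' microRNA (paired with an up-regulated target) — matching the classes the
#' per-class screen examines. `both_classes = TRUE` plants the
#' anti-correlation in both classes instead.
#'
#' Defaults emulate the primary study design: 8 matched pairs, a strong
#' effect (4 noise SDs), and near-deterministic regulation (`rho = -0.99`).
#'
#' @param n_patients Number of matched tumor/normal pairs.
#' @param n_mirna,n_mrna Feature counts for the two modalities.
#' @param n_edges Number of planted regulator-target edges.
#' @param effect_size Condition mean shift for DE features, log2 units.
#' @param rho Population correlation planted on edges, in \[-1, 0\].
#' @param noise_sd Within-class Gaussian noise SD, log2 units.
#' @param n_de_mirna,n_de_mrna Total DE feature counts (edge members
#'   included); the surplus features are DE without any edge, exercising the
#'   conservation and correlation filters.
#' @param both_classes Plant the edge correlation in both classes.
#' @param seed RNG seed (required; the generator is deterministic given it).
#' @return A list with `mirna` and `mrna` expression tables, `metadata`, and
#'   `truth` — a list recording `edges`, `de_mirna`, `de_mrna`,
#'   `mirna_ids`, `gene_ids`, `seed`, and the generating parameters.
#' @export
generate_paired_expression <- function(n_patients = 8, n_mirna = 40,
    n_mrna = 200, n_edges = 3, effect_size = 2, rho = -0.99, noise_sd = 0.5,
    n_de_mirna = n_edges + 3, n_de_mrna = n_edges + 7, both_classes = FALSE,
    seed = NULL) {
  if (n_edges > min(n_mirna, n_mrna)) {
    mirdirect_abort("n_edges exceeds available features",
      class = "mirdirect_error_config")
  }
  if (!(rho >= -1 && rho <= 0)) {
    mirdirect_abort("rho must lie in [-1, 0]", class = "mirdirect_error_config")
  }
  if (n_de_mirna < n_edges || n_de_mirna > n_mirna ||
      n_de_mrna < n_edges || n_de_mrna > n_mrna) {
    mirdirect_abort("DE feature counts must cover the edges and fit the panel",
      class = "mirdirect_error_config")
  }
  with_seed(seed, {
    patients <- sprintf("P%02d", seq_len(n_patients))
    metadata <- tibble(
      sample_id = c(paste0(patients, "_T"), paste0(patients, "_N")),
      condition = rep(c("tumor", "normal"), each = n_patients),
      patient_id = rep(patients, 2))
    mirna_ids <- sprintf("miR-%03d", seq_len(n_mirna))
    gene_ids <- sprintf("GENE%04d", seq_len(n_mrna))

    de_mir_idx <- sample.int(n_mirna, n_de_mirna)
    de_rna_idx <- sample.int(n_mrna, n_de_mrna)
    edge_classes <- rep(c("upMiR_downMRNA", "downMiR_upMRNA"),
      length.out = n_edges)
    mir_dir <- rep(NA_character_, n_mirna)
    rna_dir <- rep(NA_character_, n_mrna)
    mir_dir[de_mir_idx[seq_len(n_edges)]] <-
      ifelse(edge_classes == "upMiR_downMRNA", "up_in_tumor", "down_in_tumor")
    rna_dir[de_rna_idx[seq_len(n_edges)]] <-
      ifelse(edge_classes == "upMiR_downMRNA", "down_in_tumor", "up_in_tumor")
    extra_mir <- de_mir_idx[-seq_len(n_edges)]
    extra_rna <- de_rna_idx[-seq_len(n_edges)]
    mir_dir[extra_mir] <- sample(c("up_in_tumor", "down_in_tumor"),
      length(extra_mir), replace = TRUE)
    rna_dir[extra_rna] <- sample(c("up_in_tumor", "down_in_tumor"),
      length(extra_rna), replace = TRUE)

    mir_base <- runif(n_mirna, -2, 2)
    rna_base <- runif(n_mrna, 4, 12)
    shift <- function(dir) {
      ifelse(is.na(dir), 0, ifelse(dir == "up_in_tumor", effect_size,
        -effect_size))
    }
    build_matrix <- function(base, dir, n_feat) {
      mu <- matrix(base, n_feat, 2 * n_patients) # features x samples
      tumor_cols <- seq_len(n_patients)
      mu[, tumor_cols] <- mu[, tumor_cols] + shift(dir)
      mu + matrix(rnorm(n_feat * 2 * n_patients, sd = noise_sd),
        n_feat, 2 * n_patients)
    }
    mir_m <- build_matrix(mir_base, mir_dir, n_mirna)
    rna_m <- build_matrix(rna_base, rna_dir, n_mrna)
    rownames(mir_m) <- mirna_ids; colnames(mir_m) <- metadata$sample_id
    rownames(rna_m) <- gene_ids; colnames(rna_m) <- metadata$sample_id

    # overwrite edge rows with the bivariate draw in the correlated class
    tumor_cols <- seq_len(n_patients)
    normal_cols <- n_patients + seq_len(n_patients)
    for (e in seq_len(n_edges)) {
      mi <- de_mir_idx[e]; gi <- de_rna_idx[e]
      corr_cols <- if (both_classes) c(tumor_cols, normal_cols) else
        if (edge_classes[e] == "upMiR_downMRNA") tumor_cols else normal_cols
      z1 <- rnorm(length(corr_cols))
      z2 <- rnorm(length(corr_cols))
      mir_mu <- mir_base[mi] +
        if (mir_dir[mi] == "up_in_tumor") {
          ifelse(corr_cols %in% tumor_cols, effect_size, 0)
        } else {
          ifelse(corr_cols %in% tumor_cols, -effect_size, 0)
        }
      rna_mu <- rna_base[gi] +
        if (rna_dir[gi] == "up_in_tumor") {
          ifelse(corr_cols %in% tumor_cols, effect_size, 0)
        } else {
          ifelse(corr_cols %in% tumor_cols, -effect_size, 0)
        }
      mir_m[mi, corr_cols] <- mir_mu + noise_sd * z1
      rna_m[gi, corr_cols] <- rna_mu +
        noise_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    }

    truth <- list(
      edges = tibble(
        mirna_id = mirna_ids[de_mir_idx[seq_len(n_edges)]],
        gene_id = gene_ids[de_rna_idx[seq_len(n_edges)]],
        population_correlation = rho,
        pair_class = edge_classes),
      de_mirna = tibble(feature_id = mirna_ids[de_mir_idx],
        direction = mir_dir[de_mir_idx]),
      de_mrna = tibble(feature_id = gene_ids[de_rna_idx],
        direction = rna_dir[de_rna_idx]),
      mirna_ids = mirna_ids,
      gene_ids = gene_ids,
      seed = as.integer(seed),
      params = list(n_patients = n_patients, n_mirna = n_mirna,
        n_mrna = n_mrna, n_edges = n_edges, effect_size = effect_size,
        rho = rho, noise_sd = noise_sd, both_classes = both_classes))

    list(
      mirna = expression_table(mir_m, scale_tag = "log2"),
      mrna = expression_table(rna_m, scale_tag = "log2"),
      metadata = metadata,
      truth = truth)
  })
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Replace, in `seq_chars`, the characters of window [start, start+len) that
# fall outside every protected window.
randomize_window <- function(seq_chars, start, len, protected) {
  pos <- start:(start + len - 1L)
  for (p in seq_len(nrow(protected))) {
    keep <- protected$start[p]:(protected$start[p] + protected$len[p] - 1L)
    pos <- setdiff(pos, keep)
  }
  if (length(pos) > 0) {
    seq_chars[pos] <- sample(c("A", "C", "G", "U"), length(pos), replace = TRUE)
  }
  seq_chars
}

#' Generate a multi-species UTR universe around a synthetic truth
#'
#' Produces, for a truth object from [generate_paired_expression()]:
#' random mature microRNA sequences for the whole panel (with unique seeds);
#' random background 3'UTRs per gene and species, scrubbed of accidental
#' occurrences of the planted families' site patterns; a planted conserved
#' site in every required species for each truth edge; decoy sites for some
#' non-edge regulator-target pairs planted in a proper subset of the species
#' (so the conservation filter has something to reject); and a matching
#' TargetScan-style annotation for the annotation-path screen.
#'
#' @param truth Truth list from [generate_paired_expression()].
#' @param species Species labels; conservation requires a site in all of them.
#' @param utr_length Background UTR length in nt.
#' @param site_type Seed site type planted and annotated.
#' @param n_decoys Number of partial-conservation decoy pairs.
#' @param seed RNG seed (required).
#' @return A list with `utrs` (tibble `species`, `gene_id`, `sequence`),
#'   `mature` (tibble `mirna_id`, `mature_sequence`), `annotation`
#'   (aggregated, as from [read_target_annotation()]), `planted_sites`
#'   (tibble `mirna_id`, `gene_id`, `species`, `position`), and `decoys`.
#' @export
generate_utr_universe <- function(truth,
    species = c("human", "mouse", "rat", "dog"), utr_length = 300,
    site_type = "7mer_m8", n_decoys = 3, seed = NULL) {
  pat_len <- nchar(site_pattern(strrep("A", seed_length(site_type)), site_type))
  if (utr_length < pat_len + 2) {
    mirdirect_abort("utr_length too short for the site pattern",
      class = "mirdirect_error_config")
  }
  with_seed(seed, {
    mirna_ids <- truth$mirna_ids
    gene_ids <- truth$gene_ids
    # mature sequences with unique seeds
    mature_seq <- vapply(mirna_ids, function(id) random_rna(22), character(1))
    repeat {
      seeds_now <- extract_seed(mature_seq, site_type)
      dup <- duplicated(seeds_now)
      if (!any(dup)) break
      mature_seq[dup] <- vapply(which(dup), function(i) random_rna(22),
        character(1))
    }
    mature <- tibble(mirna_id = mirna_ids, mature_sequence = unname(mature_seq))
    seeds <- mirna_seeds(mature, site_type)

    edges <- truth$edges
    # decoy pairs: DE but non-edge regulators and targets when available
    decoy_mirs <- setdiff(truth$de_mirna$feature_id, edges$mirna_id)
    if (length(decoy_mirs) < n_decoys) {
      decoy_mirs <- c(decoy_mirs,
        setdiff(mirna_ids, c(edges$mirna_id, decoy_mirs)))
    }
    decoy_genes <- setdiff(truth$de_mrna$feature_id, edges$gene_id)
    if (length(decoy_genes) < n_decoys) {
      decoy_genes <- c(decoy_genes,
        setdiff(gene_ids, c(edges$gene_id, decoy_genes)))
    }
    n_decoys <- min(n_decoys, length(decoy_mirs), length(decoy_genes))
    decoys <- tibble(
      mirna_id = sample(decoy_mirs, n_decoys),
      gene_id = sample(decoy_genes, n_decoys),
      species_subset = purrr::map(seq_len(n_decoys),
        ~ sort(sample(species, length(species) - 1L))))

    planted_fams <- unique(c(edges$mirna_id, decoys$mirna_id))
    patterns <- seeds$pattern[match(planted_fams, seeds$mirna_id)]

    # background sequences
    seq_tbl <- tidyr::expand_grid(species = species, gene_id = gene_ids)
    seq_tbl$sequence <- vapply(seq_len(nrow(seq_tbl)),
      function(i) random_rna(utr_length), character(1))

    # plant sites, recording 0-based positions
    to_plant <- bind_rows(
      tibble(mirna_id = edges$mirna_id, gene_id = edges$gene_id,
        target_species = purrr::map(seq_len(nrow(edges)), ~ species)),
      tibble(mirna_id = decoys$mirna_id, gene_id = decoys$gene_id,
        target_species = decoys$species_subset))
    planted_rows <- list()
    for (j in seq_len(nrow(to_plant))) {
      pat <- seeds$pattern[seeds$mirna_id == to_plant$mirna_id[j]]
      for (sp in to_plant$target_species[[j]]) {
        i <- which(seq_tbl$species == sp &
          seq_tbl$gene_id == to_plant$gene_id[j])
        pos0 <- sample.int(utr_length - nchar(pat) + 1L, 1L) - 1L
        s <- seq_tbl$sequence[i]
        substr(s, pos0 + 1L, pos0 + nchar(pat)) <- pat
        seq_tbl$sequence[i] <- s
        planted_rows[[length(planted_rows) + 1L]] <- tibble(
          mirna_id = to_plant$mirna_id[j], gene_id = to_plant$gene_id[j],
          species = sp, position = pos0, len = nchar(pat))
      }
    }
    planted <- bind_rows(planted_rows)

    # scrub accidental occurrences of planted-family patterns everywhere
    # except the recorded windows
    for (iter in seq_len(50)) {
      dirty <- FALSE
      rna_set <- Biostrings::RNAStringSet(seq_tbl$sequence)
      for (k in seq_along(patterns)) {
        fam <- planted_fams[k]
        hits <- Biostrings::vmatchPattern(Biostrings::RNAString(patterns[k]),
          rna_set)
        for (i in which(lengths(hits) > 0)) {
          starts0 <- Biostrings::start(hits[[i]]) - 1L
          prot <- planted[planted$mirna_id == fam &
            planted$gene_id == seq_tbl$gene_id[i] &
            planted$species == seq_tbl$species[i], c("position", "len")]
          names(prot) <- c("start", "len")
          bad <- setdiff(starts0, prot$start)
          if (length(bad) > 0) {
            dirty <- TRUE
            # protect every planted window in this sequence, whatever family
            all_prot <- planted[planted$gene_id == seq_tbl$gene_id[i] &
              planted$species == seq_tbl$species[i], c("position", "len")]
            names(all_prot) <- c("start", "len")
            chars <- strsplit(seq_tbl$sequence[i], "")[[1]]
            for (b in bad) {
              chars <- randomize_window(chars, b + 1L, nchar(patterns[k]),
                tibble(start = all_prot$start + 1L, len = all_prot$len))
            }
            seq_tbl$sequence[i] <- paste(chars, collapse = "")
          }
        }
      }
      if (!dirty) break
    }

    annotation <- bind_rows(
      tibble(mirna_id = edges$mirna_id, gene_id = edges$gene_id,
        species_set = purrr::map(seq_len(nrow(edges)), ~ sort(species))),
      tibble(mirna_id = decoys$mirna_id, gene_id = decoys$gene_id,
        species_set = decoys$species_subset)) |>
      mutate(site_types = purrr::map(seq_along(.data$mirna_id), ~ site_type),
        n_sites = lengths(.data$species_set))

    list(
      utrs = seq_tbl[c("species", "gene_id", "sequence")],
      mature = mature,
      annotation = annotation,
      planted_sites = planted[c("mirna_id", "gene_id", "species", "position")],
      decoys = decoys)
  })
}
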