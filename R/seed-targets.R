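SITE_TYPES <- c("6mer", "7mer_m8", "7mer_1A", "8mer")

# seed length (mature-miRNA positions used) per site type
seed_length <- function(site_type) {
  switch(site_type, "6mer" = 6L, "7mer_1A" = 6L, "7mer_m8" = 7L, "8mer" = 7L)
}

#' Extract a microRNA seed
#'
#' The seed is read from the mature microRNA sequence 5'->3': positions 2-7
#' for `6mer` and `7mer_1A` sites, positions 2-8 for `7mer_m8` and `8mer`
#' sites.
#'
#' @param mature_sequence Mature microRNA sequence (RNA or DNA alphabet),
#'   length >= 9.
#' @param site_type One of `"6mer"`, `"7mer_m8"`, `"7mer_1A"`, `"8mer"`.
#' @return The seed sequence (uppercase RNA). Vectorised over
#'   `mature_sequence`.
#' @export
#' @examples
#' extract_seed("UAACACUGUCUGGUAAAGAUGG", "6mer") # "AACACU", the miR-141 seed
extract_seed <- function(mature_sequence, site_type = "7mer_m8") {
  site_type <- rlang::arg_match(site_type, SITE_TYPES)
  seqs <- canonicalize_rna(mature_sequence)
  if (any(nchar(seqs) < 9)) {
    mirdirect_abort("mature microRNA sequence must be at least 9 nt",
      class = "mirdirect_error_seed")
  }
  substr(seqs, 2L, 1L + seed_length(site_type))
}

#' UTR-strand match pattern of a seed
#'
#' The pattern a target 3'UTR must contain is the reverse complement of the
#' seed (5'->3'). For `7mer_1A` and `8mer` sites an `A` is appended at the
#' target position opposite microRNA position 1, per the standard site-type
#' definitions.
#'
#' @param seed_sequence Seed sequence (RNA), as from [extract_seed()].
#' @param site_type Site type the seed was extracted for.
#' @return The UTR match pattern (uppercase RNA). Vectorised.
#' @export
#' @examples
#' site_pattern("AACACU", "6mer") # "AGUGUU"
site_pattern <- function(seed_sequence, site_type = "7mer_m8") {
  site_type <- rlang::arg_match(site_type, SITE_TYPES)
  seeds <- canonicalize_rna(seed_sequence)
  expected <- seed_length(site_type)
  if (any(nchar(seeds) != expected)) {
    mirdirect_abort(paste0("a ", site_type, " seed must be ", expected, " nt"),
      class = "mirdirect_error_seed")
  }
  rc <- vapply(seeds, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
  }, character(1), USE.NAMES = FALSE)
  if (site_type %in% c("7mer_1A", "8mer")) paste0(rc, "A") else rc
}

#' Scan a 3'UTR for exact seed-complement sites
#'
#' Finds all exact, possibly overlapping, occurrences of a site pattern in a
#' UTR sequence. Matching is literal Watson-Crick complementarity only: no
#' G:U wobble, no mismatches or bulges.
#'
#' @param utr UTR sequence (RNA or DNA alphabet; canonicalized internally).
#' @param pattern UTR-strand match pattern, as from [site_pattern()].
#' @return Integer vector of 0-based start offsets, ascending; empty if no
#'   site (or the UTR is shorter than the pattern).
#' @export
scan_utr <- function(utr, pattern) {
  utr <- canonicalize_rna(utr)
  pattern <- canonicalize_rna(pattern)
  if (nchar(utr) < nchar(pattern) || nchar(utr) == 0) return(integer(0))
  hits <- Biostrings::matchPattern(Biostrings::RNAString(pattern),
    Biostrings::RNAString(utr))
  sort(Biostrings::start(hits) - 1L)
}

#' Seed table for a panel of mature microRNAs
#'
#' Builds the per-microRNA seed and UTR match pattern for downstream site
#' scanning.
#'
#' @param mature Tibble with columns `mirna_id`, `mature_sequence`.
#' @param site_type Site type to extract.
#' @return Tibble with `mirna_id`, `seed_sequence`, `site_type`, `pattern`.
#' @export
mirna_seeds <- function(mature, site_type = "7mer_m8") {
  seeds <- extract_seed(mature$mature_sequence, site_type)
  patterns <- site_pattern(seeds, site_type)
  tibble(
    mirna_id = mature$mirna_id,
    seed_sequence = seeds,
    site_type = site_type,
    pattern = patterns)
}

#' Collapse microRNAs sharing a seed into families
#'
#' MicroRNAs with an identical seed target the same sites and are treated as
#' one family for targeting purposes (e.g. the miR-200b/200c/429 and
#' miR-141/200a* families, which differ by a single seed nucleotide from each
#' other but are internally identical).
#'
#' @param seeds Seed table from [mirna_seeds()].
#' @return The seed table with a `family_id` column (member IDs joined with
#'   `/` in sorted order).
#' @export
mirna_families <- function(seeds) {
  seeds |>
    group_by(.data$seed_sequence) |>
    mutate(family_id = paste(sort(unique(.data$mirna_id)), collapse = "/")) |>
    ungroup()
}

#' Locate seed sites for a microRNA panel across UTR sets
#'
#' @param utrs UTR tibble with columns `species`, `gene_id`, `sequence`
#'   (one or more species stacked; see [read_utr_fasta()]).
#' @param seeds Seed table from [mirna_seeds()].
#' @return Tibble of sites: `mirna_id`, `gene_id`, `species`, `start`
#'   (0-based), `site_type`.
#' @export
find_seed_sites <- function(utrs, seeds) {
  rows <- purrr::pmap(seeds[c("mirna_id", "pattern", "site_type")],
    function(mirna_id, pattern, site_type) {
      hits <- purrr::pmap(utrs[c("species", "gene_id", "sequence")],
        function(species, gene_id, sequence) {
          starts <- scan_utr(sequence, pattern)
          if (length(starts) == 0) return(NULL)
          tibble(mirna_id = mirna_id, gene_id = gene_id, species = species,
            start = starts, site_type = site_type)
        })
      bind_rows(hits)
    })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(mirna_id = character(), gene_id = character(),
      species = character(), start = integer(), site_type = character()))
  }
  arrange(out, .data$mirna_id, .data$gene_id, .data$species, .data$start)
}

#' Cross-species conserved targets by de novo scanning
#'
#' A (microRNA, gene) relation is conserved when the gene's 3'UTR carries at
#' least one exact site in every required species. Conservation here is
#' presence-based over orthologous UTRs (the caller supplies comparable gene
#' IDs across species); no alignment-column agreement is required. A gene
#' missing from one species' UTR set simply counts as having no site there.
#'
#' @param seeds Seed table from [mirna_seeds()].
#' @param utrs Stacked UTR tibble (`species`, `gene_id`, `sequence`).
#' @param required_species Character vector of species that must all carry a
#'   site.
#' @return Tibble: `mirna_id`, `gene_id`, `species_with_site` (list-column),
#'   `conserved` flag. Pairs with no site anywhere are omitted.
#' @export
conserved_targets <- function(seeds, utrs,
    required_species = c("human", "mouse", "rat", "dog")) {
  missing_sp <- setdiff(required_species, unique(utrs$species))
  if (length(missing_sp) > 0) {
    mirdirect_abort(paste0("no UTR set supplied for required species: ",
      paste(missing_sp, collapse = ", ")), class = "mirdirect_error_species")
  }
  sites <- find_seed_sites(utrs, seeds)
  if (nrow(sites) == 0) {
    return(tibble(mirna_id = character(), gene_id = character(),
      species_with_site = list(), conserved = logical()))
  }
  sites |>
    group_by(.data$mirna_id, .data$gene_id) |>
    summarise(species_with_site = list(sort(unique(.data$species))),
      .groups = "drop") |>
    mutate(conserved = purrr::map_lgl(.data$species_with_site,
      ~ all(required_species %in% .x)))
}

#' Conserved targets from a TargetScan-style annotation
#'
#' The default Step-3 path: keeps annotation entries whose annotated species
#' cover every required species, making de novo scanning optional.
#'
#' @param annotation Aggregated annotation from [read_target_annotation()]
#'   (columns `mirna_id`, `gene_id`, `species_set`).
#' @param required_species Species that must all be annotated.
#' @return Tibble: `mirna_id`, `gene_id`, `species_with_site`, `conserved`
#'   (all `TRUE`; non-covering entries are dropped).
#' @export
targets_from_annotation <- function(annotation,
    required_species = c("human", "mouse", "rat", "dog")) {
  keep <- purrr::map_lgl(annotation$species_set,
    ~ all(required_species %in% .x))
  tibble(
    mirna_id = annotation$mirna_id[keep],
    gene_id = annotation$gene_id[keep],
    species_with_site = annotation$species_set[keep],
    conserved = TRUE)
}
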