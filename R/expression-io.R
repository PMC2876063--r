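#' Build and validate sample metadata
#'
#' Sample metadata ties every expression column to a condition (`"tumor"` or
#' `"normal"`) and a patient, so that downstream statistics can form the two
#' comparison groups and (optionally) respect patient pairing.
#'
#' @param data A data frame with columns `sample_id`, `condition`,
#'   `patient_id`.
#' @param require_paired If `TRUE`, every patient must contribute exactly one
#'   tumor and one normal sample (the matched-pair design of the primary
#'   cohort).
#'
#' @return A validated tibble with columns `sample_id`, `condition`,
#'   `patient_id`.
#' @export
#' @examples
#' sample_metadata(data.frame(
#'   sample_id = c("P1_T", "P1_N"),
#'   condition = c("tumor", "normal"),
#'   patient_id = c("P1", "P1")
#' ))
sample_metadata <- function(data, require_paired = FALSE) {
  needed <- c("sample_id", "condition", "patient_id")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    mirdirect_abort(
      paste0("metadata is missing column(s): ", paste(missing, collapse = ", ")),
      class = "mirdirect_error_metadata")
  }
  meta <- as_tibble(data)[needed]
  meta$sample_id <- as.character(meta$sample_id)
  meta$condition <- as.character(meta$condition)
  meta$patient_id <- as.character(meta$patient_id)
  if (anyDuplicated(meta$sample_id)) {
    mirdirect_abort("duplicate sample_id in metadata", class = "mirdirect_error_metadata")
  }
  bad <- setdiff(unique(meta$condition), CONDITIONS)
  if (length(bad) > 0) {
    mirdirect_abort(
      paste0("unknown condition(s): ", paste(bad, collapse = ", "),
        " (expected tumor/normal)"),
      class = "mirdirect_error_metadata")
  }
  if (require_paired) {
    counts <- meta |>
      dplyr::count(.data$patient_id, .data$condition) |>
      tidyr::pivot_wider(names_from = "condition", values_from = "n",
        values_fill = 0L)
    ok <- all(counts$tumor == 1L) && all(counts$normal == 1L) &&
      all(c("tumor", "normal") %in% names(counts))
    if (!isTRUE(ok)) {
      mirdirect_abort(
        "pairing declared complete but some patient lacks exactly one tumor and one normal sample",
        class = "mirdirect_error_metadata")
    }
  }
  meta
}

#' Read sample metadata from TSV
#'
#' @param path Path to a tab-separated file with columns `sample_id`,
#'   `condition`, `patient_id`.
#' @inheritParams sample_metadata
#' @return A metadata tibble (see [sample_metadata()]).
#' @export
read_sample_metadata <- function(path, require_paired = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  sample_metadata(raw, require_paired = require_paired)
}

#' Construct an expression table
#'
#' The package's working container for expression data is a tibble whose first
#' column is `feature_id` and whose remaining columns are samples; a
#' `scale_tag` attribute records the measurement scale (`"log2"` for
#' log2-transformed array or relative expression, `"linear_relative"` for
#' comparative-Ct relative quantities, `"ct"` for raw cycle thresholds).
#'
#' @param values Numeric matrix, features in rows and samples in columns, with
#'   dimnames, or a data frame with a `feature_id` first column.
#' @param scale_tag One of `"log2"`, `"linear_relative"`, `"ct"`, `"binary"`.
#' @return A tibble of class `mirdirect_expr`.
#' @export
expression_table <- function(values, scale_tag = "log2") {
  scale_tag <- rlang::arg_match(scale_tag, c("log2", "linear_relative", "ct", "binary"))
  if (is.matrix(values)) {
    if (is.null(rownames(values)) || is.null(colnames(values))) {
      mirdirect_abort("expression matrix needs feature rownames and sample colnames",
        class = "mirdirect_error_expression")
    }
    tbl <- as_tibble(values, rownames = "feature_id")
  } else {
    tbl <- as_tibble(values)
    if (names(tbl)[1] != "feature_id") {
      mirdirect_abort("first column of an expression table must be `feature_id`",
        class = "mirdirect_error_expression")
    }
  }
  validate_expression_table(tbl)
  attr(tbl, "scale_tag") <- scale_tag
  class(tbl) <- c("mirdirect_expr", class(tbl))
  tbl
}

validate_expression_table <- function(tbl) {
  if (anyDuplicated(tbl$feature_id)) {
    dup <- unique(tbl$feature_id[duplicated(tbl$feature_id)])
    mirdirect_abort(
      paste0("duplicate feature IDs: ", paste(head(dup, 5), collapse = ", ")),
      class = "mirdirect_error_expression")
  }
  value_cols <- setdiff(names(tbl), "feature_id")
  if (length(value_cols) == 0) {
    mirdirect_abort("expression table has no sample columns",
      class = "mirdirect_error_expression")
  }
  for (col in value_cols) {
    v <- tbl[[col]]
    if (!is.numeric(v)) {
      mirdirect_abort(paste0("non-numeric expression values in column `", col, "`"),
        class = "mirdirect_error_expression")
    }
    if (anyNA(v)) {
      bad_row <- tbl$feature_id[which(is.na(v))[1]]
      mirdirect_abort(
        paste0("missing expression value at feature `", bad_row,
          "`, sample `", col, "`; missing values are refused, not imputed"),
        class = "mirdirect_error_missing")
    }
  }
  invisible(tbl)
}

#' @export
print.mirdirect_expr <- function(x, ...) {
  cat("# Expression table (", scale_tag(x), "): ",
    nrow(x), " features x ", ncol(x) - 1L, " samples\n", sep = "")
  NextMethod()
}

#' Measurement scale of an expression table
#' @param x An expression table.
#' @return The scale tag string.
#' @export
scale_tag <- function(x) attr(x, "scale_tag") %||% "log2"

#' Expression table to numeric matrix
#' @param x An expression table.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
expr_matrix <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "feature_id")])
  rownames(m) <- x$feature_id
  storage.mode(m) <- "double"
  m
}

sample_ids <- function(x) setdiff(names(x), "feature_id")

# Align metadata to the sample columns of an expression table, preserving
# column order. Errors if any sample is unknown to the metadata.
align_metadata <- function(x, metadata) {
  metadata <- sample_metadata(metadata)
  ids <- sample_ids(x)
  unknown <- setdiff(ids, metadata$sample_id)
  if (length(unknown) > 0) {
    mirdirect_abort(
      paste0("sample(s) absent from metadata: ", paste(unknown, collapse = ", ")),
      class = "mirdirect_error_metadata")
  }
  metadata[match(ids, metadata$sample_id), ]
}

#' Read an expression matrix from TSV
#'
#' Reads a tab-separated matrix (first column feature IDs, header row sample
#' IDs) and validates it against sample metadata. Row and column order are
#' preserved from the file. GCT files are accepted: the two-line GCT preamble
#' (`#1.2` and a dimensions line) is skipped and the `Description` column, if
#' present, dropped.
#'
#' @param path Path to a TSV (or GCT) expression file.
#' @param metadata Sample metadata (data frame or path handled by caller); every
#'   sample in the file header must be present.
#' @param scale_tag Measurement scale recorded on the result.
#' @return An expression table ([expression_table()]).
#' @export
read_expression_matrix <- function(path, metadata, scale_tag = "log2") {
  first <- readr::read_lines(path, n_max = 1)
  skip <- if (length(first) == 1 && grepl("^#1\\.2", first)) 2L else 0L
  raw <- readr::read_tsv(path, skip = skip,
    col_types = readr::cols(.default = readr::col_character()))
  names(raw)[1] <- "feature_id"
  if ("Description" %in% names(raw)) raw$Description <- NULL
  value_cols <- setdiff(names(raw), "feature_id")
  for (col in value_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      mirdirect_abort(
        paste0("non-numeric cell at feature `", raw$feature_id[bad[1]],
          "`, sample `", col, "`: \"", raw[[col]][bad[1]], "\""),
        class = "mirdirect_error_expression")
    }
    raw[[col]] <- v
  }
  tbl <- expression_table(raw, scale_tag = scale_tag)
  align_metadata(tbl, metadata)  # errors on unknown samples
  tbl
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression_matrix()]: values round-trip to full double
#' precision.
#'
#' @param x Expression table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  out <- as_tibble(x)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a long-format qPCR Ct table
#'
#' Expects a tab-separated file with columns `feature`, `sample`, `replicate`,
#' `ct` (cycle-threshold cycles). Replicate slots absent from the file are
#' simply absent rows; [collapse_replicates()] averages whatever is present.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `feature_id`, `sample_id`, `replicate`, `ct`.
#' @export
read_ct_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    feature = readr::col_character(),
    sample = readr::col_character(),
    replicate = readr::col_integer(),
    ct = readr::col_double()))
  missing <- setdiff(c("feature", "sample", "replicate", "ct"), names(raw))
  if (length(missing) > 0) {
    mirdirect_abort(
      paste0("Ct table is missing column(s): ", paste(missing, collapse = ", ")),
      class = "mirdirect_error_ct")
  }
  ct_table(tibble(
    feature_id = raw$feature, sample_id = raw$sample,
    replicate = raw$replicate, ct = raw$ct))
}

#' Construct/validate a Ct table
#'
#' @param data Data frame with columns `feature_id`, `sample_id`, `replicate`,
#'   `ct`. Ct values must be finite and strictly positive.
#' @return A validated tibble.
#' @export
ct_table <- function(data) {
  tbl <- as_tibble(data)[c("feature_id", "sample_id", "replicate", "ct")]
  if (any(!is.finite(tbl$ct)) || any(tbl$ct <= 0)) {
    mirdirect_abort("Ct values must be finite and > 0",
      class = "mirdirect_error_ct")
  }
  if (anyDuplicated(tbl[c("feature_id", "sample_id", "replicate")])) {
    mirdirect_abort("duplicate (feature, sample, replicate) rows in Ct table",
      class = "mirdirect_error_ct")
  }
  tbl
}

#' Write a Ct table to long-format TSV
#' @param x Ct table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  out <- tibble(feature = x$feature_id, sample = x$sample_id,
    replicate = x$replicate, ct = x$ct)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a species' 3'UTR sequences from FASTA
#'
#' Record IDs (the first whitespace-delimited token of each header) are taken
#' as gene IDs; sequences are upper-cased and stored in the RNA alphabet
#' (T canonicalized to U), so seed-site logic is agnostic to whether UTRs were
#' supplied as DNA or RNA.
#'
#' @param path Path to a FASTA file.
#' @param species Species label attached to every record.
#' @return A tibble with columns `species`, `gene_id`, `sequence`.
#' @export
read_utr_fasta <- function(path, species) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    mirdirect_abort("empty FASTA file", class = "mirdirect_error_fasta")
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    mirdirect_abort(
      paste0("duplicate gene IDs in FASTA: ",
        paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      class = "mirdirect_error_fasta")
  }
  seqs <- canonicalize_rna(as.character(set))
  tibble(species = species, gene_id = ids, sequence = unname(seqs))
}

#' Write a UTR set to FASTA
#' @param utrs Tibble with columns `gene_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(utrs, path) {
  lines <- rbind(paste0(">", utrs$gene_id), utrs$sequence)
  readr::write_lines(as.vector(lines), path)
  invisible(path)
}

#' Canonicalize a nucleotide sequence to uppercase RNA
#'
#' @param x Character vector of sequences over `A,C,G,T,U,N` (either case).
#' @return Uppercase RNA-alphabet sequences (`T` mapped to `U`).
#' @export
canonicalize_rna <- function(x) {
  out <- chartr("T", "U", toupper(x))
  if (any(grepl("[^ACGUN]", out))) {
    mirdirect_abort("sequence contains characters outside {A,C,G,T,U,N}",
      class = "mirdirect_error_alphabet")
  }
  out
}

#' Read a TargetScan-style conserved-target annotation
#'
#' Parses a tab-separated flat file of annotated seed sites and aggregates it
#' so each (miR family, gene) entry carries the union of species in which a
#' site is annotated. Column names drift across TargetScan releases, so a
#' column mapping can be supplied; the defaults match the "Conserved Family
#' Info" layout.
#'
#' @param path Path to the TSV.
#' @param col_map Named character vector mapping the roles `family`, `gene`,
#'   `species`, `site_type` to column names in the file.
#' @return A tibble with columns `mirna_id`, `gene_id`, `species_set`
#'   (list-column of species), `site_types` (list-column), `n_sites`.
#' @export
read_target_annotation <- function(path,
    col_map = c(family = "miR Family", gene = "Gene Symbol",
      species = "Species ID", site_type = "Site type")) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(unname(col_map), names(raw))
  if (length(missing) > 0) {
    mirdirect_abort(
      paste0("annotation file is missing expected column(s): ",
        paste(missing, collapse = ", "),
        " (expected: ", paste(unname(col_map), collapse = ", "), ")"),
      class = "mirdirect_error_annotation")
  }
  long <- tibble(
    mirna_id = raw[[col_map[["family"]]]],
    gene_id = raw[[col_map[["gene"]]]],
    species = raw[[col_map[["species"]]]],
    site_type = raw[[col_map[["site_type"]]]])
  long |>
    group_by(.data$mirna_id, .data$gene_id) |>
    summarise(
      species_set = list(sort(unique(.data$species))),
      site_types = list(sort(unique(.data$site_type))),
      n_sites = dplyr::n(), .groups = "drop")
}

#' Write a target annotation in TargetScan-style layout
#'
#' Inverse of [read_target_annotation()] up to row order: each
#' (family, gene, species, site type) combination becomes one row.
#'
#' @param annotation Aggregated annotation tibble (or a long tibble with
#'   columns `mirna_id`, `gene_id`, `species`, `site_type`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_annotation <- function(annotation, path) {
  if ("species_set" %in% names(annotation)) {
    long <- annotation |>
      mutate(site_type_first = purrr::map_chr(.data$site_types,
        ~ .x[1] %||% "7mer-m8")) |>
      select("mirna_id", "gene_id", "species_set", "site_type_first") |>
      tidyr::unnest_longer("species_set", values_to = "species") |>
      rename(site_type = "site_type_first")
  } else {
    long <- annotation
  }
  out <- tibble(`miR Family` = long$mirna_id, `Gene Symbol` = long$gene_id,
    `Species ID` = long$species, `Site type` = long$site_type)
  readr::write_tsv(out, path)
  invisible(path)
}
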