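#' Screen configuration
#'
#' Collects every tunable threshold of the four-step screen with the defaults
#' used on the primary qPCR/array study design: microRNA DE at permutation
#' p < 0.001 (1000 Monte-Carlo permutations where enumeration is infeasible),
#' mRNA DE at two-fold change and permutation FDR <= 0.1 (100 permutations),
#' conservation across human/mouse/rat/dog, anti-correlation cutoff
#' P0 = -0.95 screened per class, and pair significance at permutation
#' p < 0.01 with family FDR < 0.2 (999 permutations).
#'
#' @param alpha_mirna MicroRNA DE p-value threshold.
#' @param fold_cutoff mRNA linear fold-change cutoff.
#' @param fdr_mrna mRNA DE FDR threshold.
#' @param B_mirna,B_mrna,B_pairs Monte-Carlo permutation counts for the three
#'   permutation nulls.
#' @param perm_mode Permutation mode for the DE stages: `"auto"` (default)
#'   enumerates all distinct relabelings exactly when there are at most
#'   `exhaustive_bound` of them, else falls back to Monte Carlo.
#' @param exhaustive_bound Enumeration bound for `"auto"`/`"exhaustive"`.
#' @param P0 Anti-correlation cutoff.
#' @param mode Screening correlation mode, `"per_class"` or `"combined"`.
#' @param p_threshold,fdr_pairs Pair significance thresholds.
#' @param required_species Species a seed site must be conserved in.
#' @param site_type Seed site type for de novo scanning.
#' @param seed RNG seed used for every stochastic stage.
#' @return A named list of class `screen_config`.
#' @export
screen_config <- function(alpha_mirna = 0.001, fold_cutoff = 2,
    fdr_mrna = 0.1, B_mirna = 1000, B_mrna = 100, B_pairs = 999,
    perm_mode = "auto", exhaustive_bound = 20000, P0 = -0.95,
    mode = "per_class", p_threshold = 0.01, fdr_pairs = 0.2,
    required_species = c("human", "mouse", "rat", "dog"),
    site_type = "7mer_m8", seed = 1L) {
  cfg <- list(alpha_mirna = alpha_mirna, fold_cutoff = fold_cutoff,
    fdr_mrna = fdr_mrna, B_mirna = B_mirna, B_mrna = B_mrna,
    B_pairs = B_pairs, perm_mode = perm_mode,
    exhaustive_bound = exhaustive_bound, P0 = P0, mode = mode,
    p_threshold = p_threshold, fdr_pairs = fdr_pairs,
    required_species = required_species, site_type = site_type,
    seed = as.integer(seed))
  stopifnot(cfg$alpha_mirna >= 0, cfg$alpha_mirna <= 1,
    cfg$fold_cutoff >= 1, cfg$fdr_mrna >= 0, cfg$fdr_mrna <= 1,
    cfg$P0 >= -1, cfg$P0 < 0, cfg$p_threshold >= 0, cfg$p_threshold <= 1,
    cfg$fdr_pairs >= 0, cfg$fdr_pairs <= 1, length(cfg$seed) == 1,
    !is.na(cfg$seed))
  structure(cfg, class = "screen_config")
}

#' Read or write a screen configuration as YAML
#' @param path YAML file path.
#' @return [read_screen_config()]: a `screen_config`;
#'   [write_screen_config()]: `path`, invisibly.
#' @export
read_screen_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(screen_config, vals)
}

#' @rdname read_screen_config
#' @param config A `screen_config`.
#' @export
write_screen_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the four-step direct-target screen end to end
#'
#' Executes, in order: comparative-Ct normalization when the microRNA input
#' is a raw Ct table (housekeeping selected by minimum |SNR|, log2 relative
#' expression emitted); differential-expression calling for both modalities;
#' the conserved seed-target filter (from a precomputed conserved-target
#' table, a TargetScan-style annotation, or de novo from UTR and mature
#' sequences — the first supplied is used, in that order); and the per-class
#' anti-correlation screen with permutation significance. Identical inputs
#' and configuration yield identical output.
#'
#' @param mirna MicroRNA input: an expression table on a log scale, or a long
#'   Ct table (columns `feature_id`, `sample_id`, `replicate`, `ct`).
#' @param mrna Log2 mRNA expression table.
#' @param metadata Sample metadata covering both modalities.
#' @param targets Precomputed conserved-target tibble
#'   ([conserved_targets()] / [targets_from_annotation()]).
#' @param annotation Aggregated TargetScan-style annotation
#'   ([read_target_annotation()]).
#' @param utrs,mature UTR tibble and mature-sequence tibble for de novo
#'   scanning.
#' @param config A [screen_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A `mirdirect_screen` object: list with `pairs` (the finalized
#'   candidate table), `de_mirna`, `de_mrna`, `targets`, `candidates`,
#'   `counts` (per-stage tallies), `config`, and `normalization` (report or
#'   `NULL`). [tidy()] returns `pairs`; [glance()] the stage counts.
#' @export
run_screen <- function(mirna, mrna, metadata, targets = NULL,
    annotation = NULL, utrs = NULL, mature = NULL,
    config = screen_config(), quiet = FALSE) {
  stopifnot(inherits(config, "screen_config"))
  say <- function(...) if (!quiet) inform(paste0(...))
  stage_seeds <- derive_seeds(config$seed, 3)

  normalization <- NULL
  if (is.data.frame(mirna) && "ct" %in% names(mirna)) {
    say("stage normalize: comparative-Ct normalization of microRNA Ct input")
    ct_mat <- collapse_replicates(mirna)
    normalization <- select_housekeeping(ct_mat, metadata, method = "snr")
    mirna <- comparative_ct_normalize(ct_mat, normalization$housekeeping_id,
      log2 = TRUE)
  }

  say("stage de-mirna: permutation DE of microRNA")
  de_mirna <- call_de_mirna(mirna, metadata, alpha = config$alpha_mirna,
    B = config$B_mirna, mode = config$perm_mode, seed = stage_seeds[1],
    exhaustive_bound = config$exhaustive_bound)
  say("stage de-mrna: fold-change + permutation-FDR DE of mRNA")
  de_mrna <- call_de_mrna(mrna, metadata, fold_cutoff = config$fold_cutoff,
    fdr_target = config$fdr_mrna, B = config$B_mrna,
    mode = config$perm_mode, seed = stage_seeds[2],
    exhaustive_bound = config$exhaustive_bound)

  say("stage targets: conserved seed-target filter")
  if (is.null(targets)) {
    if (!is.null(annotation)) {
      targets <- targets_from_annotation(annotation, config$required_species)
    } else if (!is.null(utrs) && !is.null(mature)) {
      seeds <- mirna_seeds(mature, config$site_type)
      targets <- conserved_targets(seeds, utrs, config$required_species)
    } else {
      mirdirect_abort(
        "supply `targets`, `annotation`, or both `utrs` and `mature`",
        class = "mirdirect_error_config")
    }
  }

  say("stage screen: per-class anti-correlation screen")
  candidates <- build_candidates(de_mirna, de_mrna, targets)
  screened <- screen_pairs(candidates, mirna, mrna, metadata,
    P0 = config$P0, mode = config$mode)
  screened <- pair_permutation_significance(screened, mirna, mrna, metadata,
    B = config$B_pairs, seed = stage_seeds[3])
  pairs <- finalize_screen(screened, p_threshold = config$p_threshold,
    fdr_threshold = config$fdr_pairs)

  counts <- tibble(
    stage = c("de_mirna_significant", "de_mrna_significant",
      "conserved_targets", "candidates", "screened", "finalized"),
    n = c(sum(de_mirna$significant), sum(de_mrna$significant),
      sum(targets$conserved %||% rep(TRUE, nrow(targets))),
      nrow(candidates), nrow(pairs), sum(pairs$passes)))
  say("finalized pairs: ", sum(pairs$passes), " of ", nrow(candidates),
    " candidate(s)")

  structure(list(pairs = pairs, de_mirna = de_mirna, de_mrna = de_mrna,
    targets = targets, candidates = candidates, counts = counts,
    config = config, normalization = normalization),
    class = "mirdirect_screen")
}

#' @export
print.mirdirect_screen <- function(x, ...) {
  cat("Direct-target screen\n")
  cat("  DE microRNA:", x$counts$n[1], " DE mRNA:", x$counts$n[2], "\n")
  cat("  candidates:", x$counts$n[4], " passing pairs:", x$counts$n[6], "\n")
  cat("  P0 =", x$config$P0, " mode =", x$config$mode,
    " seed =", x$config$seed, "\n")
  invisible(x)
}

#' @rdname run_screen
#' @param x A `mirdirect_screen`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mirdirect_screen <- function(x, ...) as_tibble(x$pairs)

#' @rdname run_screen
#' @exportS3Method generics::glance
glance.mirdirect_screen <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "stage", values_from = "n")
}

#' Write the screen's result tables and provenance to a directory
#'
#' Emits `pairs.tsv` (the candidate table with correlations, p-values and the
#' pass flag), `de_mirna.tsv`, `de_mrna.tsv`, `summary.json` (stage counts
#' plus the resolved configuration) and `config.yaml` (sufficient to
#' re-execute the run).
#'
#' @param result A `mirdirect_screen`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- as_tibble(result$pairs)
  readr::write_tsv(pairs, file.path(dir, "pairs.tsv"))
  readr::write_tsv(result$de_mirna, file.path(dir, "de_mirna.tsv"))
  readr::write_tsv(result$de_mrna, file.path(dir, "de_mrna.tsv"))
  jsonlite::write_json(list(
    counts = setNames(as.list(result$counts$n), result$counts$stage),
    config = unclass(result$config)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  write_screen_config(result$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
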