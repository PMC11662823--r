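# End-to-end orchestration: simulate (or ingest) -> traits -> profiles ->
# popgen -> community statistics -> group comparison, with deterministic
# per-step seeds, TSV outputs and a JSON run manifest.

pipeline_steps <- c("simulate", "traits", "profile", "popgen", "community", "compare")

# One master seed fans out to per-step child seeds by a fixed documented
# derivation, so steps are independently reproducible.
child_seed <- function(seed, step) {
  as.integer((as.integer(seed) + 7919L * match(step, pipeline_steps)) %% .Machine$integer.max)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Simulates a dataset from `config`, then computes genome traits,
#' TPM/KO/weighted-trait profiles, per-(OTU, sample) population-genetic
#' summaries, community statistics (Shannon, Bray-Curtis, ANOSIM), and a
#' freshwater-vs-saline group comparison. All tabular outputs are
#' written as TSV under `output_dir` together with a JSON manifest
#' recording the config hash, seed and per-step row counts; re-running
#' with the same config and seed reproduces every output.
#'
#' @param config A [synthetic_config()].
#' @param output_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param steps Subset of steps to run (dependencies are implied:
#'   everything downstream of `simulate` needs it).
#' @param pileup_otus Passed to [simulate_dataset()].
#' @param anosim_perm Permutations for the community ANOSIM.
#' @param seed Master seed; defaults to `config$seed`.
#' @return List with the computed tables (`dataset`, `traits`,
#'   `abundance`, `ko_profile`, `weighted_traits`, `popgen`, `shannon`,
#'   `anosim`, `comparison`) and the `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL, steps = pipeline_steps,
                         pileup_otus = NULL, anosim_perm = 199,
                         seed = config$seed) {
  steps <- match.arg(steps, pipeline_steps, several.ok = TRUE)
  out <- list()
  rows <- list()

  if (!"simulate" %in% steps) {
    abort_lkd("run_pipeline currently starts from the simulate step")
  }
  ds <- simulate_dataset(config, pileup_otus = pileup_otus,
                         seed = child_seed(seed, "simulate"))
  out$dataset <- ds
  rows$simulate <- length(ds$bundles)

  glen <- purrr::map_dbl(ds$bundles, "assembled_size_bp")
  abundance <- tpm_from_counts(ds$counts, glen)
  out$abundance <- abundance

  if ("traits" %in% steps) {
    out$traits <- trait_table(ds$bundles)
    rows$traits <- nrow(out$traits)
  }
  if ("profile" %in% steps) {
    out$ko_profile <- ko_profile(abundance, ds$bundles, config$uscg_list)
    if (!is.null(out$traits)) {
      out$weighted_traits <- community_weighted_traits(abundance, out$traits)
    }
    rows$profile <- nrow(out$ko_profile)
  }
  if ("popgen" %in% steps) {
    out$popgen <- purrr::imap_dfr(ds$pileups, function(p, key) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      popgen_summary(p, ds$bundles[[parts[1]]], ds$masks[[parts[1]]],
                     sample_id = parts[2])
    })
    rows$popgen <- nrow(out$popgen)
  }
  if ("community" %in% steps) {
    div <- diversity_metrics(abundance)
    out$shannon <- div$shannon
    out$bray_curtis <- div$bray_curtis
    grouping <- ds$metadata$group[
      match(attr(div$bray_curtis, "Labels"), ds$metadata$sample_id)
    ]
    out$anosim <- anosim_test(div$bray_curtis, grouping, n_perm = anosim_perm,
                              seed = child_seed(seed, "community"))
    rows$community <- nrow(out$shannon)
  }
  if ("compare" %in% steps) {
    out$comparison <- compare_groups(out, ds$metadata)
    rows$compare <- if (is.null(out$comparison)) 0L else nrow(out$comparison)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lakemicrodiv")),
    seed = as.integer(seed),
    config_hash = rlang::hash(config),
    steps = steps,
    rows = rows
  )
  out$manifest <- manifest

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      readr::write_tsv(df, file.path(output_dir, paste0(name, ".tsv")))
    }
    wr(ds$metadata, "metadata")
    wr(abundance, "abundance")
    if (!is.null(out$traits)) wr(out$traits, "traits")
    if (!is.null(out$ko_profile)) wr(out$ko_profile, "ko_profile")
    if (!is.null(out$weighted_traits)) wr(out$weighted_traits, "weighted_traits")
    if (!is.null(out$popgen)) wr(out$popgen, "popgen")
    if (!is.null(out$shannon)) wr(out$shannon, "shannon")
    if (!is.null(out$comparison)) wr(out$comparison, "comparison")
    ape::write.tree(ds$tree, file.path(output_dir, "tree.nwk"))
    jsonlite::write_json(
      manifest, file.path(output_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  out
}

#' Compare statistics between lake groups
#'
#' For each available per-sample statistic (Shannon, weighted traits,
#' normalized KO abundances, and QC-passing population-genetic
#' statistics), computes group means and standard deviations, Welch's t
#' p-value and a Benjamini--Hochberg q-value across statistics.
#'
#' @param results List of pipeline tables (as produced by
#'   [run_pipeline()]), or any list with some of `shannon`,
#'   `weighted_traits`, `ko_profile`, `popgen` present.
#' @param metadata Tibble with `sample_id` and `group`.
#' @param groups Two group labels to compare.
#' @param fdr_threshold q-value cutoff for the `enriched_in` flag.
#' @return Tibble with one row per statistic, or `NULL` (with a message)
#'   when fewer than two groups have >= 2 samples.
#' @export
compare_groups <- function(results, metadata, groups = c("freshwater", "saline"),
                           fdr_threshold = 0.01) {
  present <- intersect(groups, unique(metadata$group))
  if (length(present) < 2 ||
      any(table(metadata$group[metadata$group %in% groups]) < 2)) {
    message("compare_groups: fewer than two usable groups; comparison skipped")
    return(NULL)
  }
  feats <- list()
  if (!is.null(results$shannon)) {
    feats$shannon <- dplyr::transmute(
      results$shannon,
      feature_id = "shannon", sample_id = .data$sample_id,
      value = .data$shannon
    )
  }
  if (!is.null(results$weighted_traits)) {
    feats$traits <- dplyr::transmute(
      results$weighted_traits,
      feature_id = paste0("cwm_", .data$trait), sample_id = .data$sample_id,
      value = .data$value
    )
  }
  if (!is.null(results$ko_profile)) {
    feats$ko <- dplyr::transmute(
      results$ko_profile,
      feature_id = paste0("ko_", .data$ko_id), sample_id = .data$sample_id,
      value = .data$normalized
    )
  }
  if (!is.null(results$popgen)) {
    pg <- dplyr::filter(results$popgen, .data$qc_pass)
    for (stat in c("pi_all", "pi_4fold", "snv_per_mb_all", "pn_ps")) {
      feats[[stat]] <- tibble::tibble(
        feature_id = paste(stat, pg$otu_id, sep = "_"),
        sample_id = pg$sample_id,
        value = pg[[stat]]
      )
    }
  }
  data <- dplyr::bind_rows(feats)
  data <- data[!is.na(data$value), ]
  # drop features observed in < 2 samples of either group
  md <- metadata[metadata$group %in% groups, ]
  ok <- data |>
    dplyr::inner_join(md[, c("sample_id", "group")], by = "sample_id") |>
    dplyr::count(.data$feature_id, .data$group) |>
    tidyr::pivot_wider(names_from = "group", values_from = "n", values_fill = 0L) |>
    dplyr::filter(dplyr::if_all(-"feature_id", ~ .x >= 2))
  data <- data[data$feature_id %in% ok$feature_id, ]
  if (nrow(data) == 0) {
    message("compare_groups: no statistic observed in >= 2 samples per group")
    return(NULL)
  }
  res <- enrichment_test(data, metadata, groups, fdr_threshold)
  sds <- data |>
    dplyr::inner_join(md[, c("sample_id", "group")], by = "sample_id") |>
    dplyr::group_by(.data$feature_id, .data$group) |>
    dplyr::summarise(sd = stats::sd(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "sd",
                       names_prefix = "sd_")
  dplyr::left_join(tibble::as_tibble(res), sds, by = "feature_id")
}
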