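# Abundance and function profiles: TPM from read-recruitment counts,
# single-copy-normalized KO profiles, community-weighted traits, and
# Welch/FDR group enrichment.

#' TPM and relative abundance from read-recruitment counts
#'
#' Length-normalized rates scaled to one million per sample:
#' `rate = count / length`, `tpm = 1e6 * rate / sum(rate)`,
#' `rel_abund = tpm / 1e6`. A sample with no mapped reads yields all
#' zeros with a warning.
#'
#' @param counts Long tibble with columns `otu_id`, `sample_id`, `count`.
#' @param genome_lengths Named numeric vector of genome lengths (bp) per
#'   OTU; every OTU with a nonzero count must have a length.
#' @return Long tibble `otu_id`, `sample_id`, `tpm`, `rel_abund`.
#' @export
tpm_from_counts <- function(counts, genome_lengths) {
  assert_cols(counts, c("otu_id", "sample_id", "count"), "count table")
  if (any(counts$count < 0)) abort_lkd("negative read counts")
  len <- genome_lengths[counts$otu_id]
  missing_len <- is.na(len) & counts$count > 0
  if (any(missing_len)) {
    abort_lkd("missing genome length for OTU %s with nonzero count",
              counts$otu_id[missing_len][1])
  }
  if (any(!is.na(len) & len <= 0)) abort_lkd("genome lengths must be > 0")
  out <- counts |>
    dplyr::mutate(rate = .data$count / unname(len)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      tpm = if (sum(.data$rate) > 0) 1e6 * .data$rate / sum(.data$rate) else 0
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(rel_abund = .data$tpm / 1e6)
  zero_samples <- out |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(z = sum(.data$tpm) == 0, .groups = "drop")
  if (any(zero_samples$z)) {
    rlang::warn(sprintf(
      "sample(s) with no mapped reads: %s",
      paste(zero_samples$sample_id[zero_samples$z], collapse = ", ")
    ))
  }
  out[, c("otu_id", "sample_id", "tpm", "rel_abund")]
}

# KO copy numbers per OTU from bundle annotations.
ko_copy_table <- function(bundles) {
  dplyr::bind_rows(purrr::map(bundles, function(b) {
    if (nrow(b$ko_annotations) == 0) {
      return(tibble::tibble(otu_id = character(), ko_id = character(),
                            copies = integer()))
    }
    b$ko_annotations |>
      dplyr::count(.data$ko_id, name = "copies") |>
      dplyr::mutate(otu_id = b$otu_id)
  }))
}

#' Single-copy-normalized KO profile
#'
#' The raw abundance of a KO in a sample is the sum over OTUs of the
#' OTU's TPM times its KO copy number; the normalized abundance divides
#' this by the mean raw abundance of the universal single-copy KOs in the
#' same sample, yielding unitless copies per genome equivalent. A KO at
#' exactly one copy in every OTU therefore has normalized abundance 1 in
#' every sample.
#'
#' @param abundance Long tibble from [tpm_from_counts()].
#' @param bundles List of [genome_bundle()] objects covering every OTU in
#'   `abundance`.
#' @param uscg Character vector of universal single-copy KO ids.
#' @return Long tibble `ko_id`, `sample_id`, `raw_tpm`, `normalized`.
#' @export
ko_profile <- function(abundance, bundles, uscg = default_uscg()) {
  assert_cols(abundance, c("otu_id", "sample_id", "tpm"), "abundance")
  if (length(uscg) == 0) abort_lkd("uscg list is empty")
  copies <- ko_copy_table(bundles)
  missing_b <- setdiff(unique(abundance$otu_id), purrr::map_chr(bundles, "otu_id"))
  if (length(missing_b) > 0) {
    abort_lkd("no genome bundle for OTU %s", missing_b[1])
  }
  raw <- abundance |>
    dplyr::inner_join(copies, by = "otu_id", relationship = "many-to-many") |>
    dplyr::group_by(.data$ko_id, .data$sample_id) |>
    dplyr::summarise(raw_tpm = sum(.data$tpm * .data$copies), .groups = "drop") |>
    tidyr::complete(
      ko_id = unique(copies$ko_id),
      sample_id = unique(abundance$sample_id),
      fill = list(raw_tpm = 0)
    )
  uscg_mean <- raw |>
    dplyr::filter(.data$ko_id %in% uscg) |>
    tidyr::complete(
      ko_id = uscg, sample_id = unique(abundance$sample_id),
      fill = list(raw_tpm = 0)
    ) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(uscg_mean = mean(.data$raw_tpm), .groups = "drop")
  bad <- uscg_mean$sample_id[uscg_mean$uscg_mean <= 0]
  if (length(bad) > 0) {
    abort_lkd("mean single-copy-KO TPM is zero in sample %s", bad[1])
  }
  raw |>
    dplyr::left_join(uscg_mean, by = "sample_id") |>
    dplyr::mutate(normalized = .data$raw_tpm / .data$uscg_mean) |>
    dplyr::select("ko_id", "sample_id", "raw_tpm", "normalized")
}

#' Community-weighted mean of a genomic trait
#'
#' Mean of a per-genome trait across OTUs, weighted by each OTU's
#' relative abundance in the sample.
#'
#' @param abundance Long tibble with `otu_id`, `sample_id`, `rel_abund`.
#' @param traits Trait table ([trait_table()]) with one row per OTU.
#' @param trait_name Column of `traits` to average.
#' @return Tibble `sample_id`, `trait`, `value`.
#' @export
community_weighted_trait <- function(abundance, traits, trait_name) {
  assert_cols(abundance, c("otu_id", "sample_id", "rel_abund"), "abundance")
  assert_cols(traits, c("otu_id", trait_name), "trait table")
  tr <- stats::setNames(traits[[trait_name]], traits$otu_id)
  v <- tr[abundance$otu_id]
  bad <- (is.na(v) | is.na(match(abundance$otu_id, traits$otu_id))) &
    abundance$rel_abund > 0
  if (any(bad)) {
    abort_lkd("trait '%s' missing for abundant OTU %s",
              trait_name, abundance$otu_id[bad][1])
  }
  abundance |>
    dplyr::mutate(.trait_val = unname(v)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      value = sum(.data$rel_abund * .data$.trait_val), .groups = "drop"
    ) |>
    dplyr::mutate(trait = trait_name, .before = "value")
}

#' Community-weighted means for all numeric traits
#'
#' @inheritParams community_weighted_trait
#' @param trait_names Columns to average; defaults to all numeric trait
#'   columns except sizes-in-bp bookkeeping.
#' @return Long tibble `sample_id`, `trait`, `value`.
#' @export
community_weighted_traits <- function(abundance, traits, trait_names = NULL) {
  if (is.null(trait_names)) {
    num <- names(traits)[vapply(traits, is.numeric, logical(1))]
    trait_names <- setdiff(num, "assembled_size_bp")
  }
  purrr::map_dfr(trait_names, ~ community_weighted_trait(abundance, traits, .x))
}

# Vectorized Welch's t-test over features; handles the degenerate
# zero-variance cases explicitly (equal means -> p = 1, not NaN).
welch_table <- function(m1, m2, v1, v2, n1, n2) {
  se2 <- v1 / n1 + v2 / n2
  t_stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2),
                   ifelse(m1 == m2, 0, Inf * sign(m1 - m2)))
  dof <- ifelse(
    se2 > 0,
    se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
    n1 + n2 - 2
  )
  p <- ifelse(
    is.finite(t_stat),
    2 * stats::pt(abs(t_stat), dof, lower.tail = FALSE),
    0
  )
  p[se2 == 0 & m1 == m2] <- 1
  tibble::tibble(t_statistic = t_stat, dof_welch = dof, p_value = p)
}

#' Two-group enrichment test (Welch's t + Benjamini--Hochberg FDR)
#'
#' Per feature, Welch's unequal-variance t-test with Welch--Satterthwaite
#' degrees of freedom between two sample groups, followed by
#' Benjamini--Hochberg adjustment across features. A feature is called
#' enriched in the group with the larger mean when its q-value is below
#' `fdr_threshold`.
#'
#' @param data Long tibble with columns `feature_id`, `sample_id`,
#'   `value`.
#' @param metadata Tibble with `sample_id` and `group`.
#' @param groups The two group labels to compare (default freshwater vs
#'   saline; other groups are ignored).
#' @param fdr_threshold q-value cutoff for the `enriched_in` call.
#' @param log_transform If `TRUE`, test `log(value + pseudocount)`.
#' @param pseudocount Added before the log transform.
#' @return Tibble of class `lakemicrodiv_enrichment`, one row per
#'   feature: group means, `t_statistic`, `dof_welch`, `p_value`,
#'   `q_value`, `enriched_in` (NA when not significant).
#' @export
enrichment_test <- function(data, metadata, groups = c("freshwater", "saline"),
                            fdr_threshold = 0.01, log_transform = FALSE,
                            pseudocount = 1e-6) {
  assert_cols(data, c("feature_id", "sample_id", "value"), "feature table")
  assert_cols(metadata, c("sample_id", "group"), "metadata")
  if (length(groups) != 2) abort_lkd("exactly two groups must be compared")
  md <- metadata[metadata$group %in% groups, c("sample_id", "group")]
  n_per <- table(factor(md$group, levels = groups))
  if (any(n_per < 2)) abort_lkd("each group needs >= 2 samples")
  d <- dplyr::inner_join(data, md, by = "sample_id")
  if (log_transform) d$value <- log(d$value + pseudocount)
  stats_tbl <- d |>
    dplyr::group_by(.data$feature_id, .data$group) |>
    dplyr::summarise(
      m = mean(.data$value), v = stats::var(.data$value),
      n = dplyr::n(), .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "group", values_from = c("m", "v", "n")
    )
  g1 <- groups[1]; g2 <- groups[2]
  wt <- welch_table(
    stats_tbl[[paste0("m_", g1)]], stats_tbl[[paste0("m_", g2)]],
    stats_tbl[[paste0("v_", g1)]], stats_tbl[[paste0("v_", g2)]],
    stats_tbl[[paste0("n_", g1)]], stats_tbl[[paste0("n_", g2)]]
  )
  out <- tibble::tibble(
    feature_id = stats_tbl$feature_id,
    mean_group1 = stats_tbl[[paste0("m_", g1)]],
    mean_group2 = stats_tbl[[paste0("m_", g2)]],
    t_statistic = wt$t_statistic,
    dof_welch = wt$dof_welch,
    p_value = wt$p_value,
    q_value = stats::p.adjust(wt$p_value, method = "BH")
  )
  out$enriched_in <- dplyr::if_else(
    out$q_value < fdr_threshold,
    dplyr::if_else(out$mean_group1 > out$mean_group2, g1, g2),
    NA_character_
  )
  structure(
    out,
    groups = groups, fdr_threshold = fdr_threshold,
    class = c("lakemicrodiv_enrichment", class(out))
  )
}
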