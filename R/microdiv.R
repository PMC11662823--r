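# Intraspecific population-genetic statistics from per-site pileups:
# codon-aware site masks with synonymous/nonsynonymous opportunities and
# fourfold-degenerate flags, SNV calling, nucleotide diversity, SNV
# density, and opportunity-normalized pN/pS.

#' Build a codon-aware site mask for a genome
#'
#' For every coding position of every non-partial gene the mask records
#' the codon, codon position, the genome-strand reference base, the
#' synonymous and nonsynonymous mutational opportunities (fraction of the
#' three possible single-nucleotide changes in each class;
#' stop-introducing changes count as nonsynonymous), and whether the site
#' is fourfold degenerate. Stop codons carry no opportunity and are
#' excluded, as are codons containing N. Sites covered by more than one
#' gene are ambiguous to classify and are dropped from the mask (they
#' still contribute to all-site nucleotide diversity, which does not use
#' the mask).
#'
#' @param bundle A [genome_bundle()].
#' @return Tibble with columns `contig`, `pos` (0-based), `gene_id`,
#'   `strand`, `codon`, `codon_pos` (0..2, coding frame), `ref_base`
#'   (genome strand), `aa`, `syn_opportunity`, `nonsyn_opportunity`,
#'   `fourfold`.
#' @export
build_site_mask <- function(bundle) {
  genes <- bundle$genes[!bundle$genes$partial, ]
  if (nrow(genes) == 0) {
    return(tibble::tibble(
      contig = character(), pos = integer(), gene_id = character(),
      strand = integer(), codon = character(), codon_pos = integer(),
      ref_base = character(), aa = character(), syn_opportunity = double(),
      nonsyn_opportunity = double(), fourfold = logical()
    ))
  }
  code <- Biostrings::GENETIC_CODE
  per_gene <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    cds <- gene_sequence(bundle, g)
    len <- nchar(cds)
    n_cod <- len %/% 3L
    codons <- substring(cds, 3L * (seq_len(n_cod) - 1L) + 1L, 3L * seq_len(n_cod))
    aa <- unname(code[codons]) # NA for codons with N
    internal_stop <- which(aa[-n_cod] == "*")
    if (length(internal_stop) > 0) {
      abort_lkd(
        "internal stop codon in non-partial gene %s (codon %d)",
        g$gene_id, internal_stop[1]
      )
    }
    offset <- 0:(len - 1L)
    pos <- if (g$strand > 0) g$start + offset else g$end - 1L - offset
    tibble::tibble(
      contig = g$contig_id,
      pos = as.integer(pos),
      gene_id = g$gene_id,
      strand = as.integer(g$strand),
      codon = rep(codons, each = 3L),
      codon_pos = rep(0:2, n_cod),
      aa = rep(aa, each = 3L)
    )
  })
  mask <- dplyr::bind_rows(per_gene)
  # drop stop codons, N-containing codons, and overlapping-gene sites
  mask <- mask[!is.na(mask$aa) & mask$aa != "*", ]
  key <- paste(mask$contig, mask$pos)
  dup <- key %in% key[duplicated(key)]
  mask <- mask[!dup, ]
  opp <- codon_opportunity_table()
  mask <- dplyr::left_join(
    mask,
    opp[, c("codon", "codon_pos", "ref_base", "syn_opportunity",
            "nonsyn_opportunity", "fourfold")],
    by = c("codon", "codon_pos")
  )
  # ref_base from the opportunity table is coding-strand; report genome strand
  mask$ref_base <- ifelse(
    mask$strand < 0, lkd_complement[mask$ref_base], mask$ref_base
  )
  dplyr::arrange(mask, .data$contig, .data$pos)
}

# Reference base per (contig, pos) from bundle sequences.
ref_base_at <- function(bundle, contig, pos) {
  out <- character(length(pos))
  for (cid in unique(contig)) {
    sel <- contig == cid
    seq_c <- bundle$contigs[[cid]]
    if (is.null(seq_c)) abort_lkd("pileup refers to unknown contig %s", cid)
    if (any(pos[sel] < 0 | pos[sel] >= nchar(seq_c))) {
      abort_lkd("pileup site outside genome coordinates on contig %s", cid)
    }
    out[sel] <- substring(seq_c, pos[sel] + 1L, pos[sel] + 1L)
  }
  out
}

#' Call single-nucleotide variants from a pileup
#'
#' A site is an SNV when its depth reaches `min_depth` and at least two
#' alleles each reach `min_count` reads and `min_freq` frequency. The
#' consensus (most frequent base, ties broken toward the reference) is the
#' "from" state; each qualifying alternative allele is classified through
#' the site mask, and a multi-allelic site is nonsynonymous if any
#' qualifying alternative is. Sites absent from the mask are intergenic.
#'
#' @param pileup Pileup tibble ([read_pileup()] format).
#' @param mask Site mask from [build_site_mask()].
#' @param bundle Optional [genome_bundle()]; when supplied, reference
#'   bases are taken from the genome (and pileup positions are checked
#'   against it) instead of from the mask/consensus.
#' @param min_depth,min_freq,min_count SNV calling thresholds (defaults
#'   mirror the documented defaults of the inStrain profiler).
#' @return Tibble with one row per SNV: `contig`, `pos`, `ref_base`,
#'   `consensus`, `alt` (comma-separated qualifying alternatives),
#'   `alt_freq` (frequency of the major alternative), `depth`, `klass`
#'   (synonymous/nonsynonymous/intergenic), `fourfold`.
#' @export
call_snvs <- function(pileup, mask, bundle = NULL,
                      min_depth = 5, min_freq = 0.05, min_count = 2) {
  pileup <- validate_pileup(pileup)
  cnt <- as.matrix(pileup[, c("A", "C", "G", "T")])
  depth <- rowSums(cnt)
  keep <- depth >= min_depth
  pileup <- pileup[keep, , drop = FALSE]
  cnt <- cnt[keep, , drop = FALSE]
  depth <- depth[keep]
  empty <- tibble::tibble(
    contig = character(), pos = integer(), ref_base = character(),
    consensus = character(), alt = character(), alt_freq = double(),
    depth = double(), klass = character(), fourfold = logical()
  )
  if (nrow(pileup) == 0) return(empty)

  freq <- cnt / depth
  qual <- cnt >= min_count & freq >= min_freq
  is_snv <- rowSums(qual) >= 2
  if (!any(is_snv)) return(empty)
  cnt <- cnt[is_snv, , drop = FALSE]
  freq <- freq[is_snv, , drop = FALSE]
  qual <- qual[is_snv, , drop = FALSE]
  depth <- depth[is_snv]
  site <- pileup[is_snv, c("contig", "pos")]

  ref <- if (!is.null(bundle)) {
    ref_base_at(bundle, site$contig, site$pos)
  } else {
    NA_character_
  }
  mask_idx <- match(
    paste(site$contig, site$pos),
    paste(mask$contig, mask$pos)
  )
  if (is.null(bundle)) {
    ref <- mask$ref_base[mask_idx] # NA for intergenic sites
  }

  n <- nrow(site)
  row_max <- do.call(pmax, as.data.frame(cnt))
  cons_idx <- max.col(cnt, ties.method = "first")
  tied <- rowSums(cnt == row_max) > 1
  ref_is_top <- !is.na(ref) & cnt[cbind(seq_len(n), match(ref, lkd_bases))] == row_max
  use_ref <- tied & ref_is_top
  consensus <- lkd_bases[cons_idx]
  consensus[use_ref] <- ref[use_ref]

  # long table of (site, qualifying alt) pairs, consensus excluded
  qp <- which(qual, arr.ind = TRUE)
  keep_alt <- lkd_bases[qp[, 2]] != consensus[qp[, 1]]
  qp <- qp[keep_alt, , drop = FALSE]
  alt_site <- qp[, 1]
  alt_base <- lkd_bases[qp[, 2]]
  coding <- !is.na(mask_idx[alt_site])
  alt_cls <- rep(NA_character_, length(alt_site))
  if (any(coding)) {
    mi <- mask_idx[alt_site[coding]]
    alt_cls[coding] <- classify_substitution(
      mask$codon[mi], mask$codon_pos[mi], mask$strand[mi],
      consensus[alt_site[coding]], alt_base[coding]
    )
  }
  ord <- order(alt_site, qp[, 2])
  alt_str <- vapply(
    split(alt_base[ord], factor(alt_site[ord], levels = seq_len(n))),
    paste, character(1), collapse = ","
  )
  alt_major_freq <- vapply(
    split(freq[cbind(alt_site, qp[, 2])], factor(alt_site, levels = seq_len(n))),
    max, numeric(1)
  )
  any_nonsyn <- vapply(
    split(alt_cls, factor(alt_site, levels = seq_len(n))),
    function(x) any(x == "nonsynonymous"), logical(1)
  )
  klass <- ifelse(is.na(mask_idx), "intergenic",
                  ifelse(any_nonsyn, "nonsynonymous", "synonymous"))
  tibble::tibble(
    contig = site$contig,
    pos = as.integer(site$pos),
    ref_base = unname(ref),
    consensus = consensus,
    alt = unname(alt_str),
    alt_freq = unname(alt_major_freq),
    depth = depth,
    klass = klass,
    fourfold = !is.na(mask_idx) & mask$fourfold[mask_idx]
  )
}

#' Nucleotide diversity and SNV density
#'
#' Per-site diversity is the expected heterozygosity `1 - sum(p_b^2)` over
#' observed base frequencies; genome-wide pi is its mean over sites with
#' depth at or above `min_depth` (no finite-depth correction, matching the
#' plain inStrain-style estimator). SNV density is the number of
#' qualifying SNVs per megabase of covered sites in the chosen subset.
#'
#' @param pileup Pileup tibble.
#' @param mask Site mask; required for `subset = "fourfold"`.
#' @param subset `"all"` sites or `"fourfold"` degenerate sites only.
#' @param min_depth Minimum depth for a site to count as covered.
#' @param min_freq,min_count SNV thresholds passed to [call_snvs()].
#' @param snvs Optional precomputed SNV table from [call_snvs()] (with
#'   the same thresholds); avoids re-calling when several subsets are
#'   summarized from one pileup.
#' @return One-row tibble: `pi`, `covered_sites`, `n_snvs`, `snv_per_mb`.
#'   All statistics are `NA` when no site is covered.
#' @export
nucleotide_diversity <- function(pileup, mask = NULL,
                                 subset = c("all", "fourfold"),
                                 min_depth = 5, min_freq = 0.05, min_count = 2,
                                 snvs = NULL) {
  subset <- match.arg(subset)
  pileup <- validate_pileup(pileup)
  if (is.null(snvs)) {
    mask_eff <- mask
    if (is.null(mask_eff)) {
      mask_eff <- tibble::tibble(
        contig = character(), pos = integer(), strand = integer(),
        codon = character(), codon_pos = integer(), ref_base = character(),
        fourfold = logical()
      )
    }
    snvs <- call_snvs(pileup, mask_eff, min_depth = min_depth,
                      min_freq = min_freq, min_count = min_count)
  }
  if (subset == "fourfold") {
    if (is.null(mask)) abort_lkd("fourfold subset requires a site mask")
    ff <- mask[mask$fourfold, c("contig", "pos")]
    pileup <- dplyr::semi_join(pileup, ff, by = c("contig", "pos"))
    snvs <- snvs[snvs$fourfold, , drop = FALSE]
  }
  cnt <- as.matrix(pileup[, c("A", "C", "G", "T")])
  depth <- rowSums(cnt)
  covered <- depth >= min_depth
  n_cov <- sum(covered)
  if (n_cov == 0) {
    return(tibble::tibble(
      pi = NA_real_, covered_sites = 0L, n_snvs = NA_integer_,
      snv_per_mb = NA_real_
    ))
  }
  p <- cnt[covered, , drop = FALSE] / depth[covered]
  pi_site <- 1 - rowSums(p^2)
  tibble::tibble(
    pi = mean(pi_site),
    covered_sites = n_cov,
    n_snvs = nrow(snvs),
    snv_per_mb = nrow(snvs) / (n_cov / 1e6)
  )
}

#' Opportunity-normalized pN/pS
#'
#' The ratio of nonsynonymous to synonymous polymorphism rates, each
#' normalized by its mutational opportunity summed over *covered* coding
#' sites (Nei--Gojobori-style counting without transition/transversion
#' weighting): `(n_nonsyn / N_opp) / (n_syn / S_opp)`. Undefined (NA, with
#' a `reason` column) when no synonymous SNV is observed.
#'
#' @param snvs SNV table from [call_snvs()].
#' @param mask Site mask from [build_site_mask()].
#' @param pileup Pileup tibble used to determine covered coding sites.
#' @param min_depth Coverage threshold defining covered sites.
#' @return One-row tibble: `pn_ps`, `n_syn_snvs`, `n_nonsyn_snvs`,
#'   `s_opportunity`, `n_opportunity`, `reason` (NA when defined).
#' @export
pn_ps <- function(snvs, mask, pileup, min_depth = 5) {
  pileup <- validate_pileup(pileup)
  depth <- rowSums(as.matrix(pileup[, c("A", "C", "G", "T")]))
  cov_sites <- pileup[depth >= min_depth, c("contig", "pos")]
  cov_mask <- dplyr::semi_join(mask, cov_sites, by = c("contig", "pos"))
  s_opp <- sum(cov_mask$syn_opportunity)
  n_opp <- sum(cov_mask$nonsyn_opportunity)
  n_syn <- sum(snvs$klass == "synonymous")
  n_nonsyn <- sum(snvs$klass == "nonsynonymous")
  if (n_syn == 0 || s_opp == 0 || n_opp == 0) {
    reason <- if (n_syn == 0) "no synonymous SNVs" else "no covered opportunity"
    return(tibble::tibble(
      pn_ps = NA_real_, n_syn_snvs = n_syn, n_nonsyn_snvs = n_nonsyn,
      s_opportunity = s_opp, n_opportunity = n_opp, reason = reason
    ))
  }
  tibble::tibble(
    pn_ps = (n_nonsyn / n_opp) / (n_syn / s_opp),
    n_syn_snvs = n_syn,
    n_nonsyn_snvs = n_nonsyn,
    s_opportunity = s_opp,
    n_opportunity = n_opp,
    reason = NA_character_
  )
}

#' Per-(OTU, sample) population-genetic summary
#'
#' Computes the full panel of within-species statistics for one pileup:
#' mean depth and breadth, nucleotide diversity and SNV density over all
#' sites and over fourfold degenerate sites, and opportunity-normalized
#' pN/pS. Pairs failing QC (breadth or mean depth too low) are emitted
#' with `qc_pass = FALSE` and statistics withheld as NA.
#'
#' @param pileup Pileup tibble for one (OTU, sample) pair.
#' @param bundle The OTU's [genome_bundle()].
#' @param mask Site mask from [build_site_mask()]; built from the bundle
#'   when `NULL`.
#' @param sample_id Optional sample label carried into the output.
#' @param min_depth,min_freq,min_count SNV/coverage thresholds.
#' @param min_breadth,min_mean_depth QC thresholds; breadth is the
#'   fraction of genome positions with any read coverage.
#' @return One-row tibble with the fields above plus `otu_id`,
#'   `sample_id`, `qc_pass`.
#' @export
popgen_summary <- function(pileup, bundle, mask = NULL, sample_id = NA_character_,
                           min_depth = 5, min_freq = 0.05, min_count = 2,
                           min_breadth = 0.5, min_mean_depth = 5) {
  pileup <- validate_pileup(pileup)
  if (is.null(mask)) mask <- build_site_mask(bundle)
  genome_sites <- bundle$assembled_size_bp
  depth <- rowSums(as.matrix(pileup[, c("A", "C", "G", "T")]))
  breadth <- sum(depth > 0) / genome_sites
  mean_depth <- sum(depth) / genome_sites
  base <- tibble::tibble(
    otu_id = bundle$otu_id, sample_id = sample_id,
    mean_depth = mean_depth, breadth = breadth,
    qc_pass = breadth >= min_breadth && mean_depth >= min_mean_depth
  )
  if (!base$qc_pass) {
    return(dplyr::mutate(
      base,
      pi_all = NA_real_, pi_4fold = NA_real_,
      snv_per_mb_all = NA_real_, snv_per_mb_4fold = NA_real_,
      pn_ps = NA_real_, n_syn_snvs = NA_integer_, n_nonsyn_snvs = NA_integer_
    ))
  }
  snvs <- call_snvs(pileup, mask, bundle, min_depth, min_freq, min_count)
  div_all <- nucleotide_diversity(pileup, mask, "all", min_depth, min_freq,
                                  min_count, snvs = snvs)
  div_ff <- nucleotide_diversity(pileup, mask, "fourfold", min_depth, min_freq,
                                 min_count, snvs = snvs)
  ratio <- pn_ps(snvs, mask, pileup, min_depth)
  dplyr::mutate(
    base,
    pi_all = div_all$pi, pi_4fold = div_ff$pi,
    snv_per_mb_all = div_all$snv_per_mb, snv_per_mb_4fold = div_ff$snv_per_mb,
    pn_ps = ratio$pn_ps,
    n_syn_snvs = as.integer(ratio$n_syn_snvs),
    n_nonsyn_snvs = as.integer(ratio$n_nonsyn_snvs)
  )
}
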