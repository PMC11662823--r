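# Per-genome traits: estimated genome size, quality score, GC content,
# coding density, proteome side-chain stoichiometry (C-/N-ARSC) and
# per-Mb annotation densities.

#' Estimated genome size from assembly quality
#'
#' Corrects the assembled size of a draft genome for incompleteness and
#' contamination: the assembled size is divided by the sum of completeness
#' and contamination (as fractions), so a complete, uncontaminated genome
#' is returned unchanged.
#'
#' @param assembled_size_bp Assembled genome size in bp.
#' @param completeness,contamination Fractions (0-1) or percentages
#'   (0-100, auto-detected). Their sum must be positive.
#' @return Estimated genome size in bp.
#' @export
#' @examples
#' estimated_genome_size(2e6, 0.8, 0.0) # 2.5 Mb
estimated_genome_size <- function(assembled_size_bp, completeness, contamination) {
  completeness <- as_fraction(completeness, "completeness")
  contamination <- as_fraction(contamination, "contamination")
  denom <- completeness + contamination
  if (any(denom <= 0)) abort_lkd("completeness + contamination must be > 0")
  assembled_size_bp / denom
}

#' MAG quality score
#'
#' Completeness minus five times contamination, both on the percent scale.
#' A score of 50 with contamination < 10% is the usual medium-quality floor.
#'
#' @param completeness_pct,contamination_pct Percent-scale quality values.
#' @return Numeric quality score.
#' @export
#' @examples
#' quality_score(90, 5) # 65
quality_score <- function(completeness_pct, contamination_pct) {
  completeness_pct - 5 * contamination_pct
}

# Side-chain heavy-atom counts for the 20 canonical amino acids: the
# residue's structural formula minus the glycine backbone. E.g. lysine
# (C6H14N2O2) minus the C2/N1/O2 backbone leaves 4 C and 1 N.
aa_side_chain_table <- function() {
  tibble::tribble(
    ~aa, ~side_c, ~side_n,
    "G", 0L, 0L,
    "A", 1L, 0L,
    "S", 1L, 0L,
    "C", 1L, 0L,
    "T", 2L, 0L,
    "V", 3L, 0L,
    "P", 3L, 0L,
    "M", 3L, 0L,
    "L", 4L, 0L,
    "I", 4L, 0L,
    "F", 7L, 0L,
    "Y", 7L, 0L,
    "W", 9L, 1L,
    "D", 2L, 0L,
    "E", 3L, 0L,
    "N", 2L, 1L,
    "Q", 3L, 1L,
    "K", 4L, 1L,
    "R", 4L, 3L,
    "H", 4L, 2L
  )
}

#' Proteome side-chain stoichiometry (C-ARSC and N-ARSC)
#'
#' Average number of carbon and nitrogen atoms per amino-acid residue side
#' chain across a set of protein sequences, residue-weighted. Residues
#' outside the 20 canonical amino acids (including selenocysteine,
#' pyrrolysine, ambiguity codes and stop characters) are skipped with a
#' warning reporting how many were dropped.
#'
#' @param protein_sequences Character vector of one-letter protein
#'   sequences.
#' @return One-row tibble: `c_arsc`, `n_arsc`, `n_residues`, `n_skipped`.
#' @export
#' @examples
#' arsc_profile("KKKK") # c_arsc 4, n_arsc 1
arsc_profile <- function(protein_sequences) {
  protein_sequences <- protein_sequences[!is.na(protein_sequences)]
  if (length(protein_sequences) == 0 || sum(nchar(protein_sequences)) == 0) {
    abort_lkd("arsc_profile: no protein residues supplied")
  }
  res <- unlist(strsplit(toupper(protein_sequences), NULL), use.names = FALSE)
  tab <- aa_side_chain_table()
  idx <- match(res, tab$aa)
  n_skipped <- sum(is.na(idx))
  if (n_skipped > 0) {
    rlang::warn(sprintf(
      "arsc_profile: skipped %d non-canonical residue(s)", n_skipped
    ))
    idx <- idx[!is.na(idx)]
  }
  if (length(idx) == 0) abort_lkd("arsc_profile: no canonical residues supplied")
  tibble::tibble(
    c_arsc = sum(tab$side_c[idx]) / length(idx),
    n_arsc = sum(tab$side_n[idx]) / length(idx),
    n_residues = length(idx),
    n_skipped = n_skipped
  )
}

# Extract the coding-strand nucleotide sequence of one gene.
gene_sequence <- function(bundle, gene) {
  s <- substr(bundle$contigs[[gene$contig_id]], gene$start + 1L, gene$end)
  if (gene$strand < 0) reverse_complement(s) else s
}

#' Translate the non-partial genes of a genome bundle
#'
#' Minus-strand genes are reverse-complemented before translation; a
#' trailing stop is stripped. Codons containing N translate to `X`.
#'
#' @param bundle A [genome_bundle()].
#' @return Named character vector of protein sequences (one per
#'   non-partial gene).
#' @export
translate_genes <- function(bundle) {
  genes <- bundle$genes[!bundle$genes$partial, ]
  if (nrow(genes) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  nt <- vapply(
    seq_len(nrow(genes)),
    function(i) gene_sequence(bundle, genes[i, ]),
    character(1)
  )
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt),
    if.fuzzy.codon = "solve", no.init.codon = TRUE
  ))
  aa <- sub("\\*$", "", aa)
  stats::setNames(aa, genes$gene_id)
}

# Total length of the union of non-partial gene intervals per contig, so
# overlapping genes are not double-counted.
coding_bases <- function(genes) {
  if (nrow(genes) == 0) return(0L)
  sum(vapply(split(genes, genes$contig_id), function(g) {
    g <- g[order(g$start), ]
    tot <- 0L
    cur_s <- g$start[1]
    cur_e <- g$end[1]
    for (i in seq_len(nrow(g))[-1]) {
      if (g$start[i] <= cur_e) {
        cur_e <- max(cur_e, g$end[i])
      } else {
        tot <- tot + (cur_e - cur_s)
        cur_s <- g$start[i]
        cur_e <- g$end[i]
      }
    }
    tot + (cur_e - cur_s)
  }, numeric(1)))
}

#' Genome trait table row
#'
#' Computes the per-genome traits used for community-weighted comparisons:
#' estimated genome size, GC content (over called bases, N excluded),
#' coding density (union of non-partial gene intervals over assembled
#' size), C-/N-ARSC of the predicted proteome, quality score, and per-Mb
#' annotation densities (counts divided by estimated genome size in Mb).
#'
#' @param bundle A [genome_bundle()].
#' @param proteins Optional pre-computed protein sequences; defaults to
#'   [translate_genes()] of the bundle.
#' @return One-row tibble keyed by `otu_id`; annotation densities appear
#'   as `<category>_per_mb` columns.
#' @export
genome_traits <- function(bundle, proteins = NULL) {
  seq_all <- paste(bundle$contigs, collapse = "")
  base_counts <- vapply(
    c("A", "C", "G", "T"),
    function(b) sum(stringr::str_count(seq_all, stringr::fixed(b))),
    numeric(1)
  )
  gc_content <- sum(base_counts[c("G", "C")]) / sum(base_counts)
  est_size <- estimated_genome_size(
    bundle$assembled_size_bp, bundle$completeness_frac, bundle$contamination_frac
  )
  if (is.null(proteins)) proteins <- translate_genes(bundle)
  arsc <- if (length(proteins) > 0 && sum(nchar(proteins)) > 0) {
    arsc_profile(proteins)
  } else {
    tibble::tibble(c_arsc = NA_real_, n_arsc = NA_real_)
  }
  out <- tibble::tibble(
    otu_id = bundle$otu_id,
    assembled_size_bp = bundle$assembled_size_bp,
    estimated_genome_size_bp = est_size,
    gc_content = gc_content,
    coding_density = coding_bases(bundle$genes[!bundle$genes$partial, ]) /
      bundle$assembled_size_bp,
    c_arsc = arsc$c_arsc,
    n_arsc = arsc$n_arsc,
    quality_score = quality_score(
      100 * bundle$completeness_frac, 100 * bundle$contamination_frac
    )
  )
  for (cat in names(bundle$annotation_counts)) {
    out[[paste0(tolower(cat), "_per_mb")]] <-
      bundle$annotation_counts[[cat]] / (est_size / 1e6)
  }
  out
}

#' Trait table for a set of genome bundles
#'
#' @param bundles List of [genome_bundle()] objects.
#' @return Tibble with one row per OTU, as in [genome_traits()].
#' @export
trait_table <- function(bundles) {
  purrr::map_dfr(bundles, genome_traits)
}
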