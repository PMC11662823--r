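# Codon machinery: single-nucleotide mutant translations and per-site
# synonymous/nonsynonymous mutational opportunities under the standard
# genetic code.

.lkd_cache <- new.env(parent = emptyenv())

lkd_bases <- c("A", "C", "G", "T")

lkd_complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' The standard genetic code as a tibble
#'
#' @return A tibble with columns `codon` (DNA alphabet) and `aa`
#'   (one-letter amino acid, `*` for stop).
#' @export
genetic_code_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  tibble::tibble(codon = names(gc), aa = unname(gc))
}

# 64 x 3 x 4 array: amino acid obtained from codon i after substituting
# base b at codon position p (1-based). arr[codon, pos, ref_base] returns
# the codon's own amino acid.
mutant_aa_array <- function() {
  if (!is.null(.lkd_cache$mut_aa)) {
    return(.lkd_cache$mut_aa)
  }
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  arr <- array(
    NA_character_,
    dim = c(64L, 3L, 4L),
    dimnames = list(codons, NULL, lkd_bases)
  )
  for (p in 1:3) {
    for (b in lkd_bases) {
      mut <- codons
      substr(mut, p, p) <- b
      arr[, p, b] <- unname(gc[mut])
    }
  }
  .lkd_cache$mut_aa <- arr
  arr
}

#' Per-codon-position mutational opportunities
#'
#' For every sense codon and codon position, enumerates the three possible
#' single-nucleotide changes and reports the fraction that are synonymous
#' (`syn_opportunity`), the complementary nonsynonymous fraction
#' (stop-introducing changes count as nonsynonymous, Nei--Gojobori style),
#' and whether the position is fourfold degenerate (all three alternative
#' bases encode the reference amino acid; only possible at codon position
#' 3). Stop codons are excluded: they carry no protein-level opportunity.
#'
#' @return A tibble with one row per (sense codon, codon position):
#'   `codon`, `aa`, `codon_pos` (0-based, 0..2), `ref_base`,
#'   `syn_opportunity`, `nonsyn_opportunity`, `fourfold`.
#' @export
codon_opportunity_table <- function() {
  if (!is.null(.lkd_cache$opp_tbl)) {
    return(.lkd_cache$opp_tbl)
  }
  arr <- mutant_aa_array()
  code <- genetic_code_table()
  sense <- code$codon[code$aa != "*"]
  rows <- purrr::map_dfr(0:2, function(pos) {
    ref_base <- substr(sense, pos + 1L, pos + 1L)
    aa <- code$aa[match(sense, code$codon)]
    n_syn <- vapply(seq_along(sense), function(i) {
      alts <- setdiff(lkd_bases, ref_base[i])
      sum(arr[sense[i], pos + 1L, alts] == aa[i])
    }, integer(1))
    tibble::tibble(
      codon = sense,
      aa = aa,
      codon_pos = pos,
      ref_base = ref_base,
      syn_opportunity = n_syn / 3,
      nonsyn_opportunity = 1 - n_syn / 3,
      fourfold = pos == 2L & n_syn == 3L
    )
  })
  rows <- dplyr::arrange(rows, .data$codon, .data$codon_pos)
  .lkd_cache$opp_tbl <- rows
  rows
}

#' Classify single-nucleotide substitutions as synonymous or nonsynonymous
#'
#' Vectorized over sites. Bases are given on the genome (plus) strand; for
#' genes on the minus strand they are complemented before codon lookup.
#'
#' @param codon Reference codon (coding-strand orientation), character.
#' @param codon_pos 0-based position within the codon (0, 1 or 2).
#' @param strand +1 or -1, orientation of the gene on the genome.
#' @param from_base,to_base Genome-strand bases of the substitution.
#' @return Character vector, `"synonymous"` or `"nonsynonymous"`.
#' @export
classify_substitution <- function(codon, codon_pos, strand, from_base, to_base) {
  arr <- mutant_aa_array()
  from_cod <- ifelse(strand < 0, lkd_complement[from_base], from_base)
  to_cod <- ifelse(strand < 0, lkd_complement[to_base], to_base)
  ci <- match(codon, dimnames(arr)[[1]])
  pi_ <- as.integer(codon_pos) + 1L
  bi_from <- match(from_cod, lkd_bases)
  bi_to <- match(to_cod, lkd_bases)
  aa_from <- arr[cbind(ci, pi_, bi_from)]
  aa_to <- arr[cbind(ci, pi_, bi_to)]
  ifelse(aa_from == aa_to, "synonymous", "nonsynonymous")
}

reverse_complement <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(
    strsplit(x, NULL),
    function(s) paste(rev(s), collapse = ""),
    character(1)
  ))
}
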