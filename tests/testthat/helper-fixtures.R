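# Small hand-built fixtures shared across test files.

# A 60-bp contig with one forward gene (4 codons + stop) and one reverse
# gene (4 codons + stop), separated so they never overlap.
#   fwd gene: ATG GCT AAA GGG TAA   at [0, 15)
#   rev gene: ATG CGT CTT TTC TGA   at [30, 45) on the minus strand
tiny_bundle <- function() {
  fwd <- "ATGGCTAAAGGGTAA"
  rev_cds <- "ATGCGTCTTTTCTGA"
  filler1 <- strrep("ACGTA", 3) # 15 nt
  filler2 <- strrep("TTGCA", 3) # 15 nt
  seq <- paste0(fwd, filler1, lakemicrodiv:::reverse_complement(rev_cds), filler2)
  genome_bundle(
    otu_id = "toy",
    contigs = c(c1 = seq),
    genes = tibble::tibble(
      gene_id = c("gf", "gr"),
      contig_id = "c1",
      start = c(0L, 30L),
      end = c(15L, 45L),
      strand = c(1L, -1L)
    )
  )
}

# Pileup with a single site.
one_site_pileup <- function(a = 0, c = 0, g = 0, t = 0, pos = 0, contig = "c1") {
  tibble::tibble(contig = contig, pos = pos, A = a, C = c, G = g, T = t)
}

# Brute-force site classification oracle: for a coding-strand codon and
# position, translate all three mutants with seqinr and count synonymous
# changes. Independent of the package's lookup tables.
oracle_site <- function(codon, codon_pos) {
  bases <- c("A", "C", "G", "T")
  ref_base <- substr(codon, codon_pos + 1, codon_pos + 1)
  aa_ref <- seqinr::translate(strsplit(codon, NULL)[[1]])
  alts <- setdiff(bases, ref_base)
  aa_alt <- vapply(alts, function(b) {
    mut <- codon
    substr(mut, codon_pos + 1, codon_pos + 1) <- b
    seqinr::translate(strsplit(mut, NULL)[[1]])
  }, character(1))
  n_syn <- sum(aa_alt == aa_ref)
  list(
    syn_opportunity = n_syn / 3,
    fourfold = codon_pos == 2 && n_syn == 3,
    aa = aa_ref
  )
}

# Deterministic small synthetic config for fast tests.
fast_config <- function(seed = 42, ...) {
  synthetic_config(
    seed = seed, n_otus = 4, genome_length_bp = 15000, n_genes = 35,
    n_samples_per_group = 4, reads_per_sample = 3e4, ...
  )
}
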