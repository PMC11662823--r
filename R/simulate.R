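# Synthetic metagenome generator with known ground truth: genomes with
# clean ORFs, log-normal communities with group effects, within-species
# allele frequencies with a selection knob, binomial read sampling, and
# random trees. Every downstream estimator has a recovery test against
# the recorded truth.

#' Default universal single-copy KO list
#'
#' Placeholder identifiers for the 27 universal single-copy KOs used to
#' normalize KO profiles. The shipped list is synthetic (see
#' `inst/extdata/uscg_default_synthetic.tsv`); supply the real KO list
#' when analyzing real annotation tables.
#'
#' @return Character vector of 27 KO ids.
#' @export
default_uscg <- function() {
  path <- system.file("extdata", "uscg_default_synthetic.tsv",
                      package = "lakemicrodiv")
  readr::read_tsv(path, show_col_types = FALSE, comment = "#")$ko_id
}

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale but realistic lake-community design:
#' moderately sized genomes, three salinity groups of 20 samples,
#' log-normal abundances, bacterial-range nucleotide diversity and
#' 100x read depth.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_otus Number of OTUs (>= 2).
#' @param genome_length_bp Genome length per OTU.
#' @param gc_target Target GC content in (0, 1).
#' @param n_genes ORFs per genome (>= 28; 27 genes carry the USCG KOs).
#' @param n_samples_per_group Samples per salinity group.
#' @param abundance_sigma Log-normal sigma of true abundances.
#' @param ko_catalog_size Number of non-USCG KOs in the catalog.
#' @param uscg_list The 27 universal single-copy KO ids.
#' @param group_effects Named list `group -> named numeric vector` of
#'   multiplicative abundance effects. Keys of the inner vector may name
#'   OTUs directly or KO ids (resolved to all carrier OTUs).
#' @param pi_target Expected mean per-site heterozygosity in `[0, 0.5]`.
#' @param nonsyn_acceptance Probability that a candidate nonsynonymous
#'   mutation is retained (synonymous mutations always are); scalar, or a
#'   named vector per group for group-contrast designs.
#' @param depth_mean Mean per-site read depth of simulated pileups.
#' @param breadth_target Fraction of genome sites receiving coverage.
#' @param reads_per_sample Total recruited reads per sample.
#' @param read_length_bp Nominal read length used to convert read counts
#'   to per-site depth.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_otus = 8L,
                             genome_length_bp = 30000L,
                             gc_target = 0.5,
                             n_genes = 60L,
                             n_samples_per_group = 20L,
                             abundance_sigma = 1,
                             ko_catalog_size = 100L,
                             uscg_list = default_uscg(),
                             group_effects = list(),
                             pi_target = 0.005,
                             nonsyn_acceptance = 1,
                             depth_mean = 100,
                             breadth_target = 1,
                             reads_per_sample = 2e5,
                             read_length_bp = 150L) {
  stopifnot(
    n_otus >= 2, genome_length_bp > 0, n_genes >= 28,
    gc_target > 0, gc_target < 1,
    n_samples_per_group >= 1, abundance_sigma >= 0,
    pi_target >= 0, pi_target <= 0.5,
    all(nonsyn_acceptance >= 0), all(nonsyn_acceptance <= 1),
    breadth_target > 0, breadth_target <= 1,
    reads_per_sample > 0, read_length_bp > 0
  )
  if (depth_mean <= 0) abort_lkd("depth_mean must be > 0")
  if (length(uscg_list) != 27) {
    rlang::warn(sprintf(
      "uscg_list has %d entries (the usual universal single-copy set has 27)",
      length(uscg_list)
    ))
  }
  if (n_genes * 300 > genome_length_bp) {
    abort_lkd("infeasible packing: n_genes * 300 exceeds genome_length_bp")
  }
  structure(
    list(
      seed = as.integer(seed), n_otus = as.integer(n_otus),
      genome_length_bp = as.integer(genome_length_bp), gc_target = gc_target,
      n_genes = as.integer(n_genes),
      n_samples_per_group = as.integer(n_samples_per_group),
      abundance_sigma = abundance_sigma,
      ko_catalog_size = as.integer(ko_catalog_size),
      uscg_list = uscg_list, group_effects = group_effects,
      pi_target = pi_target, nonsyn_acceptance = nonsyn_acceptance,
      depth_mean = depth_mean, breadth_target = breadth_target,
      reads_per_sample = reads_per_sample,
      read_length_bp = as.integer(read_length_bp)
    ),
    class = "synthetic_config"
  )
}

# Sense (or stop) codons sampled with a GC tilt w^gc so the expected codon
# GC fraction hits the target; solved by uniroot on log(w).
tilted_codon_probs <- function(codons, gc_target) {
  gc_n <- stringr::str_count(codons, "[GC]")
  f <- function(logw) {
    p <- exp(logw * gc_n)
    p <- p / sum(p)
    sum(p * gc_n) / 3 - gc_target
  }
  lo <- f(-25); hi <- f(25)
  if (lo > 0 || hi < 0) abort_lkd("gc_target %.2f not achievable with codons", gc_target)
  logw <- stats::uniroot(f, c(-25, 25), tol = 1e-10)$root
  p <- exp(logw * gc_n)
  p / sum(p)
}

#' Simulate one genome bundle
#'
#' Generates a single-contig genome of the configured length containing
#' `n_genes` non-overlapping complete ORFs (ATG start, terminal stop, no
#' internal stops, length >= 300 and divisible by 3) on random strands,
#' with realized GC within ~2% of the target. Each of the 27 USCG KOs is
#' assigned to exactly one gene; other genes carry 0-3 catalog KOs. A
#' random ~5% of genes are tagged as CAZY for annotation-density traits.
#'
#' @param config A [synthetic_config()].
#' @param otu_index Index used to label the OTU (`otu_###`).
#' @param seed Seed; defaults to `config$seed + otu_index`.
#' @return List with elements `bundle` ([genome_bundle()]) and `truth`
#'   (realized GC, gene table, KO carriage).
#' @export
simulate_genome <- function(config, otu_index = 1L,
                            seed = config$seed + otu_index) {
  with_seed_opt(seed, {
    L <- config$genome_length_bp
    n_genes <- config$n_genes
    otu_id <- otu_label(otu_index)
    contig_id <- paste0(otu_id, "_c1")

    gene_len <- 300L + 3L * stats::rpois(n_genes, 15)
    if (sum(gene_len) > L) gene_len <- rep(300L, n_genes)
    if (sum(gene_len) > L) abort_lkd("infeasible packing of %d genes into %d bp", n_genes, L)

    code <- genetic_code_table()
    sense <- code$codon[code$aa != "*"]
    stops <- code$codon[code$aa == "*"]
    p_sense <- tilted_codon_probs(sense, config$gc_target)

    orf <- vapply(gene_len, function(len) {
      n_internal <- len %/% 3L - 2L
      paste0(
        "ATG",
        paste(sample(sense, n_internal, replace = TRUE, prob = p_sense),
              collapse = ""),
        sample(stops, 1)
      )
    }, character(1))

    spare <- L - sum(gene_len)
    gaps <- as.vector(stats::rmultinom(1, spare, rep(1, n_genes + 1L)))
    strand <- sample(c(1L, -1L), n_genes, replace = TRUE)
    starts <- integer(n_genes)
    pieces <- character(2L * n_genes + 1L)
    cursor <- 0L
    gc_ig <- config$gc_target
    for (i in seq_len(n_genes)) {
      ig <- paste(sample(
        lkd_bases, gaps[i], replace = TRUE,
        prob = c((1 - gc_ig) / 2, gc_ig / 2, gc_ig / 2, (1 - gc_ig) / 2)
      ), collapse = "")
      pieces[2L * i - 1L] <- ig
      cursor <- cursor + gaps[i]
      starts[i] <- cursor
      pieces[2L * i] <- if (strand[i] > 0) orf[i] else reverse_complement(orf[i])
      cursor <- cursor + gene_len[i]
    }
    pieces[2L * n_genes + 1L] <- paste(sample(
      lkd_bases, gaps[n_genes + 1L], replace = TRUE,
      prob = c((1 - gc_ig) / 2, gc_ig / 2, gc_ig / 2, (1 - gc_ig) / 2)
    ), collapse = "")
    genome <- paste(pieces, collapse = "")

    genes <- tibble::tibble(
      gene_id = sprintf("%s_g%04d", otu_id, seq_len(n_genes)),
      contig_id = contig_id,
      start = starts,
      end = starts + gene_len,
      strand = strand
    )

    uscg_genes <- sample(genes$gene_id, 27L)
    catalog <- sprintf("Ksyn%05d", seq_len(config$ko_catalog_size))
    other <- setdiff(genes$gene_id, uscg_genes)
    n_ko <- sample(0:3, length(other), replace = TRUE,
                   prob = c(0.35, 0.45, 0.15, 0.05))
    ko <- dplyr::bind_rows(
      tibble::tibble(gene_id = uscg_genes, ko_id = config$uscg_list),
      tibble::tibble(
        gene_id = rep(other, n_ko),
        ko_id = sample(catalog, sum(n_ko), replace = TRUE)
      )
    )
    n_cazy <- stats::rbinom(1, n_genes, 0.05)

    bundle <- genome_bundle(
      otu_id = otu_id,
      contigs = stats::setNames(genome, contig_id),
      genes = genes,
      ko_annotations = ko,
      completeness = 1, contamination = 0,
      annotation_counts = c(CAZY = n_cazy)
    )
    gc_real <- {
      b <- table(factor(strsplit(genome, NULL)[[1]], levels = lkd_bases))
      unname((b["G"] + b["C"]) / sum(b))
    }
    list(
      bundle = bundle,
      truth = list(otu_id = otu_id, gc_realized = gc_real, genes = genes)
    )
  })
}

resolve_group_effects <- function(config, otu_ids, ko_carriers = NULL) {
  groups <- c("freshwater", "brackish", "saline")
  eff <- matrix(1, length(otu_ids), length(groups),
                dimnames = list(otu_ids, groups))
  for (g in names(config$group_effects)) {
    if (!g %in% groups) abort_lkd("unknown group '%s' in group_effects", g)
    v <- config$group_effects[[g]]
    for (key in names(v)) {
      targets <- if (key %in% otu_ids) {
        key
      } else if (!is.null(ko_carriers) && key %in% names(ko_carriers)) {
        intersect(ko_carriers[[key]], otu_ids)
      } else {
        abort_lkd("group_effects key '%s' matches no OTU or KO", key)
      }
      eff[targets, g] <- eff[targets, g] * v[[key]]
    }
  }
  eff
}

#' Simulate a community: metadata, true abundances and read counts
#'
#' Per sample, true abundances are drawn log-normal(0, sigma), multiplied
#' by any group effects, and renormalized to sum to 1. Read counts are a
#' multinomial draw with expected count proportional to abundance times
#' genome length.
#'
#' @param config A [synthetic_config()].
#' @param genome_lengths Named vector of genome lengths per OTU.
#' @param ko_carriers Optional named list `ko_id -> carrier OTU ids`, used
#'   to resolve KO-keyed group effects.
#' @param seed Seed; defaults to `config$seed`.
#' @return List: `metadata` (sample_id, group, salinity), `abundance`
#'   (long tibble otu_id/sample_id/rel_abund, true values), `counts`
#'   (long tibble otu_id/sample_id/count).
#' @export
simulate_community <- function(config, genome_lengths, ko_carriers = NULL,
                               seed = config$seed) {
  with_seed_opt(seed, {
    otu_ids <- names(genome_lengths)
    groups <- c("freshwater", "brackish", "saline")
    n_g <- config$n_samples_per_group
    metadata <- tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(3L * n_g)),
      group = rep(groups, each = n_g),
      salinity = c(
        stats::runif(n_g, 0.01, 0.09),
        stats::runif(n_g, 0.15, 3.4),
        stats::runif(n_g, 3.6, 30)
      )
    )
    eff <- resolve_group_effects(config, otu_ids, ko_carriers)
    n_s <- nrow(metadata)
    ab <- matrix(0, length(otu_ids), n_s, dimnames = list(otu_ids, metadata$sample_id))
    cn <- ab
    for (j in seq_len(n_s)) {
      a <- stats::rlnorm(length(otu_ids), 0, config$abundance_sigma) *
        eff[, metadata$group[j]]
      a <- a / sum(a)
      ab[, j] <- a
      cn[, j] <- stats::rmultinom(1, config$reads_per_sample,
                                  a * genome_lengths)
    }
    list(
      metadata = metadata,
      abundance = tibble::as_tibble(ab, rownames = "otu_id") |>
        tidyr::pivot_longer(-"otu_id", names_to = "sample_id",
                            values_to = "rel_abund"),
      counts = tibble::as_tibble(cn, rownames = "otu_id") |>
        tidyr::pivot_longer(-"otu_id", names_to = "sample_id",
                            values_to = "count")
    )
  })
}

#' Simulate a pileup with tunable diversity and selection
#'
#' A fraction of genome sites is made biallelic so that the expected mean
#' per-site heterozygosity over all sites equals `pi_target`; minor-allele
#' frequencies are uniform on (0.05, 0.5). Candidate mutations receive a
#' uniformly random alternative base; candidates at coding sites are
#' classified through the genetic code and nonsynonymous candidates are
#' retained with probability `nonsyn_acceptance` (synonymous and
#' intergenic candidates always are) -- uniform placement plus this
#' opportunity-symmetric filter makes the neutral expectation of
#' opportunity-normalized pN/pS exactly 1. Read depth is Poisson per site;
#' a `1 - breadth_target` fraction of sites receives zero depth; allele
#' counts are binomial in depth and allele frequency.
#'
#' @param bundle A [genome_bundle()].
#' @param mask Site mask; built from the bundle when `NULL`.
#' @param pi_target Expected mean per-site heterozygosity (<= 0.5,
#'   biallelic model).
#' @param nonsyn_acceptance Retention probability for nonsynonymous
#'   candidates.
#' @param depth_mean Mean Poisson depth (> 0).
#' @param breadth_target Fraction of sites covered.
#' @param seed Seed.
#' @return List: `pileup` (tibble), `truth` (polymorphic-site table and
#'   scalars `pi_expected` -- the realized mean 2p(1-p) over all sites --
#'   and `nonsyn_acceptance`).
#' @export
simulate_pileup <- function(bundle, mask = NULL, pi_target = 0.005,
                            nonsyn_acceptance = 1, depth_mean = 100,
                            breadth_target = 1, seed = NULL) {
  if (depth_mean <= 0) abort_lkd("depth_mean must be > 0")
  if (pi_target > 0.5) abort_lkd("pi_target must be <= 0.5 (biallelic model)")
  if (is.null(mask)) mask <- build_site_mask(bundle)
  with_seed_opt(seed, {
    contig_ids <- names(bundle$contigs)
    clen <- nchar(bundle$contigs)
    site_contig <- rep(contig_ids, clen)
    site_pos <- unlist(lapply(clen, function(n) 0:(n - 1L)), use.names = FALSE)
    n_sites <- length(site_pos)
    ref <- unlist(strsplit(as.character(bundle$contigs), NULL), use.names = FALSE)

    # mean heterozygosity of a polymorphic site under p ~ U(0.05, 0.5)
    a <- 0.05; b <- 0.5
    mean_p <- (a + b) / 2
    mean_p2 <- (b - a)^2 / 12 + mean_p^2
    het_mean <- 2 * (mean_p - mean_p2)
    m <- round(pi_target / het_mean * n_sites)
    if (m > n_sites) abort_lkd("pi_target too large for genome size")

    cand <- sort(sample.int(n_sites, m))
    cand_ref <- ref[cand]
    alt <- vapply(cand_ref, function(r) sample(setdiff(lkd_bases, r), 1),
                  character(1), USE.NAMES = FALSE)
    usable <- cand_ref %in% lkd_bases
    cand <- cand[usable]; cand_ref <- cand_ref[usable]; alt <- alt[usable]

    mask_key <- paste(mask$contig, mask$pos)
    mi <- match(paste(site_contig[cand], site_pos[cand]), mask_key)
    coding <- !is.na(mi)
    klass <- rep("intergenic", length(cand))
    if (any(coding)) {
      klass[coding] <- classify_substitution(
        mask$codon[mi[coding]], mask$codon_pos[mi[coding]],
        mask$strand[mi[coding]], cand_ref[coding], alt[coding]
      )
    }
    keep <- klass != "nonsynonymous" |
      stats::runif(length(cand)) < nonsyn_acceptance
    cand <- cand[keep]; cand_ref <- cand_ref[keep]
    alt <- alt[keep]; klass <- klass[keep]

    p_minor <- stats::runif(length(cand), a, b)
    truth_sites <- tibble::tibble(
      contig = site_contig[cand], pos = site_pos[cand],
      ref_base = cand_ref, alt_base = alt,
      minor_freq = p_minor, klass = klass
    )

    n_uncov <- round((1 - breadth_target) * n_sites)
    covered <- rep(TRUE, n_sites)
    if (n_uncov > 0) covered[sample.int(n_sites, n_uncov)] <- FALSE
    depth <- stats::rpois(n_sites, depth_mean) * covered

    cnt <- matrix(0L, n_sites, 4L, dimnames = list(NULL, lkd_bases))
    ref_idx <- match(ref, lkd_bases)
    ok <- !is.na(ref_idx) & depth > 0
    cnt[cbind(which(ok), ref_idx[ok])] <- depth[ok]
    if (length(cand) > 0) {
      alt_n <- stats::rbinom(length(cand), depth[cand], p_minor)
      ai <- match(alt, lkd_bases)
      ri <- ref_idx[cand]
      cnt[cbind(cand, ri)] <- depth[cand] - alt_n
      cnt[cbind(cand, ai)] <- alt_n
    }
    keep_rows <- depth > 0
    pileup <- tibble::tibble(
      contig = site_contig[keep_rows],
      pos = site_pos[keep_rows],
      A = cnt[keep_rows, "A"], C = cnt[keep_rows, "C"],
      G = cnt[keep_rows, "G"], T = cnt[keep_rows, "T"]
    )
    list(
      pileup = pileup,
      truth = list(
        sites = truth_sites,
        pi_expected = sum(2 * p_minor * (1 - p_minor)) / n_sites,
        nonsyn_acceptance = nonsyn_acceptance,
        breadth_target = breadth_target
      )
    )
  })
}

#' Simulate a random ultrametric tree
#'
#' Birth-death tree with tips labeled like the simulated OTUs
#' (`otu_001` ...).
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Seed.
#' @param birth,death Birth-death rates.
#' @return An ape `phylo` tree with positive branch lengths.
#' @export
simulate_tree <- function(n_tips, seed = NULL, birth = 1, death = 0.2) {
  stopifnot(n_tips >= 2)
  with_seed_opt(seed, {
    tree <- ape::rphylo(n_tips, birth = birth, death = death)
    tree$tip.label <- otu_label(seq_len(n_tips))
    tree$edge.length <- pmax(tree$edge.length, 1e-8)
    tree
  })
}

#' Simulate a full dataset with ground truth
#'
#' Orchestrates genomes, tree, community and pileups. Per-site pileups
#' are the expensive artifact, so they are generated only for the OTUs in
#' `pileup_otus` (default: the first two); per-(OTU, sample) depth scales
#' with the sample's read count for that OTU. `nonsyn_acceptance` may be
#' a named per-group vector to plant a selection contrast.
#'
#' @param config A [synthetic_config()].
#' @param pileup_otus OTU ids to generate pileups for.
#' @param seed Master seed; defaults to `config$seed`.
#' @return List: `config`, `bundles`, `masks`, `tree`, `metadata`,
#'   `abundance`, `counts`, `pileups` (named `otu_id|sample_id` list of
#'   pileup tibbles), `truth`.
#' @export
simulate_dataset <- function(config, pileup_otus = NULL, seed = config$seed) {
  sims <- purrr::map(
    seq_len(config$n_otus),
    function(i) simulate_genome(config, i, seed = seed + i)
  )
  bundles <- purrr::map(sims, "bundle")
  names(bundles) <- purrr::map_chr(bundles, "otu_id")
  masks <- purrr::map(bundles, build_site_mask)
  glen <- purrr::map_dbl(bundles, "assembled_size_bp")
  ko_carriers <- dplyr::bind_rows(
    purrr::map(bundles, ~ dplyr::mutate(.x$ko_annotations, otu_id = .x$otu_id))
  ) |>
    dplyr::distinct(.data$ko_id, .data$otu_id) |>
    (\(d) split(d$otu_id, d$ko_id))()
  comm <- simulate_community(config, glen, ko_carriers, seed = seed + 10000L)
  tree <- simulate_tree(config$n_otus, seed = seed + 20000L)

  if (is.null(pileup_otus)) {
    pileup_otus <- names(bundles)[seq_len(min(2L, length(bundles)))]
  }
  counts_w <- long_to_matrix(comm$counts, "sample_id", "otu_id", "count")
  acc <- config$nonsyn_acceptance
  pileups <- list()
  truth_pileups <- list()
  k <- 0L
  for (otu in pileup_otus) {
    for (s in comm$metadata$sample_id) {
      k <- k + 1L
      depth_os <- counts_w[s, otu] * config$read_length_bp / glen[[otu]]
      if (depth_os < 1) next
      grp <- comm$metadata$group[comm$metadata$sample_id == s]
      acc_os <- if (length(acc) > 1) acc[[grp]] else acc
      sim <- simulate_pileup(
        bundles[[otu]], masks[[otu]],
        pi_target = config$pi_target, nonsyn_acceptance = acc_os,
        depth_mean = depth_os, breadth_target = config$breadth_target,
        seed = seed + 30000L + k
      )
      key <- paste(otu, s, sep = "|")
      pileups[[key]] <- sim$pileup
      truth_pileups[[key]] <- sim$truth
    }
  }
  list(
    config = config,
    bundles = bundles,
    masks = masks,
    tree = tree,
    metadata = comm$metadata,
    abundance = comm$abundance,
    counts = comm$counts,
    pileups = pileups,
    truth = list(
      abundance = comm$abundance,
      genomes = purrr::map(sims, "truth"),
      pileups = truth_pileups
    )
  )
}
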