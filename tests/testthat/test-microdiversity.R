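# Site masks, SNV calling, nucleotide diversity and pN/pS.

test_that("site mask matches the brute-force codon oracle on both strands", {
  b <- tiny_bundle()
  mask <- build_site_mask(b)
  # 2 genes x (5 codons - 1 stop codon) x 3 positions
  expect_equal(nrow(mask), 24)
  for (i in seq_len(nrow(mask))) {
    o <- oracle_site(mask$codon[i], mask$codon_pos[i])
    expect_equal(mask$syn_opportunity[i], o$syn_opportunity,
                 info = paste("site", mask$pos[i]))
    expect_equal(mask$fourfold[i], o$fourfold, info = paste("site", mask$pos[i]))
    expect_equal(mask$aa[i], o$aa)
  }
  # genome-strand ref base agrees with the actual contig sequence
  expect_equal(
    mask$ref_base,
    substring(b$contigs[["c1"]], mask$pos + 1, mask$pos + 1)
  )
})

test_that("per-codon opportunities sum to 3 and GCT behaves as expected", {
  opp <- codon_opportunity_table()
  sums <- opp |>
    dplyr::group_by(codon) |>
    dplyr::summarise(
      s = sum(syn_opportunity) + sum(nonsyn_opportunity), n = dplyr::n()
    )
  expect_true(all(sums$n == 3))
  expect_true(all(abs(sums$s - 3) < 1e-12))

  gct <- opp[opp$codon == "GCT", ]
  expect_equal(gct$syn_opportunity[gct$codon_pos == 2], 1)
  expect_true(gct$fourfold[gct$codon_pos == 2])
  expect_equal(gct$syn_opportunity[gct$codon_pos %in% c(0, 1)], c(0, 0))

  atg <- opp[opp$codon == "ATG", ]
  expect_true(all(atg$syn_opportunity == 0))
  expect_false(any(atg$fourfold))

  # fourfold implies full synonymous opportunity at the third position
  expect_true(all(opp$syn_opportunity[opp$fourfold] == 1))
  expect_true(all(opp$codon_pos[opp$fourfold] == 2))
})

test_that("internal stop codons in non-partial genes are an error", {
  seq <- paste0("ATG", "TAA", "AAA", "GGG", "TAA", strrep("A", 45))
  b <- genome_bundle(
    otu_id = "x", contigs = c(c1 = seq),
    genes = tibble::tibble(
      gene_id = "gstop", contig_id = "c1", start = 0L, end = 15L, strand = 1L
    )
  )
  expect_error(build_site_mask(b), "gstop")
})

test_that("overlapping-gene sites are excluded from the mask", {
  # g2 lies inside g1 in a shifted frame (TGG CTA AAG GGT, stop-free)
  seq <- paste0("ATGGCTAAAGGGTAA", strrep("ACGTG", 9))
  b <- genome_bundle(
    otu_id = "x", contigs = c(c1 = seq),
    genes = tibble::tibble(
      gene_id = c("g1", "g2"), contig_id = "c1",
      start = c(0L, 1L), end = c(15L, 13L), strand = 1L
    )
  )
  mask <- build_site_mask(b)
  expect_false(any(mask$pos %in% 1:11)) # doubly covered -> dropped
  expect_true(0 %in% mask$pos)          # unique to g1
  expect_true(12 %in% mask$pos)         # unique to g2 (g1's stop codon)
})

test_that("call_snvs applies depth, count and frequency thresholds", {
  b <- tiny_bundle()
  mask <- build_site_mask(b)

  # site 5 is the third position of codon GCT (fourfold): A<->C synonymous
  # fwd gene codon 2 = GCT at pos 3..5
  snv <- call_snvs(one_site_pileup(a = 0, c = 50, g = 0, t = 50, pos = 5),
                   mask, b)
  expect_equal(nrow(snv), 1)
  expect_equal(snv$klass, "synonymous")
  expect_true(snv$fourfold)
  expect_equal(snv$alt_freq, 0.5)

  # fails min_freq and min_count
  expect_equal(
    nrow(call_snvs(one_site_pileup(a = 99, c = 1, pos = 5), mask, b)), 0
  )
  # boundary: depth 6 >= 5, both alleles at count 3 >= 2, freq 0.5 >= 0.05
  expect_equal(
    nrow(call_snvs(one_site_pileup(a = 3, c = 3, pos = 5), mask, b)), 1
  )
  # below min_depth
  expect_equal(
    nrow(call_snvs(one_site_pileup(a = 2, c = 2, pos = 5), mask, b)), 0
  )
  # intergenic site
  ig <- call_snvs(one_site_pileup(a = 30, g = 30, pos = 20), mask, b)
  expect_equal(ig$klass, "intergenic")

  # nonsynonymous at codon position 1 of GCT (G->A changes Ala)
  ns <- call_snvs(one_site_pileup(a = 30, g = 30, pos = 3), mask, b)
  expect_equal(ns$klass, "nonsynonymous")

  # site outside genome coordinates errors when the bundle is supplied
  expect_error(
    call_snvs(one_site_pileup(a = 30, g = 30, pos = 500), mask, b),
    "outside genome"
  )
})

test_that("minus-strand classification uses complemented bases", {
  b <- tiny_bundle()
  mask <- build_site_mask(b)
  # gr codon 2 = CGT (Arg, fourfold at its third position). Its third
  # position in genome coordinates is end-1-5 = 39; genome base is the
  # complement of T.
  row <- mask[mask$gene_id == "gr" & mask$codon == "CGT" & mask$codon_pos == 2, ]
  expect_equal(nrow(row), 1)
  expect_true(row$fourfold)
  snv <- call_snvs(
    one_site_pileup(a = 0, c = 25, g = 25, t = 0, pos = row$pos), mask, b
  )
  expect_equal(snv$klass, "synonymous")
})

test_that("per-site diversity matches the heterozygosity formula", {
  nd <- nucleotide_diversity(one_site_pileup(a = 5, c = 5))
  expect_equal(nd$pi, 0.5)
  expect_equal(nucleotide_diversity(one_site_pileup(a = 10))$pi, 0)
  expect_equal(
    nucleotide_diversity(one_site_pileup(25, 25, 25, 25))$pi, 0.75
  )
  # zero covered sites -> missing, not zero
  empty <- nucleotide_diversity(one_site_pileup(a = 2))
  expect_true(is.na(empty$pi))
  expect_equal(empty$covered_sites, 0L)
})

test_that("pi never decreases when a polymorphic site is added, and is
           invariant to base relabeling", {
  base <- tibble::tibble(
    contig = "c1", pos = 0:9, A = 20L, C = 0L, G = 0L, T = 0L
  )
  p0 <- nucleotide_diversity(base)$pi
  withr::with_seed(31, {
    for (k in 1:25) {
      extra <- tibble::tibble(
        contig = "c1", pos = 10L + k,
        A = sample(5:20, 1), C = sample(5:20, 1), G = 0L, T = 0L
      )
      p1 <- nucleotide_diversity(dplyr::bind_rows(base, extra))$pi
      expect_gte(p1, p0)
      # relabel bases A<->T, C<->G: pi unchanged
      relab <- dplyr::bind_rows(base, extra) |>
        dplyr::rename(A = "T", T = "A", C = "G", G = "C")
      expect_equal(nucleotide_diversity(relab)$pi, p1)
    }
  })
})

test_that("pn_ps follows the opportunity-normalized formula", {
  mask <- tibble::tibble(
    contig = "c1", pos = 0:299,
    syn_opportunity = rep(1 / 3, 300), nonsyn_opportunity = rep(2 / 3, 300),
    fourfold = FALSE
  )
  # covered opportunity: S = 100, N = 200 over 300 covered sites
  pileup <- tibble::tibble(
    contig = "c1", pos = 0:299, A = 10L, C = 0L, G = 0L, T = 0L
  )
  snvs <- tibble::tibble(
    klass = c(rep("nonsynonymous", 4), rep("synonymous", 2))
  )
  res <- pn_ps(snvs, mask, pileup)
  expect_equal(res$pn_ps, 1.0) # (4/200)/(2/100)
  expect_equal(res$s_opportunity, 100)
  expect_equal(res$n_opportunity, 200)

  res0 <- pn_ps(tibble::tibble(klass = "synonymous"), mask, pileup)
  expect_equal(res0$pn_ps, 0)

  und <- pn_ps(tibble::tibble(klass = "nonsynonymous"), mask, pileup)
  expect_true(is.na(und$pn_ps))
  expect_equal(und$reason, "no synonymous SNVs")
})

test_that("popgen_summary enforces QC and reflects selection in subsets", {
  cfg <- fast_config()
  b <- simulate_genome(cfg, 1)$bundle
  mask <- build_site_mask(b)

  # low breadth withholds statistics
  low <- simulate_pileup(b, mask, pi_target = 0.005, depth_mean = 30,
                         breadth_target = 0.3, seed = 8)
  s_low <- popgen_summary(low$pileup, b, mask, "s1")
  expect_false(s_low$qc_pass)
  expect_true(is.na(s_low$pi_all))

  # neutral full coverage: recovery close to target, qc passes
  neut <- simulate_pileup(b, mask, pi_target = 0.01, depth_mean = 60, seed = 9)
  s_n <- popgen_summary(neut$pileup, b, mask, "s1")
  expect_true(s_n$qc_pass)
  expect_lt(abs(s_n$pi_all - neut$truth$pi_expected) / neut$truth$pi_expected, 0.1)

  # strong purifying selection: fourfold diversity exceeds all-site diversity
  sel <- simulate_pileup(b, mask, pi_target = 0.01, depth_mean = 60,
                         nonsyn_acceptance = 0.1, seed = 10)
  s_s <- popgen_summary(sel$pileup, b, mask, "s1")
  expect_gt(s_s$pi_4fold, s_s$pi_all)
  expect_lt(s_s$pn_ps, 0.3)
})

test_that("all-site and fourfold diversity are tightly correlated across a
           panel of populations", {
  cfg <- fast_config()
  b <- simulate_genome(cfg, 1)$bundle
  mask <- build_site_mask(b)
  pis <- withr::with_seed(77, {
    targets <- stats::runif(50, 0.002, 0.03)
    purrr::map_dfr(seq_along(targets), function(i) {
      sp <- simulate_pileup(b, mask, pi_target = targets[i], depth_mean = 60,
                            seed = 500 + i)
      s <- popgen_summary(sp$pileup, b, mask, paste0("s", i))
      tibble::tibble(pi_all = s$pi_all, pi_4fold = s$pi_4fold)
    })
  })
  r2 <- stats::cor(pis$pi_all, pis$pi_4fold)^2
  expect_gt(r2, 0.9)
})
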