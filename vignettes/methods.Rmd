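---
title: "Models and methods behind lakemicrodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lakemicrodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakemicrodiv)
library(dplyr)
```

`lakemicrodiv` implements the quantitative core of a comparative
lake-microbiome analysis built on metagenome-assembled genomes (MAGs)
clustered into species-like OTUs: normalized functional profiles,
community-weighted genomic traits, within-species population-genetic
statistics from read pileups, phylogenetic-diversity accounting, and
permutation-based community statistics. This vignette explains each model,
its assumptions and tunable parameters, and the design decisions taken
where the methodology left genuine choices open.

## Abundance and functional profiles

Read-recruitment counts per OTU and sample become length-normalized rates
scaled to one million per sample (TPM): for OTU $i$,
$\mathrm{tpm}_i = 10^6 \, (c_i/\ell_i) / \sum_j (c_j/\ell_j)$, with
$c_i$ mapped reads and $\ell_i$ the genome length in bp. Relative
abundance is TPM / $10^6$.

The abundance of a KEGG ortholog (KO) $k$ in a sample is
$\sum_i \mathrm{tpm}_i \, m_{ki}$, where $m_{ki}$ is the copy number of
$k$ in genome $i$. Dividing by the mean abundance of 27 universal
single-copy KOs (USCGs) converts this to copies per genome equivalent:
a KO present exactly once in every genome has normalized abundance
exactly 1 in every sample, regardless of community composition — a
useful identity that the test suite asserts exactly. The USCG identity
list is a configuration input; the file shipped as the default contains
synthetic placeholder ids (documented in the file header) and real
analyses must supply the real list.

Community-weighted mean traits are plain abundance-weighted averages of
per-genome traits, so they are always bounded by the trait's range over
the OTUs present.

Group enrichment uses Welch's unequal-variance $t$-test per feature with
Welch–Satterthwaite degrees of freedom and Benjamini–Hochberg FDR across
features (threshold $q < 0.01$ by default). BH is the field-default FDR
procedure. Tests default to untransformed normalized values; a log
option (`log_transform`) is exposed because the choice is not canonical.
Degenerate inputs (zero variance in both groups with equal means) yield
$p = 1$, never NaN. Only two groups are compared at a time — the
freshwater/saline contrast by default, with brackish samples carried in
profiles but excluded from testing.

## Genome traits

* **Estimated genome size** divides the assembled size by the sum of
  completeness and contamination *as fractions*, the only scale on which
  the formula is an unbiasing correction (a perfect genome is returned
  unchanged). Percent inputs (CheckM-style tables) are auto-detected by
  any value above 1.5 and rescaled.
* **Quality score** is completeness $-$ 5 $\times$ contamination on the
  percent scale; 50 is the usual medium-quality floor.
* **GC content** is computed over called bases only (N excluded).
* **Coding density** uses the union of non-partial gene intervals over
  the *assembled* size; whether an estimated-size denominator was ever
  intended is unknowable from the method description, and the assembled
  size is the observable quantity.
* **C-ARSC / N-ARSC** count side-chain carbon and nitrogen atoms per
  residue across the predicted proteome, residue-weighted (not
  gene-weighted), using a lookup table derived from the amino acids'
  structural formulas (residue minus the glycine backbone). The table is
  cross-checked in the tests against an independent tabulation of
  molecular formulas. Selenocysteine, pyrrolysine and ambiguity codes
  are skipped with a warning count.

## Population genetics from pileups

All within-species statistics consume per-site base-count tables
(`contig`, 0-based `pos`, A/C/G/T depths), the canonical reduction of a
read alignment for a single species' population.

**Site mask.** For every coding position of every non-partial gene the
mask records the codon, codon position, and the fraction of the three
possible single-nucleotide changes that are synonymous
(`syn_opportunity`) versus nonsynonymous, computed by exhaustively
translating all mutants under the standard genetic code. Stop-introducing
changes count as nonsynonymous (Nei–Gojobori convention). A third codon
position is *fourfold degenerate* when all three alternatives encode the
reference amino acid; exactly 32 sense codons (8 families) qualify, and
the implementation is verified exactly against a brute-force oracle.
Stop codons and codons containing N carry no opportunity and are
excluded. Sites covered by more than one gene are ambiguous to classify
and are dropped from the mask (they still count for all-site diversity);
whether published fourfold analyses excluded such sites is typically
unstated, and exclusion avoids double-counting opportunities.

**SNV calling.** A site is an SNV when depth $\ge$ 5 and at least two
alleles each reach 2 reads and 5% frequency — the documented defaults of
the inStrain profiler, exposed as arguments. The consensus allele (most
frequent, ties broken toward the reference) is the "from" state;
multi-allelic sites are nonsynonymous if any qualifying alternative is.

**Nucleotide diversity.** Per-site $\pi = 1 - \sum_b p_b^2$ over
observed base frequencies; genome-wide $\pi$ is the mean over sites with
depth $\ge$ 5. No finite-depth correction is applied (matching the plain
profiler estimator); the estimator is biased downward by a factor
$(1 - 1/d)$ at depth $d$, about 1% at 100×.

**pN/pS.** The ratio of nonsynonymous to synonymous polymorphism rates,
each normalized by its mutational opportunity summed over *covered*
coding sites only, so low-breadth samples are not biased by
unobserved opportunity. It is undefined (reported NA with a reason)
when no synonymous SNV is observed.

**QC.** Per-(OTU, sample) summaries gate on breadth $\ge$ 0.5 and mean
depth $\ge$ 5; failing pairs are emitted with statistics withheld.

## Community statistics

Shannon entropy uses the natural log (the base is exposed nowhere else
in the pipeline, and nats are the ecology default); all-zero samples are
missing, not zero. Bray–Curtis runs on relative abundances via `vegan`,
so distances lie in $[0,1]$; Bray–Curtis is not metric and no triangle
inequality is assumed anywhere.

ANOSIM follows Clarke: $R = (\bar r_B - \bar r_W)/(M/2)$ with
$M = n(n-1)/2$ ranked distances, giving $R \in [-1, 1]$ and $R = 1$ for
perfect separation. Significance comes from label permutations.
Mantel and partial Mantel tests correlate off-diagonal distances
(Pearson by default; Spearman exposed since the published choice is
usually unstated), partialling out a control matrix via first-order
partial correlation, with significance from permuting one matrix's
sample order and a Bonferroni convenience wrapper across factor lists.
All permutation p-values use the add-one convention and can never fall
below $1/(n_{\mathrm{perm}}+1)$; all are seed-reproducible.

Faith PD of a tip set is the branch length of the minimal spanning
subtree (root path excluded); PD gain of added genomes is the extra
branch length as a fraction of the reference PD. For a single pendant
graft of length $b$ onto a reference subtree of PD $L$ the gain is
exactly $b/L$, a closed form the tests verify on random trees.

The assembly-process analysis follows the Stegen-style two-step null
framework. βMNTD is abundance-weighted; the null shuffles tip identities
among the taxa present in the two samples' joint pool ("taxa shuffle"),
and βNTI is the z-score of the observed βMNTD. RC-Bray assembles null
communities preserving each sample's richness and total abundance, with
species drawn by occupancy and individuals by regional relative
abundance, then rescales the rank of the observed Bray–Curtis to
$[-1,1]$. Pairs classify as heterogeneous/homogeneous selection when
$|\beta NTI| > 2$, else dispersal limitation ($RC > 0.95$), homogenizing
dispersal ($RC < -0.95$), or undominated — the conventional thresholds,
configurable. When a pair's pool is fully shared the null spread is
zero and βNTI is reported missing rather than forced to a class.

## The synthetic-data generator

The generator exists so that every downstream estimator has a recovery
test against known truth; it emulates the *statistical* structure of a
lake metagenome study at desk scale, not its biology.

* **Genomes**: single-contig sequences with non-overlapping complete
  ORFs (ATG start, terminal stop, no internal stops, length ≥ 300 and
  divisible by 3) on random strands. Codons are sampled from the 61
  sense codons with an exponential GC tilt solved numerically so the
  realized GC lands within ~2% of the target. Each of the 27 USCG KOs
  is assigned to exactly one gene; other genes carry 0–3 catalog KOs.
* **Communities**: per sample, abundances are log-normal(0, σ) with
  multiplicative group effects and renormalization; read counts are
  multinomial with expected count ∝ abundance × genome length. Because
  effects act before renormalization, a 2× boost realizes as slightly
  less than 2× in mean relative abundance; the tests compare against a
  Monte-Carlo oracle of the model rather than the nominal factor.
  Samples span three salinity groups with salinities drawn inside the
  conventional cutoffs (< 0.1%, 0.1–3.5%, > 3.5%).
* **Pileups**: a fraction of sites is made biallelic such that the
  expected mean per-site heterozygosity equals `pi_target`, with minor
  allele frequencies uniform on (0.05, 0.5). Candidate mutations get a
  uniformly random alternative base; nonsynonymous candidates are
  retained with probability `nonsyn_acceptance` (the selection knob),
  synonymous and intergenic candidates always. Uniform placement plus
  this opportunity-symmetric filter makes the neutral expectation of
  opportunity-normalized pN/pS exactly 1, and makes the knob directly
  recoverable: the calibration suite recovers acceptance 0.1 and 0.3
  within a few percent. Depth is Poisson per site, independent across
  sites and free of mapping bias, with a `breadth_target` fraction of
  sites covered. The model is biallelic-only and has no haplotype
  structure, linkage, recombination or sequencing error — passing
  recovery tests therefore demonstrates estimator correctness under the
  model, not robustness to real-data artifacts such as mapping bias,
  strain mixtures or error-driven false SNVs.

Defaults describe a desk-scale but realistic design: 8 OTUs, 30-kb
genomes, 20 samples per salinity group, log-normal σ = 1, π = 0.005
(bacterial range), 100× depth, full breadth. All randomness flows
through one seed; identical seeds reproduce byte-identical outputs.

**Problem sizes in the checks.** The calibration suites run at sizes
chosen to make Monte-Carlo noise small relative to the tolerances while
remaining quick to re-run: 100-kb genomes for π and pN/pS recovery
(several hundred synonymous SNVs per replicate), 20 seeds for the
neutral calibration, 500 replicates for the permutation-test null
rates, and 100 random trees for the PD closed form.

**The planted-effect design.** The end-to-end recovery run plants a 2×
saline abundance boost on one OTU (equivalently, on the KOs it alone
carries) and a saline selection contrast (nonsynonymous acceptance 0.3
versus 1.0 in freshwater) at 20 samples per group. The required power
(≥ 0.9 for flagging the boosted KO at q < 0.01) constrains the
between-sample abundance noise: an a-priori power computation showed
power 0.04 at σ = 1, 0.96 at σ = 0.35 and 1.0 at σ = 0.25, so this
design fixes σ = 0.25. The general default stays σ = 1, which is the
realistic regime; the planted-effect run is a calibration of the
inference machinery, not a claim about detectability in noisy field
data.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; 1-based inclusive gene
  tables are converted at the read boundary.
* Quality values are accepted as fractions or percents (auto-detected at
  1.5) and stored as fractions.
* Zero-recruitment samples yield zero TPM with a warning; a zero USCG
  mean is an error naming the sample (normalization is undefined).
* Permutation p-values never reach zero; βNTI with zero null spread and
  pN/pS without synonymous SNVs are missing values with reasons, not
  zeros.
* Ties in consensus-allele choice break toward the reference base.

## Known limitations

* The pipeline consumes pileup tables, not BAM alignments; mapping
  stringency and its biases live upstream.
* Recombination statistics (ρ/θ, r/m), strain haplotypes and linkage are
  out of scope, as are NMDS ordination and any variance-partitioning of
  ordination axes.
* The π estimator has the documented small-depth downward bias.
* Community functions hold distance matrices and abundance matrices
  densely in memory; the target scale is thousands of OTUs and hundreds
  of samples, not millions.
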