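# Community-level statistics: Shannon diversity, Bray-Curtis distances,
# ANOSIM, (partial) Mantel tests, Faith phylogenetic-diversity gain, and
# the betaNTI / Raup-Crick null-model framework with assembly-process
# classification.

#' Shannon diversity and Bray-Curtis distances
#'
#' Shannon entropy uses the natural log over nonzero relative abundances
#' (samples with zero total abundance are NA, not 0); Bray-Curtis is
#' computed on relative abundances, so values lie in `[0, 1]`.
#'
#' @param abundance Long tibble `otu_id`, `sample_id`, `rel_abund`.
#' @return List: `shannon` (tibble `sample_id`, `shannon`),
#'   `bray_curtis` (a `dist` over samples).
#' @export
diversity_metrics <- function(abundance) {
  m <- long_to_matrix(abundance, "sample_id", "otu_id", "rel_abund")
  tot <- rowSums(m)
  h <- vegan::diversity(m, index = "shannon")
  h[tot == 0] <- NA_real_
  rel <- m[tot > 0, , drop = FALSE] / tot[tot > 0]
  bc <- vegan::vegdist(rel, method = "bray")
  list(
    shannon = tibble::tibble(sample_id = rownames(m), shannon = unname(h)),
    bray_curtis = bc
  )
}

pair_index <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(2:n, function(k) k:n))
  cbind(j = j, i = i) # matches as.dist column-major order: (2,1),(3,1)...
}

anosim_r <- function(rk, within, div) {
  (mean(rk[!within]) - mean(rk[within])) / div
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based permutation test of between- versus within-group
#' distances: `R = (mean between rank - mean within rank) / (M/2)` with
#' `M = n(n-1)/2` pairwise distances, so `R` lies in `[-1, 1]`.
#' Significance is assessed by permuting group labels; p-values use the
#' add-one convention and are never below `1/(n_perm + 1)`.
#'
#' @param distance A `dist` or symmetric matrix over samples.
#' @param grouping Group label per sample (in `dist` order); every group
#'   needs >= 2 members.
#' @param n_perm Number of label permutations.
#' @param seed Seed for permutation reproducibility.
#' @return Object of class `lakemicrodiv_anosim` with elements
#'   `statistic`, `p_value`, `n_perm`, `perm_stats`.
#' @export
anosim_test <- function(distance, grouping, n_perm = 999, seed = NULL) {
  d <- stats::as.dist(distance)
  n <- attr(d, "Size")
  grouping <- as.character(grouping)
  if (length(grouping) != n) abort_lkd("grouping length must match distance size")
  if (length(unique(grouping)) < 2) abort_lkd("need >= 2 groups")
  if (any(table(grouping) < 2)) abort_lkd("every group needs >= 2 samples")
  rk <- rank(as.vector(d))
  idx <- pair_index(n)
  m_pairs <- length(rk)
  div <- m_pairs / 2
  obs <- anosim_r(rk, grouping[idx[, "i"]] == grouping[idx[, "j"]], div)
  perm_stats <- with_seed_opt(seed, {
    vapply(seq_len(n_perm), function(k) {
      g <- sample(grouping)
      anosim_r(rk, g[idx[, "i"]] == g[idx[, "j"]], div)
    }, numeric(1))
  })
  structure(
    list(
      statistic = obs,
      p_value = (1 + sum(perm_stats >= obs)) / (1 + n_perm),
      n_perm = n_perm,
      perm_stats = perm_stats,
      grouping = grouping
    ),
    class = "lakemicrodiv_anosim"
  )
}

#' @export
print.lakemicrodiv_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

partial_r <- function(a, b, cc) {
  if (is.null(cc)) return(stats::cor(a, b))
  rab <- stats::cor(a, b)
  rac <- stats::cor(a, cc)
  rbc <- stats::cor(b, cc)
  (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
}

#' Mantel and partial Mantel permutation tests
#'
#' Pearson (default) correlation between the off-diagonal entries of a
#' community distance matrix and a factor distance matrix, optionally
#' partialling out a control matrix (first-order partial correlation of
#' distances). Significance comes from permuting the rows/columns of the
#' community matrix; the p-value is one-sided (`r_perm >= r_obs`) with
#' the add-one convention.
#'
#' @param dist_community,dist_factor `dist` objects or symmetric
#'   matrices over the same samples.
#' @param dist_control Optional control distance matrix (partial test).
#' @param n_perm Number of permutations.
#' @param method Correlation method, `"pearson"` or `"spearman"`.
#' @param seed Seed.
#' @return Object of class `lakemicrodiv_mantel` with `statistic`,
#'   `p_value`, `n_perm`, `partial` flag.
#' @export
partial_mantel <- function(dist_community, dist_factor, dist_control = NULL,
                           n_perm = 1000, method = c("pearson", "spearman"),
                           seed = NULL) {
  method <- match.arg(method)
  dc <- as.matrix(stats::as.dist(dist_community))
  df_ <- as.matrix(stats::as.dist(dist_factor))
  if (!identical(dim(dc), dim(df_))) abort_lkd("distance matrices must be conformable")
  ctrl <- if (!is.null(dist_control)) as.matrix(stats::as.dist(dist_control))
  n <- nrow(dc)
  prep <- function(m) {
    v <- dist_to_vec(m)
    if (method == "spearman") rank(v) else v
  }
  a <- prep(dc); b <- prep(df_)
  cc <- if (!is.null(ctrl)) prep(ctrl)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort_lkd("constant distance matrix: correlation undefined")
  }
  obs <- partial_r(a, b, cc)
  perm_stats <- with_seed_opt(seed, {
    vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      partial_r(prep(dc[p, p]), b, cc)
    }, numeric(1))
  })
  structure(
    list(
      statistic = obs,
      p_value = (1 + sum(perm_stats >= obs)) / (1 + n_perm),
      n_perm = n_perm,
      partial = !is.null(dist_control),
      method = method,
      perm_stats = perm_stats
    ),
    class = "lakemicrodiv_mantel"
  )
}

#' @export
print.lakemicrodiv_mantel <- function(x, ...) {
  cat(sprintf("%s Mantel (%s): r = %.4f, p = %.4g (%d permutations)\n",
              if (x$partial) "Partial" else "Simple", x$method,
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Screen environmental factors with (partial) Mantel tests
#'
#' Runs [partial_mantel()] for each factor distance matrix and applies a
#' Bonferroni correction across factors.
#'
#' @param dist_community Community distance matrix.
#' @param factor_dists Named list of factor distance matrices.
#' @param dist_control Optional shared control matrix.
#' @param ... Passed to [partial_mantel()].
#' @return Tibble `factor`, `r`, `p_value`, `p_bonferroni`.
#' @export
mantel_screen <- function(dist_community, factor_dists, dist_control = NULL, ...) {
  res <- purrr::imap_dfr(factor_dists, function(dm, nm) {
    m <- partial_mantel(dist_community, dm, dist_control, ...)
    tibble::tibble(factor = nm, r = m$statistic, p_value = m$p_value)
  })
  res$p_bonferroni <- pmin(1, res$p_value * nrow(res))
  res
}

# Sum of branch lengths of the minimal unrooted subtree spanning `tips`.
pd_faith <- function(tree, tips) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown) > 0) abort_lkd("unknown tip: %s", unknown[1])
  if (length(tips) < 2) return(0)
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- tr$Nnode
  in_set <- numeric(n_tip + n_node)
  in_set[match(tips, tr$tip.label)] <- 1
  for (e in seq_len(nrow(tr$edge))) {
    in_set[tr$edge[e, 1]] <- in_set[tr$edge[e, 1]] + in_set[tr$edge[e, 2]]
  }
  k <- in_set[tr$edge[, 2]]
  sum(tr$edge.length[k > 0 & k < length(tips)])
}

#' Phylogenetic diversity gain from added genomes
#'
#' Faith PD of a tip set is the total branch length of the minimal
#' subtree spanning it. The gain of a set of added tips over a reference
#' set is `(PD(ref + added) - PD(ref)) / PD(ref)` -- the extra branch
#' length the additions contribute, as a fraction of the reference
#' diversity. For a single grafted pendant tip this is exactly the
#' pendant branch length over the reference PD.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param reference_tips,added_tips Disjoint character vectors of tip
#'   labels present in the tree.
#' @return One-row tibble: `pd_ref`, `pd_all`, `pd_gain`,
#'   `gain_fraction`.
#' @export
pd_gain <- function(tree, reference_tips, added_tips) {
  validate_tree(tree)
  if (length(intersect(reference_tips, added_tips)) > 0) {
    abort_lkd("reference and added tip sets must be disjoint")
  }
  pd_ref <- pd_faith(tree, reference_tips)
  pd_all <- pd_faith(tree, union(reference_tips, added_tips))
  if (pd_ref <= 0) abort_lkd("reference set spans zero branch length")
  tibble::tibble(
    pd_ref = pd_ref,
    pd_all = pd_all,
    pd_gain = pd_all - pd_ref,
    gain_fraction = (pd_all - pd_ref) / pd_ref
  )
}

# Abundance-weighted beta mean nearest taxon distance between two
# communities given a patristic distance matrix restricted to their pool.
bmntd_pair <- function(dp, w_i, w_j, pres_i, pres_j) {
  ti <- dp[pres_i, pres_j, drop = FALSE]
  tj <- dp[pres_j, pres_i, drop = FALSE]
  0.5 * (sum(w_i[pres_i] * apply(ti, 1, min)) +
           sum(w_j[pres_j] * apply(tj, 1, min)))
}

#' Beta nearest taxon index (betaNTI)
#'
#' Abundance-weighted beta mean nearest taxon distance (betaMNTD) for
#' every sample pair, compared against a null distribution obtained by
#' shuffling tip identities among the taxa present in the pair's
#' regional pool. `betaNTI = (obs - mean(null)) / sd(null)`; values
#' beyond +/-2 are conventionally read as selection.
#'
#' @param tree `phylo` tree containing all OTUs.
#' @param abundance Long tibble `otu_id`, `sample_id`, `rel_abund`.
#' @param n_null Number of null shuffles per pair.
#' @param seed Seed.
#' @return Tibble per pair: `sample_i`, `sample_j`, `beta_mntd_obs`,
#'   `null_mean`, `null_sd`, `bnti` (NA when the null has zero spread).
#' @export
bnti <- function(tree, abundance, n_null = 999, seed = NULL) {
  m <- long_to_matrix(abundance, "sample_id", "otu_id", "rel_abund")
  unknown <- setdiff(colnames(m), tree$tip.label)
  if (length(unknown) > 0) abort_lkd("OTU %s not in tree", unknown[1])
  m <- m / rowSums(m)
  dmat <- ape::cophenetic.phylo(tree)[colnames(m), colnames(m)]
  samples <- rownames(m)
  n <- length(samples)
  with_seed_opt(seed, {
    purrr::map_dfr(utils::combn(n, 2, simplify = FALSE), function(pr) {
      i <- pr[1]; j <- pr[2]
      pool <- which(m[i, ] > 0 | m[j, ] > 0)
      dp <- dmat[pool, pool, drop = FALSE]
      w_i <- m[i, pool]; w_j <- m[j, pool]
      pres_i <- which(w_i > 0); pres_j <- which(w_j > 0)
      obs <- bmntd_pair(dp, w_i, w_j, pres_i, pres_j)
      nulls <- vapply(seq_len(n_null), function(k) {
        p <- sample.int(length(pool))
        bmntd_pair(dp[p, p, drop = FALSE], w_i, w_j, pres_i, pres_j)
      }, numeric(1))
      sd_null <- stats::sd(nulls)
      tibble::tibble(
        sample_i = samples[i], sample_j = samples[j],
        beta_mntd_obs = obs,
        null_mean = mean(nulls), null_sd = sd_null,
        bnti = if (sd_null > 0) (obs - mean(nulls)) / sd_null else NA_real_
      )
    })
  })
}

# One null community: observed richness, species drawn without
# replacement with probability ~ occupancy, individuals multinomial with
# probability ~ regional relative abundance.
rc_null_sample <- function(richness, n_ind, occupancy, regional, n_taxa) {
  sp <- sample.int(n_taxa, richness, prob = occupancy)
  x <- numeric(n_taxa)
  x[sp] <- stats::rmultinom(1, n_ind, regional[sp])
  x
}

#' Raup-Crick dissimilarity with Bray-Curtis (RC-Bray)
#'
#' For each sample pair, null communities preserving each sample's
#' richness and total abundance are assembled from the regional pool
#' (species drawn by occupancy, individuals by regional relative
#' abundance); the observed Bray-Curtis dissimilarity is ranked within
#' the null distribution and rescaled to `[-1, 1]`:
#' `RC = 2 * (frac(null < obs) + 0.5 * frac(ties)) - 1`. Values above
#' +0.95 indicate more turnover than expected (dispersal limitation),
#' below -0.95 less (homogenizing dispersal).
#'
#' @param counts Long tibble `otu_id`, `sample_id`, `count` (integer
#'   counts or rarefied equivalents).
#' @param n_null Null draws per pair.
#' @param seed Seed.
#' @return Tibble per pair: `sample_i`, `sample_j`, `bc_obs`, `rc_bray`.
#' @export
rc_bray <- function(counts, n_null = 999, seed = NULL) {
  m <- long_to_matrix(counts, "sample_id", "otu_id", "count")
  if (any(rowSums(m) == 0)) abort_lkd("empty sample: RC undefined")
  occupancy <- colMeans(m > 0)
  regional <- colSums(m) / sum(m)
  samples <- rownames(m)
  n <- length(samples)
  n_taxa <- ncol(m)
  rel <- m / rowSums(m)
  bc_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)
  with_seed_opt(seed, {
    purrr::map_dfr(utils::combn(n, 2, simplify = FALSE), function(pr) {
      i <- pr[1]; j <- pr[2]
      obs <- bc_pair(rel[i, ], rel[j, ])
      rich_i <- sum(m[i, ] > 0); rich_j <- sum(m[j, ] > 0)
      tot_i <- sum(m[i, ]); tot_j <- sum(m[j, ])
      nulls <- vapply(seq_len(n_null), function(k) {
        xi <- rc_null_sample(rich_i, tot_i, occupancy, regional, n_taxa)
        xj <- rc_null_sample(rich_j, tot_j, occupancy, regional, n_taxa)
        bc_pair(xi / sum(xi), xj / sum(xj))
      }, numeric(1))
      rc <- 2 * ((sum(nulls < obs) + 0.5 * sum(nulls == obs)) / n_null) - 1
      tibble::tibble(
        sample_i = samples[i], sample_j = samples[j],
        bc_obs = obs, rc_bray = rc
      )
    })
  })
}

#' Classify community-assembly processes from betaNTI and RC-Bray
#'
#' Stegen-style decision tree per sample pair: `|betaNTI| > 2` indicates
#' selection (heterogeneous when positive, homogeneous when negative);
#' otherwise `RC > 0.95` indicates dispersal limitation, `RC < -0.95`
#' homogenizing dispersal, and anything else is undominated.
#'
#' @param bnti_tbl Output of [bnti()].
#' @param rc_tbl Output of [rc_bray()].
#' @param bnti_threshold,rc_threshold Classification cutoffs.
#' @return Joined tibble with an `assembly_class` column.
#' @export
assembly_classes <- function(bnti_tbl, rc_tbl,
                             bnti_threshold = 2, rc_threshold = 0.95) {
  joined <- dplyr::inner_join(
    bnti_tbl, rc_tbl, by = c("sample_i", "sample_j")
  )
  joined$assembly_class <- dplyr::case_when(
    joined$bnti > bnti_threshold ~ "heterogeneous_selection",
    joined$bnti < -bnti_threshold ~ "homogeneous_selection",
    joined$rc_bray > rc_threshold ~ "dispersal_limitation",
    joined$rc_bray < -rc_threshold ~ "homogenizing_dispersal",
    is.na(joined$bnti) ~ NA_character_,
    TRUE ~ "undominated"
  )
  joined
}
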