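# Diversity indices, permutation tests, PD gain and null models.

abund_long <- function(m) {
  tibble::as_tibble(m, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "otu_id",
                        values_to = "rel_abund")
}

test_that("Shannon and Bray-Curtis match their closed forms", {
  m <- rbind(
    s1 = c(a = 0.25, b = 0.25, c = 0.25, d = 0.25),
    s2 = c(a = 1, b = 0, c = 0, d = 0),
    s3 = c(a = 0, b = 1, c = 0, d = 0)
  )
  div <- diversity_metrics(abund_long(m))
  expect_equal(div$shannon$shannon[1], log(4))
  expect_equal(div$shannon$shannon[2], 0)
  bc <- as.matrix(div$bray_curtis)
  expect_equal(bc["s2", "s3"], 1) # disjoint
  expect_equal(unname(diag(bc)), rep(0, 3))
  expect_true(all(bc >= 0 & bc <= 1))
  # identical samples
  m2 <- rbind(s1 = c(a = .5, b = .5), s2 = c(a = .5, b = .5))
  expect_equal(
    as.vector(diversity_metrics(abund_long(m2))$bray_curtis), 0
  )
})

test_that("all-zero samples get missing Shannon, not zero", {
  m <- rbind(s1 = c(a = 0.5, b = 0.5), s2 = c(a = 0, b = 0))
  sh <- diversity_metrics(abund_long(m))$shannon
  expect_true(is.na(sh$shannon[sh$sample_id == "s2"]))
})

test_that("ANOSIM gives R = 1 for perfect separation and bounded R", {
  # two groups, all between-distances larger than all within-distances
  x <- c(0, 0.1, 10, 10.1)
  d <- stats::dist(x)
  g <- c("A", "A", "B", "B")
  res <- anosim_test(d, g, n_perm = 199, seed = 1)
  expect_equal(res$statistic, 1)
  expect_true(all(abs(res$perm_stats) <= 1 + 1e-12))
  expect_gte(res$p_value, 1 / 200)
  # group of size 1 is an error
  expect_error(anosim_test(d, c("A", "B", "B", "B"), 99), ">= 2 samples")
})

test_that("ANOSIM R matches vegan and the exhaustive label enumeration", {
  withr::with_seed(5, {
    x <- matrix(stats::rnorm(8 * 3), 8)
    d <- stats::dist(x)
    g <- rep(c("A", "B"), each = 4)
    mine <- anosim_test(d, g, n_perm = 99, seed = 2)
    veg <- vegan::anosim(d, g, permutations = 99)
    expect_equal(mine$statistic, unname(veg$statistic), tolerance = 1e-12)

    # exhaustive oracle on 4 samples: R recomputed from first principles
    # for every possible labeling
    x4 <- c(0.3, 1.2, 0.7, 2.0)
    d4 <- stats::dist(x4)
    rk <- rank(as.vector(d4))
    pairs <- t(utils::combn(4, 2))
    oracle_r <- function(lab) {
      w <- lab[pairs[, 1]] == lab[pairs[, 2]]
      (mean(rk[!w]) - mean(rk[w])) / (length(rk) / 2)
    }
    # enumerate all distinct 2+2 labelings of the 4 samples
    for (cmb in utils::combn(4, 2, simplify = FALSE)) {
      lab <- rep("B", 4); lab[cmb] <- "A"
      mine4 <- anosim_test(d4, lab, n_perm = 23, seed = 3)
      expect_equal(mine4$statistic, oracle_r(lab), tolerance = 1e-12)
    }
  })
})

test_that("ANOSIM p-values are calibrated under the null", {
  rate <- withr::with_seed(11, {
    reps <- 300
    rejected <- vapply(seq_len(reps), function(r) {
      d <- stats::dist(matrix(stats::rnorm(12 * 2), 12))
      g <- sample(rep(c("A", "B"), each = 6))
      anosim_test(d, g, n_perm = 199)$p_value <= 0.05
    }, logical(1))
    mean(rejected)
  })
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("Mantel statistics match vegan and detect identical structure", {
  withr::with_seed(21, {
    x <- matrix(stats::rnorm(10 * 3), 10)
    y <- matrix(stats::rnorm(10 * 3), 10)
    z <- matrix(stats::rnorm(10 * 3), 10)
    da <- stats::dist(x); db <- stats::dist(y); dc <- stats::dist(z)

    simple <- partial_mantel(da, db, n_perm = 99, seed = 1)
    veg <- vegan::mantel(da, db, permutations = 99)
    expect_equal(simple$statistic, unname(veg$statistic), tolerance = 1e-12)

    part <- partial_mantel(da, db, dc, n_perm = 99, seed = 1)
    vegp <- vegan::mantel.partial(da, db, dc, permutations = 99)
    expect_equal(part$statistic, unname(vegp$statistic), tolerance = 1e-12)

    # factor identical to community: r = 1, minimal p
    self <- partial_mantel(da, da, dc, n_perm = 199, seed = 2)
    expect_gt(self$statistic, 0.999)
    expect_equal(self$p_value, 1 / 200)

    expect_error(
      partial_mantel(da, stats::dist(rep(1, 10)) * 0, n_perm = 9),
      "constant"
    )
  })
})

test_that("Mantel test is calibrated under the null", {
  rate <- withr::with_seed(31, {
    reps <- 300
    rejected <- vapply(seq_len(reps), function(r) {
      da <- stats::dist(matrix(stats::rnorm(10 * 2), 10))
      db <- stats::dist(matrix(stats::rnorm(10 * 2), 10))
      partial_mantel(da, db, n_perm = 99)$p_value <= 0.05
    }, logical(1))
    mean(rejected)
  })
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("mantel_screen applies Bonferroni across factors", {
  withr::with_seed(41, {
    da <- stats::dist(matrix(stats::rnorm(8 * 2), 8))
    fs <- list(
      f1 = stats::dist(matrix(stats::rnorm(8 * 2), 8)),
      f2 = da
    )
    res <- mantel_screen(da, fs, n_perm = 99, seed = 1)
    expect_equal(res$p_bonferroni, pmin(1, res$p_value * 2))
    expect_gt(res$r[res$factor == "f2"], 0.999)
  })
})

test_that("pd_gain matches closed forms on toy trees", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:0.5):0.5);")
  # reference {A,B,C} spans all edges except D's pendant: PD = 5
  g <- pd_gain(tr, c("A", "B", "C"), "D")
  expect_equal(g$pd_ref, 5)
  expect_equal(g$pd_all, 5.5)
  expect_equal(g$gain_fraction, 0.1)

  # added tip already inside the spanned subtree with zero pendant length
  tr0 <- ape::read.tree(text = "((A:1,B:1):1,(C:2,E:0):0);")
  g0 <- pd_gain(tr0, c("A", "B", "C"), "E")
  expect_equal(g0$gain_fraction, 0)

  expect_error(pd_gain(tr, c("A", "Z"), "D"), "unknown tip")
  expect_error(pd_gain(tr, c("A", "B"), c("B", "C")), "disjoint")
})

test_that("pd_gain agrees with picante and is subadditive and nonnegative", {
  skip_if_not_installed("picante")
  withr::with_seed(51, {
    for (k in 1:30) {
      tr <- ape::rtree(15)
      ref <- sample(tr$tip.label, 6)
      rest <- setdiff(tr$tip.label, ref)
      xset <- rest[1:3]
      yset <- rest[4:6]
      gx <- pd_gain(tr, ref, xset)
      gy <- pd_gain(tr, ref, yset)
      gxy <- pd_gain(tr, ref, c(xset, yset))
      expect_gte(gx$gain_fraction, 0)
      expect_lte(gxy$gain_fraction, gx$gain_fraction + gy$gain_fraction + 1e-12)
      comm <- matrix(as.numeric(tr$tip.label %in% ref), 1,
                     dimnames = list("s", tr$tip.label))
      expect_equal(
        gx$pd_ref,
        picante::pd(comm, tr, include.root = FALSE)$PD,
        tolerance = 1e-10
      )
    }
  })
})

test_that("betaMNTD matches hand computation and picante", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3);")
  ab <- tibble::tibble(
    otu_id = c("A", "B", "B", "C"),
    sample_id = c("s1", "s1", "s2", "s2"),
    rel_abund = c(0.5, 0.5, 0.6, 0.4)
  )
  b <- bnti(tr, ab, n_null = 49, seed = 1)
  # hand enumeration: 0.5 * [(0.5*3 + 0.5*0) + (0.6*0 + 0.4*5)] = 1.75
  expect_equal(b$beta_mntd_obs, 1.75)

  skip_if_not_installed("picante")
  m <- rbind(s1 = c(A = .5, B = .5, C = 0), s2 = c(A = 0, B = .6, C = .4))
  expect_equal(
    b$beta_mntd_obs,
    as.vector(picante::comdistnt(m, ape::cophenetic.phylo(tr),
                                 abundance.weighted = TRUE)),
    tolerance = 1e-12
  )

  # identical communities: betaMNTD 0, betaNTI not positive
  ab2 <- tibble::tibble(
    otu_id = rep(c("A", "B"), 2),
    sample_id = rep(c("s1", "s2"), each = 2),
    rel_abund = 0.5
  )
  b2 <- bnti(tr, ab2, n_null = 49, seed = 2)
  expect_equal(b2$beta_mntd_obs, 0)
  expect_true(is.na(b2$bnti) || b2$bnti <= 0)
})

test_that("RC-Bray hits its extremes for identical and disjoint samples", {
  # identical samples drawn from a rich pool
  taxa <- paste0("t", 1:30)
  cnt <- tibble::tibble(
    otu_id = rep(taxa, 2),
    sample_id = rep(c("s1", "s2"), each = 30),
    count = rep(c(rep(10L, 10), rep(0L, 20)), 2)
  )
  rc_same <- rc_bray(cnt, n_null = 99, seed = 1)
  expect_equal(rc_same$rc_bray, -1)

  # disjoint, equally rich samples from a large shared pool
  cnt2 <- tibble::tibble(
    otu_id = rep(taxa, 2),
    sample_id = rep(c("s1", "s2"), each = 30),
    count = c(rep(c(20L, 0L), 15), rep(c(0L, 20L), 15))
  )
  rc_disj <- rc_bray(cnt2, n_null = 199, seed = 2)
  expect_gt(rc_disj$rc_bray, 0.9)

  expect_error(
    rc_bray(dplyr::mutate(cnt, count = 0L)),
    "empty sample"
  )
})

test_that("assembly classification follows the decision tree", {
  b <- tibble::tibble(
    sample_i = "a", sample_j = letters[2:6],
    beta_mntd_obs = 1, null_mean = 1, null_sd = 1,
    bnti = c(3, -3, 0, 0, 0)
  )
  rc <- tibble::tibble(
    sample_i = "a", sample_j = letters[2:6],
    bc_obs = 0.5, rc_bray = c(0, 0, 0.99, -0.99, 0.2)
  )
  cls <- assembly_classes(b, rc)
  expect_equal(
    cls$assembly_class,
    c("heterogeneous_selection", "homogeneous_selection",
      "dispersal_limitation", "homogenizing_dispersal", "undominated")
  )
})

test_that("betaNTI null calibration holds for sparse random communities", {
  res <- withr::with_seed(61, {
    tr <- simulate_tree(20, seed = 7)
    taxa <- tr$tip.label
    draws <- 150
    hits <- vapply(seq_len(draws), function(k) {
      pick1 <- sample(taxa, 8)
      pick2 <- sample(taxa, 8)
      ab <- tibble::tibble(
        otu_id = c(pick1, pick2),
        sample_id = rep(c("s1", "s2"), each = 8),
        rel_abund = 1 / 8
      )
      z <- bnti(tr, ab, n_null = 199)$bnti
      !is.na(z) && abs(z) > 2
    }, logical(1))
    mean(hits)
  })
  expect_lt(res, 0.12)
})
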