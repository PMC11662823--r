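# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed; with seed = NULL the current
# RNG stream is used unchanged. All stochastic exported functions route
# their randomness through this single mechanism.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

abort_lkd <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "lakemicrodiv_error")
}

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_lkd(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    )
  }
  invisible(df)
}

# Interpret quality values given either as fractions (0-1) or percentages
# (0-100); any value > 1.5 flags the percent scale.
as_fraction <- function(x, what = "value") {
  if (any(!is.finite(x))) {
    abort_lkd("non-finite %s", what)
  }
  if (any(x > 1.5)) x <- x / 100
  if (any(x < 0)) abort_lkd("negative %s", what)
  x
}

# Long (otu_id/feature x sample) tibble -> samples-in-rows matrix.
long_to_matrix <- function(df, row = "sample_id", col = "otu_id", value = "rel_abund") {
  assert_cols(df, c(row, col, value), "abundance table")
  wide <- tidyr::pivot_wider(
    df[, c(row, col, value)],
    names_from = dplyr::all_of(col),
    values_from = dplyr::all_of(value),
    values_fill = 0
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide[[row]]
  m
}

dist_to_vec <- function(d) as.vector(stats::as.dist(d))

otu_label <- function(i) sprintf("otu_%03d", i)
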