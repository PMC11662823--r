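# broom-style tidiers for the permutation-test objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname anosim_test
#' @param x A `lakemicrodiv_anosim` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lakemicrodiv_anosim <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p.value = x$p_value,
    n.perm = x$n_perm
  )
}

#' @rdname anosim_test
#' @exportS3Method generics::glance
glance.lakemicrodiv_anosim <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p.value = x$p_value,
    n.perm = x$n_perm,
    n.groups = length(unique(x$grouping)),
    n.samples = length(x$grouping)
  )
}

#' @rdname partial_mantel
#' @param x A `lakemicrodiv_mantel` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lakemicrodiv_mantel <- function(x, ...) {
  tibble::tibble(
    estimate = x$statistic,
    p.value = x$p_value,
    n.perm = x$n_perm,
    partial = x$partial,
    method = x$method
  )
}

#' @rdname partial_mantel
#' @exportS3Method generics::glance
glance.lakemicrodiv_mantel <- function(x, ...) {
  tidy.lakemicrodiv_mantel(x)
}

#' @rdname enrichment_test
#' @param x A `lakemicrodiv_enrichment` table.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lakemicrodiv_enrichment <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname enrichment_test
#' @exportS3Method generics::glance
glance.lakemicrodiv_enrichment <- function(x, ...) {
  tibble::tibble(
    n.features = nrow(x),
    n.enriched = sum(!is.na(x$enriched_in)),
    fdr.threshold = attr(x, "fdr_threshold")
  )
}
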