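# Readers/writers for the external formats the pipeline touches (FASTA,
# gene tables, KO tables, pileup TSV, newick, labeled matrices, sample
# metadata), plus the GenomeBundle container. All coordinates are 0-based
# half-open internally; 1-based inclusive gene tables are converted on read.

#' Construct a validated genome bundle
#'
#' A genome bundle holds everything known about one species-representative
#' OTU: contig sequences, gene models, KO annotations, assembly quality and
#' per-category annotation counts. Gene coordinates are 0-based half-open on
#' the forward strand. Genes whose length is not a multiple of 3 are flagged
#' `partial` and excluded from codon-aware operations.
#'
#' @param otu_id OTU identifier.
#' @param contigs Named character vector of contig sequences (A/C/G/T/N).
#' @param genes Data frame with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand` (+1/-1 or "+"/"-"), and optionally
#'   `partial`.
#' @param ko_annotations Data frame with columns `gene_id`, `ko_id`
#'   (one row per gene-KO assignment), or `NULL`.
#' @param completeness,contamination Assembly quality, as fractions (0-1)
#'   or percentages (0-100; auto-detected). Their sum must be positive.
#' @param annotation_counts Named integer vector of per-category gene
#'   counts (e.g. `c(CAZY = 50)`).
#' @return An object of class `genome_bundle`.
#' @export
genome_bundle <- function(otu_id, contigs, genes, ko_annotations = NULL,
                          completeness = 1, contamination = 0,
                          annotation_counts = integer()) {
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    abort_lkd("contigs must be uniquely named")
  }
  contigs <- toupper(unname(vapply(contigs, as.character, character(1)))) |>
    stats::setNames(names(contigs))
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    abort_lkd("contig %s contains non-ACGTN characters", names(contigs)[bad][1])
  }
  genes <- tibble::as_tibble(genes)
  assert_cols(genes, c("gene_id", "contig_id", "start", "end", "strand"), "gene table")
  if (is.character(genes$strand)) {
    s <- dplyr::case_when(
      genes$strand == "+" ~ 1L,
      genes$strand == "-" ~ -1L,
      TRUE ~ NA_integer_
    )
    if (anyNA(s)) {
      abort_lkd(
        "unknown strand symbol '%s' for gene %s",
        genes$strand[is.na(s)][1], genes$gene_id[is.na(s)][1]
      )
    }
    genes$strand <- s
  }
  if (!all(genes$strand %in% c(-1L, 1L))) {
    abort_lkd("strand must be +1/-1")
  }
  if (any(genes$start >= genes$end)) {
    abort_lkd("gene %s has start >= end", genes$gene_id[genes$start >= genes$end][1])
  }
  unknown <- !(genes$contig_id %in% names(contigs))
  if (any(unknown)) {
    abort_lkd("gene %s refers to unknown contig %s",
              genes$gene_id[unknown][1], genes$contig_id[unknown][1])
  }
  clen <- nchar(contigs)[genes$contig_id]
  oob <- genes$start < 0 | genes$end > clen
  if (any(oob)) {
    abort_lkd("gene %s lies outside its contig bounds", genes$gene_id[oob][1])
  }
  if (!"partial" %in% names(genes)) genes$partial <- FALSE
  genes$partial <- genes$partial | ((genes$end - genes$start) %% 3L != 0L)

  completeness <- as_fraction(completeness, "completeness")
  contamination <- as_fraction(contamination, "contamination")
  if (completeness + contamination <= 0) {
    abort_lkd("completeness + contamination must be > 0")
  }

  ko <- if (is.null(ko_annotations)) {
    tibble::tibble(gene_id = character(), ko_id = character())
  } else {
    ko <- tibble::as_tibble(ko_annotations)
    assert_cols(ko, c("gene_id", "ko_id"), "KO table")
    stray <- setdiff(ko$gene_id, genes$gene_id)
    if (length(stray) > 0) {
      abort_lkd("KO table references unknown gene %s", stray[1])
    }
    ko[, c("gene_id", "ko_id")]
  }

  structure(
    list(
      otu_id = otu_id,
      contigs = contigs,
      genes = genes,
      ko_annotations = ko,
      assembled_size_bp = sum(nchar(contigs)),
      completeness_frac = completeness,
      contamination_frac = contamination,
      annotation_counts = annotation_counts
    ),
    class = "genome_bundle"
  )
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf(
    "<genome_bundle> %s: %d contig(s), %s bp, %d gene(s) (%d partial), %d KO assignment(s)\n",
    x$otu_id, length(x$contigs), format(x$assembled_size_bp, big.mark = ","),
    nrow(x$genes), sum(x$genes$partial), nrow(x$ko_annotations)
  ))
  cat(sprintf(
    "  completeness %.1f%%, contamination %.1f%%\n",
    100 * x$completeness_frac, 100 * x$contamination_frac
  ))
  invisible(x)
}

#' Read a genome bundle from disk
#'
#' @param fasta_path FASTA file of contig sequences.
#' @param gene_table_path TSV with columns `gene_id`, `contig` (or
#'   `contig_id`), `start`, `end`, `strand`. Declared coordinate convention
#'   is converted to the internal 0-based half-open convention.
#' @param ko_table_path Optional TSV with columns `gene_id`, `ko_id`.
#' @param quality_row Optional list/one-row data frame with `completeness`
#'   and `contamination` (fraction or percent), and optionally `otu_id`.
#' @param otu_id OTU identifier; defaults to the FASTA file stem.
#' @param coords Coordinate convention of the gene table: `"1-based"`
#'   inclusive (GFF-like, default) or `"0-based"` half-open.
#' @return A [genome_bundle()].
#' @export
read_genome_bundle <- function(fasta_path, gene_table_path, ko_table_path = NULL,
                               quality_row = NULL, otu_id = NULL,
                               coords = c("1-based", "0-based")) {
  coords <- match.arg(coords)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  genes <- readr::read_tsv(gene_table_path, show_col_types = FALSE)
  if ("contig" %in% names(genes) && !"contig_id" %in% names(genes)) {
    genes <- dplyr::rename(genes, contig_id = "contig")
  }
  assert_cols(genes, c("gene_id", "contig_id", "start", "end", "strand"), "gene table")
  if (coords == "1-based") genes$start <- genes$start - 1L
  ko <- if (!is.null(ko_table_path)) {
    readr::read_tsv(ko_table_path, show_col_types = FALSE)
  }
  if (is.null(otu_id)) {
    otu_id <- if (!is.null(quality_row) && !is.null(quality_row$otu_id)) {
      quality_row$otu_id
    } else {
      sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(fasta_path))
    }
  }
  genome_bundle(
    otu_id = otu_id,
    contigs = contigs,
    genes = genes,
    ko_annotations = ko,
    completeness = if (is.null(quality_row)) 1 else quality_row$completeness,
    contamination = if (is.null(quality_row)) 0 else quality_row$contamination
  )
}

#' Write a genome bundle's contigs as FASTA
#'
#' @param bundle A [genome_bundle()].
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(bundle, path) {
  lines <- as.vector(rbind(paste0(">", names(bundle$contigs)), bundle$contigs))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-site pileup table
#'
#' Expects a TSV with header `contig`, `pos` (0-based), `A`, `C`, `G`, `T`
#' holding per-base read depths. Positions must be unique per contig and
#' counts non-negative integers.
#'
#' @param path TSV path.
#' @return A tibble with the validated columns.
#' @export
read_pileup <- function(path) {
  p <- readr::read_tsv(
    path,
    col_types = readr::cols(
      contig = readr::col_character(),
      pos = readr::col_double(),
      A = readr::col_double(), C = readr::col_double(),
      G = readr::col_double(), T = readr::col_double()
    )
  )
  validate_pileup(p)
}

validate_pileup <- function(p) {
  assert_cols(p, c("contig", "pos", "A", "C", "G", "T"), "pileup")
  cnt <- as.matrix(p[, c("A", "C", "G", "T")])
  if (nrow(p) > 0) {
    if (anyNA(cnt) || anyNA(p$pos)) abort_lkd("pileup contains missing values")
    if (any(cnt < 0)) abort_lkd("pileup contains negative counts")
    if (any(cnt != round(cnt)) || any(p$pos != round(p$pos))) {
      abort_lkd("pileup counts and positions must be integers")
    }
    if (anyDuplicated(paste(p$contig, p$pos))) {
      abort_lkd("duplicate (contig, pos) rows in pileup")
    }
  }
  tibble::as_tibble(p)
}

#' Write a pileup table (full-precision TSV)
#'
#' @param pileup Pileup tibble as returned by [read_pileup()].
#' @param path Output path.
#' @export
write_pileup <- function(pileup, path) {
  readr::write_tsv(pileup, path)
  invisible(path)
}

#' Read a tree in newick format
#'
#' Branch lengths are required on every edge (phylogenetic diversity is
#' undefined without them) and tip labels must be unique.
#'
#' @param path Newick file path.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort_lkd("could not parse newick file %s", path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    abort_lkd("tree is missing branch lengths")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort_lkd(
      "duplicate tip label: %s",
      tree$tip.label[duplicated(tree$tip.label)][1]
    )
  }
  tree
}

#' Read a labeled numeric matrix from TSV
#'
#' First column holds row labels; remaining columns are numeric. Ragged or
#' incomplete rows are an error.
#'
#' @param path TSV path.
#' @return A numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) abort_lkd("matrix file must have a header and >= 1 row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) abort_lkd("ragged rows in matrix file")
  header <- fields[[1]][-1]
  body <- fields[-1]
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(length(header)))
  )
  m <- if (length(header) == 1) matrix(vals, ncol = 1) else t(vals)
  if (anyNA(m)) abort_lkd("missing or non-numeric cells in matrix file")
  dimnames(m) <- list(vapply(body, `[`, character(1), 1), header)
  m
}

#' Write a labeled numeric matrix as TSV
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the row-label column.
#' @export
write_matrix <- function(m, path, id_col = "id") {
  df <- tibble::as_tibble(m, rownames = id_col)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Assign salinity groups from salinity measurements
#'
#' Lakes are grouped by salinity: freshwater below 0.1%, brackish between
#' 0.1% and 3.5%, saline above 3.5%.
#'
#' @param salinity_pct Numeric vector, salinity in percent.
#' @return Factor with levels freshwater, brackish, saline.
#' @export
assign_salinity_group <- function(salinity_pct) {
  cut(
    salinity_pct,
    breaks = c(-Inf, 0.1, 3.5, Inf),
    labels = c("freshwater", "brackish", "saline")
  )
}

#' Read sample metadata
#'
#' TSV with `sample_id` plus either a `group` column or a `salinity`
#' column (percent) from which groups are derived via
#' [assign_salinity_group()]. Any further numeric columns are kept as
#' environmental factors.
#'
#' @param path TSV path.
#' @return Tibble with `sample_id`, `group`, and environmental columns.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(md, "sample_id", "sample metadata")
  if (!"group" %in% names(md)) {
    assert_cols(md, "salinity", "sample metadata (needs group or salinity)")
    md$group <- as.character(assign_salinity_group(md$salinity))
  }
  bad <- !(md$group %in% c("freshwater", "brackish", "saline"))
  if (any(bad)) abort_lkd("unknown group label '%s'", md$group[bad][1])
  tibble::as_tibble(md)
}
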