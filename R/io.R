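#' @name file_formats
#' @title Plain-text file formats
#'
#' @description
#' All interchange formats are tab-separated UTF-8 text with `.` as decimal
#' mark, chosen so every artifact diffs and version-controls cleanly:
#'
#' * matrix TSV — header `gene_id` + strain ids; one row per gene.
#' * annotation TSV — BED-like columns `chrom`, `start`, `end`, `gene_id`,
#'   `subtelomeric`, with 1-based closed coordinates declared in a `#`
#'   header comment (use `bed_strict = TRUE` for 0-based half-open BED).
#' * GMT — one category per line: id, description, then member gene ids.
#' * bands TSV — columns `strain_id`, `band_sizes_kb` (comma-separated).
#' * trees — Newick with branch lengths (via the ape package).
#'
#' Readers validate structure (ragged rows, duplicate ids, non-numeric
#' cells) and fail with descriptive errors; writers and readers round-trip
#' exactly on the test fixtures.
NULL

#' Write / read a gene x strain log2-ratio matrix as TSV
#' @param matrix numeric matrix with gene-id rownames and strain colnames.
#' @param path file path.
#' @return `read_matrix_tsv` returns the numeric matrix; writers return the
#'   path invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop(sprintf("%s: first column must be gene_id", path))
  if (anyDuplicated(df$gene_id)) stop(sprintf("%s: duplicate gene ids", path))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(sprintf("%s: non-numeric cells in matrix body", path))
  rownames(m) <- df$gene_id
  m
}

#' Write / read a genome annotation as BED-like TSV
#'
#' Columns `chrom`, `start`, `end`, `gene_id`, `subtelomeric`. Coordinates
#' are 1-based closed by default (declared in a header comment); with
#' `bed_strict = TRUE` they are converted to/from 0-based half-open BED.
#'
#' @param annotation a [genome_annotation()].
#' @param path file path.
#' @param bed_strict use 0-based half-open coordinates.
#' @return `read_annotation_tsv` returns a [genome_annotation()].
#' @export
write_annotation_tsv <- function(annotation, path, bed_strict = FALSE) {
  start <- if (bed_strict) annotation$start - 1L else annotation$start
  note <- if (bed_strict) "0-based, half-open" else "1-based, closed"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# coordinates: %s", note), con)
  utils::write.table(
    data.frame(chrom = annotation$chromosome, start = start,
               end = annotation$end, gene_id = annotation$gene_id,
               subtelomeric = as.integer(annotation$subtelomeric)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path, bed_strict = FALSE) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    bed_strict <- grepl("0-based", first)
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene_id", "subtelomeric")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  }
  start <- if (bed_strict) df$start + 1L else df$start
  genome_annotation(df$gene_id, df$chrom, start, df$end,
                    as.logical(df$subtelomeric))
}

#' Write / read functional categories as GMT
#'
#' One line per category: id, description, then the member gene ids, all
#' tab-separated.
#'
#' @param terms named list of gene-id vectors, optionally with a
#'   `descriptions` attribute.
#' @param path file path.
#' @return `read_gmt` returns a named list with a `descriptions` attribute.
#' @export
write_gmt <- function(terms, path) {
  descs <- attr(terms, "descriptions")
  lines <- vapply(names(terms), function(id) {
    d <- if (!is.null(descs) && id %in% names(descs)) descs[[id]] else ""
    paste(c(id, d, terms[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("%s: line %d has fewer than 3 fields", path, short[1]))
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop(sprintf("%s: duplicate term ids", path))
  terms <- lapply(parts, function(p) p[-(1:2)])
  names(terms) <- ids
  attr(terms, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2L), ids)
  terms
}

#' Write / read PFGE band patterns as TSV
#'
#' Columns `strain_id` and `band_sizes_kb` (comma-separated sizes).
#'
#' @param bands named list: strain id -> numeric vector of band sizes (kb).
#' @param path file path.
#' @return `read_bands_tsv` returns the named list.
#' @export
write_bands_tsv <- function(bands, path) {
  df <- data.frame(
    strain_id = names(bands),
    band_sizes_kb = vapply(bands, function(x) {
      paste(format(x, trim = TRUE, digits = 15, scientific = FALSE),
            collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bands_tsv
#' @export
read_bands_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!all(c("strain_id", "band_sizes_kb") %in% names(df))) {
    stop(sprintf("%s: expected columns strain_id, band_sizes_kb", path))
  }
  if (anyDuplicated(df$strain_id)) stop(sprintf("%s: duplicate strain ids", path))
  bands <- lapply(strsplit(df$band_sizes_kb, ",", fixed = TRUE), function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop(sprintf("%s: non-numeric band size", path))
    v
  })
  names(bands) <- df$strain_id
  bands
}

#' Write / read a tree in Newick format
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()].
#'
#' @param x a `cgh_dendrogram` or an `ape` `phylo` object.
#' @param path file path.
#' @return `read_newick` returns an `ape` `phylo` object.
#' @export
write_newick <- function(x, path) {
  phy <- if (inherits(x, "cgh_dendrogram")) dendro_to_phylo(x) else x
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
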