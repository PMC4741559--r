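#' Construct and validate a genome annotation table
#'
#' A genome annotation is the spatial backbone of the pipeline: one row per
#' gene with its chromosome, 1-based closed coordinates and a subtelomere
#' flag. Rows are sorted by `(chromosome, start, gene_id)`; this order defines
#' the genome order used by divergence profiles and heatmap tables.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chromosome integer chromosome index (1-based).
#' @param start,end 1-based closed interval of the gene, `start <= end`.
#' @param subtelomeric logical, whether the gene midpoint falls within the
#'   subtelomeric window of its chromosome.
#' @return A `data.frame` of class `genome_annotation`, sorted in genome order.
#' @export
genome_annotation <- function(gene_id, chromosome, start, end, subtelomeric) {
  ann <- data.frame(
    gene_id = as.character(gene_id),
    chromosome = as.integer(chromosome),
    start = as.integer(start),
    end = as.integer(end),
    subtelomeric = as.logical(subtelomeric),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ann$gene_id)) {
    stop("gene ids must be unique")
  }
  if (any(ann$start > ann$end)) {
    stop("gene start must not exceed end")
  }
  if (any(ann$start < 1L)) {
    stop("coordinates are 1-based; start must be >= 1")
  }
  ann <- ann[order(ann$chromosome, ann$start, ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("genome_annotation", "data.frame")
  ann
}

#' Genome order of genes in an annotation
#'
#' @param annotation a [genome_annotation()] table (or compatible data.frame).
#' @return Character vector of gene ids sorted by `(chromosome, start, gene_id)`.
#' @export
genome_order <- function(annotation) {
  idx <- order(annotation$chromosome, annotation$start, annotation$gene_id)
  annotation$gene_id[idx]
}

# midpoint of the 1-based closed interval, used both for the subtelomere flag
# and for gene-in-region membership
gene_midpoint <- function(annotation) {
  (annotation$start + annotation$end) / 2
}
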