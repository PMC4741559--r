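#' Select divergent genes by a global k-standard-deviation rule
#'
#' The global dispersion of a re-normalized cohort is summarized by one
#' number: the population standard deviation pooled over every gene x strain
#' log2 ratio (missing values excluded, grand-mean centered). A gene is
#' divergent when in at least one strain its absolute log2 ratio strictly
#' exceeds `k` times that global SD (default `k = 4`). The absolute value
#' makes both amplified and lost genes selectable; the threshold scales with
#' the data, so the selected set is invariant to multiplying the matrix by a
#' positive constant.
#'
#' @param matrix re-normalized genes x strains log2-ratio matrix.
#' @param k positive SD multiplier (default 4).
#' @return A list of class `selection_result`: `global_sd`, `k`, `threshold`
#'   (`= k * global_sd`), `selected` (character vector of gene ids, in matrix
#'   row order) and `table` (`gene_id`, `max_abs_log2`, `selected`).
#' @export
select_divergent <- function(matrix, k = 4) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (k <= 0) stop("k must be > 0")
  vals <- matrix[!is.na(matrix)]
  if (length(vals) == 0L) stop("matrix has no observed values")
  global_sd <- sqrt(mean((vals - mean(vals))^2))
  threshold <- k * global_sd
  max_abs <- apply(abs(matrix), 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) NA_real_ else max(x)
  })
  sel <- !is.na(max_abs) & max_abs > threshold
  structure(
    list(global_sd = global_sd, k = k, threshold = threshold,
         selected = rownames(matrix)[sel],
         table = data.frame(gene_id = rownames(matrix),
                            max_abs_log2 = unname(max_abs),
                            selected = unname(sel),
                            stringsAsFactors = FALSE)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: global_sd %.4f, threshold %.4f (k = %g), %d genes selected\n",
              x$global_sd, x$threshold, x$k, length(x$selected)))
  invisible(x)
}

#' Build the ordered heatmap table of selected genes
#'
#' Arranges the selected genes for rendering: rows grouped by functional
#' category and, within each category, by genome position; columns are the
#' strains in the clustering leaf order. Genes selected but absent from the
#' annotation are kept, flagged `unplaced`, and sorted to the end of their
#' category block.
#'
#' @param matrix re-normalized genes x strains log2-ratio matrix.
#' @param selection a [select_divergent()] result.
#' @param annotation a [genome_annotation()].
#' @param category_assignment `data.frame` with columns `gene_id` and
#'   `category`; selected genes without an entry are grouped under
#'   `"unassigned"`.
#' @param strain_order character vector ordering the columns (typically
#'   [leaf_order()] of the strain tree); default = matrix column order.
#' @return `data.frame` with columns `gene_id`, `category`, `chromosome`,
#'   `start`, `unplaced`, then one numeric column per strain.
#' @export
selection_heatmap_table <- function(matrix, selection, annotation,
                                    category_assignment,
                                    strain_order = colnames(matrix)) {
  stopifnot(inherits(selection, "selection_result"))
  stopifnot(all(strain_order %in% colnames(matrix)))
  genes <- selection$selected
  if (length(genes) == 0L) {
    out <- data.frame(gene_id = character(0), category = character(0),
                      chromosome = integer(0), start = integer(0),
                      unplaced = logical(0), stringsAsFactors = FALSE)
    for (s in strain_order) out[[s]] <- numeric(0)
    return(out)
  }
  cat_map <- stats::setNames(as.character(category_assignment$category),
                             category_assignment$gene_id)
  category <- unname(cat_map[genes])
  category[is.na(category)] <- "unassigned"
  ann_idx <- match(genes, annotation$gene_id)
  unplaced <- is.na(ann_idx)
  chromosome <- annotation$chromosome[ann_idx]
  start <- annotation$start[ann_idx]
  ord <- order(category, unplaced, chromosome, start, genes)
  out <- data.frame(gene_id = genes, category = category,
                    chromosome = chromosome, start = start,
                    unplaced = unplaced, stringsAsFactors = FALSE)[ord, ]
  vals <- matrix[out$gene_id, strain_order, drop = FALSE]
  out <- cbind(out, as.data.frame(vals))
  rownames(out) <- NULL
  out
}
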