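#' Euclidean distances between strain profiles
#'
#' `d(a, b) = sqrt(sum_g (x[g,a] - x[g,b])^2)` over the genes observed in
#' both strains (pairwise-complete). The number of genes shared by the
#' worst pair is recorded in `attr(, "min_shared_genes")`.
#'
#' @param matrix genes x strains log2-ratio matrix.
#' @return Symmetric strains x strains distance matrix, zero diagonal.
#' @export
euclidean_distances <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  n <- ncol(matrix)
  if (n < 2L) stop("need at least 2 strains")
  d <- matrix(0, n, n, dimnames = list(colnames(matrix), colnames(matrix)))
  min_shared <- nrow(matrix)
  if (!anyNA(matrix)) {
    cp <- crossprod(matrix)
    sq <- diag(cp)
    d2 <- outer(sq, sq, "+") - 2 * cp
    d <- sqrt(pmax(d2, 0))
  } else {
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        ok <- !is.na(matrix[, a]) & !is.na(matrix[, b])
        if (sum(ok) < 2L) {
          stop(sprintf("strains %s and %s share fewer than 2 observed genes",
                       colnames(matrix)[a], colnames(matrix)[b]))
        }
        min_shared <- min(min_shared, sum(ok))
        d[a, b] <- d[b, a] <- sqrt(sum((matrix[ok, a] - matrix[ok, b])^2))
      }
    }
  }
  diag(d) <- 0
  attr(d, "min_shared_genes") <- min_shared
  d
}

#' Complete-linkage hierarchical clustering of strains
#'
#' Agglomerative clustering where the distance between two clusters is the
#' maximum over all cross-pair leaf distances; merge heights equal the merge
#' distance and are guaranteed non-decreasing (no inversions). Ties are
#' broken by the lexicographic order of each cluster's smallest leaf label;
#' leaf order is the deterministic smaller-label-first traversal, which fixes
#' the heatmap column order.
#'
#' @param distances symmetric strain distance matrix (e.g. from
#'   [euclidean_distances()]).
#' @param labels leaf labels; default the matrix row names.
#' @return A `cgh_dendrogram`.
#' @export
complete_linkage <- function(distances, labels = rownames(distances)) {
  if (is.null(labels)) stop("distance matrix must carry labels")
  agglomerate(distances, labels, linkage = "complete")
}
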