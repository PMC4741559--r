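#' Bin electrophoretic band sizes across strains
#'
#' Pools all band sizes, sorts them, and greedily merges consecutive sizes
#' into bins such that any two sizes in one bin differ by at most
#' `tolerance` times the bin mean. Bands of similar size in different lanes
#' thereby count as the same chromosome (co-migration); duplicate bands
#' within one strain count once.
#'
#' @param patterns named list: strain id -> numeric vector of band sizes (kb).
#' @param tolerance relative size tolerance (default 0.05, i.e. 5%).
#' @return Binary matrix (strains x bins, 0/1); column names are the rounded
#'   bin mean sizes, exact means in `attr(, "bin_means")`.
#' @export
bin_bands <- function(patterns, tolerance = 0.05) {
  if (length(patterns) == 0L) stop("empty pattern list")
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (is.null(names(patterns)) || any(names(patterns) == "")) {
    stop("patterns must be a named list of strains")
  }
  for (p in patterns) {
    if (length(p) == 0L || any(p <= 0)) stop("band sizes must be positive")
  }
  sizes <- unlist(patterns, use.names = FALSE)
  strain_of <- rep(names(patterns), lengths(patterns))
  ord <- order(sizes)
  sizes <- sizes[ord]; strain_of <- strain_of[ord]

  bin_id <- integer(length(sizes))
  cur <- 1L; first <- 1L
  for (i in seq_along(sizes)) {
    if (i > first) {
      cand <- sizes[first:i]
      if (max(cand) - min(cand) > tolerance * mean(cand)) {
        cur <- cur + 1L; first <- i
      }
    }
    bin_id[i] <- cur
  }
  n_bins <- cur
  bin_means <- vapply(seq_len(n_bins), function(b) mean(sizes[bin_id == b]),
                      numeric(1))
  presence <- matrix(0L, length(patterns), n_bins,
                     dimnames = list(names(patterns),
                                     sprintf("bin_%g", round(bin_means, 1))))
  for (i in seq_along(sizes)) presence[strain_of[i], bin_id[i]] <- 1L
  attr(presence, "bin_means") <- bin_means
  presence
}

#' Jaccard similarity between strains' band-bin sets
#'
#' `J(a, b) = |bins shared| / |bins in a or b|`; the matching distance for
#' UPGMA is `1 - J`.
#'
#' @param presence binary strains x bins matrix (from [bin_bands()]).
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
jaccard_similarity <- function(presence) {
  stopifnot(is.matrix(presence))
  if (any(rowSums(presence) == 0)) {
    stop("a strain with zero bins has undefined Jaccard similarity")
  }
  p <- (presence != 0) * 1
  inter <- p %*% t(p)
  sizes <- rowSums(p)
  union <- outer(sizes, sizes, "+") - inter
  J <- inter / union
  dimnames(J) <- list(rownames(presence), rownames(presence))
  J
}

#' UPGMA dendrogram from a distance matrix
#'
#' Unweighted pair-group average clustering: repeatedly merge the two closest
#' clusters, with inter-cluster distance the size-weighted arithmetic mean of
#' all cross-pair leaf distances. Merge heights are half the merge distance
#' (ultrametric convention); ties are broken by the lexicographic order of
#' each cluster's smallest leaf label.
#'
#' @param distances symmetric non-negative matrix with zero diagonal; for the
#'   karyotype branch, `1 - jaccard_similarity(...)`.
#' @param labels leaf labels; default the matrix row names.
#' @return A `cgh_dendrogram` (see [to_newick()], [cut_dendrogram()]).
#' @export
upgma <- function(distances, labels = rownames(distances)) {
  if (is.null(labels)) stop("distance matrix must carry labels")
  agglomerate(distances, labels, linkage = "average")
}
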