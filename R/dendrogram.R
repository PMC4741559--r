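#' @name cgh_dendrogram
#' @title Agglomerative dendrograms with deterministic tie-breaking
#'
#' @description
#' Both clustering branches of the pipeline (UPGMA on karyotype distances,
#' complete linkage on array-CGH profiles) share one agglomerator. It differs
#' from [stats::hclust()] in two contractual respects: ties between equally
#' close cluster pairs are broken by the lexicographic order of the smallest
#' leaf label in each cluster (so trees are reproducible regardless of input
#' row order), and UPGMA records merge heights at half the inter-cluster
#' distance (the ultrametric convention), while complete linkage records the
#' merge distance itself.
#'
#' The returned object is hclust-compatible (`merge`, `height`, `order`,
#' `labels`) and carries the linkage method. Leaf order is a deterministic
#' recursive traversal that visits the subtree with the lexicographically
#' smaller minimum leaf label first.
NULL

# core agglomerator; d is a full symmetric matrix with zero diagonal,
# linkage "average" (UPGMA, height = d/2) or "complete" (height = d)
agglomerate <- function(d, labels, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  n <- length(labels)
  stopifnot(is.matrix(d), nrow(d) == n, ncol(d) == n, n >= 2)
  if (any(is.na(d))) stop("distance matrix contains missing values")
  if (any(d < 0)) stop("distances must be non-negative")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  d <- (d + t(d)) / 2
  diag(d) <- 0

  # active cluster bookkeeping: id in hclust convention (-leaf or +merge step)
  act_id <- -seq_len(n)
  act_size <- rep(1L, n)
  act_min <- labels          # smallest leaf label per cluster, for tie-breaks
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(act_id)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        key <- sort(c(act_min[i], act_min[j]))
        if (is.null(best) ||
            D[i, j] < best$d - 1e-15 ||
            (D[i, j] <= best$d + 1e-15 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = D[i, j], key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort_merge_pair(act_id[i], act_id[j])
    height[step] <- if (linkage == "average") best$d / 2 else best$d

    keep <- setdiff(seq_len(m), c(i, j))
    newD <- if (linkage == "average") {
      (act_size[i] * D[i, keep] + act_size[j] * D[j, keep]) /
        (act_size[i] + act_size[j])
    } else {
      pmax(D[i, keep], D[j, keep])
    }
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newD), c(newD, 0))
    act_id <- c(act_id[keep], step)
    act_size <- c(act_size[keep], act_size[i] + act_size[j])
    act_min <- c(act_min[keep], min(act_min[i], act_min[j]))
  }

  out <- structure(
    list(merge = merge, height = height, labels = labels,
         method = linkage, dist.method = "euclidean"),
    class = "cgh_dendrogram"
  )
  out$order <- dendro_leaf_order(out)
  out
}

# hclust convention: singletons (negative) before merged clusters, then by value
sort_merge_pair <- function(a, b) {
  if ((a < 0 && b < 0) || (a > 0 && b > 0)) sort(c(a, b)) else c(min(a, b), max(a, b))
}

# leaf indices of every node; element i of the list covers merge step i
merge_leafsets <- function(x) {
  sets <- vector("list", nrow(x$merge))
  for (i in seq_len(nrow(x$merge))) {
    kids <- x$merge[i, ]
    sets[[i]] <- unlist(lapply(kids, function(k) if (k < 0) -k else sets[[k]]))
  }
  sets
}

# recursive traversal: subtree with lexicographically smaller min leaf label first
dendro_leaf_order <- function(x) {
  sets <- merge_leafsets(x)
  walk <- function(node) {
    if (node < 0) return(-node)
    kids <- x$merge[node, ]
    minlab <- vapply(kids, function(k) {
      if (k < 0) x$labels[-k] else min(x$labels[sets[[k]]])
    }, character(1))
    kids <- kids[order(minlab)]
    c(walk(kids[1]), walk(kids[2]))
  }
  walk(nrow(x$merge))
}

#' @export
as.hclust.cgh_dendrogram <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = x$order,
         labels = x$labels, method = x$method, dist.method = x$dist.method,
         call = match.call()),
    class = "hclust"
  )
}

#' @export
print.cgh_dendrogram <- function(x, ...) {
  cat(sprintf("cgh_dendrogram (%s linkage): %d leaves, max height %.4g\n",
              x$method, length(x$labels), max(x$height)))
  invisible(x)
}

#' Leaf labels of a dendrogram in display order
#' @param x a `cgh_dendrogram`.
#' @return Character vector of leaf labels, deterministic traversal order.
#' @export
leaf_order <- function(x) x$labels[x$order]

#' Cut a dendrogram into k clusters
#' @param x a `cgh_dendrogram`.
#' @param k number of clusters.
#' @return Named integer vector of cluster memberships (names = leaf labels).
#' @export
cut_dendrogram <- function(x, k) {
  stats::cutree(stats::as.hclust(x), k = k)
}

#' Test whether a set of leaves forms a clade
#'
#' @param x a `cgh_dendrogram`.
#' @param leaves character vector of leaf labels.
#' @return `TRUE` iff some node's leaf set equals `leaves` exactly (a single
#'   leaf is trivially a clade).
#' @export
is_clade <- function(x, leaves) {
  leaves <- sort(unique(leaves))
  if (length(leaves) == 1L) return(leaves %in% x$labels)
  sets <- merge_leafsets(x)
  for (s in sets) {
    if (identical(sort(x$labels[s]), leaves)) return(TRUE)
  }
  FALSE
}

#' Serialize a dendrogram to Newick
#'
#' Branch lengths are differences of merge heights (leaves sit at height 0),
#' so UPGMA trees serialize as ultrametric trees.
#'
#' @param x a `cgh_dendrogram`.
#' @param path optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
to_newick <- function(x, path = NULL) {
  phy <- dendro_to_phylo(x)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

# ape::as.phylo.hclust halves heights (so path lengths between leaves equal
# cophenetic distances); pre-double them so leaves sit at the merge height
dendro_to_phylo <- function(x) {
  h <- stats::as.hclust(x)
  h$height <- 2 * h$height
  ape::as.phylo(h)
}

#' Adjusted Rand index between two partitions
#'
#' Used by the recovery checks: compares a tree cut against the planted
#' strain-to-group assignment. 1 means identical partitions, ~0 is chance
#' agreement.
#'
#' @param a,b partitions as vectors of cluster labels over the same items
#'   (matched by name when both are named, by position otherwise).
#' @return The adjusted Rand index, a real number <= 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) != length(a) || length(common) != length(b)) {
      stop("partitions must cover the same named items")
    }
    b <- b[names(a)]
  }
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
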