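#' Exact hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` members of a category of size `K` when sampling `n` genes
#' without replacement from a universe of `N`. Computed in log space
#' (log-binomials accumulated through a log-sum-exp) for numerical stability
#' at large counts.
#'
#' @param k observed overlap (selected genes in the category).
#' @param K category size in the universe.
#' @param n number of selected genes in the universe.
#' @param N universe size.
#' @return The upper-tail probability, in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  k <- as.integer(k); K <- as.integer(K); n <- as.integer(n); N <- as.integer(N)
  if (N < 0 || K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(K, n)) {
    stop("inconsistent hypergeometric counts")
  }
  lo <- max(0L, n - (N - K))   # smallest achievable overlap
  if (k <= lo) return(1)
  i <- k:min(K, n)
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_(j >= i) (p_(j) * m / j)` over the sorted p-values, clipped at
#' 1 and mapped back to the input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Functional-category overrepresentation of a gene set
#'
#' Tests every category for overrepresentation among the selected genes by
#' the exact hypergeometric upper tail, then adjusts across all tested
#' categories jointly with Benjamini-Hochberg FDR. Category membership and
#' the selected set are both intersected with the universe first; selected
#' genes outside the universe are dropped with a warning. Categories with no
#' member in the universe are skipped; categories with zero overlap are still
#' tested (p = 1).
#'
#' @param selected character vector of selected gene ids.
#' @param terms named list of gene-id vectors (optionally with a
#'   `descriptions` attribute, as from [read_gmt()] or [simulate_cohort()]).
#' @param universe character vector of all gene ids under consideration.
#' @param alpha FDR significance level (default 0.05); `significant` is
#'   `q < alpha`.
#' @return `data.frame` (`term_id`, `name`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `significant`), sorted by `q`, then `p`, then `term_id`.
#' @export
enrich <- function(selected, terms, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  selected <- unique(as.character(selected))
  outside <- setdiff(selected, universe)
  if (length(outside) > 0L) {
    warning(sprintf("%d selected gene(s) outside the universe dropped",
                    length(outside)))
    selected <- intersect(selected, universe)
  }
  if (length(terms) == 0L) {
    return(data.frame(term_id = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  if (length(selected) == 0L) {
    warning("no selected genes in the universe; all p-values are 1")
  }
  descs <- attr(terms, "descriptions")
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(terms), function(id) {
    members <- intersect(unique(terms[[id]]), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, selected))
    data.frame(term_id = id,
               name = if (!is.null(descs) && id %in% names(descs)) descs[[id]] else id,
               k = k, K = K, n = n, N = N,
               p = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no term has any member in the universe")
  res$q <- bh_fdr(res$p)
  res$significant <- res$q < alpha
  res <- res[order(res$q, res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
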