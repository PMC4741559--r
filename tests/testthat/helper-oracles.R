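# Independent brute-force oracles and small fixture builders shared by the
# module and acceptance tests. Oracles deliberately recompute everything from
# first principles (no distance-update recursions, no log-space tricks).

# small cohort config for cheap construction tests; events must be passed
# explicitly because the package defaults assume four groups on 16 chromosomes
tiny_config <- function(seed = 1L, cnv_events = list(), noise_sd = 1e-9,
                        reference_bias_sd = 0, group_sizes = c(2L, 2L),
                        n_terms = 0L, ...) {
  simulation_config(
    seed = seed, n_chromosomes = 2L, genes_per_chromosome = 20L,
    chromosome_length_bp = c(200000L, 300000L),
    subtelomere_length_bp = 30000L, group_sizes = group_sizes,
    cnv_events = cnv_events, noise_sd = noise_sd,
    reference_bias_sd = reference_bias_sd, n_terms = n_terms, ...
  )
}

# random symmetric zero-diagonal distance matrix with distinct off-diagonals
random_distance_matrix <- function(n, labels = LETTERS[seq_len(n)]) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.1, 10)
  d + t(d)
}

# naive agglomerative clustering: at every step recompute the inter-cluster
# distance as mean/max over ALL cross leaf pairs of the original matrix;
# returns the cophenetic matrix (height at which each leaf pair first joins)
oracle_cophenetic <- function(d, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- NULL
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) {
        cross <- d[clusters[[a]], clusters[[b]], drop = FALSE]
        dv <- if (linkage == "average") mean(cross) else max(cross)
        key <- sort(c(min(labels[clusters[[a]]]), min(labels[clusters[[b]]])))
        if (is.null(best) || dv < best$d - 1e-15 ||
            (dv <= best$d + 1e-15 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(a = a, b = b, d = dv, key = key)
        }
      }
    }
    h <- if (linkage == "average") best$d / 2 else best$d
    coph[clusters[[best$a]], clusters[[best$b]]] <- h
    coph[clusters[[best$b]], clusters[[best$a]]] <- h
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  coph
}

# exhaustive minimum of SSE + penalty * segments over all changepoint sets
oracle_segment_cost <- function(values, penalty) {
  n <- length(values)
  sse <- function(i, j) {
    v <- values[i:j]
    sum((v - mean(v))^2)
  }
  if (n == 1L) return(penalty)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    cost <- sum(mapply(sse, starts, ends)) + penalty * length(starts)
    if (cost < best) best <- cost
  }
  best
}

# direct-ratio hypergeometric upper tail (no logs)
oracle_hyper_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# cost of a segmentation as returned by segment_profile
segmentation_cost <- function(seg, values, penalty) {
  sse <- mapply(function(i, j) {
    v <- values[i:j]
    sum((v - mean(v))^2)
  }, seg$start_index, seg$end_index)
  sum(sse) + penalty * nrow(seg)
}

cophenetic_matrix <- function(dendro) {
  as.matrix(stats::cophenetic(stats::as.hclust(dendro)))
}
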