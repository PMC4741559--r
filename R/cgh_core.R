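#' Re-normalize log2 ratios against the cohort average
#'
#' Each gene's value is re-expressed relative to the arithmetic mean of its
#' log2 ratios over all strains in the cohort (the strain itself included;
#' missing values excluded from the mean). Because all strains were hybridized
#' against the same reference, any per-gene probe-level bias is an additive
#' constant across strains and cancels exactly; after re-normalization every
#' gene's cross-strain mean is zero. The operation is idempotent.
#'
#' @param matrix numeric genes x strains matrix of log2 ratios; `NA` allowed.
#' @return Matrix of the same shape (rows observed in no strain are dropped
#'   with a warning).
#' @export
renormalize <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (ncol(matrix) < 2L) stop("need at least 2 strains")
  n_obs <- rowSums(!is.na(matrix))
  if (any(n_obs == 0L)) {
    warning(sprintf("%d gene(s) missing in all strains dropped", sum(n_obs == 0L)))
    matrix <- matrix[n_obs > 0L, , drop = FALSE]
  }
  sweep(matrix, 1, rowMeans(matrix, na.rm = TRUE), "-")
}

# population SD (divide by n); NA excluded; NA if fewer than min_n observed
pop_sd <- function(x, min_n = 2L) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < min_n) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# centered moving average with symmetric window shrink at the ends;
# never pads, never wraps. NA values are excluded from each window mean.
moving_average_shrink <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    hh <- min(h, i - 1L, n - i)
    out[i] <- mean(x[(i - hh):(i + hh)], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Per-gene divergence profile with moving-average smoothing
#'
#' For every gene, the population standard deviation (divide by n) of its
#' log2 ratios across strains measures how much copy number diverges among
#' strains at that locus. A centered moving average over genes in genome
#' order, computed separately per chromosome (windows never cross chromosome
#' boundaries and shrink symmetrically at chromosome ends), exposes regional
#' divergence hotspots such as the subtelomeres.
#'
#' @param matrix genes x strains log2-ratio matrix (re-normalized or raw —
#'   the caller's choice).
#' @param annotation a [genome_annotation()]; only annotated genes are
#'   profiled, in genome order.
#' @param window odd positive integer smoother width in genes (default 21).
#' @return A `data.frame` (`gene_id`, `chromosome`, `start`, `order`, `sd`,
#'   `smoothed_sd`) in genome order. Genes observed in fewer than 2 strains
#'   get `NA` sd.
#' @export
divergence_profile <- function(matrix, annotation, window = 21L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 1")
  }
  ann <- annotation[annotation$gene_id %in% rownames(matrix), , drop = FALSE]
  ann <- ann[order(ann$chromosome, ann$start, ann$gene_id), , drop = FALSE]
  vals <- matrix[ann$gene_id, , drop = FALSE]
  sds <- apply(vals, 1, pop_sd)
  smoothed <- unlist(lapply(split(seq_len(nrow(ann)), ann$chromosome),
                            function(idx) moving_average_shrink(sds[idx], window)),
                     use.names = FALSE)
  data.frame(
    gene_id = ann$gene_id, chromosome = ann$chromosome, start = ann$start,
    order = seq_len(nrow(ann)), sd = unname(sds), smoothed_sd = smoothed,
    stringsAsFactors = FALSE
  )
}

#' Optimal piecewise-constant segmentation by penalized least squares
#'
#' Finds the exact minimizer of
#' `sum of squared residuals to segment means + penalty * (number of
#' segments)` over all change-point placements, by dynamic programming.
#' This is the stated, exactly testable replacement for interactive
#' piecewise-regression CGH viewers: it highlights aneuploid blocks in one
#' strain's ordered log2-ratio profile. Ties in total cost are resolved
#' toward fewer segments.
#'
#' @param values ordered numeric vector (one strain, one chromosome).
#' @param penalty positive per-segment penalty. Default `2 * sigma^2 * log(n)`
#'   with `sigma` the median absolute deviation of first differences divided
#'   by `sqrt(2) * 0.6745` (a robust noise estimate).
#' @return A `data.frame` (`start_index`, `end_index`, `mean`) partitioning
#'   `1..n`, with the penalty used stored in `attr(, "penalty")`.
#' @export
segment_profile <- function(values, penalty = NULL) {
  n <- length(values)
  if (n < 1L) stop("empty input")
  if (anyNA(values)) stop("missing values not allowed in segmentation input")
  if (is.null(penalty)) {
    sigma <- if (n >= 2L) {
      stats::mad(diff(values), constant = 1) / (sqrt(2) * 0.6745)
    } else 0
    penalty <- max(2 * sigma^2 * log(n), 1e-12)
  }
  if (penalty <= 0) stop("penalty must be > 0")

  s1 <- c(0, cumsum(values))
  s2 <- c(0, cumsum(values^2))
  cost <- c(0, rep(Inf, n))
  nseg <- c(0L, rep(0L, n))
  back <- integer(n)
  for (j in seq_len(n)) {
    i <- seq_len(j)
    sse <- (s2[j + 1] - s2[i]) - (s1[j + 1] - s1[i])^2 / (j - i + 1)
    cand <- cost[i] + sse + penalty
    ns <- nseg[i] + 1L
    # among candidates tied (to 1e-12) with the minimum, prefer fewer segments
    ties <- which(cand <= min(cand) + 1e-12)
    pick <- ties[which.min(ns[ties])]
    cost[j + 1] <- cand[pick]
    nseg[j + 1] <- ns[pick]
    back[j] <- pick
  }

  ends <- integer(0)
  j <- n
  while (j >= 1L) {
    ends <- c(j, ends)
    j <- back[j] - 1L
  }
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- data.frame(
    start_index = starts, end_index = ends,
    mean = mapply(function(i, j) mean(values[i:j]), starts, ends)
  )
  attr(out, "penalty") <- penalty
  attr(out, "cost") <- cost[n + 1]
  out
}

#' Call copy-number gains and losses over named regions
#'
#' Averages re-normalized log2 ratios over the genes of each region (gene
#' membership by midpoint) and calls a gain when the mean is at or above
#' `+threshold`, a loss at or below `-threshold`, otherwise neutral. Regions
#' containing no annotated gene are reported with call `"missing"`.
#'
#' @param matrix re-normalized genes x strains log2-ratio matrix.
#' @param annotation a [genome_annotation()].
#' @param regions `data.frame` with columns `name`, `chromosome`, `start`,
#'   `end` (1-based closed).
#' @param threshold positive call threshold in log2 units (default 0.2),
#'   boundary inclusive.
#' @return `data.frame` (`strain`, `region`, `call`, `mean_log2`, `n_genes`).
#' @export
call_region_events <- function(matrix, annotation, regions, threshold = 0.2) {
  if (threshold <= 0) stop("threshold must be > 0")
  stopifnot(all(c("name", "chromosome", "start", "end") %in% names(regions)))
  mid <- gene_midpoint(annotation)
  out <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    genes <- annotation$gene_id[annotation$chromosome == regions$chromosome[r] &
                                  mid >= regions$start[r] & mid <= regions$end[r]]
    genes <- intersect(genes, rownames(matrix))
    if (length(genes) == 0L) {
      out[[r]] <- data.frame(strain = colnames(matrix),
                             region = regions$name[r], call = "missing",
                             mean_log2 = NA_real_, n_genes = 0L,
                             stringsAsFactors = FALSE)
      next
    }
    m <- colMeans(matrix[genes, , drop = FALSE], na.rm = TRUE)
    call <- ifelse(m >= threshold, "gain",
                   ifelse(m <= -threshold, "loss", "neutral"))
    out[[r]] <- data.frame(strain = colnames(matrix),
                           region = regions$name[r], call = unname(call),
                           mean_log2 = unname(m), n_genes = length(genes),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subtelomeric windows of every chromosome as a region table
#'
#' Convenience region set for [call_region_events()]: one region per
#' chromosome end, spanning the subtelomeric window used by the annotation.
#'
#' @param annotation a [genome_annotation()].
#' @param subtelomere_length_bp window length at each end.
#' @param chromosome_length_bp chromosome lengths; by default taken as the
#'   maximum gene end per chromosome.
#' @return `data.frame` with columns `name`, `chromosome`, `start`, `end`.
#' @export
subtelomeric_regions <- function(annotation, subtelomere_length_bp = 30000L,
                                 chromosome_length_bp = NULL) {
  chroms <- sort(unique(annotation$chromosome))
  if (is.null(chromosome_length_bp)) {
    chromosome_length_bp <- vapply(chroms, function(chr) {
      max(annotation$end[annotation$chromosome == chr])
    }, numeric(1))
  }
  do.call(rbind, lapply(seq_along(chroms), function(i) {
    chr <- chroms[i]; L <- chromosome_length_bp[i]
    data.frame(
      name = sprintf(c("chr%02d_L", "chr%02d_R"), chr),
      chromosome = chr,
      start = c(1L, as.integer(L - subtelomere_length_bp + 1)),
      end = c(as.integer(subtelomere_length_bp), as.integer(L)),
      stringsAsFactors = FALSE
    )
  }))
}
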