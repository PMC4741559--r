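#' Default chromosome lengths (bp)
#'
#' The sixteen Saccharomyces cerevisiae chromosome lengths, rounded to the
#' kilobase. These double as the electrophoretic band ladder in
#' [simulate_bands()].
#'
#' @return Integer vector of length 16, in bp.
#' @export
default_chromosome_lengths <- function() {
  1000L * c(230L, 813L, 317L, 1532L, 577L, 270L, 1090L, 563L,
            440L, 746L, 667L, 1078L, 924L, 784L, 1091L, 948L)
}

#' Define a copy-number variation event
#'
#' An event adds `delta_log2` to every gene whose midpoint lies within
#' `[start, end]` on `chromosome`, for all strains of group `group`.
#' Opposite-sign events on the same region in different groups model
#' gene-family blocks (such as the Y'-element YRF1 helicase genes) gained in
#' one species group and lost in another.
#'
#' @param group 1-based group index the event applies to.
#' @param chromosome 1-based chromosome index.
#' @param start,end 1-based closed region in bp.
#' @param delta_log2 signed log2-ratio shift; must be non-zero.
#' @param label free-text description.
#' @return A list of class `cnv_event`.
#' @export
cnv_event <- function(group, chromosome, start, end, delta_log2,
                      label = "") {
  if (delta_log2 == 0) stop("delta_log2 must be non-zero")
  if (start > end || start < 1) stop("invalid event region")
  structure(
    list(group = as.integer(group), chromosome = as.integer(chromosome),
         start = as.integer(start), end = as.integer(end),
         delta_log2 = as.numeric(delta_log2), label = as.character(label)),
    class = "cnv_event"
  )
}

#' Default planted CNV event set
#'
#' Emulates the copy-number structure of a four-group distillery-yeast cohort:
#' subtelomeric YRF1-like helicase blocks gained (+1) in group 1 and group 4
#' and lost (-1) in group 2, plus two group-private subtelomeric events per
#' group. Events cover 12 of the 16 chromosomes and lie entirely inside the
#' subtelomeric windows.
#'
#' @param chromosome_length_bp chromosome lengths in bp.
#' @param subtelomere_length_bp subtelomere window at each chromosome end.
#' @param delta absolute effect size in log2 units (default 1.0).
#' @return List of [cnv_event()] objects.
#' @export
default_cnv_events <- function(chromosome_length_bp = default_chromosome_lengths(),
                               subtelomere_length_bp = 30000L,
                               delta = 1.0) {
  L <- chromosome_length_bp
  w <- subtelomere_length_bp
  left <- function(chr) c(1L, w)
  right <- function(chr) c(L[chr] - w + 1L, L[chr])
  ev <- list()
  add <- function(group, chr, reg, d, label) {
    ev[[length(ev) + 1L]] <<- cnv_event(group, chr, reg[1], reg[2], d, label)
  }
  # YRF1-like subtelomeric helicase blocks: gained in groups 1 and 4, lost in 2
  for (chr in c(5L, 7L, 12L, 15L)) {
    add(1L, chr, right(chr), +delta, "YRF1-like block gain")
    add(2L, chr, right(chr), -delta, "YRF1-like block loss")
    add(4L, chr, right(chr), +delta, "YRF1-like block gain")
  }
  # group-private subtelomeric events
  add(1L, 2L, left(2L), +delta, "group1 private gain")
  add(1L, 9L, right(9L), -delta, "group1 private loss")
  add(2L, 3L, left(3L), -delta, "group2 private loss")
  add(2L, 10L, left(10L), +delta, "group2 private gain")
  add(3L, 6L, right(6L), +delta, "group3 private gain")
  add(3L, 13L, left(13L), -delta, "group3 private loss")
  add(4L, 1L, right(1L), +delta, "group4 private gain")
  add(4L, 4L, left(4L), -delta, "group4 private loss")
  ev
}

#' Build a simulation configuration
#'
#' The defaults describe the cohort the pipeline is designed around: 22
#' diploid strains in four species groups (7, 13, 1, 1) on 16 chromosomes of
#' realistic yeast lengths with 300 genes each, copy-number divergence
#' confined to 30 kb subtelomeric windows, a per-gene reference-strain
#' hybridization bias shared by all strains, and i.i.d. Gaussian probe noise.
#'
#' @param seed integer RNG seed; the whole cohort is deterministic given it.
#' @param n_chromosomes number of chromosomes.
#' @param genes_per_chromosome genes laid out uniformly per chromosome.
#' @param chromosome_length_bp vector of chromosome lengths (recycled to
#'   `n_chromosomes`).
#' @param subtelomere_length_bp subtelomeric window at both chromosome ends.
#' @param group_sizes strains per group; their sum is the cohort size.
#' @param cnv_events list of [cnv_event()] objects (`NULL` = default set,
#'   `list()` = no events).
#' @param noise_sd per-entry Gaussian noise standard deviation (> 0).
#' @param reference_bias_sd standard deviation of the per-gene additive bias
#'   shared by all strains (>= 0); emulates probe-level hybridization
#'   differences against a common reference strain.
#' @param n_terms number of functional categories to simulate.
#' @param genes_per_term members per category.
#' @param band_jitter_sd multiplicative jitter of band sizes (sd on the
#'   relative scale; ~gel sizing error).
#' @param marker_bands list (one numeric vector per group) of group-specific
#'   marker band sizes in kb; `NULL` picks one marker per group from a preset
#'   ladder whose first entry is the ~1300 kb band characteristic of group 1.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 16L,
                              genes_per_chromosome = 300L,
                              chromosome_length_bp = default_chromosome_lengths(),
                              subtelomere_length_bp = 30000L,
                              group_sizes = c(7L, 13L, 1L, 1L),
                              cnv_events = NULL,
                              noise_sd = 0.15,
                              reference_bias_sd = 0.3,
                              n_terms = 30L,
                              genes_per_term = 40L,
                              band_jitter_sd = 0.005,
                              marker_bands = NULL) {
  n_chromosomes <- as.integer(n_chromosomes)
  chromosome_length_bp <- as.integer(rep_len(chromosome_length_bp, n_chromosomes))
  group_sizes <- as.integer(group_sizes)
  if (n_chromosomes < 1L || genes_per_chromosome < 1L) {
    stop("need at least one chromosome and one gene per chromosome")
  }
  if (length(group_sizes) < 1L || any(group_sizes < 1L)) {
    stop("group sizes must be positive; zero strains rejected")
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (reference_bias_sd < 0) stop("reference_bias_sd must be >= 0")
  if (any(subtelomere_length_bp >= chromosome_length_bp / 2)) {
    stop("subtelomere_length_bp must be < chromosome_length_bp / 2")
  }
  if (is.null(cnv_events)) {
    cnv_events <- default_cnv_events(chromosome_length_bp, subtelomere_length_bp)
  }
  for (ev in cnv_events) {
    if (ev$group > length(group_sizes)) stop("event group index out of range")
    if (ev$chromosome > n_chromosomes ||
        ev$end > chromosome_length_bp[ev$chromosome]) {
      stop("event region outside its chromosome")
    }
  }
  if (is.null(marker_bands)) {
    ladder <- c(1300, 1400, 170, 2000, 2600, 135, 3000, 120)
    if (length(group_sizes) > length(ladder)) {
      stop("supply marker_bands explicitly for more than 8 groups")
    }
    marker_bands <- lapply(seq_along(group_sizes), function(g) ladder[g])
  }
  if (length(marker_bands) != length(group_sizes)) {
    stop("marker_bands must have one entry per group")
  }
  structure(
    list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
         genes_per_chromosome = as.integer(genes_per_chromosome),
         chromosome_length_bp = chromosome_length_bp,
         subtelomere_length_bp = as.integer(subtelomere_length_bp),
         group_sizes = group_sizes, cnv_events = cnv_events,
         noise_sd = noise_sd, reference_bias_sd = reference_bias_sd,
         n_terms = as.integer(n_terms),
         genes_per_term = as.integer(genes_per_term),
         band_jitter_sd = band_jitter_sd, marker_bands = marker_bands),
    class = "simulation_config"
  )
}

# annotation implied by a config: genes tile each chromosome uniformly
config_annotation <- function(config) {
  rows <- lapply(seq_len(config$n_chromosomes), function(chr) {
    n <- config$genes_per_chromosome
    L <- config$chromosome_length_bp[chr]
    w <- L / n
    start <- floor((seq_len(n) - 1) * w) + 1
    end <- floor(seq_len(n) * w)
    mid <- (start + end) / 2
    data.frame(
      gene_id = sprintf("g%02d_%04d", chr, seq_len(n)),
      chromosome = chr, start = start, end = end,
      subtelomeric = mid <= config$subtelomere_length_bp |
        mid >= L - config$subtelomere_length_bp + 1,
      stringsAsFactors = FALSE
    )
  })
  ann <- do.call(rbind, rows)
  genome_annotation(ann$gene_id, ann$chromosome, ann$start, ann$end,
                    ann$subtelomeric)
}

config_strain_ids <- function(config) {
  sprintf("strain_%02d", seq_len(sum(config$group_sizes)))
}

# net per-gene, per-group delta matrix; warns on overlapping same-group events
config_delta_matrix <- function(config, annotation) {
  n_groups <- length(config$group_sizes)
  delta <- matrix(0, nrow(annotation), n_groups,
                  dimnames = list(annotation$gene_id, NULL))
  hits <- matrix(0L, nrow(annotation), n_groups)
  mid <- gene_midpoint(annotation)
  for (ev in config$cnv_events) {
    covered <- annotation$chromosome == ev$chromosome &
      mid >= ev$start & mid <= ev$end
    delta[covered, ev$group] <- delta[covered, ev$group] + ev$delta_log2
    hits[covered, ev$group] <- hits[covered, ev$group] + 1L
  }
  if (any(hits > 1L)) {
    warning("overlapping CNV events for the same group and gene; deltas summed")
  }
  delta
}

#' Simulate a synthetic array-CGH cohort
#'
#' Generates `value[g, s] = bias[g] + delta(g, group(s)) + N(0, noise_sd)`:
#' a per-gene additive bias shared by all strains (the reference-strain
#' hybridization artifact that cohort-average re-normalization must cancel),
#' planted group-specific copy-number shifts from the configured CNV events,
#' and i.i.d. Gaussian noise. Also produces a matched functional-category
#' collection (one term planted inside the event regions, the rest uniform
#' background) and PFGE band patterns via [simulate_bands()].
#'
#' @param config a [simulation_config()].
#' @return A list of class `synthetic_cohort` with elements `annotation`,
#'   `matrix` (genes x strains log2 ratios), `truth_divergent_genes`
#'   (gene ids with a non-zero planted shift in some group),
#'   `truth_partition` (named strain -> group index), `terms`
#'   (named list of gene-id vectors with a `descriptions` attribute),
#'   `bands` (named list of band-size vectors, kb) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  annotation <- config_annotation(config)
  strains <- config_strain_ids(config)
  groups <- rep(seq_along(config$group_sizes), config$group_sizes)
  names(groups) <- strains
  delta <- config_delta_matrix(config, annotation)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  n_genes <- nrow(annotation)
  n_strains <- length(strains)
  bias <- stats::rnorm(n_genes, 0, config$reference_bias_sd)
  noise <- matrix(stats::rnorm(n_genes * n_strains, 0, config$noise_sd),
                  n_genes, n_strains)
  mat <- bias + delta[, groups, drop = FALSE] + noise
  dimnames(mat) <- list(annotation$gene_id, strains)

  truth <- annotation$gene_id[apply(abs(delta), 1, max) > 0]

  terms <- list()
  if (config$n_terms > 0L) {
    descs <- character(config$n_terms)
    k <- config$genes_per_term
    for (i in seq_len(config$n_terms)) {
      id <- sprintf("TERM_%03d", i)
      if (i == 1L && length(truth) > 0L) {
        terms[[id]] <- sort(sample(truth, min(k, length(truth))))
        descs[i] <- "planted: subtelomeric CNV block genes"
      } else {
        terms[[id]] <- sort(sample(annotation$gene_id, min(k, n_genes)))
        descs[i] <- "background category"
      }
    }
    attr(terms, "descriptions") <- stats::setNames(descs, names(terms))
  }

  structure(
    list(annotation = annotation, matrix = mat,
         truth_divergent_genes = truth, truth_partition = groups,
         terms = terms, bands = simulate_bands(config), config = config),
    class = "synthetic_cohort"
  )
}

#' Simulate PFGE band patterns for a cohort
#'
#' Each strain receives the chromosome-size ladder (kb) under small
#' multiplicative jitter plus the marker bands of its group (for the default
#' configuration, group 1 carries the ~1300 kb band characteristic of its
#' species). Co-migration of similarly sized chromosomes is not modeled here;
#' it emerges downstream from band binning. Uses seed `config$seed + 1` so
#' band patterns are identical whether drawn standalone or as part of
#' [simulate_cohort()].
#'
#' @param config a [simulation_config()].
#' @return Named list (strain id -> sorted numeric vector of band sizes, kb).
#' @export
simulate_bands <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  strains <- config_strain_ids(config)
  groups <- rep(seq_along(config$group_sizes), config$group_sizes)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed + 1L)

  ladder <- config$chromosome_length_bp / 1000
  out <- vector("list", length(strains))
  names(out) <- strains
  for (s in seq_along(strains)) {
    sizes <- c(ladder, config$marker_bands[[groups[s]]])
    jitter <- 1 + stats::rnorm(length(sizes), 0, config$band_jitter_sd)
    out[[s]] <- sort(sizes * jitter)
  }
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d genes x %d strains (%s groups), %d divergent genes, %d terms\n",
    nrow(x$matrix), ncol(x$matrix),
    paste(x$config$group_sizes, collapse = "/"),
    length(x$truth_divergent_genes), length(x$terms)))
  invisible(x)
}
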