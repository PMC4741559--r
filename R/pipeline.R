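#' Write every artifact of a synthetic cohort to a directory
#'
#' Emits `matrix.tsv`, `annotation.tsv`, `terms.gmt`, `bands.tsv` and
#' `truth.json` (divergent gene ids and the strain-to-group assignment).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(cohort$matrix, file.path(out_dir, "matrix.tsv"))
  write_annotation_tsv(cohort$annotation, file.path(out_dir, "annotation.tsv"))
  write_gmt(cohort$terms, file.path(out_dir, "terms.gmt"))
  write_bands_tsv(cohort$bands, file.path(out_dir, "bands.tsv"))
  jsonlite::write_json(
    list(truth_divergent_genes = cohort$truth_divergent_genes,
         truth_partition = as.list(cohort$truth_partition)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Segment every strain's profile chromosome by chromosome
#'
#' Applies [segment_profile()] to each strain on each chromosome (genes in
#' genome order) and collects the segments as a BED-like table.
#'
#' @param matrix re-normalized genes x strains log2-ratio matrix.
#' @param annotation a [genome_annotation()].
#' @param penalty per-segment penalty; `NULL` = automatic per profile.
#' @return `data.frame` (`strain`, `chromosome`, `start`, `end`, `n_genes`,
#'   `mean_log2`).
#' @export
segment_matrix <- function(matrix, annotation, penalty = NULL) {
  ord <- annotation[order(annotation$chromosome, annotation$start,
                          annotation$gene_id), ]
  seg_rows <- list()
  for (s in colnames(matrix)) {
    for (chr in unique(ord$chromosome)) {
      genes <- ord$gene_id[ord$chromosome == chr]
      genes <- genes[genes %in% rownames(matrix)]
      v <- matrix[genes, s]
      keep <- !is.na(v)
      genes <- genes[keep]; v <- v[keep]
      if (length(v) == 0L) next
      seg <- segment_profile(v, penalty = penalty)
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        strain = s, chromosome = chr,
        start = ord$start[match(genes[seg$start_index], ord$gene_id)],
        end = ord$end[match(genes[seg$end_index], ord$gene_id)],
        n_genes = seg$end_index - seg$start_index + 1L,
        mean_log2 = seg$mean, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, seg_rows)
  rownames(out) <- NULL
  out
}

#' Assemble a pipeline configuration
#'
#' Collects the input paths and every tunable parameter of the end-to-end
#' analysis. All parameters carry the package defaults so a config needs
#' only the file paths.
#'
#' @param matrix path to the log2-ratio matrix TSV.
#' @param annotation path to the annotation TSV.
#' @param terms optional path to a GMT file.
#' @param bands optional path to a bands TSV (enables the karyotype branch).
#' @param out_dir output directory.
#' @param window divergence smoother width (odd, genes).
#' @param k SD multiplier of the divergent-gene selection.
#' @param alpha FDR significance level.
#' @param tolerance relative band-binning tolerance.
#' @param penalty segmentation penalty (`NULL` = automatic per profile).
#' @param threshold region gain/loss call threshold (log2 units).
#' @param n_clusters tree-cut depth reported for both trees.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix, annotation, terms = NULL, bands = NULL,
                            out_dir = ".", window = 21L, k = 4,
                            alpha = 0.05, tolerance = 0.05, penalty = NULL,
                            threshold = 0.2, n_clusters = 4L) {
  for (p in c(matrix, annotation, terms, bands)) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
  }
  structure(
    list(matrix = matrix, annotation = annotation, terms = terms,
         bands = bands, out_dir = out_dir, window = as.integer(window),
         k = k, alpha = alpha, tolerance = tolerance, penalty = penalty,
         threshold = threshold, n_clusters = as.integer(n_clusters)),
    class = "pipeline_config"
  )
}

#' Run the full strain-comparison pipeline
#'
#' Executes, in order: cohort-average re-normalization, the divergence (SD)
#' profile with moving-average smoothing, per-strain per-chromosome
#' segmentation, subtelomeric-region gain/loss calls, divergent-gene
#' selection, functional-category overrepresentation, complete-linkage
#' strain clustering — and, when band patterns are supplied, the karyotype
#' branch (band binning, Jaccard, UPGMA). Every stage writes a TSV or Newick
#' artifact into `out_dir`; a JSON run report records all parameter values
#' (defaulted ones included, so runs are auditable) and headline numbers.
#' The pipeline contains no randomness, so identical configs give identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return The run report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  mat <- read_matrix_tsv(config$matrix)
  ann <- read_annotation_tsv(config$annotation)

  norm <- renormalize(mat)
  write_matrix_tsv(norm, file.path(out, "normalized.tsv"))

  profile <- divergence_profile(norm, ann, window = config$window)
  utils::write.table(profile, file.path(out, "divergence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  segments <- segment_matrix(norm, ann, penalty = config$penalty)
  utils::write.table(segments, file.path(out, "segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  regions <- subtelomeric_regions(ann)
  calls <- call_region_events(norm, ann, regions, threshold = config$threshold)
  utils::write.table(calls, file.path(out, "region_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sel <- select_divergent(norm, k = config$k)
  utils::write.table(sel$table, file.path(out, "selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  enr <- NULL
  if (!is.null(config$terms)) {
    terms <- read_gmt(config$terms)
    universe <- intersect(rownames(norm),
                          unique(unlist(terms, use.names = FALSE)))
    if (length(terms) > 0L && length(universe) > 0L) {
      # restricting the universe to annotated genes is deliberate here, so
      # pre-intersect instead of letting enrich() warn about the rest
      enr <- enrich(intersect(sel$selected, universe), terms, universe,
                    alpha = config$alpha)
    } else {
      enr <- enrich(character(0), list(), rownames(norm))
    }
    utils::write.table(enr, file.path(out, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  tree <- complete_linkage(euclidean_distances(norm))
  write_newick(tree, file.path(out, "strain_tree.nwk"))
  writeLines(leaf_order(tree), file.path(out, "strain_order.txt"))
  cgh_cut <- cut_dendrogram(tree, min(config$n_clusters, ncol(norm)))

  kary <- NULL
  if (!is.null(config$bands)) {
    bands <- read_bands_tsv(config$bands)
    presence <- bin_bands(bands, tolerance = config$tolerance)
    J <- jaccard_similarity(presence)
    utils::write.table(
      data.frame(strain_id = rownames(J), J, check.names = FALSE),
      file.path(out, "karyotype_similarity.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    ktree <- upgma(1 - J)
    write_newick(ktree, file.path(out, "karyotype_tree.nwk"))
    kary <- list(n_bins = ncol(presence),
                 cut = cut_dendrogram(ktree, min(config$n_clusters, nrow(J))))
  }

  report <- list(
    parameters = list(window = config$window, k = config$k,
                      alpha = config$alpha, tolerance = config$tolerance,
                      penalty = if (is.null(config$penalty)) "auto" else config$penalty,
                      threshold = config$threshold,
                      n_clusters = config$n_clusters),
    n_genes = nrow(norm), n_strains = ncol(norm),
    global_sd = sel$global_sd, selection_threshold = sel$threshold,
    n_selected = length(sel$selected),
    n_segments = if (is.null(segments)) 0L else nrow(segments),
    significant_terms = if (is.null(enr)) character(0) else
      enr$term_id[enr$significant],
    cgh_clusters = as.list(cgh_cut),
    karyotype_clusters = if (is.null(kary)) NULL else as.list(kary$cut),
    tree_files = c("strain_tree.nwk",
                   if (!is.null(kary)) "karyotype_tree.nwk")
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
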