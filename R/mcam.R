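#' Multiple clustering analysis of a quantitative dataset
#'
#' The top-level entry point: expands the clustering parameter grid, builds
#' the ensemble of partitions, scores every cluster of every partition for
#' label enrichment under per-(set, category) BH FDR control, optionally
#' prunes parameters whose removal improves the ensemble-wide enrichment
#' yield, and computes the consensus co-occurrence matrix of the final
#' ensemble.
#'
#' @param dataset a [quant_dataset()] (or path to a wide TSV readable by
#'   [read_dataset()]).
#' @param annotations an `annotation_table` (or path to a long TSV).
#' @param transforms,distances,algorithms,k_grid parameter vocabularies for
#'   [expand_grid_configs()]; `k_grid = NULL` uses [default_k_grid()] on the
#'   dataset (Kmax from roughly `per_cluster` peptides per cluster).
#' @param per_cluster peptides-per-cluster bound for the default K grid.
#' @param alpha FDR level for enrichment (default 0.05).
#' @param fdr_method `"BH"` (default) or `"bonferroni"`.
#' @param include_dynamic add quartile-binned dynamic metrics
#'   ([dynamic_labels()]) as enrichable categories (default TRUE).
#' @param prune apply parameter refinement (default TRUE).
#' @param improve_threshold,degrade_threshold pruning thresholds (2% / 10%).
#' @param seed base seed for per-configuration seeds.
#' @return An object of class `mcam`: list with `dataset`, `annotations`
#'   (including dynamic categories if requested), `mca` (the full ensemble),
#'   `enrichment` (full-ensemble table), `pruned_mca`, `pruned_enrichment`,
#'   `prune_report`, `co_occurrence` (of the pruned ensemble), `alpha`,
#'   `call`.
#' @examples
#' spec <- synthetic_spec(n_peptides = 24, n_groups = 3, seed = 7)
#' gen <- generate_dataset(spec)
#' ann <- generate_annotations(gen$groups, spec)
#' fit <- mcam(gen$dataset, ann,
#'             transforms = c("raw", "zscore"),
#'             distances = "euclidean",
#'             algorithms = c("Kmeans", "Hierarchical"),
#'             k_grid = c(2, 4))
#' print(fit)
#' @export
mcam <- function(dataset, annotations,
                 transforms = transform_names(),
                 distances = distance_names(),
                 algorithms = algorithm_names(),
                 k_grid = NULL, per_cluster = 5,
                 alpha = 0.05, fdr_method = "BH",
                 include_dynamic = TRUE,
                 prune = TRUE,
                 improve_threshold = 0.02, degrade_threshold = 0.10,
                 seed = 1L) {
  cl <- match.call()
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  if (is.character(annotations)) {
    annotations <- read_annotations(annotations, dataset)
  }
  if (is.null(k_grid)) {
    k_grid <- default_k_grid(nrow(dataset$values), per_cluster)
  }
  configs <- expand_grid_configs(transforms, distances, algorithms, k_grid,
                                 base_seed = seed)
  ann <- annotations
  if (include_dynamic) {
    ann <- rbind_annotations(ann, dynamic_labels(dataset))
  }
  mca <- build_mca(dataset, configs)
  enr <- enrich_mca(mca, ann, alpha = alpha, method = fdr_method)
  pruned_mca <- mca
  pruned_enr <- enr
  report <- NULL
  if (prune) {
    pr <- prune_mca(mca, enr, improve_threshold = improve_threshold,
                    degrade_threshold = degrade_threshold)
    pruned_mca <- pr$mca
    report <- pr$report
    if (length(pr$pruned_labels) > 0L) {
      pruned_enr <- enrich_mca(pruned_mca, ann, alpha = alpha,
                               method = fdr_method)
    }
  }
  structure(list(
    dataset = dataset, annotations = ann,
    mca = mca, enrichment = enr,
    pruned_mca = pruned_mca, pruned_enrichment = pruned_enr,
    prune_report = report,
    co_occurrence = co_occurrence(pruned_mca),
    alpha = alpha, seed = seed, call = cl
  ), class = "mcam")
}

#' @export
print.mcam <- function(x, ...) {
  cat("Multiple clustering analysis\n")
  cat(sprintf("  peptides: %d, conditions: %d\n",
              nrow(x$dataset$values), ncol(x$dataset$values)))
  cat(sprintf("  ensemble: %d sets (%d after pruning, %d skipped)\n",
              length(x$mca$sets), length(x$pruned_mca$sets),
              length(x$mca$skipped)))
  cat(sprintf("  significant labels (pruned ensemble): %d at FDR %.2g\n",
              sum(x$pruned_enrichment$significant), x$alpha))
  invisible(x)
}

#' @export
summary.mcam <- function(object, ...) {
  enr <- object$pruned_enrichment
  by_cat <- if (nrow(enr)) {
    agg <- stats::aggregate(significant ~ category, enr,
                            function(z) c(tests = length(z), sig = sum(z)))
    data.frame(category = agg$category,
               tests = agg$significant[, "tests"],
               significant = agg$significant[, "sig"])
  } else data.frame(category = character(), tests = integer(),
                    significant = integer())
  structure(list(
    n_sets_full = length(object$mca$sets),
    n_sets_pruned = length(object$pruned_mca$sets),
    pruned_parameters = if (!is.null(object$prune_report)) {
      pr <- object$prune_report
      paste(pr$type[pr$pruned], pr$value[pr$pruned], sep = "=")
    } else character(),
    by_category = by_cat,
    co_occurrence = co_occurrence_summary(object$co_occurrence),
    mean_significant_per_set =
      enrichment_score(enr, seq_along(object$pruned_mca$sets)),
    alpha = object$alpha
  ), class = "summary.mcam")
}

#' @export
print.summary.mcam <- function(x, ...) {
  cat(sprintf("MCA: %d sets, %d after pruning\n",
              x$n_sets_full, x$n_sets_pruned))
  if (length(x$pruned_parameters)) {
    cat("  pruned parameters:", paste(x$pruned_parameters, collapse = ", "),
        "\n")
  }
  cat(sprintf("  mean significant labels per set: %.2f (FDR %.2g)\n",
              x$mean_significant_per_set, x$alpha))
  cat("  enrichment by category:\n")
  if (nrow(x$by_category)) {
    for (i in seq_len(nrow(x$by_category))) {
      cat(sprintf("    %-14s %5d tests, %4d significant\n",
                  x$by_category$category[i], x$by_category$tests[i],
                  x$by_category$significant[i]))
    }
  }
  s <- x$co_occurrence
  cat(sprintf("  co-occurrence: %d pairs, %.1f%% never, %.1f%% majority\n",
              s$n_pairs, s$pct_never, s$pct_majority))
  invisible(x)
}

#' Heat-map of the consensus co-occurrence matrix
#'
#' Displays the log10 co-occurrence frequencies (zeros replaced by the
#' 0.5/M pseudo-count) of the pruned ensemble, with peptides ordered by
#' average-linkage hierarchical clustering of the co-occurrence
#' dissimilarity.
#'
#' @param x an `mcam` fit.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the displayed matrix.
#' @export
plot.mcam <- function(x, ...) {
  V <- co_occurrence_heatmap_values(x$co_occurrence)
  ord <- stats::hclust(stats::as.dist(1 - x$co_occurrence$freq),
                       method = "average")$order
  V <- V[ord, ord]
  graphics::image(seq_len(nrow(V)), seq_len(ncol(V)), V,
                  xlab = "peptide (clustered order)",
                  ylab = "peptide (clustered order)",
                  main = "log10 co-occurrence frequency", ...)
  invisible(V)
}

#' Cluster assignments of the pruned ensemble
#' @param object an `mcam` fit.
#' @param ... unused.
#' @return Integer matrix (peptides x sets) of the pruned ensemble's
#'   assignments.
#' @export
coef.mcam <- function(object, ...) {
  assignment_matrix(object$pruned_mca)
}
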