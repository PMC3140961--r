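#' Hypergeometric upper-tail probability
#'
#' Probability of observing `k` or more labeled peptides in a cluster of size
#' `n` drawn without replacement from a dataset of `N` peptides of which
#' `K_label` carry the label: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K_label, n)`. This is the elementary
#' overrepresentation test behind all enrichment calls.
#'
#' @param N dataset (background) size.
#' @param K_label number of peptides in the dataset bearing the label.
#' @param n cluster size.
#' @param k number of peptides in the cluster bearing the label.
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeom_tail <- function(N, K_label, n, k) {
  if (K_label > N || n > N || k > n || k > K_label || any(c(N, K_label, n, k) < 0)) {
    stop("inconsistent hypergeometric counts")
  }
  stats::phyper(k - 1, K_label, N - K_label, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up rejection flags
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param alpha target false discovery rate (default 0.05).
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Logical vector of rejections; monotone in `alpha`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (length(pvalues) == 0L) stop("empty p-value list")
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = method) <= alpha
}

#' Quartile-binned dynamic metrics of a dataset
#'
#' Computes, for every peptide on the untransformed data, four summary
#' statistics of its trajectory — minimum value, maximum value, maximum
#' consecutive increase (0 if the trajectory never rises) and maximum
#' consecutive decrease magnitude (0 if it never falls) — and bins each
#' statistic into dataset-wide quantile bins. The bin memberships
#' (e.g. `"MaxValue:Q4"`) act as enrichable labels marking features of the
#' dynamics, alongside the biological annotation categories.
#'
#' @param dataset a [quant_dataset()].
#' @param n_bins number of quantile bins (default 4, i.e. quartiles).
#' @return An `annotation_table` with categories `MinValue`, `MaxValue`,
#'   `MaxPosChange`, `MaxNegChange`; attribute `stats` holds the raw
#'   per-peptide statistics matrix.
#' @export
dynamic_labels <- function(dataset, n_bins = 4L) {
  V <- dataset$values
  stopifnot(ncol(V) >= 2L)
  d <- t(apply(V, 1L, diff))
  if (!is.matrix(d)) d <- matrix(d, nrow = nrow(V))
  stats <- cbind(
    MinValue = apply(V, 1L, min),
    MaxValue = apply(V, 1L, max),
    MaxPosChange = pmax(apply(d, 1L, max), 0),
    MaxNegChange = pmax(apply(-d, 1L, max), 0)
  )
  rownames(stats) <- dataset$peptides$peptide_id
  recs <- do.call(rbind, lapply(colnames(stats), function(metric) {
    x <- stats[, metric]
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 3L) {
      warning("degenerate quantiles for ", metric, ": single bin")
      bin <- rep(1L, length(x))
    } else {
      bin <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
    }
    data.frame(peptide_id = rownames(stats), category = metric,
               label = paste0(metric, ":Q", bin), score = NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(annotation_table(recs), stats = stats)
}

#' Names of the four dynamic-metric categories
#' @return Character vector.
#' @export
dynamic_metric_names <- function() {
  c("MinValue", "MaxValue", "MaxPosChange", "MaxNegChange")
}

#' Enrichment of every cluster of one clustering set
#'
#' For each cluster and each category, every label observed in the cluster
#' (k >= 1) is tested for overrepresentation against the full-dataset
#' background with [hypergeom_tail()]. P-values are accumulated for all tests
#' within a category across the whole cluster set and the
#' Benjamini-Hochberg procedure at `alpha` is applied per (set, category)
#' family to set the `significant` flags. The background size `N` is the
#' total number of peptides in the partition, annotated or not.
#'
#' @param cluster_set a `cluster_set` from [run_clustering()].
#' @param annotations an `annotation_table` (biological categories, possibly
#'   rbound with [dynamic_labels()] output).
#' @param alpha FDR level (default 0.05).
#' @param method `"BH"` or `"bonferroni"`.
#' @param set_id identifier stored in the output rows.
#' @return data.frame with columns set_id, category, cluster, label, k, n,
#'   K, N, p, significant.
#' @export
enrich_set <- function(cluster_set, annotations, alpha = 0.05,
                       method = "BH", set_id = 1L) {
  assign <- cluster_set$assignment
  peptides <- names(assign)
  N <- length(assign)
  ann <- annotations[annotations$peptide_id %in% peptides, , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(.empty_enrichment())
  }
  cluster_of <- assign[ann$peptide_id]
  cluster_sizes <- tabulate(assign, nbins = cluster_set$k_eff)
  out <- list()
  for (cat in unique(ann$category)) {
    rows <- ann$category == cat
    lab <- ann$label[rows]
    K_label <- table(lab)
    tab <- table(factor(cluster_of[rows], levels = seq_len(cluster_set$k_eff)),
                 lab)
    hits <- which(tab >= 1L, arr.ind = TRUE)
    if (nrow(hits) == 0L) next
    cl <- as.integer(rownames(tab)[hits[, 1L]])
    lb <- colnames(tab)[hits[, 2L]]
    k <- tab[hits]
    n <- cluster_sizes[cl]
    K <- as.integer(K_label[lb])
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    out[[cat]] <- data.frame(
      set_id = set_id, category = cat, cluster = cl, label = lb,
      k = as.integer(k), n = as.integer(n), K = K, N = N, p = p,
      significant = bh_fdr(p, alpha = alpha, method = method),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) return(.empty_enrichment())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.empty_enrichment <- function() {
  data.frame(set_id = integer(), category = character(), cluster = integer(),
             label = character(), k = integer(), n = integer(), K = integer(),
             N = integer(), p = numeric(), significant = logical(),
             stringsAsFactors = FALSE)
}

#' Enrichment of every set of an MCA
#'
#' Applies [enrich_set()] to every clustering set of the ensemble and
#' concatenates the records; FDR families remain per (set, category).
#'
#' @param mca an `mca` from [build_mca()].
#' @param annotations an `annotation_table`.
#' @param alpha FDR level.
#' @param method `"BH"` or `"bonferroni"`.
#' @return data.frame of enrichment records for all sets (set_id = position
#'   of the set in the MCA).
#' @export
enrich_mca <- function(mca, annotations, alpha = 0.05, method = "BH") {
  stopifnot(length(mca$sets) >= 1L)
  res <- do.call(rbind, lapply(seq_along(mca$sets), function(i) {
    enrich_set(mca$sets[[i]], annotations, alpha = alpha, method = method,
               set_id = i)
  }))
  rownames(res) <- NULL
  res
}

#' Significant-label counts per set (optionally per category)
#'
#' @param enrichment enrichment table from [enrich_mca()].
#' @param set_ids the full universe of set ids (sets with no records count 0).
#' @param category optional category restriction.
#' @return Named numeric vector of counts, one per set id.
#' @export
significant_counts <- function(enrichment, set_ids, category = NULL) {
  e <- enrichment
  if (!is.null(category)) e <- e[e$category == category, , drop = FALSE]
  e <- e[e$significant, , drop = FALSE]
  cnt <- table(factor(e$set_id, levels = set_ids))
  stats::setNames(as.numeric(cnt), as.character(set_ids))
}
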