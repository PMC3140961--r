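#' Mutual information between two partitions (nats)
#'
#' `I(X;Y) = sum_xy p(x,y) log[ p(x,y) / (p(x) p(y)) ]` with the joint
#' distribution estimated from cluster co-membership counts over the common
#' peptide index, `0 log 0 = 0`, natural logarithm. Used to quantify
#' agreement between two clustering solutions of the same dataset.
#'
#' @param part_a,part_b integer/factor cluster assignments of equal length.
#' @return Nonnegative scalar; equals the partition entropy when
#'   `part_a == part_b`, and 0 for independent partitions.
#' @export
mutual_information <- function(part_a, part_b) {
  if (length(part_a) != length(part_b)) stop("partition length mismatch")
  n <- length(part_a)
  joint <- table(part_a, part_b) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  terms <- joint * log(joint / outer(px, py))
  sum(terms[joint > 0])
}

#' Entropy of a partition (nats)
#' @param part cluster assignment vector.
#' @return Nonnegative scalar `H = -sum p log p`.
#' @export
partition_entropy <- function(part) {
  p <- table(part) / length(part)
  -sum(p[p > 0] * log(p[p > 0]))
}

#' Pairwise mutual-information matrix of an MCA
#'
#' @param mca an `mca`.
#' @return Symmetric matrix (sets x sets) of pairwise MI in nats; the
#'   diagonal holds each set's self-MI, i.e. its partition entropy.
#' @export
mi_matrix <- function(mca) {
  M <- length(mca$sets)
  stopifnot(M >= 2L)
  A <- assignment_matrix(mca)
  out <- matrix(0, M, M)
  for (i in seq_len(M)) {
    out[i, i] <- partition_entropy(A[, i])
    for (j in seq_len(i - 1L)) {
      out[i, j] <- out[j, i] <- mutual_information(A[, i], A[, j])
    }
  }
  labs <- vapply(mca$configs, config_label, character(1))
  dimnames(out) <- list(labs, labs)
  out
}

#' Mean pairwise MI within a parameter-matched subset
#'
#' Average of the off-diagonal pairwise mutual information over all sets of
#' the ensemble sharing the given parameter value(s) — the device for asking
#' whether a transform (say) drives similarity between solutions.
#'
#' @param mca an `mca`.
#' @param parameters named list/vector, e.g. `list(transform = "log10")` or
#'   several selectors combined with AND.
#' @param mi optional precomputed [mi_matrix()].
#' @return Scalar mean off-diagonal MI within the subset.
#' @export
subset_mean_mi <- function(mca, parameters, mi = NULL) {
  sel <- rep(TRUE, length(mca$sets))
  for (type in names(parameters)) {
    sel <- sel & sets_with_parameter(mca, type, parameters[[type]])
  }
  if (sum(sel) < 2L) stop("parameter subset has fewer than 2 sets")
  if (is.null(mi)) mi <- mi_matrix(mca)
  sub <- mi[sel, sel, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Rank clustering sets by enrichment in one category
#'
#' @param enrichment enrichment table from [enrich_mca()].
#' @param category category (biological or dynamic metric) to rank by.
#' @param set_ids universe of set ids (default: all ids in the table).
#' @return Integer vector of set ids ordered by decreasing number of
#'   significant labels in the category, ties broken by ascending set id.
#' @export
rank_sets <- function(enrichment, category, set_ids = NULL) {
  if (is.null(set_ids)) set_ids <- sort(unique(enrichment$set_id))
  if (!category %in% enrichment$category) stop("category absent: ", category)
  cnt <- significant_counts(enrichment, set_ids, category)
  set_ids[order(-cnt, set_ids)]
}

#' Overrepresentation of clustering parameters in ranking quartiles
#'
#' Given sets ranked by enrichment in one metric, extracts the top and
#' bottom quartiles (quartile size `ceiling(M/4)`) and tests every
#' clustering parameter value for overrepresentation in each quartile with
#' the hypergeometric tail (population = all sets, successes = sets carrying
#' the parameter, sample = the quartile), BH-corrected across all tests for
#' the metric.
#'
#' @param ranked ordered set ids from [rank_sets()].
#' @param mca the `mca` the ranking refers to (set ids index its sets).
#' @param alpha FDR level for the significance flags.
#' @return data.frame: quartile (top/bottom), type, value, in_quartile,
#'   n_carriers, quartile_size, M, p, significant.
#' @export
quartile_parameter_enrichment <- function(ranked, mca, alpha = 0.05) {
  M <- length(ranked)
  stopifnot(M >= 4L)
  q <- ceiling(M / 4)
  quartiles <- list(top = ranked[seq_len(q)],
                    bottom = ranked[seq.int(M - q + 1L, M)])
  pv <- parameter_values(mca)
  rows <- list()
  for (qt in names(quartiles)) {
    ids <- quartiles[[qt]]
    for (i in seq_len(nrow(pv))) {
      has <- sets_with_parameter(mca, pv$type[i], pv$value[i])
      carriers <- which(has)
      k <- sum(ids %in% carriers)
      p <- hypergeom_tail(M, length(carriers), q, k)
      rows[[length(rows) + 1L]] <- data.frame(
        quartile = qt, type = pv$type[i], value = pv$value[i],
        in_quartile = k, n_carriers = length(carriers),
        quartile_size = q, M = M, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- bh_fdr(out$p, alpha = alpha)
  out
}

#' Bootstrap comparison of quartile overlap between two metric rankings
#'
#' Compares the observed overlap between the top (or bottom) quartiles of
#' two rankings with the overlap expected for two random same-size subsets,
#' estimated from `n_boot` random draws (normal approximation from their
#' mean and sd, as the null distribution; an exact hypergeometric mode is
#' available). The null mean converges to `q^2 / M`.
#'
#' @param rank_a,rank_b ordered set ids over the same universe.
#' @param quartile `"top"` or `"bottom"`.
#' @param n_boot number of random draws (default 1000).
#' @param seed integer seed for the draws.
#' @param exact use the exact hypergeometric null instead of the bootstrap
#'   normal approximation.
#' @return List: observed, null_mean, null_sd, z, p (two-sided), and `call`
#'   in `c("pos_sig", "neg_sig", "ns")` at uncorrected alpha 0.05 (apply BH
#'   across metric pairs before interpreting families of such calls).
#' @export
metric_overlap_bootstrap <- function(rank_a, rank_b,
                                     quartile = c("top", "bottom"),
                                     n_boot = 1000L, seed = 1L,
                                     exact = FALSE, alpha = 0.05) {
  quartile <- match.arg(quartile)
  stopifnot(length(rank_a) == length(rank_b))
  M <- length(rank_a)
  q <- ceiling(M / 4)
  if (q < 1L) stop("quartile size < 1")
  pick <- function(r) if (quartile == "top") r[seq_len(q)] else
    r[seq.int(M - q + 1L, M)]
  obs <- length(intersect(pick(rank_a), pick(rank_b)))
  if (exact) {
    null_mean <- q^2 / M
    null_sd <- sqrt(q * (q / M) * (1 - q / M) * (M - q) / (M - 1))
    p_hi <- stats::phyper(obs - 1, q, M - q, q, lower.tail = FALSE)
    p_lo <- stats::phyper(obs, q, M - q, q)
    p <- min(1, 2 * min(p_hi, p_lo))
    z <- (obs - null_mean) / null_sd
  } else {
    draws <- .with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(i) {
        length(intersect(sample.int(M, q), sample.int(M, q)))
      }, numeric(1))
    })
    null_mean <- mean(draws)
    null_sd <- stats::sd(draws)
    z <- (obs - null_mean) / null_sd
    p <- 2 * stats::pnorm(-abs(z))
  }
  call <- if (p <= alpha) {
    if (obs > null_mean) "pos_sig" else "neg_sig"
  } else "ns"
  list(observed = obs, null_mean = null_mean, null_sd = null_sd,
       z = z, p = p, call = call)
}

#' Peptide co-occurrence matrix of an MCA
#'
#' Counts, for every pair of peptides, the number of clustering sets in
#' which the two are placed in the same cluster — the consensus view of the
#' ensemble. Frequencies are counts / M.
#'
#' @param mca an `mca`.
#' @return A `co_occurrence` object: list with `counts` (symmetric integer
#'   matrix, diagonal = M), `freq`, and `M`.
#' @export
co_occurrence <- function(mca) {
  stopifnot(length(mca$sets) >= 1L)
  A <- assignment_matrix(mca)
  n <- nrow(A)
  counts <- matrix(0L, n, n, dimnames = list(rownames(A), rownames(A)))
  for (j in seq_len(ncol(A))) {
    counts <- counts + outer(A[, j], A[, j], `==`)
  }
  M <- ncol(A)
  structure(list(counts = counts, freq = counts / M, M = M),
            class = "co_occurrence")
}

#' @export
print.co_occurrence <- function(x, ...) {
  cat(sprintf("co_occurrence: %d peptides over %d sets\n",
              nrow(x$counts), x$M))
  invisible(x)
}

#' Log-scale co-occurrence values for heat-map display
#'
#' Returns `log10(freq)` after replacing zero frequencies by the
#' pseudo-count `0.5 / M`, the convention used for plotting a consensus
#' matrix whose zeros would otherwise be undefined on the log scale.
#'
#' @param co a [co_occurrence()] object.
#' @return Numeric matrix of log10 frequencies.
#' @export
co_occurrence_heatmap_values <- function(co) {
  f <- co$freq
  f[f == 0] <- 0.5 / co$M
  log10(f)
}

#' Summary statistics of a co-occurrence matrix
#'
#' @param co a [co_occurrence()] object.
#' @return List: `n_pairs` = n(n-1)/2 unordered pairs, `n_never` and
#'   `pct_never` (pairs that never co-cluster; percent to one decimal),
#'   `n_majority` and `pct_majority` (pairs with frequency > 0.5),
#'   `median_count`.
#' @export
co_occurrence_summary <- function(co) {
  up <- upper.tri(co$counts)
  cnt <- co$counts[up]
  frq <- co$freq[up]
  n_pairs <- length(cnt)
  n_never <- sum(cnt == 0)
  n_majority <- sum(frq > 0.5)
  list(n_pairs = n_pairs,
       n_never = n_never,
       pct_never = round(100 * n_never / n_pairs, 1),
       n_majority = n_majority,
       pct_majority = round(100 * n_majority / n_pairs, 1),
       median_count = stats::median(cnt))
}

#' Robust cluster of peptides tracking an enriched label
#'
#' Finds, over all clustering sets in which a label is significantly
#' enriched in some cluster, the peptides that sit inside a label-enriched
#' cluster in at least `threshold` of those sets, then re-tests the
#' resulting group for enrichment against the full dataset (the group plays
#' the role of a single cluster).
#'
#' @param mca an `mca`.
#' @param enrichment enrichment table for `mca`.
#' @param label the enriched label of interest.
#' @param annotations `annotation_table` used for the re-enrichment step.
#' @param threshold minimum participation fraction (default 0.5).
#' @param alpha FDR level for the re-enrichment.
#' @return List: `peptides` (ids in the robust cluster), `frequency`
#'   (participation fraction per peptide), `n_label_sets` (denominator),
#'   `re_enrichment` (enrichment records of the group vs the dataset).
#' @export
robust_cluster_by_label <- function(mca, enrichment, label,
                                    annotations = NULL, threshold = 0.5,
                                    alpha = 0.05) {
  hits <- enrichment[enrichment$label == label & enrichment$significant, ,
                     drop = FALSE]
  if (nrow(hits) == 0L) stop("label never significantly enriched: ", label)
  A <- assignment_matrix(mca)
  peptides <- rownames(A)
  inside <- stats::setNames(numeric(length(peptides)), peptides)
  label_sets <- unique(hits$set_id)
  for (s in label_sets) {
    cl <- hits$cluster[hits$set_id == s]
    inside <- inside + (A[, s] %in% cl)
  }
  freq <- inside / length(label_sets)
  members <- peptides[freq >= threshold]
  re <- NULL
  if (!is.null(annotations) && length(members) > 0L) {
    pseudo <- structure(list(
      config = NULL,
      assignment = stats::setNames(ifelse(peptides %in% members, 1L, 2L),
                                   peptides),
      k_eff = if (all(peptides %in% members)) 1L else 2L
    ), class = "cluster_set")
    re <- enrich_set(pseudo, annotations, alpha = alpha)
    re <- re[re$cluster == 1L, , drop = FALSE]
  }
  list(peptides = members, frequency = freq,
       n_label_sets = length(label_sets), re_enrichment = re)
}

#' Peptide-centric cluster from a co-occurrence matrix
#'
#' All peptides that co-cluster with the given peptide in at least
#' `threshold` of the sets; the seed peptide itself is always part of the
#' returned group.
#'
#' @param co a [co_occurrence()] object.
#' @param peptide peptide id present in the matrix.
#' @param threshold minimum co-occurrence frequency (default 0.5).
#' @return Character vector of peptide ids (seed first).
#' @export
peptide_centric_cluster <- function(co, peptide, threshold = 0.5) {
  ids <- rownames(co$freq)
  if (!peptide %in% ids) stop("unknown peptide: ", peptide)
  f <- co$freq[peptide, ]
  others <- ids[ids != peptide & f >= threshold]
  c(peptide, others)
}

#' Correlation between two co-occurrence matrices on shared peptides
#'
#' Pearson correlation of the upper-triangle co-occurrence frequencies of
#' two ensembles, restricted to their shared peptides — a single global
#' metric for the agreement of two datasets' consensus structures.
#'
#' @param co_a,co_b [co_occurrence()] objects.
#' @param shared_peptides character vector of peptide ids present in both.
#' @return Pearson correlation coefficient.
#' @export
compare_co_occurrence <- function(co_a, co_b, shared_peptides) {
  if (length(shared_peptides) < 3L) stop("need at least 3 shared peptides")
  stopifnot(all(shared_peptides %in% rownames(co_a$freq)),
            all(shared_peptides %in% rownames(co_b$freq)))
  Fa <- co_a$freq[shared_peptides, shared_peptides]
  Fb <- co_b$freq[shared_peptides, shared_peptides]
  up <- upper.tri(Fa)
  if (stats::sd(Fa[up]) == 0 || stats::sd(Fb[up]) == 0) {
    stop("zero variance in co-occurrence frequencies")
  }
  stats::cor(Fa[up], Fb[up])
}

#' Peptide pairs with extreme co-occurrence differences between datasets
#'
#' Flags pairs of shared peptides that co-cluster at least `hi` of the time
#' in one ensemble but less than `lo` of the time in the other — the
#' "co-cluster swap" screen for condition-specific rewiring.
#'
#' @param co_a,co_b [co_occurrence()] objects.
#' @param shared_peptides peptide ids present in both.
#' @param hi high-frequency bound (default 0.75).
#' @param lo low-frequency bound (default 0.25).
#' @return data.frame: peptide_1, peptide_2, freq_a, freq_b, direction
#'   (`"a_high_b_low"` or `"b_high_a_low"`).
#' @export
extreme_differences <- function(co_a, co_b, shared_peptides,
                                hi = 0.75, lo = 0.25) {
  stopifnot(length(shared_peptides) >= 2L)
  Fa <- co_a$freq[shared_peptides, shared_peptides]
  Fb <- co_b$freq[shared_peptides, shared_peptides]
  up <- which(upper.tri(Fa), arr.ind = TRUE)
  fa <- Fa[up]; fb <- Fb[up]
  a_hi <- fa >= hi & fb < lo
  b_hi <- fb >= hi & fa < lo
  idx <- c(which(a_hi), which(b_hi))
  out <- data.frame(
    peptide_1 = shared_peptides[up[idx, 1L]],
    peptide_2 = shared_peptides[up[idx, 2L]],
    freq_a = fa[idx], freq_b = fb[idx],
    direction = rep(c("a_high_b_low", "b_high_a_low"),
                    c(sum(a_hi), sum(b_hi))),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
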