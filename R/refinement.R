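#' Mean enrichment yield of a subset of clustering sets
#'
#' "Total enrichment" of a collection of sets, normalized per set: the mean
#' number of significant labels per clustering set, overall or restricted to
#' one category. Per-set normalization makes removal comparisons
#' well-defined — dropping sets necessarily shrinks a raw total.
#'
#' @param enrichment enrichment table from [enrich_mca()].
#' @param set_ids set ids over which to average (sets without records
#'   contribute 0).
#' @param category optional single category.
#' @return Nonnegative scalar.
#' @export
enrichment_score <- function(enrichment, set_ids, category = NULL) {
  if (length(set_ids) == 0L) stop("empty set subset")
  mean(significant_counts(enrichment, set_ids, category))
}

#' List the distinct parameter values present in an MCA
#'
#' @param mca an `mca`.
#' @return data.frame with columns `type` (transform/distance/algorithm/K)
#'   and `value`.
#' @export
parameter_values <- function(mca) {
  cfg <- mca$configs
  vals <- rbind(
    data.frame(type = "transform",
               value = unique(vapply(cfg, `[[`, "", "transform"))),
    data.frame(type = "distance",
               value = unique(vapply(cfg, `[[`, "", "distance"))),
    data.frame(type = "algorithm",
               value = unique(vapply(cfg, `[[`, "", "algorithm"))),
    data.frame(type = "K",
               value = unique(stats::na.omit(vapply(cfg, function(x)
                 if (is.null(x$k)) NA_character_ else as.character(x$k), ""))))
  )
  rownames(vals) <- NULL
  vals
}

#' Which sets of an MCA carry a given parameter value
#' @param mca an `mca`.
#' @param type one of `"transform"`, `"distance"`, `"algorithm"`, `"K"`.
#' @param value the parameter value (K as number or string).
#' @return Logical vector over sets.
#' @export
sets_with_parameter <- function(mca, type, value) {
  vapply(mca$configs, function(cf) {
    switch(type,
      transform = cf$transform == value,
      distance = cf$distance == value,
      algorithm = cf$algorithm == value,
      K = !is.null(cf$k) && cf$k == as.integer(value),
      stop("unknown parameter type: ", type))
  }, logical(1))
}

#' Effect on enrichment of removing one clustering parameter
#'
#' Drops every set generated with the given parameter value and reports the
#' relative change in the per-set mean enrichment, overall and per category.
#' A positive delta means removal improves the ensemble's biological yield.
#' Categories with zero enrichment before removal report a delta of 0 (there
#' is no power to lose).
#'
#' @param mca an `mca`.
#' @param enrichment enrichment table for the full MCA.
#' @param type,value parameter selector as in [sets_with_parameter()].
#' @return List with `overall_delta` (scalar relative change) and
#'   `category_deltas` (named vector over categories present in the table).
#' @export
evaluate_removal <- function(mca, enrichment, type, value) {
  has <- sets_with_parameter(mca, type, value)
  if (!any(has)) stop("parameter not present: ", type, "=", value)
  if (all(has)) stop("removal would empty the MCA")
  all_ids <- seq_along(mca$sets)
  keep_ids <- all_ids[!has]
  rel <- function(before, after) {
    if (before == 0) 0 else (after - before) / before
  }
  overall <- rel(enrichment_score(enrichment, all_ids),
                 enrichment_score(enrichment, keep_ids))
  cats <- unique(enrichment$category)
  cat_deltas <- vapply(cats, function(cat) {
    rel(enrichment_score(enrichment, all_ids, cat),
        enrichment_score(enrichment, keep_ids, cat))
  }, numeric(1))
  list(overall_delta = overall,
       category_deltas = stats::setNames(cat_deltas, cats))
}

#' Prune uninformative clustering parameters
#'
#' Evaluates every parameter value present in the ensemble against the full
#' MCA and removes (jointly, in one pass) all parameters whose removal
#' improves the overall per-set mean enrichment by at least
#' `improve_threshold` (default 2%) without decreasing the enrichment of any
#' single category by more than `degrade_threshold` (default 10%). An
#' iterative mode re-evaluates after each pruning round until no parameter
#' qualifies.
#'
#' @param mca an `mca`.
#' @param enrichment enrichment table for `mca`.
#' @param improve_threshold minimum relative overall improvement (0.02 = 2%).
#' @param degrade_threshold maximum tolerated relative per-category loss
#'   (0.10 = 10%).
#' @param iterative if TRUE, repeat single passes until no change.
#' @param annotations,alpha,method needed only for `iterative = TRUE`, to
#'   recompute enrichment on the shrunken ensemble between passes.
#' @return List with `mca` (pruned ensemble), `report` (a `prune_report`
#'   data.frame: type, value, n_sets, overall_delta, worst_category_delta,
#'   pruned) and `pruned_labels`.
#' @export
prune_mca <- function(mca, enrichment, improve_threshold = 0.02,
                      degrade_threshold = 0.10, iterative = FALSE,
                      annotations = NULL, alpha = 0.05, method = "BH") {
  pass <- function(mca, enrichment) {
    pv <- parameter_values(mca)
    rows <- lapply(seq_len(nrow(pv)), function(i) {
      type <- pv$type[i]; value <- pv$value[i]
      has <- sets_with_parameter(mca, type, value)
      if (all(has)) {
        return(data.frame(type = type, value = value, n_sets = sum(has),
                          overall_delta = NA_real_,
                          worst_category_delta = NA_real_, pruned = FALSE))
      }
      ev <- evaluate_removal(mca, enrichment, type, value)
      worst <- if (length(ev$category_deltas)) min(ev$category_deltas) else 0
      data.frame(type = type, value = value, n_sets = sum(has),
                 overall_delta = ev$overall_delta,
                 worst_category_delta = worst,
                 pruned = ev$overall_delta >= improve_threshold &&
                          worst >= -degrade_threshold)
    })
    report <- do.call(rbind, rows)
    drop <- rep(FALSE, length(mca$sets))
    for (i in which(report$pruned)) {
      drop <- drop | sets_with_parameter(mca, report$type[i], report$value[i])
    }
    list(report = report, drop = drop)
  }
  p <- pass(mca, enrichment)
  if (all(p$drop)) {
    warning("joint removal would empty the MCA; no pruning applied")
    p$report$pruned <- FALSE
    return(list(mca = mca,
                report = structure(p$report, class = c("prune_report",
                                                       "data.frame")),
                pruned_labels = character()))
  }
  pruned_labels <- c()
  keep_mca <- mca
  report <- p$report
  if (any(p$drop)) {
    pruned_labels <- paste(report$type[report$pruned],
                           report$value[report$pruned], sep = "=")
    keep_mca <- subset_mca(mca, !p$drop)
  }
  if (iterative && any(p$drop)) {
    if (is.null(annotations)) {
      stop("iterative pruning requires `annotations` to re-enrich")
    }
    repeat {
      enr <- enrich_mca(keep_mca, annotations, alpha = alpha, method = method)
      p <- pass(keep_mca, enr)
      if (!any(p$drop) || all(p$drop)) break
      pruned_labels <- c(pruned_labels,
                         paste(p$report$type[p$report$pruned],
                               p$report$value[p$report$pruned], sep = "="))
      keep_mca <- subset_mca(keep_mca, !p$drop)
      report <- rbind(report, p$report)
    }
  }
  list(mca = keep_mca,
       report = structure(report, class = c("prune_report", "data.frame")),
       pruned_labels = pruned_labels)
}
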