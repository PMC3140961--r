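#' Specification for a synthetic phosphoproteomic dataset
#'
#' Describes a synthetic positive-valued relative-phosphorylation time
#' course dataset with planted temporal groups and an annotation table whose
#' labels are preferentially co-assigned within groups. The defaults emulate
#' the shape of a saturating-EGF phosphotyrosine time course: 77 peptides
#' measured at 4 timepoints, with four canonical temporal archetypes
#' (early-transient, sustained, late-rising, down-regulated) and
#' multiplicative log-normal measurement noise.
#'
#' @param n_peptides number of peptides (default 77).
#' @param n_conditions number of timepoints (default 4).
#' @param n_groups number of planted temporal groups (default 4).
#' @param templates optional n_groups x n_conditions positive matrix of
#'   group temporal templates; defaults to four archetypal relative
#'   trajectories (rows recycled/truncated to `n_groups`).
#' @param noise_sd standard deviation of the multiplicative log-normal
#'   noise on the natural-log scale (default 0.2).
#' @param categories annotation category names (default four protein/site
#'   metric names).
#' @param n_background_labels background (unplanted) labels per category.
#' @param within_prob probability a group member receives its group's
#'   planted label (default 0.8).
#' @param background_prob probability any peptide receives any background
#'   label (default 0.05).
#' @param seed integer seed recorded in the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_peptides = 77L, n_conditions = 4L,
                           n_groups = 4L, templates = NULL,
                           noise_sd = 0.2,
                           categories = c("F", "P", "Pfam", "Motifs"),
                           n_background_labels = 3L,
                           within_prob = 0.8, background_prob = 0.05,
                           seed = 1L) {
  if (is.null(templates)) {
    base <- rbind(
      c(1.0, 5.0, 3.0, 1.5),   # early transient
      c(1.0, 3.0, 4.0, 4.5),   # sustained
      c(1.0, 1.2, 2.0, 5.0),   # late rising
      c(3.0, 2.0, 1.0, 0.5)    # down-regulated
    )
    templates <- base[rep_len(seq_len(nrow(base)), n_groups), , drop = FALSE]
    if (n_conditions != ncol(base)) {
      templates <- t(apply(templates, 1L, function(r) {
        stats::approx(seq_along(r), r, n = n_conditions)$y
      }))
    }
  }
  stopifnot(n_groups <= n_peptides, nrow(templates) == n_groups,
            ncol(templates) == n_conditions, all(templates > 0),
            within_prob >= 0, within_prob <= 1,
            background_prob >= 0, background_prob <= 1,
            noise_sd >= 0)
  structure(list(n_peptides = as.integer(n_peptides),
                 n_conditions = as.integer(n_conditions),
                 n_groups = as.integer(n_groups), templates = templates,
                 noise_sd = noise_sd, categories = categories,
                 n_background_labels = as.integer(n_background_labels),
                 within_prob = within_prob,
                 background_prob = background_prob,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset with planted temporal groups
#'
#' Row i is its group's template multiplied elementwise by
#' `exp(eps)`, `eps ~ Normal(0, noise_sd^2)` i.i.d. — multiplicative
#' log-normal noise, appropriate for positive ratio-scaled relative
#' phosphorylation measurements. Groups are assigned in balanced blocks (up
#' to the remainder). Fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return List: `dataset` (a [quant_dataset()]) and `groups` (integer
#'   ground-truth group label per peptide).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_peptides
  groups <- rep_len(seq_len(spec$n_groups), n)
  groups <- sort(groups)
  vals <- .with_seed(spec$seed, {
    eps <- matrix(stats::rnorm(n * spec$n_conditions, 0, spec$noise_sd),
                  n, spec$n_conditions)
    spec$templates[groups, , drop = FALSE] * exp(eps)
  })
  ids <- sprintf("pep%03d", seq_len(n))
  ds <- quant_dataset(vals, ids,
                      protein_accs = sprintf("PROT%03d", seq_len(n)),
                      site_labels = sprintf("Y%d", 100 + seq_len(n)),
                      conditions = paste0("t", seq_len(spec$n_conditions)))
  list(dataset = ds, groups = stats::setNames(groups, ids))
}

#' Generate a synthetic annotation table aligned with planted groups
#'
#' Every (group, category) pair owns one planted label, assigned to that
#' group's peptides with probability `within_prob`; in addition every
#' peptide receives each of the category's background labels with
#' probability `background_prob`. With `within_prob == background_prob` the
#' table carries no signal (a null table).
#'
#' @param groups named integer vector of group memberships (names =
#'   peptide ids), as returned by [generate_dataset()].
#' @param spec a [synthetic_spec()].
#' @param seed optional seed override (default `spec$seed + 1`).
#' @return An `annotation_table`.
#' @export
generate_annotations <- function(groups, spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- if (is.null(seed)) spec$seed + 1L else as.integer(seed)
  ids <- names(groups)
  recs <- .with_seed(seed, {
    rows <- list()
    for (cat in spec$categories) {
      for (g in seq_len(spec$n_groups)) {
        members <- ids[groups == g]
        got <- members[stats::runif(length(members)) < spec$within_prob]
        if (length(got) > 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            peptide_id = got, category = cat,
            label = sprintf("%s_group%d", cat, g), score = NA_real_,
            stringsAsFactors = FALSE)
        }
      }
      if (spec$n_background_labels > 0L) {
        for (b in seq_len(spec$n_background_labels)) {
          got <- ids[stats::runif(length(ids)) < spec$background_prob]
          if (length(got) > 0L) {
            rows[[length(rows) + 1L]] <- data.frame(
              peptide_id = got, category = cat,
              label = sprintf("%s_bg%d", cat, b), score = NA_real_,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    rows
  })
  if (length(recs) == 0L) stop("no annotation records generated")
  annotation_table(do.call(rbind, recs))
}

#' Random annotations with no relationship to any structure
#'
#' Convenience null table: every peptide receives every label of every
#' category independently with probability `prob`. Used for no-signal
#' controls.
#'
#' @param peptide_ids peptide universe.
#' @param categories category names.
#' @param n_labels labels per category.
#' @param prob per-(peptide, label) assignment probability.
#' @param seed integer seed.
#' @return An `annotation_table`.
#' @export
random_annotations <- function(peptide_ids, categories = c("F", "P", "Pfam",
                                                           "Motifs"),
                               n_labels = 6L, prob = 0.15, seed = 1L) {
  recs <- .with_seed(as.integer(seed), {
    rows <- list()
    for (cat in categories) for (l in seq_len(n_labels)) {
      got <- peptide_ids[stats::runif(length(peptide_ids)) < prob]
      if (length(got) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          peptide_id = got, category = cat,
          label = sprintf("%s_lab%d", cat, l), score = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    rows
  })
  if (length(recs) == 0L) stop("no annotation records generated")
  annotation_table(do.call(rbind, recs))
}

#' Randomize a dataset by reshuffling the data matrix
#'
#' Permutes the values of the whole n x T matrix uniformly (globally, across
#' rows and columns), destroying both temporal and peptide structure while
#' preserving the value multiset exactly; peptide ids are unchanged. A
#' within-column mode permutes each condition's values across peptides
#' instead, preserving per-condition distributions.
#'
#' @param dataset a [quant_dataset()].
#' @param seed integer seed.
#' @param mode `"global"` (default) or `"within_column"`.
#' @return A [quant_dataset()] with permuted values.
#' @export
shuffle_matrix <- function(dataset, seed, mode = c("global", "within_column")) {
  mode <- match.arg(mode)
  V <- dataset$values
  out <- dataset
  out$values <- .with_seed(as.integer(seed), {
    if (mode == "global") {
      matrix(sample(as.vector(V)), nrow(V), ncol(V), dimnames = dimnames(V))
    } else {
      apply(V, 2L, sample)
    }
  })
  dimnames(out$values) <- dimnames(V)
  out
}

#' Randomize annotations by reshuffling the peptide-to-dynamics mapping
#'
#' Permutes peptide identities against the measurement rows by a uniform
#' random bijection — equivalently, the annotation table's peptide column is
#' rewritten through that bijection. Per-category label multisets are
#' preserved exactly.
#'
#' @param dataset the companion [quant_dataset()] (defines the bijection's
#'   domain).
#' @param annotations an `annotation_table`.
#' @param seed integer seed.
#' @return A shuffled `annotation_table`.
#' @export
shuffle_labels <- function(dataset, annotations, seed) {
  ids <- dataset$peptides$peptide_id
  perm <- .with_seed(as.integer(seed), sample(ids))
  map <- stats::setNames(perm, ids)
  out <- annotations
  out$peptide_id <- unname(map[annotations$peptide_id])
  annotation_table(as.data.frame(out))
}

#' Empirical false-positive rate of control enrichment runs
#'
#' Pools enrichment tables from randomized-control runs and reports, per
#' category, the fraction of hypothesis tests that were (falsely) rejected.
#' On well-calibrated controls every category's rate should be at or below
#' the nominal FDR level.
#'
#' @param control_enrichments list of enrichment tables (one per control
#'   repetition) from [enrich_mca()].
#' @return Named numeric vector: per-category rejection rate. Attribute
#'   `n_tests` holds the per-category pooled test counts.
#' @export
empirical_fpr <- function(control_enrichments) {
  stopifnot(length(control_enrichments) >= 1L)
  all <- do.call(rbind, control_enrichments)
  if (nrow(all) == 0L) stop("no tests in control enrichment tables")
  rate <- tapply(all$significant, all$category, mean)
  n <- tapply(all$significant, all$category, length)
  structure(as.numeric(rate), names = names(rate),
            n_tests = as.integer(n))
}

#' Run randomized-control repetitions of the full enrichment procedure
#'
#' The core Type-I-error control: repeatedly randomizes the data
#' (matrix-shuffle) or the annotations (label-shuffle), reclusters with the
#' same configurations, re-runs enrichment, and collects the per-category
#' empirical null rejection rates.
#'
#' @param dataset a [quant_dataset()].
#' @param annotations an `annotation_table`.
#' @param configs list of `cluster_config`s.
#' @param n_reps number of control repetitions (default 10).
#' @param method randomization method: `"matrix"` or `"labels"`.
#' @param alpha FDR level used in enrichment.
#' @param seed integer base seed; repetition r uses `seed + r`.
#' @param include_dynamic include quartile-binned dynamic metrics as
#'   additional enrichment categories (computed on each shuffled dataset).
#' @return List: `fpr` (per-category rates pooled over repetitions, from
#'   [empirical_fpr()]), `max_fpr`, and `tables` (per-repetition enrichment
#'   tables).
#' @export
control_runs <- function(dataset, annotations, configs, n_reps = 10L,
                         method = c("matrix", "labels"), alpha = 0.05,
                         seed = 1L, include_dynamic = FALSE) {
  method <- match.arg(method)
  tables <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    s <- as.integer(seed) + r
    if (method == "matrix") {
      ds <- shuffle_matrix(dataset, seed = s)
      ann <- annotations
    } else {
      ds <- dataset
      ann <- shuffle_labels(dataset, annotations, seed = s)
    }
    if (include_dynamic) ann <- rbind_annotations(ann, dynamic_labels(ds))
    mca <- suppressMessages(build_mca(ds, configs))
    tables[[r]] <- enrich_mca(mca, ann, alpha = alpha)
  }
  fpr <- empirical_fpr(tables)
  list(fpr = fpr, max_fpr = max(fpr), tables = tables)
}

#' Combine annotation tables (e.g. biological + dynamic categories)
#' @param ... `annotation_table`s.
#' @return A single `annotation_table`.
#' @export
rbind_annotations <- function(...) {
  annotation_table(do.call(rbind, lapply(list(...), as.data.frame)))
}
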