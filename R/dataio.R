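#' Construct a quantitative peptide-by-condition dataset
#'
#' A `quant_dataset` holds one positive-valued quantitative measurement matrix
#' (rows are phosphopeptides, columns are ordered conditions or timepoints)
#' together with per-peptide identity (protein accession, modification site)
#' and per-condition metadata. Row order defines the peptide index used by
#' every downstream operation.
#'
#' @param values numeric matrix, n_peptides x n_conditions, all finite.
#' @param peptide_ids character vector of unique peptide identifiers.
#' @param protein_accs protein accession per peptide (recycled if length 1).
#' @param site_labels modification-site label per peptide (e.g. "Y1172").
#' @param conditions data.frame of condition metadata with at least a `name`
#'   column, or a character vector of condition names.
#' @return An object of class `quant_dataset`: a list with elements `values`
#'   (rownames = peptide ids), `peptides` (data.frame: peptide_id,
#'   protein_acc, site) and `conditions` (data.frame).
#' @export
quant_dataset <- function(values, peptide_ids,
                          protein_accs = NA_character_,
                          site_labels = NA_character_,
                          conditions = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (length(peptide_ids) != n) {
    stop("length(peptide_ids) must equal nrow(values)")
  }
  peptide_ids <- as.character(peptide_ids)
  if (anyDuplicated(peptide_ids)) {
    stop("duplicate peptide id: ",
         paste(unique(peptide_ids[duplicated(peptide_ids)]), collapse = ", "))
  }
  if (!all(is.finite(values))) stop("values must all be finite")
  if (ncol(values) < 2L) stop("at least 2 conditions are required")
  if (is.null(conditions)) {
    conditions <- data.frame(name = colnames(values) %||% paste0("c", seq_len(ncol(values))),
                             stringsAsFactors = FALSE)
  } else if (is.character(conditions)) {
    conditions <- data.frame(name = conditions, stringsAsFactors = FALSE)
  }
  if (nrow(conditions) != ncol(values)) {
    stop("conditions metadata must have one row per value column")
  }
  rownames(values) <- peptide_ids
  colnames(values) <- conditions$name
  ds <- list(
    values = values,
    peptides = data.frame(
      peptide_id = peptide_ids,
      protein_acc = rep_len(as.character(protein_accs), n),
      site = rep_len(as.character(site_labels), n),
      stringsAsFactors = FALSE
    ),
    conditions = conditions
  )
  class(ds) <- "quant_dataset"
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.quant_dataset <- function(x, ...) {
  cat(sprintf("quant_dataset: %d peptides x %d conditions\n",
              nrow(x$values), ncol(x$values)))
  cat("conditions:", paste(x$conditions$name, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.quant_dataset <- function(x) dim(x$values)

#' Read a quantitative dataset from a wide TSV file
#'
#' Expected columns: `peptide_id  protein_acc  site  <cond1> ... <condT>`,
#' tab-separated with a header row. Everything after the three identity
#' columns is taken as the numeric value block; condition order is preserved.
#'
#' @param path path to the TSV file.
#' @return A [quant_dataset()].
#' @export
read_dataset <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  id_cols <- c("peptide_id", "protein_acc", "site")
  if (!all(id_cols %in% names(df))) {
    stop("dataset TSV must contain columns: ", paste(id_cols, collapse = ", "))
  }
  value_cols <- setdiff(names(df), id_cols)
  if (length(value_cols) < 2L) stop("at least 2 condition columns are required")
  vals <- as.matrix(df[, value_cols, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric cell in value block")
  quant_dataset(vals, df$peptide_id, df$protein_acc, df$site,
                conditions = value_cols)
}

#' Write a quantitative dataset to a wide TSV file
#'
#' Inverse of [read_dataset()]; a read/write round trip reproduces ids and
#' values (values to full double precision).
#'
#' @param dataset a [quant_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  df <- cbind(dataset$peptides,
              as.data.frame(dataset$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation table from a long TSV file
#'
#' Expected columns: `peptide_id  category  label` and optionally `score`.
#' Categories follow the usual short names for protein- and site-level
#' metrics (GO F/P/C, Pfam, Pfam Site, PELM Kinase, Motifs, Scansite Kinase,
#' Scansite Bind), but any category vocabulary is accepted. Records for
#' peptides absent from `dataset` are dropped with a warning, and duplicate
#' (peptide, category, label) triples are collapsed.
#'
#' @param path path to the TSV file.
#' @param dataset the companion [quant_dataset()] defining the peptide
#'   universe, or `NULL` to skip restriction.
#' @return An `annotation_table`: a data.frame with columns peptide_id,
#'   category, label, score. Attributes `n_unknown` and `n_duplicate` record
#'   dropped row counts.
#' @export
read_annotations <- function(path, dataset = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("peptide_id", "category", "label")
  if (!all(need %in% names(df))) {
    stop("annotation TSV must contain columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("empty annotation table")
  if (!"score" %in% names(df)) df$score <- NA_real_
  annotation_table(df[, c("peptide_id", "category", "label", "score")],
                   dataset = dataset)
}

#' Construct/validate an annotation table
#'
#' @param records data.frame with columns peptide_id, category, label and
#'   optionally score.
#' @param dataset optional [quant_dataset()]; records for peptides not in the
#'   dataset are dropped with a warning.
#' @return An `annotation_table` data.frame.
#' @export
annotation_table <- function(records, dataset = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"score" %in% names(records)) records$score <- NA_real_
  records$peptide_id <- as.character(records$peptide_id)
  records$category <- as.character(records$category)
  records$label <- as.character(records$label)
  records$score <- as.numeric(records$score)
  if (any(!is.na(records$score) & !is.finite(records$score))) {
    stop("annotation scores must be finite when present")
  }
  n_unknown <- 0L
  if (!is.null(dataset)) {
    known <- records$peptide_id %in% dataset$peptides$peptide_id
    n_unknown <- sum(!known)
    if (n_unknown > 0L) {
      warning(sprintf("dropped %d annotation record(s) for unknown peptides",
                      n_unknown))
      records <- records[known, , drop = FALSE]
    }
  }
  key <- paste(records$peptide_id, records$category, records$label, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup > 0L) records <- records[!dup, , drop = FALSE]
  rownames(records) <- NULL
  structure(records,
            n_unknown = n_unknown, n_duplicate = n_dup,
            class = c("annotation_table", "data.frame"))
}

#' Write an annotation table to a long TSV file
#' @param annotations an `annotation_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(as.data.frame(annotations), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter scored annotation records of one category by a threshold
#'
#' Applies a stringency cutoff to a scored prediction category, e.g. keeping
#' Scansite predictions of level three and better (`threshold = 3`,
#' `direction = "le"`) or Pfam domain predictions of p <= 1e-5
#' (`threshold = 1e-5`, `direction = "le"`). Records in other categories are
#' untouched; the direction is configurable because stringency conventions
#' differ between predictors.
#'
#' @param annotations an `annotation_table`.
#' @param category category name to filter.
#' @param threshold numeric cutoff.
#' @param direction `"le"` keeps score <= threshold, `"ge"` keeps >=.
#' @return Filtered `annotation_table`.
#' @export
filter_annotations <- function(annotations, category, threshold,
                               direction = c("le", "ge")) {
  direction <- match.arg(direction)
  in_cat <- annotations$category == category
  if (!any(in_cat)) stop("category not present: ", category)
  sc <- annotations$score[in_cat]
  if (all(is.na(sc))) stop("category has no scores: ", category)
  keep_cat <- if (direction == "le") sc <= threshold else sc >= threshold
  keep_cat[is.na(keep_cat)] <- FALSE
  if (!any(keep_cat)) {
    warning("all records of category '", category, "' removed by filter")
  }
  keep <- !in_cat
  keep[which(in_cat)[keep_cat]] <- TRUE
  out <- annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("annotation_table", "data.frame"))
}

#' Normalize every row to a reference condition
#'
#' Divides each peptide's trajectory by its value at the reference condition,
#' the usual device for putting subsets of a larger experiment onto a common
#' relative scale (e.g. normalizing each subset to its own 5-minute point).
#'
#' @param dataset a [quant_dataset()].
#' @param ref_condition name (or index) of the reference condition; its values
#'   must all be nonzero.
#' @return A [quant_dataset()] with the reference column all ones.
#' @export
normalize_to_reference <- function(dataset, ref_condition) {
  j <- if (is.numeric(ref_condition)) as.integer(ref_condition) else
    match(ref_condition, dataset$conditions$name)
  if (is.na(j) || j < 1L || j > ncol(dataset$values)) {
    stop("unknown reference condition: ", ref_condition)
  }
  ref <- dataset$values[, j]
  if (any(ref == 0)) stop("zero value at reference condition")
  out <- dataset
  out$values <- dataset$values / ref
  out
}

#' Build a run manifest for reproducibility
#'
#' Records, for an ensemble run, the software version, per-clusterset random
#' seeds (every non-deterministic clusterset has one), skipped (degenerate)
#' configurations, timestamps and optional input checksums, so that a run can
#' be exactly reproduced.
#'
#' @param configs list of cluster configurations (see [expand_grid()]).
#' @param skipped character vector of labels of skipped configurations.
#' @param inputs named character vector of input file paths to checksum.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(configs, skipped = character(), inputs = NULL) {
  seeds <- vapply(configs, function(cf) cf$seed %||% NA_integer_, integer(1))
  checksums <- NULL
  if (!is.null(inputs)) {
    checksums <- vapply(inputs, function(p) {
      as.character(sum(as.integer(charToRaw(paste(readLines(p), collapse = "\n")))))
    }, character(1))
  }
  structure(list(
    package_version = as.character(utils::packageVersion("mcam")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    configs = vapply(configs, config_label, character(1)),
    seeds = seeds,
    skipped = skipped,
    input_checksums = checksums
  ), class = "run_manifest")
}

#' Write a run manifest as JSON
#' @param manifest a `run_manifest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
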