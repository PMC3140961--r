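#' @name transforms
#' @title Row-wise data transformations
#'
#' @description
#' The twelve row-wise transformations applied to each peptide trajectory
#' before clustering. All operate on a single peptide's measurement vector:
#'
#' * `raw` — untransformed.
#' * `center` — zero centered, `x - mean(x)`.
#' * `zscore` — mean center, sample (n-1) standard deviation of 1.
#' * `normMax` — normalized to the maximum value, `x / max(x)`.
#' * `rangeScale` — full range scaled to `[0, 1]`.
#' * `log10` — log base 10.
#' * `pow` — power 0.5.
#' * `pareto` — `(x - mean(x)) / sqrt(s)` with `s` the sample sd.
#' * `FFT` — magnitude spectrum of the length-T discrete Fourier transform
#'   (phase discarded, DC retained), so clustering depends on frequency
#'   content only.
#' * `diff` — first differences; reduces the vector length by one.
#' * `normMax_log10`, `zscore_log10` — composites applied left to right.
#'
#' Transforms that hit a mathematically undefined case (log of a non-positive
#' value, zero maximum, zero variance) return non-finite values; the cluster
#' engine treats any such row as marking the whole configuration degenerate
#' rather than silently repairing it.
NULL

#' Names of the available transforms
#' @return Character vector of the twelve transform names.
#' @export
transform_names <- function() {
  c("raw", "center", "zscore", "normMax", "rangeScale", "log10",
    "pow", "pareto", "FFT", "diff", "normMax_log10", "zscore_log10")
}

#' Names of the available distance metrics
#' @return Character vector of the five distance names.
#' @export
distance_names <- function() {
  c("euclidean", "correlation", "cityblock", "cosine", "chebychev")
}

.transform1 <- function(x, name) {
  switch(name,
    raw = x,
    center = x - mean(x),
    zscore = {
      s <- stats::sd(x)
      if (s == 0) rep(NaN, length(x)) else (x - mean(x)) / s
    },
    normMax = {
      m <- max(x)
      if (m == 0) rep(NaN, length(x)) else x / m
    },
    rangeScale = {
      r <- max(x) - min(x)
      if (r == 0) rep(NaN, length(x)) else (x - min(x)) / r
    },
    log10 = suppressWarnings(log10(x)),
    pow = suppressWarnings(x^0.5),
    pareto = {
      s <- stats::sd(x)
      if (s == 0) rep(NaN, length(x)) else (x - mean(x)) / sqrt(s)
    },
    FFT = Mod(stats::fft(x)),
    diff = diff(x),
    stop("unknown transform: ", name)
  )
}

#' Apply a named transform to one measurement vector
#'
#' @param x finite numeric vector (one peptide's trajectory).
#' @param name one of [transform_names()]; composite names
#'   (`normMax_log10`, `zscore_log10`) chain left to right.
#' @return The transformed vector (length `length(x)`, or `length(x) - 1`
#'   for `diff`). May contain non-finite values when the transform is
#'   undefined for `x`; see [transforms].
#' @examples
#' apply_transform(c(1, 2, 3), "zscore")   # -1 0 1
#' apply_transform(c(1, 3, 2), "diff")     #  2 -1
#' @export
apply_transform <- function(x, name) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  name <- match.arg(name, transform_names())
  parts <- if (name %in% c("normMax_log10", "zscore_log10")) {
    strsplit(name, "_", fixed = TRUE)[[1]]
  } else name
  for (p in parts) x <- .transform1(x, p)
  x
}

#' Apply a transform to every row of a dataset matrix
#'
#' @param values numeric matrix (peptides x conditions).
#' @param name transform name.
#' @return List with `values` (transformed matrix) and `degenerate` (TRUE if
#'   any output cell is non-finite, in which case the configuration using
#'   this transform must be skipped).
#' @export
transform_matrix <- function(values, name) {
  out <- t(apply(values, 1L, apply_transform, name = name))
  # apply() drops to a vector when diff reduces T=2 rows to length 1
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(values))
  rownames(out) <- rownames(values)
  list(values = out, degenerate = !all(is.finite(out)))
}

#' Distance between two vectors under a named metric
#'
#' Metrics: `euclidean` (L2, optionally squared as used by the k-means
#' criterion), `cityblock` (L1), `chebychev` (L-infinity), `correlation`
#' (1 - Pearson r) and `cosine` (1 - cosine similarity).
#'
#' @param a,b numeric vectors of equal length (>= 2 for correlation/cosine).
#' @param name one of [distance_names()].
#' @param squared square the euclidean distance.
#' @return Nonnegative scalar distance.
#' @examples
#' pair_distance(c(0, 0), c(3, 4), "euclidean")  # 5
#' pair_distance(c(1, 0), c(0, 1), "cosine")     # 1
#' @export
pair_distance <- function(a, b, name, squared = FALSE) {
  stopifnot(length(a) == length(b))
  name <- match.arg(name, distance_names())
  d <- switch(name,
    euclidean = {
      v <- sum((a - b)^2)
      if (squared) v else sqrt(v)
    },
    cityblock = sum(abs(a - b)),
    chebychev = max(abs(a - b)),
    correlation = {
      if (length(a) < 2L) stop("correlation distance needs length >= 2")
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        stop("zero-variance vector under correlation distance")
      }
      1 - stats::cor(a, b)
    },
    cosine = {
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) stop("zero vector under cosine distance")
      1 - sum(a * b) / (na * nb)
    }
  )
  # clip tiny negative round-off from the similarity-based metrics
  max(d, 0)
}

#' Pairwise distance matrix under a named metric
#'
#' @param values numeric matrix (rows are observations).
#' @param name one of [distance_names()].
#' @param squared square euclidean distances.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
distance_matrix <- function(values, name, squared = FALSE) {
  name <- match.arg(name, distance_names())
  n <- nrow(values)
  D <- switch(name,
    euclidean = {
      M <- as.matrix(stats::dist(values, method = "euclidean"))
      if (squared) M^2 else M
    },
    cityblock = as.matrix(stats::dist(values, method = "manhattan")),
    chebychev = as.matrix(stats::dist(values, method = "maximum")),
    correlation = {
      if (any(apply(values, 1L, stats::sd) == 0)) {
        stop("zero-variance row under correlation distance")
      }
      1 - stats::cor(t(values))
    },
    cosine = {
      nr <- sqrt(rowSums(values^2))
      if (any(nr == 0)) stop("zero row under cosine distance")
      V <- values / nr
      1 - tcrossprod(V)
    }
  )
  D <- pmax(D, 0)
  diag(D) <- 0
  dimnames(D) <- list(rownames(values), rownames(values))
  D
}
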