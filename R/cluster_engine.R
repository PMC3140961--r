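#' Default even-K grid from the peptides-per-cluster rule
#'
#' The largest cluster number considered is bounded so that an equally
#' distributed solution would hold roughly `per_cluster` peptides per
#' cluster: Kmax is the largest even K with `n_peptides / K >= per_cluster`.
#' For a 77-peptide dataset with the default of 5 this gives
#' K in \{2, 4, ..., 14\}.
#'
#' @param n_peptides number of peptides in the dataset.
#' @param per_cluster target minimum peptides per cluster (default 5).
#' @return Integer vector of even K values `2, 4, ..., Kmax`.
#' @export
default_k_grid <- function(n_peptides, per_cluster = 5) {
  stopifnot(n_peptides >= 1, per_cluster >= 1)
  kmax <- as.integer(floor(n_peptides / per_cluster))
  kmax <- kmax - (kmax %% 2L)
  if (kmax < 2L) {
    stop("too few peptides for K = 2 at ", per_cluster, " per cluster")
  }
  seq.int(2L, kmax, by = 2L)
}

#' Create one clustering configuration
#'
#' @param algorithm one of `"Ncut"`, `"AP"`, `"SOM"`, `"Kmeans"`,
#'   `"Hierarchical"`.
#' @param transform one of [transform_names()].
#' @param distance one of [distance_names()]; forced to `"euclidean"` for SOM.
#' @param k cluster number; must be absent (`NULL`) for AP, which determines
#'   K itself.
#' @param seed integer random seed for the non-deterministic algorithms
#'   (Kmeans, SOM); recorded so results can be exactly reproduced.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(algorithm, transform, distance, k = NULL,
                           seed = NULL) {
  algorithm <- match.arg(algorithm, algorithm_names())
  transform <- match.arg(transform, transform_names())
  distance <- match.arg(distance, distance_names())
  if (algorithm == "SOM" && distance != "euclidean") {
    stop("SOM only utilizes the euclidean distance metric")
  }
  if (algorithm == "Kmeans" && distance == "chebychev") {
    stop("Kmeans does not accept the chebychev distance metric")
  }
  if (algorithm == "AP") {
    if (!is.null(k)) stop("AP does not accept an argument for K")
  } else {
    if (is.null(k)) stop("K is required for ", algorithm)
    k <- as.integer(k)
    stopifnot(k >= 1L)
  }
  structure(list(algorithm = algorithm, transform = transform,
                 distance = distance, k = k,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "cluster_config")
}

#' Names of the available clustering algorithms
#' @return Character vector of the five algorithm names.
#' @export
algorithm_names <- function() c("Ncut", "AP", "SOM", "Kmeans", "Hierarchical")

#' Short label for a configuration
#' @param config a `cluster_config`.
#' @return A single string, e.g. `"Kmeans|zscore|euclidean|K6"`.
#' @export
config_label <- function(config) {
  paste(config$algorithm, config$transform, config$distance,
        if (is.null(config$k)) "K*" else paste0("K", config$k),
        sep = "|")
}

#' @export
print.cluster_config <- function(x, ...) {
  cat(config_label(x),
      if (!is.null(x$seed)) sprintf(" (seed %d)", x$seed), "\n", sep = "")
  invisible(x)
}

#' Expand the clustering parameter grid with algorithm-specific constraints
#'
#' Builds the full Cartesian product of transforms, distances, algorithms and
#' K values, with the constraints each algorithm imposes: affinity
#' propagation determines K itself and so contributes one configuration per
#' transform x distance; the self-organizing map is restricted to the
#' euclidean metric; k-means excludes the chebychev metric (its euclidean is
#' the squared criterion); normalized cut and hierarchical clustering take
#' the full product. With the canonical vocabulary (12 transforms, 5
#' distances, 5 algorithms, 7 K values) this yields 1,320 configurations.
#' Fresh seeds, drawn deterministically from `base_seed`, are attached to the
#' non-deterministic algorithms (Kmeans, SOM) and allowed to differ between
#' configurations so that independent runs are not forced into a shared local
#' minimum.
#'
#' @param transforms character vector of transform names.
#' @param distances character vector of distance names.
#' @param algorithms character vector of algorithm names.
#' @param k_grid integer vector of K values.
#' @param base_seed integer seed from which per-configuration seeds are drawn.
#' @return List of `cluster_config` objects (unique by construction).
#' @export
expand_grid_configs <- function(transforms = transform_names(),
                                distances = distance_names(),
                                algorithms = algorithm_names(),
                                k_grid = NULL,
                                base_seed = 1L) {
  stopifnot(length(transforms) > 0, length(distances) > 0,
            length(algorithms) > 0)
  transforms <- match.arg(transforms, transform_names(), several.ok = TRUE)
  distances <- match.arg(distances, distance_names(), several.ok = TRUE)
  algorithms <- match.arg(algorithms, algorithm_names(), several.ok = TRUE)
  if (is.null(k_grid) && any(algorithms != "AP")) {
    stop("k_grid is required unless the only algorithm is AP")
  }
  configs <- list()
  for (alg in algorithms) {
    dists <- switch(alg,
      SOM = intersect("euclidean", distances),
      Kmeans = setdiff(distances, "chebychev"),
      distances
    )
    ks <- if (alg == "AP") list(NULL) else as.list(as.integer(k_grid))
    for (tr in transforms) for (di in dists) for (k in ks) {
      configs[[length(configs) + 1L]] <-
        cluster_config(alg, tr, di, k = k)
    }
  }
  if (length(configs) == 0L) stop("empty grid after constraints")
  needs_seed <- vapply(configs, function(cf)
    cf$algorithm %in% c("Kmeans", "SOM"), logical(1))
  if (any(needs_seed)) {
    rng <- .with_seed(as.integer(base_seed),
                      sample.int(.Machine$integer.max, sum(needs_seed)))
    idx <- which(needs_seed)
    for (i in seq_along(idx)) configs[[idx[i]]]$seed <- rng[i]
  }
  configs
}

# evaluate expr under a local RNG state seeded with seed
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Run one clustering configuration on a dataset
#'
#' Applies the configured transform row-wise, computes the configured
#' distance and partitions the peptides:
#'
#' * `Hierarchical` — average-linkage agglomeration on the distance matrix,
#'   tree cut at K.
#' * `Kmeans` — Lloyd iteration with the configured metric (euclidean is
#'   used as the squared criterion; cityblock updates centroids by the
#'   component median, cosine/correlation by the normalized mean), seeded
#'   initialization; empty clusters are refilled with the point farthest
#'   from its centroid.
#' * `SOM` — a 1 x K linear self-organizing map trained under euclidean
#'   distance; map units define the clusters.
#' * `Ncut` — normalized-cut spectral partition of the similarity matrix
#'   `exp(-d^2 / sigma^2)` (sigma = median pairwise distance) into K groups,
#'   with a deterministic farthest-first k-means on the spectral embedding.
#' * `AP` — affinity propagation on negated distances with the median
#'   similarity as preference (damping 0.9, up to 1,000 iterations); the
#'   number of clusters is emergent.
#'
#' Cluster indices are relabeled to be contiguous in order of first
#' appearance, and `k_eff` counts the non-empty clusters actually produced.
#'
#' @param dataset a [quant_dataset()].
#' @param config a [cluster_config()].
#' @return A `cluster_set`: list with `config`, `assignment` (named integer
#'   vector, one entry per peptide) and `k_eff`. `NULL` if the transform is
#'   degenerate for this dataset (non-finite output), in which case the
#'   configuration must be skipped.
#' @export
run_clustering <- function(dataset, config) {
  tr <- transform_matrix(dataset$values, config$transform)
  if (tr$degenerate) return(NULL)
  X <- tr$values
  n <- nrow(X)
  if (!is.null(config$k) && config$k > n) stop("K exceeds number of peptides")
  assign <- switch(config$algorithm,
    Hierarchical = {
      D <- distance_matrix(X, config$distance)
      stats::cutree(stats::hclust(stats::as.dist(D), method = "average"),
                    k = config$k)
    },
    Kmeans = .kmeans_metric(X, config$k, config$distance, config$seed),
    SOM = .som_line(X, config$k, config$seed),
    Ncut = .ncut(distance_matrix(X, config$distance), config$k),
    AP = .affinity_propagation(distance_matrix(X, config$distance))
  )
  assign <- .relabel(assign)
  names(assign) <- dataset$peptides$peptide_id
  structure(list(config = config, assignment = assign,
                 k_eff = max(assign)),
            class = "cluster_set")
}

.relabel <- function(assign) {
  match(assign, unique(assign))
}

# Lloyd k-means under an arbitrary metric (MATLAB-style centroid updates).
.kmeans_metric <- function(X, k, distance, seed, max_iter = 100L) {
  n <- nrow(X)
  squared <- distance == "euclidean"
  prep <- function(M) {
    if (distance == "correlation") M <- M - rowMeans(M)
    M
  }
  dist_to_centroids <- function(M, C) {
    # n x k matrix of distances
    out <- matrix(0, nrow(M), nrow(C))
    for (j in seq_len(nrow(C))) {
      out[, j] <- apply(M, 1L, function(r)
        pair_distance(r, C[j, ], if (distance == "correlation") "cosine"
                      else distance, squared = squared))
    }
    out
  }
  Xw <- prep(X)
  if (distance %in% c("cosine", "correlation")) {
    nr <- sqrt(rowSums(Xw^2))
    if (any(nr == 0)) stop("zero-variance row under ", distance, " distance")
    Xw <- Xw / nr
  }
  centroid <- function(M) {
    if (distance == "cityblock") apply(M, 2L, stats::median)
    else {
      ctr <- colMeans(M)
      if (distance %in% c("cosine", "correlation")) {
        nn <- sqrt(sum(ctr^2))
        if (nn > 0) ctr <- ctr / nn
      }
      ctr
    }
  }
  init <- .with_seed(seed, sample.int(n, k))
  C <- Xw[init, , drop = FALSE]
  assign <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    Dc <- dist_to_centroids(Xw, C)
    new_assign <- max.col(-Dc, ties.method = "first")
    # refill empty clusters with the point farthest from its centroid
    repeat {
      empty <- setdiff(seq_len(k), unique(new_assign))
      if (length(empty) == 0L) break
      far <- which.max(Dc[cbind(seq_len(n), new_assign)])
      new_assign[far] <- empty[1L]
      Dc[far, ] <- -Inf  # pin so it is not moved again this round
      Dc[far, empty[1L]] <- 0
    }
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (j in seq_len(k)) {
      C[j, ] <- centroid(Xw[assign == j, , drop = FALSE])
    }
  }
  assign
}

# 1 x K linear SOM trained with class::batchSOM; units are clusters.
.som_line <- function(X, k, seed) {
  grid <- class::somgrid(xdim = k, ydim = 1L, topo = "rectangular")
  radii <- unique(pmax(seq(k / 2, 0, length.out = 6L), 0))
  som <- .with_seed(seed, class::batchSOM(X, grid, radii = radii))
  codes <- som$codes
  D <- outer(seq_len(nrow(X)), seq_len(k),
             Vectorize(function(i, j) sum((X[i, ] - codes[j, ])^2)))
  max.col(-D, ties.method = "first")
}

# Shi-Malik normalized cut: spectral embedding of the normalized affinity,
# partitioned by a deterministic farthest-first Lloyd iteration.
.ncut <- function(D, k) {
  n <- nrow(D)
  off <- D[upper.tri(D)]
  sigma <- stats::median(off)
  if (sigma == 0) sigma <- mean(off[off > 0]) %||% 1
  if (!is.finite(sigma) || sigma == 0) sigma <- 1
  S <- exp(-(D / sigma)^2)
  diag(S) <- 0
  d <- rowSums(S)
  d[d == 0] <- .Machine$double.eps
  Dm <- 1 / sqrt(d)
  L <- S * tcrossprod(Dm)       # D^{-1/2} S D^{-1/2}
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  nr <- sqrt(rowSums(U^2))
  nr[nr == 0] <- 1
  U <- U / nr
  .farthest_first_kmeans(U, k)
}

# deterministic Lloyd: first center = point with max norm from origin-mean,
# subsequent centers farthest from chosen ones
.farthest_first_kmeans <- function(U, k, max_iter = 100L) {
  n <- nrow(U)
  centers <- integer(k)
  dev <- rowSums((U - matrix(colMeans(U), n, ncol(U), byrow = TRUE))^2)
  centers[1L] <- which.max(dev)
  mind <- colSums((t(U) - U[centers[1L], ])^2)
  if (k > 1L) for (j in 2:k) {
    centers[j] <- which.max(mind)
    mind <- pmin(mind, colSums((t(U) - U[centers[j], ])^2))
  }
  C <- U[centers, , drop = FALSE]
  assign <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    Dc <- sapply(seq_len(k), function(j) colSums((t(U) - C[j, ])^2))
    if (!is.matrix(Dc)) Dc <- matrix(Dc, nrow = n)
    new_assign <- max.col(-Dc, ties.method = "first")
    repeat {
      empty <- setdiff(seq_len(k), unique(new_assign))
      if (length(empty) == 0L) break
      far <- which.max(Dc[cbind(seq_len(n), new_assign)])
      new_assign[far] <- empty[1L]
      Dc[far, ] <- -Inf
      Dc[far, empty[1L]] <- 0
    }
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (j in seq_len(k)) C[j, ] <- colMeans(U[assign == j, , drop = FALSE])
  }
  assign
}

# Frey-Dueck affinity propagation on similarity = -distance, preference =
# median similarity, damping 0.9. K is emergent.
.affinity_propagation <- function(D, damping = 0.9, max_iter = 1000L,
                                  conv_iter = 100L) {
  n <- nrow(D)
  S <- -D
  pref <- stats::median(S[upper.tri(S) | lower.tri(S)])
  diag(S) <- pref
  # deterministic symmetry-breaking jitter, scaled far below data resolution
  eps <- .Machine$double.eps * 100
  jit <- matrix(seq_len(n * n) %% 7L - 3L, n, n) * eps * max(abs(S), 1)
  S <- S + jit
  R <- A <- matrix(0, n, n)
  stable <- 0L
  last_ex <- NULL
  for (it in seq_len(max_iter)) {
    AS <- A + S
    max1 <- apply(AS, 1L, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1L, max)
    Rmax <- matrix(max1, n, n)
    Rmax[cbind(seq_len(n), which1)] <- max2
    Rnew <- S - Rmax
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, last_ex) && length(ex) > 0L) {
      stable <- stable + 1L
      if (stable >= conv_iter) break
    } else stable <- 0L
    last_ex <- ex
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (length(ex) == 0L) ex <- which.max(diag(R) + diag(A))
  assign <- max.col(S[, ex, drop = FALSE], ties.method = "first")
  assign[ex] <- seq_along(ex)
  # refine: reassign to best exemplar by similarity (standard final step)
  assign
}

#' Build a multiple clustering analysis (MCA) ensemble
#'
#' Runs every configuration on the dataset, skipping (with a recorded count)
#' configurations whose transform is degenerate for this data, and collects
#' the resulting partitions plus a reproducibility manifest.
#'
#' @param dataset a [quant_dataset()].
#' @param configs list of `cluster_config`s, e.g. from
#'   [expand_grid_configs()].
#' @return An `mca` object: list with `sets` (list of `cluster_set`),
#'   `configs` (the non-degenerate configs, aligned with `sets`),
#'   `skipped` (labels of degenerate configs) and `manifest`.
#' @export
build_mca <- function(dataset, configs) {
  stopifnot(length(configs) >= 1L)
  labels <- vapply(configs, config_label, character(1))
  sets <- vector("list", length(configs))
  keep <- logical(length(configs))
  for (i in seq_along(configs)) {
    cs <- run_clustering(dataset, configs[[i]])
    if (!is.null(cs)) {
      sets[[i]] <- cs
      keep[i] <- TRUE
    }
  }
  if (!any(keep)) stop("all configurations degenerate for this dataset")
  skipped <- labels[!keep]
  if (length(skipped) > 0L) {
    message(length(skipped), " degenerate configuration(s) skipped")
  }
  structure(list(
    sets = sets[keep],
    configs = configs[keep],
    skipped = skipped,
    manifest = run_manifest(configs[keep], skipped = skipped)
  ), class = "mca")
}

#' @export
print.mca <- function(x, ...) {
  cat(sprintf("mca: %d clustering sets over %d peptides (%d skipped)\n",
              length(x$sets), length(x$sets[[1]]$assignment),
              length(x$skipped)))
  invisible(x)
}

#' Number of sets in an MCA
#' @param x an `mca`.
#' @return Integer count of clustering sets.
#' @export
n_sets <- function(x) length(x$sets)

#' Extract the partition matrix of an MCA
#' @param x an `mca`.
#' @return Integer matrix, peptides x sets, of cluster assignments.
#' @export
assignment_matrix <- function(x) {
  sapply(x$sets, function(s) s$assignment)
}

#' Subset an MCA by set index
#' @param x an `mca`.
#' @param i integer or logical index over sets.
#' @return An `mca` with the selected sets.
#' @export
subset_mca <- function(x, i) {
  out <- x
  out$sets <- x$sets[i]
  out$configs <- x$configs[i]
  if (length(out$sets) == 0L) stop("subset leaves an empty MCA")
  out
}
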