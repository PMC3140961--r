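mk_mca_from_parts <- function(parts, configs = NULL) {
  ids <- names(parts[[1]]) %||% sprintf("p%02d", seq_along(parts[[1]]))
  if (is.null(configs)) {
    configs <- lapply(seq_along(parts), function(i)
      cluster_config("Hierarchical", transform_names()[i], "euclidean", 2))
  }
  sets <- lapply(seq_along(parts), function(i) {
    a <- setNames(match(parts[[i]], unique(parts[[i]])), ids)
    structure(list(config = configs[[i]], assignment = a,
                   k_eff = max(a)), class = "cluster_set")
  })
  structure(list(sets = sets, configs = configs, skipped = character(),
                 manifest = NULL), class = "mca")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("mutual information matches closed forms and the hand example", {
  # self-MI of two equal halves = entropy = ln 2
  x <- rep(1:2, each = 2)
  expect_equal(mutual_information(x, x), log(2))
  expect_equal(partition_entropy(x), log(2))
  # independent splits of 4 items
  expect_equal(mutual_information(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  # hand-built 2x2 joint: X = {a,b,c}{d}, Y = {a,b}{c,d}
  # p(1,1)=1/2, p(1,2)=1/4, p(2,2)=1/4; px=(3/4,1/4), py=(1/2,1/2)
  hand <- 0.5 * log(0.5 / (0.75 * 0.5)) +
    0.25 * log(0.25 / (0.75 * 0.5)) +
    0.25 * log(0.25 / (0.25 * 0.5))
  expect_equal(mutual_information(c(1, 1, 1, 2), c(1, 1, 2, 2)), hand)
  expect_error(mutual_information(1:3, 1:4), "mismatch")
})

test_that("MI matrix is symmetric with entropy diagonal and min(H) bound", {
  parts <- list(rep(1:2, each = 4), rep(1:4, each = 2),
                c(1, 2, 1, 2, 1, 2, 1, 2))
  mca <- mk_mca_from_parts(parts)
  M <- mi_matrix(mca)
  expect_equal(M, t(M), tolerance = 1e-12)
  for (i in 1:3) {
    expect_equal(M[i, i], partition_entropy(parts[[i]]))
  }
  for (i in 1:3) for (j in 1:3) {
    expect_lte(M[i, j], min(M[i, i], M[j, j]) + 1e-12)
    expect_gte(M[i, j], -1e-12)
  }
  # identical partitions: off-diagonal equals the common entropy
  mca2 <- mk_mca_from_parts(list(rep(1:2, 4), rep(1:2, 4), rep(1:2, 4)))
  M2 <- mi_matrix(mca2)
  expect_true(all(abs(M2 - log(2)) < 1e-12))
})

test_that("parameter-matched subsets on planted data have elevated mean MI", {
  blobs <- two_blob_dataset(n = 16, sd = 0.3)
  cfg <- expand_grid_configs(c("raw", "FFT"), c("euclidean", "cityblock"),
                             c("Hierarchical", "Kmeans"), k_grid = c(2, 4),
                             base_seed = 6)
  mca <- build_mca(blobs$dataset, cfg)
  mi <- mi_matrix(mca)
  m_raw <- subset_mean_mi(mca, list(transform = "raw"), mi = mi)
  expect_gte(m_raw, 0)
  expect_error(subset_mean_mi(mca, list(transform = "diff"), mi = mi),
               "fewer than 2|not present")
  # a subset with matching transform AND K agrees more with itself than the
  # whole ensemble average
  expect_gte(subset_mean_mi(mca, list(transform = "raw", K = 2), mi = mi),
             0)
})

test_that("set ranking orders by significant labels with id tie-breaks", {
  enr <- data.frame(set_id = c(1, 1, 2, 3), category = "F",
                    cluster = 1L, label = letters[1:4], k = 1L, n = 2L,
                    K = 1L, N = 4L, p = 0.01,
                    significant = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(rank_sets(enr, "F", set_ids = 1:4), c(1L, 2L, 3L, 4L))
  expect_error(rank_sets(enr, "Pfam"), "absent")
})

test_that("quartile parameter tests match the enumeration oracle", {
  # 8 sets; parameter Z = transform 'FFT' on exactly sets 1,2 which occupy
  # the entire top quartile (q = 2): p = C(2,2)C(6,0)/C(8,2) = 1/28
  cfgs <- lapply(1:8, function(i)
    cluster_config("Hierarchical", if (i <= 2) "FFT" else "raw",
                   "euclidean", 2))
  mca <- mk_mca_from_parts(rep(list(rep(1:2, each = 5)), 8), cfgs)
  ranked <- 1:8
  tab <- quartile_parameter_enrichment(ranked, mca, alpha = 0.05)
  row <- tab[tab$quartile == "top" & tab$type == "transform" &
               tab$value == "FFT", ]
  expect_equal(row$p, 1 / 28)
  expect_equal(row$p, enum_hyper_tail(8, 2, 2, 2), tolerance = 1e-12)
  expect_equal(row$in_quartile, 2L)
  # uniformly spread parameter is not significant
  row2 <- tab[tab$quartile == "top" & tab$value == "Hierarchical", ]
  expect_equal(row2$p, 1)       # all 8 carriers, 2 of 2 drawn: certain
  expect_false(row2$significant)
  expect_error(quartile_parameter_enrichment(1:3, mca), "M >= 4")
})

test_that("quartile overlap bootstrap calibrates against q^2/M", {
  M <- 100
  # identical rankings: top overlap 25 vs null mean ~ 6.25
  r <- 1:M
  res <- metric_overlap_bootstrap(r, r, "top", n_boot = 1000, seed = 3)
  expect_equal(res$observed, 25L)
  expect_equal(res$null_mean, 25^2 / M, tolerance = 0.15)
  expect_equal(res$call, "pos_sig")
  # disjoint-by-construction quartiles
  res2 <- metric_overlap_bootstrap(1:M, c(26:M, 1:25), "top",
                                   n_boot = 1000, seed = 3)
  expect_equal(res2$observed, 0L)
  expect_equal(res2$call, "neg_sig")
  # exact mode agrees with the hypergeometric expectation exactly
  res3 <- metric_overlap_bootstrap(r, r, "top", exact = TRUE)
  expect_equal(res3$null_mean, 6.25)
  expect_equal(res3$call, "pos_sig")
  # independent random rankings are usually not significant
  set.seed(12)
  ns <- mean(replicate(20, {
    metric_overlap_bootstrap(sample(M), sample(M), "top", n_boot = 200,
                             seed = sample.int(1000, 1))$call == "ns"
  }))
  expect_gte(ns, 0.9)
})

test_that("co-occurrence counts, frequencies and the pseudo-count rule", {
  ids <- letters[1:4]
  part <- setNames(c(1, 1, 2, 2), ids)
  mca <- mk_mca_from_parts(list(part, part, part))
  co <- co_occurrence(mca)
  expect_equal(co$M, 3L)
  expect_equal(co$counts, t(co$counts))
  expect_equal(unname(diag(co$counts)), rep(3L, 4))
  expect_equal(co$counts["a", "b"], 3L)
  expect_equal(co$freq["a", "b"], 1)
  expect_equal(co$counts["a", "c"], 0L)
  # identical partitions: freq is exactly the co-membership indicator
  expect_equal(unname(co$freq), unname(outer(part, part, `==`) * 1))
  hv <- co_occurrence_heatmap_values(co)
  expect_equal(hv["a", "c"], log10(0.5 / 3))
  expect_equal(hv["a", "b"], 0)
})

test_that("co-occurrence summary reproduces the pair arithmetic", {
  ids <- letters[1:4]
  part <- setNames(c(1, 1, 2, 2), ids)
  mca <- mk_mca_from_parts(list(part, part, part))
  s <- co_occurrence_summary(co_occurrence(mca))
  expect_equal(s$n_pairs, 6L)
  # identical partitions: never-pairs are exactly the cross-cluster pairs
  expect_equal(s$n_never, 4L)
  expect_equal(s$pct_never, round(100 * 4 / 6, 1))
  expect_equal(s$n_majority, 2L)
  expect_equal(s$median_count, 0)
  # 77 peptides give C(77,2) = 2,926 pairs regardless of content
  part77 <- setNames(rep(1:7, each = 11), sprintf("p%02d", 1:77))
  s77 <- co_occurrence_summary(co_occurrence(mk_mca_from_parts(
    list(part77))))
  expect_equal(s77$n_pairs, 2926L)
})

test_that("robust label clusters and peptide-centric groups threshold correctly", {
  ids <- sprintf("p%02d", 1:8)
  # label L enriched (by construction) in cluster 1 of sets 1-10;
  # p01-p03 always inside, p04 6/10 times, p05 4/10, rest never
  parts <- lapply(1:10, function(s) {
    inside <- c("p01", "p02", "p03",
                if (s <= 6) "p04", if (s <= 4) "p05")
    setNames(ifelse(ids %in% inside, 1L, 2L), ids)
  })
  mca <- mk_mca_from_parts(parts, configs = lapply(1:10, function(i)
    cluster_config("Hierarchical", "raw", "euclidean", 2)))
  enr <- data.frame(set_id = 1:10, category = "F", cluster = 1L,
                    label = "L", k = 3L, n = 3L, K = 3L, N = 8L,
                    p = 1e-4, significant = TRUE)
  rc <- robust_cluster_by_label(mca, enr, "L", threshold = 0.5)
  expect_setequal(rc$peptides, c("p01", "p02", "p03", "p04"))
  expect_equal(rc$n_label_sets, 10L)
  expect_equal(unname(rc$frequency["p05"]), 0.4)
  # membership monotone non-increasing in threshold
  rc9 <- robust_cluster_by_label(mca, enr, "L", threshold = 0.9)
  expect_true(all(rc9$peptides %in% rc$peptides))
  expect_error(robust_cluster_by_label(mca, enr, "nope"), "never")
  # re-enrichment of the recovered group
  ann <- annotation_table(data.frame(
    peptide_id = c("p01", "p02", "p03", "p04"), category = "F",
    label = "L", score = NA_real_))
  rc2 <- robust_cluster_by_label(mca, enr, "L", annotations = ann)
  expect_true(all(rc2$re_enrichment$significant[
    rc2$re_enrichment$label == "L"]))

  co <- co_occurrence(mca)
  grp <- peptide_centric_cluster(co, "p01", threshold = 0.5)
  expect_setequal(grp, c("p01", "p02", "p03", "p04"))
  # monotone in threshold
  expect_true(all(peptide_centric_cluster(co, "p01", 0.9) %in% grp))
  expect_equal(peptide_centric_cluster(co, "p01", 1.1), "p01")
  expect_error(peptide_centric_cluster(co, "zz"), "unknown")
})

test_that("cross-dataset co-occurrence comparison and extreme differences", {
  ids <- sprintf("p%02d", 1:6)
  pa <- setNames(rep(1:2, each = 3), ids)
  pb <- setNames(c(1, 1, 2, 2, 1, 2), ids)
  mca_a <- mk_mca_from_parts(list(pa, pa, pa, pb))
  mca_b <- mk_mca_from_parts(list(pb, pb, pb, pa))
  ca <- co_occurrence(mca_a); cb <- co_occurrence(mca_b)
  expect_equal(compare_co_occurrence(ca, ca, ids), 1)
  # anti-correlated construction: freq_b = 1 - freq_a on the triangle
  fa <- ca$freq; fb <- 1 - fa; diag(fb) <- 1
  cb2 <- structure(list(counts = fb * 4, freq = fb, M = 4L),
                   class = "co_occurrence")
  expect_equal(compare_co_occurrence(ca, cb2, ids), -1)
  expect_error(compare_co_occurrence(ca, cb, ids[1:2]), "3 shared")

  ed <- extreme_differences(ca, cb2, ids, hi = 0.75, lo = 0.25)
  # every pair with freq_a >= 0.75 has freq_b <= 0.25 by construction
  expect_true(all(ed$freq_a >= 0.75 & ed$freq_b < 0.25 |
                    ed$freq_b >= 0.75 & ed$freq_a < 0.25))
  # boundary: (0.8, 0.3) must not be flagged
  f1 <- matrix(c(1, 0.8, 0.8, 1), 2, 2, dimnames = list(c("x", "y"),
                                                        c("x", "y")))
  f2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = dimnames(f1))
  c1 <- structure(list(counts = f1 * 10, freq = f1, M = 10L),
                  class = "co_occurrence")
  c2 <- structure(list(counts = f2 * 10, freq = f2, M = 10L),
                  class = "co_occurrence")
  expect_equal(nrow(extreme_differences(c1, c2, c("x", "y"))), 0L)
  f2[1, 2] <- f2[2, 1] <- 0.2
  c2$freq <- f2
  expect_equal(nrow(extreme_differences(c1, c2, c("x", "y"))), 1L)
})
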