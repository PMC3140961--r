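test_that("hypergeometric tail equals the enumeration oracle for N <= 12", {
  set.seed(4)
  cases <- expand.grid(N = c(5, 8, 12), K = c(0, 2, 4), n = c(1, 3, 5))
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]; K <- cases$K[i]; n <- cases$n[i]
    for (k in 0:min(n, K)) {
      expect_equal(hypergeom_tail(N, K, n, k), enum_hyper_tail(N, K, n, k),
                   tolerance = 1e-12,
                   info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
    }
  }
})

test_that("hypergeometric tail matches worked values and guards counts", {
  expect_equal(hypergeom_tail(20, 5, 4, 0), 1.0)
  # all four draws labeled: C(5,4)*C(15,0)/C(20,4) = 5/4845
  expect_equal(hypergeom_tail(20, 5, 4, 4), choose(5, 4) / choose(20, 4))
  expect_equal(hypergeom_tail(20, 5, 4, 4), enum_hyper_tail(20, 5, 4, 4),
               tolerance = 1e-12)
  expect_error(hypergeom_tail(20, 3, 5, 4), "inconsistent")
  expect_error(hypergeom_tail(10, 12, 5, 2), "inconsistent")
})

test_that("BH step-up matches the hand-computed procedure and is monotone", {
  # thresholds i/m * alpha: 0.0125, 0.025, 0.0375, 0.05 -> all rejected
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(bh_fdr(c(0.9, 0.8), 0.05), rep(FALSE, 2))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(15)^2
    expect_equal(bh_fdr(p, 0.05), step_up_bh(p, 0.05))
    expect_true(all(bh_fdr(p, 0.01) <= bh_fdr(p, 0.05)))  # monotone in alpha
  }
  expect_error(bh_fdr(numeric(0)), "empty")
  # bonferroni alternative is stricter or equal
  p <- c(0.001, 0.01, 0.04, 0.2)
  expect_true(all(bh_fdr(p, 0.05, method = "bonferroni") <= bh_fdr(p, 0.05)))
})

test_that("dynamic metrics compute trajectory statistics and quartile bins", {
  ds <- quant_dataset(rbind(c(1, 3, 2), c(1, 2, 3), c(3, 2, 1)),
                      c("a", "b", "c"))
  dl <- suppressWarnings(dynamic_labels(ds))  # 3 values collapse some bins
  st <- attr(dl, "stats")
  expect_equal(unname(st["a", ]), c(1, 3, 2, 1))   # min max +2 -1
  expect_equal(unname(st["b", "MaxNegChange"]), 0) # monotone rise
  expect_equal(unname(st["c", "MaxPosChange"]), 0)
  # 8 peptides with MaxValue 1..8 into quartile bins of exactly 2
  ds8 <- quant_dataset(cbind(rep(0.5, 8), 1:8), sprintf("q%d", 1:8))
  dl8 <- suppressWarnings(dynamic_labels(ds8))  # MinValue is constant here
  mv <- dl8[dl8$category == "MaxValue", ]
  expect_equal(as.integer(table(mv$label)), rep(2L, 4))
  expect_equal(mv$label[match(sprintf("q%d", 1:8), mv$peptide_id)],
               paste0("MaxValue:Q", rep(1:4, each = 2)))
  # constant statistic collapses to a single bin with a warning
  dsc <- quant_dataset(matrix(1, 4, 3), letters[1:4])
  w <- capture_warnings(dynamic_labels(dsc))
  expect_true(any(grepl("single bin", w)))
})

test_that("planted labels are significant in the matching clusters", {
  # 3 planted groups of 6, labels perfectly aligned, correct partition
  n <- 18
  ids <- sprintf("p%02d", 1:n)
  groups <- rep(1:3, each = 6)
  ann <- annotation_table(data.frame(
    peptide_id = ids, category = "F",
    label = paste0("lab", groups), score = NA_real_))
  cs <- structure(list(config = NULL,
                       assignment = setNames(groups, ids), k_eff = 3L),
                  class = "cluster_set")
  enr <- enrich_set(cs, ann)
  planted <- enr[enr$label == paste0("lab", enr$cluster), ]
  expect_equal(nrow(planted), 3L)
  expect_true(all(planted$significant))
  expect_equal(planted$k, rep(6L, 3))
  # p-value agrees with the elementary tail call
  expect_equal(planted$p[1], hypergeom_tail(18, 6, 6, 6))
})

test_that("a single-cluster partition can enrich nothing", {
  ds <- two_blob_dataset(12)$dataset
  ids <- ds$peptides$peptide_id
  ann <- random_annotations(ids, seed = 8)
  cs <- structure(list(config = NULL,
                       assignment = setNames(rep(1L, 12), ids), k_eff = 1L),
                  class = "cluster_set")
  enr <- enrich_set(cs, ann)
  expect_true(all(!enr$significant))
  expect_true(all(enr$p == 1))  # k = K when the cluster is the dataset
})

test_that("enrichment counts are invariant under cluster relabeling", {
  set.seed(9)
  ids <- sprintf("p%02d", 1:20)
  assign <- sample(1:4, 20, replace = TRUE)
  ann <- random_annotations(ids, prob = 0.3, seed = 10)
  mk <- function(a) structure(list(config = NULL,
                                   assignment = setNames(match(a, unique(a)),
                                                         ids),
                                   k_eff = length(unique(a))),
                              class = "cluster_set")
  e1 <- enrich_set(mk(assign), ann)
  e2 <- enrich_set(mk(5 - assign), ann)  # relabeled
  expect_equal(sum(e1$significant), sum(e2$significant))
  expect_equal(sort(e1$p), sort(e2$p))
})

test_that("ensemble enrichment concatenates per-set families deterministically", {
  blobs <- two_blob_dataset(14, sd = 1)
  cfg <- expand_grid_configs("raw", "euclidean", c("Hierarchical", "Kmeans"),
                             k_grid = 2, base_seed = 2)
  mca <- build_mca(blobs$dataset, cfg)
  ann <- random_annotations(blobs$dataset$peptides$peptide_id, seed = 3)
  e1 <- enrich_mca(mca, ann)
  e2 <- enrich_mca(mca, ann)
  expect_identical(e1, e2)
  expect_setequal(unique(e1$set_id), 1:2)
  # per-set totals via significant_counts cover sets with zero records
  cnt <- significant_counts(e1, 1:2)
  expect_length(cnt, 2L)
})

test_that("set enrichment reproduces a hand-enumerated worked fixture", {
  # 6 peptides, clusters {a,b,c} {d,e,f}; category X: label L on a,b,c;
  # label M on d only. Tests with k>=1: (cl1,L k=3), (cl2,M k=1).
  ids <- letters[1:6]
  ann <- annotation_table(data.frame(
    peptide_id = c("a", "b", "c", "d"), category = "X",
    label = c("L", "L", "L", "M"), score = NA_real_))
  cs <- structure(list(config = NULL,
                       assignment = setNames(rep(1:2, each = 3), ids),
                       k_eff = 2L), class = "cluster_set")
  enr <- enrich_set(cs, ann, alpha = 0.11)
  expect_equal(nrow(enr), 2L)
  pL <- 1 / choose(6, 3)            # only draw {a,b,c} has all three
  pM <- 1 - choose(5, 3) / choose(6, 3)  # P(d in a random 3-subset)
  expect_equal(enr$p[enr$label == "L"], pL)
  expect_equal(enr$p[enr$label == "M"], pM)
  # BH over {0.05, 0.5}: adjusted p for L is 2*(1/20) = 0.1, rejected at
  # alpha 0.11 while M (0.5) is not
  expect_equal(enr$significant[enr$label == "L"], TRUE)
  expect_equal(enr$significant[enr$label == "M"], FALSE)
})
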