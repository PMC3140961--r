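# Shared fixtures built in code.

# tiny 3-peptide, 4-timepoint dataset
tiny_dataset <- function() {
  quant_dataset(
    rbind(c(1, 2, 4, 8), c(2, 4, 8, 16), c(8, 4, 2, 1)),
    peptide_ids = c("p1", "p2", "p3"),
    protein_accs = c("A1", "A2", "A3"),
    site_labels = c("Y10", "Y20", "Y30"),
    conditions = c("t0", "t5", "t10", "t30")
  )
}

tiny_annotations <- function() {
  annotation_table(data.frame(
    peptide_id = c("p1", "p2", "p3", "p1", "p2"),
    category = c("F", "F", "F", "Pfam", "Pfam"),
    label = c("kinase", "kinase", "phosphatase", "SH2", "SH2"),
    score = NA_real_
  ))
}

# two well-separated groups in 2-d, n points
two_blob_dataset <- function(n = 20, sep = 10, sd = 0.2, seed = 42) {
  set.seed(seed)
  half <- n %/% 2
  vals <- rbind(
    matrix(rnorm(half * 3, mean = 1, sd = sd), half, 3),
    matrix(rnorm((n - half) * 3, mean = 1 + sep, sd = sd), n - half, 3)
  )
  list(
    dataset = quant_dataset(vals, sprintf("p%02d", seq_len(n))),
    groups = rep(1:2, c(half, n - half))
  )
}

# exhaustive enumeration oracle for the hypergeometric upper tail:
# draw all C(N, n) subsets of an N-item urn with K labeled items and count
# draws containing >= k labeled items
enum_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  labeled <- seq_len(K)
  hits <- apply(draws, 2L, function(d) sum(d %in% labeled))
  mean(hits >= k)
}

# hand-rolled one-pass BH step-up: largest i with p_(i) <= i/m*alpha
step_up_bh <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) / m * alpha)
  rej <- logical(m)
  if (length(below) > 0L) rej[o[seq_len(max(below))]] <- TRUE
  rej
}
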