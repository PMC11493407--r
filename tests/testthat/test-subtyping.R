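test_that("variable features are ranked by raw MAD with stable ties", {
  # raw MAD (no consistency constant): x has MAD 1, y has MAD 2, while
  # sd(x) >> sd(y) — selection must follow the MAD ordering
  block <- cbind(x = c(1, 2, 3, 4, 100), y = c(0, 2, 4, 6, 8),
                 z = c(5, 5, 5, 5, 5))
  rownames(block) <- paste0("S", 1:5)
  expect_equal(stats::median(abs(block[, "x"] - stats::median(block[, "x"]))),
               1)
  expect_equal(select_variable_features(block, 1), "y")
  expect_equal(select_variable_features(block, 2), c("y", "x"))

  # ties break deterministically by feature id
  tied <- cbind(b = c(1, 2, 3), a = c(3, 2, 1), c = c(2, 3, 1))
  rownames(tied) <- paste0("S", 1:3)
  expect_equal(select_variable_features(tied, 2), c("a", "b"))

  expect_warning(sel <- select_variable_features(block, 10), "exceeds")
  expect_equal(length(sel), 3L)
  expect_error(select_variable_features(block[, "z", drop = FALSE], 1),
               "constant")
})

test_that("consensus clustering recovers well-separated clusters", {
  sim <- simulate_omics(n_samples = 60, k_clusters = 3, effect_size = 5,
                        seed = 11)
  cc <- consensus_cluster(sim$blocks, max_k = 6, reps = 100, seed = 7)
  expect_equal(cc$chosen_k, 3L)
  expect_equal(ari(cc$labels, sim$labels), 1)
  expect_false(cc$low_confidence)
  # consensus matrices are symmetric unit-diagonal proportion matrices
  for (cm in cc$consensus) {
    expect_equal(cm, t(cm))
    expect_true(all(diag(cm) == 1))
    expect_true(all(cm >= 0 & cm <= 1))
  }
})

test_that("consensus clustering is deterministic and order-invariant", {
  sim <- simulate_omics(n_samples = 42, k_clusters = 3, effect_size = 5,
                        n_features = c(rna = 150, protein = 150), seed = 3)
  cc1 <- consensus_cluster(sim$blocks, max_k = 4, reps = 30, seed = 5)
  cc2 <- consensus_cluster(sim$blocks, max_k = 4, reps = 30, seed = 5)
  expect_identical(cc1$consensus, cc2$consensus)
  expect_identical(cc1$labels, cc2$labels)

  # permuting sample order yields the same partition (ARI = 1)
  perm <- withr::with_seed(6, sample(nrow(sim$blocks$rna)))
  blocks_p <- lapply(sim$blocks, function(b) b[perm, ])
  cc3 <- consensus_cluster(blocks_p, max_k = 4, reps = 30, seed = 5)
  expect_equal(ari(cc3$labels[names(cc1$labels)], cc1$labels), 1)
})

test_that("single-resample consensus entries are 0/1", {
  sim <- simulate_omics(n_samples = 30, k_clusters = 2, effect_size = 5,
                        n_features = c(rna = 80), seed = 9)
  cc <- consensus_cluster(sim$blocks, max_k = 3, reps = 1, seed = 2,
                          delta_threshold = 0.1)
  vals <- cc$consensus[["2"]]
  expect_true(all(vals %in% c(0, 1)))
})

test_that("CDF/delta-area selection finds the last k before the plateau", {
  # constructed consensus: perfect 4-block structure; k = 5 only splits
  # one block with 0.5 co-clustering, so its delta-area is negligible
  n <- 60
  truth <- rep(1:4, each = 15)
  mk_cons <- function(groups, soft = NULL) {
    cm <- outer(groups, groups, function(a, b) as.numeric(a == b))
    if (!is.null(soft)) cm[soft] <- 0.5
    diag(cm) <- 1
    cm
  }
  cons <- list(
    "2" = mk_cons(ifelse(truth <= 2, 1, 2)),
    "3" = mk_cons(pmin(truth, 3)),
    "4" = mk_cons(truth),
    "5" = local({
      g <- truth
      soft <- outer(seq_len(n), seq_len(n), function(i, j)
        truth[i] == 4 & truth[j] == 4 & i != j)
      mk_cons(g, soft)
    }),
    "6" = local({
      soft <- outer(seq_len(n), seq_len(n), function(i, j)
        truth[i] >= 3 & truth[j] >= 3 & truth[i] == truth[j] & i != j)
      mk_cons(truth, soft)
    }))
  sel <- select_k_cdf_delta(cons)
  expect_equal(sel$chosen_k, 4L)
  expect_false(sel$low_confidence)

  # identical consensus for every k: smallest k, low confidence
  flat <- lapply(cons[c("2", "3", "4")], function(x) cons[["4"]])
  names(flat) <- c("2", "3", "4")
  sel2 <- select_k_cdf_delta(flat)
  expect_equal(sel2$chosen_k, 2L)
  expect_true(sel2$low_confidence)

  # monotone area growth with no plateau: max k, flagged
  ramp <- list("2" = mk_cons(ifelse(truth <= 2, 1, 2)),
               "3" = mk_cons(pmin(truth, 3)),
               "4" = mk_cons(truth))
  sel3 <- select_k_cdf_delta(ramp)
  expect_equal(sel3$chosen_k, 4L)
  expect_true(sel3$low_confidence)
})

test_that("cluster markers require both FDR and fold-change thresholds", {
  sim <- simulate_omics(n_samples = 60, k_clusters = 2, effect_size = 0,
                        n_features = c(protein = 50), seed = 19,
                        scale = "positive")
  blocks <- sim$blocks
  labels <- sim$labels
  # plant one feature shifted +3 SD (on the log scale) in cluster 1
  blocks$protein[labels == 1, 1] <- blocks$protein[labels == 1, 1] * exp(3)
  mk <- isolate_cluster_markers(blocks, labels)
  expect_true("F0001" %in% mk$feature[mk$cluster == 1])

  # fold change exactly at the threshold is excluded (strict inequality)
  two <- matrix(c(rep(1.2, 10), rep(1, 10)), ncol = 1,
                dimnames = list(paste0("S", 1:20), "f"))
  lab2 <- stats::setNames(rep(1:2, each = 10), rownames(two))
  mk2 <- isolate_cluster_markers(list(lv = two), lab2)
  expect_equal(nrow(mk2), 0L)
  # ...while anything strictly above passes
  two[1:10, 1] <- 1.21
  mk3 <- isolate_cluster_markers(list(lv = two), lab2)
  expect_equal(mk3$feature, "f")

  # undersized clusters are skipped with a warning
  lab_bad <- stats::setNames(c(1, 1, rep(2, 18)), rownames(two))
  expect_warning(isolate_cluster_markers(list(lv = two), lab_bad),
                 "fewer than")
})

test_that("marker calling is calibrated under the global null", {
  sim <- simulate_omics(n_samples = 60, k_clusters = 2, effect_size = 0,
                        n_features = c(protein = 1000), seed = 29,
                        scale = "positive")
  mk <- isolate_cluster_markers(sim$blocks, sim$labels)
  # false-positive fraction within binomial slack of the 0.05 FDR level
  expect_lte(nrow(mk) / 1000, 0.05 + 4 * sqrt(0.05 * 0.95 / 1000))
})

test_that("Fisher association matches exhaustive enumeration", {
  # direct 2x2 check against the hypergeometric enumeration oracle
  set.seed(31)
  for (i in 1:15) {
    cells <- as.vector(stats::rmultinom(1, sample(10:40, 1), rep(0.25, 4)))
    if (any(rowSums(matrix(cells, 2)) == 0) ||
        any(colSums(matrix(cells, 2)) == 0)) next
    p_oracle <- oracle_fisher_two_sided(cells[1], cells[2], cells[3],
                                        cells[4])
    labels <- stats::setNames(
      rep(c(1, 1, 2, 2), cells), paste0("S", seq_len(sum(cells))))
    clinical <- stats::setNames(
      rep(c("mut", "wt", "mut", "wt"), cells), names(labels))
    res <- fisher_association(labels, clinical)
    got <- res$p_value[res$cluster == 1 & res$category == "mut"]
    expect_equal(got, p_oracle, tolerance = 1e-12)
  }

  # balanced table is exactly null
  lab <- stats::setNames(rep(1:2, each = 10), paste0("S", 1:20))
  cli <- stats::setNames(rep(c("a", "b"), 10), names(lab))
  res <- fisher_association(lab, cli)
  expect_true(all(res$p_value == 1))

  # zero margin is degenerate with p = 1
  cli0 <- stats::setNames(rep("a", 20), names(lab))
  res0 <- fisher_association(lab, cli0)
  expect_true(all(res0$degenerate) && all(res0$p_value == 1))
})
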