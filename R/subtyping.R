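# Multi-omic consensus subtyping: variable-feature selection, resampling
# consensus clustering on 1 - Pearson distance, CDF/delta-area selection of
# the cluster number, cluster-marker isolation, and cluster-clinical
# association testing.

#' Select the most variable features of an omics block
#'
#' Ranks features by raw median absolute deviation (no 1.4826 consistency
#' constant — only the ranking matters) and returns the top `n`. Ties break
#' deterministically by feature id.
#'
#' @param block numeric matrix, samples in rows, features in columns (named).
#' @param n number of features to keep (default 2000); when `n` exceeds the
#'   feature count all features are returned with a warning.
#' @return character vector of selected feature ids, MAD-descending.
#' @export
select_variable_features <- function(block, n = 2000L) {
  stopifnot(is.matrix(block), !is.null(colnames(block)))
  mads <- apply(block, 2L, function(x) stats::median(abs(x - stats::median(x))))
  if (all(mads == 0)) stop("all features are constant; empty selection")
  if (n > length(mads)) {
    warning("n (", n, ") exceeds feature count (", length(mads),
            "); returning all features")
    n <- length(mads)
  }
  ord <- order(-mads, colnames(block))
  colnames(block)[ord][seq_len(n)]
}

# z-score features and concatenate blocks on the shared sample universe
prepare_consensus_input <- function(blocks, n_features = 2000L) {
  stopifnot(length(blocks) >= 1L)
  samples <- rownames(blocks[[1L]])
  mats <- lapply(seq_along(blocks), function(b) {
    blk <- blocks[[b]]
    if (!identical(rownames(blk), samples))
      stop("blocks must share an identical ordered sample universe")
    keep <- select_variable_features(blk, min(n_features, ncol(blk)))
    m <- blk[, keep, drop = FALSE]
    mu <- colMeans(m)
    sdv <- apply(m, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    m <- sweep(sweep(m, 2L, mu, "-"), 2L, sdv, "/")
    colnames(m) <- paste0(names(blocks)[b] %||% paste0("block", b), ":",
                          colnames(m))
    m
  })
  do.call(cbind, mats)
}

#' Resampling consensus clustering of concatenated omics blocks
#'
#' For each candidate k and each of `reps` resamples (a fraction `p_item`
#' of samples and `p_feature` of features), samples are clustered by
#' average-linkage hierarchical clustering on 1 - Pearson correlation
#' distance. The consensus matrix entry (i, j) is the fraction of
#' co-sampled runs in which i and j landed in the same cluster. k is chosen
#' from the consensus CDF / delta-area curves (see [select_k_cdf_delta()])
#' and final labels come from hierarchical clustering of 1 - consensus at
#' the chosen k.
#'
#' @param blocks named list of numeric matrices (samples x features, shared
#'   ordered sample rownames). Each block is reduced to its most variable
#'   features and z-scored per feature before concatenation.
#' @param max_k largest k evaluated (k = 2..max_k; default 6).
#' @param reps number of resamples per k (default 1000).
#' @param p_item,p_feature sample/feature resampling fractions (default 0.8).
#' @param seed integer seed; fixed seed gives identical results.
#' @param n_features per-block variable-feature cap (default 2000).
#' @param delta_threshold relative delta-area plateau threshold passed to
#'   [select_k_cdf_delta()].
#' @return object of class `consensus_result`: list with `k_range`,
#'   `consensus` (list of sample x sample matrices), `cdf`, `delta_area`,
#'   `chosen_k`, `labels` (named integer vector) and `low_confidence`.
#' @export
consensus_cluster <- function(blocks, max_k = 6L, reps = 1000L,
                              p_item = 0.8, p_feature = 0.8, seed = 1L,
                              n_features = 2000L, delta_threshold = 0.1) {
  X <- prepare_consensus_input(blocks, n_features = n_features)
  n <- nrow(X)
  if (n < 2L * max_k)
    stop("need at least 2 * max_k samples (", 2L * max_k, "); got ", n)
  ks <- 2:max_k
  consensus <- with_seed(seed, {
    lapply(ks, function(k) {
      hits <- matrix(0, n, n)
      both <- matrix(0, n, n)
      for (r in seq_len(reps)) {
        items <- sort(sample.int(n, max(2L * k, round(p_item * n))))
        feats <- sort(sample.int(ncol(X), max(2L, round(p_feature * ncol(X)))))
        sub <- X[items, feats, drop = FALSE]
        keep <- apply(sub, 1L, stats::sd) > 0
        items <- items[keep]
        sub <- sub[keep, , drop = FALSE]
        if (length(items) <= k) next
        d <- stats::as.dist(1 - stats::cor(t(sub)))
        cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
        same <- outer(cl, cl, "==")
        hits[items, items] <- hits[items, items] + same
        both[items, items] <- both[items, items] + 1
      }
      cons <- ifelse(both > 0, hits / both, 0)
      diag(cons) <- 1
      dimnames(cons) <- list(rownames(X), rownames(X))
      cons
    })
  })
  names(consensus) <- as.character(ks)
  sel <- select_k_cdf_delta(consensus, delta_threshold = delta_threshold)
  final_d <- stats::as.dist(1 - consensus[[as.character(sel$chosen_k)]])
  labels <- stats::cutree(stats::hclust(final_d, method = "average"),
                          k = sel$chosen_k)
  names(labels) <- rownames(X)
  structure(list(k_range = ks, consensus = consensus, cdf = sel$cdf,
                 delta_area = sel$delta_area, chosen_k = sel$chosen_k,
                 labels = labels, low_confidence = sel$low_confidence),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result: k evaluated", min(x$k_range), "..", max(x$k_range),
      "; chosen k =", x$chosen_k,
      if (x$low_confidence) "(low confidence)" else "", "\n")
  cat("cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Choose the number of clusters from consensus CDF / delta-area curves
#'
#' Computes the empirical CDF of the upper-triangle consensus values for
#' each k and the area under each CDF. The delta-area curve is the relative
#' area increase from k-1 to k (the area itself at the smallest k). The
#' visual rule "CDF reaches an approximate maximum and the delta-area plot
#' shows no appreciable increase" is operationalized as: chosen k is the
#' last k before the plateau, i.e. one less than the smallest k >= 3 whose
#' relative delta-area increase falls below `delta_threshold`. If every
#' delta is ~0 (identical consensus across k) the smallest k is returned
#' flagged low-confidence; if no plateau exists the largest k is returned
#' flagged.
#'
#' @param consensus named list of consensus matrices, names = k values.
#' @param delta_threshold relative-increase plateau threshold (default 0.1).
#' @param grid evaluation grid for the CDF (default 101 points on [0, 1]).
#' @return list with `chosen_k`, `cdf` (matrix k x grid), `area`,
#'   `delta_area` and `low_confidence`.
#' @export
select_k_cdf_delta <- function(consensus, delta_threshold = 0.1,
                               grid = seq(0, 1, length.out = 101L)) {
  ks <- as.integer(names(consensus))
  if (length(ks) < 2L) stop("need at least 2 candidate k values")
  cdf <- t(vapply(consensus, function(cm) {
    v <- cm[upper.tri(cm)]
    stats::ecdf(v)(grid)
  }, numeric(length(grid))))
  rownames(cdf) <- names(consensus)
  # area under the CDF by the trapezoid rule
  area <- apply(cdf, 1L, function(f)
    sum(diff(grid) * (utils::head(f, -1L) + utils::tail(f, -1L)) / 2))
  delta <- c(area[1L],
             diff(area) / utils::head(area, -1L))
  names(delta) <- names(consensus)
  low_confidence <- FALSE
  eligible <- which(ks >= 3L & delta < delta_threshold)
  if (all(abs(delta[-1L]) < 1e-8)) {
    chosen <- min(ks)
    low_confidence <- TRUE
  } else if (length(eligible) == 0L) {
    chosen <- max(ks)
    low_confidence <- TRUE
  } else {
    chosen <- max(ks[min(eligible)] - 1L, min(ks))
  }
  list(chosen_k = chosen, cdf = cdf, area = area, delta_area = delta,
       low_confidence = low_confidence)
}

#' Isolate cluster-specific up-regulated markers
#'
#' One-vs-rest Wilcoxon rank-sum test per feature per cluster on log-scale
#' values, BH adjustment across features within each omics level, and a
#' marker call requiring `fdr < fdr_max` and fold change strictly greater
#' than `fc_min` (group-mean ratio on the natural scale).
#'
#' @param blocks named list of numeric matrices (samples x features) on the
#'   natural (positive) scale.
#' @param labels named integer cluster labels covering the block samples.
#' @param fdr_max FDR threshold (default 0.05).
#' @param fc_min fold-change threshold, strict (default 1.2).
#' @param min_cluster_size clusters below this size are skipped with a
#'   warning (default 3).
#' @return data.frame with `cluster`, `level`, `feature`, `fold_change`,
#'   `fdr` for every marker call.
#' @export
isolate_cluster_markers <- function(blocks, labels, fdr_max = 0.05,
                                    fc_min = 1.2, min_cluster_size = 3L) {
  out <- list()
  for (lev in names(blocks)) {
    blk <- blocks[[lev]]
    lab <- labels[rownames(blk)]
    for (cl in sort(unique(lab))) {
      in_cl <- lab == cl
      if (sum(in_cl) < min_cluster_size) {
        warning("cluster ", cl, " has fewer than ", min_cluster_size,
                " samples; skipped")
        next
      }
      pvals <- numeric(ncol(blk)); fc <- numeric(ncol(blk))
      lx <- log(blk)
      for (j in seq_len(ncol(blk))) {
        pvals[j] <- stats::wilcox.test(lx[in_cl, j], lx[!in_cl, j],
                                       alternative = "greater",
                                       exact = FALSE)$p.value
        fc[j] <- mean(blk[in_cl, j]) / mean(blk[!in_cl, j])
      }
      fdr <- stats::p.adjust(pvals, method = "BH")
      hit <- fdr < fdr_max & fc > fc_min
      if (any(hit))
        out[[length(out) + 1L]] <- data.frame(
          cluster = cl, level = lev, feature = colnames(blk)[hit],
          fold_change = fc[hit], fdr = fdr[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(cluster = integer(0), level = character(0),
                      feature = character(0), fold_change = numeric(0),
                      fdr = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster-clinical association by Fisher's exact test
#'
#' For each (cluster, category) combination, forms the 2x2 table
#' (in-cluster vs out-of-cluster) x (category vs not) and applies the
#' two-sided exact test. A table with a zero margin gets p = 1 and a
#' degenerate flag.
#'
#' @param labels named integer cluster labels.
#' @param clinical named character vector: sample -> category, on the same
#'   samples.
#' @return data.frame with `cluster`, `category`, the 2x2 cell counts
#'   (`a`, `b`, `c`, `d`), `odds_ratio`, `p_value`, `degenerate` and
#'   `significant` (`p < 0.05`).
#' @export
fisher_association <- function(labels, clinical) {
  common <- intersect(names(labels), names(clinical))
  if (length(common) == 0L) stop("labels and clinical share no samples")
  labels <- labels[common]; clinical <- clinical[common]
  grid <- expand.grid(cluster = sort(unique(labels)),
                      category = sort(unique(clinical)),
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    in_cl <- labels == grid$cluster[i]
    in_cat <- clinical == grid$category[i]
    a <- sum(in_cl & in_cat); b <- sum(in_cl & !in_cat)
    cc <- sum(!in_cl & in_cat); d <- sum(!in_cl & !in_cat)
    tab <- matrix(c(a, b, cc, d), 2L, byrow = TRUE)
    degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
    if (degenerate) {
      p <- 1; or <- NA_real_
    } else {
      ft <- stats::fisher.test(tab)
      p <- ft$p.value; or <- unname(ft$estimate)
    }
    data.frame(cluster = grid$cluster[i], category = grid$category[i],
               a = a, b = b, c = cc, d = d, odds_ratio = or, p_value = p,
               degenerate = degenerate, significant = p < 0.05,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}
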