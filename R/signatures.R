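# Mutational-signature extraction, rank selection, catalog matching, and
# exposure refitting.
#
# A signature is a probability distribution over the 96 trinucleotide
# channels; a sample's spectrum is modeled as a non-negative mixture of
# signatures. Extraction factorizes per-sample normalized spectra by NMF;
# exposures are refit on raw counts by non-negative least squares.

spectrum_counts <- function(spectrum) {
  if (inherits(spectrum, "spectrum_matrix")) spectrum <- spectrum$counts
  stopifnot(is.matrix(spectrum), ncol(spectrum) == 96L)
  spectrum
}

#' Extract mutational signatures by NMF
#'
#' Normalizes each sample's spectrum to frequencies, factorizes by NMF with
#' Frobenius multiplicative updates (best of `restarts` initializations),
#' and reports L1-normalized signature profiles with the scale absorbed
#' into the exposures.
#'
#' @param spectrum `spectrum_matrix` or samples x 96 count matrix.
#' @param k number of signatures; `2 <= k < min(n_samples, 96)`.
#' @param seed integer seed (restart noise), making the run deterministic.
#' @param restarts number of NMF initializations.
#' @param max_iter,tol multiplicative-update iteration cap and relative
#'   convergence tolerance.
#' @return list with `signatures` (k x 96 matrix, rows sum to 1),
#'   `exposures` (samples x k relative contributions, rows sum to 1),
#'   `rss` (Frobenius residual on the normalized spectra) and
#'   `explained_variance` (1 - rss / sum(V^2)).
#' @export
extract_signatures <- function(spectrum, k, seed = 1L, restarts = 5L,
                               max_iter = 5000L, tol = 1e-6) {
  counts <- spectrum_counts(spectrum)
  rs <- rowSums(counts)
  if (any(rs == 0)) stop("spectrum contains all-zero sample rows")
  if (k < 2L || k >= min(nrow(counts), 96L))
    stop("k must satisfy 2 <= k < min(n_samples, 96); got k = ", k,
         " with ", nrow(counts), " samples")
  V <- counts / rs
  fit <- nmf_fit(V, k, seed = seed, restarts = restarts,
                 max_iter = max_iter, tol = tol)
  scale <- rowSums(fit$H)
  signatures <- fit$H / scale
  exposures <- fit$W * rep(scale, each = nrow(fit$W))
  er <- rowSums(exposures)
  exposures <- exposures / ifelse(er > 0, er, 1)
  sig_names <- paste0("S", seq_len(k))
  dimnames(signatures) <- list(sig_names, colnames(counts))
  dimnames(exposures) <- list(rownames(counts), sig_names)
  list(signatures = signatures, exposures = exposures, rss = fit$rss,
       explained_variance = 1 - fit$rss / sum(V^2), k = k,
       converged = fit$converged)
}

#' Select the number of signatures from RSS/explained-variance curves
#'
#' Runs the extraction over a range of ranks and operationalizes the visual
#' "reflection point" rule as the k maximizing the second difference
#' (discrete curvature) of the RSS curve, ties broken toward smaller k.
#' A flat RSS curve (relative range < 1%) returns `k_min` flagged
#' low-confidence.
#'
#' @param spectrum `spectrum_matrix` or samples x 96 count matrix.
#' @param k_min,k_max rank range (`k_min >= 2`).
#' @param seed integer seed passed to each extraction.
#' @param restarts NMF restarts per rank.
#' @return list with `chosen_k`, `k` (the grid), `rss`,
#'   `explained_variance`, and `low_confidence`.
#' @export
select_rank <- function(spectrum, k_min = 2L, k_max = 6L, seed = 1L,
                        restarts = 3L) {
  counts <- spectrum_counts(spectrum)
  if (k_min > k_max) stop("k_min (", k_min, ") exceeds k_max (", k_max, ")")
  if (k_min < 2L || k_max >= min(nrow(counts), 96L))
    stop("rank range must satisfy 2 <= k_min <= k_max < min(n_samples, 96)")
  ks <- k_min:k_max
  fits <- lapply(ks, function(k)
    extract_signatures(counts, k, seed = seed, restarts = restarts))
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  evar <- vapply(fits, `[[`, numeric(1), "explained_variance")
  low_confidence <- FALSE
  if (length(ks) == 1L) {
    chosen <- ks
  } else if (length(ks) == 2L) {
    chosen <- k_min
    low_confidence <- TRUE
  } else {
    inner <- 2:(length(ks) - 1L)
    curvature <- rss[inner - 1L] - 2 * rss[inner] + rss[inner + 1L]
    total_drop <- rss[1L] - rss[length(rss)]
    # a structured spectrum concentrates the RSS drop at the true rank,
    # producing a curvature spike; pure noise declines near-linearly, so
    # the largest curvature stays a small fraction of the total drop
    if (total_drop <= 0 || max(curvature) < 0.2 * total_drop) {
      chosen <- k_min
      low_confidence <- TRUE
    } else {
      chosen <- ks[inner][which.max(curvature)]
    }
  }
  list(chosen_k = chosen, k = ks, rss = rss, explained_variance = evar,
       low_confidence = low_confidence)
}

#' Cosine similarity between two non-negative profiles
#'
#' `u . v / (||u|| ||v||)`; for non-negative vectors the value lies in
#' `[0, 1]`, 0 meaning maximal dissimilarity and 1 maximal similarity.
#'
#' @param u,v numeric vectors of equal length, non-negative, non-zero.
#' @return cosine similarity.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("undefined similarity: zero vector supplied")
  sum(u * v) / (nu * nv)
}

#' Match extracted signatures to a reference catalog by cosine similarity
#'
#' For each query signature, reports the best-matching reference signature
#' (argmax cosine); exact ties break deterministically to the first
#' reference index and are flagged. The full similarity matrix is retained
#' for reporting.
#'
#' @param query,reference signature matrices (rows = signatures, 96 columns
#'   in the same channel order; rownames are signature names).
#' @return list with `matches` (data.frame query, reference, cosine, tie)
#'   and `similarity` (query x reference cosine matrix).
#' @export
match_signatures <- function(query, reference) {
  if (!identical(colnames(query), colnames(reference)))
    stop("query and reference channel orders differ; align columns first")
  sim <- matrix(0, nrow(query), nrow(reference),
                dimnames = list(rownames(query), rownames(reference)))
  for (i in seq_len(nrow(query)))
    for (j in seq_len(nrow(reference)))
      sim[i, j] <- cosine_similarity(query[i, ], reference[j, ])
  best <- apply(sim, 1L, which.max)
  tie <- vapply(seq_len(nrow(sim)), function(i)
    sum(abs(sim[i, ] - sim[i, best[i]]) < 1e-12) > 1L, logical(1))
  matches <- data.frame(
    query = rownames(sim) %||% paste0("S", seq_len(nrow(sim))),
    reference = colnames(sim)[best] %||% paste0("R", best),
    cosine = sim[cbind(seq_len(nrow(sim)), best)],
    tie = tie,
    stringsAsFactors = FALSE)
  list(matches = matches, similarity = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Refit per-sample exposures onto fixed signatures
#'
#' Non-negative least-squares projection of each sample's raw channel
#' counts onto a fixed set of L1-normalized signature profiles.
#'
#' @param spectrum `spectrum_matrix` or samples x 96 count matrix.
#' @param signatures k x 96 matrix of row-normalized signature profiles.
#' @return list with `counts` (samples x k non-negative mutation counts
#'   attributed to each signature), `relative` (rows normalized to 1;
#'   all-zero samples stay zero and are flagged) and `zero_samples`.
#' @export
attribute_exposures <- function(spectrum, signatures) {
  counts <- spectrum_counts(spectrum)
  stopifnot(ncol(signatures) == 96L)
  if (any(abs(rowSums(signatures) - 1) > 1e-8))
    stop("signature rows must sum to 1")
  A <- t(signatures)  # 96 x k
  expo <- matrix(0, nrow(counts), nrow(signatures),
                 dimnames = list(rownames(counts), rownames(signatures)))
  for (i in seq_len(nrow(counts)))
    expo[i, ] <- pracma::lsqnonneg(A, counts[i, ])$x
  rs <- rowSums(expo)
  zero_samples <- rownames(counts)[rs == 0]
  if (length(zero_samples) > 0L)
    warning(length(zero_samples), " sample(s) with all-zero exposures")
  relative <- expo / ifelse(rs > 0, rs, 1)
  list(counts = expo, relative = relative, zero_samples = zero_samples)
}
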