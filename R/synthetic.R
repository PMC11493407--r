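# Synthetic-data generators. Each generator emulates the statistical
# structure one analysis stage assumes (multinomial signature mixtures,
# uniform-within-gene interface nulls with optional planted enrichment,
# cluster-structured omics matrices, shifted kinase substrates, linearly
# separated radiomic features), is seeded explicitly, and returns its
# ground truth alongside the data.

#' Simulate a mutation catalog from a signature mixture
#'
#' Per sample, draws `load` mutations from the multinomial mixture
#' `sum_s w_s * signature_s` over the 96 channels and synthesizes MAF-like
#' SNV records whose `ref_context` is consistent with the drawn channel
#' (pyrimidine-strand representation).
#'
#' @param signatures k x 96 matrix of row-normalized signature profiles.
#' @param exposures samples x k matrix of mixing weights, rows sum to 1.
#' @param loads integer vector of per-sample mutation counts (>= 0).
#' @param seed integer seed.
#' @return list with `records` (mutation record table), `spectrum`
#'   (`spectrum_matrix`), and `truth` (the generating signatures,
#'   exposures, loads).
#' @export
simulate_catalog <- function(signatures, exposures, loads, seed = 1L) {
  stopifnot(ncol(signatures) == 96L, nrow(exposures) == length(loads))
  if (any(loads < 0)) stop("negative mutation load")
  if (any(abs(rowSums(exposures) - 1) > 1e-8))
    stop("exposure rows must sum to 1")
  channels <- sbs_channels()
  sample_ids <- rownames(exposures) %||% sprintf("S%03d", seq_len(nrow(exposures)))
  recs <- with_seed(seed, {
    lapply(seq_along(loads), function(i) {
      if (loads[i] == 0L) return(NULL)
      p <- drop(exposures[i, , drop = FALSE] %*% signatures)
      counts <- stats::rmultinom(1L, loads[i], p)[, 1L]
      ch <- rep(channels, counts)
      ref <- substr(ch, 3L, 3L)
      alt <- substr(ch, 5L, 5L)
      ctx <- paste0(substr(ch, 1L, 1L), ref, substr(ch, 7L, 7L))
      data.frame(sample_id = sample_ids[i], gene = "SYN", chrom = "chr1",
                 pos = seq_along(ch) * 10L, ref = ref, alt = alt,
                 variant_class = "missense", protein_change = NA_character_,
                 ref_context = ctx, stringsAsFactors = FALSE)
    })
  })
  records <- do.call(rbind, recs)
  spectrum <- build_spectrum(records, sample_ids = sample_ids)
  list(records = records, spectrum = spectrum,
       truth = list(signatures = signatures, exposures = exposures,
                    loads = loads))
}

#' Simulate a cohort of genes with interface intervals and missense mutations
#'
#' Genes come in pairs; each gene's interface is a single interval covering
#' `interface_fraction` of the gene. Null genes place mutations uniformly
#' along the gene; in enriched pairs, within-interface placement
#' probability is multiplied by `enrichment_factor` (with renormalization)
#' for both partners.
#'
#' @param n_pairs number of gene pairs (2 * n_pairs genes).
#' @param gene_length length of each gene in bases.
#' @param interface_fraction fraction of the gene covered by the interface,
#'   in (0, 1].
#' @param mutations_per_gene missense mutations drawn per gene.
#' @param n_enriched number of pairs with planted enrichment (the first
#'   `n_enriched` pairs).
#' @param enrichment_factor within-interface rate multiplier (>= 1).
#' @param seed integer seed.
#' @return list with `mutations` (record table), `interfaces` (BED-like
#'   data.frame with 0-based half-open intervals, `M`, `N` in bases), and
#'   `truth` (`enriched_pairs` character vector).
#' @export
simulate_interface_cohort <- function(n_pairs = 100L, gene_length = 1500L,
                                      interface_fraction = 0.1,
                                      mutations_per_gene = 30L,
                                      n_enriched = 0L,
                                      enrichment_factor = 1,
                                      seed = 1L) {
  if (interface_fraction <= 0 || interface_fraction > 1)
    stop("interface_fraction must be in (0, 1]")
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  n_genes <- 2L * n_pairs
  genes <- sprintf("G%04d", seq_len(n_genes))
  pair_ids <- sprintf("%s--%s", genes[seq(1L, n_genes, 2L)],
                      genes[seq(2L, n_genes, 2L)])
  Mlen <- max(1L, round(interface_fraction * gene_length))
  interfaces <- data.frame(
    chrom = rep(genes, each = 1L),
    start = 0L, end = Mlen,
    pair_id = rep(pair_ids, each = 2L),
    partner = genes,
    M = Mlen, N = gene_length,
    stringsAsFactors = FALSE)
  enriched_pairs <- if (n_enriched > 0L) pair_ids[seq_len(n_enriched)]
    else character(0)
  enriched_gene <- interfaces$partner[interfaces$pair_id %in% enriched_pairs]
  muts <- with_seed(seed, {
    lapply(seq_len(n_genes), function(g) {
      f <- if (genes[g] %in% enriched_gene) enrichment_factor else 1
      p_in <- f * Mlen / (f * Mlen + (gene_length - Mlen))
      k_in <- stats::rbinom(1L, mutations_per_gene, p_in)
      pos_in <- if (k_in > 0L) sample.int(Mlen, k_in, replace = TRUE)
        else integer(0)
      n_out <- mutations_per_gene - k_in
      pos_out <- if (n_out > 0L && gene_length > Mlen)
        Mlen + sample.int(gene_length - Mlen, n_out, replace = TRUE)
        else integer(0)
      pos <- c(pos_in, pos_out)  # 1-based positions
      data.frame(sample_id = sprintf("P%03d",
                                     sample.int(200L, length(pos),
                                                replace = TRUE)),
                 gene = genes[g], chrom = genes[g], pos = pos,
                 ref = "C", alt = "A", variant_class = "missense",
                 protein_change = NA_character_,
                 ref_context = NA_character_, stringsAsFactors = FALSE)
    })
  })
  list(mutations = do.call(rbind, muts), interfaces = interfaces,
       truth = list(enriched_pairs = enriched_pairs,
                    enriched_genes = enriched_gene))
}

#' Simulate cluster-structured multi-omic blocks
#'
#' Samples are assigned to `k_clusters` balanced clusters. On a random
#' `frac_informative` of each level's features, cluster means are separated
#' by `effect_size * noise_sd`; all entries get Gaussian noise with SD
#' `noise_sd`.
#'
#' @param n_samples number of samples.
#' @param n_features named integer vector: features per level, e.g.
#'   `c(rna = 300, protein = 200)`.
#' @param k_clusters number of clusters (>= 2, <= n_samples).
#' @param effect_size cluster-mean separation in noise-SD units (>= 0).
#' @param noise_sd Gaussian noise SD.
#' @param frac_informative fraction of features carrying the separation.
#' @param seed integer seed.
#' @param scale `"gaussian"` returns the raw values; `"positive"`
#'   exponentiates them (log-normal), suitable for fold-change analyses.
#' @return list with `blocks` (named list of samples x features matrices)
#'   and `labels` (integer cluster truth).
#' @export
simulate_omics <- function(n_samples = 60L,
                           n_features = c(rna = 300L, protein = 200L,
                                          phospho = 200L),
                           k_clusters = 3L, effect_size = 5,
                           noise_sd = 1, frac_informative = 0.1,
                           seed = 1L, scale = c("gaussian", "positive")) {
  scale <- match.arg(scale)
  if (k_clusters < 2L || k_clusters > n_samples)
    stop("k_clusters must be in [2, n_samples]")
  if (effect_size < 0) stop("effect_size must be >= 0")
  samples <- sprintf("S%03d", seq_len(n_samples))
  labels <- rep(seq_len(k_clusters), length.out = n_samples)
  out <- with_seed(seed, {
    lapply(n_features, function(p) {
      n_inf <- max(1L, round(frac_informative * p))
      inf <- sample.int(p, n_inf)
      mu <- matrix(0, k_clusters, p)
      # orthogonal-ish cluster means on informative features
      mu[, inf] <- effect_size * noise_sd *
        matrix(sample(c(-1, 0, 1), k_clusters * n_inf, replace = TRUE),
               k_clusters)
      m <- mu[labels, , drop = FALSE] +
        matrix(stats::rnorm(n_samples * p, sd = noise_sd), n_samples)
      dimnames(m) <- list(samples, sprintf("F%04d", seq_len(p)))
      if (scale == "positive") exp(m) else m
    })
  })
  names(out) <- names(n_features)
  list(blocks = out, labels = stats::setNames(labels, samples))
}

#' Simulate phosphosite fold-changes with planted kinase activation
#'
#' Background site log2 fold-changes are N(0, 1). Each kinase is annotated
#' to a disjoint random set of substrate sites with NetworKIN scores drawn
#' at or above the usual filter threshold; planted kinases' substrates are
#' shifted by the requested amount.
#'
#' @param n_sites total phosphosites.
#' @param n_kinases number of kinases.
#' @param substrates_per_kinase substrates annotated per kinase.
#' @param planted named numeric vector: kinase name (e.g. `"K01"`) ->
#'   mean log2FC shift; may be empty.
#' @param seed integer seed.
#' @return list with `fold_changes` (named numeric vector), `ks_map`
#'   (data.frame kinase, substrate_site, networkin_score) and `truth`.
#' @export
simulate_phospho <- function(n_sites = 1000L, n_kinases = 10L,
                             substrates_per_kinase = 25L,
                             planted = c(), seed = 1L) {
  stopifnot(n_kinases * substrates_per_kinase <= n_sites)
  if (length(planted) > 0 && !all(is.finite(planted)))
    stop("planted shifts must be finite")
  sites <- sprintf("site%05d", seq_len(n_sites))
  kinases <- sprintf("K%02d", seq_len(n_kinases))
  with_seed(seed, {
    fc <- stats::setNames(stats::rnorm(n_sites), sites)
    assign_idx <- sample.int(n_sites, n_kinases * substrates_per_kinase)
    ks_map <- data.frame(
      kinase = rep(kinases, each = substrates_per_kinase),
      substrate_site = sites[assign_idx],
      networkin_score = stats::runif(length(assign_idx), 5, 30),
      stringsAsFactors = FALSE)
    for (kn in names(planted)) {
      subs <- ks_map$substrate_site[ks_map$kinase == kn]
      fc[subs] <- fc[subs] + planted[[kn]]
    }
    list(fold_changes = fc, ks_map = ks_map,
         truth = list(planted = planted))
  })
}

#' Simulate a radiomic feature table with a planted linear separation
#'
#' Draws the five signature features at plausible pyradiomics magnitudes
#' (intensity maxima around 10^3, probabilities around 10^-1) and shifts
#' the positive class along the signature's coefficient directions by
#' `separation` feature-SD units.
#'
#' @param n number of patients.
#' @param class_balance fraction of positive-class patients.
#' @param separation class-mean separation in per-feature SD units (>= 0).
#' @param seed integer seed.
#' @return list with `features` (data.frame, pyradiomics-style columns) and
#'   `labels` (integer 0/1).
#' @export
simulate_radiomic_table <- function(n = 100L, class_balance = 0.5,
                                    separation = 2, seed = 1L) {
  if (separation < 0) stop("separation must be >= 0")
  base_mean <- c(original_firstorder_Maximum = 1000,
                 original_firstorder_RootMeanSquared = 500,
                 original_glcm_MaximumProbability = 0.30,
                 original_glrlm_GrayLevelNonUniformityNormalized = 0.30,
                 original_ngtdm_Busyness = 5)
  base_sd <- c(200, 100, 0.08, 0.08, 1.5)
  coef_sign <- sign(load_radscore_signature()$terms[names(base_mean)])
  with_seed(seed, {
    labels <- stats::rbinom(n, 1L, class_balance)
    feats <- vapply(seq_along(base_mean), function(j) {
      mu <- base_mean[j] + labels * separation * base_sd[j] * coef_sign[j]
      stats::rnorm(n, mu, base_sd[j])
    }, numeric(n))
    colnames(feats) <- names(base_mean)
    list(features = as.data.frame(feats), labels = labels)
  })
}
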