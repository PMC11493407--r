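# Single-sample gene-set scoring (ssGSEA) and kinase-substrate enrichment
# (KSEA) from phosphosite log2 ratios.

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Symbols are uppercased; empty sets are dropped with a
#' warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    toupper(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1),
    USE.NAMES = FALSE)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropped ", sum(empty), " empty gene set(s)")
    sets <- sets[!empty]
  }
  sets
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based running-sum score of one gene set in one sample's profile
#' (Barbie-style ssGSEA). Genes are ranked by value in descending order
#' (midranks for ties); walking down the ranking, the score accumulates the
#' difference between the weighted in-set empirical CDF (weights
#' `|rank|^alpha`) and the unweighted out-of-set CDF.
#'
#' @param profile named numeric vector: gene -> value for one sample.
#' @param gene_set character vector of member gene symbols.
#' @param alpha rank-weighting exponent (default 0.25; 0 gives the
#'   unweighted Kolmogorov-style running sum).
#' @return enrichment score (unbounded real).
#' @export
ssgsea_score <- function(profile, gene_set, alpha = 0.25) {
  if (is.null(names(profile))) stop("profile must be named by gene")
  gene_set <- unique(toupper(gene_set))
  genes <- toupper(names(profile))
  in_set <- genes %in% gene_set
  if (!any(in_set))
    stop("gene set has no members in the profile (",
         paste(utils::head(gene_set, 3L), collapse = ", "), ", ...)")
  n <- length(profile)
  r <- rank(profile, ties.method = "average")  # midranks; high value = high rank
  # ties in value are walked in gene-name order so the score does not
  # depend on the input ordering of tied genes
  ord <- order(-profile, genes)
  in_ord <- in_set[ord]
  w <- abs(r[ord])^alpha
  w[!in_ord] <- 0
  cum_in <- cumsum(w) / sum(w)
  cum_out <- cumsum(!in_ord) / sum(!in_ord)
  sum(cum_in - cum_out)
}

#' Score a sample x gene matrix against a list of gene sets
#'
#' Applies [ssgsea_score()] per sample and per set. Sets with no member in
#' the matrix yield an `NA` column and a warning (never silently dropped);
#' set members missing from the matrix are ignored.
#'
#' @param matrix numeric matrix, samples in rows, genes in columns.
#' @param sets named list of gene sets (as from [read_gmt()]).
#' @param alpha rank-weighting exponent.
#' @param normalize if `TRUE`, min-max normalize each set's scores across
#'   samples (off by default).
#' @return samples x sets numeric matrix of enrichment scores.
#' @export
score_matrix <- function(matrix, sets, alpha = 0.25, normalize = FALSE) {
  stopifnot(is.matrix(matrix), !is.null(colnames(matrix)))
  scores <- base::matrix(NA_real_, nrow(matrix), length(sets),
                         dimnames = list(rownames(matrix), names(sets)))
  genes <- toupper(colnames(matrix))
  for (s in seq_along(sets)) {
    members <- intersect(toupper(sets[[s]]), genes)
    if (length(members) == 0L) {
      warning("gene set '", names(sets)[s],
              "' has zero coverage in the matrix; scores set to NA")
      next
    }
    for (i in seq_len(nrow(matrix))) {
      prof <- stats::setNames(matrix[i, ], genes)
      scores[i, s] <- ssgsea_score(prof, members, alpha = alpha)
    }
  }
  if (normalize) {
    rng <- apply(scores, 2L, function(x) diff(range(x, na.rm = TRUE)))
    mins <- apply(scores, 2L, min, na.rm = TRUE)
    scores <- sweep(sweep(scores, 2L, mins, "-"), 2L,
                    ifelse(rng > 0, rng, 1), "/")
  }
  scores
}

#' Kinase-substrate enrichment analysis
#'
#' Infers kinase activity from phosphosite log2 fold-changes using the
#' mean-shift z-score convention of the KSEA App:
#' `z = (mean_substrates - mean_all_sites) * sqrt(m) / sd_all_sites`,
#' with `m` the number of the kinase's annotated substrate sites present in
#' the data. Kinase-substrate links are filtered by NetworKIN prediction
#' score, and kinases by a minimum substrate count.
#'
#' @param fold_changes named numeric vector: phosphosite id -> log2 ratio.
#' @param ks_map data.frame with columns `kinase`, `substrate_site`,
#'   `networkin_score` linking kinases to phosphosite ids.
#' @param min_substrates minimum substrates a kinase must have among the
#'   measured sites (default 5).
#' @param networkin_min minimum NetworKIN prediction score for a link to
#'   count (default 5).
#' @return data.frame with `kinase`, `m`, `mean_fc`, `z`, `p` (two-sided
#'   normal) and `significant` (`p < 0.05`), sorted by p.
#' @export
ksea <- function(fold_changes, ks_map, min_substrates = 5L,
                 networkin_min = 5) {
  stopifnot(!is.null(names(fold_changes)))
  need <- c("kinase", "substrate_site", "networkin_score")
  if (!all(need %in% names(ks_map)))
    stop("ks_map must have columns: ", paste(need, collapse = ", "))
  fc <- fold_changes[is.finite(fold_changes)]
  delta <- stats::sd(fc)
  if (!is.finite(delta) || delta == 0)
    stop("degenerate data: phosphosite log2 ratios have zero spread")
  pbar <- mean(fc)
  map <- ks_map[ks_map$networkin_score >= networkin_min &
                  ks_map$substrate_site %in% names(fc), , drop = FALSE]
  if (nrow(map) == 0L) stop("no kinase passes the NetworKIN/coverage filters")
  out <- do.call(rbind, lapply(split(map$substrate_site, map$kinase),
                               function(sites) {
    sites <- unique(sites)
    m <- length(sites)
    if (m < min_substrates) return(NULL)
    sbar <- mean(fc[sites])
    z <- (sbar - pbar) * sqrt(m) / delta
    data.frame(m = m, mean_fc = sbar, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  }))
  if (is.null(out)) stop("no kinase passes the minimum-substrate filter")
  out$kinase <- rownames(out)
  out$significant <- out$p < 0.05
  out <- out[order(out$p), c("kinase", "m", "mean_fc", "z", "p",
                             "significant")]
  rownames(out) <- NULL
  out
}
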