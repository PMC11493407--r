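# Structure-resolved interface-mutation enrichment (oncoPPI calling).
#
# For each gene g participating in a protein-protein interaction, with M the
# interface length and N the protein product length (same units), the number
# of missense mutations falling in the interface out of n total missense
# mutations in g is modeled as binomial(n, M/N) under the null that the
# interface is not recurrently mutated. A pair is an oncoPPI when either
# partner's interface is enriched at FDR < 0.01 (Benjamini-Hochberg across
# all tested (pair, partner) hypotheses).

#' Load structure-resolved interface intervals
#'
#' Reads a BED-like tab-separated table of interface intervals with columns
#' `chrom`, `start` (0-based), `end` (half-open), `pair_id`, `partner`,
#' `M`, `N`. Intervals are merged per (pair, partner); records with
#' `M > N`, `M <= 0` or malformed intervals are dropped with a warning.
#'
#' @param path path to the interface table.
#' @return data.frame of merged intervals with one row per interval and
#'   attributes preserved per (pair_id, partner): columns `chrom`, `start`,
#'   `end`, `pair_id`, `partner`, `M`, `N`.
#' @export
load_interfaces <- function(path) {
  if (!file.exists(path)) stop("interface table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "pair_id", "partner", "M", "N")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    stop("interface table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("interface table is empty")
    return(tab[, need])
  }
  bad_iv <- !is.finite(tab$start) | !is.finite(tab$end) | tab$end <= tab$start
  if (any(bad_iv)) {
    warning("dropped ", sum(bad_iv), " malformed interval row(s)")
    tab <- tab[!bad_iv, , drop = FALSE]
  }
  bad_mn <- tab$M > tab$N | tab$M <= 0 | tab$N <= 0
  if (any(bad_mn)) {
    warning("dropped ", sum(bad_mn),
            " row(s) with invalid interface/protein lengths (need 0 < M <= N)")
    tab <- tab[!bad_mn, , drop = FALSE]
  }
  if (nrow(tab) == 0L) {
    warning("no valid interface records remain after filtering")
    return(tab[, need])
  }
  # merge overlapping intervals within each (pair, partner)
  key <- interaction(tab$pair_id, tab$partner, drop = TRUE)
  merged <- do.call(rbind, lapply(split(tab, key), function(grp) {
    gr <- GenomicRanges::GRanges(grp$chrom,
                                 IRanges::IRanges(grp$start, grp$end - 1L))
    red <- GenomicRanges::reduce(gr)
    data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
               start = GenomicRanges::start(red),
               end = GenomicRanges::end(red) + 1L,
               pair_id = grp$pair_id[1L], partner = grp$partner[1L],
               M = grp$M[1L], N = grp$N[1L],
               stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  merged
}

#' Count missense mutations inside interface intervals
#'
#' For each (pair, partner) interface: `k` is the number of cohort missense
#' mutations falling in the partner gene's merged interface intervals and
#' `n` is the total number of missense mutations in that gene. Mutation
#' positions are 1-based and converted to 0-based half-open space before
#' intersection; recurrent mutations count once per cohort occurrence.
#'
#' @param records mutation record table (only `variant_class == "missense"`
#'   SNV rows are used).
#' @param interfaces merged interface table from [load_interfaces()].
#' @return data.frame with `pair_id`, `partner`, `k`, `n`, `M`, `N`; one
#'   row per (pair, partner). Partners whose gene carries zero missense
#'   mutations get `k = n = 0` (excluded from testing downstream).
#' @export
count_interface_mutations <- function(records, interfaces) {
  mis <- records[records$variant_class == "missense" & is_snv(records), ,
                 drop = FALSE]
  n_by_gene <- table(mis$gene)
  keys <- unique(interfaces[, c("pair_id", "partner", "M", "N")])
  key_id <- paste(keys$pair_id, keys$partner, sep = "\r")
  n <- integer(nrow(keys))
  have <- keys$partner %in% names(n_by_gene)
  n[have] <- as.integer(n_by_gene[keys$partner[have]])
  k <- integer(nrow(keys))
  if (nrow(mis) > 0L && nrow(interfaces) > 0L) {
    mut0 <- coord_1based_to_0h(mis$pos)
    mut_gr <- GenomicRanges::GRanges(
      mis$chrom, IRanges::IRanges(mut0$start, mut0$end - 1L))
    iv_gr <- GenomicRanges::GRanges(
      interfaces$chrom,
      IRanges::IRanges(interfaces$start, interfaces$end - 1L))
    hits <- GenomicRanges::findOverlaps(mut_gr, iv_gr)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    same_gene <- mis$gene[q] == interfaces$partner[s]
    hit_key <- paste(interfaces$pair_id[s], interfaces$partner[s],
                     sep = "\r")[same_gene]
    # one count per mutation per (pair, partner), whatever the interval count
    uniq <- !duplicated(paste(q[same_gene], hit_key, sep = "\r"))
    tab <- table(factor(hit_key[uniq], levels = key_id))
    k <- as.integer(tab)
  }
  data.frame(pair_id = keys$pair_id, partner = keys$partner,
             k = k, n = n, M = keys$M, N = keys$N,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exact binomial upper-tail p-value for interface mutation enrichment
#'
#' `P(X >= k)` for `X ~ binomial(n, M/N)`:
#' `1 - sum_{x=0}^{k-1} C(n, x) p^x (1-p)^(n-x)` with `p = M/N`, computed
#' through the stable binomial tail rather than naive summation.
#'
#' @param k observed interface mutations (`0 <= k <= n`).
#' @param n total mutations observed in the gene.
#' @param M interface length.
#' @param N protein product length, same units as `M` (`0 < M <= N`).
#' @return upper-tail probability in `[0, 1]`; `k = 0` gives 1.
#' @export
binomial_interface_pvalue <- function(k, n, M, N) {
  if (any(k > n) || any(k < 0)) stop("need 0 <= k <= n")
  if (any(M > N) || any(M <= 0)) stop("need 0 < M <= N")
  p <- M / N
  ifelse(k == 0, 1, stats::pbinom(k - 1, n, p, lower.tail = FALSE))
}

#' Call oncoPPIs from interface mutation counts
#'
#' Applies the binomial interface enrichment test to every (pair, partner)
#' hypothesis with `n >= 1`, adjusts across all tests by Benjamini-Hochberg,
#' and declares a pair an oncoPPI when either partner passes the FDR
#' threshold.
#'
#' @param counts data.frame from [count_interface_mutations()] (columns
#'   `pair_id`, `partner`, `k`, `n`, `M`, `N`).
#' @param fdr_threshold FDR significance threshold (default 0.01).
#' @return data.frame sorted by (q, p) with added columns `p_value`,
#'   `q_value`, `partner_significant` and `is_oncoppi` (pair-level verdict,
#'   identical for both partners of a pair).
#' @export
call_oncoppis <- function(counts, fdr_threshold = 0.01) {
  testable <- counts[counts$n >= 1L, , drop = FALSE]
  if (nrow(testable) == 0L) {
    warning("no testable (pair, partner) hypotheses (all n = 0)")
    out <- counts[0, , drop = FALSE]
    out$p_value <- numeric(0); out$q_value <- numeric(0)
    out$partner_significant <- logical(0); out$is_oncoppi <- logical(0)
    return(out)
  }
  testable$p_value <- binomial_interface_pvalue(testable$k, testable$n,
                                                testable$M, testable$N)
  testable$q_value <- stats::p.adjust(testable$p_value, method = "BH")
  testable$partner_significant <- testable$q_value < fdr_threshold
  sig_pairs <- unique(testable$pair_id[testable$partner_significant])
  testable$is_oncoppi <- testable$pair_id %in% sig_pairs
  testable <- testable[order(testable$q_value, testable$p_value), ,
                       drop = FALSE]
  rownames(testable) <- NULL
  testable
}

#' Export an oncoPPI network as edge and node tables
#'
#' Edge weight is the total number of interface missense mutations summed
#' over the pair's two partners (drives edge thickness in graph viewers);
#' node size is the gene's connectivity (degree) in the oncoPPI network.
#'
#' @param results data.frame from [call_oncoppis()].
#' @return list with `edges` (`gene_a`, `gene_b`,
#'   `interface_mutation_count`) and `nodes` (`gene`, `degree`).
#' @export
export_network <- function(results) {
  sig <- results[results$is_oncoppi, , drop = FALSE]
  if (nrow(sig) == 0L) {
    warning("no significant oncoPPIs to export")
    return(list(edges = data.frame(gene_a = character(0),
                                   gene_b = character(0),
                                   interface_mutation_count = integer(0)),
                nodes = data.frame(gene = character(0), degree = integer(0))))
  }
  ksum <- tapply(sig$k, sig$pair_id, sum)
  pairs <- strsplit(names(ksum), "--", fixed = TRUE)
  edges <- data.frame(
    gene_a = vapply(pairs, `[`, character(1), 1L),
    gene_b = vapply(pairs, `[`, character(1), 2L),
    interface_mutation_count = as.integer(ksum),
    stringsAsFactors = FALSE, row.names = NULL)
  genes <- c(edges$gene_a, edges$gene_b)
  deg <- table(genes)
  nodes <- data.frame(gene = names(deg), degree = as.integer(deg),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(edges = edges, nodes = nodes)
}
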