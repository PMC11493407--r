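# Independent oracles and tiny fixture builders used across the suite.
# Oracles are deliberately naive (loops, direct summation, exhaustive
# enumeration) so they share no code path with the implementations they
# check.

# upper-tail binomial P(X >= k) by direct summation of the mass function
oracle_binom_upper <- function(k, n, p) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(x) choose(n, x) * p^x * (1 - p)^(n - x),
             numeric(1)))
}

# AUC by exhaustive pairwise comparison (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# two-sided Fisher p by exhaustive enumeration of the hypergeometric
# tables sharing the margins (point-probability method)
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, m, n, k), numeric(1))
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ssGSEA by an explicit position-by-position walk
oracle_ssgsea <- function(profile, gene_set, alpha) {
  r <- rank(profile, ties.method = "average")
  ord <- order(-profile, toupper(names(profile)))
  genes <- toupper(names(profile))[ord]
  in_set <- genes %in% toupper(gene_set)
  rw <- abs(r[ord])^alpha
  denom_in <- sum(rw[in_set])
  n_out <- sum(!in_set)
  score <- 0; cin <- 0; cout <- 0
  for (i in seq_along(genes)) {
    if (in_set[i]) cin <- cin + rw[i] else cout <- cout + 1
    score <- score + cin / denom_in - cout / n_out
  }
  unname(score)
}

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# disjoint-support synthetic signature profiles (k x 96, rows sum to 1)
make_disjoint_signatures <- function(k, seed = 1) {
  stopifnot(k <= 6)
  withr::with_seed(seed, {
    sigs <- matrix(0, k, 96, dimnames = list(paste0("R", seq_len(k)),
                                             sbs_channels()))
    cuts <- floor(seq(0, 96, length.out = k + 1))
    for (i in seq_len(k)) {
      idx <- (cuts[i] + 1):cuts[i + 1]
      sigs[i, idx] <- stats::runif(length(idx))
    }
    sigs / rowSums(sigs)
  })
}

# write a small MAF-like table and return its path
write_toy_maf <- function(rows, path = tempfile(fileext = ".maf.tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

toy_maf_rows <- function() {
  data.frame(
    Tumor_Sample_Barcode = c("T1", "T1", "T2", "T2"),
    Hugo_Symbol = c("EGFR", "TP53", "EGFR", "KRAS"),
    Chromosome = c("chr7", "chr17", "chr7", "chr12"),
    Start_Position = c(55174014L, 7675088L, 55174015L, 25245350L),
    Reference_Allele = c("G", "C", "GA", "C"),
    Tumor_Seq_Allele2 = c("T", "T", "-", "A"),
    Variant_Classification = c("Missense_Mutation", "Nonsense_Mutation",
                               "Frame_Shift_Del", "Silent"),
    HGVSp_Short = c("p.G719C", "p.R213*", NA, NA),
    ref_context = c("GGG", "ACA", "TGC", "GCT"),
    stringsAsFactors = FALSE)
}
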