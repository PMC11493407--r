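# Somatic mutation catalogs: MAF-like parsing, 96-channel spectra, and
# flank-context distributions for hotspot substitution classes.

MAF_REQUIRED <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
                  "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
                  "Variant_Classification")

VARIANT_CLASS_MAP <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Nonstop_Mutation  = "nonstop",
  Frame_Shift_Del   = "frameshift_indel",
  Frame_Shift_Ins   = "frameshift_indel",
  In_Frame_Del      = "inframe_indel",
  In_Frame_Ins      = "inframe_indel",
  Silent            = "silent"
)

VARIANT_CLASSES <- c("missense", "nonsense", "nonstop", "frameshift_indel",
                     "inframe_indel", "silent", "other")

#' Convert 1-based inclusive positions to 0-based half-open intervals
#'
#' Mutation tables use 1-based inclusive coordinates (MAF convention); all
#' interval arithmetic in the package is done in 0-based half-open space. A
#' single base at 1-based position `p` occupies `[p-1, p)`.
#'
#' @param pos integer vector of 1-based positions.
#' @return data.frame with columns `start` (0-based) and `end` (exclusive).
#' @seealso [coord_0h_to_1based()]
#' @export
coord_1based_to_0h <- function(pos) {
  stopifnot(all(pos >= 1))
  data.frame(start = pos - 1L, end = pos)
}

#' Convert 0-based half-open single-base intervals back to 1-based positions
#' @param start integer vector of 0-based starts.
#' @return integer vector of 1-based positions.
#' @export
coord_0h_to_1based <- function(start) {
  as.integer(start + 1L)
}

#' Read a MAF-like somatic mutation table
#'
#' Parses a tab-separated mutation table with MAF column names into a
#' normalized record table. Variant classification strings are mapped onto
#' the internal classes (`missense`, `nonsense`, `nonstop`,
#' `frameshift_indel`, `inframe_indel`, `silent`); unknown strings map to
#' `other` with a warning. Duplicate records on (sample, chrom, pos, alt)
#' are collapsed to one occurrence with a message.
#'
#' @param path path to a tab-separated file with columns
#'   `Tumor_Sample_Barcode`, `Hugo_Symbol`, `Chromosome`, `Start_Position`,
#'   `Reference_Allele`, `Tumor_Seq_Allele2`, `Variant_Classification`, and
#'   optionally `HGVSp_Short` and `ref_context`.
#' @param dialect input dialect; only `"maf_like"` is supported.
#' @return data.frame with columns `sample_id`, `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `variant_class`, `protein_change`, `ref_context`.
#' @export
read_mutation_table <- function(path, dialect = c("maf_like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("mutation table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  missing_cols <- setdiff(MAF_REQUIRED, names(tab))
  if (length(missing_cols) > 0L)
    stop("mutation table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0L) return(empty_mutation_records())

  pos <- suppressWarnings(as.integer(tab$Start_Position))
  bad <- which(is.na(pos))
  if (length(bad) > 0L)
    stop("unparseable Start_Position at data line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))

  ref <- toupper(as.character(tab$Reference_Allele))
  alt <- toupper(as.character(tab$Tumor_Seq_Allele2))
  same <- which(ref == alt)
  if (length(same) > 0L)
    stop("Reference_Allele equals Tumor_Seq_Allele2 at data line(s): ",
         paste(utils::head(same, 5L), collapse = ", "))

  raw_class <- as.character(tab$Variant_Classification)
  variant_class <- unname(VARIANT_CLASS_MAP[raw_class])
  unknown <- is.na(variant_class)
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with unrecognized ",
            "Variant_Classification mapped to class 'other' (e.g. '",
            raw_class[which(unknown)[1L]], "')")
    variant_class[unknown] <- "other"
  }

  rec <- data.frame(
    sample_id = as.character(tab$Tumor_Sample_Barcode),
    gene = as.character(tab$Hugo_Symbol),
    chrom = as.character(tab$Chromosome),
    pos = pos,
    ref = ref,
    alt = alt,
    variant_class = variant_class,
    protein_change = if ("HGVSp_Short" %in% names(tab))
      as.character(tab$HGVSp_Short) else NA_character_,
    ref_context = if ("ref_context" %in% names(tab))
      toupper(as.character(tab$ref_context)) else NA_character_,
    stringsAsFactors = FALSE
  )

  key <- paste(rec$sample_id, rec$chrom, rec$pos, rec$alt, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message("collapsed ", sum(dup),
            " duplicate record(s) on (sample, chrom, pos, alt)")
    rec <- rec[!dup, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

empty_mutation_records <- function() {
  data.frame(sample_id = character(0), gene = character(0),
             chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), variant_class = character(0),
             protein_change = character(0), ref_context = character(0),
             stringsAsFactors = FALSE)
}

#' Identify single-nucleotide variant records
#' @param records mutation record table as from [read_mutation_table()].
#' @return logical vector.
#' @export
is_snv <- function(records) {
  nchar(records$ref) == 1L & nchar(records$alt) == 1L &
    records$ref %in% BASES & records$alt %in% BASES
}

#' Summarize mutation class counts in a catalog
#'
#' Tabulates records per variant class, reporting indel classes as a single
#' `indel` count alongside `missense`, `nonsense`, `nonstop` and the total —
#' the partition used in cohort-level reporting.
#'
#' @param records mutation record table.
#' @return list with `by_class` (named integer vector) and `total`.
#' @export
mutation_class_summary <- function(records) {
  cls <- records$variant_class
  by_class <- c(
    indel = sum(cls %in% c("frameshift_indel", "inframe_indel")),
    missense = sum(cls == "missense"),
    nonsense = sum(cls == "nonsense"),
    nonstop = sum(cls == "nonstop"),
    silent = sum(cls == "silent"),
    other = sum(cls == "other")
  )
  list(by_class = by_class, total = nrow(records))
}

#' Resolve trinucleotide contexts for SNV records
#'
#' Uses the `ref_context` column when present, otherwise fetches the 3-base
#' window around each position from an indexed genome FASTA.
#'
#' @param records mutation record table (SNV rows are resolved; others NA).
#' @param fasta optional path to a genome FASTA with a `.fai` index.
#' @return character vector of 3-base contexts (NA where unresolvable).
#' @keywords internal
resolve_contexts <- function(records, fasta = NULL) {
  ctx <- rep(NA_character_, nrow(records))
  snv <- is_snv(records)
  have_col <- !is.null(records$ref_context) & !is.na(records$ref_context) &
    nchar(records$ref_context) > 0L
  use_col <- snv & have_col
  if (any(use_col)) {
    rc <- records$ref_context[use_col]
    # a longer odd-length window is accepted; the central 3 bases are used
    n <- nchar(rc)
    mid <- (n + 1L) %/% 2L
    ctx[use_col] <- substr(rc, mid - 1L, mid + 1L)
  }
  need <- snv & is.na(ctx)
  if (any(need)) {
    if (is.null(fasta))
      stop("no ref_context for ", sum(need),
           " SNV record(s) and no FASTA supplied")
    fa <- Rsamtools::FaFile(fasta)
    gr <- GenomicRanges::GRanges(
      records$chrom[need],
      IRanges::IRanges(start = records$pos[need] - 1L,
                       end = records$pos[need] + 1L))
    ctx[need] <- as.character(Biostrings::getSeq(fa, gr))
  }
  toupper(ctx)
}

#' Build the samples x 96 trinucleotide spectrum
#'
#' Aggregates SNV records into the 96-channel pyrimidine-centered spectrum.
#' Non-SNV records are ignored; SNVs whose context contains an ambiguous
#' base are excluded and counted in the QC report rather than erroring.
#'
#' @param records mutation record table.
#' @param fasta optional genome FASTA path used when `ref_context` is absent.
#' @param sample_ids optional ordered sample universe; defaults to the
#'   samples observed in `records`.
#' @return object of class `spectrum_matrix`: a list with `counts`
#'   (samples x 96 integer matrix, columns in [sbs_channels()] order) and
#'   `qc` (counts of non-SNV and unassignable records).
#' @export
build_spectrum <- function(records, fasta = NULL, sample_ids = NULL) {
  snv <- is_snv(records)
  if (!any(snv)) stop("catalog contains no SNV records; spectrum is empty")
  if (is.null(sample_ids)) sample_ids <- unique(records$sample_id[snv])
  ctx <- resolve_contexts(records, fasta = fasta)

  channels <- sbs_channels()
  counts <- matrix(0L, nrow = length(sample_ids), ncol = 96L,
                   dimnames = list(sample_ids, channels))
  n_unassignable <- 0L
  idx <- which(snv)
  ch <- character(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    ch[j] <- snv_channel(records$ref[i], records$alt[i], ctx[i])
  }
  keep <- ch != "unassignable"
  n_unassignable <- sum(!keep)
  tab <- table(factor(records$sample_id[idx[keep]], levels = sample_ids),
               factor(ch[keep], levels = channels))
  counts[] <- as.integer(tab)
  structure(
    list(counts = counts,
         qc = c(n_records = nrow(records),
                n_snv = sum(snv),
                n_non_snv = sum(!snv),
                n_unassignable = n_unassignable)),
    class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat("spectrum_matrix:", nrow(x$counts), "samples x 96 channels;",
      sum(x$counts), "assignable SNVs\n")
  cat("QC:", paste(names(x$qc), x$qc, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a spectrum to TSV
#'
#' Samples in rows, the 96 channels in columns; a header comment documents
#' the channel order convention.
#'
#' @param spectrum `spectrum_matrix` object.
#' @param path output path.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# 96 pyrimidine-centered trinucleotide channels in ",
                    "COSMIC display order (C>A, C>G, C>T, T>A, T>C, T>G; ",
                    "flanks lexicographic)"), con)
  df <- data.frame(sample_id = rownames(spectrum$counts), spectrum$counts,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a spectrum TSV written by [write_spectrum()]
#' @param path input path.
#' @return `spectrum_matrix` object (QC counts unavailable, set to NA).
#' @export
read_spectrum <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1L]]
  stopifnot(identical(colnames(counts), sbs_channels()))
  structure(list(counts = counts, qc = c(n_records = NA, n_snv = NA,
                                         n_non_snv = NA, n_unassignable = NA)),
            class = "spectrum_matrix")
}

#' Flank-context distribution for one substitution class
#'
#' Normalized counts of the 16 (5', 3') flank pairs among SNVs of one
#' pyrimidine-centered substitution class. Storage is pyrimidine-centered;
#' the returned table additionally carries the purine-strand triplet label
#' (e.g. `GpGpG` for the C>A channel with C,C flanks) used when displaying
#' purine-strand hotspots.
#'
#' @param records mutation record table.
#' @param substitution_class one of `"C>A"`, `"C>G"`, `"C>T"`, `"T>A"`,
#'   `"T>C"`, `"T>G"`.
#' @param fasta optional genome FASTA path.
#' @return object of class `context_distribution`: list with `weights`
#'   (16 named reals summing to 1, or all zero), `n_events`, `table`
#'   (data.frame with flank pair, purine-strand triplet, count, weight) and
#'   `substitution_class`.
#' @export
context_distribution <- function(records, substitution_class, fasta = NULL) {
  if (!substitution_class %in% SUB_CLASSES)
    stop("substitution_class must be one of: ",
         paste(SUB_CLASSES, collapse = ", "))
  spec <- build_spectrum(records, fasta = fasta)
  totals <- colSums(spec$counts)
  in_class <- channel_class(names(totals)) == substitution_class
  counts <- totals[in_class]
  pairs <- channel_flanks(names(counts))
  names(counts) <- pairs
  n_events <- sum(counts)
  weights <- if (n_events > 0) counts / n_events else counts * 0
  pyr <- substr(substitution_class, 1L, 1L)
  p5 <- substr(pairs, 1L, 1L)
  p3 <- substr(pairs, 3L, 3L)
  purine_triplet <- paste(COMPLEMENT[p3], COMPLEMENT[pyr], COMPLEMENT[p5],
                          sep = "p")
  structure(
    list(substitution_class = substitution_class,
         n_events = n_events,
         weights = weights,
         table = data.frame(flank_pair = pairs,
                            purine_triplet = unname(purine_triplet),
                            count = as.integer(counts),
                            weight = as.numeric(weights),
                            stringsAsFactors = FALSE)),
    class = "context_distribution")
}

#' @export
print.context_distribution <- function(x, ...) {
  cat("context_distribution for", x$substitution_class, "(",
      x$n_events, "events )\n")
  if (x$n_events == 0) cat("  [no events of this class]\n")
  else {
    top <- x$table[order(-x$table$weight), ][1:3, ]
    cat("  top flank pairs:",
        paste(sprintf("%s (%s, %.3f)", top$flank_pair, top$purine_triplet,
                      top$weight), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Pearson correlation of per-gene mutation frequencies between two cohorts
#'
#' Frequencies are the fraction of mutated samples per gene. The gene
#' universe is the union of genes present in either vector; genes absent
#' from one cohort are imputed as frequency 0.
#'
#' @param freq_a,freq_b named numeric vectors of per-gene mutated-sample
#'   fractions.
#' @return Pearson correlation coefficient.
#' @export
mutation_frequency_correlation <- function(freq_a, freq_b) {
  if (is.null(names(freq_a)) || is.null(names(freq_b)))
    stop("frequency vectors must be named by gene")
  genes <- union(names(freq_a), names(freq_b))
  a <- stats::setNames(rep(0, length(genes)), genes)
  b <- a
  a[names(freq_a)] <- freq_a
  b[names(freq_b)] <- freq_b
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero variance in a frequency vector")
  stats::cor(a, b, method = "pearson")
}
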