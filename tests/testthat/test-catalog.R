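test_that("channel labeling follows the pyrimidine-centered convention", {
  expect_equal(snv_channel("C", "A", "ACA"), "A[C>A]A")
  # purine-strand G>T in a GpGpG context folds onto C[C>A]C
  expect_equal(snv_channel("G", "T", "GGG"), "C[C>A]C")
  # reverse complement of TGC is GCA, so G>A in TGC is G[C>T]A
  expect_equal(snv_channel("G", "A", "TGC"), "G[C>T]A")
  expect_equal(snv_channel("C", "G", "NCA"), "unassignable")
  expect_error(snv_channel("C", "A", "AGA"), "does not match ref")
  expect_error(snv_channel("C", "C", "ACA"), "identical")
})

test_that("labeling a purine-strand SNV and its reverse complement agree", {
  set.seed(41)
  for (i in 1:50) {
    ref <- sample(c("C", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ctx <- paste0(sample(c("A", "C", "G", "T"), 1), ref,
                  sample(c("A", "C", "G", "T"), 1))
    pyr <- snv_channel(ref, alt, ctx)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    rc <- paste(rev(comp[strsplit(ctx, "")[[1]]]), collapse = "")
    pur <- snv_channel(comp[[ref]], comp[[alt]], rc)
    expect_identical(pyr, pur)
  }
})

test_that("MAF-like tables parse with normalized variant classes", {
  path <- write_toy_maf(toy_maf_rows())
  rec <- read_mutation_table(path)
  expect_equal(nrow(rec), 4L)
  expect_equal(rec$variant_class,
               c("missense", "nonsense", "frameshift_indel", "silent"))
  expect_equal(rec$protein_change[1], "p.G719C")

  # header-only file gives an empty record table
  empty <- write_toy_maf(toy_maf_rows()[0, ])
  expect_equal(nrow(read_mutation_table(empty)), 0L)

  # missing mandatory column is named in the error
  bad <- toy_maf_rows(); bad$Chromosome <- NULL
  expect_error(read_mutation_table(write_toy_maf(bad)), "Chromosome")

  # ref == alt is a row error
  same <- toy_maf_rows(); same$Tumor_Seq_Allele2[1] <- "G"
  expect_error(read_mutation_table(write_toy_maf(same)), "equals")

  # unknown classes map to other with a warning
  odd <- toy_maf_rows(); odd$Variant_Classification[4] <- "Splice_Site"
  expect_warning(rec2 <- read_mutation_table(write_toy_maf(odd)),
                 "unrecognized")
  expect_equal(rec2$variant_class[4], "other")

  # duplicates on (sample, chrom, pos, alt) collapse to one record
  dup <- rbind(toy_maf_rows(), toy_maf_rows()[1, ])
  expect_message(rec3 <- read_mutation_table(write_toy_maf(dup)),
                 "duplicate")
  expect_equal(nrow(rec3), 4L)
})

test_that("spectrum aggregation conserves assignable SNV counts", {
  rec <- data.frame(sample_id = "S1", gene = "G", chrom = "chr1",
                    pos = c(10L, 20L, 30L), ref = "C", alt = "A",
                    variant_class = "missense",
                    protein_change = NA_character_, ref_context = "ACA",
                    stringsAsFactors = FALSE)
  spec <- build_spectrum(rec)
  expect_equal(unname(spec$counts["S1", "A[C>A]A"]), 3L)
  expect_equal(sum(spec$counts), 3L)

  # indels never contribute to row sums
  indel <- rec[1, ]; indel$ref <- "CT"; indel$alt <- "-"
  indel$variant_class <- "frameshift_indel"
  spec2 <- build_spectrum(rbind(rec, indel))
  expect_equal(sum(spec2$counts), 3L)
  expect_equal(unname(spec2$qc["n_non_snv"]), 1L)

  # ambiguous contexts are excluded and counted, not errored
  amb <- rec; amb$ref_context[2] <- "NCA"
  spec3 <- build_spectrum(amb)
  expect_equal(sum(spec3$counts), 2L)
  expect_equal(unname(spec3$qc["n_unassignable"]), 1L)

  expect_error(build_spectrum(rbind(indel)), "no SNV")
})

test_that("uniform catalogs give near-uniform channel counts", {
  unif <- matrix(1 / 96, 1, 96, dimnames = list("U", sbs_channels()))
  sim <- simulate_catalog(unif, matrix(1, 1, 1), loads = 1000L, seed = 7)
  counts <- sim$spectrum$counts[1, ]
  expect_equal(sum(counts), 1000L)
  mu <- 1000 / 96
  expect_true(all(abs(counts - mu) <= 4 * sqrt(mu)))
})

test_that("contexts resolve from an indexed genome FASTA", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "AACATGGGTT"), fa)
  Rsamtools::indexFa(fa)
  rec <- data.frame(sample_id = "S1", gene = "G", chrom = "chr1",
                    pos = c(3L, 7L), ref = c("C", "G"), alt = c("A", "T"),
                    variant_class = "missense",
                    protein_change = NA_character_,
                    ref_context = NA_character_, stringsAsFactors = FALSE)
  spec <- build_spectrum(rec, fasta = fa)
  # pos 3 in AACATGGGTT has context ACA; pos 7 has GGG -> C[C>A]C
  expect_equal(unname(spec$counts["S1", "A[C>A]A"]), 1L)
  expect_equal(unname(spec$counts["S1", "C[C>A]C"]), 1L)
  # no context column and no FASTA is an error
  expect_error(build_spectrum(rec), "no ref_context")
})

test_that("context distributions mirror spectrum column marginals", {
  set.seed(13)
  ctxs <- apply(expand.grid(c("A","C","G","T"), "C", c("A","C","G","T")),
                1, paste, collapse = "")
  rec <- data.frame(sample_id = sample(c("S1", "S2"), 80, replace = TRUE),
                    gene = "G", chrom = "chr1", pos = 1:80,
                    ref = "C", alt = sample(c("A", "G", "T"), 80, TRUE),
                    variant_class = "missense",
                    protein_change = NA_character_,
                    ref_context = sample(ctxs, 80, TRUE),
                    stringsAsFactors = FALSE)
  spec <- build_spectrum(rec)
  for (cls in c("C>A", "C>G", "C>T")) {
    cd <- context_distribution(rec, cls)
    in_cls <- grepl(paste0("\\[", cls, "\\]"), colnames(spec$counts),
                    fixed = FALSE)
    marg <- colSums(spec$counts)[in_cls]
    expect_equal(unname(cd$weights * cd$n_events), unname(marg))
    if (cd$n_events > 0) expect_equal(sum(cd$weights), 1)
  }
})

test_that("purine-strand hotspot contexts report the purine triplet", {
  # ten G>T events in GpGpG context: stored as C[C>A]C, displayed as GpGpG
  rec <- data.frame(sample_id = "S1", gene = "EGFR", chrom = "chr7",
                    pos = 1:10, ref = "G", alt = "T",
                    variant_class = "missense",
                    protein_change = NA_character_, ref_context = "GGG",
                    stringsAsFactors = FALSE)
  cd <- context_distribution(rec, "C>A")
  expect_equal(unname(cd$weights["C,C"]), 1)
  expect_equal(cd$table$purine_triplet[cd$table$flank_pair == "C,C"],
               "GpGpG")

  # a single event concentrates all weight
  cd1 <- context_distribution(rec[1, ], "C>A")
  expect_equal(sum(cd1$weights == 1), 1L)

  # absent class flags zero events with all-zero weights
  cd0 <- context_distribution(rec, "T>G")
  expect_equal(cd0$n_events, 0L)
  expect_true(all(cd0$weights == 0))
})

test_that("mutation frequency correlation handles shared gene universes", {
  a <- c(EGFR = 0.1, TP53 = 0.2, KRAS = 0.3)
  expect_equal(mutation_frequency_correlation(a, a), 1)
  expect_equal(mutation_frequency_correlation(a, 1 - a), -1)
  # hand-computed: cov = 0.04, sd_a = sqrt(0.02), sd_b = sqrt(0.14)
  b <- c(EGFR = 0.2, TP53 = 0.1, KRAS = 0.6)
  expect_equal(mutation_frequency_correlation(a, b),
               0.04 / sqrt(0.02 * 0.14), tolerance = 1e-12)
  # genes absent from one cohort are imputed zero
  expect_equal(
    mutation_frequency_correlation(c(a, RBM10 = 0.5),
                                   c(b, RBM10 = 0)),
    mutation_frequency_correlation(c(a, RBM10 = 0.5), b))
  expect_error(
    mutation_frequency_correlation(c(EGFR = 1, TP53 = 1, KRAS = 1), a),
    "zero variance")
})

test_that("coordinate conversion round-trips exactly", {
  pos <- c(1L, 2L, 10L, 55174014L, 1000000000L)
  iv <- coord_1based_to_0h(pos)
  expect_equal(iv$start, pos - 1L)
  expect_equal(iv$end, pos)
  expect_identical(coord_0h_to_1based(iv$start), pos)
})

test_that("class summary partitions a catalog", {
  path <- write_toy_maf(toy_maf_rows())
  s <- mutation_class_summary(read_mutation_table(path))
  expect_equal(unname(s$by_class[c("missense", "nonsense", "indel",
                                   "silent")]), c(1L, 1L, 1L, 1L))
  expect_equal(s$total, 4L)
  expect_equal(sum(s$by_class), s$total)
})
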