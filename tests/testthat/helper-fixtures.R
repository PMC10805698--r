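# Shared fixtures, all built in code at test time.

# rank-based AUC of scores for a binary truth vector
auc_of <- function(truth, score) {
  as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

# tiny MAF written to a tempfile; dialect: "minimal" or "mc3"
write_toy_maf <- function(rows, dialect = "minimal") {
  cols <- maf_dialect(dialect)
  names(rows) <- cols[names(rows)]
  path <- tempfile(fileext = ".maf")
  data.table::fwrite(rows, path, sep = "\t")
  path
}

toy_maf_rows <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(100L, 200L, 300L),
    ref = c("C", "-", "TTG"),
    alt = c("T", "AG", "-"),
    ref_count = c(70L, 50L, 30L),
    alt_count = c(30L, 50L, 70L),
    filter = c("PASS", "PASS", "wga"),
    sample_id = c("s1", "s1", "s2"),
    stringsAsFactors = FALSE
  )
}

# random plausible SBS records for merge property tests
random_sbs_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample(1:500, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    ref_count = sample(0:200, n, replace = TRUE),
    alt_count = sample(0:200, n, replace = TRUE),
    filter = "PASS",
    sample_id = sample(c("s1", "s2"), n, replace = TRUE),
    gene = NA_character_, strand = NA_character_, cds_pos = NA_integer_,
    stringsAsFactors = FALSE
  ) |>
    (\(d) d[d$ref != d$alt, ])() |>
    (\(d) d[!duplicated(d[c("sample_id", "chrom", "pos")]), ])()
}

# random bags with non-negative features (valid for every aggregation mode)
random_bags <- function(n_bags, d = 6, size = 2:8, seed = 1) {
  set.seed(seed)
  mats <- lapply(seq_len(n_bags), function(i) {
    sz <- size[sample.int(length(size), 1)]
    matrix(abs(stats::rnorm(sz * d)), ncol = d)
  })
  bags_from_list(mats, labels = factor(sample(c("a", "b"), n_bags,
                                              replace = TRUE)))
}

# hand-built two-ORF genome used by the consequence-oracle fixture tests
#
# layout (1-based):
#   1-5     TTTTT            intergenic
#   6-17    ATGGCTGAACGT     + strand CDS  (M A E R)
#   18-20   TAA              stop codon (excluded from CDS)
#   21-25   CCCCC            intergenic
#   26-28   TCA              revcomp'd stop of the - strand ORF
#   29-37   GCAAAACAT        - strand CDS, coding = ATGTTTTGC (M F C)
#   38-42   GGGGG            intergenic
hand_orf_genome <- function() {
  contig <- paste0("TTTTT", "ATGGCTGAACGT", "TAA", "CCCCC",
                   "TCA", "GCAAAACAT", "GGGGG")
  genome <- Biostrings::DNAStringSet(contig)
  names(genome) <- "toy"
  ann <- data.frame(
    gene = c("plus1", "minus1"), chrom = "toy",
    start = c(6L, 29L), end = c(17L, 37L), strand = c("+", "-"),
    coding = c("ATGGCTGAACGT", "ATGTTTTGC"),
    stringsAsFactors = FALSE
  )
  list(genome = genome, annotation = ann)
}
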