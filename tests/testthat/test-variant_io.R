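test_that("read_maf parses SBS, insertion and deletion records", {
  path <- write_toy_maf(toy_maf_rows(), "minimal")
  rec <- read_maf(path, dialect = maf_dialect("minimal"))
  expect_equal(nrow(rec), 3L)
  expect_equal(variant_class(rec$ref, rec$alt),
               c("SBS", "insertion", "deletion"))
  expect_equal(rec$pos, c(100L, 200L, 300L))
  expect_equal(rec$alt_count, c(30L, 50L, 70L))
})

test_that("MC3-style and minimal dialects parse equivalent content alike", {
  rows <- toy_maf_rows()
  p1 <- write_toy_maf(rows, "minimal")
  p2 <- write_toy_maf(rows, "mc3")
  r1 <- read_maf(p1, dialect = maf_dialect("minimal"))
  r2 <- read_maf(p2, dialect = maf_dialect("mc3"))
  expect_equal(r1, r2)
})

test_that("format and row errors name the offending column or line", {
  rows <- toy_maf_rows()
  path <- write_toy_maf(rows[, setdiff(names(rows), "pos")], "minimal")
  expect_error(read_maf(path, maf_dialect("minimal")), "pos")

  rows2 <- toy_maf_rows()
  rows2$pos <- c("100", "NA", "300")
  path2 <- write_toy_maf(rows2, "minimal")
  expect_error(read_maf(path2, maf_dialect("minimal")), "line 3")
})

test_that("FILTER retention is subset-based, allowing flag combinations", {
  rec <- toy_maf_rows()
  rec$filter <- c("PASS", "PASS,broad_PoN_v2", "NonExonic,wga")
  allowed_public <- c("PASS", "wga", "native_wga_mix")
  allowed_controlled <- c("PASS", "NonExonic", "wga", "bitgt",
                          "broad_PoN_v2", "native_wga_mix")
  expect_equal(filter_by_flags(rec, allowed_public)$pos, 100L)
  kept <- filter_by_flags(rec, allowed_controlled)
  expect_equal(nrow(kept), 3L)
  # outputs are a subset of inputs, never new records
  expect_true(all(kept$pos %in% rec$pos))
})

test_that("interval intersection keeps only fully covered reference spans", {
  rec <- data.frame(
    chrom = c("chr1", "chr1", "chr1"),
    pos = c(100L, 199L, 150L),
    ref = c("C", "TTG", "-"),
    alt = c("T", "-", "AA"),
    ref_count = 50L, alt_count = 50L, filter = "PASS", sample_id = "s1",
    stringsAsFactors = FALSE
  )
  iv <- data.frame(chrom = "chr1", start = 0L, end = 200L)
  kept <- intersect_intervals(rec, iv)
  # the 3-bp deletion at 199 spans [198, 201), exiting the interval
  expect_equal(kept$pos, c(100L, 150L))

  expect_equal(nrow(intersect_intervals(rec, iv[0, ])), 0L)
  rec$chrom <- "chrX"
  expect_warning(out <- intersect_intervals(rec, iv), "chrX")
  expect_equal(nrow(out), 0L)
})

merge_input <- function(pos, refc, altc, chrom = "chr1", sample = "s1") {
  data.frame(
    chrom = chrom, pos = pos,
    ref = rep(c("C", "T"), length.out = length(pos)),
    alt = rep(c("T", "G"), length.out = length(pos)),
    ref_count = refc, alt_count = altc, filter = "PASS",
    sample_id = sample, gene = NA_character_, strand = NA_character_,
    cds_pos = NA_integer_, stringsAsFactors = FALSE
  )
}

test_that("consecutive SBSs with concordant counts merge into one DBS", {
  rec <- merge_input(c(100L, 101L), c(70L, 69L), c(30L, 31L))
  out <- merge_consecutive_snvs(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$ref, "CT")
  expect_equal(out$alt, "TG")
  # counts are the run means rounded half-up
  expect_equal(out$ref_count, 70L)
  expect_equal(out$alt_count, 31L)
  expect_equal(variant_class(out$ref, out$alt), "DBS")
})

test_that("discordant counts leave consecutive SBSs unmerged", {
  # VAFs 0.10 vs 0.91: every criterion fails
  rec <- merge_input(c(100L, 101L), c(90L, 20L), c(10L, 200L))
  out <- merge_consecutive_snvs(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$pos, c(100L, 101L))
})

test_that("merging respects run boundaries: chromosome, sample, adjacency", {
  single <- merge_input(100L, 70L, 30L)
  expect_equal(merge_consecutive_snvs(single), single)

  gap <- merge_input(c(100L, 102L), c(70L, 70L), c(30L, 30L))
  expect_equal(nrow(merge_consecutive_snvs(gap)), 2L)

  cross_chrom <- rbind(merge_input(100L, 70L, 30L),
                       merge_input(101L, 70L, 30L, chrom = "chr2"))
  expect_equal(nrow(merge_consecutive_snvs(cross_chrom)), 2L)

  cross_sample <- rbind(merge_input(100L, 70L, 30L),
                        merge_input(101L, 70L, 30L, sample = "s2"))
  expect_equal(nrow(merge_consecutive_snvs(cross_sample)), 2L)
})

test_that("runs of three or more merge in a single pass", {
  rec <- merge_input(c(50L, 51L, 52L), c(60L, 61L, 59L), c(40L, 39L, 41L))
  out <- merge_consecutive_snvs(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(nchar(out$ref), 3L)
  # merged evidence stays within the range of its constituents
  expect_gte(out$alt_count, 39L)
  expect_lte(out$alt_count, 41L)
})

test_that("merge is idempotent over many random records", {
  rec <- random_sbs_records(1000, seed = 7)
  once <- merge_consecutive_snvs(rec)
  twice <- merge_consecutive_snvs(once)
  expect_equal(once, twice)
  expect_lte(nrow(once), nrow(rec))
})
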