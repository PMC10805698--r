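toy_genome <- function() {
  g <- Biostrings::DNAStringSet("AAAAAAAAAACGGGGGGGGGG")
  names(g) <- "toy"
  g
}

test_that("sequence concept reads flanks and alleles off the genome", {
  cc <- sequence_concept("toy", 11L, "C", "T", toy_genome(), W = 6L)
  expect_equal(cc$fwd$five_prime, rep("A", 6))
  expect_equal(cc$fwd$three_prime, rep("G", 6))
  expect_equal(cc$fwd$ref_seq, c("C", rep("PAD", 5)))
  expect_equal(cc$fwd$alt_seq, c("T", rep("PAD", 5)))
  # reverse-complement orientation: roles swapped, bases complemented
  expect_equal(cc$rev$five_prime, rep("C", 6))
  expect_equal(cc$rev$three_prime, rep("T", 6))
  expect_equal(cc$rev$ref_seq, c("G", rep("PAD", 5)))
  expect_equal(cc$rev$alt_seq, c("A", rep("PAD", 5)))
})

test_that("insertions give an all-PAD ref and contig edges pad the flanks", {
  cc <- sequence_concept("toy", 11L, "-", "AT", toy_genome(), W = 6L)
  expect_true(all(cc$fwd$ref_seq == "PAD"))
  expect_equal(cc$fwd$alt_seq, c("A", "T", rep("PAD", 4)))

  edge <- sequence_concept("toy", 2L, "A", "G", toy_genome(), W = 6L)
  # only one base exists 5' of position 2; distal side is padded
  expect_equal(edge$fwd$five_prime, c(rep("PAD", 5), "A"))
})

test_that("reverse-complement transform is an involution", {
  set.seed(3)
  g <- Biostrings::DNAStringSet(paste(sample(c("A", "C", "G", "T"), 200,
                                             replace = TRUE),
                                      collapse = ""))
  names(g) <- "r"
  for (i in 1:20) {
    pos <- sample(20:180, 1)
    ref <- as.character(Biostrings::subseq(g[[1]], pos, pos))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    cc <- sequence_concept("r", pos, ref, alt, g, W = 5L)
    rc <- mutmil:::revcomp_chars
    expect_equal(cc$rev$five_prime, rc(cc$fwd$three_prime))
    expect_equal(cc$rev$three_prime, rc(cc$fwd$five_prime))
    # applying the transform to the reverse view returns the forward view
    expect_equal(rc(cc$rev$three_prime), cc$fwd$five_prime)
  }
})

test_that("encoded concepts have one-hot blocks and component slices align", {
  cc <- sequence_concept("toy", 11L, "C", "T", toy_genome(), W = 6L)
  x <- encode_sequence_concepts(list(cc))
  expect_equal(ncol(x), 2 * 4 * 6 * 4)
  sl <- sequence_component_slices(6)
  expect_equal(length(sl), 8L)
  # 5' flank block of the forward orientation: six A's, one-hot
  blk <- matrix(x[1, sl[["fwd five_prime"]]], ncol = 4, byrow = TRUE)
  expect_equal(blk, matrix(rep(c(1, 0, 0, 0), 6), ncol = 4, byrow = TRUE))
  # PAD rows encode as all-zero
  alt_blk <- matrix(x[1, sl[["fwd alt_seq"]]], ncol = 4, byrow = TRUE)
  expect_equal(rowSums(alt_blk), c(1, 0, 0, 0, 0, 0))
})

test_that("the 96 pyrimidine contexts enumerate to distinct indices", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(five = bases, ref = c("C", "T"), alt = bases,
                      three = bases, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  idx <- sbs96_from_context(grid$five, grid$ref, grid$alt, grid$three)
  expect_equal(sort(unique(idx)), 0:95)
  expect_equal(length(idx), 96L)
  expect_equal(length(sbs96_labels()), 96L)
})

test_that("purine-centred contexts map to their reverse complement's index", {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  grid <- expand.grid(five = bases, ref = c("A", "G"), alt = bases,
                      three = bases, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  fwd <- sbs96_from_context(grid$five, grid$ref, grid$alt, grid$three)
  rc <- sbs96_from_context(comp[grid$three], comp[grid$ref],
                           comp[grid$alt], comp[grid$five])
  expect_equal(fwd, rc)
  expect_true(all(fwd %in% 0:95))
})

test_that("non-SBS and ambiguous contexts fall into the 97th outgroup", {
  rec <- data.frame(
    chrom = c("toy", "toy", "toy"),
    pos = c(11L, 11L, 1L),
    ref = c("TTG", "C", "A"),      # deletion, SBS, contig-edge SBS
    alt = c("-", "T", "G"),
    stringsAsFactors = FALSE
  )
  idx <- sbs96_index(rec, toy_genome())
  expect_equal(idx[1], 96L)
  expect_equal(idx[3], 96L)        # no 5' base: outgroup, nothing discarded
  expect_equal(idx[2], sbs96_from_context("A", "C", "T", "G"))
  expect_equal(ncol(encode_sbs96(idx)), 97L)
})

test_that("position bins follow concatenated-genome arithmetic", {
  lens <- c(chrA = 1.5e6, chrB = 0.7e6)
  expect_equal(position_bin("chrA", 1L, lens), 0L)
  expect_equal(position_bin("chrA", 1000001L, lens), 1L)
  # last base of the 2.2 Mb concatenated genome lands in bin 2 of 3
  expect_equal(position_bin("chrB", 700000L, lens), 2L)
  expect_equal(n_position_bins(lens), 3L)
  expect_error(position_bin("chrC", 5L, lens), "chrC")

  # monotone in the concatenated coordinate
  pos <- c(1, 5e5, 1.4e6, 1.5e6)
  bins <- c(position_bin(rep("chrA", 4), pos, lens),
            position_bin(rep("chrB", 2), c(1, 7e5), lens))
  expect_true(all(diff(bins) >= 0))
})

test_that("gene vocabulary is order-independent with an OTHER catch-all", {
  genes <- c("TP53", "KRAS", "BRAF", "TP53")
  v1 <- gene_vocabulary(genes)
  v2 <- gene_vocabulary(sample(genes))
  expect_equal(v1, v2)
  expect_equal(v1[length(v1)], "OTHER")
  expect_equal(gene_index("KRAS", v1), match("KRAS", v1))
  expect_equal(gene_index("NOVEL", v1), length(v1))
})

test_that("reading frame is strand plus cds position modulo 3", {
  rec <- data.frame(strand = c("+", NA, "-"),
                    cds_pos = c(10L, NA, 3L), stringsAsFactors = FALSE)
  fr <- reading_frame(rec)
  expect_equal(fr$frame, c(1L, NA, 0L))
  expect_equal(fr$is_coding, c(TRUE, FALSE, TRUE))
  enc <- encode_reading_frame(fr)
  expect_equal(enc[2, ], stats::setNames(rep(0, 5), colnames(enc)))
  expect_equal(unname(enc[1, ]), c(1, 0, 0, 1, 0))
  expect_equal(unname(enc[3, ]), c(0, 1, 1, 0, 0))
})
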