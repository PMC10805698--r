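test_that("generators are pure functions of the task spec", {
  spec <- task_spec("presence", n_bags = 30, bag_size = c(5L, 15L),
                    witness_rate = 0.2, seed = 9)
  t1 <- gen_presence_task(spec)
  t2 <- gen_presence_task(spec)
  expect_identical(t1$bags$x, t2$bags$x)
  expect_identical(t1$bags$labels, t2$bags$labels)
  expect_identical(t1$instance_key, t2$instance_key)
})

test_that("presence bags plant key instances only in positives", {
  spec <- task_spec("presence", n_bags = 120, bag_size = c(10L, 30L),
                    witness_rate = 0.1, seed = 2)
  task <- gen_presence_task(spec)
  has_key <- as.vector(tapply(task$bags$x[, 1] == 1, task$bags$bag, any))
  expect_equal(has_key, unname(task$bags$labels == "pos"))
  # the key flag marks exactly the code-1 instances
  expect_equal(task$instance_key, task$bags$x[, 1] == 1)
  # label base rate near one half
  expect_gt(mean(task$bags$labels == "pos"), 0.35)
  expect_lt(mean(task$bags$labels == "pos"), 0.65)
})

test_that("an infeasible witness rate warns and degenerate bags are labelled", {
  expect_warning(task_spec("presence", bag_size = c(5L, 10L),
                           witness_rate = 0.05, seed = 1),
                 "at least one key")
  spec <- task_spec("presence", n_bags = 40, bag_size = c(1L, 1L),
                    witness_rate = 1, seed = 3)
  task <- gen_presence_task(spec)
  # bag of one instance at witness 1: the label is the instance identity
  expect_equal(unname(task$bags$x[, 1] == 1),
               unname(task$bags$labels == "pos"))
})

test_that("count labels are reproduced exactly by a brute-force recount", {
  spec <- task_spec("count", n_bags = 150, bag_size = c(20L, 100L),
                    threshold = 8L, seed = 5)
  task <- gen_count_task(spec)
  counts <- as.vector(tapply(task$bags$x[, 1], task$bags$bag, sum))
  expect_equal(counts > spec$threshold,
               unname(task$bags$labels == "pos"))
  expect_equal(task$instance_key, task$bags$x[, 1] == 1)
})

test_that("context bags are positive only when key and marker co-occur", {
  spec <- task_spec("context", n_bags = 150, bag_size = c(10L, 30L),
                    witness_rate = 0.15, seed = 6)
  task <- gen_context_task(spec)
  both <- vapply(seq_len(task$bags$n_bags), function(b) {
    ix <- which(task$bags$bag == b)
    any(task$bags$x[ix, 1] == 1) && any(task$bags$x[ix, 2] == 1)
  }, logical(1))
  expect_equal(both, unname(task$bags$labels == "pos"))
})

test_that("repeat-indel key instances carry a homopolymer-spanning deletion", {
  spec <- task_spec("repeat_indel", n_bags = 60, bag_size = c(5L, 15L),
                    witness_rate = 0.25, W = 20L, seed = 4)
  task <- gen_repeat_indel_task(spec)
  # independent oracle: single-base deletion whose window holds a run >= 5
  oracle <- vapply(task$concepts, function(cc) {
    is_del <- all(cc$fwd$alt_seq == "PAD") &&
      sum(cc$fwd$ref_seq != "PAD") == 1L
    if (!is_del) return(FALSE)
    win <- c(cc$fwd$five_prime, cc$fwd$ref_seq[1], cc$fwd$three_prime)
    any(rle(win)$lengths >= 5)
  }, logical(1))
  expect_equal(oracle, task$instance_key)
  neg_bags <- which(task$bags$labels == "neg")
  expect_false(any(task$instance_key[task$bags$bag %in% neg_bags]))
})

test_that("the consequence oracle agrees with hand-worked labels", {
  hg <- hand_orf_genome()
  rec <- data.frame(
    chrom = "toy",
    pos = c(2L, 11L, 12L, 12L, 9L, 9L, 10L, 10L, 31L, 32L),
    ref = c("T", "T", "G", "G", "G", "GCT", "-", "-", "A", "A"),
    alt = c("A", "A", "C", "T", "-", "-", "AA", "AAA", "T", "G"),
    stringsAsFactors = FALSE
  )
  expected <- c(
    "noncoding",       # pos 2: intergenic
    "silent",          # GCT -> GCA, both Ala
    "missense",        # GAA -> CAA, Glu -> Gln
    "nonsense",        # GAA -> TAA, stop gained
    "frameshift_del",  # 1-bp deletion in CDS
    "inframe_del",     # 3-bp deletion entirely within the ORF
    "frameshift_ins",  # 2-bp insertion in CDS
    "inframe_ins",     # 3-bp insertion in CDS
    "missense",        # minus strand: TGC -> AGC, Cys -> Ser
    "silent"           # minus strand: TTT -> TTC, both Phe
  )
  orc <- consequence_oracle(rec, hg$genome, hg$annotation)
  expect_equal(as.character(orc$label), expected)
  # strand and cds positions for the two minus-strand variants
  expect_equal(orc$cds$strand[9:10], c("-", "-"))
  expect_equal(orc$cds$cds_pos[9:10], c(7L, 6L))
})

test_that("the consequence generator yields balanced oracle-relabelled data", {
  spec <- task_spec("consequence", n_per_class = 40L, seed = 12)
  task <- gen_consequence_task(spec)
  expect_true(all(table(task$labels) == 40L))
  # relabelling every record from scratch reproduces the stored labels
  orc <- consequence_oracle(task$records, task$genome, task$annotation)
  expect_equal(orc$label, task$labels)
  fr <- reading_frame(task$records)
  expect_equal(fr$is_coding, task$labels != "noncoding")
})

test_that("the MAF-emitting presence task round-trips through the file path", {
  dir <- file.path(tempdir(), "maf_task")
  spec <- task_spec("presence", n_bags = 30, bag_size = c(5L, 10L),
                    witness_rate = 0.3, seed = 8)
  paths <- write_presence_maf_task(spec, dir)
  rec <- read_maf(paths$maf, dialect = maf_dialect("minimal"))
  genome <- read_genome(paths$genome)
  idx <- sbs96_index(rec, genome)
  lab <- data.table::fread(paths$labels, data.table = FALSE)
  key_idx <- sbs96_from_context("A", "C", "T", "G")
  has_key <- tapply(idx == key_idx, rec$sample_id, any)
  expect_equal(as.vector(has_key[lab$sample_id]),
               unname(lab$label == "pos"))
})
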