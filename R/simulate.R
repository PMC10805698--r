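# Synthetic-data generators: desk-scale MIL bag tasks with planted
# structure (presence / count / context / repeat-indel) and a toy
# coding-sequence consequence task for the sequence encoder. These are
# analogs of the simulation axes the attention-MIL design cares about —
# witness rate, aggregation choice, bag-size information, strand and
# reading-frame learnability — not replications of any particular dataset.
# Every generator is a pure function of its task_spec (deterministic given
# the seed).

#' Specification of a synthetic MIL task
#'
#' @param task One of `"presence"`, `"count"`, `"context"`,
#'   `"repeat_indel"`, `"consequence"`.
#' @param n_bags Number of bags to generate.
#' @param bag_size Length-2 integer vector: bag sizes drawn uniformly from
#'   `bag_size[1]:bag_size[2]`.
#' @param witness_rate Fraction of instances in a positive bag carrying the
#'   label-determining signal, in (0, 1].
#' @param n_codes Alphabet size for categorical-code tasks.
#' @param threshold Key-instance count threshold for the count task.
#' @param noise Label-flip probability (default 0).
#' @param W Flank width for sequence-concept tasks.
#' @param n_per_class Instances per class for the (instance-level)
#'   consequence task.
#' @param seed Integer seed; generation is deterministic given it.
#' @return A list of class `task_spec`.
#' @export
task_spec <- function(task = c("presence", "count", "context",
                               "repeat_indel", "consequence"),
                      n_bags = 200L, bag_size = c(50L, 100L),
                      witness_rate = 0.1, n_codes = 20L, threshold = 8L,
                      noise = 0, W = 20L, n_per_class = 600L, seed = 1L) {
  task <- match.arg(task)
  stopifnot(witness_rate > 0, witness_rate <= 1, all(bag_size >= 1L),
            noise >= 0, noise < 1)
  if (witness_rate * bag_size[1] < 1) {
    warning("witness_rate * min bag size < 1: positive bags are forced to ",
            "contain at least one key instance")
  }
  structure(
    list(task = task, n_bags = as.integer(n_bags),
         bag_size = as.integer(bag_size), witness_rate = witness_rate,
         n_codes = as.integer(n_codes), threshold = as.integer(threshold),
         noise = noise, W = as.integer(W),
         n_per_class = as.integer(n_per_class), seed = as.integer(seed)),
    class = "task_spec"
  )
}

random_dna <- function(n) sample(BASES, n, replace = TRUE)

flip_labels <- function(labels, noise) {
  if (noise <= 0) return(labels)
  flip <- stats::runif(length(labels)) < noise
  labels[flip] <- 1L - labels[flip]
  labels
}

# shared scaffolding for categorical-code bag tasks; fill_bag(size, positive)
# must return list(codes, key) with key a logical vector
code_task_bags <- function(spec, assign_label, fill_bag) {
  set.seed(spec$seed)
  sizes <- sample(spec$bag_size[1]:spec$bag_size[2], spec$n_bags,
                  replace = TRUE)
  mats <- vector("list", spec$n_bags)
  key <- vector("list", spec$n_bags)
  labels <- integer(spec$n_bags)
  for (b in seq_len(spec$n_bags)) {
    bb <- fill_bag(sizes[b])
    labels[b] <- bb$label
    key[[b]] <- bb$key
    mats[[b]] <- encode_onehot(bb$codes, spec$n_codes)
  }
  labels <- flip_labels(labels, spec$noise)
  bags <- bags_from_list(
    mats, labels = factor(labels, levels = c(0L, 1L),
                          labels = c("neg", "pos"))
  )
  list(bags = bags, instance_key = unlist(key), spec = spec)
}

#' Presence task: positive bags contain key instances at the witness rate
#'
#' Instances are categorical codes (one-hot). Code 1 is the key motif;
#' background instances are uniform over the remaining codes. Positive bags
#' plant key instances at the witness rate (at least one); negative bags
#' contain none.
#'
#' @param spec A [task_spec()] with `task = "presence"`.
#' @return List with `bags` (a labelled [mil_bags]), `instance_key`
#'   (logical per instance row) and `spec`.
#' @export
gen_presence_task <- function(spec) {
  stopifnot(spec$task == "presence")
  code_task_bags(spec, NULL, function(size) {
    positive <- stats::rbinom(1L, 1L, 0.5)
    codes <- sample(2:spec$n_codes, size, replace = TRUE)
    key <- rep(FALSE, size)
    if (positive == 1L) {
      key <- stats::runif(size) < spec$witness_rate
      if (!any(key)) key[sample.int(size, 1L)] <- TRUE
      codes[key] <- 1L
    }
    list(codes = codes, key = key, label = positive)
  })
}

#' Count task: the label depends on the absolute number of key instances
#'
#' The bag is positive iff the COUNT of key instances exceeds the
#' threshold. Key counts are drawn independently of bag size (uniform on
#' `0:(2 * threshold)`, capped by the bag size), so the key FRACTION is
#' uninformative and only an aggregation that preserves totals (a weighted
#' sum) can recover the label.
#'
#' @param spec A [task_spec()] with `task = "count"`.
#' @return As [gen_presence_task()].
#' @export
gen_count_task <- function(spec) {
  stopifnot(spec$task == "count")
  code_task_bags(spec, NULL, function(size) {
    k <- min(sample(0:(2L * spec$threshold), 1L), size)
    codes <- sample(2:spec$n_codes, size, replace = TRUE)
    key <- rep(FALSE, size)
    if (k > 0L) key[sample.int(size, k)] <- TRUE
    codes[key] <- 1L
    list(codes = codes, key = key, label = as.integer(k > spec$threshold))
  })
}

#' Context task: a key instance counts only when a marker instance co-occurs
#'
#' Code 1 (key) and code 2 (marker) are each planted independently with
#' probability 0.5 per bag (at the witness rate when present); the label is
#' positive iff BOTH occur. Static per-instance attention cannot express
#' the conjunction at the attention level; dynamic (two-round) attention
#' can.
#'
#' @param spec A [task_spec()] with `task = "context"`.
#' @return As [gen_presence_task()]; `instance_key` flags key and marker
#'   instances.
#' @export
gen_context_task <- function(spec) {
  stopifnot(spec$task == "context")
  code_task_bags(spec, NULL, function(size) {
    has_key <- stats::rbinom(1L, 1L, 0.5) == 1L
    has_marker <- stats::rbinom(1L, 1L, 0.5) == 1L
    codes <- sample(3:spec$n_codes, size, replace = TRUE)
    key <- rep(FALSE, size)
    plant <- function(codes, code, taken) {
      free <- which(!taken)
      if (!length(free)) free <- seq_along(codes)
      sel <- free[stats::runif(length(free)) < spec$witness_rate]
      if (!length(sel)) sel <- free[sample.int(length(free), 1L)]
      codes[sel] <- code
      out <- rep(FALSE, length(codes))
      out[sel] <- TRUE
      list(codes = codes, sel = out)
    }
    if (has_key) {
      p <- plant(codes, 1L, key)
      codes <- p$codes
      key <- key | p$sel
    }
    if (has_marker) {
      p <- plant(codes, 2L, key)
      codes <- p$codes
      key <- key | p$sel
    }
    list(codes = codes, key = key,
         label = as.integer(has_key && has_marker))
  })
}

# build a sequence_concept directly from local window parts
concept_from_parts <- function(five, ref_chars, alt_chars, three, W) {
  fwd <- list(
    five_prime = pad_to(five, W, side = "left"),
    ref_seq = pad_to(ref_chars, W),
    alt_seq = pad_to(alt_chars, W),
    three_prime = pad_to(three, W)
  )
  rev <- list(
    five_prime = revcomp_chars(pad_to(three, W)),
    ref_seq = pad_to(revcomp_chars(ref_chars), W),
    alt_seq = pad_to(revcomp_chars(alt_chars), W),
    three_prime = revcomp_chars(pad_to(five, W, side = "left"))
  )
  structure(list(fwd = fwd, rev = rev, W = W), class = "sequence_concept")
}

has_long_run <- function(x, min_len = 5L) {
  r <- rle(x)
  any(r$lengths >= min_len)
}

# one key instance: 1-bp deletion inside a planted mononucleotide run
repeat_del_instance <- function(W) {
  base <- sample(BASES, 1L)
  run_len <- sample(5:15, 1L)
  del_at <- sample.int(run_len, 1L)  # which copy of the run is deleted
  left_run <- rep(base, del_at - 1L)
  right_run <- rep(base, run_len - del_at)
  five <- c(random_dna(W), left_run)
  five <- five[(length(five) - W + 1L):length(five)]
  three <- c(right_run, random_dna(W))[1:W]
  concept_from_parts(five, base, character(0), three, W)
}

# background: SBS or a 1-3 bp deletion away from any >=5 homopolymer
background_instance <- function(W) {
  repeat {
    if (stats::runif(1) < 0.7) {
      five <- random_dna(W)
      three <- random_dna(W)
      ref <- sample(BASES, 1L)
      alt <- sample(setdiff(BASES, ref), 1L)
      cc <- concept_from_parts(five, ref, alt, three, W)
    } else {
      five <- random_dna(W)
      three <- random_dna(W)
      del <- random_dna(sample(1:3, 1L))
      cc <- concept_from_parts(five, del, character(0), three, W)
    }
    win <- c(cc$fwd$five_prime, cc$fwd$ref_seq[cc$fwd$ref_seq != "PAD"],
             cc$fwd$three_prime)
    if (!has_long_run(win)) return(cc)
  }
}

#' Repeat-indel task: positives are enriched for deletions at homopolymers
#'
#' The microsatellite-instability analog. Positive bags plant, at the
#' witness rate, 1-bp deletions inside mononucleotide runs of length 5-15
#' embedded in W-nt sequence concepts; negative bags (and the background of
#' positive bags) contain SBSs and short non-repeat deletions. Per-instance
#' key flags are retained for attention-separation checks.
#'
#' @param spec A [task_spec()] with `task = "repeat_indel"`.
#' @return List with `bags`, `instance_key`, `concepts` (the
#'   `sequence_concept` list, row-aligned with `bags$x`) and `spec`.
#' @export
gen_repeat_indel_task <- function(spec) {
  stopifnot(spec$task == "repeat_indel")
  set.seed(spec$seed)
  sizes <- sample(spec$bag_size[1]:spec$bag_size[2], spec$n_bags,
                  replace = TRUE)
  labels <- stats::rbinom(spec$n_bags, 1L, 0.5)
  concepts <- list()
  key <- logical(0)
  bag_idx <- integer(0)
  for (b in seq_len(spec$n_bags)) {
    kflag <- rep(FALSE, sizes[b])
    if (labels[b] == 1L) {
      kflag <- stats::runif(sizes[b]) < spec$witness_rate
      if (!any(kflag)) kflag[sample.int(sizes[b], 1L)] <- TRUE
    }
    cc <- lapply(kflag, function(k) {
      if (k) repeat_del_instance(spec$W) else background_instance(spec$W)
    })
    concepts <- c(concepts, cc)
    key <- c(key, kflag)
    bag_idx <- c(bag_idx, rep(b, sizes[b]))
  }
  labels <- flip_labels(labels, spec$noise)
  x <- encode_sequence_concepts(concepts)
  bags <- mil_bags(x, bag_idx,
                   labels = factor(labels, levels = c(0L, 1L),
                                   labels = c("neg", "pos")),
                   n_bags = spec$n_bags)
  list(bags = bags, instance_key = key, concepts = concepts, spec = spec)
}

# ---------------------------------------------------------------------------
# consequence task: toy genome of random ORFs on both strands

CONSEQUENCE_CLASSES <- c("frameshift_del", "frameshift_ins", "inframe_del",
                         "inframe_ins", "missense", "nonsense", "silent",
                         "noncoding")

# random ORF genome: alternating-strand single-exon ORFs with intergenic gaps
# CDS excludes the stop codon
make_orf_genome <- function(n_orfs = 40L, orf_codons = c(30L, 60L),
                            gap = c(10L, 30L)) {
  codons <- names(Biostrings::GENETIC_CODE)
  stops <- codons[Biostrings::GENETIC_CODE == "*"]
  sense <- setdiff(codons, stops)
  seqs <- character(0)
  ann <- data.frame(gene = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    coding = character(0), stringsAsFactors = FALSE)
  offset <- 0L
  for (i in seq_len(n_orfs)) {
    g <- paste(random_dna(sample(gap[1]:gap[2], 1L)), collapse = "")
    nc <- sample(orf_codons[1]:orf_codons[2], 1L)
    body <- c("ATG", sample(sense, nc, replace = TRUE))
    coding <- paste(body, collapse = "")
    with_stop <- paste0(coding, sample(stops, 1L))
    strand <- if (i %% 2L == 0L) "-" else "+"
    genomic <- if (strand == "+") with_stop else {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(with_stop)))
    }
    offset <- offset + nchar(g)
    cds_len <- nchar(coding)
    # genomic coordinates of the CDS (stop codon excluded)
    if (strand == "+") {
      s <- offset + 1L
      e <- offset + cds_len
    } else {
      s <- offset + 4L            # skip the (revcomp'd) stop codon
      e <- offset + 3L + cds_len
    }
    ann <- rbind(ann, data.frame(
      gene = sprintf("ORF%03d", i), start = s, end = e, strand = strand,
      coding = coding, stringsAsFactors = FALSE
    ))
    seqs <- c(seqs, g, genomic)
    offset <- offset + nchar(genomic)
  }
  tail_gap <- paste(random_dna(30L), collapse = "")
  contig <- paste(c(seqs, tail_gap), collapse = "")
  genome <- Biostrings::DNAStringSet(contig)
  names(genome) <- "toy1"
  ann$chrom <- "toy1"
  list(genome = genome, annotation = ann)
}

#' Consequence oracle: label variants by their coding effect
#'
#' Brute-force labelling of variants against a single-exon ORF annotation
#' using the standard genetic code: deletions and insertions anchored in a
#' CDS are frameshift or in-frame by length modulo 3; SBSs in a CDS are
#' silent / missense / nonsense by translating the affected codon (strand
#' aware); everything else is noncoding.
#'
#' @param records Variant record data.frame.
#' @param genome A `DNAStringSet`.
#' @param annotation ORF table from the generator: `gene`, `chrom`,
#'   `start`, `end`, `strand`, `coding` (CDS sequence, stop codon
#'   excluded).
#' @return List with `label` (factor over the eight consequence classes)
#'   and `cds` (data frame of `gene`, `strand`, `cds_pos`; NA when
#'   noncoding).
#' @export
consequence_oracle <- function(records, genome, annotation) {
  code <- Biostrings::GENETIC_CODE
  n <- nrow(records)
  label <- rep("noncoding", n)
  gene <- rep(NA_character_, n)
  strand <- rep(NA_character_, n)
  cds_pos <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    pos <- records$pos[i]
    hit <- which(annotation$chrom == records$chrom[i] &
                   annotation$start <= pos & annotation$end >= pos)
    if (!length(hit)) next
    a <- annotation[hit[1L], ]
    gene[i] <- a$gene
    strand[i] <- a$strand
    ci <- if (a$strand == "+") pos - a$start + 1L else a$end - pos + 1L
    cds_pos[i] <- ci
    vc <- variant_class(records$ref[i], records$alt[i])
    if (vc == "insertion") {
      label[i] <- if (nchar(records$alt[i]) %% 3L == 0L) {
        "inframe_ins"
      } else {
        "frameshift_ins"
      }
    } else if (vc == "deletion") {
      label[i] <- if (nchar(records$ref[i]) %% 3L == 0L) {
        "inframe_del"
      } else {
        "frameshift_del"
      }
    } else if (vc == "SBS") {
      f <- (ci - 1L) %% 3L
      codon <- substr(a$coding, ci - f, ci - f + 2L)
      alt_coding <- if (a$strand == "+") records$alt[i] else
        COMPLEMENT[[records$alt[i]]]
      mutated <- codon
      substr(mutated, f + 1L, f + 1L) <- alt_coding
      aa0 <- code[[codon]]
      aa1 <- code[[mutated]]
      label[i] <- if (aa1 == aa0) {
        "silent"
      } else if (aa1 == "*") {
        "nonsense"
      } else {
        "missense"
      }
    } else {
      label[i] <- "noncoding"  # multi-base substitutions not generated
    }
  }
  list(
    label = factor(label, levels = CONSEQUENCE_CLASSES),
    cds = data.frame(gene = gene, strand = strand, cds_pos = cds_pos,
                     stringsAsFactors = FALSE)
  )
}

# draw a chunk of random variants on the toy genome
draw_random_variants <- function(genome, n) {
  chars <- genome_letters(genome)[[1L]]
  L <- length(chars)
  pos <- sample(seq(5L, L - 10L), n, replace = TRUE)
  type <- sample(c("SBS", "del", "ins"), n, replace = TRUE,
                 prob = c(0.5, 0.25, 0.25))
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    if (type[i] == "SBS") {
      ref[i] <- chars[pos[i]]
      alt[i] <- sample(setdiff(BASES, ref[i]), 1L)
    } else if (type[i] == "del") {
      len <- sample(1:3, 1L)
      ref[i] <- paste(chars[pos[i]:(pos[i] + len - 1L)], collapse = "")
      alt[i] <- "-"
    } else {
      ref[i] <- "-"
      alt[i] <- paste(random_dna(sample(1:3, 1L)), collapse = "")
    }
  }
  data.frame(chrom = names(genome_letters(genome))[1L] %||% "toy1",
             pos = pos, ref = ref, alt = alt,
             ref_count = 50L, alt_count = 50L, filter = "PASS",
             sample_id = "toy", gene = NA_character_,
             strand = NA_character_, cds_pos = NA_integer_,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Consequence task: toy ORF genome with class-balanced labelled variants
#'
#' Generates a toy genome of random single-exon ORFs on both strands,
#' samples SBS and short indel variants, labels each with
#' [consequence_oracle()], and keeps a class-balanced subset
#' (`n_per_class` per consequence class, rejection-sampled). This is a
#' per-instance supervised task (each variant its own bag of size 1 when
#' fed to the MIL model).
#'
#' @param spec A [task_spec()] with `task = "consequence"`.
#' @return List with `records` (variant table, gene/strand/cds_pos filled
#'   for coding variants), `labels` (factor), `genome`, `annotation` and
#'   `spec`.
#' @export
gen_consequence_task <- function(spec) {
  stopifnot(spec$task == "consequence")
  set.seed(spec$seed)
  tg <- make_orf_genome()
  quota <- spec$n_per_class
  buckets <- stats::setNames(
    vector("list", length(CONSEQUENCE_CLASSES)), CONSEQUENCE_CLASSES)
  got <- stats::setNames(integer(length(CONSEQUENCE_CLASSES)),
                         CONSEQUENCE_CLASSES)
  for (iter in seq_len(200L)) {
    rec <- draw_random_variants(tg$genome, 4000L)
    orc <- consequence_oracle(rec, tg$genome, tg$annotation)
    rec$gene <- orc$cds$gene
    rec$strand <- orc$cds$strand
    rec$cds_pos <- orc$cds$cds_pos
    rec$label <- as.character(orc$label)
    for (cl in CONSEQUENCE_CLASSES) {
      need <- quota - got[cl]
      if (need <= 0L) next
      sel <- which(rec$label == cl)[seq_len(min(need, sum(rec$label == cl)))]
      if (!length(sel)) next
      buckets[[cl]] <- rbind(buckets[[cl]], rec[sel, , drop = FALSE])
      got[cl] <- got[cl] + length(sel)
    }
    if (all(got >= quota)) break
  }
  out <- do.call(rbind, buckets)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  labels <- factor(out$label, levels = CONSEQUENCE_CLASSES)
  out$label <- NULL
  list(records = out, labels = labels, genome = tg$genome,
       annotation = tg$annotation, spec = spec)
}

#' Instance features for the consequence task
#'
#' Flattened two-orientation sequence concept plus (optionally) the
#' reading-frame feature.
#'
#' @param records Variant record table.
#' @param genome `DNAStringSet`.
#' @param W Flank width (default 6).
#' @param use_frame Include the reading-frame block; when `FALSE` the five
#'   frame columns are zero (same dimensionality, no information).
#' @return Numeric instance feature matrix.
#' @export
consequence_features <- function(records, genome, W = 6L, use_frame = TRUE) {
  x <- encode_sequence_concepts(extract_sequence_concepts(records, genome,
                                                          W = W))
  fr <- encode_reading_frame(reading_frame(records))
  if (!use_frame) fr[] <- 0
  cbind(x, fr)
}

# ---------------------------------------------------------------------------
# MAF-emitting presence task: exercises the full file path
# (read_maf -> sbs96 -> bags -> model) end-to-end

#' Write a presence task as MAF + FASTA + labels files
#'
#' Builds a random toy contig, plants a key trinucleotide substitution
#' (`A[C>T]G`) for key instances and any other SBS96 context for
#' background, and writes `genome.fa`, `variants.maf` (minimal dialect,
#' one sample per bag) and `labels.tsv` into `dir`. Reading these back
#' through [read_maf()], [sbs96_index()] and [bags_from_list()] exercises
#' the full real-data path on synthetic data.
#'
#' @param spec A [task_spec()] with `task = "presence"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_presence_maf_task <- function(spec, dir) {
  stopifnot(spec$task == "presence")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  contig <- random_dna(50000L)
  genome <- Biostrings::DNAStringSet(paste(contig, collapse = ""))
  names(genome) <- "toy1"

  inner <- contig[2:(length(contig) - 1L)]
  ctx5 <- contig[1:(length(contig) - 2L)]
  ctx3 <- contig[3:length(contig)]
  key_pos <- which(ctx5 == "A" & inner == "C" & ctx3 == "G") + 1L
  bg_pos <- setdiff(which(inner %in% BASES) + 1L, key_pos)

  sizes <- sample(spec$bag_size[1]:spec$bag_size[2], spec$n_bags,
                  replace = TRUE)
  labels <- stats::rbinom(spec$n_bags, 1L, 0.5)
  rows <- list()
  for (b in seq_len(spec$n_bags)) {
    kflag <- rep(FALSE, sizes[b])
    if (labels[b] == 1L) {
      kflag <- stats::runif(sizes[b]) < spec$witness_rate
      if (!any(kflag)) kflag[sample.int(sizes[b], 1L)] <- TRUE
    }
    pos <- integer(sizes[b])
    alt <- character(sizes[b])
    pos[kflag] <- sample(key_pos, sum(kflag), replace = TRUE)
    alt[kflag] <- "T"
    nbg <- sum(!kflag)
    if (nbg) {
      p <- sample(bg_pos, nbg, replace = TRUE)
      r <- contig[p]
      a <- vapply(r, function(x) sample(setdiff(BASES, x), 1L), character(1))
      # avoid accidentally producing the key context
      redo <- which(contig[p - 1L] == "A" & r == "C" & a == "T" &
                      contig[p + 1L] == "G")
      for (j in redo) a[j] <- "G"
      pos[!kflag] <- p
      alt[!kflag] <- a
    }
    rows[[b]] <- data.frame(
      chrom = "toy1", pos = pos, ref = contig[pos], alt = alt,
      ref_count = 60L, alt_count = 40L, filter = "PASS",
      sample_id = sprintf("S%04d", b), stringsAsFactors = FALSE
    )
  }
  maf <- do.call(rbind, rows)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    maf = file.path(dir, "variants.maf"),
    labels = file.path(dir, "labels.tsv")
  )
  Biostrings::writeXStringSet(genome, paths$genome)
  data.table::fwrite(maf, paths$maf, sep = "\t")
  data.table::fwrite(
    data.frame(sample_id = sprintf("S%04d", seq_len(spec$n_bags)),
               label = ifelse(labels == 1L, "pos", "neg")),
    paths$labels, sep = "\t"
  )
  invisible(paths)
}
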