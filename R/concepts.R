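# Genomic concepts: conversions from variant records to instance feature
# encodings — local sequence context (padded nucleotide arrays in both
# orientations), SBS96 trinucleotide category with a 97th outgroup, genomic
# position bin, gene identity and reading frame.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", PAD = "PAD", N = "N")

#' Read a reference genome from FASTA
#'
#' @param path FASTA path.
#' @return A `Biostrings::DNAStringSet` with names truncated to the first
#'   whitespace-delimited token.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# cache of per-contig character vectors for fast random access
genome_letters <- function(genome) {
  if (is.list(genome) && !is.null(attr(genome, "mutmil_letters"))) {
    return(genome)
  }
  out <- lapply(seq_along(genome), function(i) {
    strsplit(as.character(genome[[i]]), "")[[1]]
  })
  names(out) <- names(genome)
  attr(out, "mutmil_letters") <- TRUE
  out
}

pad_to <- function(x, W, side = c("right", "left")) {
  side <- match.arg(side)
  if (length(x) >= W) return(x[seq_len(W)])
  pad <- rep("PAD", W - length(x))
  if (side == "right") c(x, pad) else c(pad, x)
}

# bases at positions lo..hi of a contig, PAD outside the contig
slice_padded <- function(chars, lo, hi) {
  n <- length(chars)
  pos <- lo:hi
  out <- rep("PAD", length(pos))
  ok <- pos >= 1L & pos <= n
  out[ok] <- chars[pos[ok]]
  out
}

revcomp_chars <- function(x) {
  unname(rev(COMPLEMENT[x]))
}

#' Extract the local-sequence concept for one variant
#'
#' The concept holds four fixed-width arrays over \{A, C, G, T, PAD\} — the
#' W bases immediately 5' of the variant (genomic order, so the proximal
#' base is the last element and PAD fills the distal end near a contig
#' edge), the reference allele, the alternate allele (each right-padded to
#' W; a `"-"` allele is all PAD) and the W bases immediately 3' of the
#' reference span — in both the forward orientation and the
#' reverse-complement orientation (5'/3' roles swapped, sequences reversed
#' and complemented, alleles reverse-complemented and re-padded at the
#' tail). Insertions use the bases flanking the insertion point.
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles (1-based MAF
#'   convention, `"-"` for the absent allele).
#' @param genome A `DNAStringSet` (see [read_genome()]) or the cached
#'   letter list produced internally.
#' @param W Flank width (6 for classification-scale context, 20 for
#'   repeat-sensitive tasks).
#' @return A list of class `sequence_concept` with elements `fwd` and
#'   `rev`, each holding `five_prime`, `ref_seq`, `alt_seq`, `three_prime`
#'   (character vectors of length `W`), plus `W`.
#' @export
sequence_concept <- function(chrom, pos, ref, alt, genome, W = 6L) {
  chars <- genome_letters(genome)
  if (!chrom %in% names(chars)) stop("chromosome not in genome: ", chrom)
  ch <- chars[[chrom]]
  ins <- ref == "-"
  ref_len <- if (ins) 0L else nchar(ref)
  five_end <- if (ins) pos else pos - 1L
  three_start <- if (ins) pos + 1L else pos + ref_len

  five <- slice_padded(ch, five_end - W + 1L, five_end)
  three <- slice_padded(ch, three_start, three_start + W - 1L)
  ref_chars <- if (ins) character(0) else strsplit(ref, "")[[1]]
  alt_chars <- if (alt == "-") character(0) else strsplit(alt, "")[[1]]
  if (length(ref_chars) > W || length(alt_chars) > W) {
    warning("allele longer than flank width W=", W, "; truncated")
  }
  fwd <- list(
    five_prime = five,
    ref_seq = pad_to(ref_chars, W),
    alt_seq = pad_to(alt_chars, W),
    three_prime = three
  )
  rev <- list(
    five_prime = revcomp_chars(three),
    ref_seq = pad_to(revcomp_chars(ref_chars), W),
    alt_seq = pad_to(revcomp_chars(alt_chars), W),
    three_prime = revcomp_chars(five)
  )
  structure(list(fwd = fwd, rev = rev, W = W), class = "sequence_concept")
}

#' Extract sequence concepts for a table of variant records
#'
#' @param records Variant record data.frame (see [read_maf()]).
#' @param genome A `DNAStringSet`.
#' @param W Flank width.
#' @return List of `sequence_concept` objects, one per record.
#' @export
extract_sequence_concepts <- function(records, genome, W = 6L) {
  chars <- genome_letters(genome)
  lapply(seq_len(nrow(records)), function(i) {
    sequence_concept(records$chrom[i], records$pos[i], records$ref[i],
                     records$alt[i], chars, W = W)
  })
}

onehot_block <- function(x) {
  m <- matrix(0, length(x), 4L, dimnames = list(NULL, BASES))
  hit <- match(x, BASES)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  m
}

concept_vector <- function(concept, orientations) {
  parts <- list()
  for (o in orientations) {
    side <- concept[[o]]
    for (blk in c("five_prime", "ref_seq", "alt_seq", "three_prime")) {
      parts[[paste(o, blk)]] <- as.vector(t(onehot_block(side[[blk]])))
    }
  }
  unlist(parts, use.names = FALSE)
}

#' One-hot encode sequence concepts into an instance feature matrix
#'
#' Each of the four component arrays is one-hot encoded over \{A, C, G, T\}
#' with PAD (and N) as the all-zero row, flattened position-major, and
#' concatenated in the order 5' flank, ref, alt, 3' flank — for the forward
#' and then the reverse-complement orientation.
#'
#' @param concepts List of `sequence_concept` objects with a common `W`.
#' @param orientations `c("fwd", "rev")` (default both) or a single
#'   orientation.
#' @return Numeric matrix, one row per concept,
#'   `length(orientations) * 4 * W * 4` columns.
#' @export
encode_sequence_concepts <- function(concepts,
                                     orientations = c("fwd", "rev")) {
  stopifnot(length(concepts) >= 1L)
  t(vapply(concepts, concept_vector, orientations = orientations,
           numeric(length(orientations) * 4L * concepts[[1]]$W * 4L)))
}

#' Column slices of the encoded sequence components
#'
#' Returns the column index ranges of each component block produced by
#' [encode_sequence_concepts()], for use as independent kernel slices in
#' [mil_config()].
#'
#' @param W Flank width used at encoding time.
#' @param orientations As passed to [encode_sequence_concepts()].
#' @return Named list of integer vectors (one per component block).
#' @export
sequence_component_slices <- function(W, orientations = c("fwd", "rev")) {
  blk <- 4L * W
  nms <- as.vector(outer(c("five_prime", "ref_seq", "alt_seq",
                           "three_prime"), orientations,
                         function(b, o) paste(o, b)))
  out <- lapply(seq_along(nms), function(i) ((i - 1L) * blk + 1L):(i * blk))
  names(out) <- nms
  out
}

# ---------------------------------------------------------------------------
# SBS96

#' The 96 pyrimidine-centred substitution context labels
#'
#' Conventional mutational-signature ordering: substitution types C>A, C>G,
#' C>T, T>A, T>C, T>G in blocks of 16, flanking bases lexicographic
#' (A, C, G, T) with the 5' base outermost.
#'
#' @return Character vector of 96 labels like `"A[C>A]A"`.
#' @export
sbs96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(96)
  i <- 0L
  for (s in subs) for (f in BASES) for (t in BASES) {
    i <- i + 1L
    out[i] <- paste0(f, "[", s, "]", t)
  }
  out
}

SBS96_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' SBS96 index from an explicit trinucleotide context
#'
#' Maps a single-base substitution with its immediate 5' and 3' bases to
#' the 0-based index of its pyrimidine-centred category (0..95), reverse
#' complementing purine-reference substitutions first. Anything that is not
#' an unambiguous SBS context (non-ACGT base, `ref == alt`) maps to the
#' outgroup index 96.
#'
#' @param five,ref,alt,three Character vectors of single bases.
#' @return Integer vector with values in 0..96.
#' @export
sbs96_from_context <- function(five, ref, alt, three) {
  n <- length(ref)
  out <- rep(96L, n)
  ok <- five %in% BASES & ref %in% BASES & alt %in% BASES &
    three %in% BASES & ref != alt
  pur <- ok & ref %in% c("A", "G")
  f <- five; r <- ref; a <- alt; t3 <- three
  f[pur] <- COMPLEMENT[three[pur]]
  t3[pur] <- COMPLEMENT[five[pur]]
  r[pur] <- COMPLEMENT[ref[pur]]
  a[pur] <- COMPLEMENT[alt[pur]]
  sub_idx <- match(paste0(r, ">", a), SBS96_SUBS) - 1L
  idx <- sub_idx * 16L + (match(f, BASES) - 1L) * 4L + (match(t3, BASES) - 1L)
  out[ok] <- idx[ok]
  out
}

#' SBS96 index (with outgroup) for variant records
#'
#' Single-base substitutions map to their pyrimidine-centred trinucleotide
#' category in 0..95 (see [sbs96_labels()] for the ordering); everything
#' else — indels, multi-base substitutions, ambiguous context, contig-edge
#' variants — maps to the 97th outgroup category, index 96, so that no
#' variant is discarded.
#'
#' @param records Variant record data.frame.
#' @param genome A `DNAStringSet` providing the flanking bases.
#' @return Integer vector with values in 0..96.
#' @export
sbs96_index <- function(records, genome) {
  chars <- genome_letters(genome)
  n <- nrow(records)
  out <- rep(96L, n)
  is_sbs <- variant_class(records$ref, records$alt) == "SBS" &
    records$chrom %in% names(chars)
  for (i in which(is_sbs)) {
    ch <- chars[[records$chrom[i]]]
    p <- records$pos[i]
    if (p < 2L || p > length(ch) - 1L) next
    out[i] <- sbs96_from_context(ch[p - 1L], records$ref[i],
                                 records$alt[i], ch[p + 1L])
  }
  out
}

#' One-hot encode SBS96 indices (97 categories)
#'
#' @param idx Integer vector from [sbs96_index()] (values 0..96).
#' @return Numeric matrix `length(idx) x 97`.
#' @export
encode_sbs96 <- function(idx) {
  m <- matrix(0, length(idx), 97L,
              dimnames = list(NULL, c(sbs96_labels(), "outgroup")))
  m[cbind(seq_along(idx), idx + 1L)] <- 1
  m
}

# ---------------------------------------------------------------------------
# position bins, gene vocabulary, reading frame

#' Fixed-width genomic position bins over a concatenated genome
#'
#' Chromosomes are laid end to end in the order of `chrom_lengths`; the bin
#' of a variant is `floor((offset[chrom] + pos - 1) / bin_size)` (0-based).
#' The total number of bins is `ceiling(sum(lengths) / bin_size)`.
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param chrom_lengths Named integer vector of chromosome lengths in
#'   concatenation order.
#' @param bin_size Bin width in bases (1e6 for megabase bins).
#' @return Integer vector of 0-based bin indices.
#' @export
position_bin <- function(chrom, pos, chrom_lengths, bin_size = 1e6) {
  unknown <- setdiff(unique(chrom), names(chrom_lengths))
  if (length(unknown)) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  offsets <- c(0, cumsum(as.numeric(chrom_lengths)))[seq_along(chrom_lengths)]
  names(offsets) <- names(chrom_lengths)
  as.integer(floor((offsets[chrom] + pos - 1) / bin_size))
}

#' Total number of position bins for a genome
#'
#' @inheritParams position_bin
#' @return Integer bin count.
#' @export
n_position_bins <- function(chrom_lengths, bin_size = 1e6) {
  as.integer(ceiling(sum(as.numeric(chrom_lengths)) / bin_size))
}

#' Build a deterministic gene vocabulary
#'
#' Unique gene names sorted alphabetically, with a terminal `OTHER`
#' category for genes outside the vocabulary. Sorting makes the mapping
#' independent of input order, so a vocabulary built from a shuffled
#' training fold is identical.
#'
#' @param genes Character vector of gene names (NA ignored).
#' @return Character vector of vocabulary entries ending in `"OTHER"`.
#' @export
gene_vocabulary <- function(genes) {
  c(sort(unique(genes[!is.na(genes)]), method = "radix"), "OTHER")
}

#' Map gene names to vocabulary indices
#'
#' @param genes Character vector.
#' @param vocabulary From [gene_vocabulary()].
#' @return Integer vector of 1-based indices; absent or NA genes get the
#'   `OTHER` index (the last).
#' @export
gene_index <- function(genes, vocabulary) {
  idx <- match(genes, vocabulary)
  idx[is.na(idx)] <- length(vocabulary)
  idx
}

#' Reading-frame feature for variant records
#'
#' Strand plus coding-sequence position modulo 3; noncoding variants (no
#' CDS position) are represented by the all-zero vector.
#'
#' @param records Variant record data.frame with `strand` and `cds_pos`.
#' @return Data frame with `strand`, `frame` (`cds_pos %% 3`, NA when
#'   noncoding) and `is_coding`.
#' @export
reading_frame <- function(records) {
  is_coding <- !is.na(records$cds_pos)
  data.frame(
    strand = ifelse(is_coding, records$strand, NA_character_),
    frame = ifelse(is_coding, records$cds_pos %% 3L, NA_integer_),
    is_coding = is_coding,
    stringsAsFactors = FALSE
  )
}

#' One-hot encode the reading-frame feature
#'
#' Five columns: strand + / strand -, frame 0 / 1 / 2. Noncoding variants
#' are the zero vector.
#'
#' @param frame_df Output of [reading_frame()].
#' @return Numeric matrix `nrow(frame_df) x 5`.
#' @export
encode_reading_frame <- function(frame_df) {
  n <- nrow(frame_df)
  m <- matrix(0, n, 5L,
              dimnames = list(NULL, c("strand+", "strand-",
                                      "frame0", "frame1", "frame2")))
  cod <- which(frame_df$is_coding)
  m[cbind(cod, ifelse(frame_df$strand[cod] == "+", 1L, 2L))] <- 1
  m[cbind(cod, 3L + frame_df$frame[cod])] <- 1
  m
}

#' One-hot encode categorical indices
#'
#' @param idx Integer vector of 1-based category indices.
#' @param n_levels Number of categories.
#' @return Numeric matrix `length(idx) x n_levels`.
#' @export
encode_onehot <- function(idx, n_levels) {
  m <- matrix(0, length(idx), n_levels)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}
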