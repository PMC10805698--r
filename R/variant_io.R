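# Reading, filtering and normalizing somatic variant calls from MAF-style
# tab-delimited tables. Variant records are kept as a plain data.frame with
# canonical columns:
#   chrom, pos (1-based), ref, alt ("-" encodes the absent allele of an
#   insertion/deletion), ref_count, alt_count, filter (flag string),
#   sample_id, gene, strand, cds_pos
# A record's class (SBS / DBS / MNV / insertion / deletion) is derivable via
# variant_class().

#' Column-name dialects for MAF-style tables
#'
#' Maps canonical record fields to the column names used by a particular
#' MAF flavour. `"mc3"` covers the TCGA multi-centre calling column names;
#' `"minimal"` expects the canonical names themselves.
#'
#' @param name `"mc3"` or `"minimal"`.
#' @return Named character vector: canonical field -> column name.
#' @export
maf_dialect <- function(name = c("mc3", "minimal")) {
  name <- match.arg(name)
  switch(name,
    mc3 = c(
      chrom = "Chromosome", pos = "Start_Position",
      ref = "Reference_Allele", alt = "Tumor_Seq_Allele2",
      ref_count = "t_ref_count", alt_count = "t_alt_count",
      filter = "FILTER", sample_id = "Tumor_Sample_Barcode",
      gene = "Hugo_Symbol", strand = "STRAND", cds_pos = "CDS_position"
    ),
    minimal = c(
      chrom = "chrom", pos = "pos", ref = "ref", alt = "alt",
      ref_count = "ref_count", alt_count = "alt_count",
      filter = "filter", sample_id = "sample_id",
      gene = "gene", strand = "strand", cds_pos = "cds_pos"
    )
  )
}

#' Classify a variant by its alleles
#'
#' SBS when both alleles are single bases, DBS when both have length 2,
#' insertion when `ref == "-"`, deletion when `alt == "-"`, otherwise MNV.
#'
#' @param ref,alt Allele strings (`"-"` for the absent allele).
#' @return Character vector.
#' @export
variant_class <- function(ref, alt) {
  out <- rep("MNV", length(ref))
  out[ref == "-"] <- "insertion"
  out[alt == "-"] <- "deletion"
  sbs <- ref != "-" & alt != "-" & nchar(ref) == 1L & nchar(alt) == 1L
  out[sbs] <- "SBS"
  dbs <- ref != "-" & alt != "-" & nchar(ref) == 2L & nchar(alt) == 2L
  out[dbs] <- "DBS"
  out
}

#' Read somatic variant calls from a MAF-style table
#'
#' Tab-delimited with a header row. Required columns (via the dialect):
#' chrom, pos, ref, alt. Counts, FILTER, sample, gene, strand and CDS
#' position are optional and filled with `NA` when absent. Positions and
#' counts must parse as non-negative integers; offending rows raise an
#' error naming their line.
#'
#' @param path File path.
#' @param dialect Named character vector from [maf_dialect()] (or a custom
#'   map with the same names).
#' @param min_callers Optional integer: when the dialect maps a
#'   `n_callers` column, keep only rows called by at least this many
#'   mutation callers. Default `NULL` (off).
#' @return A data.frame of variant records (one row per retained call).
#' @export
read_maf <- function(path, dialect = maf_dialect("mc3"),
                     min_callers = NULL) {
  if (!file.exists(path)) stop("MAF not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  for (f in required) {
    if (!dialect[[f]] %in% names(dt)) {
      stop("MAF format error: required column '", dialect[[f]],
           "' (field ", f, ") missing from ", path)
    }
  }
  n <- nrow(dt)
  grab <- function(f, default = NA_character_) {
    col <- dialect[f]
    if (!is.na(col) && col %in% names(dt)) dt[[col]] else rep(default, n)
  }
  parse_int <- function(x, what, allow_na = FALSE) {
    out <- suppressWarnings(as.integer(x))
    bad <- is.na(out) & !(allow_na & (is.na(x) | x == "" | x == "."))
    if (any(bad)) {
      stop("MAF row error: unparseable ", what, " at line ",
           paste(which(bad)[seq_len(min(5L, sum(bad)))] + 1L,
                 collapse = ", "),
           if (sum(bad) > 5L) " ..." else "")
    }
    out
  }
  rec <- data.frame(
    chrom = grab("chrom"),
    pos = parse_int(grab("pos"), "position"),
    ref = toupper(grab("ref")),
    alt = toupper(grab("alt")),
    ref_count = parse_int(grab("ref_count"), "ref count", allow_na = TRUE),
    alt_count = parse_int(grab("alt_count"), "alt count", allow_na = TRUE),
    filter = grab("filter", default = "PASS"),
    sample_id = grab("sample_id", default = "sample"),
    gene = grab("gene"),
    strand = grab("strand"),
    cds_pos = suppressWarnings(as.integer(grab("cds_pos"))),
    stringsAsFactors = FALSE
  )
  bad <- which(rec$pos < 1L | rec$ref == rec$alt |
                 (rec$ref == "-" & rec$alt == "-"))
  if (length(bad)) {
    stop("MAF row error: invalid record (pos < 1, ref == alt, or both ",
         "alleles '-') at line ", paste(bad + 1L, collapse = ", "))
  }
  if (!is.null(min_callers)) {
    ncall_col <- dialect["n_callers"]
    if (is.na(ncall_col) || !ncall_col %in% names(dt)) {
      stop("min_callers requested but dialect maps no 'n_callers' column")
    }
    ncall <- parse_int(dt[[ncall_col]], "caller count")
    rec <- rec[ncall >= min_callers, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

split_flags <- function(filter) {
  strsplit(ifelse(is.na(filter) | filter == "", "PASS", filter), "[,;]")
}

#' Retain variants whose FILTER flags are all allowed
#'
#' A record is kept iff its set of FILTER flags (the FILTER string split on
#' `,` or `;`) is a subset of `allowed` — so combinations of allowed flags
#' are permitted.
#'
#' @param records Variant record data.frame from [read_maf()].
#' @param allowed Character vector of acceptable flag values.
#' @param verbose Log retained/dropped counts.
#' @return Filtered records.
#' @export
filter_by_flags <- function(records,
                            allowed = c("PASS", "wga", "native_wga_mix"),
                            verbose = FALSE) {
  flags <- split_flags(records$filter)
  keep <- vapply(flags, function(f) all(f %in% allowed), logical(1))
  if (verbose) {
    message("filter_by_flags: kept ", sum(keep), "/", length(keep))
  }
  records[keep, , drop = FALSE]
}

#' Keep variants whose reference span lies within coverage intervals
#'
#' Intervals are BED-style: 0-based half-open `[start, end)` with columns
#' `chrom`, `start`, `end`. A record is kept iff its full reference span
#' `[pos - 1, pos - 1 + max(nchar(ref), 1))` (insertions use their 1-bp
#' anchor) falls within the union of intervals on its chromosome. Records
#' on chromosomes absent from the interval set are dropped with a warning.
#'
#' @param records Variant record data.frame.
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. read from a 3-column BED via [read_bed()].
#' @param verbose Log retained/dropped counts.
#' @return Filtered records.
#' @export
intersect_intervals <- function(records, intervals, verbose = FALSE) {
  if (nrow(records) == 0L) return(records)
  if (nrow(intervals) == 0L) return(records[0L, , drop = FALSE])
  span_w <- pmax(ifelse(records$ref == "-", 1L, nchar(records$ref)), 1L)
  keep <- logical(nrow(records))
  unknown <- setdiff(unique(records$chrom), unique(intervals$chrom))
  if (length(unknown)) {
    warning("records on chromosomes without intervals dropped: ",
            paste(unknown, collapse = ", "))
  }
  for (chr in intersect(unique(records$chrom), unique(intervals$chrom))) {
    iv <- intervals[intervals$chrom == chr, , drop = FALSE]
    # BED [start, end) 0-based -> 1-based closed
    cov <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L,
                                            end = iv$end))
    ix <- which(records$chrom == chr)
    q <- IRanges::IRanges(start = records$pos[ix],
                          end = records$pos[ix] + span_w[ix] - 1L)
    keep[ix] <- IRanges::countOverlaps(q, cov, type = "within") > 0L
  }
  if (verbose) {
    message("intersect_intervals: kept ", sum(keep), "/", length(keep))
  }
  records[keep, , drop = FALSE]
}

#' Read a 3-column BED file of intervals
#'
#' @param path BED path (tab-delimited, no header, 0-based half-open).
#' @return Data frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE)
  if (ncol(dt) < 3L) stop("BED needs at least 3 columns: ", path)
  data.frame(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
             end = as.integer(dt[[3]]), stringsAsFactors = FALSE)
}

round_half_up <- function(x) floor(x + 0.5)

# decide whether a run of consecutive SBS calls looks like one mutational
# event: read-count evidence must agree by any of the three tolerances
run_qualifies <- function(refc, altc, count_tol, pct_tol, vaf_tol) {
  if (any(is.na(refc)) || any(is.na(altc))) return(FALSE)
  dev_ref <- abs(refc - mean(refc))
  dev_alt <- abs(altc - mean(altc))
  crit_count <- max(dev_ref, dev_alt) < count_tol
  pct <- function(dev, m) if (m == 0) ifelse(dev == 0, 0, Inf) else dev / m
  crit_pct <- max(pct(max(dev_ref), mean(refc)),
                  pct(max(dev_alt), mean(altc))) < pct_tol
  tot <- refc + altc
  crit_vaf <- if (any(tot == 0)) FALSE else {
    vaf <- altc / tot
    (max(vaf) - min(vaf)) < vaf_tol
  }
  crit_count || crit_pct || crit_vaf
}

#' Merge runs of consecutive SBS calls into single multi-nucleotide variants
#'
#' Variant callers are inconsistent about whether a doublet or longer
#' substitution is reported as one call or a run of single-base calls.
#' Maximal runs of same-sample, same-chromosome SBSs at strictly
#' consecutive positions are merged into one record when the read counts
#' agree by ANY of three criteria over the run: the maximum deviation of
#' any alternative or reference count from its run mean is below
#' `count_tol` reads; or that maximum deviation is below `pct_tol` as a
#' fraction of the mean; or the maximum pairwise difference in variant
#' allele fraction is below `vaf_tol`. The merged record concatenates
#' ref/alt alleles and takes count means rounded half-up. Non-qualifying
#' runs are left untouched. Idempotent: merged records are no longer SBSs,
#' so a second pass changes nothing.
#'
#' @param records Variant record data.frame.
#' @param count_tol Absolute read-count tolerance (default 5).
#' @param pct_tol Relative count tolerance (default 0.05).
#' @param vaf_tol Variant-allele-fraction tolerance (default 0.05).
#' @return Records with qualifying runs merged, ordered by sample,
#'   chromosome and position.
#' @export
merge_consecutive_snvs <- function(records, count_tol = 5, pct_tol = 0.05,
                                   vaf_tol = 0.05) {
  if (nrow(records) == 0L) return(records)
  is_sbs <- variant_class(records$ref, records$alt) == "SBS"
  ord <- order(records$sample_id, records$chrom, records$pos)
  rec <- records[ord, , drop = FALSE]
  sbs <- which(is_sbs[ord])
  drop <- logical(nrow(rec))
  merged <- list()
  if (length(sbs) >= 2L) {
    consec <- c(FALSE,
                rec$sample_id[sbs[-1]] == rec$sample_id[sbs[-length(sbs)]] &
                rec$chrom[sbs[-1]] == rec$chrom[sbs[-length(sbs)]] &
                rec$pos[sbs[-1]] == rec$pos[sbs[-length(sbs)]] + 1L)
    run_id <- cumsum(!consec)
    for (ix in split(sbs, run_id)) {
      if (length(ix) < 2L) next
      if (!run_qualifies(rec$ref_count[ix], rec$alt_count[ix],
                         count_tol, pct_tol, vaf_tol)) next
      m <- rec[ix[1L], , drop = FALSE]
      m$ref <- paste(rec$ref[ix], collapse = "")
      m$alt <- paste(rec$alt[ix], collapse = "")
      m$ref_count <- as.integer(round_half_up(mean(rec$ref_count[ix])))
      m$alt_count <- as.integer(round_half_up(mean(rec$alt_count[ix])))
      m$filter <- paste(unique(unlist(split_flags(rec$filter[ix]))),
                        collapse = ",")
      drop[ix] <- TRUE
      merged[[length(merged) + 1L]] <- m
    }
  }
  out <- rbind(rec[!drop, , drop = FALSE], do.call(rbind, merged))
  out <- out[order(out$sample_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
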