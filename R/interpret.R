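# Post-hoc explainability: attention z-scores across heads and folds,
# instance clustering ordered by attention, position probability matrices
# (sequence logos) and per-position information content.

#' Attention z-scores averaged across heads and folds
#'
#' For a feature-by-head attention table (e.g. mean attention received by
#' each genomic bin or gene, per attention head), standardizes each head to
#' mean 0 / sd 1 across features, averages over heads, and then averages
#' over folds. Heads with zero variance contribute 0 with a warning. The
#' result is invariant under per-head affine rescaling of the raw
#' attention.
#'
#' @param folds A single numeric matrix (features x heads) or a list of
#'   such matrices, one per cross-validation fold, with identical rows.
#' @return Numeric vector of per-feature averaged z-scores.
#' @export
attention_zscores <- function(folds) {
  if (is.matrix(folds)) folds <- list(folds)
  stopifnot(length(folds) >= 1L)
  per_fold <- lapply(folds, function(tab) {
    tab <- as.matrix(tab)
    if (nrow(tab) < 2L) stop("need >= 2 features per head for z-scores")
    z <- apply(tab, 2L, function(a) {
      s <- stats::sd(a)
      if (s == 0) {
        warning("zero-variance attention head contributes 0")
        rep(0, length(a))
      } else {
        (a - mean(a)) / s
      }
    })
    rowMeans(as.matrix(z))
  })
  Reduce(`+`, per_fold) / length(per_fold)
}

#' Highest-attention instances of one head
#'
#' The `ceiling(frac * n)` instances with the largest attention in the
#' given head; ties are broken by stable input order.
#'
#' @param attn Numeric matrix of attention weights (instances x heads) from
#'   [attention_weights()].
#' @param head Head (column) index.
#' @param frac Fraction of instances to keep, in (0, 1].
#' @return Integer vector of instance (row) indices.
#' @export
top_attention <- function(attn, head = 1L, frac = 0.05) {
  stopifnot(frac > 0, frac <= 1)
  a <- attn[, head]
  n <- length(a)
  m <- ceiling(frac * n)
  order(-a)[seq_len(m)]
}

#' K-means instance clusters ordered by median attention
#'
#' Clusters instance feature vectors with `stats::kmeans` (features scaled
#' to unit variance by default) and relabels the clusters in descending
#' order of their median attention, so cluster 1 always has the highest
#' median attention. Deterministic given `seed`.
#'
#' @param features Numeric matrix, one row per instance.
#' @param attn Numeric vector of per-instance attention (one head).
#' @param k Number of clusters (<= number of instances).
#' @param scale_features Standardize columns to unit variance first.
#' @param seed Integer seed for the k-means starts.
#' @return Integer vector of cluster labels in `1..k`.
#' @export
cluster_instances <- function(features, attn, k = 6L, scale_features = TRUE,
                              seed = 1L) {
  features <- as.matrix(features)
  if (k > nrow(features)) stop("k exceeds the number of instances")
  if (k == nrow(features)) {
    # one instance per cluster: ordering by attention is the whole answer
    return(match(seq_len(k), order(-attn)))
  }
  if (scale_features) {
    sds <- apply(features, 2L, stats::sd)
    keep <- sds > 0
    features <- scale(features[, keep, drop = FALSE])
  }
  set.seed(seed)
  km <- stats::kmeans(features, centers = k, nstart = 5L, iter.max = 50L)
  med <- vapply(seq_len(k), function(cl) {
    stats::median(attn[km$cluster == cl])
  }, numeric(1))
  relabel <- match(seq_len(k), order(-med))
  relabel[km$cluster]
}

#' Position probability matrix for a set of sequence concepts
#'
#' Column-wise nucleotide frequencies over the concatenated
#' 5' flank | allele | 3' flank layout (the allele block sits between the
#' flanks; `allele = "alt"` uses the alternate allele block, `"ref"` the
#' reference). PAD (and N) positions are excluded from the per-column
#' denominator, so every row is a probability distribution over A/C/G/T
#' (rows with no observed base are left at 0 and flagged).
#'
#' @param concepts List of `sequence_concept` objects sharing `W`.
#' @param allele `"alt"` or `"ref"`: which allele block to include.
#' @param orientation `"fwd"` or `"rev"`.
#' @return An object of class `ppm`: list with `probs` (positions x 4
#'   matrix, rows summing to 1), `n_sequences` and `counts`.
#' @export
logo_matrix <- function(concepts, allele = c("alt", "ref"),
                        orientation = c("fwd", "rev")) {
  allele <- match.arg(allele)
  orientation <- match.arg(orientation)
  if (!length(concepts)) stop("no concepts supplied")
  W <- concepts[[1]]$W
  blk <- if (allele == "alt") "alt_seq" else "ref_seq"
  mat <- t(vapply(concepts, function(cc) {
    side <- cc[[orientation]]
    c(side$five_prime, side[[blk]], side$three_prime)
  }, character(3L * W)))
  counts <- t(apply(mat, 2L, function(col) {
    tabulate(match(col, BASES), nbins = 4L)
  }))
  colnames(counts) <- BASES
  tot <- rowSums(counts)
  probs <- counts / ifelse(tot == 0, 1, tot)
  structure(
    list(probs = probs, counts = counts, n_sequences = length(concepts),
         layout = c(five_prime = W, allele = W, three_prime = W),
         note = paste("information content computed from observed",
                      "high-attention instances is a lower bound when a",
                      "head attends to several distinct motifs")),
    class = "ppm"
  )
}

#' Per-position information content of a position probability matrix
#'
#' `2 - H(p)` bits per position, with `H` the Shannon entropy over the four
#' nucleotides. Uniform columns give 0 bits, one-hot columns 2 bits.
#' Positions with no observations (all-PAD columns) return `NA`. No
#' small-sample correction is applied.
#'
#' @param ppm A `ppm` from [logo_matrix()], or a positions x 4 probability
#'   matrix.
#' @return Numeric vector of bits per position, in `[0, 2]`.
#' @export
information_bits <- function(ppm) {
  probs <- if (inherits(ppm, "ppm")) ppm$probs else as.matrix(ppm)
  apply(probs, 1L, function(p) {
    if (sum(p) == 0) return(NA_real_)
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Write a position probability matrix as TSV
#'
#' Tab-delimited positions x A/C/G/T table consumable by standard
#' logo-drawing tools.
#'
#' @param ppm A `ppm` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ppm <- function(ppm, path) {
  df <- data.frame(pos = seq_len(nrow(ppm$probs)), ppm$probs,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
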