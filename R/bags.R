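# Bag container: a set of samples, each a variable-length set of encoded
# mutation instances. Instances live in one feature matrix with a parallel
# bag index so that batches stay ragged (no padding to the largest bag).

#' Construct a set of MIL bags
#'
#' A bag is one sample: a variable-length set of instance feature vectors,
#' optional fixed-length sample covariates and a label. Instance order
#' carries no meaning. Internally all instances are stored in one numeric
#' matrix with a parallel integer bag index, so reductions are segment-wise
#' and bags are never padded.
#'
#' @param x Numeric matrix, one row per instance.
#' @param bag Integer vector, same length as `nrow(x)`, with values in
#'   `1..n_bags` assigning each instance to its bag.
#' @param labels Optional factor (or vector coercible to factor) of length
#'   `n_bags` with one class label per bag.
#' @param sample_features Optional numeric matrix with `n_bags` rows of
#'   per-sample covariates, concatenated to the aggregated vector.
#' @param sample_ids Optional character vector of bag identifiers.
#' @param n_bags Number of bags; defaults to `max(bag)`.
#' @return An object of class `mil_bags`.
#' @export
mil_bags <- function(x, bag, labels = NULL, sample_features = NULL,
                     sample_ids = NULL, n_bags = max(bag)) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  bag <- as.integer(bag)
  stopifnot(nrow(x) == length(bag), all(bag >= 1L), all(bag <= n_bags))
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    stopifnot(length(labels) == n_bags)
  }
  if (!is.null(sample_features)) {
    sample_features <- as.matrix(sample_features)
    stopifnot(nrow(sample_features) == n_bags)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("bag", seq_len(n_bags))
  structure(
    list(
      x = x, bag = bag, n_bags = as.integer(n_bags), labels = labels,
      sample_features = sample_features, sample_ids = sample_ids
    ),
    class = "mil_bags"
  )
}

#' Assemble bags from a list of per-sample instance matrices
#'
#' @param mats List of numeric matrices, one per bag, equal column count.
#' @inheritParams mil_bags
#' @return A [mil_bags] object.
#' @export
bags_from_list <- function(mats, labels = NULL, sample_features = NULL,
                           sample_ids = NULL) {
  stopifnot(length(mats) >= 1L)
  ni <- vapply(mats, nrow, integer(1))
  mil_bags(
    x = do.call(rbind, mats),
    bag = rep.int(seq_along(mats), ni),
    labels = labels,
    sample_features = sample_features,
    sample_ids = sample_ids,
    n_bags = length(mats)
  )
}

#' @export
print.mil_bags <- function(x, ...) {
  cat(
    "<mil_bags> ", x$n_bags, " bags, ", nrow(x$x), " instances, ",
    ncol(x$x), " instance features",
    if (!is.null(x$labels)) paste0(", ", nlevels(x$labels), " classes"),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Number of instances per bag
#'
#' @param bags A [mil_bags] object.
#' @return Integer vector of length `n_bags`.
#' @export
bag_sizes <- function(bags) {
  tabulate(bags$bag, nbins = bags$n_bags)
}

#' Subset bags by bag index
#'
#' Keeps the selected bags (and their instances) and renumbers bag indices
#' to `1..length(idx)`.
#'
#' @param bags A [mil_bags] object.
#' @param idx Integer vector of bag indices to keep.
#' @return A [mil_bags] object.
#' @export
subset_bags <- function(bags, idx) {
  idx <- as.integer(idx)
  keep <- bags$bag %in% idx
  remap <- integer(bags$n_bags)
  remap[idx] <- seq_along(idx)
  mil_bags(
    x = bags$x[keep, , drop = FALSE],
    bag = remap[bags$bag[keep]],
    labels = if (!is.null(bags$labels)) bags$labels[idx],
    sample_features = if (!is.null(bags$sample_features)) {
      bags$sample_features[idx, , drop = FALSE]
    },
    sample_ids = bags$sample_ids[idx],
    n_bags = length(idx)
  )
}

#' Randomly permute instance order within the instance table
#'
#' Utility for permutation-invariance checks; bag membership is preserved,
#' only row order changes.
#'
#' @param bags A [mil_bags] object.
#' @return A [mil_bags] object with rows shuffled.
#' @export
shuffle_instances <- function(bags) {
  ord <- sample.int(nrow(bags$x))
  mil_bags(
    x = bags$x[ord, , drop = FALSE],
    bag = bags$bag[ord],
    labels = bags$labels,
    sample_features = bags$sample_features,
    sample_ids = bags$sample_ids,
    n_bags = bags$n_bags
  )
}
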