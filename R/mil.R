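# Attention-based multiple instance learning model.
#
# Architecture: optional per-component "kernel" blocks (independent ARU
# projections of column slices, used by the sequence encoder) -> dense
# encoder -> multi-headed attention (linear map + adaptive sigmoid, so every
# weight is strictly inside (0,1)) -> permutation-invariant aggregation
# (attention-weighted mean, log1p of the attention-weighted sum, or dynamic
# two-round attention) -> dense head -> softmax (multiclass) or a single
# ASU-squashed logit (binary).
#
# The whole forward/backward pass is written against a ragged layout: one
# instance matrix plus a bag index, all reductions segment-wise. Gradients
# are derived by hand and validated against finite differences in the tests.

#' Model configuration for the attention MIL classifier
#'
#' @param n_classes Number of classes (>= 2).
#' @param n_heads Number of attention heads. Defaults to `n_classes`, in
#'   which case each head can be read as class-specific attention.
#' @param aggregation One of `"mean"` (attention-weighted average, weights
#'   normalized per bag and head), `"sum"` (attention-weighted sum followed
#'   by elementwise `log1p`) or `"dynamic"` (two-round attention: a weighted
#'   mean is computed first, the resulting sample vector is broadcast back
#'   to every instance, and a second attention drives the final
#'   aggregation).
#' @param dynamic_second Aggregation used for the second round of dynamic
#'   attention, `"mean"` or `"sum"`.
#' @param encoder_widths Integer vector of hidden widths for the instance
#'   encoder; empty for an identity encoder.
#' @param encoder_activation `"aru"` (adaptive rectifier, trainable
#'   curvature per unit) or `"relu"`.
#' @param kernel_slices Optional list of integer column-index vectors; each
#'   slice gets its own independent block of `kernel_units` ARU kernels and
#'   the outputs are concatenated (columns outside every slice are passed
#'   through unchanged). This is how the sequence components (5' flank, ref,
#'   alt, 3' flank in both orientations) each receive independent kernels.
#' @param kernel_units Number of kernels per component block.
#' @param kernel_type `"conv"` (shared filter of width `kernel_width`
#'   positions slid over the one-hot block, ARU, global max pool — the
#'   convolutional sequence encoder) or `"dense"` (one projection of the
#'   whole block).
#' @param kernel_width Convolution filter width in sequence positions.
#' @param head_widths Integer vector of hidden widths for the
#'   post-aggregation classifier head (ReLU).
#' @param dropout Dropout rate applied to the encoder output and after each
#'   head hidden layer during training.
#' @param instance_dropout Fraction of instances dropped per bag per
#'   gradient update (MIL data dropout); all instances are used at
#'   evaluation.
#' @param attention_l1 Weight of the L1 activity penalty on the attention
#'   output (mean absolute attention); pushes background instances toward 0
#'   so key instances separate.
#' @param l2 L2 penalty weight on dense weight matrices (kernel, encoder,
#'   head, output; attention weights are exempt).
#' @param output `"softmax"` or `"asu"` (single logit squashed by the
#'   adaptive sigmoid; binary tasks only).
#' @param attention_frozen If `TRUE` every attention weight is fixed at 1
#'   (no attention parameters). Useful for reducing the model to a plain
#'   pooled classifier.
#' @param sample_feature_dim Number of per-sample covariate columns
#'   concatenated after aggregation.
#' @param lr Adam learning rate.
#' @param batch_size Bags per gradient update.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without improvement of
#'   validation weighted cross-entropy); `Inf` disables early stopping.
#' @param seed Integer seed controlling parameter initialization and all
#'   training-time randomness.
#' @return A list of class `mil_config`.
#' @export
mil_config <- function(n_classes,
                       n_heads = n_classes,
                       aggregation = c("mean", "sum", "dynamic"),
                       dynamic_second = c("mean", "sum"),
                       encoder_widths = integer(0),
                       encoder_activation = c("aru", "relu"),
                       kernel_slices = NULL,
                       kernel_units = 8L,
                       kernel_type = c("conv", "dense"),
                       kernel_width = 6L,
                       head_widths = integer(0),
                       dropout = 0,
                       instance_dropout = 0,
                       attention_l1 = 0,
                       l2 = 0,
                       output = c("softmax", "asu"),
                       attention_frozen = FALSE,
                       sample_feature_dim = 0L,
                       lr = 0.01,
                       batch_size = 32L,
                       epochs = 100L,
                       patience = Inf,
                       seed = 1L) {
  aggregation <- match.arg(aggregation)
  dynamic_second <- match.arg(dynamic_second)
  kernel_type <- match.arg(kernel_type)
  encoder_activation <- match.arg(encoder_activation)
  output <- match.arg(output)
  stopifnot(
    n_classes >= 2L, n_heads >= 1L,
    instance_dropout >= 0, instance_dropout < 1,
    dropout >= 0, dropout < 1,
    attention_l1 >= 0, l2 >= 0
  )
  if (output == "asu" && n_classes != 2L) {
    stop("output = 'asu' is a binary head; n_classes must be 2")
  }
  structure(
    list(
      n_classes = as.integer(n_classes), n_heads = as.integer(n_heads),
      aggregation = aggregation, dynamic_second = dynamic_second,
      encoder_widths = as.integer(encoder_widths),
      encoder_activation = encoder_activation,
      kernel_slices = kernel_slices, kernel_units = as.integer(kernel_units),
      kernel_type = kernel_type, kernel_width = as.integer(kernel_width),
      head_widths = as.integer(head_widths),
      dropout = dropout, instance_dropout = instance_dropout,
      attention_l1 = attention_l1, l2 = l2, output = output,
      attention_frozen = attention_frozen,
      sample_feature_dim = as.integer(sample_feature_dim),
      lr = lr, batch_size = as.integer(batch_size),
      epochs = as.integer(epochs), patience = patience,
      seed = as.integer(seed)
    ),
    class = "mil_config"
  )
}

#' Reference binary architecture for microsatellite-instability-style tasks
#'
#' A named configuration reproducing the binary reference stack: 8
#' independent ARU kernels per sequence component, fused to 128 with ReLU
#' and 0.01 L2, dropout 0.5, a single attention head with ASU activation
#' and 0.05 L1 activity regularization, log-sum aggregation, then a
#' 256-ReLU / 0.5-dropout / 128-ReLU / 0.5-dropout head to a single logit.
#' Instance (data) dropout 0.4.
#'
#' @param kernel_slices List of column slices, one per sequence component
#'   (see [sequence_component_slices()]).
#' @param ... Overrides passed on to [mil_config()].
#' @return A `mil_config`.
#' @export
msi_reference_config <- function(kernel_slices, ...) {
  defaults <- list(
    n_classes = 2L, n_heads = 1L, aggregation = "sum",
    encoder_widths = 128L, encoder_activation = "relu",
    kernel_slices = kernel_slices, kernel_units = 8L,
    head_widths = c(256L, 128L), dropout = 0.5,
    instance_dropout = 0.4, attention_l1 = 0.05, l2 = 0.01,
    output = "asu"
  )
  override <- list(...)
  defaults[names(override)] <- override
  do.call(mil_config, defaults)
}

# encoder output dimension implied by config + input dim
mil_encoded_dim <- function(config, input_dim) {
  d <- input_dim
  if (!is.null(config$kernel_slices)) {
    rest <- setdiff(seq_len(input_dim), unlist(config$kernel_slices))
    d <- length(config$kernel_slices) * config$kernel_units + length(rest)
  }
  if (length(config$encoder_widths)) {
    d <- config$encoder_widths[length(config$encoder_widths)]
  }
  d
}

#' Initialize an attention MIL model
#'
#' @param input_dim Number of instance feature columns the model expects.
#' @param config A [mil_config()].
#' @return An object of class `mil_model` holding the parameter list and
#'   configuration; train with [mil_train()], apply with
#'   [predict.mil_model()].
#' @export
mil_new <- function(input_dim, config) {
  stopifnot(inherits(config, "mil_config"))
  set.seed(config$seed)
  p <- list()
  d <- input_dim

  if (!is.null(config$kernel_slices)) {
    for (s in seq_along(config$kernel_slices)) {
      sl <- config$kernel_slices[[s]]
      w_in <- if (config$kernel_type == "conv") {
        min(4L * config$kernel_width, length(sl))
      } else {
        length(sl)
      }
      p[[paste0("ker_W", s)]] <- he_init(w_in, config$kernel_units)
      p[[paste0("ker_b", s)]] <- numeric(config$kernel_units)
      p[[paste0("ker_a", s)]] <- rep(aru_default_alpha(), config$kernel_units)
    }
    rest <- setdiff(seq_len(input_dim), unlist(config$kernel_slices))
    d <- length(config$kernel_slices) * config$kernel_units + length(rest)
  }

  for (l in seq_along(config$encoder_widths)) {
    w <- config$encoder_widths[l]
    p[[paste0("enc_W", l)]] <- he_init(d, w)
    p[[paste0("enc_b", l)]] <- numeric(w)
    if (config$encoder_activation == "aru") {
      p[[paste0("enc_a", l)]] <- rep(aru_default_alpha(), w)
    }
    d <- w
  }
  dE <- d
  K <- config$n_heads

  if (!config$attention_frozen) {
    if (config$aggregation == "dynamic") {
      p$att1_W <- he_init(dE, 1L) * 0.1
      p$att1_b <- 0
      p$att1_al <- asu_default_alpha()
      p$att1_au <- asu_default_alpha()
      p$att2_W <- he_init(2L * dE, K) * 0.1
      p$att2_b <- numeric(K)
      p$att2_al <- rep(asu_default_alpha(), K)
      p$att2_au <- rep(asu_default_alpha(), K)
    } else {
      p$att_W <- he_init(dE, K) * 0.1
      p$att_b <- numeric(K)
      p$att_al <- rep(asu_default_alpha(), K)
      p$att_au <- rep(asu_default_alpha(), K)
    }
  }

  d <- K * dE + config$sample_feature_dim
  for (l in seq_along(config$head_widths)) {
    w <- config$head_widths[l]
    p[[paste0("head_W", l)]] <- he_init(d, w)
    p[[paste0("head_b", l)]] <- numeric(w)
    d <- w
  }
  n_out <- if (config$output == "asu") 1L else config$n_classes
  p$out_W <- he_init(d, n_out) * 0.1
  p$out_b <- numeric(n_out)
  if (config$output == "asu") {
    p$out_al <- asu_default_alpha()
    p$out_au <- asu_default_alpha()
  }

  structure(
    list(params = p, config = config, input_dim = as.integer(input_dim),
         encoded_dim = as.integer(dE), classes = NULL),
    class = "mil_model"
  )
}

#' @export
print.mil_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<mil_model> input_dim=", x$input_dim,
      " heads=", x$config$n_heads,
      " aggregation=", x$config$aggregation,
      " params=", np, "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# forward

# x: instance matrix, bag: index 1..nb, sf: sample features or NULL
mil_forward <- function(model, x, bag, nb, sf = NULL, training = FALSE) {
  cfg <- model$config
  p <- model$params
  K <- cfg$n_heads
  cache <- list(bag = bag, nb = nb, n = nrow(x))

  h <- x
  if (!is.null(cfg$kernel_slices)) {
    rest <- setdiff(seq_len(ncol(x)), unlist(cfg$kernel_slices))
    kc <- vector("list", length(cfg$kernel_slices))
    outs <- vector("list", length(cfg$kernel_slices))
    for (s in seq_along(cfg$kernel_slices)) {
      sl <- cfg$kernel_slices[[s]]
      kc[[s]] <- if (cfg$kernel_type == "conv") {
        conv_forward(x[, sl, drop = FALSE],
                     p[[paste0("ker_W", s)]], p[[paste0("ker_b", s)]],
                     alpha = p[[paste0("ker_a", s)]], fw = cfg$kernel_width)
      } else {
        dense_forward(x[, sl, drop = FALSE],
                      p[[paste0("ker_W", s)]], p[[paste0("ker_b", s)]],
                      act = "aru", alpha = p[[paste0("ker_a", s)]])
      }
      outs[[s]] <- kc[[s]]$h
    }
    h <- do.call(cbind, c(outs, list(x[, rest, drop = FALSE])))
    cache$kernel <- kc
    cache$kernel_rest <- rest
  }

  enc <- vector("list", length(cfg$encoder_widths))
  for (l in seq_along(cfg$encoder_widths)) {
    enc[[l]] <- dense_forward(
      h, p[[paste0("enc_W", l)]], p[[paste0("enc_b", l)]],
      act = cfg$encoder_activation,
      alpha = p[[paste0("enc_a", l)]]
    )
    h <- enc[[l]]$h
  }
  cache$enc <- enc

  if (training && cfg$dropout > 0) {
    cache$enc_mask <- dropout_mask(dim(h), cfg$dropout)
    h <- h * cache$enc_mask
  }
  cache$H <- h
  dE <- ncol(h)

  # attention + aggregation
  if (cfg$aggregation == "dynamic" && !cfg$attention_frozen) {
    u1 <- sweep(h %*% p$att1_W, 2L, p$att1_b, "+")
    a1 <- asu(u1, bycol(u1, p$att1_al), bycol(u1, p$att1_au))
    z1 <- segment_sum(a1, bag, nb)
    t1 <- segment_sum(h * a1[, 1L], bag, nb)
    s1 <- t1 / z1[, 1L]
    g <- cbind(h, s1[bag, , drop = FALSE])
    u2 <- sweep(g %*% p$att2_W, 2L, p$att2_b, "+")
    a <- asu(u2, bycol(u2, p$att2_al), bycol(u2, p$att2_au))
    cache[c("u1", "a1", "z1", "t1", "s1", "g", "u2")] <-
      list(u1, a1, z1, t1, s1, g, u2)
    agg_mode <- cfg$dynamic_second
  } else if (cfg$attention_frozen) {
    a <- matrix(1, nrow(h), K)
    agg_mode <- if (cfg$aggregation == "dynamic") cfg$dynamic_second else cfg$aggregation
  } else {
    u <- sweep(h %*% p$att_W, 2L, p$att_b, "+")
    a <- asu(u, bycol(u, p$att_al), bycol(u, p$att_au))
    cache$u <- u
    agg_mode <- cfg$aggregation
  }
  cache$A <- a
  cache$agg_mode <- agg_mode

  Sh <- vector("list", K)
  cache$Z <- cache$P <- vector("list", K)
  for (k in seq_len(K)) {
    wsum <- segment_sum(h * a[, k], bag, nb)
    if (agg_mode == "mean") {
      z <- segment_sum(a[, k, drop = FALSE], bag, nb)[, 1L]
      if (anyNA(z) || any(z == 0)) {
        stop("non-finite or zero total attention in a bag ",
             "(empty bag, or training diverged)")
      }
      cache$Z[[k]] <- z
      Sh[[k]] <- wsum / z
    } else {
      cache$P[[k]] <- wsum
      Sh[[k]] <- log1p(wsum)
    }
  }
  S <- do.call(cbind, Sh)
  cache$S <- S
  if (!is.null(sf)) S <- cbind(S, sf)
  cache$sf_dim <- if (is.null(sf)) 0L else ncol(sf)

  hd <- vector("list", length(cfg$head_widths))
  cache$head_mask <- vector("list", length(cfg$head_widths))
  hh <- S
  for (l in seq_along(cfg$head_widths)) {
    hd[[l]] <- dense_forward(
      hh, p[[paste0("head_W", l)]], p[[paste0("head_b", l)]], act = "relu"
    )
    hh <- hd[[l]]$h
    if (training && cfg$dropout > 0) {
      cache$head_mask[[l]] <- dropout_mask(dim(hh), cfg$dropout)
      hh <- hh * cache$head_mask[[l]]
    }
  }
  cache$head <- hd
  cache$Hh <- hh
  logits <- sweep(hh %*% p$out_W, 2L, p$out_b, "+")
  cache$logits <- logits

  if (cfg$output == "asu") {
    cache$prob_pos <- asu(logits, bycol(logits, p$out_al),
                          bycol(logits, p$out_au))[, 1L]
  } else {
    m <- logits - apply(logits, 1L, max)
    e <- exp(m)
    cache$probs <- e / rowSums(e)
  }
  cache
}

# ---------------------------------------------------------------------------
# backward: dlogits -> gradients for every parameter

mil_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  K <- cfg$n_heads
  bag <- cache$bag
  g <- list()

  g$out_W <- crossprod(cache$Hh, dlogits)
  g$out_b <- colSums(dlogits)
  dhh <- dlogits %*% t(p$out_W)

  for (l in rev(seq_along(cfg$head_widths))) {
    if (!is.null(cache$head_mask[[l]])) dhh <- dhh * cache$head_mask[[l]]
    bk <- dense_backward(cache$head[[l]], dhh, p[[paste0("head_W", l)]])
    g[[paste0("head_W", l)]] <- bk$dW
    g[[paste0("head_b", l)]] <- bk$db
    dhh <- bk$dx
  }

  if (cache$sf_dim > 0L) {
    dS <- dhh[, seq_len(ncol(cache$S)), drop = FALSE]
  } else {
    dS <- dhh
  }

  H <- cache$H
  dE <- ncol(H)
  A <- cache$A
  n <- cache$n
  dH <- matrix(0, n, dE)
  dA <- matrix(0, n, K)

  for (k in seq_len(K)) {
    cols <- ((k - 1L) * dE + 1L):(k * dE)
    dSk <- dS[, cols, drop = FALSE]
    if (cache$agg_mode == "mean") {
      z <- cache$Z[[k]]
      Sk <- cache$S[, cols, drop = FALSE]
      dT <- dSk / z
      dZ <- -rowSums(dSk * Sk) / z
      dTi <- dT[bag, , drop = FALSE]
      dA[, k] <- dA[, k] + rowSums(H * dTi) + dZ[bag]
      dH <- dH + A[, k] * dTi
    } else {
      dP <- dSk / (1 + cache$P[[k]])
      dPi <- dP[bag, , drop = FALSE]
      dA[, k] <- dA[, k] + rowSums(H * dPi)
      dH <- dH + A[, k] * dPi
    }
  }

  # L1 activity penalty on attention (attention is strictly positive)
  if (cfg$attention_l1 > 0 && !cfg$attention_frozen) {
    n_att <- length(A) + if (cfg$aggregation == "dynamic") length(cache$a1) else 0L
    dA <- dA + cfg$attention_l1 / n_att
  }

  if (!cfg$attention_frozen && cfg$aggregation == "dynamic") {
    ag2 <- asu_grad(cache$u2, bycol(cache$u2, p$att2_al),
                    bycol(cache$u2, p$att2_au))
    dU2 <- dA * ag2$dx
    g$att2_W <- crossprod(cache$g, dU2)
    g$att2_b <- colSums(dU2)
    g$att2_al <- colSums(dA * ag2$dalpha_lower)
    g$att2_au <- colSums(dA * ag2$dalpha_upper)
    dG <- dU2 %*% t(p$att2_W)
    dH <- dH + dG[, seq_len(dE), drop = FALSE]
    ds1 <- segment_sum(dG[, dE + seq_len(dE), drop = FALSE], bag, cache$nb)

    z1 <- cache$z1[, 1L]
    dT1 <- ds1 / z1
    dZ1 <- -rowSums(ds1 * cache$s1) / z1
    dT1i <- dT1[bag, , drop = FALSE]
    da1 <- rowSums(H * dT1i) + dZ1[bag]
    if (cfg$attention_l1 > 0) {
      n_att <- length(A) + length(cache$a1)
      da1 <- da1 + cfg$attention_l1 / n_att
    }
    dH <- dH + cache$a1[, 1L] * dT1i

    ag1 <- asu_grad(cache$u1, bycol(cache$u1, p$att1_al),
                    bycol(cache$u1, p$att1_au))
    dU1 <- da1 * ag1$dx
    g$att1_W <- crossprod(H, dU1)
    g$att1_b <- sum(dU1)
    g$att1_al <- sum(da1 * ag1$dalpha_lower)
    g$att1_au <- sum(da1 * ag1$dalpha_upper)
    dH <- dH + dU1 %*% t(p$att1_W)
  } else if (!cfg$attention_frozen) {
    ag <- asu_grad(cache$u, bycol(cache$u, p$att_al),
                   bycol(cache$u, p$att_au))
    dU <- dA * ag$dx
    g$att_W <- crossprod(H, dU)
    g$att_b <- colSums(dU)
    g$att_al <- colSums(dA * ag$dalpha_lower)
    g$att_au <- colSums(dA * ag$dalpha_upper)
    dH <- dH + dU %*% t(p$att_W)
  }

  if (!is.null(cache$enc_mask)) dH <- dH * cache$enc_mask

  for (l in rev(seq_along(cfg$encoder_widths))) {
    bk <- dense_backward(cache$enc[[l]], dH, p[[paste0("enc_W", l)]])
    g[[paste0("enc_W", l)]] <- bk$dW
    g[[paste0("enc_b", l)]] <- bk$db
    if (!is.null(bk$dalpha)) g[[paste0("enc_a", l)]] <- bk$dalpha
    dH <- bk$dx
  }

  if (!is.null(cfg$kernel_slices)) {
    ku <- cfg$kernel_units
    for (s in seq_along(cfg$kernel_slices)) {
      cols <- ((s - 1L) * ku + 1L):(s * ku)
      bk <- if (cfg$kernel_type == "conv") {
        conv_backward(cache$kernel[[s]], dH[, cols, drop = FALSE],
                      p[[paste0("ker_W", s)]])
      } else {
        dense_backward(cache$kernel[[s]], dH[, cols, drop = FALSE],
                       p[[paste0("ker_W", s)]])
      }
      g[[paste0("ker_W", s)]] <- bk$dW
      g[[paste0("ker_b", s)]] <- bk$db
      g[[paste0("ker_a", s)]] <- bk$dalpha
    }
  }
  g
}

# ---------------------------------------------------------------------------
# loss

is_l2_param <- function(nm) {
  grepl("^(ker_W|enc_W|head_W|out_W)", nm)
}

# weights: per-bag sample weights (class weights looked up per label)
# y: integer class index 1..C per bag
mil_loss_grad <- function(model, x, bag, nb, y, weights = NULL, sf = NULL,
                          training = TRUE) {
  cfg <- model$config
  p <- model$params
  if (is.null(weights)) weights <- rep(1, nb)
  wsum <- sum(weights)
  cache <- mil_forward(model, x, bag, nb, sf = sf, training = training)

  if (cfg$output == "asu") {
    yb <- as.numeric(y == 2L)
    pr <- pmin(pmax(cache$prob_pos, 1e-12), 1 - 1e-12)
    ce <- -(yb * log(pr) + (1 - yb) * log(1 - pr))
    loss <- sum(weights * ce) / wsum
    dprob <- weights * (pr - yb) / (pr * (1 - pr)) / wsum
    og <- asu_grad(cache$logits, bycol(cache$logits, p$out_al),
                   bycol(cache$logits, p$out_au))
    dlogits <- matrix(dprob * og$dx[, 1L], ncol = 1L)
    extra <- list(
      out_al = sum(dprob * og$dalpha_lower[, 1L]),
      out_au = sum(dprob * og$dalpha_upper[, 1L])
    )
  } else {
    pr <- cache$probs
    ce <- -log(pmax(pr[cbind(seq_len(nb), y)], 1e-12))
    loss <- sum(weights * ce) / wsum
    dlogits <- pr
    dlogits[cbind(seq_len(nb), y)] <- dlogits[cbind(seq_len(nb), y)] - 1
    dlogits <- dlogits * (weights / wsum)
    extra <- NULL
  }

  if (cfg$attention_l1 > 0 && !cfg$attention_frozen) {
    if (cfg$aggregation == "dynamic") {
      loss <- loss + cfg$attention_l1 *
        (sum(cache$A) + sum(cache$a1)) / (length(cache$A) + length(cache$a1))
    } else {
      loss <- loss + cfg$attention_l1 * mean(cache$A)
    }
  }

  g <- mil_backward(model, cache, dlogits)
  if (!is.null(extra)) g[names(extra)] <- extra

  if (cfg$l2 > 0) {
    for (nm in names(p)) {
      if (is_l2_param(nm)) {
        loss <- loss + cfg$l2 * sum(p[[nm]]^2)
        g[[nm]] <- g[[nm]] + 2 * cfg$l2 * p[[nm]]
      }
    }
  }
  list(loss = loss, grads = g, cache = cache)
}

# ---------------------------------------------------------------------------
# prediction and attention extraction

#' Predict class probabilities for a set of bags
#'
#' Output is invariant to instance order within each bag. Every bag must
#' contain at least one instance.
#'
#' @param object A `mil_model`.
#' @param bags A [mil_bags] object.
#' @param ... Unused.
#' @return Numeric matrix `n_bags x n_classes` of class probabilities (rows
#'   sum to 1); column names are class levels when the model was trained on
#'   a labelled set.
#' @export
predict.mil_model <- function(object, bags, ...) {
  stopifnot(inherits(bags, "mil_bags"))
  if (any(bag_sizes(bags) == 0L)) {
    stop("empty bag at evaluation time: every bag needs >= 1 instance")
  }
  cache <- mil_forward(object, bags$x, bags$bag, bags$n_bags,
                       sf = bags$sample_features, training = FALSE)
  pr <- if (object$config$output == "asu") {
    cbind(1 - cache$prob_pos, cache$prob_pos)
  } else {
    cache$probs
  }
  if (!is.null(object$classes)) colnames(pr) <- object$classes
  rownames(pr) <- bags$sample_ids
  pr
}

#' Extract per-instance, per-head attention weights
#'
#' Returns the attention actually used for the final aggregation (the
#' second-round attention when the model is dynamic). Every entry is
#' strictly inside (0, 1) by the ASU bound; for a frozen-attention model all
#' entries are exactly 1.
#'
#' @param model A `mil_model`.
#' @param bags A [mil_bags] object.
#' @return Matrix `n_instances x n_heads`; rows align with `bags$x`.
#' @export
attention_weights <- function(model, bags) {
  stopifnot(inherits(bags, "mil_bags"))
  cache <- mil_forward(model, bags$x, bags$bag, bags$n_bags,
                       sf = bags$sample_features, training = FALSE)
  cache$A
}

# ---------------------------------------------------------------------------
# finite-difference gradient check (used by the test suite)

mil_numeric_grad <- function(model, x, bag, nb, y, weights = NULL, sf = NULL,
                             eps = 1e-5) {
  f <- function(m) {
    mil_loss_grad(m, x, bag, nb, y, weights, sf, training = FALSE)$loss
  }
  out <- list()
  for (nm in names(model$params)) {
    pg <- model$params[[nm]] * 0
    for (i in seq_along(model$params[[nm]])) {
      m1 <- model
      m1$params[[nm]][i] <- m1$params[[nm]][i] + eps
      m2 <- model
      m2$params[[nm]][i] <- m2$params[[nm]][i] - eps
      pg[i] <- (f(m1) - f(m2)) / (2 * eps)
    }
    out[[nm]] <- pg
  }
  out
}
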