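# Internal numeric building blocks for the MIL model: initializers, dense
# layers with column-wise trainable activation curvature, segment reductions
# over ragged bags, and an Adam optimizer. All gradients are hand-derived and
# checked against finite differences in the test suite.

he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

# broadcast a per-column parameter vector over a matrix
bycol <- function(x, v) {
  if (length(v) == 1L) return(array(v, dim(x)))
  matrix(v, nrow(x), ncol(x), byrow = TRUE)
}

# dense layer forward: act in {"linear","relu","aru"}; alpha used for "aru"
dense_forward <- function(x, W, b, act = "linear", alpha = NULL) {
  z <- x %*% W
  z <- sweep(z, 2L, b, "+")
  h <- switch(act,
    linear = z,
    relu = pmax(z, 0),
    aru = aru(z, bycol(z, alpha)),
    stop("unknown activation: ", act)
  )
  list(x = x, z = z, h = h, act = act, alpha = alpha)
}

# dense layer backward: returns dx, dW, db, dalpha
dense_backward <- function(cache, dh, W) {
  dz <- switch(cache$act,
    linear = dh,
    relu = dh * (cache$z > 0),
    aru = {
      g <- aru_grad(cache$z, bycol(cache$z, cache$alpha))
      dh * g$dx
    }
  )
  dalpha <- NULL
  if (cache$act == "aru") {
    g <- aru_grad(cache$z, bycol(cache$z, cache$alpha))
    da <- dh * g$dalpha
    dalpha <- colSums(da)
  }
  list(
    dx = dz %*% t(W),
    dW = crossprod(cache$x, dz),
    db = colSums(dz),
    dalpha = dalpha
  )
}

# 1-D convolution over a one-hot sequence block (position-major layout,
# `depth` channels per position) with a shared filter of width `fw`, ARU
# activation and global max pooling over positions. Patches are expressed
# as dense products on column windows, so the backward pass routes each
# unit's gradient to its argmax patch.
conv_forward <- function(x, W, b, alpha, fw, depth = 4L) {
  n_pos <- ncol(x) %/% depth
  n_patch <- max(1L, n_pos - fw + 1L)
  z <- vector("list", n_patch)
  best <- matrix(-Inf, nrow(x), ncol(W))
  arg <- matrix(1L, nrow(x), ncol(W))
  for (p in seq_len(n_patch)) {
    cols <- ((p - 1L) * depth + 1L):min(((p + fw - 1L) * depth), ncol(x))
    zp <- sweep(x[, cols, drop = FALSE] %*% W[seq_along(cols), , drop = FALSE],
                2L, b, "+")
    z[[p]] <- zp
    hp <- aru(zp, bycol(zp, alpha))
    upd <- hp > best
    best[upd] <- hp[upd]
    arg[upd] <- p
  }
  list(x = x, z = z, h = best, arg = arg, fw = fw, depth = depth,
       alpha = alpha, n_patch = n_patch)
}

conv_backward <- function(cache, dh, W) {
  dW <- W * 0
  db <- numeric(ncol(W))
  dalpha <- numeric(ncol(W))
  dx <- cache$x * 0
  depth <- cache$depth
  for (p in seq_len(cache$n_patch)) {
    mask <- cache$arg == p
    if (!any(mask)) next
    dhp <- dh * mask
    zp <- cache$z[[p]]
    g <- aru_grad(zp, bycol(zp, cache$alpha))
    dzp <- dhp * g$dx
    cols <- ((p - 1L) * depth + 1L):min(((p + cache$fw - 1L) * depth),
                                        ncol(cache$x))
    dW[seq_along(cols), ] <- dW[seq_along(cols), ] +
      crossprod(cache$x[, cols, drop = FALSE], dzp)
    db <- db + colSums(dzp)
    dalpha <- dalpha + colSums(dhp * g$dalpha)
    dx[, cols] <- dx[, cols] + dzp %*% t(W[seq_along(cols), , drop = FALSE])
  }
  list(dx = dx, dW = dW, db = db, dalpha = dalpha)
}

# segment sum of rows of x grouped by bag index (1..nb); empty groups -> 0
segment_sum <- function(x, bag, nb) {
  out <- matrix(0, nb, ncol(x))
  r <- rowsum(x, bag)
  out[as.integer(rownames(r)), ] <- r
  out
}

# inverted dropout mask
dropout_mask <- function(n, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(n[1] * n[2], 1L, 1 - p) / (1 - p), n[1], n[2])
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
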