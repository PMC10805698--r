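# Adaptive activation functions with trainable curvature.
#
# All three are built on the adaptive square root; the input x only ever
# enters squared, so none of them can overflow the way exp(x) saturates in a
# sum-aggregated MIL graph.

#' Adaptive square root
#'
#' `asr(x, alpha) = sqrt(exp(alpha) + x^2)`. A smooth upper envelope of
#' `abs(x)`: always strictly greater than `|x|`, converging to `|x|` as
#' `alpha` goes to minus infinity. The curvature parameter `alpha` is
#' unconstrained because it enters through `exp(alpha) > 0`.
#'
#' @param x Numeric vector, matrix or array.
#' @param alpha Curvature parameter(s); recycled against `x`.
#' @return Numeric object of the same shape as `x`.
#' @examples
#' asr(0, 0)       # 1
#' asr(4, log(9))  # 5
#' @export
asr <- function(x, alpha) {
  sqrt(exp(alpha) + x^2)
}

#' Adaptive rectifying unit
#'
#' `aru(x, alpha) = 0.5 * (x + asr(x, alpha))`. A smooth rectifier: strictly
#' positive and strictly above `max(x, 0)` for all finite inputs, monotone
#' increasing, and approaching ReLU as `alpha` goes to minus infinity. The
#' default `alpha` (see [aru_default_alpha()]) makes it agree with softplus
#' at the origin.
#'
#' @inheritParams asr
#' @return Numeric object of the same shape as `x`.
#' @seealso [asr()], [asu()]
#' @export
aru <- function(x, alpha) {
  0.5 * (x + asr(x, alpha))
}

#' Adaptive sigmoid unit
#'
#' `asu(x, al, au) = (x + asr(x, al)) / (asr(x, al) + asr(x, au))`, a smooth
#' monotone squashing function with range the open interval (0, 1), like the
#' logistic sigmoid. `al` and `au` control the curvature of the approach to
#' the lower and upper bound respectively. With the defaults from
#' [asu_default_alpha()] it matches the logistic function's value (0.5) and
#' slope (0.25) at the origin.
#'
#' @inheritParams asr
#' @param alpha_lower,alpha_upper Curvature parameters for the lower/upper
#'   bound; recycled against `x`.
#' @return Numeric object of the same shape as `x`, values in (0, 1).
#' @examples
#' asu(0, log(1), log(9))  # 0.25
#' @export
asu <- function(x, alpha_lower, alpha_upper) {
  rl <- asr(x, alpha_lower)
  ru <- asr(x, alpha_upper)
  (x + rl) / (rl + ru)
}

#' Default curvature for the adaptive rectifier
#'
#' Solves `aru(0, alpha) = softplus(0) = log(2)`, i.e.
#' `alpha = 2 * log(2 * log(2))`. The slope at the origin is 0.5 for any
#' `alpha`, matching softplus, so value matching at 0 pins the initialization.
#'
#' @return A scalar.
#' @export
aru_default_alpha <- function() {
  2 * log(2 * log(2))
}

#' Default curvature for the adaptive sigmoid
#'
#' With `alpha_lower == alpha_upper == alpha` the unit is antisymmetric about
#' `x = 0` where it takes value 0.5; its slope there is `exp(-alpha / 2) / 2`.
#' Matching the logistic slope 0.25 gives `alpha = 2 * log(2)`.
#'
#' @return A scalar, used for both curvature parameters.
#' @export
asu_default_alpha <- function() {
  2 * log(2)
}

# --- analytic derivatives (internal; backbone of the backward pass) ------

# d asr / dx and d asr / dalpha
asr_grad <- function(x, alpha) {
  r <- asr(x, alpha)
  list(dx = x / r, dalpha = exp(alpha) / (2 * r), value = r)
}

# aru: value, d/dx, d/dalpha
aru_grad <- function(x, alpha) {
  g <- asr_grad(x, alpha)
  list(
    value = 0.5 * (x + g$value),
    dx = 0.5 * (1 + g$dx),
    dalpha = 0.5 * g$dalpha
  )
}

# asu: value, d/dx, d/dalpha_lower, d/dalpha_upper
asu_grad <- function(x, alpha_lower, alpha_upper) {
  gl <- asr_grad(x, alpha_lower)
  gu <- asr_grad(x, alpha_upper)
  num <- x + gl$value
  den <- gl$value + gu$value
  inv_den2 <- 1 / den^2
  list(
    value = num / den,
    dx = ((1 + gl$dx) * den - num * (gl$dx + gu$dx)) * inv_den2,
    dalpha_lower = gl$dalpha * (den - num) * inv_den2,
    dalpha_upper = -num * gu$dalpha * inv_den2
  )
}
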