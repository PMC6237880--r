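#' Initialize projection weights
#'
#' Present connections are drawn i.i.d. uniform on `[0.25, 0.75]` (mean 0.5,
#' half-range 0.25); absent connections are exactly zero. Uses R's global
#' RNG, so results are reproducible under `set.seed()`.
#'
#' @param mask binary connectivity matrix (receivers in rows).
#' @param low,high support of the uniform draw.
#' @return weight matrix, same shape as `mask`.
#' @export
init_weights <- function(mask, low = 0.25, high = 0.75) {
  w <- matrix(0, nrow(mask), ncol(mask))
  idx <- which(mask != 0)
  w[idx] <- stats::runif(length(idx), low, high)
  w
}

#' Sigmoidal weight contrast enhancement
#'
#' Transmission weights are a contrast-enhanced function of the stored
#' (linear) weights: `sig(w) = 1 / (1 + (off * (1 - w) / w)^gain)`, with
#' `sig(0) = 0` and `sig(1) = 1`. Learning always operates on the linear
#' weights; the forward pass uses `sig(w)`. With the default gain 6 and
#' offset 4, the sigmoid midpoint sits at w = 0.8, just above the
#' initialization ceiling of 0.75: initial weights transmit weakly while
#' learned weights near 1 transmit at almost full strength - this is what
#' makes tuned synapses decisive against the random initialization during
#' pattern completion. `gain = 1, off = 1` is the identity.
#'
#' @param w linear weights in `[0, 1]`.
#' @param gain sigmoid gain.
#' @param off sigmoid offset (>1 shifts the midpoint above 0.5; the
#'   midpoint sits at `off / (1 + off)`).
#' @return effective weights, same shape as `w`.
#' @export
wt_sig <- function(w, gain = 6, off = 4) {
  out <- 1 / (1 + (off * (1 - w) / pmax(w, .Machine$double.eps))^gain)
  out[w <= 0] <- 0
  out[w >= 1] <- 1
  out
}

#' Hebbian weight change
#'
#' `delta_ih = y_i * (x_h - w_ih)`, evaluated at plus-phase activities. The
#' subtractive form is self-bounding: with activities in `[0, 1)` the weights
#' converge toward the presynaptic activity pattern on rows with active
#' postsynaptic cells and never leave `[0, 1]`.
#'
#' @param x_plus presynaptic activities at the end of the plus phase.
#' @param y_plus postsynaptic activities at the end of the plus phase.
#' @param w current weight matrix (receivers in rows).
#' @return matrix of weight changes (before learning-rate scaling).
#' @export
hebbian_delta <- function(x_plus, y_plus, w) {
  y_plus * (matrix(x_plus, nrow(w), ncol(w), byrow = TRUE) - w)
}

#' Error-driven (contrastive Hebbian) weight change
#'
#' `delta_ih = x_h^+ y_i^+ - x_h^- y_i^-`: the difference between the
#' plus-phase and minus-phase coproducts. Which minus half-phase supplies
#' `(x^-, y^-)` is a property of the pathway (monosynaptic pathways use the
#' first half of the minus phase, all others the second).
#'
#' @param x_plus,y_plus activities at the end of the plus phase.
#' @param x_minus,y_minus activities at the end of the pathway's minus phase.
#' @return matrix of raw (unbounded) weight changes.
#' @export
errdriven_delta <- function(x_plus, y_plus, x_minus, y_minus) {
  outer(y_plus, x_plus) - outer(y_minus, x_minus)
}

#' Soft-bound an error-driven weight change
#'
#' Positive changes are scaled by `(1 - w)`, negative changes by `w`, so the
#' update cannot push a weight past 0 or 1.
#'
#' @param d raw error-driven change.
#' @param w current weights.
#' @return bounded change, same shape.
#' @export
soft_bound <- function(d, w) {
  ifelse(d > 0, d * (1 - w), d * w)
}

#' Apply the end-of-plus-phase weight update to one projection
#'
#' Mixes the Hebbian and soft-bounded error-driven components,
#' `dw = eps * (k_hebb * dw_hebb + (1 - k_hebb) * bound(dw_err))`, clips the
#' result to `[0, 1]`, and leaves masked-out entries untouched.
#'
#' @param w weight matrix (receivers in rows).
#' @param mask binary connectivity.
#' @param x_plus,y_plus plus-phase activities (pre, post).
#' @param x_minus,y_minus minus-phase activities (pre, post); may be NULL
#'   when `k_hebb = 1`.
#' @param k_hebb Hebbian fraction in `[0, 1]`.
#' @param eps learning rate.
#' @return updated weight matrix.
#' @export
apply_update <- function(w, mask, x_plus, y_plus,
                         x_minus = NULL, y_minus = NULL,
                         k_hebb = 1, eps = 0.1) {
  dh <- hebbian_delta(x_plus, y_plus, w)
  if (k_hebb < 1) {
    if (is.null(x_minus) || is.null(y_minus))
      stop("minus-phase snapshot required when k_hebb < 1")
    de <- soft_bound(errdriven_delta(x_plus, y_plus, x_minus, y_minus), w)
  } else {
    de <- 0
  }
  w_new <- w + eps * (k_hebb * dh + (1 - k_hebb) * de)
  w_new <- pmin(pmax(w_new, 0), 1)
  w_new * (mask != 0)
}
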