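#' Layer parameters for a rate-coded competitive layer
#'
#' Bundles the conductance and activation parameters of one cell population.
#' Defaults follow the standard parameterization used throughout the model:
#' leak conductance 0.1, maximal excitatory conductance 1, reversal potentials
#' (El, Ee, Ei) = (0.3, 1, 0.25) on a normalized 0-1 potential scale,
#' activation gain 100 with threshold 0.5, and kWTA interpolation factor
#' q = 0.25. `gi_bar` may be a vector with one entry per cell, which is how
#' contextual suppression of dentate ensembles is expressed (1 for the
#' facilitated ensemble, 5 for suppressed ones).
#'
#' @param n number of cells in the layer.
#' @param kwta_frac fraction of cells allowed to be active (e.g. 0.25 for
#'   entorhinal layers, 0.01 for the dentate gyrus, 0.025 for CA3/CA1).
#' @param gl_bar leak conductance.
#' @param ge_bar maximal excitatory conductance.
#' @param gi_bar maximal inhibitory conductance; scalar or length-`n` vector.
#' @param El,Ee,Ei reversal potentials of the leak, excitatory and inhibitory
#'   channels.
#' @param Vrest resting (initial) membrane potential.
#' @param gamma activation gain.
#' @param theta activation threshold on the membrane potential.
#' @param q kWTA interpolation factor, strictly between 0 and 1.
#' @param tau integration rate per 1-ms Euler step.
#' @return An object of class `hippo_layer_params`.
#' @export
layer_params <- function(n, kwta_frac,
                         gl_bar = 0.1, ge_bar = 1, gi_bar = 1,
                         El = 0.3, Ee = 1, Ei = 0.25, Vrest = 0.3,
                         gamma = 100, theta = 0.5, q = 0.25, tau = 0.3) {
  stopifnot(n >= 1, kwta_frac > 0, kwta_frac <= 1,
            q > 0, q < 1, Ei < theta, theta < Ee,
            all(gi_bar > 0), length(gi_bar) %in% c(1L, n))
  k <- max(1L, as.integer(round(kwta_frac * n)))
  structure(list(n = as.integer(n), kwta_frac = kwta_frac, k = k,
                 gl_bar = gl_bar, ge_bar = ge_bar,
                 gi_bar = rep_len(gi_bar, n),
                 El = El, Ee = Ee, Ei = Ei, Vrest = Vrest,
                 gamma = gamma, theta = theta, q = q, tau = tau),
            class = "hippo_layer_params")
}

#' Rate-code activation function
#'
#' Half-wave rectified saturating activation: `y = chi / (1 + chi)` with
#' `chi = gamma * max(Vm - theta, 0)`. Cells at or below threshold are
#' silent; output is bounded in `[0, 1)`.
#'
#' @param vm membrane potential vector.
#' @param gamma gain.
#' @param theta threshold.
#' @return activity vector, same length as `vm`.
#' @export
activation <- function(vm, gamma = 100, theta = 0.5) {
  chi <- gamma * pmax(vm - theta, 0)
  chi / (1 + chi)
}

#' One Euler step of the shunting membrane equation
#'
#' Integrates `dVm/dt = tau * (gl_bar*(El-Vm) + ge*ge_bar*(Ee-Vm) +
#' gi*gi_bar*(Ei-Vm))` over one 1-ms step, where `ge` is the per-cell net
#' excitatory synaptic weight and `gi` the shared inhibitory drive set by
#' the layer's kWTA rule. The step is semi-implicit (backward Euler): the
#' driving conductances are evaluated at the current step but Vm is solved
#' implicitly, `Vm' = (Vm + tau*(gl_bar*El + ge*ge_bar*Ee + gi*gi_bar*Ei)) /
#' (1 + tau*(gl_bar + ge*ge_bar + gi*gi_bar))`. This has the same fixed
#' point as the forward form (see [vm_fixed_point()]) and agrees with it to
#' first order in `tau`, but remains stable for arbitrarily large total
#' conductance - which matters here because contextual suppression
#' multiplies `gi_bar` by 5 and learned mossy-fiber drives can push the
#' shunting conductance well past the forward-Euler stability bound
#' `tau * g_total < 2`.
#'
#' @param vm membrane potential vector.
#' @param ge net excitatory drive (vector, per cell).
#' @param gi shared inhibitory drive (scalar).
#' @param p a [layer_params()] object.
#' @return updated membrane potential vector.
#' @export
step_vm <- function(vm, ge, gi, p) {
  if (!all(is.finite(ge)) || !all(is.finite(gi)))
    stop("non-finite conductances in step_vm()")
  num <- p$gl_bar * p$El + ge * p$ge_bar * p$Ee + gi * p$gi_bar * p$Ei
  den <- p$gl_bar + ge * p$ge_bar + gi * p$gi_bar
  (vm + p$tau * num) / (1 + p$tau * den)
}

#' Closed-form membrane equilibrium under constant conductances
#'
#' @inheritParams step_vm
#' @return the fixed point of the shunting equation, per cell.
#' @export
vm_fixed_point <- function(ge, gi, p) {
  num <- p$gl_bar * p$El + ge * p$ge_bar * p$Ee + gi * p$gi_bar * p$Ei
  den <- p$gl_bar + ge * p$ge_bar + gi * p$gi_bar
  num / den
}

#' Net excitatory drive from a set of incoming projections
#'
#' For each projection j with relative weight `r_j` and absolute scale `a_j`,
#' the raw drive onto receiving cell i is the summed `x_h * w_ih` over the
#' connections cell i actually receives, divided by
#' `n_connections_i * alpha_j`, where `alpha_j` is the expected activity of
#' the sending layer (its kWTA fraction). With `alpha = 1` this is a plain
#' average over received connections; supplying the sender's expected
#' activity keeps sparse, potent pathways (mossy fibers, CA3 recurrents) on
#' the same conductance scale as dense ones. Contributions are then combined
#' as `sum_j (r_j / sum_k r_k) * a_j * gate_j * drive_j`.
#'
#' @param inputs a list; each element is a list with fields `x` (sender
#'   activity vector), `w` (weight matrix, receivers in rows, senders in
#'   columns), and optionally `mask` (binary connectivity, defaults to all
#'   ones), `r` (relative weight, default 1), `a` (absolute scale, default
#'   1), `alpha` (expected sender activity, default 1), `gate`
#'   (multiplicative phase gate, default 1).
#' @return `ge` vector over receiving cells.
#' @export
net_excitation <- function(inputs) {
  stopifnot(length(inputs) >= 1)
  rs <- vapply(inputs, function(z) if (is.null(z[["r"]])) 1 else z[["r"]],
               numeric(1))
  r_sum <- sum(rs)
  if (r_sum == 0) stop("sum of relative weights is zero")
  ge <- NULL
  for (j in seq_along(inputs)) {
    z <- inputs[[j]]
    w <- z[["w"]]
    if (length(z[["x"]]) != ncol(w))
      stop("sender activity length does not match weight matrix columns")
    mask <- if (is.null(z[["mask"]])) matrix(1, nrow(w), ncol(w)) else z[["mask"]]
    a <- if (is.null(z[["a"]])) 1 else z[["a"]]
    alpha <- if (is.null(z[["alpha"]])) 1 else z[["alpha"]]
    gate <- if (is.null(z[["gate"]])) 1 else z[["gate"]]
    n_conn <- rowSums(mask)
    raw <- as.numeric((w * mask) %*% z[["x"]])
    denom <- pmax(n_conn, 1) * alpha
    contrib <- (rs[j] / r_sum) * a * gate * raw / denom
    ge <- if (is.null(ge)) contrib else ge + contrib
  }
  ge
}

#' Per-cell threshold inhibition
#'
#' The shared inhibitory drive at which a cell with excitatory drive `ge_i`
#' (and unit inhibitory conductance) would sit exactly at the activation
#' threshold: `g_theta = (ge_i*ge_bar*(Ee-theta) + gl_bar*(El-theta)) /
#' (theta - Ei)`.
#'
#' @param ge_i excitatory drive (scalar or vector).
#' @param p a [layer_params()] object.
#' @return threshold inhibition, same shape as `ge_i`.
#' @export
kwta_threshold <- function(ge_i, p) {
  if (p$theta == p$Ei) stop("theta equals Ei: threshold inhibition undefined")
  (ge_i * p$ge_bar * (p$Ee - p$theta) + p$gl_bar * (p$El - p$theta)) /
    (p$theta - p$Ei)
}

#' Layer-wide kWTA inhibition
#'
#' Computes the shared inhibitory drive `gi` so that only the top-k driven
#' cells can cross threshold: `gi = s(k+1) + q * (s(k) - s(k+1))`, where
#' `s_i = g_theta(ge_i) / gi_bar_i` is the inhibition level at which cell i
#' reaches threshold given its own inhibitory conductance, and `s(k)` is the
#' k-th largest support. With homogeneous `gi_bar` this is the textbook kWTA
#' rule on `g_theta`; per-cell `gi_bar` lets contextual suppression compete
#' within a single layer-wide pool. The result is floored at 0.
#'
#' @param ge excitatory drive vector for the whole layer.
#' @param p a [layer_params()] object (uses `k`, `q`, `gi_bar`).
#' @return scalar `gi`.
#' @export
kwta_layer <- function(ge, p) {
  n <- length(ge)
  k <- p$k
  if (n < k + 1) stop("layer smaller than k+1: kWTA undefined")
  s <- kwta_threshold(ge, p) / p$gi_bar
  srt <- sort(s, decreasing = TRUE, method = "quick")
  gi <- srt[k + 1] + p$q * (srt[k] - srt[k + 1])
  max(gi, 0)
}

#' Settle a single layer under constant inputs
#'
#' Iterates net excitation -> kWTA inhibition -> Euler membrane step ->
#' activation for `n_steps` steps. A clamped layer bypasses the dynamics and
#' returns the clamp values. This is the single-layer reference
#' implementation; the assembled circuit uses the same arithmetic in
#' compiled form (see [run_trial()]).
#'
#' @param state list with `vm` (membrane potentials) and optionally
#'   `clamp` (activity vector; if non-NULL the layer is clamped).
#' @param p a [layer_params()] object.
#' @param inputs as in [net_excitation()]; sender activities are held fixed.
#' @param n_steps number of 1-ms steps (default 30, one theta half-phase).
#' @return list with `vm`, `y`, `ge`, `gi` at the final step.
#' @export
settle <- function(state, p, inputs, n_steps = 30) {
  stopifnot(n_steps >= 1)
  if (!is.null(state$clamp)) {
    return(list(vm = state$vm, y = state$clamp, ge = rep(0, p$n), gi = 0))
  }
  vm <- state$vm
  ge <- rep(0, p$n)
  gi <- 0
  for (s in seq_len(n_steps)) {
    ge <- net_excitation(inputs)
    gi <- kwta_layer(ge, p)
    vm <- step_vm(vm, ge, gi, p)
  }
  list(vm = vm, y = activation(vm, p$gamma, p$theta), ge = ge, gi = gi)
}
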