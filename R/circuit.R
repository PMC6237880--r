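#' Network configuration
#'
#' Assembles the default architecture: superficial and deep lateral
#' entorhinal layers (ECin, ECout) of three 24-cell fields each (odor X,
#' odor Y, reward R), a dentate gyrus partitioned into equal contextual
#' ensembles, and recurrent CA3 and CA1. Pathways, connection
#' probabilities, learning mixes and conductance scales follow the model's
#' connectivity table: perforant path ECin->{DG, CA3, CA1} at p = 25%
#' (CA1 branch mostly error-driven, k_hebb = 0.05), mossy fibers DG->CA3 at
#' p = 4% with (absolute, relative) scale (10, 3.5), full Schaffer
#' collaterals CA3->CA1 with scale (5, 1), full CA3 recurrents, full
#' CA1->ECout with relative weight 2, and a one-to-one ECout->ECin
#' intracortical return.
#'
#' @param field_size cells per entorhinal field (one odor grid).
#' @param dg_ensembles number of contextual DG ensembles.
#' @param dg_ensemble_size granule cells per ensemble.
#' @param ca3_size,ca1_size subfield sizes.
#' @param lec_kwta,dg_kwta,ca_kwta kWTA fractions per region.
#' @param gi_bar_normal,gi_bar_suppressed inhibitory conductance of DG cells
#'   inside / outside the facilitated ensemble.
#' @param tau integration rate per 1-ms step.
#' @param phase_steps settling steps for the three theta phases.
#' @param eps_hebb,eps_err learning rates for the fully Hebbian
#'   (k_hebb = 1) and the mostly error-driven (k_hebb = 0.05) pathways.
#' @param wt_sig_gain,wt_sig_off contrast-enhancement sigmoid applied to
#'   weights in the forward pass (see [wt_sig()]); `gain = 1, off = 1`
#'   disables it.
#' @param contexts context labels; length must equal `dg_ensembles`.
#' @param gate_scheme which pathways the theta phases suppress:
#'   `"ca1_input"` (default) gates CA3->CA1 off in the first minus half and
#'   the plus phase and ECin->CA1 off in the second minus half, so recall is
#'   CA3-driven exactly when the trisynaptic pathway owns CA1;
#'   `"full_trisynaptic"` additionally silences ECin->DG, ECin->CA3, DG->CA3
#'   and CA3->CA3 outside the second minus half (kept for comparison; it
#'   prevents plus-phase Hebbian learning on the trisynaptic pathways).
#' @return A list of class `hippo_config`.
#' @export
network_config <- function(field_size = 24, dg_ensembles = 4,
                           dg_ensemble_size = 400, ca3_size = 240,
                           ca1_size = 400, lec_kwta = 0.25, dg_kwta = 0.01,
                           ca_kwta = 0.025, gi_bar_normal = 1,
                           gi_bar_suppressed = 5, tau = 0.3,
                           phase_steps = c(30, 30, 30),
                           eps_hebb = 0.7, eps_err = 0.3,
                           wt_sig_gain = 6, wt_sig_off = 4,
                           contexts = c("A", "B", "C", "D"),
                           gate_scheme = c("ca1_input", "full_trisynaptic")) {
  stopifnot(length(contexts) == dg_ensembles, field_size >= 1,
            length(phase_steps) == 3)
  gate_scheme <- match.arg(gate_scheme)
  lec_size <- 3L * field_size
  pathways <- list(
    list(name = "ECin_DG",   from = "ecin", to = "dg",   type = "prob",
         p = 0.25, k_hebb = 1,    a = 1,  r = 1,   contrast = FALSE),
    list(name = "ECin_CA3",  from = "ecin", to = "ca3",  type = "prob",
         p = 0.25, k_hebb = 1,    a = 1,  r = 1,   contrast = FALSE),
    list(name = "ECin_CA1",  from = "ecin", to = "ca1",  type = "prob",
         p = 0.25, k_hebb = 0.05, a = 1,  r = 1,   contrast = FALSE),
    list(name = "DG_CA3",    from = "dg",   to = "ca3",  type = "prob",
         p = 0.04, k_hebb = 1,    a = 10, r = 3.5, contrast = FALSE),
    list(name = "CA3_CA3",   from = "ca3",  to = "ca3",  type = "full",
         p = 1,    k_hebb = 1,    a = 4,  r = 1,   contrast = TRUE),
    list(name = "CA3_CA1",   from = "ca3",  to = "ca1",  type = "full",
         p = 1,    k_hebb = 1,    a = 5,  r = 1,   contrast = FALSE),
    list(name = "CA1_ECout", from = "ca1",  to = "ecout", type = "full",
         p = 1,    k_hebb = 0.05, a = 1,  r = 2,   contrast = FALSE),
    list(name = "ECout_ECin", from = "ecout", to = "ecin", type = "one_to_one",
         p = 1,    k_hebb = 0.05, a = 1,  r = 1,   contrast = FALSE)
  )
  structure(list(
    field_size = as.integer(field_size), lec_size = lec_size,
    dg_ensembles = as.integer(dg_ensembles),
    dg_ensemble_size = as.integer(dg_ensemble_size),
    dg_size = as.integer(dg_ensembles * dg_ensemble_size),
    ca3_size = as.integer(ca3_size), ca1_size = as.integer(ca1_size),
    lec_kwta = lec_kwta, dg_kwta = dg_kwta, ca_kwta = ca_kwta,
    gi_bar_normal = gi_bar_normal, gi_bar_suppressed = gi_bar_suppressed,
    tau = tau, phase_steps = as.integer(phase_steps),
    eps_hebb = eps_hebb, eps_err = eps_err,
    wt_sig_gain = wt_sig_gain, wt_sig_off = wt_sig_off,
    contexts = contexts, gate_scheme = gate_scheme,
    pathways = pathways
  ), class = "hippo_config")
}

layer_order <- c("ecin", "dg", "ca3", "ca1", "ecout")

kernel_layer <- function(p, clamped = FALSE, reset_each_phase = FALSE) {
  list(n = p$n, k = p$k, gl_bar = p$gl_bar, ge_bar = p$ge_bar,
       gi_bar = p$gi_bar, El = p$El, Ee = p$Ee, Ei = p$Ei,
       gamma = p$gamma, theta = p$theta, q = p$q, tau = p$tau,
       Vrest = p$Vrest, clamped = clamped, reset_each_phase = reset_each_phase)
}

make_mask <- function(n_to, n_from, type, p) {
  switch(type,
    prob = {
      stopifnot(p >= 0, p <= 1)
      matrix(stats::rbinom(n_to * n_from, 1L, p), n_to, n_from)
    },
    full = matrix(1, n_to, n_from),
    one_to_one = {
      if (n_to != n_from)
        stop("one-to-one connectivity requires equal layer sizes")
      diag(n_to)
    },
    stop("unknown connectivity type: ", type))
}

default_gates <- function(cfg) {
  np <- length(cfg$pathways)
  g <- matrix(1, np, 3,
              dimnames = list(vapply(cfg$pathways, `[[`, "", "name"), NULL))
  g["CA3_CA1", 1] <- 0   # first minus half: CA1 decoupled from CA3
  g["ECin_CA1", 2] <- 0  # recall: trisynaptic pathway owns CA1
  # plus phase: CA1 gets both streams, so its encoding representation is
  # conjunctive (cue and hippocampal context), not a pure EC auto-encoding
  if (cfg$gate_scheme == "full_trisynaptic") {
    g[c("ECin_DG", "ECin_CA3", "DG_CA3", "CA3_CA3"), c(1, 3)] <- 0
  }
  g
}

#' Build the entorhinal-hippocampal network
#'
#' Samples connectivity masks at the configured probabilities, initializes
#' all present weights uniform on `[0.25, 0.75]` via [init_weights()], and
#' returns a mutable network object (an environment): [run_trial()] updates
#' its weights in place, which is what lets a simulated rat carry its
#' synaptic state across trials without copying megabytes per trial.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed; identical seeds give identical masks and
#'   weights. If `NULL`, the current RNG state is used.
#' @return An environment of class `hippo_network`.
#' @export
build_network <- function(cfg = network_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- c(ecin = cfg$lec_size, dg = cfg$dg_size, ca3 = cfg$ca3_size,
             ca1 = cfg$ca1_size, ecout = cfg$lec_size)
  fracs <- c(ecin = cfg$lec_kwta, dg = cfg$dg_kwta, ca3 = cfg$ca_kwta,
             ca1 = cfg$ca_kwta, ecout = cfg$lec_kwta)
  params <- lapply(layer_order, function(nm)
    layer_params(sizes[[nm]], fracs[[nm]], tau = cfg$tau))
  names(params) <- layer_order
  layers <- list(
    ecin  = kernel_layer(params$ecin, clamped = TRUE),
    dg    = kernel_layer(params$dg),
    ca3   = kernel_layer(params$ca3),
    ca1   = kernel_layer(params$ca1, reset_each_phase = TRUE),
    ecout = kernel_layer(params$ecout, reset_each_phase = TRUE)
  )
  projections <- lapply(cfg$pathways, function(pw) {
    n_to <- sizes[[pw$to]]; n_from <- sizes[[pw$from]]
    mask <- make_mask(n_to, n_from, pw$type, pw$p)
    w <- init_weights(mask)
    alpha <- fracs[[pw$from]]
    list(name = pw$name,
         from = match(pw$from, layer_order), to = match(pw$to, layer_order),
         w = w,
         w_eff = if (isTRUE(pw$contrast))
           wt_sig(w, cfg$wt_sig_gain,
                  if (!is.null(pw$sig_off)) pw$sig_off else cfg$wt_sig_off) *
           mask else w,
         mask = mask * 1,
         denom = pmax(rowSums(mask), 1) * alpha,
         r = pw$r, a = pw$a, k_hebb = pw$k_hebb,
         sig_gain = if (isTRUE(pw$contrast)) cfg$wt_sig_gain else 1,
         sig_off = if (!isTRUE(pw$contrast)) 1
                   else if (!is.null(pw$sig_off)) pw$sig_off
                   else cfg$wt_sig_off,
         epsilon = if (pw$k_hebb < 1) cfg$eps_err else cfg$eps_hebb,
         minus_phase = if (pw$name %in%
                           c("ECin_CA1", "CA1_ECout", "ECout_ECin")) 1L else 2L)
  })
  names(projections) <- vapply(projections, `[[`, "", "name")
  incoming <- lapply(seq_along(layer_order), function(l)
    which(vapply(projections, function(pr) pr$to == l, logical(1))))
  r_sum <- vapply(seq_along(layer_order), function(l) {
    inc <- incoming[[l]]
    if (length(inc) == 0) 1 else sum(vapply(projections[inc], `[[`, 0, "r"))
  }, numeric(1))

  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$layers <- layers
  net$projections <- projections
  net$incoming <- incoming
  net$r_sum <- r_sum
  net$gates <- default_gates(cfg)
  net$mode <- "normal"
  net$active_context <- NA_character_
  net$mossy_lesion <- FALSE
  class(net) <- "hippo_network"
  net
}

dg_ensemble_ids <- function(cfg) {
  rep(cfg$contexts, each = cfg$dg_ensemble_size)
}

#' Select the contextual DG ensemble (normal PFC operation)
#'
#' Raises the maximal inhibitory conductance of every granule cell outside
#' the named ensemble to the suppressed level, and restores the normal level
#' inside it. Weights are untouched.
#'
#' @param net a `hippo_network`.
#' @param context_id one of the configured context labels.
#' @return the network, invisibly (modified in place).
#' @export
set_context <- function(net, context_id) {
  cfg <- net$cfg
  if (!context_id %in% cfg$contexts)
    stop("unknown context id: ", context_id)
  ids <- dg_ensemble_ids(cfg)
  net$layers$dg$gi_bar <- ifelse(ids == context_id,
                                 cfg$gi_bar_normal, cfg$gi_bar_suppressed)
  net$mode <- "normal"
  net$active_context <- context_id
  invisible(net)
}

#' Remove the top-down contextual bias (PFC inactivation)
#'
#' All DG cells return to the normal excitability level, so every contextual
#' ensemble can compete for the layer's kWTA slots.
#'
#' @param net a `hippo_network`.
#' @return the network, invisibly (modified in place).
#' @export
set_pfc_inactivated <- function(net) {
  net$layers$dg$gi_bar <- rep(net$cfg$gi_bar_normal, net$cfg$dg_size)
  net$mode <- "pfc_inactivated"
  invisible(net)
}

#' Lesion the mossy fibers
#'
#' Gates the DG->CA3 projection off in every phase, removing the dentate
#' bias on CA3 attractor selection while leaving all other pathways intact.
#'
#' @param net a `hippo_network`.
#' @param lesioned logical; `FALSE` restores the pathway.
#' @return the network, invisibly (modified in place).
#' @export
set_mossy_lesion <- function(net, lesioned = TRUE) {
  net$mossy_lesion <- isTRUE(lesioned)
  invisible(net)
}

#' Run one trial through the theta phases
#'
#' An encoding trial runs the three phases in sequence (first minus half,
#' second minus half, plus), each settling for the configured number of
#' steps. ECin is clamped to the upstream cortical cue (the two odor fields)
#' during the minus half-phases; the reward field is missing there and must
#' be pattern-completed. Only in the plus phase - when the outcome is
#' revealed - does ECin carry the full pattern and ECout get clamped to the
#' target. CA1 membrane potentials
#' are reset to rest at the start of each phase; all other layers reset at
#' trial start. The recalled reward pattern is the third ECout field at the
#' end of the second minus half, when CA3 pattern completion owns CA1. If
#' `learn` is `TRUE` (encoding mode only), all pathways are updated at the
#' end of the plus phase. A test trial zeroes the reward field at ECin, runs
#' only the two minus half-phases, and never learns.
#'
#' @param net a `hippo_network` with its context state set (normal mode
#'   requires [set_context()] first).
#' @param x_code,y_code binary odor codes for the two ECin odor fields.
#' @param r_code binary code of the rewarded odor (ignored in test mode).
#' @param mode `"encode"` or `"test"`.
#' @param learn apply plasticity at the end of the plus phase.
#' @return list with `r_out` (recalled reward-field activities), `dg_active`
#'   (number of active DG cells during recall), `dg_active_ids` (their
#'   indices) and `snapshots` (per-phase, per-layer activity vectors).
#' @export
run_trial <- function(net, x_code, y_code, r_code = NULL,
                      mode = c("encode", "test"), learn = TRUE) {
  mode <- match.arg(mode)
  cfg <- net$cfg
  if (net$mode == "normal" && is.na(net$active_context))
    stop("context not set; call set_context() or set_pfc_inactivated()")
  stopifnot(length(x_code) == cfg$field_size,
            length(y_code) == cfg$field_size)
  zero <- numeric(cfg$field_size)
  ecin_minus <- c(x_code, y_code, zero)
  if (mode == "encode") {
    if (is.null(r_code)) stop("encoding trials need the rewarded-odor code")
    ecin_plus <- c(x_code, y_code, r_code)
    ecout_clamp <- ecin_plus
    steps <- cfg$phase_steps
  } else {
    ecin_plus <- NULL
    ecout_clamp <- NULL
    steps <- cfg$phase_steps[1:2]
    learn <- FALSE
  }
  gates <- net$gates[, seq_along(steps), drop = FALSE]
  if (net$mossy_lesion) gates["DG_CA3", ] <- 0
  res <- trial_kernel_cpp(net$layers, net$projections, net$r_sum,
                          net$incoming, steps, gates,
                          as.numeric(ecin_minus), ecin_plus, ecout_clamp,
                          isTRUE(learn), 1L, 5L)
  snaps <- res$snapshots
  recall <- snaps[[2]]
  r_field <- (2 * cfg$field_size + 1):(3 * cfg$field_size)
  dg_y <- recall[[2]]
  list(r_out = recall[[5]][r_field],
       dg_active = sum(dg_y > 0),
       dg_active_ids = which(dg_y > 0),
       snapshots = snaps)
}

#' @export
print.hippo_network <- function(x, ...) {
  cfg <- x$cfg
  cat("<hippo_network>\n")
  cat(sprintf("  ECin/ECout: %d cells (3 x %d), DG: %d (%d x %d), CA3: %d, CA1: %d\n",
              cfg$lec_size, cfg$field_size, cfg$dg_size, cfg$dg_ensembles,
              cfg$dg_ensemble_size, cfg$ca3_size, cfg$ca1_size))
  cat(sprintf("  mode: %s%s%s\n", x$mode,
              if (x$mode == "normal") paste0(" (context ", x$active_context, ")") else "",
              if (x$mossy_lesion) ", mossy fibers lesioned" else ""))
  invisible(x)
}

#' Save / load network weights
#'
#' Serializes every pathway's weight matrix and mask (plus the context
#' state) to JSON keyed by pathway name, so a trained simulated rat can be
#' archived and restored as plain text.
#'
#' @param net a `hippo_network`.
#' @param path file path.
#' @return `save_weights` returns `path` invisibly; `load_weights` returns
#'   the network invisibly after overwriting its weights in place.
#' @export
save_weights <- function(net, path) {
  out <- list(
    mode = net$mode, active_context = net$active_context,
    pathways = lapply(net$projections, function(pr)
      list(w = pr$w, mask = pr$mask, denom = pr$denom))
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(net, path) {
  blob <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(net$projections)) {
    w <- blob$pathways[[nm]]$w
    stopifnot(!is.null(w),
              all(dim(w) == dim(net$projections[[nm]]$w)))
    w <- matrix(as.numeric(w), nrow(w), ncol(w))
    mask <- blob$pathways[[nm]]$mask
    mask <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
    pr <- net$projections[[nm]]
    pr$w <- w
    pr$mask <- mask
    pr$denom <- as.numeric(blob$pathways[[nm]]$denom)
    pr$w_eff <- if (pr$sig_gain != 1 || pr$sig_off != 1)
      wt_sig(w, pr$sig_gain, pr$sig_off) * mask else w
    net$projections[[nm]] <- pr
  }
  net$mode <- blob$mode
  net$active_context <- blob$active_context
  invisible(net)
}
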