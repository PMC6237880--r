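#' Retrieval performance from recall error
#'
#' Maps the root-mean-squared error `E` between the recalled and target
#' reward patterns to a percent-correct scale:
#' `P = max(50, 100 * (1-E)^10 / (0.5^10 + (1-E)^10))`.
#' The sharpening exponent makes the metric saturate near 100% for accurate
#' recall and fall off steeply past `E = 0.5`; the floor encodes that a rat
#' choosing between two odors cannot do worse than chance (50%). `P` is
#' monotone nonincreasing in `E` and lies in `[50, 100)`.
#'
#' @param E RMSE in `[0, 1]`.
#' @return performance in percent, same length as `E`.
#' @export
performance_from_rmse <- function(E) {
  if (any(E < 0 | E > 1)) stop("E must lie in [0, 1]")
  raw <- 100 * (1 - E)^10 / (0.5^10 + (1 - E)^10)
  pmax(50, raw)
}

#' Root-mean-squared error between recalled and target patterns
#'
#' @param r_out recalled activity vector (values in `[0, 1]`).
#' @param r_targ binary target pattern, same length.
#' @return scalar RMSE in `[0, 1]` for inputs in `[0, 1]`.
#' @export
rmse_pattern <- function(r_out, r_targ) {
  if (length(r_out) != length(r_targ)) stop("pattern length mismatch")
  sqrt(mean((r_out - r_targ)^2))
}

#' Discrete odor choice from the recalled reward pattern
#'
#' Returns the index (1 or 2) of the pair member whose code is closer (in
#' RMSE) to the recalled pattern; exact ties are broken uniformly at random
#' from the current RNG stream.
#'
#' @param r_out recalled reward-field activities.
#' @param code_a,code_b the two odor codes.
#' @return 1L or 2L.
#' @export
choose_odor <- function(r_out, code_a, code_b) {
  ea <- rmse_pattern(r_out, code_a)
  eb <- rmse_pattern(r_out, code_b)
  if (ea < eb) 1L else if (eb < ea) 2L else sample(c(1L, 2L), 1)
}

#' Classify an incorrect list-2 choice
#'
#' During acquisition of a conflicting list, an error is *perseverative*
#' when the chosen odor was rewarded under the old list and is unrewarded
#' under the new one, and *non-perseverative* when the novel odor is chosen
#' in a problem whose retained odor was unrewarded under the old list.
#'
#' @param problem2 the list-2 problem (see [make_experiment_stimuli()]).
#' @param problem1 its list-1 counterpart.
#' @param choice index (1 or 2) of the chosen odor within `problem2`.
#' @return `"perseverative"` or `"non_perseverative"`.
#' @export
classify_error <- function(problem2, problem1, choice) {
  chosen <- if (choice == 1L) problem2$a else problem2$b
  rewarded2 <- if (problem2$rewarded == 1L) problem2$a else problem2$b
  if (chosen == rewarded2) stop("classify_error() called on a correct trial")
  labs1 <- c(problem1$a, problem1$b)
  retained <- intersect(c(problem2$a, problem2$b), labs1)
  stopifnot(length(retained) == 1)
  rewarded1 <- labs1[problem1$rewarded]
  if (retained == rewarded1) "perseverative" else "non_perseverative"
}

# --- trial bookkeeping -------------------------------------------------------

new_recorder <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- vector("list", 1024L)
  e$n <- 0L
  e
}

record_trial <- function(rec, row) {
  n <- rec$n + 1L
  if (n > length(rec$rows)) rec$rows <- c(rec$rows, vector("list", length(rec$rows)))
  rec$rows[[n]] <- row
  rec$n <- n
  invisible(rec)
}

recorder_df <- function(rec) {
  rows <- rec$rows[seq_len(rec$n)]
  col <- function(nm) unlist(lapply(rows, `[[`, nm), use.names = FALSE)
  data.frame(rat = col("rat"), group = col("group"), phase = col("phase"),
             context = col("context"), block = col("block"),
             problem = col("problem"), mode = col("mode"),
             E = col("E"), P = col("P"), choice = col("choice"),
             correct = col("correct"), error_type = col("error_type"),
             dg_active = col("dg_active"), stringsAsFactors = FALSE)
}

run_one_trial <- function(net, stim, prob, mode, learn = TRUE) {
  code_a <- stim$codes[[prob$a]]
  code_b <- stim$codes[[prob$b]]
  r_code <- if (prob$rewarded == 1L) code_a else code_b
  res <- run_trial(net, code_a, code_b,
                   r_code = if (mode == "encode") r_code else NULL,
                   mode = mode, learn = learn)
  E <- min(rmse_pattern(res$r_out, r_code), 1)
  choice <- choose_odor(res$r_out, code_a, code_b)
  list(E = E, P = performance_from_rmse(E), choice = choice,
       correct = choice == prob$rewarded, dg_active = res$dg_active,
       dg_active_ids = res$dg_active_ids)
}

run_block_trials <- function(net, stim, problems, rec, rat, group, phase,
                             mode, block, list1_map = NULL) {
  ord <- block_order(problems)
  ps <- numeric(length(ord))
  for (j in seq_along(ord)) {
    i <- ord[j]
    tr <- run_one_trial(net, stim, problems[[i]], mode = mode)
    etype <- NA_character_
    if (!tr$correct && !is.null(list1_map))
      etype <- classify_error(problems[[i]], list1_map[[i]], tr$choice)
    ctx <- if (net$mode == "normal") net$active_context else "inactivated"
    record_trial(rec, list(rat = rat, group = group, phase = phase,
                           context = ctx, block = block, problem = i,
                           mode = mode, E = tr$E, P = tr$P,
                           choice = tr$choice, correct = tr$correct,
                           error_type = etype, dg_active = tr$dg_active))
    ps[j] <- tr$P
  }
  mean(ps)
}

#' Criterion block from a block-accuracy curve
#'
#' The training criterion is met on the first block that completes
#' `n_consecutive` consecutive blocks at or above `criterion` percent;
#' e.g. accuracies `c(85, 92, 95)` meet a 90%-twice criterion at block 3,
#' and `c(92, 85, 92, 95)` at block 4.
#'
#' @param block_P vector of block mean performances.
#' @param criterion threshold in percent.
#' @param n_consecutive required run length.
#' @return the criterion block index, or `NA` if never met.
#' @export
criterion_from_curve <- function(block_P, criterion = 90, n_consecutive = 2) {
  streak <- 0L
  for (b in seq_along(block_P)) {
    streak <- if (block_P[b] >= criterion) streak + 1L else 0L
    if (streak >= n_consecutive) return(b)
  }
  NA_integer_
}

#' Train a list to criterion
#'
#' Runs encoding blocks (one presentation of every problem per block, fresh
#' random order each block) until mean block performance reaches the
#' criterion in two consecutive blocks, or the block cap is hit. The
#' inactivation schedule lists the block numbers run with the PFC bias
#' removed; all other blocks run under [set_context()].
#'
#' @param net,stim a built network and its stimulus set.
#' @param problems the problem list to train.
#' @param context context label for non-inactivated blocks.
#' @param rec a recorder (internal); pass `NULL` to create one.
#' @param rat,group,phase record labels.
#' @param inactivated_blocks integer vector of blocks run under inactivation.
#' @param criterion,n_consecutive criterion rule (default 90% in two
#'   consecutive blocks).
#' @param max_blocks cap; on non-convergence `criterion_block` is `NA`.
#' @param n_blocks if non-`NULL`, run exactly this many blocks and ignore
#'   the criterion rule.
#' @param list1_map optional list of prior-list counterparts (same indexing
#'   as `problems`) used to classify incorrect choices.
#' @return list with `criterion_block`, `n_blocks_run`, `block_P` and (when
#'   `rec` was `NULL`) `trials`.
#' @export
run_to_criterion <- function(net, stim, problems, context, rec = NULL,
                             rat = 1L, group = "saline", phase = "train",
                             inactivated_blocks = integer(0),
                             criterion = 90, n_consecutive = 2,
                             max_blocks = 50, n_blocks = NULL,
                             list1_map = NULL) {
  own_rec <- is.null(rec)
  if (own_rec) rec <- new_recorder()
  total <- if (is.null(n_blocks)) max_blocks else n_blocks
  block_P <- numeric(0)
  cr <- NA_integer_
  for (b in seq_len(total)) {
    if (b %in% inactivated_blocks) set_pfc_inactivated(net)
    else set_context(net, context)
    bp <- run_block_trials(net, stim, problems, rec, rat, group, phase,
                           mode = "encode", block = b, list1_map = list1_map)
    block_P <- c(block_P, bp)
    if (is.null(n_blocks)) {
      cr <- criterion_from_curve(block_P, criterion, n_consecutive)
      if (!is.na(cr)) break
    }
  }
  out <- list(criterion_block = cr, n_blocks_run = length(block_P),
              block_P = block_P)
  if (own_rec) out$trials <- recorder_df(rec)
  out
}

pretrain_rat <- function(net, stim, rec, rat, group, n_blocks = 10) {
  for (spec in list(list(ctx = "C", problems = stim$pretrain_C),
                    list(ctx = "D", problems = stim$pretrain_D))) {
    set_context(net, spec$ctx)
    for (b in seq_len(n_blocks)) {
      run_block_trials(net, stim, spec$problems, rec, rat, group,
                       phase = paste0("pretrain_", spec$ctx),
                       mode = "encode", block = b)
    }
  }
  invisible(net)
}

rat_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2^30, n)
}

new_rat <- function(rat_seed, cfg, rec, rat, group,
                    pretraining = TRUE, pretrain_blocks = 10) {
  set.seed(rat_seed)
  stim <- make_experiment_stimuli(field_size = cfg$field_size)
  net <- build_network(cfg)
  if (pretraining) pretrain_rat(net, stim, rec, rat, group, pretrain_blocks)
  list(net = net, stim = stim)
}

# --- experiment protocols ----------------------------------------------------

#' Context-guided retrieval with and without PFC inactivation
#'
#' Each simulated rat learns a list of odor discriminations in context A to
#' criterion, then the same pairs with reversed reward in context B to
#' criterion, and is finally given test blocks (reward cue absent, learning
#' off) in each context under the control condition (context bias applied)
#' and under inactivation (bias removed). Lifetime pre-training on
#' interfering lists in contexts C and D precedes the experiment.
#'
#' @param n_rats simulated rats (within-subject design).
#' @param cfg a [network_config()].
#' @param seed master seed.
#' @param pretraining include the contexts C/D pre-training phase.
#' @param pretrain_blocks blocks per pre-training list.
#' @param n_test_blocks test blocks per context per condition.
#' @param mossy_lesion lesion DG->CA3 for the whole experiment (prediction
#'   variant).
#' @param max_blocks training-block cap.
#' @return list of class `hippo_experiment` with `trials` (one row per
#'   trial) and `rats` (per-rat criterion blocks).
#' @export
run_navawongse <- function(n_rats = 10, cfg = network_config(), seed = 1,
                           pretraining = TRUE, pretrain_blocks = 10,
                           n_test_blocks = 2, mossy_lesion = FALSE,
                           max_blocks = 50) {
  seeds <- rat_seeds(seed, n_rats)
  rec <- new_recorder()
  rats <- vector("list", n_rats)
  for (r in seq_len(n_rats)) {
    st <- new_rat(seeds[r], cfg, rec, r, "within", pretraining, pretrain_blocks)
    if (mossy_lesion) set_mossy_lesion(st$net)
    tr_a <- run_to_criterion(st$net, st$stim, st$stim$list1, "A", rec,
                             r, "within", "list1", max_blocks = max_blocks)
    tr_b <- run_to_criterion(st$net, st$stim, st$stim$list1_reversed, "B", rec,
                             r, "within", "list1_reversed",
                             max_blocks = max_blocks)
    for (cond in c("saline", "muscimol")) {
      for (ctx in c("A", "B")) {
        problems <- if (ctx == "A") st$stim$list1 else st$stim$list1_reversed
        for (b in seq_len(n_test_blocks)) {
          if (cond == "saline") set_context(st$net, ctx)
          else set_pfc_inactivated(st$net)
          run_block_trials(st$net, st$stim, problems, rec, r, cond,
                           phase = paste0("test_", ctx), mode = "test",
                           block = b)
        }
      }
    }
    rats[[r]] <- list(rat = r, cr_A = tr_a$criterion_block,
                      cr_B = tr_b$criterion_block)
  }
  structure(list(experiment = "navawongse", trials = recorder_df(rec),
                 rats = rats), class = "hippo_experiment")
}

#' Concurrent acquisition and performance under PFC inactivation
#'
#' Two groups learn an eight-problem list in context A to criterion. The
#' muscimol group trains with the PFC bias removed during the first three
#' training blocks only; the saline group trains normally throughout. After
#' criterion, four test blocks follow: the saline group is tested under
#' inactivation on test blocks 1-3 and normally on block 4, while the
#' muscimol group is always tested normally.
#'
#' @inheritParams run_navawongse
#' @param n_rats rats per group.
#' @return `hippo_experiment` with `trials` and `rats`.
#' @export
run_p1a <- function(n_rats = 10, cfg = network_config(), seed = 1,
                    pretraining = TRUE, pretrain_blocks = 10,
                    max_blocks = 50) {
  seeds <- rat_seeds(seed, 2 * n_rats)
  rec <- new_recorder()
  rats <- vector("list", 2 * n_rats)
  id <- 0L
  for (group in c("saline", "muscimol")) {
    for (g in seq_len(n_rats)) {
      id <- id + 1L
      st <- new_rat(seeds[id], cfg, rec, id, group, pretraining,
                    pretrain_blocks)
      inact <- if (group == "muscimol") 1:3 else integer(0)
      tr <- run_to_criterion(st$net, st$stim, st$stim$list1, "A", rec,
                             id, group, "list1", inactivated_blocks = inact,
                             max_blocks = max_blocks)
      for (b in 1:4) {
        if (group == "saline" && b <= 3) set_pfc_inactivated(st$net)
        else set_context(st$net, "A")
        run_block_trials(st$net, st$stim, st$stim$list1, rec, id, group,
                         phase = "test", mode = "test", block = b)
      }
      rats[[id]] <- list(rat = id, group = group,
                         cr = tr$criterion_block)
    }
  }
  structure(list(experiment = "p1a", trials = recorder_df(rec), rats = rats),
            class = "hippo_experiment")
}

#' Blocked (one-at-a-time) acquisition under PFC inactivation
#'
#' Each rat learns ten discrimination problems one at a time to criterion,
#' in a random order. A "block" here is a run of consecutive trials of the
#' single problem under acquisition. The muscimol group trains entirely
#' under inactivation; the saline group under the context-A bias.
#'
#' @inheritParams run_p1a
#' @param block_size trials per block for the single problem.
#' @return `hippo_experiment`; `rats` carries per-problem trials-to-criterion.
#' @export
run_p1b <- function(n_rats = 10, cfg = network_config(), seed = 1,
                    pretraining = TRUE, pretrain_blocks = 10,
                    block_size = 4, max_blocks = 50) {
  seeds <- rat_seeds(seed, 2 * n_rats)
  rec <- new_recorder()
  rats <- vector("list", 2 * n_rats)
  id <- 0L
  for (group in c("saline", "muscimol")) {
    for (g in seq_len(n_rats)) {
      id <- id + 1L
      st <- new_rat(seeds[id], cfg, rec, id, group, pretraining,
                    pretrain_blocks)
      order_idx <- sample.int(st$stim$n_blocked)
      ttc <- rep(NA_real_, st$stim$n_blocked)
      for (pi in order_idx) {
        prob <- st$stim$blocked[[pi]]
        streak <- 0L
        for (b in seq_len(max_blocks)) {
          if (group == "muscimol") set_pfc_inactivated(st$net)
          else set_context(st$net, "A")
          reps <- replicate(block_size, {
            tr <- run_one_trial(st$net, st$stim, prob, mode = "encode")
            record_trial(rec, list(rat = id, group = group,
                                   phase = "blocked",
                                   context = if (group == "muscimol")
                                     "inactivated" else "A",
                                   block = b, problem = pi, mode = "encode",
                                   E = tr$E, P = tr$P, choice = tr$choice,
                                   correct = tr$correct,
                                   error_type = NA_character_,
                                   dg_active = tr$dg_active))
            tr$P
          })
          streak <- if (mean(reps) >= 90) streak + 1L else 0L
          if (streak >= 2L) { ttc[pi] <- b * block_size; break }
        }
        if (is.na(ttc[pi])) ttc[pi] <- max_blocks * block_size
      }
      rats[[id]] <- list(rat = id, group = group, trials_to_criterion = ttc)
    }
  }
  structure(list(experiment = "p1b", trials = recorder_df(rec), rats = rats),
            class = "hippo_experiment")
}

#' Conflicting-list acquisition in same vs. different context
#'
#' A 2x2 between-subject design (inactivation x context). All four groups
#' first learn list 1 in context A to criterion under normal operation,
#' then learn the conflicting list 2 for five blocks, either in the same
#' context A or in context B. Muscimol groups have the PFC bias removed for
#' the first three list-2 blocks. Incorrect list-2 choices are classified
#' as perseverative or non-perseverative.
#'
#' @inheritParams run_p1a
#' @param n_rats rats per group (four groups).
#' @param list2_blocks blocks of list-2 training.
#' @return `hippo_experiment`.
#' @export
run_p2 <- function(n_rats = 10, cfg = network_config(), seed = 1,
                   pretraining = TRUE, pretrain_blocks = 10,
                   list2_blocks = 5, max_blocks = 50) {
  groups <- expand.grid(inact = c("saline", "muscimol"),
                        ctx = c("same", "different"),
                        stringsAsFactors = FALSE)
  seeds <- rat_seeds(seed, nrow(groups) * n_rats)
  rec <- new_recorder()
  rats <- vector("list", nrow(groups) * n_rats)
  id <- 0L
  for (gr in seq_len(nrow(groups))) {
    gname <- paste(groups$inact[gr], groups$ctx[gr], sep = "_")
    for (g in seq_len(n_rats)) {
      id <- id + 1L
      st <- new_rat(seeds[id], cfg, rec, id, gname, pretraining,
                    pretrain_blocks)
      tr1 <- run_to_criterion(st$net, st$stim, st$stim$list1, "A", rec,
                              id, gname, "list1", max_blocks = max_blocks)
      ctx2 <- if (groups$ctx[gr] == "same") "A" else "B"
      inact <- if (groups$inact[gr] == "muscimol") 1:3 else integer(0)
      run_to_criterion(st$net, st$stim, st$stim$list2, ctx2, rec,
                       id, gname, "list2", inactivated_blocks = inact,
                       n_blocks = list2_blocks, list1_map = st$stim$list1)
      rats[[id]] <- list(rat = id, group = gname, cr1 = tr1$criterion_block)
    }
  }
  structure(list(experiment = "p2", trials = recorder_df(rec), rats = rats),
            class = "hippo_experiment")
}

#' Facilitation of conflicting-list learning by prior inactivation
#'
#' Both groups learn list 1 in context A for five blocks (the muscimol
#' group with the PFC bias removed on blocks 1-3 only), then both learn the
#' conflicting list 2 in the same context for five blocks under normal
#' operation. The headline effect is the reversal: the muscimol-trained
#' group acquires list 2 *faster* than controls.
#'
#' @inheritParams run_p1a
#' @param list_blocks blocks per list.
#' @param dg_kwta optional override of the DG kWTA fraction (sparseness
#'   sweep prediction).
#' @return `hippo_experiment`.
#' @export
run_p3 <- function(n_rats = 10, cfg = network_config(), seed = 1,
                   pretraining = TRUE, pretrain_blocks = 10,
                   list_blocks = 5, dg_kwta = NULL) {
  if (!is.null(dg_kwta)) {
    cfg$dg_kwta <- dg_kwta
  }
  seeds <- rat_seeds(seed, 2 * n_rats)
  rec <- new_recorder()
  rats <- vector("list", 2 * n_rats)
  id <- 0L
  for (group in c("saline", "muscimol")) {
    for (g in seq_len(n_rats)) {
      id <- id + 1L
      st <- new_rat(seeds[id], cfg, rec, id, group, pretraining,
                    pretrain_blocks)
      inact <- if (group == "muscimol") 1:3 else integer(0)
      run_to_criterion(st$net, st$stim, st$stim$list1, "A", rec,
                       id, group, "list1", inactivated_blocks = inact,
                       n_blocks = list_blocks)
      run_to_criterion(st$net, st$stim, st$stim$list2, "A", rec,
                       id, group, "list2", n_blocks = list_blocks,
                       list1_map = st$stim$list1)
      rats[[id]] <- list(rat = id, group = group)
    }
  }
  structure(list(experiment = "p3", trials = recorder_df(rec), rats = rats),
            class = "hippo_experiment")
}

#' Interference index per rat
#'
#' Mean list-2 performance minus mean list-1 performance over each list's
#' first five training blocks; more negative values mean stronger proactive
#' interference from list 1.
#'
#' @param trials a trial data frame with `phase` in
#'   `c("list1", "list2")`.
#' @param n_blocks blocks entering each mean.
#' @return data frame with one row per rat (`rat`, `group`, `index`).
#' @export
interference_index <- function(trials, n_blocks = 5) {
  rats <- unique(trials$rat)
  out <- lapply(rats, function(r) {
    t1 <- trials[trials$rat == r & trials$phase == "list1" &
                 trials$block <= n_blocks, ]
    t2 <- trials[trials$rat == r & trials$phase == "list2" &
                 trials$block <= n_blocks, ]
    if (nrow(t1) == 0 || nrow(t2) == 0)
      stop("rat ", r, " lacks list-1 or list-2 blocks")
    data.frame(rat = r, group = t1$group[1],
               index = mean(t2$P) - mean(t1$P))
  })
  do.call(rbind, out)
}

#' Dentate activity with and without the contextual bias
#'
#' Runs fresh encoding trials under the context-A bias and under
#' inactivation and tallies active granule cells and their ensemble
#' membership per trial: the model predicts more active DG cells, spread
#' over more ensembles, once the top-down bias is removed.
#'
#' @param n_trials encoding trials per condition.
#' @param cfg a [network_config()].
#' @param seed seed.
#' @param pretraining pre-train contexts C and D first (gives the
#'   out-of-context ensembles tuned responses to the probe odors).
#' @return list with `trials` (one row per trial: `condition`, `dg_active`
#'   cells this trial, `in_ensemble` = active cells within the context-A
#'   ensemble) and `distinct` (named vector: number of distinct granule
#'   cells recruited across the whole session per condition - the
#'   immediate-early-gene analogue; per-trial counts are pinned at k by
#'   the kWTA rule, the session union is not).
#' @export
dg_activity_experiment <- function(n_trials = 20, cfg = network_config(),
                                   seed = 1, pretraining = TRUE) {
  set.seed(seed)
  stim <- make_experiment_stimuli(field_size = cfg$field_size)
  net <- build_network(cfg)
  if (pretraining) pretrain_rat(net, stim, new_recorder(), 1L, "na", 10)
  ids <- dg_ensemble_ids(cfg)
  rows <- list()
  distinct <- c(normal = 0, inactivated = 0)
  for (cond in c("normal", "inactivated")) {
    ever <- integer(0)
    for (t in seq_len(n_trials)) {
      i <- ((t - 1) %% length(stim$list1)) + 1
      if (cond == "normal") set_context(net, "A") else set_pfc_inactivated(net)
      prob <- stim$list1[[i]]
      tr <- run_one_trial(net, stim, prob, mode = "encode", learn = FALSE)
      ever <- union(ever, tr$dg_active_ids)
      rows[[length(rows) + 1]] <-
        data.frame(condition = cond, trial = t, dg_active = tr$dg_active,
                   in_ensemble = sum(ids[tr$dg_active_ids] == "A"))
    }
    distinct[cond] <- length(ever)
  }
  list(trials = do.call(rbind, rows), distinct = distinct)
}

#' Per-block group summaries
#'
#' Mean performance and its standard error per group, phase and block.
#'
#' @param trials a trial data frame.
#' @return data frame with `group`, `phase`, `block`, `mean_P`, `sem_P`,
#'   `n`.
#' @export
summarize_blocks <- function(trials) {
  key <- interaction(trials$group, trials$phase, trials$block, drop = TRUE)
  parts <- split(trials, key)
  out <- lapply(parts, function(d) {
    per_rat <- tapply(d$P, d$rat, mean)
    data.frame(group = d$group[1], phase = d$phase[1], block = d$block[1],
               mean_P = mean(per_rat),
               sem_P = stats::sd(per_rat) / sqrt(length(per_rat)),
               n = length(per_rat))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$phase, out$group, out$block), ]
}

#' Condition-by-block analysis of variance
#'
#' The standard analysis applied to each training window: per-rat,
#' per-block mean performances are submitted to a two-way ANOVA with
#' inactivation condition and training block as factors.
#'
#' @param trials a trial data frame.
#' @param phase which phase to analyze (e.g. `"list1"`).
#' @param blocks block window (default first three).
#' @return the fitted `aov` object.
#' @export
condition_block_anova <- function(trials, phase, blocks = 1:3) {
  d <- trials[trials$phase == phase & trials$block %in% blocks, ]
  agg <- stats::aggregate(P ~ rat + group + block, d, mean)
  agg$group <- factor(agg$group)
  agg$block <- factor(agg$block)
  stats::aov(P ~ group * block, data = agg)
}

#' Test-phase performance drop in the concurrent-acquisition experiment
#'
#' From a [run_p1a()] result: group-mean performance of the muscimol-trained
#' rats (tested normally) minus that of the saline-trained rats (tested
#' under inactivation) across the first three test blocks.
#'
#' @param exp a `hippo_experiment` from [run_p1a()].
#' @return list with `drop` (percentage points), plus the per-group means.
#' @export
p1a_test_drop <- function(exp) {
  te <- exp$trials[exp$trials$phase == "test" & exp$trials$block <= 3, ]
  per_rat <- tapply(te$P, list(te$rat), mean)
  grp <- tapply(te$group, list(te$rat), `[`, 1)
  m_sal <- mean(per_rat[grp == "saline"])
  m_mus <- mean(per_rat[grp == "muscimol"])
  list(drop = m_mus - m_sal, saline_mean = m_sal, muscimol_mean = m_mus,
       per_rat = data.frame(rat = as.integer(names(per_rat)),
                            group = as.character(grp),
                            P = as.numeric(per_rat)))
}

#' Write experiment outputs
#'
#' Dumps the trial log, block summaries and (via JSON) top-level metadata
#' of an experiment run.
#'
#' @param exp a `hippo_experiment`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(exp$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(summarize_blocks(exp$trials),
                   file.path(dir, "blocks.csv"), row.names = FALSE)
  jsonlite::write_json(list(experiment = exp$experiment,
                            n_trials = nrow(exp$trials)),
                       file.path(dir, "summary.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.hippo_experiment <- function(x, ...) {
  cat(sprintf("<hippo_experiment: %s> %d trials, %d rats\n", x$experiment,
              nrow(x$trials), length(unique(x$trials$rat))))
  invisible(x)
}
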