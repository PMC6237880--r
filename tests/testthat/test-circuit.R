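test_that("network construction samples the documented connectivity", {
  cfg <- small_config()
  net <- build_network(cfg, seed = 4)
  # mossy fibers: 4% connection probability within a binomial band
  m <- net$projections$DG_CA3$mask
  phat <- mean(m)
  se <- sqrt(0.04 * 0.96 / length(m))
  expect_lt(abs(phat - 0.04), 4 * se)
  # perforant path 25%
  expect_lt(abs(mean(net$projections$ECin_DG$mask) - 0.25), 0.02)
  # intracortical return is one-to-one
  expect_identical(net$projections$ECout_ECin$mask, diag(72) * 1)
  # full pathways
  expect_true(all(net$projections$CA3_CA1$mask == 1))
  # weights masked and in range
  w <- net$projections$ECin_CA3$w
  expect_true(all(w[net$projections$ECin_CA3$mask == 0] == 0))
  expect_true(all(w[net$projections$ECin_CA3$mask == 1] >= 0.25 &
                  w[net$projections$ECin_CA3$mask == 1] <= 0.75))
  # same seed, identical network
  net2 <- build_network(cfg, seed = 4)
  expect_identical(net$projections$ECin_DG$w, net2$projections$ECin_DG$w)
  expect_identical(net$projections$DG_CA3$mask, net2$projections$DG_CA3$mask)
})

test_that("contextual gating writes the per-cell inhibitory conductances", {
  cfg <- small_config()
  net <- build_network(cfg, seed = 4)
  set_context(net, "A")
  gb <- net$layers$dg$gi_bar
  expect_equal(sum(gb == cfg$gi_bar_suppressed), 3 * cfg$dg_ensemble_size)
  expect_true(all(gb[1:cfg$dg_ensemble_size] == cfg$gi_bar_normal))
  set_context(net, "C")
  set_context(net, "A")
  expect_identical(net$layers$dg$gi_bar, gb)
  set_pfc_inactivated(net)
  expect_true(all(net$layers$dg$gi_bar == cfg$gi_bar_normal))
  expect_equal(net$mode, "pfc_inactivated")
  expect_error(set_context(net, "E"), "unknown context")
})

test_that("trials without a context fail, and test trials never learn", {
  net <- build_network(small_config(), seed = 6)
  set.seed(6)
  stim <- make_experiment_stimuli()
  p <- stim$list1[[1]]
  expect_error(run_trial(net, stim$codes[[p$a]], stim$codes[[p$b]],
                         mode = "test"), "context not set")
  set_context(net, "A")
  before <- lapply(net$projections, function(pr) pr$w + 0)
  run_trial(net, stim$codes[[p$a]], stim$codes[[p$b]], mode = "test")
  run_trial(net, stim$codes[[p$a]], stim$codes[[p$b]],
            stim$codes[[p$a]], mode = "encode", learn = FALSE)
  after <- lapply(net$projections, function(pr) pr$w + 0)
  expect_identical(before, after)
})

test_that("active granule cells stay inside the selected ensemble", {
  cfg <- small_config()
  set.seed(9)
  stim <- make_experiment_stimuli()
  net <- build_network(cfg)
  ids <- rep(cfg$contexts, each = cfg$dg_ensemble_size)
  for (ctx in c("A", "B")) {
    set_context(net, ctx)
    for (i in 1:6) {
      p <- stim$list1[[i]]
      tr <- run_trial(net, stim$codes[[p$a]], stim$codes[[p$b]],
                      stim$codes[[p$a]], mode = "encode")
      expect_true(all(ids[tr$dg_active_ids] == ctx))
      expect_equal(tr$dg_active, net$layers$dg$k)
    }
  }
})

test_that("trials are deterministic given the seed", {
  out <- replicate(2, {
    net <- build_network(small_config(), seed = 12)
    set.seed(12)
    stim <- make_experiment_stimuli()
    set_context(net, "A")
    p <- stim$list1[[2]]
    for (i in 1:3)
      run_trial(net, stim$codes[[p$a]], stim$codes[[p$b]],
                stim$codes[[p$b]], mode = "encode")
    run_trial(net, stim$codes[[p$a]], stim$codes[[p$b]], mode = "test")$r_out
  }, simplify = FALSE)
  expect_identical(out[[1]], out[[2]])
})

test_that("the compiled phase dynamics match the R single-layer primitives", {
  # one clamped sender driving one free layer through a masked projection
  set.seed(15)
  n_in <- 24; n_out <- 40
  mask <- matrix(rbinom(n_in * n_out, 1, 0.4), n_out, n_in)
  w <- init_weights(mask)
  x <- as.numeric(rbinom(n_in, 1, 0.3))
  p_in <- layer_params(n_in, 0.25)
  p_out <- layer_params(n_out, 0.1, tau = 0.3)
  alpha <- 0.25
  layers <- list(
    c(list(clamped = TRUE, reset_each_phase = FALSE), unclass(p_in)),
    c(list(clamped = FALSE, reset_each_phase = FALSE), unclass(p_out))
  )
  proj <- list(name = "in_out", from = 1L, to = 2L, w = w, w_eff = w,
               mask = mask * 1, denom = pmax(rowSums(mask), 1) * alpha,
               r = 1, a = 1, k_hebb = 1, epsilon = 0.1, minus_phase = 2L,
               sig_gain = 1, sig_off = 1)
  res <- trial_kernel_cpp(layers, list(proj), c(1, 1),
                          list(integer(0), 1L), 25L, matrix(1, 1, 1),
                          x, NULL, NULL, FALSE, 1L, 99L)
  y_cpp <- res$snapshots[[1]][[2]]
  st <- settle(list(vm = rep(p_out$Vrest, n_out)), p_out,
               list(list(x = x, w = w, mask = mask, alpha = alpha)),
               n_steps = 25)
  expect_equal(y_cpp, st$y, tolerance = 1e-12)
})

test_that("a lesioned mossy pathway decouples CA3 from the dentate context", {
  cfg <- small_config()
  set.seed(18)
  stim <- make_experiment_stimuli()
  net <- build_network(cfg)
  set_mossy_lesion(net)
  p <- stim$list1[[1]]
  ca3 <- lapply(c("A", "B"), function(ctx) {
    set_context(net, ctx)
    tr <- run_trial(net, stim$codes[[p$a]], stim$codes[[p$b]],
                    stim$codes[[p$a]], mode = "encode", learn = FALSE)
    tr$snapshots[[2]][[3]]
  })
  expect_identical(ca3[[1]], ca3[[2]])
  set_mossy_lesion(net, FALSE)
  ca3b <- lapply(c("A", "B"), function(ctx) {
    set_context(net, ctx)
    tr <- run_trial(net, stim$codes[[p$a]], stim$codes[[p$b]],
                    stim$codes[[p$a]], mode = "encode", learn = FALSE)
    tr$snapshots[[2]][[3]]
  })
  expect_false(identical(ca3b[[1]], ca3b[[2]]))
})

test_that("a trained association is recalled from the cue alone", {
  ts <- trained_single(seed = 7, n_trials = 15)
  tt <- run_trial(ts$net, ts$stim$codes[[ts$prob$a]],
                  ts$stim$codes[[ts$prob$b]], mode = "test")
  targ <- ts$stim$codes[[c(ts$prob$a, ts$prob$b)[ts$prob$rewarded]]]
  expect_lt(rmse_pattern(tt$r_out, targ), 0.15)
})

test_that("network weights survive a JSON round trip", {
  ts <- trained_single(seed = 22, n_trials = 4)
  path <- tempfile(fileext = ".json")
  save_weights(ts$net, path)
  net2 <- build_network(ts$net$cfg, seed = 999)
  load_weights(net2, path)
  for (nm in names(ts$net$projections)) {
    expect_equal(net2$projections[[nm]]$w, ts$net$projections[[nm]]$w,
                 tolerance = 1e-12)
  }
  set_context(net2, "A")
  tt2 <- run_trial(net2, ts$stim$codes[[ts$prob$a]],
                   ts$stim$codes[[ts$prob$b]], mode = "test")
  tt1 <- run_trial(ts$net, ts$stim$codes[[ts$prob$a]],
                   ts$stim$codes[[ts$prob$b]], mode = "test")
  expect_equal(tt2$r_out, tt1$r_out, tolerance = 1e-10)
})
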