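test_that("retrieval metric floors at chance and caps below 100", {
  expect_equal(performance_from_rmse(0.5), 50)
  expect_equal(performance_from_rmse(1), 50)
  expect_equal(performance_from_rmse(0), 100 / (0.5^10 + 1))
  E <- seq(0, 1, by = 0.001)
  P <- performance_from_rmse(E)
  expect_true(all(P >= 50 & P < 100))
  expect_true(all(diff(P) <= 1e-12))          # monotone nonincreasing
  # strictly decreasing below the floor region
  E2 <- seq(0, 0.49, by = 0.01)
  expect_true(all(diff(performance_from_rmse(E2)) < 0))
  expect_error(performance_from_rmse(1.2), "\\[0, 1\\]")
})

test_that("pattern RMSE behaves like a distance on the unit cube", {
  t6 <- c(rep(1, 6), rep(0, 18))
  expect_equal(rmse_pattern(t6, t6), 0)
  expect_equal(rmse_pattern(1 - t6, t6), 1)
  expect_equal(rmse_pattern(rep(0.5, 24), t6), 0.5)
  expect_error(rmse_pattern(1:3, 1:4), "mismatch")
})

test_that("choice selects the nearer odor and splits exact ties", {
  set.seed(2)
  a <- make_odor(); b <- make_odor()
  expect_equal(choose_odor(a, a, b), 1L)
  expect_equal(choose_odor(b, a, b), 2L)
  flip <- b; i <- which(flip == 1)[1]; flip[i] <- 0
  flip[which(flip == 0 & a == 0)[1]] <- 1
  expect_equal(choose_odor(flip, a, b), 2L)
  # symmetric input: both answers occur across the RNG stream
  mid <- (a + b) / 2
  picks <- replicate(200, choose_odor(mid, a, b))
  expect_gt(mean(picks == 1), 0.3)
  expect_lt(mean(picks == 1), 0.7)
})

test_that("list-2 errors are classified by the retained odor's history", {
  p1 <- list(a = "X1", b = "Y1", rewarded = 1L)            # X1 rewarded
  p2 <- list(a = "X1", b = "W1", rewarded = 2L)            # retained X1, now W1
  expect_equal(classify_error(p2, p1, 1L), "perseverative")
  p2b <- list(a = "Z1", b = "Y1", rewarded = 2L)           # retained Y1 (was unrewarded)
  expect_equal(classify_error(p2b, p1, 1L), "non_perseverative")
  expect_error(classify_error(p2, p1, 2L), "correct trial")
})

test_that("the criterion rule needs two consecutive blocks at 90", {
  expect_equal(criterion_from_curve(c(85, 92, 95)), 3L)
  expect_equal(criterion_from_curve(c(92, 85, 92, 95)), 4L)
  expect_true(is.na(criterion_from_curve(c(91, 80, 91, 80))))
  expect_equal(criterion_from_curve(c(95, 95)), 2L)
  expect_true(is.na(criterion_from_curve(numeric(0))))
})

test_that("interference index is the list-2 minus list-1 mean difference", {
  toy <- data.frame(
    rat = rep(1:2, each = 20),
    group = rep(c("saline_same", "muscimol_same"), each = 20),
    phase = rep(rep(c("list1", "list2"), each = 10), 2),
    block = rep(rep(1:5, times = 2), 4),
    P = c(rep(80, 10), rep(60, 10),      # rat 1: index -20
          rep(70, 10), rep(70, 10))      # rat 2: index 0
  )
  ii <- interference_index(toy)
  expect_equal(ii$index[ii$rat == 1], -20)
  expect_equal(ii$index[ii$rat == 2], 0)
  expect_error(interference_index(toy[toy$phase == "list1", ]), "lacks")
})

test_that("test-phase drop summarizes the group contrast", {
  toy <- data.frame(
    rat = rep(1:4, each = 3), group = rep(c("saline", "muscimol"), each = 6),
    phase = "test", block = rep(1:3, 4),
    P = c(rep(60, 6), rep(90, 6))
  )
  d <- p1a_test_drop(list(trials = toy))
  expect_equal(d$drop, 30)
  expect_equal(d$saline_mean, 60)
  expect_equal(d$muscimol_mean, 90)
})

test_that("block summaries aggregate rats before averaging", {
  toy <- data.frame(
    rat = c(1, 1, 2), group = "g", phase = "p", block = 1,
    P = c(50, 100, 80)
  )
  s <- summarize_blocks(toy)
  expect_equal(s$mean_P, mean(c(75, 80)))
  expect_equal(s$n, 2)
})

test_that("a short training run logs complete, traceable records", {
  cfg <- small_config()
  set.seed(44)
  stim <- make_experiment_stimuli()
  net <- build_network(cfg)
  out <- run_to_criterion(net, stim, stim$list1, "A", n_blocks = 2)
  tr <- out$trials
  expect_equal(nrow(tr), 16)
  expect_setequal(unique(tr$block), 1:2)
  expect_setequal(unique(tr$problem), 1:8)
  expect_true(all(tr$P >= 50 & tr$P < 100))
  expect_true(all(tr$E >= 0 & tr$E <= 1))
  expect_true(all(tr$choice %in% 1:2))
  expect_equal(out$n_blocks_run, 2)
  # experiment writer produces the three artifact files
  dir <- tempfile()
  write_experiment(list(experiment = "toy", trials = tr), dir)
  expect_true(all(file.exists(file.path(dir, c("trials.csv", "blocks.csv",
                                               "summary.json")))))
  unlink(dir, recursive = TRUE)
})
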