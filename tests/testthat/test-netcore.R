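test_that("activation is a bounded rectifier with the documented values", {
  expect_equal(activation(0.5), 0)
  expect_equal(activation(0.51), 0.5)
  expect_equal(activation(0.3), 0)
  vm <- seq(-0.5, 2, by = 0.01)
  y <- activation(vm)
  expect_true(all(y >= 0 & y < 1))
  expect_true(all(diff(y) >= 0))
  expect_true(all(y[vm <= 0.5] == 0))
})

test_that("membrane step converges to the closed-form fixed point", {
  p <- tbl1_params(n = 1)
  # leak only: equilibrium at El
  expect_equal(vm_fixed_point(0, 0, p), 0.3)
  # worked example: ge*ge_bar = 0.1, gi = 0
  expect_equal(vm_fixed_point(0.1, 0, p), (0.1 * 0.3 + 0.1 * 1) / 0.2)
  # tau = 0 freezes the dynamics
  p0 <- tbl1_params(n = 1, tau = 0)
  expect_equal(step_vm(0.42, 0.7, 0.3, p0), 0.42)
  # iteration reaches equilibrium to 1e-6 for assorted conductances,
  # including ones far beyond the forward-Euler stability bound
  for (case in list(c(0, 0), c(0.5, 0.2), c(3, 1.6), c(40, 20))) {
    vm <- p$Vrest
    for (s in 1:400) vm <- step_vm(vm, case[1], case[2], p)
    expect_equal(vm, vm_fixed_point(case[1], case[2], p), tolerance = 1e-6)
  }
  expect_error(step_vm(0.3, NaN, 0, p), "non-finite")
})

test_that("net excitation normalizes relative weights and averages per connection", {
  # single projection, one sender, plain average
  ge <- net_excitation(list(list(x = 1, w = matrix(0.4, 1, 1))))
  expect_equal(ge, 0.4)
  # two projections with relative weights 1 and 3, each raw drive 1.0
  one <- matrix(1, 1, 1)
  ge <- net_excitation(list(list(x = 1, w = one, r = 1),
                            list(x = 1, w = one, r = 3)))
  expect_equal(ge, 0.25 * 1 + 0.75 * 1)
  # silent senders contribute nothing
  ge <- net_excitation(list(list(x = c(0, 0), w = matrix(0.9, 3, 2))))
  expect_equal(ge, rep(0, 3))
  # expected-activity scaling divides the plain average by alpha
  ge <- net_excitation(list(list(x = c(1, 1), w = matrix(0.5, 1, 2),
                                 alpha = 0.25)))
  expect_equal(ge, 0.5 / 0.25)
  # gates multiply
  ge <- net_excitation(list(list(x = 1, w = one, gate = 0)))
  expect_equal(ge, 0)
  expect_error(net_excitation(list(list(x = c(1, 1), w = one))), "length")
  expect_error(net_excitation(list(list(x = 1, w = one, r = 0))), "zero")
})

test_that("threshold inhibition matches hand-computed cases exactly", {
  p <- tbl1_params(n = 1)
  expect_equal(kwta_threshold(0.2, p), 0.32, tolerance = 1e-12)
  expect_equal(kwta_threshold(0.1, p), 0.12, tolerance = 1e-12)
  expect_equal(kwta_threshold(0.04, p), 0, tolerance = 1e-12)
  p_bad <- tbl1_params(n = 1)
  p_bad$Ei <- p_bad$theta
  expect_error(kwta_threshold(0.2, p_bad), "undefined")
})

test_that("layer kWTA interpolates between the k-th and (k+1)-th supports", {
  # construct a layer whose k-th and (k+1)-th thresholds are 0.32 and 0.12
  p <- tbl1_params(n = 10, kwta_frac = 0.3)   # k = 3
  ge <- c(0.5, 0.4, 0.2, 0.1, 0.05, 0.05, 0, 0, 0, 0)
  gi <- kwta_layer(ge, p)
  expect_equal(gi, 0.12 + 0.25 * (0.32 - 0.12), tolerance = 1e-12)
  # all-equal drives give the common threshold
  gi_eq <- kwta_layer(rep(0.2, 10), p)
  expect_equal(gi_eq, 0.32, tolerance = 1e-12)
  # q endpoints
  p0 <- tbl1_params(n = 10, kwta_frac = 0.3, q = 1e-9)
  p1 <- tbl1_params(n = 10, kwta_frac = 0.3, q = 1 - 1e-9)
  expect_equal(kwta_layer(ge, p0), 0.12, tolerance = 1e-6)
  expect_equal(kwta_layer(ge, p1), 0.32, tolerance = 1e-6)
  # negative supports floor at zero
  expect_equal(kwta_layer(rep(0, 10), p), 0)
  expect_error(kwta_layer(ge[1:3], p), "kWTA undefined")
})

test_that("settling yields exactly k active units on distinct drives", {
  set.seed(1)
  for (rep in 1:5) {
    n <- 80
    p <- tbl1_params(n = n, kwta_frac = 0.1)   # k = 8
    w <- matrix(runif(n, 0.3, 1.2), n, 1)      # distinct per-unit drive
    st <- settle(list(vm = rep(p$Vrest, n)), p,
                 list(list(x = 1, w = w)), n_steps = 120)
    expect_equal(sum(st$y > 0), p$k)
  }
})

test_that("clamped layers bypass dynamics and zero input silences a layer", {
  p <- tbl1_params(n = 5, kwta_frac = 0.4)
  clamp <- c(1, 0, 1, 0, 0)
  st <- settle(list(vm = rep(0.3, 5), clamp = clamp), p,
               list(list(x = 1, w = matrix(1, 5, 1))), n_steps = 10)
  expect_equal(st$y, clamp)
  st0 <- settle(list(vm = rep(0.3, 5)), p,
                list(list(x = 0, w = matrix(1, 5, 1))), n_steps = 60)
  expect_equal(st0$y, rep(0, 5))
})

test_that("equilibrium activity is monotone in a unit's own drive", {
  p <- tbl1_params(n = 20, kwta_frac = 0.25)
  base <- seq(0.1, 0.6, length.out = 20)
  eq_y <- function(ge) {
    gi <- kwta_layer(ge, p)
    activation(vm_fixed_point(ge, gi * 0 + gi, p))
  }
  for (bump in c(0.05, 0.2)) {
    ge2 <- base
    ge2[7] <- ge2[7] + bump
    expect_gte(eq_y(ge2)[7], eq_y(base)[7])
  }
})

test_that("raising a unit's inhibitory conductance lowers its equilibrium", {
  p1 <- tbl1_params(n = 4, kwta_frac = 0.5)
  p5 <- tbl1_params(n = 4, kwta_frac = 0.5, gi_bar = c(1, 5, 1, 1))
  ge <- c(0.4, 0.4, 0.3, 0.2)
  gi <- 0.3
  vm1 <- vm_fixed_point(ge, gi, p1)
  vm5 <- vm_fixed_point(ge, gi, p5)
  expect_lt(vm5[2], vm1[2])
  expect_equal(vm5[-2], vm1[-2])
})
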