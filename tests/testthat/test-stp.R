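test_that("backward-Euler update matches hand-computed values", {
  p <- stp_params()
  expect_equal(step_depression(1, 0, p), 1)                     # rest fixed
  expect_equal(step_depression(0.5, 0, p), 4 / 7)               # (.5+1/6)/(7/6)
  expect_equal(step_depression(c(1, 0.5), c(0, 0), p), c(1, 4 / 7))
})

test_that("iterates under constant drive converge to the analytic steady state", {
  p <- stp_params()
  x <- 1
  for (i in 1:200) x <- step_depression(x, 2, p)
  expect_equal(x, 0.4, tolerance = 1e-10)
  expect_equal(stp_steady_state(2, p), 0.4)
  # the steady state is an exact fixed point of the discrete map
  for (r in c(0, 0.5, 1, 2, 10)) {
    xs <- stp_steady_state(r, p)
    expect_equal(step_depression(xs, r, p), xs, tolerance = 1e-12)
  }
})

test_that("resource fraction stays in (0, 1] under fuzzed trajectories", {
  set.seed(99)
  p <- stp_params()
  for (rep in 1:20) {
    x <- runif(8, 1e-6, 1)
    for (t in 1:50) {
      r <- rexp(8, rate = 0.5) * rbinom(8, 1, 0.5)
      x <- step_depression(x, r, p)
      expect_true(all(x > 0 & x <= 1))
    }
  }
})

test_that("coarse implicit steps track a fine explicit integration", {
  # oracle: explicit Euler at 1 ms on dx/dt = (1-x)/tau - U x r, constant r.
  # At weak drive the 250-ms implicit step stays within 2% of the fine
  # trajectory everywhere (max relative error 1.3% at r = 0.5); at stronger
  # drive it lags the fast transient (2.9% at r = 1, worse beyond), but both
  # integrators share the same fixed point, to which the iterates converge.
  p <- stp_params()
  fine_traj <- function(r, n) {
    fine <- 1
    out <- numeric(n)
    for (i in 1:n) {
      for (j in 1:250) fine <- fine + 0.001 * ((1 - fine) / p$tau_x -
                                                 p$U * fine * r)
      out[i] <- fine
    }
    out
  }
  for (r in c(0.25, 0.5)) {
    oracle <- fine_traj(r, 40)
    x <- 1
    for (i in 1:40) {
      x <- step_depression(x, r, p)
      expect_lt(abs(x - oracle[i]) / oracle[i], 0.02)
    }
  }
  for (r in c(1, 2, 5)) {
    oracle <- fine_traj(r, 60)
    x <- 1
    for (i in 1:60) x <- step_depression(x, r, p)
    expect_lt(abs(x - oracle[60]) / oracle[60], 0.005)
  }
})

test_that("update is monotone decreasing in presynaptic activity", {
  p <- stp_params()
  r <- seq(0, 10, by = 0.5)
  out <- step_depression(rep(0.8, length(r)), r, p)
  expect_true(all(diff(out) < 0))
})

test_that("effective input gates synaptic drive by the resource fraction", {
  expect_equal(effective_input(matrix(2), 0.5, 3), 3)
  W <- matrix(rnorm(12), 3, 4)
  r <- c(1, 2, 0, 4)
  expect_equal(effective_input(W, rep(1, 4), r), drop(W %*% r))
  expect_equal(effective_input(W, runif(4), rep(0, 4)), rep(0, 3))
  expect_error(effective_input(W, c(1, 1), r), "shape")
})

test_that("invalid states and parameters error", {
  expect_error(stp_params(U = 0), "U")
  expect_error(stp_params(tau_x = -1), "tau_x")
  expect_error(step_depression(0.5, -1, stp_params()), "activity")
  expect_error(step_depression(1.5, 0, stp_params()), "state")
  expect_error(step_depression(NaN, 0, stp_params()), "state")
})
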