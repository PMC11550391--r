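test_that("make_model enforces each structure's free-parameter set", {
  m <- make_model("P1D", list(k = 25.0, tau1 = 47.7, Td = 13.1))
  expect_s3_class(m, "process_model")
  expect_equal(free_params(m), c(k = 25.0, tau1 = 47.7, Td = 13.1))
  expect_equal(unname(m$params["Tz"]), 0)  # constrained parameters zeroed

  expect_error(make_model("P1", list(k = 1, tau1 = 10, Td = 5)),
               "parameter error")
  expect_error(make_model("P2", list(k = 1, tau1 = 10)), "parameter error")
  expect_error(make_model("P2", list(k = 1, tau1 = -3, tau2 = 5)),
               "domain error")
  expect_error(make_model("nope", list(k = 1)), "unknown model structure")
  # Tz may be negative (non-minimum-phase)
  expect_silent(make_model("P2Z", list(k = 1, tau1 = 10, tau2 = 20, Tz = -15)))
})

test_that("simulated step responses match closed forms for all structures", {
  h <- 5
  t <- seq(0, 1200, by = h)
  for (st in names(reference_truths())) {
    p <- reference_truths()[[st]]
    m <- make_model(st, p)
    got <- step_response(m, 1, horizon = 1200, sample_period = h)
    want <- closed_step(st, p, t)
    expect_lt(max(abs(got$y - want)) / max(abs(want)), 1e-9,
              label = paste("step response error for", st))
  }
})

test_that("fractional dead time off every grid is simulated exactly", {
  m <- make_model("P1D", list(k = 3, tau1 = 20, Td = pi))
  s <- step_response(m, 2, horizon = 300, sample_period = 5)
  want <- closed_step("P1D", list(k = 3, tau1 = 20, Td = pi), s$time_s, amp = 2)
  expect_equal(s$y, want, tolerance = 1e-12)
})

test_that("simulation is linear in the input for zero initial state", {
  set.seed(11)
  u <- rnorm(120)
  v <- rnorm(120)
  a <- 1.7
  b <- -0.4
  for (st in c("P1", "P2ZD", "P1parP1D")) {
    m <- make_model(st, reference_truths()[[st]])
    lhs <- simulate_response(m, a * u + b * v, 5)
    rhs <- a * simulate_response(m, u, 5) + b * simulate_response(m, v, 5)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
  expect_equal(simulate_response(make_model("P2", reference_truths()$P2),
                                 rep(0, 50), 5),
               rep(0, 50))
})

test_that("whole-sample dead time equals a shifted, zero-padded response", {
  set.seed(12)
  u <- rnorm(80)
  md <- make_model("P2D", list(k = 2, tau1 = 15, tau2 = 40, Td = 3 * 5))
  m0 <- make_model("P2", list(k = 2, tau1 = 15, tau2 = 40))
  yd <- simulate_response(md, u, 5)
  y0 <- simulate_response(m0, u, 5)
  expect_equal(yd, c(rep(0, 3), y0[1:(80 - 3)]), tolerance = 1e-12)
})

test_that("constrained structures reduce to their nested forms", {
  set.seed(13)
  u <- rnorm(100)
  h <- 5
  y_p2zd <- simulate_response(
    make_model("P2ZD", list(k = 2, tau1 = 20, tau2 = 55, Tz = 0, Td = 0)), u, h)
  y_p2 <- simulate_response(
    make_model("P2", list(k = 2, tau1 = 20, tau2 = 55)), u, h)
  expect_equal(y_p2zd, y_p2, tolerance = 1e-9)

  y_p2_red <- simulate_response(
    make_model("P2", list(k = 2, tau1 = 20, tau2 = 0)), u, h)
  y_p1 <- simulate_response(make_model("P1", list(k = 2, tau1 = 20)), u, h)
  expect_equal(y_p2_red, y_p1, tolerance = 1e-9)

  y_par <- simulate_response(
    make_model("P1parP1D",
               list(kp1 = 0, taup1 = 99, kp2 = 25, taup2 = 47.7, Td = 13.1)),
    u, h)
  y_p1d <- simulate_response(
    make_model("P1D", list(k = 25, tau1 = 47.7, Td = 13.1)), u, h)
  expect_equal(y_par, y_p1d, tolerance = 1e-9)
})

test_that("a zero cancelling a pole collapses to the remaining first-order lag", {
  set.seed(14)
  u <- rnorm(100)
  y_z <- simulate_response(
    make_model("P2Z", list(k = 1.4, tau1 = 30, tau2 = 80, Tz = 30)), u, 5)
  y_1 <- simulate_response(make_model("P1", list(k = 1.4, tau1 = 80)), u, 5)
  expect_equal(y_z, y_1, tolerance = 1e-9)
})

test_that("parallel response is exactly the sum of its branches", {
  set.seed(15)
  u <- rnorm(150)
  p <- reference_truths()$P1parP1D
  y_par <- simulate_response(make_model("P1parP1D", p), u, 5)
  y_b1 <- simulate_response(make_model("P1", list(k = p$kp1, tau1 = p$taup1)),
                            u, 5)
  y_b2 <- simulate_response(
    make_model("P1D", list(k = p$kp2, tau1 = p$taup2, Td = p$Td)), u, 5)
  expect_identical(y_par, y_b1 + y_b2)
})

test_that("degenerate pole configurations collapse to a delayed static gain", {
  set.seed(16)
  u <- rnorm(40)
  y <- simulate_response(make_model("P2D",
                                    list(k = 3, tau1 = 0, tau2 = 0, Td = 10)),
                         u, 5)
  expect_equal(y, c(0, 0, 3 * u[1:38]))
  # repeated poles use the analytic propagator, continuous at the tie
  y_rep <- simulate_response(make_model("P2", list(k = 1, tau1 = 30, tau2 = 30)),
                             u, 5)
  y_near <- simulate_response(
    make_model("P2", list(k = 1, tau1 = 30, tau2 = 30 * (1 + 1e-7))), u, 5)
  expect_equal(y_rep, y_near, tolerance = 1e-5)
})

test_that("initial modal state decays and shifts the early response only", {
  m <- make_model("P1", list(k = 2, tau1 = 10))
  expect_equal(n_states(m), 1L)
  y <- simulate_response(m, rep(0, 40), 5, initial_state = 5)
  expect_gt(abs(y[1]), 0)
  expect_lt(abs(y[40]), 1e-7)
  expect_equal(y[2] / y[1], exp(-5 / 10), tolerance = 1e-12)
  expect_error(simulate_response(m, rep(0, 10), 5, initial_state = c(1, 2)),
               "initial_state")
})

test_that("step_response approaches amplitude times the steady-state gain", {
  p <- reference_truths()$P1parP1D
  m <- make_model("P1parP1D", p)
  expect_equal(dc_gain(m), p$kp1 + p$kp2)
  s <- step_response(m, 1, horizon = 1e4, sample_period = 5)
  expect_equal(tail(s$y, 1), 27.2, tolerance = 1e-6)
  expect_equal(step_response(m, 0, horizon = 100)$y, rep(0, 21))
})
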