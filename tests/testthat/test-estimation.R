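test_that("compute_fit matches its defining cases", {
  y <- c(1, 2, 3, 4)
  expect_equal(compute_fit(y, y), 100)
  expect_equal(compute_fit(y, rep(mean(y), 4)), 0)
  expect_equal(compute_fit(y, c(1, 2, 3, 0)), 100 * (1 - 4 / sqrt(5)))
  # translation invariance
  expect_equal(compute_fit(y + 7, c(1, 2, 3, 0) + 7),
               compute_fit(y, c(1, 2, 3, 0)))
  expect_error(compute_fit(rep(2, 5), rnorm(5)), "domain error")
  expect_error(compute_fit(1:4, 1:5), "equal length")
  # sum-of-squares variant
  expect_equal(compute_fit(y, c(1, 2, 3, 0), variant = "ss"),
               100 * (1 - 16 / 5))
})

test_that("default bounds cover the reported estimates and accept overrides", {
  for (mod in c("TM", "CE")) {
    b <- default_bounds(mod)
    for (st in names(reference_truths())) {
      p <- reference_truths()[[st]]
      if (mod == "CE") {  # rescale gains to ergometer magnitudes
        for (g in intersect(names(p), c("k", "kp1", "kp2"))) p[[g]] <- p[[g]] / 60
      }
      for (nm in names(p)) {
        expect_gte(p[[nm]], b[[nm]][1])
        expect_lte(p[[nm]], b[[nm]][2])
      }
    }
  }
  b2 <- default_bounds("TM", Td = c(0, 30))
  expect_equal(b2$Td, c(0, 30))
  expect_error(default_bounds("TM", Td = c(5, 5)), "lower < upper")
  expect_error(default_bounds("TM", foo = c(0, 1)), "unknown bound")
})

test_that("fit_model recovers a first-order truth from noise-free data", {
  truth <- make_model("P1", list(k = 2, tau1 = 30))
  rec <- make_truth_record(truth, prbs_seed = 5)
  f <- fit_model(rec, "P1", options = fit_options(seed = 7))
  est <- free_params(f$model)
  expect_lt(abs(est["k"] - 2) / 2, 0.01)
  expect_lt(abs(est["tau1"] - 30) / 30, 0.01)
  expect_gt(f$fit_estimation, 99.99)
  expect_equal(f$N, n_samples(rec))
  expect_length(f$residuals, f$N)
})

test_that("fit_model demands deviation form and persistent excitation", {
  raw <- signal_record("s", 1, "TM", u = runif(50, 1, 2), y = rnorm(50, 120))
  expect_error(fit_model(raw, "P1"), "deviation form")
  flat <- signal_record("s", 1, "TM", u = rep(2, 50), y = rnorm(50, 120))
  flat <- to_deviations(flat)
  expect_error(fit_model(flat, "P1"), "excitation error")
})

test_that("objective never worsens along the nested-structure chain", {
  set.seed(31)
  truth <- make_model("P2D", list(k = 20, tau1 = 15, tau2 = 40, Td = 8))
  rec <- make_truth_record(truth, prbs_seed = 9)
  rec$y <- rec$y + rnorm(n_samples(rec), 0, 2)
  obj <- sapply(c("P1", "P1D", "P2D", "P2ZD"), function(st) {
    fit_model(rec, st, options = fit_options(seed = 3))$objective
  })
  # each structure nests the previous one, so the optimum cannot be worse
  for (i in 2:4) expect_lte(obj[i], obj[i - 1] * (1 + 1e-6))
})

test_that("two-pole fits report poles in canonical order tau1 <= tau2", {
  truth <- make_model("P2", list(k = 10, tau1 = 12, tau2 = 55))
  rec <- make_truth_record(truth, prbs_seed = 11)
  f <- fit_model(rec, "P2", options = fit_options(seed = 5))
  est <- free_params(f$model)
  expect_lte(est["tau1"], est["tau2"])
})

test_that("cross-validation on identical records equals the estimation fit", {
  truth <- make_model("P1D", list(k = 25, tau1 = 47.7, Td = 13.1))
  r1 <- make_truth_record(truth, prbs_seed = 13)
  r2 <- r1
  r2$test_index <- 2L
  cv <- cross_validate(record_pair(r1, r2), "P1D",
                       options = fit_options(seed = 2))
  expect_equal(cv$first$fit_validation, cv$first$fit_estimation,
               tolerance = 1e-9)
  expect_equal(cv$second$fit_validation, cv$second$fit_estimation,
               tolerance = 1e-9)
})

test_that("cross-validation refuses mismatched pairs and uncentered data", {
  truth <- make_model("P1", list(k = 2, tau1 = 30))
  r1 <- make_truth_record(truth)
  r2 <- r1
  r2$test_index <- 2L
  pair <- record_pair(r1, r2)
  pair$second$sample_period <- 10
  expect_error(cross_validate(pair, "P1"), "sample_period")
  pair2 <- record_pair(from_deviations(r1), {
    x <- from_deviations(r2); x
  })
  expect_error(cross_validate(pair2, "P1"), "deviation form")
})
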