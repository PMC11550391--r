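test_that("PRBS is a two-level maximal-length sequence with the m-sequence period", {
  cfg <- prbs_config(low_level = 1, high_level = 2, clock_period = 30,
                     register_length = 4, sample_period = 5,
                     duration = 30 * 15 * 3, seed = 4)
  u <- generate_prbs(cfg)
  expect_setequal(unique(u), c(1, 2))
  per_tick <- 30 / 5
  ticks <- u[seq(1, length(u), by = per_tick)]
  # period is exactly 2^4 - 1 = 15 clock ticks: shift 15 matches ...
  expect_identical(ticks[1:30], ticks[16:45])
  # ... and no shorter shift does
  for (s in 1:14) {
    expect_false(identical(ticks[1:15], ticks[(1 + s):(15 + s)]),
                 label = paste("no period at shift", s))
  }
  # a maximal-length sequence is nearly balanced: mean within one tick's worth
  expect_lt(abs(mean(ticks[1:15]) - 1.5), (2 - 1) / 2 / 15 + 1e-9)
})

test_that("PRBS generation is deterministic and validates its config", {
  cfg <- default_prbs("TM", seed = 9)
  expect_identical(generate_prbs(cfg), generate_prbs(cfg))
  expect_false(identical(generate_prbs(cfg),
                         generate_prbs(default_prbs("TM", seed = 10))))
  expect_error(prbs_config(1, 2, register_length = 2), "domain error")
  expect_error(prbs_config(1, 2, register_length = 17), "domain error")
  expect_error(prbs_config(2, 1), "low_level")
  expect_error(prbs_config(1, 2, clock_period = 7, sample_period = 5),
               "multiple")
  expect_warning(generate_prbs(prbs_config(1, 1)), "degenerate")
})

test_that("a drift-free noiseless record reduces to its fast branch response", {
  tr <- synthetic_truth(
    "TM",
    truth_model = make_model("P1parP1D",
                             list(kp1 = 0, taup1 = 100, kp2 = 20.2,
                                  taup2 = 34.3, Td = 17.9)),
    noise_sd = 0, seed = 2)
  prbs <- default_prbs("TM", seed = 2)
  rec <- generate_record(tr, prbs, 1L)
  u <- rec$u
  want <- simulate_response(
    make_model("P1D", list(k = 20.2, tau1 = 34.3, Td = 17.9)),
    u - mean(u), 5)
  expect_equal(rec$y - tr$baseline_hr, want, tolerance = 1e-12)
})

test_that("measurement noise has the configured standard deviation", {
  tr0 <- synthetic_truth("TM", noise_sd = 0, seed = 5)
  tr2 <- synthetic_truth("TM", noise_sd = 2, seed = 5)
  prbs <- default_prbs("TM", seed = 5, duration = 3000)  # 600 samples
  clean <- generate_record(tr0, prbs, 1L)
  noisy <- generate_record(tr2, prbs, 1L)
  expect_equal(sd(noisy$y - clean$y), 2, tolerance = 0.2)
})

test_that("the two tests of a pair share truth and excitation but not noise", {
  tr <- synthetic_truth("CE", noise_sd = 2, seed = 8)
  r1 <- generate_record(tr, test_index = 1L)
  r2 <- generate_record(tr, test_index = 2L)
  expect_identical(r1$u, r2$u)
  expect_false(identical(r1$y, r2$y))
  expect_identical(r1$y, generate_record(tr, test_index = 1L)$y)
})

test_that("truth models outside the estimation bounds are rejected", {
  bad <- make_model("P1parP1D",
                    list(kp1 = 7, taup1 = 700, kp2 = 20, taup2 = 34, Td = 18))
  expect_error(synthetic_truth("TM", truth_model = bad), "configuration error")
  expect_error(synthetic_truth("TM", noise_sd = -1), "noise_sd")
})

test_that("cohorts have the paired design sizes and are reproducible", {
  co <- generate_cohort(11, "TM", seed = 3)
  expect_length(co, 11)  # 11 subjects -> 22 records
  expect_equal(sum(vapply(co, function(p) 2L, 1L)), 22L)
  truth <- attr(co, "truth")
  expect_equal(nrow(truth), 11)
  b <- default_bounds("TM")
  for (p in c("kp1", "taup1", "kp2", "taup2", "Td")) {
    expect_true(all(truth[[p]] >= b[[p]][1] & truth[[p]] <= b[[p]][2]))
  }
  co2 <- generate_cohort(11, "TM", seed = 3)
  expect_identical(co, co2)
  # byte-identical after serialization
  f1 <- file.path(tempdir(), "c1.csv")
  f2 <- file.path(tempdir(), "c2.csv")
  write_record(co[[4]]$second, f1)
  write_record(co2[[4]]$second, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(attr(generate_cohort(11, "TM", seed = 4), "truth"),
                         truth))
  expect_error(generate_cohort(0, "TM"), "n_subjects")
})

test_that("a cycle-ergometer cohort of 27 subjects yields 54 records", {
  co <- generate_cohort(27, "CE", seed = 6, noise_sd = 0, jitter = 0)
  expect_length(co, 27)
  recs <- unlist(lapply(co, function(p) list(p$first, p$second)),
                 recursive = FALSE)
  expect_length(recs, 54)
  expect_true(all(vapply(recs, function(r) r$modality == "CE", TRUE)))
  # jitter = 0 gives every subject the nominal truth
  truth <- attr(co, "truth")
  expect_equal(unique(truth$kp2), 0.35)
})
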