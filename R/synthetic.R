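# Synthetic PRBS exercise experiments.
#
# Emulates the structure of open-loop heart-rate identification tests: a
# pseudo-random binary sequence (PRBS) switches the exercise intensity
# between two levels; heart rate responds with a fast, delayed first-order
# component plus a small-gain, slow first-order drift component (the
# parallel P1||P1D truth), plus white measurement noise. Each synthetic
# subject performs two tests with identical excitation and independent
# noise, matching the paired counterbalanced design.

# maximal-length LFSR feedback taps (Fibonacci form), by register length
.lfsr_taps <- list(
  `3` = c(3, 2), `4` = c(4, 3), `5` = c(5, 3), `6` = c(6, 5),
  `7` = c(7, 6), `8` = c(8, 6, 5, 4), `9` = c(9, 5), `10` = c(10, 7),
  `11` = c(11, 9), `12` = c(12, 6, 4, 1), `13` = c(13, 4, 3, 1),
  `14` = c(14, 5, 3, 1), `15` = c(15, 14), `16` = c(16, 15, 13, 4)
)

#' PRBS excitation configuration
#'
#' @param low_level,high_level The two input intensity levels (m/s or W);
#'   `low_level <= high_level`. Equal levels give a constant (degenerate)
#'   input and are flagged with a warning.
#' @param clock_period Switching granularity in seconds; must be a multiple
#'   of `sample_period`. Default 30 s, so the excitation bandwidth brackets
#'   response time constants in the 30-180 s range.
#' @param register_length Shift-register order (3-16); the binary sequence
#'   repeats after `2^register_length - 1` clock ticks. Default 7.
#' @param sample_period Sampling interval in seconds (default 5).
#' @param duration Test duration in seconds (default 1800).
#' @param seed Integer; selects the (non-zero) register initial state.
#' @return Named list of class `prbs_config`.
#' @export
prbs_config <- function(low_level, high_level, clock_period = 30,
                        register_length = 7, sample_period = 5,
                        duration = 1800, seed = 1L) {
  if (register_length < 3 || register_length > 16) {
    stop("domain error: register_length must be in [3, 16]")
  }
  if (low_level > high_level) stop("low_level must be <= high_level")
  ratio <- clock_period / sample_period
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("clock_period must be a multiple of sample_period")
  }
  if (duration < clock_period) stop("duration must cover at least one clock tick")
  structure(list(low_level = low_level, high_level = high_level,
                 clock_period = clock_period,
                 register_length = as.integer(register_length),
                 sample_period = sample_period, duration = duration,
                 seed = as.integer(seed)),
            class = "prbs_config")
}

# maximal-length binary sequence of n_ticks clock ticks (values 0/1)
.lfsr_bits <- function(register_length, n_ticks, seed) {
  taps <- .lfsr_taps[[as.character(register_length)]]
  state <- with_seed(seed, sample(c(0L, 1L), register_length, replace = TRUE))
  if (all(state == 0L)) state[1] <- 1L  # all-zero state is absorbing
  bits <- integer(n_ticks)
  for (i in seq_len(n_ticks)) {
    bits[i] <- state[register_length]
    fb <- Reduce(bitwXor, state[taps])
    state <- c(fb, state[-register_length])
  }
  bits
}

#' Generate a PRBS input signal
#'
#' Produces a maximal-length shift-register sequence mapped to the two
#' intensity levels, held for one clock period per bit and sampled at the
#' sample period. Deterministic given `config$seed` (which selects the
#' register's initial state).
#'
#' @param config A [prbs_config()].
#' @return Numeric vector of input samples of length
#'   `duration / sample_period` (the sample at time `duration` itself is the
#'   start of the next hold and is not included... the grid is
#'   `0, h, ..., duration - h`).
#' @export
generate_prbs <- function(config) {
  stopifnot(inherits(config, "prbs_config"))
  if (config$low_level == config$high_level) {
    warning("degenerate PRBS: low_level == high_level gives a constant input")
  }
  n_samp <- floor(config$duration / config$sample_period + 1e-9)
  per_tick <- as.integer(round(config$clock_period / config$sample_period))
  n_ticks <- ceiling(n_samp / per_tick)
  bits <- .lfsr_bits(config$register_length, n_ticks, config$seed)
  levels <- ifelse(bits == 1L, config$high_level, config$low_level)
  rep(levels, each = per_tick)[seq_len(n_samp)]
}

# nominal parallel-model truth per modality: slow low-gain drift branch
# (kp1, taup1) plus fast delayed response branch (kp2, taup2, Td)
.truth_centers <- function(modality) {
  switch(modality,
    TM = list(kp1 = 7.0, taup1 = 141.5, kp2 = 20.2, taup2 = 34.3, Td = 17.9),
    CE = list(kp1 = 0.09, taup1 = 180.7, kp2 = 0.35, taup2 = 37.9, Td = 17.1),
    stop("modality must be 'TM' or 'CE'"))
}

.default_prbs_levels <- function(modality) {
  # moderate-to-vigorous two-level protocols: treadmill speed around
  # 2 m/s, ergometer work rate around 100 W
  switch(modality, TM = c(1.6, 2.4), CE = c(75, 125))
}

#' Default PRBS design for a modality
#'
#' @param modality `"TM"` or `"CE"`.
#' @param seed Integer seed for the register initial state.
#' @param ... Overrides passed to [prbs_config()].
#' @return A `prbs_config` with modality-appropriate intensity levels.
#' @export
default_prbs <- function(modality = c("TM", "CE"), seed = 1L, ...) {
  modality <- match.arg(modality)
  lv <- .default_prbs_levels(modality)
  args <- modifyList(list(low_level = lv[1], high_level = lv[2], seed = seed),
                     list(...))
  do.call(prbs_config, args)
}

#' Ground truth for one synthetic subject
#'
#' Bundles the true generating model (by default the parallel two-branch
#' structure: a small-gain slow drift branch plus a fast delayed response
#' branch), the measurement-noise level, the mean heart-rate working level,
#' and the subject's seed. The truth model must lie inside the default
#' estimation bounds, otherwise recovery experiments would be ill-posed.
#'
#' @param modality `"TM"` or `"CE"`.
#' @param truth_model A `process_model`; default is the modality's nominal
#'   parallel model.
#' @param noise_sd Measurement noise standard deviation, bpm (default 2).
#' @param baseline_hr Mean heart-rate level, bpm, around which deviations
#'   play out (defaults: 140 TM, 120 CE).
#' @param drift_ramp Optional additive linear heart-rate ramp in bpm/min
#'   (default 0), for stressing the detrending stage.
#' @param subject_id Subject label.
#' @param seed Integer seed; test noise is derived from `(seed, test_index)`
#'   so a pair shares its truth but not its noise.
#' @return Named list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(modality = c("TM", "CE"), truth_model = NULL,
                            noise_sd = 2, baseline_hr = NULL, drift_ramp = 0,
                            subject_id = "S1", seed = 1L) {
  modality <- match.arg(modality)
  if (is.null(truth_model)) {
    truth_model <- make_model("P1parP1D", .truth_centers(modality))
  }
  stopifnot(inherits(truth_model, "process_model"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  b <- default_bounds(modality)
  p <- free_params(truth_model)
  for (nm in names(p)) {
    if (p[nm] < b[[nm]][1] || p[nm] > b[[nm]][2]) {
      stop("configuration error: truth parameter ", nm, " = ", p[nm],
           " outside the default estimation bounds [", b[[nm]][1], ", ",
           b[[nm]][2], "]")
    }
  }
  if (is.null(baseline_hr)) baseline_hr <- if (modality == "TM") 140 else 120
  structure(list(truth_model = truth_model, noise_sd = noise_sd,
                 baseline_hr = baseline_hr, drift_ramp = drift_ramp,
                 modality = modality, subject_id = as.character(subject_id),
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Generate one synthetic test record
#'
#' Simulates the truth model's response to the mean-centred PRBS input from
#' rest, adds the mean heart-rate level, an optional linear ramp and white
#' Gaussian measurement noise, and returns the record in absolute units.
#' The noise stream is seeded by `(truth$seed, test_index)`: the two tests
#' of a pair share the excitation and the truth but not the noise.
#'
#' @param truth A [synthetic_truth()].
#' @param prbs A [prbs_config()]; defaults to [default_prbs()] for the
#'   truth's modality.
#' @param test_index 1 or 2.
#' @return A `signal_record` in absolute units.
#' @export
generate_record <- function(truth, prbs = default_prbs(truth$modality),
                            test_index = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(prbs, "prbs_config"))
  u <- generate_prbs(prbs)
  h <- prbs$sample_period
  yclean <- truth$baseline_hr +
    simulate_response(truth$truth_model, u - mean(u), h)
  if (truth$drift_ramp != 0) {
    yclean <- yclean + truth$drift_ramp / 60 * (seq_along(u) - 1) * h
  }
  noise_seed <- (truth$seed + 1664525L * as.integer(test_index)) %%
    .Machine$integer.max
  noise <- if (truth$noise_sd > 0) {
    with_seed(noise_seed, rnorm(length(u), 0, truth$noise_sd))
  } else 0
  signal_record(subject_id = truth$subject_id, test_index = test_index,
                modality = truth$modality, u = u, y = yclean + noise,
                sample_period = h)
}

#' Generate a synthetic cohort of paired test records
#'
#' Per subject, truth parameters are drawn around the modality's nominal
#' parallel-model values with independent uniform jitter of +/-`jitter`
#' (relative), and two replicate records are generated with shared
#' excitation and independent noise. Fully reproducible from `seed`.
#'
#' @param n_subjects Number of subjects (pairs).
#' @param modality `"TM"` or `"CE"`.
#' @param seed Integer cohort seed.
#' @param noise_sd Measurement noise SD in bpm (default 2).
#' @param jitter Relative half-width of the uniform parameter jitter
#'   (default 0.2, i.e. +/-20%); 0 gives every subject the nominal truth.
#' @param prbs A [prbs_config()]; default [default_prbs()] for the modality.
#' @return List of `record_pair` objects with attribute `truth`: a data
#'   frame of each subject's true parameters (the truth manifest).
#' @export
generate_cohort <- function(n_subjects, modality = c("TM", "CE"), seed = 1L,
                            noise_sd = 2, jitter = 0.2,
                            prbs = NULL) {
  modality <- match.arg(modality)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (is.null(prbs)) prbs <- default_prbs(modality)
  centers <- unlist(.truth_centers(modality))
  jit <- with_seed(seed, {
    matrix(runif(n_subjects * length(centers), 1 - jitter, 1 + jitter),
           nrow = n_subjects)
  })
  pairs <- vector("list", n_subjects)
  truth_rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    p <- centers * jit[i, ]
    sid <- sprintf("S%02d", i)
    tr <- synthetic_truth(
      modality = modality,
      truth_model = make_model("P1parP1D", as.list(p)),
      noise_sd = noise_sd, subject_id = sid,
      seed = (seed + 104729L * i) %% .Machine$integer.max
    )
    pairs[[i]] <- record_pair(generate_record(tr, prbs, 1L),
                              generate_record(tr, prbs, 2L))
    truth_rows[[i]] <- data.frame(subject_id = sid, t(p), noise_sd = noise_sd,
                                  baseline_hr = tr$baseline_hr,
                                  modality = modality)
  }
  attr(pairs, "truth") <- do.call(rbind, truth_rows)
  pairs
}

#' Write a cohort's truth manifest
#'
#' Saves the `truth` attribute of [generate_cohort()] output as CSV for
#' later recovery scoring with [score_recovery()].
#'
#' @param cohort Output of [generate_cohort()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(cohort, path) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) stop("cohort carries no truth attribute")
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
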