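# Bounded least-squares estimation and the NRMSE fit metric.
#
# Each structure's free parameters are estimated by minimising the sum of
# squared output errors with Levenberg-Marquardt under box constraints
# (physiologically plausible ranges), from multiple starting points: one
# mid-range start plus seeded random draws (log-uniform for time constants
# and dead time, uniform for gains and the zero). Dead time is a continuous
# decision variable inside the search, not a grid over whole samples.

#' Physiologically plausible parameter bounds
#'
#' Box constraints used to focus the least-squares search. Defaults: time
#' constants 1-600 s, dead time 0-60 s, zero time constant -120 to 120 s
#' (either sign; non-minimum-phase allowed), gains 0-100 bpm/(m/s) for the
#' treadmill or 0-2 bpm/W for the cycle ergometer. All are overridable.
#'
#' @param modality `"TM"` or `"CE"` (sets the gain bounds' units).
#' @param ... Named overrides, each a numeric `c(lower, upper)`, for any of
#'   `k, tau1, tau2, Tz, Td, kp1, taup1, kp2, taup2`.
#' @return Named list of `c(lower, upper)` vectors, class `parameter_bounds`.
#' @export
default_bounds <- function(modality = c("TM", "CE"), ...) {
  modality <- match.arg(modality)
  gain <- if (modality == "TM") c(0, 100) else c(0, 2)
  tau <- c(1, 600)
  b <- list(k = gain, tau1 = tau, tau2 = tau, Tz = c(-120, 120), Td = c(0, 60),
            kp1 = gain, taup1 = tau, kp2 = gain, taup2 = tau)
  over <- list(...)
  bad <- setdiff(names(over), names(b))
  if (length(bad)) stop("unknown bound name(s): ", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    v <- as.numeric(over[[nm]])
    if (length(v) != 2L || !(v[1] < v[2])) {
      stop("bound for ", nm, " must be c(lower, upper) with lower < upper")
    }
    b[[nm]] <- v
  }
  structure(b, class = "parameter_bounds", modality = modality)
}

#' Optimizer settings for model fitting
#'
#' @param n_starts Number of multi-start points (default 10): one mid-range
#'   start plus `n_starts - 1` seeded random draws.
#' @param seed Integer seed for the random starts (recorded in the result).
#' @param ftol Relative convergence tolerance on the sum of squares.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param fit_variant `"rms"` for the 2-norm NRMSE fit (default) or `"ss"`
#'   for the sum-of-squares variant, see [compute_fit()].
#' @param center_sim Compare the measured deviations against the simulated
#'   output's own deviations around its mean over the evaluation period
#'   (default `TRUE`). Measured data carry an unknown operating-point
#'   offset that mean-centering cannot remove exactly (the mean of the
#'   model's own start-up transient survives it); matching means on both
#'   sides concentrates that nuisance offset out of the least-squares
#'   problem. Set `FALSE` to compare raw zero-state simulations.
#' @return Named list of class `fit_options`.
#' @export
fit_options <- function(n_starts = 10, seed = 1L, ftol = 1e-10,
                        maxiter = 500, fit_variant = c("rms", "ss"),
                        center_sim = TRUE) {
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 ftol = ftol, maxiter = as.integer(maxiter),
                 fit_variant = match.arg(fit_variant),
                 center_sim = isTRUE(center_sim)),
            class = "fit_options")
}

#' NRMSE model fit in percent
#'
#' The primary goodness-of-fit measure:
#' \deqn{fit = 100\,\Big(1 - \frac{\lVert y - y_{sim}\rVert_2}
#'   {\lVert y - \bar y\rVert_2}\Big)}
#' 100 means a perfect reproduction, 0 means no better than the mean heart
#' rate, and negative values are possible. `variant = "ss"` instead uses the
#' ratio of sums of squares (no square root).
#'
#' @param y Measured output samples.
#' @param ysim Simulated output samples, same length.
#' @param variant `"rms"` (default) or `"ss"`.
#' @return Fit in percent (at most 100, unbounded below).
#' @examples
#' compute_fit(c(1, 2, 3, 4), c(1, 2, 3, 0))  # about -78.9
#' @export
compute_fit <- function(y, ysim, variant = c("rms", "ss")) {
  variant <- match.arg(variant)
  y <- as.numeric(y)
  ysim <- as.numeric(ysim)
  if (length(y) != length(ysim)) stop("y and ysim must have equal length")
  if (length(y) < 2L) stop("fit needs at least 2 samples")
  denom <- sum((y - mean(y))^2)
  if (denom == 0) stop("domain error: y is constant, fit is undefined")
  num <- sum((y - ysim)^2)
  if (variant == "rms") 100 * (1 - sqrt(num / denom)) else 100 * (1 - num / denom)
}

# starting points: mid-range first, then seeded draws (log-uniform for
# positive time-scale parameters, uniform otherwise)
.make_starts <- function(free, lower, upper, options) {
  logpar <- free %in% c("tau1", "tau2", "taup1", "taup2", "Td")
  mid <- (lower + upper) / 2
  starts <- list(mid)
  ndraw <- options$n_starts - 1L
  if (ndraw > 0L) {
    draws <- with_seed(options$seed, {
      lapply(seq_len(ndraw), function(i) {
        p <- numeric(length(free))
        for (j in seq_along(free)) {
          if (logpar[j]) {
            lo <- max(lower[j], 0.5)
            p[j] <- exp(runif(1, log(lo), log(max(upper[j], lo * 1.0001))))
          } else {
            p[j] <- runif(1, lower[j], upper[j])
          }
        }
        p
      })
    })
    starts <- c(starts, draws)
  }
  starts
}

#' Fit one model structure to a record by bounded least squares
#'
#' Minimises the sum of squared differences between the measured heart-rate
#' deviations and the simulated model output over the structure's free
#' parameters, within `bounds`, restarting from `n_starts` points and
#' keeping the best local optimum. The record must already be in deviation
#' form ([preprocess_record()]); simulation starts from zero initial state.
#'
#' For the two-pole structures the exchangeable poles are reported
#' canonically with `tau1 <= tau2`.
#'
#' @param record A centered `signal_record`.
#' @param structure_name One of `names(model_structures())`.
#' @param bounds A [default_bounds()] object.
#' @param options A [fit_options()] object.
#' @return An object of class `fit_result`: fields `model`,
#'   `fit_estimation` (percent), `residuals`, `ysim`, `objective` (sum of
#'   squared residuals), `n_starts_converged`, `ybar`, `N`, `seed`,
#'   and `fit_validation` (`NA` until cross-validated).
#' @export
fit_model <- function(record, structure_name,
                      bounds = default_bounds(record$modality),
                      options = fit_options()) {
  stopifnot(inherits(record, "signal_record"), inherits(options, "fit_options"))
  if (!record$centered) {
    stop("record must be preprocessed to deviation form (see preprocess_record)")
  }
  if (sd(record$u) == 0) {
    stop("excitation error: input is constant, parameters are not identifiable")
  }
  free <- model_structures()[[structure_name]]
  if (is.null(free)) stop("unknown model structure: ", structure_name)
  lower <- vapply(free, function(p) bounds[[p]][1], 0)
  upper <- vapply(free, function(p) bounds[[p]][2], 0)
  y <- record$y
  u <- record$u
  h <- record$sample_period

  simfun <- function(m, uu, hh) {
    ys <- simulate_response(m, uu, hh)
    if (options$center_sim) ys - mean(ys) else ys
  }
  resid_fn <- function(p) {
    p <- pmin(pmax(p, lower), upper)
    m <- make_model(structure_name, setNames(as.list(p), free))
    y - simfun(m, u, h)
  }

  starts <- .make_starts(free, lower, upper, options)
  if (structure_name == "P1parP1D") {
    # staged start: the parallel form's dominant local minimum swaps the
    # branch roles, so seed one start from a quick P1D fit — fast branch at
    # the P1D estimate, slow branch small-gain and slow
    opt_pre <- options
    opt_pre$n_starts <- min(4L, options$n_starts)
    pre <- tryCatch(fit_model(record, "P1D", bounds, opt_pre),
                    error = function(e) NULL)
    if (!is.null(pre)) {
      pp <- free_params(pre$model)
      st <- c(0.25 * pp[["k"]], min(4 * pp[["tau1"]], upper[2]),
              pp[["k"]], pp[["tau1"]], pp[["Td"]])
      starts <- c(list(pmin(pmax(st, lower), upper)), starts)
    }
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = options$ftol, ptol = 1e-10,
                                     maxiter = options$maxiter)
  best <- NULL
  n_conv <- 0L
  for (s in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn, lower = lower, upper = upper,
                         control = ctrl),
      error = function(e) NULL
    )
    if (is.null(res)) next
    n_conv <- n_conv + 1L
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) {
    stop("convergence error: no start converged for ", structure_name,
         " (", length(starts), " starts attempted)")
  }
  p <- setNames(pmin(pmax(best$par, lower), upper), free)
  if (all(c("tau1", "tau2") %in% free) && p["tau1"] > p["tau2"]) {
    p[c("tau1", "tau2")] <- p[c("tau2", "tau1")]
  }
  model <- make_model(structure_name, as.list(p))
  ysim <- simfun(model, u, h)
  structure(
    list(model = model,
         fit_estimation = compute_fit(y, ysim, options$fit_variant),
         fit_validation = NA_real_,
         residuals = y - ysim, ysim = ysim,
         objective = sum((y - ysim)^2),
         n_starts_converged = n_conv, n_starts = length(starts),
         ybar = mean(y), N = length(y), seed = options$seed,
         subject_id = record$subject_id, test_index = record$test_index,
         modality = record$modality, fit_variant = options$fit_variant),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s on subject %s test %d: fit %.1f%%%s\n",
              x$model$structure, x$subject_id, x$test_index, x$fit_estimation,
              if (is.na(x$fit_validation)) ""
              else sprintf(" (validation %.1f%%)", x$fit_validation)))
  invisible(x)
}

#' Counterbalanced cross-validation of a structure on a record pair
#'
#' Estimates the structure separately on each of the subject's two replicate
#' tests; the model estimated on one record is then simulated against the
#' other record's input (from zero initial state) and scored against its
#' measured output, giving each `fit_result` its `fit_validation`. Reported
#' fits downstream of the pipeline are these validation fits.
#'
#' @param pair A `record_pair`, both members preprocessed identically
#'   (deviation form).
#' @param structure_name One of `names(model_structures())`.
#' @param bounds A [default_bounds()] object.
#' @param options A [fit_options()] object.
#' @return List with elements `first` and `second`, each a `fit_result`
#'   whose `fit_validation` was computed on the opposite record.
#' @export
cross_validate <- function(pair, structure_name,
                           bounds = default_bounds(pair$first$modality),
                           options = fit_options()) {
  stopifnot(inherits(pair, "record_pair"))
  if (pair$first$sample_period != pair$second$sample_period) {
    stop("pair members have different sample_period")
  }
  if (!pair$first$centered || !pair$second$centered) {
    stop("both records must be in deviation form before cross-validation")
  }
  sides <- list(first = pair$first, second = pair$second)
  fits <- lapply(names(sides), function(nm) {
    tryCatch(fit_model(sides[[nm]], structure_name, bounds, options),
             error = function(e) stop("fit failed on record '", nm, "': ",
                                      conditionMessage(e)))
  })
  names(fits) <- names(sides)
  for (est in c("first", "second")) {
    val <- setdiff(c("first", "second"), est)
    vrec <- sides[[val]]
    ysim <- simulate_response(fits[[est]]$model, vrec$u, vrec$sample_period)
    if (options$center_sim) ysim <- ysim - mean(ysim)
    fits[[est]]$fit_validation <- compute_fit(vrec$y, ysim, options$fit_variant)
  }
  fits
}
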