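# Deviation-form preprocessing.
#
# All estimation works on deviations around mean levels. Optionally the
# first part of a record (initial cardiovascular transient / slow drift)
# can be dropped, and a least-squares straight line removed from the heart
# rate. The pipeline always trims first and centers afterwards, so means
# are computed over the retained evaluation period.

#' Preprocessing configuration
#'
#' @param center Subtract the mean from `u` and `y` (deviation form).
#' @param skip_initial Seconds to drop from the start of the record before
#'   estimation; rounded up to a whole number of sample periods.
#' @param detrend Remove a least-squares straight line from `y`.
#' @return A list of class `preprocess_config`.
#' @details The default profile (`center = TRUE`, `skip_initial = 0`,
#'   `detrend = FALSE`) mirrors the primary analysis pipeline. A stricter
#'   profile with `skip_initial = 300` discards the initial heart-rate
#'   drift, whose observed time constants are in the 140-180 s range.
#' @export
preprocess_config <- function(center = TRUE, skip_initial = 0, detrend = FALSE) {
  if (!is.numeric(skip_initial) || skip_initial < 0) {
    stop("skip_initial must be >= 0 seconds")
  }
  structure(list(center = isTRUE(center), skip_initial = as.numeric(skip_initial),
                 detrend = isTRUE(detrend)),
            class = "preprocess_config")
}

#' Put a record into deviation form
#'
#' Subtracts the arithmetic means of `u` and `y`, storing them so the
#' transformation is invertible. Applying it twice is an error: deviation
#' form is a state, not an idempotent filter.
#'
#' @param record A `signal_record` in absolute units.
#' @return The record with zero-mean `u`, `y` and `centered = TRUE`.
#' @seealso [from_deviations()]
#' @export
to_deviations <- function(record) {
  stopifnot(inherits(record, "signal_record"))
  if (record$centered) stop("state error: record is already in deviation form")
  record$u_mean <- mean(record$u)
  record$y_mean <- mean(record$y)
  record$u <- record$u - record$u_mean
  record$y <- record$y - record$y_mean
  record$centered <- TRUE
  record
}

#' Restore a deviation-form record to absolute units
#'
#' @param record A centered `signal_record`.
#' @return The record with the stored means added back.
#' @export
from_deviations <- function(record) {
  stopifnot(inherits(record, "signal_record"))
  if (!record$centered) stop("state error: record is not in deviation form")
  record$u <- record$u + record$u_mean
  record$y <- record$y + record$y_mean
  record$u_mean <- NA_real_
  record$y_mean <- NA_real_
  record$centered <- FALSE
  record
}

#' Drop the initial transient from a record
#'
#' Removes the first `skip_initial` seconds from both `u` and `y`. Values
#' that are not a multiple of the sample period are rounded up to the next
#' sample instant (with a message).
#'
#' @param record A `signal_record`.
#' @param skip_initial Seconds to drop; must leave at least 2 samples.
#' @return The shortened record.
#' @export
trim_transient <- function(record, skip_initial) {
  stopifnot(inherits(record, "signal_record"))
  if (!is.numeric(skip_initial) || skip_initial < 0) {
    stop("domain error: skip_initial must be >= 0")
  }
  if (skip_initial == 0) return(record)
  h <- record$sample_period
  k <- ceiling(skip_initial / h - 1e-9)
  if (abs(k * h - skip_initial) > 1e-9 * h) {
    message("skip_initial rounded up to ", k * h, " s (", k, " samples)")
  }
  if (k >= n_samples(record) - 1L) {
    stop("domain error: skip_initial (", skip_initial,
         " s) leaves fewer than 2 samples")
  }
  keep <- (k + 1L):n_samples(record)
  record$u <- record$u[keep]
  record$y <- record$y[keep]
  record
}

#' Remove a least-squares straight line from the heart-rate signal
#'
#' Fits `y ~ time` by ordinary least squares over the record and keeps the
#' residual. The removed intercept and slope are logged in
#' `record$meta$detrend` (units bpm and bpm/s). Applying it twice changes
#' nothing beyond the first application.
#'
#' @param record A `signal_record` with at least 3 samples.
#' @return The detrended record.
#' @export
detrend_linear_hr <- function(record) {
  stopifnot(inherits(record, "signal_record"))
  if (n_samples(record) < 3L) stop("data error: detrending needs >= 3 samples")
  t <- (seq_len(n_samples(record)) - 1) * record$sample_period
  fit <- lm(record$y ~ t)
  record$y <- as.numeric(record$y - fitted(fit))
  record$meta$detrend <- list(intercept_bpm = unname(coef(fit)[1]),
                              slope_bpm_per_s = unname(coef(fit)[2]))
  record
}

#' Apply a full preprocessing profile to a record
#'
#' Order of operations: trim the initial transient, detrend (optional),
#' then center — so means (and the removed trend) are computed over the
#' retained evaluation period only.
#'
#' @param record A `signal_record` in absolute units.
#' @param config A [preprocess_config()].
#' @return The preprocessed record.
#' @export
preprocess_record <- function(record, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  if (config$skip_initial > 0) record <- trim_transient(record, config$skip_initial)
  if (config$detrend) record <- detrend_linear_hr(record)
  if (config$center) record <- to_deviations(record)
  record
}
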