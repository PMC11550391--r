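# Data model and on-disk format for exercise test records.
#
# A record is one open-loop identification test: treadmill speed (m/s) or
# cycle-ergometer work rate (W) as input, heart rate (bpm) as output, both
# uniformly sampled (default every 5 s). On disk a record is a plain CSV
# `time_s,u,y` plus a YAML sidecar `<path>.meta` carrying identity, units
# and preprocessing state, so that write/read round-trips every field.

.modality_units <- function(modality) {
  switch(modality, TM = "m/s", CE = "W",
         stop("modality must be 'TM' or 'CE'"))
}

#' Create a signal record
#'
#' One test's uniformly sampled input/heart-rate series with its pairing
#' metadata. Two replicate tests per subject (`test_index` 1 and 2) form a
#' pair for counterbalanced cross-validation.
#'
#' @param subject_id Character subject identifier.
#' @param test_index Replicate index within the subject's pair, 1 or 2.
#' @param modality `"TM"` (treadmill; input in m/s) or `"CE"` (cycle
#'   ergometer; input in W).
#' @param u,y Numeric vectors of input and heart-rate samples, equal length
#'   (at least 2), no missing values.
#' @param sample_period Sampling interval in seconds (default 5).
#' @param u_mean,y_mean Offsets removed when the record was put into
#'   deviation form; `NA` otherwise.
#' @param centered Logical; `TRUE` when `u` and `y` are deviations around
#'   the stored means.
#' @param meta Optional named list of additional metadata (e.g. detrend
#'   coefficients); round-trips through the sidecar file.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(subject_id, test_index, modality, u, y,
                          sample_period = 5, u_mean = NA_real_,
                          y_mean = NA_real_, centered = FALSE, meta = list()) {
  u <- as.numeric(u)
  y <- as.numeric(y)
  if (length(u) != length(y)) stop("data error: u and y must have equal length")
  if (length(u) < 2L) stop("data error: a record needs at least 2 samples")
  if (any(!is.finite(u)) || any(!is.finite(y))) {
    stop("data error: NaN/NA/Inf samples are not allowed")
  }
  if (!is.numeric(sample_period) || sample_period <= 0) {
    stop("sampling error: sample_period must be positive")
  }
  test_index <- as.integer(test_index)
  if (!test_index %in% c(1L, 2L)) stop("data error: test_index must be 1 or 2")
  modality <- as.character(modality)
  .modality_units(modality)  # validates
  structure(
    list(subject_id = as.character(subject_id), test_index = test_index,
         modality = modality, sample_period = as.numeric(sample_period),
         u = u, y = y, u_mean = as.numeric(u_mean), y_mean = as.numeric(y_mean),
         centered = isTRUE(centered), meta = meta),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> subject %s test %d (%s, input %s)\n",
              x$subject_id, x$test_index, x$modality,
              .modality_units(x$modality)))
  cat(sprintf("  %d samples at %g s (%.0f s), %s\n",
              n_samples(x), x$sample_period,
              (n_samples(x) - 1) * x$sample_period,
              if (x$centered) "deviation form" else "absolute units"))
  invisible(x)
}

#' Number of samples in a record
#' @param record A `signal_record`.
#' @return Integer sample count.
#' @export
n_samples <- function(record) length(record$u)

#' Read a test record from CSV + sidecar
#'
#' Expects a CSV with header `time_s,u,y` and a YAML sidecar at
#' `<path>.meta` holding `subject_id`, `test_index`, `modality`,
#' `sample_period` and preprocessing state. The time column must be the
#' uniform grid `0, h, 2h, ...` (tolerance `1e-6 * h`); it is validation
#' only, the grid itself is defined by `sample_period`.
#'
#' @param path Path to the CSV file.
#' @return A validated `signal_record`.
#' @seealso [write_record()]
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) stop("format error: missing sidecar ", meta_path)
  d <- read.csv(path, check.names = FALSE)
  need <- c("time_s", "u", "y")
  if (!all(need %in% names(d))) {
    stop("format error: CSV must have columns time_s,u,y (got: ",
         paste(names(d), collapse = ","), ")")
  }
  m <- yaml::read_yaml(meta_path)
  for (f in c("subject_id", "test_index", "modality", "sample_period")) {
    if (is.null(m[[f]])) stop("format error: sidecar missing field ", f)
  }
  h <- as.numeric(m$sample_period)
  grid <- (seq_len(nrow(d)) - 1) * h
  if (any(abs(d$time_s - grid) > 1e-6 * h)) {
    stop("sampling error: time_s is not the uniform grid at sample_period = ", h)
  }
  if (any(is.na(d$u)) || any(is.na(d$y))) stop("data error: NaN samples in ", path)
  signal_record(
    subject_id = m$subject_id, test_index = m$test_index,
    modality = m$modality, u = d$u, y = d$y, sample_period = h,
    u_mean = as.numeric(m$u_mean %||% NA_real_),
    y_mean = as.numeric(m$y_mean %||% NA_real_),
    centered = isTRUE(m$centered),
    meta = m$meta %||% list()
  )
}

#' Write a test record to CSV + sidecar
#'
#' Inverse of [read_record()]: samples are serialized at full double
#' precision so the round trip reproduces them bit-exactly, and all metadata
#' (including deviation-form offsets) goes to the `<path>.meta` sidecar.
#'
#' @param record A `signal_record`.
#' @param path Destination CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  n <- n_samples(record)
  d <- data.frame(
    time_s = sprintf("%.17g", (seq_len(n) - 1) * record$sample_period),
    u = sprintf("%.17g", record$u),
    y = sprintf("%.17g", record$y)
  )
  tryCatch(
    write.csv(d, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("I/O error: cannot write ", path, ": ",
                             conditionMessage(e))
  )
  m <- list(
    subject_id = record$subject_id,
    test_index = record$test_index,
    modality = record$modality,
    units_u = .modality_units(record$modality),
    units_y = "bpm",
    sample_period = record$sample_period,
    centered = record$centered,
    u_mean = if (is.na(record$u_mean)) NULL else record$u_mean,
    y_mean = if (is.na(record$y_mean)) NULL else record$y_mean,
    meta = if (length(record$meta)) record$meta else NULL
  )
  yaml::write_yaml(m[!vapply(m, is.null, TRUE)], paste0(path, ".meta"),
                   precision = 17)
  invisible(path)
}

#' Pair the two replicate tests of each subject
#'
#' Groups records into subject pairs (test indices 1 and 2) for
#' counterbalanced cross-validation. Subjects with only one test are
#' excluded and listed in the `unpaired` attribute of the result.
#'
#' @param records List of `signal_record` objects.
#' @return List of `record_pair` objects (fields `subject_id`, `first`,
#'   `second`), with attribute `unpaired` naming excluded subjects.
#' @export
pair_records <- function(records) {
  stopifnot(length(records) > 0,
            all(vapply(records, inherits, TRUE, "signal_record")))
  key <- vapply(records, function(r) paste(r$subject_id, r$test_index), "")
  if (anyDuplicated(key)) {
    stop("data error: duplicate (subject, test_index): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  subjects <- unique(vapply(records, function(r) r$subject_id, ""))
  pairs <- list()
  unpaired <- character(0)
  for (s in subjects) {
    rs <- records[vapply(records, function(r) r$subject_id == s, TRUE)]
    idx <- vapply(rs, function(r) r$test_index, 1L)
    if (!all(c(1L, 2L) %in% idx)) {
      unpaired <- c(unpaired, s)
      next
    }
    pairs[[length(pairs) + 1L]] <-
      record_pair(rs[[which(idx == 1L)]], rs[[which(idx == 2L)]])
  }
  if (length(unpaired)) {
    message("excluded ", length(unpaired), " unpaired subject(s): ",
            paste(unpaired, collapse = ", "))
  }
  attr(pairs, "unpaired") <- unpaired
  pairs
}

#' Construct a record pair
#'
#' @param first,second The subject's two replicate `signal_record`s
#'   (test indices 1 and 2); they must share subject, modality and sample
#'   period.
#' @return An object of class `record_pair`.
#' @export
record_pair <- function(first, second) {
  stopifnot(inherits(first, "signal_record"), inherits(second, "signal_record"))
  if (first$subject_id != second$subject_id) {
    stop("data error: pair members have different subject_id")
  }
  if (first$modality != second$modality) {
    stop("data error: pair members have different modality")
  }
  if (first$sample_period != second$sample_period) {
    stop("data error: pair members have different sample_period")
  }
  if (first$test_index != 1L || second$test_index != 2L) {
    stop("data error: pair must be (test_index 1, test_index 2)")
  }
  structure(list(subject_id = first$subject_id, first = first, second = second),
            class = "record_pair")
}

#' @export
print.record_pair <- function(x, ...) {
  cat(sprintf("<record_pair> subject %s (%s), %d + %d samples\n",
              x$subject_id, x$first$modality,
              n_samples(x$first), n_samples(x$second)))
  invisible(x)
}
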