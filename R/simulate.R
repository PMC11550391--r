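# Exact continuous-time simulation under zero-order hold with (possibly
# fractional) dead time.
#
# Each rational block is decomposed into decoupled first-order modes (or a
# Jordan pair when the two poles coincide, plus a direct feedthrough term
# when a pole degenerates), and the state is propagated exactly across every
# sub-interval on which the delayed, held input is constant. Sub-interval
# boundaries are the union of the sample instants and the delayed input's
# switch times, so a dead time that is not a multiple of the sample period
# introduces no discretization error. The zero (Tz) enters through the modal
# residues / feedthrough, never by differentiating sampled data.

# modal decomposition of k*(Tz*s+1)/((tau1*s+1)*(tau2*s+1)):
# list(a, r) simple modes, optional Jordan pair (repeated pole), direct term D
.branch_modes <- function(k, tau1, tau2, Tz = 0) {
  ztol <- 1e-12
  t1 <- if (tau1 > ztol) tau1 else 0
  t2 <- if (tau2 > ztol) tau2 else 0
  if (t1 == 0 && t2 == 0) {
    # both poles degenerate: static gain (an improper zero is dropped)
    return(list(a = numeric(0), r = numeric(0), jordan = NULL, D = k))
  }
  if (t1 == 0 || t2 == 0) {
    tau <- max(t1, t2)
    return(list(a = 1 / tau, r = k * (1 - Tz / tau) / tau,
                jordan = NULL, D = k * Tz / tau))
  }
  if (abs(t1 - t2) < 1e-9 * max(t1, t2)) {
    tau <- (t1 + t2) / 2
    return(list(a = numeric(0), r = numeric(0),
                jordan = list(a = 1 / tau,
                              w1 = k * (1 - Tz / tau) / tau^2,
                              w2 = k * Tz / tau^2),
                D = 0))
  }
  a1 <- 1 / t1
  a2 <- 1 / t2
  pref <- k / (t1 * t2)
  list(a = c(a1, a2),
       r = c(pref * (1 - Tz * a1) / (a2 - a1),
             pref * (1 - Tz * a2) / (a1 - a2)),
       jordan = NULL, D = 0)
}

.n_mode_states <- function(modes) length(modes$a) + if (is.null(modes$jordan)) 0L else 2L

# delayed held input evaluated at times t (new value holds at a switch time)
.delayed_input_at <- function(t, u, h, Td) {
  j <- floor((t - Td) / h + 1e-9)
  out <- numeric(length(t))
  ok <- j >= 0
  out[ok] <- u[pmin(j[ok], length(u) - 1L) + 1L]
  out
}

# simulate one delayed rational block against held input u at period h
.sim_branch <- function(u, h, modes, Td, x0) {
  N <- length(u)
  ts <- (seq_len(N) - 1) * h
  tol <- 1e-9 * h
  if (Td <= tol) {
    ev <- ts
    vals <- if (N > 1L) u[-N] else numeric(0)
    samp <- 0:(N - 1L)
  } else {
    tend <- ts[N]
    sw <- Td + (0:(N - 1L)) * h
    sw <- sw[sw < tend - tol]
    ev <- sort(c(ts, sw))
    ev <- ev[c(TRUE, diff(ev) > tol)]
    delta <- diff(ev)
    mid <- ev[-length(ev)] + delta / 2
    vals <- .delayed_input_at(mid, u, h, Td)
    samp <- findInterval(ts + tol, ev) - 1L
  }
  jd <- modes$jordan
  y <- sim_events(diff(ev), vals, as.integer(samp),
                  modes$a, modes$r,
                  if (is.null(jd)) 0 else jd$a,
                  if (is.null(jd)) 0 else jd$w1,
                  if (is.null(jd)) 0 else jd$w2,
                  !is.null(jd), x0)
  if (modes$D != 0) y <- y + modes$D * .delayed_input_at(ts, u, h, Td)
  y
}

# branch decomposition of a process_model: list of (modes, Td)
.model_branches <- function(model) {
  p <- model$params
  if (model$structure == "P1parP1D") {
    list(
      list(modes = .branch_modes(p[["kp1"]], p[["taup1"]], 0, 0), Td = 0),
      list(modes = .branch_modes(p[["kp2"]], p[["taup2"]], 0, 0), Td = p[["Td"]])
    )
  } else {
    list(list(modes = .branch_modes(p[["k"]], p[["tau1"]], p[["tau2"]], p[["Tz"]]),
              Td = p[["Td"]]))
  }
}

#' Number of internal states of a process model
#'
#' One state per non-degenerate first-order mode (two when the two poles
#' coincide). Used to size the `initial_state` argument of
#' [simulate_response()].
#'
#' @param model A `process_model`.
#' @return Integer state count.
#' @export
n_states <- function(model) {
  sum(vapply(.model_branches(model), function(b) .n_mode_states(b$modes), 0L))
}

#' Simulate the continuous-time response to a zero-order-held input
#'
#' Computes the exact response of the model's transfer function to the
#' piecewise-constant input defined by holding each sample of `u` for one
#' `sample_period`, delayed by the model's dead time, and returns the output
#' at the sample instants \eqn{t = 0, h, 2h, \dots}. The input is taken to be
#' zero before \eqn{t = 0}. Dead times that are not multiples of the sample
#' period are handled exactly by splitting integration at the delayed
#' switch times; no numerical integration or differentiation is involved.
#'
#' @param model A `process_model` from [make_model()].
#' @param u Numeric vector of input samples (zero-order held).
#' @param sample_period Sampling interval in seconds (default 5).
#' @param initial_state Optional numeric vector of length
#'   [n_states()]`(model)` giving the modal state at \eqn{t = 0}; defaults to
#'   zero (rest). States are ordered branch by branch, fast-structure modes
#'   in the order of their poles as constructed.
#' @return Numeric vector of output samples, same length as `u`.
#' @examples
#' m <- make_model("P1", list(k = 1, tau1 = 10))
#' y <- simulate_response(m, rep(1, 5), sample_period = 5)
#' y[3]  # response at t = 10 s: 1 - exp(-1)
#' @export
simulate_response <- function(model, u, sample_period = 5, initial_state = NULL) {
  stopifnot(inherits(model, "process_model"))
  if (!is.numeric(sample_period) || length(sample_period) != 1L ||
      !is.finite(sample_period) || sample_period <= 0) {
    stop("sample_period must be a positive number")
  }
  u <- as.numeric(u)
  if (length(u) < 1L) stop("u must contain at least one sample")
  if (any(!is.finite(u))) stop("data error: non-finite input samples")
  branches <- .model_branches(model)
  ns <- vapply(branches, function(b) .n_mode_states(b$modes), 0L)
  if (is.null(initial_state)) {
    initial_state <- numeric(sum(ns))
  } else {
    initial_state <- as.numeric(initial_state)
    if (length(initial_state) != sum(ns)) {
      stop("initial_state must have length ", sum(ns))
    }
  }
  y <- numeric(length(u))
  off <- 0L
  for (i in seq_along(branches)) {
    x0 <- if (ns[i] > 0L) initial_state[(off + 1L):(off + ns[i])] else numeric(0)
    off <- off + ns[i]
    y <- y + .sim_branch(u, sample_period, branches[[i]]$modes, branches[[i]]$Td, x0)
  }
  y
}

#' Step response of a process model
#'
#' Convenience wrapper around [simulate_response()] for a constant input of
#' the given amplitude applied at \eqn{t = 0} from rest. As the horizon grows
#' the response approaches `amplitude` times the steady-state gain
#' ([dc_gain()]).
#'
#' @param model A `process_model`.
#' @param amplitude Step height in input units.
#' @param horizon Duration to simulate, seconds.
#' @param sample_period Sampling interval in seconds (default 5).
#' @return A data frame with columns `time_s` and `y`.
#' @examples
#' m <- make_model("P1D", list(k = 25, tau1 = 47.7, Td = 13.1))
#' tail(step_response(m, 1, horizon = 600), 1)  # approaches k = 25
#' @export
step_response <- function(model, amplitude, horizon, sample_period = 5) {
  if (!is.numeric(horizon) || horizon <= 0) stop("horizon must be positive")
  n <- floor(horizon / sample_period) + 1L
  u <- rep(as.numeric(amplitude), n)
  data.frame(time_s = (seq_len(n) - 1) * sample_period,
             y = simulate_response(model, u, sample_period))
}
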