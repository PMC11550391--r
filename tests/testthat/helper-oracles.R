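# Independent oracles used across the suite. These never call the package's
# simulation internals: step responses come from textbook closed forms
# (residue expansions), and the dense-grid simulator below uses a
# companion-form state space propagated with a matrix exponential on an
# oversampled time grid.

# Closed-form unit-scaled step response of k(Tz s+1)/((tau1 s+1)(tau2 s+1))
# shifted by Td, evaluated at times t (t >= 0, step applied at 0).
# Assumes tau1 != tau2 and both > 0 (tests pick distinct poles).
closed_step_branch <- function(t, k, tau1, tau2 = 0, Tz = 0, Td = 0) {
  ts <- t - Td
  y <- numeric(length(t))
  on <- ts >= 0
  s <- ts[on]
  if (tau2 == 0) {
    y[on] <- k * (1 - (1 - Tz / tau1) * exp(-s / tau1))
  } else {
    A1 <- k * (Tz - tau1) / (tau1 - tau2)
    A2 <- k * (Tz - tau2) / (tau2 - tau1)
    y[on] <- k + A1 * exp(-s / tau1) + A2 * exp(-s / tau2)
  }
  y
}

# Closed-form step response for any of the seven structures, amplitude amp.
closed_step <- function(structure, p, t, amp = 1) {
  p <- as.list(p)
  if (structure == "P1parP1D") {
    amp * (closed_step_branch(t, p$kp1, p$taup1) +
           closed_step_branch(t, p$kp2, p$taup2, Td = p$Td))
  } else {
    amp * closed_step_branch(t, p$k, p$tau1,
                             tau2 = if (is.null(p$tau2)) 0 else p$tau2,
                             Tz = if (is.null(p$Tz)) 0 else p$Tz,
                             Td = if (is.null(p$Td)) 0 else p$Td)
  }
}

# Dense-grid reference simulation: companion-form state space, input held on
# a grid oversampled `over`-fold, delay realised by shifting the fine-grid
# input. Exact when Td is a multiple of h/over. Returns output at the
# coarse sample instants.
dense_sim <- function(structure, p, u, h, over = 100) {
  p <- as.list(p)
  N <- length(u)
  hf <- h / over
  nf <- (N - 1) * over + 1
  uf <- u[pmin(floor((seq_len(nf) - 1) / over) + 1, N)]

  one_branch <- function(k, tau1, tau2, Tz, Td) {
    shift <- as.integer(round(Td / hf))
    ub <- if (shift > 0) c(rep(0, shift), uf)[seq_len(nf)] else uf
    if (tau2 == 0 && tau1 == 0) return(k * ub)
    if (tau2 == 0) {
      A <- matrix(-1 / tau1)
      B <- matrix(1)
      C <- matrix((k - k * Tz / tau1) / tau1)
      D <- k * Tz / tau1
    } else {
      a0 <- 1 / (tau1 * tau2)
      a1 <- (tau1 + tau2) / (tau1 * tau2)
      A <- matrix(c(0, -a0, 1, -a1), 2, 2)
      B <- matrix(c(0, 1))
      C <- matrix(c(k * a0, k * Tz * a0), 1, 2)
      D <- 0
    }
    Ad <- as.matrix(Matrix::expm(A * hf))
    Bd <- solve(A, (Ad - diag(nrow(A))) %*% B)
    x <- matrix(0, nrow(A), 1)
    y <- numeric(nf)
    for (i in seq_len(nf)) {
      y[i] <- C %*% x + D * ub[i]
      x <- Ad %*% x + Bd * ub[i]
    }
    y
  }

  yf <- if (structure == "P1parP1D") {
    one_branch(p$kp1, p$taup1, 0, 0, 0) +
      one_branch(p$kp2, p$taup2, 0, 0, p$Td)
  } else {
    one_branch(p$k, p$tau1,
               if (is.null(p$tau2)) 0 else p$tau2,
               if (is.null(p$Tz)) 0 else p$Tz,
               if (is.null(p$Td)) 0 else p$Td)
  }
  yf[seq(1, nf, by = over)]
}

# Representative parameter sets (one per structure) used by several tests.
reference_truths <- function() {
  list(
    P1       = list(k = 28.6, tau1 = 70.6),
    P1D      = list(k = 25.0, tau1 = 47.7, Td = 13.1),
    P2       = list(k = 24.7, tau1 = 18.6, tau2 = 37.8),
    P2D      = list(k = 23.9, tau1 = 13.7, tau2 = 37.8, Td = 5.4),
    P2Z      = list(k = 24.1, tau1 = 24.9, tau2 = 40.2, Tz = 7.3),
    P2ZD     = list(k = 23.7, tau1 = 33.2, tau2 = 50.6, Tz = 38.4, Td = 11.1),
    P1parP1D = list(kp1 = 7.0, taup1 = 141.5, kp2 = 20.2, taup2 = 34.3,
                    Td = 17.9)
  )
}

# Noise-free centered record whose deviations are the exact zero-state
# response of `model` to the centered PRBS input.
make_truth_record <- function(model, prbs_seed = 3, modality = "TM",
                              duration = 1800) {
  cfg <- default_prbs(modality, seed = prbs_seed, duration = duration)
  u <- generate_prbs(cfg)
  y <- simulate_response(model, u - mean(u), cfg$sample_period)
  to_deviations(signal_record("S1", 1, modality, u, y + 120,
                              cfg$sample_period))
}
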