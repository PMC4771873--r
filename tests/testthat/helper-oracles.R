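# Shared fixtures and independent oracles used across the suite.

# Explicit-Euler propagation oracle for piecewise-constant protocols:
# independent of the eigendecomposition path used by propagate().
euler_oracle <- function(p0, segments, conditions, params, sample_times, h) {
  out <- matrix(NA_real_, length(sample_times), 4)
  t <- 0
  p <- as.numeric(p0)
  i <- 1
  for (sg in seq_len(nrow(segments))) {
    Q <- rate_matrix(segments$mV[sg], conditions, params)
    for (k in seq_len(round(segments$ms[sg] / h))) {
      while (i <= length(sample_times) && abs(sample_times[i] - t) < h / 2) {
        out[i, ] <- p
        i <- i + 1
      }
      p <- p + h * (Q %*% p)
      t <- t + h
    }
  }
  while (i <= length(sample_times)) {
    out[i, ] <- p
    i <- i + 1
  }
  out
}

# Noise-free synthetic exponential trace: I(t) = a * exp(-t/tau) + b.
make_exp_trace <- function(tau = 4, a = 120, b = 10, t_max = 40, dt = 0.05) {
  t <- seq(0, t_max, by = dt)
  current_trace(t, rep(0, length(t)), a * exp(-t / tau) + b)
}

# Synthetic G-V curve from an exact Boltzmann.
make_boltzmann_gv <- function(z, v_half, amp = 1, offset = 0,
                              v = seq(-100, 100, 20), temperature = 294) {
  s <- thermal_voltage(temperature) / z
  data.frame(prepulse_mV = v,
             amplitude_pA = amp / (1 + exp(-(v - v_half) / s)) + offset)
}

# Hand-built crossing trajectory: `n_cross` ions each making one complete
# outward passage, plus one distractor ion making `n_excursion` partial
# excursions that reach S2 and return.
make_hand_trajectory <- function(n_cross = 3, n_excursion = 2,
                                 n_frames = 200) {
  path <- c(-0.3, 0.15, 0.45, 0.75, 1.05, 1.3)
  exc <- c(-0.3, 0.45, 0.75, 0.45, -0.3)
  pos <- matrix(-3, n_frames, n_cross + 1)
  for (j in seq_len(n_cross)) {
    f_end <- 20 * j + length(path)
    pos[(f_end - length(path) + 1):f_end, j] <- path
    pos[(f_end + 1):n_frames, j] <- 4
  }
  for (e in seq_len(n_excursion)) {
    f_end <- 100 + 15 * e
    pos[(f_end - length(exc) + 1):f_end, n_cross + 1] <- exc
  }
  ion_trajectory(pos, dt_ns = 1)
}

# Small fast step family for pipeline tests (shorter segments, coarser dt).
quick_family <- function(preset, prepulse_mV = c(-100, -80, 0, 100),
                         ...) {
  generate_family(preset, prepulse_mV = prepulse_mV,
                  hold_ms = 20, step_ms = 120, tail_ms = 60, dt = 0.1, ...)
}
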