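# Four-state selectivity-filter kinetic scheme driven by the electrochemical
# driving force Dmu = Vm - Erev:
#
#   ID  (ion-depleted inactive)  <->  IO (ion-occupied inactive)
#   IO  --k_act-->  AO (active, outward-conducting)   [Dmu >= 0 only]
#   AO  --k_deact--> IO
#   AO <-> AI relabeling by the sign of Dmu (conduction-direction tag)
#   AI  --k_inact--> ID (inactivation of the unstable inward-conducting state)
#
# Ion loading ID<->IO carries the gating charge: forward/backward rates are
# k_load0 * exp(+-(Dmu - Dmu1/2)/(2 s)) with s = RT/(zF), so the equilibrium
# occupancy of IO among the inactive states is the Boltzmann of the driving
# force. Macroscopic current is the open-pore GHK flux weighted by the active
# occupancy (plus a small residual conductance of the inactive states), mixed
# with a fraction m of channels in GHK leak mode.

.FILTER_STATES <- c("ID", "IO", "AO", "AI")

#' Enumerated filter states
#'
#' @return Character vector `c("ID", "IO", "AO", "AI")`: ion-depleted
#'   inactive, ion-occupied inactive, active outward-conducting, and active
#'   inward-conducting (unstable).
#' @export
filter_states <- function() .FILTER_STATES

#' Kinetic and thermodynamic parameters of one channel model
#'
#' @param z Equivalent gating charge (e0), > 0. Sets the Boltzmann slope
#'   RT/(zF) of the ion-loading equilibrium.
#' @param dmu_half Driving force at half-maximal ion loading (mV).
#' @param k_load0 Base loading rate (1/ms). Loading is presumed fast relative
#'   to the conformational step; default 10/ms.
#' @param k_act Voltage-independent activation rate IO -> AO (1/ms). Applies
#'   whenever Dmu >= 0 (outward flux regime).
#' @param k_deact AO -> IO back-rate (1/ms); small by default so activation
#'   is near-irreversible at positive driving force.
#' @param k_inact AI -> ID inactivation rate (1/ms); 1/k_inact is the tail
#'   decay time constant.
#' @param po_floor Residual conductance fraction of the inactive states
#'   (dimensionless, in [0, 1)). Provides the finite inward current of
#'   inactive channels that yields a finite rectification coefficient.
#' @param mode_shift Fraction m of channels in GHK leak mode (0..1); leak-mode
#'   channels conduct the open-pore GHK current with no gating.
#' @param n_channels Channel count in the patch.
#' @param gamma_scale Unitary conductance scale, pA per unit GHK flux.
#' @param k_switch AO <-> AI conduction-direction relabeling rate (1/ms);
#'   fast by default (200/ms) so the tag follows the sign of Dmu essentially
#'   instantaneously on the sampling grid.
#' @return An object of class `gating_params`.
#' @export
gating_params <- function(z, dmu_half, k_load0 = 10, k_act, k_deact = 0.02,
                          k_inact, po_floor = 0, mode_shift = 0,
                          n_channels = 100, gamma_scale = 0.01,
                          k_switch = 200) {
  rates <- c(k_load0 = k_load0, k_act = k_act, k_deact = k_deact,
             k_inact = k_inact, k_switch = k_switch)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rate constants must be finite and > 0")
  stopifnot(is.numeric(z), length(z) == 1, z > 0,
            is.numeric(dmu_half), is.finite(dmu_half))
  if (!(po_floor >= 0 && po_floor < 1)) stop("po_floor must be in [0, 1)")
  if (!(mode_shift >= 0 && mode_shift <= 1)) stop("mode_shift must be in [0, 1]")
  stopifnot(n_channels >= 0, gamma_scale > 0)
  structure(list(z = z, dmu_half = dmu_half, k_load0 = k_load0,
                 k_act = k_act, k_deact = k_deact, k_inact = k_inact,
                 po_floor = po_floor, mode_shift = mode_shift,
                 n_channels = n_channels, gamma_scale = gamma_scale,
                 k_switch = k_switch),
            class = "gating_params")
}

#' @export
print.gating_params <- function(x, ...) {
  cat(sprintf(paste0(
    "Gating parameters: z = %g e0, Dmu1/2 = %g mV\n",
    "  rates (1/ms): load0 %g, act %g, deact %g, inact %g\n",
    "  po_floor %g, mode_shift %g, %g channels, gamma %g pA/flux\n"),
    x$z, x$dmu_half, x$k_load0, x$k_act, x$k_deact, x$k_inact,
    x$po_floor, x$mode_shift, x$n_channels, x$gamma_scale))
  invisible(x)
}

#' State probability vector
#'
#' @param p Numeric vector of four probabilities, optionally named after
#'   [filter_states()]; must be in [0, 1] and sum to 1 within 1e-9.
#' @return Named numeric vector of class `state_vector`.
#' @export
state_vector <- function(p) {
  if (length(p) != 4) stop("state vector must have four entries")
  if (!is.null(names(p))) {
    if (!setequal(names(p), .FILTER_STATES)) stop("bad state names")
    p <- p[.FILTER_STATES]
  } else names(p) <- .FILTER_STATES
  if (any(p < -1e-12) || any(p > 1 + 1e-12) || abs(sum(p) - 1) > 1e-9)
    stop("state probabilities must lie in [0, 1] and sum to 1")
  structure(pmin(pmax(as.numeric(p), 0), 1),
            names = .FILTER_STATES, class = "state_vector")
}

#' Equilibrium probability of the ion-occupied state among inactive states
#'
#' The Boltzmann 1 / (1 + exp(-(Dmu - Dmu1/2)/s)) with slope s = RT/(zF) mV,
#' i.e. the voltage-sensing step of the model: the distribution between the
#' ion-depleted and ion-occupied inactive filter set by the driving force.
#'
#' @param dmu Driving force, mV (vectorised).
#' @param params A [gating_params()] object.
#' @param temperature Kelvin (default 294).
#' @return Probability in (0, 1).
#' @export
loading_equilibrium <- function(dmu, params, temperature = 294) {
  stopifnot(inherits(params, "gating_params"), all(is.finite(dmu)))
  s <- thermal_voltage(temperature) / params$z
  stats::plogis((dmu - params$dmu_half) / s)
}

# Exponent clamp for the loading rates: keeps the generator non-stiff
# (rate factor <= ~1e3) while preserving the equilibrium ratio wherever the
# Boltzmann is not already within 1e-3 of saturation.
.LOAD_EXP_CAP <- 6.9

#' Generator matrix of the four-state scheme
#'
#' Returns the 4x4 continuous-time Markov generator Q (convention
#' dP/dt = Q P; off-diagonals >= 0, columns sum to zero) at a given membrane
#' voltage. The ID<->IO rates satisfy detailed balance with
#' [loading_equilibrium()] through a symmetric barrier (delta = 0.5); the
#' conformational activation IO -> AO proceeds at the voltage-independent
#' rate `k_act` in the outward-flux regime (Dmu >= 0); the active state is
#' relabeled AO or AI by the sign of Dmu; and the unstable inward-conducting
#' AI state inactivates to the structurally distinct ion-depleted ID state
#' at `k_inact`.
#'
#' @param vm Membrane voltage, mV.
#' @param conditions A [bath_conditions()] object.
#' @param params A [gating_params()] object.
#' @return 4x4 generator matrix with dimnames [filter_states()].
#' @export
rate_matrix <- function(vm, conditions, params) {
  df <- driving_force(vm, conditions)
  dmu <- df$dmu
  s <- thermal_voltage(conditions$temperature) / params$z
  x <- (dmu - params$dmu_half) / s
  kf <- params$k_load0 * exp(min(max(x / 2, -.LOAD_EXP_CAP), .LOAD_EXP_CAP))
  kb <- params$k_load0 * exp(min(max(-x / 2, -.LOAD_EXP_CAP), .LOAD_EXP_CAP))
  Q <- matrix(0, 4, 4, dimnames = list(.FILTER_STATES, .FILTER_STATES))
  Q["IO", "ID"] <- kf
  Q["ID", "IO"] <- kb
  Q["IO", "AO"] <- params$k_deact
  Q["ID", "AI"] <- params$k_inact
  if (dmu >= 0) {
    Q["AO", "IO"] <- params$k_act
    Q["AO", "AI"] <- params$k_switch
  } else {
    Q["AI", "AO"] <- params$k_switch
  }
  diag(Q) <- -colSums(Q)
  Q
}

#' Stationary state of the scheme at a fixed voltage
#'
#' Solves Q pi = 0 with sum(pi) = 1 (least-squares on the stacked system).
#' Errors if the generator admits no unique stationary distribution.
#'
#' @inheritParams rate_matrix
#' @return A [state_vector()].
#' @export
steady_state <- function(vm, conditions, params) {
  Q <- rate_matrix(vm, conditions, params)
  A <- rbind(Q, rep(1, 4))
  b <- c(numeric(4), 1)
  sol <- tryCatch(qr.solve(A, b), error = function(e)
    stop("no unique steady state: ", conditionMessage(e)))
  if (max(abs(A %*% sol - b)) > 1e-8)
    stop("no unique steady state for this generator")
  state_vector(pmin(pmax(sol, 0), 1) / sum(pmin(pmax(sol, 0), 1)))
}

#' Voltage-clamp protocol
#'
#' An ordered list of constant-voltage (or linear-ramp) segments sampled on a
#' uniform grid.
#'
#' @param segments `data.frame` with columns `ms` (duration, > 0) and `mV`
#'   (segment voltage); an optional `mV_end` column makes a segment a linear
#'   ramp from `mV` to `mV_end`.
#' @param dt Sample interval, ms; must not exceed the shortest segment.
#' @return An object of class `voltage_protocol`.
#' @export
#' @examples
#' voltage_protocol(data.frame(ms = c(50, 300, 100), mV = c(-80, 100, -80)))
voltage_protocol <- function(segments, dt = 0.05) {
  stopifnot(is.data.frame(segments), all(c("ms", "mV") %in% names(segments)))
  if (nrow(segments) == 0) stop("protocol needs at least one segment")
  if (any(segments$ms <= 0)) stop("segment durations must be > 0")
  if (!(dt > 0)) stop("dt must be > 0")
  if (dt > min(segments$ms)) stop("dt must not exceed the shortest segment")
  if (is.null(segments$mV_end)) segments$mV_end <- NA_real_
  structure(list(segments = segments, dt = dt), class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat("Voltage protocol, dt =", x$dt, "ms\n")
  print(x$segments)
  invisible(x)
}

# Dense matrix exponential by scaling-and-squaring of a truncated Taylor
# series; fallback path only (the main propagator is eigendecomposition).
.expm_dense <- function(A) {
  nrm <- max(colSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.xmin))) + 1L)
  As <- A / 2^s
  E <- diag(nrow(A))
  term <- E
  for (k in 1:18) {
    term <- term %*% As / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

# Propagate p0 under constant generator Q, returning the state at each of
# `times` (>= 0, ms) plus the state at `t_end`. Eigendecomposition when well
# conditioned, otherwise stepping with a dense matrix exponential.
.propagate_const <- function(Q, p0, times, t_end) {
  ok <- FALSE
  S <- NULL
  p_end <- NULL
  ev <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(ev)) {
    co <- tryCatch(solve(ev$vectors, p0), error = function(e) NULL)
    if (!is.null(co)) {
      S <- Re(ev$vectors %*% (co * exp(outer(ev$values, times))))
      p_end <- Re(ev$vectors %*% (co * exp(ev$values * t_end)))
      ok <- all(is.finite(S)) && max(abs(colSums(S) - 1)) < 1e-7
    }
  }
  if (!ok) {
    # step on the union grid of sample times and t_end
    dtv <- diff(c(0, times, t_end))
    S <- matrix(NA_real_, 4, length(times))
    p <- p0
    for (i in seq_along(dtv)) {
      if (dtv[i] > 0) p <- .expm_dense(Q * dtv[i]) %*% p
      if (i <= length(times)) S[, i] <- p
    }
    p_end <- p
  }
  list(states = S, p_end = as.numeric(p_end))
}

#' Propagate the state vector through a voltage protocol
#'
#' Piecewise-constant propagation: within each constant-voltage segment the
#' generator is fixed and the state is advanced by its exact matrix
#' exponential (via eigendecomposition); ramp segments are stepped per sample
#' with the generator evaluated at the midpoint voltage. Samples are at
#' t = 0, dt, 2 dt, ...; the first sample of each segment is at the segment
#' start (voltage already switched).
#'
#' @param initial_state A [state_vector()] (or NULL to equilibrate at the
#'   first segment's starting voltage).
#' @param protocol A [voltage_protocol()].
#' @param conditions A [bath_conditions()] object.
#' @param params A [gating_params()] object.
#' @return A list with `time` (ms), `voltage` (mV) and `states`
#'   (n x 4 matrix of probabilities, columns [filter_states()]).
#' @export
propagate <- function(initial_state, protocol, conditions, params) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  seg <- protocol$segments
  dt <- protocol$dt
  if (is.null(initial_state)) {
    p <- steady_state(seg$mV[1], conditions, params)
  } else {
    p <- state_vector(initial_state)  # validates normalisation
  }
  n_seg <- round(seg$ms / dt)
  n_tot <- sum(n_seg)
  time <- (seq_len(n_tot) - 1) * dt
  voltage <- numeric(n_tot)
  states <- matrix(NA_real_, n_tot, 4,
                   dimnames = list(NULL, .FILTER_STATES))
  at <- 0L
  for (i in seq_len(nrow(seg))) {
    n <- n_seg[i]
    idx <- at + seq_len(n)
    if (is.na(seg$mV_end[i])) {
      v <- rep(seg$mV[i], n)
      Q <- rate_matrix(seg$mV[i], conditions, params)
      res <- .propagate_const(Q, as.numeric(p), (seq_len(n) - 1) * dt,
                              seg$ms[i])
      states[idx, ] <- t(res$states)
      p <- res$p_end
    } else {
      v <- seg$mV[i] + (seg$mV_end[i] - seg$mV[i]) * (seq_len(n) - 1) / n
      pcur <- as.numeric(p)
      for (k in seq_len(n)) {
        states[idx[k], ] <- pcur
        vmid <- seg$mV[i] +
          (seg$mV_end[i] - seg$mV[i]) * (k - 0.5) / n
        Q <- rate_matrix(vmid, conditions, params)
        pcur <- as.numeric(.expm_dense(Q * dt) %*% pcur)
      }
      p <- pcur
    }
    voltage[idx] <- v
    at <- at + n
  }
  states <- pmin(pmax(states, 0), 1)
  list(time = time, voltage = voltage, states = states,
       final = state_vector(p / sum(p)))
}

#' Sampled current record
#'
#' @param time Strictly increasing, uniformly spaced sample times (ms).
#' @param voltage Command voltage at each sample (mV).
#' @param current Current at each sample (pA).
#' @param meta Optional metadata list (preset name, conditions, seed, ...).
#' @return A `data.frame` of class `current_trace` with columns `time_ms`,
#'   `voltage_mV`, `current_pA`; metadata kept in attributes.
#' @export
current_trace <- function(time, voltage, current, meta = list()) {
  n <- length(time)
  stopifnot(length(voltage) == n, length(current) == n, n >= 2)
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt))
    stop("time must be strictly increasing and uniformly sampled")
  structure(data.frame(time_ms = time, voltage_mV = voltage,
                       current_pA = current),
            meta = meta, class = c("current_trace", "data.frame"))
}

#' Simulate the macroscopic current under a protocol
#'
#' Every protocol is preceded by a steady-state equilibration at the first
#' segment's voltage (the holding potential). The current is
#' `I(t) = n_channels * gamma_scale * ghk(V(t)) *
#'   [(1 - m) * (P_AO + P_AI + po_floor * (P_ID + P_IO)) + m]`
#' where `ghk` is the total open-pore GHK flux over all permeant species and
#' `m` the leak-mode fraction. Flux-gated presets (m = 0) in symmetric K+
#' rectify outward and produce transient inward tails that decay with
#' 1/k_inact; m = 1 gives an instantaneous, history-free GHK conductance.
#'
#' @inheritParams propagate
#' @param meta Metadata list stored on the trace.
#' @return A [current_trace()].
#' @export
simulate_current <- function(protocol, conditions, params, meta = list()) {
  res <- propagate(NULL, protocol, conditions, params)
  flux <- ghk_current_total(res$voltage, conditions)
  m <- params$mode_shift
  po <- (1 - m) * (res$states[, "AO"] + res$states[, "AI"] +
                     params$po_floor *
                       (res$states[, "ID"] + res$states[, "IO"])) + m
  i_pa <- params$n_channels * params$gamma_scale * flux * po
  meta$dt_ms <- protocol$dt
  current_trace(res$time, res$voltage, i_pa, meta = meta)
}
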