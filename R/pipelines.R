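# End-to-end analysis helpers chaining the simulator and the measurement
# pipeline, as a bench scientist would: simulate a family, build the G-V,
# fit the Boltzmann; fit activation/deactivation time constants; scan the
# V1/2-versus-Erev coupling across external K+.

#' G-V curve and Boltzmann fit for one trace family
#'
#' @param family A `trace_family` from [generate_family()].
#' @return List with `gv` ([build_gv()] result) and `fit`
#'   ([fit_boltzmann()] result).
#' @export
fit_gv_family <- function(family) {
  gv <- build_gv(family)
  list(gv = gv, fit = fit_boltzmann(gv, temperature = family$temperature))
}

#' Activation time constants across step voltages
#'
#' Single-exponential fits of the current onset during the depolarising
#' step, one per requested voltage.
#'
#' @param family A `trace_family`.
#' @param step_mV Voltages to fit (default: all steps above +10 mV).
#' @param skip_ms Initial samples to skip after the step edge (default 0.2).
#' @param fit_ms Onset window length to fit, ms (default 80).
#' @return `data.frame` with columns `mV` and `tau_ms`.
#' @export
activation_tau <- function(family, step_mV = NULL, skip_ms = 0.2,
                           fit_ms = 80) {
  stopifnot(inherits(family, "trace_family"))
  if (is.null(step_mV)) step_mV <- family$step_mV[family$step_mV > 10]
  if (!all(step_mV %in% family$step_mV)) stop("requested step not in family")
  t0 <- family$step_start_ms
  t1 <- min(t0 + fit_ms, family$tail_start_ms)
  tau <- vapply(step_mV, function(v) {
    tr <- family$traces[[match(v, family$step_mV)]]
    fit_exponential(tr, c(t0 + skip_ms, t1))$tau
  }, numeric(1))
  data.frame(mV = step_mV, tau_ms = tau)
}

#' Tail (deactivation/inactivation) time constant
#'
#' @param family A `trace_family`.
#' @param step_mV Pre-pulse voltage whose tail to fit (default +100 mV).
#' @return Tail decay time constant, ms.
#' @export
tail_tau <- function(family, step_mV = 100) {
  stopifnot(inherits(family, "trace_family"),
            step_mV %in% family$step_mV)
  tr <- family$traces[[match(step_mV, family$step_mV)]]
  extract_tail_amplitude(tr, family$tail_start_ms)$tau
}

#' V1/2-versus-Erev scan over external K+
#'
#' Re-simulates noise-free G-V families for one preset at several external
#' K+ concentrations and regresses the fitted V1/2 on the computed reversal
#' potential. Each condition's protocol is anchored at its own Erev
#' (hold/tail at Erev - 80 mV, pre-pulses Erev - 80 .. Erev + 120 mV) so the
#' Boltzmann is sampled through both plateaus everywhere; V1/2 is still
#' measured in absolute mV, so a voltage- rather than flux-sensing channel
#' would give slope 0, not 1.
#'
#' @param preset Preset name or object.
#' @param ext_K External K+ concentrations, mM (default 4, 8, 120).
#' @param prepulse_offsets Pre-pulse voltages relative to Erev, mV.
#' @param dt Sample interval, ms.
#' @return A [v_half_vs_erev()] result (slope, intercept, table) with the
#'   per-condition Boltzmann fits attached as `fits`.
#' @export
scan_vhalf_vs_erev <- function(preset, ext_K = c(4, 8, 120),
                               prepulse_offsets = seq(-80, 120, by = 20),
                               dt = 0.05) {
  preset <- .as_preset(preset)
  rows <- lapply(ext_K, function(k) {
    cond <- bath_conditions(int = preset$conditions$int, ext = c(K = k),
                            temperature = preset$conditions$temperature)
    erev <- ghk_reversal(cond)
    fam <- generate_family(preset, prepulse_mV = erev + prepulse_offsets,
                           hold_mV = erev - 80, tail_mV = erev - 80,
                           dt = dt, conditions = cond)
    fit <- fit_gv_family(fam)$fit
    list(erev = erev, fit = fit)
  })
  tbl <- data.frame(
    erev_mV = vapply(rows, `[[`, numeric(1), "erev"),
    v_half_mV = vapply(rows, function(r) r$fit$v_half, numeric(1)))
  res <- v_half_vs_erev(tbl)
  res$fits <- lapply(rows, `[[`, "fit")
  res
}
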