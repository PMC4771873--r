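# Measurement pipeline mirroring patch-clamp practice: exponential tau fits,
# tail-current extraction, G-V construction, Boltzmann z/V1/2 fitting,
# rectification and fold-change statistics, Hill dose-response fits, and the
# V1/2-versus-Erev coupling line.

# Shared Levenberg-Marquardt driver over minpack.lm::nls.lm with box
# constraints; returns estimates and standard errors from the approximate
# Hessian. Avoids the post-fit model reconstruction of nls(), which rejects
# perfect (zero-residual) fits as singular.
.lm_fit <- function(par0, lower, upper, residual_fn, maxiter = 300) {
  res <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = residual_fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter))
  if (!(res$info %in% 1:4))
    stop("nonlinear fit failed to converge: ", res$message)
  p <- length(par0)
  n <- length(res$fvec)
  sigma2 <- sum(res$fvec^2) / max(n - p, 1)
  se <- tryCatch(sqrt(pmax(diag(solve(res$hessian)) * sigma2, 0)),
                 error = function(e) rep(NA_real_, p))
  names(se) <- names(par0)
  list(par = res$par, se = se, rms = sqrt(mean(res$fvec^2)))
}

.trace_window <- function(trace, window) {
  stopifnot(inherits(trace, "current_trace"), length(window) == 2,
            window[2] > window[1])
  sel <- trace$time_ms >= window[1] & trace$time_ms <= window[2]
  if (!any(sel)) stop("fit window lies outside the trace")
  trace[sel, , drop = FALSE]
}

#' Single-exponential fit of a trace segment
#'
#' Least-squares fit of A * exp(-(t - t0)/tau) + B over the window (t0 = the
#' window start), by Levenberg-Marquardt with analytic initial guesses.
#'
#' @param trace A [current_trace()].
#' @param window `c(start_ms, end_ms)` within the trace; at least 10 samples.
#' @param tau_bounds Optional `c(min, max)` bounds on the fitted time
#'   constant, ms; defaults to a wide range tied to the sampling interval
#'   and window length.
#' @return An object of class `exp_fit`: `tau` (ms), `amplitude` (A, pA),
#'   `baseline` (B, pA), `rms` residual (pA), `t_ref` (t0, ms).
#' @export
fit_exponential <- function(trace, window, tau_bounds = NULL) {
  seg <- .trace_window(trace, window)
  if (nrow(seg) < 10) stop("fit window must contain at least 10 samples")
  tr <- seg$time_ms - seg$time_ms[1]
  y <- seg$current_pA
  span <- diff(range(y))
  if (span < max(1e-9 * max(abs(y)), 1e-12))
    stop("trace is flat over the fit window; no exponential component")
  n <- length(y)
  b0 <- mean(y[max(1, floor(0.8 * n)):n])
  a0 <- y[1] - b0
  # crude tau from the 1/e point of the transient
  rel <- abs(y - b0)
  ie <- which(rel <= abs(a0) / exp(1))[1]
  tau0 <- if (!is.na(ie) && ie > 1) tr[ie] else max(tr) / 5
  if (is.null(tau_bounds))
    tau_bounds <- c((tr[2] - tr[1]) / 10, 50 * max(tr))
  tau0 <- min(max(tau0, max(tau_bounds[1], 10 * (tr[2] - tr[1]))),
              min(tau_bounds[2], max(tr)))
  fit <- tryCatch(
    .lm_fit(c(A = a0, tau = tau0, B = b0),
            lower = c(A = -Inf, tau = tau_bounds[1], B = -Inf),
            upper = c(A = Inf, tau = tau_bounds[2], B = Inf),
            function(p) p[["A"]] * exp(-tr / p[["tau"]]) + p[["B"]] - y),
    error = function(e)
      stop("exponential fit failed to converge: ", conditionMessage(e)))
  cf <- fit$par
  structure(list(tau = unname(cf["tau"]), amplitude = unname(cf["A"]),
                 baseline = unname(cf["B"]), rms = fit$rms,
                 t_ref = seg$time_ms[1], window = window),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fit: tau = %.4g ms, A = %.4g pA, B = %.4g pA (rms %.3g)\n",
              x$tau, x$amplitude, x$baseline, x$rms))
  invisible(x)
}

#' Tail-current amplitude at the repolarisation instant
#'
#' Fits a single exponential to the tail, excluding a short blanking window
#' after the voltage step (capacitive settle), and extrapolates back to the
#' repolarisation instant. `amplitude` is the extrapolated instantaneous
#' total current (transient plus fitted steady baseline) -- the quantity
#' plotted in tail I-V and G-V curves; the decaying component alone is in
#' `transient` and the fitted steady tail current in `baseline`. A tail with
#' no resolvable decay (e.g. a pure leak-mode trace) is handled as flat:
#' the amplitude is then the mean tail current and `tau` is NA.
#'
#' @param trace A [current_trace()].
#' @param repolarization_time Time (ms) at which the tail segment begins.
#' @param blank_ms Blanking window after repolarisation (default 0.3 ms).
#' @param fit_ms Length of tail to fit (default: to the end of the trace);
#'   the tail must be at least 5 ms long.
#' @param tau_bounds Bounds on the tail decay time constant, ms (default
#'   0.5-200): decays faster than the capacitive settle cannot be resolved
#'   and would make the back-extrapolation meaningless on noisy data.
#' @return An object of class `tail_fit` with `amplitude` (pA),
#'   `transient` (pA), `baseline` (pA), `tau` (ms or NA).
#' @export
extract_tail_amplitude <- function(trace, repolarization_time,
                                   blank_ms = 0.3, fit_ms = NULL,
                                   tau_bounds = c(0.5, 200)) {
  t_end <- if (is.null(fit_ms)) max(trace$time_ms)
           else repolarization_time + fit_ms
  if (t_end - repolarization_time < 5)
    stop("tail segment must be at least 5 ms long")
  window <- c(repolarization_time + blank_ms, t_end)
  fit <- tryCatch(fit_exponential(trace, window, tau_bounds = tau_bounds),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    seg <- .trace_window(trace, window)
    i0 <- mean(seg$current_pA)
    return(structure(list(amplitude = i0, transient = 0, baseline = i0,
                          tau = NA_real_, flat = TRUE),
                     class = "tail_fit"))
  }
  a_inst <- fit$amplitude * exp(blank_ms / fit$tau)
  structure(list(amplitude = a_inst + fit$baseline, transient = a_inst,
                 baseline = fit$baseline, tau = fit$tau, flat = FALSE),
            class = "tail_fit")
}

#' @export
print.tail_fit <- function(x, ...) {
  cat(sprintf("Tail: I0 = %.4g pA (transient %.4g, baseline %.4g), tau = %s ms\n",
              x$amplitude, x$transient, x$baseline,
              ifelse(is.na(x$tau), "NA", sprintf("%.3g", x$tau))))
  invisible(x)
}

#' Conductance-voltage (G-V) curve from a trace family
#'
#' Extracts the tail amplitude of every trace in a voltage-step family and
#' tabulates it against the pre-pulse voltage. Normalisation follows a
#' Boltzmann fit of the raw amplitudes: when the fit saturates within the
#' sampled range, amplitudes are normalised to the fitted plateau
#' (offset..offset+amplitude mapped to 0..1); otherwise to the maximum
#' observed amplitude, and the curve is flagged as non-saturating.
#'
#' @param family A `trace_family` from [generate_family()].
#' @return A `data.frame` of class `gv_curve` with columns `prepulse_mV`,
#'   `amplitude_pA` (signed instantaneous tail current) and `normalized`;
#'   attributes `tail_mV` and `saturated`.
#' @export
build_gv <- function(family) {
  stopifnot(inherits(family, "trace_family"))
  if (length(family$traces) < 5)
    stop("G-V construction needs at least 5 pre-pulse voltages")
  tails <- lapply(family$traces, extract_tail_amplitude,
                  repolarization_time = family$tail_start_ms)
  amp <- vapply(tails, `[[`, numeric(1), "amplitude")
  gv <- data.frame(prepulse_mV = family$step_mV, amplitude_pA = unname(amp))
  bf <- tryCatch(fit_boltzmann(gv, temperature = family$temperature),
                 error = function(e) NULL)
  if (!is.null(bf) && bf$saturated) {
    norm <- (bf$sign * gv$amplitude_pA - bf$offset) / bf$amplitude
    saturated <- TRUE
  } else {
    norm <- abs(gv$amplitude_pA) / max(abs(gv$amplitude_pA))
    saturated <- FALSE
  }
  gv$normalized <- norm
  structure(gv, tail_mV = family$tail_mV, saturated = saturated,
            class = c("gv_curve", "data.frame"))
}

#' Boltzmann fit of a G-V curve
#'
#' Fits f(v) = amplitude / (1 + exp(-(v - v_half)/slope)) + offset and
#' reports the equivalent gating charge z = RT/(F * slope). Inward-tail
#' curves (negative amplitudes) are flipped internally; the flip is recorded
#' in `sign`. The fit is flagged `saturated` only when the fitted upper
#' plateau is approached within the sampled voltage range (v_half + 3 slope
#' inside the range); z from non-saturating curves is still reported but
#' should be quoted with that caution flag, mirroring the practice of not
#' fitting non-saturating K+ tail curves.
#'
#' @param gv A [build_gv()] result, or any data.frame with `prepulse_mV` and
#'   `amplitude_pA` columns; at least 5 points.
#' @param temperature Kelvin used to convert the slope into z.
#' @return An object of class `boltzmann_fit`: `v_half` (mV), `z` (e0),
#'   `slope_mV`, `amplitude`, `offset`, `sign`, standard errors
#'   (`v_half_se`, `z_se`), `saturated`, `temperature`.
#' @export
fit_boltzmann <- function(gv, temperature = 294) {
  stopifnot(all(c("prepulse_mV", "amplitude_pA") %in% names(gv)))
  v <- gv$prepulse_mV
  if (length(v) < 5) stop("Boltzmann fit needs at least 5 points")
  ord <- order(v)
  v <- v[ord]
  y <- gv$amplitude_pA[ord]
  n <- length(y)
  top <- mean(y[(n - 2):n])
  bot <- mean(y[1:3])
  sgn <- if (top < bot) -1 else 1
  y <- sgn * y
  vt <- thermal_voltage(temperature)
  off0 <- min(y)
  amp0 <- max(y) - off0
  if (amp0 <= 0) stop("Boltzmann fit: amplitudes carry no voltage dependence")
  yr <- (y - off0) / amp0
  vh0 <- v[which.min(abs(yr - 0.5))]
  v20 <- v[which(yr >= 0.2)[1]]
  v80 <- v[which(yr >= 0.8)[1]]
  s0 <- if (!is.na(v20) && !is.na(v80) && v80 > v20)
    (v80 - v20) / (2 * log(4)) else vt / 2
  s0 <- min(max(s0, vt / 20), vt / 0.1)  # z in (0.1, 20]
  fit <- tryCatch(
    .lm_fit(c(amp = amp0, vh = vh0, s = s0, off = off0),
            lower = c(amp = 0, vh = -Inf, s = vt / 20, off = -Inf),
            upper = c(amp = Inf, vh = Inf, s = vt / 0.1, off = Inf),
            function(p)
              p[["amp"]] / (1 + exp(-(v - p[["vh"]]) / p[["s"]])) +
                p[["off"]] - y),
    error = function(e)
      stop("Boltzmann fit failed to converge: ", conditionMessage(e)))
  cf <- fit$par
  se <- fit$se
  slope <- unname(cf["s"])
  z <- vt / slope
  z_se <- unname(vt / slope^2 * se["s"])
  saturated <- (unname(cf["vh"]) + 3 * slope) <= max(v)
  structure(list(v_half = unname(cf["vh"]), z = z, slope_mV = slope,
                 amplitude = unname(cf["amp"]), offset = unname(cf["off"]),
                 sign = sgn, v_half_se = unname(se["vh"]), z_se = z_se,
                 saturated = saturated, temperature = temperature),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: V1/2 = %.2f mV, z = %.3f e0 (slope %.2f mV)%s\n",
              x$v_half, x$z, x$slope_mV,
              if (x$saturated) "" else "  [non-saturating]"))
  invisible(x)
}

# End-of-step current: mean over the last `frac` of the step segment. The
# sample at step_end_ms itself already belongs to the next (tail) segment
# and is excluded.
end_of_step_current <- function(trace, step_start_ms, step_end_ms,
                                frac = 0.05) {
  t0 <- step_end_ms - frac * (step_end_ms - step_start_ms)
  sel <- trace$time_ms >= t0 & trace$time_ms < step_end_ms
  if (!any(sel)) stop("step window lies outside the trace")
  mean(trace$current_pA[sel])
}

#' Rectification coefficient of a step family
#'
#' Ratio of the end-of-step currents at +100 and -100 mV,
#' I(+100) / |I(-100)| (end of step = mean of the last 5% of the step
#' samples). A linear conductance in symmetric K+ gives 1; flux-gated
#' channels rectify strongly outward.
#'
#' @param family A `trace_family` containing steps to +100 and -100 mV.
#' @return Dimensionless ratio.
#' @export
rectification_coefficient <- function(family) {
  stopifnot(inherits(family, "trace_family"))
  need <- c(-100, 100)
  if (!all(need %in% family$step_mV))
    stop("family must contain steps to +100 and -100 mV")
  iv <- vapply(need, function(v) {
    tr <- family$traces[[match(v, family$step_mV)]]
    end_of_step_current(tr, family$step_start_ms, family$tail_start_ms)
  }, numeric(1))
  scale <- max(abs(iv))
  if (abs(iv[1]) < max(1e-9 * scale, 1e-12))
    stop("current at -100 mV is below the noise floor")
  iv[2] / abs(iv[1])
}

#' Fold change in tail amplitude upon depolarisation
#'
#' Tail amplitude following the +100 mV pre-pulse divided by the tail
#' amplitude following a pre-pulse at the holding level. Equals 1 for a
#' history-free leak conductance.
#'
#' @param family A `trace_family` containing the +100 mV step and a step at
#'   the holding potential.
#' @return Dimensionless fold change.
#' @export
tail_fold_change <- function(family) {
  stopifnot(inherits(family, "trace_family"))
  hold <- family$hold_mV
  if (!(100 %in% family$step_mV) || !(hold %in% family$step_mV))
    stop("family must contain steps to +100 mV and to the holding level")
  amp <- vapply(c(hold, 100), function(v) {
    tr <- family$traces[[match(v, family$step_mV)]]
    extract_tail_amplitude(tr, family$tail_start_ms)$amplitude
  }, numeric(1))
  if (abs(amp[1]) < 1e-9 * max(abs(amp), 1e-12) || amp[1] == 0)
    stop("reference tail amplitude is indistinguishable from zero")
  amp[2] / amp[1]
}

#' Hill fit of a dose-response series
#'
#' Fits fold-activation versus agonist concentration to the standard Hill
#' form f(c) = 1 + (fmax - 1) * c^n / (ec50^n + c^n) (fold 1 at zero
#' concentration by definition).
#'
#' @param dose_response `data.frame` with columns `concentration_uM` and
#'   `fold_activation`; at least 4 concentrations.
#' @return An object of class `hill_fit`: `ec50` (uM), `n` (Hill
#'   coefficient), `fmax` (maximal fold-activation), standard errors.
#' @export
fit_hill <- function(dose_response) {
  stopifnot(all(c("concentration_uM", "fold_activation") %in%
                  names(dose_response)))
  cc <- dose_response$concentration_uM
  y <- dose_response$fold_activation
  if (length(cc) < 4) stop("Hill fit needs at least 4 concentrations")
  if (any(cc <= 0)) stop("concentrations must be > 0")
  ord <- order(cc)
  cc <- cc[ord]
  y <- y[ord]
  if (diff(range(y)) < max(1e-9 * max(abs(y)), 1e-12))
    stop("dose-response is flat; no activation to fit")
  if (stats::cor(cc, y, method = "spearman") <= 0)
    stop("dose-response is not monotonically increasing; refusing Hill fit")
  fmax0 <- max(y)
  half <- 1 + (fmax0 - 1) / 2
  ec0 <- cc[which.min(abs(y - half))]
  fit <- tryCatch(
    .lm_fit(c(fmax = fmax0, ec50 = ec0, n = 1),
            lower = c(fmax = 1, ec50 = min(cc) / 100, n = 0.1),
            upper = c(fmax = Inf, ec50 = max(cc) * 100, n = 10),
            function(p)
              1 + (p[["fmax"]] - 1) / (1 + (p[["ec50"]] / cc)^p[["n"]]) - y),
    error = function(e)
      stop("Hill fit failed to converge: ", conditionMessage(e)))
  cf <- fit$par
  se <- fit$se
  structure(list(ec50 = unname(cf["ec50"]), n = unname(cf["n"]),
                 fmax = unname(cf["fmax"]), ec50_se = unname(se["ec50"]),
                 n_se = unname(se["n"]), fmax_se = unname(se["fmax"])),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: EC50 = %.3g uM, n = %.2f, max fold %.3g\n",
              x$ec50, x$n, x$fmax))
  invisible(x)
}

#' V1/2 versus Erev coupling line
#'
#' Least-squares line of the Boltzmann half-activation voltage against the
#' computed reversal potential across ion-condition sets. A filter that
#' senses only the driving force Dmu gives slope 1; a sensor of the absolute
#' membrane voltage gives slope 0.
#'
#' @param results Either a `data.frame` with columns `erev_mV` and
#'   `v_half_mV`, or a list of `list(conditions =, fit =)` pairs
#'   ([bath_conditions()] and [fit_boltzmann()] objects).
#' @return List with `slope`, `intercept`, `slope_se` and the per-point
#'   `table`.
#' @export
v_half_vs_erev <- function(results) {
  if (is.data.frame(results)) {
    tbl <- results
    stopifnot(all(c("erev_mV", "v_half_mV") %in% names(tbl)))
  } else {
    tbl <- do.call(rbind, lapply(results, function(r) {
      data.frame(erev_mV = ghk_reversal(r$conditions),
                 v_half_mV = r$fit$v_half)
    }))
  }
  if (nrow(tbl) < 3) stop("need at least 3 condition sets")
  if (stats::var(tbl$erev_mV) == 0)
    stop("reversal potentials are identical; slope undefined")
  fit <- stats::lm(v_half_mV ~ erev_mV, data = tbl)
  cf <- stats::coef(fit)
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["erev_mV", "Std. Error"]),
    error = function(e) NA_real_)
  list(slope = unname(cf["erev_mV"]), intercept = unname(cf["(Intercept)"]),
       slope_se = se, table = tbl)
}
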