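# Preset registry and synthetic-data generators. Presets are shipped as a
# single JSON file (inst/extdata/presets.json); each non-default parameter
# carries a provenance note naming the measured observable it was calibrated
# to, or stating that it is an assumption.

.preset_cache <- new.env(parent = emptyenv())

.presets_raw <- function() {
  if (is.null(.preset_cache$raw)) {
    path <- system.file("extdata", "presets.json", package = "fluxgate")
    if (!nzchar(path)) stop("presets.json not found in installed package")
    .preset_cache$raw <- jsonlite::read_json(path)
  }
  .preset_cache$raw
}

#' List available channel presets
#'
#' @return `data.frame` with columns `name`, `channel`, `description`.
#' @export
#' @examples
#' list_presets()
list_presets <- function() {
  raw <- .presets_raw()
  do.call(rbind, lapply(raw, function(p) {
    data.frame(name = p$name, channel = p$channel,
               description = p$description)
  }))
}

#' Fetch one channel preset
#'
#' @param name Preset name (see [list_presets()]).
#' @return A list of class `channel_preset`: `name`, `channel`, `params`
#'   ([gating_params()]), `conditions` ([bath_conditions()]), optional `hill`
#'   (agonist mode-shift law: `ec50_uM`, `n`, `m_max`), and `provenance`
#'   notes keyed by parameter.
#' @export
get_preset <- function(name) {
  raw <- .presets_raw()
  hit <- Filter(function(p) identical(p$name, name), raw)
  if (length(hit) != 1)
    stop("unknown preset '", name, "'; see list_presets()")
  p <- hit[[1]]
  params <- do.call(gating_params, p$params)
  cond <- bath_conditions(
    int = unlist(p$conditions$int), ext = unlist(p$conditions$ext),
    temperature = p$conditions$temperature_K)
  structure(list(name = p$name, channel = p$channel,
                 description = p$description, params = params,
                 conditions = cond, hill = p$hill,
                 provenance = p$provenance),
            class = "channel_preset")
}

.as_preset <- function(preset) {
  if (is.character(preset)) get_preset(preset)
  else if (inherits(preset, "channel_preset")) preset
  else stop("preset must be a name or a channel_preset object")
}

#' @export
print.channel_preset <- function(x, ...) {
  cat("Preset '", x$name, "' (", x$channel, "): ", x$description, "\n",
      sep = "")
  print(x$params)
  print(x$conditions)
  invisible(x)
}

#' Agonist mode-shift fraction
#'
#' Hill law mapping agonist concentration to the fraction m of channels in
#' GHK leak mode: m(c) = m_max * c^n / (ec50^n + c^n).
#'
#' @param preset A preset (name or object) carrying a `hill` law.
#' @param concentration_uM Agonist concentrations, uM (vectorised; 0 allowed).
#' @return Mode-shift fractions in [0, m_max].
#' @export
mode_shift_fraction <- function(preset, concentration_uM) {
  preset <- .as_preset(preset)
  if (is.null(preset$hill))
    stop("preset '", preset$name, "' has no agonist mode-shift law")
  h <- preset$hill
  ifelse(concentration_uM <= 0, 0,
         h$m_max / (1 + (h$ec50_uM / concentration_uM)^h$n))
}

#' Simulate a voltage-step trace family
#'
#' One trace per pre-pulse voltage under the standard three-segment protocol
#' (hold, step, tail), with optional additive Gaussian recording noise whose
#' standard deviation is `noise` times the maximum absolute noise-free
#' current of the family. Bitwise reproducible for a fixed seed; `noise = 0`
#' returns the [simulate_current()] output exactly.
#'
#' @param preset Preset name or `channel_preset` object.
#' @param prepulse_mV Step voltages (default -100..+100 mV in 20 mV steps).
#' @param hold_mV Holding/equilibration voltage, mV (default -80).
#' @param tail_mV Tail voltage, mV (default: the holding voltage).
#' @param hold_ms,step_ms,tail_ms Segment durations, ms (defaults 50/300/100).
#' @param dt Sample interval, ms (default 0.05).
#' @param noise Relative noise sigma (fraction of max |I|; default 0).
#' @param seed Optional RNG seed.
#' @param conditions Optional [bath_conditions()] override.
#' @param params Optional [gating_params()] override.
#' @return A list of class `trace_family`: `traces` (one [current_trace()]
#'   per step), `step_mV`, protocol bookkeeping (`hold_mV`, `tail_mV`,
#'   `step_start_ms`, `tail_start_ms`, `dt`), `temperature`, `noise`, `seed`.
#' @export
generate_family <- function(preset, prepulse_mV = seq(-100, 100, by = 20),
                            hold_mV = -80, tail_mV = hold_mV,
                            hold_ms = 50, step_ms = 300, tail_ms = 100,
                            dt = 0.05, noise = 0, seed = NULL,
                            conditions = NULL, params = NULL) {
  preset <- .as_preset(preset)
  if (is.null(conditions)) conditions <- preset$conditions
  if (is.null(params)) params <- preset$params
  if (noise < 0) stop("noise sigma must be >= 0")
  traces <- lapply(prepulse_mV, function(v) {
    prot <- voltage_protocol(
      data.frame(ms = c(hold_ms, step_ms, tail_ms),
                 mV = c(hold_mV, v, tail_mV)), dt = dt)
    simulate_current(prot, conditions, params,
                     meta = list(preset = preset$name, prepulse_mV = v,
                                 seed = seed, noise = noise))
  })
  names(traces) <- paste0(prepulse_mV, "mV")
  fam <- structure(
    list(traces = traces, step_mV = prepulse_mV, preset = preset$name,
         hold_mV = hold_mV, tail_mV = tail_mV,
         step_start_ms = hold_ms, tail_start_ms = hold_ms + step_ms,
         dt = dt, temperature = conditions$temperature,
         conditions = conditions, params = params,
         noise = 0, seed = seed),
    class = "trace_family")
  if (noise > 0) fam <- add_trace_noise(fam, noise, seed) else fam
}

#' Add Gaussian recording noise to a trace family
#'
#' @param family A `trace_family`.
#' @param sigma Relative noise (fraction of the family's max |current|).
#' @param seed Optional RNG seed.
#' @return The family with noise added and `noise`/`seed` updated.
#' @export
add_trace_noise <- function(family, sigma, seed = NULL) {
  stopifnot(inherits(family, "trace_family"), sigma >= 0)
  if (sigma == 0) return(family)
  if (!is.null(seed)) set.seed(seed)
  sd_pa <- sigma * max(vapply(family$traces,
                              function(tr) max(abs(tr$current_pA)),
                              numeric(1)))
  family$traces <- lapply(family$traces, function(tr) {
    tr$current_pA <- tr$current_pA + stats::rnorm(nrow(tr), 0, sd_pa)
    tr
  })
  family$noise <- family$noise + sigma
  family$seed <- seed
  family
}

#' @export
print.trace_family <- function(x, ...) {
  cat(sprintf(paste0(
    "Trace family '%s': %d steps (%g..%g mV), hold %g mV, tail %g mV\n",
    "  dt %g ms, noise %g, seed %s\n"),
    x$preset, length(x$step_mV), min(x$step_mV), max(x$step_mV),
    x$hold_mV, x$tail_mV, x$dt, x$noise,
    ifelse(is.null(x$seed), "none", x$seed)))
  invisible(x)
}

#' Synthetic agonist dose-response series
#'
#' Fold-activation of the steady-state current at a fixed voltage versus
#' agonist concentration, generated from the preset's Hill mode-shift law:
#' the leak-mode fraction m(c) converts the residual flux-gated current into
#' the full open-pore GHK current. Noise is multiplicative Gaussian
#' (sd = `noise` times each response value).
#'
#' @param preset Preset (name or object) with a `hill` law, e.g. "traak_aa".
#' @param concentrations Agonist concentrations, uM (non-empty; >= 0).
#' @param vm Test voltage, mV (default -80, where flux-gated current is
#'   minimal and activation maximal).
#' @param noise Relative noise sigma (default 0).
#' @param seed Optional RNG seed.
#' @return `data.frame` with `concentration_uM` and `fold_activation`;
#'   attribute `truth` records the generating law.
#' @export
generate_dose_response <- function(preset, concentrations, vm = -80,
                                   noise = 0, seed = NULL) {
  preset <- .as_preset(preset)
  if (length(concentrations) == 0) stop("concentration list is empty")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  m <- mode_shift_fraction(preset, concentrations)
  ss <- steady_state(vm, preset$conditions, preset$params)
  po_gated <- ss["AO"] + ss["AI"] +
    preset$params$po_floor * (ss["ID"] + ss["IO"])
  if (po_gated <= 0)
    stop("gated steady-state conductance is zero at vm = ", vm,
         "; fold-activation undefined")
  fold <- unname(((1 - m) * po_gated + m) / po_gated)
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    fold <- fold * (1 + stats::rnorm(length(fold), 0, noise))
  }
  structure(data.frame(concentration_uM = concentrations,
                       fold_activation = fold),
            truth = list(hill = preset$hill, vm = vm,
                         po_gated = unname(po_gated), seed = seed))
}
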