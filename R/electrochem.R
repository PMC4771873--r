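# Equilibrium and flux electrochemistry: Nernst / GHK reversal potentials,
# GHK current, and the electrochemical driving force Dmu = Vm - Erev.
# Units throughout the package: mV, ms, pA, mM; temperature in kelvin.

.GAS_CONSTANT <- 8.314462618   # J / (mol K), CODATA 2018
.FARADAY      <- 96485.33212   # C / mol

#' Thermal voltage RT/F in millivolts
#'
#' @param temperature Absolute temperature in kelvin. The package default of
#'   294 K corresponds to the room-temperature recordings the presets emulate;
#'   RT/F is about 25.33 mV there.
#' @return RT/F in mV.
#' @export
#' @examples
#' thermal_voltage(294)
thermal_voltage <- function(temperature = 294) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1000 * .GAS_CONSTANT * temperature / .FARADAY
}

#' Default relative permeability table
#'
#' Relative permeabilities versus K+ for the monovalent cations used in the
#' recording-solution variants. Only K+ (reference, 1) is constrained by the
#' model itself; the others are stated assumptions: Rb+ is modestly less
#' permeant, Cs+ poorly permeant, Na+ nearly impermeant, and NMDG+ is treated
#' as a pure substituent that carries no current and contributes to no
#' reversal potential.
#'
#' @return Named numeric vector of permeability ratios (dimensionless, >= 0).
#' @export
ion_permeabilities <- function() {
  c(K = 1, Tl = 1.2, Rb = 0.3, NH4 = 0.15, Cs = 0.05, Na = 0.01, NMDG = 0)
}

#' Bath (recording-solution) conditions
#'
#' Per-side ion concentrations, the permeability table, and temperature.
#' This object is the source of the reversal potential and hence of the
#' electrochemical driving force that the filter senses.
#'
#' @param int Named numeric vector of intracellular concentrations (mM),
#'   e.g. `c(K = 120)`.
#' @param ext Named numeric vector of extracellular concentrations (mM).
#' @param temperature Kelvin (default 294).
#' @param permeabilities Named permeability ratios; defaults to
#'   [ion_permeabilities()]. Species absent from the table get permeability 0.
#' @return An object of class `bath_conditions`.
#' @export
#' @examples
#' bath_conditions(int = c(K = 120), ext = c(K = 4))
bath_conditions <- function(int = c(K = 120), ext = c(K = 120),
                            temperature = 294,
                            permeabilities = ion_permeabilities()) {
  check_side <- function(x, side) {
    if (length(x) == 0 || is.null(names(x)) || any(!nzchar(names(x))))
      stop(side, " concentrations must be a named numeric vector")
    if (any(!is.finite(x)) || any(x < 0))
      stop(side, " concentrations must be finite and >= 0")
    x
  }
  int <- check_side(int, "intracellular")
  ext <- check_side(ext, "extracellular")
  stopifnot(is.numeric(temperature), length(temperature) == 1, temperature > 0)
  if (is.null(names(permeabilities)))
    stop("permeabilities must be named")
  if (any(permeabilities < 0))
    stop("permeabilities must be >= 0")
  cond <- structure(
    list(int = int, ext = ext, temperature = temperature,
         permeabilities = permeabilities),
    class = "bath_conditions")
  # at least one permeant species with concentration > 0 on each side
  for (side in c("int", "ext")) {
    x <- cond[[side]]
    perm <- .perm_of(cond, names(x))
    if (!any(x > 0 & perm > 0))
      stop("no permeant species with concentration > 0 on side '", side, "'")
  }
  cond
}

#' @export
print.bath_conditions <- function(x, ...) {
  fmt <- function(v) paste(sprintf("%s=%g mM", names(v), v), collapse = ", ")
  cat("Bath conditions (", x$temperature, " K)\n", sep = "")
  cat("  int: ", fmt(x$int), "\n  ext: ", fmt(x$ext), "\n", sep = "")
  invisible(x)
}

.perm_of <- function(conditions, species) {
  p <- conditions$permeabilities[species]
  p[is.na(p)] <- 0
  unname(p)
}

.conc_of <- function(side, species) {
  x <- side[species]
  x[is.na(x)] <- 0
  unname(x)
}

#' Nernst equilibrium potential for a single ion species
#'
#' Returns (RT/zF) * ln(c_ext / c_int) in mV for a monovalent cation.
#'
#' @param species Species name (must have concentration > 0 on both sides).
#' @param conditions A [bath_conditions()] object.
#' @return Potential in mV.
#' @export
#' @examples
#' nernst_potential("K", bath_conditions(c(K = 120), c(K = 4)))  # ~ -86.2 mV
nernst_potential <- function(species, conditions) {
  stopifnot(inherits(conditions, "bath_conditions"))
  ci <- .conc_of(conditions$int, species)
  co <- .conc_of(conditions$ext, species)
  if (ci <= 0 || co <= 0)
    stop("nernst_potential requires concentration > 0 on both sides for '",
         species, "'")
  thermal_voltage(conditions$temperature) * log(co / ci)
}

#' GHK voltage-equation reversal potential
#'
#' Multi-ion reversal potential for monovalent cations,
#' Erev = (RT/F) * ln(sum P_s c_ext,s / sum P_s c_int,s).
#' Reduces exactly to [nernst_potential()] when a single permeant species is
#' present.
#'
#' @param conditions A [bath_conditions()] object.
#' @return Reversal potential in mV.
#' @export
ghk_reversal <- function(conditions) {
  stopifnot(inherits(conditions, "bath_conditions"))
  species <- union(names(conditions$int), names(conditions$ext))
  perm <- .perm_of(conditions, species)
  num <- sum(perm * .conc_of(conditions$ext, species))
  den <- sum(perm * .conc_of(conditions$int, species))
  if (num <= 0 || den <= 0)
    stop("ghk_reversal undefined: permeant concentrations are all zero on one side")
  thermal_voltage(conditions$temperature) * log(num / den)
}

#' GHK flux (current) equation for one species
#'
#' Open-pore Goldman-Hodgkin-Katz current for a monovalent cation, in
#' permeability-scaled flux units (mM): multiply by a unitary conductance
#' scale (pA per flux unit, see [gating_params()]) to obtain pA. Outward
#' current is positive. The removable singularity at Vm = 0 is handled by a
#' series expansion below |Vm| < 1e-6 mV, so the function is continuous
#' through 0; with symmetric concentrations it is exactly linear in Vm.
#'
#' @param vm Membrane voltage(s), mV; vectorised.
#' @param species Species name.
#' @param conditions A [bath_conditions()] object.
#' @return Numeric vector of fluxes, same length as `vm`.
#' @export
ghk_flux <- function(vm, species, conditions) {
  stopifnot(inherits(conditions, "bath_conditions"), all(is.finite(vm)))
  p  <- .perm_of(conditions, species)
  ci <- .conc_of(conditions$int, species)
  co <- .conc_of(conditions$ext, species)
  vt <- thermal_voltage(conditions$temperature)
  u  <- vm / vt
  out <- numeric(length(u))
  small <- abs(vm) < 1e-6
  if (any(!small)) {
    us <- u[!small]
    out[!small] <- us * (ci - co * exp(-us)) / (1 - exp(-us))
  }
  if (any(small)) {
    # limit of u*(ci - co e^-u)/(1 - e^-u): (ci - co) + u (ci + co)/2 + O(u^2)
    out[small] <- (ci - co) + u[small] * (ci + co) / 2
  }
  p * out
}

# Total open-pore GHK current over all species, flux units (mM).
ghk_current_total <- function(vm, conditions) {
  species <- union(names(conditions$int), names(conditions$ext))
  total <- numeric(length(vm))
  for (s in species) total <- total + ghk_flux(vm, s, conditions)
  total
}

#' Electrochemical driving force
#'
#' The quantity the flux-gated filter senses: Dmu = Vm - Erev, with Erev from
#' the GHK voltage equation.
#'
#' @param vm Membrane voltage, mV.
#' @param conditions A [bath_conditions()] object.
#' @return An object of class `driving_force` with fields `vm`, `erev`, `dmu`
#'   (all mV).
#' @export
#' @examples
#' driving_force(-80, bath_conditions())  # symmetric K+: erev = 0, dmu = -80
driving_force <- function(vm, conditions) {
  stopifnot(is.numeric(vm), all(is.finite(vm)))
  erev <- ghk_reversal(conditions)
  structure(list(vm = vm, erev = erev, dmu = vm - erev),
            class = "driving_force")
}

#' @export
print.driving_force <- function(x, ...) {
  cat(sprintf("Vm = %g mV, Erev = %.3f mV, Dmu = %.3f mV\n",
              x$vm[1], x$erev, x$dmu[1]))
  invisible(x)
}
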