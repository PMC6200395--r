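#' Nernst potential
#'
#' `E = (RT/zF) ln(C_o/C_i)` for an ion of the given valence. Any consistent
#' concentration unit may be used.
#'
#' @param c_i,c_o intra- and extracellular concentrations (> 0).
#' @param valence signed integer ionic valence (non-zero).
#' @return Potential in volts.
#' @examples
#' nernst_potential(122.9, 3.5, 1) * 1000   # E_K, about -95.1 mV
#' nernst_potential(5.2, 119, -1) * 1000    # E_Cl, about -83.8 mV
#' @export
nernst_potential <- function(c_i, c_o, valence) {
  if (any(c_i <= 0) || any(c_o <= 0))
    stop("Nernst potential requires strictly positive concentrations")
  if (any(valence == 0)) stop("valence must be non-zero")
  pc <- phys_constants()
  (pc$rtf / valence) * log(c_o / c_i)
}

#' Charge-difference membrane potential
#'
#' `Vm = F w (Na + K - Cl + z X) / (Cm SA)`, i.e. the net intracellular
#' charge divided by the membrane capacitance. Unlike the GHK voltage
#' equation this requires no steady-state assumption.
#'
#' @param state a [compartment_state()].
#' @param c_m specific membrane capacitance in F/dm^2 (canonical), or a
#'   [membrane_params()] object.
#' @return Membrane potential in volts.
#' @export
membrane_voltage <- function(state, c_m) {
  if (inherits(c_m, "membrane_params")) c_m <- c_m$c_m
  pc <- phys_constants()
  am <- 2 / state$radius  # SA/w for a cylinder with fixed length
  pc$f * (state$na + state$k - state$cl + state$xz) / (c_m * am)
}

#' Osmolarity
#'
#' Sum of all solute concentrations (osmotic coefficient 1); every
#' impermeant species counts by concentration irrespective of valence.
#'
#' @param x a [compartment_state()] or [bath_composition()].
#' @return Osmolarity in mM.
#' @export
osmolarity <- function(x) {
  if (inherits(x, "compartment_state"))
    return(M_to_mM(x$na + x$k + x$cl + x$x))
  if (inherits(x, "bath_composition"))
    return(M_to_mM(x$na + x$k + x$cl + x$x))
  stop("osmolarity() expects a compartment_state or bath_composition")
}

#' ATPase pump flux
#'
#' Effective Na+/K+-ATPase pump rate. In dynamic mode the pump is a cubic
#' function of the transmembrane sodium gradient, `J_p = P (Na_i/Na_o)^3`;
#' in fixed mode the configured constant is returned regardless of sodium.
#'
#' @param na_i,na_o intra-/extracellular sodium (any consistent unit,
#'   `na_o > 0`, `na_i >= 0`).
#' @param p pump-rate constant P, C/(dm^2 s).
#' @param pump_mode `"dynamic"` or `"fixed"`.
#' @param fixed_jp constant pump rate for fixed mode.
#' @return J_p in C/(dm^2 s).
#' @examples
#' pump_flux(14, 145, 0.1)  # about 9.0e-5
#' @export
pump_flux <- function(na_i, na_o, p, pump_mode = c("dynamic", "fixed"),
                      fixed_jp = NULL) {
  pump_mode <- match.arg(pump_mode)
  if (pump_mode == "fixed") {
    if (is.null(fixed_jp)) stop("fixed pump mode requires fixed_jp")
    return(fixed_jp)
  }
  if (any(na_o <= 0)) stop("extracellular sodium must be positive")
  if (any(na_i < 0)) stop("intracellular sodium must be non-negative")
  p * (na_i / na_o)^3
}

#' KCC2 cotransporter flux
#'
#' `J_KCC2 = g_KCC2 (E_K - E_Cl)`: electroneutral 1:1 K+/Cl- cotransport
#' driven by the difference of the two Nernst potentials. Positive values
#' denote inward Cl-/K+-coupled flux; the flux vanishes when E_K = E_Cl.
#'
#' @param e_k,e_cl Nernst potentials, V.
#' @param g_kcc2 KCC2 conductance, S/dm^2 (canonical).
#' @return J_KCC2 in C/(dm^2 s).
#' @export
kcc2_flux <- function(e_k, e_cl, g_kcc2) g_kcc2 * (e_k - e_cl)

#' Ion concentration derivatives
#'
#' Rates of change of the three permeant intracellular concentrations:
#' ohmic leaks, 3:2 ATPase stoichiometry, KCC2 cotransport and the dilution
#' term from volume change.
#'
#' @param state a [compartment_state()].
#' @param params a [membrane_params()].
#' @param bath a [bath_composition()].
#' @param j_p effective pump rate, C/(dm^2 s).
#' @param j_kcc2 KCC2 flux, C/(dm^2 s).
#' @param dwdt volume rate of change, dm^3/s.
#' @return Named numeric vector `c(na, k, cl)` in mM/s.
#' @export
ion_derivatives <- function(state, params, bath, j_p, j_kcc2, dwdt = 0) {
  pc <- phys_constants()
  am <- 2 / state$radius
  w <- volume(state)
  vm <- membrane_voltage(state, params)
  e_na <- nernst_potential(state$na, bath$na, 1)
  e_k <- nernst_potential(state$k, bath$k, 1)
  e_cl <- nernst_potential(state$cl, bath$cl, -1)
  dil <- dwdt / w
  dna <- -(am / pc$f) * (params$g_na * (vm - e_na) + 3 * j_p) -
    dil * state$na
  dk <- -(am / pc$f) * (params$g_k * (vm - e_k) - 2 * j_p - j_kcc2) -
    dil * state$k
  dcl <- (am / pc$f) * (params$g_cl * (vm - e_cl) + j_kcc2) -
    dil * state$cl
  M_to_mM(c(na = dna, k = dk, cl = dcl))
}

#' Hydrostatic (membrane-tension) pressure term
#'
#' Hookean membrane tension with Laplace's law: `H_p = 4 pi k_m (1 - r_a/r)`
#' for radii beyond the resting radius, zero otherwise.
#'
#' @param radius current radius, dm.
#' @param r_a resting radius, dm.
#' @param k_m membrane spring constant, N/dm.
#' @return H_p (a tension-derived mixed unit; divided by RT it
#'   acts as an osmolarity offset in mol/dm^3).
#' @export
hydrostatic_pressure <- function(radius, r_a, k_m) {
  stopifnot(all(radius > 0))
  ifelse(radius > r_a, 4 * pi * k_m * (1 - r_a / radius), 0)
}

#' Osmotic water flux
#'
#' `dw/dt = v_w p_w SA (Pi_i - Pi_o)` in osmotic mode; in tension mode the
#' hydrostatic term `H_p/(RT)` is subtracted from the osmotic differential,
#' allowing a sustained transmembrane osmotic difference at equilibrium.
#'
#' @param state a [compartment_state()].
#' @param bath a [bath_composition()].
#' @param params a [membrane_params()] (fields `v_w`, `p_w`, `k_m`, `r_a`,
#'   `volume_mode`).
#' @return dw/dt in dm^3/s.
#' @export
volume_flux <- function(state, bath, params) {
  pc <- phys_constants()
  sa <- surface_area(state)
  dpi <- mM_to_M(osmolarity(state) - osmolarity(bath))
  if (params$volume_mode == "tension") {
    hp <- hydrostatic_pressure(state$radius, params$r_a, params$k_m)
    dpi <- dpi - hp / (pc$r * pc$t)
  }
  params$v_w * params$p_w * sa * dpi
}

#' One forward-Euler step (reference implementation)
#'
#' Pure-R single-compartment update used as the cross-check for the compiled
#' integrator: (1) compute Vm, Nernst potentials, pump and KCC2 fluxes and
#' dw/dt from the pre-step state; (2) advance the permeant ions including
#' the dilution term; (3) apply any impermeant injection; (4) update volume
#' (radius changes, length fixed); (5) rescale impermeant concentrations so
#' their moles are conserved exactly.
#'
#' @param state a [compartment_state()].
#' @param params a [membrane_params()].
#' @param bath a [bath_composition()].
#' @param dt_s step size, s.
#' @param inject_rate impermeant injection rate, mM/s.
#' @param inject_valence valence of the injected species.
#' @return The updated [compartment_state()].
#' @export
step_compartment <- function(state, params, bath, dt_s,
                             inject_rate = 0, inject_valence = -0.85) {
  e_k <- nernst_potential(state$k, bath$k, 1)
  e_cl <- nernst_potential(state$cl, bath$cl, -1)
  j_p <- pump_flux(state$na, bath$na, params$p, params$pump_mode,
                   params$fixed_jp)
  j_kcc2 <- kcc2_flux(e_k, e_cl, params$g_kcc2)
  dwdt <- volume_flux(state, bath, params)
  d <- mM_to_M(ion_derivatives(state, params, bath, j_p, j_kcc2, dwdt))

  na <- state$na + dt_s * d[["na"]]
  k <- state$k + dt_s * d[["k"]]
  cl <- state$cl + dt_s * d[["cl"]]
  if (na < 0 || k < 0 || cl < 0)
    stop(sprintf("integration failure: [%s]i went negative",
                 c("Na", "K", "Cl")[which(c(na, k, cl) < 0)[1]]))

  x <- state$x + mM_to_M(inject_rate) * dt_s
  xz <- state$xz + mM_to_M(inject_rate) * inject_valence * dt_s

  w <- volume(state)
  wn <- w + dwdt * dt_s
  if (wn <= 0) stop("integration failure: volume collapsed")
  scale <- w / wn
  out <- state
  out$na <- na; out$k <- k; out$cl <- cl
  out$x <- x * scale; out$xz <- xz * scale
  out$radius <- sqrt(wn / (pi * state$length))
  zbar <- if (out$x > 0) out$xz / out$x else 0
  out$pool <- impermeant_pool(M_to_mM(out$x), zbar)
  out
}

#' Chloride driving force
#'
#' `DF = Vm - E_Cl`, the electrochemical force on chloride through an open
#' chloride-permeable channel.
#'
#' @param state a [compartment_state()].
#' @param params a [membrane_params()].
#' @param bath a [bath_composition()].
#' @return DF in volts.
#' @export
driving_force <- function(state, params, bath) {
  membrane_voltage(state, params) -
    nernst_potential(state$cl, bath$cl, -1)
}
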