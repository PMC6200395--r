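#' Membrane parameters
#'
#' Conductances, pump-rate constant, capacitance and water/tension parameters
#' of one compartment's membrane. Constructor arguments use the units in
#' which these quantities are conventionally reported (uS/cm^2, F/cm^2);
#' values are stored canonically in S/dm^2 and F/dm^2.
#'
#' @param g_na,g_k,g_cl leak conductances, uS/cm^2.
#' @param g_kcc2 KCC2 conductance, uS/cm^2.
#' @param p pump-rate constant P, C/(dm^2 s). The effective pump rate is
#'   `J_p = P (Na_i/Na_o)^3` when `pump_mode = "dynamic"`.
#' @param c_m specific membrane capacitance, F/cm^2.
#' @param v_w partial molar volume of water, dm^3/mol.
#' @param p_w osmotic water permeability, dm/s.
#' @param k_m membrane spring constant for the tension mode, N/dm.
#' @param r_a resting radius for membrane tension, dm. Defaults to the
#'   default cell radius (5 um).
#' @param pump_mode `"dynamic"` (sodium-dependent cubic pump) or `"fixed"`
#'   (constant effective pump rate `fixed_jp`).
#' @param fixed_jp constant effective pump rate J_p, C/(dm^2 s); required
#'   when `pump_mode = "fixed"`.
#' @param volume_mode `"osmotic"` (water flux driven by the osmotic
#'   differential alone) or `"tension"` (hydrostatic membrane-tension term
#'   included).
#' @return An object of class `membrane_params`.
#' @examples
#' p <- membrane_params()
#' p$g_kcc2  # 20 uS/cm^2 in canonical S/dm^2
#' @export
membrane_params <- function(g_na = 20, g_k = 70, g_cl = 20, g_kcc2 = 20,
                            p = 0.1, c_m = 2e-6,
                            v_w = 0.018, p_w = 0.0015,
                            k_m = 25, r_a = um_to_dm(5),
                            pump_mode = c("dynamic", "fixed"),
                            fixed_jp = NULL,
                            volume_mode = c("osmotic", "tension")) {
  pump_mode <- match.arg(pump_mode)
  volume_mode <- match.arg(volume_mode)
  stopifnot(g_na >= 0, g_k >= 0, g_cl >= 0, g_kcc2 >= 0, p >= 0, c_m > 0,
            v_w > 0, p_w >= 0, k_m >= 0, r_a > 0)
  if (pump_mode == "fixed") {
    if (is.null(fixed_jp) || fixed_jp < 0)
      stop("pump_mode = \"fixed\" requires a constant fixed_jp >= 0")
  } else {
    fixed_jp <- NA_real_
  }
  structure(list(
    g_na = uS_cm2_to_S_dm2(g_na), g_k = uS_cm2_to_S_dm2(g_k),
    g_cl = uS_cm2_to_S_dm2(g_cl), g_kcc2 = uS_cm2_to_S_dm2(g_kcc2),
    p = p, c_m = F_cm2_to_F_dm2(c_m),
    v_w = v_w, p_w = p_w, k_m = k_m, r_a = r_a,
    pump_mode = pump_mode, fixed_jp = fixed_jp, volume_mode = volume_mode
  ), class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("<membrane_params>\n")
  cat(sprintf("  g_Na %.4g  g_K %.4g  g_Cl %.4g  g_KCC2 %.4g uS/cm^2\n",
              S_dm2_to_uS_cm2(x$g_na), S_dm2_to_uS_cm2(x$g_k),
              S_dm2_to_uS_cm2(x$g_cl), S_dm2_to_uS_cm2(x$g_kcc2)))
  cat(sprintf("  pump: %s (P = %.4g C/(dm^2 s)%s)\n", x$pump_mode, x$p,
              if (x$pump_mode == "fixed")
                sprintf(", J_p = %.4g", x$fixed_jp) else ""))
  cat(sprintf("  volume mode: %s\n", x$volume_mode))
  invisible(x)
}

#' Extracellular bath composition
#'
#' The extracellular space is an infinite bath: its composition is never
#' updated by transmembrane flux. Extracellular impermeant anions have a
#' fixed valence of -1.
#'
#' @param na,k,cl,x extracellular concentrations, mM.
#' @return An object of class `bath_composition` with canonical mol/L fields.
#' @examples
#' osmolarity(bath_composition())  # 297 mM
#' @export
bath_composition <- function(na = 145, k = 3.5, cl = 119, x = 29.5) {
  stopifnot(na >= 0, k >= 0, cl >= 0, x >= 0)
  structure(list(na = mM_to_M(na), k = mM_to_M(k), cl = mM_to_M(cl),
                 x = mM_to_M(x)),
            class = "bath_composition")
}

#' @export
print.bath_composition <- function(x, ...) {
  cat(sprintf(
    "<bath> Na %.4g, K %.4g, Cl %.4g, X- %.4g mM (osmolarity %.4g mM)\n",
    M_to_mM(x$na), M_to_mM(x$k), M_to_mM(x$cl), M_to_mM(x$x),
    osmolarity(x)))
  invisible(x)
}

#' Impermeant-anion pool
#'
#' A pool of membrane-impermeant intracellular species, each with a
#' concentration and a (signed, possibly fractional) valence. The pool's
#' mean charge z is the concentration-weighted mean valence; uncharged
#' species count toward the mean.
#'
#' @param concentrations species concentrations, mM.
#' @param valences species valences (dimensionless signed reals).
#' @return An object of class `impermeant_pool`.
#' @examples
#' pool <- impermeant_pool(c(100, 54.9), c(-1, -0.5767))
#' mean_charge(pool)
#' @export
impermeant_pool <- function(concentrations, valences) {
  stopifnot(length(concentrations) == length(valences),
            length(concentrations) >= 1,
            all(concentrations >= 0), all(is.finite(valences)))
  structure(list(conc = mM_to_M(concentrations), valence = valences),
            class = "impermeant_pool")
}

#' @rdname impermeant_pool
#' @param pool an `impermeant_pool`.
#' @export
mean_charge <- function(pool) {
  stopifnot(inherits(pool, "impermeant_pool"))
  tot <- sum(pool$conc)
  if (tot <= 0) stop("mean charge undefined for an empty impermeant pool")
  sum(pool$conc * pool$valence) / tot
}

#' @rdname impermeant_pool
#' @export
total_concentration <- function(pool) {
  stopifnot(inherits(pool, "impermeant_pool"))
  M_to_mM(sum(pool$conc))
}

#' @export
print.impermeant_pool <- function(x, ...) {
  cat(sprintf("<impermeant_pool> %d species, total %.4g mM, mean z %.4g\n",
              length(x$conc), total_concentration(x), mean_charge(x)))
  invisible(x)
}

#' Compartment state
#'
#' Intracellular concentrations, the impermeant pool and the cylinder
#' geometry of one compartment. Volume `w = pi r^2 L` (length fixed), lateral
#' surface area `SA = 2 pi r L`, and the area-to-volume ratio `A_m = 2/r`.
#'
#' @param na,k,cl intracellular concentrations, mM.
#' @param pool an [impermeant_pool()].
#' @param radius_um,length_um cylinder radius and length, um.
#' @return An object of class `compartment_state` with canonical fields
#'   (mol/L, dm) including the derived totals `x` and `xz` (= z * X).
#' @examples
#' s <- default_state()
#' dm3_to_pL(volume(s))
#' @export
compartment_state <- function(na, k, cl, pool, radius_um = 5,
                              length_um = 25) {
  stopifnot(na >= 0, k >= 0, cl >= 0, inherits(pool, "impermeant_pool"),
            radius_um > 0, length_um > 0)
  structure(list(
    na = mM_to_M(na), k = mM_to_M(k), cl = mM_to_M(cl),
    pool = pool,
    x = sum(pool$conc), xz = sum(pool$conc * pool$valence),
    radius = um_to_dm(radius_um), length = um_to_dm(length_um)
  ), class = "compartment_state")
}

#' @rdname compartment_state
#' @param state a `compartment_state`.
#' @export
volume <- function(state) pi * state$radius^2 * state$length

#' @rdname compartment_state
#' @export
surface_area <- function(state) 2 * pi * state$radius * state$length

#' @export
print.compartment_state <- function(x, ...) {
  cat(sprintf(
    "<compartment_state> Na %.4g, K %.4g, Cl %.4g, X %.4g mM (z %.4g)\n",
    M_to_mM(x$na), M_to_mM(x$k), M_to_mM(x$cl), M_to_mM(x$x),
    if (x$x > 0) x$xz / x$x else NA_real_))
  cat(sprintf("  r %.4g um, L %.4g um, w %.4g pL\n",
              dm_to_um(x$radius), dm_to_um(x$length),
              dm3_to_pL(volume(x))))
  invisible(x)
}

#' Initial states close to electroneutrality
#'
#' Builds an initial compartment state with the requested target
#' concentrations and restores exact electroneutrality (so the initial
#' charge-difference membrane potential is 0 V) by adjusting one component:
#' the impermeant-pool concentration (`balance = "x"`, the default used to
#' build the default cell), the potassium concentration (`balance = "k"`,
#' used when sweeping initial chloride or impermeant concentrations so the
#' pool - and hence the final volume - is unchanged), or nothing
#' (`balance = "none"`).
#'
#' @param na,k,cl target intracellular concentrations, mM.
#' @param x target impermeant concentration, mM (single-species pool).
#' @param z impermeant mean charge.
#' @param balance which component absorbs the residual charge.
#' @param radius_um,length_um geometry, um.
#' @return A [compartment_state()].
#' @export
initial_state <- function(na = 14, k = 122.9, cl = 5.2, x = NULL, z = -0.85,
                          balance = c("x", "k", "none"),
                          radius_um = 5, length_um = 25) {
  balance <- match.arg(balance)
  if (is.null(x)) {
    if (balance != "x")
      x <- (14 + 122.9 - 5.2) / 0.85  # default pool, mM
    else
      x <- NA_real_
  }
  if (balance == "x") {
    if (z >= 0) stop("balancing via the pool requires z < 0")
    x <- (na + k - cl) / (-z)
  } else if (balance == "k") {
    k <- cl - na - z * x
    if (k < 0) stop("cannot balance charge with a negative [K+]i")
  }
  compartment_state(na, k, cl, impermeant_pool(x, z),
                    radius_um = radius_um, length_um = length_um)
}

#' @rdname initial_state
#' @export
default_state <- function() initial_state()

#' Simulation configuration
#'
#' @param dt_ms forward-Euler time step, ms (default 1 ms for a single
#'   compartment; chain simulations use 1e-3 ms unless coarsened).
#' @param duration_ms simulated duration, ms.
#' @param record_every_ms recording interval, ms.
#' @param steady_tol steady-state tolerance on max |d ion/dt|, mM/s.
#' @param steady_w_tol steady-state tolerance on |dw/dt|/w, 1/s.
#' @param steady_hold number of membrane steps over which the tolerances must
#'   hold.
#' @param check_steady stop early once the steady tolerances are sustained.
#' @param membrane_every number of electrodiffusion substeps per membrane
#'   step (two-rate scheme for chains; 1 = single-rate).
#' @param ed_mode electrodiffusion discretization: `"per_length"` (each
#'   compartment normalises interface fluxes by its own length; exactly
#'   mole-conserving only for identical geometries) or `"conservative"`
#'   (flux routed through the shared interface area, exactly
#'   mole-conserving).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt_ms = 1, duration_ms = 3.6e6,
                       record_every_ms = 1000,
                       steady_tol = 1e-6, steady_w_tol = 1e-9,
                       steady_hold = 1000, check_steady = FALSE,
                       membrane_every = 1,
                       ed_mode = c("per_length", "conservative")) {
  ed_mode <- match.arg(ed_mode)
  stopifnot(dt_ms > 0, duration_ms > 0, record_every_ms > 0,
            steady_tol > 0, steady_w_tol > 0, steady_hold >= 1,
            membrane_every >= 1)
  structure(list(dt_ms = dt_ms, duration_ms = duration_ms,
                 record_every_ms = record_every_ms,
                 steady_tol = steady_tol, steady_w_tol = steady_w_tol,
                 steady_hold = steady_hold, check_steady = check_steady,
                 membrane_every = as.integer(membrane_every),
                 ed_mode = ed_mode),
            class = "sim_config")
}
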