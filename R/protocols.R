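# Timed protocol events applied during integration. Each event is a plain
# list with class "protocol_event"; the engine in engine.R splits the run
# into segments at event boundaries.

new_event <- function(kind, start_ms, stop_ms, payload) {
  stopifnot(is.numeric(start_ms), is.numeric(stop_ms), stop_ms >= start_ms)
  structure(list(kind = kind, start_ms = start_ms, stop_ms = stop_ms,
                 payload = payload),
            class = "protocol_event")
}

#' Protocol events
#'
#' Constructors for timed manipulations applied during integration:
#' exponential ATPase on/off ramps, instantaneous or ramped parameter
#' changes, impermeant-anion injection at a constant rate, linear
#' mean-charge ramps at fixed impermeant moles, osmo- and electroneutral
#' extracellular anion/chloride swaps, switching the pump to a fixed
#' effective rate, and switching the volume mode.
#'
#' @param start_ms,stop_ms,at_ms event timing, ms.
#' @param direction pump ramp direction, `"off"` (P -> 0) or `"on"`
#'   (P -> `target`).
#' @param target pump-rate constant the "on" ramp approaches; defaults to
#'   the run's original P.
#' @param name parameter name: one of `g_na`, `g_k`, `g_cl`, `g_kcc2`
#'   (uS/cm^2) or `p` (C/(dm^2 s)).
#' @param value,to,from parameter values (same units as `name`).
#' @param rate injection rate, mM/s.
#' @param valence valence of the injected impermeant species.
#' @param target_z mean charge reached at `stop_ms`.
#' @param delta_x extracellular impermeant anions added (and chloride
#'   removed), mM.
#' @param jp fixed effective pump rate, C/(dm^2 s), or `"auto"` to freeze
#'   the dynamic rate at its current value.
#' @param mode volume mode, `"osmotic"` or `"tension"`.
#' @param compartment 1-based compartment index the event targets (chains).
#' @return A `protocol_event`.
#' @name protocol_event
NULL

#' @rdname protocol_event
#' @export
ev_pump_ramp <- function(direction = c("off", "on"), start_ms,
                         stop_ms = start_ms + 9e5, target = NULL) {
  direction <- match.arg(direction)
  new_event("pump_ramp", start_ms, stop_ms,
            list(direction = direction, target = target))
}

#' @rdname protocol_event
#' @export
ev_set_param <- function(name, value, at_ms, compartment = NULL) {
  stopifnot(name %in% c("g_na", "g_k", "g_cl", "g_kcc2", "p"))
  new_event("set_param", at_ms, at_ms,
            list(name = name, value = value, compartment = compartment))
}

#' @rdname protocol_event
#' @export
ev_param_ramp <- function(name, to, start_ms, stop_ms, from = NULL,
                          compartment = NULL) {
  stopifnot(name %in% c("g_na", "g_k", "g_cl", "g_kcc2", "p"),
            is.finite(to))
  new_event("param_ramp", start_ms, stop_ms,
            list(name = name, from = from, to = to,
                 compartment = compartment))
}

#' @rdname protocol_event
#' @param unit injection-rate unit: `"mM_s"` (concentration per second,
#'   relative to the instantaneous volume) or `"mol_s"` (fixed molar rate,
#'   so the total added moles are exactly `rate * (stop - start)`).
#' @export
ev_inject <- function(rate, valence, start_ms, stop_ms, compartment = 1,
                      unit = c("mM_s", "mol_s")) {
  unit <- match.arg(unit)
  stopifnot(is.finite(rate))  # negative rates model removal
  new_event("inject", start_ms, stop_ms,
            list(rate = rate, valence = valence, compartment = compartment,
                 unit = unit))
}

#' @rdname protocol_event
#' @export
ev_ramp_charge <- function(target_z, start_ms, stop_ms, compartment = 1) {
  stopifnot(is.finite(target_z))
  new_event("ramp_charge", start_ms, stop_ms,
            list(target_z = target_z, compartment = compartment))
}

#' @rdname protocol_event
#' @export
ev_bath_swap <- function(delta_x, at_ms) {
  new_event("bath_swap", at_ms, at_ms, list(delta_x = delta_x))
}

#' @rdname protocol_event
#' @export
ev_fix_pump <- function(at_ms, jp = "auto") {
  new_event("fix_pump", at_ms, at_ms, list(jp = jp))
}

#' @rdname protocol_event
#' @export
ev_volume_mode <- function(mode = c("osmotic", "tension"), at_ms) {
  mode <- match.arg(mode)
  new_event("volume_mode", at_ms, at_ms, list(mode = mode))
}

#' @export
print.protocol_event <- function(x, ...) {
  cat(sprintf("<protocol_event:%s> %g..%g ms\n", x$kind, x$start_ms,
              x$stop_ms))
  invisible(x)
}

#' Direct impermeant-anion manipulations
#'
#' State-level counterparts of the protocol events, useful for constructing
#' states and for tests. `inject_impermeant()` adds `rate * dt` of a species
#' of the given valence to the pool (creating it if absent); the pool mean
#' charge follows the concentration-weighted mean rule.
#' `ramp_mean_charge()` moves the pool's mean valence toward `target_z` by
#' the fraction `frac` of the remaining distance, holding impermeant moles
#' constant. `extracellular_swap()` adds impermeant anions to the bath while
#' removing the same amount of chloride, leaving bath osmolarity and net
#' charge unchanged.
#'
#' @param state a [compartment_state()].
#' @param rate injection rate, mM/s.
#' @param valence valence of the injected species.
#' @param dt_s time step, s.
#' @param target_z target mean charge.
#' @param frac fraction of the current-to-target distance applied.
#' @param bath a [bath_composition()].
#' @param delta_x amount swapped, mM (`bath$cl` must remain non-negative).
#' @return The updated state or bath.
#' @export
inject_impermeant <- function(state, rate, valence, dt_s) {
  stopifnot(rate >= 0)
  add <- mM_to_M(rate) * dt_s
  if (add == 0) return(state)
  pool <- state$pool
  hit <- which(pool$valence == valence)
  if (length(hit) == 1) {
    pool$conc[hit] <- pool$conc[hit] + add
  } else {
    pool$conc <- c(pool$conc, add)
    pool$valence <- c(pool$valence, valence)
  }
  state$pool <- pool
  state$x <- sum(pool$conc)
  state$xz <- sum(pool$conc * pool$valence)
  state
}

#' @rdname inject_impermeant
#' @export
ramp_mean_charge <- function(state, target_z, frac = 1) {
  stopifnot(is.finite(target_z), frac >= 0, frac <= 1)
  if (state$x <= 0) stop("mean-charge ramp requires a non-empty pool")
  z0 <- state$xz / state$x
  z1 <- z0 + (target_z - z0) * frac
  state$xz <- z1 * state$x
  state$pool <- impermeant_pool(M_to_mM(state$x), z1)
  state
}

#' @rdname inject_impermeant
#' @export
extracellular_swap <- function(bath, delta_x) {
  d <- mM_to_M(delta_x)
  if (bath$cl - d < 0)
    stop("extracellular swap would drive bath chloride negative")
  bath$x <- bath$x + d
  bath$cl <- bath$cl - d
  bath
}

#' Time-varying pump-rate constant during an on/off ramp
#'
#' Exponential approach of the pump-rate constant toward 0 ("off") or a
#' restored value ("on") with time constant `duration/5`, mirroring the
#' slow pharmacological on/off kinetics of ATPase blockade. A zero duration
#' gives a step change.
#'
#' @param p0 pump-rate constant at ramp start, C/(dm^2 s).
#' @param target value approached.
#' @param t_s time since ramp start, s.
#' @param duration_s ramp duration, s.
#' @return The pump-rate constant at `t_s`.
#' @export
pump_ramp_value <- function(p0, target, t_s, duration_s) {
  if (duration_s <= 0) return(rep(target, length(t_s)))
  tau <- duration_s / 5
  target + (p0 - target) * exp(-t_s / tau)
}
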