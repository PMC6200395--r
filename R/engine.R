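# Shared driver around the compiled forward-Euler integrator. A run is split
# into segments at protocol-event boundaries; within a segment the event
# context (ramps, injections, bath, pump mode) is fixed and handed to
# run_segment_cpp().

state_to_row <- function(s) c(s$na, s$k, s$cl, s$x, s$xz, s$radius)

row_to_state <- function(row, length_dm) {
  x_mM <- M_to_mM(row[4])
  zbar <- if (row[4] > 0) row[5] / row[4] else 0
  compartment_state(M_to_mM(row[1]), M_to_mM(row[2]), M_to_mM(row[3]),
                    impermeant_pool(x_mM, zbar),
                    radius_um = dm_to_um(row[6]),
                    length_um = dm_to_um(length_dm))
}

rec_names <- c("na_mM", "k_mM", "cl_mM", "x_mM", "z", "radius_um",
               "volume_pL", "vm_mV", "ena_mV", "ek_mV", "ecl_mV", "df_mV",
               "jp", "jkcc2")

records_to_df <- function(rec, n, t0_ms) {
  nr <- nrow(rec)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    o <- 1 + (i - 1) * 14
    out[[i]] <- data.frame(
      time_ms = t0_ms + rec[, 1] * 1000,
      compartment = i,
      na_mM = M_to_mM(rec[, o + 1]),
      k_mM = M_to_mM(rec[, o + 2]),
      cl_mM = M_to_mM(rec[, o + 3]),
      x_mM = M_to_mM(rec[, o + 4]),
      z = rec[, o + 5],
      radius_um = dm_to_um(rec[, o + 6]),
      volume_pL = dm3_to_pL(rec[, o + 7]),
      vm_mV = rec[, o + 8] * 1000,
      ena_mV = rec[, o + 9] * 1000,
      ek_mV = rec[, o + 10] * 1000,
      ecl_mV = rec[, o + 11] * 1000,
      df_mV = rec[, o + 12] * 1000,
      jp = rec[, o + 13],
      jkcc2 = rec[, o + 14]
    )
  }
  do.call(rbind, out)
}

lin_interp <- function(from, to, start, stop, t) {
  if (stop <= start) return(to)
  from + (to - from) * min(1, max(0, (t - start) / (stop - start)))
}

run_engine <- function(states, params, bath, config, protocol = list(),
                       diffusion = NULL, overrides = list()) {
  stopifnot(inherits(params, "membrane_params"),
            inherits(bath, "bath_composition"),
            inherits(config, "sim_config"))
  if (inherits(states, "compartment_state")) states <- list(states)
  n <- length(states)
  length_dm <- states[[1]]$length
  for (s in states) stopifnot(abs(s$length - length_dm) < 1e-12)
  pc <- phys_constants()

  per_comp <- function(name) {
    v <- rep(params[[name]], n)
    if (!is.null(overrides[[name]])) {
      ov <- uS_cm2_to_S_dm2(overrides[[name]])
      stopifnot(length(ov) %in% c(1, n))
      v <- rep(ov, length.out = n)
    }
    v
  }
  gna <- per_comp("g_na"); gk <- per_comp("g_k")
  gcl <- per_comp("g_cl"); gkcc2 <- per_comp("g_kcc2")

  ctx <- new.env(parent = emptyenv())
  ctx$p <- params$p
  ctx$pump_fixed <- identical(params$pump_mode, "fixed")
  ctx$fixed_jp <- if (ctx$pump_fixed) params$fixed_jp else 0
  ctx$vmode <- if (identical(params$volume_mode, "tension")) 1L else 0L
  ctx$bath <- c(bath$na, bath$k, bath$cl, bath$x)
  ctx$gkcc2 <- gkcc2; ctx$gna <- gna; ctx$gk <- gk; ctx$gcl <- gcl

  if (is.null(diffusion)) diffusion <- list(d_na = 0, d_k = 0, d_cl = 0)
  dvec <- c(diffusion$d_na, diffusion$d_k, diffusion$d_cl)
  if (n > 1) {
    cfl <- max(dvec) * config$dt_ms * 1e-3 / length_dm^2
    if (cfl > 0.5)
      stop(sprintf("electrodiffusion stability violated: D dt/dx^2 = %.3g",
                   cfl))
  }

  for (ev in protocol)
    if (!inherits(ev, "protocol_event"))
      stop("protocol must be a list of protocol_event objects")

  dur <- config$duration_ms
  snap <- function(t) round(t / config$dt_ms) * config$dt_ms
  bounds <- c(0, dur)
  for (ev in protocol) {
    bounds <- c(bounds, snap(ev$start_ms), snap(ev$stop_ms))
    # generic conductance ramps run piecewise-constant over sub-segments
    if (ev$kind == "param_ramp" && !ev$payload$name %in% c("g_kcc2", "p")) {
      span <- ev$stop_ms - ev$start_ms
      bounds <- c(bounds, snap(ev$start_ms + span * seq_len(24) / 25))
    }
  }
  bounds <- sort(unique(pmin(pmax(bounds, 0), dur)))

  eps <- config$dt_ms / 2
  captured <- vector("list", length(protocol))
  comp_idx <- function(ev) {
    ci <- ev$payload$compartment
    if (is.null(ci)) seq_len(n) else as.integer(ci)
  }
  state_mat <- do.call(rbind, lapply(states, state_to_row))

  all_rec <- list()
  steady <- FALSE
  t_end_ms <- 0

  for (si in seq_len(length(bounds) - 1)) {
    t0 <- bounds[si]; t1 <- bounds[si + 1]
    if (t1 - t0 < eps) next

    # point events firing at this boundary
    for (j in seq_along(protocol)) {
      ev <- protocol[[j]]
      if (abs(snap(ev$start_ms) - t0) > eps) next
      pl <- ev$payload
      if (ev$kind == "set_param") {
        val <- pl$value
        tgt <- comp_idx(ev)
        switch(pl$name,
          g_na = { ctx$gna[tgt] <- uS_cm2_to_S_dm2(val) },
          g_k = { ctx$gk[tgt] <- uS_cm2_to_S_dm2(val) },
          g_cl = { ctx$gcl[tgt] <- uS_cm2_to_S_dm2(val) },
          g_kcc2 = { ctx$gkcc2[tgt] <- uS_cm2_to_S_dm2(val) },
          p = { ctx$p <- val })
      } else if (ev$kind == "bath_swap") {
        d <- mM_to_M(pl$delta_x)
        if (ctx$bath[3] - d < 0)
          stop("extracellular swap would drive bath chloride negative")
        ctx$bath[4] <- ctx$bath[4] + d
        ctx$bath[3] <- ctx$bath[3] - d
      } else if (ev$kind == "fix_pump") {
        ctx$pump_fixed <- TRUE
        ctx$fixed_jp <- if (identical(pl$jp, "auto"))
          ctx$p * (state_mat[1, 1] / ctx$bath[1])^3 else pl$jp
      } else if (ev$kind == "volume_mode") {
        ctx$vmode <- if (identical(pl$mode, "tension")) 1L else 0L
      }
    }

    # interval context for [t0, t1]
    gk2_0 <- ctx$gkcc2; gk2_1 <- ctx$gkcc2
    p0 <- ctx$p; p1 <- ctx$p; pump_exp <- 0L; tau <- 1
    inj_rate <- numeric(n); inj_val <- numeric(n)
    inj_molar <- integer(n)
    zflag <- integer(n); ztar <- numeric(n)

    for (j in seq_along(protocol)) {
      ev <- protocol[[j]]
      a <- snap(ev$start_ms); b <- snap(ev$stop_ms)
      covering <- a <= t0 + eps && b >= t1 - eps && b > a
      if (!covering) next
      pl <- ev$payload
      if (ev$kind == "param_ramp") {
        if (is.null(captured[[j]])) {
          from <- pl$from
          if (is.null(from)) {
            from <- switch(pl$name,
              g_na = S_dm2_to_uS_cm2(ctx$gna[comp_idx(ev)[1]]),
              g_k = S_dm2_to_uS_cm2(ctx$gk[comp_idx(ev)[1]]),
              g_cl = S_dm2_to_uS_cm2(ctx$gcl[comp_idx(ev)[1]]),
              g_kcc2 = S_dm2_to_uS_cm2(ctx$gkcc2[comp_idx(ev)[1]]),
              p = ctx$p)
          }
          captured[[j]] <- from
        }
        from <- captured[[j]]
        if (pl$name == "g_kcc2") {
          tgt <- comp_idx(ev)
          gk2_0[tgt] <- uS_cm2_to_S_dm2(lin_interp(from, pl$to, a, b, t0))
          gk2_1[tgt] <- uS_cm2_to_S_dm2(lin_interp(from, pl$to, a, b, t1))
        } else if (pl$name == "p") {
          p0 <- lin_interp(from, pl$to, a, b, t0)
          p1 <- lin_interp(from, pl$to, a, b, t1)
        } else {
          mid <- lin_interp(from, pl$to, a, b, (t0 + t1) / 2)
          tgt <- comp_idx(ev)
          switch(pl$name,
            g_na = { ctx$gna[tgt] <- uS_cm2_to_S_dm2(mid) },
            g_k = { ctx$gk[tgt] <- uS_cm2_to_S_dm2(mid) },
            g_cl = { ctx$gcl[tgt] <- uS_cm2_to_S_dm2(mid) })
        }
      } else if (ev$kind == "pump_ramp") {
        if (is.null(captured[[j]]))
          captured[[j]] <- list(p_start = ctx$p,
                                target = if (pl$direction == "off") 0
                                         else if (is.null(pl$target))
                                           params$p else pl$target)
        cap <- captured[[j]]
        dur_s <- (b - a) / 1000
        pump_exp <- 1L
        tau <- max(dur_s / 5, config$dt_ms / 1000)
        p0 <- pump_ramp_value(cap$p_start, cap$target, (t0 - a) / 1000,
                              dur_s)
        p1 <- cap$target
      } else if (ev$kind == "inject") {
        tgt <- comp_idx(ev)
        molar <- identical(pl$unit, "mol_s")
        inj_rate[tgt] <- if (molar) pl$rate else mM_to_M(pl$rate)
        inj_val[tgt] <- pl$valence
        inj_molar[tgt] <- as.integer(molar)
      } else if (ev$kind == "ramp_charge") {
        tgt <- comp_idx(ev)
        if (is.null(captured[[j]]))
          captured[[j]] <- state_mat[tgt[1], 5] / state_mat[tgt[1], 4]
        z0 <- captured[[j]]
        zflag[tgt] <- 1L
        ztar[tgt] <- lin_interp(z0, pl$target_z, a, b, t1)
      }
    }

    is_last <- si == length(bounds) - 1
    res <- run_segment_cpp(
      state_mat, length_dm,
      pc$f, pc$r, pc$t,
      ctx$gna, ctx$gk, ctx$gcl, gk2_0, gk2_1,
      params$c_m, params$v_w, params$p_w, params$k_m, params$r_a,
      p0, p1, pump_exp, tau,
      as.integer(ctx$pump_fixed), ctx$fixed_jp,
      ctx$vmode, ctx$bath,
      inj_rate, inj_val, inj_molar, zflag, ztar,
      dvec[1], dvec[2], dvec[3],
      if (config$ed_mode == "per_length") 0L else 1L,
      config$membrane_every,
      config$dt_ms / 1000, (t1 - t0) / 1000,
      config$record_every_ms / 1000,
      as.integer(config$check_steady && is_last),
      mM_to_M(config$steady_tol), config$steady_w_tol,
      as.integer(config$steady_hold))
    state_mat <- res$final_state
    steady <- isTRUE(res$steady)
    t_end_ms <- t0 + res$t_end * 1000

    rec <- res$records
    if (si > 1 && nrow(rec) > 1) rec <- rec[-1, , drop = FALSE]
    all_rec[[length(all_rec) + 1]] <- records_to_df(rec, n, t0)

    # commit exact end-of-ramp values at this boundary
    for (j in seq_along(protocol)) {
      ev <- protocol[[j]]
      if (abs(snap(ev$stop_ms) - t1) > eps) next
      pl <- ev$payload
      if (ev$kind == "param_ramp") {
        tgt <- comp_idx(ev)
        switch(pl$name,
          g_na = { ctx$gna[tgt] <- uS_cm2_to_S_dm2(pl$to) },
          g_k = { ctx$gk[tgt] <- uS_cm2_to_S_dm2(pl$to) },
          g_cl = { ctx$gcl[tgt] <- uS_cm2_to_S_dm2(pl$to) },
          g_kcc2 = { ctx$gkcc2[tgt] <- uS_cm2_to_S_dm2(pl$to) },
          p = { ctx$p <- pl$to })
      } else if (ev$kind == "pump_ramp") {
        # zero-duration ramps (never "covering") act as step changes here
        ctx$p <- if (!is.null(captured[[j]])) captured[[j]]$target
                 else if (ev$payload$direction == "off") 0
                 else if (is.null(ev$payload$target)) params$p
                 else ev$payload$target
      }
    }
    if (steady) break
  }

  data <- do.call(rbind, all_rec)
  rownames(data) <- NULL
  final_states <- lapply(seq_len(n), function(i)
    row_to_state(state_mat[i, ], length_dm))
  structure(list(data = data, final_states = final_states,
                 steady = steady, t_end_ms = t_end_ms,
                 n_compartments = n, config = config),
            class = "timeseries_result")
}

#' @export
print.timeseries_result <- function(x, ...) {
  cat(sprintf(
    "<timeseries_result> %d compartment(s), %d records, t_end %.4g s%s\n",
    x$n_compartments, nrow(x$data), x$t_end_ms / 1000,
    if (x$steady) " (steady)" else ""))
  invisible(x)
}

#' Simulate a single compartment
#'
#' Forward-Euler integration of the single-compartment pump-leak model,
#' optionally under a protocol of timed events. Records the full state and
#' the derived quantities (Vm, Nernst potentials, chloride driving force,
#' volume, mean charge, pump and KCC2 fluxes) every `record_every_ms`.
#'
#' @param state initial [compartment_state()].
#' @param params [membrane_params()].
#' @param bath [bath_composition()].
#' @param config [sim_config()].
#' @param protocol list of [protocol_event][ev_pump_ramp] objects.
#' @return A `timeseries_result`: `data` (long data frame of traces),
#'   `final_states`, `steady` flag and `t_end_ms`.
#' @examples
#' cell <- make_default_cell()
#' res <- simulate_compartment(cell$state, cell$params, cell$bath,
#'                             sim_config(duration_ms = 5000))
#' tail(res$data$cl_mM, 1)
#' @export
simulate_compartment <- function(state, params, bath,
                                 config = sim_config(),
                                 protocol = list()) {
  run_engine(state, params, bath, config, protocol)
}

#' Integrate a single compartment to its fixed point
#'
#' Runs with early stopping once max |d ion/dt| and |dw/dt|/w stay below the
#' configured tolerances, and errors if no fixed point is reached within
#' `max_ms` (e.g. with the pump off, where volume grows without bound).
#'
#' @inheritParams simulate_compartment
#' @param dt_ms time step, ms.
#' @param max_ms maximum simulated time, ms.
#' @param error_if_unsteady error (rather than warn) when the tolerances are
#'   never met.
#' @return A list with the final `state`, `steady` flag, `t_ms` and the
#'   transmembrane flux `residuals` (C/(dm^2 s)).
#' @export
run_to_steady <- function(state, params, bath, dt_ms = 1, max_ms = 7.2e6,
                          error_if_unsteady = TRUE) {
  cfg <- sim_config(dt_ms = dt_ms, duration_ms = max_ms,
                    record_every_ms = max_ms, check_steady = TRUE)
  res <- run_engine(state, params, bath, cfg)
  st <- res$final_states[[1]]
  if (!res$steady) {
    msg <- sprintf(
      "no steady state reached within %g s simulated time", max_ms / 1000)
    if (error_if_unsteady) stop(msg) else warning(msg)
  }
  list(state = st, steady = res$steady, t_ms = res$t_end_ms,
       residuals = flux_residuals(st, params, bath))
}

#' Transmembrane flux residuals
#'
#' Per-ion net transmembrane flux (C/(dm^2 s)) and the osmotic differential
#' (mM); all are zero at a fixed point of the osmotic-mode model.
#'
#' @inheritParams simulate_compartment
#' @return Named vector `c(na, k, cl, osm)`.
#' @export
flux_residuals <- function(state, params, bath) {
  e_na <- nernst_potential(state$na, bath$na, 1)
  e_k <- nernst_potential(state$k, bath$k, 1)
  e_cl <- nernst_potential(state$cl, bath$cl, -1)
  vm <- membrane_voltage(state, params)
  j_p <- pump_flux(state$na, bath$na, params$p, params$pump_mode,
                   params$fixed_jp)
  j_kcc2 <- kcc2_flux(e_k, e_cl, params$g_kcc2)
  c(na = params$g_na * (vm - e_na) + 3 * j_p,
    k = params$g_k * (vm - e_k) - 2 * j_p - j_kcc2,
    cl = params$g_cl * (vm - e_cl) + j_kcc2,
    osm = osmolarity(state) - osmolarity(bath))
}
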