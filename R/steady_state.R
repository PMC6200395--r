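# Direct computation of the model's fixed points by damped Newton
# root-finding, the counterpart of integrating the ODEs to convergence.
# Unknowns are (log Na, log K, log Cl, log w, Vm): log-concentration and
# log-volume parameterization keeps the iterates positive. The five
# constraints are the three zero-derivative flux balances, osmotic balance
# (with the tension or offset term where configured) and consistency of Vm
# with the charge-difference relation.

ss_residual <- function(u, params, bath, x_moles, z, length_dm,
                        osmotic_offset = 0) {
  pc <- phys_constants()
  na <- exp(u[1]); k <- exp(u[2]); cl <- exp(u[3]); w <- exp(u[4])
  vm <- u[5]
  x <- x_moles / w
  r <- sqrt(w / (pi * length_dm))
  am <- 2 / r
  e_na <- pc$rtf * log(bath$na / na)
  e_k <- pc$rtf * log(bath$k / k)
  e_cl <- -pc$rtf * log(bath$cl / cl)
  j_p <- if (params$pump_mode == "fixed") params$fixed_jp
         else params$p * (na / bath$na)^3
  j_kcc2 <- params$g_kcc2 * (e_k - e_cl)
  osm_o <- bath$na + bath$k + bath$cl + bath$x
  hp_term <- if (params$volume_mode == "tension")
    hydrostatic_pressure(r, params$r_a, params$k_m) / (pc$r * pc$t) else 0
  c(
    (params$g_na * (vm - e_na) + 3 * j_p) / 1e-4,
    (params$g_k * (vm - e_k) - 2 * j_p - j_kcc2) / 1e-4,
    (params$g_cl * (vm - e_cl) + j_kcc2) / 1e-4,
    (na + k + cl + x - osm_o - hp_term - mM_to_M(osmotic_offset)) / 1e-3,
    (vm - pc$f * (na + k - cl + z * x) / (params$c_m * am)) / 1e-3
  )
}

newton_solve <- function(fn, u0, tol = 1e-8, max_iter = 200) {
  u <- u0
  f <- fn(u)
  f0 <- max(abs(f))
  nonmono <- 0
  stalls <- 0
  try_step <- function(u, f, step) {
    lambda <- 1
    for (half in 1:30) {
      ut <- u + lambda * step
      ft <- tryCatch(fn(ut), error = function(e) NULL)
      if (!is.null(ft) && all(is.finite(ft)) &&
          max(abs(ft)) < max(abs(f)))
        return(list(u = ut, f = ft))
      lambda <- lambda / 2
    }
    NULL
  }
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) return(list(u = u, f = f, converged = TRUE,
                                       iterations = it - 1))
    jac <- matrix(0, length(f), length(u))
    for (j in seq_along(u)) {
      h <- 1e-7 * max(1, abs(u[j]))
      up <- u; up[j] <- u[j] + h
      um <- u; um[j] <- u[j] - h
      jac[, j] <- (fn(up) - fn(um)) / (2 * h)
    }
    step <- tryCatch(solve(jac, -f), error = function(e) NULL)
    res <- if (!is.null(step)) try_step(u, f, step) else NULL
    stalled <- is.null(res) ||
      max(abs(res$f)) > 0.99 * max(abs(f))  # negligible progress
    if (stalled) stalls <- stalls + 1 else stalls <- 0
    if (stalls >= 3 && !is.null(step) && nonmono < 5) {
      # watchdog: accept a full (possibly worsening) Newton step; damping
      # alone stalls when the iterate must first overshoot a ridge
      ft <- tryCatch(fn(u + step), error = function(e) NULL)
      if (!is.null(ft) && all(is.finite(ft)) &&
          max(abs(ft)) < 1e8 * max(1, f0)) {
        res <- list(u = u + step, f = ft)
        nonmono <- nonmono + 1
        stalls <- 0
      }
    }
    if (is.null(res)) break
    u <- res$u; f <- res$f
  }
  list(u = u, f = f, converged = max(abs(f)) < tol, iterations = max_iter)
}

#' Solve directly for the model's fixed point
#'
#' Computes the steady state of the single-compartment model by damped
#' Newton root-finding on (log Na, log K, log Cl, log w, Vm), imposing the
#' three zero-flux balances, osmotic balance (or its tension-offset form)
#' and the charge-difference voltage relation. The compartment's impermeant
#' content is specified as an amount of moles and a mean charge; the
#' steady-state volume follows from them.
#'
#' @param params [membrane_params()].
#' @param bath [bath_composition()].
#' @param x_moles total impermeant moles in the compartment, mol.
#' @param z impermeant mean charge.
#' @param length_dm cylinder length, dm.
#' @param osmotic_offset imposed steady transmembrane osmotic differential
#'   `Pi_i - Pi_o`, mM (used by offset sweeps).
#' @param guess optional [compartment_state()] used as the starting point;
#'   defaults to the default cell composition.
#' @param stability classify the root's linear stability and refuse
#'   dynamically unstable roots (e.g. the pump-off Donnan point, from which
#'   trajectories swell without bound).
#' @return An object of class `steady_state`: the fixed-point
#'   [compartment_state()], `vm`, `e_na`, `e_k`, `e_cl`, `df` (V), `j_p`,
#'   `j_kcc2` (C/(dm^2 s)), `w` (dm^3) and per-equation `residuals`.
#'   Non-convergence (e.g. with the pump off, where volume grows without
#'   bound) raises a condition of class `pumpleak_no_steady_state` carrying
#'   the residual report.
#' @examples
#' cell <- make_default_cell()
#' ss <- solve_steady_state(cell$params, cell$bath,
#'                          x_moles = cell$state$x * volume(cell$state),
#'                          z = -0.85, length_dm = cell$state$length)
#' round(M_to_mM(ss$state$cl), 1)  # 5.2 mM
#' @export
solve_steady_state <- function(params, bath, x_moles, z,
                               length_dm = um_to_dm(25),
                               osmotic_offset = 0, guess = NULL,
                               stability = TRUE) {
  stopifnot(x_moles > 0, inherits(params, "membrane_params"),
            inherits(bath, "bath_composition"))
  if (is.null(guess)) guess <- default_state()
  u0 <- c(log(guess$na), log(guess$k), log(guess$cl), log(volume(guess)),
          membrane_voltage(guess, params))
  fn <- function(u) ss_residual(u, params, bath, x_moles, z, length_dm,
                                osmotic_offset)
  sol <- newton_solve(fn, u0)
  if (!sol$converged) {
    # refine the guess by integrating briefly toward the attractor, then
    # retry; divergent volume growth marks a genuinely absent fixed point
    refined <- tryCatch({
      cfg <- sim_config(dt_ms = 1, duration_ms = 3e5,
                        record_every_ms = 3e5)
      run_engine(guess, params, bath, cfg)
    }, error = function(e) NULL)
    if (!is.null(refined)) {
      st <- refined$final_states[[1]]
      if (volume(st) < 10 * volume(guess)) {
        # rebuild the guess at the requested impermeant moles
        u0 <- c(log(st$na), log(st$k), log(st$cl), log(volume(st)),
                membrane_voltage(st, params))
        sol <- newton_solve(fn, u0)
      }
    }
  }
  if (!sol$converged) {
    cond <- structure(
      class = c("pumpleak_no_steady_state", "error", "condition"),
      list(message = paste0(
        "no steady state found (the flux balances have no reachable root ",
        "for these parameters); scaled residuals: ",
        paste(sprintf("%.3g", sol$f), collapse = ", ")),
        call = sys.call(-1), residuals = sol$f))
    stop(cond)
  }
  u <- sol$u
  w <- exp(u[4])
  x_conc <- x_moles / w
  r_um <- dm_to_um(sqrt(w / (pi * length_dm)))
  state <- compartment_state(M_to_mM(exp(u[1])), M_to_mM(exp(u[2])),
                             M_to_mM(exp(u[3])),
                             impermeant_pool(M_to_mM(x_conc), z),
                             radius_um = r_um,
                             length_um = dm_to_um(length_dm))
  e_na <- nernst_potential(state$na, bath$na, 1)
  e_k <- nernst_potential(state$k, bath$k, 1)
  e_cl <- nernst_potential(state$cl, bath$cl, -1)
  vm <- u[5]
  stab <- steady_state_stability(state, params, bath)
  if (stability && stab$max_re > 1e-9) {
    cond <- structure(
      class = c("pumpleak_no_steady_state", "error", "condition"),
      list(message = sprintf(
        paste0("no stable steady state: the flux-balance root is ",
               "dynamically unstable (max eigenvalue %.3g 1/s); ",
               "trajectories diverge (e.g. unbounded swelling)"),
        stab$max_re),
        call = sys.call(-1), eigenvalues = stab$eigenvalues))
    stop(cond)
  }
  structure(list(
    state = state, vm = vm, e_na = e_na, e_k = e_k, e_cl = e_cl,
    df = vm - e_cl,
    j_p = pump_flux(state$na, bath$na, params$p, params$pump_mode,
                    params$fixed_jp),
    j_kcc2 = kcc2_flux(e_k, e_cl, params$g_kcc2),
    w = w, residuals = sol$f, iterations = sol$iterations,
    eigenvalues = stab$eigenvalues
  ), class = "steady_state")
}

# Linear stability of a flux-balance root: Jacobian of the reduced
# (Na, K, Cl, w) dynamics (impermeant moles fixed, Vm algebraic) by central
# finite differences.
steady_state_stability <- function(state, params, bath) {
  n_x <- state$x * volume(state)
  z <- if (state$x > 0) state$xz / state$x else 0
  length_dm <- state$length
  rhs <- function(v) {
    w <- v[4]
    st <- state
    st$na <- v[1]; st$k <- v[2]; st$cl <- v[3]
    st$radius <- sqrt(w / (pi * length_dm))
    st$x <- n_x / w
    st$xz <- z * st$x
    j_p <- pump_flux(st$na, bath$na, params$p, params$pump_mode,
                     params$fixed_jp)
    j_kcc2 <- kcc2_flux(nernst_potential(st$k, bath$k, 1),
                        nernst_potential(st$cl, bath$cl, -1),
                        params$g_kcc2)
    dwdt <- volume_flux(st, bath, params)
    c(mM_to_M(ion_derivatives(st, params, bath, j_p, j_kcc2, dwdt)), dwdt)
  }
  v0 <- c(state$na, state$k, state$cl, volume(state))
  jac <- matrix(0, 4, 4)
  for (j in 1:4) {
    h <- 1e-6 * abs(v0[j])
    vp <- v0; vp[j] <- v0[j] + h
    vm_ <- v0; vm_[j] <- v0[j] - h
    jac[, j] <- (rhs(vp) - rhs(vm_)) / (2 * h)
  }
  ev <- eigen(jac, only.values = TRUE)$values
  list(eigenvalues = ev, max_re = max(Re(ev)))
}

#' @export
print.steady_state <- function(x, ...) {
  s <- x$state
  cat("<steady_state>\n")
  cat(sprintf("  Na %.4g, K %.4g, Cl %.4g, X %.4g mM; w %.4g pL\n",
              M_to_mM(s$na), M_to_mM(s$k), M_to_mM(s$cl), M_to_mM(s$x),
              dm3_to_pL(x$w)))
  cat(sprintf("  Vm %.4g, E_Na %.4g, E_K %.4g, E_Cl %.4g, DF %.4g mV\n",
              x$vm * 1000, x$e_na * 1000, x$e_k * 1000, x$e_cl * 1000,
              x$df * 1000))
  invisible(x)
}

apply_sweep_value <- function(parameter, value, params, bath, z) {
  os <- 0
  if (parameter %in% c("g_na", "g_k", "g_cl", "g_kcc2")) {
    params[[parameter]] <- uS_cm2_to_S_dm2(value)
  } else if (parameter == "p") {
    params$p <- value
  } else if (parameter == "fixed_jp") {
    params$pump_mode <- "fixed"
    params$fixed_jp <- value
  } else if (parameter == "z") {
    z <- value
  } else if (parameter == "k_o") {
    bath$k <- mM_to_M(value)
  } else if (parameter == "osmotic_offset") {
    os <- value
  } else {
    stop("unknown sweep parameter: ", parameter)
  }
  list(params = params, bath = bath, z = z, osmotic_offset = os)
}

#' Steady-state parameter sweeps
#'
#' Solves the fixed point along a grid of values of one parameter, with
#' continuation (each grid point warm-started from its solved neighbour,
#' walking outward from the value closest to the default). Failed points
#' are flagged, never dropped.
#'
#' @param parameter one of `"p"`, `"g_na"`, `"g_k"`, `"g_cl"`, `"g_kcc2"`
#'   (uS/cm^2), `"z"`, `"k_o"` (mM), `"fixed_jp"` (C/(dm^2 s)) or
#'   `"osmotic_offset"` (mM). For `"z"` sweeps the impermeant moles are
#'   held fixed and the volume adjusts.
#' @param values strictly monotone numeric grid.
#' @param params,bath,x_moles,z,length_dm as in [solve_steady_state()].
#' @return An object of class `sweep_result`: a data frame `grid` with one
#'   row per value (all steady-state scalars in output units plus a
#'   `converged` flag) and the list of `steady_state` objects.
#' @export
sweep_steady_state <- function(parameter, values, params, bath,
                               x_moles, z = -0.85,
                               length_dm = um_to_dm(25)) {
  stopifnot(length(values) >= 1, !is.unsorted(values) ||
              !is.unsorted(rev(values)))
  if (any(diff(values) == 0)) stop("sweep grid must be strictly monotone")
  m <- length(values)
  solutions <- vector("list", m)
  converged <- logical(m)

  default_value <- switch(parameter,
    g_na = S_dm2_to_uS_cm2(params$g_na), g_k = S_dm2_to_uS_cm2(params$g_k),
    g_cl = S_dm2_to_uS_cm2(params$g_cl),
    g_kcc2 = S_dm2_to_uS_cm2(params$g_kcc2),
    p = params$p, fixed_jp = params$p * (0.014 / 0.145)^3,
    z = z, k_o = M_to_mM(bath$k), osmotic_offset = 0)
  start <- which.min(abs(values - default_value))

  solve_at <- function(i, guess) {
    ctxi <- apply_sweep_value(parameter, values[i], params, bath, z)
    tryCatch(
      solve_steady_state(ctxi$params, ctxi$bath, x_moles, ctxi$z,
                         length_dm, ctxi$osmotic_offset, guess = guess),
      pumpleak_no_steady_state = function(e) NULL)
  }

  order_idx <- c(seq(start, m), if (start > 1) seq(start - 1, 1))
  guess_up <- NULL; guess_down <- NULL
  for (i in order_idx) {
    guess <- if (i >= start) guess_up else guess_down
    sol <- solve_at(i, guess)
    solutions[i] <- list(sol)  # [[<-]] with NULL would drop the element
    converged[i] <- !is.null(sol)
    if (!is.null(sol)) {
      if (i >= start) guess_up <- sol$state
      if (i <= start) guess_down <- sol$state
    }
  }

  grid <- data.frame(
    value = values,
    converged = converged,
    na_mM = NA_real_, k_mM = NA_real_, cl_mM = NA_real_, x_mM = NA_real_,
    z = NA_real_, volume_pL = NA_real_, vm_mV = NA_real_,
    ena_mV = NA_real_, ek_mV = NA_real_, ecl_mV = NA_real_,
    df_mV = NA_real_, jp = NA_real_, jkcc2 = NA_real_)
  for (i in seq_len(m)) {
    sol <- solutions[[i]]
    if (is.null(sol)) next
    s <- sol$state
    grid[i, 3:15] <- c(M_to_mM(s$na), M_to_mM(s$k), M_to_mM(s$cl),
                       M_to_mM(s$x), mean_charge(s$pool), dm3_to_pL(sol$w),
                       sol$vm * 1000, sol$e_na * 1000, sol$e_k * 1000,
                       sol$e_cl * 1000, sol$df * 1000, sol$j_p, sol$j_kcc2)
  }
  structure(list(parameter = parameter, grid = grid,
                 solutions = solutions),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s over %d values (%d converged)\n",
              x$parameter, nrow(x$grid), sum(x$grid$converged)))
  invisible(x)
}
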