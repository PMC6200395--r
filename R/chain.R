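#' Axial diffusion constants
#'
#' Diffusion constants for the permeant ions used by the Nernst-Planck
#' electrodiffusion coupling between compartments. Impermeant anions never
#' diffuse between compartments.
#'
#' @param d_na,d_k,d_cl diffusion constants, dm^2/s.
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(d_na = 1.33e-7, d_k = 1.96e-7,
                             d_cl = 2.03e-7) {
  stopifnot(d_na >= 0, d_k >= 0, d_cl >= 0)
  structure(list(d_na = d_na, d_k = d_k, d_cl = d_cl),
            class = "diffusion_params")
}

#' Chain of compartments ("virtual dendrite")
#'
#' An ordered, unbranched chain of identical-length cylindrical
#' compartments sharing one set of membrane parameters (optionally
#' overridden per compartment) and coupled by electrodiffusion. Ends are
#' sealed (no-flux).
#'
#' @param n number of compartments (>= 2).
#' @param radius_um,length_um per-compartment geometry, um.
#' @param params shared [membrane_params()].
#' @param bath [bath_composition()].
#' @param diffusion [diffusion_params()].
#' @param states optional list of `n` [compartment_state()]s; by default
#'   each compartment starts at the electroneutral default composition.
#' @param overrides named list of per-compartment parameter vectors
#'   (`g_na`, `g_k`, `g_cl`, `g_kcc2`, in uS/cm^2) overriding `params`.
#' @return An object of class `chain_model`.
#' @export
chain_model <- function(n = 10, radius_um = 0.5, length_um = 10,
                        params = membrane_params(),
                        bath = bath_composition(),
                        diffusion = diffusion_params(),
                        states = NULL, overrides = list()) {
  stopifnot(n >= 2, inherits(diffusion, "diffusion_params"))
  if (is.null(states))
    states <- replicate(n, initial_state(radius_um = radius_um,
                                         length_um = length_um),
                        simplify = FALSE)
  stopifnot(length(states) == n)
  for (nm in names(overrides))
    stopifnot(nm %in% c("g_na", "g_k", "g_cl", "g_kcc2"),
              length(overrides[[nm]]) %in% c(1, n))
  structure(list(n = n, states = states, params = params, bath = bath,
                 diffusion = diffusion, overrides = overrides),
            class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("<chain_model> %d compartments, %g um each, r %.4g um\n",
              x$n, dm_to_um(x$states[[1]]$length),
              dm_to_um(x$states[[1]]$radius)))
  invisible(x)
}

#' Simulate a compartment chain
#'
#' Per membrane step every compartment runs the single-compartment physics
#' (with per-compartment volume expressed as a radius change at fixed
#' length); electrodiffusion fluxes between neighbours are applied every
#' substep. Protocol events target compartments through their
#' `compartment` field.
#'
#' @param chain a [chain_model()].
#' @param config [sim_config()]; chains default to `dt_ms = 1e-3` and the
#'   discretization mode/substep ratio set there.
#' @param protocol list of protocol events.
#' @return A `timeseries_result` with one block of columns per compartment.
#' @export
simulate_chain <- function(chain,
                           config = sim_config(dt_ms = 1e-3,
                                               duration_ms = 1000),
                           protocol = list()) {
  stopifnot(inherits(chain, "chain_model"))
  run_engine(chain$states, chain$params, chain$bath, config, protocol,
             diffusion = chain$diffusion, overrides = chain$overrides)
}

#' One electrodiffusion update (reference implementation)
#'
#' Pure-R Nernst-Planck update between neighbouring compartments used as
#' the oracle for the compiled path. For each interior interface the flux
#' density per permeant ion is
#' `J = -D (zF/RT * (Ci+Cj)/2 * (Vi-Vj)/dx + (Ci-Cj)/dx)` with
#' `dx = (hi+hj)/2`; concentrations are updated either per length
#' (`mode = "per_length"`, each side normalised by its own length) or
#' mole-conservatively through the shared interface area
#' (`mode = "conservative"`). Chain ends are sealed.
#'
#' @param chain a [chain_model()].
#' @param dt_s time step, s.
#' @param mode `"per_length"` or `"conservative"`.
#' @return The chain with updated permeant concentrations.
#' @export
electrodiffusion_update <- function(chain, dt_s,
                                    mode = c("per_length", "conservative")) {
  mode <- match.arg(mode)
  pc <- phys_constants()
  n <- chain$n
  st <- chain$states
  h <- st[[1]]$length
  vm <- vapply(st, membrane_voltage, numeric(1), c_m = chain$params)
  conc <- sapply(st, function(s) c(s$na, s$k, s$cl))  # 3 x n
  dnew <- conc
  dd <- c(chain$diffusion$d_na, chain$diffusion$d_k, chain$diffusion$d_cl)
  zz <- c(1, 1, -1)
  for (q in 1:3) {
    if (dd[q] <= 0) next
    for (i in seq_len(n - 1)) {
      dx <- h
      cav <- (conc[q, i] + conc[q, i + 1]) / 2
      term <- dd[q] * (zz[q] * pc$f / (pc$r * pc$t) * cav *
                         (vm[i] - vm[i + 1]) / dx +
                       (conc[q, i] - conc[q, i + 1]) / dx)
      if (mode == "per_length") {
        dnew[q, i] <- dnew[q, i] - dt_s * term / h
        dnew[q, i + 1] <- dnew[q, i + 1] + dt_s * term / h
      } else {
        rmin <- min(st[[i]]$radius, st[[i + 1]]$radius)
        a <- pi * rmin^2
        dnew[q, i] <- dnew[q, i] - term * a * dt_s / volume(st[[i]])
        dnew[q, i + 1] <- dnew[q, i + 1] +
          term * a * dt_s / volume(st[[i + 1]])
      }
    }
  }
  for (i in seq_len(n)) {
    st[[i]]$na <- dnew[1, i]
    st[[i]]$k <- dnew[2, i]
    st[[i]]$cl <- dnew[3, i]
  }
  chain$states <- st
  chain
}
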