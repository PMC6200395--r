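test_that("pool injection follows the weighted-mean charge rule", {
  st <- default_state()
  z0 <- mean_charge(st$pool)
  x0 <- M_to_mM(st$x)
  out <- inject_impermeant(st, rate = 1, valence = -1.5, dt_s = 10)
  expect_equal(M_to_mM(out$x), x0 + 10)
  expect_equal(out$xz / out$x, (z0 * x0 - 1.5 * 10) / (x0 + 10),
               tolerance = 1e-12)
  expect_identical(inject_impermeant(st, 0, -1.5, 10), st)
})

test_that("mean-charge ramps conserve impermeant moles", {
  st <- default_state()
  out <- ramp_mean_charge(st, target_z = -1)
  expect_equal(out$x, st$x)
  expect_equal(out$xz / out$x, -1)
  expect_identical(ramp_mean_charge(st, mean_charge(st$pool))$xz, st$xz)
})

test_that("extracellular swaps preserve bath osmolarity and charge", {
  bath <- bath_composition()
  out <- extracellular_swap(bath, 25)
  expect_equal(osmolarity(out), osmolarity(bath))
  charge <- function(b) b$na + b$k - b$cl - b$x  # X_o valence is -1
  expect_equal(charge(out), charge(bath))
  expect_identical(extracellular_swap(bath, 0), bath)
  expect_error(extracellular_swap(bath, 125), "negative")
})

test_that("amount-only impermeant addition leaves the potentials alone", {
  cell <- fix_cell()
  ss <- fix_ss()
  prot <- list(ev_inject(rate = 0.5, valence = mean_charge(ss$state$pool),
                         start_ms = 1e4, stop_ms = 7e4))
  res <- simulate_compartment(ss$state, cell$params, cell$bath,
                              sim_config(duration_ms = 36e5,
                                         record_every_ms = 1e4,
                                         check_steady = TRUE,
                                         steady_tol = 1e-8), prot)
  last <- res$data[nrow(res$data), ]
  expect_lt(abs(last$ecl_mV - 1000 * ss$e_cl), 1e-2)
  expect_lt(abs(last$ek_mV - 1000 * ss$e_k), 1e-2)
  expect_lt(abs(last$vm_mV - 1000 * ss$vm), 1e-2)
  expect_lt(abs(last$df_mV - 1000 * ss$df), 1e-2)
  expect_gt(last$volume_pL, dm3_to_pL(ss$w) * 1.05)  # swelling persists
})

test_that("injection then removal of equal moles restores the original
           steady state", {
  cell <- fix_cell()
  ss <- fix_ss()
  z <- mean_charge(ss$state$pool)
  moles <- 0.2 * ss$state$x * ss$w
  prot <- list(
    ev_inject(rate = moles / 60, valence = z, start_ms = 1e4,
              stop_ms = 7e4, unit = "mol_s"),
    ev_inject(rate = -moles / 60, valence = z, start_ms = 1.2e6,
              stop_ms = 1.26e6, unit = "mol_s"))
  res <- simulate_compartment(ss$state, cell$params, cell$bath,
                              sim_config(duration_ms = 48e5,
                                         record_every_ms = 1e4,
                                         check_steady = TRUE,
                                         steady_tol = 1e-8), prot)
  fin <- res$final_states[[1]]
  expect_equal(M_to_mM(fin$cl), M_to_mM(ss$state$cl), tolerance = 1e-4)
  expect_equal(M_to_mM(fin$na), M_to_mM(ss$state$na), tolerance = 1e-4)
  expect_equal(dm3_to_pL(volume(fin)), dm3_to_pL(ss$w), tolerance = 1e-4)
})

test_that("persistent DF shifts vanish under a fixed pump rate", {
  cell <- fix_cell()
  ss <- fix_ss()
  par <- membrane_params(pump_mode = "fixed", fixed_jp = ss$j_p)
  prot <- list(ev_ramp_charge(target_z = -1, start_ms = 6e4,
                              stop_ms = 66e4))
  res <- simulate_compartment(ss$state, par, cell$bath,
                              sim_config(duration_ms = 72e5,
                                         record_every_ms = 1e4), prot)
  last <- res$data[nrow(res$data), ]
  expect_lt(abs(last$df_mV - 1000 * ss$df), 1e-3)
  expect_lt(last$ecl_mV, 1000 * ss$e_cl - 1)  # E_Cl itself did move
})

test_that("persistent DF requires cotransport even with a dynamic pump", {
  cell <- fix_cell()
  xm <- cell$state$x * volume(cell$state)
  par0 <- membrane_params(g_kcc2 = 0)
  ss0 <- solve_steady_state(par0, cell$bath, xm, -0.85,
                            cell$state$length)
  prot <- list(ev_ramp_charge(target_z = -1, start_ms = 6e4,
                              stop_ms = 66e4))
  res <- simulate_compartment(ss0$state, par0, cell$bath,
                              sim_config(duration_ms = 72e5,
                                         record_every_ms = 1e4), prot)
  expect_lt(abs(res$data$df_mV[nrow(res$data)]), 1e-2)
})

test_that("the pump off/on ramp collapses and restores the gradients", {
  cell <- fix_cell()
  ss <- fix_ss()
  prot <- list(ev_pump_ramp("off", start_ms = 3e4, stop_ms = 9e4),
               ev_pump_ramp("on", start_ms = 27e4, stop_ms = 33e4))
  res <- simulate_compartment(ss$state, cell$params, cell$bath,
                              sim_config(duration_ms = 42e5,
                                         record_every_ms = 5e3,
                                         check_steady = TRUE), prot)
  d <- res$data
  off_end <- d[which.min(abs(d$time_ms - 27e4)), ]
  expect_gt(off_end$volume_pL, dm3_to_pL(ss$w))          # swelling
  expect_gt(off_end$vm_mV, 1000 * ss$vm + 5)             # depolarization
  fin <- d[nrow(d), ]
  expect_equal(fin$cl_mM, M_to_mM(ss$state$cl), tolerance = 1e-3)
  expect_equal(fin$vm_mV, 1000 * ss$vm, tolerance = 1e-3)
  # a zero-duration ramp acts as a step change
  prot0 <- list(ev_pump_ramp("off", start_ms = 1e3, stop_ms = 1e3))
  res0 <- simulate_compartment(ss$state, cell$params, cell$bath,
                               sim_config(duration_ms = 3e3,
                                          record_every_ms = 1e3), prot0)
  expect_equal(res0$data$jp[nrow(res0$data)], 0)
})

test_that("protocol files round-trip through the YAML loader", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "- kind: pump_ramp",
    "  direction: off",
    "  start_ms: 1000",
    "  stop_ms: 2000",
    "- kind: inject",
    "  rate: 0.5",
    "  valence: -1.5",
    "  start_ms: 0",
    "  stop_ms: 500",
    "  compartment: 2"), path)
  prot <- load_protocol(path)
  expect_length(prot, 2)
  expect_identical(prot[[1]]$kind, "pump_ramp")
  expect_equal(prot[[2]]$payload$compartment, 2)
  writeLines("- kind: teleport\n  start_ms: 0", path)
  expect_error(load_protocol(path), "unknown protocol event kind")
})
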