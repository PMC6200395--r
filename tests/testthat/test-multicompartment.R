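# Electrodiffusion coupling between compartments, checked against the
# pure-R Nernst-Planck reference and its conservation properties.

inert_params <- function()
  membrane_params(g_na = 0, g_k = 0, g_cl = 0, g_kcc2 = 0, p = 0,
                  p_w = 0)

perturbed_chain <- function(n = 6, params = membrane_params()) {
  states <- lapply(seq_len(n), function(i)
    initial_state(cl = 5.2 + 2 * (i %% 3), k = 122.9 - (i %% 2),
                  balance = "x", radius_um = 0.5 + 0.05 * (i %% 2),
                  length_um = 10))
  chain_model(n, params = params, bath = bath_composition(),
              states = states)
}

test_that("a uniform chain carries no electrodiffusive flux", {
  ch <- chain_model(5)
  out <- electrodiffusion_update(ch, dt_s = 1e-6)
  for (i in 1:5) {
    expect_equal(out$states[[i]]$na, ch$states[[i]]$na)
    expect_equal(out$states[[i]]$cl, ch$states[[i]]$cl)
  }
})

test_that("with equal voltages the flux reduces to Fickian diffusion", {
  pc <- phys_constants()
  # equal net charge (hence equal Vm) but a chloride gradient
  s1 <- initial_state(cl = 5.2, balance = "x", radius_um = 0.5,
                      length_um = 10)
  s2 <- initial_state(cl = 7.2, k = 124.9, balance = "none",
                      radius_um = 0.5, length_um = 10)
  s2$pool <- s1$pool; s2$x <- s1$x; s2$xz <- s1$xz
  ch <- chain_model(2, states = list(s1, s2))
  expect_equal(membrane_voltage(s1, ch$params),
               membrane_voltage(s2, ch$params))
  dt <- 1e-6
  out <- electrodiffusion_update(ch, dt)
  h <- s1$length
  expected <- ch$diffusion$d_cl * (s1$cl - s2$cl) / h  # pure -D dC/dx
  expect_equal(out$states[[1]]$cl - s1$cl, -dt * expected / h,
               tolerance = 1e-12)
  expect_equal(out$states[[2]]$cl - s2$cl, dt * expected / h,
               tolerance = 1e-12)
})

test_that("compiled electrodiffusion matches the reference update", {
  ch <- perturbed_chain(params = inert_params())
  # an inert membrane isolates the electrodiffusive part of one step
  cfg <- sim_config(dt_ms = 1e-3, duration_ms = 1e-3,
                    record_every_ms = 1e-3)
  res <- simulate_chain(ch, cfg)
  ref <- electrodiffusion_update(ch, 1e-6, mode = "per_length")
  for (i in seq_len(ch$n)) {
    expect_equal(res$final_states[[i]]$na, ref$states[[i]]$na,
                 tolerance = 1e-12)
    expect_equal(res$final_states[[i]]$k, ref$states[[i]]$k,
                 tolerance = 1e-12)
    expect_equal(res$final_states[[i]]$cl, ref$states[[i]]$cl,
                 tolerance = 1e-12)
  }
})

test_that("conservative mode conserves every permeant ion's moles", {
  ch <- perturbed_chain()
  moles <- function(states, field)
    sum(vapply(states, function(s) s[[field]] * volume(s), numeric(1)))
  n0 <- sapply(c("na", "k", "cl"), function(f) moles(ch$states, f))
  cfg <- sim_config(dt_ms = 1e-3, duration_ms = 200,
                    record_every_ms = 200, ed_mode = "conservative")
  res <- simulate_chain(ch, cfg)
  # transmembrane fluxes change totals; isolate axial exchange with an
  # inert membrane
  ch_inert <- perturbed_chain(params = inert_params())
  res_i <- simulate_chain(ch_inert, cfg)
  n1 <- sapply(c("na", "k", "cl"), function(f) moles(res_i$final_states,
                                                     f))
  expect_lt(max(abs(n1 - n0) / n0), 1e-9)
  expect_false(isTRUE(all.equal(res$final_states[[1]]$cl,
                                res_i$final_states[[1]]$cl)))
})

test_that("the per-length update conserves moles only for equal radii", {
  mk <- function(radius2) {
    states <- list(
      initial_state(cl = 5.2, balance = "x", radius_um = 0.5,
                    length_um = 10),
      initial_state(cl = 9.2, balance = "x", radius_um = radius2,
                    length_um = 10))
    chain_model(2, params = inert_params(), states = states)
  }
  moles <- function(states)
    sum(vapply(states, function(s) s$cl * volume(s), numeric(1)))
  cfg <- function(mode) sim_config(dt_ms = 1e-3, duration_ms = 50,
                                   record_every_ms = 50, ed_mode = mode)
  equal <- mk(0.5)
  res_eq <- simulate_chain(equal, cfg("per_length"))
  expect_equal(moles(res_eq$final_states), moles(equal$states),
               tolerance = 1e-12)
  uneven <- mk(0.7)
  res_p <- simulate_chain(uneven, cfg("per_length"))
  res_c <- simulate_chain(uneven, cfg("conservative"))
  expect_gt(abs(moles(res_p$final_states) / moles(uneven$states) - 1),
            1e-6)
  expect_lt(abs(moles(res_c$final_states) / moles(uneven$states) - 1),
            1e-12)
})

test_that("mirroring the chain mirrors the solution exactly", {
  par <- membrane_params()
  ssb <- fix_chain_ss()
  gk <- rep(20, 6); gk[2] <- 200
  run <- function(gk2) {
    ch <- chain_model(6, params = par,
                      states = replicate(6, ssb$state, simplify = FALSE),
                      overrides = list(g_kcc2 = gk2))
    simulate_chain(ch, sim_config(dt_ms = 2e-3, duration_ms = 5e3,
                                  record_every_ms = 5e3,
                                  membrane_every = 50))
  }
  fwd <- run(gk)$final_states
  rev_ <- run(rev(gk))$final_states
  for (i in 1:6) {
    expect_equal(fwd[[i]]$cl, rev_[[7 - i]]$cl, tolerance = 1e-9)
    expect_equal(fwd[[i]]$radius, rev_[[7 - i]]$radius, tolerance = 1e-9)
  }
})

test_that("with no diffusion each compartment is an isolated cell", {
  par <- membrane_params()
  bath <- bath_composition()
  st <- initial_state(cl = 20, balance = "k", radius_um = 0.5,
                      length_um = 10)
  ch <- chain_model(4, params = par, bath = bath,
                    states = replicate(4, st, simplify = FALSE),
                    diffusion = diffusion_params(0, 0, 0))
  cfg <- sim_config(dt_ms = 1, duration_ms = 3e4, record_every_ms = 3e4)
  res <- simulate_chain(ch, cfg)
  single <- simulate_compartment(st, par, bath, cfg)
  vm1 <- 1000 * membrane_voltage(single$final_states[[1]], par)
  for (i in 1:4) {
    vmi <- 1000 * membrane_voltage(res$final_states[[i]], par)
    expect_lt(abs(vmi - vm1), 1e-3)
  }
})

test_that("the two-rate scheme matches single-rate integration", {
  par <- membrane_params()
  ssb <- fix_chain_ss()
  gk <- rep(20, 10); gk[2] <- 600
  mk <- function() chain_model(10, params = par,
                               states = replicate(10, ssb$state,
                                                  simplify = FALSE),
                               overrides = list(g_kcc2 = gk))
  fine <- simulate_chain(mk(), sim_config(dt_ms = 1e-3, duration_ms = 100,
                                          record_every_ms = 100))
  coarse <- simulate_chain(mk(), sim_config(dt_ms = 2e-3,
                                            duration_ms = 100,
                                            record_every_ms = 100,
                                            membrane_every = 50))
  for (i in 1:10) {
    dvm <- 1000 * abs(membrane_voltage(fine$final_states[[i]], par) -
                        membrane_voltage(coarse$final_states[[i]], par))
    expect_lt(dvm, 1e-2)
    dcl <- 1000 * abs(fine$final_states[[i]]$cl -
                        coarse$final_states[[i]]$cl)
    expect_lt(dcl, 1e-2)
  }
})

test_that("electrodiffusion stability violations are rejected", {
  ch <- chain_model(3)
  expect_error(
    simulate_chain(ch, sim_config(dt_ms = 50, duration_ms = 100)),
    "stability")
})

test_that("chains refuse fewer than two compartments", {
  expect_error(chain_model(1), "n >= 2")
})
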