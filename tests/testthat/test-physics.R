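test_that("Nernst potentials reproduce the default reversal potentials", {
  expect_equal(nernst_potential(122.9, 3.5, 1), -0.0951, tolerance = 2e-3)
  expect_equal(nernst_potential(5.2, 119, -1), -0.0838, tolerance = 2e-3)
  expect_equal(nernst_potential(7.3, 7.3, 1), 0)
  expect_equal(nernst_potential(7.3, 7.3, -2), 0)
  expect_error(nernst_potential(0, 100, 1), "positive")
  expect_error(nernst_potential(10, -1, -1), "positive")
  expect_error(nernst_potential(10, 100, 0), "valence")
})

test_that("charge-difference voltage is linear in the net charge", {
  cell <- fix_cell()
  expect_equal(membrane_voltage(cell$state, cell$params), 0)
  # net charge concentration of -6.03 uM over the default geometry
  mk <- function(scale) {
    x <- (14 + 122.9 - 5.2 + scale * 6.03e-3) / 0.85
    initial_state(x = x, balance = "none")
  }
  v1 <- membrane_voltage(mk(1), cell$params)
  expect_equal(v1, -0.0727, tolerance = 1e-3)
  expect_equal(membrane_voltage(mk(2), cell$params), 2 * v1,
               tolerance = 1e-9)
})

test_that("the pump flux is cubic in the sodium gradient", {
  expect_equal(pump_flux(14, 145, 0.1), 9.00078e-05, tolerance = 1e-6)
  expect_equal(pump_flux(0, 145, 0.1), 0)
  expect_equal(pump_flux(145, 145, 0.1), 0.1)
  # fixed mode ignores sodium entirely
  expect_equal(pump_flux(50, 145, 0.1, "fixed", fixed_jp = 9e-5), 9e-5)
  expect_error(pump_flux(-1, 145, 0.1), "non-negative")
  expect_error(pump_flux(14, 0, 0.1), "positive")
})

test_that("KCC2 flux is driven by E_K - E_Cl", {
  expect_equal(kcc2_flux(-0.0838, -0.0838, 2e-3), 0)
  expect_equal(kcc2_flux(-0.0951, -0.0838, 2e-3), -2.26e-5,
               tolerance = 1e-3)
  expect_equal(kcc2_flux(-0.02, -0.08, 0), 0)
})

test_that("membrane tension follows the piecewise Laplace law", {
  expect_equal(hydrostatic_pressure(1, 2, 25), 0)
  expect_equal(hydrostatic_pressure(2, 2, 25), 0)
  expect_equal(hydrostatic_pressure(2.2, 2, 25), 28.56, tolerance = 1e-3)
  expect_equal(hydrostatic_pressure(1e9, 2, 25), 4 * pi * 25,
               tolerance = 1e-6)
})

test_that("water flux follows the osmotic differential", {
  cell <- fix_cell()
  st <- fix_ss()$state
  expect_equal(volume_flux(st, cell$bath, cell$params), 0,
               tolerance = 1e-22)
  swollen <- initial_state(x = 200, balance = "none")  # hyperosmotic
  expect_gt(volume_flux(swollen, cell$bath, cell$params), 0)
  shrunk <- initial_state(x = 100, balance = "none")
  expect_lt(volume_flux(shrunk, cell$bath, cell$params), 0)
})

test_that("tension mode sustains an osmotic differential at equilibrium", {
  cell <- fix_cell()
  pc <- phys_constants()
  par <- membrane_params(volume_mode = "tension", r_a = um_to_dm(5) / 1.1)
  st <- fix_ss()$state  # radius 5 um = 1.1 r_a
  hp <- hydrostatic_pressure(st$radius, par$r_a, par$k_m)
  offset_mM <- M_to_mM(hp / (pc$r * pc$t))
  expect_gt(offset_mM, 1)  # about 11 mM of balanced differential
  st$na <- st$na + mM_to_M(offset_mM)  # impose Pi_i - Pi_o = Hp/RT
  expect_equal(volume_flux(st, cell$bath, par) /
                 (par$v_w * par$p_w * surface_area(st)), 0,
               tolerance = 1e-9)
})

test_that("ion derivatives vanish at the fixed point and obey dilution", {
  cell <- fix_cell()
  ss <- fix_ss()
  d <- ion_derivatives(ss$state, cell$params, cell$bath, ss$j_p,
                       ss$j_kcc2, dwdt = 0)
  expect_lt(max(abs(d)), 1e-4)  # mM/s
  # no conductances, no pump: nothing moves
  quiet <- membrane_params(g_na = 0, g_k = 0, g_cl = 0, g_kcc2 = 0, p = 0)
  d0 <- ion_derivatives(ss$state, quiet, cell$bath, 0, 0, dwdt = 0)
  expect_equal(unname(d0), c(0, 0, 0))
  # swelling with no transmembrane flux dilutes every ion
  dsw <- ion_derivatives(ss$state, quiet, cell$bath, 0, 0, dwdt = 1e-15)
  expect_true(all(dsw < 0))
})

test_that("flux balances close at the solved fixed point", {
  cell <- fix_cell()
  r <- flux_residuals(fix_ss()$state, cell$params, cell$bath)
  expect_lt(max(abs(r[c("na", "k", "cl")])), 1e-8)   # C/(dm^2 s)
  expect_lt(abs(r[["osm"]]), 1e-3)                   # mM
})
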