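test_that("the default fixed point reproduces the reference composition", {
  ss <- fix_ss()
  expect_equal(M_to_mM(ss$state$na), 14.0, tolerance = 0.1 / 14)
  expect_equal(M_to_mM(ss$state$k), 122.9, tolerance = 0.1 / 122.9)
  expect_equal(M_to_mM(ss$state$cl), 5.2, tolerance = 0.1 / 5.2)
  expect_equal(M_to_mM(ss$state$x), 154.9, tolerance = 0.1 / 154.9)
  expect_equal(1000 * ss$vm, -72.6, tolerance = 0.1 / 72.6)
  expect_equal(1000 * ss$e_cl, -83.8, tolerance = 0.1 / 83.8)
  expect_equal(1000 * ss$e_k, -95.1, tolerance = 0.1 / 95.1)
  expect_equal(1000 * ss$df, 11.3, tolerance = 0.1 / 11.3)
  expect_equal(dm3_to_pL(ss$w), 2.0, tolerance = 0.1 / 2)
  expect_lt(max(abs(ss$residuals)), 1e-8)
})

test_that("driving force needs cotransport: g_KCC2 = 0 pins E_Cl to Vm", {
  cell <- fix_cell()
  xm <- cell$state$x * volume(cell$state)
  ss0 <- solve_steady_state(membrane_params(g_kcc2 = 0), cell$bath, xm,
                            -0.85, cell$state$length)
  expect_lt(abs(1000 * ss0$df), 1e-2)
})

test_that("E_K bounds E_Cl from below at high KCC2 conductance", {
  cell <- fix_cell()
  xm <- cell$state$x * volume(cell$state)
  hi <- solve_steady_state(membrane_params(g_kcc2 = 600), cell$bath, xm,
                           -0.85, cell$state$length)
  expect_gt(hi$e_cl, hi$e_k)
  expect_lt(1000 * (hi$e_cl - hi$e_k), 1.0)
})

test_that("DF grows monotonically with g_KCC2 and stays non-negative", {
  cell <- fix_cell()
  sw <- sweep_steady_state("g_kcc2", seq(0, 600, by = 50), cell$params,
                           cell$bath, cell$state$x * volume(cell$state))
  expect_true(all(sw$grid$converged))
  expect_true(all(sw$grid$df_mV >= -1e-9))
  expect_true(all(diff(sw$grid$df_mV) >= -1e-9))
})

test_that("a fixed pump rate makes DF independent of the mean charge", {
  cell <- fix_cell()
  ss <- fix_ss()
  par <- membrane_params(pump_mode = "fixed", fixed_jp = ss$j_p)
  sw <- sweep_steady_state("z", seq(-1.1, -0.7, by = 0.05), par,
                           cell$bath, cell$state$x * volume(cell$state))
  expect_true(all(sw$grid$converged))
  expect_lt(diff(range(sw$grid$df_mV)), 1e-3)
})

test_that("a sodium-dependent pump lets z shift DF by under a millivolt", {
  cell <- fix_cell()
  sw <- sweep_steady_state("z", seq(-1.1, -0.7, by = 0.05), cell$params,
                           cell$bath, cell$state$x * volume(cell$state))
  expect_true(all(sw$grid$converged))
  expect_lt(diff(range(sw$grid$df_mV)), 1.0)
  expect_gt(diff(range(sw$grid$df_mV)), 0)  # but not exactly constant
})

test_that("steady-state volume is proportional to impermeant moles", {
  cell <- fix_cell()
  xm <- cell$state$x * volume(cell$state)
  ws <- sapply(c(0.5, 1, 2), function(s)
    solve_steady_state(cell$params, cell$bath, s * xm, -0.85,
                       cell$state$length)$w)
  # linear up to the (muM-scale) net-charge correction to A_m
  expect_equal(ws[2] / ws[1], 2, tolerance = 1e-4)
  expect_equal(ws[3] / ws[2], 2, tolerance = 1e-4)
})

test_that("steady-state Vm rises with bath potassium, log-linearly when
           potassium dominates", {
  cell <- fix_cell()
  sw <- sweep_steady_state("k_o", c(2, 3.5, 7, 14, 28, 56, 112), cell$params,
                           cell$bath, cell$state$x * volume(cell$state))
  vm <- sw$grid$vm_mV
  expect_true(all(diff(vm) > 0))
  # roughly constant mV per doubling once potassium dominates
  inc <- diff(vm[4:7])
  expect_lt(max(abs(inc - mean(inc))) / mean(inc), 0.25)
})

test_that("impossible balances raise the no-steady-state condition", {
  cell <- fix_cell()
  xm <- cell$state$x * volume(cell$state)
  # a fixed pump with no sodium leak can never be balanced
  expect_error(
    solve_steady_state(membrane_params(g_na = 0, pump_mode = "fixed",
                                       fixed_jp = 9e-5),
                       cell$bath, xm, -0.85, cell$state$length),
    class = "pumpleak_no_steady_state")
})

test_that("sweeps flag failed grid points instead of dropping them", {
  cell <- fix_cell()
  parf <- membrane_params(pump_mode = "fixed", fixed_jp = 9e-5)
  sw <- sweep_steady_state("g_na", c(0, 10, 20), parf, cell$bath,
                           cell$state$x * volume(cell$state))
  expect_equal(nrow(sw$grid), 3)
  expect_false(sw$grid$converged[1])
  expect_true(all(sw$grid$converged[2:3]))
  expect_true(is.na(sw$grid$cl_mM[1]))
  expect_error(sweep_steady_state("g_na", c(10, 10, 20), cell$params,
                                  cell$bath,
                                  cell$state$x * volume(cell$state)),
               "monotone")
})

test_that("the pump-off composition retains a distant stable Donnan root", {
  cell <- fix_cell()
  xm <- cell$state$x * volume(cell$state)
  donnan <- solve_steady_state(membrane_params(p = 0), cell$bath, xm,
                               -0.85, cell$state$length)
  # all gradients collapse and the cell sits about 5x its resting volume
  expect_lt(abs(1000 * donnan$df), 1e-6)
  expect_equal(donnan$vm, donnan$e_k, tolerance = 1e-6)
  expect_gt(dm3_to_pL(donnan$w), 5 * 1.96)
  expect_lt(max(Re(donnan$eigenvalues)), 1e-9)  # linearly stable
})
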