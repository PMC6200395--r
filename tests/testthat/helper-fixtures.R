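# Shared fixtures, computed lazily once per test run.

.fix <- new.env()

fix_cell <- function() {
  if (is.null(.fix$cell)) .fix$cell <- make_default_cell()
  .fix$cell
}

# solved default fixed point (10 um diameter x 25 um cell)
fix_ss <- function() {
  if (is.null(.fix$ss)) {
    cell <- fix_cell()
    .fix$ss <- solve_steady_state(cell$params, cell$bath,
                                  cell$state$x * volume(cell$state),
                                  mean_charge(cell$state$pool),
                                  cell$state$length)
  }
  .fix$ss
}

# solved per-compartment fixed point of the dendrite geometry
fix_chain_ss <- function() {
  if (is.null(.fix$chain_ss)) {
    cell <- fix_cell()
    st <- initial_state(radius_um = 0.5, length_um = 10)
    .fix$chain_ss <- solve_steady_state(cell$params, cell$bath,
                                        st$x * volume(st),
                                        mean_charge(st$pool), st$length,
                                        guess = st)
  }
  .fix$chain_ss
}

df_of <- function(state, params, bath) 1000 * driving_force(state, params,
                                                            bath)
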