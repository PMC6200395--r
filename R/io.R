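#' Default single cell and virtual dendrite
#'
#' `make_default_cell()` builds the default 10 um diameter x 25 um cylinder
#' with the default bath and membrane parameters, initialized exactly
#' electroneutral at the default target concentrations.
#' `make_default_dendrite()` builds the default 10-compartment chain
#' (10 um length, 0.5 um radius per compartment) with the default axial
#' diffusion constants.
#'
#' @return `make_default_cell()`: a list with `state`, `params`, `bath`.
#'   `make_default_dendrite()`: a [chain_model()].
#' @examples
#' cell <- make_default_cell()
#' dm3_to_pL(volume(cell$state))  # about 2.0 pL
#' @export
make_default_cell <- function() {
  list(state = default_state(), params = membrane_params(),
       bath = bath_composition())
}

#' @rdname make_default_cell
#' @export
make_default_dendrite <- function() chain_model()

#' Write and read time-series results
#'
#' CSV dialect with one row per record per compartment and the header
#' `time_ms, compartment, na_mM, k_mM, cl_mM, x_mM, z, radius_um,
#' volume_pL, vm_mV, ena_mV, ek_mV, ecl_mV, df_mV, jp, jkcc2`. Numbers are
#' written with 17 significant digits so that identical runs produce
#' byte-identical files.
#'
#' @param result a `timeseries_result` (or its `data` data frame).
#' @param path file path.
#' @return `write_timeseries()` returns `path` invisibly;
#'   `read_timeseries()` returns the data frame.
#' @export
write_timeseries <- function(result, path) {
  data <- if (inherits(result, "timeseries_result")) result$data else result
  stopifnot(is.data.frame(data))
  fmt <- vapply(data, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, FUN.VALUE = character(nrow(data)))
  if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = nrow(data))
  lines <- c(paste(names(data), collapse = ","),
             apply(fmt, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  read.csv(path, check.names = FALSE)
}

#' Write a steady-state sweep
#'
#' One row per grid value with all steady-state scalar fields, sharing
#' column names with the time-series dialect.
#'
#' @param sweep a `sweep_result`.
#' @param path file path.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  df <- sweep$grid
  names(df)[1] <- sweep$parameter
  write_timeseries(df, path)
}

config_keys <- c(
  "g_na_uS_cm2", "g_k_uS_cm2", "g_cl_uS_cm2", "g_kcc2_uS_cm2",
  "p_pump", "cm_F_cm2", "vw", "pw", "km",
  "bath.na_mM", "bath.k_mM", "bath.cl_mM", "bath.x_mM",
  "cell.diameter_um", "cell.length_um",
  "sim.dt_ms", "sim.duration_ms", "sim.record_every_ms",
  "chain.n_compartments", "chain.compartment_length_um",
  "chain.initial_radius_um",
  "chain.d_na", "chain.d_k", "chain.d_cl")

default_config_values <- function() {
  list(
    g_na_uS_cm2 = 20, g_k_uS_cm2 = 70, g_cl_uS_cm2 = 20,
    g_kcc2_uS_cm2 = 20, p_pump = 0.1, cm_F_cm2 = 2e-6,
    vw = 0.018, pw = 0.0015, km = 25,
    bath.na_mM = 145, bath.k_mM = 3.5, bath.cl_mM = 119,
    bath.x_mM = 29.5,
    cell.diameter_um = 10, cell.length_um = 25,
    sim.dt_ms = 1, sim.duration_ms = 3.6e6, sim.record_every_ms = 1000,
    chain.n_compartments = 10, chain.compartment_length_um = 10,
    chain.initial_radius_um = 0.5,
    chain.d_na = 1.33e-7, chain.d_k = 1.96e-7, chain.d_cl = 2.03e-7)
}

#' Load a configuration file
#'
#' Reads a flat YAML (or `key: value` text) file whose keys mirror the
#' default parameter table (`g_na_uS_cm2`, `bath.na_mM`, `sim.dt_ms`, ...),
#' overlays it on the built-in defaults and resolves it into the package's
#' objects. Unknown keys are rejected by name.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @param overrides named list applied after the file (e.g. CLI flags).
#' @return A list with `state`, `params`, `bath`, `config`, `chain` (a
#'   [chain_model()] built from the chain.* keys) and the resolved
#'   flat key-value list `resolved`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- default_config_values()
  if (!is.null(path)) {
    raw <- yaml::yaml.load_file(path)
    raw <- unlist(raw)  # flatten nested blocks into dotted keys
    bad <- setdiff(names(raw), config_keys)
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    vals[names(raw)] <- as.numeric(raw)
  }
  bad <- setdiff(names(overrides), config_keys)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  vals[names(overrides)] <- as.numeric(overrides)

  params <- membrane_params(
    g_na = vals$g_na_uS_cm2, g_k = vals$g_k_uS_cm2,
    g_cl = vals$g_cl_uS_cm2, g_kcc2 = vals$g_kcc2_uS_cm2,
    p = vals$p_pump, c_m = vals$cm_F_cm2, v_w = vals$vw, p_w = vals$pw,
    k_m = vals$km, r_a = um_to_dm(vals$`cell.diameter_um` / 2))
  bath <- bath_composition(vals$`bath.na_mM`, vals$`bath.k_mM`,
                           vals$`bath.cl_mM`, vals$`bath.x_mM`)
  state <- initial_state(radius_um = vals$`cell.diameter_um` / 2,
                         length_um = vals$`cell.length_um`)
  config <- sim_config(dt_ms = vals$`sim.dt_ms`,
                       duration_ms = vals$`sim.duration_ms`,
                       record_every_ms = vals$`sim.record_every_ms`)
  chain <- chain_model(
    n = vals$`chain.n_compartments`,
    radius_um = vals$`chain.initial_radius_um`,
    length_um = vals$`chain.compartment_length_um`,
    params = params, bath = bath,
    diffusion = diffusion_params(vals$`chain.d_na`, vals$`chain.d_k`,
                                 vals$`chain.d_cl`))
  list(state = state, params = params, bath = bath, config = config,
       chain = chain, resolved = vals)
}

#' @rdname load_config
#' @param resolved a resolved flat key-value list (field `resolved` of
#'   [load_config()]'s result).
#' @export
write_config <- function(resolved, path) {
  writeLines(yaml::as.yaml(resolved), path)
  invisible(path)
}

#' Load a protocol file
#'
#' Reads a YAML list of timed events. Each entry needs a `kind` (one of
#' `pump_ramp`, `set_param`, `param_ramp`, `inject`, `ramp_charge`,
#' `bath_swap`, `fix_pump`, `volume_mode`) plus the fields of the matching
#' [protocol event constructor][ev_pump_ramp].
#'
#' @param path protocol file path.
#' @return A list of `protocol_event` objects.
#' @export
load_protocol <- function(path) {
  raw <- yaml::yaml.load_file(path)
  ctors <- list(pump_ramp = ev_pump_ramp, set_param = ev_set_param,
                param_ramp = ev_param_ramp, inject = ev_inject,
                ramp_charge = ev_ramp_charge, bath_swap = ev_bath_swap,
                fix_pump = ev_fix_pump, volume_mode = ev_volume_mode)
  lapply(raw, function(e) {
    kind <- e$kind
    if (is.null(kind) || !kind %in% names(ctors))
      stop("unknown protocol event kind: ", kind)
    e$kind <- NULL
    # YAML 1.1 reads a bare off/on as a logical
    if (kind == "pump_ramp" && is.logical(e$direction))
      e$direction <- if (e$direction) "on" else "off"
    do.call(ctors[[kind]], e)
  })
}
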