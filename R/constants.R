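#' Physical constants
#'
#' Faraday constant, gas constant and absolute temperature used throughout
#' the model. Temperature is fixed at 37 degrees C; no Q10 scaling is applied
#' anywhere in the package.
#'
#' @return A list with elements `f` (C/mol), `r` (J/(K mol)), `t` (K) and the
#'   derived thermal voltage `rtf` = RT/F (V, about 26.73 mV).
#' @examples
#' phys_constants()$rtf * 1000  # thermal voltage in mV
#' @export
phys_constants <- function() {
  f <- 96485.33
  r <- 8.31446
  t <- 310.15
  list(f = f, r = r, t = t, rtf = r * t / f)
}

# Unit conversions between the conventional mixed cm-based units and the
# package's canonical dm-based units (dm, dm^3 = L, mol/L, V, s, S/dm^2,
# F/dm^2).
# 1 uS/cm^2 = 1e-6 S/cm^2 = 1e-4 S/dm^2; 1 F/cm^2 = 100 F/dm^2; 1 um = 1e-5 dm.

#' Unit conversions
#'
#' Convert between the mixed units conventionally used to report membrane
#' parameters (uS/cm^2, F/cm^2, um, mM, pL) and the canonical dm-based unit
#' system used internally (S/dm^2, F/dm^2, dm, mol/L, dm^3).
#'
#' @param x numeric vector to convert.
#' @return Converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
uS_cm2_to_S_dm2 <- function(x) x * 1e-4

#' @rdname units
#' @export
S_dm2_to_uS_cm2 <- function(x) x * 1e4

#' @rdname units
#' @export
F_cm2_to_F_dm2 <- function(x) x * 100

#' @rdname units
#' @export
um_to_dm <- function(x) x * 1e-5

#' @rdname units
#' @export
dm_to_um <- function(x) x * 1e5

#' @rdname units
#' @export
dm3_to_pL <- function(x) x * 1e12

#' @rdname units
#' @export
mM_to_M <- function(x) x * 1e-3

#' @rdname units
#' @export
M_to_mM <- function(x) x * 1e3
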