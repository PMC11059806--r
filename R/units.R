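# Unit conversions. All internal physics is SI (Pa, m, m^3/s, Pa*s);
# user-facing quantities follow clinical convention: pressures in mmHg,
# flow in uL/min, velocity in cm/s, radii in um, planar coordinates in mm.

MMHG_PA <- 133.322387415

#' Unit conversion helpers
#'
#' Conversions between the clinical units used at the interface (mmHg,
#' uL/min, cm/s, um, mm) and the SI units used internally.
#'
#' @param x numeric vector.
#' @return numeric vector in the target unit.
#' @name units
#' @keywords internal
NULL

mmHg_to_Pa <- function(x) x * MMHG_PA
Pa_to_mmHg <- function(x) x / MMHG_PA
ulmin_to_m3s <- function(x) x * 1e-9 / 60
m3s_to_ulmin <- function(x) x * 60 * 1e9
um_to_m <- function(x) x * 1e-6
mm_to_m <- function(x) x * 1e-3
m_to_mm <- function(x) x * 1e3
cms_to_ms <- function(x) x * 1e-2
ms_to_cms <- function(x) x * 1e2

# resistance: mmHg*s/mL <-> Pa*s/m^3 (1 mL = 1e-6 m^3)
mmHgsml_to_SI <- function(x) x * MMHG_PA / 1e-6
SI_to_mmHgsml <- function(x) x * 1e-6 / MMHG_PA
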