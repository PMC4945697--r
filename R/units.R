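# Canonical unit system: mass in g, length in mm, time in s.
# Derived units: pressure g/(mm s^2) (numerically equal to Pa),
# flow mm^3/s, resistance g/(mm^4 s), compliance mm^4 s^2/g,
# elastance g/(mm^4 s^2), energy g mm^2/s^2 (= 1e-9 J).

#' Millimetres of mercury in canonical pressure units
#'
#' The single place where the mmHg conversion constant is defined:
#' 1 mmHg = 133.32 g/(mm s^2). All pressures inside the package are
#' canonical; this constant converts at the user-facing boundary.
#'
#' @format A length-one numeric.
#' @export
MMHG <- 133.32

#' Unit conversions between mmHg / mL and canonical g-mm-s units
#'
#' Pressures are stored internally in g/(mm s^2) (numerically pascals);
#' flows in mm^3/s; energies in g mm^2/s^2, which is 1e-9 joule.
#'
#' @param p pressure in mmHg (or canonical units for the inverse).
#' @return Converted numeric of the same shape.
#' @examples
#' mmhg_to_canonical(120)        # 15998.4
#' canonical_to_mmhg(533.28)     # 4 mmHg, the atrial preload scale
#' @export
mmhg_to_canonical <- function(p) p * MMHG

#' @rdname mmhg_to_canonical
#' @export
canonical_to_mmhg <- function(p) p / MMHG

#' @rdname mmhg_to_canonical
#' @param e energy in canonical g mm^2/s^2 units.
#' @export
canonical_to_joule <- function(e) e * 1e-9

#' @rdname mmhg_to_canonical
#' @param q flow in mL/s (cm^3/s).
#' @export
ml_per_s_to_canonical <- function(q) q * 1000

#' @rdname mmhg_to_canonical
#' @export
canonical_to_ml_per_s <- function(q) q / 1000

#' Blood properties
#'
#' Density and dynamic viscosity of blood in canonical units. Defaults are
#' 1.060e-3 g/mm^3 (1060 kg/m^3) and 4e-3 g/(mm s) (4 mPa s), the standard
#' Newtonian approximation for large-vessel haemodynamics.
#'
#' @param rho density, g/mm^3.
#' @param mu dynamic viscosity, g/(mm s).
#' @return An object of class `blood_properties`.
#' @export
blood_properties <- function(rho = 1.060e-3, mu = 4e-3) {
  stopifnot(is.numeric(rho), length(rho) == 1L, rho > 0,
            is.numeric(mu), length(mu) == 1L, mu > 0)
  structure(list(rho = rho, mu = mu), class = "blood_properties")
}
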