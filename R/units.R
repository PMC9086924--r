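# Unit conventions
#
# All computation inside the package is done in SI:
#   length m, pressure Pa, volumetric flow m^3 s^-1, dynamic viscosity Pa s,
#   hydrodynamic resistance Pa s m^-3, interfacial tension N m^-1, time s.
# User-facing constructors, tables and printed output use the field units
# customary for droplet microfluidics: um, mbar, ul/min, mPa s, N/m, s.

.UL_MIN_TO_M3S <- 1e-9 / 60
.MBAR_TO_PA <- 100

#' Convert a quantity from field units to SI
#'
#' The package computes internally in SI and converses with the user in the
#' units customary on chip: micrometres, millibar, microlitres per minute,
#' millipascal-seconds. These two helpers convert between the conventions and
#' are exact inverses of each other.
#'
#' @param x numeric vector.
#' @param quantity one of `"length"` (um to m), `"pressure"` (mbar to Pa),
#'   `"flow"` (ul/min to m^3/s), `"viscosity"` (mPa s to Pa s),
#'   `"resistance"` (mbar/(ul/min) to Pa s/m^3), `"speed"` (mm/s to m/s),
#'   `"interfacial_tension"` (N/m, identity), `"time"` (s, identity).
#' @return numeric vector in the target convention.
#' @examples
#' to_si(1000, "length")          # 1 mm
#' from_si(to_si(3.5, "flow"), "flow")
#' @export
to_si <- function(x, quantity = c("length", "pressure", "flow", "viscosity",
                                  "resistance", "speed",
                                  "interfacial_tension", "time")) {
  quantity <- match.arg(quantity)
  x * .si_factor(quantity)
}

#' @rdname to_si
#' @export
from_si <- function(x, quantity = c("length", "pressure", "flow", "viscosity",
                                    "resistance", "speed",
                                    "interfacial_tension", "time")) {
  quantity <- match.arg(quantity)
  x / .si_factor(quantity)
}

.si_factor <- function(quantity) {
  switch(quantity,
    length = 1e-6,
    pressure = .MBAR_TO_PA,
    flow = .UL_MIN_TO_M3S,
    viscosity = 1e-3,
    resistance = .MBAR_TO_PA / .UL_MIN_TO_M3S,
    speed = 1e-3,
    interfacial_tension = 1,
    time = 1
  )
}
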