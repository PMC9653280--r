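# Internal unit conventions:
#   geometry tables        : micrometres (um)
#   longitudinal position  : millimetres (mm), measured from the cochlear base
#   elastic moduli         : megapascals (MPa)
#   direct stiffnesses     : millinewtons per metre (mN/m)
#   assembled systems      : SI (m, kg, s, N)

#' Pressure of a water column
#'
#' Converts a change in water-column height to the hydrostatic pressure step it
#' applies across the preparation, `rho * g * h`.
#'
#' @param height_mm Column height change in millimetres.
#' @param rho Fluid density in kg/m^3 (default water, 1000).
#' @param g Gravitational acceleration in m/s^2.
#' @return Pressure in pascals.
#' @examples
#' hydrostatic_pressure(0.57) # ~5.6 Pa
#' @export
hydrostatic_pressure <- function(height_mm, rho = 1000, g = 9.81) {
  rho * g * height_mm * 1e-3
}

# convenient scalar constants
.MPa <- 1e6      # Pa per MPa
.um <- 1e-6      # m per um
.um2 <- 1e-12    # m^2 per um^2
.um4 <- 1e-24    # m^4 per um^4
.mN_per_m <- 1e-3

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
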