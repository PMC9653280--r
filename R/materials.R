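#' Anchored material properties of the organ of Corti
#'
#' Physical properties of the gerbil organ of Corti anchored at two
#' longitudinal positions, x = 10 mm (apical anchor) and x = 2 mm (basal
#' anchor), with every property varying exponentially in between (see
#' [interpolate_property()]). Dimensions are in micrometres, Young's moduli in
#' MPa, and direct stiffnesses in mN/m.
#'
#' The basilar membrane (BM) is split into an arcuate zone (beneath the tunnel
#' of Corti, half-thickness collagen fiber layer) and a pectinate zone; the
#' tympanic/midpectinate layer carries mass but negligible stiffness. The
#' tectorial membrane (TM) is split into a root region (attached to the spiral
#' limbus, half as long and half as thick as the body) and a body region
#' overlying the hair bundles.
#'
#' @return A data frame with columns `property`, `value_a` (at `x_a` = 10 mm),
#'   `value_b` (at `x_b` = 2 mm), and `units`.
#' @export
material_table <- function() {
  tab <- rbind(
    c("bm_width",                  330,    180,    "um"),
    c("bm_fiber_thickness",        0.7,    3.2,    "um"),
    c("bm_midpectinate_thickness", 55,     35,     "um"),
    c("bm_modulus_radial",         2000,   2000,   "MPa"),
    c("bm_modulus_long",           0.4,    0.4,    "MPa"),
    c("ohc_diameter",              7,      9,      "um"),
    c("ohc_length",                56,     24,     "um"),
    c("ohc_modulus",               0.005,  0.005,  "MPa"),
    c("hb_height",                 10,     4,      "um"),
    c("hb_stiffness",              3,      40,     "mN/m"),
    c("pc_diameter",               4,      6,      "um"),
    c("pc_modulus",                400,    400,    "MPa"),
    c("dc_diameter",               10,     10,     "um"),
    c("dc_modulus",                0.01,   0.01,   "MPa"),
    c("php_diameter",              1,      1.5,    "um"),
    c("php_modulus",               40,     40,     "MPa"),
    c("rl_thickness_tunnel",       5,      5,      "um"),
    c("rl_thickness_ohc",          2,      2,      "um"),
    c("rl_modulus_radial",         500,    500,    "MPa"),
    c("rl_modulus_long",           0.2,    0.2,    "MPa"),
    c("tm_width",                  156,    110,    "um"),
    c("tm_thickness_root",         25,     20,     "um"),
    c("tm_thickness_body",         50,     30,     "um"),
    c("tm_modulus_root",           0.018,  0.29,   "MPa"),
    c("tm_modulus_body",           0.0044, 0.074,  "MPa"),
    c("tm_modulus_trans",          0.002,  0.002,  "MPa")
  )
  out <- data.frame(
    property = tab[, 1],
    value_a = as.numeric(tab[, 2]),
    value_b = as.numeric(tab[, 3]),
    units = tab[, 4],
    stringsAsFactors = FALSE
  )
  attr(out, "x_a") <- 10
  attr(out, "x_b") <- 2
  class(out) <- c("material_table", class(out))
  out
}

#' Exponential longitudinal interpolation of a material property
#'
#' All organ-of-Corti properties are taken to vary exponentially along the
#' cochlear length between the two anchor positions:
#' `p(x) = p_b * exp(s * (x - x_b))` with
#' `s = (log(p_b) - log(p_a)) / (x_b - x_a)`, which is exact at both anchors
#' and log-linear (hence monotone) in between.
#'
#' @param p_a Property value at `x_a`.
#' @param p_b Property value at `x_b`.
#' @param x Position(s) in mm at which to evaluate.
#' @param x_a,x_b Anchor positions in mm (defaults 10 and 2).
#' @return Interpolated value(s), same units as the anchors.
#' @examples
#' interpolate_property(56, 24, 10) # 56 (anchor identity)
#' interpolate_property(56, 24, 8.5) # outer hair cell length ~47.8 um
#' @export
interpolate_property <- function(p_a, p_b, x, x_a = 10, x_b = 2) {
  if (any(!is.finite(p_a)) || any(!is.finite(p_b)) ||
      any(p_a <= 0) || any(p_b <= 0)) {
    stop("interpolate_property: properties must be strictly positive for log-interpolation")
  }
  if (x_a == x_b) stop("interpolate_property: anchor positions must differ")
  s <- (log(p_b) - log(p_a)) / (x_b - x_a)
  p_b * exp(s * (x - x_b))
}

#' Material properties at a longitudinal position
#'
#' Interpolates every row of a [material_table()] to position `x` and applies
#' optional multiplicative overrides (used by the stiffness-ratio sweeps,
#' which rescale exactly one property set while all others stay fixed).
#'
#' @param x Longitudinal position in mm; must lie within the anchor range.
#' @param table A [material_table()].
#' @param mult Named numeric vector of multipliers applied to interpolated
#'   values, e.g. `c(tm_modulus_body = 0.5, tm_modulus_root = 0.5)`.
#' @return Named list of property values at `x`.
#' @export
material_at <- function(x, table = material_table(), mult = NULL) {
  x_a <- attr(table, "x_a")
  x_b <- attr(table, "x_b")
  if (length(x) != 1 || !is.finite(x)) stop("material_at: x must be a single finite value")
  if (x < min(x_a, x_b) || x > max(x_a, x_b)) {
    stop(sprintf("material_at: x = %g mm outside anchor range [%g, %g] (no extrapolation)",
                 x, min(x_a, x_b), max(x_a, x_b)))
  }
  vals <- interpolate_property(table$value_a, table$value_b, x, x_a, x_b)
  names(vals) <- table$property
  if (!is.null(mult)) {
    bad <- setdiff(names(mult), names(vals))
    if (length(bad)) stop("material_at: unknown properties in mult: ", paste(bad, collapse = ", "))
    vals[names(mult)] <- vals[names(mult)] * mult
  }
  as.list(vals)
}
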