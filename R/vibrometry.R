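# Measurement-side computations: subpixel NCC displacement estimation,
# two-angle decomposition of beam-axis displacements into radial/transverse
# components, elliptical-motion summaries, basilar-membrane compliance and
# deforming-pattern metrics, and the deformation ratios used to infer the
# tectorial-membrane and Deiters-cell stiffness ratios.

#' Decompose two-angle beam displacements into radial and transverse motion
#'
#' Solves the 2x2 linear system relating the complex displacements measured
#' along two beam orientations to the in-plane components:
#' `d_i = sin(theta_i) d_r + cos(theta_i) d_t`. Angles are measured from the
#' transverse (optical-when-vertical) axis, positive toward the lateral
#' radial direction.
#'
#' @param d1,d2 Complex displacements (m) along beams 1 and 2.
#' @param theta1,theta2 Beam angles in degrees; must differ.
#' @return Object of class `motion_vector`: list with complex `d_r`, `d_t`.
#' @export
decompose_two_angle <- function(d1, d2, theta1, theta2) {
  if (isTRUE(all.equal(theta1 %% 180, theta2 %% 180))) {
    stop("decompose_two_angle: beam angles coincide (singular geometry)")
  }
  t1 <- deg2rad(theta1); t2 <- deg2rad(theta2)
  A <- matrix(c(sin(t1), cos(t1), sin(t2), cos(t2)), 2, 2, byrow = TRUE)
  v <- solve(A, c(d1, d2))
  motion_vector(v[1], v[2])
}

#' Construct a motion vector
#'
#' @param d_r,d_t Complex radial and transverse displacement components (m).
#' @return `motion_vector` object.
#' @export
motion_vector <- function(d_r, d_t) {
  structure(list(d_r = as.complex(d_r), d_t = as.complex(d_t)),
            class = "motion_vector")
}

#' Project a motion vector onto a beam direction
#'
#' Inverse of [decompose_two_angle()] for one beam: `sin(theta) d_r +
#' cos(theta) d_t`.
#'
#' @param v A `motion_vector`.
#' @param theta Beam angle in degrees from the transverse axis.
#' @return Complex displacement along the beam.
#' @export
project_on_beam <- function(v, theta) {
  sin(deg2rad(theta)) * v$d_r + cos(deg2rad(theta)) * v$d_t
}

#' Major axis of the elliptical trajectory of a motion vector
#'
#' The instantaneous displacement `(Re(d_r e^{iwt}), Re(d_t e^{iwt}))` traces
#' an ellipse. Its major half-axis amplitude and direction are computed
#' analytically: the squared displacement along a real unit vector `u` peaks
#' at `|u . d|`, so the major axis is the dominant eigenvector of
#' `Re(d d^H)`.
#'
#' @param v A `motion_vector`.
#' @return List with `amplitude` (m), `theta_deg` (degrees from the
#'   transverse axis, in (-90, 90]), `minor` (m), and `degenerate` (TRUE for
#'   circular or zero motion, where the direction is arbitrary and reported
#'   as 0).
#' @export
ellipse_major_axis <- function(v) {
  d <- c(v$d_r, v$d_t)
  if (all(Mod(d) == 0)) {
    return(list(amplitude = 0, theta_deg = 0, minor = 0, degenerate = TRUE))
  }
  S <- Re(d %*% Conj(t(d)))
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  amp <- sqrt(max(ev$values[1], 0))
  minor <- sqrt(max(ev$values[2], 0))
  u <- ev$vectors[, 1]
  degen <- (amp - minor) <= 1e-9 * amp
  if (degen) {
    theta <- 0
  } else {
    theta <- rad2deg(atan2(u[1], u[2])) # from transverse axis toward radial
    if (theta <= -90) theta <- theta + 180
    if (theta > 90) theta <- theta - 180
  }
  list(amplitude = amp, theta_deg = theta, minor = minor, degenerate = degen)
}

#' Hair-bundle deflection from tectorial-membrane and reticular-lamina motion
#'
#' `u_HB = u_TM - u_RL`, component-wise on the complex motion vectors; the
#' deflection amplitude is the major axis of the difference.
#'
#' @param u_tm,u_rl `motion_vector`s at the same anatomic point (the
#'   second-row outer-hair-cell bundle).
#' @return List with `amplitude` (m), `theta_deg`, and the difference
#'   `motion_vector` as `u_hb`.
#' @export
hair_bundle_deflection <- function(u_tm, u_rl) {
  u <- motion_vector(u_tm$d_r - u_rl$d_r, u_tm$d_t - u_rl$d_t)
  mj <- ellipse_major_axis(u)
  list(amplitude = mj$amplitude, theta_deg = mj$theta_deg, u_hb = u)
}

#' Radial deflection profile of the basilar membrane
#'
#' @param field A `displacement_field`.
#' @param system The `ooc_system`.
#' @param s Section index (default: middle section).
#' @return Object of class `deflection_profile`: data frame with `r_um`,
#'   `disp_nm` plus attributes `pressure_pa` and `bm_width_um`.
#' @export
bm_profile <- function(field, system, s = NULL) {
  if (is.null(s)) s <- (system$nsec + 1) %/% 2
  nodes <- system$section$nodes
  bmn <- which(startsWith(nodes$label, "bm"))
  u <- field$values[dof_index(system, s, bmn, 2)]
  dp <- suppressWarnings(as.numeric(sub(".*dP = ([-0-9.eE+]+) Pa.*", "\\1",
                                        field$load)))
  prof <- data.frame(r_um = nodes$r[bmn], disp_nm = Re(u) * 1e9)
  attr(prof, "pressure_pa") <- dp
  attr(prof, "bm_width_um") <- system$section$bm_width_um
  class(prof) <- c("deflection_profile", class(prof))
  prof
}

#' Peak and volume compliance of a deflection profile
#'
#' Peak compliance is the maximum absolute displacement divided by the
#' applied pressure; volume compliance is the trapezoid area between the
#' deformed and undeformed membrane divided by the pressure, reported in
#' mm^4/N (area per unit pressure).
#'
#' @param profile A `deflection_profile` (or data frame with `r_um`,
#'   `disp_nm`) with attribute `pressure_pa`, or `pressure` given explicitly.
#' @param pressure Applied pressure in Pa (overrides the attribute).
#' @return List with `peak_nm_per_pa` and `volume_mm4_per_n`.
#' @export
volume_compliance <- function(profile, pressure = NULL) {
  if (is.null(pressure)) pressure <- attr(profile, "pressure_pa")
  if (is.null(pressure) || is.na(pressure) || pressure == 0) {
    stop("volume_compliance: nonzero applied pressure required")
  }
  r <- profile$r_um * 1e-6
  w <- profile$disp_nm * 1e-9
  if (is.unsorted(r, strictly = TRUE)) stop("volume_compliance: positions must increase")
  area <- sum(diff(r) * (utils::head(w, -1) + utils::tail(w, -1)) / 2) # m^2
  list(peak_nm_per_pa = max(abs(w)) * 1e9 / abs(pressure),
       volume_mm4_per_n = abs(area) / abs(pressure) * 1e12)
}

#' Full width at half maximum of a deflection profile, as a width fraction
#'
#' Linear interpolation of the half-maximum crossings around the peak; if
#' several disjoint half-max regions exist, the one containing the peak is
#' used (flagged). The result is divided by the membrane width.
#'
#' @param profile A `deflection_profile` (columns `r_um`, `disp_nm`,
#'   attribute `bm_width_um` or `width` given).
#' @param width Membrane width in um (overrides the attribute).
#' @return List with `fraction`, `fwhm_um`, and `flag_multimodal`.
#' @export
fwhm_fraction <- function(profile, width = NULL) {
  if (is.null(width)) width <- attr(profile, "bm_width_um")
  if (is.null(width)) stop("fwhm_fraction: membrane width required")
  r <- profile$r_um
  w <- abs(profile$disp_nm)
  ipk <- which.max(w)
  if (ipk == 1 || ipk == length(w)) stop("fwhm_fraction: need an interior maximum")
  half <- w[ipk] / 2
  above <- w >= half
  # crossings left and right of the peak
  xl <- NA_real_
  for (i in seq(ipk, 2)) {
    if (!above[i - 1]) {
      xl <- r[i - 1] + (half - w[i - 1]) / (w[i] - w[i - 1]) * (r[i] - r[i - 1])
      break
    }
  }
  xr <- NA_real_
  for (i in seq(ipk, length(w) - 1)) {
    if (!above[i + 1]) {
      xr <- r[i] + (half - w[i]) / (w[i + 1] - w[i]) * (r[i + 1] - r[i])
      break
    }
  }
  if (is.na(xl)) xl <- r[1]
  if (is.na(xr)) xr <- r[length(r)]
  regions <- rle(above)
  flag <- sum(regions$values) > 1
  list(fraction = (xr - xl) / width, fwhm_um = xr - xl, flag_multimodal = flag)
}

#' Point-force contact stiffness at a basilar-membrane node
#'
#' Applies a unit transverse point force at the given BM node of the middle
#' section and returns force over local displacement, comparable to probe
#' measurements.
#'
#' @param system An `ooc_system`.
#' @param node Node label (default `"bm06"`, the first-row Deiters root /
#'   peak-displacement point) or node id.
#' @param s Section index (default middle).
#' @return Contact stiffness in mN/m.
#' @export
contact_stiffness <- function(system, node = "bm06", s = NULL) {
  if (is.null(s)) s <- (system$nsec + 1) %/% 2
  if (is.character(node)) node <- match(node, system$section$nodes$label)
  d <- dof_index(system, s, node, 2)
  if (system$fixed[d]) stop("contact_stiffness: node is constrained")
  f <- numeric(system$ndof)
  f[d] <- 1e-9 # 1 nN probe force
  fld <- solve_static(system, load = f)
  u <- fld$values[d]
  1e-9 / abs(u) * 1e3 # mN/m
}

#' Tectorial-membrane deformation ratio
#'
#' `Delta_TM` is the radial elongation of the tectorial membrane between its
#' limbal attachment and the point above the second-row hair bundle
#' (end-to-end elongation of the TM span, projected on its axis);
#' `Delta_HB` is the hair-bundle deflection from
#' [hair_bundle_deflection()] at the same bundle. `theta_TM` is the
#' major-axis direction of the TM point's elliptical motion.
#'
#' @param field A (typically complex) `displacement_field`.
#' @param system The `ooc_system`.
#' @param s Section index (default middle).
#' @return List with `ratio` (Delta_TM / Delta_HB), `theta_tm_deg`,
#'   `delta_tm`, `delta_hb` (m).
#' @export
deformation_ratio_tm <- function(field, system, s = NULL) {
  if (is.null(s)) s <- (system$nsec + 1) %/% 2
  nodes <- system$section$nodes
  u_t1 <- field_at(field, system, s, "limbus")
  u_t4 <- field_at(field, system, s, "tm_hb2")
  # radial elongation between the limbal attachment and the point above the
  # second-row bundle; the limbal attachment is bone-fixed, so this is the
  # radial displacement of the TM point, as in the measurement
  delta_tm <- Mod(u_t4[["u_r"]] - u_t1[["u_r"]])
  # secondary: end-to-end stretch along the chord, which is insensitive to
  # rigid rotation of the membrane and isolates true elongation
  p1 <- unlist(nodes[match("limbus", nodes$label), c("r", "t")])
  p4 <- unlist(nodes[match("tm_hb2", nodes$label), c("r", "t")])
  ax <- (p4 - p1) / sqrt(sum((p4 - p1)^2))
  delta_tm_chord <- Mod(sum((u_t4 - u_t1) * ax))
  u_rl <- field_at(field, system, s, "ohc2_apex")
  hb <- hair_bundle_deflection(motion_vector(u_t4[1], u_t4[2]),
                               motion_vector(u_rl[1], u_rl[2]))
  if (hb$amplitude == 0) stop("deformation_ratio_tm: zero hair-bundle deflection")
  mj <- ellipse_major_axis(motion_vector(u_t4[1], u_t4[2]))
  list(ratio = delta_tm / hb$amplitude, theta_tm_deg = mj$theta_deg,
       delta_tm = delta_tm, delta_hb = hb$amplitude,
       ratio_elong = delta_tm_chord / hb$amplitude)
}

#' Deiters-cell deformation ratio
#'
#' From the displacements of three first-row points (outer-hair-cell apex,
#' OHC-Deiters joint, Deiters root), `Delta_OHC` is the axial length change
#' apex-to-joint and `Delta_DC` the axial length change joint-to-root;
#' `theta_DC` is the major-axis direction of the joint's motion.
#'
#' @param field A `displacement_field`.
#' @param system The `ooc_system`.
#' @param s Section index (default middle).
#' @return List with `ratio` (Delta_DC / Delta_OHC), `theta_dc_deg`,
#'   `delta_dc`, `delta_ohc` (m).
#' @export
deformation_ratio_dc <- function(field, system, s = NULL) {
  if (is.null(s)) s <- (system$nsec + 1) %/% 2
  nodes <- system$section$nodes
  sec <- system$section
  h <- system$spacing_um * 1e-6
  lab <- c(apex = "ohc1_apex", joint = "ohc1_cup", root = "bm06")
  u <- lapply(lab, function(l) {
    field$values[dof_index(system, s, match(l, nodes$label), 1:3)]
  })
  e_ohc <- sec$elements[sec$elements$role == "OHC row 1", ]
  ax_ohc <- element_axis3(sec, e_ohc, h)$e3
  e_dc <- sec$elements[sec$elements$role == "DC base", ]
  ax_dc <- element_axis3(sec, e_dc, h)$e3
  delta_ohc <- Mod(sum((u$apex - u$joint) * ax_ohc))
  delta_dc <- Mod(sum((u$joint - u$root) * ax_dc))
  if (delta_ohc == 0) stop("deformation_ratio_dc: zero outer-hair-cell deformation")
  mj <- ellipse_major_axis(motion_vector(u$joint[1], u$joint[2]))
  list(ratio = delta_dc / delta_ohc, theta_dc_deg = mj$theta_deg,
       delta_dc = delta_dc, delta_ohc = delta_ohc)
}

#' Stiffness of the organ-of-Corti scaffold felt by an outer hair cell
#'
#' Applies a unit force couple per cell along the first-row outer hair
#' cells (uniform contraction of the modelled span), solves statically, and
#' returns, at the requested section,
#' `k_OoC,OHC = f_OHC / Delta_OHC - k_OHC`, where `k_OHC = EA/L` of that
#' cell. An effectively rigid scaffold (`Delta_OHC` from the supports near
#' zero) is reported as `Inf` with a flag when it exceeds `1e3 * k_OHC`.
#'
#' @param system An `ooc_system`.
#' @param s Section index (default middle).
#' @param row OHC row (only row 1 is articulated).
#' @return List with `k_ooc_ohc_mn_per_m`, `k_ohc_mn_per_m`, `ratio`
#'   (k_OoC,OHC / k_OHC), and `rigid_flag`.
#' @export
stiffness_felt_by_ohc <- function(system, s = NULL, row = 1) {
  if (row != 1) stop("stiffness_felt_by_ohc: only row 1 carries an articulated cup")
  if (is.null(s)) s <- (system$nsec + 1) %/% 2
  sec <- system$section
  e <- sec$elements[sec$elements$role == "OHC row 1", ]
  ax3 <- element_axis3(sec, e, system$spacing_um * 1e-6)
  k_ohc <- e$E * .MPa * e$A * .um2 / ax3$L3 # N/m
  f_mag <- 1e-9
  # uniform contraction of all interior sections (forces are per cell), read
  # at the requested section: the per-10-um-section stiffness felt by one cell
  load <- apply_ohc_force_couple(system, rows = row, f_ohc = f_mag)
  fld <- solve_static(system, load = load)
  u_apex <- Re(fld$values[dof_index(system, s, e$n2, 1:3)])
  u_base <- Re(fld$values[dof_index(system, s, e$n1, 1:3)])
  delta <- abs(sum((u_apex - u_base) * ax3$e3))
  if (delta == 0) stop("stiffness_felt_by_ohc: zero OHC deformation")
  k_tot <- f_mag / delta
  k_ooc <- k_tot - k_ohc
  rigid <- k_ooc > 1e3 * k_ohc
  list(k_ooc_ohc_mn_per_m = if (rigid) Inf else k_ooc * 1e3,
       k_ohc_mn_per_m = k_ohc * 1e3,
       ratio = if (rigid) Inf else k_ooc / k_ohc,
       rigid_flag = rigid)
}
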