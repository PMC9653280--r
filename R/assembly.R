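# Assembly of the multi-section structural system.
#
# Each node carries 4 DOF: radial u_r, transverse u_t, longitudinal u_l and
# the in-plane rotation. Radial sections are planar frames (axial +
# Euler-Bernoulli bending on u_r/u_t/rotation); the longitudinal DOF makes
# the outer-hair-cell / phalangeal-process Y-truss three-dimensional: the
# OHC axis is tilted one cell spacing basally while the phalangeal process
# reaches the reticular lamina a few sections apically, so the two members
# share load only through genuine 3-D kinematics. Longitudinal coupling of
# the BM / TM / RL member lines uses membrane (axial) springs on u_l and
# curvature-penalty triplets (the finite-difference form of Euler-Bernoulli
# bending) on u_t; out-of-plane shear of in-section members is a
# clamped-guided (12 E I / L^3) link on u_l. SI units throughout.

.RHO_TISSUE <- 1000 # kg/m^3

# 6x6 planar frame element stiffness (global in-plane coords). EA in N,
# EI in N m^2, L in m, c/s direction cosines.
frame_k <- function(EA, EI, L, c, s) {
  a <- EA / L
  b1 <- 12 * EI / L^3; b2 <- 6 * EI / L^2; b3 <- 4 * EI / L; b4 <- 2 * EI / L
  kl <- matrix(c(
     a,   0,   0,  -a,   0,   0,
     0,  b1,  b2,   0, -b1,  b2,
     0,  b2,  b3,   0, -b2,  b4,
    -a,   0,   0,   a,   0,   0,
     0, -b1, -b2,   0,  b1, -b2,
     0,  b2,  b4,   0, -b2,  b3), 6, 6, byrow = TRUE)
  Tm <- matrix(0, 6, 6)
  rot <- matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Tm[1:3, 1:3] <- rot; Tm[4:6, 4:6] <- rot
  t(Tm) %*% kl %*% Tm
}

# element in-plane length and orientation from section coordinates (um -> m)
element_geom <- function(section, e) {
  p1 <- c(section$nodes$r[e$n1], section$nodes$t[e$n1]) * 1e-6
  p2 <- c(section$nodes$r[e$n2], section$nodes$t[e$n2]) * 1e-6
  d <- p2 - p1
  L <- sqrt(sum(d^2))
  list(L = L, c = d[1] / L, s = d[2] / L, d = d)
}

# 3-D axis of an element including longitudinal offset/span (m)
element_axis3 <- function(section, e, h) {
  g <- element_geom(section, e)
  dl <- if (!is.null(e$lspan) && e$lspan > 0) e$lspan * h else 0
  dl <- dl + (if (!is.null(e$lofs)) e$lofs * 1e-6 else 0)
  d3 <- c(g$d, dl)
  L3 <- sqrt(sum(d3^2))
  list(L3 = L3, e3 = d3 / L3, g = g)
}

#' Rayleigh damping matrix
#'
#' @param M,K Mass and stiffness matrices.
#' @param alpha Mass-proportional coefficient (1/s), >= 0.
#' @param beta Stiffness-proportional coefficient (s), >= 0.
#' @return `C = alpha * M + beta * K`.
#' @export
rayleigh_damping <- function(M, K, alpha, beta) {
  if (alpha < 0 || beta < 0) stop("rayleigh_damping: alpha and beta must be >= 0")
  alpha * M + beta * K
}

#' Calibrate Rayleigh coefficients to the cell dissipation target
#'
#' Chooses `alpha` and `beta` so that the isolated first-row outer hair cell
#' and Deiters cell elements dissipate the target 5 nN s/m per 10 um of cell
#' length (`c = alpha m + beta k` per element, solved for the two elements;
#' negative solutions are clipped and refit).
#'
#' @param section An `ooc_section`.
#' @param per_10um Dissipation target in N s/m per 10 um of cell length.
#' @return Named vector `c(alpha = , beta = )`.
#' @export
calibrate_rayleigh <- function(section, per_10um = 5e-9) {
  rows <- section$elements[section$elements$role %in% c("OHC row 1", "DC base"), ]
  h <- section$spacing_um * 1e-6
  cell_frac <- section$spacing_um / 10
  mk <- t(vapply(seq_len(nrow(rows)), function(i) {
    e <- rows[i, ]
    ax <- element_axis3(section, e, h)
    m <- .RHO_TISSUE * e$A * .um2 * ax$L3
    k <- e$E * .MPa * e$A * .um2 / ax$L3
    # target is per cell; the element carries cell_frac of a cell
    c(m = m, k = k, c = cell_frac * per_10um * ax$L3 / 10e-6)
  }, c(m = 0, k = 0, c = 0)))
  A <- mk[, 1:2, drop = FALSE]
  cc <- mk[, 3]
  ab <- as.vector(tryCatch(qr.solve(A, cc), error = function(e) c(0, 0)))
  if (any(ab < 0)) {
    j <- which.max(ab)
    ab[-j] <- 0
    ab[j] <- sum(A[, j] * cc) / sum(A[, j]^2)
    ab <- pmax(ab, 0)
  }
  c(alpha = ab[1], beta = ab[2])
}

#' Assemble the structural system
#'
#' Builds mass, damping and stiffness matrices for a row of radial sections
#' with clamped apical/basal end sections and clamped BM edges and limbus.
#' Damping is Rayleigh (`alpha M + beta K`, coefficients calibrated to the
#' outer-hair-cell / Deiters-cell dissipation target) plus discrete
#' subtectorial-gap dashpots acting on the relative motion across each hair
#' bundle, the dominant fluid-film dissipation of the organ of Corti
#' complex.
#'
#' @param sections Either a single `ooc_section` (replicated `nsec` times) or
#'   a list of sections with identical topology.
#' @param nsec Number of sections when `sections` is a single section (>= 3).
#' @param spacing Longitudinal spacing in um (default from the section).
#' @param alpha,beta Rayleigh coefficients; if `NULL`, calibrated with
#'   [calibrate_rayleigh()] on the first section.
#' @param damping_per_10um Dissipation target passed to the calibration.
#' @param c_subtectorial Subtectorial-gap shear damping per section in
#'   N s/m (split equally across the three bundle gaps; 0 disables it).
#' @param squeeze_factor Ratio of squeeze-film (gap-normal) to shear damping
#'   of the subtectorial gap; lubrication theory gives order
#'   (overlap width / gap height)^2 down-weighted by the open lateral
#'   boundary of the gap.
#' @param beta_tm Stiffness-proportional material damping of the tectorial
#'   membrane in s (gel viscoelasticity; loss factor `beta_tm * omega` at
#'   angular frequency omega). 0 disables it.
#' @param f_bl Reference frequency (Hz) for the viscous boundary-layer drag
#'   on tangential motion of the immersed tectorial-membrane surfaces,
#'   `sqrt(mu rho omega / 2)` per unit area on both faces (the inviscid
#'   interface model carries no tangential traction); 0 disables it.
#' @param mu_fluid Dynamic viscosity of the fluid (Pa s).
#' @param rot_inertia Lumped rotational inertia per element end as a
#'   multiple of `m L^2`; default 0 (quasi-static rotations, standard
#'   lumped-mass practice).
#' @param extra_dampers Optional list of `list(role =, c =, mode =)` adding
#'   discrete dashpots on all elements of a role; `mode` `"axial"` damps
#'   relative motion along the element axis, `"iso"` all three translations.
#' @return Object of class `ooc_system` with `M`, `C`, `K` (sparse, SI; 4
#'   DOF per node: radial, transverse, longitudinal, rotation), DOF map
#'   helpers, fixed-DOF set, interface tables and metadata.
#' @export
assemble_structure <- function(sections, nsec = NULL, spacing = NULL,
                               alpha = NULL, beta = NULL,
                               damping_per_10um = 5e-9,
                               c_subtectorial = 100e-9,
                               squeeze_factor = 30,
                               beta_tm = 5e-5,
                               f_bl = 1000, mu_fluid = 1e-3,
                               rot_inertia = 0,
                               extra_dampers = NULL) {
  if (inherits(sections, "ooc_section")) {
    if (is.null(nsec)) stop("assemble_structure: give nsec with a single section")
    sections <- rep(list(sections), nsec)
  }
  nsec <- length(sections)
  if (nsec < 3) stop("assemble_structure: need at least 3 sections")
  proto <- sections[[1]]
  if (is.null(spacing)) spacing <- proto$spacing_um
  h <- spacing * 1e-6
  nn <- nrow(proto$nodes)
  ndof_sec <- 4 * nn
  ndof <- nsec * ndof_sec
  gdof <- function(s, n, d) (s - 1) * ndof_sec + (n - 1) * 4 + d

  kt <- list(); ct <- list()
  mi <- integer(0); mv <- numeric(0)
  addK <- function(idx, kmat) {
    kt[[length(kt) + 1]] <<- cbind(rep(idx, times = length(idx)),
                                   rep(idx, each = length(idx)),
                                   as.vector(kmat))
  }
  addC <- function(idx, cmat) {
    ct[[length(ct) + 1]] <<- cbind(rep(idx, times = length(idx)),
                                   rep(idx, each = length(idx)),
                                   as.vector(cmat))
  }
  addM <- function(idx, vals) {
    mi <<- c(mi, idx); mv <<- c(mv, vals)
  }
  pm2 <- function(kmat) rbind(cbind(kmat, -kmat), cbind(-kmat, kmat))

  extra_roles <- vapply(extra_dampers %||% list(), `[[`, "", "role")

  for (s in seq_len(nsec)) {
    sec <- sections[[s]]
    els <- sec$elements
    for (k in seq_len(nrow(els))) {
      e <- els[k, ]
      if (!is.na(e$kdir)) {
        # hair-bundle link: deflection stiffness against radial and
        # longitudinal shear of the subtectorial gap, stiff vertical
        # (stereocilia-axis) support; no cross-coupling, as for a pivoting
        # bundle
        k3 <- diag(c(e$kdir, e$kdir_ax, e$kdir) * .mN_per_m)
        idx <- c(gdof(s, e$n1, 1:3), gdof(s, e$n2, 1:3))
        addK(idx, pm2(k3))
        if (c_subtectorial > 0) {
          # shear (Couette) damping on the in-plane-of-gap components;
          # squeeze-film damping, larger by ~(overlap width / gap height)^2,
          # on the gap-normal (vertical) component
          cd <- diag(c(1, squeeze_factor, 1)) * c_subtectorial / 3
          addC(idx, pm2(cd))
        }
        next
      }
      ax3 <- element_axis3(sec, e, h)
      s2 <- s + e$lspan
      if (e$lspan > 0 && s2 > nsec) next
      kax <- e$E * .MPa * e$A * .um2 / ax3$L3
      G3 <- kax * (ax3$e3 %o% ax3$e3)
      idx3 <- c(gdof(s, e$n1, 1:3), gdof(s2, e$n2, 1:3))
      m <- .RHO_TISSUE * e$A * .um2 * ax3$L3
      if (e$lspan > 0 || e$lofs != 0) {
        # oblique member: 3-D axial link + in-plane bending frame +
        # out-of-plane shear
        addK(idx3, pm2(G3))
        EI <- e$Ebend * .MPa * e$I * .um4
        if (e$lspan == 0) {
          idx <- c(gdof(s, e$n1, c(1, 2, 4)), gdof(s, e$n2, c(1, 2, 4)))
          addK(idx, frame_k(0, EI, ax3$g$L, ax3$g$c, ax3$g$s))
          addK(gdof(s, c(e$n1, e$n2), 3), pm2(matrix(12 * EI / ax3$g$L^3)))
        }
        addM(idx3, rep(m / 2, 6))
      } else {
        EA <- e$E * .MPa * e$A * .um2
        EI <- e$Ebend * .MPa * e$I * .um4
        idx <- c(gdof(s, e$n1, c(1, 2, 4)), gdof(s, e$n2, c(1, 2, 4)))
        kf <- frame_k(EA, EI, ax3$g$L, ax3$g$c, ax3$g$s)
        ks <- pm2(matrix(12 * EI / ax3$g$L^3))
        addK(idx, kf)
        addK(gdof(s, c(e$n1, e$n2), 3), ks)
        addM(idx3, rep(m / 2, 6))
        # rotations carry no lumped inertia (quasi-static), as in standard
        # lumped-mass beam practice; a tiny floor added after assembly keeps
        # M positive definite
        addM(gdof(s, c(e$n1, e$n2), 4), rep(rot_inertia * m * ax3$g$L^2, 2))
        if (beta_tm > 0 && startsWith(e$role, "TM")) {
          addC(idx, beta_tm * kf)
          addC(gdof(s, c(e$n1, e$n2), 3), beta_tm * ks)
        }
      }
      if (e$role %in% extra_roles) {
        dd <- extra_dampers[[match(e$role, extra_roles)]]
        cmat <- if (identical(dd$mode, "axial")) dd$c * (ax3$e3 %o% ax3$e3)
                else dd$c * diag(3)
        addC(idx3, pm2(cmat))
      }
    }
    # viscous boundary-layer drag on tangential (radial and longitudinal)
    # motion of the immersed TM faces
    if (f_bl > 0) {
      cbl_area <- sqrt(mu_fluid * 1000 * 2 * pi * f_bl / 2)
      tm_ids <- match(c("limbus", "tm_junction", "tm_hb1", "tm_hb2",
                        "tm_hb3", "tm_lateral"), sec$nodes$label)
      wt_tm <- tributary_widths(sec$nodes$r[tm_ids])
      for (q in seq_along(tm_ids)) {
        cq <- cbl_area * 2 * wt_tm[q] * .um * spacing * .um
        addC(gdof(s, tm_ids[q], c(1, 3)), diag(2) * cq)
      }
    }
    # distributed midpectinate (tympanic) layer mass on BM chord nodes
    bmn <- which(startsWith(sec$nodes$label, "bm"))
    wt <- tributary_widths(sec$nodes$r[bmn])
    mmid <- .RHO_TISSUE * sec$materials_at_x$bm_midpectinate_thickness * .um *
      wt * .um * spacing * .um
    for (q in seq_along(bmn)) {
      addM(gdof(s, bmn[q], 1:3), rep(mmid[q], 3))
    }
  }

  # longitudinal coupling of the member lines: membrane axial springs on u_l
  # and curvature-penalty bending triplets on u_t
  lines <- longitudinal_lines(proto)
  for (ln in lines) {
    for (q in seq_along(ln$nodes)) {
      EI <- ln$EI[q]; EA <- ln$EA[q]
      if (EA > 0) {
        kax <- EA / h
        for (s in seq_len(nsec - 1)) {
          addK(c(gdof(s, ln$nodes[q], 3), gdof(s + 1, ln$nodes[q], 3)),
               pm2(matrix(kax)))
        }
      }
      if (EI > 0) {
        coef <- EI / h^3
        v <- c(1, -2, 1)
        for (s in 2:(nsec - 1)) {
          idx <- c(gdof(s - 1, ln$nodes[q], 2), gdof(s, ln$nodes[q], 2),
                   gdof(s + 1, ln$nodes[q], 2))
          addK(idx, coef * (v %o% v))
        }
      }
    }
  }

  tr <- do.call(rbind, kt)
  K <- Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                            dims = c(ndof, ndof))
  K <- as(Matrix::forceSymmetric((K + Matrix::t(K)) / 2), "generalMatrix")
  M <- Matrix::sparseMatrix(i = mi, j = mi, x = mv, dims = c(ndof, ndof))
  dM <- Matrix::diag(M)
  floor_m <- max(dM) * 1e-9
  M <- M + Matrix::Diagonal(ndof, x = pmax(floor_m - dM, 0))

  fixed <- logical(ndof)
  fixed[seq_len(ndof_sec)] <- TRUE
  fixed[(nsec - 1) * ndof_sec + seq_len(ndof_sec)] <- TRUE
  cl <- which(proto$nodes$clamped)
  for (s in seq_len(nsec)) for (n in cl) fixed[gdof(s, n, 1:4)] <- TRUE

  if (is.null(alpha) || is.null(beta)) {
    ab <- calibrate_rayleigh(proto, damping_per_10um)
    if (is.null(alpha)) alpha <- ab[["alpha"]]
    if (is.null(beta)) beta <- ab[["beta"]]
  }
  C <- rayleigh_damping(M, K, alpha, beta)
  if (length(ct)) {
    trc <- do.call(rbind, ct)
    Cx <- Matrix::sparseMatrix(i = trc[, 1], j = trc[, 2], x = trc[, 3],
                               dims = c(ndof, ndof))
    C <- C + as(Matrix::forceSymmetric((Cx + Matrix::t(Cx)) / 2), "generalMatrix")
  }

  structure(list(
    M = M, C = C, K = K, alpha = alpha, beta = beta,
    c_subtectorial = c_subtectorial, beta_tm = beta_tm,
    nsec = nsec, spacing_um = spacing, ndof = ndof, ndof_sec = ndof_sec,
    nodes_per_sec = nn, fixed = fixed, free = which(!fixed),
    section = proto, sections = sections, x = proto$x,
    interface = interface_table(proto)
  ), class = "ooc_system")
}

# tributary widths (um) along a line of radial positions
tributary_widths <- function(r) {
  n <- length(r)
  edges <- c(r[1], (r[-n] + r[-1]) / 2, r[n])
  diff(edges)
}

# member lines carrying longitudinal coupling, with per-node EI (N m^2,
# bending) and EA (N, membrane stretching)
longitudinal_lines <- function(section) {
  mat <- section$materials_at_x
  nodes <- section$nodes
  line_of <- function(labels, E_long, thick_of) {
    ids <- match(labels, nodes$label)
    wt <- tributary_widths(nodes$r[ids])
    th <- vapply(seq_along(ids), thick_of, 0)
    EI <- E_long * .MPa * (wt * .um) * (th * .um)^3 / 12
    EA <- E_long * .MPa * (wt * .um) * (th * .um)
    list(nodes = ids, EI = EI, EA = EA)
  }
  bm_labels <- nodes$label[startsWith(nodes$label, "bm")]
  bm_ids <- match(bm_labels, nodes$label)
  opc_r <- nodes$r[match("bm05", nodes$label)]
  bm <- line_of(bm_labels, mat$bm_modulus_long, function(q) {
    mat$bm_fiber_thickness * if (nodes$r[bm_ids[q]] < opc_r) 0.5 else 1
  })
  tm_labels <- c("limbus", "tm_junction", "tm_hb1", "tm_hb2", "tm_hb3", "tm_lateral")
  tm <- line_of(tm_labels, mat$tm_modulus_trans, function(q) {
    if (q <= 2) mat$tm_thickness_root else mat$tm_thickness_body
  })
  rl_labels <- c("pillar_head", "ohc1_apex", "ohc2_apex", "ohc3_apex")
  rl <- line_of(rl_labels, mat$rl_modulus_long, function(q) {
    if (q == 1) mat$rl_thickness_tunnel else mat$rl_thickness_ohc
  })
  list(bm = bm, tm = tm, rl = rl)
}

# fluid-facing interface entities with tributary spans (mm from slit start)
interface_table <- function(section) {
  nodes <- section$nodes
  bmn <- which(startsWith(nodes$label, "bm"))
  r <- nodes$r[bmn]
  edges <- c(0, (r[-length(r)] + r[-1]) / 2, section$bm_width_um)
  bottom <- data.frame(entity = nodes$label[bmn], node = bmn,
                       x0 = edges[-length(edges)] * 1e-3, x1 = edges[-1] * 1e-3,
                       stringsAsFactors = FALSE)
  tm_labels <- c("limbus", "tm_junction", "tm_hb1", "tm_hb2", "tm_hb3", "tm_lateral")
  tmn <- match(tm_labels, nodes$label)
  rt <- nodes$r[tmn]
  edges_t <- c(rt[1], (rt[-length(rt)] + rt[-1]) / 2, rt[length(rt)])
  edges_t <- pmin(pmax(edges_t, 0), section$bm_width_um)
  top <- data.frame(entity = nodes$label[tmn], node = tmn,
                    x0 = edges_t[-length(edges_t)] * 1e-3, x1 = edges_t[-1] * 1e-3,
                    stringsAsFactors = FALSE)
  list(bottom = bottom, top = top)
}

#' Global DOF index
#'
#' @param system An `ooc_system`.
#' @param s Section index.
#' @param node Node id within the section.
#' @param dir Direction: 1 = radial, 2 = transverse, 3 = longitudinal,
#'   4 = in-plane rotation.
#' @return Integer DOF index.
#' @export
dof_index <- function(system, s, node, dir) {
  (s - 1) * system$ndof_sec + (node - 1) * 4 + dir
}

#' @export
print.ooc_system <- function(x, ...) {
  cat(sprintf("ooc_system: %d sections x %d nodes (%d DOF, %d free), spacing %g um, x = %g mm\n",
              x$nsec, x$nodes_per_sec, x$ndof, length(x$free), x$spacing_um, x$x))
  cat(sprintf("  Rayleigh alpha = %.4g 1/s, beta = %.4g s; subtectorial c = %g nN s/m\n",
              x$alpha, x$beta, x$c_subtectorial * 1e9))
  invisible(x)
}
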