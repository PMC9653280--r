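# Two-compartment microchamber fluid, discretized as a Laplace problem.
#
# The chamber is modelled in the radial-transverse plane of the preparation:
# two rectangular compartments separated by a partition at z = 0 whose central
# slit is sealed by the organ of Corti. The bottom compartment carries the
# stimulus (prescribed pressure at its left end) and the pressure release
# (zero pressure, right end); the top compartment is open to air at both ends
# and closed by the coverslip above. The out-of-plane depth equals the
# longitudinal section spacing, so each structural section sees its own
# planar fluid problem.

#' Build the two-compartment fluid mesh
#'
#' Tensor-product finite-volume grids for the two compartments, graded so the
#' finest cells sit at the slit (matching the structural grid there) and grow
#' geometrically toward the far field.
#'
#' @param chamber_width Chamber width in mm.
#' @param channel_height Height of each fluid channel in mm.
#' @param slit_span Open slit span in mm (the membrane width).
#' @param slit_center Slit center position in mm (default chamber middle).
#' @param refinement Ratio of far-field to slit cell size; must be >= 1.
#' @param bottom_faces,top_faces Optional face breakpoints (mm, measured from
#'   the slit start) subdividing the slit on the basilar-membrane (bottom) and
#'   tectorial-membrane (top) sides. `top_faces` may cover only part of the
#'   slit; the remainder is a rigid partition. Defaults: 12 and 6 equal cells.
#' @param growth Geometric grading factor for far-field cells.
#' @return Object of class `fluid_mesh`.
#' @export
build_fluid_mesh <- function(chamber_width = 10, channel_height = 1,
                             slit_span = 0.3, slit_center = chamber_width / 2,
                             refinement = 4, bottom_faces = NULL,
                             top_faces = NULL, growth = 1.5) {
  if (chamber_width <= 0 || channel_height <= 0 || slit_span <= 0) {
    stop("build_fluid_mesh: dimensions must be positive")
  }
  if (refinement < 1) stop("build_fluid_mesh: refinement must be >= 1")
  x0 <- slit_center - slit_span / 2
  x1 <- slit_center + slit_span / 2
  if (x0 < 0 || x1 > chamber_width) {
    stop("build_fluid_mesh: slit span exceeds the partition span")
  }
  if (is.null(bottom_faces)) bottom_faces <- seq(0, slit_span, length.out = 13)
  if (is.null(top_faces)) top_faces <- seq(0, slit_span, length.out = 7)
  bottom_faces <- sort(unique(bottom_faces))
  top_faces <- sort(unique(top_faces))
  if (min(bottom_faces) < 0 || max(bottom_faces) > slit_span ||
      min(top_faces) < 0 || max(top_faces) > slit_span) {
    stop("build_fluid_mesh: slit faces must lie within the slit span")
  }

  # representative slit cell size seeds the far-field grading (the smallest
  # tributary can be a sliver at a membrane edge)
  h0 <- stats::median(c(diff(bottom_faces), diff(top_faces)))
  hmax <- h0 * refinement

  grade_up <- function(from, to, h0, hmax, growth) {
    # boundaries from `from` to `to` with sizes growing from h0 up to hmax
    if (to - from < 1e-12) return(numeric(0))
    sizes <- c()
    h <- h0
    pos <- from
    while (pos < to - 1e-12) {
      sizes <- c(sizes, min(h, to - pos))
      pos <- pos + sizes[length(sizes)]
      h <- min(h * growth, hmax)
    }
    sizes <- sizes * (to - from) / sum(sizes)
    from + cumsum(sizes)
  }

  xb_of <- function(slit_faces) {
    # absolute x boundaries: graded left wing, slit faces, graded right wing
    left <- rev(x0 - (grade_up(0, x0, h0, hmax, growth)))
    right <- grade_up(x1, chamber_width, h0, hmax, growth)
    xb <- unique(c(0, left, x0 + slit_faces, right))
    sort(xb)
  }
  zb <- c(0, grade_up(0, channel_height, h0, hmax, growth))

  comp <- function(name, slit_faces) {
    xb <- xb_of(slit_faces)
    list(name = name, xb = xb, zb = zb,
         slit_faces_abs = x0 + slit_faces)
  }

  structure(list(
    bottom = comp("bottom", bottom_faces),
    top = comp("top", top_faces),
    chamber_width = chamber_width, channel_height = channel_height,
    slit = c(x0, x1), refinement = refinement, h0 = h0
  ), class = "fluid_mesh")
}

#' @export
print.fluid_mesh <- function(x, ...) {
  nb <- (length(x$bottom$xb) - 1) * (length(x$bottom$zb) - 1)
  nt <- (length(x$top$xb) - 1) * (length(x$top$zb) - 1)
  cat(sprintf("fluid_mesh: %g x %g mm chamber, slit [%.3f, %.3f] mm, %d + %d cells\n",
              x$chamber_width, x$channel_height, x$slit[1], x$slit[2], nb, nt))
  invisible(x)
}

# cell table for one compartment: centers and sizes in metres
comp_cells <- function(comp) {
  xb <- comp$xb * 1e-3
  zb <- comp$zb * 1e-3
  nx <- length(xb) - 1
  nz <- length(zb) - 1
  xc <- (xb[-1] + xb[-length(xb)]) / 2
  zc <- (zb[-1] + zb[-length(zb)]) / 2
  list(nx = nx, nz = nz, xb = xb, zb = zb, xc = xc, zc = zc,
       dx = diff(xb), dz = diff(zb))
}

#' Assemble the fluid pressure operator and fluid-structure coupling
#'
#' Builds `A_pp` (discrete Laplacian with boundary conditions), `A_pa`
#' (interface acceleration to pressure-equation source), `A_ap` (pressure to
#' interface force) and the prescribed-pressure load vector `b` (for unit
#' stimulus pressure). Interface entities are the structural nodes facing the
#' fluid: each carries a tributary span of the slit, and its force is the
#' facing pressure times the tributary area (span times depth).
#'
#' @param mesh A [build_fluid_mesh()] mesh.
#' @param interface List with data frames `bottom` and `top`, each with
#'   columns `entity` (structural node label or id), `x0`, `x1` (tributary
#'   span in mm from the slit start). Tributaries must match the mesh slit
#'   faces one-to-one.
#' @param depth Out-of-plane depth in mm (longitudinal section spacing).
#' @param rho Fluid density, kg/m^3.
#' @param nsec Number of longitudinal slices (structural sections). With
#'   `nsec > 1` the planar mesh is extruded into a 3-D slab of `nsec`
#'   slices of thickness `depth`, coupled by longitudinal conductances and
#'   closed by rigid walls at both ends; interface entities are then
#'   (node, slice) pairs in slice-major order. `nsec = 1` keeps the planar
#'   model.
#' @return Object of class `coupling_ops` with sparse `A_pp`, `A_pa`, `A_ap`,
#'   `b`, the cell table, interface entity table, and `ref_cell` (hydrophone
#'   reference cell in the bottom compartment near the slit, middle slice).
#' @export
assemble_coupling <- function(mesh, interface, depth = 0.01, rho = 1000,
                              nsec = 1) {
  stopifnot(inherits(mesh, "fluid_mesh"))
  depth_m <- depth * 1e-3
  comps <- list(bottom = comp_cells(mesh$bottom), top = comp_cells(mesh$top))
  offs <- c(bottom = 0, top = comps$bottom$nx * comps$bottom$nz)
  ncell <- offs[["top"]] + comps$top$nx * comps$top$nz
  idx <- function(comp, i, j) offs[[comp]] + (j - 1) * comps[[comp]]$nx + i

  trips <- list()
  add_t <- function(i, j, v) {
    trips[[length(trips) + 1]] <<- cbind(i, j, v)
  }
  b <- numeric(ncell)

  # entity tables
  ents <- rbind(
    cbind(interface$bottom, side = "bottom", stringsAsFactors = FALSE),
    cbind(interface$top, side = "top", stringsAsFactors = FALSE)
  )
  nent <- nrow(ents)
  pa_i <- integer(0); pa_j <- integer(0); pa_v <- numeric(0)
  ap_i <- integer(0); ap_j <- integer(0); ap_v <- numeric(0)

  slit0 <- mesh$slit[1]
  for (side in c("bottom", "top")) {
    cc <- comps[[side]]
    nx <- cc$nx; nz <- cc$nz
    # interior fluxes, vectorized over cell pairs
    if (nx > 1) {
      i <- rep(seq_len(nx - 1), times = nz)
      j <- rep(seq_len(nz), each = nx - 1)
      g <- cc$dz[j] * depth_m / (cc$xc[i + 1] - cc$xc[i])
      c0 <- idx(side, i, j); c1 <- idx(side, i + 1, j)
      add_t(c(c0, c1, c0, c1), c(c0, c1, c1, c0), c(g, g, -g, -g))
    }
    if (nz > 1) {
      i <- rep(seq_len(nx), times = nz - 1)
      j <- rep(seq_len(nz - 1), each = nx)
      g <- cc$dx[i] * depth_m / (cc$zc[j + 1] - cc$zc[j])
      c0 <- idx(side, i, j); c1 <- idx(side, i, j + 1)
      add_t(c(c0, c1, c0, c1), c(c0, c1, c1, c0), c(g, g, -g, -g))
    }
    # vertical end faces: bottom compartment has pressure input (left, p = 1)
    # and pressure release (right, p = 0); top compartment open to air (p = 0)
    j <- seq_len(nz)
    gl <- cc$dz * depth_m / (cc$xc[1] - cc$xb[1])
    cl <- idx(side, 1, j)
    add_t(cl, cl, gl)
    if (side == "bottom") b[cl] <- b[cl] + gl * 1
    gr <- cc$dz * depth_m / (cc$xb[nx + 1] - cc$xc[nx])
    cr <- idx(side, nx, j)
    add_t(cr, cr, gr)
    # partition row (j = 1): rigid wall except interface faces
    side_ents <- which(ents$side == side)
    for (e in side_ents) {
      xa <- slit0 + ents$x0[e]; xb_ <- slit0 + ents$x1[e]
      if (xb_ - xa <= 0) next
      cells <- which(cc$xb[-length(cc$xb)] * 1e3 > xa - 1e-9 &
                     cc$xb[-1] * 1e3 < xb_ + 1e-9)
      if (!length(cells)) {
        stop("assemble_coupling: interface entity '", ents$entity[e],
             "' has no facing fluid cell (tributary area mismatch)")
      }
      for (i in cells) {
        cid <- idx(side, i, 1)
        Af <- cc$dx[i] * depth_m
        sgn <- if (side == "bottom") 1 else -1
        pa_i <- c(pa_i, cid); pa_j <- c(pa_j, e); pa_v <- c(pa_v, sgn * rho * Af)
        ap_i <- c(ap_i, e); ap_j <- c(ap_j, cid); ap_v <- c(ap_v, sgn * Af)
      }
    }
    # far z face (channel bottom / coverslip): rigid wall -> nothing
  }

  tr <- do.call(rbind, trips)
  A_pp <- Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                               dims = c(ncell, ncell))
  A_pa <- Matrix::sparseMatrix(i = pa_i, j = pa_j, x = pa_v,
                               dims = c(ncell, nent))
  A_ap <- Matrix::sparseMatrix(i = ap_i, j = ap_j, x = ap_v,
                               dims = c(nent, ncell))

  if (nsec > 1) {
    # extrude into a 3-D slab: nsec slices coupled by longitudinal
    # conductances (cell area / spacing), rigid walls at both ends
    areas <- numeric(ncell)
    for (side in c("bottom", "top")) {
      cc <- comps[[side]]
      i <- rep(seq_len(cc$nx), times = cc$nz)
      j <- rep(seq_len(cc$nz), each = cc$nx)
      areas[idx(side, i, j)] <- cc$dx[i] * cc$dz[j]
    }
    L1 <- Matrix::bandSparse(nsec, k = c(-1, 0, 1),
                             diagonals = list(rep(-1, nsec - 1),
                                              c(1, rep(2, nsec - 2), 1),
                                              rep(-1, nsec - 1)))
    h <- depth_m
    A_pp <- Matrix::kronecker(Matrix::Diagonal(nsec), A_pp) +
      Matrix::kronecker(L1, Matrix::Diagonal(x = areas / h))
    A_pa <- Matrix::kronecker(Matrix::Diagonal(nsec), A_pa)
    A_ap <- Matrix::kronecker(Matrix::Diagonal(nsec), A_ap)
    b <- rep(b, nsec)
  }

  # hydrophone reference: bottom-compartment cell nearest to (slit start -
  # 0.5 mm, mid-channel depth)
  cb <- comps$bottom
  xt <- (mesh$slit[1] - 0.5) * 1e-3
  if (xt < cb$xc[1]) xt <- cb$xc[1]
  ri <- which.min(abs(cb$xc - xt))
  rj <- which.min(abs(cb$zc - mesh$channel_height * 1e-3 / 2))
  ref_cell <- idx("bottom", ri, rj) + ((nsec + 1) %/% 2 - 1) * ncell

  cells <- do.call(rbind, lapply(c("bottom", "top"), function(side) {
    cc <- comps[[side]]
    data.frame(comp = side,
               x_mm = rep(cc$xc, cc$nz) * 1e3,
               z_mm = rep(cc$zc, each = cc$nx) * 1e3 *
                 if (side == "bottom") -1 else 1,
               stringsAsFactors = FALSE)
  }))

  structure(list(A_pp = A_pp, A_pa = A_pa, A_ap = A_ap, b = b, rho = rho,
                 depth_mm = depth, entities = ents, cells = cells,
                 nsec = nsec, nent_total = nent * nsec,
                 ref_cell = ref_cell, mesh = mesh),
            class = "coupling_ops")
}

#' Solve the fluid pressure field
#'
#' Solves `A_pp p = b * p_in - A_pa a` for a prescribed stimulus pressure and
#' (optionally complex) interface accelerations.
#'
#' @param coupling A [assemble_coupling()] object.
#' @param accel Interface acceleration vector (m/s^2), one entry per entity;
#'   defaults to zero.
#' @param p_in Stimulus pressure at the input port, Pa.
#' @return List with `p` (pressure per cell, Pa), `forces` (interface forces,
#'   N, `A_ap p`), and `p_ref` (pressure at the hydrophone reference cell).
#' @export
solve_pressure <- function(coupling, accel = NULL, p_in = 1) {
  nent <- if (!is.null(coupling$nent_total)) coupling$nent_total
          else nrow(coupling$entities)
  if (is.null(accel)) accel <- numeric(nent)
  # real sparse operators: complex vectors are handled by parts
  sp_mult <- function(A, v) {
    if (is.complex(v)) {
      as.vector(A %*% Re(v)) + 1i * as.vector(A %*% Im(v))
    } else {
      as.vector(A %*% v)
    }
  }
  rhs <- coupling$b * p_in - sp_mult(coupling$A_pa, accel)
  p <- if (is.complex(rhs)) {
    as.vector(Matrix::solve(coupling$A_pp, Re(rhs))) +
      1i * as.vector(Matrix::solve(coupling$A_pp, Im(rhs)))
  } else {
    as.vector(Matrix::solve(coupling$A_pp, rhs))
  }
  list(p = p, forces = sp_mult(coupling$A_ap, p), p_ref = p[coupling$ref_cell])
}

#' Export a pressure field as a delimited table
#'
#' @param coupling A `coupling_ops` object.
#' @param p Pressure vector (possibly complex) as from [solve_pressure()].
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_pressure_table <- function(coupling, p, path) {
  df <- coupling$cells
  df$re_p <- Re(p)
  df$im_p <- Im(p)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
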