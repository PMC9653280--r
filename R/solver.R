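# Static and frequency-domain solution of the coupled fluid-structure system.
#
# The incompressible fluid contributes an added-mass operator and an
# effective load: substituting the pressure equation into the structural one
# gives M_EFF = M + A_ap App^-1 A_pa and f_EFF = A_ap App^-1 b, and the
# coupled system (-w^2 M_EFF + i w C + K) x = f_EFF is solved per frequency.

new_field <- function(values, freq, load, p_ref = NA) {
  structure(list(values = values, freq = freq, load = load, p_ref = p_ref),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("displacement_field: %s, %d DOF, load: %s\n",
              if (x$freq > 0) sprintf("%g Hz", x$freq) else "static",
              length(x$values), x$load))
  invisible(x)
}

#' Complex nodal displacement at a node
#'
#' @param field A `displacement_field`.
#' @param system The `ooc_system` it was solved on.
#' @param s Section index.
#' @param node Node id or label.
#' @return Complex (or real) vector `c(u_r, u_t)` in metres.
#' @export
field_at <- function(field, system, s, node) {
  if (is.character(node)) node <- match(node, system$section$nodes$label)
  v <- field$values[dof_index(system, s, node, 1:2)]
  names(v) <- c("u_r", "u_t")
  v
}

solve_constrained <- function(system, A, rhs_free) {
  # symmetric Jacobi scaling: rotational stiffnesses sit many orders below
  # translational ones and unscaled sparse LU loses several digits
  d <- Matrix::diag(A)
  D <- 1 / sqrt(pmax(abs(d), 1e-300))
  Ds <- Matrix::Diagonal(x = D)
  tryCatch({
    x <- D * as.vector(Matrix::solve(Ds %*% A %*% Ds, D * rhs_free))
    resid <- as.vector(A %*% x) - rhs_free
    if (!all(is.finite(x)) ||
        max(abs(resid)) > 1e-6 * max(abs(rhs_free))) {
      stop("residual check failed")
    }
    x
  },
    error = function(e) {
      # identify the dominant near-null mode to aid diagnosis
      msg <- "singular constrained stiffness matrix"
      if (length(rhs_free) <= 2500) {
        ev <- eigen(as.matrix(A), symmetric = TRUE)
        vec <- ev$vectors[, length(rhs_free)]
        d <- system$free[which.max(abs(vec))]
        s <- (d - 1) %/% system$ndof_sec + 1
        rem <- (d - 1) %% system$ndof_sec
        node <- rem %/% 4 + 1
        dir <- rem %% 4 + 1
        msg <- sprintf(
          "singular constrained stiffness matrix: unconstrained mode peaks at section %d, node %s, dof %d",
          s, system$section$nodes$label[node], dir)
      }
      stop(msg, call. = FALSE)
    })
}

#' Static solution under hydrostatic pressure or an explicit load
#'
#' A transepithelial pressure step loads the basilar-membrane-facing
#' interface: each BM chord node receives `dP` times its tributary area
#' (tributary radial span times section spacing). Alternatively an explicit
#' global load vector (N, length `ndof`) can be given.
#'
#' @param system An `ooc_system`.
#' @param dP Transepithelial pressure in Pa (scala-tympani side positive).
#' @param load Optional explicit load vector in N.
#' @return A real `displacement_field` (m).
#' @export
solve_static <- function(system, dP = NULL, load = NULL) {
  if (is.null(dP) && is.null(load)) stop("solve_static: give dP or load")
  f <- numeric(system$ndof)
  desc <- ""
  if (!is.null(load)) {
    stopifnot(length(load) == system$ndof)
    f <- f + load
    desc <- "explicit load"
  }
  if (!is.null(dP)) {
    if (!is.finite(dP)) stop("solve_static: dP must be finite")
    f <- f + hydrostatic_load(system, dP)
    desc <- paste0("hydrostatic dP = ", dP, " Pa")
  }
  x <- numeric(system$ndof)
  if (any(f[system$free] != 0)) {
    x[system$free] <- as.vector(
      solve_constrained(system, system$K[system$free, system$free], f[system$free]))
  }
  new_field(x, 0, desc)
}

# tributary-area-weighted pressure load on the BM chord (N)
hydrostatic_load <- function(system, dP) {
  f <- numeric(system$ndof)
  bt <- system$interface$bottom
  area <- (bt$x1 - bt$x0) * 1e-3 * system$spacing_um * 1e-6
  for (s in seq_len(system$nsec)) {
    f[dof_index(system, s, bt$node, 2)] <- dP * area
  }
  f
}

#' Effective (fluid-loaded) system
#'
#' Factorizes the fluid operator once and condenses it onto the structural
#' interface: returns the interface added-mass block `A_ap App^-1 A_pa`,
#' the effective load `A_ap App^-1 b` (for unit stimulus pressure), and the
#' interface DOF map. With a planar (single-slice) coupling the block is
#' replicated on every structural section; with an extruded slab coupling
#' the block spans all (node, section) interface entities and couples
#' sections through the fluid. The effective-mass action `x -> M_EFF x` is
#' exposed without forming a dense global inverse.
#'
#' @param system An `ooc_system`.
#' @param coupling A `coupling_ops` built with the system's interface table
#'   and depth equal to the section spacing.
#' @return Object of class `ooc_effective`.
#' @export
effective_system <- function(system, coupling) {
  nent <- if (!is.null(coupling$nent_total)) coupling$nent_total
          else nrow(coupling$entities)
  csec <- if (!is.null(coupling$nsec)) coupling$nsec else 1
  if (!(csec %in% c(1, system$nsec))) {
    stop("effective_system: coupling has ", csec,
         " slices but the structure has ", system$nsec, " sections")
  }
  App <- coupling$A_pp
  fac <- tryCatch(Matrix::lu(App), error = function(e) {
    stop("effective_system: fluid operator A_pp is singular", call. = FALSE)
  })
  X <- as.matrix(Matrix::solve(fac, as.matrix(cbind(coupling$A_pa, coupling$b))))
  Madd <- as.matrix(coupling$A_ap %*% X[, seq_len(nent), drop = FALSE])
  fent <- as.vector(coupling$A_ap %*% X[, nent + 1])
  # entity -> node id in the section (order: bottom table then top table)
  ent_nodes <- c(system$interface$bottom$node, system$interface$top$node)
  # global DOFs of the interface entities, slice-major to match the slab
  ent_dofs <- unlist(lapply(seq_len(system$nsec), function(s) {
    dof_index(system, s, ent_nodes, 2)
  }))
  structure(list(system = system, coupling = coupling, Madd = Madd,
                 f_ent = fent, ent_nodes = ent_nodes, ent_dofs = ent_dofs,
                 per_section = (csec == 1), fluid_factor = fac,
                 cache = new.env(parent = emptyenv())),
            class = "ooc_effective")
}

#' Effective fluid load vector
#'
#' The global load `f_EFF = A_ap App^-1 b` over all sections, for a unit
#' stimulus pressure.
#'
#' @param eff An `ooc_effective`.
#' @param p_in Stimulus pressure, Pa.
#' @return Load vector (N) of length `ndof`.
#' @export
effective_load <- function(eff, p_in = 1) {
  sys <- eff$system
  f <- numeric(sys$ndof)
  if (eff$per_section) {
    ne <- length(eff$ent_nodes)
    for (s in seq_len(sys$nsec)) {
      idx <- eff$ent_dofs[(s - 1) * ne + seq_len(ne)]
      f[idx] <- f[idx] + eff$f_ent * p_in
    }
  } else {
    f[eff$ent_dofs] <- f[eff$ent_dofs] + eff$f_ent * p_in
  }
  f
}

#' Apply the effective mass operator to a vector
#'
#' @param eff An `ooc_effective`.
#' @param x Vector of length `ndof`.
#' @return `M_EFF x`.
#' @export
meff_apply <- function(eff, x) {
  sys <- eff$system
  out <- as.vector(sys$M %*% x)
  if (eff$per_section) {
    ne <- length(eff$ent_nodes)
    for (s in seq_len(sys$nsec)) {
      idx <- eff$ent_dofs[(s - 1) * ne + seq_len(ne)]
      out[idx] <- out[idx] + as.vector(eff$Madd %*% x[idx])
    }
  } else {
    out[eff$ent_dofs] <- out[eff$ent_dofs] +
      as.vector(eff$Madd %*% x[eff$ent_dofs])
  }
  out
}

# sparse M_EFF and global f_EFF
eff_assembled <- function(eff) {
  sys <- eff$system
  ne <- length(eff$ent_nodes)
  if (eff$per_section) {
    bi <- integer(0); bj <- integer(0); bv <- numeric(0)
    for (s in seq_len(sys$nsec)) {
      idx <- eff$ent_dofs[(s - 1) * ne + seq_len(ne)]
      bi <- c(bi, rep(idx, times = ne))
      bj <- c(bj, rep(idx, each = ne))
      bv <- c(bv, as.vector(eff$Madd))
    }
  } else {
    bi <- rep(eff$ent_dofs, times = length(eff$ent_dofs))
    bj <- rep(eff$ent_dofs, each = length(eff$ent_dofs))
    bv <- as.vector(eff$Madd)
  }
  Meff <- sys$M + Matrix::sparseMatrix(i = bi, j = bj, x = bv,
                                       dims = c(sys$ndof, sys$ndof))
  list(M = Meff, f = effective_load(eff))
}

#' Frequency-domain solution of the coupled system
#'
#' Solves `(-w^2 M_EFF + i w C + K) x = f_EFF * p_in` at `w = 2 pi f`. The
#' returned field also carries `p_ref`, the fluid pressure at the hydrophone
#' reference cell (bottom compartment near the slit) for the middle section,
#' which emulates the measured stimulus-pressure normalization.
#'
#' @param system An `ooc_system`.
#' @param coupling A `coupling_ops` or a prebuilt [effective_system()].
#' @param f Frequency in Hz (> 0).
#' @param p_in Stimulus pressure at the input port, Pa.
#' @return A complex `displacement_field`.
#' @export
solve_frequency <- function(system, coupling, f, p_in = 1) {
  if (f <= 0) stop("solve_frequency: f must be > 0")
  eff <- if (inherits(coupling, "ooc_effective")) coupling
         else effective_system(system, coupling)
  sys <- eff$system
  w <- 2 * pi * f
  free <- sys$free
  if (is.null(eff$cache$Mf)) {
    ea <- eff_assembled(eff)
    eff$cache$Mf <- ea$M[free, free]
    eff$cache$Cf <- sys$C[free, free]
    eff$cache$Kf <- sys$K[free, free]
    eff$cache$ff <- ea$f[free]
  }
  # complex system solved as a real 2x2 block sparse system, with symmetric
  # Jacobi scaling for conditioning (rotation DOFs carry stiffnesses many
  # orders below the translational ones)
  Are <- eff$cache$Kf - w^2 * eff$cache$Mf
  Aim <- w * eff$cache$Cf
  D <- 1 / sqrt(pmax(abs(Matrix::diag(Are)) + abs(Matrix::diag(Aim)), 1e-300))
  Ds <- Matrix::Diagonal(x = D)
  Ar <- Ds %*% Are %*% Ds
  Ai <- Ds %*% Aim %*% Ds
  Z <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
  rhs <- c(D * (eff$cache$ff * p_in), numeric(length(free)))
  xf <- tryCatch(as.vector(Matrix::solve(Z, rhs)), error = function(e) {
    stop(sprintf("solve_frequency: dynamic matrix singular at f = %g Hz", f),
         call. = FALSE)
  })
  n1 <- length(free)
  x <- complex(length.out = sys$ndof)
  x[free] <- complex(real = D * xf[1:n1], imaginary = D * xf[n1 + (1:n1)])
  # hydrophone pressure given the interface accelerations (middle section
  # for a planar coupling, all entities for a slab coupling)
  a_ent <- if (eff$per_section) {
    smid <- (sys$nsec + 1) %/% 2
    -w^2 * x[dof_index(sys, smid, eff$ent_nodes, 2)]
  } else {
    -w^2 * x[eff$ent_dofs]
  }
  pr <- solve_pressure(eff$coupling, accel = a_ent, p_in = p_in)
  new_field(x, f, sprintf("boundary pressure %g Pa", p_in), p_ref = pr$p_ref)
}

#' Outer-hair-cell force couple load
#'
#' Equal and opposite forces along the cell axis at the apical and basal ends
#' of the selected outer hair cells (contraction positive: the ends are
#' pulled toward each other). Net force and net moment per cell are zero.
#'
#' @param system An `ooc_system`.
#' @param sections Section indices (default: all interior sections, i.e.
#'   uniform contraction along the modelled span; a single loaded cell
#'   instead probes how the phalangeal truss grounds to its unloaded
#'   neighbours).
#' @param rows OHC rows, subset of 1:3.
#' @param f_ohc Force magnitude per cell in N.
#' @return Load vector (N) of length `ndof`.
#' @export
apply_ohc_force_couple <- function(system, sections = NULL, rows = 1,
                                   f_ohc = 1e-9) {
  if (!all(rows %in% 1:3)) stop("apply_ohc_force_couple: rows must be within 1:3")
  if (is.null(sections)) sections <- 2:(system$nsec - 1)
  if (any(sections < 1 | sections > system$nsec)) {
    stop("apply_ohc_force_couple: section range outside the model")
  }
  if (!is.finite(f_ohc)) stop("apply_ohc_force_couple: force must be finite")
  sec <- system$section
  h <- system$spacing_um * 1e-6
  f <- numeric(system$ndof)
  for (s in sections) {
    for (r in rows) {
      e <- sec$elements[sec$elements$role == paste("OHC row", r), ]
      ax <- element_axis3(sec, e, h)$e3 # n1 (basal) -> n2 (apical), 3-D
      # contraction pulls apex toward base and base toward apex
      f[dof_index(system, s, e$n1, 1:3)] <- f[dof_index(system, s, e$n1, 1:3)] + f_ohc * ax
      f[dof_index(system, s, e$n2, 1:3)] <- f[dof_index(system, s, e$n2, 1:3)] - f_ohc * ax
    }
  }
  f
}

#' Coupled frequency sweep at the basilar-membrane midpoint
#'
#' Runs [solve_frequency()] over a set of frequencies and reports the BM
#' midpoint (first-row Deiters root, middle section) transverse amplitude and
#' phase, both raw and normalized by the hydrophone reference pressure.
#'
#' @param system An `ooc_system`.
#' @param coupling `coupling_ops` or `ooc_effective`.
#' @param freqs Frequencies in Hz.
#' @param p_in Stimulus pressure, Pa.
#' @param node Node label observed (default `"bm06"`, the first-row Deiters
#'   root where the peak displacement occurs).
#' @return Data frame with columns `f_hz`, `amp_m`, `phase_rad`, `p_ref_pa`,
#'   `amp_norm` (m/Pa re hydrophone), `phase_norm`.
#' @export
frequency_sweep <- function(system, coupling, freqs, p_in = 1, node = "bm06") {
  eff <- if (inherits(coupling, "ooc_effective")) coupling
         else effective_system(system, coupling)
  smid <- (system$nsec + 1) %/% 2
  rows <- lapply(freqs, function(fq) {
    fld <- solve_frequency(system, eff, fq, p_in)
    u <- field_at(fld, system, smid, node)[["u_t"]]
    un <- u / fld$p_ref
    data.frame(f_hz = fq, amp_m = Mod(u), phase_rad = Arg(u),
               p_ref_pa = Mod(fld$p_ref), amp_norm = Mod(un),
               phase_norm = Arg(un))
  })
  do.call(rbind, rows)
}

#' Corner frequency of an amplitude response
#'
#' Operational definition: the -3 dB point of the amplitude relative to its
#' low-frequency asymptote (the amplitude at the lowest frequency), taken as
#' the first downward crossing at or above the response peak, interpolated
#' in log-frequency.
#'
#' @param f_hz Frequencies (Hz, increasing).
#' @param amp Amplitudes (linear units).
#' @return Corner frequency in Hz (NA if no crossing inside the band).
#' @export
corner_frequency <- function(f_hz, amp) {
  ref <- amp[1] / sqrt(2)
  ipk <- which.max(amp)
  below <- which(amp < ref & seq_along(amp) >= ipk)
  if (!length(below)) return(NA_real_)
  i2 <- below[1]
  if (i2 == 1) return(f_hz[1])
  i1 <- i2 - 1
  lf <- log(f_hz[i1]) + (log(ref) - log(amp[i1])) /
    (log(amp[i2]) - log(amp[i1])) * (log(f_hz[i2]) - log(f_hz[i1]))
  exp(lf)
}

#' High-frequency amplitude slope in dB per octave
#'
#' Least-squares fit of `20*log10(amp)` against `log2(f)` over a band.
#'
#' @param f_hz Frequencies (Hz).
#' @param amp Amplitudes.
#' @param band Two-element frequency band (Hz) for the fit.
#' @return Slope in dB/octave.
#' @export
hf_slope_db_oct <- function(f_hz, amp, band = c(2500, 5000)) {
  sel <- f_hz >= band[1] & f_hz <= band[2]
  if (sum(sel) < 2) stop("hf_slope_db_oct: need >= 2 points in the band")
  unname(stats::coef(stats::lm(I(20 * log10(amp[sel])) ~ log2(f_hz[sel])))[2])
}

#' Total phase accumulation across a sweep
#'
#' Phase at the first frequency minus phase at the last, as the principal
#' value in [0, 360) degrees (positive for accumulating lag). A second-order
#' resonator accumulates ~180 degrees across its corner; the principal value
#' is robust to the sharp antiresonance-resonance excursions of internal
#' modes, which cancel in the net lag but alias a cumulative unwrap at
#' practical frequency sampling.
#'
#' @param phase_rad Phases in radians along increasing frequency.
#' @return Net accumulated phase lag in degrees, in [0, 360).
#' @export
phase_accumulation_deg <- function(phase_rad) {
  d <- (phase_rad[1] - phase_rad[length(phase_rad)]) * 180 / pi
  d %% 360
}
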