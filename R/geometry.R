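# Radial-section geometry of the organ of Corti.
#
# Coordinates: r (radial, um) runs from the medial edge of the basilar
# membrane (0) toward the spiral ligament; t (transverse, um) is perpendicular
# to the BM chord, positive toward the tectorial membrane.

.LANDMARK_LABELS <- c(
  "ipc_root", "tunnel_tip", "opc_root",
  "ohc1_base", "ohc1_apex", "ohc2_base", "ohc2_apex", "ohc3_base", "ohc3_apex",
  "hb1_tip", "hb2_tip", "hb3_tip",
  "bm_lateral", "tm_medial"
)

# OHC tilt in the radial plane (base lateral of apex), radians
.OHC_TILT <- 21 * pi / 180

#' Default (mean-anatomy) landmark set
#'
#' Fourteen anatomic landmarks in the radial-transverse plane: the roots of
#' the inner and outer pillar cells, the tip of the tunnel of Corti, top and
#' bottom of the three outer hair cells, tips of the three hair bundles, the
#' lateral end of the basilar membrane, and the medial edge of the tectorial
#' membrane. Radial positions scale with the interpolated BM width, heights
#' with the interpolated outer-hair-cell length and hair-bundle height. At the
#' two most-measured positions (x = 8.5 and 7.5 mm) the BM width uses the
#' measured mean (299 and 274 um) rather than the anchored interpolation.
#'
#' @param x Longitudinal position in mm (2 to 10).
#' @param materials Optional [material_table()].
#' @return Data frame with columns `label`, `r_um`, `t_um`.
#' @export
default_landmarks <- function(x, materials = material_table()) {
  mat <- material_at(x, materials)
  W <- if (isTRUE(all.equal(x, 8.5))) 299 else if (isTRUE(all.equal(x, 7.5))) 274 else mat$bm_width
  L <- mat$ohc_length
  H <- mat$hb_height
  Wtm <- mat$tm_width

  ipc <- c(0.184 * W, 0)
  opc <- c(0.401 * W, 0)
  tip <- c(0.318 * W, 1.30 * L)
  apex <- lapply(1:3, function(i) {
    c((0.452 + 0.0769 * (i - 1)) * W, (1.507 - 0.126 * (i - 1)) * L)
  })
  base <- lapply(apex, function(a) a + L * c(sin(.OHC_TILT), -cos(.OHC_TILT)))
  hb <- lapply(apex, function(a) a + H * c(-0.25, 0.968))
  # TM lateral end just beyond the third bundle tip; the medial (limbal)
  # edge lies one TM width medially and only slightly above the bundle
  # plane - the limbus sits near the level of the reticular lamina, so the
  # TM runs nearly flat from its attachment over the bundles
  m_dir <- hb[[1]] - hb[[2]]
  m_dir <- m_dir / sqrt(sum(m_dir^2))
  t6 <- hb[[3]] - 0.04 * Wtm * m_dir
  flat_dir <- c(-1, 0.05) / sqrt(1 + 0.05^2)
  tm_med <- t6 + Wtm * flat_dir

  pts <- rbind(ipc, tip, opc,
               base[[1]], apex[[1]], base[[2]], apex[[2]], base[[3]], apex[[3]],
               hb[[1]], hb[[2]], hb[[3]],
               c(W, 0), tm_med)
  data.frame(label = .LANDMARK_LABELS, r_um = pts[, 1], t_um = pts[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a landmark table from CSV
#'
#' Expects columns `label`, `r_um`, `t_um` with the fourteen standard labels.
#'
#' @param path Path to a delimited text file.
#' @return Landmark data frame as from [default_landmarks()].
#' @export
read_landmarks <- function(path) {
  lm <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_landmarks(lm)
  lm
}

validate_landmarks <- function(landmarks) {
  need <- c("label", "r_um", "t_um")
  if (!all(need %in% names(landmarks))) {
    stop("landmarks must have columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(.LANDMARK_LABELS, landmarks$label)
  if (length(missing)) {
    stop("missing landmark(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(landmarks$r_um)) || any(!is.finite(landmarks$t_um))) {
    stop("landmarks contain non-finite coordinates")
  }
  invisible(landmarks)
}

lm_get <- function(landmarks, label) {
  i <- match(label, landmarks$label)
  c(landmarks$r_um[i], landmarks$t_um[i])
}

#' Build a radial section of the organ-of-Corti model
#'
#' Constructs the 23-node radial section: 12 nodes along the basilar membrane
#' chord plus the spiral-lamina/limbus support node (13 BM-group nodes), 6
#' tectorial-membrane nodes (the limbus support is shared between the BM and
#' TM groups as the clamped attachment of both), and 5 nodes in the organ of
#' Corti proper (pillar head, three outer-hair-cell apices on the reticular
#' lamina, and the first-row OHC-Deiters-cell cup). Elements are planar frame
#' members (axial + bending) except the hair bundles, which are direct-
#' stiffness links, and the phalangeal process, which spans `php_span`
#' longitudinal sections from the first-row cup to the reticular lamina.
#' Second- and third-row outer hair cells and their Deiters cells are
#' series-equivalent single elements (the 23-node budget articulates a cup
#' for the measured first row only).
#'
#' @param x Longitudinal position in mm (2 to 10; no extrapolation).
#' @param materials A [material_table()].
#' @param landmarks Optional landmark data frame (default mean anatomy).
#' @param mult Named multipliers passed to [material_at()] (used by sweeps).
#' @param spacing Longitudinal section spacing in um (sets element depth).
#' @param php_span Phalangeal-process span in longitudinal cell spacings.
#' @param hb_axial_factor Stiffness of the hair-bundle link along the bundle
#'   axis, as a multiple of the deflection stiffness `hb_stiffness`.
#' @return An object of class `ooc_section`: list with `x`, `nodes`,
#'   `elements`, `bm_width_um`, `landmarks`, `spacing_um`, `materials_at_x`.
#' @export
build_section <- function(x, materials = material_table(), landmarks = NULL,
                          mult = NULL, spacing = 10, php_span = 3,
                          hb_axial_factor = 50) {
  x_a <- attr(materials, "x_a"); x_b <- attr(materials, "x_b")
  if (x < min(x_a, x_b) || x > max(x_a, x_b)) {
    stop(sprintf("build_section: x = %g mm outside anchor range (no extrapolation)", x))
  }
  mat <- material_at(x, materials, mult)
  if (is.null(landmarks)) landmarks <- default_landmarks(x, materials)
  validate_landmarks(landmarks)

  ipc <- lm_get(landmarks, "ipc_root")
  opc <- lm_get(landmarks, "opc_root")
  tip <- lm_get(landmarks, "tunnel_tip")
  bmL <- lm_get(landmarks, "bm_lateral")
  tmM <- lm_get(landmarks, "tm_medial")
  apex <- lapply(1:3, function(i) lm_get(landmarks, paste0("ohc", i, "_apex")))
  base <- lapply(1:3, function(i) lm_get(landmarks, paste0("ohc", i, "_base")))
  hb <- lapply(1:3, function(i) lm_get(landmarks, paste0("hb", i, "_tip")))

  W <- bmL[1]
  dc_root_r <- vapply(base, function(b) b[1] + 0.013 * W, 0)

  # --- nodes -----------------------------------------------------------------
  # BM chord (12 nodes, medial -> lateral)
  g <- (W - dc_root_r[3]) / 4
  bm_r <- c(0, ipc[1] / 2, ipc[1], (ipc[1] + opc[1]) / 2, opc[1],
            dc_root_r, dc_root_r[3] + g * (1:3), W)
  if (is.unsorted(bm_r, strictly = TRUE)) {
    stop("build_section: landmark layout yields non-monotone BM node positions")
  }
  # TM polyline: limbus attachment, root/body junction, three bundle tips,
  # lateral end
  t6 <- hb[[3]] + 0.04 * mat$tm_width * (hb[[3]] - hb[[2]]) / sqrt(sum((hb[[3]] - hb[[2]])^2))
  # root region is half as long as the body: root spans 1/3 of the TM width
  t2 <- tmM + (hb[[1]] - tmM) / 3

  labels <- c(paste0("bm", sprintf("%02d", 1:12)), "limbus",
              "tm_junction", "tm_hb1", "tm_hb2", "tm_hb3", "tm_lateral",
              "pillar_head", "ohc1_apex", "ohc2_apex", "ohc3_apex", "ohc1_cup")
  coords <- rbind(cbind(bm_r, 0), tmM, t2, hb[[1]], hb[[2]], hb[[3]], t6,
                  tip, apex[[1]], apex[[2]], apex[[3]], base[[1]])
  tag <- c(rep("BM", 12), "BM,TM", rep("TM", 5), rep("OoC", 5))
  clamped <- labels %in% c("bm01", "bm12", "limbus")
  nodes <- data.frame(id = seq_along(labels), label = labels,
                      r = coords[, 1], t = coords[, 2], tag = tag,
                      clamped = clamped, stringsAsFactors = FALSE)
  nid <- function(lab) match(lab, nodes$label)

  # --- element helper --------------------------------------------------------
  el <- list()
  add <- function(n1, n2, role, E, A, I, Ebend = E, kdir = NA_real_,
                  kdir_ax = NA_real_, lspan = 0, lofs = 0) {
    el[[length(el) + 1]] <<- data.frame(
      n1 = n1, n2 = n2, role = role, E = E, A = A, I = I, Ebend = Ebend,
      kdir = kdir, kdir_ax = kdir_ax, lspan = lspan, lofs = lofs,
      stringsAsFactors = FALSE)
  }
  rect <- function(thick) list(A = thick * spacing, I = spacing * thick^3 / 12)
  # cellular elements come one per ~10 um anatomical cell spacing; a section
  # of numerical spacing h carries h/10um of a cell
  cell_frac <- spacing / 10
  circ <- function(d) list(A = cell_frac * pi * d^2 / 4,
                           I = cell_frac * pi * d^4 / 64)

  # BM beams: arcuate zone (medial of OPC root) has a half-thickness fiber layer
  for (i in 1:11) {
    mid_r <- (bm_r[i] + bm_r[i + 1]) / 2
    arc <- mid_r < opc[1]
    thick <- mat$bm_fiber_thickness * if (arc) 0.5 else 1
    s <- rect(thick)
    add(i, i + 1, if (arc) "BM-arcuate" else "BM-pectinate",
        mat$bm_modulus_radial, s$A, s$I)
  }
  # TM: root (limbus -> junction) and body (junction -> lateral end)
  s <- rect(mat$tm_thickness_root)
  add(nid("limbus"), nid("tm_junction"), "TM-root", mat$tm_modulus_root, s$A, s$I)
  s <- rect(mat$tm_thickness_body)
  tm_chain <- c("tm_junction", "tm_hb1", "tm_hb2", "tm_hb3", "tm_lateral")
  for (i in 1:4) add(nid(tm_chain[i]), nid(tm_chain[i + 1]), "TM-body",
                     mat$tm_modulus_body, s$A, s$I)
  # pillar cells
  s <- circ(mat$pc_diameter)
  add(nid("bm03"), nid("pillar_head"), "IPC", mat$pc_modulus, s$A, s$I)
  add(nid("bm05"), nid("pillar_head"), "OPC", mat$pc_modulus, s$A, s$I)
  # reticular lamina
  s <- rect(mat$rl_thickness_tunnel)
  add(nid("pillar_head"), nid("ohc1_apex"), "RL-tunnel", mat$rl_modulus_radial, s$A, s$I)
  s <- rect(mat$rl_thickness_ohc)
  add(nid("ohc1_apex"), nid("ohc2_apex"), "RL-OHC", mat$rl_modulus_radial, s$A, s$I)
  add(nid("ohc2_apex"), nid("ohc3_apex"), "RL-OHC", mat$rl_modulus_radial, s$A, s$I)
  # first row: articulated OHC, Deiters cell, phalangeal process
  so <- circ(mat$ohc_diameter)
  sd <- circ(mat$dc_diameter)
  sp <- circ(mat$php_diameter)
  # OHC apices sit one anatomical cell spacing (~10 um) basal of the cups;
  # the phalangeal process leans the other way, completing the Y-truss.
  # Both are anatomical distances, independent of the numerical spacing.
  cell_um <- 10
  lspan_php <- max(1L, as.integer(round(php_span * cell_um / spacing)))
  add(nid("ohc1_cup"), nid("ohc1_apex"), "OHC row 1", mat$ohc_modulus, so$A,
      so$I, lofs = -cell_um)
  add(nid("bm06"), nid("ohc1_cup"), "DC base", mat$dc_modulus, sd$A, sd$I)
  add(nid("ohc1_cup"), nid("ohc1_apex"), "DC phalangeal process",
      mat$php_modulus, sp$A, sp$I, lspan = lspan_php)
  # rows 2-3: series-equivalent OHC+DC from the Deiters root to the RL apex
  for (i in 2:3) {
    root <- nodes[nid(paste0("bm0", 5 + i)), ]
    ap <- apex[[i]]
    Ltot <- sqrt(sum((c(root$r, root$t) - ap)^2))
    Lohc <- mat$ohc_length
    Ldc <- max(Ltot - Lohc, 0.15 * Ltot)
    k_ohc <- mat$ohc_modulus * so$A / Lohc
    k_dc <- mat$dc_modulus * sd$A / Ldc
    k_ser <- 1 / (1 / k_ohc + 1 / k_dc)
    E_eff <- k_ser * Ltot / so$A
    add(nid(paste0("bm0", 5 + i)), nid(paste0("ohc", i, "_apex")),
        paste("OHC row", i), E_eff, so$A, so$I, Ebend = mat$ohc_modulus,
        lofs = -cell_um)
  }
  # hair bundles: direct-stiffness links RL apex -> TM underside (one bundle
  # per row per cell spacing)
  for (i in 1:3) {
    add(nid(paste0("ohc", i, "_apex")), nid(paste0("tm_hb", i)), "hair bundle",
        NA_real_, NA_real_, NA_real_, kdir = cell_frac * mat$hb_stiffness,
        kdir_ax = cell_frac * hb_axial_factor * mat$hb_stiffness)
  }

  elements <- do.call(rbind, el)
  section <- structure(list(
    x = x, nodes = nodes, elements = elements, bm_width_um = W,
    landmarks = landmarks, spacing_um = spacing,
    materials_at_x = mat, php_span = php_span
  ), class = "ooc_section")
  validate_section(section)
  section
}

validate_section <- function(section) {
  nodes <- section$nodes
  counts <- section_node_counts(section)
  if (nrow(nodes) != 23 || counts["BM"] != 13 || counts["TM"] != 6 || counts["OoC"] != 5) {
    stop("section must have 23 nodes tagged 13 BM / 6 TM / 5 OoC")
  }
  # connectivity: TM nodes reachable from the limbus attachment, OoC nodes
  # from the BM, over the element graph
  adj <- section_adjacency(section)
  tm_ok <- all(reachable(adj, match("limbus", nodes$label))[grepl("TM", nodes$tag)])
  bm_ids <- which(grepl("BM", nodes$tag))
  reach_bm <- Reduce(`|`, lapply(bm_ids[1], function(i) reachable(adj, i)))
  ooc_ok <- all(reach_bm[nodes$tag == "OoC"])
  if (!tm_ok) stop("section invariant violated: TM not reachable from the spiral limbus")
  if (!ooc_ok) stop("section invariant violated: OoC interior not reachable from the BM")
  invisible(section)
}

#' Node counts per anatomic group
#'
#' @param section An `ooc_section`.
#' @return Named integer vector with BM, TM and OoC tag counts (a node may
#'   carry more than one tag; the limbus attachment is shared by BM and TM).
#' @export
section_node_counts <- function(section) {
  tag <- section$nodes$tag
  c(BM = sum(grepl("BM", tag)), TM = sum(grepl("TM", tag)),
    OoC = sum(grepl("OoC", tag)))
}

section_adjacency <- function(section) {
  n <- nrow(section$nodes)
  adj <- vector("list", n)
  for (k in seq_len(nrow(section$elements))) {
    a <- section$elements$n1[k]; b <- section$elements$n2[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

reachable <- function(adj, start) {
  seen <- logical(length(adj))
  stack <- start
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
  }
  seen
}

#' Axial and bending stiffness of an element
#'
#' Frame members report `EA/L` (axial) and `3*E*Iz/L^3` (cantilever bending);
#' direct-stiffness links (hair bundles) return their tabulated stiffness
#' unchanged. Inputs are in table units (MPa, um^2, um^4, um); outputs in
#' mN/m.
#'
#' @param element One row of a section's `elements` data frame (or a list
#'   with fields `E`, `A`, `I`, `L` or `kdir`).
#' @param section Optional `ooc_section` used to compute the element length
#'   from node coordinates when `element$L` is absent.
#' @return Named numeric vector `c(axial = , bending = )` in mN/m.
#' @export
element_stiffness <- function(element, section = NULL) {
  if (!is.na(element$kdir[1])) {
    return(c(axial = unname(element$kdir_ax[1]), bending = unname(element$kdir[1])))
  }
  L <- element$L
  if (is.null(L)) {
    if (is.null(section)) stop("element_stiffness: need element$L or a section")
    p1 <- unlist(section$nodes[element$n1, c("r", "t")])
    p2 <- unlist(section$nodes[element$n2, c("r", "t")])
    L <- sqrt(sum((p2 - p1)^2))
    if (element$lspan > 0) L <- sqrt(L^2 + (element$lspan * section$spacing_um)^2)
    if (!is.null(element$lofs) && element$lofs != 0) L <- sqrt(L^2 + element$lofs^2)
  }
  if (!is.finite(L) || L <= 0) stop("element_stiffness: element length must be positive")
  if (any(c(element$E, element$A, element$I) <= 0)) {
    stop("element_stiffness: E, A, I must be positive")
  }
  Eb <- if (!is.null(element$Ebend)) element$Ebend else element$E
  # MPa * um^2 / um = N/m; report mN/m
  c(axial = 1000 * element$E * element$A / L,
    bending = 1000 * 3 * Eb * element$I / L^3)
}

#' Export a section geometry to structured JSON
#'
#' @param section An `ooc_section`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_section_json <- function(section, path) {
  payload <- list(
    x_mm = section$x,
    bm_width_um = section$bm_width_um,
    spacing_um = section$spacing_um,
    nodes = section$nodes,
    elements = section$elements,
    boundary_conditions = section$nodes$label[section$nodes$clamped]
  )
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
print.ooc_section <- function(x, ...) {
  counts <- section_node_counts(x)
  cat(sprintf("ooc_section at x = %.2f mm: %d nodes (%d BM / %d TM / %d OoC), %d elements, BM width %.1f um\n",
              x$x, nrow(x$nodes), counts["BM"], counts["TM"], counts["OoC"],
              nrow(x$elements), x$bm_width_um))
  invisible(x)
}
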