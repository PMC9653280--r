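# End-to-end orchestration: model building, stiffness-ratio bookkeeping,
# parameter sweeps, log-log inference against measured deformation ratios,
# basilar-membrane modulus calibration, and reproducible run reports.

#' Log-spaced sweep grid
#'
#' @param lo,hi Grid limits (positive).
#' @param n Number of points.
#' @return Strictly increasing log-spaced vector.
#' @export
log_grid <- function(lo = 0.1, hi = 10, n = 9) {
  if (lo <= 0 || hi <= lo) stop("log_grid: need 0 < lo < hi")
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Build a coupled chamber model
#'
#' Convenience constructor: builds the radial section at `x`, replicates it
#' into a clamped multi-section structure, meshes the two-compartment
#' chamber with the slit spanning the basilar membrane, and assembles the
#' fluid-structure coupling operators.
#'
#' @param x Longitudinal position, mm.
#' @param span_mm Model span (>= 3 sections); default 0.2 mm.
#' @param spacing_um Section spacing, um.
#' @param mult Named property multipliers (see [material_at()]).
#' @param landmarks Optional landmark table.
#' @param chamber_width,channel_height Chamber dimensions, mm.
#' @param refinement Fluid mesh refinement factor (far-field to slit cell
#'   size ratio; the default 32 grows the ~12 um slit cells to ~0.4 mm in
#'   the far field).
#' @param alpha,beta Optional Rayleigh coefficients (default calibrated).
#' @param php_span Phalangeal-process span in sections.
#' @param rho_fluid Fluid density, kg/m^3.
#' @return Object of class `ooc_model`: list with `section`, `system`,
#'   `mesh`, `coupling` and the configuration.
#' @export
build_model <- function(x = 8.5, span_mm = 0.2, spacing_um = 10, mult = NULL,
                        landmarks = NULL, chamber_width = 10,
                        channel_height = 1, refinement = 32, alpha = NULL,
                        beta = NULL, php_span = 3, rho_fluid = 1000) {
  section <- build_section(x, landmarks = landmarks, mult = mult,
                           spacing = spacing_um, php_span = php_span)
  nsec <- max(3, round(span_mm * 1000 / spacing_um) + 1)
  system <- assemble_structure(section, nsec = nsec, alpha = alpha, beta = beta)
  iface <- system$interface
  mesh <- build_fluid_mesh(
    chamber_width = chamber_width, channel_height = channel_height,
    slit_span = section$bm_width_um * 1e-3, refinement = refinement,
    bottom_faces = c(iface$bottom$x0, utils::tail(iface$bottom$x1, 1)),
    top_faces = c(iface$top$x0, utils::tail(iface$top$x1, 1)))
  coupling <- assemble_coupling(mesh, iface, depth = spacing_um * 1e-3,
                                rho = rho_fluid, nsec = nsec)
  structure(list(section = section, system = system, mesh = mesh,
                 coupling = coupling,
                 config = list(x = x, span_mm = span_mm,
                               spacing_um = spacing_um, mult = mult,
                               chamber_width = chamber_width,
                               channel_height = channel_height,
                               refinement = refinement, php_span = php_span,
                               rho_fluid = rho_fluid)),
            class = "ooc_model")
}

#' @export
print.ooc_model <- function(x, ...) {
  cat(sprintf("ooc_model at x = %g mm, span %g mm (%d sections)\n",
              x$config$x, x$config$span_mm, x$system$nsec))
  invisible(x)
}

#' Operational stiffness-ratio bookkeeping for a section
#'
#' `k_HB` is the tabulated hair-bundle deflection stiffness; `k_TM` the
#' radial attachment stiffness of the tectorial membrane per section,
#' i.e. the series stiffness of the root and body segments from the limbal
#' attachment to the point above the second-row bundle, each projected on
#' the radial axis; `k_OHC`, `k_DC` and `k_PhP` the axial `EA/L` of the
#' respective first-row elements; `k_RL` the tip bending stiffness
#' `3EI/L^3` of the reticular-lamina cantilever. All in mN/m per section.
#'
#' @param section An `ooc_section`.
#' @return Named list of stiffnesses and the ratios `r_tm`, `r_dc`.
#' @export
stiffness_ratios <- function(section) {
  mat <- section$materials_at_x
  nodes <- section$nodes
  els <- section$elements
  dist <- function(a, b) {
    pa <- unlist(nodes[match(a, nodes$label), c("r", "t")])
    pb <- unlist(nodes[match(b, nodes$label), c("r", "t")])
    sqrt(sum((pb - pa)^2))
  }
  # TM radial attachment stiffness: series of the chain limbus -> junction
  # -> bundle 1 -> bundle 2, each element's EA/L times cos^2 of its angle
  # from the radial axis
  tm_chain <- list(c("limbus", "tm_junction"), c("tm_junction", "tm_hb1"),
                   c("tm_hb1", "tm_hb2"))
  inv_k <- vapply(tm_chain, function(pr) {
    pa <- unlist(nodes[match(pr[1], nodes$label), c("r", "t")])
    pb <- unlist(nodes[match(pr[2], nodes$label), c("r", "t")])
    L <- sqrt(sum((pb - pa)^2))
    cos2 <- ((pb[1] - pa[1]) / L)^2
    e <- els[els$n1 == match(pr[1], nodes$label) &
             els$n2 == match(pr[2], nodes$label), ][1, ]
    1 / (1000 * e$E * e$A / L * cos2)
  }, 0)
  k_tm <- 1 / sum(inv_k)
  k_hb <- mat$hb_stiffness
  axial <- function(role) {
    e <- els[els$role == role, ][1, ]
    unname(element_stiffness(e, section)["axial"])
  }
  k_ohc <- axial("OHC row 1")
  k_dc <- axial("DC base")
  k_php <- axial("DC phalangeal process")
  e_rl <- els[els$role == "RL-tunnel", ][1, ]
  L_rl <- dist("pillar_head", "ohc3_apex")
  k_rl <- 1000 * 3 * e_rl$Ebend * e_rl$I / L_rl^3
  list(k_hb = k_hb, k_tm = k_tm, k_ohc = k_ohc, k_dc = k_dc, k_php = k_php,
       k_rl = k_rl, r_tm = k_tm / k_hb, r_dc = k_dc / k_ohc)
}

# property multipliers realizing a target ratio value
ratio_mult <- function(ratio, value, base_ratios) {
  switch(ratio,
    rtm = {
      f <- value / base_ratios$r_tm
      c(tm_modulus_body = f, tm_modulus_root = f)
    },
    rdc = c(dc_modulus = value / base_ratios$r_dc),
    kphp = c(php_modulus = value / (base_ratios$k_php / base_ratios$k_ohc)),
    krl = c(rl_modulus_radial = value / (base_ratios$k_rl / base_ratios$k_ohc)),
    stop("ratio_mult: unsupported ratio ", ratio)
  )
}

#' Stiffness-ratio sweep
#'
#' Re-builds the model at each grid value with exactly one property set
#' rescaled (tectorial-membrane moduli for `rtm`, Deiters-cell modulus for
#' `rdc`, phalangeal-process modulus for `kphp`, reticular-lamina modulus
#' for `krl`, global damping multiplier for `cdc`), solves the coupled
#' response at the stated frequency, and records the deformation ratios and
#' motion directions. Solver failures at single grid points are recorded as
#' missing and the sweep continues.
#'
#' @param ratio One of `"rtm"`, `"rdc"`, `"kphp"`, `"krl"`, `"cdc"`.
#' @param grid Positive, strictly increasing ratio values (for `cdc`, the
#'   damping multiplier).
#' @param freq_hz Stimulus frequency, Hz.
#' @param x,span_mm,spacing_um,... Model configuration, as [build_model()].
#' @param base_mult Extra property multipliers applied at every grid point.
#' @return Object of class `sweep_result` with the grid and a `metrics`
#'   data frame (`value`, `dtm_dhb`, `theta_tm_deg`, `ddc_dohc`,
#'   `theta_dc_deg`).
#' @export
sweep_ratio <- function(ratio = c("rtm", "rdc", "kphp", "krl", "cdc"),
                        grid = log_grid(0.1, 10, 9), freq_hz = 1000,
                        x = 8.5, span_mm = 0.2, spacing_um = 10,
                        base_mult = NULL, ...) {
  ratio <- match.arg(ratio)
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE)) {
    stop("sweep_ratio: grid must be positive and strictly increasing")
  }
  base <- stiffness_ratios(build_section(x, mult = base_mult,
                                         spacing = spacing_um))
  rows <- lapply(grid, function(v) {
    res <- tryCatch({
      mult <- base_mult
      dampscale <- 1
      if (ratio == "cdc") dampscale <- v else {
        rm <- ratio_mult(ratio, v, base)
        mult <- c(mult[setdiff(names(mult), names(rm))], rm)
      }
      model <- build_model(x = x, span_mm = span_mm, spacing_um = spacing_um,
                           mult = mult, ...)
      sys <- model$system
      if (dampscale != 1) {
        sys$C <- sys$C * dampscale
      }
      fld <- solve_frequency(sys, model$coupling, freq_hz)
      tm <- deformation_ratio_tm(fld, sys)
      dc <- deformation_ratio_dc(fld, sys)
      data.frame(value = v, dtm_dhb = tm$ratio, theta_tm_deg = tm$theta_tm_deg,
                 ddc_dohc = dc$ratio, theta_dc_deg = dc$theta_dc_deg)
    }, error = function(e) {
      warning(sprintf("sweep_ratio: grid value %g failed: %s", v, conditionMessage(e)))
      data.frame(value = v, dtm_dhb = NA, theta_tm_deg = NA,
                 ddc_dohc = NA, theta_dc_deg = NA)
    })
    res
  })
  structure(list(ratio = ratio, grid = grid, freq_hz = freq_hz, x = x,
                 metrics = do.call(rbind, rows), base_ratios = base),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %s over [%g, %g] (%d points) at %g Hz, x = %g mm\n",
              x$ratio, min(x$grid), max(x$grid), length(x$grid), x$freq_hz, x$x))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Infer a stiffness ratio from a measured deformation ratio
#'
#' Log-log linear interpolation of the sweep curve at the measured value and
#' at measured +/- SD.
#'
#' @param sweep A `sweep_result`.
#' @param measured Measured deformation ratio.
#' @param sd Measurement SD (propagated to the bounds).
#' @param metric Metric column (default by sweep type: `dtm_dhb` for `rtm`,
#'   `ddc_dohc` otherwise).
#' @return List with `ratio`, `lower`, `upper`.
#' @export
infer_ratio <- function(sweep, measured, sd = 0, metric = NULL) {
  if (is.null(metric)) metric <- if (sweep$ratio == "rtm") "dtm_dhb" else "ddc_dohc"
  m <- sweep$metrics
  ok <- is.finite(m[[metric]])
  if (sum(ok) < 2) stop("infer_ratio: need at least two valid sweep points")
  lx <- log(m$value[ok]); ly <- log(m[[metric]][ok])
  # interpolate on the longest strictly monotone branch of the curve (the
  # asymptotic ends can flatten or fold where leakage terms take over)
  sgn <- sign(diff(ly))
  if (length(unique(sgn)) > 1) {
    runs <- rle(sgn)
    ends <- cumsum(runs$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    ibest <- which.max(runs$lengths)
    sel <- starts[ibest]:(ends[ibest] + 1)
    lx <- lx[sel]; ly <- ly[sel]
  }
  interp_one <- function(target) {
    lt <- log(target)
    if (lt > max(ly) || lt < min(ly)) {
      nearest <- m$value[ok][which.min(abs(ly - lt))]
      stop(sprintf("infer_ratio: measured value %g outside the sweep output range [%g, %g]; nearest endpoint ratio %g",
                   target, exp(min(ly)), exp(max(ly)), nearest))
    }
    o <- order(ly)
    exp(stats::approx(ly[o], lx[o], xout = lt, ties = "ordered")$y)
  }
  central <- interp_one(measured)
  if (sd > 0) {
    b <- sort(c(tryCatch(interp_one(measured - sd), error = function(e) NA),
                tryCatch(interp_one(measured + sd), error = function(e) NA)),
              na.last = TRUE)
    lower <- b[1]; upper <- b[2]
  } else {
    lower <- upper <- central
  }
  list(ratio = central, lower = lower, upper = upper)
}

#' Log-log slope of a sweep curve
#'
#' @param sweep A `sweep_result`.
#' @param range Restrict the fit to grid values within this range.
#' @param metric Metric column (defaults as in [infer_ratio()]).
#' @return Least-squares slope of `log(metric)` vs `log(value)`.
#' @export
sweep_loglog_slope <- function(sweep, range = c(0.3, 3), metric = NULL) {
  if (is.null(metric)) metric <- if (sweep$ratio == "rtm") "dtm_dhb" else "ddc_dohc"
  m <- sweep$metrics
  sel <- is.finite(m[[metric]]) & m$value >= range[1] & m$value <= range[2]
  if (sum(sel) < 2) stop("sweep_loglog_slope: need >= 2 points in range")
  unname(stats::coef(stats::lm(log(m[[metric]][sel]) ~ log(m$value[sel])))[2])
}

#' Calibrate the basilar-membrane modulus to a measured volume compliance
#'
#' Scales the BM fiber-layer modulus (radial and longitudinal together) so
#' that the simulated volume compliance under a uniform transepithelial
#' pressure equals the measured target, then returns the calibrated model.
#'
#' @param x Longitudinal position, mm.
#' @param target_mm4_per_n Target volume compliance.
#' @param dP Pressure step used in the static solves, Pa.
#' @param interval Search interval for the modulus multiplier.
#' @param ... Passed to [build_model()].
#' @return List with `model`, `mult` (the calibrated multiplier), and
#'   `compliance` (achieved value).
#' @export
calibrate_bm_modulus <- function(x = 8.5, target_mm4_per_n = 16.1, dP = 5.6,
                                 interval = c(0.02, 50), ...) {
  vc_of <- function(mlt) {
    model <- build_model(x = x, mult = c(bm_modulus_radial = mlt,
                                         bm_modulus_long = mlt), ...)
    fld <- solve_static(model$system, dP = dP)
    vc <- volume_compliance(bm_profile(fld, model$system))
    list(model = model, vc = vc$volume_mm4_per_n)
  }
  root <- stats::uniroot(function(lm_) log(vc_of(exp(lm_))$vc / target_mm4_per_n),
                         interval = log(interval), tol = 1e-4)
  mlt <- exp(root$root)
  fin <- vc_of(mlt)
  list(model = fin$model, mult = mlt, compliance = fin$vc)
}

#' Execute a declared multi-stage run and write a results bundle
#'
#' Validates the configuration schema up front, executes the declared
#' stages, and writes CSV tables, a JSON summary, and a plain-text log
#' carrying the configuration hash and seed.
#'
#' @param config Named list: `outdir` (required), optional `seed`, `x`,
#'   `span_mm`, `spacing_um`, `freq_hz`, and `stages` (subset of
#'   `"build"`, `"static"`, `"freq_sweep"`, `"sweep_rtm"`, `"sweep_rdc"`).
#' @return Named list of stage results, invisibly; files under `outdir`.
#' @export
run_report <- function(config) {
  allowed <- c("outdir", "seed", "x", "span_mm", "spacing_um", "freq_hz",
               "stages", "dP", "rtm_grid", "rdc_grid")
  bad <- setdiff(names(config), allowed)
  if (length(bad)) stop("run_report: unknown config field(s): ", paste(bad, collapse = ", "))
  if (is.null(config$outdir)) stop("run_report: config$outdir is required")
  stages <- config$stages %||% c("build", "static")
  known <- c("build", "static", "freq_sweep", "sweep_rtm", "sweep_rdc")
  if (!all(stages %in% known)) {
    stop("run_report: unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  x <- config$x %||% 8.5
  span <- config$span_mm %||% 0.2
  spacing <- config$spacing_um %||% 10
  freq <- config$freq_hz %||% 1000
  seed <- config$seed %||% 1
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  cfg_json <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  tf <- tempfile(fileext = ".json"); writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)

  results <- list()
  logline <- c(sprintf("cortimech run_report; config md5 %s; seed %d", cfg_hash, seed),
               sprintf("R %s; cortimech %s", getRversion(),
                       tryCatch(as.character(utils::packageVersion("cortimech")),
                                error = function(e) "dev")))
  model <- NULL
  for (st in stages) {
    if (st == "build" || is.null(model)) {
      model <- build_model(x = x, span_mm = span, spacing_um = spacing)
      results$build <- list(nodes = nrow(model$section$nodes),
                            sections = model$system$nsec)
      utils::write.csv(model$section$nodes,
                       file.path(config$outdir, "section_nodes.csv"),
                       row.names = FALSE)
    }
    if (st == "static") {
      fld <- solve_static(model$system, dP = config$dP %||% 5.6)
      prof <- bm_profile(fld, model$system)
      vc <- volume_compliance(prof)
      results$static <- c(vc, fwhm = fwhm_fraction(prof)$fraction)
      utils::write.csv(prof, file.path(config$outdir, "bm_profile_static.csv"),
                       row.names = FALSE)
    }
    if (st == "freq_sweep") {
      fr <- frequency_sweep(model$system, model$coupling,
                            freqs = log_grid(300, 5000, 15))
      results$freq_sweep <- list(
        corner_hz = corner_frequency(fr$f_hz, fr$amp_m),
        slope_db_oct = hf_slope_db_oct(fr$f_hz, fr$amp_m),
        phase_deg = phase_accumulation_deg(fr$phase_rad))
      utils::write.csv(fr, file.path(config$outdir, "frequency_sweep.csv"),
                       row.names = FALSE)
    }
    if (st == "sweep_rtm") {
      sw <- sweep_ratio("rtm", grid = config$rtm_grid %||% log_grid(0.1, 10, 9),
                        freq_hz = freq, x = x, span_mm = span,
                        spacing_um = spacing)
      results$sweep_rtm <- infer_ratio(sw, 0.57, 0.07)
      utils::write.csv(sw$metrics, file.path(config$outdir, "sweep_rtm.csv"),
                       row.names = FALSE)
    }
    if (st == "sweep_rdc") {
      sw <- sweep_ratio("rdc", grid = config$rdc_grid %||% log_grid(0.1, 10, 9),
                        freq_hz = freq, x = x, span_mm = span,
                        spacing_um = spacing)
      results$sweep_rdc <- infer_ratio(sw, 0.89, 0.21)
      utils::write.csv(sw$metrics, file.path(config$outdir, "sweep_rdc.csv"),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(results, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(logline, paste("stages:", paste(stages, collapse = ", "))),
             file.path(config$outdir, "run.log"))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
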