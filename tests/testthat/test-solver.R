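test_that("static solve is linear in the pressure step and zero at rest", {
  sys <- small_system()
  expect_equal(max(abs(solve_static(sys, dP = 0)$values)), 0)
  u1 <- solve_static(sys, dP = 5.6)$values
  u2 <- solve_static(sys, dP = 11.2)$values
  expect_equal(u2, 2 * u1, tolerance = 1e-12)
  expect_true(all(u1[sys$fixed] == 0))
  expect_error(solve_static(sys), "dP or load")
})

test_that("an unconstrained model is reported as singular", {
  sys <- assemble_structure(default_section(), nsec = 3)
  sys$fixed[] <- FALSE
  sys$free <- seq_len(sys$ndof)
  f <- numeric(sys$ndof); f[1] <- 1e-9
  expect_error(solve_static(sys, load = f), "singular")
})

test_that("zero fluid density removes the added mass but keeps the load path", {
  sys <- small_system()
  sec <- default_section()
  ifc <- sys$interface
  mesh <- build_fluid_mesh(chamber_width = 2, channel_height = 0.5,
                           slit_span = sec$bm_width_um * 1e-3, slit_center = 1,
                           refinement = 4,
                           bottom_faces = c(ifc$bottom$x0, tail(ifc$bottom$x1, 1)),
                           top_faces = c(ifc$top$x0, tail(ifc$top$x1, 1)))
  cpl0 <- assemble_coupling(mesh, ifc, depth = 0.01, rho = 0)
  eff0 <- effective_system(sys, cpl0)
  set.seed(3)
  x <- rnorm(sys$ndof)
  expect_equal(meff_apply(eff0, x), as.vector(sys$M %*% x), tolerance = 1e-12)
  expect_gt(max(abs(effective_load(eff0))), 0)
  # and a zeroed load vector gives a zero effective load
  cplz <- small_coupling()
  cplz$b[] <- 0
  effz <- effective_system(sys, cplz)
  expect_equal(max(abs(effective_load(effz))), 0)
})

test_that("effective mass action matches a dense computation of the condensed system", {
  sys <- small_system()
  cpl <- small_coupling()
  eff <- effective_system(sys, cpl)
  App <- as.matrix(cpl$A_pp)
  Madd <- as.matrix(cpl$A_ap) %*% solve(App, as.matrix(cpl$A_pa))
  M <- as.matrix(sys$M)
  for (s in seq_len(sys$nsec)) {
    idx <- dof_index(sys, s, eff$ent_nodes, 2)
    M[idx, idx] <- M[idx, idx] + Madd
  }
  set.seed(5)
  x <- rnorm(sys$ndof)
  mx <- as.vector(M %*% x)
  expect_equal(meff_apply(eff, x), mx, tolerance = 1e-9)
})

test_that("the frequency solution approaches the static limit at low frequency", {
  model <- default_model()
  eff <- default_eff()
  f1 <- solve_frequency(model$system, eff, 1)
  fs <- solve_static(model$system, load = effective_load(eff))
  err <- max(Mod(f1$values - fs$values)) / max(abs(fs$values))
  expect_lt(err, 0.01)
  expect_error(solve_frequency(model$system, eff, -10), "> 0")
})

test_that("with zero damping the response phase is exactly 0 or pi", {
  sec <- default_section()
  sys <- assemble_structure(sec, nsec = 5, alpha = 0, beta = 0,
                            c_subtectorial = 0, beta_tm = 0, f_bl = 0)
  cpl <- small_coupling()
  eff <- effective_system(sys, cpl)
  fld <- solve_frequency(sys, eff, 700)
  expect_lt(max(abs(Im(fld$values))) / max(Mod(fld$values)), 1e-8)
})

test_that("fluid loading lowers the corner frequency", {
  sec <- default_section()
  sys <- assemble_structure(sec, nsec = 11)
  ifc <- sys$interface
  mesh <- build_fluid_mesh(slit_span = sec$bm_width_um * 1e-3, refinement = 32,
                           bottom_faces = c(ifc$bottom$x0, tail(ifc$bottom$x1, 1)),
                           top_faces = c(ifc$top$x0, tail(ifc$top$x1, 1)))
  freqs <- log_grid(300, 8000, 7)
  corner_with_rho <- function(rho) {
    cpl <- assemble_coupling(mesh, ifc, depth = 0.01, rho = rho, nsec = 11)
    fr <- frequency_sweep(sys, effective_system(sys, cpl), freqs)
    corner_frequency(fr$f_hz, fr$amp_m)
  }
  cf_fluid <- corner_with_rho(1000)
  cf_dry <- corner_with_rho(0)
  expect_true(is.na(cf_dry) || cf_fluid <= cf_dry)
})

test_that("the OHC force couple is self-equilibrated and spares the BM", {
  # uniform contraction of all interior sections, as in the active-force
  # simulations
  model <- default_model()
  load <- apply_ohc_force_couple(model$system, rows = 1, f_ohc = 1e-9)
  # net external force vanishes in all three directions
  for (d in 1:3) {
    idx <- seq(d, model$system$ndof, by = 4)
    expect_lt(abs(sum(load[idx])), 1e-24)
  }
  fld <- solve_static(model$system, load = load)
  s <- (model$system$nsec + 1) %/% 2
  u_bm <- abs(fld$values[dof_index(model$system, s,
                                   match("bm06", model$system$section$nodes$label), 2)])
  u_rl <- abs(fld$values[dof_index(model$system, s,
                                   match("ohc1_apex", model$system$section$nodes$label), 2)])
  expect_lt(u_bm / u_rl, 0.5)
  expect_error(apply_ohc_force_couple(model$system, sections = 99), "outside")
  expect_error(apply_ohc_force_couple(model$system, rows = 4), "rows")
})

test_that("scaffold stiffness felt by the OHC matches a dense static condensation", {
  sys <- small_system()
  st <- stiffness_felt_by_ohc(sys)
  sec <- sys$section
  e <- sec$elements[sec$elements$role == "OHC row 1", ]
  ax <- cortimech:::element_axis3(sec, e, sys$spacing_um * 1e-6)
  s <- (sys$nsec + 1) %/% 2
  load <- apply_ohc_force_couple(sys, rows = 1, f_ohc = 1e-9)
  # independent dense solve, with Jacobi scaling for the wide stiffness range
  Kff <- as.matrix(sys$K[sys$free, sys$free])
  D <- 1 / sqrt(diag(Kff))
  u <- numeric(sys$ndof)
  u[sys$free] <- D * solve(Kff * (D %o% D), D * load[sys$free])
  d <- sum((u[dof_index(sys, s, e$n2, 1:3)] - u[dof_index(sys, s, e$n1, 1:3)]) * ax$e3)
  k_tot <- 1e-9 / abs(d)
  expect_equal(st$k_ooc_ohc_mn_per_m + st$k_ohc_mn_per_m, k_tot * 1e3,
               tolerance = 1e-6)
})

test_that("an effectively rigid scaffold is flagged", {
  # stiffen every modulus except the OHC soma by 1e4: the scaffold then
  # exceeds 1e3 x k_OHC and the condition is reported as rigid
  mods <- c("bm_modulus_radial", "bm_modulus_long", "pc_modulus",
            "dc_modulus", "php_modulus", "rl_modulus_radial",
            "rl_modulus_long", "tm_modulus_root", "tm_modulus_body",
            "tm_modulus_trans", "hb_stiffness")
  stiffen <- stats::setNames(rep(1e4, length(mods)), mods)
  sec <- build_section(8.5, mult = stiffen)
  sys <- assemble_structure(sec, nsec = 5)
  st <- stiffness_felt_by_ohc(sys)
  expect_true(st$rigid_flag)
  expect_equal(st$ratio, Inf)
})

test_that("response metrics recover the analytics of a second-order resonator", {
  fn <- 1000; z <- 0.4
  f <- log_grid(100, 8000, 200)
  r <- f / fn
  H <- 1 / sqrt((1 - r^2)^2 + (2 * z * r)^2)
  phase <- -atan2(2 * z * r, 1 - r^2)
  r3 <- sqrt(1 - 2 * z^2 + sqrt((1 - 2 * z^2)^2 + 1)) # analytic -3 dB point
  expect_equal(corner_frequency(f, H), fn * r3, tolerance = 0.02)
  expect_equal(hf_slope_db_oct(f, H, band = c(4000, 8000)), -12, tolerance = 0.6)
  expect_equal(phase_accumulation_deg(phase), 180, tolerance = 12)
})
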