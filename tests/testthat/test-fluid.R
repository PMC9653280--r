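# single-cell-high channel: the discrete Laplace solution is exactly linear
channel_mesh <- function(n = 20) {
  build_fluid_mesh(chamber_width = 2, channel_height = 0.1, slit_span = 0.4,
                   slit_center = 1, refinement = 1,
                   bottom_faces = seq(0, 0.4, length.out = 5),
                   top_faces = seq(0, 0.4, length.out = 3))
}

channel_interface <- function() {
  list(bottom = data.frame(entity = paste0("b", 1:4),
                           x0 = seq(0, 0.3, by = 0.1),
                           x1 = seq(0.1, 0.4, by = 0.1),
                           stringsAsFactors = FALSE),
       top = data.frame(entity = paste0("t", 1:2),
                        x0 = c(0, 0.2), x1 = c(0.2, 0.4),
                        stringsAsFactors = FALSE))
}

test_that("mesh construction validates its inputs", {
  expect_error(build_fluid_mesh(refinement = 0.5), "refinement")
  expect_error(build_fluid_mesh(chamber_width = 1, slit_span = 2), "slit")
  m <- build_fluid_mesh()
  expect_s3_class(m, "fluid_mesh")
  # two compartments, slit centered
  expect_equal(mean(m$slit), m$chamber_width / 2)
})

test_that("default refinement sets the far-field to slit cell-size ratio", {
  m <- build_fluid_mesh(refinement = 4)
  dx <- diff(m$bottom$xb)
  in_slit <- m$bottom$xb[-1] > m$slit[1] & m$bottom$xb[-length(m$bottom$xb)] < m$slit[2]
  expect_equal(max(dx) / stats::median(dx[in_slit]), 4, tolerance = 0.3)
})

test_that("pressure in a closed 1-D channel is exactly linear", {
  cpl <- assemble_coupling(channel_mesh(), channel_interface(), depth = 0.01)
  sol <- solve_pressure(cpl, p_in = 1)
  bottom <- cpl$cells$comp == "bottom"
  x <- cpl$cells$x_mm[bottom]
  # Dirichlet p = 1 at x = 0 face, p = 0 at x = 2 face
  expect_equal(sol$p[bottom], 1 - x / 2, tolerance = 1e-10)
  # top compartment has zero pressure everywhere (both ends open, no source)
  expect_equal(max(abs(sol$p[!bottom])), 0, tolerance = 1e-12)
})

test_that("discrete operator is symmetric and obeys the maximum principle", {
  cpl <- small_coupling()
  expect_lt(max(abs(cpl$A_pp - Matrix::t(cpl$A_pp))) / max(abs(cpl$A_pp)), 1e-12)
  sol <- solve_pressure(cpl, p_in = 1)
  expect_true(all(sol$p >= -1e-12 & sol$p <= 1 + 1e-12))
})

test_that("interface pressures match a dense-matrix solve of the same system", {
  cpl <- small_coupling()
  nent <- nrow(cpl$entities)
  set.seed(42)
  a <- rnorm(nent)
  sol <- solve_pressure(cpl, accel = a, p_in = 1)
  p_dense <- solve(as.matrix(cpl$A_pp), cpl$b - as.matrix(cpl$A_pa) %*% a)
  expect_equal(sol$p, as.vector(p_dense), tolerance = 1e-9)
  expect_equal(sol$forces, as.vector(as.matrix(cpl$A_ap) %*% p_dense),
               tolerance = 1e-9)
})

test_that("interface force converges under mesh refinement", {
  sec <- default_section()
  sys <- small_system()
  ifc <- sys$interface
  force_of <- function(growth) {
    mesh <- build_fluid_mesh(chamber_width = 4, channel_height = 0.5,
                             slit_span = sec$bm_width_um * 1e-3,
                             slit_center = 2, refinement = 8, growth = growth,
                             bottom_faces = c(ifc$bottom$x0, tail(ifc$bottom$x1, 1)),
                             top_faces = c(ifc$top$x0, tail(ifc$top$x1, 1)))
    cpl <- assemble_coupling(mesh, ifc, depth = 0.01)
    a <- c(rep(1, nrow(ifc$bottom)), rep(0, nrow(ifc$top)))
    sum(solve_pressure(cpl, accel = a, p_in = 0)$forces[seq_len(nrow(ifc$bottom))])
  }
  f_coarse <- force_of(growth = 2.0)
  f_fine <- force_of(growth = 1.2)
  expect_lt(abs(f_coarse - f_fine) / abs(f_fine), 0.02)
})

test_that("an interface entity without facing cells is rejected", {
  ifc <- channel_interface()
  ifc$bottom$x0[1] <- 0.41
  ifc$bottom$x1[1] <- 0.45 # outside the meshed slit faces
  expect_error(assemble_coupling(channel_mesh(), ifc, depth = 0.01),
               "facing|tributary")
})

test_that("slab extrusion reduces to the planar model for uniform motion", {
  cpl1 <- small_coupling()
  sys <- small_system()
  sec <- default_section()
  ifc <- sys$interface
  mesh <- build_fluid_mesh(chamber_width = 2, channel_height = 0.5,
                           slit_span = sec$bm_width_um * 1e-3,
                           slit_center = 1, refinement = 4,
                           bottom_faces = c(ifc$bottom$x0, tail(ifc$bottom$x1, 1)),
                           top_faces = c(ifc$top$x0, tail(ifc$top$x1, 1)))
  cpl3 <- assemble_coupling(mesh, ifc, depth = 0.01, nsec = 3)
  nent <- nrow(cpl1$entities)
  set.seed(7)
  a1 <- rnorm(nent)
  f1 <- solve_pressure(cpl1, accel = a1, p_in = 1)$forces
  f3 <- solve_pressure(cpl3, accel = rep(a1, 3), p_in = 1)$forces
  # uniform longitudinal motion: every slice reproduces the planar solution
  expect_equal(f3[seq_len(nent)], f1, tolerance = 1e-8)
  expect_equal(f3[2 * nent + seq_len(nent)], f1, tolerance = 1e-8)
})

test_that("pressure fields export as delimited tables", {
  cpl <- small_coupling()
  sol <- solve_pressure(cpl, p_in = 1)
  tf <- tempfile(fileext = ".tsv")
  write_pressure_table(cpl, sol$p, tf)
  back <- utils::read.delim(tf)
  expect_equal(nrow(back), length(sol$p))
  expect_true(all(c("re_p", "im_p") %in% names(back)))
  unlink(tf)
})
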