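test_that("two-angle decomposition solves the beam-projection system", {
  # axis-aligned beams reproduce the components directly
  v <- decompose_two_angle(1 + 2i, 3 - 1i, 90, 0)
  expect_equal(v$d_r, 1 + 2i)
  expect_equal(v$d_t, 3 - 1i)
  # worked-example angles, solved by hand with Cramer's rule
  v2 <- decompose_two_angle(1, 1, -30, 13)
  expect_equal(Re(v2$d_r), -0.15886, tolerance = 1e-4)
  expect_equal(Re(v2$d_t), 1.06295, tolerance = 1e-4)
  expect_error(decompose_two_angle(1, 1, 25, 25), "singular|coincide")
})

test_that("compose-then-decompose is the identity over random states", {
  set.seed(91)
  for (k in 1:50) {
    truth <- motion_vector(complex(real = rnorm(1), imaginary = rnorm(1)),
                           complex(real = rnorm(1), imaginary = rnorm(1)))
    th <- sort(runif(2, -80, 80))
    if (abs(diff(th)) < 5) next
    d1 <- project_on_beam(truth, th[1])
    d2 <- project_on_beam(truth, th[2])
    back <- decompose_two_angle(d1, d2, th[1], th[2])
    expect_equal(back$d_r, truth$d_r, tolerance = 1e-12)
    expect_equal(back$d_t, truth$d_t, tolerance = 1e-12)
  }
})

test_that("ellipse major axis matches a brute-force trajectory maximization", {
  brute <- function(v) {
    t <- seq(0, 2 * pi, length.out = 4001)
    x <- Re(v$d_r * exp(1i * t)); y <- Re(v$d_t * exp(1i * t))
    i <- which.max(x^2 + y^2)
    amp <- sqrt(x[i]^2 + y[i]^2)
    th <- atan2(x[i], y[i]) * 180 / pi
    if (th <= -90) th <- th + 180
    if (th > 90) th <- th - 180
    list(amplitude = amp, theta_deg = th)
  }
  # pure transverse motion
  mj <- ellipse_major_axis(motion_vector(0, 2e-9))
  expect_equal(mj$amplitude, 2e-9)
  expect_equal(mj$theta_deg, 0)
  # in-phase oblique motion
  mj2 <- ellipse_major_axis(motion_vector(0.5e-9, 1e-9))
  expect_equal(mj2$theta_deg, atan(0.5) * 180 / pi, tolerance = 1e-6)
  expect_equal(mj2$amplitude, sqrt(1.25) * 1e-9, tolerance = 1e-12)
  # circular motion is flagged degenerate
  mj3 <- ellipse_major_axis(motion_vector(1e-9, 1i * 1e-9))
  expect_true(mj3$degenerate)
  expect_equal(mj3$amplitude, 1e-9, tolerance = 1e-9)
  expect_equal(mj3$theta_deg, 0)
  # zero vector
  mj0 <- ellipse_major_axis(motion_vector(0, 0))
  expect_true(mj0$degenerate)
  expect_equal(mj0$amplitude, 0)
  set.seed(17)
  for (k in 1:20) {
    v <- motion_vector(complex(real = rnorm(1), imaginary = rnorm(1)) * 1e-9,
                       complex(real = rnorm(1), imaginary = rnorm(1)) * 1e-9)
    mj <- ellipse_major_axis(v)
    bf <- brute(v)
    expect_equal(mj$amplitude, bf$amplitude, tolerance = 1e-5)
    if (!mj$degenerate) {
      dth <- abs(mj$theta_deg - bf$theta_deg)
      expect_lt(min(dth, abs(dth - 180)), 0.5)
    }
  }
})

test_that("hair-bundle deflection is the vector difference of TM and RL motion", {
  u <- motion_vector(1e-9, 2e-9)
  expect_equal(hair_bundle_deflection(u, u)$amplitude, 0)
  hb <- hair_bundle_deflection(u, motion_vector(0, 0))
  expect_equal(hb$amplitude, ellipse_major_axis(u)$amplitude)
  anti <- hair_bundle_deflection(u, motion_vector(-u$d_r, -u$d_t))
  expect_equal(anti$amplitude, 2 * ellipse_major_axis(u)$amplitude)
})

test_that("volume compliance integrates the deflection profile", {
  # triangular profile: area = base * peak / 2, by hand
  prof <- data.frame(r_um = c(0, 150, 300), disp_nm = c(0, 100, 0))
  vc <- volume_compliance(prof, pressure = 5.6)
  expect_equal(vc$volume_mm4_per_n, 0.5 * 100e-9 * 300e-6 / 5.6 * 1e12,
               tolerance = 1e-10)
  expect_equal(vc$volume_mm4_per_n, 2.679, tolerance = 1e-3)
  expect_equal(vc$peak_nm_per_pa, 100 / 5.6, tolerance = 1e-10)
  # linear in the profile
  prof2 <- prof; prof2$disp_nm <- prof$disp_nm * 3
  expect_equal(volume_compliance(prof2, pressure = 5.6)$volume_mm4_per_n,
               3 * vc$volume_mm4_per_n)
  zero <- data.frame(r_um = c(0, 150, 300), disp_nm = 0)
  expect_equal(volume_compliance(zero, pressure = 5.6)$volume_mm4_per_n, 0)
  expect_error(volume_compliance(prof, pressure = 0), "pressure")
})

test_that("FWHM fraction matches analytic profiles and is scale invariant", {
  r <- seq(0, 300, length.out = 2001)
  tri <- data.frame(r_um = r, disp_nm = 100 * (1 - abs(r - 150) / 150))
  expect_equal(fwhm_fraction(tri, width = 300)$fraction, 0.5, tolerance = 1e-3)
  # half-cosine spanning the full width crosses half-max at +/- W/3
  hc <- data.frame(r_um = r, disp_nm = cos(pi * (r - 150) / 300))
  expect_equal(fwhm_fraction(hc, width = 300)$fraction, 2 / 3, tolerance = 1e-3)
  hc2 <- hc; hc2$disp_nm <- hc$disp_nm * 42
  expect_equal(fwhm_fraction(hc2, width = 300)$fraction,
               fwhm_fraction(hc, width = 300)$fraction)
  # two disjoint half-max regions: the one containing the peak is used
  bim <- data.frame(r_um = r,
                    disp_nm = pmax(100 * (1 - abs(r - 80) / 40),
                                   60 * (1 - abs(r - 220) / 40), 0))
  out <- fwhm_fraction(bim, width = 300)
  expect_true(out$flag_multimodal)
  expect_lt(out$fwhm_um, 60)
})

test_that("contact stiffness matches an independent static computation and is monotone", {
  sys <- small_system()
  k <- contact_stiffness(sys)
  s <- (sys$nsec + 1) %/% 2
  node <- match("bm06", sys$section$nodes$label)
  d <- dof_index(sys, s, node, 2)
  f <- numeric(sys$ndof); f[d] <- 1e-9
  Kff <- as.matrix(sys$K[sys$free, sys$free])
  D <- 1 / sqrt(diag(Kff))
  u <- D * solve(Kff * (D %o% D), D * f[sys$free])
  expect_equal(k, 1e-9 / abs(u[match(d, sys$free)]) * 1e3, tolerance = 1e-6)
  sys_stiff <- assemble_structure(
    build_section(8.5, mult = c(bm_modulus_radial = 2, bm_modulus_long = 2)),
    nsec = 5)
  expect_gt(contact_stiffness(sys_stiff), k)
  expect_error(contact_stiffness(sys, node = "bm01"), "constrained")
})

test_that("a rigid tectorial membrane stops elongating", {
  f_soft <- default_field_1khz()
  tm_soft <- deformation_ratio_tm(f_soft, default_model()$system)
  base <- stiffness_ratios(default_section())
  mult <- c(tm_modulus_body = 100 / base$r_tm, tm_modulus_root = 100 / base$r_tm)
  model <- build_model(8.5, span_mm = 0.05, mult = mult)
  fld <- solve_frequency(model$system, model$coupling, 1000)
  tm <- deformation_ratio_tm(fld, model$system)
  expect_lt(tm$ratio_elong, 0.1)
  expect_lt(tm$ratio_elong, tm_soft$ratio_elong / 5)
})

test_that("a rigid Deiters cell stops deforming", {
  base <- stiffness_ratios(default_section())
  model <- build_model(8.5, span_mm = 0.05,
                       mult = c(dc_modulus = 100 / base$r_dc))
  fld <- solve_frequency(model$system, model$coupling, 1000)
  dc <- deformation_ratio_dc(fld, model$system)
  model1 <- build_model(8.5, span_mm = 0.05,
                        mult = c(dc_modulus = 1 / base$r_dc))
  fld1 <- solve_frequency(model1$system, model1$coupling, 1000)
  dc1 <- deformation_ratio_dc(fld1, model1$system)
  # rigid asymptote: the Deiters deformation collapses relative to r_DC = 1
  expect_lt(dc$delta_dc / dc1$delta_dc, 0.2)
  expect_lt(dc$ratio, dc1$ratio / 4)
})
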