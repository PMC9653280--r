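test_that("speckle pairs are reproducible and exactly shiftable", {
  a1 <- generate_speckle_pair(seed = 10)
  a2 <- generate_speckle_pair(seed = 10)
  expect_identical(a1$a, a2$a)
  expect_identical(a1$b, a2$b)
  z <- generate_speckle_pair(shift_nm = c(0, 0), noise_sd = 0, seed = 3)
  expect_equal(z$a, z$b, tolerance = 1e-12)
  expect_error(generate_speckle_pair(shift_nm = c(1e9, 0), n = 32), "extent")
})

test_that("noiseless scans decompose back to the truth", {
  truth <- data.frame(point = c("p1", "p2"),
                      d_r = c(1e-9 + 2e-9i, -3e-9 + 0.5e-9i),
                      d_t = c(2e-9 - 1e-9i, 1e-9 + 1e-9i),
                      stringsAsFactors = FALSE)
  sc <- generate_scan(truth, noise_frac = 0, seed = 5)
  mv <- decompose_scan(sc)
  expect_equal(mv$p1$d_r, truth$d_r[1], tolerance = 1e-12)
  expect_equal(mv$p2$d_t, truth$d_t[2], tolerance = 1e-12)
  sc1 <- generate_scan(truth, noise_frac = 0.1, seed = 9)
  sc2 <- generate_scan(truth, noise_frac = 0.1, seed = 9)
  expect_identical(sc1$sets[[1]]$d, sc2$sets[[1]]$d)
  expect_error(generate_scan(truth, theta1 = 10, theta2 = 10), "coincide")
})

test_that("scan noise is isotropic in the complex plane", {
  truth <- data.frame(point = sprintf("p%05d", 1:10000),
                      d_r = rep(1e-9 + 0i, 10000),
                      d_t = rep(0.5e-9 + 0i, 10000),
                      stringsAsFactors = FALSE)
  sc <- generate_scan(truth, noise_frac = 0.1, seed = 12)
  proj <- sin(-30 * pi / 180) * truth$d_r + cos(-30 * pi / 180) * truth$d_t
  noise <- sc$sets[[1]]$d - proj
  ph <- Arg(noise)
  # mean resultant length of uniform phases is O(1/sqrt(n))
  expect_lt(Mod(mean(exp(1i * ph))), 0.05)
  # relative magnitude close to the requested fraction
  expect_equal(sqrt(mean(Mod(noise)^2)) / Mod(proj[1]), 0.1, tolerance = 0.05)
})

test_that("landmark scatter reproduces the measured width spread", {
  mean_lm <- generate_landmarks(8.5, jitter = FALSE)
  expect_equal(mean_lm, default_landmarks(8.5))
  widths <- vapply(1:1000, function(i) {
    lm <- generate_landmarks(8.5, seed = i)
    lm$r_um[lm$label == "bm_lateral"]
  }, 0)
  expect_gt(sd(widths), 9)
  expect_lt(sd(widths), 15)
  expect_equal(mean(widths), 299, tolerance = 0.01)
  expect_identical(generate_landmarks(8.5, seed = 33),
                   generate_landmarks(8.5, seed = 33))
})

test_that("scans round-trip through the delimited container", {
  truth <- data.frame(point = c("a", "b"), r_um = c(1, 2), t_um = c(3, 4),
                      d_r = c(1e-9 + 2e-9i, 2e-9), d_t = c(0.5e-9, 1e-9 - 1e-9i),
                      stringsAsFactors = FALSE)
  sc <- generate_scan(truth, noise_frac = 0, seed = 1)
  tf <- tempfile(fileext = ".tsv")
  write_scan(sc, tf)
  back <- read_scan(tf)
  expect_equal(back$points, sc$points)
  expect_equal(back$sets[[1]]$d, sc$sets[[1]]$d, tolerance = 1e-12)
  expect_equal(back$sets[[2]]$theta, sc$sets[[2]]$theta)
  unlink(tf)
})
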