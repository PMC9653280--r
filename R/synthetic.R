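# Synthetic two-angle OCT scans, speckle image pairs and landmark sets with
# the statistical structure the analysis chain assumes, so every pipeline
# stage is testable without external data.

#' Synthetic band-limited speckle image pair with a known subpixel shift
#'
#' Generates a Gaussian-correlated random speckle texture; the second image
#' is the exactly (Fourier-)shifted first image. Independent Gaussian sensor
#' noise is added to both. Rows correspond to the optical (transverse) axis,
#' columns to the lateral axis.
#'
#' @param shift_nm Shift vector `c(row_nm, col_nm)` in nanometres.
#' @param pixel_pitch_um Pixel pitch `c(row, col)` in um/px (defaults 1.9
#'   optical, 0.7 lateral).
#' @param n Image size in pixels (n x n).
#' @param corr_px Speckle correlation length in pixels.
#' @param noise_sd Sensor noise standard deviation relative to unit image SD.
#' @param seed Random seed (generator is a pure function of its arguments).
#' @return List with matrices `a`, `b`, the true `shift_px`, and the inputs.
#' @export
generate_speckle_pair <- function(shift_nm = c(100, 0),
                                  pixel_pitch_um = c(1.9, 0.7), n = 128,
                                  corr_px = 2, noise_sd = 0.05, seed = 1) {
  shift_px <- shift_nm / (pixel_pitch_um * 1e3)
  if (any(abs(shift_px) >= n / 2)) stop("generate_speckle_pair: shift exceeds image extent")
  set.seed(seed)
  W <- matrix(stats::rnorm(n * n), n, n)
  FW <- stats::fft(W)
  fr <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  H <- exp(-2 * pi^2 * corr_px^2 * (outer(fr^2, fr^2, `+`)) / n^2)
  Fa <- FW * H
  a <- Re(stats::fft(Fa, inverse = TRUE)) / (n * n)
  a <- a / stats::sd(a)
  ramp <- exp(-2i * pi * (outer(fr * shift_px[1], rep(1, n)) +
                          outer(rep(1, n), fr * shift_px[2])) / n)
  b <- Re(stats::fft(Fa * ramp, inverse = TRUE)) / (n * n)
  b <- b / stats::sd(b)
  if (noise_sd > 0) {
    a <- a + stats::rnorm(n * n, sd = noise_sd)
    b <- b + stats::rnorm(n * n, sd = noise_sd)
  }
  list(a = a, b = b, shift_px = shift_px, shift_nm = shift_nm,
       pixel_pitch_um = pixel_pitch_um, noise_sd = noise_sd, seed = seed)
}

#' Synthetic two-angle scan of known in-plane motion
#'
#' Projects true complex in-plane motion vectors onto two beam directions
#' and adds independent complex Gaussian noise of the given relative
#' magnitude (isotropic in the complex plane), emulating two spatial-sweep
#' acquisitions of the same section at different optical-head orientations.
#'
#' @param truth Data frame with columns `point` (label), `d_r`, `d_t`
#'   (complex, m); optionally `r_um`, `t_um` coordinates.
#' @param theta1,theta2 Beam angles in degrees (must differ); defaults are
#'   the worked-example pair (-30, 13).
#' @param noise_frac Noise magnitude relative to each point's beam-projected
#'   amplitude.
#' @param freq_hz Stimulus frequency recorded in the object.
#' @param landmarks Optional landmark table carried along.
#' @param seed Random seed.
#' @return Object of class `two_angle_scan`.
#' @export
generate_scan <- function(truth, theta1 = -30, theta2 = 13, noise_frac = 0.1,
                          freq_hz = 1000, landmarks = NULL, seed = 1) {
  if (isTRUE(all.equal(theta1 %% 180, theta2 %% 180))) {
    stop("generate_scan: beam angles coincide")
  }
  if (noise_frac < 0) stop("generate_scan: noise_frac must be >= 0")
  set.seed(seed)
  proj <- function(theta) {
    d <- sin(deg2rad(theta)) * truth$d_r + cos(deg2rad(theta)) * truth$d_t
    if (noise_frac > 0) {
      np <- length(d)
      d <- d + noise_frac * Mod(d) *
        complex(real = stats::rnorm(np, sd = 1 / sqrt(2)),
                imaginary = stats::rnorm(np, sd = 1 / sqrt(2)))
    }
    d
  }
  sets <- list(list(theta = theta1, d = proj(theta1)),
               list(theta = theta2, d = proj(theta2)))
  structure(list(points = truth$point, sets = sets,
                 coords = truth[intersect(c("r_um", "t_um"), names(truth))],
                 freq_hz = freq_hz, noise_frac = noise_frac,
                 landmarks = landmarks, seed = seed),
            class = "two_angle_scan")
}

#' Decompose a two-angle scan into per-point motion vectors
#'
#' @param scan A `two_angle_scan`.
#' @return Named list of `motion_vector`s, one per point.
#' @export
decompose_scan <- function(scan) {
  out <- lapply(seq_along(scan$points), function(i) {
    decompose_two_angle(scan$sets[[1]]$d[i], scan$sets[[2]]$d[i],
                        scan$sets[[1]]$theta, scan$sets[[2]]$theta)
  })
  names(out) <- scan$points
  out
}

#' Extract a scan truth table from a model displacement field
#'
#' @param field A `displacement_field`.
#' @param system The `ooc_system`.
#' @param points Node labels to sample.
#' @param s Section index (default middle).
#' @return Data frame suitable for [generate_scan()].
#' @export
scan_truth_from_field <- function(field, system,
                                  points = c("limbus", "tm_hb2", "ohc2_apex",
                                             "ohc1_apex", "ohc1_cup", "bm06"),
                                  s = NULL) {
  if (is.null(s)) s <- (system$nsec + 1) %/% 2
  nodes <- system$section$nodes
  rows <- lapply(points, function(p) {
    u <- field_at(field, system, s, p)
    i <- match(p, nodes$label)
    data.frame(point = p, r_um = nodes$r[i], t_um = nodes$t[i],
               d_r = u[["u_r"]], d_t = u[["u_t"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Synthetic landmark sets with anatomic scatter
#'
#' Mean anatomy from [default_landmarks()] plus independent Gaussian jitter
#' on every coordinate, scaled so that the basilar-membrane width spread
#' matches the measured preparation-to-preparation scatter (SD ~12 um at
#' x = 8.5 mm).
#'
#' @param x Longitudinal position in mm.
#' @param jitter Logical; `FALSE` returns the mean anatomy exactly.
#' @param sd_um Per-coordinate jitter SD in um.
#' @param seed Random seed.
#' @return Landmark data frame.
#' @export
generate_landmarks <- function(x, jitter = TRUE, sd_um = 12, seed = 1) {
  lm <- default_landmarks(x)
  if (jitter) {
    set.seed(seed)
    lm$r_um <- lm$r_um + stats::rnorm(nrow(lm), sd = sd_um)
    lm$t_um <- lm$t_um + stats::rnorm(nrow(lm), sd = sd_um)
  }
  lm
}

#' @export
print.two_angle_scan <- function(x, ...) {
  cat(sprintf("two_angle_scan: %d points, angles %g / %g deg, %g Hz, noise %g\n",
              length(x$points), x$sets[[1]]$theta, x$sets[[2]]$theta,
              x$freq_hz, x$noise_frac))
  invisible(x)
}
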