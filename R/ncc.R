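# Subpixel displacement estimation by normalized cross-correlation (NCC),
# as used on consecutive B-scan images under stepped hydrostatic pressure.
# The global estimator computes the full cross-correlation via FFT and
# refines the peak with a locally upsampled discrete Fourier transform; the
# per-pixel estimator applies windowed NCC with parabolic subpixel
# refinement around each pixel.

# cyclic cross-correlation surface of two equally sized matrices (mean
# removed), peak at the shift of b relative to a
xcorr_fft <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  Re(stats::fft(Conj(Fa) * Fb, inverse = TRUE)) / length(a)
}

# upsampled cross-correlation in a small neighborhood of (r0, c0) (0-based
# cyclic shifts), by matrix-multiply DFT
upsampled_peak <- function(Fcross, r0, c0, usf, radius = 1.5) {
  nr <- nrow(Fcross); nc <- ncol(Fcross)
  fr <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1)) # FFT frequencies
  fc <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1))
  rows <- r0 + seq(-radius, radius, by = 1 / usf)
  cols <- c0 + seq(-radius, radius, by = 1 / usf)
  Er <- exp(2i * pi * outer(rows, fr) / nr)   # length(rows) x nr
  Ec <- exp(2i * pi * outer(fc, cols) / nc)   # nc x length(cols)
  CC <- Re(Er %*% Fcross %*% Ec) / length(Fcross)
  ij <- which(CC == max(CC), arr.ind = TRUE)[1, ]
  c(rows[ij[1]], cols[ij[2]])
}

#' Global subpixel shift between two images
#'
#' Estimates the rigid translation of `image_b` relative to `image_a` by
#' FFT cross-correlation with upsampled-DFT peak refinement.
#'
#' @param image_a,image_b Numeric matrices of identical dimensions.
#' @param upsample Upsampling factor for the subpixel refinement (>= 1).
#' @return Numeric `c(dy, dx)` shift in pixels (row, column), such that
#'   `b(y, x) ~ a(y - dy, x - dx)`.
#' @export
ncc_shift <- function(image_a, image_b, upsample = 100) {
  stopifnot(all(dim(image_a) == dim(image_b)), upsample >= 1)
  a <- image_a - mean(image_a); b <- image_b - mean(image_b)
  Fcross <- Conj(stats::fft(a)) * stats::fft(b)
  cc <- Re(stats::fft(Fcross, inverse = TRUE)) / length(a)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  r0 <- pk[1] - 1; c0 <- pk[2] - 1
  nr <- nrow(a); nc <- ncol(a)
  if (r0 > nr / 2) r0 <- r0 - nr
  if (c0 > nc / 2) c0 <- c0 - nc
  if (upsample > 1) {
    sh <- upsampled_peak(Fcross, r0, c0, upsample)
  } else {
    sh <- c(r0, c0)
  }
  c(dy = sh[1], dx = sh[2])
}

#' Per-pixel displacement field by windowed normalized cross-correlation
#'
#' For each evaluated pixel, the window around it in `image_a` is compared
#' against shifted windows in `image_b` over a small integer search range;
#' the NCC peak is refined to subpixel precision by separable parabolic
#' interpolation (or by upsampled NCC of the window when `upsample > 1`
#' behaves equivalently; parabolic refinement is used here). Pixels whose
#' window has (near) zero variance are flagged invalid rather than raising
#' an error.
#'
#' @param image_a,image_b Numeric matrices of identical dimensions.
#' @param window Odd window size in pixels.
#' @param upsample Subpixel refinement factor (>= 1; 1 disables refinement).
#' @param search Integer search radius in pixels.
#' @param stride Evaluate every `stride`-th pixel in each direction.
#' @param pixel_pitch Optional `c(row, col)` pitch in um/px; when given, the
#'   output gains displacement columns in nm.
#' @return Data frame with `row`, `col`, `dy_px`, `dx_px`, `valid` (and
#'   `dy_nm`, `dx_nm` when `pixel_pitch` is given).
#' @export
ncc_displacement <- function(image_a, image_b, window = 15, upsample = 10,
                             search = 3, stride = 1, pixel_pitch = NULL) {
  stopifnot(all(dim(image_a) == dim(image_b)))
  if (window %% 2 != 1) stop("ncc_displacement: window must be odd")
  if (upsample < 1) stop("ncc_displacement: upsample must be >= 1")
  hw <- (window - 1) / 2
  nr <- nrow(image_a); nc <- ncol(image_a)
  margin <- hw + search
  rows <- seq(margin + 1, nr - margin, by = stride)
  cols <- seq(margin + 1, nc - margin, by = stride)
  out <- vector("list", length(rows) * length(cols))
  k <- 0
  shifts <- -search:search
  parab <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) return(0) # not a local max; no refinement
    delta <- 0.5 * (cm - cp) / den
    max(min(delta, 0.5), -0.5)
  }
  for (r in rows) {
    wa_rows <- (r - hw):(r + hw)
    for (cl in cols) {
      wa <- image_a[wa_rows, (cl - hw):(cl + hw)]
      va <- stats::sd(wa)
      k <- k + 1
      if (!is.finite(va) || va < 1e-12 * (abs(mean(wa)) + 1)) {
        out[[k]] <- c(r, cl, NA, NA, 0)
        next
      }
      wa0 <- (wa - mean(wa)) / va
      cc <- matrix(-Inf, length(shifts), length(shifts))
      for (si in seq_along(shifts)) {
        for (sj in seq_along(shifts)) {
          wb <- image_b[wa_rows + shifts[si], (cl - hw + shifts[sj]):(cl + hw + shifts[sj])]
          vb <- stats::sd(wb)
          if (!is.finite(vb) || vb < 1e-15) next
          cc[si, sj] <- mean(wa0 * (wb - mean(wb)) / vb)
        }
      }
      pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      dy <- shifts[pk[1]]; dx <- shifts[pk[2]]
      if (upsample > 1 && pk[1] > 1 && pk[1] < nrow(cc) &&
          pk[2] > 1 && pk[2] < ncol(cc) && all(is.finite(cc))) {
        dy <- dy + parab(cc[pk[1] - 1, pk[2]], cc[pk[1], pk[2]], cc[pk[1] + 1, pk[2]])
        dx <- dx + parab(cc[pk[1], pk[2] - 1], cc[pk[1], pk[2]], cc[pk[1], pk[2] + 1])
      }
      out[[k]] <- c(r, cl, dy, dx, 1)
    }
  }
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c("row", "col", "dy_px", "dx_px", "valid")
  res$valid <- res$valid > 0
  if (!is.null(pixel_pitch)) {
    res$dy_nm <- res$dy_px * pixel_pitch[1] * 1e3
    res$dx_nm <- res$dx_px * pixel_pitch[2] * 1e3
  }
  res
}
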