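# Plain-text export/import of assembled systems (MatrixMarket sparse
# triplets plus a JSON sidecar for the DOF map) and of two-angle scans
# (flat delimited tables).

#' Export an assembled system
#'
#' Writes `M`, `C`, `K` as MatrixMarket coordinate (sparse triplet) files
#' and a JSON sidecar with the DOF map and metadata, under a common prefix.
#'
#' @param system An `ooc_system`.
#' @param prefix Path prefix; files `<prefix>_M.mtx`, `<prefix>_C.mtx`,
#'   `<prefix>_K.mtx` and `<prefix>.json` are created.
#' @return The sidecar path, invisibly.
#' @export
write_system <- function(system, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  for (nm in c("M", "C", "K")) {
    Matrix::writeMM(as(as(system[[nm]], "generalMatrix"), "TsparseMatrix"),
                    paste0(prefix, "_", nm, ".mtx"))
  }
  sidecar <- list(
    x_mm = system$x, nsec = system$nsec, spacing_um = system$spacing_um,
    ndof = system$ndof, dofs_per_node = 4,
    dof_order = c("radial", "transverse", "longitudinal", "rotation"),
    node_labels = system$section$nodes$label,
    fixed_dofs = which(system$fixed),
    rayleigh = list(alpha = system$alpha, beta = system$beta)
  )
  path <- paste0(prefix, ".json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import system matrices written by [write_system()]
#'
#' @param prefix Path prefix used at export.
#' @return List with sparse `M`, `C`, `K` and the `sidecar` metadata.
#' @export
read_system <- function(prefix) {
  out <- lapply(c(M = "M", C = "C", K = "K"), function(nm) {
    as(Matrix::readMM(paste0(prefix, "_", nm, ".mtx")), "CsparseMatrix")
  })
  out$sidecar <- jsonlite::read_json(paste0(prefix, ".json"),
                                     simplifyVector = TRUE)
  out
}

#' Export a two-angle scan as a flat delimited table
#'
#' One row per (point, set): point label, coordinates, beam angle, set id,
#' and the complex displacement split into real and imaginary parts.
#'
#' @param scan A `two_angle_scan`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  rows <- do.call(rbind, lapply(seq_along(scan$sets), function(k) {
    st <- scan$sets[[k]]
    data.frame(point = scan$points,
               r_um = if (ncol(scan$coords)) scan$coords$r_um else NA,
               t_um = if (ncol(scan$coords) > 1) scan$coords$t_um else NA,
               set = k, theta_deg = st$theta,
               re_d = Re(st$d), im_d = Im(st$d), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import a two-angle scan written by [write_scan()]
#'
#' @param path Path to the delimited table.
#' @param freq_hz Stimulus frequency to record.
#' @return A `two_angle_scan`.
#' @export
read_scan <- function(path, freq_hz = NA) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sets <- lapply(sort(unique(df$set)), function(k) {
    dk <- df[df$set == k, ]
    list(theta = dk$theta_deg[1], d = complex(real = dk$re_d,
                                              imaginary = dk$im_d))
  })
  d1 <- df[df$set == df$set[1], ]
  structure(list(points = d1$point, sets = sets,
                 coords = d1[intersect(c("r_um", "t_um"), names(d1))],
                 freq_hz = freq_hz, noise_frac = NA, landmarks = NULL,
                 seed = NA),
            class = "two_angle_scan")
}
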