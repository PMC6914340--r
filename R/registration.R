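#' Affine channel registration
#'
#' Dual-color single-molecule experiments image the two spectral channels on
#' different halves of the camera; before co-localization the channels must be
#' brought into a common coordinate frame. Registration is an affine transform
#' fitted by least squares to fiducial beads visible in both channels; by
#' convention channel B is mapped into channel A's frame.
#'
#' @param linear 2x2 numeric matrix (linear part).
#' @param offset length-2 numeric vector (nm).
#' @param rms_nm residual root-mean-square of the fit (nm), if known.
#' @return an `affine2d` object.
#' @export
affine2d <- function(linear = diag(2), offset = c(0, 0), rms_nm = NA_real_) {
  linear <- matrix(as.numeric(linear), 2, 2)
  offset <- as.numeric(offset)
  if (length(offset) != 2 || any(!is.finite(linear)) || any(!is.finite(offset)))
    stopf("affine2d requires a finite 2x2 linear part and length-2 offset")
  if (abs(det(linear)) <= 1e-12)
    stopf("affine transform is singular (|det| <= 1e-12)")
  structure(list(linear = linear, offset = offset, rms_nm = rms_nm),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("affine2d transform (nm):\n")
  m <- cbind(x$linear, x$offset)
  dimnames(m) <- list(c("x'", "y'"), c("x", "y", "offset"))
  print(round(m, 6))
  if (is.finite(x$rms_nm)) cat(sprintf("fit residual RMS: %.3f nm\n", x$rms_nm))
  invisible(x)
}

#' Fit an affine transform to matched fiducial bead positions
#'
#' Least-squares fit of the transform T minimizing `sum(|T(B_i) - A_i|^2)`
#' over matched bead pairs, i.e. the transform that maps channel B
#' coordinates into channel A's frame. Exact (machine precision) on noiseless
#' affine-related point sets.
#'
#' @param bead_pairs data.frame with columns `xa`, `ya`, `xb`, `yb` (nm), one
#'   row per bead; e.g. from [simulate_fiducial_beads()].
#' @return an [affine2d()] with the residual RMS of the fit (per coordinate,
#'   nm; converges to the bead localization noise SD for many beads).
#' @export
fit_affine <- function(bead_pairs) {
  req <- c("xa", "ya", "xb", "yb")
  if (!all(req %in% names(bead_pairs)))
    stopf("bead_pairs must have columns %s", paste(req, collapse = ", "))
  n <- nrow(bead_pairs)
  if (n < 3) stopf("affine registration needs at least 3 bead pairs, got %d", n)
  X <- cbind(bead_pairs$xb, bead_pairs$yb, 1)
  if (qr(X)$rank < 3)
    stopf("bead configuration is collinear; affine fit is degenerate")
  Y <- cbind(bead_pairs$xa, bead_pairs$ya)
  beta <- qr.solve(X, Y)                      # 3 x 2: rows xb, yb, 1
  linear <- t(beta[1:2, ])
  offset <- as.numeric(beta[3, ])
  resid <- Y - X %*% beta
  rms <- sqrt(mean(resid^2))     # per-coordinate residual RMS
  affine2d(linear, offset, rms_nm = rms)
}

#' Apply an affine transform to coordinates
#'
#' Maps the `x_nm`/`y_nm` coordinates of a localization table (or a two-column
#' matrix) through the transform; all other columns are untouched. Tables get
#' a `registered` attribute so downstream co-localization can verify that the
#' channels share a coordinate frame.
#'
#' @param table a [localization_table()] or a two-column matrix of nm
#'   coordinates.
#' @param transform an [affine2d()].
#' @return object of the same shape with transformed coordinates.
#' @export
apply_transform <- function(table, transform) {
  if (!inherits(transform, "affine2d")) stopf("'transform' must be an affine2d")
  if (is.matrix(table)) {
    return(t(transform$linear %*% t(table) + transform$offset))
  }
  xy <- t(transform$linear %*% t(cbind(table$x_nm, table$y_nm)) + transform$offset)
  table$x_nm <- xy[, 1]
  table$y_nm <- xy[, 2]
  attr(table, "registered") <- TRUE
  table
}

#' Invert an affine transform
#' @param transform an [affine2d()].
#' @return the inverse [affine2d()].
#' @export
invert_transform <- function(transform) {
  li <- solve(transform$linear)
  affine2d(li, as.numeric(-li %*% transform$offset), rms_nm = transform$rms_nm)
}

#' Serialize / read an affine transform as a small text file
#'
#' Six coefficients plus the residual RMS, one `key = value` per line.
#' @param transform an [affine2d()].
#' @param path file path.
#' @return `write_transform`: the path invisibly; `read_transform`: an
#'   [affine2d()].
#' @export
write_transform <- function(transform, path) {
  lines <- c(
    sprintf("a11 = %.17g", transform$linear[1, 1]),
    sprintf("a12 = %.17g", transform$linear[1, 2]),
    sprintf("a21 = %.17g", transform$linear[2, 1]),
    sprintf("a22 = %.17g", transform$linear[2, 2]),
    sprintf("tx = %.17g", transform$offset[1]),
    sprintf("ty = %.17g", transform$offset[2]),
    sprintf("rms_nm = %.17g", transform$rms_nm)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  kv <- utils::read.table(path, sep = "=", strip.white = TRUE,
                          col.names = c("key", "value"))
  v <- stats::setNames(as.numeric(kv$value), trimws(kv$key))
  affine2d(matrix(c(v["a11"], v["a21"], v["a12"], v["a22"]), 2, 2),
           c(v["tx"], v["ty"]), rms_nm = unname(v["rms_nm"]))
}
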