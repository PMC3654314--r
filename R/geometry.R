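## Coordinate conventions used throughout:
##   incident beam along +x, rotation (vertical) axis +z, the in-plane
##   diffraction angle 2theta_B opens toward +y; phi is a right-handed
##   rotation about +z.  Angles are degrees at every interface, radians
##   internally.  Detector channels are 0-based and fractional.

DEG <- pi / 180

deg2rad <- function(x) x * DEG
rad2deg <- function(x) x / DEG

#' Detector geometry description
#'
#' Bundles the machine constants of a curved position-sensitive detector:
#' the sample-to-detector radius, channel counts, the channel-to-angle
#' conversion factors, the origin channel of the detector arm, the small
#' rotation (shear) between channel axes and the laboratory axes, and the
#' active channel window.
#'
#' The channel-to-angle model is
#' \deqn{2\theta_B = 2\theta_c + c_x (X - X_0 - s (Y - Y_0))}
#' \deqn{\chi_d = \arctan\{c_y ((Y - Y_0) + s (X - X_0))\}}
#' i.e. the slope \eqn{s} is a small rotation of the channel axes, so a
#' misaligned detector draws tilted layer lines; this is what makes the
#' slope measurable from a full-rotation calibration scan.  Setting
#' \code{chi_mode = "linear"} replaces the arctangent by its small-angle
#' form, for cross-checks against a purely linear vertical conversion.
#'
#' @param L sample-to-detector radius in mm.
#' @param n_x,n_y number of channels in X (curved, horizontal) and Y
#'   (vertical).
#' @param c_x conversion factor, degrees of 2theta_B per X channel.
#' @param c_y conversion factor, tangent units per Y channel
#'   (vertical pitch / L).
#' @param x0,y0 origin point in fractional channels: the channel hit by a
#'   ray at \code{2theta_B = arm_angle}, \code{chi_d = 0}.
#' @param xy_slope dimensionless coupling (rotation) between the X and Y
#'   channel axes.
#' @param arm_angle nominal detector arm position 2theta_c in degrees.
#' @param active_window numeric length-4 vector
#'   \code{(x_min, y_min, x_max, y_max)} in channels.
#' @param chi_mode \code{"tan"} (default) or \code{"linear"}.
#' @return An object of class \code{"detector_geometry"}.
#' @examples
#' geom <- detector_geometry()   # HANARO-like default profile
#' channels_to_angles(geom$x0 + 100, geom$y0, geom)
#' @export
detector_geometry <- function(L = 530, n_x = 512, n_y = 512,
                              c_x = 0.2614, c_y = 0.003917,
                              x0 = 181.50, y0 = 94.135,
                              xy_slope = 0.0041, arm_angle = 40,
                              active_window = c(60, 9.06, 460, 269.60),
                              chi_mode = c("tan", "linear")) {
  chi_mode <- match.arg(chi_mode)
  stopifnot(L > 0, c_x > 0, c_y > 0, n_x >= 1, n_y >= 1)
  aw <- as.numeric(active_window)
  if (length(aw) != 4 || aw[1] >= aw[3] || aw[2] >= aw[4])
    stop("active_window must be (x_min, y_min, x_max, y_max) with min < max")
  if (aw[1] < 0 || aw[2] < 0 || aw[3] > n_x || aw[4] > n_y)
    stop("active_window must lie inside [0, n_x) x [0, n_y)")
  structure(list(L = L, n_x = as.integer(n_x), n_y = as.integer(n_y),
                 c_x = c_x, c_y = c_y, x0 = x0, y0 = y0,
                 xy_slope = xy_slope, arm_angle = arm_angle,
                 active_window = aw, chi_mode = chi_mode),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat("Curved-PSD geometry\n")
  cat(sprintf("  radius L: %g mm, face %d x %d channels\n", x$L, x$n_x, x$n_y))
  cat(sprintf("  c_x: %g deg/channel, c_y: %g /channel (%s), slope: %g\n",
              x$c_x, x$c_y, x$chi_mode, x$xy_slope))
  cat(sprintf("  origin (X0, Y0): (%g, %g), arm 2theta_c: %g deg\n",
              x$x0, x$y0, x$arm_angle))
  cat(sprintf("  active window: (%g, %g)-(%g, %g)\n",
              x$active_window[1], x$active_window[2],
              x$active_window[3], x$active_window[4]))
  invisible(x)
}

#' Rotation-scan configuration
#'
#' @param wavelength neutron wavelength in Angstrom.
#' @param phi_start first frame's starting phi in degrees.
#' @param delta_phi angular increment per frame in degrees.
#' @param n_frames number of frames.
#' @param omega_offset fixed omega offset in degrees (two-axis mode,
#'   chi = 0); kept for provenance, not used by the transforms.
#' @return An object of class \code{"scan_config"}.
#' @export
scan_config <- function(wavelength, phi_start = 0, delta_phi = 0.2,
                        n_frames = round(360 / delta_phi),
                        omega_offset = 0) {
  stopifnot(wavelength > 0, delta_phi > 0, n_frames >= 0)
  if (n_frames * delta_phi > 360 + 1e-6)
    stop("scan range n_frames * delta_phi exceeds 360 degrees")
  structure(list(wavelength = wavelength, phi_start = phi_start,
                 delta_phi = delta_phi, n_frames = as.integer(n_frames),
                 omega_offset = omega_offset),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf(
    "Rotation scan: lambda %g A, phi %g..%g deg in %d frames of %g deg\n",
    x$wavelength, x$phi_start, x$phi_start + x$n_frames * x$delta_phi,
    x$n_frames, x$delta_phi))
  invisible(x)
}

## TRUE when the scan closes the full circle (phi wraps around).
scan_full_circle <- function(scan)
  isTRUE(abs(scan$n_frames * scan$delta_phi - 360) < 1e-6)

#' Unit-cell parameters
#'
#' @param a,b,c cell edges in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @return An object of class \code{"xtal_cell"} (a named numeric vector).
#' @examples
#' cell_volume(xtal_cell(5.6402, 5.6402, 5.6402))   # NaCl
#' @export
xtal_cell <- function(a, b = a, c = a, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(p))) stop("non-finite cell parameter")
  if (any(p[1:3] <= 0)) stop("cell edges must be positive")
  if (any(p[4:6] <= 0 | p[4:6] >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  if (cell_discriminant(p) <= 0)
    stop("degenerate cell: triclinic volume discriminant is not positive")
  structure(p, class = "xtal_cell")
}

cell_discriminant <- function(p) {
  ca <- cos(deg2rad(p[["alpha"]])); cb <- cos(deg2rad(p[["beta"]]))
  cg <- cos(deg2rad(p[["gamma"]]))
  1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
}

#' @export
print.xtal_cell <- function(x, ...) {
  cat(sprintf("Cell: a %.4f b %.4f c %.4f A, alpha %.3f beta %.3f gamma %.3f deg, V %.2f A^3\n",
              x[["a"]], x[["b"]], x[["c"]], x[["alpha"]], x[["beta"]],
              x[["gamma"]], cell_volume(x)))
  invisible(x)
}

#' Unit-cell volume
#'
#' \eqn{V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma
#' +2\cos\alpha\cos\beta\cos\gamma}}.
#'
#' @param cell an [xtal_cell()].
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  disc <- cell_discriminant(cell)
  if (disc <= 0) stop("degenerate cell: non-positive volume discriminant")
  cell[["a"]] * cell[["b"]] * cell[["c"]] * sqrt(disc)
}

## Direct-basis matrix (columns a, b, c) in the standard crystallographic
## frame: a along x, b in the xy plane.
cell_basis <- function(cell) {
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  al <- deg2rad(cell[["alpha"]]); be <- deg2rad(cell[["beta"]])
  ga <- deg2rad(cell[["gamma"]])
  v <- c(cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(1 - cos(be)^2 - v^2, 0))
  cbind(c(a, 0, 0),
        c(b * cos(ga), b * sin(ga), 0),
        c(cc * cos(be), cc * v, cc * cz))
}

## Busing-Levy style B matrix (no 2*pi): q = B %*% hkl has |q| = 1/d.
bl_matrix <- function(cell) {
  A <- cell_basis(cell)
  t(solve(A))           # reciprocal basis as columns
}

#' Reciprocal lattice spacing
#'
#' d-spacing of a reflection from the general triclinic reciprocal metric.
#'
#' @param cell an [xtal_cell()].
#' @param hkl integer (or real) Miller indices, length-3 vector or a
#'   3-column matrix with one reflection per row.
#' @return d in Angstrom (vector if `hkl` is a matrix).
#' @examples
#' d_spacing(xtal_cell(5.6402), c(2, 2, 0))
#' @export
d_spacing <- function(cell, hkl) {
  B <- bl_matrix(cell)
  h <- if (is.matrix(hkl)) t(hkl) else matrix(hkl, nrow = 3)
  if (any(colSums(h^2) == 0)) stop("hkl = (0,0,0) has no d-spacing")
  q <- B %*% h
  1 / sqrt(colSums(q^2))
}

## Cell parameters (and B) from a UB or B matrix via the reciprocal metric.
cell_from_ub <- function(ub) {
  Gstar <- t(ub) %*% ub
  A <- solve(ub)                       # rows are direct basis vectors
  a <- sqrt(sum(A[1, ]^2)); b <- sqrt(sum(A[2, ]^2)); cc <- sqrt(sum(A[3, ]^2))
  al <- rad2deg(acos(sum(A[2, ] * A[3, ]) / (b * cc)))
  be <- rad2deg(acos(sum(A[1, ] * A[3, ]) / (a * cc)))
  ga <- rad2deg(acos(sum(A[1, ] * A[2, ]) / (a * b)))
  xtal_cell(a, b, cc, al, be, ga)
}

#' Convert detector channels to diffraction angles
#'
#' Applies the channel-to-angle model of [detector_geometry()]: the
#' in-plane angle \code{2theta_B} grows linearly with the slope-corrected
#' X channel, and the elevation \code{chi_d} follows the arctangent of the
#' slope-corrected Y channel (the detector is curved horizontally and flat
#' vertically).
#'
#' @param x,y fractional channel coordinates (vectors allowed).
#' @param geom a [detector_geometry()].
#' @return A data.frame with columns \code{two_theta_b}, \code{chi_d}
#'   (degrees) and \code{in_window} (logical flag; points outside the
#'   active window are converted, not rejected).
#' @export
channels_to_angles <- function(x, y, geom) {
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite channel coordinates")
  dx <- x - geom$x0; dy <- y - geom$y0
  s <- geom$xy_slope
  u <- dx - s * dy
  v <- dy + s * dx
  tth <- geom$arm_angle + geom$c_x * u
  chi <- if (geom$chi_mode == "tan") rad2deg(atan(geom$c_y * v))
         else rad2deg(geom$c_y * v)
  aw <- geom$active_window
  data.frame(two_theta_b = tth, chi_d = chi,
             in_window = x >= aw[1] & x <= aw[3] & y >= aw[2] & y <= aw[4])
}

#' Convert diffraction angles to detector channels
#'
#' Exact algebraic inverse of [channels_to_angles()].
#'
#' @param two_theta_b,chi_d angles in degrees (vectors allowed).
#' @param geom a [detector_geometry()].
#' @param check if TRUE (default) error when the position falls outside the
#'   full detector face; set FALSE to obtain off-face coordinates.
#' @return A data.frame with columns \code{x}, \code{y}, \code{on_face},
#'   \code{in_window}.
#' @export
angles_to_channels <- function(two_theta_b, chi_d, geom, check = TRUE) {
  u <- (two_theta_b - geom$arm_angle) / geom$c_x
  v <- if (geom$chi_mode == "tan") tan(deg2rad(chi_d)) / geom$c_y
       else deg2rad(chi_d) / geom$c_y
  s <- geom$xy_slope
  dx <- (u + s * v) / (1 + s^2)
  dy <- (v - s * u) / (1 + s^2)
  x <- geom$x0 + dx; y <- geom$y0 + dy
  on_face <- x >= 0 & x <= geom$n_x - 1 & y >= 0 & y <= geom$n_y - 1
  if (check && any(!on_face)) {
    i <- which(!on_face)[1]
    stop(sprintf("angle (%g, %g) deg maps off the detector face at (%.2f, %.2f)",
                 two_theta_b[i], chi_d[i], x[i], y[i]))
  }
  aw <- geom$active_window
  data.frame(x = x, y = y, on_face = on_face,
             in_window = x >= aw[1] & x <= aw[3] & y >= aw[2] & y <= aw[4])
}

#' Laboratory scattering vector of a detector direction
#'
#' With the incident unit vector along +x and the rotation axis +z, the
#' diffracted unit vector is
#' \eqn{\hat s = (\cos\chi_d \cos 2\theta_B, \cos\chi_d \sin 2\theta_B,
#' \sin\chi_d)} and \eqn{Q = (\hat s - \hat x)/\lambda} (units 1/Angstrom,
#' no factor \eqn{2\pi}).  The total scattering angle obeys
#' \eqn{\cos 2\theta = \cos\chi_d \cos 2\theta_B}.
#'
#' @param two_theta_b,chi_d angles in degrees (vectors allowed).
#' @param wavelength wavelength in Angstrom.
#' @return A 3-column matrix of laboratory Q vectors (one row per input).
#' @export
scattering_vector_lab <- function(two_theta_b, chi_d, wavelength) {
  stopifnot(wavelength > 0)
  tb <- deg2rad(two_theta_b); ch <- deg2rad(chi_d)
  s_hat <- cbind(cos(ch) * cos(tb), cos(ch) * sin(tb), sin(ch))
  sweep(s_hat, 2, c(1, 0, 0)) / wavelength
}

## Inverse: angles (degrees) from a laboratory Q vector.
lab_vector_to_angles <- function(q_lab, wavelength) {
  q_lab <- rbind(q_lab)
  s_hat <- q_lab * wavelength
  s_hat[, 1] <- s_hat[, 1] + 1
  n <- sqrt(rowSums(s_hat^2))
  s_hat <- s_hat / n
  data.frame(two_theta_b = rad2deg(atan2(s_hat[, 2], s_hat[, 1])),
             chi_d = rad2deg(asin(pmin(pmax(s_hat[, 3], -1), 1))))
}

rot_z <- function(phi_deg) {
  p <- deg2rad(phi_deg)
  matrix(c(cos(p), sin(p), 0, -sin(p), cos(p), 0, 0, 0, 1), 3, 3)
}

#' Rotate a laboratory Q vector into the crystal frame
#'
#' The crystal is rotated by \code{phi} (right-handed about +z) relative
#' to its phi = 0 setting, so a laboratory vector is carried back by
#' \eqn{q = R_z(-\phi)\, Q_{lab}}.
#'
#' @param q_lab 3-vector or 3-column matrix of laboratory Q vectors.
#' @param phi rotation angle(s) in degrees.
#' @return Crystal-frame vectors, same shape as the input rows.
#' @export
lab_to_crystal <- function(q_lab, phi) {
  q_lab <- rbind(q_lab)
  phi <- rep_len(phi, nrow(q_lab))
  out <- q_lab
  for (p in unique(phi)) {
    i <- which(phi == p)
    out[i, ] <- q_lab[i, , drop = FALSE] %*% rot_z(p)  # = t(Rz(-p) %*% q)
  }
  out
}

#' @rdname lab_to_crystal
#' @param q_crystal crystal-frame vectors at phi = 0.
#' @export
crystal_to_lab <- function(q_crystal, phi) {
  q_crystal <- rbind(q_crystal)
  phi <- rep_len(phi, nrow(q_crystal))
  out <- q_crystal
  for (p in unique(phi)) {
    i <- which(phi == p)
    out[i, ] <- q_crystal[i, , drop = FALSE] %*% rot_z(-p)
  }
  out
}

#' Monochromator wavelength selection
#'
#' Wavelength reflected by a germanium monochromator plane at a fixed
#' take-off angle: \eqn{\lambda = 2 d_{hkl} \sin(2\theta_M/2)}.  The
#' mounted crystal is a Ge(311) slab with the vertical axis along
#' \eqn{[0\bar 1 1]}, so only planes in that zone are reachable by
#' rotating the slab; other planes are accepted with a warning.
#'
#' @param plane Miller indices of the reflecting plane (length-3).
#' @param a_ge germanium lattice constant in Angstrom.
#' @param takeoff take-off angle 2theta_M in degrees.
#' @return Wavelength in Angstrom.
#' @examples
#' monochromator_wavelength(c(3, 1, 1))   # 1.153 A primary beam
#' @export
monochromator_wavelength <- function(plane, a_ge = 5.6575, takeoff = 39.5) {
  stopifnot(length(plane) == 3, a_ge > 0)
  if (abs(sum(plane * c(0, -1, 1))) > 1e-9)
    warning("plane is not in the [0,-1,1] zone of the mounted Ge(311) slab")
  lam <- 2 * (a_ge / sqrt(sum(plane^2))) * sin(deg2rad(takeoff) / 2)
  if (!is.finite(lam) || lam <= 0) stop("implausible wavelength")
  lam
}

## Orthonormal frame pair used by the two-reflection orientation.
tri_frame <- function(v1, v2) {
  t1 <- v1 / sqrt(sum(v1^2))
  t3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  n3 <- sqrt(sum(t3^2))
  if (n3 < 1e-12) stop("collinear vectors: orientation frame undefined")
  t3 <- t3 / n3
  t2 <- c(t3[2] * t1[3] - t3[3] * t1[2],
          t3[3] * t1[1] - t3[1] * t1[3],
          t3[1] * t1[2] - t3[2] * t1[1])
  cbind(t1, t2, t3)
}
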