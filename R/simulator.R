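## Synthetic rotation-scan simulator.
##
## The simulator is the test bed for every downstream stage: it predicts
## where each reflection crosses the Ewald sphere during the phi rotation,
## renders Gaussian spots into image frames, and reproduces the NaCl
## calibration protocols (detector-arm stepping and full-rotation layer
## lines).  Intensities are user-assigned; there is no structure-factor
## physics.

#' Orientation matrix from a cell and a rotation
#'
#' Builds \code{UB = U B} where B is the Busing-Levy reciprocal basis of
#' the cell (units 1/Angstrom, no 2 pi) and U a proper rotation giving the
#' crystal orientation at phi = 0.  \code{UB \%*\% hkl} is the
#' crystal-frame scattering vector with \code{|UB hkl| = 1/d}.
#'
#' @param cell an [xtal_cell()].
#' @param u 3x3 proper orthogonal orientation matrix (default identity).
#' @return 3x3 UB matrix.
#' @export
ub_matrix <- function(cell, u = diag(3)) {
  stopifnot(all(dim(u) == 3))
  if (max(abs(t(u) %*% u - diag(3))) > 1e-8 || det(u) < 0)
    stop("u must be a proper rotation matrix")
  u %*% bl_matrix(cell)
}

#' Uniform random rotation matrix
#'
#' Proper rotation drawn uniformly from SO(3) via a normalised Gaussian
#' quaternion.  Uses R's RNG stream (seed with [set.seed()]).
#'
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

## All integer hkl with |UB hkl| <= qmax (excluding 000).
enumerate_hkl <- function(ub, qmax) {
  inv <- solve(ub)
  hmax <- pmax(1, ceiling(qmax * sqrt(rowSums(inv^2))))
  g <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                   l = -hmax[3]:hmax[3])
  g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
  q <- as.matrix(g) %*% t(ub)
  keep <- sqrt(rowSums(q^2)) <= qmax
  list(hkl = as.matrix(g)[keep, , drop = FALSE],
       q = q[keep, , drop = FALSE])
}

#' Predict diffraction spots for a rotation scan
#'
#' For every reflection \code{q = UB hkl} inside the Ewald-sphere limit
#' \code{|q| <= 2/lambda}, solves the rotation-method diffraction
#' condition \eqn{(R_z(\phi) q) \cdot \hat x = -\lambda |q|^2 / 2} for
#' phi.  Each reflection gives up to two crossings (entry and exit
#' branch); reflections too close to the rotation axis never satisfy the
#' condition (the blind region) and are omitted.
#'
#' @param ub 3x3 UB matrix.
#' @param geom a [detector_geometry()].
#' @param scan a [scan_config()].
#' @param hkl optional integer matrix (rows = reflections) restricting the
#'   enumeration; default: all reflections inside the Ewald limit.
#' @param keep one of \code{"window"} (default: active-window hits within
#'   the scanned phi range), \code{"face"}, or \code{"all"} (every
#'   solution, with off-face coordinates and flags).
#' @return data.frame with columns \code{h, k, l, branch, phi, frame,
#'   two_theta_b, chi_d, x, y, on_face, in_window, in_scan}.
#' @export
predict_spots <- function(ub, geom, scan, hkl = NULL,
                          keep = c("window", "face", "all")) {
  keep <- match.arg(keep)
  if (abs(det(ub)) < 1e-12) stop("singular UB matrix")
  lam <- scan$wavelength
  if (is.null(hkl)) {
    e <- enumerate_hkl(ub, 2 / lam)
    hkl <- e$hkl; qs <- e$q
  } else {
    hkl <- rbind(hkl)
    qs <- hkl %*% t(ub)
  }
  if (nrow(hkl) == 0) return(empty_pred())
  q2 <- rowSums(qs^2)
  rhs <- -lam * q2 / 2
  rho <- sqrt(qs[, 1]^2 + qs[, 2]^2)
  ok <- rho > 1e-12 & abs(rhs) <= rho            # else blind / no crossing
  if (!any(ok)) return(empty_pred())
  hkl <- hkl[ok, , drop = FALSE]; qs <- qs[ok, , drop = FALSE]
  rhs <- rhs[ok]; rho <- rho[ok]
  delta <- atan2(-qs[, 2], qs[, 1])              # lab x(phi) = rho cos(phi - delta)
  half <- acos(pmax(pmin(rhs / rho, 1), -1))
  two <- half >= 1e-10                           # tangent crossing -> one solution
  i2 <- c(seq_len(nrow(hkl)), which(two))
  phis_r <- c(delta + half, (delta - half)[two])
  branch <- c(rep("entry", nrow(hkl)), rep("exit", sum(two)))
  hkl <- hkl[i2, , drop = FALSE]; qs <- qs[i2, , drop = FALSE]
  phi <- (rad2deg(phis_r) - scan$phi_start) %% 360 + scan$phi_start
  ## rotate each q by its own phi about z (vectorised)
  cp <- cos(deg2rad(phi)); sp <- sin(deg2rad(phi))
  q_lab <- cbind(cp * qs[, 1] - sp * qs[, 2],
                 sp * qs[, 1] + cp * qs[, 2], qs[, 3])
  ang <- lab_vector_to_angles(q_lab, lam)
  ch <- angles_to_channels(ang$two_theta_b, ang$chi_d, geom, check = FALSE)
  frame <- floor((phi - scan$phi_start) / scan$delta_phi)
  res <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    branch = branch, phi = phi, frame = as.integer(frame),
                    two_theta_b = ang$two_theta_b, chi_d = ang$chi_d,
                    x = ch$x, y = ch$y, on_face = ch$on_face,
                    in_window = ch$in_window,
                    in_scan = frame >= 0 & frame < scan$n_frames)
  res <- res[order(res$h, res$k, res$l, res$branch), ]
  res <- switch(keep,
                all = res,
                face = res[res$on_face & res$in_scan, ],
                window = res[res$in_window & res$in_scan, ])
  rownames(res) <- NULL
  res
}

empty_pred <- function()
  data.frame(h = integer(0), k = integer(0), l = integer(0),
             branch = character(0), phi = numeric(0), frame = integer(0),
             two_theta_b = numeric(0), chi_d = numeric(0), x = numeric(0),
             y = numeric(0), on_face = logical(0), in_window = logical(0),
             in_scan = logical(0))

#' Render predicted spots into image frames
#'
#' Deposits each spot as a separable Gaussian in (X, Y) with its total
#' intensity partitioned over frames by the Gaussian mosaic profile in phi
#' (pixel- and frame-integrated, truncated at 4 sigma); adds a flat
#' background and optional Poisson noise.  For a full-circle scan the phi
#' profile wraps across the 0/360 boundary.
#'
#' @param preds prediction table from [predict_spots()] (rows outside the
#'   face are skipped).
#' @param intensity total counts per spot (scalar or vector along rows of
#'   \code{preds}).
#' @param scan,geom scan and geometry.
#' @param sigma_x,sigma_y spot widths in channels (defaults from the
#'   instrument point-spread FWHM 3.16 and 2.66 channels / 2.355).
#' @param sigma_phi mosaic width across frames, degrees.
#' @param background flat background, counts per pixel per frame.
#' @param noise \code{"none"} or \code{"poisson"}.
#' @param seed RNG seed, required for Poisson noise.
#' @return A [frame_stack()].
#' @export
render_frames <- function(preds, intensity, scan, geom,
                          sigma_x = 1.34, sigma_y = 1.13, sigma_phi = 0.3,
                          background = 0, noise = c("none", "poisson"),
                          seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(sigma_x > 0, sigma_y > 0, sigma_phi > 0, background >= 0)
  if (noise == "poisson" && is.null(seed))
    stop("Poisson noise requires a seed")
  n <- scan$n_frames
  frames <- replicate(n, matrix(background, geom$n_x, geom$n_y),
                      simplify = FALSE)
  intensity <- rep_len(intensity, max(nrow(preds), 1L))
  wrap <- scan_full_circle(scan)
  edges <- scan$phi_start + (0:n) * scan$delta_phi
  for (i in seq_len(nrow(preds))) {
    x <- preds$x[i]; y <- preds$y[i]; phi <- preds$phi[i]
    if (x < -4 * sigma_x || x > geom$n_x - 1 + 4 * sigma_x ||
        y < -4 * sigma_y || y > geom$n_y - 1 + 4 * sigma_y) {
      message(sprintf("spot %d entirely off-face; skipped", i))
      next
    }
    ## frame weights: integral of N(phi, sigma_phi) over each frame bin,
    ## with +-360 images when the scan closes the circle
    centers <- phi + if (wrap) c(-360, 0, 360) else 0
    w <- numeric(n)
    for (p0 in centers)
      w <- w + stats::pnorm((edges[-1] - p0) / sigma_phi) -
               stats::pnorm((edges[-(n + 1)] - p0) / sigma_phi)
    sel <- which(w > 1e-8)
    if (!length(sel)) next
    ix <- max(0, floor(x - 5 * sigma_x)):min(geom$n_x - 1, ceiling(x + 5 * sigma_x))
    iy <- max(0, floor(y - 5 * sigma_y)):min(geom$n_y - 1, ceiling(y + 5 * sigma_y))
    wx <- stats::pnorm((ix + 0.5 - x) / sigma_x) -
          stats::pnorm((ix - 0.5 - x) / sigma_x)
    wy <- stats::pnorm((iy + 0.5 - y) / sigma_y) -
          stats::pnorm((iy - 0.5 - y) / sigma_y)
    patch <- outer(wx, wy)
    for (f in sel)
      frames[[f]][ix + 1, iy + 1] <- frames[[f]][ix + 1, iy + 1] +
        intensity[i] * w[f] * patch
  }
  if (noise == "poisson") {
    set.seed(seed)
    for (f in seq_len(n)) {
      m <- frames[[f]]
      frames[[f]] <- matrix(stats::rpois(length(m), m), nrow(m), ncol(m))
    }
  }
  frame_stack(frames, scan, geom)
}

#' Simulate the NaCl calibration measurements
#'
#' Two protocols:
#' \describe{
#'   \item{arm_scan}{one equatorial reflection (NaCl 220 by default)
#'     imaged at successive detector-arm angles (5 degree steps); returns
#'     one single-frame stack per arm position plus the ground truth.}
#'   \item{full_rotation}{a complete 360 degree NaCl rotation with the
#'     cube c axis along the rotation axis, exhibiting the l layer
#'     lines.}
#' }
#'
#' @param kind \code{"arm_scan"} or \code{"full_rotation"}.
#' @param geom truth geometry.
#' @param cell reference crystal (default NaCl, a = 5.6402 A).
#' @param wavelength wavelength in Angstrom.
#' @param arm_angles arm positions for \code{arm_scan}, degrees.
#' @param hkl reflection used in \code{arm_scan}.
#' @param delta_phi frame width for \code{full_rotation}, degrees.
#' @param hkl_max optional index limit for \code{full_rotation} (keeps
#'   small test scans light); default: all reflections in the Ewald
#'   sphere.
#' @param intensity spot intensity in counts.
#' @param background,noise,seed passed to [render_frames()].
#' @return List with elements \code{stacks} (list of [frame_stack()]s for
#'   \code{arm_scan}; length-1 for \code{full_rotation}), \code{truth}
#'   (data.frame of simulated spot positions) and \code{geoms}.
#' @export
simulate_calibration_sets <- function(kind = c("arm_scan", "full_rotation"),
                                      geom = detector_geometry(),
                                      cell = xtal_cell(5.6402),
                                      wavelength = 1.153,
                                      arm_angles = seq(20, 60, by = 5),
                                      hkl = c(2, 2, 0),
                                      delta_phi = 1, hkl_max = NULL,
                                      intensity = 1e4, background = 0,
                                      noise = "none", seed = NULL) {
  kind <- match.arg(kind)
  ub <- ub_matrix(cell)          # c axis along the rotation axis
  if (kind == "arm_scan") {
    d <- d_spacing(cell, hkl)
    tth <- 2 * rad2deg(asin(wavelength / (2 * d)))
    stacks <- list(); geoms <- list(); truth <- NULL
    scan1 <- scan_config(wavelength, phi_start = 0, delta_phi = 1, n_frames = 1)
    for (a in arm_angles) {
      g <- geom; g$arm_angle <- a
      ch <- angles_to_channels(tth, 0, g, check = FALSE)
      if (!ch$on_face) next
      pred <- data.frame(x = ch$x, y = ch$y, phi = 0.5)
      st <- render_frames(pred, intensity, scan1, g, background = background,
                          noise = noise, seed = if (!is.null(seed)) seed + a)
      stacks[[length(stacks) + 1]] <- st
      geoms[[length(geoms) + 1]] <- g
      truth <- rbind(truth, data.frame(arm_angle = a, x = ch$x, y = ch$y,
                                       two_theta_b = tth))
    }
    list(stacks = stacks, truth = truth, geoms = geoms)
  } else {
    scan <- scan_config(wavelength, phi_start = 0, delta_phi = delta_phi,
                        n_frames = round(360 / delta_phi))
    hkl <- NULL
    if (!is.null(hkl_max)) {
      g <- as.matrix(expand.grid(h = -hkl_max:hkl_max, k = -hkl_max:hkl_max,
                                 l = -hkl_max:hkl_max))
      hkl <- g[rowSums(abs(g)) > 0, ]
    }
    preds <- predict_spots(ub, geom, scan, hkl = hkl)
    st <- render_frames(preds, intensity, scan, geom,
                        background = background, noise = noise, seed = seed)
    list(stacks = list(st), truth = preds, geoms = list(geom))
  }
}

#' Measurement-time model: point detector versus area detector
#'
#' Compares the time to survey all reflections of a cell on a four-circle
#' point-detector instrument (a fixed time per reciprocal lattice point,
#' counted by direct enumeration up to \code{two_theta_max}) with a
#' rotation scan on an area detector (fixed scan range / scan speed per
#' arm setting, independent of the cell).
#'
#' @param cell an [xtal_cell()].
#' @param mode \code{"fcd"} (four-circle, point detector) or
#'   \code{"area"}.
#' @param minutes_per_point FCD time per reflection (minutes).
#' @param wavelength FCD survey wavelength, Angstrom.
#' @param two_theta_max FCD maximum scattering angle, degrees.
#' @param scan_range,scan_speed area-detector rotation range (degrees) and
#'   speed (degrees/minute).
#' @param n_settings number of detector arm settings for the area scan.
#' @return Measurement time in minutes.
#' @export
throughput_model <- function(cell, mode = c("fcd", "area"),
                             minutes_per_point = 10, wavelength = 1.24,
                             two_theta_max = 150,
                             scan_range = 180, scan_speed = 0.2,
                             n_settings = 1) {
  mode <- match.arg(mode)
  if (mode == "area") return(scan_range / scan_speed * n_settings)
  qmax <- 2 * sin(deg2rad(two_theta_max) / 2) / wavelength
  n <- nrow(enumerate_hkl(bl_matrix(cell), qmax)$hkl)
  minutes_per_point * n
}
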