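## Machine-parameter calibration against a standard crystal (NaCl).
##
## The protocols mirror the commissioning sequence: (1) the X conversion
## factor from stepping the detector arm under a fixed equatorial
## reflection; (2) the equator line, channel-axis slope and Y conversion
## factor from the layer lines of a full-rotation scan; (3) the
## wavelength from Bragg-law least squares on indexed equatorial
## reflections.  Later fits consume earlier results.

new_calibration <- function(protocol, estimates, su, residuals, extra = list()) {
  structure(c(list(protocol = protocol, estimates = estimates, su = su,
                   residuals = residuals), extra),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration fit (%s), %d observations\n", x$protocol,
              length(x$residuals)))
  for (nm in names(x$estimates)) {
    s <- x$su[[nm]]
    cat(sprintf("  %-10s %.6g%s\n", nm, x$estimates[[nm]],
                if (is.finite(s) && s > 0) sprintf("  (s.u. %.2g)", s) else ""))
  }
  invisible(x)
}

#' X conversion factor from a detector-arm scan
#'
#' A fixed equatorial reflection is imaged at successive detector-arm
#' angles; its X channel moves linearly with the arm angle with slope
#' \code{-1/c_x} (increasing arm angle moves the spot to lower X).  A
#' weighted straight-line fit of X against the arm angle yields
#' \code{c_x}; if the reflection's true \code{2theta_B} is supplied
#' (known cell and wavelength), the origin channel \code{X0} is also
#' reported as the fitted X at \code{arm = 2theta_B}.
#'
#' @param arm_angle detector arm angles 2theta_c, degrees.
#' @param x observed spot X channels (same length).
#' @param weights optional fit weights.
#' @param two_theta_b optional true in-plane angle of the reflection.
#' @return A \code{"calibration_result"} with estimates \code{c_x} (and
#'   \code{x0} when identifiable).
#' @export
fit_x_conversion <- function(arm_angle, x, weights = NULL,
                             two_theta_b = NULL) {
  if (length(unique(arm_angle)) < 2)
    stop("need at least two distinct arm angles")
  fit <- stats::lm(x ~ arm_angle, weights = weights)
  sl <- stats::coef(fit)[["arm_angle"]]
  if (sl >= 0)
    stop("spot X does not decrease with arm angle: check the sign convention")
  cv <- stats::vcov(fit)
  c_x <- -1 / sl
  su_cx <- sqrt(cv[2, 2]) / sl^2
  est <- list(c_x = c_x); su <- list(c_x = su_cx)
  if (!is.null(two_theta_b)) {
    ## X0 = fitted X where the arm reading equals the reflection's 2theta
    pr <- stats::coef(fit)[[1]] + sl * two_theta_b
    g <- c(1, two_theta_b)
    est$x0 <- pr
    su$x0 <- sqrt(drop(t(g) %*% cv %*% g))
  }
  new_calibration("arm_scan", est, su, stats::residuals(fit))
}

## Split sorted values into clusters at gaps wider than min_gap.
gap_cluster <- function(v, min_gap) {
  o <- order(v)
  breaks <- which(diff(v[o]) > min_gap)
  cl <- integer(length(v))
  cl[o] <- rep(seq_len(length(breaks) + 1), diff(c(0, breaks, length(v))))
  cl
}

#' Equator, channel slope and Y conversion from layer lines
#'
#' Peaks of a full-rotation scan group into horizontal layer bands
#' (constant Miller index l along the rotation axis).  Each band is fitted
#' with a straight line in (X, Y); the common tilt gives the X-Y channel
#' slope, the l = 0 band's height at \code{X = X0} gives \code{Y0}, and
#' the band spacing, which must follow
#' \eqn{\tan(\arcsin(\lambda l / c))/c_y}, gives \code{c_y}.  Band
#' l-indices are assigned by searching the integer offset that best
#' explains the spacings.  Line fits are repeated-median (Siegel) fits so
#' single spurious peaks cannot tilt a band.
#'
#' @param x,y peak channel coordinates from the full-rotation scan.
#' @param cell reference [xtal_cell()] (its c axis is the rotation axis).
#' @param wavelength wavelength in Angstrom.
#' @param x0 origin channel from the arm-scan fit.
#' @param min_gap minimum Y gap between layer bands, channels.
#' @return A \code{"calibration_result"} with estimates \code{y0},
#'   \code{xy_slope} and (with >= 2 bands) \code{c_y}; extra fields
#'   \code{layers} (per-band table) and \code{c_y_fitted}.
#' @export
fit_layer_lines <- function(x, y, cell, wavelength, x0,
                            min_gap = 5) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  cl <- gap_cluster(y, min_gap)
  bands <- sort(unique(cl))
  fits <- lapply(bands, function(b) {
    xs <- x[cl == b]; ys <- y[cl == b]
    if (length(xs) >= 2 && diff(range(xs)) > 1e-9) {
      f <- siegel_line(xs, ys)
      list(n = length(xs), slope = f$slope,
           y_at_x0 = f$intercept + f$slope * x0,
           spread = f$spread)
    } else list(n = length(xs), slope = NA_real_, y_at_x0 = mean(ys),
                spread = 0)
  })
  layers <- data.frame(band = bands,
                       n = vapply(fits, `[[`, 0, "n"),
                       slope = vapply(fits, `[[`, 0, "slope"),
                       y_at_x0 = vapply(fits, `[[`, 0, "y_at_x0"))
  ## common tilt: weighted mean of band slopes; slope parameter s = -tilt
  ok <- is.finite(layers$slope)
  tilt <- if (any(ok)) sum(layers$slope[ok] * layers$n[ok]) / sum(layers$n[ok])
          else 0
  s_hat <- -tilt
  if (nrow(layers) == 1) {
    res <- y[cl == bands[1]] - layers$y_at_x0[1] - tilt * (x[cl == bands[1]] - x0)
    return(new_calibration("layer_lines",
                           list(y0 = layers$y_at_x0[1], xy_slope = s_hat,
                                c_y = NA_real_),
                           list(y0 = stats::sd(res) / sqrt(sum(cl == 1)),
                                xy_slope = NA_real_, c_y = NA_real_),
                           res, list(layers = layers, c_y_fitted = FALSE)))
  }
  ## assign l indices: search the integer offset whose predicted spacings
  ## tan(asin(lambda l / c)) best match the band heights linearly
  nb <- nrow(layers)
  ccell <- cell[["c"]]
  lmax <- floor(ccell * 2 / wavelength)
  best <- NULL
  for (l0 in -lmax:(lmax - nb + 1)) {
    ls <- l0 + seq_len(nb) - 1
    sinx <- wavelength * ls / ccell
    if (any(abs(sinx) >= 1)) next
    t_l <- tan(asin(sinx))
    f <- stats::lm(layers$y_at_x0 ~ t_l, weights = layers$n)
    if (stats::coef(f)[["t_l"]] <= 0) next       # c_y must be positive
    sse <- sum(layers$n * stats::residuals(f)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, fit = f, ls = ls)
  }
  if (is.null(best)) stop("could not assign layer indices")
  f <- best$fit
  cv <- stats::vcov(f)
  inv_cy <- stats::coef(f)[["t_l"]]
  layers$l <- best$ls
  res <- stats::residuals(f)
  new_calibration("layer_lines",
                  list(y0 = stats::coef(f)[[1]], xy_slope = s_hat,
                       c_y = 1 / inv_cy),
                  list(y0 = sqrt(cv[1, 1]),
                       xy_slope = stats::sd(layers$slope[ok]) /
                         sqrt(max(sum(ok), 1)),
                       c_y = sqrt(cv[2, 2]) / inv_cy^2),
                  res, list(layers = layers, c_y_fitted = TRUE))
}

## Siegel repeated-median line fit (robust to isolated outliers).
siegel_line <- function(x, y) {
  n <- length(x)
  slopes <- vapply(seq_len(n), function(i) {
    dx <- x[-i] - x[i]
    sl <- (y[-i] - y[i]) / dx
    stats::median(sl[is.finite(sl)])
  }, 0)
  slope <- stats::median(slopes, na.rm = TRUE)
  if (!is.finite(slope)) slope <- 0
  intercept <- stats::median(y - slope * x)
  list(slope = slope, intercept = intercept,
       spread = stats::mad(y - slope * x - intercept))
}

#' Wavelength calibration by Bragg-law least squares
#'
#' Equatorial (hk0) reflections of a crystal with known cell are
#' converted from their X channels to \code{2theta} through the
#' calibrated geometry; each gives
#' \eqn{\lambda_i = 2 d_{hkl} \sin\theta_i}, and the calibrated
#' wavelength is their least-squares (mean) estimate with its standard
#' uncertainty from the scatter.
#'
#' @param x observed X channels of the equatorial reflections.
#' @param hkl integer matrix (one row per reflection).
#' @param cell the reference [xtal_cell()].
#' @param geom calibrated [detector_geometry()].
#' @param y observed Y channels (defaults to the equator \code{y0}).
#' @return A \code{"calibration_result"} with estimate \code{wavelength}.
#' @export
fit_wavelength <- function(x, hkl, cell, geom, y = NULL) {
  hkl <- rbind(hkl)
  stopifnot(nrow(hkl) == length(x))
  if (is.null(y)) y <- rep(geom$y0, length(x))
  ang <- channels_to_angles(x, y, geom)
  d <- d_spacing(cell, hkl)
  lam <- 2 * d * sin(deg2rad(ang$two_theta_b) / 2)
  est <- mean(lam)
  su <- if (length(lam) > 1) stats::sd(lam) / sqrt(length(lam)) else NA_real_
  new_calibration("wavelength", list(wavelength = est),
                  list(wavelength = su), lam - est)
}
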