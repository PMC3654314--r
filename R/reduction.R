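## Final reduction: pair predictions with observations, classify peak
## quality, apply the Lorentz correction and export the reflection list.

#' Lorentz factor for the fixed-chi rotation geometry
#'
#' Normal-beam rotation geometry about the vertical axis:
#' \deqn{L = 1 / (\cos\chi_d \, \sin 2\theta_B)}
#' which is the inverse speed at which the rotating reciprocal-lattice
#' point crosses the Ewald sphere; on the equator it reduces to the
#' classic \eqn{1/\sin 2\theta}.  The corrected intensity is
#' \code{I / L}.
#'
#' @param two_theta_b,chi_d spot angles in degrees (vectors allowed).
#' @param eps blind-region guard: an error is raised when
#'   \eqn{\cos\chi_d \sin 2\theta_B \le} \code{eps} (the crossing speed
#'   vanishes and no correction is defined).
#' @return Dimensionless Lorentz factor L.
#' @export
lorentz_factor <- function(two_theta_b, chi_d, eps = 1e-3) {
  den <- cos(deg2rad(chi_d)) * sin(deg2rad(two_theta_b))
  if (any(den <= eps))
    stop("reflection too close to the blind region: Lorentz correction undefined")
  1 / den
}

quality_levels <- c("good_peak", "no_peak", "no_good_peak",
                    "out_of_expected_region", "out_of_experimental_area",
                    "partial")

#' Classify predicted reflections against observed peaks
#'
#' Each prediction is matched to the nearest observation in (frame, X, Y)
#' (greedy, distance ordered, each observation used once; phi distance
#' wraps on a full-circle scan).  Quality labels, mutually exclusive and
#' exhaustive:
#' \describe{
#'   \item{good_peak}{matched within \code{tol_recip} fractional-hkl
#'     distance (the 0.1 reciprocal-space criterion).}
#'   \item{partial}{as good_peak, but the observation touches a frame or
#'     window boundary so its integral is incomplete.}
#'   \item{no_good_peak}{a peak exists nearby (within
#'     \code{near_factor * tol_recip}) but fails the criterion.}
#'   \item{no_peak}{the position was measured and no peak is there.}
#'   \item{out_of_expected_region}{predicted on the detector face but at
#'     a phi outside the scanned range.}
#'   \item{out_of_experimental_area}{predicted off the active detector
#'     area.}
#' }
#'
#' @param preds prediction table from [predict_observations()] with
#'   \code{keep = "all"} (in-window rows of a filtered table work too).
#' @param obs3d 3D peak table from [merge_frames()].
#' @param ub refined UB matrix.
#' @param geom,scan geometry and scan.
#' @param tol_recip indexing criterion, fractional hkl units.
#' @param near_factor multiplier defining "a peak exists nearby".
#' @param phi_window maximum |phi_pred - phi_obs| for a match, degrees.
#' @return data.frame: prediction columns plus \code{quality},
#'   \code{obs} (matched peak3d id or NA), \code{intensity}, \code{sigma},
#'   \code{residual}.
#' @export
classify_reflections <- function(preds, obs3d, ub, geom, scan,
                                 tol_recip = 0.1, near_factor = 3,
                                 phi_window = 3) {
  np <- nrow(preds); no <- nrow(obs3d)
  quality <- rep(NA_character_, np)
  obs_id <- rep(NA_integer_, np)
  residual <- rep(NA_real_, np)
  intensity <- rep(NA_real_, np); sigma <- rep(NA_real_, np)
  measurable <- preds$in_window & preds$in_scan
  quality[!preds$in_window] <- "out_of_experimental_area"
  quality[preds$in_window & !preds$in_scan] <- "out_of_expected_region"
  if (no > 0 && any(measurable)) {
    qs <- observations_to_q(obs3d, geom, scan)
    hreal <- index_residuals(ub, qmat(qs))$hreal
    wrap <- scan_full_circle(scan)
    pd <- function(a, b) { d <- abs(a - b); if (wrap) pmin(d, 360 - d) else d }
    ## candidate pairs within the phi window, ordered by XY distance
    cand <- NULL
    for (i in which(measurable)) {
      dphi <- pd(preds$phi[i], obs3d$phi)
      j <- which(dphi <= phi_window)
      if (!length(j)) next
      dxy <- sqrt((preds$x[i] - obs3d$x[j])^2 + (preds$y[i] - obs3d$y[j])^2)
      cand <- rbind(cand, data.frame(i = i, j = j, dxy = dxy))
    }
    if (!is.null(cand)) {
      cand <- cand[order(cand$dxy), ]
      used_p <- logical(np); used_o <- logical(no)
      for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        if (used_p[i] || used_o[j]) next
        hr <- hreal[j, ]
        resid <- sqrt(sum((hr - c(preds$h[i], preds$k[i], preds$l[i]))^2))
        if (resid < near_factor * tol_recip) {
          used_p[i] <- TRUE; used_o[j] <- TRUE
          obs_id[i] <- obs3d$peak3d[j]
          residual[i] <- resid
          intensity[i] <- obs3d$intensity[j]; sigma[i] <- obs3d$sigma[j]
          quality[i] <- if (resid >= tol_recip) "no_good_peak"
                        else if (obs3d$partial[j]) "partial"
                        else "good_peak"
        }
      }
    }
  }
  quality[is.na(quality)] <- "no_peak"
  out <- preds
  out$quality <- factor(quality, levels = quality_levels)
  out$obs <- obs_id
  out$intensity <- intensity
  out$sigma <- sigma
  out$residual <- residual
  out
}

#' Build the Lorentz-corrected reflection-intensity list
#'
#' Good and partial peaks are Lorentz-corrected
#' (\code{F2 = I * cos(chi_d) * sin(2theta_B) * scale}); when the entry
#' and exit Ewald crossings of the same hkl were both observed, the two
#' are averaged with 1/sigma^2 weights (each crossing is an independent
#' measurement of the same |F|^2) and an internal-agreement statistic is
#' reported.  All other categories go to a rejects table with reasons.
#'
#' @param classified output of [classify_reflections()].
#' @param scale user scale factor applied to F2 and sigma.
#' @param include_partial include partial peaks in the output list
#'   (flagged) rather than rejecting them.
#' @return List with \code{reflections} (h, k, l, f2, sig_f2, flag,
#'   n_obs, agreement), \code{rejects}, and \code{counts} per quality
#'   category.
#' @export
build_reflection_list <- function(classified, scale = 1,
                                  include_partial = TRUE) {
  counts <- table(classified$quality)
  keep_lv <- c("good_peak", if (include_partial) "partial")
  sel <- classified$quality %in% keep_lv & !is.na(classified$intensity)
  acc <- classified[sel, ]
  refl <- NULL
  if (nrow(acc)) {
    L <- lorentz_factor(acc$two_theta_b, acc$chi_d)
    f2 <- acc$intensity / L * scale
    sg <- acc$sigma / L * scale
    key <- paste(acc$h, acc$k, acc$l)
    refl <- do.call(rbind, lapply(split(seq_len(nrow(acc)), key), function(ii) {
      w <- 1 / sg[ii]^2
      m <- sum(w * f2[ii]) / sum(w)
      agreement <- if (length(ii) > 1)
        sqrt(sum(w * (f2[ii] - m)^2) / (length(ii) - 1)) else NA_real_
      data.frame(h = acc$h[ii[1]], k = acc$k[ii[1]], l = acc$l[ii[1]],
                 f2 = m, sig_f2 = 1 / sqrt(sum(w)),
                 flag = if (any(acc$quality[ii] == "partial")) "partial"
                        else "good",
                 n_obs = length(ii), agreement = agreement)
    }))
    refl <- refl[order(refl$h, refl$k, refl$l), ]
    rownames(refl) <- NULL
  } else {
    refl <- data.frame(h = integer(0), k = integer(0), l = integer(0),
                       f2 = numeric(0), sig_f2 = numeric(0),
                       flag = character(0), n_obs = integer(0),
                       agreement = numeric(0))
  }
  rejects <- classified[!sel, c("h", "k", "l", "frame", "x", "y", "quality")]
  names(rejects)[names(rejects) == "quality"] <- "reason"
  list(reflections = refl, rejects = rejects, counts = counts)
}

#' Export a reflection list
#'
#' \code{format = "shelx_hkl"} writes fixed-width HKLF-4 style records
#' (three integer fields of width 4, two fixed-point fields of width 8
#' with two decimals); \code{format = "plain"} writes the hkl text table
#' dialect (lossless, re-readable with [read_table_file()]).
#'
#' @param reflections data.frame with \code{h, k, l, f2, sig_f2} (and
#'   \code{flag} for plain format).
#' @param path output file.
#' @param format \code{"shelx_hkl"} or \code{"plain"}.
#' @return Invisibly, \code{path}.
#' @export
export_reflections <- function(reflections, path,
                               format = c("shelx_hkl", "plain")) {
  format <- match.arg(format)
  if (format == "plain") {
    df <- reflections
    if (is.null(df$flag)) df$flag <- "good"
    write_table_file(df[, c("h", "k", "l", "f2", "sig_f2", "flag")],
                     "hkl", path)
    return(invisible(path))
  }
  for (i in seq_len(nrow(reflections))) {
    r <- reflections[i, ]
    if (any(abs(c(r$h, r$k, r$l)) > 999) || r$f2 >= 1e6 - 0.005 ||
        r$f2 <= -1e5 || r$sig_f2 >= 1e6 - 0.005)
      stop(sprintf("reflection (%d %d %d) overflows the fixed-width format",
                   r$h, r$k, r$l))
  }
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f", reflections$h, reflections$k,
                   reflections$l, reflections$f2, reflections$sig_f2)
  writeLines(lines, path)
  invisible(path)
}
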