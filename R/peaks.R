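## Two-dimensional peak search and cross-frame integration.
##
## Seeds are local maxima above a user threshold; each seed's square box
## is iteratively re-centred on the background-subtracted centre of
## gravity until the centre pixel is stable.  Background is estimated
## from the box's border rim; claimed pixels are masked so no pixel
## contributes to two peaks in one frame.

#' Find peaks in one image frame
#'
#' @param frame numeric matrix (n_x by n_y, channel (i, j) at element
#'   \code{[i+1, j+1]}).
#' @param threshold counts a seed pixel must exceed.
#' @param box odd box width in channels (>= 3).
#' @param geom a [detector_geometry()] (for the active-window flag).
#' @param frame_index 0-based frame number recorded in the output.
#' @param rim rim width in pixels used for the background estimate.
#' @param max_iter maximum centre-of-gravity relocations.
#' @return data.frame with one row per peak: \code{frame, x, y,
#'   net_intensity, background, sigma, box, converged, in_window, edge}.
#'   Peaks are ordered by decreasing net intensity.
#' @export
find_peaks_2d <- function(frame, threshold, box = 11, geom,
                          frame_index = 0L, rim = 1L, max_iter = 20L) {
  stopifnot(box %% 2 == 1, box >= 3, threshold > 0, rim >= 1)
  nx <- nrow(frame); ny <- ncol(frame)
  ## 8-neighbourhood local maxima above threshold, vectorised via shifts
  pad <- matrix(-Inf, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- frame
  ismax <- frame > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & frame >= pad[(2 + di):(nx + 1 + di),
                                  (2 + dj):(ny + 1 + dj)]
  }
  seeds <- which(ismax, arr.ind = TRUE)
  if (nrow(seeds) == 0) return(empty_peaks2d())
  ord <- order(frame[seeds], decreasing = TRUE)
  seeds <- seeds[ord, , drop = FALSE]
  claimed <- matrix(FALSE, nx, ny)
  half <- (box - 1L) %/% 2L
  res <- list()
  for (s in seq_len(nrow(seeds))) {
    ci <- seeds[s, 1] - 1L; cj <- seeds[s, 2] - 1L   # 0-based centre
    if (claimed[ci + 1L, cj + 1L]) next
    visited <- character(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      key <- paste(ci, cj)
      if (key %in% visited) break                     # oscillation
      visited <- c(visited, key)
      bx <- boxstats(frame, ci, cj, half, rim, nx, ny)
      if (bx$mass <= 0) break
      ni <- as.integer(round(bx$cogx)); nj <- as.integer(round(bx$cogy))
      ni <- min(max(ni, 0L), nx - 1L); nj <- min(max(nj, 0L), ny - 1L)
      if (ni == ci && nj == cj) { converged <- TRUE; break }
      ## tie-break toward smaller X then Y on equal distance handled by
      ## round(); just move the centre
      ci <- ni; cj <- nj
    }
    bx <- boxstats(frame, ci, cj, half, rim, nx, ny)
    if (bx$mass <= 0 || bx$net <= 0) next
    if (claimed[ci + 1L, cj + 1L]) next
    claimed[bx$ii[bx$inner_i] + 1L, bx$jj[bx$inner_j] + 1L] <- TRUE
    aw <- geom$active_window
    res[[length(res) + 1]] <- data.frame(
      frame = as.integer(frame_index), x = bx$cogx, y = bx$cogy,
      net_intensity = bx$net, background = bx$bg, sigma = bx$sigma,
      box = as.integer(box), converged = converged,
      in_window = bx$cogx >= aw[1] & bx$cogx <= aw[3] &
                  bx$cogy >= aw[2] & bx$cogy <= aw[4],
      edge = bx$edge)
  }
  if (!length(res)) return(empty_peaks2d())
  out <- do.call(rbind, res)
  out <- out[order(out$net_intensity, decreasing = TRUE), ]
  rownames(out) <- NULL
  out
}

empty_peaks2d <- function()
  data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
             net_intensity = numeric(0), background = numeric(0),
             sigma = numeric(0), box = integer(0), converged = logical(0),
             in_window = logical(0), edge = logical(0))

## Box statistics around 0-based centre (ci, cj): rim-background estimate,
## background-subtracted COG over the inner pixels, net intensity and its
## Poisson-propagated sigma.
boxstats <- function(frame, ci, cj, half, rim, nx, ny) {
  i1 <- ci - half; i2 <- ci + half; j1 <- cj - half; j2 <- cj + half
  edge <- i1 < 0 || j1 < 0 || i2 > nx - 1 || j2 > ny - 1
  i1c <- max(i1, 0L); i2c <- min(i2, nx - 1L)
  j1c <- max(j1, 0L); j2c <- min(j2, ny - 1L)
  ii <- i1c:i2c; jj <- j1c:j2c
  sub <- frame[ii + 1L, jj + 1L, drop = FALSE]
  inner_i <- ii >= i1 + rim & ii <= i2 - rim
  inner_j <- jj >= j1 + rim & jj <= j2 - rim
  rim_mask <- !(outer(inner_i, inner_j))
  rimv <- sub[rim_mask]
  bg <- if (length(rimv)) mean(rimv) else 0
  inner <- sub[inner_i, inner_j, drop = FALSE]
  n_inner <- length(inner); n_rim <- length(rimv)
  net <- sum(inner) - n_inner * bg
  w <- pmax(inner - bg, 0)
  mass <- sum(w)
  cogx <- if (mass > 0) sum(rowSums(w) * ii[inner_i]) / mass else ci
  cogy <- if (mass > 0) sum(colSums(w) * jj[inner_j]) / mass else cj
  sigma <- sqrt(max(sum(inner), 0) +
                if (n_rim > 0) (n_inner / n_rim)^2 * max(sum(rimv), 0) else 0)
  list(bg = bg, net = net, sigma = sigma, cogx = cogx, cogy = cogy,
       mass = mass, edge = edge, ii = ii, jj = jj,
       inner_i = inner_i, inner_j = inner_j)
}

#' Find peaks in every frame of a stack
#'
#' @param stack a [frame_stack()].
#' @inheritParams find_peaks_2d
#' @return Combined peak table over all frames, with a \code{peak} id
#'   column (schema of the \code{peaks} table kind, plus diagnostics).
#' @export
find_peaks_stack <- function(stack, threshold, box = 11, rim = 1L,
                             max_iter = 20L) {
  out <- lapply(seq_along(stack$frames) - 1L, function(f)
    find_peaks_2d(stack$frames[[f + 1L]], threshold, box, stack$geom,
                  frame_index = f, rim = rim, max_iter = max_iter))
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) {
    out <- empty_peaks2d(); out$peak <- integer(0); return(out)
  }
  out$peak <- seq_len(nrow(out))
  out
}

#' Merge 2D peaks across consecutive frames
#'
#' Single-linkage grouping: two 2D peaks join the same 3D peak when their
#' (X, Y) centres agree within \code{xy_tol} and their frames are within
#' \code{gap_tol + 1} of each other (wrapping across the scan boundary
#' for a full 360 degree scan).  The integrated intensity is the exact
#' sum of the member net intensities, sigmas add in quadrature, and the
#' phi centroid is intensity weighted.
#'
#' By default the integrated intensity is the exact sum of the member
#' net intensities.  When the frame stack is supplied, each group is
#' instead re-integrated with a fixed box at the group centroid over its
#' full frame span extended by \code{extend} frames on both sides: the
#' weak leading/trailing frames of a spot fall below the peak-search
#' threshold, and without them the summed intensity is biased low under
#' counting noise.
#'
#' @param peaks 2D peak table from [find_peaks_stack()].
#' @param scan the [scan_config()] of the stack.
#' @param xy_tol channel tolerance for grouping (default 1.5).
#' @param gap_tol allowed frame gap (0 = strictly consecutive).
#' @param stack optional [frame_stack()] for fixed-box re-integration.
#' @param extend frames added on each side of the span when
#'   re-integrating.
#' @param rim background rim width for re-integration.
#' @return data.frame with one row per 3D peak: \code{peak3d, x, y, phi,
#'   frame_first, frame_last, n_frames, intensity, sigma, partial}.
#'   Result is independent of the input row order.
#' @export
merge_frames <- function(peaks, scan, xy_tol = 1.5, gap_tol = 0L,
                         stack = NULL, extend = 1L, rim = 1L) {
  stopifnot(xy_tol > 0, gap_tol >= 0)
  n <- nrow(peaks)
  if (n == 0)
    return(data.frame(peak3d = integer(0), x = numeric(0), y = numeric(0),
                      phi = numeric(0), frame_first = integer(0),
                      frame_last = integer(0), n_frames = integer(0),
                      intensity = numeric(0), sigma = numeric(0),
                      partial = logical(0)))
  peaks <- peaks[order(peaks$frame, peaks$x, peaks$y), ]
  wrap <- scan_full_circle(scan)
  nf <- scan$n_frames
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  ## link only frame pairs within reach (bucketed by frame; wraps for a
  ## full-circle scan) instead of all O(n^2) peak pairs
  buckets <- split(seq_len(n), peaks$frame)
  fkeys <- as.integer(names(buckets))
  for (bi in seq_along(buckets)) {
    f1 <- fkeys[bi]
    for (df in 0:(gap_tol + 1L)) {
      f2 <- f1 + df
      if (wrap) f2 <- f2 %% nf
      bj <- match(f2, fkeys)
      if (is.na(bj)) next
      ii <- buckets[[bi]]; jj <- buckets[[bj]]
      for (i in ii) {
        close <- jj[abs(peaks$x[jj] - peaks$x[i]) <= xy_tol &
                    abs(peaks$y[jj] - peaks$y[i]) <= xy_tol & jj != i]
        for (j in close) union(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), roots)
  res <- lapply(seq_along(groups), function(g) {
    m <- peaks[groups[[g]], ]
    w <- pmax(m$net_intensity, 1e-12)
    phi_mid <- frame_phi_mid(scan, m$frame)
    ## circular intensity-weighted phi centroid (narrow spread assumed)
    ref <- phi_mid[which.max(w)]
    dphi <- ((phi_mid - ref + 180) %% 360) - 180
    phi <- ref + sum(w * dphi) / sum(w)
    span_edge <- if (wrap) FALSE
                 else min(m$frame) == 0 || max(m$frame) == nf - 1
    gx <- sum(w * m$x) / sum(w); gy <- sum(w * m$y) / sum(w)
    intensity <- sum(m$net_intensity)
    sigma <- sqrt(sum(m$sigma^2))
    if (!is.null(stack)) {
      if (wrap) {
        ## unwrap member frames around the strongest member
        f_ref <- m$frame[which.max(w)]
        df <- ((m$frame - f_ref + nf %/% 2) %% nf) - nf %/% 2
        fr <- unique((f_ref + (min(df) - extend):(max(df) + extend)) %% nf)
      } else {
        fr <- (min(m$frame) - extend):(max(m$frame) + extend)
        fr <- fr[fr >= 0 & fr < nf]
      }
      half <- (max(m$box) - 1L) %/% 2L
      ci <- as.integer(round(gx)); cj <- as.integer(round(gy))
      intensity <- 0; var <- 0
      for (f in fr) {
        bs <- boxstats(stack$frames[[f + 1L]], ci, cj, half, rim,
                       stack$geom$n_x, stack$geom$n_y)
        intensity <- intensity + bs$net
        var <- var + bs$sigma^2
      }
      sigma <- sqrt(var)
    }
    data.frame(peak3d = g,
               x = gx, y = gy,
               phi = phi %% 360,
               frame_first = min(m$frame), frame_last = max(m$frame),
               n_frames = length(unique(m$frame)),
               intensity = intensity,
               sigma = sigma,
               partial = span_edge || any(m$edge) || any(!m$in_window))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$intensity, decreasing = TRUE), ]
  out$peak3d <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
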