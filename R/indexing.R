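## UB-matrix determination and reflection indexing.
##
## Observed 3D peaks are converted to crystal-frame reciprocal vectors q
## at phi = 0; a UB matrix is then found by one of four routes
## (vector-minimum auto-indexing, two- or three-reflection construction,
## Monte-Carlo orientation search with a known cell), optionally carried
## to a Bravais lattice, and refined by linear least squares.

#' Convert integrated 3D peaks to reciprocal-space vectors
#'
#' Composition channels -> angles -> laboratory Q -> crystal frame at the
#' peak's phi centroid.
#'
#' @param peaks3d table from [merge_frames()] (needs columns \code{x, y,
#'   phi, intensity}).
#' @param geom,scan geometry and scan of the stack.
#' @return data.frame \code{peak, qx, qy, qz, intensity, in_window}.
#' @export
observations_to_q <- function(peaks3d, geom, scan) {
  ang <- channels_to_angles(peaks3d$x, peaks3d$y, geom)
  q_lab <- scattering_vector_lab(ang$two_theta_b, ang$chi_d, scan$wavelength)
  q <- lab_to_crystal(q_lab, peaks3d$phi)
  data.frame(peak = if (!is.null(peaks3d$peak3d)) peaks3d$peak3d
                    else seq_len(nrow(peaks3d)),
             qx = q[, 1], qy = q[, 2], qz = q[, 3],
             intensity = peaks3d$intensity, in_window = ang$in_window)
}

qmat <- function(qs) {
  if (is.data.frame(qs)) as.matrix(qs[, c("qx", "qy", "qz")]) else rbind(qs)
}

## Fractional-index residuals of q rows under a UB: list(hreal, hint, resid).
index_residuals <- function(ub, q) {
  hreal <- t(solve(ub, t(q)))
  hint <- round(hreal)
  list(hreal = hreal, hint = hint,
       resid = sqrt(rowSums((hreal - hint)^2)))
}

#' Index observations with a known UB
#'
#' @param qs q table from [observations_to_q()] (or a 3-column matrix).
#' @param ub 3x3 UB matrix.
#' @param tol indexing tolerance, fractional hkl units (the classic 0.1
#'   reciprocal-space criterion).
#' @return data.frame with \code{h, k, l} (nearest integers),
#'   \code{residual} and \code{indexed} flag, one row per observation.
#' @export
index_q <- function(qs, ub, tol = 0.1) {
  q <- qmat(qs)
  r <- index_residuals(ub, q)
  data.frame(h = r$hint[, 1], k = r$hint[, 2], l = r$hint[, 3],
             residual = r$resid, indexed = r$resid < tol)
}

#' Auto-indexing by the vector-minimum method
#'
#' Builds the closed set of the observed q vectors and all pairwise
#' differences, deduplicates, and searches the shortest linearly
#' independent triples (determinant above a volume floor) for a basis
#' that integer-indexes at least \code{accept_frac} of the observations
#' within \code{tol}.  The accepted basis is polished by least squares
#' against the points it indexes and returned as a primitive UB.
#'
#' @param qs q table or 3-column matrix of observed reciprocal vectors.
#' @param tol indexing tolerance in fractional hkl units.
#' @param accept_frac fraction of observations a basis must index.
#' @param det_floor minimum |det| of a candidate basis (1/Angstrom^3).
#' @param max_candidates number of shortest candidate vectors searched.
#' @return List of class \code{"ub_fit"}: \code{ub}, \code{cell},
#'   \code{indexed} (table from [index_q()]), \code{frac_indexed},
#'   \code{method}.
#' @export
vector_minimum <- function(qs, tol = 0.1, accept_frac = 0.8,
                           det_floor = 1e-6, max_candidates = 40) {
  q <- qmat(qs)
  if (nrow(q) < 3) stop("need at least 3 q vectors")
  ## coplanarity guard on the inputs
  if (qr(q)$rank < 3)
    stop("all q vectors are coplanar: cannot form a 3D basis")
  ## candidate set: inputs plus pairwise differences, shortest first
  idx <- utils::combn(nrow(q), 2)
  cand <- rbind(q, q[idx[1, ], , drop = FALSE] - q[idx[2, ], , drop = FALSE])
  nrm <- sqrt(rowSums(cand^2))
  keepn <- nrm > 1e-6
  cand <- cand[keepn, , drop = FALSE]; nrm <- nrm[keepn]
  ord <- order(nrm)
  cand <- cand[ord, , drop = FALSE]; nrm <- nrm[ord]
  ## merge duplicates (up to sign) into running-mean clusters; the merge
  ## radius adapts to the observation noise but never drops below the
  ## nominal 1e-4 resolution
  merge_tol <- max(1e-4, 0.02 * nrm[1])
  reps <- matrix(0, 0, 3); wts <- numeric(0)
  for (i in seq_len(min(nrow(cand), 5000L))) {
    v <- cand[i, ]
    if (nrow(reps)) {
      d1 <- sqrt(colSums((t(reps) - v)^2))
      d2 <- sqrt(colSums((t(reps) + v)^2))
      j <- which.min(pmin(d1, d2))
      if (min(d1[j], d2[j]) < merge_tol) {
        vv <- if (d1[j] <= d2[j]) v else -v
        reps[j, ] <- (reps[j, ] * wts[j] + vv) / (wts[j] + 1)
        wts[j] <- wts[j] + 1
        next
      }
    }
    if (nrow(reps) < max_candidates) { reps <- rbind(reps, v); wts <- c(wts, 1) }
  }
  cand <- reps[order(rowSums(reps^2)), , drop = FALSE]
  k <- nrow(cand)
  if (qr(cand)$rank < 3)
    stop("candidate difference vectors are coplanar: cannot form a 3D basis")
  best_frac <- 0
  for (i in 1:(k - 2)) for (j in (i + 1):(k - 1)) for (m in (j + 1):k) {
    ub <- cbind(cand[i, ], cand[j, ], cand[m, ])
    dt <- det(ub)
    if (abs(dt) < det_floor) next
    if (dt < 0) ub[, 3] <- -ub[, 3]       # right-handed basis
    r <- index_residuals(ub, q)
    frac <- mean(r$resid < tol)
    if (frac > best_frac) best_frac <- frac
    if (frac >= accept_frac) {
      sel <- r$resid < tol
      ub <- polish_ub(ub, q[sel, , drop = FALSE], r$hint[sel, , drop = FALSE])
      ix <- index_q(q, ub, tol)
      return(structure(list(ub = ub, cell = cell_from_ub(ub), indexed = ix,
                            frac_indexed = mean(ix$indexed),
                            method = "vector_minimum"),
                       class = "ub_fit"))
    }
  }
  stop(sprintf("no candidate basis indexed >= %.0f%% of the observations (best %.0f%%)",
               100 * accept_frac, 100 * best_frac))
}

## One linear LS pass of UB against (hkl, q) pairs.
polish_ub <- function(ub, q, hint) {
  if (nrow(q) < 3 || qr(hint)$rank < 3) return(ub)
  t(lm.fit(hint, q)$coefficients)
}

#' @export
print.ub_fit <- function(x, ...) {
  cat(sprintf("UB fit (%s)\n", x$method))
  print(round(x$ub, 6))
  print(x$cell)
  if (!is.null(x$frac_indexed))
    cat(sprintf("  indexed: %.1f%% of %d observations\n",
                100 * x$frac_indexed, nrow(x$indexed)))
  if (!is.null(x$lattice)) cat("  Bravais lattice:", x$lattice, "\n")
  if (!is.null(x$cell_su))
    cat("  cell s.u.:", paste(signif(x$cell_su, 3), collapse = " "), "\n")
  invisible(x)
}

#' UB from two indexed reflections and a known cell
#'
#' Standard two-reflection orientation: B is built from the cell; U
#' aligns the orthonormal frame spanned by (B h1, B h2) with the frame
#' spanned by (q1, q2).
#'
#' @param q1,q2 observed crystal-frame reciprocal vectors (1/Angstrom).
#' @param cell an [xtal_cell()].
#' @param hkl1,hkl2 assigned Miller indices.
#' @param norm_tol relative tolerance between |q| and 1/d from the cell.
#' @return A \code{"ub_fit"} list.
#' @export
ub_from_two_reflections <- function(q1, q2, cell, hkl1, hkl2,
                                    norm_tol = 0.02) {
  B <- bl_matrix(cell)
  h1 <- drop(B %*% hkl1); h2 <- drop(B %*% hkl2)
  if (sqrt(sum((h1 / sqrt(sum(h1^2)) - h2 / sqrt(sum(h2^2)))^2)) < 1e-6 ||
      sqrt(sum((h1 / sqrt(sum(h1^2)) + h2 / sqrt(sum(h2^2)))^2)) < 1e-6)
    stop("hkl1 and hkl2 are collinear")
  for (pair in list(list(q = q1, h = h1, lab = "q1"),
                    list(q = q2, h = h2, lab = "q2"))) {
    mism <- abs(sqrt(sum(pair$q^2)) - sqrt(sum(pair$h^2))) / sqrt(sum(pair$h^2))
    if (mism > norm_tol)
      stop(sprintf("|%s| disagrees with the cell prediction by %.1f%%",
                   pair$lab, 100 * mism))
  }
  Tc <- tri_frame(h1, h2)
  To <- tri_frame(q1, q2)
  U <- To %*% t(Tc)
  structure(list(ub = U %*% B, cell = cell, method = "two_reflections"),
            class = "ub_fit")
}

#' UB from three indexed reflections (no cell assumed)
#'
#' \code{UB = [q1 q2 q3] [h1 h2 h3]^-1}; exact on noise-free data.
#'
#' @param q1,q2,q3 observed reciprocal vectors.
#' @param hkl1,hkl2,hkl3 assigned Miller indices (linearly independent).
#' @return A \code{"ub_fit"} list.
#' @export
ub_from_three_reflections <- function(q1, q2, q3, hkl1, hkl2, hkl3) {
  H <- cbind(hkl1, hkl2, hkl3)
  if (abs(det(H)) < 1e-9) stop("hkl triple is coplanar (singular)")
  ub <- cbind(q1, q2, q3) %*% solve(H)
  dimnames(ub) <- NULL
  structure(list(ub = ub, cell = cell_from_ub(ub),
                 method = "three_reflections"), class = "ub_fit")
}

#' Monte-Carlo orientation search with a known cell
#'
#' Samples orientations uniformly on SO(3), scores each by the number of
#' observations indexed within \code{tol}, and refines the best by least
#' squares.  Deterministic for a given seed.
#'
#' @param qs q table or matrix.
#' @param cell the known [xtal_cell()].
#' @param seed mandatory RNG seed.
#' @param n_trials number of random orientations.
#' @param tol indexing tolerance (fractional hkl units).
#' @param min_frac minimum fraction that must be indexed for success.
#' @return A \code{"ub_fit"} list.
#' @export
ub_montecarlo <- function(qs, cell, seed, n_trials = 20000, tol = 0.1,
                          min_frac = 0.5) {
  if (missing(seed)) stop("ub_montecarlo requires a seed")
  q <- qmat(qs)
  B <- bl_matrix(cell)
  set.seed(seed)
  ## score candidate orientations on the lowest-order (shortest) q
  ## vectors: their fractional indices move slowest under misorientation,
  ## so a coarse random hit is still recognisable there
  ns <- min(12, nrow(q))
  short <- q[order(rowSums(q^2))[seq_len(ns)], , drop = FALSE]
  best <- NULL; best_n <- -1; best_sum <- Inf
  for (t in seq_len(n_trials)) {
    ub <- random_rotation() %*% B
    r <- index_residuals(ub, short)
    n_ok <- sum(r$resid < tol)
    s_ok <- sum(pmin(r$resid, tol))
    if (n_ok > best_n || (n_ok == best_n && s_ok < best_sum)) {
      best_n <- n_ok; best_sum <- s_ok; best <- ub
    }
  }
  ## grow from the low-order anchor: polish on whatever is indexed,
  ## re-index everything, repeat until the indexed count stops rising
  for (tol_i in unique(c(2 * tol, tol))) {
    repeat {
      r <- index_residuals(best, q)
      sel <- r$resid < tol_i
      if (sum(sel) < 3 || qr(r$hint[sel, , drop = FALSE])$rank < 3) break
      ub2 <- polish_ub(best, q[sel, , drop = FALSE],
                       r$hint[sel, , drop = FALSE])
      n_new <- sum(index_residuals(ub2, q)$resid < tol_i)
      if (n_new >= sum(sel)) best <- ub2
      if (n_new <= sum(sel)) break
    }
  }
  ix <- index_q(q, best, tol)
  frac <- mean(ix$indexed)
  if (frac < min_frac)
    stop(sprintf("Monte-Carlo search failed: best orientation indexes only %.0f%%",
                 100 * frac))
  structure(list(ub = best, cell = cell_from_ub(best), indexed = ix,
                 frac_indexed = frac, method = "montecarlo"),
            class = "ub_fit")
}

## ---- Bravais lattice handling -------------------------------------------

## Buerger-type reduction: shortest right-handed basis by iterated
## pair subtraction.  Returns list(ub, m) with ub = ub0 %*% solve(m),
## m integer, so conventional/reduced hkl = m %*% hkl_original.
reduce_basis <- function(ub0) {
  m <- diag(3)
  ub <- ub0
  repeat {
    changed <- FALSE
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      for (s in c(-1, 1)) {
        v <- ub[, i] + s * ub[, j]
        if (sum(v^2) < sum(ub[, i]^2) - 1e-12) {
          ub[, i] <- v
          m[, i] <- m[, i] + s * m[, j]   # track column ops on the basis
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  if (det(ub) < 0) { ub[, 3] <- -ub[, 3]; m[, 3] <- -m[, 3] }
  ## normalise: sort by length, then make all pairwise angles acute
  ## (type I) if possible, else all obtuse
  ord <- order(colSums(ub^2))
  ub <- ub[, ord]; m <- m[, ord]
  if (det(ub) < 0) { ub[, 3] <- -ub[, 3]; m[, 3] <- -m[, 3] }
  dots <- c(sum(ub[, 2] * ub[, 3]), sum(ub[, 1] * ub[, 3]),
            sum(ub[, 1] * ub[, 2]))
  n_acute <- sum(dots > 1e-9)
  if (n_acute == 2 || n_acute == 1) {
    ## flip one vector to make the count 3 or 0
    for (i in 1:3) {
      ub2 <- ub; ub2[, i] <- -ub2[, i]
      d2 <- c(sum(ub2[, 2] * ub2[, 3]), sum(ub2[, 1] * ub2[, 3]),
              sum(ub2[, 1] * ub2[, 2]))
      if (all(d2 > -1e-9) || all(d2 < 1e-9)) {
        ub[, i] <- -ub[, i]; m[, i] <- -m[, i]; break
      }
    }
  }
  if (det(ub) < 0) {
    ub <- ub[, c(2, 1, 3)]; m <- m[, c(2, 1, 3)]
  }
  ## hkl transform: q = ub0 h0 = ub h_new with ub = ub0 %*% Minv
  ## (columns of ub are integer combinations of columns of ub0: ub = ub0 %*% m)
  list(ub = ub, m = m)
}

lattice_signature <- function(cell, tol_len, tol_ang) {
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  al <- cell[["alpha"]]; be <- cell[["beta"]]; ga <- cell[["gamma"]]
  eq <- function(u, v) abs(u - v) <= tol_len * (u + v) / 2
  aeq <- function(u, v) abs(u - v) <= tol_ang
  angs <- c(al, be, ga)
  list(ab = eq(a, b), bc = eq(b, cc), ac = eq(a, cc),
       a90 = aeq(al, 90), b90 = aeq(be, 90), g90 = aeq(ga, 90),
       all90 = all(aeq(angs, 90)),
       all60 = all(aeq(angs, 60)),
       all109 = all(aeq(angs, rad2deg(acos(-1 / 3)))),
       allsame = aeq(al, be) && aeq(be, ga))
}

#' Bravais lattice search from a primitive UB
#'
#' Reduces the primitive basis (Buerger-type shortest basis), then tests
#' metric signatures of the reduced cell against lattice symmetries in
#' decreasing symmetry order: cubic P/F/I, rhombohedral, hexagonal,
#' tetragonal P, orthorhombic P/C, monoclinic P, triclinic P.  The
#' returned UB is transformed to the conventional cell of the assigned
#' lattice by the corresponding integer matrix.
#'
#' @param ub primitive 3x3 UB matrix.
#' @param tol_len relative length tolerance (default 0.2\%).
#' @param tol_ang angle tolerance in degrees (default 0.2).
#' @return List \code{(ub, cell, lattice, m)} where \code{lattice} is a
#'   symbol such as \code{"cF"}, \code{"mP"}, \code{"aP"} and \code{m}
#'   maps original hkl to conventional hkl.
#' @export
bravais_search <- function(ub, tol_len = 0.002, tol_ang = 0.2) {
  ub_orig <- ub
  red <- reduce_basis(ub)
  cell <- cell_from_ub(red$ub)
  sig <- lattice_signature(cell, tol_len, tol_ang)
  ## h_conv = m h_orig follows from q = UB_orig h_orig = UB_conv h_conv;
  ## m must come out integer for a valid lattice transformation
  finish <- function(ub_c, symbol) {
    if (det(ub_c) < 0) ub_c[, 3] <- -ub_c[, 3]
    m <- solve(ub_c) %*% ub_orig
    if (max(abs(m - round(m))) > 0.05)
      return(NULL)                       # not a lattice-preserving map
    list(ub = ub_c, cell = cell_from_ub(ub_c), lattice = symbol,
         m = round(m))
  }
  samelen <- sig$ab && sig$bc && sig$ac
  if (samelen && sig$all90) {
    r <- finish(red$ub, "cP"); if (!is.null(r)) return(r)
  }
  if (samelen && sig$all60) {
    ## FCC primitive (all 60 deg): conventional a = -p1+p2+p3 etc.
    p <- red$ub
    ub_c <- cbind(-p[, 1] + p[, 2] + p[, 3], p[, 1] - p[, 2] + p[, 3],
                  p[, 1] + p[, 2] - p[, 3]) / 2
    ## reciprocal: conventional a* such that a_conv = (p2+p3-p1)...
    ## the conventional *reciprocal* basis is ub_c above only if the
    ## direct cells relate by the F transform; build from direct space:
    A <- solve(t(red$ub))                 # direct basis columns
    Ac <- cbind(-A[, 1] + A[, 2] + A[, 3], A[, 1] - A[, 2] + A[, 3],
                A[, 1] + A[, 2] - A[, 3])
    r <- finish(t(solve(Ac)), "cF"); if (!is.null(r)) return(r)
  }
  if (samelen && sig$all109) {
    A <- solve(t(red$ub))
    Ac <- cbind(A[, 2] + A[, 3], A[, 1] + A[, 3], A[, 1] + A[, 2])
    r <- finish(t(solve(Ac)), "cI"); if (!is.null(r)) return(r)
  }
  if (samelen && sig$allsame && !sig$all90) {
    r <- finish(red$ub, "hR"); if (!is.null(r)) return(r)
  }
  ## hexagonal: two equal edges both perpendicular to c, angle 60/120
  for (p in list(c(1, 2, 3), c(2, 3, 1), c(1, 3, 2))) {
    ubp <- red$ub[, p]
    cp <- cell_from_ub(ubp)
    s <- lattice_signature(cp, tol_len, tol_ang)
    g <- cp[["gamma"]]
    if (s$ab && s$a90 && s$b90 && abs(g - 120) <= tol_ang) {
      r <- finish(ubp, "hP"); if (!is.null(r)) return(r)
    }
    if (s$ab && s$a90 && s$b90 && abs(g - 60) <= tol_ang) {
      ub2 <- ubp; ub2[, 2] <- ubp[, 2] - ubp[, 1]   # open gamma to 120
      r <- finish(ub2, "hP"); if (!is.null(r)) return(r)
    }
  }
  if (sig$all90 && (sig$ab || sig$bc || sig$ac)) {
    ## tetragonal: unique axis last
    p <- if (sig$ab) c(1, 2, 3) else if (sig$bc) c(2, 3, 1) else c(3, 1, 2)
    r <- finish(red$ub[, p], "tP"); if (!is.null(r)) return(r)
  }
  if (sig$all90) {
    r <- finish(red$ub, "oP"); if (!is.null(r)) return(r)
  }
  ## C-centred orthorhombic: two equal edges perpendicular to the third,
  ## included angle free; conventional a, b are the diagonals
  for (p in list(c(1, 2, 3), c(2, 3, 1), c(1, 3, 2))) {
    ubp <- red$ub[, p]
    cp <- cell_from_ub(ubp)
    s <- lattice_signature(cp, tol_len, tol_ang)
    if (s$ab && s$a90 && s$b90 && !s$g90 &&
        !(abs(cp[["gamma"]] - 60) <= tol_ang) &&
        !(abs(cp[["gamma"]] - 120) <= tol_ang)) {
      A <- solve(t(ubp))
      Ac <- cbind(A[, 1] + A[, 2], A[, 2] - A[, 1], A[, 3])
      r <- finish(t(solve(Ac)), "oC"); if (!is.null(r)) return(r)
    }
  }
  ## monoclinic: exactly one non-90 angle; unique axis -> b, beta > 90
  n90 <- c(sig$a90, sig$b90, sig$g90)
  if (sum(n90) == 2) {
    free <- which(!n90)          # 1: alpha free, 2: beta free, 3: gamma free
    ## cyclic permutations keep handedness and carry the free angle to beta
    p <- switch(free, c(3, 1, 2), c(1, 2, 3), c(2, 3, 1))
    ubp <- red$ub[, p]
    ## beta >= 90 convention: flipping a and b together sends beta to
    ## 180 - beta while keeping alpha = gamma = 90 and the handedness
    if (cell_from_ub(ubp)[["beta"]] < 90) ubp[, 1:2] <- -ubp[, 1:2]
    r <- finish(ubp, "mP"); if (!is.null(r)) return(r)
  }
  f <- finish(red$ub, "aP")
  if (is.null(f)) f <- list(ub = red$ub, cell = cell, lattice = "aP",
                            m = red$m)
  f
}

#' Least-squares UB refinement
#'
#' Refines the nine UB elements linearly against indexed (hkl, q) pairs:
#' each Cartesian component of q is an independent regression on the
#' integer indices.  Reports the refined cell with standard
#' uncertainties propagated from the fit covariance (delta method).
#'
#' @param ub0 starting UB (used to index if \code{hkl} missing).
#' @param qs q table or matrix.
#' @param hkl optional integer matrix of assigned indices; default:
#'   nearest integers under \code{ub0} for observations within
#'   \code{tol}.
#' @param tol indexing tolerance when assigning.
#' @return A \code{"ub_fit"} list with \code{cell_su} (s.u. of a, b, c,
#'   alpha, beta, gamma), \code{rms_residual} before/after, and the
#'   indexed table.
#' @export
refine_ub_lsq <- function(ub0, qs, hkl = NULL, tol = 0.1) {
  q <- qmat(qs)
  if (is.null(hkl)) {
    r <- index_residuals(ub0, q)
    sel <- r$resid < tol
    q <- q[sel, , drop = FALSE]
    hkl <- r$hint[sel, , drop = FALSE]
  } else hkl <- rbind(hkl)
  n <- nrow(q)
  if (n < 3 || qr(hkl)$rank < 3)
    stop("need >= 3 indexed observations spanning three dimensions")
  H <- hkl
  fit <- lm.fit(H, q)
  ub <- t(fit$coefficients)
  dimnames(ub) <- NULL
  rms_before <- sqrt(mean(rowSums((q - t(ub0 %*% t(H)))^2)))
  rms_after <- sqrt(mean(rowSums(fit$residuals^2)))
  ## covariance: per component j, sigma_j^2 * (H'H)^-1 (block diagonal)
  HtHinv <- solve(t(H) %*% H)
  dof <- max(n - 3, 1)
  sig2 <- colSums(fit$residuals^2) / dof
  cov_rows <- lapply(sig2, function(s) s * HtHinv)
  ## delta method for the six cell parameters
  cellp <- function(u) unclass(cell_from_ub(matrix(u, 3, 3)))
  u0 <- as.numeric(ub)
  J <- matrix(0, 6, 9)
  epsu <- 1e-7
  for (i in 1:9) {
    up <- u0; up[i] <- up[i] + epsu
    um <- u0; um[i] <- um[i] - epsu
    J[, i] <- (cellp(up) - cellp(um)) / (2 * epsu)
  }
  ## element (j, i) of ub = row j, col i -> as.numeric stacks columns:
  ## index 3*(i-1)+j; covariance couples elements of the same row j
  Sigma <- matrix(0, 9, 9)
  for (j in 1:3) {
    rows <- j + 3 * (0:2)
    Sigma[rows, rows] <- cov_rows[[j]]
  }
  cell_su <- sqrt(pmax(diag(J %*% Sigma %*% t(J)), 0))
  names(cell_su) <- c("a", "b", "c", "alpha", "beta", "gamma")
  ix <- index_q(q, ub, tol)
  structure(list(ub = ub, cell = cell_from_ub(ub), cell_su = cell_su,
                 indexed = ix, frac_indexed = mean(ix$indexed),
                 rms_before = rms_before, rms_residual = rms_after,
                 method = "lsq"), class = "ub_fit")
}

#' Predict observable reflections for a scan
#'
#' Enumerates every hkl inside the Ewald limit, solves the rotation
#' diffraction condition and returns the (frame, X, Y) where each
#' reachable reflection will appear.  Thin wrapper over [predict_spots()]
#' with the indexing-side defaults.
#'
#' @param ub UB matrix.
#' @param geom,scan geometry and scan.
#' @param keep which predictions to keep (see [predict_spots()]).
#' @return Prediction table (see [predict_spots()]).
#' @export
predict_observations <- function(ub, geom, scan, keep = "window")
  predict_spots(ub, geom, scan, keep = keep)
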