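## Frame-stack container and on-disk dialects.
##
## A frame stack holds the ordered image frames of one continuous
## phi-rotation scan.  On disk a stack is one raw binary file per frame
## (little-endian) plus a single human-readable sidecar describing the
## geometry, the scan and the frame files:
##   full mode    - 4-byte unsigned pixels over the whole face
##                  (512 x 512 -> exactly 1 MiB per frame)
##   reduced mode - 2-byte pixels cropped to the active window; values
##                  above 65535 saturate with a warning

#' Build a frame stack
#'
#' @param frames list of numeric matrices (n_x rows by n_y columns;
#'   element \code{[i+1, j+1]} is channel (i, j), 0-based).  Counts may be
#'   fractional in memory (noiseless simulations); files store integers.
#' @param scan a [scan_config()].
#' @param geom a [detector_geometry()].
#' @return An object of class \code{"frame_stack"}.
#' @export
frame_stack <- function(frames, scan, geom) {
  stopifnot(inherits(scan, "scan_config"), inherits(geom, "detector_geometry"))
  if (length(frames) != scan$n_frames)
    stop(sprintf("got %d frames but scan declares %d", length(frames),
                 scan$n_frames))
  for (f in frames) {
    if (!is.matrix(f) || nrow(f) != geom$n_x || ncol(f) != geom$n_y)
      stop("frame shape does not match the detector geometry")
    if (any(f < 0)) stop("negative counts in frame")
  }
  structure(list(frames = frames, scan = scan, geom = geom),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  tot <- sum(vapply(x$frames, sum, 0))
  cat(sprintf("Frame stack: %d frames of %d x %d, delta_phi %g deg, total counts %.4g\n",
              length(x$frames), x$geom$n_x, x$geom$n_y, x$scan$delta_phi, tot))
  invisible(x)
}

## Mid-phi of frame index f (0-based).
frame_phi_mid <- function(scan, f) scan$phi_start + (f + 0.5) * scan$delta_phi

#' Raw-data size bookkeeping
#'
#' Exact byte counts of a stack's binary payload together with the
#' decimal-convention sizes conventionally quoted for this instrument
#' (1 "MB" = one 512 x 512 x 4-byte frame; a 1800-frame scan is "1.8 GB").
#'
#' @param n_frames number of frames.
#' @param n_x,n_y face dimensions in channels.
#' @param mode \code{"full"} (4 bytes/pixel, whole face) or
#'   \code{"reduced"} (2 bytes/pixel over the active window).
#' @param geom geometry (needed for the reduced-mode crop).
#' @return List with \code{bytes_per_frame}, \code{total_bytes},
#'   \code{mb_per_frame} and \code{gb_total} (decimal convention).
#' @export
stack_size_report <- function(n_frames, n_x = 512, n_y = 512,
                              mode = c("full", "reduced"), geom = NULL) {
  mode <- match.arg(mode)
  if (mode == "full") {
    bpf <- n_x * n_y * 4
  } else {
    if (is.null(geom)) stop("reduced mode needs the geometry for the crop")
    cr <- window_crop(geom)
    bpf <- cr$nx * cr$ny * 2
  }
  list(bytes_per_frame = bpf, total_bytes = n_frames * bpf,
       mb_per_frame = bpf / 2^20, gb_total = n_frames * bpf / 2^20 / 1000)
}

## Integer channel crop of the active window (inclusive of boundary pixels).
window_crop <- function(geom) {
  aw <- geom$active_window
  x1 <- max(0L, floor(aw[1])); x2 <- min(geom$n_x - 1L, ceiling(aw[3]))
  y1 <- max(0L, floor(aw[2])); y2 <- min(geom$n_y - 1L, ceiling(aw[4]))
  list(x1 = x1, x2 = x2, y1 = y1, y2 = y2,
       nx = x2 - x1 + 1L, ny = y2 - y1 + 1L)
}

#' Write a frame stack to disk
#'
#' @param stack a [frame_stack()].
#' @param path directory to create/use; one binary file per frame plus a
#'   \code{stack.info} sidecar is written there.
#' @param mode \code{"full"} or \code{"reduced"} (see [frame_stack()]).
#' @return Invisibly, the sidecar path.
#' @export
write_stack <- function(stack, path, mode = c("full", "reduced")) {
  mode <- match.arg(mode)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  geom <- stack$geom; scan <- stack$scan
  cr <- window_crop(geom)
  n <- length(stack$frames)
  files <- sprintf("frame_%05d.raw", seq_len(n) - 1L)
  for (i in seq_len(n)) {
    m <- round(stack$frames[[i]])
    if (mode == "reduced") {
      m <- m[(cr$x1 + 1L):(cr$x2 + 1L), (cr$y1 + 1L):(cr$y2 + 1L), drop = FALSE]
      if (any(m > 65535)) {
        warning("pixel value above 65535 saturated in reduced mode")
        m[m > 65535] <- 65535
      }
      ## writeBin has no unsigned 16-bit type: map to signed range losslessly
      v <- as.integer(m); v[v > 32767L] <- v[v > 32767L] - 65536L
      con <- file(file.path(path, files[i]), "wb")
      writeBin(v, con, size = 2, endian = "little")
    } else {
      con <- file(file.path(path, files[i]), "wb")
      writeBin(as.integer(m), con, size = 4, endian = "little")
    }
    close(con)
  }
  side <- file.path(path, "stack.info")
  aw <- geom$active_window
  lines <- c(
    "format = psdred-stack-1",
    paste("mode =", mode),
    paste("n_frames =", n),
    paste("n_x =", geom$n_x), paste("n_y =", geom$n_y),
    paste("crop =", paste(c(cr$x1, cr$y1, cr$x2, cr$y2), collapse = " ")),
    paste("wavelength =", format(scan$wavelength, digits = 12)),
    paste("phi_start =", format(scan$phi_start, digits = 12)),
    paste("delta_phi =", format(scan$delta_phi, digits = 12)),
    paste("omega_offset =", format(scan$omega_offset, digits = 12)),
    paste("L =", geom$L), paste("c_x =", geom$c_x), paste("c_y =", geom$c_y),
    paste("x0 =", geom$x0), paste("y0 =", geom$y0),
    paste("xy_slope =", geom$xy_slope), paste("arm_angle =", geom$arm_angle),
    paste("chi_mode =", geom$chi_mode),
    paste("active_window =", paste(aw, collapse = " ")),
    paste("frames =", paste(files, collapse = " ")))
  writeLines(lines, side)
  invisible(side)
}

read_kv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  stats::setNames(as.list(vals), keys)
}

#' Read a frame stack from disk
#'
#' Lossless inverse of [write_stack()].  Reduced-mode frames are
#' re-embedded into full-face coordinates with zeros outside the crop.
#'
#' @param path directory holding \code{stack.info} and the frame binaries.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path) {
  side <- file.path(path, "stack.info")
  if (!file.exists(side)) stop("no stack.info sidecar in ", path)
  kv <- read_kv(side)
  num <- function(k) as.numeric(kv[[k]])
  geom <- detector_geometry(L = num("L"), n_x = num("n_x"), n_y = num("n_y"),
                            c_x = num("c_x"), c_y = num("c_y"),
                            x0 = num("x0"), y0 = num("y0"),
                            xy_slope = num("xy_slope"),
                            arm_angle = num("arm_angle"),
                            active_window = as.numeric(strsplit(kv$active_window, " +")[[1]]),
                            chi_mode = kv$chi_mode)
  scan <- scan_config(wavelength = num("wavelength"), phi_start = num("phi_start"),
                      delta_phi = num("delta_phi"), n_frames = num("n_frames"),
                      omega_offset = num("omega_offset"))
  mode <- kv$mode
  files <- if (is.null(kv$frames) || !nzchar(kv$frames)) character(0)
           else strsplit(kv$frames, " +")[[1]]
  if (length(files) != scan$n_frames)
    stop("sidecar lists ", length(files), " frames but declares ", scan$n_frames)
  cr <- as.integer(strsplit(kv$crop, " +")[[1]])   # x1 y1 x2 y2
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    fp <- file.path(path, files[i])
    if (mode == "reduced") {
      nx <- cr[3] - cr[1] + 1L; ny <- cr[4] - cr[2] + 1L
      expected <- nx * ny
      con <- file(fp, "rb")
      v <- readBin(con, "integer", n = expected + 1L, size = 2,
                   endian = "little", signed = TRUE)
      close(con)
      if (length(v) != expected)
        stop("corrupt frame file ", files[i], ": expected ", expected,
             " pixels, found ", length(v))
      v[v < 0L] <- v[v < 0L] + 65536L
      full <- matrix(0, geom$n_x, geom$n_y)
      full[(cr[1] + 1L):(cr[3] + 1L), (cr[2] + 1L):(cr[4] + 1L)] <-
        matrix(v, nx, ny)
      frames[[i]] <- full
    } else {
      expected <- geom$n_x * geom$n_y
      con <- file(fp, "rb")
      v <- readBin(con, "integer", n = expected + 1L, size = 4,
                   endian = "little")
      close(con)
      if (length(v) != expected)
        stop("corrupt frame file ", files[i], ": expected ", expected,
             " pixels, found ", length(v))
      frames[[i]] <- matrix(v, geom$n_x, geom$n_y)
    }
  }
  frame_stack(frames, scan, geom)
}

## ---- text table dialects -------------------------------------------------
## whitespace-delimited, one header line; the four kinds link the pipeline
## stages (peaks list, reciprocal-space list, UB matrix, hkl intensities).

table_schemas <- list(
  peaks = c("peak", "frame", "x", "y", "intensity"),
  qlist = c("peak", "qx", "qy", "qz", "intensity"),
  hkl   = c("h", "k", "l", "f2", "sig_f2", "flag"))

#' Write a pipeline table
#'
#' Writes the whitespace-delimited text tables linking pipeline stages:
#' \describe{
#'   \item{peaks}{\code{peak frame x y intensity} (2D peak list)}
#'   \item{qlist}{\code{peak qx qy qz intensity} (reciprocal-space list,
#'     1/Angstrom, 9 significant digits)}
#'   \item{ub}{3x3 UB matrix row-major plus the derived cell}
#'   \item{hkl}{\code{h k l f2 sig_f2 flag}}
#' }
#'
#' @param records a data.frame matching the kind's schema (for
#'   \code{kind = "ub"}, a list with elements \code{ub} and \code{cell}).
#' @param kind one of \code{"peaks"}, \code{"qlist"}, \code{"ub"},
#'   \code{"hkl"}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_table_file <- function(records, kind = c("peaks", "qlist", "ub", "hkl"),
                             path) {
  kind <- match.arg(kind)
  if (kind == "ub") {
    ub <- records$ub; cell <- records$cell
    stopifnot(is.matrix(ub), all(dim(ub) == 3))
    lines <- c("# psdred ub",
               apply(format(ub, digits = 12), 1, paste, collapse = " "),
               paste("# cell", paste(format(unclass(cell), digits = 10),
                                     collapse = " ")))
    writeLines(lines, path)
    return(invisible(path))
  }
  sch <- table_schemas[[kind]]
  miss <- setdiff(sch, names(records))
  if (length(miss))
    stop("missing column(s) for '", kind, "' table: ", paste(miss, collapse = ", "))
  df <- records[, sch, drop = FALSE]
  for (cn in sch) {
    bad <- if (is.character(df[[cn]])) !nzchar(df[[cn]]) else !is.finite(df[[cn]])
    if (any(bad))
      stop(sprintf("invalid value in row %d, column '%s'", which(bad)[1], cn))
  }
  if (kind == "qlist")
    for (cn in c("qx", "qy", "qz"))
      df[[cn]] <- formatC(df[[cn]], digits = 9, format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(sch, collapse = " "), con)
  utils::write.table(df, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a pipeline table
#'
#' @param path file written by [write_table_file()].
#' @param kind table kind (see [write_table_file()]).
#' @return A data.frame, or for \code{kind = "ub"} a list
#'   \code{(ub, cell)}.
#' @export
read_table_file <- function(path, kind = c("peaks", "qlist", "ub", "hkl")) {
  kind <- match.arg(kind)
  if (kind == "ub") {
    lines <- readLines(path, warn = FALSE)
    rows <- lines[!startsWith(trimws(lines), "#")]
    ub <- do.call(rbind, lapply(strsplit(trimws(rows), " +"), as.numeric))
    if (!all(dim(ub) == 3)) stop("malformed ub file")
    cl <- grep("^# cell", lines, value = TRUE)
    cell <- NULL
    if (length(cl)) {
      p <- as.numeric(strsplit(trimws(sub("^# cell", "", cl[1])), " +")[[1]])
      cell <- xtal_cell(p[1], p[2], p[3], p[4], p[5], p[6])
    }
    return(list(ub = ub, cell = cell))
  }
  sch <- table_schemas[[kind]]
  if (length(readLines(path, warn = FALSE)) <= 1) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(sch)), sch))
    if (kind == "hkl") df$flag <- character(0)
    return(df)
  }
  utils::read.table(path, header = FALSE, skip = 1,
                    col.names = sch, stringsAsFactors = FALSE)
}
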