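## End-to-end pipeline: simulate -> findpeaks -> merge -> index ->
## predict -> reduce, with a run manifest (config snapshot, file digests,
## seeds, per-stage counts and timings).

#' Read or write a configuration profile
#'
#' One flat, human-editable \code{key = value} text format carries the
#' geometry, scan and processing parameters for every stage.  A packaged
#' profile \code{"hanaro"} holds the curved-detector instrument constants
#' (conversion factors, origin, slope, window) and the primary 1.153 A
#' wavelength; \code{"demo"} is a small orthorhombic test crystal sized
#' so a full synthetic run takes seconds.
#'
#' @param path file path, or the name of a packaged profile.
#' @return A named list with elements \code{geom} ([detector_geometry()]),
#'   \code{scan} ([scan_config()]), \code{cell} ([xtal_cell()]) and
#'   \code{params} (remaining scalar settings).
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) {
    sys <- system.file("extdata", paste0(path, ".profile"), package = "psdred")
    if (!nzchar(sys)) stop("no such profile or file: ", path)
    path <- sys
  }
  kv <- read_kv(path)
  num <- function(k, d = NULL) if (!is.null(kv[[k]])) as.numeric(kv[[k]]) else d
  geom <- detector_geometry(
    L = num("L", 530), n_x = num("n_x", 512), n_y = num("n_y", 512),
    c_x = num("c_x", 0.2614), c_y = num("c_y", 0.003917),
    x0 = num("x0", 181.50), y0 = num("y0", 94.135),
    xy_slope = num("xy_slope", 0.0041), arm_angle = num("arm_angle", 40),
    active_window = c(num("win_x_min", 60), num("win_y_min", 9.06),
                      num("win_x_max", 460), num("win_y_max", 269.60)),
    chi_mode = if (!is.null(kv$chi_mode)) kv$chi_mode else "tan")
  scan <- scan_config(wavelength = num("wavelength", 1.153),
                      phi_start = num("phi_start", 0),
                      delta_phi = num("delta_phi", 0.2),
                      n_frames = num("n_frames",
                                     round(360 / num("delta_phi", 0.2))),
                      omega_offset = num("omega_offset", 0))
  cell <- if (!is.null(kv$cell_a))
    xtal_cell(num("cell_a"), num("cell_b", num("cell_a")),
              num("cell_c", num("cell_a")), num("cell_alpha", 90),
              num("cell_beta", 90), num("cell_gamma", 90))
  params <- list(threshold = num("threshold", 10),
                 box = num("box", 11),
                 xy_tol = num("xy_tol", 1.5),
                 gap_tol = num("gap_tol", 0),
                 index_tol = num("index_tol", 0.1),
                 intensity = num("intensity", 1e4),
                 background = num("background", 0),
                 sigma_x = num("sigma_x", 1.34),
                 sigma_y = num("sigma_y", 1.13),
                 sigma_phi = num("sigma_phi", 0.3),
                 hkl_max = num("hkl_max", NA),
                 noise = if (!is.null(kv$noise)) kv$noise else "none")
  list(geom = geom, scan = scan, cell = cell, params = params)
}

#' @rdname read_profile
#' @param profile a profile list as returned by [read_profile()].
#' @export
write_profile <- function(profile, path) {
  g <- profile$geom; s <- profile$scan; p <- profile$params
  fmt <- function(x) format(x, digits = 12)
  lines <- c("# psdred configuration profile",
             paste("L =", fmt(g$L)), paste("n_x =", g$n_x),
             paste("n_y =", g$n_y), paste("c_x =", fmt(g$c_x)),
             paste("c_y =", fmt(g$c_y)), paste("x0 =", fmt(g$x0)),
             paste("y0 =", fmt(g$y0)), paste("xy_slope =", fmt(g$xy_slope)),
             paste("arm_angle =", fmt(g$arm_angle)),
             paste("win_x_min =", fmt(g$active_window[1])),
             paste("win_y_min =", fmt(g$active_window[2])),
             paste("win_x_max =", fmt(g$active_window[3])),
             paste("win_y_max =", fmt(g$active_window[4])),
             paste("chi_mode =", g$chi_mode),
             paste("wavelength =", fmt(s$wavelength)),
             paste("phi_start =", fmt(s$phi_start)),
             paste("delta_phi =", fmt(s$delta_phi)),
             paste("n_frames =", s$n_frames),
             paste("omega_offset =", fmt(s$omega_offset)))
  if (!is.null(profile$cell)) {
    cl <- profile$cell
    lines <- c(lines,
               paste("cell_a =", fmt(cl[["a"]])), paste("cell_b =", fmt(cl[["b"]])),
               paste("cell_c =", fmt(cl[["c"]])),
               paste("cell_alpha =", fmt(cl[["alpha"]])),
               paste("cell_beta =", fmt(cl[["beta"]])),
               paste("cell_gamma =", fmt(cl[["gamma"]])))
  }
  for (nm in names(p))
    if (!is.na(p[[nm]])) lines <- c(lines, paste(nm, "=", fmt(p[[nm]])))
  writeLines(lines, path)
  invisible(path)
}

pipeline_stages <- c("simulate", "findpeaks", "merge", "index", "predict",
                     "reduce")

#' Run the reduction pipeline
#'
#' Executes the stages in order, writing each stage's output file to
#' \code{outdir} so any stage can be resumed from prior outputs.  With
#' identical configuration and seed the outputs are bit-identical.
#'
#' @param profile a profile list from [read_profile()] (must include a
#'   cell when the \code{simulate} stage runs).
#' @param outdir output directory.
#' @param stages subset of \code{c("simulate", "findpeaks", "merge",
#'   "index", "predict", "reduce")}; earlier outputs must exist when a
#'   prefix is skipped.
#' @param seed integer seed controlling the simulated orientation and any
#'   Poisson noise.
#' @param orientation optional 3x3 rotation for the simulated crystal;
#'   default: random from \code{seed}.
#' @return A run-manifest list: per-stage record counts, timings,
#'   output-file md5 digests, the seed and a config snapshot path.
#' @export
run_pipeline <- function(profile, outdir, stages = pipeline_stages,
                         seed = 1, orientation = NULL) {
  stopifnot(all(stages %in% pipeline_stages))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  geom <- profile$geom; scan <- profile$scan; p <- profile$params
  manifest <- list(package_version = as.character(utils::packageVersion("psdred")),
                   seed = seed, stages = list())
  snap <- file.path(outdir, "config.profile")
  write_profile(profile, snap)
  manifest$config <- unname(tools::md5sum(snap))
  paths <- list(stack = file.path(outdir, "stack"),
                truth = file.path(outdir, "truth.dat"),
                peaks = file.path(outdir, "peaks.dat"),
                peaks3d = file.path(outdir, "peaks3d.dat"),
                qlist = file.path(outdir, "qlist.dat"),
                ub = file.path(outdir, "ub.dat"),
                pred = file.path(outdir, "predictions.dat"),
                hkl = file.path(outdir, "reflections.hkl"),
                rejects = file.path(outdir, "rejects.dat"))
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- fun()
    manifest$stages[[name]] <<- c(out,
                                  list(seconds = proc.time()[["elapsed"]] - t0))
    out
  }
  mem <- new.env()
  if ("simulate" %in% stages) stage("simulate", function() {
    if (is.null(profile$cell)) stop("simulate stage needs a cell in the profile")
    set.seed(seed)
    u <- if (is.null(orientation)) random_rotation() else orientation
    ub <- ub_matrix(profile$cell, u)
    hkl <- NULL
    if (!is.na(p$hkl_max)) {
      g <- as.matrix(expand.grid(h = -p$hkl_max:p$hkl_max,
                                 k = -p$hkl_max:p$hkl_max,
                                 l = -p$hkl_max:p$hkl_max))
      hkl <- g[rowSums(abs(g)) > 0, ]
    }
    preds <- predict_spots(ub, geom, scan, hkl = hkl)
    st <- render_frames(preds, p$intensity, scan, geom,
                        sigma_x = p$sigma_x, sigma_y = p$sigma_y,
                        sigma_phi = p$sigma_phi, background = p$background,
                        noise = p$noise,
                        seed = if (p$noise == "poisson") seed)
    write_stack(st, paths$stack)
    utils::write.table(cbind(preds, intensity = p$intensity), paths$truth,
                       row.names = FALSE, quote = FALSE)
    mem$stack <- st; mem$ub_truth <- ub
    list(records = nrow(preds),
         digest = unname(tools::md5sum(file.path(paths$stack, "stack.info"))))
  })
  if ("findpeaks" %in% stages) stage("findpeaks", function() {
    if (is.null(mem$stack)) mem$stack <- read_stack(paths$stack)
    pk <- find_peaks_stack(mem$stack, threshold = p$threshold, box = p$box)
    write_table_file(data.frame(peak = pk$peak, frame = pk$frame, x = pk$x,
                                y = pk$y, intensity = pk$net_intensity),
                     "peaks", paths$peaks)
    mem$peaks <- pk
    list(records = nrow(pk), digest = unname(tools::md5sum(paths$peaks)))
  })
  if ("merge" %in% stages) stage("merge", function() {
    if (is.null(mem$peaks)) stop("merge stage needs the findpeaks output")
    if (is.null(mem$stack) && dir.exists(paths$stack))
      mem$stack <- read_stack(paths$stack)
    m <- merge_frames(mem$peaks, scan, xy_tol = p$xy_tol, gap_tol = p$gap_tol,
                      stack = mem$stack)
    utils::write.table(m, paths$peaks3d, row.names = FALSE, quote = FALSE)
    qs <- observations_to_q(m, geom, scan)
    write_table_file(qs[, c("peak", "qx", "qy", "qz", "intensity")],
                     "qlist", paths$qlist)
    mem$peaks3d <- m; mem$qs <- qs
    list(records = nrow(m), digest = unname(tools::md5sum(paths$qlist)))
  })
  if ("index" %in% stages) stage("index", function() {
    if (is.null(mem$qs)) {
      if (!file.exists(paths$qlist)) stop("index stage needs the qlist output")
      mem$qs <- read_table_file(paths$qlist, "qlist")
    }
    fit <- vector_minimum(mem$qs, tol = p$index_tol)
    fit <- refine_ub_lsq(fit$ub, mem$qs, tol = p$index_tol)
    write_table_file(list(ub = fit$ub, cell = fit$cell), "ub", paths$ub)
    mem$ub <- fit$ub
    list(records = nrow(fit$indexed),
         frac_indexed = fit$frac_indexed,
         digest = unname(tools::md5sum(paths$ub)))
  })
  if ("predict" %in% stages) stage("predict", function() {
    if (is.null(mem$ub)) mem$ub <- read_table_file(paths$ub, "ub")$ub
    pr <- predict_observations(mem$ub, geom, scan, keep = "all")
    utils::write.table(pr, paths$pred, row.names = FALSE, quote = FALSE)
    mem$pred <- pr
    list(records = nrow(pr), digest = unname(tools::md5sum(paths$pred)))
  })
  if ("reduce" %in% stages) stage("reduce", function() {
    if (is.null(mem$pred) || is.null(mem$peaks3d) || is.null(mem$ub))
      stop("reduce stage needs predict, merge and index outputs")
    cls <- classify_reflections(mem$pred, mem$peaks3d, mem$ub, geom, scan,
                                tol_recip = p$index_tol)
    out <- build_reflection_list(cls)
    export_reflections(out$reflections, paths$hkl, "plain")
    utils::write.table(out$rejects, paths$rejects, row.names = FALSE,
                       quote = FALSE)
    mem$reduced <- out
    list(records = nrow(out$reflections),
         counts = as.list(out$counts),
         digest = unname(tools::md5sum(paths$hkl)))
  })
  manifest$paths <- paths
  manifest$results <- as.list(mem)
  class(manifest) <- "psdred_manifest"
  manifest
}

#' @export
print.psdred_manifest <- function(x, ...) {
  cat("psdred pipeline run (seed", x$seed, ")\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-10s %6d records  %6.2f s  %s\n", nm,
                as.integer(s$records), s$seconds,
                if (!is.null(s$digest)) substr(s$digest, 1, 8) else ""))
  }
  invisible(x)
}
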