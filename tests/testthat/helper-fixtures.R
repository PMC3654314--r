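# Shared fixtures: all synthetic, built in code at test time.

nacl_cell <- function() xtal_cell(5.6402)

demo_profile <- function() read_profile("demo")

# Match each prediction row to its nearest 3D peak (X, Y and wrapped phi).
match_obs <- function(preds, m) {
  vapply(seq_len(nrow(preds)), function(i) {
    dphi <- ((preds$phi[i] - m$phi + 180) %% 360) - 180
    which.min(sqrt((preds$x[i] - m$x)^2 + (preds$y[i] - m$y)^2 + dphi^2))
  }, 0L)
}

# Independent d-spacing oracle: full reciprocal metric tensor built from
# scratch (not via the package's basis code).
d_oracle <- function(cell, hkl) {
  r <- pi / 180
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  al <- cell[["alpha"]] * r; be <- cell[["beta"]] * r; ga <- cell[["gamma"]] * r
  G <- matrix(c(a^2, a * b * cos(ga), a * cc * cos(be),
                a * b * cos(ga), b^2, b * cc * cos(al),
                a * cc * cos(be), b * cc * cos(al), cc^2), 3, 3)
  Gstar <- solve(G)
  1 / sqrt(drop(t(hkl) %*% Gstar %*% hkl))
}

# Sorted cell edges for permutation-free comparisons.
cell_edges <- function(cell) sort(unname(unclass(cell)[1:3]))

# Deterministic small rotation stack with a handful of isolated spots.
tiny_spot_stack <- function(xs = 200, ys = 150, phi = 10.3, intensity = 1e4,
                            background = 0, n_frames = 20, delta_phi = 1,
                            sigma_phi = 0.6, noise = "none", seed = NULL) {
  geom <- detector_geometry(n_x = 320, n_y = 240, x0 = 40, y0 = 120,
                            c_x = 0.3, c_y = 0.004,
                            active_window = c(10, 12, 310, 228))
  scan <- scan_config(1.5, 0, delta_phi, n_frames)
  preds <- data.frame(x = xs, y = ys, phi = phi)
  st <- render_frames(preds, intensity, scan, geom, sigma_phi = sigma_phi,
                      background = background, noise = noise, seed = seed)
  list(stack = st, geom = geom, scan = scan, preds = preds)
}
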