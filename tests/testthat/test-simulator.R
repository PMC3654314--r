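test_that("Ewald crossings match a brute-force phi-grid oracle", {
  geom <- detector_geometry()
  scan <- scan_config(1.153, 0, 0.2, 1800)
  lam <- scan$wavelength
  set.seed(10)
  n_checked <- 0
  for (rep in 1:8) {
    u <- random_rotation()
    ub <- ub_matrix(nacl_cell(), u)
    hkl <- as.matrix(expand.grid(h = -3:3, k = -3:3, l = -3:3))
    hkl <- hkl[rowSums(abs(hkl)) > 0, ]
    hkl <- hkl[sample(nrow(hkl), 25), ]
    p <- predict_spots(ub, geom, scan, hkl = hkl, keep = "all")
    for (i in seq_len(nrow(p))) {
      q0 <- drop(ub %*% c(p$h[i], p$k[i], p$l[i]))
      f <- function(phi) {
        ql <- drop(crystal_to_lab(q0, phi))
        ql[1] + lam * sum(ql^2) / 2
      }
      # refine a 0.001-degree bracket around the reported angle
      r <- uniroot(f, c(p$phi[i] - 0.01, p$phi[i] + 0.01), tol = 1e-10)
      expect_lt(abs(r$root - p$phi[i]), 0.005)
      n_checked <- n_checked + 1
    }
    # Bragg closed form for the total scattering angle
    idx <- which(p$h == 2 & p$k == 0 & p$l == 0)
    if (length(idx)) {
      c2t <- cos(p$chi_d[idx] * pi / 180) * cos(p$two_theta_b[idx] * pi / 180)
      expect_equal(acos(c2t) * 180 / pi,
                   rep(2 * asin(lam / (2 * d_spacing(nacl_cell(), c(2, 0, 0)))) *
                         180 / pi, length(idx)),
                   tolerance = 1e-6)
    }
  }
  expect_gte(n_checked, 200)
})

test_that("unreachable reflections yield no crossings", {
  ub <- ub_matrix(nacl_cell())
  geom <- detector_geometry()
  scan <- scan_config(1.153, 0, 1, 360)
  # |q| beyond the Ewald limit 2/lambda
  far <- predict_spots(ub, geom, scan, hkl = rbind(c(12, 12, 12)),
                       keep = "all")
  expect_equal(nrow(far), 0)
  # a vector along the rotation axis never crosses (blind region)
  axis <- predict_spots(ub, geom, scan, hkl = rbind(c(0, 0, 2)), keep = "all")
  expect_equal(nrow(axis), 0)
  expect_error(predict_spots(matrix(0, 3, 3), geom, scan), "singular")
})

test_that("rendering conserves spot mass and background", {
  geom <- detector_geometry(n_x = 64, n_y = 48, x0 = 32, y0 = 24,
                            c_x = 0.3, c_y = 0.004,
                            active_window = c(4, 4, 59, 43))
  scan <- scan_config(1.5, 0, 1, 30)
  empty <- render_frames(data.frame(x = numeric(0), y = numeric(0),
                                    phi = numeric(0))[0, ], 1, scan, geom)
  expect_true(all(vapply(empty$frames, function(f) all(f == 0), TRUE)))
  bg <- render_frames(empty_preds <- data.frame(x = numeric(0),
                                                y = numeric(0),
                                                phi = numeric(0)),
                      1, scan, geom, background = 2)
  expect_true(all(vapply(bg$frames, function(f) all(f == 2), TRUE)))
  # one in-face spot spanning ~4 frames: total deposit within 0.5%
  st <- render_frames(data.frame(x = 30, y = 20, phi = 15.2), 1e4, scan,
                      geom, sigma_phi = 1)
  expect_equal(sum(vapply(st$frames, sum, 0)), 1e4, tolerance = 5e-3)
  # off-face spot skipped with a message
  expect_message(render_frames(data.frame(x = 500, y = 20, phi = 5), 1e4,
                               scan, geom), "off-face")
})

test_that("Poisson noise is seed-reproducible and unbiased", {
  fx <- tiny_spot_stack(background = 3, noise = "poisson", seed = 99)
  fx2 <- tiny_spot_stack(background = 3, noise = "poisson", seed = 99)
  expect_identical(fx$stack$frames, fx2$stack$frames)
  expect_error(tiny_spot_stack(noise = "poisson"), "seed")
  # one pixel over 100 seeds: mean equals the noiseless value within 3 sigma
  noiseless <- tiny_spot_stack(background = 3)
  px <- noiseless$stack$frames[[11]][201, 151]
  draws <- vapply(1:100, function(s)
    tiny_spot_stack(background = 3, noise = "poisson",
                    seed = s)$stack$frames[[11]][201, 151], 0)
  expect_lt(abs(mean(draws) - px), 3 * sqrt(px / 100))
})

test_that("arm-scan simulation moves the spot linearly at slope -1/c_x", {
  sim <- simulate_calibration_sets("arm_scan", arm_angles = seq(20, 60, 5))
  fit <- lm(x ~ arm_angle, data = sim$truth)
  expect_equal(unname(coef(fit)[2]), -1 / 0.2614, tolerance = 1e-4)
  expect_equal(length(sim$stacks), nrow(sim$truth))
})

test_that("full-rotation scans draw layer lines", {
  g0 <- detector_geometry(xy_slope = 0)
  sim <- simulate_calibration_sets("full_rotation", geom = g0,
                                   wavelength = 1.153, delta_phi = 10,
                                   hkl_max = 3)
  tr <- sim$truth
  # equatorial layer (l = 0) sits exactly on the equator line Y0
  expect_true(all(abs(tr$y[tr$l == 0] - g0$y0) < 1e-9))
  # layers are horizontal bands: one Y per l
  for (l in unique(tr$l))
    expect_lt(diff(range(tr$y[tr$l == l])), 1e-6)
})

test_that("throughput model reproduces the survey-time comparison", {
  cell <- xtal_cell(3)
  # area-detector scan time is fixed by range and speed, cell-independent
  expect_equal(throughput_model(cell, "area"), 900)
  expect_equal(throughput_model(xtal_cell(30), "area"), 900)
  expect_equal(throughput_model(cell, "area", n_settings = 2), 1800)
  # point-detector time = 10 min x brute-force count of lattice points
  lam <- 1.24; qmax <- 2 * sin(75 * pi / 180) / lam
  cnt <- 0
  for (h in -10:10) for (k in -10:10) for (l in -10:10) {
    if (h == 0 && k == 0 && l == 0) next
    if (sqrt(h^2 + k^2 + l^2) / 3 <= qmax) cnt <- cnt + 1
  }
  expect_equal(throughput_model(cell, "fcd"), 10 * cnt)
  # fcd time grows with the cell; the area mode stays flat (the crossing
  # behaviour of the survey-time comparison)
  t1 <- throughput_model(xtal_cell(4), "fcd")
  t2 <- throughput_model(xtal_cell(8), "fcd")
  t3 <- throughput_model(xtal_cell(12), "fcd")
  expect_true(t1 < t2 && t2 < t3)
  expect_gt(t3, throughput_model(xtal_cell(12), "area"))
})
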