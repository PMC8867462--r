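test_that("truncation keeps exactly the points within the energy window", {
  # anharmonic Morse scan; expected retention computed from the closed form
  m <- morse_model(D = 100, a = 1.5, x0 = 1.86)
  x <- seq(1.86 - 0.3, 1.86 + 0.3, length.out = 13)
  V <- 100 * (1 - exp(-1.5 * (x - 1.86)))^2 # independent evaluation
  scan <- generate_scan(m, 1.86 - 0.3, 1.86 + 0.3, 13)
  expect_equal(scan$energy, V)
  tr <- truncate_scan(scan, cutoff = 5)
  expect_identical(tr$x, x[V - min(V) <= 5])
  expect_true(all(tr$energy - min(tr$energy) <= 5))
  expect_lt(length(tr$x), 13) # the wings really are cut

  flat <- pes_scan(1:5, rep(0, 5), "bond")
  expect_identical(truncate_scan(flat, 5)$x, flat$x)

  steep <- pes_scan(c(1, 2, 3), c(0, 10, 12), "bond")
  expect_error(truncate_scan(steep, 5), class = "chalcogenmm_degenerate_scan")
})

test_that("truncation is monotone in the cutoff", {
  set.seed(402)
  for (i in 1:10) {
    scan <- pes_scan(sort(runif(15, 1, 3)), runif(15, 0, 12), "bond")
    small <- tryCatch(truncate_scan(scan, 3), error = function(e) NULL)
    big <- truncate_scan(scan, 8)
    if (!is.null(small)) expect_true(all(small$x %in% big$x))
  }
})

test_that("harmonic fits recover bond and angle force constants exactly", {
  bond <- generate_scan(harmonic_term(1.8586, 434.67, "bond"),
                        1.8586 - 0.3, 1.8586 + 0.3, 13)
  k_bond <- fit_harmonic(truncate_scan(bond, 5))$k
  expect_equal(k_bond, 434.67, tolerance = 1e-8)

  angle <- generate_scan(harmonic_term(119.6, 182.7, "angle"),
                         119.6 - 10, 119.6 + 10, 13)
  k_angle <- fit_harmonic(truncate_scan(angle, 5))$k
  expect_equal(k_angle, 182.7, tolerance = 1e-8)

  flat <- pes_scan(seq(1.5, 2.1, length.out = 7), rep(0, 7), "bond", x0 = 1.8)
  expect_equal(fit_harmonic(flat)$k, 0)

  expect_error(fit_harmonic(pes_scan(1:5, rep(1, 5), "bond", x0 = 9)),
               "outside the scanned range")
})

test_that("harmonic fit on a truncated Morse scan matches the normal-equations oracle", {
  m <- morse_model(D = 100, a = 1.0, x0 = 1.86)
  scan <- truncate_scan(generate_scan(m, 1.86 - 0.3, 1.86 + 0.3, 13), 5)
  k_fit <- fit_harmonic(scan, x0 = 1.86)$k
  # independent brute-force least squares on the same points
  X <- cbind(1, 0.5 * (scan$x - 1.86)^2)
  beta <- solve(t(X) %*% X, t(X) %*% scan$energy)
  expect_equal(k_fit, beta[2, 1], tolerance = 1e-10)
  # the window keeps anharmonic wings, so the fit underestimates the
  # true curvature 2 D a^2 = 200
  expect_lt(k_fit, 200)
  expect_gt(k_fit, 160)
})

test_that("angle force constants are stored per radian squared", {
  scan <- generate_scan(harmonic_term(119.6, 182.7, "angle"), 109.6, 129.6, 13)
  k_rad <- fit_harmonic(scan)$k
  # naive per-degree fit of the same data
  X <- cbind(1, 0.5 * (scan$x - 119.6)^2)
  k_deg <- solve(t(X) %*% X, t(X) %*% scan$energy)[2, 1]
  expect_equal(k_rad / k_deg, (180 / pi)^2, tolerance = 1e-10)
})

test_that("torsion fits recover the generating amplitudes", {
  gen <- torsion_series(n = c(1L, 2L), vmax = c(-0.9653, 0.5108))
  phi <- seq(-180, 170, by = 10) # 36 points on [-180, 180)
  fit <- fit_torsion(phi, evaluate_torsion(gen, phi), c(1, 2))
  expect_equal(fit$vmax, c(-0.9653, 0.5108), tolerance = 1e-8)
  expect_equal(fit$gamma, c(180, 180))

  const <- fit_torsion(phi, rep(3, length(phi)), c(1, 2))
  expect_equal(const$vmax, c(0, 0), tolerance = 1e-12)
  expect_equal(evaluate_torsion(const, 77), 3, tolerance = 1e-12)
})

test_that("a pure cos(3 phi) surface loads only the n = 3 term", {
  phi <- seq(-180, 170, by = 10)
  dV <- 1.7 * cos(3 * phi * pi / 180)
  fit <- fit_torsion(phi, dV, c(1, 2, 3))
  # brute-force normal-equations solve in the same basis
  X <- cbind(1, cos(phi * pi / 180), cos(2 * phi * pi / 180), cos(3 * phi * pi / 180))
  beta <- solve(t(X) %*% X, t(X) %*% dV)
  expect_equal(fit$vmax, as.numeric(-2 * beta[2:4]), tolerance = 1e-10)
  expect_equal(fit$vmax[1:2], c(0, 0), tolerance = 1e-10)
  expect_equal(fit$vmax[3], -2 * 1.7, tolerance = 1e-10)

  expect_error(fit_torsion(rep(30, 10), rnorm(10), c(1, 2)),
               class = "chalcogenmm_degenerate_scan")
})

test_that("torsion evaluation matches hand calculations and is periodic", {
  s <- torsion_series(n = c(1L, 2L), vmax = c(-0.9653, 0.5108), baseline = 0.25)
  # phi = 0: cos(0 + 180) = -1 annihilates both terms
  expect_equal(evaluate_torsion(s, 0), 0.25, tolerance = 1e-12)
  # phi = 180: first term (Vmax1/2)*2, second (Vmax2/2)(1 + cos 540) = 0
  expect_equal(evaluate_torsion(s, 180), -0.9653 + 0.25, tolerance = 1e-12)
  empty <- torsion_series(integer(0), numeric(0), numeric(0), baseline = 1.5)
  expect_equal(evaluate_torsion(empty, 123), 1.5)
  phis <- seq(-180, 180, by = 7.3)
  expect_equal(evaluate_torsion(s, phis), evaluate_torsion(s, phis + 360),
               tolerance = 1e-12)
})

test_that("scan generation is exact without noise and reproducible with it", {
  h <- harmonic_term(1.8586, 434.67, "bond")
  scan <- generate_scan(h, 1.5586, 2.1586, 13)
  expect_equal(scan$energy, 0.5 * 434.67 * (scan$x - 1.8586)^2)

  a <- generate_scan(h, 1.5, 2.2, 13, noise_sd = 0.01, seed = 99)
  b <- generate_scan(h, 1.5, 2.2, 13, noise_sd = 0.01, seed = 99)
  expect_identical(a$energy, b$energy)
  c_ <- generate_scan(h, 1.5, 2.2, 13, noise_sd = 0.01, seed = 100)
  expect_false(identical(a$energy, c_$energy))

  m <- generate_scan(morse_model(100, 1.5, 1.86), 1.56, 2.16, 13)
  i0 <- which.min(abs(m$x - 1.86))
  expect_equal(m$energy[i0], 0, tolerance = 1e-12)
  expect_true(all(diff(m$energy[i0:13]) > 0))
  expect_true(all(diff(m$energy[1:i0]) < 0))

  expect_error(generate_scan(h, 1, 2, 2), "at least 3")
})

test_that("scan files round-trip through both text formats", {
  scan <- generate_scan(harmonic_term(1.8586, 434.67, "bond"), 1.6, 2.1, 9)
  tf <- withr::local_tempfile(fileext = ".dat")
  write_scan(scan, tf, comment = "fixture")
  back <- read_scan(tf, kind = "bond", x0 = 1.8586)
  expect_equal(back$x, scan$x, tolerance = 1e-9)
  expect_equal(back$energy, scan$energy, tolerance = 1e-9)

  cf <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = scan$x, energy = scan$energy), cf, row.names = FALSE)
  back2 <- read_scan(cf, kind = "bond")
  expect_equal(back2$energy, scan$energy, tolerance = 1e-9)
})
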