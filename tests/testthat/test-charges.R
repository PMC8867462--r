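test_that("cube files round-trip and convert bohr to angstrom", {
  b <- 0.52917721092
  vals <- array(seq_len(8) / 10, dim = c(2, 2, 2))
  atoms <- rbind(c(0, 0, 0), c(1, 0.5, -0.25))
  tf <- withr::local_tempfile(fileext = ".cube")
  write_cube(tf, atoms, vals, origin = c(0, 0, 0), step = b) # 1 bohr steps
  grid <- read_cube(tf)
  expect_equal(grid$site_positions, atoms, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(length(grid$potentials), 8)
  # Fortran order: z varies fastest, so the second sample sits one step up z
  expect_equal(grid$sample_points[2, ], c(0, 0, b), tolerance = 1e-6)
  # value-to-point alignment: values[i,j,k] belongs to origin + (i-1,j-1,k-1)*step
  expect_equal(grid$potentials[2], vals[1, 1, 2])
  expect_equal(grid$potentials[3], vals[1, 2, 1])
  expect_equal(grid$potentials[5], vals[2, 1, 1])

  # truncated volumetric section
  lines <- readLines(tf)
  writeLines(lines[-length(lines)], tf)
  expect_error(read_cube(tf), "voxels")
})

test_that("point-charge ESP obeys Coulomb's law in atomic units", {
  b <- 0.52917721092
  # unit charge at the origin, sample at 1 bohr -> potential exactly 1 a.u.
  expect_equal(esp_from_point_charges(rbind(c(0, 0, 0)), 1, rbind(c(0, 0, b))), 1)
  # opposite charges, sample on the perpendicular bisector plane -> 0
  pos <- rbind(c(0, 0, 1), c(0, 0, -1))
  pts <- cbind(runif(5, -2, 2), runif(5, -2, 2), 0)
  expect_equal(esp_from_point_charges(pos, c(1, -1), pts), rep(0, 5),
               tolerance = 1e-14)
  expect_error(esp_from_point_charges(rbind(c(0, 0, 0)), 1, rbind(c(0, 0, 0))),
               class = "chalcogenmm_singularity")
})

test_that("ESP of the toy system matches term-by-term summation", {
  sys <- toy_resp_system()
  set.seed(12)
  pts <- matrix(rnorm(15, sd = 6), 5, 3)
  V <- esp_from_point_charges(sys$positions, sys$charges, pts)
  b <- 0.52917721092
  for (p in 1:5) {
    acc <- 0
    for (s in 1:6) {
      acc <- acc + sys$charges[s] /
        (sqrt(sum((pts[p, ] - sys$positions[s, ])^2)) / b)
    }
    expect_equal(V[p], unname(acc), tolerance = 1e-12)
  }
})

test_that("shell sampling respects geometry, exclusions and the seed", {
  one <- rbind(c(1, 2, 3))
  pts <- sample_shells(one, radii = 1.8, scale_factors = 1.4, density = 2, seed = 5)
  d <- sqrt(rowSums((pts - matrix(c(1, 2, 3), nrow(pts), 3, byrow = TRUE))^2))
  expect_equal(d, rep(1.4 * 1.8, length(d)), tolerance = 1e-9)

  two <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  pts2 <- sample_shells(two, radii = c(1.8, 1.6), scale_factors = c(1.4, 1.8),
                        density = 3, seed = 6)
  d1 <- sqrt(rowSums(pts2^2))
  d2 <- sqrt(rowSums((pts2 - matrix(c(1.5, 0, 0), nrow(pts2), 3, byrow = TRUE))^2))
  expect_true(all(d1 >= 1.4 * 1.8 - 1e-9))
  expect_true(all(d2 >= 1.4 * 1.6 - 1e-9))

  expect_identical(sample_shells(two, c(1.8, 1.6), density = 1, seed = 42),
                   sample_shells(two, c(1.8, 1.6), density = 1, seed = 42))
})

test_that("unrestrained RESP recovers the generating charges of the toy system", {
  sys <- toy_resp_system()
  pts <- sample_shells(sys$positions, sys$radii, density = 1, seed = 7)
  expect_gte(nrow(pts), 1000)
  V <- esp_from_point_charges(sys$positions, sys$charges, pts)
  grid <- esp_grid(sys$positions, pts, V, labels = sys$labels)
  fit <- resp_fit(grid, resp_config(restraint_a = 0, total_charge = 0))
  expect_equal(fit$charges[fit$labels == "Se1"], -0.372631, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit$charges[fit$labels == "E26"], 0.281382, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit$charges, unname(sys$charges), tolerance = 1e-6,
               ignore_attr = TRUE)

  # null model: a grid of zeros fits to all-zero charges
  null <- resp_fit(esp_grid(sys$positions, pts, rep(0, nrow(pts))),
                   resp_config(restraint_a = 0, total_charge = 0))
  expect_equal(null$charges, rep(0, 6), tolerance = 1e-10)
})

test_that("charge conservation holds to 1e-10 for any restraint strength", {
  sys <- toy_resp_system()
  pts <- sample_shells(sys$positions, sys$radii, density = 0.6, seed = 8)
  V <- esp_from_point_charges(sys$positions, sys$charges, pts)
  grid <- esp_grid(sys$positions, pts, V, labels = sys$labels)
  for (a in c(0, 5e-4, 5e-3, 5e-2)) {
    fit <- resp_fit(grid, resp_config(restraint_a = a, total_charge = 0))
    expect_lt(abs(sum(fit$charges) - 0), 1e-10)
  }
})

test_that("the hyperbolic restraint shrinks charges, matching a brute-force optimizer", {
  sys <- toy_resp_system()
  pts <- sample_shells(sys$positions, sys$radii, density = 0.6, seed = 9)
  V <- esp_from_point_charges(sys$positions, sys$charges, pts)
  grid <- esp_grid(sys$positions, pts, V, labels = sys$labels)

  free <- resp_fit(grid, resp_config(restraint_a = 0, total_charge = 0))
  maxq_prev <- Inf
  b2a <- 0.52917721092
  A <- matrix(0, nrow(pts), 6)
  for (j in 1:6) {
    A[, j] <- 1 / (sqrt(rowSums((pts - matrix(sys$positions[j, ], nrow(pts), 3,
                                              byrow = TRUE))^2)) / b2a)
  }
  for (a in c(2e-3, 2e-2, 2e-1)) {
    fit <- resp_fit(grid, resp_config(restraint_a = a, total_charge = 0))
    # monotone restraint: the largest |q| never grows with a
    expect_lte(max(abs(fit$charges)), maxq_prev + 1e-12)
    maxq_prev <- max(abs(fit$charges))
    # dominant sites shrink site-wise relative to the unrestrained fit
    # (marginal sites may grow slightly: the total-charge constraint
    # redistributes what the restraint takes from the big charges)
    dom <- abs(free$charges) > 0.3
    expect_true(all(abs(fit$charges[dom]) <= abs(free$charges[dom]) + 1e-10))
    # generic nonlinear-optimizer oracle: eliminate the constraint via the
    # last charge and minimize the penalized objective directly
    obj <- function(q5) {
      q <- c(q5, -sum(q5))
      sum((V - drop(A %*% q))^2) + sum(a * (sqrt(q^2 + 0.1^2) - 0.1))
    }
    oracle <- optim(fit$charges[1:5], obj, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-15))
    expect_equal(fit$charges, c(oracle$par, -sum(oracle$par)),
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("equivalence classes produce bit-identical charges", {
  sys <- toy_resp_system()
  q <- sys$charges
  q[2] <- q[3] <- (q[2] + q[3]) / 2 # make the generating set class-consistent
  pts <- sample_shells(sys$positions, sys$radii, density = 0.6, seed = 10)
  V <- esp_from_point_charges(sys$positions, q, pts)
  grid <- esp_grid(sys$positions, pts, V, labels = sys$labels)
  fit <- resp_fit(grid, resp_config(restraint_a = 0, total_charge = 0),
                  equivalences = list(c(2L, 3L)))
  expect_identical(fit$charges[2], fit$charges[3])
  expect_equal(fit$charges, unname(q), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("pseudoatom insertion extends the site list along the bond axis", {
  pos <- rbind(Se = c(0, 0, 0), N = c(0, 0, 1.8586))
  aug <- add_pseudoatom_site(pos, parent = 1, reference = 2, distance = 1.189)
  expect_equal(unname(aug[3, ]), c(0, 0, -1.189), tolerance = 1e-12)

  same <- add_pseudoatom_site(pos, 1, 2, 0)
  expect_equal(unname(same[3, ]), c(0, 0, 0))

  # equivariance under a fixed rotation + translation
  set.seed(31)
  R <- random_rotation(); tvec <- c(1, -2, 0.5)
  pos2 <- pos %*% t(R) + matrix(tvec, 2, 3, byrow = TRUE)
  aug2 <- add_pseudoatom_site(pos2, 1, 2, 1.189)
  expect_equal(unname(aug2[3, ]), drop(R %*% aug[3, ]) + tvec, tolerance = 1e-12)

  expect_error(add_pseudoatom_site(rbind(c(0, 0, 0), c(0, 0, 0)), 1, 2, 1),
               class = "chalcogenmm_singularity")
})
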