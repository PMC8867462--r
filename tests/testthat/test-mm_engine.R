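test_that("Lorentz-Berthelot mixing follows the closed forms", {
  mixed <- mix_lj(2.12, 0.2910, 1.5, 0.08)
  expect_equal(mixed$sigma, 1.81)
  expect_equal(mixed$epsilon, sqrt(0.2910 * 0.08))
  self <- mix_lj(3.3, 0.21, 3.3, 0.21)
  expect_equal(self$sigma, 3.3)
  expect_equal(self$epsilon, 0.21)
  expect_equal(mix_lj(3, 0, 2, 0.5)$epsilon, 0)
})

two_atom_top <- function(q1 = 0, q2 = 0, s = 0, e = 0, bond = NULL) {
  at <- rbind(atom_spec("A", "A", q1, s, e, 10),
              atom_spec("B", "B", q2, s, e, 10))
  bonds <- if (is.null(bond)) list() else list(list(i = 1L, j = 2L, term = bond))
  mm_topology(at, bonds = bonds)
}

test_that("energy components match closed-form reference points", {
  # LJ zero crossing at r = sigma_ij
  lj <- two_atom_top(s = 3.0, e = 0.1)
  expect_equal(total_energy(lj, rbind(c(0, 0, 0), c(3, 0, 0)))$lj, 0,
               tolerance = 1e-12)
  # Coulomb: ke/r arithmetic gives -100 kcal/mol at 3.320636 A
  ion <- two_atom_top(q1 = 1, q2 = -1)
  e <- total_energy(ion, rbind(c(0, 0, 0), c(0, 0, 3.320636)))
  expect_equal(e$coulomb, -100.0, tolerance = 1e-10)
  expect_equal(e$total, e$bond + e$angle + e$torsion + e$lj + e$coulomb)
  # a bonded pair at its equilibrium length stores no bond energy
  dia <- two_atom_top(bond = harmonic_term(1.8586, 434.67, "bond"))
  expect_equal(total_energy(dia, rbind(c(0, 0, 0), c(0, 0, 1.8586)))$bond, 0)
  # overlapping non-excluded atoms raise a singularity
  expect_error(total_energy(ion, rbind(c(0, 0, 0), c(0, 0, 1e-8))),
               class = "chalcogenmm_singularity")
})

test_that("energy is invariant under rigid rotation and translation", {
  set.seed(21)
  sys <- random_vsite_system()
  e0 <- total_energy(sys$topology, sys$positions)$total
  for (i in 1:5) {
    R <- random_rotation(); tv <- rnorm(3, sd = 5)
    moved <- sys$positions %*% t(R) + matrix(tv, nrow(sys$positions), 3, byrow = TRUE)
    expect_equal(total_energy(sys$topology, moved)$total, e0, tolerance = 1e-9)
  }
})

test_that("analytic gradients match finite differences on randomized systems", {
  set.seed(22)
  for (i in 1:5) {
    sys <- random_vsite_system()
    g <- mm_gradient(sys$topology, sys$positions)
    fd <- fd_gradient(sys$topology, sys$positions)
    expect_lt(max(abs(g - fd)), 1e-6)
    # Newton's third law: net force vanishes
    expect_lt(max(abs(colSums(g))), 1e-9)
    # site rows carry no independent gradient
    expect_equal(g[sys$topology$is_vsite, ], c(0, 0, 0))
  }
  # isolated atom: nothing pulls on it
  lone <- mm_topology(atom_spec("X", "X", 0.4, 3, 0.1, 12))
  expect_equal(mm_gradient(lone, rbind(c(1, 2, 3))), matrix(0, 1, 3))
})

test_that("the core fixture gradient including the sigma-hole site is exact", {
  fx <- build_core_fixture(TRUE)
  g <- mm_gradient(fx$topology, fx$positions)
  fd <- fd_gradient(fx$topology, fx$positions)
  expect_lt(max(abs(g - fd)), 1e-6)
  expect_lt(max(abs(colSums(g))), 1e-9)
})

test_that("minimization reaches known minima", {
  dia <- two_atom_top(bond = harmonic_term(1.8586, 434.67, "bond"))
  mp <- mm_minimize(dia, rbind(c(0, 0, 0), c(0, 0, 2.1)))
  expect_equal(sqrt(sum((mp[1, ] - mp[2, ])^2)), 1.8586, tolerance = 1e-4)
  expect_lte(attr(mp, "energy"),
             total_energy(dia, rbind(c(0, 0, 0), c(0, 0, 2.1)))$total)

  # an LJ dimer settles at 2^(1/6) sigma
  lj <- two_atom_top(s = 3.0, e = 0.1)
  mp2 <- mm_minimize(lj, rbind(c(0, 0, 0), c(0, 0, 3.5)))
  expect_equal(sqrt(sum((mp2[1, ] - mp2[2, ])^2)), 2^(1 / 6) * 3.0,
               tolerance = 1e-4)

  # an already-minimal configuration is returned unchanged (within tolerance)
  mp3 <- mm_minimize(dia, mp)
  expect_equal(mp3, mp, tolerance = 1e-6, ignore_attr = TRUE)

  expect_error(mm_minimize(dia, rbind(c(0, 0, 0), c(0, 0, 2.1)), 1e-10, max_steps = 1L),
               class = "chalcogenmm_no_convergence")
})

test_that("dimer interaction energies are separable and match a grid oracle", {
  A <- mm_topology(atom_spec("P", "P", 1, 3, 0.1, 20))
  B <- mm_topology(atom_spec("M", "M", -1, 3, 0.1, 20))
  far <- dimer_interaction_energy(A, B, rbind(c(0, 0, 0), c(0, 0, 1e6)),
                                  max_steps = 10L)
  expect_lt(abs(as.numeric(far)), 1e-3)

  ei <- dimer_interaction_energy(A, B, rbind(c(0, 0, 0), c(0, 0, 3.2)))
  r <- seq(2, 8, by = 1e-4) # dense 1-D brute-force scan
  oracle <- min(4 * 0.1 * ((3 / r)^12 - (3 / r)^6) - 332.0636 / r)
  expect_equal(as.numeric(ei), oracle, tolerance = 1e-6)

  # sigma-hole fixture against a single probe: attractive on the axis
  fx <- build_core_fixture(TRUE)
  probe <- build_probe()
  start <- rbind(fx$positions, vsite_position(fx$positions[1, ],
                                              fx$positions[2, ], 3.2))
  eint <- dimer_interaction_energy(fx$topology, probe, start)
  expect_lt(as.numeric(eint), 0)
})

test_that("chalcogen-bond geometry measurements are exact on constructed cases", {
  se <- c(0, 0, 0); nn <- c(0, 0, 1.8586)
  on_axis <- rbind(se, nn, c(0, 0, -3))
  g <- measure_chalcogen_geometry(on_axis, 1, 2, 3)
  expect_equal(g$theta, 180)
  expect_equal(g$r, 3)
  toward_n <- rbind(se, nn, c(0, 0, 2.5))
  expect_equal(measure_chalcogen_geometry(toward_n, 1, 2, 3)$theta, 0)
  right <- rbind(se, nn, c(3, 0, 0))
  gr <- measure_chalcogen_geometry(right, 1, 2, 3)
  expect_equal(gr$r, 3)
  expect_equal(gr$theta, 90)
  expect_error(measure_chalcogen_geometry(on_axis, 1, 1, 3), "distinct")
})

test_that("the angular probe scan shows sigma-hole directionality", {
  grid <- seq(60, 180, by = 5) # sub-60 placements collide with the core atoms
  probe <- build_probe()
  fx1 <- build_core_fixture(TRUE)
  sc1 <- angular_probe_scan(fx1$topology, fx1$positions, probe, 3.0, grid, 1, 2)
  expect_gte(sc1$theta[which.min(sc1$energy)], 175)

  fx0 <- build_core_fixture(FALSE)
  sc0 <- angular_probe_scan(fx0$topology, fx0$positions, probe, 3.0, grid, 1, 2)
  contrast1 <- abs(sc1$energy[sc1$theta == 180] - sc1$energy[sc1$theta == 120])
  contrast0 <- abs(sc0$energy[sc0$theta == 180] - sc0$energy[sc0$theta == 120])
  expect_lt(contrast0, contrast1)

  # an inert probe sees a flat (all-zero) profile
  ghost <- build_probe(charge = 0, lj_sigma = 0, lj_epsilon = 0)
  e_fixed <- total_energy(fx1$topology, fx1$positions)$total
  sc_g <- angular_probe_scan(fx1$topology, fx1$positions, ghost, 3.0, grid, 1, 2)
  expect_equal(sc_g$energy, rep(e_fixed, length(grid)), tolerance = 1e-10)
})

test_that("virtual sites inherit their parent's exclusions", {
  fx <- build_core_fixture(TRUE)
  top <- fx$topology
  # Se (atom 1) excludes N (1-2), C (1-3); the site must mirror that plus Se
  expect_true(all(c(1L, 2L, 3L) %in% top$exclusions[[5]]))
  expect_true(5L %in% top$exclusions[[1]])
  # exclusion symmetry everywhere
  for (i in seq_along(top$exclusions)) {
    for (j in top$exclusions[[i]]) expect_true(i %in% top$exclusions[[j]])
  }
})
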