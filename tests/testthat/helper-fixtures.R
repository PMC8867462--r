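# shared helpers: oracles and randomized-but-reproducible geometries

# random proper rotation matrix (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1] # force a proper rotation
  R
}

# central finite-difference gradient of total_energy w.r.t. real atoms
fd_gradient <- function(topology, positions, h = 1e-5) {
  g <- matrix(0, nrow(positions), 3)
  for (i in which(!topology$is_vsite)) {
    for (d in 1:3) {
      pp <- positions; pp[i, d] <- pp[i, d] + h
      pm <- positions; pm[i, d] <- pm[i, d] - h
      g[i, d] <- (total_energy(topology, pp)$total -
                    total_energy(topology, pm)$total) / (2 * h)
    }
  }
  g
}

# a small randomized molecule with bonds/angle/torsion/vsite and charges,
# placed without pathological contacts (atoms jittered around a chain)
random_vsite_system <- function() {
  base <- rbind(c(0, 0, 0), c(1.6, 0.2, -0.1), c(2.4, 1.4, 0.3), c(3.9, 1.5, 1.1))
  pos <- base + matrix(stats::rnorm(12, sd = 0.15), 4, 3)
  atoms <- rbind(
    atom_spec("A1", "A", -0.35, 2.8, 0.2, 30),
    atom_spec("A2", "B", 0.25, 3.1, 0.1, 14),
    atom_spec("A3", "C", 0.4, 3.3, 0.09, 12),
    atom_spec("A4", "D", -0.3, 3.0, 0.15, 16),
    atom_spec("EP", "EP", 0.28, 0, 0, 0))
  top <- mm_topology(
    atoms,
    bonds = list(list(i = 1L, j = 2L, term = harmonic_term(1.62, 380, "bond")),
                 list(i = 2L, j = 3L, term = harmonic_term(1.48, 420, "bond")),
                 list(i = 3L, j = 4L, term = harmonic_term(1.71, 350, "bond"))),
    angles = list(list(i = 1L, j = 2L, k = 3L, term = harmonic_term(112, 120, "angle")),
                  list(i = 2L, j = 3L, k = 4L, term = harmonic_term(118, 95, "angle"))),
    torsions = list(list(i = 1L, j = 2L, k = 3L, l = 4L,
                         series = torsion_series(c(1L, 2L, 3L), c(-0.8, 0.5, 0.2)))),
    vsites = list(virtual_site_fd(5L, 1L, 2L, 1.1)))
  list(topology = top, positions = apply_vsites(top, rbind(pos, c(0, 0, 0))))
}
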