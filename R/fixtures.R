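#' Bundled selenium-core parameter set
#'
#' The published parameters for the selenium heterocycle of an
#' ebselen-like molecule, transcribed once into code: harmonic bond and
#' angle constants (kcal/mol·Å², kcal/mol·radian²; equilibria in Å and
#' degrees), the aryl-N-Se torsion series, the RESP charge sets with and
#' without the sigma-hole pseudoatom, the selenium Lennard-Jones
#' parameters (lowered to account for polar flattening), the softened
#' carbonyl-oxygen Lennard-Jones parameters, and the 1.189 Å pseudoatom
#' placement distance.
#'
#' The two charge columns cover five printed sites (pseudoatom E26,
#' Se1, N2, C3, O4). A sixth neutralizing dummy site (`DUM`) is added so
#' that each charge set sums to exactly zero, making the printed values
#' a valid total-charge-zero RESP target; the dummy is a fixture device,
#' not part of any published parameter set.
#'
#' @return A named list of parameter tables and constants.
#' @export
ebselen_core_params <- function() {
  list(
    bonds = data.frame(
      name = c("Se-N", "Se-C"),
      x0 = c(1.8586, 1.8829),
      k = c(434.67, 422.33)),
    angles = data.frame(
      name = c("C-Se-N", "Se-N-Car", "Se-N-Cco", "C-C-Se"),
      x0 = c(86.6, 119.6, 115.8, 119.4),
      k = c(610.7, 182.7, 404.5, 329.2)),
    torsion = list(name = "Car-Car-N-Se",
                   series = torsion_series(n = c(1L, 2L),
                                           vmax = c(-0.9653, 0.5108),
                                           gamma = c(180, 180))),
    charges_pseudoatom = c(E26 = 0.281382, Se1 = -0.372631, N2 = -0.241674,
                           C3 = 0.463064, O4 = -0.558076, DUM = 0.427935),
    charges_no_pseudoatom = c(Se1 = 0.056728, N2 = -0.599430,
                              C3 = 0.827981, O4 = -0.613468, DUM = 0.328189),
    lj = list(Se = list(sigma = 2.12, epsilon = 0.2910),
              S  = list(sigma = 1.9825, epsilon = 0.2824),
              O_carbonyl = list(sigma = 1.5, epsilon = 0.08)),
    pseudoatom_distance = 1.189
  )
}

# Fixture geometry for the four real core atoms plus the neutralizing
# dummy. The Se-N distance and the Se-N-C angle reproduce the bundled
# equilibrium values; C=O length/angle are chemically plausible choices
# (the reference DFT geometry is not part of the parameter set). The
# dummy sits out of the Se/N/C/O plane so the six RESP sites are
# non-coplanar.
core_positions_real <- function() {
  p <- ebselen_core_params()
  se <- c(0, 0, 0)
  nn <- c(0, 0, p$bonds$x0[p$bonds$name == "Se-N"])
  ang_senc <- p$angles$x0[p$angles$name == "Se-N-Cco"]
  r_nc <- 1.3823
  cc <- nn + r_nc * c(sin(deg2rad(ang_senc)), 0, -cos(deg2rad(ang_senc)))
  # carbonyl O: 1.229 A from C, N-C-O angle 122 deg, in the same plane,
  # on the side away from Se
  u <- (nn - cc) / vnorm(nn - cc)
  perp <- c(-u[3], 0, u[1])
  if (sum(perp * (se - cc)) > 0) perp <- -perp
  vdir <- cos(deg2rad(122)) * u + sin(deg2rad(122)) * perp
  oo <- cc + 1.229 * vdir
  dum <- c(-1.2, 1.4, 0.9)
  pos <- rbind(se, nn, cc, oo, dum)
  rownames(pos) <- c("Se1", "N2", "C3", "O4", "DUM")
  pos
}

#' Build the selenium-core fixture topology
#'
#' Deterministic test molecule: the Se/N/C(=O)/O fragment carrying the
#' bundled parameters, in a fixed fixture geometry, with or without the
#' sigma-hole virtual site. With the pseudoatom, the pseudoatom-model
#' charge set is used and a fixed-distance site (1.189 Å beyond Se on
#' the extension of the N-Se bond, charge +0.281382 e) is added; without
#' it, the no-pseudoatom charge set is used and there is no site. Both
#' variants share identical real-atom positions. The neutralizing dummy
#' charge is not part of the energy topology.
#'
#' @param with_pseudoatom Logical.
#' @return A list with `topology` ([mm_topology()]) and `positions`
#'   (coordinates in Å; the site row, when present, is last).
#' @export
build_core_fixture <- function(with_pseudoatom = TRUE) {
  p <- ebselen_core_params()
  pos <- core_positions_real()[c("Se1", "N2", "C3", "O4"), ]
  q <- if (with_pseudoatom) p$charges_pseudoatom else p$charges_no_pseudoatom
  atoms <- rbind(
    atom_spec("Se1", "Se", q[["Se1"]], p$lj$Se$sigma, p$lj$Se$epsilon, 78.97),
    atom_spec("N2", "N", q[["N2"]], 3.25, 0.17, 14.007),
    atom_spec("C3", "C", q[["C3"]], 3.40, 0.086, 12.011),
    atom_spec("O4", "O", q[["O4"]], p$lj$O_carbonyl$sigma,
              p$lj$O_carbonyl$epsilon, 15.999))
  bonds <- list(
    list(i = 1L, j = 2L, term = harmonic_term(p$bonds$x0[1], p$bonds$k[1], "bond")),
    list(i = 2L, j = 3L, term = harmonic_term(1.3823, 477.0, "bond")),
    list(i = 3L, j = 4L, term = harmonic_term(1.229, 637.0, "bond")))
  angles <- list(
    list(i = 1L, j = 2L, k = 3L,
         term = harmonic_term(p$angles$x0[p$angles$name == "Se-N-Cco"],
                              p$angles$k[p$angles$name == "Se-N-Cco"], "angle")),
    list(i = 2L, j = 3L, k = 4L, term = harmonic_term(122.0, 80.0, "angle")))
  vsites <- list()
  if (with_pseudoatom) {
    atoms <- rbind(atoms, atom_spec("E26", "EP", q[["E26"]], 0, 0, 0))
    vsites <- list(virtual_site_fd(site = 5L, parent = 1L, reference = 2L,
                                   distance = p$pseudoatom_distance))
    pos <- rbind(pos, E26 = vsite_position(pos["Se1", ], pos["N2", ],
                                           p$pseudoatom_distance))
  }
  top <- mm_topology(atoms, bonds = bonds, angles = angles, vsites = vsites)
  list(topology = top, positions = pos)
}

#' Six-site toy RESP system
#'
#' The synthetic charge-fitting target: the five printed core sites
#' (Se1, N2, C3, O4 and the pseudoatom E26, placed 1.189 Å beyond Se via
#' [add_pseudoatom_site()]) plus the neutralizing dummy, at the fixed
#' fixture geometry, carrying the pseudoatom-model charges (sum exactly
#' zero). `radii` are Bondi-style vdW radii for shell sampling; the
#' pseudoatom has radius 0 since it sits on the parent's surface by
#' construction.
#'
#' @return A list with `positions` (6 x 3, Å, E26 last), `charges`
#'   (named, e), `labels`, and `radii` (Å).
#' @export
toy_resp_system <- function() {
  p <- ebselen_core_params()
  pos <- core_positions_real()
  pos <- add_pseudoatom_site(pos, parent = 1L, reference = 2L,
                             distance = p$pseudoatom_distance, label = "E26")
  q <- p$charges_pseudoatom[c("Se1", "N2", "C3", "O4", "DUM", "E26")]
  list(positions = pos, charges = q, labels = names(q),
       radii = c(Se1 = 1.90, N2 = 1.55, C3 = 1.70, O4 = 1.52,
                 DUM = 1.50, E26 = 0))
}

#' Single-particle probe topology
#'
#' A Lewis-base surrogate for directionality scans: one particle with a
#' point charge and Lennard-Jones sphere, no bonded terms.
#'
#' @param charge Probe charge, e (default -0.5, an electron-pair-donor
#'   caricature).
#' @param lj_sigma,lj_epsilon Lennard-Jones parameters (default 3.0 Å,
#'   0.1 kcal/mol).
#' @return An [mm_topology()] with a single atom.
#' @export
build_probe <- function(charge = -0.5, lj_sigma = 3.0, lj_epsilon = 0.1) {
  mm_topology(atom_spec("PRB", "PRB", charge, lj_sigma, lj_epsilon, 10))
}
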