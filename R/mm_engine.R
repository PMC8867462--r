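#' Atom specification row
#'
#' @param name Atom name (e.g. `"Se1"`).
#' @param type Force-field type label (e.g. `"Se"`).
#' @param charge Partial charge, e.
#' @param sigma,epsilon Lennard-Jones parameters, Å and kcal/mol
#'   (both 0 for charge-only sites).
#' @param mass Mass in amu; 0 marks a massless virtual site.
#' @return A one-row data frame; rbind rows to build an atom table.
#' @export
atom_spec <- function(name, type, charge = 0, sigma = 0, epsilon = 0, mass = 1) {
  if (sigma < 0 || epsilon < 0) stop_format("Lennard-Jones parameters must be non-negative")
  data.frame(name = name, type = type, charge = charge,
             sigma = sigma, epsilon = epsilon, mass = mass,
             stringsAsFactors = FALSE)
}

#' Lorentz-Berthelot mixing rules
#'
#' Cross-term Lennard-Jones parameters for an unlike pair: arithmetic
#' mean of sigma, geometric mean of epsilon.
#'
#' @param sigma_i,epsilon_i,sigma_j,epsilon_j Like-pair parameters
#'   (Å, kcal/mol).
#' @return A list with elements `sigma` and `epsilon`.
#' @examples
#' mix_lj(2.12, 0.2910, 1.5, 0.08) # selenium with a modified carbonyl O
#' @export
mix_lj <- function(sigma_i, epsilon_i, sigma_j, epsilon_j) {
  list(sigma = (sigma_i + sigma_j) / 2,
       epsilon = sqrt(epsilon_i * epsilon_j))
}

#' Molecular topology
#'
#' Atoms (including massless virtual-site rows), bonded terms, virtual
#' sites and the nonbonded bookkeeping of a small molecule. Exclusions
#' follow the usual convention: 1-2 and 1-3 neighbours are fully
#' excluded, 1-4 pairs interact with scaled Lennard-Jones and Coulomb
#' (AMBER/GAFF factors 0.5 and 1/1.2 by default). A virtual site
#' inherits its parent atom's exclusions and 1-4 pairs, plus an
#' exclusion with the parent itself, so the sigma-hole charge never
#' interacts with its own molecule's near neighbourhood.
#'
#' @param atoms Data frame of [atom_spec()] rows; virtual-site rows have
#'   `mass = 0` and no Lennard-Jones parameters.
#' @param bonds List of `list(i, j, term)` with a `"bond"`
#'   [harmonic_term()].
#' @param angles List of `list(i, j, k, term)` (`j` the apex) with an
#'   `"angle"` [harmonic_term()] (x0 degrees, k per radian²).
#' @param torsions List of `list(i, j, k, l, series)` with a
#'   [torsion_series()].
#' @param vsites List of [virtual_site_fd()]; `site` indices must point
#'   at `mass = 0` rows of `atoms`.
#' @param scale_lj_14,scale_coul_14 1-4 scale factors.
#' @param extra_exclusions Optional list of integer pairs to exclude on
#'   top of the bond-graph-derived set.
#' @return An object of class `mm_topology`.
#' @export
mm_topology <- function(atoms, bonds = list(), angles = list(), torsions = list(),
                        vsites = list(), scale_lj_14 = 0.5,
                        scale_coul_14 = 1 / 1.2, extra_exclusions = list()) {
  n <- nrow(atoms)
  is_vsite <- rep(FALSE, n)
  for (vs in vsites) {
    stopifnot(inherits(vs, "virtual_site_fd"))
    if (vs$site < 1L || vs$site > n) stop_format("virtual site index out of range")
    if (atoms$mass[vs$site] != 0) stop_format("virtual-site rows must have mass 0")
    if (atoms$mass[vs$parent] == 0 || atoms$mass[vs$reference] == 0) {
      stop_format("virtual-site parent and reference must be real atoms")
    }
    is_vsite[vs$site] <- TRUE
  }
  check_idx <- function(idx, term_name) {
    if (any(idx < 1L | idx > n)) stop_format(paste(term_name, "index out of range"))
    if (anyDuplicated(idx)) stop_format(paste(term_name, "indices must be distinct"))
  }
  for (b in bonds) check_idx(c(b$i, b$j), "bond")
  for (a in angles) check_idx(c(a$i, a$j, a$k), "angle")
  for (t in torsions) check_idx(c(t$i, t$j, t$k, t$l), "torsion")

  # bonded graph over real atoms
  adj <- vector("list", n)
  for (b in bonds) {
    adj[[b$i]] <- c(adj[[b$i]], b$j)
    adj[[b$j]] <- c(adj[[b$j]], b$i)
  }
  uints <- function(x) as.integer(sort(unique(x))) # never NULL, so list slots survive
  excl <- lapply(seq_len(n), function(i) integer(0))
  pairs14 <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    one2 <- unique(unlist(adj[i]))
    one3 <- setdiff(unique(unlist(adj[one2])), c(i, one2))
    excl[[i]] <- uints(c(one2, one3))
    one4 <- setdiff(unique(unlist(adj[one3])), c(i, one2, one3))
    for (j in one4) if (j > i) pairs14 <- rbind(pairs14, c(i, j))
  }
  for (p in extra_exclusions) {
    excl[[p[1]]] <- uints(c(excl[[p[1]]], p[2]))
    excl[[p[2]]] <- uints(c(excl[[p[2]]], p[1]))
  }
  # virtual sites mirror their parent's nonbonded environment
  for (vs in vsites) {
    inherited <- uints(c(excl[[vs$parent]], vs$parent))
    excl[[vs$site]] <- uints(c(excl[[vs$site]], inherited))
    for (j in inherited) excl[[j]] <- uints(c(excl[[j]], vs$site))
    if (nrow(pairs14)) {
      pp <- pairs14[pairs14[, 1] == vs$parent | pairs14[, 2] == vs$parent, ,
                    drop = FALSE]
      for (r in seq_len(nrow(pp))) {
        other <- if (pp[r, 1] == vs$parent) pp[r, 2] else pp[r, 1]
        pairs14 <- rbind(pairs14, c(min(vs$site, other), max(vs$site, other)))
      }
    }
  }

  top <- structure(list(atoms = atoms, bonds = bonds, angles = angles,
                        torsions = torsions, vsites = vsites,
                        is_vsite = is_vsite, exclusions = excl,
                        pairs14 = pairs14, scale_lj_14 = scale_lj_14,
                        scale_coul_14 = scale_coul_14),
                   class = "mm_topology")
  top$nb <- build_nb_table(top)
  top
}

#' @export
print.mm_topology <- function(x, ...) {
  cat(sprintf("<mm_topology> %d atoms (%d virtual sites), %d bonds, %d angles, %d torsions\n",
              nrow(x$atoms), sum(x$is_vsite), length(x$bonds),
              length(x$angles), length(x$torsions)))
  invisible(x)
}

# Precompute the nonbonded pair table: every i<j pair that is not
# excluded, with mixed LJ parameters, charge product and 1-4 scaling.
build_nb_table <- function(top) {
  n <- nrow(top$atoms)
  p14 <- top$pairs14
  key14 <- if (nrow(p14)) paste(p14[, 1], p14[, 2]) else character(0)
  ii <- jj <- integer(0); slj <- sco <- numeric(0)
  for (i in seq_len(n)) {
    js <- setdiff(seq_len(n), c(seq_len(i), top$exclusions[[i]]))
    if (!length(js)) next
    ii <- c(ii, rep(i, length(js))); jj <- c(jj, js)
  }
  if (!length(ii)) {
    return(data.frame(i = integer(0), j = integer(0), sigma = numeric(0),
                      epsilon = numeric(0), qq = numeric(0),
                      slj = numeric(0), scoul = numeric(0)))
  }
  is14 <- paste(ii, jj) %in% key14
  at <- top$atoms
  data.frame(i = ii, j = jj,
             sigma = (at$sigma[ii] + at$sigma[jj]) / 2,
             epsilon = sqrt(at$epsilon[ii] * at$epsilon[jj]),
             qq = at$charge[ii] * at$charge[jj],
             slj = ifelse(is14, top$scale_lj_14, 1),
             scoul = ifelse(is14, top$scale_coul_14, 1))
}

#' Re-derive virtual-site positions in a conformation
#'
#' Virtual-site coordinates are never free variables: this enforces the
#' fixed-distance construction for every site, overwriting the site rows.
#'
#' @param topology An [mm_topology()].
#' @param positions n x 3 coordinate matrix, Å.
#' @return The coordinate matrix with site rows re-derived.
#' @export
apply_vsites <- function(topology, positions) {
  for (vs in topology$vsites) {
    positions[vs$site, ] <- vsite_position(positions[vs$parent, ],
                                           positions[vs$reference, ],
                                           vs$distance)
  }
  positions
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m <- c(n1[2] * b2[3] - n1[3] * b2[2],
         n1[3] * b2[1] - n1[1] * b2[3],
         n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  atan2(sum(m * n2), sum(n1 * n2))
}

#' Total classical energy of a conformation
#'
#' Bond and angle terms `1/2 k (x - x0)^2` (angles in radians
#' internally), torsions `sum_n (Vmax_n/2)(1 + cos(n phi + gamma_n))`,
#' Lennard-Jones `4 eps ((sigma/r)^12 - (sigma/r)^6)` with
#' Lorentz-Berthelot mixed parameters on all non-excluded pairs, and
#' Coulomb `ke qi qj / r` with `ke = 332.0636` kcal·Å/(mol·e²).
#' 1-4 pairs are scaled; virtual-site charges take part in every
#' non-excluded Coulomb pair. No cutoffs, no periodic boundary
#' conditions: everything here is a small gas-phase system.
#'
#' @param topology An [mm_topology()].
#' @param positions n x 3 coordinate matrix, Å (virtual-site rows are
#'   re-derived before evaluation).
#' @return An `energy_report`: list with components `bond`, `angle`,
#'   `torsion`, `lj`, `coulomb` and their sum `total`, kcal/mol.
#' @export
total_energy <- function(topology, positions) {
  positions <- apply_vsites(topology, positions)
  e_bond <- e_angle <- e_torsion <- 0
  for (b in topology$bonds) {
    r <- vnorm(positions[b$i, ] - positions[b$j, ])
    e_bond <- e_bond + 0.5 * b$term$k * (r - b$term$x0)^2
  }
  for (a in topology$angles) {
    th <- angle_at(positions[a$i, ], positions[a$j, ], positions[a$k, ])
    e_angle <- e_angle + 0.5 * a$term$k * (th - deg2rad(a$term$x0))^2
  }
  for (t in topology$torsions) {
    phi <- rad2deg(dihedral_angle(positions[t$i, ], positions[t$j, ],
                                  positions[t$k, ], positions[t$l, ]))
    s <- t$series
    e_torsion <- e_torsion + sum(s$vmax / 2 * (1 + cospi((s$n * phi + s$gamma) / 180)))
  }
  nb <- topology$nb
  e_lj <- e_coul <- 0
  if (nrow(nb)) {
    dvec <- positions[nb$i, , drop = FALSE] - positions[nb$j, , drop = FALSE]
    r <- sqrt(rowSums(dvec^2))
    if (any(r < 1e-6)) {
      stop_singularity("non-excluded atoms overlap (r < 1e-6 A)")
    }
    live <- nb$epsilon > 0
    if (any(live)) {
      sr6 <- (nb$sigma[live] / r[live])^6
      e_lj <- sum(nb$slj[live] * 4 * nb$epsilon[live] * (sr6^2 - sr6))
    }
    e_coul <- sum(nb$scoul * mm_constants$coulomb_kcal * nb$qq / r)
  }
  structure(list(bond = e_bond, angle = e_angle, torsion = e_torsion,
                 lj = e_lj, coulomb = e_coul,
                 total = e_bond + e_angle + e_torsion + e_lj + e_coul),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf(paste0("<energy_report> (kcal/mol)\n  bond    %12.6f\n  angle   %12.6f\n",
                     "  torsion %12.6f\n  LJ      %12.6f\n  coulomb %12.6f\n  total   %12.6f\n"),
              x$bond, x$angle, x$torsion, x$lj, x$coulomb, x$total))
  invisible(x)
}

angle_at <- function(pi_, pj, pk) {
  u <- pi_ - pj; v <- pk - pj
  cu <- vnorm(u); cv <- vnorm(v)
  if (cu < 1e-12 || cv < 1e-12) stop_singularity("degenerate angle (coincident atoms)")
  acos(max(-1, min(1, sum(u * v) / (cu * cv))))
}

#' Analytic energy gradient
#'
#' Derivative of [total_energy()] with respect to the real-atom
#' coordinates. Forces acting on massless virtual sites are redistributed
#' onto their defining atoms via [project_vsite_gradient()]; the returned
#' matrix has zero rows for site coordinates (they are not degrees of
#' freedom).
#'
#' @param topology An [mm_topology()].
#' @param positions n x 3 coordinate matrix, Å.
#' @return n x 3 gradient matrix, kcal/mol/Å.
#' @export
mm_gradient <- function(topology, positions) {
  positions <- apply_vsites(topology, positions)
  n <- nrow(positions)
  g <- matrix(0, n, 3)
  for (b in topology$bonds) {
    d <- positions[b$i, ] - positions[b$j, ]
    r <- vnorm(d)
    f <- b$term$k * (r - b$term$x0) / r
    g[b$i, ] <- g[b$i, ] + f * d
    g[b$j, ] <- g[b$j, ] - f * d
  }
  for (a in topology$angles) {
    u <- positions[a$i, ] - positions[a$j, ]
    v <- positions[a$k, ] - positions[a$j, ]
    lu <- vnorm(u); lv <- vnorm(v)
    uh <- u / lu; vh <- v / lv
    cth <- max(-1, min(1, sum(uh * vh)))
    sth <- sqrt(max(1 - cth^2, 1e-14))
    th <- acos(cth)
    pref <- -a$term$k * (th - deg2rad(a$term$x0)) / sth
    dci <- (vh - cth * uh) / lu
    dck <- (uh - cth * vh) / lv
    g[a$i, ] <- g[a$i, ] + pref * dci
    g[a$k, ] <- g[a$k, ] + pref * dck
    g[a$j, ] <- g[a$j, ] - pref * (dci + dck)
  }
  for (t in topology$torsions) {
    p1 <- positions[t$i, ]; p2 <- positions[t$j, ]
    p3 <- positions[t$k, ]; p4 <- positions[t$l, ]
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- crossv(b1, b2); n2 <- crossv(b2, b3)
    lb2 <- vnorm(b2)
    phi <- dihedral_angle(p1, p2, p3, p4)
    s <- t$series
    # dE/dphi in kcal/mol/rad
    dEdphi <- sum(-s$vmax / 2 * s$n * sin(s$n * phi + deg2rad(s$gamma)))
    # signs follow the atan2 convention of dihedral_angle()
    dphi_d1 <- lb2 / sum(n1 * n1) * n1
    dphi_d4 <- -lb2 / sum(n2 * n2) * n2
    c1 <- sum(b1 * b2) / lb2^2
    c2 <- sum(b3 * b2) / lb2^2
    dphi_d2 <- -(1 + c1) * dphi_d1 + c2 * dphi_d4
    dphi_d3 <- c1 * dphi_d1 - (1 + c2) * dphi_d4
    g[t$i, ] <- g[t$i, ] + dEdphi * dphi_d1
    g[t$j, ] <- g[t$j, ] + dEdphi * dphi_d2
    g[t$k, ] <- g[t$k, ] + dEdphi * dphi_d3
    g[t$l, ] <- g[t$l, ] + dEdphi * dphi_d4
  }
  nb <- topology$nb
  if (nrow(nb)) {
    dvec <- positions[nb$i, , drop = FALSE] - positions[nb$j, , drop = FALSE]
    r <- sqrt(rowSums(dvec^2))
    if (any(r < 1e-6)) stop_singularity("non-excluded atoms overlap (r < 1e-6 A)")
    dEdr <- -nb$scoul * mm_constants$coulomb_kcal * nb$qq / r^2
    live <- nb$epsilon > 0
    if (any(live)) {
      sr6 <- (nb$sigma[live] / r[live])^6
      dEdr[live] <- dEdr[live] + nb$slj[live] * 4 * nb$epsilon[live] *
        (-12 * sr6^2 + 6 * sr6) / r[live]
    }
    fv <- dvec * (dEdr / r)
    for (row in seq_len(nrow(nb))) {
      g[nb$i[row], ] <- g[nb$i[row], ] + fv[row, ]
      g[nb$j[row], ] <- g[nb$j[row], ] - fv[row, ]
    }
  }
  # massless sites: push their gradient onto the defining atoms
  for (vs in topology$vsites) {
    proj <- project_vsite_gradient(g[vs$site, ], positions[vs$parent, ],
                                   positions[vs$reference, ], vs$distance)
    g[vs$parent, ] <- g[vs$parent, ] + proj$parent
    g[vs$reference, ] <- g[vs$reference, ] + proj$reference
    g[vs$site, ] <- 0
  }
  g
}

crossv <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Minimize the energy of a conformation
#'
#' Quasi-Newton (BFGS) minimization over the real-atom coordinates with
#' the analytic gradient; virtual-site positions are re-derived at every
#' evaluation. Convergence is judged on the gradient max-norm. The
#' energy is non-increasing across accepted steps (BFGS line searches
#' only accept descent).
#'
#' @param topology An [mm_topology()].
#' @param positions Starting n x 3 coordinates, Å.
#' @param gradient_tolerance Convergence threshold on
#'   `max |dE/dx|`, kcal/mol/Å (default 1e-4).
#' @param max_steps Iteration budget across restarts.
#' @return The minimized coordinate matrix with attributes `energy`
#'   (kcal/mol), `converged`, and `iterations`. Raises a
#'   `chalcogenmm_no_convergence` error if the budget is exhausted.
#' @export
mm_minimize <- function(topology, positions, gradient_tolerance = 1e-4,
                        max_steps = 5000L) {
  free <- which(!topology$is_vsite)
  positions <- apply_vsites(topology, positions)
  if (!length(topology$bonds) && !length(topology$angles) &&
      !length(topology$torsions) && !nrow(topology$nb)) {
    attr(positions, "energy") <- 0
    attr(positions, "converged") <- TRUE
    attr(positions, "iterations") <- 0L
    return(positions)
  }
  unpack <- function(x) {
    p <- positions
    p[free, ] <- matrix(x, ncol = 3)
    apply_vsites(topology, p)
  }
  fn <- function(x) total_energy(topology, unpack(x))$total
  gr <- function(x) as.vector(mm_gradient(topology, unpack(x))[free, , drop = FALSE])
  x <- as.vector(positions[free, , drop = FALSE])
  used <- 0L
  repeat {
    gmax <- max(abs(gr(x)))
    if (gmax <= gradient_tolerance) break
    if (used >= max_steps) {
      stop(errorCondition(sprintf(
        "minimization did not reach |grad| <= %g within %d steps (now %.3g)",
        gradient_tolerance, max_steps, gmax),
        class = c("chalcogenmm_no_convergence", "chalcogenmm_error")))
    }
    budget <- min(200L, max_steps - used)
    res <- stats::optim(x, fn, gr, method = "BFGS",
                        control = list(maxit = budget, reltol = 1e-16))
    used <- used + budget
    if (max(abs(x - res$par)) == 0) {
      # BFGS stalled (flat to machine precision); accept if close enough
      if (max(abs(gr(res$par))) <= gradient_tolerance * 10) { x <- res$par; break }
      stop(errorCondition("minimizer stalled before reaching the gradient tolerance",
                          class = c("chalcogenmm_no_convergence", "chalcogenmm_error")))
    }
    x <- res$par
  }
  out <- unpack(x)
  attr(out, "energy") <- fn(x)
  attr(out, "converged") <- TRUE
  attr(out, "iterations") <- used
  out
}

#' Combine two topologies into one system
#'
#' Concatenates atom tables and bonded terms, shifting the second
#' molecule's indices. No exclusions are created between the molecules:
#' all intermolecular pairs interact fully.
#'
#' @param top_a,top_b [mm_topology()] objects.
#' @return An `mm_topology` for the combined system; attribute
#'   `offset` gives the index shift applied to `top_b`.
#' @export
combine_topologies <- function(top_a, top_b) {
  na <- nrow(top_a$atoms)
  shift <- function(terms, fields) {
    lapply(terms, function(t) { for (f in fields) t[[f]] <- t[[f]] + na; t })
  }
  vs_b <- lapply(top_b$vsites, function(v) {
    virtual_site_fd(v$site + na, v$parent + na, v$reference + na, v$distance)
  })
  extra <- c(
    unlist(lapply(seq_len(na), function(i) {
      lapply(top_a$exclusions[[i]][top_a$exclusions[[i]] > i],
             function(j) c(i, j))
    }), recursive = FALSE),
    unlist(lapply(seq_len(nrow(top_b$atoms)), function(i) {
      lapply(top_b$exclusions[[i]][top_b$exclusions[[i]] > i],
             function(j) c(i + na, j + na))
    }), recursive = FALSE)
  )
  out <- mm_topology(rbind(top_a$atoms, top_b$atoms),
                     bonds = c(top_a$bonds, shift(top_b$bonds, c("i", "j"))),
                     angles = c(top_a$angles, shift(top_b$angles, c("i", "j", "k"))),
                     torsions = c(top_a$torsions,
                                  shift(top_b$torsions, c("i", "j", "k", "l"))),
                     vsites = c(top_a$vsites, vs_b),
                     scale_lj_14 = top_a$scale_lj_14,
                     scale_coul_14 = top_a$scale_coul_14,
                     extra_exclusions = extra)
  attr(out, "offset") <- na
  out
}

#' Interaction energy of a dimer
#'
#' `E_int = E(minimized dimer) - E(minimized A) - E(minimized B)`: the
#' complex is minimized from the supplied start, each monomer is
#' minimized separately from its own rows of the same start, and the
#' difference is returned. Intermolecular pairs carry no exclusions.
#'
#' @param top_a,top_b Monomer topologies.
#' @param positions (nA+nB) x 3 starting coordinates for the dimer, Å
#'   (A's atoms first).
#' @param gradient_tolerance,max_steps Passed to [mm_minimize()].
#' @return The interaction energy in kcal/mol, with attributes
#'   `dimer_positions`, `energy_dimer`, `energy_a`, `energy_b`.
#' @export
dimer_interaction_energy <- function(top_a, top_b, positions,
                                     gradient_tolerance = 1e-4,
                                     max_steps = 5000L) {
  na <- nrow(top_a$atoms)
  dimer <- combine_topologies(top_a, top_b)
  min_d <- mm_minimize(dimer, positions, gradient_tolerance, max_steps)
  min_a <- mm_minimize(top_a, positions[seq_len(na), , drop = FALSE],
                       gradient_tolerance, max_steps)
  min_b <- mm_minimize(top_b, positions[-seq_len(na), , drop = FALSE],
                       gradient_tolerance, max_steps)
  e_int <- attr(min_d, "energy") - attr(min_a, "energy") - attr(min_b, "energy")
  structure(e_int, dimer_positions = min_d,
            energy_dimer = attr(min_d, "energy"),
            energy_a = attr(min_a, "energy"),
            energy_b = attr(min_b, "energy"))
}

#' Chalcogen-bond geometry of a complex
#'
#' Reports the acceptor distance and the donor-axis angle of a chalcogen
#' bond: `r = |r_Se - r_B|` and `theta`, the N-Se...B angle at the
#' chalcogen between the vectors (N - Se) and (B - Se). A base sitting
#' exactly on the sigma-hole axis gives theta = 180 degrees.
#'
#' @param positions Coordinate matrix, Å.
#' @param chalcogen,reference,base Row indices of the chalcogen (Se),
#'   the axis-defining atom (N) and the Lewis-base atom (B).
#' @return A list with `r` (Å) and `theta` (degrees).
#' @export
measure_chalcogen_geometry <- function(positions, chalcogen, reference, base) {
  if (length(unique(c(chalcogen, reference, base))) != 3L) {
    stop_format("chalcogen, reference and base indices must be distinct")
  }
  se <- positions[chalcogen, ]; nn <- positions[reference, ]; bb <- positions[base, ]
  r <- vnorm(bb - se)
  if (r < 1e-9 || vnorm(nn - se) < 1e-9) stop_singularity("coincident atoms in geometry measurement")
  theta <- rad2deg(angle_at(nn, se, bb))
  list(r = r, theta = theta)
}

#' Angular probe scan around a chalcogen
#'
#' Places a single-particle probe at a fixed distance from the chalcogen
#' and sweeps the N-Se...probe angle through `theta_grid`, reporting the
#' single-point interaction energy at each placement (no minimization).
#' The probe moves in the plane spanned by the Se-N axis and a third
#' in-plane atom, so theta = 180 degrees puts it exactly on the
#' sigma-hole axis. This is the desk-scale surrogate for the
#' directionality of chalcogen bonding: with the pseudoatom the profile
#' develops a marked minimum near 180 degrees, without it the profile is
#' nearly flat.
#'
#' @param topology Topology of the host molecule (may contain the
#'   sigma-hole virtual site).
#' @param positions Host coordinates, Å.
#' @param probe One-row topology for the probe (see [build_probe()]).
#' @param r_fixed Probe distance from the chalcogen, Å.
#' @param theta_grid Angles in degrees, within \[0, 180\].
#' @param chalcogen,reference Indices of Se and N in `topology`.
#' @param plane_atom Index of a third atom defining the scan plane;
#'   defaults to the first real atom that is neither chalcogen nor
#'   reference and not collinear with them.
#' @return A data frame with columns `theta` and `energy` (kcal/mol,
#'   host-probe system total).
#' @export
angular_probe_scan <- function(topology, positions, probe, r_fixed, theta_grid,
                               chalcogen, reference, plane_atom = NULL) {
  if (any(theta_grid < 0 | theta_grid > 180)) {
    stop_format("theta_grid must lie within [0, 180] degrees")
  }
  se <- positions[chalcogen, ]
  nhat <- positions[reference, ] - se
  nhat <- nhat / vnorm(nhat)
  if (is.null(plane_atom)) {
    cands <- setdiff(which(!topology$is_vsite), c(chalcogen, reference))
    for (c_ in cands) {
      w <- positions[c_, ] - se
      if (vnorm(w - nhat * sum(w * nhat)) > 1e-6) { plane_atom <- c_; break }
    }
    if (is.null(plane_atom)) stop_format("no non-collinear atom available to define the scan plane")
  }
  w <- positions[plane_atom, ] - se
  mhat <- w - nhat * sum(w * nhat)
  mhat <- mhat / vnorm(mhat)
  system_top <- combine_topologies(topology, probe)
  energies <- vapply(theta_grid, function(th) {
    dir <- cos(deg2rad(th)) * nhat + sin(deg2rad(th)) * mhat
    pp <- rbind(positions, se + r_fixed * dir)
    total_energy(system_top, pp)$total
  }, numeric(1))
  data.frame(theta = theta_grid, energy = energies)
}
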