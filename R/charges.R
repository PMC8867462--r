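#' Electrostatic-potential grid
#'
#' Bundles the charge-carrying site positions (atoms plus any manually
#' inserted pseudoatom sites) with the ESP sample points and potential
#' values the charges will be fitted to. Positions are in Å at the
#' interface; potentials are in atomic units (Hartree/e).
#'
#' @param site_positions n_sites x 3 numeric matrix, Å.
#' @param sample_points n_points x 3 numeric matrix, Å.
#' @param potentials Numeric vector of length n_points, atomic units.
#' @param labels Optional per-site names.
#' @return An object of class `esp_grid`.
#' @export
esp_grid <- function(site_positions, sample_points, potentials, labels = NULL) {
  site_positions <- as.matrix(site_positions)
  sample_points <- as.matrix(sample_points)
  if (ncol(site_positions) != 3L || ncol(sample_points) != 3L) {
    stop_format("positions must be n x 3 matrices")
  }
  if (nrow(sample_points) != length(potentials)) {
    stop_format("sample_points and potentials must align")
  }
  if (is.null(labels)) labels <- paste0("site", seq_len(nrow(site_positions)))
  structure(list(site_positions = site_positions,
                 sample_points = sample_points,
                 potentials = as.numeric(potentials),
                 labels = labels),
            class = "esp_grid")
}

#' @export
print.esp_grid <- function(x, ...) {
  cat(sprintf("<esp_grid> %d sites, %d sample points\n",
              nrow(x$site_positions), nrow(x$sample_points)))
  invisible(x)
}

#' Read a Gaussian cube file as an ESP grid
#'
#' Parses the standard cube layout: two comment lines; a line with the
#' atom count and grid origin; three axis lines (voxel counts and step
#' vectors); the atom block (atomic number, charge, position); then the
#' volumetric values in Fortran order (z fastest). Cube geometry is in
#' bohr and is converted to Å (factor 0.52917721092); the potential
#' values are kept in atomic units.
#'
#' @param path Path to a cube file.
#' @param exclusion_radii Optional per-atom radii in Å; grid points closer
#'   than an atom's radius are dropped, mirroring the exclusion zone used
#'   when sampling ESP shells.
#' @return An [esp_grid()] whose sites are the cube's atoms and whose
#'   sample points are the (optionally filtered) voxel centres.
#' @export
read_cube <- function(path, exclusion_radii = NULL) {
  lines <- readLines(path)
  if (length(lines) < 7L) stop_format("cube file too short")
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  hdr <- nums(lines[3L])
  if (length(hdr) < 4L || is.na(hdr[1L])) stop_format("malformed cube header line 3")
  natoms <- as.integer(hdr[1L])
  if (natoms <= 0) stop_format("cube files with negative/zero atom counts are not supported")
  origin <- hdr[2:4]
  ax <- lapply(4:6, function(i) nums(lines[i]))
  nvox <- vapply(ax, function(a) as.integer(a[1L]), integer(1))
  steps <- t(vapply(ax, function(a) a[2:4], numeric(3)))
  if (any(is.na(nvox)) || any(nvox <= 0)) stop_format("malformed cube axis lines")
  atom_lines <- lines[7:(6 + natoms)]
  atoms <- t(vapply(atom_lines, nums, numeric(5)))
  site_positions <- atoms[, 3:5, drop = FALSE] * mm_constants$bohr_to_angstrom
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[(7 + natoms):length(lines)]), "\\s+"))))
  vals <- vals[!is.na(vals)]
  nexp <- prod(nvox)
  if (length(vals) != nexp) {
    stop_format(sprintf("cube declares %d voxels but %d values were parsed",
                        nexp, length(vals)))
  }
  # Fortran order: the last axis index varies fastest
  idx <- expand.grid(k = seq_len(nvox[3L]) - 1L,
                     j = seq_len(nvox[2L]) - 1L,
                     i = seq_len(nvox[1L]) - 1L)
  pts_bohr <- cbind(origin[1L], origin[2L], origin[3L]) [rep(1, nrow(idx)), , drop = FALSE] +
    outer(idx$i, steps[1L, ]) + outer(idx$j, steps[2L, ]) + outer(idx$k, steps[3L, ])
  pts <- pts_bohr * mm_constants$bohr_to_angstrom
  keep <- rep(TRUE, nrow(pts))
  if (!is.null(exclusion_radii)) {
    if (length(exclusion_radii) != natoms) {
      stop_format("exclusion_radii must have one entry per cube atom")
    }
    for (a in seq_len(natoms)) {
      d <- sqrt(rowSums((pts - matrix(site_positions[a, ], nrow(pts), 3,
                                      byrow = TRUE))^2))
      keep <- keep & (d >= exclusion_radii[a])
    }
  }
  esp_grid(site_positions, pts[keep, , drop = FALSE], vals[keep],
           labels = paste0("atom", seq_len(natoms)))
}

#' Write a minimal Gaussian cube file
#'
#' Counterpart of [read_cube()] used to build test inputs and to export
#' synthetic grids; geometry is given in Å and written in bohr.
#'
#' @param path Output path.
#' @param atom_positions n x 3 matrix, Å.
#' @param values Numeric array with `dim = c(n1, n2, n3)` of potential
#'   values on the voxel grid, atomic units.
#' @param origin Length-3 grid origin, Å.
#' @param step Voxel step length along each axis, Å (axis-aligned grid).
#' @param atomic_numbers Integer vector per atom (default 6).
#' @return `path`, invisibly.
#' @export
write_cube <- function(path, atom_positions, values, origin = c(0, 0, 0),
                       step = 0.5, atomic_numbers = NULL) {
  atom_positions <- as.matrix(atom_positions)
  if (length(dim(values)) != 3L) stop_format("values must be a 3-d array")
  b <- mm_constants$bohr_to_angstrom
  n <- nrow(atom_positions)
  if (is.null(atomic_numbers)) atomic_numbers <- rep(6L, n)
  if (length(step) == 1L) step <- rep(step, 3L)
  dims <- dim(values)
  lines <- c("synthetic ESP cube",
             "written by chalcogenmm (geometry in bohr, potential in a.u.)",
             sprintf("%5d %11.6f %11.6f %11.6f", n,
                     origin[1] / b, origin[2] / b, origin[3] / b),
             sprintf("%5d %11.6f %11.6f %11.6f", dims[1], step[1] / b, 0, 0),
             sprintf("%5d %11.6f %11.6f %11.6f", dims[2], 0, step[2] / b, 0),
             sprintf("%5d %11.6f %11.6f %11.6f", dims[3], 0, 0, step[3] / b))
  for (a in seq_len(n)) {
    lines <- c(lines, sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                              atomic_numbers[a], 0,
                              atom_positions[a, 1] / b,
                              atom_positions[a, 2] / b,
                              atom_positions[a, 3] / b))
  }
  # Fortran cube order (z fastest), 6 values per line, %13.5E like cubegen
  flat <- as.vector(aperm(values, c(3, 2, 1)))
  grp <- split(flat, ceiling(seq_along(flat) / 6))
  lines <- c(lines, vapply(grp, function(g) paste(sprintf("%13.5E", g), collapse = " "),
                           character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Electrostatic potential of point charges
#'
#' Direct Coulomb sum `V(r) = sum_i q_i / |r - r_i|` in atomic units:
#' charges in e, distances converted Å to bohr. This is the forward model
#' that RESP inverts, and doubles as the generator for synthetic grids.
#'
#' @param positions n_sites x 3 matrix, Å.
#' @param charges Length-n_sites vector, e.
#' @param sample_points m x 3 matrix, Å.
#' @return Length-m vector of potentials, atomic units.
#' @export
esp_from_point_charges <- function(positions, charges, sample_points) {
  positions <- as.matrix(positions)
  sample_points <- as.matrix(sample_points)
  stopifnot(nrow(positions) == length(charges))
  V <- numeric(nrow(sample_points))
  for (i in seq_len(nrow(positions))) {
    d <- sqrt(rowSums((sample_points - matrix(positions[i, ], nrow(sample_points),
                                              3, byrow = TRUE))^2))
    if (any(d < 1e-9)) stop_singularity("a sample point coincides with a charge site")
    V <- V + charges[i] / (d / mm_constants$bohr_to_angstrom)
  }
  V
}

#' Sample ESP points on scaled van der Waals shells
#'
#' Connolly-style shell sampling for synthetic RESP problems: points are
#' drawn uniformly on spheres of radius `factor * radius` around each
#' site, then points falling inside the smallest shell
#' (`min(scale_factors) * radius`) of *any* site are discarded, so no
#' retained point sits in any site's exclusion zone.
#'
#' @param positions n_sites x 3 matrix, Å.
#' @param radii Per-site base radii, Å (e.g. Bondi vdW radii; use 0 for a
#'   pseudoatom that sits on its parent's surface by construction).
#' @param scale_factors Shell scale factors, each >= 1
#'   (default `c(1.4, 1.6, 1.8, 2.0)`).
#' @param density Target surface density, points per Å².
#' @param seed Integer seed; fixed seeds give identical point sets.
#' @return An m x 3 matrix of sample points, Å.
#' @export
sample_shells <- function(positions, radii, scale_factors = c(1.4, 1.6, 1.8, 2.0),
                          density = 1, seed = NULL) {
  positions <- as.matrix(positions)
  n_sites <- nrow(positions)
  stopifnot(length(radii) == n_sites)
  if (!any(scale_factors >= 1)) stop_format("need at least one shell factor >= 1")
  fmin <- min(scale_factors)
  pts <- with_seed(seed, {
    out <- list()
    for (f in scale_factors) {
      for (s in seq_len(n_sites)) {
        r <- f * radii[s]
        if (r <= 0) next
        npt <- max(1L, ceiling(density * 4 * pi * r^2))
        # uniform on the sphere via normalized Gaussians
        g <- matrix(stats::rnorm(3 * npt), ncol = 3)
        g <- g / sqrt(rowSums(g^2))
        out[[length(out) + 1L]] <- g * r +
          matrix(positions[s, ], npt, 3, byrow = TRUE)
      }
    }
    do.call(rbind, out)
  })
  if (is.null(pts) || nrow(pts) == 0L) stop_format("no shell points generated")
  keep <- rep(TRUE, nrow(pts))
  for (s in seq_len(n_sites)) {
    if (radii[s] <= 0) next
    d <- sqrt(rowSums((pts - matrix(positions[s, ], nrow(pts), 3, byrow = TRUE))^2))
    keep <- keep & (d >= fmin * radii[s] - 1e-9)
  }
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0L) stop_format("all shell points fell inside exclusion zones; increase density")
  pts
}

#' RESP configuration
#'
#' @param restraint_a Hyperbolic restraint strength, atomic units
#'   (default 0.0005, the standard stage-1 value; 0 disables the
#'   restraint and the fit becomes exact constrained linear least
#'   squares).
#' @param restraint_b Restraint width, e (default 0.1).
#' @param total_charge Constrained total charge, e.
#' @param frozen Optional numeric vector, one entry per site: a fixed
#'   charge for that site, or `NA` to fit it.
#' @param max_iterations Cap on the reweighting iterations.
#' @param tolerance Convergence threshold on the max charge change, e.
#' @return An object of class `resp_config`.
#' @export
resp_config <- function(restraint_a = 0.0005, restraint_b = 0.1,
                        total_charge = 0, frozen = NULL,
                        max_iterations = 100L, tolerance = 1e-10) {
  if (restraint_a < 0) stop_format("restraint_a must be >= 0")
  if (!(restraint_b > 0)) stop_format("restraint_b must be > 0")
  structure(list(restraint_a = restraint_a, restraint_b = restraint_b,
                 total_charge = total_charge, frozen = frozen,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "resp_config")
}

#' Fitted point-charge model
#'
#' @param labels Per-site names.
#' @param charges Per-site charges, e.
#' @param equivalence_classes List of integer vectors; sites within one
#'   class carry identical charges.
#' @param total_charge The constrained sum, e.
#' @return An object of class `charge_model`.
#' @export
charge_model <- function(labels, charges, equivalence_classes = list(),
                         total_charge = sum(charges)) {
  structure(list(labels = labels, charges = as.numeric(charges),
                 equivalence_classes = equivalence_classes,
                 total_charge = total_charge),
            class = "charge_model")
}

#' @export
print.charge_model <- function(x, ...) {
  cat("<charge_model>\n")
  for (i in seq_along(x$charges)) {
    cat(sprintf("  %-8s %+0.6f e\n", x$labels[i], x$charges[i]))
  }
  cat(sprintf("  total = %+0.6f e\n", sum(x$charges)))
  invisible(x)
}

#' Restrained ESP (RESP) charge fit
#'
#' Fits atom- and pseudoatom-centred point charges to an electrostatic
#' potential grid by minimizing
#' `sum_p (V_p - sum_j q_j / r_jp)^2 + sum_j a (sqrt(q_j^2 + b^2) - b)`
#' subject to a fixed total charge and optional equivalence classes
#' (sites constrained to share one charge), via iteratively reweighted
#' constrained linear solves with a Lagrange multiplier for the
#' total-charge constraint. The hyperbolic restraint pulls charges toward
#' zero; with `restraint_a = 0` the first solve is exact and the fit
#' reduces to constrained linear least squares. Single-stage fitting with
#' explicit equivalences; no second-stage refit of buried atoms.
#'
#' @param grid An [esp_grid()].
#' @param config A [resp_config()].
#' @param equivalences Optional list of integer vectors of site indices
#'   constrained to share a charge.
#' @return A [charge_model()]; attribute `rrms` holds the relative RMS of
#'   the potential fit and `iterations` the reweighting count.
#' @export
resp_fit <- function(grid, config = resp_config(), equivalences = list()) {
  stopifnot(inherits(grid, "esp_grid"))
  n_sites <- nrow(grid$site_positions)
  npts <- nrow(grid$sample_points)
  frozen <- config$frozen
  if (is.null(frozen)) frozen <- rep(NA_real_, n_sites)
  if (length(frozen) != n_sites) stop_format("frozen must have one entry per site")

  # site -> class map; frozen sites are excluded from the parameter vector
  class_of <- seq_len(n_sites)
  for (cl in equivalences) {
    cl <- as.integer(cl)
    if (any(!is.na(frozen[cl]))) stop_format("frozen sites cannot join equivalence classes")
    class_of[cl] <- min(cl)
  }
  free_mask <- is.na(frozen)
  free_classes <- sort(unique(class_of[free_mask]))
  ncls <- length(free_classes)
  if (ncls == 0L) stop_format("no free charges to fit")
  if (npts < ncls) stop_format("fewer sample points than free charge parameters")

  # design: A[p, j] = 1 / r_jp (bohr); columns collapsed by class
  b2a <- mm_constants$bohr_to_angstrom
  A <- matrix(0, npts, n_sites)
  for (j in seq_len(n_sites)) {
    d <- sqrt(rowSums((grid$sample_points -
                         matrix(grid$site_positions[j, ], npts, 3, byrow = TRUE))^2))
    if (any(d < 1e-9)) stop_singularity("a sample point coincides with a charge site")
    A[, j] <- 1 / (d / b2a)
  }
  B <- matrix(0, npts, ncls)
  mult <- integer(ncls)        # how many sites share each class
  members <- vector("list", ncls)
  for (c in seq_len(ncls)) {
    m <- which(class_of == free_classes[c] & free_mask)
    members[[c]] <- m
    mult[c] <- length(m)
    B[, c] <- rowSums(A[, m, drop = FALSE])
  }
  rhs_pot <- grid$potentials
  q_frozen_total <- 0
  if (any(!free_mask)) {
    rhs_pot <- rhs_pot - A[, !free_mask, drop = FALSE] %*% frozen[!free_mask]
    q_frozen_total <- sum(frozen[!free_mask])
  }
  target <- config$total_charge - q_frozen_total

  BtB <- crossprod(B)
  Btv <- crossprod(B, rhs_pot)
  a <- config$restraint_a
  bwidth <- config$restraint_b

  q <- rep(0, ncls)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    # KKT system: [2 B'B + R, m; m', 0] [q; lambda] = [2 B'v; target]
    R <- if (a > 0) diag(mult * a / sqrt(q^2 + bwidth^2), ncls) else matrix(0, ncls, ncls)
    K <- rbind(cbind(2 * BtB + R, mult), c(mult, 0))
    rhs <- c(2 * Btv, target)
    sol <- tryCatch(solve(K, rhs),
                    error = function(e) stop_degenerate(
                      "rank-deficient RESP system after applying constraints"))
    qnew <- sol[seq_len(ncls)]
    delta <- max(abs(qnew - q))
    q <- qnew
    if (a == 0 || delta < config$tolerance) break
    if (iterations >= config$max_iterations) {
      stop(errorCondition(sprintf("RESP did not converge in %d iterations (last change %.3g e)",
                                  iterations, delta),
                          class = c("chalcogenmm_no_convergence", "chalcogenmm_error")))
    }
  }

  charges <- frozen
  for (c in seq_len(ncls)) charges[members[[c]]] <- q[c]
  model <- charge_model(labels = grid$labels, charges = charges,
                        equivalence_classes = equivalences,
                        total_charge = config$total_charge)
  fitted <- drop(B %*% q)
  attr(model, "rrms") <- sqrt(sum((rhs_pot - fitted)^2) / max(sum(rhs_pot^2), .Machine$double.xmin))
  attr(model, "iterations") <- iterations
  model
}

#' Insert a sigma-hole pseudoatom into a site list
#'
#' Appends a charge site at
#' `r_parent + distance * (r_parent - r_reference)/|r_parent - r_reference|`
#' — along the extension of the reference-parent bond, beyond the parent.
#' The new site then joins the charge-fit parameter vector like any atom,
#' which is how the pseudoatom charge is obtained: insert the site
#' manually, rerun RESP.
#'
#' @param positions n x 3 matrix of site positions, Å.
#' @param parent,reference Row indices of the parent (chalcogen) and the
#'   axis-defining atom.
#' @param distance Distance beyond the parent, Å.
#' @param label Name for the new site.
#' @return The augmented (n+1) x 3 matrix; the new site is the last row.
#'   Row names are preserved/extended when present.
#' @export
add_pseudoatom_site <- function(positions, parent, reference, distance,
                                label = "EP") {
  positions <- as.matrix(positions)
  if (parent == reference) stop_format("parent and reference must differ")
  pos <- vsite_position(positions[parent, ], positions[reference, ], distance)
  out <- rbind(positions, pos)
  if (!is.null(rownames(positions))) rownames(out) <- c(rownames(positions), label)
  out
}
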