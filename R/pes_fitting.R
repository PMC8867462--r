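#' Potential-energy-scan container
#'
#' Holds the samples of a relaxed potential-energy surface scan along one
#' internal coordinate (a bond length, a valence angle, or a dihedral), the
#' raw material for harmonic and torsion fits.
#'
#' @param x Numeric vector of coordinate values, strictly increasing.
#'   Bonds in Å, angles and dihedrals in degrees; dihedral values must lie
#'   in \[-180, 180).
#' @param energy Numeric vector of energies (kcal/mol), same length as `x`.
#' @param kind One of `"bond"`, `"angle"`, `"dihedral"`.
#' @param x0 Optional equilibrium coordinate value (from the optimized
#'   geometry); fixed during harmonic fits, never refit.
#' @return An object of class `pes_scan`: a list with elements `x`,
#'   `energy`, `kind`, `x0`.
#' @export
pes_scan <- function(x, energy, kind = c("bond", "angle", "dihedral"), x0 = NULL) {
  kind <- match.arg(kind)
  x <- as.numeric(x)
  energy <- as.numeric(energy)
  if (length(x) != length(energy)) {
    stop_format("coordinate and energy vectors differ in length")
  }
  if (length(x) < 3L) {
    stop_degenerate("a scan needs at least 3 points")
  }
  if (any(diff(x) <= 0)) {
    stop_format("coordinate values must be strictly increasing")
  }
  if (kind == "dihedral" && (any(x < -180) || any(x >= 180))) {
    stop_format("dihedral coordinates must lie in [-180, 180) degrees")
  }
  structure(list(x = x, energy = energy, kind = kind, x0 = x0),
            class = "pes_scan")
}

#' @export
print.pes_scan <- function(x, ...) {
  cat(sprintf("<pes_scan> %s scan, %d points, range [%g, %g]%s\n",
              x$kind, length(x$x), min(x$x), max(x$x),
              if (is.null(x$x0)) "" else sprintf(", x0 = %g", x$x0)))
  invisible(x)
}

#' Truncate a scan to an energy window above its minimum
#'
#' Relaxed scans are appreciably anharmonic far from equilibrium; before a
#' harmonic fit the surface is truncated to the points within `cutoff` of
#' the lowest sampled energy. Truncation is applied before, never after,
#' fitting.
#'
#' @param scan A [pes_scan()].
#' @param cutoff Energy window in kcal/mol above the scan minimum
#'   (default 5).
#' @return A `pes_scan` containing exactly the points with
#'   `energy - min(energy) <= cutoff`, in the original order.
#' @export
truncate_scan <- function(scan, cutoff = 5) {
  stopifnot(inherits(scan, "pes_scan"), cutoff > 0)
  keep <- (scan$energy - min(scan$energy)) <= cutoff
  if (sum(keep) < 3L) {
    stop_degenerate(sprintf(
      "only %d point(s) within %g kcal/mol of the minimum; fit would be under-determined",
      sum(keep), cutoff))
  }
  pes_scan(scan$x[keep], scan$energy[keep], kind = scan$kind, x0 = scan$x0)
}

#' Harmonic bonded term
#'
#' @param x0 Equilibrium value (Å for bonds, degrees for angles).
#' @param k Force constant; kcal/mol·Å² for bonds, kcal/mol·radian² for
#'   angles (the equilibrium angle stays in degrees, the curvature is per
#'   radian²).
#' @param kind `"bond"` or `"angle"`.
#' @param baseline Fitted constant energy offset (kcal/mol); kept for
#'   evaluation, not exported to topologies.
#' @return An object of class `harmonic_term`.
#' @export
harmonic_term <- function(x0, k, kind = c("bond", "angle"), baseline = 0) {
  kind <- match.arg(kind)
  if (k < 0) stop_format("harmonic force constants must be non-negative")
  structure(list(x0 = x0, k = k, kind = kind, baseline = baseline),
            class = "harmonic_term")
}

#' @export
print.harmonic_term <- function(x, ...) {
  unit <- if (x$kind == "bond") "kcal/mol/A^2" else "kcal/mol/rad^2"
  cat(sprintf("<harmonic_term> %s: x0 = %g, k = %g %s\n", x$kind, x$x0, x$k, unit))
  invisible(x)
}

#' Evaluate a harmonic term
#'
#' @param term A [harmonic_term()].
#' @param x Coordinate values (same units as `term$x0`).
#' @return Energies in kcal/mol, `1/2 k (x - x0)^2` plus the baseline;
#'   for angles the displacement is converted to radians first.
#' @export
evaluate_harmonic <- function(term, x) {
  dx <- x - term$x0
  if (term$kind == "angle") dx <- deg2rad(dx)
  0.5 * term$k * dx^2 + term$baseline
}

#' Fit a harmonic potential to a truncated scan
#'
#' Linear least squares of `V = c + 1/2 k (x - x0)^2` with the equilibrium
#' value `x0` held fixed (taken from the optimized geometry) and a free
#' baseline `c` absorbing the arbitrary energy zero of the scan. For angle
#' scans the displacement is converted degrees to radians before squaring,
#' so the force constant comes out per radian².
#'
#' @param scan A [pes_scan()], already truncated via [truncate_scan()].
#' @param x0 Equilibrium coordinate; defaults to `scan$x0`.
#' @return A [harmonic_term()] with the fitted `k` (clamped at 0 from
#'   below) and baseline.
#' @export
fit_harmonic <- function(scan, x0 = scan$x0) {
  stopifnot(inherits(scan, "pes_scan"))
  if (is.null(x0)) stop_format("x0 must be given (fixed from the optimized geometry)")
  if (scan$kind == "dihedral") {
    stop_format("dihedral scans are fitted with fit_torsion(), not a harmonic")
  }
  if (x0 < min(scan$x) || x0 > max(scan$x)) {
    stop_format("x0 lies outside the scanned range")
  }
  dx <- scan$x - x0
  if (scan$kind == "angle") dx <- deg2rad(dx)
  if (all(abs(dx) < .Machine$double.eps^0.5)) {
    stop_degenerate("all scan points coincide with x0; curvature is undetermined")
  }
  X <- cbind(1, 0.5 * dx^2)
  fit <- stats::lm.fit(X, scan$energy)
  beta <- fit$coefficients
  k <- unname(beta[2L])
  harmonic_term(x0 = x0, k = max(k, 0), kind = scan$kind,
                baseline = unname(beta[1L]))
}

#' Periodic torsion series
#'
#' A proper-dihedral Fourier series
#' `V(phi) = sum_n (Vmax_n / 2) (1 + cos(n phi + gamma_n))` with phases
#' restricted to 0 or 180 degrees and signed amplitudes, plus a constant
#' baseline absorbed during fitting (not exported to topologies).
#'
#' @param n Integer vector of multiplicities (distinct, positive).
#' @param vmax Signed amplitudes in kcal/mol, aligned with `n`.
#' @param gamma Phases in degrees, each 0 or 180 (default 180 for all).
#' @param baseline Constant offset in kcal/mol.
#' @return An object of class `torsion_series`.
#' @export
torsion_series <- function(n, vmax, gamma = rep(180, length(n)), baseline = 0) {
  n <- as.integer(n)
  if (length(n) != length(vmax) || length(n) != length(gamma)) {
    stop_format("n, vmax and gamma must have the same length")
  }
  if (anyDuplicated(n)) stop_format("multiplicities must be distinct")
  if (any(n < 1L)) stop_format("multiplicities must be positive integers")
  if (!all(gamma %in% c(0, 180))) stop_format("phases are restricted to 0 or 180 degrees")
  structure(list(n = n, vmax = as.numeric(vmax), gamma = as.numeric(gamma),
                 baseline = baseline),
            class = "torsion_series")
}

#' @export
print.torsion_series <- function(x, ...) {
  cat("<torsion_series>\n")
  if (length(x$n)) {
    for (i in seq_along(x$n)) {
      cat(sprintf("  n = %d  Vmax = %+.6g kcal/mol  gamma = %g deg\n",
                  x$n[i], x$vmax[i], x$gamma[i]))
    }
  } else cat("  (no terms)\n")
  cat(sprintf("  baseline = %g kcal/mol\n", x$baseline))
  invisible(x)
}

#' Evaluate a torsion series
#'
#' @param series A [torsion_series()].
#' @param phi Dihedral angle(s) in degrees.
#' @return `sum_n (Vmax_n/2)(1 + cos(n phi + gamma_n))` plus the baseline,
#'   in kcal/mol. Periodic: `phi` and `phi + 360` give identical energies.
#' @export
evaluate_torsion <- function(series, phi) {
  stopifnot(inherits(series, "torsion_series"))
  out <- rep(series$baseline, length(phi))
  for (i in seq_along(series$n)) {
    # cospi keeps the 360-degree periodicity exact in floating point
    out <- out + series$vmax[i] / 2 *
      (1 + cospi((series$n[i] * phi + series$gamma[i]) / 180))
  }
  out
}

#' Fit a periodic torsion series to a QM-minus-MM difference surface
#'
#' The residual torsional profile (QM scan minus the MM surface with the
#' torsion term zeroed) is fitted by linear least squares in the basis
#' `{1, cos(n phi)}`, which is equivalent to signed amplitudes with all
#' phases fixed at 180 degrees: a negative amplitude with gamma = 180 plays
#' the role of a positive amplitude with gamma = 0. Sine components are
#' also fitted and reported as a diagnostic (they should vanish for a
#' surface symmetric about phi = 0) but are never stored as terms.
#'
#' @param phi Dihedral angles in degrees.
#' @param dV Energy differences in kcal/mol, aligned with `phi`.
#' @param multiplicities Integer vector of multiplicities to include.
#' @return A [torsion_series()] with attribute `sine_diagnostic`: the
#'   least-squares sine amplitudes per multiplicity and the residual RMS.
#' @export
fit_torsion <- function(phi, dV, multiplicities = 1:3) {
  phi <- as.numeric(phi)
  dV <- as.numeric(dV)
  multiplicities <- sort(unique(as.integer(multiplicities)))
  if (length(phi) != length(dV)) stop_format("phi and dV differ in length")
  if (any(multiplicities < 1L)) stop_format("multiplicities must be positive")
  if (length(unique(phi)) < length(multiplicities) + 1L) {
    stop_degenerate("need at least |multiplicities| + 1 distinct angles")
  }
  rad <- deg2rad(phi)
  Xcos <- vapply(multiplicities, function(n) cos(n * rad), numeric(length(rad)))
  X <- cbind(1, Xcos)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop_degenerate("rank-deficient torsion design (angles do not resolve the multiplicities)")
  }
  beta <- qr.coef(qrX, dV)
  vmax <- -2 * unname(beta[-1L])          # model term: (Vmax/2)(1 - cos(n phi))
  baseline <- unname(beta[1L]) - sum(vmax) / 2

  # diagnostic: how much signal lives in the antisymmetric (sine) components
  Xsin <- vapply(multiplicities, function(n) sin(n * rad), numeric(length(rad)))
  Xfull <- cbind(X, Xsin)
  qrF <- qr(Xfull)
  sine_amp <- if (qrF$rank == ncol(Xfull)) {
    unname(qr.coef(qrF, dV)[(ncol(X) + 1L):ncol(Xfull)])
  } else rep(NA_real_, length(multiplicities))
  resid <- dV - drop(X %*% beta)

  out <- torsion_series(n = multiplicities, vmax = vmax,
                        gamma = rep(180, length(multiplicities)),
                        baseline = baseline)
  attr(out, "sine_diagnostic") <- list(amplitudes = sine_amp,
                                       residual_rms = sqrt(mean(resid^2)))
  out
}

#' Morse potential model (scan generator input)
#'
#' `V(x) = D (1 - exp(-a (x - x0)))^2`; used to generate realistically
#' anharmonic synthetic bond scans whose curvature at the minimum is
#' `2 D a^2`.
#'
#' @param D Well depth, kcal/mol.
#' @param a Width parameter, 1/Å.
#' @param x0 Equilibrium distance, Å.
#' @return An object of class `morse_model`.
#' @export
morse_model <- function(D, a, x0) {
  stopifnot(D > 0, a > 0)
  structure(list(D = D, a = a, x0 = x0), class = "morse_model")
}

#' Evaluate a Morse model
#' @param model A [morse_model()].
#' @param x Coordinate values (Å).
#' @return Energies in kcal/mol, zero at `x0`.
#' @export
evaluate_morse <- function(model, x) {
  model$D * (1 - exp(-model$a * (x - model$x0)))^2
}

#' Generate a synthetic potential-energy scan
#'
#' Deterministic fixture generator: evaluates a model (harmonic term,
#' Morse model, or torsion series) on a uniform grid and optionally adds
#' independent Gaussian noise per point. `noise_sd = 0` gives exact model
#' evaluations; a fixed `seed` gives identical output across calls.
#'
#' @param model A [harmonic_term()], [morse_model()], or
#'   [torsion_series()].
#' @param from,to Grid limits (Å or degrees, matching the model).
#' @param n_points Number of grid points (at least 3).
#' @param kind Coordinate kind for the returned scan; defaults to the
#'   natural kind of the model (`"bond"` for Morse, the term's own kind
#'   for harmonics, `"dihedral"` for torsion series).
#' @param noise_sd Gaussian noise standard deviation, kcal/mol.
#' @param seed Integer seed for the noise; required when `noise_sd > 0`
#'   for reproducibility, ignored otherwise.
#' @return A [pes_scan()]; its `x0` is set from the model where the model
#'   defines one.
#' @export
generate_scan <- function(model, from, to, n_points = 13, kind = NULL,
                          noise_sd = 0, seed = NULL) {
  if (n_points < 3) stop_format("n_points must be at least 3")
  x <- seq(from, to, length.out = n_points)
  if (inherits(model, "harmonic_term")) {
    V <- evaluate_harmonic(model, x)
    if (is.null(kind)) kind <- model$kind
    x0 <- model$x0
  } else if (inherits(model, "morse_model")) {
    V <- evaluate_morse(model, x)
    if (is.null(kind)) kind <- "bond"
    x0 <- model$x0
  } else if (inherits(model, "torsion_series")) {
    V <- evaluate_torsion(model, x)
    if (is.null(kind)) kind <- "dihedral"
    x0 <- NULL
  } else {
    stop_format("model must be a harmonic_term, morse_model or torsion_series")
  }
  if (noise_sd > 0) {
    V <- V + with_seed(seed, stats::rnorm(length(V), sd = noise_sd))
  }
  pes_scan(x, V, kind = kind, x0 = x0)
}

#' Read a two-column scan file
#'
#' Accepts either whitespace-separated two-column text with `#` comments,
#' or CSV with an `x,energy` header. Units default to Å (or degrees) and
#' kcal/mol and are the caller's responsibility to declare via `kind`.
#'
#' @param path File path.
#' @param kind Coordinate kind, as in [pes_scan()].
#' @param x0 Optional equilibrium value to attach.
#' @return A [pes_scan()].
#' @export
read_scan <- function(path, kind = c("bond", "angle", "dihedral"), x0 = NULL) {
  kind <- match.arg(kind)
  head_lines <- readLines(path, n = 50L)
  data_lines <- head_lines[!grepl("^\\s*(#|$)", head_lines)]
  if (!length(data_lines)) stop_format("scan file has no data lines")
  first <- data_lines[1L]
  if (grepl(",", first, fixed = TRUE)) {
    df <- utils::read.csv(path, comment.char = "#")
    if (!all(c("x", "energy") %in% names(df))) {
      stop_format("CSV scan files need an 'x,energy' header")
    }
    pes_scan(df$x, df$energy, kind = kind, x0 = x0)
  } else {
    df <- utils::read.table(path, comment.char = "#",
                            col.names = c("x", "energy"))
    pes_scan(df$x, df$energy, kind = kind, x0 = x0)
  }
}

#' Write a two-column scan file
#'
#' @param scan A [pes_scan()].
#' @param path Output path.
#' @param comment Optional comment line(s) written with a leading `#`.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, comment = NULL) {
  lines <- character(0)
  if (!is.null(comment)) lines <- paste0("# ", comment)
  lines <- c(lines,
             sprintf("# %s scan (x, energy kcal/mol)", scan$kind),
             sprintf("%.10g %.10g", scan$x, scan$energy))
  writeLines(lines, path)
  invisible(path)
}
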