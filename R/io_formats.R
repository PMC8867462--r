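#' Read an XYZ coordinate file
#'
#' Standard XYZ layout: atom-count line, comment line, then
#' `element x y z` rows in Å. Plain and exponent-notation numbers are
#' accepted.
#'
#' @param path File path.
#' @return A list with `positions` (n x 3 matrix, Å) and `labels`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop_format("XYZ file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop_format("malformed XYZ count line")
  rows <- lines[-(1:2)]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) < n) {
    stop_format(sprintf("XYZ declares %d atoms but has %d coordinate rows", n, length(rows)))
  }
  rows <- rows[seq_len(n)]
  parts <- strsplit(trimws(rows), "\\s+")
  bad <- vapply(parts, function(p) length(p) < 4L, logical(1))
  if (any(bad)) stop_format("malformed XYZ coordinate row")
  labels <- vapply(parts, `[[`, character(1), 1L)
  xyz <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[2:4]))
    if (any(is.na(v))) stop_format("non-numeric coordinate in XYZ row")
    v
  }, numeric(3)))
  list(positions = xyz, labels = labels)
}

#' Write an XYZ coordinate file
#'
#' @param positions n x 3 matrix, Å.
#' @param labels Element/atom labels, length n.
#' @param path Output path.
#' @param comment Comment line (default states the writer).
#' @return `path`, invisibly. Coordinates are written with 6 decimals,
#'   so a write/read round trip preserves them to 1e-6 Å.
#' @export
write_xyz <- function(positions, labels, path, comment = "written by chalcogenmm") {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(labels))
  lines <- c(sprintf("%d", nrow(positions)), comment,
             sprintf("%-4s %14.6f %14.6f %14.6f", labels,
                     positions[, 1], positions[, 2], positions[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read coordinates from a PDB file
#'
#' Coordinate-only reader for ATOM/HETATM records using the fixed-width
#' columns of the PDB standard (x/y/z in columns 31-54, 1-based). For
#' atoms with alternate locations only the first encountered locator is
#' kept. Parsing stops at the first `END` record; `TER` records are
#' skipped.
#'
#' @param path File path.
#' @return A list with `positions` (n x 3, Å) and `labels` (atom names).
#' @export
read_pdb_coords <- function(path) {
  lines <- readLines(path)
  keep_alt <- NULL
  labels <- character(0)
  pos <- matrix(numeric(0), ncol = 3)
  seen <- character(0)
  for (ln in lines) {
    rec <- substr(ln, 1, 6)
    if (trimws(rec) == "END") break
    if (trimws(rec) == "TER") next
    if (!(rec %in% c("ATOM  ", "HETATM"))) next
    name <- trimws(substr(ln, 13, 16))
    alt <- substr(ln, 17, 17)
    if (alt != " ") {
      key <- paste(name, substr(ln, 18, 27))
      if (key %in% seen) next
      seen <- c(seen, key)
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) stop_format("malformed fixed-width coordinate field in PDB record")
    labels <- c(labels, name)
    pos <- rbind(pos, xyz)
  }
  if (!length(labels)) stop_format("no ATOM/HETATM records found")
  rownames(pos) <- NULL
  list(positions = pos, labels = labels)
}

#' Write a plain-text parameter card
#'
#' Key-value serialization of fitted parameters: bonded terms, atom
#' types, charges and virtual sites, in the package's interface units
#' (Å, kcal/mol, e, degrees; angle force constants per radian²).
#' Section layout:
#' \preformatted{
#' [bonds]      name x0 k
#' [angles]     name x0 k
#' [torsions]   name n vmax gamma     (one line per term)
#' [atomtypes]  type sigma epsilon
#' [charges]    label q
#' [virtual_sites] label parent reference distance
#' }
#' Output is bit-stable: fixed number formats, no timestamps.
#'
#' @param card A list with any of the elements `bonds`, `angles`
#'   (data frames with `name`, `x0`, `k`), `torsions` (named list of
#'   [torsion_series()]), `atomtypes` (data frame `type`, `sigma`,
#'   `epsilon`), `charges` (named numeric), `vsites` (data frame
#'   `label`, `parent`, `reference`, `distance`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameter_card <- function(card, path) {
  fmt <- function(x) sprintf("%.10g", x)
  lines <- c("# chalcogenmm parameter card",
             "# units: length=angstrom energy=kcal/mol charge=e angle=degree (angle k per radian^2)")
  if (!is.null(card$bonds) && nrow(card$bonds)) {
    lines <- c(lines, "[bonds]",
               sprintf("%s %s %s", card$bonds$name, fmt(card$bonds$x0), fmt(card$bonds$k)))
  }
  if (!is.null(card$angles) && nrow(card$angles)) {
    lines <- c(lines, "[angles]",
               sprintf("%s %s %s", card$angles$name, fmt(card$angles$x0), fmt(card$angles$k)))
  }
  if (!is.null(card$torsions) && length(card$torsions)) {
    lines <- c(lines, "[torsions]")
    for (nm in names(card$torsions)) {
      s <- card$torsions[[nm]]
      lines <- c(lines, sprintf("%s %d %s %s", nm, s$n, fmt(s$vmax), fmt(s$gamma)))
    }
  }
  if (!is.null(card$atomtypes) && nrow(card$atomtypes)) {
    lines <- c(lines, "[atomtypes]",
               sprintf("%s %s %s", card$atomtypes$type, fmt(card$atomtypes$sigma),
                       fmt(card$atomtypes$epsilon)))
  }
  if (!is.null(card$charges) && length(card$charges)) {
    lines <- c(lines, "[charges]",
               sprintf("%s %s", names(card$charges), fmt(unname(card$charges))))
  }
  if (!is.null(card$vsites) && nrow(card$vsites)) {
    lines <- c(lines, "[virtual_sites]",
               sprintf("%s %s %s %s", card$vsites$label, card$vsites$parent,
                       card$vsites$reference, fmt(card$vsites$distance)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter card
#'
#' Inverse of [write_parameter_card()] on its own format.
#'
#' @param path File path.
#' @return A card list (see [write_parameter_card()]).
#' @export
read_parameter_card <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  card <- list()
  section <- NULL
  tors <- list()
  for (ln in lines) {
    if (grepl("^\\[", ln)) { section <- gsub("[][]", "", trimws(ln)); next }
    p <- strsplit(trimws(ln), "\\s+")[[1]]
    if (is.null(section)) stop_format("parameter-card line outside any section")
    if (section == "bonds") {
      card$bonds <- rbind(card$bonds,
                          data.frame(name = p[1], x0 = as.numeric(p[2]),
                                     k = as.numeric(p[3])))
    } else if (section == "angles") {
      card$angles <- rbind(card$angles,
                           data.frame(name = p[1], x0 = as.numeric(p[2]),
                                      k = as.numeric(p[3])))
    } else if (section == "torsions") {
      tors[[p[1]]] <- rbind(tors[[p[1]]],
                            data.frame(n = as.integer(p[2]), vmax = as.numeric(p[3]),
                                       gamma = as.numeric(p[4])))
    } else if (section == "atomtypes") {
      card$atomtypes <- rbind(card$atomtypes,
                              data.frame(type = p[1], sigma = as.numeric(p[2]),
                                         epsilon = as.numeric(p[3])))
    } else if (section == "charges") {
      q <- as.numeric(p[2]); names(q) <- p[1]
      card$charges <- c(card$charges, q)
    } else if (section == "virtual_sites") {
      card$vsites <- rbind(card$vsites,
                           data.frame(label = p[1], parent = p[2],
                                      reference = p[3],
                                      distance = as.numeric(p[4])))
    } else {
      stop_format(sprintf("unknown parameter-card section [%s]", section))
    }
  }
  if (length(tors)) {
    card$torsions <- lapply(tors, function(df) {
      torsion_series(df$n, df$vmax, df$gamma)
    })
  }
  card
}

# GROMACS unit conversions: interface units (A, kcal/mol, e) to
# GROMACS units (nm, kJ/mol).
gmx_units <- list(
  length = 0.1,                               # A    -> nm
  energy = 4.184,                             # kcal -> kJ
  bond_k = 4.184 * 100,                       # kcal/A^2   -> kJ/nm^2
  angle_k = 4.184                             # per radian^2, energy only
)

#' Write a GROMACS-dialect .itp topology
#'
#' Emits `[atomtypes]`, `[moleculetype]`, `[atoms]`, `[bonds]` (funct 1),
#' `[pairs]` (funct 1), `[angles]` (funct 1), `[dihedrals]` (funct 9,
#' one line per periodic term), `[virtual_sites2]` (fixed-distance
#' funct 2) and `[exclusions]`. Unit conversions: Å to nm (×0.1),
#' kcal to kJ (×4.184), bond k ×418.4 (per nm²), angle k ×4.184
#' (per radian²); dihedral force constants are `|Vmax_n|/2 × 4.184` with
#' phase `gamma_n`, and a negative amplitude is re-expressed as a
#' positive one with the phase shifted by 180° (GROMACS requires
#' non-negative k; the rewrite changes the energy only by a constant).
#' Both the harmonic terms here and the GROMACS bond/angle functional
#' forms carry the 1/2 prefactor, so the conversion is units-only.
#'
#' Dialect note, written into the file header as well: the
#' fixed-distance virtual site is emitted with atoms (parent, reference)
#' and a *negative* distance in nm, which places the site beyond the
#' parent on the side away from the reference — the sigma-hole
#' construction of [vsite_position()].
#'
#' Output is bit-stable: fixed formats, no timestamps.
#'
#' @param topology An [mm_topology()].
#' @param path Output path.
#' @param name Molecule name for `[moleculetype]`.
#' @return `path`, invisibly.
#' @export
write_gromacs_itp <- function(topology, path, name = "MOL") {
  at <- topology$atoms
  if (any(is.na(at$sigma)) || any(is.na(at$epsilon))) {
    stop_format("every atom needs Lennard-Jones parameters (use 0 for charge-only sites)")
  }
  f <- function(x, d = 6) formatC(x, digits = d, format = "f")
  lines <- c("; chalcogenmm GROMACS topology",
             "; virtual_sites2 funct 2 uses a signed distance: negative places the",
             "; site beyond atom i (the parent), away from atom j (the reference).",
             "", "[ atomtypes ]",
             "; name  at.num  mass  charge  ptype  sigma(nm)  epsilon(kJ/mol)")
  types <- !duplicated(at$type)
  lines <- c(lines, sprintf("%-6s 0 %10s %10s  A %12s %12s",
                            at$type[types], f(at$mass[types], 4), f(0, 4),
                            f(at$sigma[types] * gmx_units$length),
                            f(at$epsilon[types] * gmx_units$energy)))
  lines <- c(lines, "", "[ moleculetype ]", "; name  nrexcl",
             sprintf("%s  3", name), "", "[ atoms ]",
             ";  nr  type  resnr  residue  atom  cgnr  charge  mass")
  lines <- c(lines, sprintf("%5d %-6s 1 %-6s %-6s %5d %12s %10s",
                            seq_len(nrow(at)), at$type, name, at$name,
                            seq_len(nrow(at)), f(at$charge), f(at$mass, 4)))
  if (length(topology$bonds)) {
    lines <- c(lines, "", "[ bonds ]", ";  ai  aj  funct  b0(nm)  k(kJ/mol/nm^2)")
    for (b in topology$bonds) {
      lines <- c(lines, sprintf("%5d %5d  1 %12s %14s", b$i, b$j,
                                f(b$term$x0 * gmx_units$length),
                                f(b$term$k * gmx_units$bond_k, 4)))
    }
  }
  if (nrow(topology$pairs14)) {
    lines <- c(lines, "", "[ pairs ]", ";  ai  aj  funct")
    for (r in seq_len(nrow(topology$pairs14))) {
      lines <- c(lines, sprintf("%5d %5d  1", topology$pairs14[r, 1],
                                topology$pairs14[r, 2]))
    }
  }
  if (length(topology$angles)) {
    lines <- c(lines, "", "[ angles ]", ";  ai  aj  ak  funct  th0(deg)  k(kJ/mol/rad^2)")
    for (a in topology$angles) {
      lines <- c(lines, sprintf("%5d %5d %5d  1 %12s %14s", a$i, a$j, a$k,
                                f(a$term$x0, 4),
                                f(a$term$k * gmx_units$angle_k, 4)))
    }
  }
  if (length(topology$torsions)) {
    lines <- c(lines, "", "[ dihedrals ]",
               ";  ai  aj  ak  al  funct  phase(deg)  k(kJ/mol)  mult")
    for (t in topology$torsions) {
      s <- t$series
      for (m in seq_along(s$n)) {
        k_kj <- s$vmax[m] / 2 * gmx_units$energy
        phase <- s$gamma[m]
        if (k_kj < 0) {             # re-express with non-negative k
          k_kj <- -k_kj
          phase <- (phase + 180) %% 360
        }
        lines <- c(lines, sprintf("%5d %5d %5d %5d  9 %10s %14s %3d",
                                  t$i, t$j, t$k, t$l, f(phase, 2),
                                  f(k_kj, 8), s$n[m]))
      }
    }
  }
  if (length(topology$vsites)) {
    lines <- c(lines, "", "[ virtual_sites2 ]", ";  site  ai  aj  funct  d(nm)")
    for (vs in topology$vsites) {
      lines <- c(lines, sprintf("%5d %5d %5d  2 %12s", vs$site, vs$parent,
                                vs$reference,
                                f(-vs$distance * gmx_units$length)))
    }
  }
  has_excl <- vapply(topology$exclusions, length, integer(1)) > 0
  if (any(has_excl)) {
    lines <- c(lines, "", "[ exclusions ]")
    for (i in which(has_excl)) {
      lines <- c(lines, paste(c(i, topology$exclusions[[i]]), collapse = " "))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GROMACS .itp written by this package
#'
#' Round-trip reader for the subset [write_gromacs_itp()] emits.
#' Dihedral lines written with phase 0 are restored as negative
#' amplitudes with phase 180 (the canonical signed-amplitude form);
#' unsupported function types raise an explicit error.
#'
#' @param path File path.
#' @return An [mm_topology()] rebuilt from the file (units converted
#'   back to Å and kcal/mol).
#' @export
read_gromacs_itp <- function(path) {
  lines <- readLines(path)
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_format("empty topology file")
  section <- NULL
  types <- list(); atoms <- NULL; bonds <- list(); angles <- list()
  dihed <- list(); vsites <- list()
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("[][ ]", "", ln)
      next
    }
    p <- strsplit(ln, "\\s+")[[1]]
    if (is.null(section)) stop_format("content before any [ section ]")
    if (section == "atomtypes") {
      types[[p[1]]] <- list(sigma = as.numeric(p[6]) / gmx_units$length,
                            epsilon = as.numeric(p[7]) / gmx_units$energy)
    } else if (section == "atoms") {
      ty <- types[[p[2]]]
      if (is.null(ty)) stop_format(sprintf("atom references undeclared type '%s'", p[2]))
      atoms <- rbind(atoms, atom_spec(p[5], p[2], as.numeric(p[7]),
                                      ty$sigma, ty$epsilon, as.numeric(p[8])))
    } else if (section == "bonds") {
      if (p[3] != "1") stop_format("unsupported bond function type")
      bonds[[length(bonds) + 1L]] <- list(
        i = as.integer(p[1]), j = as.integer(p[2]),
        term = harmonic_term(as.numeric(p[4]) / gmx_units$length,
                             as.numeric(p[5]) / gmx_units$bond_k, "bond"))
    } else if (section == "angles") {
      if (p[4] != "1") stop_format("unsupported angle function type")
      angles[[length(angles) + 1L]] <- list(
        i = as.integer(p[1]), j = as.integer(p[2]), k = as.integer(p[3]),
        term = harmonic_term(as.numeric(p[5]),
                             as.numeric(p[6]) / gmx_units$angle_k, "angle"))
    } else if (section == "dihedrals") {
      if (p[5] != "9") stop_format("unsupported dihedral function type")
      key <- paste(p[1:4], collapse = " ")
      phase <- as.numeric(p[6])
      vmax <- 2 * as.numeric(p[7]) / gmx_units$energy
      if (phase == 0) { vmax <- -vmax; phase <- 180 }
      dihed[[key]] <- rbind(dihed[[key]],
                            data.frame(n = as.integer(p[8]), vmax = vmax,
                                       gamma = phase))
    } else if (section == "virtual_sites2") {
      if (p[4] != "2") stop_format("unsupported virtual-site function type")
      d_nm <- as.numeric(p[5])
      vsites[[length(vsites) + 1L]] <- virtual_site_fd(
        as.integer(p[1]), as.integer(p[2]), as.integer(p[3]),
        abs(d_nm) / gmx_units$length)
    } else if (section %in% c("moleculetype", "exclusions", "pairs")) {
      if (section == "pairs" && length(p) >= 3 && p[3] != "1") {
        stop_format("unsupported pair function type")
      }
      next
    } else {
      stop_format(sprintf("unsupported section [%s]", section))
    }
  }
  if (is.null(atoms)) stop_format("topology file contains no atoms")
  torsions <- lapply(names(dihed), function(key) {
    idx <- as.integer(strsplit(key, " ")[[1]])
    df <- dihed[[key]]
    list(i = idx[1], j = idx[2], k = idx[3], l = idx[4],
         series = torsion_series(df$n, df$vmax, df$gamma))
  })
  mm_topology(atoms, bonds = bonds, angles = angles, torsions = torsions,
              vsites = vsites)
}
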