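# chalcogenmm

Sigma-hole pseudoatom force fields for chalcogen bonding, in R.

Electron-poor chalcogens such as the selenium in ebselen form *chalcogen
bonds*: directional noncovalent contacts between a region of positive
electrostatic potential opposite a polarizing bond (the **sigma-hole**,
here opposite Se–N) and a Lewis base. Ordinary atom-centred point-charge
force fields are blind to this anisotropy. The established remedy is a
**massless, positively charged pseudoatom** (virtual site) placed on the
chalcogen's van der Waals surface along the bond extension, so the
electrostatics become directional while the dynamics stay classical.

`chalcogenmm` implements the complete parameterization workflow around
that idea, for force-field developers and modellers working on
selenium/sulfur pharmacophores:

* **PES fitting** — truncate relaxed quantum scans to a 5 kcal/mol window
  and fit `V(x) = ½ k (x − x₀)²` with x₀ fixed (`truncate_scan()`,
  `fit_harmonic()`), and fit torsional residuals with
  `V(φ) = Σₙ (V_max,n/2)(1 + cos(nφ + γₙ))`, γₙ = 180°, signed
  amplitudes (`fit_torsion()`).
* **RESP charges** — restrained electrostatic-potential fitting with
  total-charge and equivalence constraints, and manual insertion of the
  pseudoatom as an extra fit site (`resp_fit()`, `add_pseudoatom_site()`,
  `read_cube()`, `sample_shells()`).
* **Virtual-site geometry** — the fixed-distance (2fd-style) site
  `r_site = r_Se + d·(r_Se − r_N)/|r_Se − r_N|`, its default placement
  `d = σ·2^{1/6}/2` (half the Lennard-Jones minimum distance), and the
  force projection onto the defining atoms (`vsite_position()`,
  `default_distance()`, `project_vsite_gradient()`).
* **MM engine** — energies, analytic gradients, BFGS minimization,
  dimer interaction energies (complex minus minimized monomers),
  chalcogen-bond geometry (r(Se⋯B), ∠N–Se⋯B) and angular probe scans for
  small gas-phase systems (`total_energy()`, `mm_minimize()`,
  `angular_probe_scan()`).
* **I/O** — XYZ/PDB coordinates, Gaussian cube grids, plain-text
  parameter cards, and a GROMACS-dialect `.itp` writer/reader with the
  massless site as a signed-distance `virtual_sites2` record
  (`write_gromacs_itp()`).

A deterministic fixture (an ebselen-like selenium core with published
bond, angle, torsion, Lennard-Jones and charge parameters) ships with the
package, so the entire workflow runs and is tested without any
quantum-chemistry input.

## Worked example

Fit a bond force constant from a synthetic scan, place the pseudoatom,
and recover charges from a shell-sampled ESP grid:

```r
library(chalcogenmm)

# 13-point scan on ±0.3 Å, truncated at 5 kcal/mol, then fitted
scan <- generate_scan(harmonic_term(1.8586, 434.67, "bond"), 1.5586, 2.1586, 13)
fit_harmonic(truncate_scan(scan, 5))
#> <harmonic_term> bond: x0 = 1.8586, k = 434.67 kcal/mol/A^2

# default pseudoatom placement from the selenium LJ sigma
default_distance(2.12)
#> [1] 1.18981

# RESP on the six-site toy system (5 published charges + neutralizing dummy)
sys <- toy_resp_system()
pts <- sample_shells(sys$positions, sys$radii, density = 1, seed = 7)
V   <- esp_from_point_charges(sys$positions, sys$charges, pts)
resp_fit(esp_grid(sys$positions, pts, V, labels = sys$labels),
         resp_config(restraint_a = 0, total_charge = 0))
#> <charge_model>
#>   Se1      -0.372631 e
#>   N2       -0.241674 e
#>   C3       +0.463064 e
#>   O4       -0.558076 e
#>   DUM      +0.427935 e
#>   E26      +0.281382 e
#>   total = -0.000000 e
```

The fitted bond constant (434.67 kcal/mol·Å²) and the selenium and
pseudoatom charges (−0.372631 e, +0.281382 e) are exact recoveries of the
generating parameters, and 1.18981 Å is the half-rmin placement that the
published 1.189 Å rule rounds to.

Directionality — sweep a −0.5 e probe around the selenium at 3 Å:

```r
fx <- build_core_fixture(with_pseudoatom = TRUE)
angular_probe_scan(fx$topology, fx$positions, build_probe(), 3.0,
                   seq(60, 180, by = 20), chalcogen = 1, reference = 2)
#>   theta  energy
#> 1    60 983.550
#> ...
#> 6   160  10.262
#> 7   180   8.779
```

The scan minimum sits at θ = 180°, on the sigma-hole axis; rebuilding the
fixture with `with_pseudoatom = FALSE` flattens the angular profile —
the directional signature the pseudoatom exists to create.

A thin command-line wrapper over the same functions is installed at
`inst/cli/chalcogenmm.R` (`fit-bond`, `fit-dihedral`, `fit-charges`,
`add-sigma-hole`, `export-gromacs`, `energy`, `minimize`, `probe-scan`).

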