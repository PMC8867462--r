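---
title: "Modelling chalcogen-bond sigma-holes with a massless pseudoatom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chalcogen-bond sigma-holes with a massless pseudoatom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chalcogenmm)
```

## The problem

Electron-poor chalcogens (Se, S, Te) in molecules such as ebselen carry a
*sigma-hole*: a patch of positive electrostatic potential on the far side of a
polarizing covalent bond (here, opposite the Se–N bond). The sigma-hole makes
the chalcogen a directional electrophile that binds Lewis bases — a chalcogen
bond, the congener of the hydrogen and halogen bond. Atom-centred point-charge
force fields cannot represent this anisotropy: a single charge on the selenium
is spherically symmetric, so the directionality of the interaction is lost.

`chalcogenmm` implements the pseudoatom remedy: a **massless, charge-only
virtual site** placed on the van der Waals surface of the chalcogen, on the
extension of the polarizing bond. The package covers the full parameterization
workflow around that idea:

1. fitting harmonic bond/angle constants and periodic torsion amplitudes to
   relaxed potential-energy-scan data (`fit_harmonic()`, `fit_torsion()`);
2. restrained electrostatic-potential (RESP) charge fitting with the
   pseudoatom inserted as an extra fit site (`add_pseudoatom_site()`,
   `resp_fit()`);
3. the fixed-distance virtual-site geometry and its force projection
   (`vsite_position()`, `project_vsite_gradient()`);
4. a small gas-phase molecular-mechanics engine to evaluate and minimize
   energies, measure chalcogen-bond geometry and run directional probe scans;
5. GROMACS-dialect topology export, since GROMACS natively supports massless
   interaction sites.

## Bonded-parameter fitting

A relaxed scan steps one internal coordinate (±0.3 Å for bonds, ±10° for
angles in the bundled defaults) while relaxing the rest of the molecule. Far
from equilibrium the surface is appreciably anharmonic, so the scan is first
**truncated to within 5 kcal/mol of its minimum** (`truncate_scan()`, the
cutoff is a parameter) and only then fitted with

$$V(x) = \tfrac{1}{2}\,k\,(x - x_0)^2 .$$

Two choices matter:

* $x_0$ is *fixed* to the optimized-geometry value, never refit — the scan
  decides only the curvature;
* a free baseline constant absorbs the arbitrary energy zero of the scan.
  With energies referenced to the minimum the baseline converges to ≈ 0, but
  keeping it free makes the fit robust to any reference convention.

The fit is linear least squares in $(x-x_0)^2$. Angle displacements are
converted to radians before squaring, so angle force constants are in
kcal/mol·radian² while equilibrium angles stay in degrees — the unit
convention of the bundled parameter table.

Torsional residuals (QM scan minus the MM surface with the torsion zeroed)
are fitted with the periodic series

$$V(\phi) = \sum_n \frac{V_{\max,n}}{2}\bigl(1 + \cos(n\phi + \gamma_n)\bigr),$$

with $\gamma_n$ fixed at 180° and **signed** amplitudes. This keeps the fit
linear (basis $\{1, \cos n\phi\}$) and matches the sign convention of the
bundled torsion table, where a negative amplitude appears with $\gamma=180°$.
Sine components are fitted alongside as a diagnostic — a symmetric surface
should not need them — but are never stored as terms. Dihedral grids live on
the half-open interval $[-180°, 180°)$; all trigonometry is done in radians
internally.

```{r}
bond_scan <- generate_scan(harmonic_term(1.8586, 434.67, "bond"),
                           1.8586 - 0.3, 1.8586 + 0.3, n_points = 13)
fit_harmonic(truncate_scan(bond_scan, cutoff = 5))
```

The synthetic generator (`generate_scan()`) doubles as the test-data module:
it evaluates a harmonic, Morse, or torsion-series model on a uniform grid and
adds independent Gaussian noise per point, with the seed always an explicit
argument. A Morse scan ($V = D(1-e^{-a(x-x_0)})^2$) is the anharmonicity
stand-in: fitted after truncation, its harmonic constant approaches the true
curvature $2Da^2$ from below, which is exactly the behaviour the truncation
protocol is designed to bound.

## RESP charges with a pseudoatom

RESP fits atom-centred charges to an electrostatic-potential grid by
minimizing

$$\sum_p \Bigl(V_p - \sum_j \frac{q_j}{r_{jp}}\Bigr)^2
  + \sum_j a\bigl(\sqrt{q_j^2 + b^2} - b\bigr)$$

subject to a fixed total charge and optional equivalence classes. The
hyperbolic restraint (defaults $a = 0.0005$ a.u., $b = 0.1$ e, the standard
stage-1 values) pulls statistically ill-determined charges toward zero. The
package uses a **single-stage** fit with explicit equivalences: the published
workflow names RESP without stage detail, and a single stage with explicit
constraints is simpler to verify while serving the same purpose. The solver
is an iteratively reweighted KKT system with a Lagrange multiplier for the
total charge; with $a = 0$ it reduces to exact constrained linear least
squares in one solve.

The pseudoatom enters the fit exactly as it enters the published workflow:
`add_pseudoatom_site()` appends a site on the bond extension, and RESP is
rerun with the site as one more charge parameter. ESP grids come from
Gaussian cube files (`read_cube()`, bohr → Å via 0.52917721092) or from the
synthetic generator: `esp_from_point_charges()` is the forward Coulomb model
in atomic units, and `sample_shells()` draws Connolly-style points on scaled
vdW shells (defaults 1.4–2.0 × Bondi radii, seeded). The bundled six-site toy
system (`toy_resp_system()`) carries the five published core charges plus a
neutralizing dummy, so the printed values are an exactly recoverable
total-charge-zero target:

```{r}
sys <- toy_resp_system()
pts <- sample_shells(sys$positions, sys$radii, density = 1, seed = 7)
V <- esp_from_point_charges(sys$positions, sys$charges, pts)
resp_fit(esp_grid(sys$positions, pts, V, labels = sys$labels),
         resp_config(restraint_a = 0, total_charge = 0))
```

## The virtual site

The site is the two-atom fixed-distance construction: with parent (Se) and
reference (N) atoms,

$$\mathbf{r}_{\text{site}} = \mathbf{r}_{\text{Se}} +
  d\,\frac{\mathbf{r}_{\text{Se}} - \mathbf{r}_{\text{N}}}
          {\lvert \mathbf{r}_{\text{Se}} - \mathbf{r}_{\text{N}}\rvert}.$$

The default distance is **half the Lennard-Jones minimum distance** of the
chalcogen, $d = \sigma\,2^{1/6}/2$ (`default_distance()`), which puts the
charge on the vdW surface — keeping it on or inside that surface matters for
numerical stability. For the bundled selenium $\sigma = 2.12$ Å this gives
1.1898 Å, matching the published 1.189 Å placement to the printed precision.
The quoted $\sigma$ values are of AMBER rmin/2 magnitude, so the convention
is ambiguous; the function takes an explicit `convention` flag and defaults
to the true-$\sigma$ reading, which is the one that reproduces 1.189.

Only the single on-axis site is implemented. The true sigma-hole centre is
slightly off-axis (aromatic-ring potential spilling onto the selenium), and
three-atom constructions could represent that, but at a simulation cost; the
secondary, much weaker hole opposite the Se–C bond shows no evidence of
bonding and is likewise not modelled. The site carries **no Lennard-Jones
parameters and no mass**; it inherits its parent's nonbonded exclusions and
1-4 pairs (plus an exclusion with the parent), so the sigma-hole charge never
interacts with its own near neighbourhood.

Because the site is massless, forces on it must be chain-ruled onto the
defining atoms. `project_vsite_gradient()` applies the Jacobian of the
position rule: the axial component of the site gradient lands entirely on the
parent; the perpendicular component is amplified on the parent by $(1 + d/L)$
and countered on the reference by $-d/L$. The projection conserves total
force and torque exactly, which the tests verify along with agreement against
finite differences.

## The MM engine

`total_energy()` evaluates harmonic bonds and angles, the periodic torsion
series, Lennard-Jones with Lorentz–Berthelot mixing, and Coulomb with
$k_e = 332.0636$ kcal·Å/(mol·e²). Design choices:

* **no cutoffs, no periodic boundaries, no switching** — the engine targets
  small gas-phase complexes only (condensed-phase validation is out of
  scope);
* 1-4 scaling defaults to the AMBER/GAFF convention (LJ × 0.5,
  Coulomb × 1/1.2), both configurable, since the parameter set extends GAFF;
* angles are degrees at every interface and radians internally; overlapping
  non-excluded atoms (r < 1e-6 Å) raise a singularity error rather than
  returning infinities.

`mm_gradient()` is fully analytic (including the dihedral derivative and the
virtual-site projection) and is validated against central finite differences
at step 1e-5 Å to 1e-6 kcal/mol/Å on randomized fixtures. `mm_minimize()` is
a quasi-Newton (BFGS) loop with convergence judged on the gradient max-norm
(default 1e-4 kcal/mol/Å); it raises rather than silently returning an
unconverged structure. `dimer_interaction_energy()` implements the
complex-minus-minimized-monomers convention, with no intermolecular
exclusions.

Directionality is probed at desk scale: `angular_probe_scan()` sweeps a
single charged Lennard-Jones particle (default −0.5 e, the electron-donor
caricature from `build_probe()`) around the chalcogen at fixed distance and
reports single-point energies as a function of the N–Se⋯probe angle. With
the pseudoatom the profile develops its minimum on the sigma-hole axis
(θ ∈ [175°, 180°] on the bundled fixture); switching to the no-pseudoatom
charge set flattens the angular contrast — the package's testable surrogate
for the full complex-geometry validation, which would require unpublished
Lewis-base topologies and lone-pair parameters.

## What the synthetic fixtures do and do not show

The bundled core fixture is a four-atom Se/N/C(=O)/O fragment plus the site,
with the published force constants and charges at a fixed geometry. Its Se–N
distance and Se–N–C angle are the published equilibria; the C=O internals and
the out-of-plane dummy position are chemically plausible package constants —
the reference DFT geometry is not published, and none of the fixture's claims
depend on matching it. Tests built on these fixtures demonstrate that the
*machinery* is correct: exact recovery of generating parameters, conservation
laws, unit conversions, and the qualitative sigma-hole physics. They do not
demonstrate force-field accuracy for real complexes: published complex
energies (e.g. −7.5 kcal/mol for the pyridine adduct) depend on the full
molecule and base topologies, which are outside this package's data.

Numerical conventions collected in one place: truncation happens before,
never after, fitting; rank-deficient designs raise classed degenerate-scan
errors instead of returning pseudo-inverses; RESP convergence is a 1e-10
max-charge-change with iteration cap; the toy RESP problem uses ≥ 1000 shell
points for a 6-parameter fit; random draws always flow through an explicit
seed (`with_seed()`), never global state. Test problem sizes (13-point scans,
36-point torsion surfaces, ~1200-point ESP grids, 4–6-atom systems) were
chosen so each property is sharply testable while the whole suite runs in
seconds.

## GROMACS export

`write_gromacs_itp()` serializes a topology in a GROMACS-compatible dialect:
Å → nm (× 0.1), kcal → kJ (× 4.184), bond constants × 418.4 (per nm²), angle
constants × 4.184 (per radian²). Both this package's harmonic forms and the
GROMACS bond/angle functions carry the ½ prefactor, so the conversion is
units-only (asserted in a test — no AMBER-style doubling). Each torsion term
becomes one funct-9 dihedral line with $k = |V_{\max,n}|/2 × 4.184$; negative
amplitudes are re-expressed as positive with the phase shifted by 180°, which
changes the energy only by a constant. The virtual site is a
`[ virtual_sites2 ]` funct-2 record whose distance is written *negative*:
GROMACS's fixed-distance site lies toward the second atom for positive
distances, and the sigma-hole sits the other way. The sign convention is
documented in the file header because GROMACS versions differ here.
`read_gromacs_itp()` inverts the writer on its own subset (round-trip
identity to 6 significant digits is a test), and errors explicitly on any
function type it does not support. The published work provides no reference
.itp, so the dialect is validated by round trip, not against an external
file.

## Limitations

* Single on-axis site; no off-axis (3fd/3fad) or massive-tethered variants,
  no polarizability.
* Single-conformer, single-stage RESP; no multi-molecule fits.
* No dynamics, solvent, or long-range electrostatics; the engine is a
  verification tool, not a simulation engine.
* The bundled parameters describe the selenium core of one molecule class;
  transfer to derivatives requires refitting charges.
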