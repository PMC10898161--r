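---
title: "Preventing probe aggregation in cosolvent MD: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preventing probe aggregation in cosolvent MD: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosolvr)
```

## The problem

Cosolvent molecular dynamics replaces part of the water around a
protein with small organic probes and converts the probes' residence
densities into binding-hotspot maps. Mixtures that include hydrophobic
probes (benzene, propane) are attractive because hydrophobic and
aromatic features dominate many pharmacophores — but at practical
concentrations those probes demix into droplets, and a droplet maps
nothing. The two classical escapes are low concentrations (slow
convergence) or force-field surgery (repulsive non-bonded terms
between probes, with modified cut-offs). This package takes the third
route: leave the force field alone and let the bias plugin (PLUMED)
apply an explicit repulsive restraint between probe pairs, generated
automatically from the structure file.

## The wall model

Each restrained pair contributes a one-sided polynomial wall on the
intermolecular distance $x$:

$$V(x) = k\left(\frac{x-a}{s}\right)^{e} \;\; (x < a), \qquad
  V(x) = 0 \;\; (x \ge a).$$

The wall only acts when two probes approach within $a$; beyond it the
simulation is untouched, so solvation structure and probe–protein
interactions are unperturbed. The force along the distance is
$-\mathrm{d}V/\mathrm{d}x = -k\,e\,((x-a)/s)^{e-1}/s$, repulsive below
$a$ for even exponents. `wall_energy()` / `wall_force()` implement
this closed form and serve as the in-package oracle for everything the
script generator emits: tests parse the emitted `LOWER_WALLS`
parameters back and require identical energies.

Parameter defaults, and why:

| parameter | default (engine units) | kcal/Å equivalent | role |
|---|---|---|---|
| `KAPPA` ($k$) | 20000 kJ mol⁻¹ nm⁻⁴ | 0.478 kcal mol⁻¹ Å⁻⁴ | stiffness; units depend on $e$ |
| `AT` ($a$) | 0.8 nm | 8.0 Å | wall location: just beyond the 7 Å aggregation criterion |
| `EPS` ($s$) | 1.0 | 1.0 | dimensionless rescaling |
| `EXP` ($e$) | 4 | 4 | quartic: gentle onset, stiff core |
| soft set | 10 kJ mol⁻¹ nm⁻², $e=2$ | 0.024 kcal mol⁻¹ Å⁻² | equilibration: avoids large initial forces |

The canonical values are stored in engine units (kJ/mol, nm — what a
GROMACS-coupled PLUMED consumes) so that emitted files contain round
numbers; the commonly quoted "≈ 0.5 kcal mol⁻¹ Å⁻⁴" and
"≈ 0.02 kcal mol⁻¹ Å⁻²" are exactly these constants divided by
4.184 × 10^e/Å-power. `convert_wall_params()` moves between the unit
systems with exact round trips; the force-constant conversion carries
the length factor to the power $-e$. Odd exponents are accepted with a
warning (the branch below $a$ changes sign); all defaults are even.

## Which pairs get walls

A restraint scheme names the probe types (residue code + distance
anchor) and the unordered type pairs to restrain. The default
seven-probe scheme restrains exactly benzene–benzene,
propane–benzene, propane–propane (lipophilic aggregation) and
acetate–methylammonium (ion pairing); water-soluble neutral probes
need no walls. Distances are point-based: benzene uses its centre of
mass (mass-weighted, masses from a packaged element table — unknown
elements are an error rather than a guessed mass), propane its central
carbon, methylammonium its nitrogen, acetate its carboxylic carbon,
formamide its carbon. Schemes are constructed in code or loaded from a
YAML config; the shipped `inst/extdata/default_scheme.yaml` makes the
command-line tool work out of the box. Residue codes are package
defaults (BENX, PRPN, …) and deliberately configurable: force-field
topology generators disagree on probe residue naming.

The generator emits, in order: one `COM` per COM-anchored molecule,
one `DISTANCE` per enumerated pair (all $\binom{N}{2}$ same-type pairs
or the full $N_A \times N_B$ cross product, lexicographic), one
grouped `LOWER_WALLS` per rule with per-argument parameter lists, and
a single `PRINT` of all `.bias` values (default stride 500 steps).
Per-pair `DISTANCE` plus a grouped vectorized wall was chosen over
PLUMED's multicolvar many-restraints shorthand: the file stays
line-by-line checkable (`validate_plumed()` re-parses it, enforcing
grammar, label uniqueness and definition-before-use) and the energy
function is identical. Rendering uses fixed ordering and fixed numeric
formatting with a content hash in the header instead of a timestamp,
so identical inputs give byte-identical files. Rules whose types have
too few molecules are skipped with a warning, never silently.

Periodicity is left to the engine: no `NOPBC` is emitted, and
distances in the analysis code use the minimum-image convention
(orthorhombic shortcut, or a 27-cell search over the reduced triclinic
lattice — correct for GROMACS dodecahedra, and checked against a
brute-force 5×5×5 image enumeration).

## Analyses

* **RDF** — all minimum-image anchor–anchor distances binned over
  frames, normalized per frame by the ideal-gas shell expectation
  $N_\mathrm{pairs}\,V_\mathrm{shell}(r)/V$, so a uniform system gives
  $g(r)=1$. The exact shell volume $\tfrac{4}{3}\pi(r_2^3-r_1^3)$ is
  used rather than the $4\pi r^2\Delta r$ approximation. $r_{max}$ may
  not exceed half the smallest box dimension. The normalization
  convention is a package choice (the conventional ideal-gas one);
  aggregation reads as short-range peaks plus a depleted tail.
* **Interaction fractions** — per frame, a molecule interacts iff some
  distance to another molecule is *strictly* below the cutoff ("below
  4 Å" / "below 7 Å" read as strict; boundary distances are excluded,
  and this is tested). Frames are pooled with equal weight across
  replicas; `frames_subset()` supports per-replica weighting if
  wanted. Cross-set fractions (ion pairs) count over the union of both
  sets.
* **Density grids** — selected atoms binned into cubic voxels
  (default edge 1.0 Å, the conventional grid spacing for such maps)
  covering the first-frame box after periodic wrapping; counts are
  divided by frames × voxel volume to give a number density. Rigid
  alignment to a reference before binning is available
  (`align_idx`/`align_ref`, Kabsch fit) but off by default — for a
  diffusing protein you must align or the map smears; the synthetic
  fixtures don't diffuse.
* **Grid free energy** — $-RT\ln(n/n_\mathrm{expected})$ per voxel at
  $T = 300\,\mathrm{K}$ with $R = 1.98720\times10^{-3}$
  kcal mol⁻¹ K⁻¹, where $n_\mathrm{expected}$ is total group atoms
  over mean box volume. Empty voxels would be $+\infty$; they are
  capped at +3 kcal/mol so grids stay finite for export (the cap is a
  package convention, safely above any displayed level; hotspot maps
  are read at ≤ −1.5 kcal/mol). Export is OpenDX text with an optional
  0/1 threshold mask; grids are written z-fastest and round-trip
  through `read_dx()`.

The five standard density groups — hydrophobic (propane + benzene
carbons), donor (formamide + methanol donor hydrogens), acceptor
(formamide + methanol + acetaldehyde oxygens), negative (acetate
oxygens), positive (methylammonium polar hydrogens) — resolve against
the packaged probe templates' atom names.

## The synthetic-data engine, and what it does not show

All tests run without an MD engine. `insert_probes()` fills a box by
uniform random placement with uniform random rotations (Shoemake
quaternions), rejecting copies with any heavy-atom minimum-image
contact under 2.0 Å; `molecules_for_concentration()` converts
molarity to copy numbers (0.25 M in a 100 Å cube ⇒ 151 copies).
`make_synthetic_trajectory()` produces two ground truths: *dispersed*
frames (independent uniform re-placements — flat RDF, Poisson
neighbour statistics) and *clustered* frames (molecule centres inside
a 6 Å-radius sphere, each linked to a previous centre within 6 Å, so
the 7 Å aggregation fraction is 1 by construction).

`toy_brownian()` is a deliberately labelled *surrogate*: overdamped
Langevin point particles in a 40 Å periodic cube (kT at 300 K,
friction 1, dt 0.05, 6000 steps), with a soft repulsive core
(σ = 3 Å), a short-range polynomial attraction between hydrophobic
particles (depth 4 kcal/mol, range 7 Å — a stand-in for the
hydrophobic effect), and optionally the exact production wall force on
every hydrophobic–hydrophobic distance. With the attraction on and the
wall off the system collapses into clusters; switching the wall on
keeps it dispersed, and with the attraction zeroed the unbiased run
sits at the ideal-gas Poisson baseline. The quartic wall is stiff at
short range, so the deterministic drift is clamped at 1 Å per step (a
standard Brownian-dynamics stabilization; the half-box displacement
guard still fires if clamping is disabled and the time step is
absurd). Box size, particle count, well depth/range and step count
were fixed once from desk-scale pilot runs and are the package
defaults.

What passing these tests shows: the emitted restraint energy is
exactly the analytic wall; the analysis statistics agree with
brute-force oracles and closed forms; and the wall mechanism
suppresses clustering in a minimal model that contains nothing but
attraction, noise and the wall. What they do not show: behaviour of
real solvated proteins — no water, no electrostatics, no force field,
no thermostat/barostat artefacts, and no claim about the quantitative
aggregation percentages of production MD, which require engine-scale
simulation beyond the scope of this package.

## Numerical and degenerate-input choices

* Coordinates are ångström internally; GRO files convert (×10) at the
  boundary. GRO stores 0.001 nm, PDB 0.001 Å — round-trip tests use
  those precisions.
* Atom serials are 1-based file order, not the PDB serial column:
  these must match the MD topology order PLUMED addresses. PDB serials
  above 99999 wrap modulo 100000 on output.
* Molecule identity is (chain, residue id, residue name); insertion
  codes ignored; alternate locations other than blank/'A' are dropped
  with a warning. Probes are single residues, so nothing finer is
  needed.
* Triclinic boxes follow the GROMACS reduced form (lower-triangular
  rows); the minimum image uses the 27-cell search there, never the
  per-axis shortcut.
* A truncated trajectory tail warns and leaves the complete frames
  usable; indexing past them errors, naming the frame. Malformed
  fixed-column lines error with their line number.
* Oversized atom/residue names are a write-time error — silent
  truncation would break the read/write round trip.
* Degenerate rules (one molecule of a same-type pair, an empty side of
  a cross pair) skip with a warning; an all-empty script still fails
  grammar-validation loudly rather than emitting an empty `PRINT`.

## Known limitations

* Density grids require orthorhombic boxes; triclinic production runs
  should be re-wrapped/transformed upstream.
* Native trajectory formats are multi-frame GRO/PDB; binary formats
  (XTC/TRR/DCD) need conversion before analysis.
* No topology/force-field parsing, bond perception, solvation or
  protein preparation: the package starts at a prepared structure file
  and ends at the PLUMED input plus post-hoc analyses.
* The command-line `analyze` subcommands assume the default scheme's
  probe labels; custom schemes are a two-line R script instead.
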