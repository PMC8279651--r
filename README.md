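# crystalhop

Basin-hopping crystal structure prediction for rigid molecules under
periodic boundary conditions with a dynamically optimized triclinic unit
cell — an R package with a compiled (Rcpp) energy/gradient core.

## What problem this solves, and for whom

A molecular crystal can pack in several stable forms (polymorphs), each a
local minimum of the lattice-energy surface; finding *all* the low-lying
minima — not just the deepest — is the central task of crystal structure
prediction (CSP). `crystalhop` is for computational chemists and method
developers who want a transparent, fully scriptable CSP engine for rigid
molecules: it searches the joint space of molecular positions, orientations
and cell parameters with basin-hopping global optimization, requiring no
prior knowledge of cell parameters or space group.

The state of an N-molecule crystal is
`(X̄¹..X̄ᴺ | p¹..pᴺ | a b c α β γ)`: fractional centers of mass, absolute
angle-axis orientations, and the six cell parameters. Site *i* of molecule
*m* sits at

    xᵢᵐ = H X̄ᵐ + R(pᵐ) xᵢ⁰ ,

where `H` is the cell matrix (columns = cell vectors) and `xᵢ⁰` the rigid
body-frame geometry. The lattice energy combines

* an anisotropic site–site model
  `U = A exp(−B (r − ρ(Ω))) − f₆(Br) C₆/r⁶`, where the contact distance
  `ρ(Ω)` depends on the orientation of each molecular plane relative to the
  interatomic direction,
* Ewald electrostatics of atomic point charges in the triclinic cell, and
* a WCA-style penalty on the angular volume factor
  `P = √(1 − cos²α − cos²β − cos²γ + 2cosα cosβ cosγ)` that switches on at
  `P = σ_P^(1/6) = 0.818` and keeps optimizations away from degenerate
  cells,

with analytic gradients in all `6N+6` coordinates. Because a small cell is
smaller than the interaction radius, pair interactions are summed over
periodic images out to `M = ⌊2 r_c a*⌋ + 1` cells per direction, which
covers the full interaction sphere of every molecule. Each basin-hopping
step perturbs all molecules (≤ 0.159 Å translation, ≤ 0.3 rad rotation) and
every third step also the cell (≤ 0.159 Å, ≤ 0.1 rad), LBFGS-minimizes to
an RMS gradient of 1.8897e-6 kJ/mol/Å, and applies a Metropolis test on the
*minimized* energies at a temperature adapted to hold ~50% acceptance.
Distinct minima are archived (deduplicated via Niggli-reduced cells,
energies, and COM-distance fingerprints) together with first-encounter
statistics.

**Parameter caveat:** the package ships a clearly labelled *synthetic*
benzene parameter set (`benzene_params_synthetic()`), chosen once for
physical plausibility (Williams-type exp-6 magnitudes, quadrupole-matched
point charges). It produces a realistic benzene landscape but does not
reproduce any published potential's polymorph energies; see the methods
vignette.

## Worked example

```r
library(crystalhop)

ref      <- benzene_geometry()           # rigid D6h benzene, q_H = +0.145 e
params   <- benzene_params_synthetic()   # synthetic exp-6 + anisotropy table
settings <- energy_settings(r_c = 8)     # 8 A cutoff for fast exploration

start <- random_start(4, seed = 3, ref = ref)    # N = 4, random cell
run   <- run_basin_hopping(start, ref, params, settings,
                           bh = bh_config(steps = 25, max_translation = 1.0,
                                          max_rotation = 1.5,
                                          max_cell_length_step = 0.8,
                                          max_cell_angle_step = 0.25),
                           seed = 3)
print(run)
```

```
basin-hopping run: 25 steps, 13 accepted (ratio 0.52), seed 3
minima archive: 11 distinct minima
 id energy_per_molecule       a       b        c    alpha     beta   gamma
  8            -44.9320 7.05837 7.52206  9.14373  90.0000  90.0000 90.0000
 10            -44.4788 6.83879 7.30129  9.70795  97.6282  90.0000 90.0000
  1            -44.1619 5.55922 8.37693 10.85976 111.5662  90.0000 90.0000
 11            -44.1619 7.82383 7.82383  7.98412 101.0198 101.0198 90.5593
  2            -43.9528 5.41809 9.03170  9.83804  90.0000  90.0000 90.0000
  4            -43.2433 5.55415 9.13869  9.69503  88.7645  83.9798 78.0795
  7            -42.8386 5.52469 7.92333 11.29572  95.1364 103.9062 90.1528
  9            -42.3036 6.47886 8.61567  9.58757  69.8113  76.3919 79.7303
  5            -41.8351 5.36671 7.42101 12.44210  87.7156  81.1167 83.4809
  6            -40.5525 6.05985 9.05356  9.25487  90.8167 102.3083 97.1879
  3            -38.3501 5.10917 8.40765 12.17000 100.1003  98.1468 97.8105
     V_m first_step encounters
 121.368         10         11
 120.112         18          1
 117.581          0          3
 ...
```

Each archive row is a distinct local minimum with its Niggli-reduced cell,
energy per molecule (kJ/mol), molecular volume (Å³) and first-encounter
step: 25 steps from one random start locate eleven packings, with an
orthorhombic global minimum at −44.93 kJ/mol per molecule and 121.4 Å³ per
molecule — the same minimum a herringbone benzene-I-like start relaxes
into. (This example enlarges the hop sizes; at the reference protocol's
0.159 Å / 0.3 rad steps this synthetic landscape's basins are wider than a
single hop, and landscape diversity comes from independent seeded runs
instead — see the vignette.) `archive_merge()` pools runs,
`lowest_within(archive, 5)` lists everything within 5 kJ/mol of the global
minimum, `orientation_angle_set()` counts distinct molecular orientations
(supporting Z determination), and `mfet()` computes mean first-encounter
statistics across independent runs. `write_cif()` / `read_cif()` exchange
P1 structures with standard crystallography tools.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/crystalhop.R hop --seed 1 --steps 50 --out run1
Rscript inst/scripts/crystalhop.R analyze --run run1
```

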