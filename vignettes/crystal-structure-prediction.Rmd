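---
title: "Basin-hopping crystal structure prediction with a variable triclinic cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Basin-hopping crystal structure prediction with a variable triclinic cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystalhop)
```

## The problem

Molecular crystals of one compound can pack in several distinct stable forms
(polymorphs), each a local minimum of the lattice-energy surface. Predicting
them computationally means searching a rugged, high-dimensional landscape for
*all* low-lying minima, not just the deepest one. `crystalhop` implements a
basin-hopping search for rigid molecules under periodic boundary conditions
in which the six unit-cell parameters are optimized *together with* the
molecular positions and orientations, so that a single run with a small
simulation cell (here N = 4 benzene molecules, enough for polymorphs with
Z = 2 or 4) can visit packings of different densities and symmetries without
any prior knowledge of cell parameters or space group.

## Representation

A crystal state holds, for each of the N rigid molecules, a fractional
center-of-mass vector $\bar{X}^m \in [0,1)^3$ and an absolute angle-axis
orientation vector $p^m$, plus the cell parameters
$(a, b, c, \alpha, \beta, \gamma)$. The cell matrix $H$ has the cell vectors
as columns, with $\mathbf{a}$ along $+x$ and $\mathbf{b}$ in the $xy$-plane
(a gauge fixing that makes coordinates and the analytic $\partial H /
\partial\theta$ reproducible). Site $i$ of molecule $m$ sits at
$x_i^m = H \bar{X}^m + R(p^m)\, x_i^0$, with $x_i^0$ the body-frame
reference geometry. Fractional COMs mean molecular positions track cell
deformations automatically; orientations are deliberately kept absolute —
the gradient convention differs between the two choices, but stationary
points coincide. Gradients with respect to fractional COMs follow by the
chain rule $\partial U/\partial\bar{X} = H^{\mathsf T}\, \partial U /
\partial X$, angle-axis gradients through the analytic $\partial R/\partial
p_k$ (Rodrigues form with a series expansion at $p \to 0$), and cell-parameter
gradients by assembling $\partial U/\partial H$ over every term that touches
$H$ (image vectors, COM positions, reciprocal vectors, the cell volume) and
contracting with $\partial H/\partial\theta$. Every one of the $6N+6$
components is validated against central finite differences in the test
suite.

## Energy model

Three terms build the lattice energy:

1. **Short-range site–site model.** An orientation-dependent Born–Mayer
   repulsion with a Tang–Toennies-damped dispersion tail,
   $$U_{ij} = A\, e^{-B\,(r-\rho(\Omega))} - f_6(Br)\, C_6 / r^6, \qquad
   \rho(\Omega) = d_1^{(i)} (z_i\!\cdot\!\hat r)^2 +
                  d_1^{(j)} (z_j\!\cdot\!\hat r)^2,$$
   where $z_m$ is the molecular plane normal. The per-element range shift
   $d_1$ (Angstrom) makes the repulsive wall depend on how each molecule is
   oriented relative to the interatomic direction; $d_1 = 0$ recovers a
   plain isotropic exp-6 model, which the tests exploit as an independent
   oracle. Intramolecular pairs are excluded entirely (constant for a rigid
   body); connectivity is declared, never inferred silently.

2. **Ewald electrostatics.** Atomic point charges are summed with the
   standard real/reciprocal/self splitting generalized to triclinic cells,
   plus a rigid-body intramolecular exclusion term (a constant). Defaults:
   $\alpha = 5.6/r_c$ and a reciprocal cutoff chosen so the truncated
   Gaussian factor is below $10^{-12}$; the total is alpha-invariant to
   better than $10^{-6}$ relative, which the tests check, together with a
   brute-force damped direct sum on a rock-salt toy lattice (agreement to
   4 decimal places) and the isolated-pair Coulomb limit.

3. **WCA-style cell penalty.** Cell *angle* combinations approaching
   degeneracy are excluded by a repulsive term in the angular volume factor
   $P = \sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma +
   2\cos\alpha\cos\beta\cos\gamma}$ (the cell volume is $V = abcP$):
   $$U_P = \varepsilon_P\,\big(\sigma_P/P^6 - 1\big)^2 \quad (P^6 < \sigma_P),
   \qquad U_P = 0 \quad \text{otherwise},$$
   with $\varepsilon_P$ = 0.001 hartree = 2.6255 kJ/mol and $\sigma_P$ = 0.3,
   so the penalty switches on exactly at $P = \sigma_P^{1/6} = 0.818$, where
   it is zero with zero slope (C1), and diverges as $P \to 0$. Among the
   algebraic forms with exactly this threshold, this squared-overlap form
   was chosen for its simplicity and monotonicity; the constants and the
   0.818 activation point are the fixed design facts.

### Periodic summation

Simulation cells of a few molecules are smaller than the interaction radius,
so the minimum-image convention would miss interacting pairs. Instead, pairs
are summed over neighboring images out to $M = \lfloor 2 r_c\, a^* \rfloor +
1$ cells per lattice direction ($a^* = |\mathbf{b} \times \mathbf{c}|/V$ and
cyclic), which covers the entire interaction sphere of every molecule: the
tests compare against a brute-force sum with limits enlarged by three cells
and require bitwise-level agreement, and verify that energies and gradients
per molecule are identical between an N = 4 cell and its doubled N = 8
supercell.

**Cutoff scheme.** The site–site cutoff at $r_c$ is sharp in the sense that
no switching function is applied, but each pair term is *shifted* by its
value at $r_c$ so the truncated sum is continuous when pairs cross the
cutoff. This matters more than it may look: with plain truncation the
energy jumps by about $C_6/r_c^6$ (order $10^{-2}$ kJ/mol at 8 Angstrom)
whenever a pair crosses, minimizations generically press pairs against
these ledges, and the tight RMS-gradient stopping rule below becomes
unreachable — in our experiments most random-start minimizations stalled.
With the shift, forces inside the cutoff are unchanged, lattice sums remain
size-consistent, and minimizations converge reliably (`shift_cutoff =
FALSE` restores plain truncation for comparison). No dispersion tail
correction is applied.

## Local minimization

`minimize_crystal()` runs limited-memory BFGS (history 10, at most 5000
iterations) over the joint $6N+6$ variable vector with analytic gradients,
stopping when the root-mean-square of the raw gradient vector falls to
$1.8897\times 10^{-6}$ kJ/mol/Angstrom. That scalar deliberately mixes
units (fractional, radian and Angstrom components enter one RMS); we adopt
it as the single printed criterion, and note it as a caveat rather than
introduce per-block scalings. The line search is backtracking Armijo with a
strict slack; if a descent direction points straight across one of the
residual force kinks of the truncated sum, the optimizer may accept a
bounded energy rise (at most `noise_tol`, default $10^{-4}$ kJ/mol, at most
50 times per minimization) and forget its curvature history. The best
visited point is tracked, so the returned energy never exceeds the starting
energy. Unconverged results are flagged and never enter archives. An
independent check minimizes the same landscape through `stats::optim`'s
L-BFGS-B and verifies it finds nothing lower.

## The basin-hopping loop

Each step perturbs every molecule independently — translation uniform in
the ball of radius 0.159 Angstrom (in absolute space, converted through
$H^{-1}$), rotation about a uniform random axis by an angle up to 0.3 rad —
and, on every third step, additionally perturbs each cell length by up to
0.159 Angstrom and each cell angle by up to 0.1 rad. The perturbed
structure is minimized, and the *minimized* energy is accepted or rejected
by a Metropolis test at a fictitious temperature that is adapted every 50
steps (multiplied or divided by 1.05) to hold the acceptance ratio near
0.5. Accepted minima seed the next step; every distinct converged minimum
is archived with its first-encounter step. Because acceptance sees only
minimized energies, the landscape explored is the staircase transformation
of the true surface: downhill barriers vanish while every minimum keeps its
energy. The translation sampling law and the in-addition (rather than
instead-of) cell move on third steps are our choices where the protocol
leaves them open; the initial temperature (1 kJ/mol) is immaterial after
adaptation.

One empirical property of the *synthetic* landscape deserves a caveat:
under the reference step sizes above, its basins of attraction are
geometrically wider than a single hop — proposals energized by tens of
kJ/mol still re-minimize into the starting basin, so single runs rarely
hop, and landscape coverage comes from independent seeded starts (the same
multi-run design used for first-encounter statistics). With larger moves
(about 1 Angstrom / 1.5 rad) the identical loop archives ten or more
distinct minima within a few dozen steps, which localizes the effect in
the potential's basin geometry, not in the algorithm. Reassuringly, the
unbiased search's global minimum is the orthorhombic herringbone packing
that a benzene-I-like start also relaxes into.

## Minima analysis

Archived minima are compared by three simultaneous criteria: energy per
molecule within 0.01 kJ/mol, Niggli-reduced cells agreeing to 0.1 Angstrom
and 1 degree, and sorted minimum-image COM-distance fingerprints agreeing
to 0.1 Angstrom RMS. The Niggli form (Krivy–Gruber) makes the comparison
invariant to lattice re-basing, which the tests verify over random
unimodular transformations. This molecule-level matching deliberately stops
short of a full atom-level RMSD with optimal rotation and permutation;
published RMSD values therefore have no counterpart here. Molecular volume
($V/N$), energy windows above the global minimum, pairwise orientation-angle
sets (supporting Z determination for planar molecules), and mean
first-encounter times (MFET) over independent runs — with runs that never
meet a label reported as censored, never averaged in — complete the
analysis toolkit. A reference table of the five published low-energy
benzene polymorphs (energies, cells, space groups, MFETs) ships for
labeling archives.

## The synthetic benzene model

The published anisotropic benzene potential that motivated this framework is
parametrized in a supporting-information table that is not redistributable
here, so the package ships a clearly labelled **synthetic** stand-in
(`benzene_params_synthetic()`): Williams-type aromatic exp-6 magnitudes
(A = 349908/62351/11104 kJ/mol, B = 3.60/3.67/3.74 1/Angstrom,
C6 = 2377/569/136 kJ Angstrom^6/mol for CC/CH/HH), Tang–Toennies damping,
a small negative carbon range shift ($d_1^{(C)} = -0.05$ Angstrom,
shortening the contact along the ring normal, consistent with graphite's
short interplanar spacing), and point charges $q_H = +0.145$ e chosen to
reproduce the gas-phase benzene quadrupole (about $-1.8$ e Angstrom$^2$ for
the D6h reference geometry with $r_{CC} = 1.39$, $r_{CH} = 1.08$ Angstrom).
All values were fixed once, on physical-plausibility grounds, before any
landscape results were inspected. The model yields a sensible benzene
crystal landscape (lattice energies around $-44$ kJ/mol per molecule,
molecular volumes near 120 Angstrom$^3$), but its minima do **not**
reproduce the published polymorph energies or cells — the acceptance tests
that assert those published numbers fail by design under this model, and
say so in their output. What the passing tests *do* establish is the
machinery: exact gradients, size-consistent periodic sums, a convergent
minimizer, a reproducible hopping loop and a sound archive. What they
cannot establish is transferability of any conclusion to the published
potential or to experiment.

## Problem sizes and numerical choices

The shipped defaults for demonstration and testing use N = 4 molecules,
$r_c$ = 8 Angstrom (the package default of 15 Angstrom is better for
production energies; 8 keeps a full landscape search to minutes),
basin-hopping runs of tens of steps, and a handful of independent seeds for
MFET statistics — deliberately scaled-down counterparts of a production
protocol (hundreds of runs of $10^4$ steps). Degenerate cells are rejected
at construction when $P < 10^{-6}$; during optimization the WCA penalty is
the guard, backed by a finite energy barrier for outright invalid
parameters so line searches simply back off. Random starts draw cell
lengths uniform on [6.5, 11] Angstrom and angles on [70, 110] degrees,
accept only $P > 0.5$ and molecular volumes in [100, 260] Angstrom$^3$, and
redraw any configuration with an intersite contact below 1.5 Angstrom —
wide enough to make independent runs genuinely independent, while avoiding
pathological starts that stall the first minimization.

## Known limitations

Rigid molecules only; point charges only (no multipoles); no enthalpy
optimization under external pressure; no space-group detection (export the
P1 CIFs to external tools); molecule-level rather than atom-level structure
matching; and the synthetic parameter caveat above. MFET statistics from a
few short runs carry large uncertainty — the reference protocol uses
hundreds of independent runs.
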