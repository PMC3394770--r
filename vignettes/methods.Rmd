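---
title: "Methods: crystal packing, binding geometry and thermodynamics of a tetrameric lectin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crystal packing, binding geometry and thermodynamics of a tetrameric lectin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipolectin)
```

This vignette documents the models, parameter choices and numerical
conventions behind `ipolectin`. The package characterizes a small
oligomeric carbohydrate-binding protein — ipomoelin, a jacalin-related
lectin of sweet potato that forms a compact tetramer — through five
computational stages: crystal-packing arithmetic, symmetry expansion and
assembly, surface burial, binding-pocket contact geometry, and two fitted
models (a single-site titration isotherm and a size-exclusion
calibration line). Each stage is exercised by a synthetic-data generator
with known ground truth.

## Crystal packing

The unit-cell volume uses the general triclinic formula
$V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma+2\cos\alpha\cos\beta\cos\gamma}$,
which collapses to $abc$ and $abc\sin\beta$ for orthorhombic and
monoclinic cells; it is cross-checked in the tests against the
determinant of the orthogonalization matrix on random cells.

The Matthews coefficient is $V_m = V/(N \cdot M)$ with $N$ the number of
chains in the *whole* cell (chains per asymmetric unit times space-group
multiplicity) and $M$ the monomer mass in Da. Solvent content is
$V_s = 1 - 1.66 \times 0.74 / V_m = 1 - 1.2284/V_m$, using the standard
protein partial specific volume of 0.74 cm³/g. We keep the constant at
its unrounded product 1.2284 rather than 1.23: for a coefficient of
2.21 ų/Da this reproduces the conventional 44.4% to the printed digit;
the two constants differ by at most 0.3 percentage points anywhere in
the physical range. $V_s$ is undefined (and the function errors) at
$V_m \le 1.2284$.

**Monomer mass.** Crystallographic reports rarely print the mass used in
their packing arithmetic. For the lectin studied here, the His-tagged
monomer is quoted at 17.3 kDa, yet the printed coefficients
(3.51/2.19/2.21/2.26/2.25 ų/Da across four crystal forms) are all
mutually consistent only with $M \approx 16.51$ kDa — presumably the
untagged chain. `ipolectin` therefore treats the mass as an explicit
user input (`matthews()`, `crystal_summary()`), defaulting to
`chain_mass()` of the longest chain, and the acceptance script states the
16,510 Da value it uses. `chain_mass()` sums free amino-acid average
masses minus one water per peptide bond; unknown codes are excluded and
reported.

**Space groups.** Operator lists are hard-coded for the five groups the
package needs (P1, P2₁, P2₁2₁2₁, C222₁, I222), with centring
translations expanded so the list length is the multiplicity. Anything
else raises an error naming the supported symbols — guessing operators
for an arbitrary Hermann–Mauguin symbol silently corrupts every
downstream number. Closure under composition modulo lattice translations
is asserted in the tests.

**PDB io.** Fixed-column `ATOM`/`HETATM`/`CRYST1` records only; mmCIF is
out of scope. Malformed records error with the offending line number.
Alternate locations keep the highest-occupancy conformer, ties broken by
the alphabetically first altloc label, so parsing is deterministic.
Coordinates are stored in Å in the orthogonal frame;
fractionalization happens on demand inside the symmetry module.

## Symmetry expansion and oligomer assembly

Operators act in fractional coordinates:
$x' = \mathrm{orth}(R\,\mathrm{frac}(x) + t + s)$ with $s$ an integer
lattice shift. Triplet strings such as `"-X-1, -Y, Z"` are parsed by
term; integer or fractional offsets accumulate into $t$, so the `-1`
enters as the lattice translation $(-1,0,0)$.

`assemble_oligomers()` expands every protein chain over all operators
and lattice shifts in $-1..+1$ per axis (sufficient to cover
neighbour-cell operators like the one above), then links two mates when
any inter-chain heavy-atom distance is below the contact cutoff.
Connected components containing an identity mate are reported, largest
first. The published packing analysis states no numeric contact
criterion; 5.0 Å heavy-atom is this package's choice, validated on the
designed fixtures — it is generous enough to capture any interface that
buries meaningful area, and interface *significance* is judged
downstream by buried area, not by the graph. Waters, free ions and
sugars are excluded from the contact graph. Assemblies equivalent under
crystal symmetry are deduplicated by a canonical signature: the
lexicographically smallest sorted list of member operators expressed
relative to each member in turn.

A deliberately simple behaviour falls out of this design: a toy chain
placed near a 222 point axis in I222 assembles into a tetramer whose
members are generated by the operator family
$(X,-Y,-Z), (-X,Y,-Z), (-X,-Y,Z)$, the same mechanism by which a
four-fifths-complete asymmetric unit completes its tetramer in a real
crystal; in C222₁ the same placement yields the two-chain assembly
through $(X,-Y,-Z)$ alone.

## Surface areas and buried interfaces

SASA is computed by the Shrake–Rupley method: each atom's sphere of
radius $r_{vdw} + r_{probe}$ carries a quasi-uniform Fibonacci lattice of
points (default 960), and the accessible fraction times the sphere area
is the per-atom SASA. The Fibonacci lattice is deterministic — no random
rotation — so results are bit-reproducible. Radii follow the
NACCESS-style set (C 1.70, N 1.55, O 1.52, S 1.80, Cd 1.58; 1.70 for
unlisted elements), probe 1.4 Å (water). Convergence between 960 and
4000 points is under 1% on the fixtures, and the implementation is
compared against an independent Shrake–Rupley implementation (Python
`biotite`, same radii passed explicitly) to within 2%.

One degenerate case needs a convention: a lattice point lying *exactly*
on a neighbour's expanded sphere. Such ties are counted as buried only
against lower-index atoms, so two exactly coincident identical spheres
jointly expose one sphere's worth of area — the analytic union — rather
than two or zero.

Buried interface area follows the PISA convention,
$(\mathrm{SASA}(A)+\mathrm{SASA}(B)-\mathrm{SASA}(A\cup B))/2$, computed
on protein heavy atoms only (waters, ions and sugars excluded, matching
how interface residue lists are reported for protein–protein contacts).
Interface residues are those losing more than 0.1 Ų — a threshold low
enough to keep contiguous residue ranges intact while suppressing
floating-point dust. Reference implementations of the PISA service do
not publish their exact radii or point density, so benchmark comparisons
against service-derived areas should be read with a ±5% allowance.

## Binding-pocket contact geometry

The deposited structures contain no hydrogens, so hydrogen bonds are
detected by a distance-only heavy-atom criterion: donor–acceptor pairs
(either direction) within 3.5 Å, no angle term. The donor/acceptor
dictionary gives every standard residue its backbone amide donor
(except proline) and carbonyl acceptor plus side-chain roles; pyranoside
ligands treat the glycosidic O1 and ring O5 as acceptors only and the
hydroxyls O2/O3/O4/O6 as both donor and acceptor. Residues missing from
the dictionary are skipped with a warning, never silently dropped.
Distances are carried at full precision and rounded to 0.1 Å only in the
reported column.

Methyl–π contacts use the standard CH–π survey geometry: methyl carbon
within 4.5 Å of an aromatic ring centroid and at least 30° elevation
above the ring plane; tryptophan contributes both its five- and
six-membered ring centroids, and a methyl perched above the fused edge
can legitimately register against both. Metal coordination counts O/N
atoms within 3.0 Å of each metal.

All three detectors are invariant under rigid motion (tested with random
rotations/translations), monotone in their cutoffs, and agree exactly
with a brute-force all-pairs oracle on small fixtures.

## The single-site titration model

For injection $i$ of a titration with cell volume $V_0$, injection
volume $dV$ and displaced fraction $x = i\,dV/V_0$, cell concentrations
follow the symmetric displacement convention used by the Origin software
that virtually all published one-site fits come from:
$M_t = M_0(1-x/2)/(1+x/2)$, $X_t = X_0\,x/(1+x/2)$. The bound fraction
solves the single-site quadratic
$$\theta = \tfrac12\left[r - \sqrt{r^2 - 4X_t/(nM_t)}\right],\qquad
r = 1 + \frac{X_t}{nM_t} + \frac{1}{nK_AM_t},$$
and the per-injection heat is the increment of
$Q = n\theta M_t \Delta H V_0$ plus the displaced-volume correction
$\frac{dV}{V_0}\frac{Q_i+Q_{i-1}}{2}$. At the total injected volume of
the default protocol (36 of 280 µl) the alternative exponential
dilution model differs by well under 1%, so the choice is immaterial at
these conditions. Heats are stored in µcal and reported per mole of
injectant in kcal/mol; $R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹ and
$T = 298.15$ K by default.

**Fitting.** `itc_fit()` runs Levenberg–Marquardt least squares over
$(\log_{10}K_A, \Delta H)$, with $n$ fixed at 1 by default (the common
practice for low-c titrations, and how the reference experiments were
fitted) and an optional constant baseline offset, on by default, that
absorbs unsubtracted dilution heat in real data. The log
parameterization bars negative $K_A$ excursions; initialization is
$K_A^{(0)} = 1/[\mathrm{cell}]$ and $\Delta H^{(0)}$ from the
largest-magnitude normalized heat, with a few log-spaced restarts before
giving up. Derived quantities satisfy the identities
$\Delta G = -RT\ln K_A$, $-T\Delta S = \Delta G - \Delta H$ and
$c = nK_A[\mathrm{cell}]$ exactly by construction. The fit warns outside
the reliable sigmoidicity window ($c < 1$ or $c > 1000$). The first
injection is *not* excluded by default because the reference experiments
fit all 18 points; an exclusion can be emulated by passing control
heats.

**Recovery study.** The simulation studies (tests and acceptance
script) fit with `offset = FALSE`: simulated data contain no dilution
baseline, and estimating a needless third parameter from 18 points
costs real $K_A$ precision at moderate c (roughly doubling the median
error at 2% noise). With the matched model, noise-free round trips
recover $(K_A, \Delta H)$ to $10^{-3}$% over a grid
$K_A \in \{10^3,10^4,10^5\}$ M⁻¹, $\Delta H \in \{-2,-6,-12\}$ kcal/mol,
and at noise of 2% of the first-injection heat the median $K_A$ error
over 20 seeded replicates stays under 10% for $c \in [1, 100]$.

Known quirk of published tables worth documenting: printed ΔG values are
not always $-RT\ln$ of the printed mean $K_A$ (they are typically means
of per-replicate ΔG), and one published c-value (6.80 for a 13.6×10³
M⁻¹ constant at 0.75 mM) is inconsistent with $c = nK_A[\mathrm{cell}]$
(10.2). `ipolectin` always reports its own computed decomposition and
never reproduces such inconsistencies.

## SEC calibration and oligomer calls

`sec_calibration()` is ordinary least squares of $\log_{10}$(mass, kDa)
on elution volume (ml) — the kDa convention is forced by the published
line $y = -0.0423x + 5.1333$, which yields a sensible 22.0 kDa at
89.6 ml only if $y$ is $\log_{10}$(kDa). Mass prediction warns outside
the calibrated volume range extended by 20% of its width. The oligomer
call rounds the mass ratio to the nearest integer with ties rounding up
(a ratio of 3.65, typical for a tetramer eluting slightly light, calls a
4-mer); apparent masses below half the monomer raise a
matrix-interaction flag, motivated by lectins binding the dextran of the
column matrix and eluting absurdly late. The same published line
evaluates to 63.1 kDa at 78.8 ml where the study text reports 63.2 and,
for a different run at the same volume, 64.7 — sub-0.2% discrepancies of
the printed equation's rounding, which the package does not attempt to
absorb.

## The synthetic-data generators

`make_toy_crystal()` builds an idealized extended glycine backbone
(3.8 Å Cα spacing) and optionally: a pyranoside-like ligand whose O5 is
placed at an exact designed distance above a chosen backbone nitrogen,
with the remaining sugar atoms stacked strictly further away so the
designed bond is the *only* donor–acceptor pair within the cutoff (the
generator verifies this and refuses geometries below van der Waals
contact); a Cd ion with $k$ water oxygens at 2.3 Å; an idealized planar
indole with the ligand methyl carbon at a designed elevation; and a
chain placement that brings a chosen symmetry mate to a designed closest
approach. Ground truth is recorded at construction, and the tests assert
*exact set equality* between designed and detected contacts.

`make_itc_dataset()` wraps the forward model at the published protocol
(280 µl cell, 18 × 2 µl, 25 °C) with i.i.d. Gaussian noise scaled to the
first-injection heat; `make_sec_standards()` places the Bio-Rad marker
masses (670, 158, 44, 17, 1.35 kDa) on a truth line with Gaussian
elution noise. All generators are deterministic under a fixed seed.

**What passing tests do and do not show.** The toy crystals exercise the
detectors' geometry exactly but share none of the β-prism fold's
complexity: no side chains beyond the one indole, no water-mediated
bridges, no conformational heterogeneity, idealized ring geometry. The
ITC noise model is homoscedastic Gaussian, while real instruments drift
and their integration errors scale with peak size. Passing these tests
demonstrates correctness of the computations, not fidelity to any
particular deposited structure; the benchmark tier against the deposited
entries covers that and requires the coordinate files to be supplied
locally.

## Problem sizes and limitations

The test fixtures use 5–20 residue chains (≤ 200 atoms), 960-point SASA
lattices (9,600 for the high-density oracle), 18-injection titrations
and 20-replicate recovery studies — sizes chosen so the full suite
exercises every code path in a few minutes on one core while keeping
every tolerance meaningful. Known limitations: no mmCIF, no anisotropic
B-factors, no hydrogen placement or angle-dependent hydrogen-bond
scoring, no multi-site or competitive binding models, no raw thermogram
peak integration (inputs are integrated heats), no chromatogram peak
detection, and space-group support restricted to the five listed groups.
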