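---
title: "Methods: rigid-molecule crystal structure prediction in cspland"
author: "cspland authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rigid-molecule crystal structure prediction in cspland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Crystal structure prediction (CSP) asks: given only a molecule's
structure, which crystal packings are thermodynamically plausible? For a
rigid organic molecule the answer is a *crystal energy landscape* — the
set of local minima of the lattice energy over the packing variables
(unit cell, molecular position and orientation within a space group),
ranked by energy. cspland implements the full rigid-molecule, Z′ = 1
workflow at desk scale: quasi-random trial generation, staged rigid-body
lattice-energy minimisation under an exp-6 + atomic-multipole model,
duplicate removal, reference matching, landscape statistics, and a
committee Δ-ML energy correction with query-by-committee active
learning. Everything is exercised on synthetic fixtures bundled with the
package; no external structure database or electronic-structure code is
required.

# The energy model

The lattice energy per molecule (kJ mol⁻¹, Z′ = 1, rigid monomers so
the intramolecular energy is a constant set to zero) is

$$E_\mathrm{latt} = E_\mathrm{rep-disp} + E_\mathrm{elec},$$

with all intermolecular atom–atom pairs over the periodic lattice
counted half each.

**Repulsion–dispersion.** Each atom pair interacts through the exp-6
(Buckingham) form $U(r) = A e^{-Br} - C r^{-6}$, with homonuclear
parameters per force-field type and cross terms from combining rules
(geometric mean for $A$ and $C$, arithmetic for $B$; configurable). The
sum runs to a real-space cutoff (default 15 Å). Two numerical details
matter:

* *Cutoff smoothing.* A hard cutoff leaves $O(C/r_c^6)$ jumps in the
  energy as pairs cross $r_c$ during minimisation, which defeats
  quasi-Newton line searches. The pair term is therefore switched off
  smoothly over the final 1 Å below the cutoff by a quintic (C²)
  switching polynomial, and the uniform-density tail correction is
  extended analytically over both the switched sliver and everything
  beyond the cutoff.
* *Inner cap.* The exp-6 form turns attractive again at very short
  range ($-C/r^6$ diverges). Below the curve's inner maximum
  $r_\mathrm{wall}$ the pair energy is replaced by
  $U(r_\mathrm{wall}) + K (r_\mathrm{wall} - r)^2$ with
  $K = 10^4$ kJ mol⁻¹ Å⁻²; because the exp-6 derivative vanishes at
  $r_\mathrm{wall}$ the join is C¹. This only matters while the
  minimiser escapes overlapped trial geometries; converged structures
  never sit in the capped region, and user-level evaluation treats
  contacts below a hard floor (0.3 Å) as an error.

**Electrostatics.** Atoms carry point charges and optionally dipoles
and quadrupoles (real spherical components stored per atom in the
molecular frame, e·Åˡ units; the Coulomb constant is
1389.35458 kJ mol⁻¹ Å e⁻²). The charge–charge term is computed by Ewald
summation (tin-foil boundary conditions; the splitting parameter is
derived from the cutoff and the result is independent of it to well
below 10⁻⁶ kJ mol⁻¹, which the tests assert). Dipole and quadrupole
terms (interactions through rank 2; higher ranks are out of scope) are
computed by direct summation over *whole neutral image cells* out to the
electrostatic cutoff. A spherical atom-based cutoff was tried first and
rejected: the conditionally convergent charge–dipole and dipole–dipole
sums acquire fluctuating partial-cell boundary contributions of order
0.1 kJ mol⁻¹, whereas whole neutral cells cancel them.

**Polar cells.** For a cell with non-zero net dipole the lattice sum is
conditionally convergent and the result depends on the summation
convention; Ewald corresponds to the tin-foil (conducting boundary)
limit, while an expanding block in vacuum differs by a shape-dependent
surface term. `lattice_energy()` reports the cell dipole magnitude so
users can recognise the situation. The brute-force oracle used in
testing is compared with production only on packings whose space-group
symmetry forces the cell dipole to vanish, so the two machineries are
compared under matched assumptions.

**Oracle.** `brute_force_energy()` is an independent R implementation:
plain double sums over expanding cubic shells of whole cells, no
neighbour logic, no Ewald, with an optional Aitken Δ² extrapolation of
the last three shell sums for the slowly decaying Coulomb tail. The
production path agrees with it to better than 0.01 kJ mol⁻¹ on the
bundled fixtures (asserted in the acceptance tests).

# Sampling

Trial structures are generated per space group from a Halton sequence
(first 13 prime bases, leaped, with a seeded Cranley–Patterson rotation
so each seed gives an independent deterministic stream). The sequence
dimensions map to: axial ratios, free cell angles (per crystal system),
a target volume drawn from a window around the multiplicity-scaled
molecular volume estimate (vdW sphere volume / 0.7 packing efficiency;
window 0.5–2.5×), centroid fractional coordinates, and an orientation
drawn uniformly over rotations through Shoemake's quaternion
construction. Structures pass a geometry check — no intermolecular
contact below 0.6 × the vdW-radius sum (ties pass), volume inside the
window — before minimisation. The 21 bundled space groups cover the
triclinic, monoclinic and orthorhombic systems most common for Z′ = 1
organics; other groups load from a plain-text operation table.

# Minimisation

Minimisation is a bounded quasi-Newton (L-BFGS-B) descent over the free
packing variables only — 6/4/3 cell parameters for
triclinic/monoclinic/orthorhombic, the centroid fractional coordinates,
and a 3-parameter rotation increment composed onto the orientation
quaternion — so space-group symmetry is preserved exactly by
construction. Gradients are forward finite differences reusing the
cached objective value. Line-search failures (finite-difference noise
near convergence) are handled by interleaving derivative-free
Nelder–Mead polishing with fresh L-BFGS-B restarts, and finally by a
numerical-gradient convergence certificate. Cells that collapse or
explode (volume outside 0.15–25 × the molecular volume estimate) are
discarded as divergent; only converged structures count toward batch
targets.

Three schedules are bundled: `default_schedule()` (three stages —
charges at a coarse cutoff, charges at production cutoffs, full
multipole rank at the tightest tolerance, 10⁻⁶ kJ mol⁻¹),
`quick_schedule()` (two stages at 8 Å cutoffs, final tolerance 10⁻⁶,
used for planting and certifying fixture minima) and
`search_schedule()` (final tolerance 10⁻⁴, used when sweeping hundreds
of trial structures; structures need only be well enough converged to
identify and rank packings). The problem sizes used throughout the test
suite — 12–200 accepted trials per group, molecules of 2–8 atoms — are
the package's declared desk-scale study conditions.

# Comparison and deduplication

Duplicate removal is two-stage, as is standard: a fast screen on
simulated powder X-ray diffraction patterns nominates candidate pairs,
and a COMPACK-style molecular-cluster comparison confirms them.

* *PXRD.* Bragg positions from the reciprocal lattice, intensities
  from structure factors with atomic-number form factors (declared
  sufficient for similarity screening, not Rietveld work), pseudo-Voigt
  broadening, max-normalisation. Similarity is a normalised triangle-
  weighted cross-correlation (de Gelder style), computed through a
  single triangle smoothing so all-pairs screening is a matrix product.
  The nomination threshold (0.85) was set low deliberately: imperfectly
  converged copies of one minimum can shift peaks enough to reach
  ~0.89 similarity, and the screen must stay conservative because the
  cluster comparison makes the actual decision.
* *Cluster matching.* An n-molecule cluster (15 for dedup, 30-molecule
  convention for reported match quality; both run the same code path)
  is built around a central molecule in each structure. Alignments are
  seeded by the central molecule *plus one neighbour* — a central
  molecule alone leaves linear molecules with an undetermined axial
  spin — the pairing is made on atom-level squared distances (globally
  smallest first, deterministic), refined by joint superpositions, and
  accepted if every pair satisfies the distance-fraction (20%) and
  orientation-angle (20°) tolerances. The comparison cluster carries a
  buffer beyond n so that symmetry-equidistant shells at the cluster
  boundary cannot spoil the pairing. Orientation angles for linear
  molecules use the signed molecular axis. Matching uses proper
  rotations only, so enantiomorphous packings of an achiral molecule
  are treated as distinct, which is also why no symmetry re-detection
  is attempted — CSP space-group labels are lower bounds on symmetry.
* *Dedup.* Nominated and confirmed pairs are collapsed by connected
  components; representatives are lowest-energy (ties: higher density,
  then input order) and the result is sorted by energy. Dedup is
  idempotent on the fixture suite.

# Landscape analyses

`delta_e()` is the energy above the landscape minimum, optionally over
the Sohncke-group subset (the convention for single-enantiomer chiral
molecules). `spacegroup_frequencies()` implements three selectors:
global minimum and maximum density count one structure per landscape;
the energy-window selector (default 7.2 kJ mol⁻¹, the usual limit of
polymorphism) pools all structures, with a per-landscape-normalised
variant behind a flag because the pooled-versus-normalised choice is
genuinely open. `chirality_analysis()` compares the best Sohncke
(enantiopure) and non-Sohncke (racemic) packings:
ΔE_latt = E_min(Sohncke) − E_min(racemic), so positive values mean the
racemate is favoured; Δρ = relative density difference at those minima,
negative when the enantiopure crystal is less dense (the Wallach
direction); spontaneous resolution is predicted only for strictly
negative ΔE_latt (exact ties are not resolution).

# The committee correction

The Δ-ML stage learns the difference between a cheap energy (the force
field) and a high-level reference, not the energy itself. Structures
are featurised by atom-centred symmetry functions (radial G2 over a
grid of centres, angular G4 over neighbour pairs, element-resolved
channels, 6 Å cutoff, periodic neighbours included); the tests assert
the rotation/translation/permutation invariances numerically.

Each committee member (default M = 8) is a small feed-forward regressor
on per-atom descriptors: a seeded random tanh hidden layer (64 units
over the standardised atom descriptor plus an element one-hot block) is
applied to every atom, the per-atom activations are summed over the
molecule, a linear skip connection adds the summed descriptors
themselves, and only the output weights are trained — by closed-form
ridge regression with the penalty chosen per member by generalised
cross-validation on that member's training rows. Training is therefore
exactly deterministic given the seed. Members differ by their hidden
layers and by bootstrap resampling; with bootstrapping off, all members
coincide and the predictive spread is exactly zero.

Two numerical details were learned the hard way and are worth
recording. First, a purely linear committee cannot support
query-by-committee: its predictive spread is proportional to the
feature magnitude, which vanishes precisely on the highest-error
out-of-distribution structures (gas-like packings whose neighbour
descriptors are all ≈ 0), so uncertainty and error decouple. Random
hidden layers restore disagreement off the training manifold; with
them, committee spread and true error correlate strongly on the fixture
suite, and uncertainty-guided selection beats random selection by a
factor of 2–6 in mean selected error. Second, GCV must exclude
penalties whose effective degrees of freedom approach the row count:
in the overparameterised regime a vanishing penalty interpolates and
the GCV score degenerates to 0/0, silently selecting it.

The committee mean is the predicted correction and the committee
standard deviation its uncertainty; query-by-committee selects the
highest-uncertainty pool structures (deterministic id tie-break), and
corrected landscapes exclude structures above an uncertainty cap
(default 25 kJ mol⁻¹) before re-ranking.

# Synthetic data: what it does and does not emulate

The fixture generator provides (a) small rigid neutral C/H/N/O/F
molecules, including chiral templates verified non-superimposable on
their mirror images; (b) planted reference crystals, found by a short
CSP and re-minimised until certified as fixed points of the energy
model, which play the role of experimentally observed structures in
matching tests; and (c) a deterministic high-level energy oracle
E_high = E_latt + f + ε, where f is a fixed seeded linear functional of
the summed descriptor vector plus a mild quadratic density term (the
part a linear model cannot represent, which gives active learning a
real signal to find) and ε is Gaussian noise seeded per structure id. The toy force field was derived once from per-element
well positions (2.6–3.6 Å) and depths (0.08–0.55 kJ mol⁻¹) with
steepness α = 13 and frozen; it is documented as *not* the published
FIT parameter set, which loads from a plain-text file instead. Planted
minima land at sane organic densities (≈1.4 g cm⁻³ for the standard
templates; the deliberately charge-amplified chiral fixture packs
denser).

The `chiral_dipolar` template is engineered so that heterochiral
contacts are electrostatically favoured: a strongly dipolar chiral
tetrahedron whose inversion-related pair packs head-to-tail. The
end-to-end analysis on this fixture yields ΔE_latt > 0 (racemate
favoured) with the enantiopure minimum less dense — a known-sign answer
the acceptance tests check, not a claim about any real compound.

What passing these tests shows: the sampling covers the packing space
well enough to rediscover planted minima; the minimiser descends to
certified local minima without breaking symmetry; identity and
similarity decisions are stable under re-description; and the
correction machinery recovers a correction that is, by construction,
learnable. What it does not show: accuracy of the toy energy model for
real chemistry, transferability of corrections to real DFT references,
or behaviour for flexible molecules, Z′ > 1, or special positions — all
outside this package's scope.

# Known limitations

* Electrostatic ranks above quadrupole are not implemented.
* Monoclinic groups are used in the b-unique standard setting only;
  origin/setting variants of a group are not recognised as such.
* Matching uses proper rotations only; inversion-related packings are
  distinct by convention.
* The dipole/quadrupole block sum and the tin-foil Ewald convention
  disagree by a surface term for strongly polar cells; the cell dipole
  is reported so the situation is visible.
* The CIF reader covers the subset the writer emits (cell, symmetry
  operations or symbol, fractional sites), not the full CIF grammar.

# Reproducibility

Every stochastic component is a pure function of an integer seed:
Halton rotations, bootstrap resampling, dataset splits, perturbations
and the oracle noise all draw from seeded streams that never touch the
global RNG state. Identical configuration and seed give bit-identical
serialised outputs, which the test suite asserts by hashing.
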