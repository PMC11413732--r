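# cspland

Crystal structure prediction (CSP) landscapes for small rigid organic
molecules, at desk scale, in R.

Given a rigid molecule (Cartesian geometry, force-field atom types,
point charges and optionally atom-centred dipoles/quadrupoles), cspland
searches for its plausible crystal packings: trial structures are
generated quasi-randomly in the common space groups (one molecule in
the asymmetric unit, Z′ = 1), lattice-energy minimised as rigid bodies
under an exp-6 (Buckingham) + atomic-multipole model, deduplicated, and
assembled into an energy-ranked *crystal energy landscape*. On top of
the landscapes the package implements the standard analyses: matching
against reference structures (simulated-PXRD screening plus
COMPACK-style cluster RMSD), energy ranking (ΔE above the global
minimum), space-group preference statistics, the enantiopure-vs-racemic
stability comparison for chiral molecules, and a committee Δ-ML
lattice-energy correction with query-by-committee active learning.

The lattice energy per molecule is

    E_latt = Σ'ᵢⱼ ½ [ Aᵢⱼ exp(−Bᵢⱼ rᵢⱼ) − Cᵢⱼ rᵢⱼ⁻⁶ ]  +  E_elec ,

summed over intermolecular atom pairs of the periodic crystal;
`E_elec` combines Ewald summation for the charge–charge term with
direct whole-cell sums for dipole and quadrupole interactions (ranks
≤ 2). Minimisation is a symmetry-constrained quasi-Newton descent over
the free cell parameters, the molecular centroid and an orientation
quaternion, staged from coarse to tight settings. The methods vignette
(`vignettes/csp-methods.Rmd`) documents the model, the numerical
choices and their rationale.

Everything runs on bundled synthetic fixtures — toy molecules, planted
reference crystals that are certified minima of the implemented model,
and a deterministic stand-in "high-level" energy oracle for the Δ-ML
stage — so no structure database or electronic-structure code is
needed.

## Worked example

A small end-to-end search for a polar diatomic in P1, matched against a
planted reference structure:

```r
library(cspland)

mol <- make_toy_molecule("diatomic")     # CO-like rod, charges +/-0.2 e
ff  <- toy_forcefield()

## plant a reference "experimental" structure (a certified minimum)
ref <- plant_reference(mol, "P1", seed = 101)

## fresh search: 200 geometry-checked trials, minimised and deduplicated
trials <- generate_batch("P1", mol, sampler_config(seed = 1), 200)
minima <- minimize_batch(trials, ff, search_schedule())
ls     <- landscape(deduplicate(minima, compare_config())$unique, mol)
print(ls)
head(ls$summary[, c("group", "E_latt", "density")])

## does the search rediscover the planted structure?
match_reference(ls, ref, compare_config(), n = 15)[c("matched", "rank", "delta_e", "rmsd_n")]
```

Output from this run:

```
<landscape 'diatomic': 5 unique structures, E_min = -13.7050 kJ/mol (P1)>
  group     E_latt   density
1    P1 -13.704979 1.4167304
2    P1 -13.212778 1.3543734
3    P1  -6.748779 0.2310948
4    P1  -5.444698 0.1546164
5    P1  -3.178485 0.0446515

$matched
[1] TRUE
$rank
[1] 1
$delta_e
[1] 0
$rmsd_n
[1] 0.0005137444
```

The search finds the planted packing as its global minimum (`rank` 1,
`delta_e` 0 — the match *is* the most stable predicted structure) with
a 15-molecule cluster RMSD of ~0.0005 Å against the reference. The
second entry is a slightly less dense polymorph 0.49 kJ mol⁻¹ above
the minimum; the low-density tail entries are gas-like local minima of
the truncated model, which a production run would discard by a density
floor. Densities are in g cm⁻³, energies in kJ mol⁻¹ per molecule.

The chiral analysis works the same way: search a Sohncke group and a
racemic group with `make_toy_molecule("chiral_dipolar")`, combine, and
call `chirality_analysis()`; on that engineered fixture the racemate is
favoured (ΔE_latt > 0) and the enantiopure crystal is less dense.

A thin command-line wrapper over the same functions ships as
`inst/scripts/csp.R` (`fixtures`, `generate`, `minimize`, `dedupe`,
`match`, `analyze`).

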