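---
title: "Coarse-grained elongation of docked GAGs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained elongation of docked GAGs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagcg)
```

## The problem and the model

Glycosaminoglycans (GAGs) are long, linear, highly negatively charged
polysaccharides. Their specific binding epitope on a protein is short
— docking tools place dp4–dp6 oligomers reliably — but the binding
free energy keeps growing well beyond that length, because every added
sulfated unit adds roughly −2 e of charge interacting with the
positively charged binding site. A model that stops at the docked
fragment therefore systematically underestimates binding.

`gagcg` implements a single-pseudoatom coarse-grained (CG) extension:
each monosaccharide unit outside the binding core is replaced by one
bead of atom type `Z1` carrying the unit's integer charge, a mass of
225 au and one Lennard-Jones sphere (RvdW 4 Å, well depth
3.4 kcal/mol, the doubled internal-pyranose-ring values of an earlier
multi-bead model). Glycosidic linkages between CG units carry no
explicit atoms; chain connectivity is expressed through bonded terms
between beads and, at the all-atom/CG junction, through the anchor
types `Cg` (ring carbon), `Os` (glycosidic oxygen) and the junction
hydrogens/nitrogen `H1`, `H2`, `Ng`, which remain owned by the
standard carbohydrate force field and are not re-parameterized here.

The bead model deliberately captures only electrostatics plus soft
excluded volume. That is appropriate *only* for chain parts not in
contact with the receptor: in the shipped benchmark the all-atom
vs coarse-grained electrostatic binding components correlate at
Pearson 0.997 across ten protein–GAG systems while the van der Waals
components correlate at 0.645 — vdW detail is lost, electrostatics is
kept.

## The shipped parameter set

`default_forcefield()` returns the complete published parameterization
(3 bonds, 7 angles, 15 dihedrals, 1 LJ entry) in AMBER conventions:

* bonds `E = RK (r − REQ)²` — Z1–Z1 and Z1–Cg at 120 kcal/mol/Å²,
  REQ 5.2 Å (one monosaccharide rise); Os–Z1 at 2.8 Å for the
  junction through the glycosidic oxygen;
* angles `E = TK (θ − TEQ)²` (θ in radians) — backbone-like triples at
  TEQ 160°, junction triples at 108.5–110°;
* dihedrals `E = (PK/IDIVF)(1 + cos(PN φ − phase))` — all phases 0°,
  periodicities only 1 or 3. Negative printed amplitudes (e.g. −1.3
  for Z1–Cg–Cg–Ng) are kept verbatim rather than rewritten as
  phase = 180°, for fidelity to the published table; `write_frcmod()`
  notes this when writing.

`write_frcmod()`/`read_frcmod()` round-trip the set exactly. Bond
lookup is order-normalized, dihedral lookup tries both orientations,
and type names are case-sensitive and limited to AMBER's two
characters.

## Boltzmann inversion

Bonded CG parameters are derived from conformational samples (e.g.
internal coordinates measured across the models of a multi-model PDB
with `measure_internal_coordinates()`):

* `pmf_from_samples()` inverts the histogram,
  `U(x) = −k_B T ln(P(x)/P_max)`, so the best-populated bin is exactly
  0. Empty bins stay `NA` — an unvisited region has unknown, not zero,
  free energy. No Jacobian correction (r², sin θ) is applied by
  default because the parameters describe the raw coordinate
  distributions the simulation should reproduce; a `jacobian` flag
  enables the correction.
* `fit_harmonic()` uses the equipartition identity
  `K = k_B T / (2 var)` for the AMBER form `E = K (x − x₀)²` (the ½ is
  absorbed into K) and the sample mean as equilibrium; angle variances
  are converted to radians. A multi-well PMF triggers a bimodality
  warning, since a single harmonic term is then a poor model.
* `fit_dihedral()` bins the samples periodically (72 × 5° bins by
  default), smooths with a circular 3-bin moving average — raw
  histograms produce spurious extrema, and this deterministic rule
  replaces any manual refinement — and counts wells per 360°: one
  well means PN = 1, three mean PN = 3; other counts are rejected
  because the shipped set uses only these two. The amplitude follows
  from the barrier height between the global minimum and the highest
  separating maximum: for `PK (1 + cos(PN φ))` that barrier is `2 PK`,
  so PK = barrier/2. The phase is snapped to 0° or 180° so the cosine
  minimum coincides with the PMF minimum. Profiles flatter than
  0.1 kcal/mol yield PK ≈ 0 with PN = 1 and a warning.

Temperature defaults to 300 K (the usual simulation temperature) and
is configurable everywhere.

The generator side (`sample_boltzmann()`) draws bonds/angles from the
exact Gaussian of a harmonic well and dihedrals by exact rejection
sampling of the cosine Boltzmann weight. Rejection sampling was chosen
over a Metropolis chain deliberately: it yields independent,
seed-deterministic samples with no burn-in or autocorrelation to
reason about. Recovery of every shipped harmonic term from 10⁶ samples
is within 1% on equilibria and 5% on force constants (in practice
≪ 1%), and the two dihedral classes refit PN exactly and PK within
20%; `scripts/acceptance.R` recomputes this end to end.

## Elongation geometry

The published workflow adds beads "manually" in a model-building tool
and lets MD relax them; `gagcg` replaces that with a deterministic,
clash-aware rule (`elongate()`), on the argument that downstream
minimization/MD will relax whatever reasonable start it gets:

* propagation direction = unit vector from the penultimate to the
  terminal residue centroid (non-reducing → reducing taken as
  ascending residue number; the CLI's `--reverse-chain` flips it);
* the first bead bonds through the terminal residue's glycosidic
  oxygen when it points outward (Os–Z1, 2.8 Å), otherwise from the
  ring centroid (Z1–Cg class, 5.2 Å);
* subsequent beads are placed by internal coordinates at exactly
  REQ = 5.2 Å, the equilibrium angle 160°, and trans (180°) dihedral
  continuation — an extended zig-zag;
* a candidate bead closer than `clash_distance` (default 4 Å) to any
  receptor atom is rotated about the previous bond axis in 15° steps;
  the first clash-free pose wins (logged). A full 360° scan without a
  clash-free pose is an error rather than a silent overlap.

Placement never touches pre-existing atoms, and the total GAG charge
changes by exactly `n_beads × bead_charge`. When beads are prepended,
residue numbers are shifted to stay positive and the shift is recorded
in the `resno_offset` attribute.

`substitute_by_energy()` implements the decomposition-guided variant:
every all-atom GAG residue whose per-residue MM/GBSA contribution is
*less favorable than* −0.5 kcal/mol (strictly `dg > threshold`;
exactly −0.5 is kept atomistic) becomes one bead at its ring centroid
with the residue's unit charge. The benchmark tables show this variant
deviating more from the all-atom reference (≈10% on average) than
plain terminal elongation (≈5–6%), so terminal elongation is the
recommended default.

## Energy evaluation

`bonded_energy()`, `pair_energy()` and `lie_energy()` form a
self-contained evaluator used as the package's testing oracle in place
of an MD engine. Conventions: Coulomb constant 332.0636
kcal Å mol⁻¹ e⁻² (AMBER); LJ mixing on Rmin
(`Rmin_ij = RvdW_i + RvdW_j`, `ε_ij = √(ε_i ε_j)`), matching frcmod
NONBON semantics; atoms without an LJ entry (everything but `Z1` in
this set) contribute no vdW term. The Debye–Hückel variant multiplies
each Coulomb term by `exp(−κr)` with `κ⁻¹ = 3.04/√I` Å at the 298 K
water constants (≈7.85 Å at 0.15 M); the stored model temperature does
not silently rescale the solvent constants unless passed to
`debye_length()` explicitly. LIE scoring uses non-calibrated weights
α = β = 1 at dielectric 80 and no cutoff — whether a cutoff should be
applied is genuinely open, and no cutoff is the conservative choice
for a method whose electrostatics decays only as 1/(80 r). For
nonbonded sums, all-atom GAG residues spread their unit charge
uniformly over their atoms when no per-atom charges are present; this
preserves the monopole, which is the only moment the CG model claims
to represent.

## The W factor

For each GAG residue, `W = ΔG_res / S`, where `ΔG_res` is its
per-residue decomposition energy and
`S = Σ_{+ sites} f(d) − Σ_{− sites} f(d)` sums (optionally screened)
reciprocal distances to the charged receptor residues within a cutoff
(default 10 Å, standing in for the nonbonded cutoff of the generating
simulation). Distances run from the residue centroid (bead position
for CG residues) to one reference point per charged residue: Lys NZ,
Arg CZ, Asp CG, Glu CD, with side-chain-centroid and Cα fallbacks.
Histidine is not counted — at physiological pH it is mostly neutral —
and termini are optional. The complex-level W is the arithmetic mean
over residues; residues with |S| < 10⁻⁶ are excluded with a warning.

`predict_elongated_energy()` then extrapolates:
`ΔG_pred = ΔG_base + W̄ Σ_added S`. Applying a complex's own mean W to
its own residues with base 0 reproduces the summed per-residue
energies exactly whenever the per-residue W are equal — the
self-consistency identity the acceptance script verifies. Across the
published peptide–heparin systems the Coulomb-model W is nearly
constant (−3.35/−3.31/−3.33 kcal mol⁻¹ e⁻¹), which motivates the
shipped `PEPTIDE_W = −3.33` for small peptides; protein receptors show
system-specific W values of either sign, so no protein-level constant
is shipped. The published screened-electrostatics W values for the
same peptides are positive and two orders larger than the Coulomb
ones; their normalization cannot be reconstructed from the published
description, so the package takes no side: both electrostatics kinds
and both sign conventions (`pos_minus_neg`, `neg_minus_pos`) are
selectable, with the literal positive-minus-negative reading as
default.

## Benchmark tables and their statistics

Three published benchmark tables ship as CSVs under `inst/extdata/`:
the AA-vs-CG MM/PBSA comparison over ten binding sites (one chemokine
structure contributes two independent sites, and both enter the
correlations — the convention that reproduces all six published
coefficients to three decimals), the heparin length series (dp4–dp16
against five receptors), and the mixed-model dp16 comparison. For the
length series, the InLys dp6 entry uses the published
dissociation-free value (−27.6 kcal/mol). Underestimation percentages
are computed per system as `100(|G₁₆| − |G_dp|)/|G₁₆|` at the tables'
one-decimal precision and then averaged; the summary integers (39%
for dp4, 24% for dp6) follow that reporting convention — with
full-precision intermediates the dp6 mean is 23.5%, on the rounding
boundary. Mixed-model differences are `100|G_AA − G_mixed|/|G_AA|`
rounded to integers (7% APRIL peptide, 14% FGF-1, 3% FGF-2 and
OutLys, 0% InLys after recomputation).

## Synthetic fixtures

`make_gag_helix()` produces an idealized helical sugar chain (default
rise 4.5 Å per residue, approximating heparin's ~4-fold helical
repeat; turn 180°; hexagonal ring template plus an off-axis glycosidic
oxygen) and `make_peptide_complex()` an extended-backbone peptide
parallel to it with charged side-chain tips pointing at the GAG. These
fixtures emulate the *shape* of docked complexes — chain periodicity,
charge placement, AA/CG partitioning — not their chemistry: no ring
pucker, no sulfation geometry, no realistic side-chain rotamers, no
solvent. Tests passing on them demonstrate correctness of the
geometry, bookkeeping and electrostatics pipelines, not predictive
accuracy on real systems, which continues to require MD-derived
ensembles and decompositions. All generators are seed-deterministic;
the structural builders consume no randomness at all.

## Numerical choices and problem sizes

Histogram defaults (50 bins; 72 for dihedrals), the 3-bin smoothing
window, the 0.1 kcal/mol flat-profile tolerance, the 10⁻⁶ |S|
exclusion threshold and the 15° clash-scan step are all deliberate
small constants, chosen once for robustness on the synthetic fixtures
and documented rather than tuned. The test suite exercises parameter
recovery at 10⁵–10⁶ samples and oracle comparisons on ~500-atom
systems; `scripts/acceptance.R` uses 10⁶ samples per refit — sizes at
which the statistical error of the estimators (∝ n^−1/2) is far inside
the stated tolerances while the whole script stays in the seconds
range.

## Known limitations

* The bead model carries no directional vdW or hydrogen-bonding
  detail; it must not be used for chain parts in receptor contact.
* Bead placement is a starting geometry, not a conformational
  prediction; run MD before interpreting energies.
* The W extrapolation assumes the added residues bind purely
  electrostatically and that the calibrating complex's W transfers;
  for protein (as opposed to peptide) receptors the published data
  show it does not transfer across systems.
* PB/GB solvation, topology generation and MD itself are out of scope;
  outputs are designed to feed the AMBER tool chain.
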