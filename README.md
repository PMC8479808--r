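# gagcg

Tools for modelling protein/peptide complexes with **long
glycosaminoglycans (GAGs)**.

Standard docking programs handle GAG oligomers only up to roughly
hexameric length (dp6): longer chains have too many rotatable bonds.
Yet binding free energies keep growing with chain length — truncating
heparin to dp4 or dp6 underestimates the dp16 binding strength by tens
of percent — so stopping at the docked fragment misrepresents the
energetics of natural, much longer chains. `gagcg` implements a simple
workaround for anyone running AMBER-style simulations of protein–GAG
systems: keep the docked core in full atomistic detail and **elongate
the chain with one coarse-grained pseudoatom (type `Z1`) per added
monosaccharide unit**, carrying only the unit's charge (−1 per sulfate
or carboxyl group, −2 for a fully sulfated heparin unit), its mass
(225 au) and a single Lennard-Jones sphere. The lateral parts of a
bound GAG interact with the receptor almost purely electrostatically,
so this is enough.

The package provides, in tidyverse style (tibbles in and out, `tidy()`
/ `glance()` / `autoplot()` on fitted objects):

* the complete Z1 parameter set (3 bonds, 7 angles, 15 dihedrals, 1 LJ
  entry) with AMBER `frcmod` read/write — `default_forcefield()`,
  `read_frcmod()`, `write_frcmod()`; a generated copy ships as
  `inst/extdata/z1.frcmod`;
* PDB-backed complex handling with a GAG chain partitioned into
  all-atom residues and CG beads — `read_complex()`, `write_complex()`;
* deterministic, clash-aware bead placement at either terminus
  (`elongate()`) and threshold-based replacement of weakly contributing
  residues by beads (`substitute_by_energy()`, default threshold
  −0.5 kcal/mol on the per-residue MM/GBSA decomposition);
* Boltzmann inversion to derive bonded CG parameters from
  conformational samples — `pmf_from_samples()`, `fit_harmonic()`
  (`K = k_B T / (2 var)`, AMBER convention `E = K (x − x₀)²`),
  `fit_dihedral()` (periodicity 1 or 3 from the well count per 360°);
* a self-contained energy evaluator (bonded terms, 12-6 LJ, Coulomb,
  Debye–Hückel screened Coulomb, LIE scoring) used as the test oracle;
* the **W factor**: per GAG residue, `W = ΔG_res / S` with
  `S = Σ₊ f(d) − Σ₋ f(d)` over charged receptor residues within a
  cutoff, `f(d) = 1/d` (Coulomb) or `exp(−κd)/d` (Debye–Hückel at
  0.15 M). The complex-level W is the residue mean; it extrapolates
  binding energies to any chain length without new simulations:
  `ΔG_pred = ΔG_base + W̄ · Σ_added S`. For small peptide receptors the
  shipped constant `PEPTIDE_W = −3.33` kcal mol⁻¹ e⁻¹ can be used
  directly — `compute_w()`, `predict_elongated_energy()`;
* published benchmark energy tables and their derived statistics —
  `aa_cg_correlations()`, `length_underestimation()`,
  `mixed_model_difference()`;
* a deterministic synthetic-fixture generator (`make_gag_helix()`,
  `make_peptide_complex()`, `sample_boltzmann()`,
  `make_decomposition()`) so everything is testable offline;
* a CLI: `exec/gagcg` with subcommands `elongate`, `substitute`,
  `fitparams`, `energy`, `wfactor`, `predict`, `benchstats`, `synth`.

## Worked example

```r
library(gagcg)

dp6  <- make_gag_helix(6)                               # docked-core stand-in
pep  <- make_peptide_complex("GKGKG", dp6, offset = 6)  # Lys-rich peptide receptor
dp16 <- elongate(gag_complex(pep$receptor, dp6$gag, "A"),
                 spec = elongation_spec(n_reducing = 10))
glance(dp16)
#>   chain_id n_residues  n_aa  n_cg n_receptor_atoms gag_charge
#> 1 A                16     6    10               24        -32

dec <- make_decomposition(pep, core_dg = -3.0, tail_dg = -0.4, n_core = 4)
w   <- compute_w(pep, dec, cutoff = 15)
w
#> <wfactor_model> mean W = -5.288 kcal/mol/e (coulomb electrostatics, cutoff 15 A, 6 residues)

added <- setdiff(gag_residues(dp16)$resno, gag_residues(dp6)$resno)
predict_elongated_energy(-27.1, dp16, added, w, cutoff = 15)
#> [1] -27.54
```

The 16 residues are the 6 original all-atom sugars plus 10 beads, each
bead adding −2 e (total GAG charge −32 e). The mean W of
−5.29 kcal mol⁻¹ e⁻¹ converts the electrostatic reach of the 10 added
beads into an energy increment; here the beads point away from the
peptide, so the dp16 prediction (−27.54 kcal/mol) barely deepens the
dp6 input energy (−27.1 kcal/mol).

The shipped benchmark statistics:

```r
aa_cg_correlations()
#>   component pearson spearman
#> 1 elect       0.997    0.988
#> 2 vdw         0.645    0.503
#> 3 total       0.920    0.758
length_underestimation(4)$percent   # 39 (% weaker binding of dp4 vs dp16)
length_underestimation(6)$percent   # 24
```

Electrostatic components correlate almost perfectly between all-atom
and coarse-grained GAG models; van der Waals components correlate
poorly, which is exactly why only the non-contacting chain parts are
coarse-grained.

## Scope

The package prepares and scores structures; it does not run molecular
dynamics, compute implicit-solvent (PB/GB) solvation terms, or build
AMBER topologies — those remain with the AMBER tool chain the output
files are designed to feed.
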