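Package: gagcg
Title: Coarse-Grained Elongation and Electrostatic Scoring of
    Protein-Glycosaminoglycan Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling protein and peptide complexes with long
    glycosaminoglycans (GAGs). Ships a single-pseudoatom coarse-grained
    (CG) parameter set for sulfated monosaccharide units with AMBER
    frcmod input/output, elongates docked all-atom GAG oligomers with CG
    beads, replaces weakly contributing sugar residues by beads using a
    per-residue binding free-energy threshold, derives bonded CG
    parameters from conformational samples by Boltzmann inversion, and
    extrapolates binding free energies to arbitrary GAG lengths through
    a per-residue electrostatic W factor under Coulomb or Debye-Hueckel
    screened electrostatics. Includes a deterministic synthetic fixture
    generator and a self-contained energy evaluator used as a testing
    oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
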