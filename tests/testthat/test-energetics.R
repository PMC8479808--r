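test_that("bonded terms evaluate the AMBER functional forms", {
  ## two beads at equilibrium: zero bond energy
  expect_equal(bonded_energy(build_topology(bead_chain(2)))$bond, 0,
               tolerance = 1e-12)
  ## stretched by 1 A: E = RK * 1^2 = 120
  expect_equal(bonded_energy(build_topology(bead_chain(2, spacing = 6.2)))$bond,
               120, tolerance = 1e-9)
  ## collinear 4-bead chain: dihedral undefined-free (angle terms penalized)
  t4 <- build_topology(bead_chain(4))
  e4 <- bonded_energy(t4)
  ## each angle is 180 deg vs TEQ 160: TK * (20 deg in rad)^2, twice
  expect_equal(e4$angle, 2 * 100 * (20 * pi / 180)^2, tolerance = 1e-9)
  expect_equal(e4$total, e4$bond + e4$angle + e4$dihedral + e4$lj + e4$coulomb)
})

test_that("a trans dihedral with PN=1 and phase 0 contributes zero energy", {
  ## zig-zag planar chain with exact 160 deg angles and 180 deg dihedrals
  chain <- elongate(bead_chain(2), spec = elongation_spec(n_reducing = 2))
  topo <- build_topology(chain)
  e <- bonded_energy(topo)
  expect_equal(e$dihedral, 0, tolerance = 1e-9)   # PK (1 + cos 180) = 0
  expect_equal(e$bond, 0, tolerance = 1e-9)
  expect_equal(e$angle, 0, tolerance = 1e-9)
})

test_that("Lennard-Jones and Coulomb pair terms match their closed forms", {
  ff <- default_forcefield()
  es <- electrostatics_model("coulomb")
  ## two beads at Rmin = 8 A with zero charge: LJ minimum = -EDEP
  a <- toy_atoms("Z1", c(0, 0, 0), charges = 0)
  b <- toy_atoms("Z1", c(8, 0, 0), charges = 0)
  e <- pair_energy(a, b, ff, es)
  expect_equal(e$lj, -3.4, tolerance = 1e-12)
  expect_equal(e$coulomb, 0)
  ## unit charges at 3.32 A in vacuo
  p <- toy_atoms("CA", c(0, 0, 0), charges = 1)
  q <- toy_atoms("CA", c(3.32, 0, 0), charges = -1)
  expect_equal(pair_energy(p, q, ff, es)$coulomb, -332.0636 / 3.32,
               tolerance = 1e-12)
  ## Debye screening damps the same pair by exp(-r/lambda_D)
  esd <- electrostatics_model("debye", ionic_strength = 0.15)
  lam <- debye_length(0.15)
  expect_equal(lam, 7.849, tolerance = 1e-3)
  expect_equal(pair_energy(p, q, ff, esd)$coulomb,
               pair_energy(p, q, ff, es)$coulomb * exp(-3.32 / lam),
               tolerance = 1e-12)
  expect_error(pair_energy(p, toy_atoms("CA", c(0, 0, 0), charges = 1),
                           ff, es), "singular")
})

test_that("the evaluator equals an independent all-pairs brute force on mixed systems", {
  ff <- default_forcefield()
  set.seed(91)
  n_a <- 60; n_b <- 40
  a <- toy_atoms(sample(c("Z1", "CA", "NZ"), n_a, TRUE),
                 t(replicate(n_a, runif(3, 0, 30))),
                 charges = round(runif(n_a, -1, 1), 2))
  b <- toy_atoms(sample(c("Z1", "OD1"), n_b, TRUE),
                 t(replicate(n_b, runif(3, 35, 60))),
                 charges = round(runif(n_b, -2, 1), 2))
  for (es in list(electrostatics_model("coulomb", dielectric = 2),
                  electrostatics_model("debye", ionic_strength = 0.15))) {
    for (cutoff in list(NULL, 18)) {
      got <- pair_energy(a, b, ff, es, cutoff = cutoff)
      ref <- brute_force_nonbonded(a, b, ff, es, cutoff = cutoff)
      expect_equal(got$lj, ref$lj, tolerance = 1e-9)
      expect_equal(got$coulomb, ref$coulomb, tolerance = 1e-9)
    }
  }
})

test_that("all energy terms are invariant under rigid transformations", {
  ff <- default_forcefield()
  chain <- elongate(make_gag_helix(4), spec = elongation_spec(n_reducing = 3))
  pep <- make_peptide_complex("GKGKG", chain, offset = 7)
  pep$receptor$charge <- rep_len(c(0.4, -0.3, 0.1), nrow(pep$receptor))
  e0 <- bonded_energy(build_topology(pep, ff))
  nb0 <- pair_energy(pep$receptor, gagcg:::gag_charged_atoms(pep), ff,
                     electrostatics_model("debye"))
  lie0 <- lie_energy(pep)
  for (seed in 1:3) {
    tf <- gagcg:::rigid_transform(seed)
    moved <- apply_rigid(pep, tf)
    e1 <- bonded_energy(build_topology(moved, ff))
    nb1 <- pair_energy(moved$receptor, gagcg:::gag_charged_atoms(moved), ff,
                       electrostatics_model("debye"))
    expect_equal(e1$total, e0$total, tolerance = 1e-6)
    expect_equal(nb1$total, nb0$total, tolerance = 1e-6)
    expect_equal(lie_energy(moved), lie0, tolerance = 1e-6)
  }
})

test_that("the screened model converges to bare Coulomb as ionic strength vanishes", {
  ff <- default_forcefield()
  p <- toy_atoms("CA", c(0, 0, 0, 4, 1, -2, -3, 6, 2), charges = c(1, -1, 0.5))
  q <- toy_atoms("CA", c(9, 0, 0, 7, 5, 3), charges = c(-2, 1))
  coul <- pair_energy(p, q, ff, electrostatics_model("coulomb"))$coulomb
  for (ii in c(1e-14, 1e-16, 0)) {
    deb <- pair_energy(p, q, ff,
                       electrostatics_model("debye", ionic_strength = ii))$coulomb
    expect_equal(deb, coul, tolerance = 1e-6)
  }
})

test_that("LIE scoring reduces to weighted receptor-GAG interaction terms", {
  chain <- make_gag_helix(4)
  pep <- make_peptide_complex("GKGKG", chain, offset = 6)
  ## alpha = beta = 0 is exactly zero
  expect_identical(lie_energy(pep, alpha = 0, beta = 0), 0)
  ## equals the independent term-by-term sum at dielectric 80
  pep$receptor$charge <- rep_len(c(1, 0, -1), nrow(pep$receptor))
  ref <- brute_force_nonbonded(pep$receptor, gagcg:::gag_charged_atoms(pep),
                               default_forcefield(),
                               electrostatics_model("coulomb", dielectric = 80))
  expect_equal(lie_energy(pep), ref$lj + ref$coulomb, tolerance = 1e-9)
  ## distant uncharged system scores ~ 0
  far <- make_peptide_complex("GGGGG", chain, offset = 40)
  expect_lt(abs(lie_energy(far)), 0.1)
  expect_error(lie_energy(chain), "receptor")
})
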