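site_at <- function(xyz, sign = 1, resname = "LYS", resno = 1) {
  tibble::tibble(chain = "P", resno = resno, resname = resname,
                 sign = sign, x = xyz[1], y = xyz[2], z = xyz[3])
}

test_that("the electrostatic distance sum follows the signed reciprocal-distance rule", {
  es <- electrostatics_model("coulomb")
  expect_equal(electrostatic_sum(c(0, 0, 0), site_at(c(2, 0, 0)), es, 10), 0.5)
  ## opposite charges at equal distance cancel
  sites <- dplyr::bind_rows(site_at(c(4, 0, 0), 1),
                            site_at(c(0, 4, 0), -1, "ASP", 2))
  expect_equal(electrostatic_sum(c(0, 0, 0), sites, es, 10), 0)
  ## outside the cutoff nothing counts
  expect_equal(electrostatic_sum(c(0, 0, 0), site_at(c(10, 0, 0)), es, 8), 0)
  ## screened variant multiplies each reciprocal by exp(-kappa d)
  esd <- electrostatics_model("debye", ionic_strength = 0.15)
  expect_equal(electrostatic_sum(c(0, 0, 0), site_at(c(2, 0, 0)), esd, 10),
               exp(-2 / debye_length(0.15)) / 2, tolerance = 1e-12)
  ## the inverted sign convention flips the score
  expect_equal(electrostatic_sum(c(0, 0, 0), site_at(c(2, 0, 0)), es, 10,
                                 sign_convention = "neg_minus_pos"), -0.5)
  expect_error(electrostatic_sum(c(2, 0, 0), site_at(c(2, 0, 0)), es, 10),
               "coincides")
})

test_that("per-residue W is the decomposed energy over the distance sum", {
  b1 <- bead_chain(2)
  sites <- site_at(c(0, 2, 0))
  dec <- decomposition_table(tibble::tibble(residue = 1:2, dg = c(-6.66, 0)))
  w <- compute_w(b1, dec, cutoff = 10, sites = sites)
  per <- tidy(w)
  expect_equal(per$w[1], -6.66 / 0.5)   # = -13.32
  expect_equal(per$w[2], 0)
  expect_equal(glance(w)$mean_w, mean(per$w))
})

test_that("a complex whose energies are proportional to S has exactly that W everywhere", {
  ## self-consistency construction: dG_res = -3.33 * S per residue
  chain <- bead_chain(3)
  sites <- dplyr::bind_rows(site_at(c(2, 3, 0)), site_at(c(7, -4, 2)))
  es <- electrostatics_model("coulomb")
  s_vals <- purrr::pmap_dbl(residue_centroids(chain)[, c("x", "y", "z")],
                            function(x, y, z)
                              electrostatic_sum(c(x, y, z), sites, es, 10))
  dec <- decomposition_table(tibble::tibble(residue = 1:3,
                                            dg = -3.33 * s_vals))
  w <- compute_w(chain, dec, es, cutoff = 10, sites = sites)
  expect_equal(w$mean_w, -3.33, tolerance = 1e-12)
  ## predicting the complex's own residues from its mean W with base 0
  ## reproduces the summed per-residue energies
  pred <- predict_elongated_energy(0, chain, 1:3, w, sites = sites)
  expect_equal(pred, sum(dec$dg), tolerance = 1e-12)
})

test_that("elongation prediction is additive and reduces to the base with nothing added", {
  chain <- bead_chain(4)
  sites <- dplyr::bind_rows(site_at(c(3, 3, 0)), site_at(c(12, -3, 1)))
  expect_equal(predict_elongated_energy(-27.1, chain, integer(0), PEPTIDE_W,
                                        sites = sites), -27.1)
  both <- predict_elongated_energy(0, chain, 1:4, PEPTIDE_W, sites = sites)
  left <- predict_elongated_energy(0, chain, 1:2, PEPTIDE_W, sites = sites)
  right <- predict_elongated_energy(0, chain, 3:4, PEPTIDE_W, sites = sites)
  expect_equal(both, left + right, tolerance = 1e-12)
  expect_error(predict_elongated_energy(0, chain, c(3, 9), PEPTIDE_W,
                                        sites = sites), "not in")
})

test_that("W factors are invariant under rigid motion and negative with positive sites only", {
  chain <- elongate(make_gag_helix(6), spec = elongation_spec(n_reducing = 4))
  pep <- make_peptide_complex("GKGKG", chain, offset = 6)
  dec <- make_decomposition(pep, core_dg = -3, tail_dg = -0.4, n_core = 4)
  w0 <- suppressWarnings(compute_w(pep, dec, cutoff = 15))
  ## only positive sites, all dG negative: W < 0 for every included residue
  expect_true(all(tidy(w0)$w[!tidy(w0)$excluded] <= 0))
  for (seed in 4:5) {
    moved <- apply_rigid(pep, gagcg:::rigid_transform(seed))
    w1 <- suppressWarnings(compute_w(moved, dec, cutoff = 15))
    expect_equal(w1$mean_w, w0$mean_w, tolerance = 1e-6)
  }
  ## coulomb and debye W converge at vanishing ionic strength
  wd <- suppressWarnings(compute_w(pep, dec, cutoff = 15,
                                   es = electrostatics_model("debye",
                                                             ionic_strength = 1e-16)))
  expect_equal(wd$mean_w, w0$mean_w, tolerance = 1e-6)
})

test_that("residues without reachable charged sites are excluded, all-excluded errors", {
  chain <- bead_chain(3)
  far_site <- site_at(c(100, 0, 0))
  dec <- decomposition_table(tibble::tibble(residue = 1:3, dg = -1))
  expect_error(compute_w(chain, dec, cutoff = 10, sites = far_site),
               "every GAG residue")
  near_far <- dplyr::bind_rows(site_at(c(0, 2, 0)), far_site)
  expect_warning(w <- compute_w(chain, dec, cutoff = 5, sites = near_far),
                 "excluded")
  expect_equal(sum(tidy(w)$excluded), 2)
  expect_error(compute_w(chain, dec[1:2, ], cutoff = 10, sites = near_far),
               "residue")
})

test_that("charged receptor sites are detected at canonical atoms with fallbacks", {
  pep <- make_peptide_complex("GKGKG", make_gag_helix(6), offset = 6)
  sites <- detect_charged_sites(pep$receptor)
  expect_equal(nrow(sites), 2)
  expect_true(all(sites$sign == 1))
  nz <- dplyr::filter(pep$receptor, name == "NZ")
  expect_equal(sort(sites$z), sort(nz$z))
  ## both Lys NZ within 8 A of the GAG chain
  cen <- residue_centroids(pep)
  mind <- purrr::map_dbl(seq_len(nrow(sites)), function(i)
    min(sqrt((cen$x - sites$x[i])^2 + (cen$y - sites$y[i])^2 +
               (cen$z - sites$z[i])^2)))
  expect_true(all(mind < 8))
  ## poly-glycine has no charged sites
  gg <- make_peptide_complex("GGGGG", make_gag_helix(6), offset = 6)
  expect_equal(nrow(suppressMessages(detect_charged_sites(gg$receptor))), 0)
  ## mixed charges: acidic residues count negative
  mix <- make_peptide_complex("KDEGR", make_gag_helix(6), offset = 6)
  sm <- detect_charged_sites(mix$receptor)
  expect_equal(sum(sm$sign == 1), 2)   # K, R
  expect_equal(sum(sm$sign == -1), 2)  # D, E
  ## missing NZ falls back to the side-chain centroid with a warning
  broken <- dplyr::filter(pep$receptor, name != "NZ")
  warns <- testthat::capture_warnings(sb <- detect_charged_sites(broken))
  expect_match(warns, "centroid", all = TRUE)
  expect_equal(length(warns), 2)
  expect_equal(nrow(sb), 2)
  ## termini flag adds one positive and one negative site
  st <- detect_charged_sites(pep$receptor, include_termini = TRUE)
  expect_equal(nrow(st), 4)
  expect_equal(sum(st$sign), 2)
})
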