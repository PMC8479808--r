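test_that("a docked hexamer elongates to dp16 with ten beads and conserved charge", {
  dp6 <- make_gag_helix(6)
  out <- elongate(dp6, spec = elongation_spec(n_reducing = 10))
  g <- glance(out)
  expect_equal(g$n_residues, 16)
  expect_equal(g$n_aa, 6)
  expect_equal(g$n_cg, 10)
  ## charge conservation: original + n_beads * bead_charge
  expect_equal(gag_total_charge(out), gag_total_charge(dp6) + 10 * (-2))
  ## pre-existing atoms bitwise untouched
  orig <- dplyr::semi_join(out$gag, dp6$gag, by = "serial")
  expect_identical(orig[, c("x", "y", "z")],
                   dp6$gag[, c("x", "y", "z")])
})

test_that("elongation with zero counts is the identity and single residues are rejected", {
  dp6 <- make_gag_helix(6)
  expect_identical(elongate(dp6, spec = elongation_spec(0, 0)), dp6)
  one <- bead_chain(1)
  expect_error(elongate(one, spec = elongation_spec(n_reducing = 1)),
               "direction")
})

test_that("bead placement hits the equilibrium bond length and internal angle exactly", {
  b2 <- bead_chain(2)
  b3 <- elongate(b2, spec = elongation_spec(n_reducing = 1))
  cen <- residue_centroids(b3)
  p <- lapply(1:3, function(i) unlist(cen[i, c("x", "y", "z")]))
  expect_equal(sqrt(sum((p[[3]] - p[[2]])^2)), 5.2, tolerance = 1e-9)
  ang <- gagcg:::vec_angle_deg(p[[1]], p[[2]], p[[3]])
  expect_equal(ang, 160, tolerance = 1e-6)
  ## every consecutive bead pair sits at REQ(Z1-Z1) at placement
  long <- elongate(b2, spec = elongation_spec(n_reducing = 6))
  cl <- residue_centroids(long)
  d <- sqrt(diff(cl$x)^2 + diff(cl$y)^2 + diff(cl$z)^2)
  expect_true(all(abs(d - 5.2) < 1e-6))
})

test_that("both termini can be elongated and residue numbering is shifted positive", {
  dp4 <- make_gag_helix(4)
  out <- elongate(dp4, spec = elongation_spec(n_nonreducing = 3,
                                              n_reducing = 2))
  g <- glance(out)
  expect_equal(g$n_residues, 9)
  expect_equal(g$n_cg, 5)
  expect_equal(min(out$gag$resno), 1)
  expect_equal(attr(out, "resno_offset"), 3)
})

test_that("clash-aware placement rotates away from receptor atoms or fails loudly", {
  b3 <- bead_chain(3)
  ## receptor atom sitting exactly where the trans-placed bead would go
  free <- elongate(b3, spec = elongation_spec(n_reducing = 1))
  p_free <- unlist(residue_centroids(free)[4, c("x", "y", "z")])
  blocker <- toy_atoms("CA", p_free)
  blocked <- gag_complex(blocker, b3$gag, "A")
  expect_message(
    out <- elongate(blocked, spec = elongation_spec(n_reducing = 1,
                                                    clash_distance = 2)),
    "rotated")
  cen <- residue_centroids(out)
  p4 <- unlist(cen[4, c("x", "y", "z")])
  expect_gt(sqrt(sum((p4 - c(blocker$x, blocker$y, blocker$z))^2)), 2)
  ## an enclosing cage leaves no clash-free pose
  cage <- dplyr::bind_rows(purrr::map(seq(0, 330, 30), function(a) {
    toy_atoms("CA", c(2 * 5.2 + 5.2 * cospi(20 / 180),
                      5.2 * sinpi(20 / 180) * cospi(a / 180),
                      5.2 * sinpi(20 / 180) * sinpi(a / 180)))
  }))
  caged <- gag_complex(dplyr::mutate(cage, serial = dplyr::row_number(),
                                     resno = dplyr::row_number()),
                       b3$gag, "A")
  expect_error(elongate(caged, spec = elongation_spec(n_reducing = 1,
                                                      clash_distance = 4)),
               "clash-free")
})

test_that("energy-based substitution replaces weak residues above the threshold only", {
  dp16 <- elongate(make_gag_helix(6), spec = elongation_spec(n_reducing = 10))
  ## work on an all-atom dp16 instead: rebuild as a pure AA helix
  aa16 <- make_gag_helix(16)
  dec <- make_decomposition(aa16, core_dg = -3.0, tail_dg = -0.1, n_core = 6)
  out <- substitute_by_energy(aa16, dec, threshold = -0.5)
  res <- gag_residues(out)
  expect_equal(sum(res$representation == "CG"), 10)
  expect_equal(sum(res$representation == "AA"), 6)
  ## core residues keep their representation; beads sit at ring centroids
  core <- dplyr::filter(dec, dg == -3.0)$residue
  expect_true(all(res$representation[res$resno %in% core] == "AA"))
  bead_pos <- dplyr::filter(res, representation == "CG")
  orig_cen <- dplyr::filter(residue_centroids(aa16),
                            resno %in% bead_pos$resno)
  expect_equal(bead_pos$x, orig_cen$x)
  ## idempotent
  again <- substitute_by_energy(out, dec, threshold = -0.5)
  expect_equal(gag_residues(again), res)
})

test_that("substitution honors the strict threshold boundary and flags missing entries", {
  aa4 <- make_gag_helix(4)
  dec <- decomposition_table(tibble::tibble(residue = 1:4,
                                            dg = c(-3, -0.5, -0.499, -3)))
  out <- substitute_by_energy(aa4, dec, threshold = -0.5)
  res <- gag_residues(out)
  ## exactly -0.5 is kept atomistic ("less favorable than" is strict)
  expect_equal(res$representation, c("AA", "AA", "CG", "AA"))
  ## all strong contributors: unchanged
  strong <- decomposition_table(tibble::tibble(residue = 1:4, dg = -3))
  expect_identical(substitute_by_energy(aa4, strong), aa4)
  expect_error(substitute_by_energy(aa4, strong[1:2, ]),
               "residue\\(s\\): 3, 4")
})

test_that("topology enumeration counts CG terms and resolves junction parameters", {
  t3 <- build_topology(bead_chain(3))
  expect_equal(c(nrow(t3$bonds), nrow(t3$angles), nrow(t3$dihedrals)),
               c(2, 1, 0))
  t4 <- build_topology(bead_chain(4))
  expect_equal(c(nrow(t4$bonds), nrow(t4$angles), nrow(t4$dihedrals)),
               c(3, 2, 1))
  expect_equal(t4$dihedrals$pattern, "Z1-Z1-Z1-Z1")
  ## glycosidic junction resolves to the Os-Z1 bond at 2.8 A
  mixed <- elongate(make_gag_helix(6), spec = elongation_spec(n_reducing = 1))
  topo <- build_topology(mixed)
  junction <- dplyr::filter(topo$bonds, type_i == "Os" | type_j == "Os")
  expect_equal(nrow(junction), 1)
  expect_equal(junction$req, 2.8)
  expect_error(build_topology(make_gag_helix(4)), "at least one CG bead")
})
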