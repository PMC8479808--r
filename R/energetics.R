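#' Electrostatics model specification
#'
#' @param kind `"coulomb"` for unscreened Coulomb electrostatics or
#'   `"debye"` for Debye-Hueckel screened Coulomb (each pair term damped
#'   by `exp(-kappa r)`).
#' @param dielectric Relative permittivity (1 for vacuum terms, 80 for
#'   aqueous linear-interaction-energy scoring).
#' @param ionic_strength Ionic strength in mol/L (debye kind; 0.15 M is
#'   the physiological value, giving a Debye length of ~7.85 A).
#' @param temperature Temperature, K (enters the Debye length through
#'   the solvent constants; 298.15 K water values are used as baseline).
#' @return An `es_model` object.
#' @export
electrostatics_model <- function(kind = c("coulomb", "debye"),
                                 dielectric = 1, ionic_strength = 0.15,
                                 temperature = 300) {
  kind <- match.arg(kind)
  stopifnot(dielectric > 0, ionic_strength >= 0)
  structure(list(kind = kind, dielectric = dielectric,
                 ionic_strength = ionic_strength,
                 temperature = temperature),
            class = "es_model")
}

#' @export
print.es_model <- function(x, ...) {
  scr <- if (x$kind == "debye")
    sprintf(", I = %g M (Debye length %.2f A)", x$ionic_strength,
            debye_length(x$ionic_strength)) else ""
  cat(sprintf("<es_model> %s, dielectric %g%s\n", x$kind, x$dielectric, scr))
  invisible(x)
}

es_kappa <- function(es) {
  if (es$kind != "debye") return(0)
  ld <- debye_length(es$ionic_strength)
  if (is.infinite(ld)) 0 else 1 / ld
}

energy_breakdown <- function(bond = 0, angle = 0, dihedral = 0,
                             lj = 0, coulomb = 0) {
  tibble(bond = bond, angle = angle, dihedral = dihedral,
         lj = lj, coulomb = coulomb,
         total = bond + angle + dihedral + lj + coulomb)
}

#' Bonded energy of the coarse-grained terms of a complex
#'
#' Evaluates the AMBER functional forms over a topology produced by
#' [build_topology()]: `E_bond = sum RK (r - REQ)^2`,
#' `E_angle = sum TK (theta - TEQ)^2` (theta in radians),
#' `E_dihedral = sum (PK / IDIVF) (1 + cos(PN phi - phase))`. Only
#' CG-involving terms are covered; all-atom internal energies belong to
#' the standard carbohydrate force field and are out of scope here.
#'
#' @param topology A `cg_topology` from [build_topology()].
#' @return A one-row tibble energy breakdown (kcal/mol): `bond`,
#'   `angle`, `dihedral`, `lj`, `coulomb`, `total` (nonbonded fields 0).
#' @export
bonded_energy <- function(topology) {
  stopifnot(inherits(topology, "cg_topology"))
  st <- topology$sites
  pos <- function(id) unlist(st[st$site_id == id, c("x", "y", "z")])
  e_bond <- if (nrow(topology$bonds)) sum(purrr::pmap_dbl(topology$bonds,
    function(i, j, rk, req, ...) {
      r <- vnorm(pos(i) - pos(j))
      rk * (r - req)^2
    })) else 0
  e_angle <- if (nrow(topology$angles)) sum(purrr::pmap_dbl(topology$angles,
    function(i, j, k, tk, teq, ...) {
      th <- vec_angle_deg(pos(i), pos(j), pos(k)) * pi / 180
      tk * (th - teq * pi / 180)^2
    })) else 0
  e_dih <- if (nrow(topology$dihedrals)) sum(purrr::pmap_dbl(topology$dihedrals,
    function(i, j, k, l, idivf, pk, phase, pn, ...) {
      phi <- vec_dihedral_deg(pos(i), pos(j), pos(k), pos(l)) * pi / 180
      (pk / idivf) * (1 + cos(pn * phi - phase * pi / 180))
    })) else 0
  energy_breakdown(bond = e_bond, angle = e_angle, dihedral = e_dih)
}

## atom type used for nonbonded parameter lookup: beads are Z1, everything
## else has no LJ entry in this parameter set (GLYCAM-owned) -> eps 0.
atom_lj_type <- function(names) ifelse(names == "Z1", "Z1", NA_character_)

#' Intermolecular nonbonded energy between two atom sets
#'
#' 12-6 Lennard-Jones with Rmin-based Lorentz-like mixing
#' (`Rmin_ij = RvdW_i + RvdW_j`, `eps_ij = sqrt(eps_i eps_j)`) plus
#' (screened) Coulomb `332.0636 q_i q_j / (eps_r r)`; the `debye` model
#' multiplies each Coulomb term by `exp(-kappa r)`. Atoms without a
#' Lennard-Jones entry in `ff` (all non-bead atoms in this parameter
#' set) contribute no vdW term. All pairs are summed unless a `cutoff`
#' is given.
#'
#' @param atoms_a,atoms_b Atom tibbles with columns `name`, `x`, `y`,
#'   `z` and `charge` (NA charge = 0).
#' @param ff A [pseudoatom_forcefield()] supplying LJ parameters.
#' @param es An [electrostatics_model()].
#' @param cutoff Pair-distance cutoff in Angstrom, or `NULL` for none.
#' @return A one-row energy-breakdown tibble (bonded fields 0).
#' @export
pair_energy <- function(atoms_a, atoms_b, ff = default_forcefield(),
                        es = electrostatics_model("coulomb"),
                        cutoff = NULL) {
  if (!nrow(atoms_a) || !nrow(atoms_b)) return(energy_breakdown())
  ax <- as.matrix(atoms_a[, c("x", "y", "z")])
  bx <- as.matrix(atoms_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rep(1, nrow(bx))) +
    outer(rep(1, nrow(ax)), rowSums(bx^2)) - 2 * ax %*% t(bx)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 1e-9))
    abort("zero distance between distinct atoms: nonbonded energy singular")
  mask <- if (is.null(cutoff)) r >= 0 else r <= cutoff
  ## LJ
  lj_tbl <- ff$lj
  lj_of <- function(names) {
    ty <- atom_lj_type(names)
    m <- match(ty, lj_tbl$type)
    list(rvdw = lj_tbl$rvdw[m], edep = lj_tbl$edep[m])
  }
  la <- lj_of(atoms_a$name); lb <- lj_of(atoms_b$name)
  eps <- sqrt(outer(ifelse(is.na(la$edep), 0, la$edep),
                    ifelse(is.na(lb$edep), 0, lb$edep)))
  rmin <- outer(ifelse(is.na(la$rvdw), 0, la$rvdw),
                ifelse(is.na(lb$rvdw), 0, lb$rvdw), `+`)
  lj_terms <- ifelse(eps > 0 & mask,
                     eps * ((rmin / r)^12 - 2 * (rmin / r)^6), 0)
  ## Coulomb
  qa <- ifelse(is.na(atoms_a$charge), 0, atoms_a$charge)
  qb <- ifelse(is.na(atoms_b$charge), 0, atoms_b$charge)
  qq <- outer(qa, qb)
  scr <- if (es$kind == "debye") exp(-es_kappa(es) * r) else 1
  coul_terms <- ifelse(mask & qq != 0,
                       COULOMB_KCAL * qq * scr / (es$dielectric * r), 0)
  energy_breakdown(lj = sum(lj_terms), coulomb = sum(coul_terms))
}

## GAG atoms with per-atom charges for nonbonded sums: beads carry their
## residue unit charge; all-atom residues spread the unit charge over
## their atoms (electrostatic monopole preserved).
gag_charged_atoms <- function(x) {
  x$gag |>
    group_by(.data$resno) |>
    mutate(charge = ifelse(is.na(.data$charge),
                           .data$res_charge[1] / n(), .data$charge)) |>
    ungroup()
}

#' Linear interaction energy of a receptor-GAG complex
#'
#' `alpha * E_vdW + beta * E_elec` over all receptor-GAG atom pairs with
#' no cutoff, the electrostatic part at the given dielectric. With the
#' noncalibrated weights `alpha = beta = 1` and dielectric 80 this is
#' the plain interaction-energy score used to cross-check MM/GBSA
#' trends. Bead charges are the residue unit charges; all-atom GAG
#' residues spread their unit charge uniformly over their atoms unless
#' per-atom charges are present.
#'
#' @param x A [gag_complex()] with a non-empty receptor.
#' @param ff A [pseudoatom_forcefield()].
#' @param alpha,beta vdW and electrostatic weights.
#' @param dielectric Relative permittivity for the electrostatic part.
#' @return Interaction energy, kcal/mol.
#' @export
lie_energy <- function(x, ff = default_forcefield(),
                       alpha = 1, beta = 1, dielectric = 80) {
  stopifnot(inherits(x, "gag_complex"))
  if (!nrow(x$receptor)) abort("lie_energy needs a non-empty receptor")
  if (alpha == 0 && beta == 0) return(0)
  gag_atoms <- gag_charged_atoms(x)
  e <- pair_energy(x$receptor, gag_atoms, ff,
                   es = electrostatics_model("coulomb",
                                             dielectric = dielectric))
  alpha * e$lj + beta * e$coulomb
}
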