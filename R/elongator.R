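#' Elongation specification
#'
#' @param n_nonreducing Number of CG beads to prepend at the
#'   non-reducing end.
#' @param n_reducing Number of CG beads to append at the reducing end.
#' @param bead_charge Charge per added bead, elementary charges
#'   (default -2, one fully sulfated heparin unit; use the -1 per
#'   sulfate/carboxyl group rule for other GAGs).
#' @param clash_distance Minimum allowed bead-receptor distance,
#'   Angstrom.
#' @return An `elongation_spec` object.
#' @export
elongation_spec <- function(n_nonreducing = 0, n_reducing = 0,
                            bead_charge = -2, clash_distance = 4.0) {
  stopifnot(n_nonreducing >= 0, n_reducing >= 0, clash_distance >= 0)
  structure(list(n_nonreducing = as.integer(n_nonreducing),
                 n_reducing = as.integer(n_reducing),
                 bead_charge = bead_charge,
                 clash_distance = clash_distance),
            class = "elongation_spec")
}

#' Elongate a docked GAG with coarse-grained beads
#'
#' Appends Z1 pseudoatoms to either terminus of the GAG chain of a
#' docked complex, leaving every pre-existing atom untouched. The
#' placement is deterministic extended geometry: each bead is placed at
#' the equilibrium bond length of the junction it forms (2.8 A from the
#' glycosidic oxygen of an all-atom terminal residue when present,
#' otherwise 5.2 A from the terminal residue centroid), at the
#' equilibrium internal angle of 160 degrees when two upstream reference
#' points exist, in trans (180 degree) dihedral continuation. The chain
#' propagates along the unit vector from the penultimate to the terminal
#' residue centroid. If a candidate bead falls within `clash_distance`
#' of any receptor atom it is rotated about the previous bond axis in
#' 15 degree steps until clash-free (logged); if a full turn finds no
#' clash-free pose, an error is raised.
#'
#' Downstream energy minimization / MD is expected to relax the placed
#' geometry; this function only provides a sensible clash-aware start.
#'
#' @param x A [gag_complex()] with >= 2 GAG residues.
#' @param ff A [pseudoatom_forcefield()] supplying the equilibrium
#'   geometry.
#' @param spec An [elongation_spec()].
#' @return A new [gag_complex()]; added beads have atom name `Z1`,
#'   residue name `ZCG` and the requested bead charge. Residue numbers are
#'   shifted to stay positive when beads are prepended; the shift is
#'   recorded in attribute `resno_offset`.
#' @examples
#' dp6 <- make_gag_helix(6)
#' dp16 <- elongate(dp6, spec = elongation_spec(n_reducing = 10))
#' glance(dp16)
#' @export
elongate <- function(x, ff = default_forcefield(),
                     spec = elongation_spec()) {
  stopifnot(inherits(x, "gag_complex"), inherits(spec, "elongation_spec"))
  if (spec$n_nonreducing == 0 && spec$n_reducing == 0) return(x)
  res <- gag_residues(x)
  if (nrow(res) < 2)
    abort("cannot elongate a single-residue chain: no direction defined")
  gag <- x$gag
  next_serial <- max(c(x$receptor$serial, gag$serial), 0) + 1
  add_end <- function(gag, end, n_beads) {
    if (n_beads == 0) return(gag)
    res <- gag_residues(gag_complex(x$receptor, gag, x$chain_id))
    ord <- if (end == "reducing") seq_len(nrow(res)) else rev(seq_len(nrow(res)))
    term <- res[ord[length(ord)], ]
    penult <- res[ord[length(ord) - 1], ]
    ## reference-point chain used for internal-coordinate placement
    tc <- c(term$x, term$y, term$z)
    pc <- c(penult$x, penult$y, penult$z)
    refs <- list(pc, tc)
    first_bond <- if (term$representation == "CG")
      lookup_bond(ff, "Z1", "Z1")$req else lookup_bond(ff, "Z1", "Cg")$req
    if (term$representation == "AA" && term$has_glycosidic_o) {
      oat <- gag |> filter(.data$resno == term$resno,
                           .data$name == GLYCOSIDIC_O)
      opos <- c(oat$x[1], oat$y[1], oat$z[1])
      ## bond through the glycosidic oxygen only when it points outward
      ## along the propagation direction (it belongs to this terminus)
      if (sum((opos - tc) * (tc - pc)) > 0) {
        refs <- c(refs, list(opos))
        first_bond <- lookup_bond(ff, "Os", "Z1")$req
      }
    }
    zz_req <- lookup_bond(ff, "Z1", "Z1")$req
    teq <- lookup_angle(ff, "Z1", "Z1", "Z1")$teq
    step <- if (end == "reducing") 1L else -1L
    new_resno <- term$resno
    beads <- list()
    for (b in seq_len(n_beads)) {
      nr <- length(refs)
      bond <- if (b == 1) first_bond else zz_req
      c_ref <- refs[[nr]]
      b_ref <- refs[[nr - 1]]
      a_ref <- if (nr >= 3) refs[[nr - 2]] else c_ref + (c_ref - b_ref) + perp_vec(unit_vec(c_ref - b_ref))
      pos <- NULL
      for (rot in seq(0, 345, by = 15)) {
        cand <- place_internal(a_ref, b_ref, c_ref, bond, teq, 180 + rot)
        if (!clashes(cand, x$receptor, spec$clash_distance)) {
          if (rot > 0)
            inform(sprintf("bead %d rotated %d degrees to avoid receptor clash", b, rot))
          pos <- cand
          break
        }
      }
      if (is.null(pos))
        abort(sprintf("no clash-free placement for bead %d within a full 360 degree scan (clash distance %.1f A)",
                      b, spec$clash_distance))
      new_resno <- new_resno + step
      beads[[b]] <- tibble(
        serial = next_serial, name = "Z1", resname = "ZCG",
        chain = x$chain_id, resno = as.integer(new_resno),
        x = pos[1], y = pos[2], z = pos[3],
        element = "C", charge = spec$bead_charge,
        res_charge = spec$bead_charge
      )
      next_serial <<- next_serial + 1
      refs <- c(refs, list(pos))
    }
    bind_rows(gag, bind_rows(beads))
  }
  gag <- add_end(gag, "reducing", spec$n_reducing)
  gag <- add_end(gag, "nonreducing", spec$n_nonreducing)
  offset <- 0L
  if (min(gag$resno) < 1L) {
    offset <- 1L - min(gag$resno)
    gag$resno <- gag$resno + offset
  }
  out <- gag_complex(x$receptor, gag, x$chain_id)
  attr(out, "resno_offset") <- offset
  out
}

clashes <- function(pos, receptor, clash_distance) {
  if (!nrow(receptor) || clash_distance <= 0) return(FALSE)
  d2 <- (receptor$x - pos[1])^2 + (receptor$y - pos[2])^2 +
    (receptor$z - pos[3])^2
  any(d2 < clash_distance^2)
}

#' Replace weakly contributing GAG residues by coarse-grained beads
#'
#' Every all-atom GAG residue whose per-residue binding free energy is
#' less favorable than the threshold (`dg > threshold`, strict) is
#' replaced by a single Z1 bead at its ring centroid carrying the
#' residue's unit charge; residues contributing at or below the
#' threshold are kept atomistic. The default threshold of -0.5 kcal/mol
#' keeps the binding core in full detail while coarse-graining the
#' lateral parts. The operation is idempotent.
#'
#' @param x A [gag_complex()].
#' @param decomposition A [decomposition_table()] covering every AA GAG
#'   residue of `x`.
#' @param threshold Free-energy threshold, kcal/mol.
#' @return A new [gag_complex()].
#' @export
substitute_by_energy <- function(x, decomposition, threshold = -0.5) {
  stopifnot(inherits(x, "gag_complex"))
  decomposition <- decomposition_table(decomposition)
  res <- gag_residues(x)
  aa <- res |> filter(.data$representation == "AA")
  missing <- setdiff(aa$resno, decomposition$residue)
  if (length(missing))
    abort(sprintf("no decomposition entry for GAG residue(s): %s",
                  paste(missing, collapse = ", ")))
  dg <- setNames(decomposition$dg, decomposition$residue)
  to_replace <- aa$resno[dg[as.character(aa$resno)] > threshold]
  if (!length(to_replace)) return(x)
  keep <- x$gag |> filter(!.data$resno %in% to_replace)
  serial0 <- max(c(x$receptor$serial, x$gag$serial), 0)
  cid <- x$chain_id
  beads <- res |>
    filter(.data$resno %in% to_replace) |>
    mutate(serial = serial0 + row_number(),
           name = "Z1", resname = "ZCG", chain = cid,
           element = "C", charge = .data$res_charge) |>
    select("serial", "name", "resname", "chain", "resno",
           "x", "y", "z", "element", "charge", "res_charge")
  gag_complex(x$receptor, bind_rows(keep, beads), x$chain_id)
}

## site chain of a complex: for runs of CG beads plus the junction
## anchors of adjacent AA residues. Each AA residue adjacent to a bead
## contributes a ring-carbon anchor (type Cg, at its ring centroid) and,
## when present, its glycosidic oxygen (type Os).
topology_sites <- function(x) {
  res <- gag_residues(x)
  gag <- x$gag
  n <- nrow(res)
  is_cg <- res$representation == "CG"
  sites <- list()
  for (k in seq_len(n)) {
    r <- res[k, ]
    if (is_cg[k]) {
      sites[[length(sites) + 1]] <-
        tibble(type = "Z1", resno = r$resno, x = r$x, y = r$y, z = r$z)
      next
    }
    s <- tibble(type = "Cg", resno = r$resno, x = r$x, y = r$y, z = r$z)
    ## the glycosidic oxygen enters the site chain only at an AA/CG
    ## junction, on the side of its bonded bead
    if (r$has_glycosidic_o) {
      oat <- gag |> filter(.data$resno == r$resno,
                           .data$name == GLYCOSIDIC_O)
      opos <- c(oat$x[1], oat$y[1], oat$z[1])
      cenk <- c(r$x, r$y, r$z)
      towards <- function(j) {
        nb <- c(res$x[j], res$y[j], res$z[j])
        sum((opos - cenk) * (nb - cenk)) > 0
      }
      os <- tibble(type = "Os", resno = r$resno,
                   x = opos[1], y = opos[2], z = opos[3])
      if (k < n && is_cg[k + 1] && towards(k + 1)) {
        s <- bind_rows(s, os)
      } else if (k > 1 && is_cg[k - 1] && towards(k - 1)) {
        s <- bind_rows(os, s)
      }
    }
    sites[[length(sites) + 1]] <- s
  }
  bind_rows(sites) |> mutate(site_id = row_number())
}

#' Enumerate the coarse-grained bonded terms of a complex
#'
#' Walks the GAG chain (non-reducing to reducing) and lists every bond,
#' angle and dihedral that involves at least one Z1 bead, resolved
#' against the parameter tables. All-atom residues adjacent to beads
#' contribute their junction anchors: a ring-carbon site (`Cg`, at the
#' ring centroid) and the glycosidic oxygen (`Os`) when present.
#' Glycosidic linkages between coarse-grained units themselves carry no
#' explicit atoms (omitted by construction in this model); terms
#' internal to all-atom residues are owned by the standard carbohydrate
#' force field and excluded. Consecutive term tuples whose type pattern
#' matches no parameter raise an error naming the pattern, except
#' spectator tuples with no bead, which are skipped.
#'
#' @param x A [gag_complex()] containing at least one CG bead.
#' @param ff A [pseudoatom_forcefield()].
#' @return A `cg_topology`: list of tibbles `sites` (site_id, type,
#'   resno, coordinates), `bonds` (i, j + parameters), `angles`,
#'   `dihedrals`.
#' @examples
#' chain <- elongate(make_gag_helix(2, with_ring_atoms = FALSE),
#'                   spec = elongation_spec(n_reducing = 2))
#' topo <- build_topology(chain)
#' nrow(topo$bonds); nrow(topo$angles)
#' @export
build_topology <- function(x, ff = default_forcefield()) {
  stopifnot(inherits(x, "gag_complex"))
  res <- gag_residues(x)
  if (!any(res$representation == "CG"))
    abort("build_topology needs at least one CG bead in the chain")
  sites <- topology_sites(x)
  n <- nrow(sites)
  has_z1 <- function(idx) any(sites$type[idx] == "Z1")
  bonds <- list(); angles <- list(); dihedrals <- list()
  for (i in seq_len(n - 1)) {
    idx <- c(i, i + 1)
    if (!has_z1(idx)) next
    ty <- sites$type[idx]
    p <- lookup_bond(ff, ty[1], ty[2])
    if (is.null(p))
      abort(sprintf("no bond parameter for CG-involving pattern %s",
                    paste(ty, collapse = "-")))
    bonds[[length(bonds) + 1]] <-
      tibble(i = idx[1], j = idx[2], type_i = ty[1], type_j = ty[2],
             rk = p$rk, req = p$req)
  }
  for (i in seq_len(max(n - 2, 0))) {
    idx <- i:(i + 2)
    if (!has_z1(idx)) next
    ty <- sites$type[idx]
    p <- lookup_angle(ff, ty[1], ty[2], ty[3])
    if (is.null(p))
      abort(sprintf("no angle parameter for CG-involving pattern %s",
                    paste(ty, collapse = "-")))
    angles[[length(angles) + 1]] <-
      tibble(i = idx[1], j = idx[2], k = idx[3],
             pattern = paste(ty, collapse = "-"), tk = p$tk, teq = p$teq)
  }
  for (i in seq_len(max(n - 3, 0))) {
    idx <- i:(i + 3)
    if (!has_z1(idx)) next
    ty <- sites$type[idx]
    p <- lookup_dihedral(ff, ty[1], ty[2], ty[3], ty[4])
    if (is.null(p))
      abort(sprintf("no dihedral parameter for CG-involving pattern %s",
                    paste(ty, collapse = "-")))
    dihedrals[[length(dihedrals) + 1]] <-
      tibble(i = idx[1], j = idx[2], k = idx[3], l = idx[4],
             pattern = paste(ty, collapse = "-"),
             idivf = p$idivf, pk = p$pk, phase = p$phase, pn = p$pn)
  }
  structure(list(
    sites = sites,
    bonds = if (length(bonds)) bind_rows(bonds) else
      tibble(i = integer(), j = integer(), type_i = character(),
             type_j = character(), rk = double(), req = double()),
    angles = if (length(angles)) bind_rows(angles) else
      tibble(i = integer(), j = integer(), k = integer(),
             pattern = character(), tk = double(), teq = double()),
    dihedrals = if (length(dihedrals)) bind_rows(dihedrals) else
      tibble(i = integer(), j = integer(), k = integer(), l = integer(),
             pattern = character(), idivf = double(), pk = double(),
             phase = double(), pn = double())
  ), class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("<cg_topology> %d sites: %d bonds, %d angles, %d dihedrals\n",
              nrow(x$sites), nrow(x$bonds), nrow(x$angles),
              nrow(x$dihedrals)))
  invisible(x)
}
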