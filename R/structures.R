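#' Receptor-GAG complex container
#'
#' A `gag_complex` bundles a receptor (protein or peptide, all-atom) and
#' one glycosaminoglycan chain. The GAG chain is an ordered sequence of
#' residues running from the non-reducing to the reducing end (taken as
#' ascending residue number); each residue is represented either in full
#' atomistic detail (`AA`) or as a single coarse-grained bead (`CG`, atom
#' name `Z1`, residue name `ZCG`).
#'
#' Atom tables are tibbles with columns `serial`, `name`, `resname`,
#' `chain`, `resno`, `x`, `y`, `z`, `element`, `charge` (per-atom,
#' usually `NA`), and, for the GAG, `res_charge` (the unit charge of the
#' residue, elementary charges, <= 0).
#'
#' @param receptor Tibble of receptor atoms (may have zero rows for a
#'   ligand-only structure).
#' @param gag Tibble of GAG atoms.
#' @param chain_id Chain identifier of the GAG chain.
#' @return A `gag_complex` object.
#' @export
gag_complex <- function(receptor, gag, chain_id = "A") {
  stopifnot(is.data.frame(receptor), is.data.frame(gag))
  if (!nrow(gag)) abort("GAG chain must contain at least one residue")
  gag <- as_tibble(gag) |> arrange(.data$resno, .data$serial)
  if (!"res_charge" %in% names(gag)) gag$res_charge <- -2
  x <- structure(list(receptor = as_tibble(receptor), gag = gag,
                      chain_id = chain_id),
                 class = "gag_complex")
  validate_gag_complex(x)
  x
}

validate_gag_complex <- function(x) {
  cen <- residue_centroids(x)
  if (nrow(cen) > 1) {
    d <- sqrt(diff(cen$x)^2 + diff(cen$y)^2 + diff(cen$z)^2)
    if (any(d > 8))
      warn(sprintf("consecutive GAG residues more than 8 A apart (max %.1f A): chain may be discontinuous",
                   max(d)))
  }
  bead_rows <- x$gag |> filter(.data$name == "Z1")
  multi <- bead_rows |> dplyr::count(.data$resno) |> filter(.data$n > 1)
  if (nrow(multi)) abort("a CG residue must contain exactly one Z1 bead")
  invisible(x)
}

#' @export
print.gag_complex <- function(x, ...) {
  res <- gag_residues(x)
  cat(sprintf("<gag_complex> chain %s: %d GAG residues (%d AA, %d CG), %d receptor atoms\n",
              x$chain_id, nrow(res), sum(res$representation == "AA"),
              sum(res$representation == "CG"), nrow(x$receptor)))
  invisible(x)
}

PYRANOSE_RING <- c("C1", "C2", "C3", "C4", "C5", "O5")
GLYCOSIDIC_O <- "O1"

#' Per-residue summary of the GAG chain
#'
#' @param x A [gag_complex()].
#' @return A tibble with one row per GAG residue in chain order:
#'   `resno`, `representation` ("AA" or "CG"), `n_atoms`, centroid
#'   coordinates `x`, `y`, `z` (ring-atom centroid for AA residues when
#'   the pyranose template C1-C5/O5 is present, all-atom centroid
#'   otherwise, bead position for CG), `res_charge`, and
#'   `has_glycosidic_o`.
#' @export
gag_residues <- function(x) {
  stopifnot(inherits(x, "gag_complex"))
  x$gag |>
    group_by(.data$resno) |>
    summarise(
      representation = if (any(.data$name == "Z1")) "CG" else "AA",
      n_atoms = n(),
      x = centroid_coord(.data$name, .data$x),
      y = centroid_coord(.data$name, .data$y),
      z = centroid_coord(.data$name, .data$z),
      res_charge = .data$res_charge[1],
      has_glycosidic_o = any(.data$name == GLYCOSIDIC_O),
      .groups = "drop"
    ) |>
    arrange(.data$resno)
}

centroid_coord <- function(names, coord) {
  if (any(names == "Z1")) return(coord[names == "Z1"][1])
  ring <- names %in% PYRANOSE_RING
  if (sum(ring) >= 3) mean(coord[ring]) else mean(coord)
}

#' Residue centroids of the GAG chain
#'
#' @param x A [gag_complex()].
#' @return Tibble `resno`, `x`, `y`, `z` in chain order (for CG residues
#'   the bead position itself).
#' @export
residue_centroids <- function(x) {
  stopifnot(inherits(x, "gag_complex"))
  gag_residues(x) |> select("resno", "x", "y", "z")
}

#' Total charge of the GAG chain
#'
#' @param x A [gag_complex()].
#' @return Sum of per-residue unit charges, elementary charges.
#' @export
gag_total_charge <- function(x) sum(gag_residues(x)$res_charge)

#' Tidy method for complexes
#'
#' @param x A [gag_complex()].
#' @param ... Unused.
#' @return [tidy.gag_complex()]: the per-residue table of
#'   [gag_residues()]. [glance.gag_complex()]: a one-row summary.
#' @export
tidy.gag_complex <- function(x, ...) gag_residues(x)

#' @rdname tidy.gag_complex
#' @export
glance.gag_complex <- function(x, ...) {
  res <- gag_residues(x)
  tibble(chain_id = x$chain_id, n_residues = nrow(res),
         n_aa = sum(res$representation == "AA"),
         n_cg = sum(res$representation == "CG"),
         n_receptor_atoms = nrow(x$receptor),
         gag_charge = sum(res$res_charge))
}

bio3d_to_tibble <- function(atom) {
  tibble(
    serial = as.integer(atom$eleno),
    name = trimws(atom$elety),
    resname = trimws(atom$resid),
    chain = ifelse(is.na(atom$chain), " ", atom$chain),
    resno = as.integer(atom$resno),
    x = atom$x, y = atom$y, z = atom$z,
    element = trimws(ifelse(is.na(atom$elesy) | atom$elesy == "",
                            substr(trimws(atom$elety), 1, 1), atom$elesy)),
    charge = rep(NA_real_, nrow(atom))
  )
}

#' Read a receptor-GAG complex from a PDB file
#'
#' All chains except `gag_chain_id` become the receptor. Atoms named
#' `Z1` are classified as coarse-grained beads; every other residue on
#' the GAG chain is taken as an all-atom monosaccharide.
#'
#' @param path PDB file path.
#' @param gag_chain_id Chain identifier of the GAG ligand.
#' @param unit_charge Charge assigned to each GAG residue (single value
#'   or one per residue), elementary charges. Default -2 per
#'   monosaccharide, the fully sulfated heparin value.
#' @return A [gag_complex()].
#' @export
read_complex <- function(path, gag_chain_id, unit_charge = -2) {
  if (!file.exists(path)) abort(sprintf("PDB file not found: %s", path))
  pdb <- suppressWarnings(bio3d::read.pdb(path))
  atoms <- bio3d_to_tibble(pdb$atom)
  if (!any(atoms$chain == gag_chain_id))
    abort(sprintf("chain '%s' not present in %s", gag_chain_id, path))
  gag <- atoms |> filter(.data$chain == gag_chain_id)
  if (!nrow(gag)) abort("GAG chain contains no atoms")
  rec <- atoms |> filter(.data$chain != gag_chain_id)
  n_res <- length(unique(gag$resno))
  uc <- if (length(unit_charge) == 1) rep(unit_charge, n_res) else unit_charge
  if (length(uc) != n_res)
    abort("unit_charge must be length 1 or one per GAG residue")
  charge_map <- setNames(uc, sort(unique(gag$resno)))
  gag$res_charge <- unname(charge_map[as.character(gag$resno)])
  gag_complex(rec, gag, chain_id = gag_chain_id)
}

#' Write a receptor-GAG complex as a PDB file
#'
#' Coarse-grained beads are emitted as HETATM records with residue name
#' `ZCG` and a placeholder element `C`; CONECT records are appended for
#' consecutive bead pairs and for the all-atom/coarse-grained junction.
#'
#' @param x A [gag_complex()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_complex <- function(x, path) {
  stopifnot(inherits(x, "gag_complex"))
  all_atoms <- bind_rows(
    x$receptor |> mutate(is_bead = FALSE),
    x$gag |> mutate(is_bead = .data$name == "Z1") |>
      select(-dplyr::any_of("res_charge"))
  )
  if (nrow(all_atoms) > 99999) abort("more than 99999 atoms cannot be written to PDB")
  all_atoms$serial <- seq_len(nrow(all_atoms))
  xyz <- as.vector(t(as.matrix(all_atoms[, c("x", "y", "z")])))
  suppressWarnings(bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = ifelse(all_atoms$is_bead, "HETATM", "ATOM"),
    resno = all_atoms$resno,
    resid = ifelse(all_atoms$is_bead, "ZCG", all_atoms$resname),
    eleno = all_atoms$serial,
    elety = all_atoms$name,
    chain = all_atoms$chain,
    elesy = ifelse(all_atoms$is_bead, "C", all_atoms$element)
  ))
  conect <- bead_conect_records(x, all_atoms)
  if (length(conect)) {
    lines <- readLines(path)
    end_at <- grepl("^END", lines)
    lines <- c(lines[!end_at], conect, "END")
    writeLines(lines, path)
  }
  invisible(path)
}

bead_conect_records <- function(x, all_atoms) {
  cid <- x$chain_id
  gag_atoms <- all_atoms |> filter(.data$chain == cid)
  res <- gag_residues(x)
  out <- character()
  for (k in seq_len(nrow(res) - 1)) {
    r1 <- res[k, ]; r2 <- res[k + 1, ]
    if (r1$representation == "CG" || r2$representation == "CG") {
      pick <- function(r) {
        at <- gag_atoms |> filter(.data$resno == r$resno)
        if (r$representation == "CG") at$serial[at$name == "Z1"][1]
        else if (any(at$name == GLYCOSIDIC_O)) at$serial[at$name == GLYCOSIDIC_O][1]
        else at$serial[1]
      }
      out <- c(out, sprintf("CONECT%5d%5d", pick(r1), pick(r2)))
    }
  }
  out
}
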