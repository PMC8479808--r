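#' Single-pseudoatom coarse-grained force field for GAG elongation
#'
#' A `pseudoatom_ff` object holds the bonded and nonbonded parameters of
#' the Z1 coarse-grained bead model, in which one pseudoatom replaces a
#' whole monosaccharide unit of a glycosaminoglycan. Glycosidic linkages
#' between coarse-grained units are not represented explicitly; the model
#' exists to carry the electrostatics of chain parts that make no direct
#' contact with the protein receptor.
#'
#' The parameter tables use AMBER conventions throughout:
#' * bonds: `E = RK * (r - REQ)^2`, RK in kcal/mol/A^2, REQ in Angstrom;
#' * angles: `E = TK * (theta - TEQ)^2`, TK in kcal/mol/rad^2, TEQ in degrees;
#' * dihedrals: `E = (PK / IDIVF) * (1 + cos(PN * phi - phase))`;
#' * Lennard-Jones: Rmin/2-style radius `RvdW` (A) and well depth `EDEP`
#'   (kcal/mol), combined as `Rmin_ij = RvdW_i + RvdW_j`,
#'   `eps_ij = sqrt(EDEP_i * EDEP_j)`.
#'
#' Atom types `Cg`, `Os`, `H1`, `H2` and `Ng` appearing in bonded terms
#' are external GLYCAM-owned types at the all-atom/coarse-grained
#' junction; only `Z1` carries Lennard-Jones parameters here.
#'
#' @param bonds,angles,dihedrals,lj Tibbles with the columns documented
#'   in [default_forcefield()].
#' @param default_bead_charge Charge assigned to a bead when nothing more
#'   specific is known, elementary charges. The default -2 corresponds to
#'   a fully sulfated heparin unit (one sulfate + one carboxyl or two
#'   sulfates, -1 per group).
#' @return A `pseudoatom_ff` object.
#' @seealso [default_forcefield()], [write_frcmod()], [read_frcmod()]
#' @export
pseudoatom_forcefield <- function(bonds = empty_bonds(),
                                  angles = empty_angles(),
                                  dihedrals = empty_dihedrals(),
                                  lj = empty_lj(),
                                  default_bead_charge = -2) {
  ff <- structure(
    list(
      bonds = as_tibble(bonds),
      angles = as_tibble(angles),
      dihedrals = as_tibble(dihedrals),
      lj = as_tibble(lj),
      default_bead_charge = default_bead_charge
    ),
    class = "pseudoatom_ff"
  )
  validate_forcefield(ff)
  ff
}

empty_bonds <- function() {
  tibble(type1 = character(), type2 = character(),
         rk = double(), req = double())
}
empty_angles <- function() {
  tibble(type1 = character(), type2 = character(), type3 = character(),
         tk = double(), teq = double())
}
empty_dihedrals <- function() {
  tibble(type1 = character(), type2 = character(), type3 = character(),
         type4 = character(), idivf = double(), pk = double(),
         phase = double(), pn = double())
}
empty_lj <- function() {
  tibble(type = character(), mass = double(),
         rvdw = double(), edep = double())
}

validate_forcefield <- function(ff) {
  b <- ff$bonds; a <- ff$angles; d <- ff$dihedrals; l <- ff$lj
  if (nrow(b) && any(b$rk <= 0 | b$req <= 0))
    abort("bond parameters must have RK > 0 and REQ > 0")
  if (nrow(a) && any(a$tk <= 0 | a$teq <= 0 | a$teq > 180))
    abort("angle parameters must have TK > 0 and 0 < TEQ <= 180")
  if (nrow(d) && any(d$idivf < 1))
    abort("dihedral IDIVF must be >= 1")
  if (nrow(l) && any(!is.na(l$mass) & l$mass <= 0))
    abort("atomic masses must be positive")
  invisible(ff)
}

#' The shipped Z1 bead parameter set
#'
#' Returns the complete published parameterization of the Z1 pseudoatom:
#' 3 bond terms, 7 angle terms, 15 dihedral terms and one Lennard-Jones
#' entry. The bonded terms were derived from all-atom molecular dynamics
#' of heparin by Boltzmann inversion (see [fit_harmonic()] and
#' [fit_dihedral()] for the procedure); the Lennard-Jones radius and well
#' depth are the doubled pyranose-ring values of an earlier multi-bead
#' model, and the bead mass (225 au) matches a sulfated monosaccharide
#' unit.
#'
#' Negative `PK` entries are kept verbatim as published even though AMBER
#' more conventionally encodes the same term with a 180 degree phase.
#'
#' @return A [pseudoatom_forcefield()] object. Repeated calls return
#'   identical values.
#' @examples
#' ff <- default_forcefield()
#' ff$bonds        # Z1-Z1 bond: RK = 120 kcal/mol/A^2, REQ = 5.2 A
#' ff$lj           # Z1 bead: mass 225, RvdW 4 A, EDEP 3.4 kcal/mol
#' @export
default_forcefield <- function() {
  bonds <- tibble(
    type1 = c("Z1", "Z1", "Os"),
    type2 = c("Z1", "Cg", "Z1"),
    rk  = c(120, 120, 120),
    req = c(5.2, 5.2, 2.8)
  )
  angles <- tibble(
    type1 = c("Z1", "Z1", "Z1", "Z1", "Z1", "Cg", "Os"),
    type2 = c("Z1", "Z1", "Cg", "Cg", "Cg", "Os", "Z1"),
    type3 = c("Z1", "Cg", "H2", "Cg", "Os", "Z1", "Z1"),
    tk  = c(100, 100, 70, 70, 60, 100, 100),
    teq = c(160, 160, 108.5, 108.5, 110, 160, 160)
  )
  dihedrals <- tibble(
    type1 = c("Z1", "Z1", "Z1", "Z1", "Z1", "Z1", "Z1", "Z1",
              "Z1", "Z1", "Cg", "Cg", "H1", "Z1", "Os"),
    type2 = c("Z1", "Z1", "Z1", "Cg", "Cg", "Z1", "Z1", "Cg",
              "Cg", "Cg", "Cg", "Os", "Cg", "Cg", "Z1"),
    type3 = c("Z1", "Z1", "Cg", "Cg", "Cg", "Cg", "Cg", "Cg",
              "Cg", "Os", "Os", "Z1", "Os", "Cg", "Z1"),
    type4 = c("Z1", "Cg", "Cg", "H1", "H2", "H2", "Os", "Ng",
              "Cg", "Cg", "Z1", "Z1", "Z1", "Os", "Z1"),
    idivf = rep(1, 15),
    pk    = c(1, 1, 0.16, 0.16, 0.16, 0.16, 0.16, -1.3,
              -0.27, -0.27, 0.16, 0.16, 0.27, 0.16, 0.16),
    phase = rep(0, 15),
    pn    = c(1, 1, 3, 3, 3, 3, 3, 1, 1, 1, 3, 3, 3, 3, 3)
  )
  lj <- tibble(type = "Z1", mass = 225, rvdw = 4, edep = 3.4)
  pseudoatom_forcefield(bonds, angles, dihedrals, lj,
                        default_bead_charge = -2)
}

#' @export
print.pseudoatom_ff <- function(x, ...) {
  cat("<pseudoatom_ff> Z1 coarse-grained parameter set\n")
  cat(sprintf("  %d bond, %d angle, %d dihedral, %d LJ terms; bead charge %+g e\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals), nrow(x$lj),
              x$default_bead_charge))
  invisible(x)
}

#' @export
format.pseudoatom_ff <- function(x, ...) {
  sprintf("<pseudoatom_ff: %d/%d/%d/%d terms>",
          nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals), nrow(x$lj))
}

#' Tidy a force field into one long parameter table
#'
#' @param x A `pseudoatom_ff`.
#' @param ... Unused.
#' @return A tibble with one row per parameter record: `term` (bond /
#'   angle / dihedral / lj), `types` (hyphen-joined type names) and the
#'   numeric fields relevant to each term kind (others `NA`).
#' @export
tidy.pseudoatom_ff <- function(x, ...) {
  bind_rows(
    x$bonds |> mutate(term = "bond",
                      types = paste(.data$type1, .data$type2, sep = "-")) |>
      select("term", "types", "rk", "req"),
    x$angles |> mutate(term = "angle",
                       types = paste(.data$type1, .data$type2, .data$type3,
                                     sep = "-")) |>
      select("term", "types", "tk", "teq"),
    x$dihedrals |> mutate(term = "dihedral",
                          types = paste(.data$type1, .data$type2, .data$type3,
                                        .data$type4, sep = "-")) |>
      select("term", "types", "idivf", "pk", "phase", "pn"),
    x$lj |> mutate(term = "lj", types = .data$type) |>
      select("term", "types", "mass", "rvdw", "edep")
  )
}

#' @rdname tidy.pseudoatom_ff
#' @export
glance.pseudoatom_ff <- function(x, ...) {
  tibble(n_bonds = nrow(x$bonds), n_angles = nrow(x$angles),
         n_dihedrals = nrow(x$dihedrals), n_lj = nrow(x$lj),
         default_bead_charge = x$default_bead_charge)
}

## ---- parameter lookup ---------------------------------------------------

## Bond pairs are order-normalized lexicographically; dihedrals are looked
## up in both orientations (AMBER matching semantics). Case-sensitive.
lookup_bond <- function(ff, t1, t2) {
  key <- sort(c(t1, t2))
  hit <- ff$bonds |>
    filter(purrr::map2_lgl(.data$type1, .data$type2,
                           ~ identical(sort(c(.x, .y)), key)))
  if (!nrow(hit)) return(NULL)
  hit[1, ]
}

lookup_angle <- function(ff, t1, t2, t3) {
  hit <- ff$angles |>
    filter((.data$type1 == t1 & .data$type2 == t2 & .data$type3 == t3) |
           (.data$type1 == t3 & .data$type2 == t2 & .data$type3 == t1))
  if (!nrow(hit)) return(NULL)
  hit[1, ]
}

lookup_dihedral <- function(ff, t1, t2, t3, t4) {
  hit <- ff$dihedrals |>
    filter((.data$type1 == t1 & .data$type2 == t2 &
            .data$type3 == t3 & .data$type4 == t4) |
           (.data$type1 == t4 & .data$type2 == t3 &
            .data$type3 == t2 & .data$type4 == t1))
  if (!nrow(hit)) return(NULL)
  hit[1, ]
}

lookup_lj <- function(ff, type) {
  hit <- ff$lj |> filter(.data$type == !!type)
  if (!nrow(hit)) return(NULL)
  hit[1, ]
}

## ---- frcmod I/O ---------------------------------------------------------

fmt_type <- function(x) {
  if (any(nchar(x) > 2))
    abort(sprintf("atom-type name longer than 2 characters: %s",
                  paste(x[nchar(x) > 2], collapse = ", ")))
  sprintf("%-2s", x)
}

fmt_num <- function(x) {
  ## fixed point, >= 1 decimal, trailing zeros trimmed to keep files legible
  out <- sprintf("%.6f", x)
  out <- sub("0+$", "", out)
  sub("\\.$", ".0", out)
}

#' Write a coarse-grained parameter set as an AMBER frcmod file
#'
#' Emits the MASS / BOND / ANGLE / DIHE / NONBON sections of the AMBER
#' parameter-modification dialect, with type names padded to two
#' characters and hyphen-joined. Negative barrier heights are written
#' verbatim (with a note to the console) rather than being re-expressed
#' through a 180 degree phase.
#'
#' @param ff A [pseudoatom_forcefield()].
#' @param path Destination file, or `NULL` to return the text invisibly
#'   without writing.
#' @param title First (comment) line of the file.
#' @return The frcmod text, invisibly, as a character vector of lines.
#' @examples
#' txt <- write_frcmod(default_forcefield(), NULL)
#' head(txt)
#' @export
write_frcmod <- function(ff, path = NULL,
                         title = "Z1 coarse-grained pseudoatom parameters") {
  stopifnot(inherits(ff, "pseudoatom_ff"))
  if (nrow(ff$dihedrals) && any(ff$dihedrals$pk < 0))
    inform("note: negative PK dihedral terms written verbatim (no phase-180 rewrite)")
  lines <- title
  mass_rows <- ff$lj |> filter(!is.na(.data$mass))
  lines <- c(lines, "MASS",
             sprintf("%s %s", fmt_type(mass_rows$type), fmt_num(mass_rows$mass)),
             "")
  lines <- c(lines, "BOND",
             sprintf("%s-%s  %s  %s",
                     fmt_type(ff$bonds$type1), fmt_type(ff$bonds$type2),
                     fmt_num(ff$bonds$rk), fmt_num(ff$bonds$req)),
             "")
  lines <- c(lines, "ANGLE",
             sprintf("%s-%s-%s  %s  %s",
                     fmt_type(ff$angles$type1), fmt_type(ff$angles$type2),
                     fmt_type(ff$angles$type3),
                     fmt_num(ff$angles$tk), fmt_num(ff$angles$teq)),
             "")
  lines <- c(lines, "DIHE",
             sprintf("%s-%s-%s-%s  %d  %s  %s  %s",
                     fmt_type(ff$dihedrals$type1), fmt_type(ff$dihedrals$type2),
                     fmt_type(ff$dihedrals$type3), fmt_type(ff$dihedrals$type4),
                     as.integer(ff$dihedrals$idivf), fmt_num(ff$dihedrals$pk),
                     fmt_num(ff$dihedrals$phase), fmt_num(ff$dihedrals$pn)),
             "")
  nb_rows <- ff$lj |> filter(!is.na(.data$rvdw))
  lines <- c(lines, "NONBON",
             sprintf("  %s  %s  %s", fmt_type(nb_rows$type),
                     fmt_num(nb_rows$rvdw), fmt_num(nb_rows$edep)),
             "")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

parse_nums <- function(fields, lineno) {
  vals <- suppressWarnings(as.numeric(fields))
  if (any(is.na(vals)))
    abort(sprintf("frcmod parse error at line %d: malformed numeric field '%s'",
                  lineno, fields[which(is.na(vals))[1]]))
  vals
}

split_types <- function(token) trimws(strsplit(token, "-", fixed = TRUE)[[1]])

#' Read an AMBER frcmod file into a coarse-grained parameter set
#'
#' Parses the MASS, BOND, ANGLE, DIHE and NONBON sections; unknown
#' sections are skipped with a warning. MASS and NONBON records for the
#' same atom type are merged into one Lennard-Jones entry (missing halves
#' stay `NA`).
#'
#' @param path Path to an frcmod file, or a character vector of lines.
#' @param default_bead_charge Passed through to [pseudoatom_forcefield()].
#' @return A [pseudoatom_forcefield()].
#' @export
read_frcmod <- function(path, default_bead_charge = -2) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  known <- c("MASS", "BOND", "ANGL", "DIHE", "NONB")
  section <- NA_character_
  bonds <- list(); angles <- list(); dihedrals <- list()
  mass <- list(); nonbon <- list()
  for (i in seq_along(lines)) {
    if (i == 1) next  # title line
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) { section <- NA_character_; next }
    tok <- toupper(substr(trimws(ln), 1, 4))
    if (tok %in% known && length(strsplit(trimws(ln), "\\s+")[[1]]) == 1) {
      section <- tok
      next
    }
    if (is.na(section)) {
      if (grepl("^[A-Z]+$", trimws(ln)))
        warn(sprintf("frcmod: ignoring unknown section '%s'", trimws(ln)))
      section <- "SKIP"
      next
    }
    if (section == "SKIP") next
    fields <- strsplit(trimws(ln), "\\s+")[[1]]
    if (section == "MASS") {
      mass[[length(mass) + 1]] <-
        tibble(type = fields[1], mass = parse_nums(fields[2], i))
    } else if (section == "BOND") {
      ty <- split_types(fields[1]); v <- parse_nums(fields[2:3], i)
      bonds[[length(bonds) + 1]] <-
        tibble(type1 = ty[1], type2 = ty[2], rk = v[1], req = v[2])
    } else if (section == "ANGL") {
      ty <- split_types(fields[1]); v <- parse_nums(fields[2:3], i)
      angles[[length(angles) + 1]] <-
        tibble(type1 = ty[1], type2 = ty[2], type3 = ty[3],
               tk = v[1], teq = v[2])
    } else if (section == "DIHE") {
      ty <- split_types(fields[1]); v <- parse_nums(fields[2:5], i)
      dihedrals[[length(dihedrals) + 1]] <-
        tibble(type1 = ty[1], type2 = ty[2], type3 = ty[3], type4 = ty[4],
               idivf = v[1], pk = v[2], phase = v[3], pn = v[4])
    } else if (section == "NONB") {
      v <- parse_nums(fields[2:3], i)
      nonbon[[length(nonbon) + 1]] <-
        tibble(type = fields[1], rvdw = v[1], edep = v[2])
    }
  }
  mass_tbl <- if (length(mass)) bind_rows(mass) else
    tibble(type = character(), mass = double())
  nb_tbl <- if (length(nonbon)) bind_rows(nonbon) else
    tibble(type = character(), rvdw = double(), edep = double())
  lj <- dplyr::full_join(mass_tbl, nb_tbl, by = "type")
  pseudoatom_forcefield(
    bonds = if (length(bonds)) bind_rows(bonds) else empty_bonds(),
    angles = if (length(angles)) bind_rows(angles) else empty_angles(),
    dihedrals = if (length(dihedrals)) bind_rows(dihedrals) else empty_dihedrals(),
    lj = lj,
    default_bead_charge = default_bead_charge
  )
}
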