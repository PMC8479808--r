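#' Synthetic idealized GAG chain
#'
#' Builds a ligand-only [gag_complex()] whose residue centroids lie on an
#' ideal helix (rise per residue along z, fixed turn per residue). With
#' `with_ring_atoms = TRUE` each residue carries a planar hexagonal
#' pyranose-ring template (atoms C1-C5, O5) around its centroid plus a
#' glycosidic oxygen `O1` pointing along the chain toward the next
#' residue (for the reducing-end residue, along the outgoing chain
#' direction, so elongation can bond through it). Otherwise each residue
#' is a single `C1` centroid particle.
#'
#' These fixtures are geometric stand-ins: ring puckering, sulfation
#' geometry and docking-pose realism are deliberately absent. The
#' default rise of 4.5 A per residue approximates heparin's helical
#' repeat; the construction is fully deterministic.
#'
#' @param dp Degree of polymerization (number of monosaccharide units),
#'   >= 2.
#' @param rise Helical rise per residue, Angstrom.
#' @param turn_deg Turn per residue, degrees (0 gives a straight chain).
#' @param with_ring_atoms Emit the 6-atom ring template + `O1` per
#'   residue (`TRUE`) or a single particle (`FALSE`).
#' @param radius Helix radius, Angstrom.
#' @param unit_charge Charge per residue, elementary charges (default -2,
#'   fully sulfated heparin).
#' @param chain_id Chain identifier.
#' @param seed Accepted for interface uniformity; the construction is
#'   deterministic and does not consume randomness.
#' @return A ligand-only [gag_complex()].
#' @examples
#' hx <- make_gag_helix(6)
#' gag_residues(hx)
#' @export
make_gag_helix <- function(dp, rise = 4.5, turn_deg = 180,
                           with_ring_atoms = TRUE, radius = 1.5,
                           unit_charge = -2, chain_id = "A", seed = 1) {
  if (dp < 2) abort("dp must be >= 2")
  i <- seq_len(dp)
  th <- (i - 1) * turn_deg * pi / 180
  cen <- cbind(radius * cos(th), radius * sin(th), (i - 1) * rise)
  rows <- list()
  serial <- 0L
  for (k in i) {
    ck <- cen[k, ]
    nxt <- if (k < dp) cen[k + 1, ] else ck + (ck - cen[k - 1, ])
    u <- unit_vec(nxt - ck)
    if (with_ring_atoms) {
      ## hexagon of radius 0.75 A in a plane containing the chain axis
      p <- perp_vec(u)
      ring_names <- PYRANOSE_RING
      ang <- (0:5) * 60 * pi / 180
      ring <- t(vapply(ang, function(a)
        ck + 0.75 * (cos(a) * u + sin(a) * p), numeric(3)))
      ## glycosidic oxygen sits off the chain axis, as in a real
      ## 1->4 linkage, so junction dihedrals are well defined
      o1 <- ck + 1.4 * u + 0.8 * p
      xyz <- unname(rbind(ring, o1, deparse.level = 0))
      names_k <- c(ring_names, GLYCOSIDIC_O)
      elem_k <- c("C", "C", "C", "C", "C", "O", "O")
    } else {
      xyz <- matrix(ck, nrow = 1)
      names_k <- "C1"
      elem_k <- "C"
    }
    rows[[k]] <- tibble(
      serial = serial + seq_len(nrow(xyz)),
      name = names_k,
      resname = "SGC",
      chain = chain_id,
      resno = k,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      element = elem_k,
      charge = NA_real_,
      res_charge = unit_charge
    )
    serial <- serial + nrow(xyz)
  }
  gag_complex(receptor = empty_atoms(), gag = bind_rows(rows),
              chain_id = chain_id)
}

empty_atoms <- function() {
  tibble(serial = integer(), name = character(), resname = character(),
         chain = character(), resno = integer(),
         x = double(), y = double(), z = double(),
         element = character(), charge = double())
}

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

parse_sequence <- function(sequence) {
  if (length(sequence) == 1 && grepl("-", sequence, fixed = TRUE))
    sequence <- strsplit(sequence, "-", fixed = TRUE)[[1]]
  if (length(sequence) == 1 && !sequence %in% AA3) {
    codes <- strsplit(sequence, "")[[1]]
    bad <- setdiff(codes, names(AA3))
    if (length(bad))
      abort(sprintf("unknown residue code(s): %s", paste(bad, collapse = ", ")))
    return(unname(AA3[codes]))
  }
  sequence <- toupper(sequence)
  bad <- setdiff(sequence, AA3)
  if (length(bad))
    abort(sprintf("unknown residue code(s): %s", paste(bad, collapse = ", ")))
  sequence
}

## Side-chain reference atom emitted per residue type (beyond N/CA/C/O/CB).
SIDE_TIP <- c(LYS = "NZ", ARG = "CZ", ASP = "CG", GLU = "CD")
SIDE_TIP_DIST <- c(LYS = 4.8, ARG = 4.9, ASP = 2.0, GLU = 3.1)

#' Synthetic peptide-GAG complex
#'
#' Places an extended-backbone peptide parallel to an existing GAG chain
#' at a given offset, with charged side-chain tips (Lys NZ, Arg CZ, Asp
#' CG, Glu CD) oriented toward the GAG. Geometry is idealized: the
#' backbone runs along the GAG axis at 3.8 A per residue, and side
#' chains are straight spokes. Intended as a deterministic docking-pose
#' stand-in for testing charged-site detection and electrostatic sums.
#'
#' @param sequence Peptide sequence: 1-letter string (`"GKGKG"`),
#'   dash-joined 3-letter string (`"GLY-LYS-GLY"`), or character vector
#'   of 3-letter codes.
#' @param gag A [gag_complex()] providing the GAG ligand (its receptor
#'   atoms, if any, are ignored).
#' @param offset Backbone-to-GAG-axis distance, Angstrom.
#' @param chain_id Peptide chain identifier.
#' @param seed Accepted for interface uniformity; deterministic.
#' @return A [gag_complex()] whose receptor is the peptide.
#' @examples
#' cx <- make_peptide_complex("GKGKG", make_gag_helix(6), offset = 6)
#' detect_charged_sites(cx$receptor)
#' @export
make_peptide_complex <- function(sequence, gag, offset = 6,
                                 chain_id = "P", seed = 1) {
  stopifnot(inherits(gag, "gag_complex"))
  resnames <- parse_sequence(sequence)
  cen <- residue_centroids(gag)
  p0 <- c(cen$x[1], cen$y[1], cen$z[1])
  pn <- c(cen$x[nrow(cen)], cen$y[nrow(cen)], cen$z[nrow(cen)])
  axis <- unit_vec(pn - p0)
  side <- perp_vec(axis)              # direction from GAG axis to peptide
  up <- cross3(axis, side)
  rows <- list()
  serial <- 0L
  n <- length(resnames)
  start <- (p0 + pn) / 2 + offset * side - (n - 1) / 2 * 3.8 * axis
  for (k in seq_len(n)) {
    ca <- start + (k - 1) * 3.8 * axis
    atoms <- list(
      N  = ca - 1.45 * axis + 0.3 * up,
      CA = ca,
      C  = ca + 1.52 * axis + 0.3 * up,
      O  = ca + 1.52 * axis + 1.5 * up
    )
    elems <- c("N", "C", "C", "O")
    rn <- resnames[k]
    if (rn != "GLY") {
      atoms$CB <- ca - 1.0 * side + 0.9 * up
      elems <- c(elems, "C")
      tip <- SIDE_TIP[rn]
      if (!is.na(tip)) {
        atoms[[tip]] <- ca - SIDE_TIP_DIST[rn] * side
        elems <- c(elems, substr(tip, 1, 1))
      }
    }
    xyz <- unname(do.call(rbind, atoms))
    rows[[k]] <- tibble(
      serial = serial + seq_len(nrow(xyz)),
      name = names(atoms),
      resname = rn,
      chain = chain_id,
      resno = k,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      element = elems,
      charge = NA_real_
    )
    serial <- serial + nrow(xyz)
  }
  gag_complex(receptor = bind_rows(rows), gag = gag$gag,
              chain_id = gag$chain_id)
}

#' Draw samples from the Boltzmann distribution of a bonded term
#'
#' The inverse of the Boltzmann-inversion fitters: generates the sample
#' series a harmonic or cosine term would produce at equilibrium.
#' Bonds and angles follow the exact Gaussian with variance
#' `k_B T / (2 K)` implied by `E = K (x - x0)^2`; dihedrals are drawn by
#' exact rejection sampling from `exp(-E(phi)/k_B T)` with
#' `E = (PK/IDIVF) (1 + cos(PN phi - phase))`, giving independent
#' samples (no Markov-chain burn-in or autocorrelation).
#'
#' @param kind One of `"bond"` (Angstrom), `"angle"` (degrees),
#'   `"dihedral"` (degrees in (-180, 180]).
#' @param equilibrium Equilibrium value (bonds/angles only).
#' @param force_constant Harmonic constant K: kcal/mol/A^2 for bonds,
#'   kcal/mol/rad^2 for angles.
#' @param pk,pn,phase Cosine-term parameters (dihedrals only); `phase`
#'   in degrees.
#' @param temperature Temperature, K.
#' @param n Number of samples.
#' @param seed RNG seed.
#' @return A `sample_series` object: tibble of `value` with attributes
#'   `kind` and `temperature`.
#' @examples
#' s <- sample_boltzmann("bond", 5.2, 120, n = 1000, seed = 1)
#' mean(s$value); sd(s$value)  # ~5.2, ~sqrt(kT/240)
#' @export
sample_boltzmann <- function(kind = c("bond", "angle", "dihedral"),
                             equilibrium = NULL, force_constant = NULL,
                             pk = NULL, pn = NULL, phase = 0,
                             temperature = 300, n = 1000L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  set.seed(seed)
  kt <- kT(temperature)
  if (kind %in% c("bond", "angle")) {
    if (is.null(force_constant) || force_constant <= 0)
      abort("force_constant must be > 0")
    sigma <- sqrt(kt / (2 * force_constant))
    if (kind == "angle") sigma <- sigma * 180 / pi  # K is per rad^2
    vals <- rnorm(n, mean = equilibrium, sd = sigma)
    if (kind == "angle") vals <- pmin(pmax(vals, 1e-6), 180)
  } else {
    if (is.null(pk) || is.null(pn)) abort("dihedral sampling needs pk and pn")
    energy <- function(phi_deg) {
      pk * (1 + cos((pn * phi_deg - phase) * pi / 180))
    }
    emin <- min(energy(seq(-180, 180, by = 0.1)))
    vals <- numeric(0)
    while (length(vals) < n) {
      m <- max(2L * (n - length(vals)), 1000L)
      cand <- runif(m, -180, 180)
      acc <- runif(m) < exp(-(energy(cand) - emin) / kt)
      vals <- c(vals, cand[acc])
    }
    vals <- vals[seq_len(n)]
  }
  sample_series(vals, kind = kind, temperature = temperature)
}

#' Synthetic per-residue decomposition table
#'
#' Emulates the per-residue binding free-energy decomposition of an
#' MM/GBSA analysis: the central `n_core` GAG residues get a strong
#' (core) contribution and the flanking residues a weak (tail) one.
#'
#' @param gag A [gag_complex()].
#' @param core_dg,tail_dg Free energy per residue, kcal/mol.
#' @param n_core Number of central residues treated as the binding core.
#' @return A `decomposition_tbl`: tibble with columns `residue` (resno)
#'   and `dg` (kcal/mol).
#' @export
make_decomposition <- function(gag, core_dg = -3.0, tail_dg = -0.1,
                               n_core = 4) {
  stopifnot(inherits(gag, "gag_complex"))
  res <- gag_residues(gag)
  dp <- nrow(res)
  if (n_core > dp) abort("n_core cannot exceed the chain length")
  first <- floor((dp - n_core) / 2) + 1
  core_idx <- seq(first, length.out = n_core)
  decomposition_table(tibble(
    residue = res$resno,
    dg = ifelse(seq_len(dp) %in% core_idx, core_dg, tail_dg)
  ))
}

#' Per-residue decomposition table constructor
#'
#' @param x Data frame with columns `residue` and `dg` (kcal/mol).
#' @return A `decomposition_tbl`.
#' @export
decomposition_table <- function(x) {
  x <- as_tibble(x)
  if (!all(c("residue", "dg") %in% names(x)))
    abort("a decomposition table needs columns 'residue' and 'dg'")
  if (anyDuplicated(x$residue)) abort("duplicate residue ids in decomposition table")
  class(x) <- c("decomposition_tbl", class(x))
  x
}

#' Read a per-residue decomposition table from CSV
#'
#' Expects a two-column CSV with header `residue,dg` (free energies in
#' kcal/mol), as exported from an MM/GBSA per-residue decomposition.
#'
#' @param path CSV file path.
#' @return A [decomposition_table()].
#' @export
read_decomposition <- function(path) {
  if (!file.exists(path)) abort(sprintf("decomposition file not found: %s", path))
  decomposition_table(readr::read_csv(path, show_col_types = FALSE))
}
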