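BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "HA")

## canonical reference atom per charged residue type
CHARGED_REF <- list(
  LYS = list(sign = 1, atom = "NZ"),
  ARG = list(sign = 1, atom = "CZ"),
  ASP = list(sign = -1, atom = "CG"),
  GLU = list(sign = -1, atom = "CD")
)

#' Detect charged receptor sites
#'
#' Scans the receptor for formally charged residues and returns one
#' reference point per site: Lys NZ, Arg CZ, Asp CG, Glu CD. If the
#' canonical atom is absent the side-chain centroid is used (with a
#' warning), and failing that the C-alpha. Histidine is not counted as
#' charged. Optionally the chain termini (first N as +1, last C/OXT as
#' -1 per chain) are added.
#'
#' @param receptor Atom tibble (columns `name`, `resname`, `chain`,
#'   `resno`, `x`, `y`, `z`).
#' @param include_termini Add the backbone termini as charged sites.
#' @return Tibble of charged sites: `chain`, `resno`, `resname`,
#'   `sign` (+1/-1), `x`, `y`, `z`. Zero rows (with a message) when no
#'   charged residue is present.
#' @export
detect_charged_sites <- function(receptor, include_termini = FALSE) {
  receptor <- as_tibble(receptor)
  sites <- list()
  res_tbl <- receptor |> distinct(.data$chain, .data$resno, .data$resname)
  for (k in seq_len(nrow(res_tbl))) {
    r <- res_tbl[k, ]
    ref <- CHARGED_REF[[r$resname]]
    if (is.null(ref)) next
    at <- receptor |> filter(.data$chain == r$chain, .data$resno == r$resno)
    hit <- at |> filter(.data$name == ref$atom)
    if (!nrow(hit)) {
      side <- at |> filter(!.data$name %in% BACKBONE_ATOMS)
      if (nrow(side)) {
        warn(sprintf("%s %s%d lacks %s: using side-chain centroid",
                     r$resname, r$chain, r$resno, ref$atom))
        hit <- tibble(x = mean(side$x), y = mean(side$y), z = mean(side$z))
      } else {
        warn(sprintf("%s %s%d lacks a side chain: using CA",
                     r$resname, r$chain, r$resno))
        hit <- at |> filter(.data$name == "CA")
        if (!nrow(hit)) next
      }
    }
    sites[[length(sites) + 1]] <-
      tibble(chain = r$chain, resno = r$resno, resname = r$resname,
             sign = ref$sign, x = hit$x[1], y = hit$y[1], z = hit$z[1])
  }
  if (include_termini) {
    for (ch in unique(receptor$chain)) {
      at <- receptor |> filter(.data$chain == ch) |> arrange(.data$resno)
      nt <- at |> filter(.data$resno == min(.data$resno), .data$name == "N")
      ct <- at |> filter(.data$resno == max(.data$resno),
                         .data$name %in% c("OXT", "C"))
      if (nrow(nt))
        sites[[length(sites) + 1]] <-
          tibble(chain = ch, resno = nt$resno[1], resname = "NTER",
                 sign = 1, x = nt$x[1], y = nt$y[1], z = nt$z[1])
      if (nrow(ct))
        sites[[length(sites) + 1]] <-
          tibble(chain = ch, resno = ct$resno[1], resname = "CTER",
                 sign = -1, x = ct$x[1], y = ct$y[1], z = ct$z[1])
    }
  }
  if (!length(sites)) {
    inform("no charged receptor sites detected")
    return(tibble(chain = character(), resno = integer(),
                  resname = character(), sign = double(),
                  x = double(), y = double(), z = double()))
  }
  bind_rows(sites)
}

#' Signed electrostatic distance sum for one GAG residue
#'
#' The score `S = sum_(+ sites) f(d) - sum_(- sites) f(d)` over charged
#' receptor sites within the cutoff, with `f(d) = 1/d` (Coulomb) or
#' `f(d) = exp(-kappa d)/d` (Debye-Hueckel). Distances run from the GAG
#' residue centroid (bead position for CG residues) to each site's
#' reference point. Inverting the sign convention (summing negative
#' minus positive sites) is exposed for exploration since the screened
#' variant's published normalization is ambiguous.
#'
#' @param centroid Numeric length-3 GAG residue centroid, or a one-row
#'   tibble with `x`, `y`, `z`.
#' @param sites Charged-site tibble from [detect_charged_sites()].
#' @param es An [electrostatics_model()].
#' @param cutoff Site inclusion cutoff, Angstrom (> 0).
#' @param sign_convention `"pos_minus_neg"` (default) or
#'   `"neg_minus_pos"`.
#' @return The score S (units 1/Angstrom).
#' @examples
#' sites <- tibble::tibble(chain = "P", resno = 1, resname = "LYS",
#'                         sign = 1, x = 2, y = 0, z = 0)
#' electrostatic_sum(c(0, 0, 0), sites)  # 1/2
#' @export
electrostatic_sum <- function(centroid, sites,
                              es = electrostatics_model("coulomb"),
                              cutoff = 10,
                              sign_convention = c("pos_minus_neg",
                                                  "neg_minus_pos")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(cutoff > 0)
  if (is.data.frame(centroid))
    centroid <- c(centroid$x[1], centroid$y[1], centroid$z[1])
  if (!nrow(sites)) return(0)
  d <- sqrt((sites$x - centroid[1])^2 + (sites$y - centroid[2])^2 +
              (sites$z - centroid[3])^2)
  if (any(d < 1e-9)) abort("charged site coincides with GAG residue centroid")
  f <- if (es$kind == "debye") exp(-es_kappa(es) * d) / d else 1 / d
  keep <- d <= cutoff
  s <- sum(sites$sign[keep] * f[keep])
  if (sign_convention == "neg_minus_pos") -s else s
}

#' Per-residue W factors of a receptor-GAG complex
#'
#' For each GAG residue the W factor is the ratio of its decomposed
#' binding free energy to its electrostatic distance sum,
#' `W = dG_res / S` (kcal/mol per e/A-like score unit); the
#' complex-level W is the arithmetic mean over residues. Residues with
#' `|S| < 1e-6` (no charged site in range) are excluded with a warning.
#' The resulting mean W extrapolates binding energies to longer chains
#' through [predict_elongated_energy()].
#'
#' @param x A [gag_complex()].
#' @param decomposition A [decomposition_table()] covering every GAG
#'   residue.
#' @param es An [electrostatics_model()].
#' @param cutoff Site inclusion cutoff, Angstrom.
#' @param sites Optional precomputed charged-site tibble; detected from
#'   the receptor when `NULL`.
#' @param sign_convention Passed to [electrostatic_sum()].
#' @return A `wfactor_model` with fields `per_residue` (tibble `resno`,
#'   `dg`, `s`, `w`, `excluded`), `mean_w`, `es`, `cutoff`.
#' @export
compute_w <- function(x, decomposition,
                      es = electrostatics_model("coulomb"), cutoff = 10,
                      sites = NULL,
                      sign_convention = "pos_minus_neg") {
  stopifnot(inherits(x, "gag_complex"))
  decomposition <- decomposition_table(decomposition)
  if (is.null(sites)) sites <- detect_charged_sites(x$receptor)
  cen <- residue_centroids(x)
  missing <- setdiff(cen$resno, decomposition$residue)
  if (length(missing))
    abort(sprintf("no decomposition entry for GAG residue(s): %s",
                  paste(missing, collapse = ", ")))
  dg <- setNames(decomposition$dg, decomposition$residue)
  per <- cen |>
    mutate(
      dg = unname(dg[as.character(.data$resno)]),
      s = purrr::pmap_dbl(list(.data$x, .data$y, .data$z),
                          function(x, y, z)
                            electrostatic_sum(c(x, y, z), sites, es, cutoff,
                                              sign_convention)),
      excluded = abs(.data$s) < 1e-6,
      w = ifelse(.data$excluded, NA_real_, .data$dg / .data$s)
    ) |>
    select("resno", "dg", "s", "w", "excluded")
  if (all(per$excluded))
    abort("every GAG residue lacks charged sites within the cutoff: W undefined")
  if (any(per$excluded))
    warn(sprintf("%d residue(s) excluded from W (|S| < 1e-6)",
                 sum(per$excluded)))
  structure(list(per_residue = per,
                 mean_w = mean(per$w, na.rm = TRUE),
                 es = es, cutoff = cutoff,
                 sign_convention = sign_convention),
            class = "wfactor_model")
}

#' @export
print.wfactor_model <- function(x, ...) {
  cat(sprintf("<wfactor_model> mean W = %.4g kcal/mol/e (%s electrostatics, cutoff %g A, %d residues)\n",
              x$mean_w, x$es$kind, x$cutoff,
              sum(!x$per_residue$excluded)))
  invisible(x)
}

#' Broom-style accessors for W-factor models
#'
#' @param x A `wfactor_model`.
#' @param ... Unused.
#' @return `tidy()`: the per-residue table (`resno`, `dg`, `s`, `w`,
#'   `excluded`); `glance()`: one-row summary with `mean_w`.
#' @export
tidy.wfactor_model <- function(x, ...) x$per_residue

#' @rdname tidy.wfactor_model
#' @export
glance.wfactor_model <- function(x, ...) {
  tibble(mean_w = x$mean_w, es_kind = x$es$kind,
         dielectric = x$es$dielectric,
         ionic_strength = x$es$ionic_strength,
         cutoff = x$cutoff,
         n_residues = nrow(x$per_residue),
         n_excluded = sum(x$per_residue$excluded))
}

#' Plot per-residue W factors
#'
#' @param object A `wfactor_model`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-residue W with the complex mean
#'   marked.
#' @export
autoplot.wfactor_model <- function(object, ...) {
  per <- tidy(object) |> filter(!.data$excluded)
  ggplot2::ggplot(per, ggplot2::aes(x = factor(.data$resno), y = .data$w)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$mean_w, linetype = 2,
                        colour = "red3") +
    ggplot2::labs(x = "GAG residue", y = "W (kcal/mol/e)")
}

#' Predict the binding energy of an elongated GAG
#'
#' Extrapolates a known binding free energy to an elongated chain
#' without further simulation:
#' `dG_pred = base_energy + mean_W * sum_added S(residue)`, where the
#' sum runs over the added residues' electrostatic distance sums in the
#' elongated pose. Applying a complex's own mean W to its own residues
#' with base 0 reproduces the summed per-residue energies exactly when
#' all per-residue W equal the mean (self-consistency). For small
#' peptide receptors the shipped [PEPTIDE_W] can stand in for a
#' system-specific calibration.
#'
#' @param base_energy Binding free energy of the unelongated complex,
#'   kcal/mol.
#' @param elongated A [gag_complex()] containing the added residues
#'   (typically beads placed by [elongate()]).
#' @param added_residues Residue numbers of the added residues.
#' @param w A `wfactor_model` from [compute_w()], or a bare numeric
#'   mean W (e.g. [PEPTIDE_W]).
#' @param es,cutoff,sites,sign_convention Electrostatics settings; when
#'   `w` is a `wfactor_model` its stored settings are the defaults.
#' @return Predicted binding free energy, kcal/mol.
#' @export
predict_elongated_energy <- function(base_energy, elongated, added_residues,
                                     w, es = NULL, cutoff = NULL,
                                     sites = NULL,
                                     sign_convention = NULL) {
  stopifnot(inherits(elongated, "gag_complex"))
  if (inherits(w, "wfactor_model")) {
    es <- es %||% w$es
    cutoff <- cutoff %||% w$cutoff
    sign_convention <- sign_convention %||% w$sign_convention
    mean_w <- w$mean_w
  } else {
    es <- es %||% electrostatics_model("coulomb")
    cutoff <- cutoff %||% 10
    sign_convention <- sign_convention %||% "pos_minus_neg"
    mean_w <- as.numeric(w)
  }
  if (!length(added_residues)) return(base_energy)
  cen <- residue_centroids(elongated)
  missing <- setdiff(added_residues, cen$resno)
  if (length(missing))
    abort(sprintf("added residue(s) not in the elongated chain: %s",
                  paste(missing, collapse = ", ")))
  if (is.null(sites)) sites <- detect_charged_sites(elongated$receptor)
  cen <- cen |> filter(.data$resno %in% added_residues)
  s_sum <- sum(purrr::pmap_dbl(list(cen$x, cen$y, cen$z),
                               function(x, y, z)
                                 electrostatic_sum(c(x, y, z), sites, es,
                                                   cutoff, sign_convention)))
  base_energy + mean_w * s_sum
}
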