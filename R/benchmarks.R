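gagcg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "gagcg")
  if (path == "") path <- file.path("inst", "extdata", file)  # pre-install
  if (!file.exists(path)) abort(sprintf("packaged fixture not found: %s", file))
  path
}

#' Published MM/PBSA benchmark: all-atom vs coarse-grained GAG models
#'
#' Binding free energies (kcal/mol) of ten protein-GAG binding sites
#' (one structure contributes two independent sites) evaluated with the
#' GAG modeled all-atom and with an earlier multi-bead coarse-grained
#' model: in-vacuo electrostatic, van der Waals and total components.
#' Both rows of the two-site system enter correlation analyses as
#' independent data points.
#'
#' @return A 10-row tibble: `pdb_id`, `site`, `aa_elect`, `aa_vdw`,
#'   `aa_total`, `cg_elect`, `cg_vdw`, `cg_total`.
#' @export
benchmark_aa_cg <- function() {
  readr::read_csv(gagcg_extdata("aa_cg_gbsa_benchmark.csv"),
                  show_col_types = FALSE)
}

#' Published MM/GBSA energies of heparin oligomers of increasing length
#'
#' Binding free energies (kcal/mol) of heparin dp4, dp6, dp10 and dp16
#' bound to five receptors (two model peptides, a naturally occurring
#' peptide epitope, and two fibroblast growth factors). For the InLys
#' dp6 entry the source reports a second value from a run in which
#' dissociation occurred; the primary (dissociation-free) value is
#' shipped.
#'
#' @return A 4-row tibble: `dp` plus one column per receptor system.
#' @export
hp_length_energies <- function() {
  readr::read_csv(gagcg_extdata("hp_length_gbsa.csv"),
                  show_col_types = FALSE)
}

#' Published MM/GBSA energies of mixed AA/CG dp16 heparin simulations
#'
#' Binding free energies (kcal/mol) of heparin dp16 with the same five
#' receptors under three chain representations: fully all-atom (`aa`),
#' the elongated lateral fragments replaced by single-pseudoatom beads
#' (`elongated_cg`), and residues replaced by beads according to the
#' per-residue decomposition threshold (`decomposition_cg`).
#'
#' @return A 3-row tibble: `model` plus one column per receptor system.
#' @export
mixed_model_energies <- function() {
  readr::read_csv(gagcg_extdata("mixed_dp16_gbsa.csv"),
                  show_col_types = FALSE)
}

#' AA-vs-CG correlation of binding free-energy components
#'
#' Correlates an energy component of the all-atom GAG model against the
#' coarse-grained model over the ten benchmark binding sites of
#' [benchmark_aa_cg()].
#'
#' @param component `"elect"`, `"vdw"` or `"total"`.
#' @param method `"pearson"` or `"spearman"`.
#' @return The correlation coefficient.
#' @examples
#' aa_cg_correlation("elect", "spearman")  # 0.988
#' aa_cg_correlation("total", "pearson")   # 0.920
#' @export
aa_cg_correlation <- function(component = c("elect", "vdw", "total"),
                              method = c("pearson", "spearman")) {
  component <- match.arg(component)
  method <- match.arg(method)
  tbl <- benchmark_aa_cg()
  cor(tbl[[paste0("aa_", component)]], tbl[[paste0("cg_", component)]],
      method = method)
}

#' All six AA-vs-CG correlation coefficients
#'
#' @return Tibble with columns `component`, `pearson`, `spearman`.
#' @export
aa_cg_correlations <- function() {
  tidyr::expand_grid(component = c("elect", "vdw", "total")) |>
    mutate(pearson = map_dbl(.data$component, aa_cg_correlation,
                             method = "pearson"),
           spearman = map_dbl(.data$component, aa_cg_correlation,
                              method = "spearman"))
}

systems_of <- function(tbl) setdiff(names(tbl), c("dp", "model"))

#' Binding-strength underestimation of short heparin oligomers
#'
#' How much weaker a dp4/dp6/dp10 heparin binds than dp16, averaged over
#' the five benchmark systems: per system
#' `100 * (|G_dp16| - |G_dp|) / |G_dp16|`. Per-system percentages are
#' taken at one-decimal precision (the precision of the shipped
#' energies) before averaging; the summary is the rounded mean.
#'
#' @param dp 4, 6 or 10.
#' @return A list with `per_system` (named percentages), `mean`
#'   (unrounded) and `percent` (integer summary).
#' @examples
#' length_underestimation(4)$percent  # 39
#' length_underestimation(6)$percent  # 24
#' @export
length_underestimation <- function(dp) {
  tbl <- hp_length_energies()
  if (!dp %in% tbl$dp) abort(sprintf("dp%d is not in the shipped table", dp))
  sys <- systems_of(tbl)
  g_dp <- abs(unlist(tbl[tbl$dp == dp, sys]))
  g_16 <- abs(unlist(tbl[tbl$dp == 16, sys]))
  per <- round(100 * (g_16 - g_dp) / g_16, 1)
  list(per_system = per, mean = mean(per), percent = round(mean(per)))
}

#' AA vs mixed-model binding free-energy difference per system
#'
#' Percent difference between the all-atom dp16 simulation and a mixed
#' AA/CG representation, `100 * |G_AA - G_mixed| / |G_AA|`, rounded to
#' the nearest integer.
#'
#' @param system One of the receptor columns of
#'   [mixed_model_energies()] (e.g. `"april"`, `"fgf1_2axm"`).
#' @param model Mixed-model row to compare: `"elongated_cg"` (lateral
#'   fragments replaced by beads) or `"decomposition_cg"`.
#' @return A list with `percent` (integer), `raw` (unrounded percent).
#' @examples
#' mixed_model_difference("april")$percent      # 7
#' mixed_model_difference("fgf1_2axm")$percent  # 14
#' @export
mixed_model_difference <- function(system,
                                   model = c("elongated_cg",
                                             "decomposition_cg")) {
  model <- match.arg(model)
  tbl <- mixed_model_energies()
  if (!system %in% systems_of(tbl))
    abort(sprintf("unknown system '%s'; choose from: %s", system,
                  paste(systems_of(tbl), collapse = ", ")))
  g_aa <- tbl[[system]][tbl$model == "aa"]
  g_cg <- tbl[[system]][tbl$model == model]
  raw <- 100 * abs(g_aa - g_cg) / abs(g_aa)
  list(percent = round(raw), raw = raw)
}

#' Plot the AA-vs-CG benchmark correlation
#'
#' @param component Energy component, as in [aa_cg_correlation()].
#' @return A ggplot scatter of AA vs CG energies with the identity line.
#' @export
plot_aa_cg_benchmark <- function(component = c("elect", "vdw", "total")) {
  component <- match.arg(component)
  tbl <- benchmark_aa_cg()
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data[[paste0("aa_", component)]],
                                    y = .data[[paste0("cg_", component)]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("all-atom dG_%s (kcal/mol)", component),
                  y = sprintf("coarse-grained dG_%s (kcal/mol)", component))
}
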