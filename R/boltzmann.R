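#' Conformational sample series
#'
#' Container for scalar internal-coordinate measurements (bond lengths,
#' angles or dihedrals) harvested from conformational ensembles, used as
#' input to the Boltzmann-inversion fitters.
#'
#' @param values Numeric measurements: Angstrom for bonds, degrees for
#'   angles (0, 180] and dihedrals (-180, 180].
#' @param kind `"bond"`, `"angle"` or `"dihedral"`.
#' @param temperature Temperature of the generating ensemble, K.
#' @return A `sample_series` tibble with column `value`.
#' @export
sample_series <- function(values, kind = c("bond", "angle", "dihedral"),
                          temperature = 300) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (any(!is.finite(values))) abort("sample values must be finite")
  if (kind == "angle" && any(values <= 0 | values > 180))
    abort("angle samples must lie in (0, 180]")
  if (kind == "dihedral") {
    values <- ((values + 180) %% 360) - 180
    values[values == -180] <- 180
  }
  structure(tibble(value = values),
            kind = kind, temperature = temperature,
            class = c("sample_series", class(tibble())))
}

series_kind <- function(s) attr(s, "kind")
series_temp <- function(s) attr(s, "temperature")

#' Read a plain-text column of measurements
#'
#' @param path Text file with one numeric measurement per line (comments
#'   starting with `#` allowed).
#' @param kind,temperature Passed to [sample_series()].
#' @return A [sample_series()].
#' @export
read_samples <- function(path, kind, temperature = 300) {
  if (!file.exists(path)) abort(sprintf("sample file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sample_series(as.numeric(lines), kind = kind, temperature = temperature)
}

#' Potential of mean force by Boltzmann inversion
#'
#' Histograms the samples and inverts the distribution:
#' `U(x) = -k_B T ln(P(x) / P_max)`, so the best-populated bin sits at
#' exactly 0 kcal/mol. Empty bins are left `NA` (undefined free energy,
#' not zero). Dihedral profiles are treated as periodic on
#' (-180, 180]. No Jacobian correction (`r^2`, `sin(theta)`) is applied
#' by default - the inversion acts on the raw distribution - but
#' `jacobian = TRUE` enables it for users who want the corrected PMF.
#'
#' @param s A [sample_series()].
#' @param n_bins Number of histogram bins (>= 10).
#' @param jacobian Apply the geometric Jacobian correction
#'   (`U <- U + 2 kT ln r` for bonds, `U <- U + kT ln sin(theta)` for
#'   angles) before re-zeroing.
#' @return A `pmf_profile`: tibble of `bin_mid`, `count`, `pmf`
#'   (kcal/mol) with attributes `kind`, `temperature`, `bin_width`.
#' @examples
#' s <- sample_boltzmann("bond", 5.2, 120, n = 5000, seed = 2)
#' pmf <- pmf_from_samples(s, 40)
#' @export
pmf_from_samples <- function(s, n_bins = 50, jacobian = FALSE) {
  stopifnot(inherits(s, "sample_series"))
  if (n_bins < 10) abort("n_bins must be >= 10")
  v <- s$value
  kind <- series_kind(s)
  if (diff(range(v)) < 1e-12)
    abort("degenerate distribution: all samples identical")
  if (kind == "dihedral") {
    breaks <- seq(-180, 180, length.out = n_bins + 1)
  } else {
    pad <- diff(range(v)) * 1e-9
    breaks <- seq(min(v) - pad, max(v) + pad, length.out = n_bins + 1)
  }
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  occ <- which(counts > 0)
  if (diff(range(occ)) + 1 < 3) abort("samples must span at least 3 bins")
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  kt <- kT(series_temp(s))
  u <- ifelse(counts > 0, -kt * log(counts / max(counts)), NA_real_)
  if (jacobian) {
    corr <- switch(kind,
                   bond = 2 * kt * log(mids),
                   angle = kt * log(pmax(sin(mids * pi / 180), 1e-12)),
                   dihedral = 0)
    u <- u + corr
  }
  u <- u - min(u, na.rm = TRUE)
  structure(tibble(bin_mid = mids, count = counts, pmf = u),
            kind = kind, temperature = series_temp(s),
            bin_width = diff(breaks[1:2]),
            class = c("pmf_profile", class(tibble())))
}

## circular 3-bin moving average; NA bins treated as the profile maximum
## (an unvisited region is a high barrier, not a well)
smooth_pmf <- function(pmf, periodic) {
  u <- pmf$pmf
  hi <- max(u, na.rm = TRUE)
  u[is.na(u)] <- hi
  n <- length(u)
  if (periodic) {
    uu <- c(u[n], u, u[1])
    (uu[1:n] + uu[2:(n + 1)] + uu[3:(n + 2)]) / 3
  } else {
    sm <- u
    sm[2:(n - 1)] <- (u[1:(n - 2)] + u[2:(n - 1)] + u[3:n]) / 3
    sm
  }
}

circular_extrema <- function(u) {
  n <- length(u)
  prv <- u[c(n, 1:(n - 1))]
  nxt <- u[c(2:n, 1)]
  list(minima = which(u < prv & u <= nxt),
       maxima = which(u > prv & u >= nxt))
}

#' Fit a harmonic bond or angle term from samples
#'
#' Boltzmann inversion of a (near-)Gaussian distribution: the
#' equilibrium value is the sample mean and the force constant follows
#' from the equipartition relation `K = k_B T / (2 var)` in the AMBER
#' convention `E = K (x - x0)^2` (the conventional 1/2 is absorbed into
#' K). Angle variances are converted to radians so K comes out in
#' kcal/mol/rad^2 while the equilibrium stays in degrees.
#'
#' A warning is emitted when the inverted PMF shows more than one well
#' (bimodality), in which case a single harmonic term is a poor model.
#'
#' @param s A [sample_series()] of kind `"bond"` or `"angle"` (>= 100
#'   samples recommended).
#' @return A `pmf_fit` with fields `kind`, `equilibrium`,
#'   `force_constant`, `pmf` and `n`.
#' @examples
#' s <- sample_boltzmann("bond", 5.2, 120, n = 20000, seed = 3)
#' fit_harmonic(s)
#' @export
fit_harmonic <- function(s) {
  stopifnot(inherits(s, "sample_series"))
  kind <- series_kind(s)
  if (!kind %in% c("bond", "angle"))
    abort("fit_harmonic applies to bond or angle series; use fit_dihedral for dihedrals")
  v <- s$value
  vv <- var(v)
  if (vv < 1e-14) abort("zero variance: cannot invert a delta distribution")
  pmf <- pmf_from_samples(s, n_bins = max(20L, min(60L, length(v) %/% 50)))
  sm <- smooth_pmf(pmf, periodic = FALSE)
  interior_minima <- which(diff(sign(diff(sm))) > 0) + 1
  depth <- max(sm) - min(sm)
  real_minima <- interior_minima[sm[interior_minima] < min(sm) + 0.5 * depth]
  if (length(real_minima) > 1)
    warn("PMF shows more than one well: harmonic fit may be inappropriate")
  kt <- kT(series_temp(s))
  var_fit <- if (kind == "angle") vv * (pi / 180)^2 else vv
  new_pmf_fit(
    kind = kind,
    equilibrium = mean(v),
    force_constant = kt / (2 * var_fit),
    pmf = pmf,
    temperature = series_temp(s),
    n = length(v)
  )
}

#' Fit a cosine dihedral term from periodic samples
#'
#' The dihedral PMF is computed on a periodic grid, smoothed with a
#' circular 3-bin moving average (raw histograms produce spurious
#' extrema), and its wells are counted: one well per 360 degrees gives
#' periodicity PN = 1, three wells give PN = 3. Other well counts are
#' rejected, since the shipped parameter set only uses these two.
#'
#' The barrier height - the highest maximum separating the global
#' minimum from the local minima, measured from the global minimum -
#' equals the peak-to-peak range `2 PK` of the AMBER term
#' `PK (1 + cos(PN phi - phase))`, so the amplitude is recovered as
#' barrier / 2. The phase is snapped to 0 or 180 degrees so that the
#' cosine minimum coincides with the PMF global minimum.
#'
#' A nearly flat profile (range below `flat_tol`) yields PK ~ 0 with
#' PN = 1 and a warning.
#'
#' @param s A [sample_series()] of kind `"dihedral"`.
#' @param n_bins Histogram bins over 360 degrees.
#' @param flat_tol Range (kcal/mol) below which the profile is treated
#'   as flat.
#' @return A `pmf_fit` with fields `pk`, `pn`, `phase`, `idivf`.
#' @examples
#' s <- sample_boltzmann("dihedral", pk = 1, pn = 1, n = 50000, seed = 4)
#' fit_dihedral(s)
#' @export
fit_dihedral <- function(s, n_bins = 72, flat_tol = 0.1) {
  stopifnot(inherits(s, "sample_series"))
  if (series_kind(s) != "dihedral") abort("fit_dihedral needs dihedral samples")
  pmf <- pmf_from_samples(s, n_bins = n_bins)
  sm <- smooth_pmf(pmf, periodic = TRUE)
  sm <- sm - min(sm)
  rng <- max(sm)
  if (rng < flat_tol) {
    warn("flat dihedral PMF: PK ~ 0, defaulting to PN = 1")
    return(new_pmf_fit(kind = "dihedral", pk = rng / 2, pn = 1L, phase = 0,
                       idivf = 1L, pmf = pmf, temperature = series_temp(s),
                       n = nrow(s)))
  }
  ext <- circular_extrema(sm)
  ## keep only wells deeper than a quarter of the range below the barriers
  minima <- ext$minima[sm[ext$minima] < 0.5 * rng]
  n_min <- length(minima)
  if (!n_min %in% c(1L, 3L))
    abort(sprintf("unsupported dihedral periodicity: %d well(s) per 360 degrees (only 1 and 3 are modelled)",
                  n_min))
  pn <- n_min
  barrier <- max(sm[ext$maxima])
  pk <- barrier / 2
  phi_min <- pmf$bin_mid[minima[which.min(sm[minima])]]
  phase <- if (cos(pn * phi_min * pi / 180) < 0) 0 else 180
  new_pmf_fit(kind = "dihedral", pk = pk, pn = as.integer(pn), phase = phase,
              idivf = 1L, pmf = pmf, temperature = series_temp(s),
              n = nrow(s))
}

new_pmf_fit <- function(kind, equilibrium = NA_real_,
                        force_constant = NA_real_, pk = NA_real_,
                        pn = NA_integer_, phase = NA_real_, idivf = 1L,
                        pmf = NULL, temperature = 300, n = NA_integer_) {
  structure(list(kind = kind, equilibrium = equilibrium,
                 force_constant = force_constant, pk = pk, pn = pn,
                 phase = phase, idivf = idivf, pmf = pmf,
                 temperature = temperature, n = n),
            class = "pmf_fit")
}

#' @export
print.pmf_fit <- function(x, ...) {
  if (x$kind == "dihedral") {
    cat(sprintf("<pmf_fit> dihedral: PK = %.4g kcal/mol, PN = %d, phase = %g deg (n = %d)\n",
                x$pk, x$pn, x$phase, x$n))
  } else {
    unit <- if (x$kind == "bond") c("A", "kcal/mol/A^2") else c("deg", "kcal/mol/rad^2")
    cat(sprintf("<pmf_fit> %s: equilibrium = %.4g %s, K = %.4g %s (n = %d)\n",
                x$kind, x$equilibrium, unit[1], x$force_constant, unit[2], x$n))
  }
  invisible(x)
}

#' Broom-style accessors for Boltzmann-inversion fits
#'
#' @param x A `pmf_fit`.
#' @param ... Unused.
#' @return `tidy()` returns the binned PMF as a tibble; `glance()`
#'   returns a one-row tibble of the fitted parameters.
#' @export
tidy.pmf_fit <- function(x, ...) {
  if (is.null(x$pmf)) return(tibble())
  as_tibble(x$pmf)
}

#' @rdname tidy.pmf_fit
#' @export
glance.pmf_fit <- function(x, ...) {
  tibble(kind = x$kind, equilibrium = x$equilibrium,
         force_constant = x$force_constant, pk = x$pk, pn = x$pn,
         phase = x$phase, temperature = x$temperature, n = x$n)
}

#' Plot a fitted potential of mean force
#'
#' @param object A `pmf_fit`.
#' @param ... Unused.
#' @return A ggplot of the binned PMF with the fitted analytic term
#'   overlaid.
#' @export
autoplot.pmf_fit <- function(object, ...) {
  pmf <- tidy(object)
  p <- ggplot2::ggplot(pmf, ggplot2::aes(x = .data$bin_mid, y = .data$pmf)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = switch(object$kind, bond = "distance (Å)",
                             "angle (deg)"),
                  y = "PMF (kcal/mol)")
  grid <- tibble(bin_mid = seq(min(pmf$bin_mid), max(pmf$bin_mid),
                               length.out = 200))
  if (object$kind == "dihedral") {
    grid$fit <- object$pk *
      (1 + cos((object$pn * grid$bin_mid - object$phase) * pi / 180))
  } else {
    dx <- grid$bin_mid - object$equilibrium
    if (object$kind == "angle") dx <- dx * pi / 180
    grid$fit <- object$force_constant * dx^2
  }
  p + ggplot2::geom_line(data = grid,
                         ggplot2::aes(y = .data$fit), colour = "red3")
}

#' Measure internal coordinates across the models of a multi-model PDB
#'
#' Computes one distance (2 atoms), angle (3) or dihedral (4, signed by
#' the right-hand rule) per MODEL of a multi-model PDB file, yielding a
#' sample series ready for [fit_harmonic()] or [fit_dihedral()].
#'
#' @param path Multi-model PDB file.
#' @param selection Character vector of 2-4 atom names identifying the
#'   atoms (first match per name, optionally restricted to `chain`).
#' @param chain Optional chain id restriction.
#' @param temperature Ensemble temperature, K.
#' @return A [sample_series()] of the matching kind.
#' @export
measure_internal_coordinates <- function(path, selection, chain = NULL,
                                         temperature = 300) {
  if (!length(selection) %in% 2:4)
    abort("selection must name 2, 3 or 4 atoms")
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
  atoms <- pdb$atom
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  idx <- vapply(selection, function(nm) {
    hits <- which(keep & trimws(atoms$elety) == nm)
    if (!length(hits))
      abort(sprintf("atom '%s' not found in model 1", nm))
    hits[1]
  }, integer(1))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  get_pos <- function(model, i) xyz[model, (3 * (i - 1) + 1):(3 * i)]
  vals <- vapply(seq_len(n_models), function(m) {
    pts <- lapply(idx, function(i) get_pos(m, i))
    if (any(!vapply(pts, function(p) all(is.finite(p)), logical(1))))
      abort(sprintf("selection missing coordinates in model %d", m))
    switch(length(pts) - 1,
           vnorm(pts[[2]] - pts[[1]]),
           vec_angle_deg(pts[[1]], pts[[2]], pts[[3]]),
           vec_dihedral_deg(pts[[1]], pts[[2]], pts[[3]], pts[[4]]))
  }, numeric(1))
  kind <- c("bond", "angle", "dihedral")[length(selection) - 1]
  sample_series(vals, kind = kind, temperature = temperature)
}
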