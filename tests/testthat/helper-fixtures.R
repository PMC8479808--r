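## shared in-code fixtures; everything is generated, nothing is stored

## straight chain of n Z1 beads along +x at the given spacing
bead_chain <- function(n, spacing = 5.2, charge = -2) {
  gag_complex(
    receptor = tibble::tibble(
      serial = integer(), name = character(), resname = character(),
      chain = character(), resno = integer(),
      x = double(), y = double(), z = double(),
      element = character(), charge = double()),
    gag = tibble::tibble(
      serial = seq_len(n), name = "Z1", resname = "ZCG", chain = "A",
      resno = seq_len(n), x = spacing * (seq_len(n) - 1), y = 0, z = 0,
      element = "C", charge = charge, res_charge = charge),
    chain_id = "A")
}

## free-standing atom tibble for nonbonded tests
toy_atoms <- function(names, xyz, charges = NA_real_) {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  tibble::tibble(
    serial = seq_len(nrow(xyz)), name = names, resname = "TOY",
    chain = "T", resno = seq_len(nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = substr(names, 1, 1),
    charge = rep_len(charges, nrow(xyz)))
}

## independent all-pairs nonbonded sum (the brute-force oracle): plain
## double loop, no vectorization shared with the implementation
brute_force_nonbonded <- function(a, b, ff, es, cutoff = NULL) {
  kappa <- if (es$kind == "debye" && es$ionic_strength > 0)
    sqrt(es$ionic_strength) / 3.04 else 0
  lj_row <- ff$lj[ff$lj$type == "Z1", ]
  e_lj <- 0; e_c <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      r <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (!is.null(cutoff) && r > cutoff) next
      if (a$name[i] == "Z1" && b$name[j] == "Z1") {
        rmin <- 2 * lj_row$rvdw
        eps <- lj_row$edep
        e_lj <- e_lj + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
      }
      qi <- ifelse(is.na(a$charge[i]), 0, a$charge[i])
      qj <- ifelse(is.na(b$charge[j]), 0, b$charge[j])
      if (qi != 0 && qj != 0)
        e_c <- e_c + 332.0636 * qi * qj * exp(-kappa * r) /
          (es$dielectric * r)
    }
  }
  list(lj = e_lj, coulomb = e_c)
}

## minimal fixed-width multi-model PDB writer for measurement tests
write_multimodel_pdb <- function(path, atom_names, models,
                                 resname = "TOY", chain = "A") {
  lines <- character()
  for (m in seq_along(models)) {
    xyz <- matrix(models[[m]], ncol = 3, byrow = TRUE)
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_along(atom_names)) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, atom_names[i], resname, chain, i,
        xyz[i, 1], xyz[i, 2], xyz[i, 3], substr(atom_names[i], 1, 1)))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

apply_rigid <- function(x, tf) {
  new_xyz <- function(df) {
    if (!nrow(df)) return(df)
    m <- tf(as.matrix(df[, c("x", "y", "z")]))
    df$x <- m[, 1]; df$y <- m[, 2]; df$z <- m[, 3]
    df
  }
  gag_complex(new_xyz(x$receptor), new_xyz(x$gag), x$chain_id)
}
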