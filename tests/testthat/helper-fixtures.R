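# Fixtures are built in code: PDB text writers for ideal geometries and
# in-memory atomic models for kernel-level checks.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z, el,
                     het = FALSE) {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, paste0(" ", name), resname,
          chain, resno, x, y, z, 1.0, 10.0, el)
}

# Ideal poly-alanine helix backbone: N, CA, C, O all on a cylinder of the
# given radius, 1.5 A rise and 100 degree twist per residue.
make_helix_pdb_lines <- function(n_res = 20, radius = 2.3, rise = 1.5,
                                 twist = 100, chain = "A", z0 = 0,
                                 serial0 = 0) {
  phase_bb <- c(N = -25, CA = 0, C = 25, O = 35)
  lines <- character(0)
  serial <- serial0
  for (i in seq_len(n_res)) {
    base_ang <- (i - 1) * twist
    z <- (i - 1) * rise + z0
    for (at in names(phase_bb)) {
      ang <- (base_ang + phase_bb[[at]]) * pi / 180
      serial <- serial + 1
      lines <- c(lines, pdb_line(serial, at, "ALA", chain, i,
                                 radius * cos(ang), radius * sin(ang), z,
                                 substr(at, 1, 1)))
    }
  }
  lines
}

write_helix_pdb <- function(n_res = 20, ...) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(make_helix_pdb_lines(n_res, ...), "END"), tf)
  tf
}

# Bare atomic model from coordinates, bypassing file parsing (for kernel
# checks on arbitrary point sets).
raw_atomic_model <- function(xyz, element = "C", residue = "ALA") {
  n <- nrow(xyz)
  structure(list(
    atoms = data.frame(
      element = rep(element, length.out = n),
      atom_name = rep("CA", n), residue = rep(residue, length.out = n),
      resno = seq_len(n), chain = rep("A", n),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = rep(1, n), type = rep("ATOM", n),
      stringsAsFactors = FALSE),
    assembly = "asis"), class = "atomic_model")
}

# Noisy realization of an exact intensity with fixed fractional noise.
noisy_curve <- function(q, ideal, frac, seed, ...) {
  set.seed(seed)
  scattering_curve(q, ideal + stats::rnorm(length(q), 0, frac * ideal),
                   sigma = frac * ideal, ...)
}
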