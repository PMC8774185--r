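#' Read a 1D SAS curve from ASCII
#'
#' Reads the 2- or 3-column ASCII dialect used by reduced small-angle
#' scattering data (SASBDB-style `.dat`): columns Q (Angstrom^-1), I(Q), and
#' optionally sigma(I). Any line whose first token does not parse as a number
#' (comment, header, footer) is skipped; whitespace and comma separation are
#' both accepted, because deposited files vary.
#'
#' Metadata written by [write_curve()] (`# label:`, `# concentration:`,
#' `# pD:`) is recovered when present.
#'
#' @param path path to the file.
#' @param dialect one of `"auto"`, `"sasbdb"`, `"csv"`; `"csv"` forces comma
#'   splitting, the others sniff each line.
#' @return A [scattering_curve()].
#' @export
read_curve <- function(path, dialect = c("auto", "sasbdb", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)

  meta <- list(label = "", concentration = NA_real_, pd_value = NA_real_)
  for (ln in grep("^\\s*#", lines, value = TRUE)) {
    body <- sub("^\\s*#\\s*", "", ln)
    if (grepl("^label\\s*:", body, ignore.case = TRUE)) {
      meta$label <- trimws(sub("^label\\s*:", "", body, ignore.case = TRUE))
    } else if (grepl("^concentration\\s*:", body, ignore.case = TRUE)) {
      meta$concentration <- suppressWarnings(
        as.numeric(sub("mg/mL", "", sub("^concentration\\s*:", "", body, ignore.case = TRUE))))
    } else if (grepl("^pD\\s*:", body, ignore.case = TRUE)) {
      meta$pd_value <- suppressWarnings(
        as.numeric(sub("^pD\\s*:", "", body, ignore.case = TRUE)))
    }
  }

  rows <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    toks <- if (dialect == "csv") strsplit(ln, ",")[[1]] else
      strsplit(ln, "[,[:space:]]+")[[1]]
    toks <- trimws(toks)
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) < 2 || is.na(vals[1])) next  # header / non-data line
    if (any(is.na(vals[1:2]))) next
    rows[[length(rows) + 1L]] <- vals[seq_len(min(3, length(vals)))]
  }
  if (length(rows) < 5) {
    stop(sprintf("%s: found %d data rows; at least 5 are required", path, length(rows)))
  }
  ncols <- min(vapply(rows, length, 1L))
  m <- do.call(rbind, lapply(rows, function(r) r[seq_len(ncols)]))
  sigma <- if (ncols >= 3 && !anyNA(m[, 3])) m[, 3] else NULL
  scattering_curve(m[, 1], m[, 2], sigma, label = meta$label,
                   concentration = meta$concentration, pd_value = meta$pd_value)
}

#' Write a scattering curve as 3-column ASCII
#'
#' Writes `# `-prefixed metadata (label, concentration, pD) followed by the
#' data table: `Q I sigma`, or two columns when sigma is absent. Files written
#' here round-trip through [read_curve()] to 1e-9 relative precision.
#'
#' @param curve a [scattering_curve()].
#' @param path output path.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  hdr <- c(
    sprintf("# label: %s", curve$label),
    sprintf("# concentration: %s", if (is.na(curve$concentration)) "NA" else
      format(curve$concentration, digits = 15)),
    sprintf("# pD: %s", if (is.na(curve$pd_value)) "NA" else
      format(curve$pd_value, digits = 15)),
    if (is.null(curve$sigma)) "# Q I" else "# Q I sigma"
  )
  body <- if (is.null(curve$sigma)) {
    sprintf("%.12e %.12e", curve$q, curve$intensity)
  } else {
    sprintf("%.12e %.12e %.12e", curve$q, curve$intensity, curve$sigma)
  }
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write to %s", path))
  invisible(path)
}

WATER_RESIDUES <- c("HOH", "DOD", "WAT", "H2O", "D2O")

#' Read an atomic model from a PDB file
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}) into a flat atom table.
#' Waters are always dropped; HETATM groups such as the heme cofactor are
#' retained because they are part of the scatterer. Hydrogens are kept if
#' present.
#'
#' @param path path to a PDB-format file.
#' @param assembly `"monomer"` (first protein chain plus its non-water
#'   HETATM groups), `"dimer"` (all chains), or `"asis"` (everything except
#'   waters).
#' @return An object of class `atomic_model`: a list with `atoms` (data.frame
#'   with columns `element`, `atom_name`, `residue`, `resno`, `chain`, `x`,
#'   `y`, `z`, `occupancy`, `type`) and `assembly`.
#' @export
read_atomic_model <- function(path, assembly = c("asis", "monomer", "dimer")) {
  assembly <- match.arg(assembly)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0 || !any(at$type == "ATOM")) {
    stop(sprintf("%s: no ATOM records", path))
  }
  at <- at[!(toupper(at$resid) %in% WATER_RESIDUES), , drop = FALSE]

  elem <- toupper(trimws(at$elesy))
  need <- is.na(elem) | !nzchar(elem)
  if (any(need)) elem[need] <- infer_element(at$elety[need])
  known <- elem %in% names(NEUTRON_B)
  if (any(!known)) {
    stop(sprintf("unrecognized element for atom serial(s): %s",
                 paste(at$eleno[!known], collapse = ", ")))
  }
  xyz <- cbind(at$x, at$y, at$z)
  if (any(!is.finite(xyz))) stop("non-finite coordinates in PDB file")

  atoms <- data.frame(
    element = elem, atom_name = trimws(at$elety), residue = toupper(at$resid),
    resno = at$resno, chain = as.character(at$chain),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o), type = at$type,
    stringsAsFactors = FALSE
  )

  if (assembly == "monomer") {
    first_chain <- atoms$chain[atoms$type == "ATOM"][1]
    atoms <- atoms[atoms$chain == first_chain, , drop = FALSE]
  }
  structure(list(atoms = atoms, assembly = assembly), class = "atomic_model")
}

# Infer an element symbol from a PDB atom name: strip digits/primes, try the
# leading two characters, then one. Handles " CA " (carbon) vs "CA" ions by
# preferring the single-letter element for standard protein atom names.
infer_element <- function(atom_name) {
  vapply(atom_name, function(nm) {
    nm <- toupper(gsub("[0-9' ]", "", nm))
    if (!nzchar(nm)) return(NA_character_)
    one <- substr(nm, 1, 1)
    two <- substr(nm, 1, 2)
    if (one %in% c("C", "N", "O", "H", "S", "P")) return(one)
    if (two %in% names(NEUTRON_B)) return(two)
    if (one %in% names(NEUTRON_B)) return(one)
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %d atoms, %d chain(s), assembly = %s\n",
              nrow(x$atoms), length(unique(x$atoms$chain)), x$assembly))
  invisible(x)
}
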