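#' Molecule container
#'
#' The MD state carrier: element symbols, Cartesian coordinates (Angstrom),
#' nuclear velocities (Angstrom/fs), total charge and spin multiplicity.
#'
#' @param symbols Character vector of element symbols (validated against
#'   the packaged element table).
#' @param coords Numeric n x 3 matrix of positions, Angstrom.
#' @param velocities Numeric n x 3 matrix, Angstrom/fs; defaults to zeros.
#' @param charge Integer total charge.
#' @param multiplicity Positive integer spin multiplicity.
#' @return Object of class `molecule`.
#' @export
molecule <- function(symbols, coords, velocities = NULL, charge = 0L,
                     multiplicity = 1L) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (is.null(velocities)) velocities <- matrix(0, nrow(coords), 3)
  velocities <- matrix(as.numeric(velocities), ncol = 3)
  if (length(symbols) != nrow(coords) || nrow(coords) != nrow(velocities))
    stop("symbols, coords and velocities must describe the same atom count",
         call. = FALSE)
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  if (multiplicity < 1) stop("multiplicity must be >= 1", call. = FALSE)
  covalent_radii(symbols)  # errors on unknown symbols
  structure(list(symbols = as.character(symbols), coords = coords,
                 velocities = velocities, charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity)),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", format(formula_of(x)), ", ", length(x$symbols),
      " atoms, charge ", x$charge, ", mult ", x$multiplicity, "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A [molecule()].
#' @export
n_atoms <- function(mol) length(mol$symbols)

#' Parse XYZ text into a molecule
#'
#' Standard XYZ dialect: first line the atom count, second line a free
#' comment, then one `symbol x y z` line per atom (Angstrom).  A
#' `charge=<q>` and/or `mult=<m>` token in the comment line overrides the
#' defaults (charge 0, multiplicity 1).  Velocities are initialized to
#' zero.
#'
#' @param text A single string or character vector of lines.
#' @return A [molecule()].
#' @export
parse_xyz <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) < 2L) stop("XYZ parse error: fewer than 2 lines", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L)
    stop("XYZ parse error at line 1: malformed atom count '",
         trimws(lines[1]), "'", call. = FALSE)
  comment <- if (length(lines) >= 2L) lines[2] else ""
  atom_lines <- lines[-(1:2)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  if (length(atom_lines) != n)
    stop("XYZ parse error: declared ", n, " atoms but found ",
         length(atom_lines), " atom lines", call. = FALSE)
  symbols <- character(n); coords <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(atom_lines[i]), "\\s+")[[1]]
    if (length(parts) < 4L)
      stop("XYZ parse error at atom line ", i, ": '", atom_lines[i], "'",
           call. = FALSE)
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (any(is.na(xyz)))
      stop("XYZ parse error at atom line ", i, ": non-numeric coordinate",
           call. = FALSE)
    symbols[i] <- parts[1]; coords[i, ] <- xyz
  }
  charge <- 0L; mult <- 1L
  qm <- regmatches(comment, regexec("charge=(-?[0-9]+)", comment))[[1]]
  if (length(qm) == 2L) charge <- as.integer(qm[2])
  mm <- regmatches(comment, regexec("mult=([0-9]+)", comment))[[1]]
  if (length(mm) == 2L) mult <- as.integer(mm[2])
  tryCatch(
    molecule(symbols, coords, charge = charge, multiplicity = mult),
    error = function(e)
      stop("XYZ parse error: ", conditionMessage(e), call. = FALSE)
  )
}

#' Write a molecule as XYZ text
#'
#' @param mol A [molecule()].
#' @param comment Comment line; charge/multiplicity tokens are appended so
#'   that `parse_xyz(write_xyz(m))` round-trips them.
#' @param digits Coordinate digits (default 10, well inside the 1e-6
#'   Angstrom round-trip guarantee).
#' @return A single XYZ string.
#' @export
write_xyz <- function(mol, comment = "", digits = 10) {
  tokens <- comment
  if (mol$charge != 0L) tokens <- paste(tokens, sprintf("charge=%d", mol$charge))
  if (mol$multiplicity != 1L)
    tokens <- paste(tokens, sprintf("mult=%d", mol$multiplicity))
  body <- sprintf(paste0("%-3s %.", digits, "f %.", digits, "f %.", digits, "f"),
                  mol$symbols, mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  paste(c(as.character(n_atoms(mol)), trimws(tokens), body, ""), collapse = "\n")
}

#' Append one trajectory frame to a multi-frame XYZ file
#'
#' The per-frame comment carries the simulation time and energies so
#' trajectories can be inspected with standard viewers.
#'
#' @param state An `md_state` (see [md_state()]).
#' @param path File to append to.
#' @export
write_trajectory_frame <- function(state, path) {
  comment <- sprintf("t=%.3f fs Epot=%.8f eV Ekin=%.8f eV",
                     state$time, state$potential_energy, state$kinetic_energy)
  cat(write_xyz(state$mol, comment = comment), file = path, append = TRUE)
  invisible(path)
}

# subset a molecule's atoms (keeps velocities); used by fragment splitting
.subset_molecule <- function(mol, idx, charge = 0L) {
  molecule(mol$symbols[idx], mol$coords[idx, , drop = FALSE],
           mol$velocities[idx, , drop = FALSE], charge = charge,
           multiplicity = 1L)
}
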