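#' Molecular structure record
#'
#' The basic container for a chemical species: element symbols, Cartesian
#' coordinates in Angstrom, optional harmonic wavenumbers (negative values
#' encode imaginary modes, the quantum-chemistry flat-file convention),
#' a ground-state electronic energy in hartree, a spin multiplicity and a
#' role in a reaction (reactant, transition state or product).
#'
#' @param atoms character vector of element symbols.
#' @param coords numeric N x 3 matrix of Cartesian coordinates, Angstrom.
#' @param frequencies numeric vector of harmonic wavenumbers in cm^-1, or
#'   `NULL` if not yet attached.  A negative value encodes an imaginary mode.
#' @param electronic_energy ground-state electronic energy, hartree.
#' @param multiplicity positive integer spin multiplicity.
#' @param role one of `"reactant"`, `"transition_state"`, `"product"`.
#' @param id opaque identifier string.
#' @param comment free-text comment (XYZ line 2), kept as metadata.
#' @return an object of class `qest_structure`.
#' @export
structure_record <- function(atoms, coords, frequencies = NULL,
                             electronic_energy = NA_real_,
                             multiplicity = 1L,
                             role = c("reactant", "transition_state", "product"),
                             id = NULL, comment = "") {
  role <- match.arg(role)
  atoms <- as.character(atoms)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(atoms) < 1) stop("a structure needs at least one atom")
  if (nrow(coords) != length(atoms)) {
    stop("coords must have one row per atom (", length(atoms), " atoms, ",
         nrow(coords), " coordinate rows)")
  }
  atomic_mass(atoms)  # validates symbols
  if (!is.null(frequencies)) frequencies <- as.numeric(frequencies)
  multiplicity <- as.integer(multiplicity)
  if (is.na(multiplicity) || multiplicity < 1) {
    stop("multiplicity must be a positive integer")
  }
  s <- list(atoms = atoms, coords = coords, frequencies = frequencies,
            electronic_energy = as.numeric(electronic_energy),
            multiplicity = multiplicity, role = role,
            id = id %||% paste0("structure-", .hash_string(c(atoms, format(coords)))),
            comment = comment)
  class(s) <- "qest_structure"
  validate_structure(s, check_modes = FALSE)
  s
}

#' Validate a structure record
#'
#' Checks the structural invariants: coordinate/atom count agreement, the
#' mode-count bound (at most 3N - 5 real modes for N atoms), and the
#' role-dependent imaginary-mode rule -- a transition state carries exactly
#' one imaginary frequency, a reactant or product none beyond the
#' spurious-mode tolerance.
#'
#' @param s a `qest_structure`.
#' @param spurious_tol wavenumber magnitude (cm^-1) below which a mode is
#'   treated as numerical noise.
#' @param check_modes if `FALSE`, skip frequency-dependent checks (used
#'   before frequencies are attached).
#' @return `s`, invisibly; errors describe the violated invariant.
#' @export
validate_structure <- function(s, spurious_tol = 1.0, check_modes = TRUE) {
  stopifnot(inherits(s, "qest_structure"))
  n <- length(s$atoms)
  if (n < 1 || nrow(s$coords) != n) stop("len(coords) must equal len(atoms) >= 1")
  if (check_modes && !is.null(s$frequencies) && length(s$frequencies) > 0) {
    freqs <- s$frequencies
    n_imag <- sum(freqs < 0 & abs(freqs) >= spurious_tol)
    n_real <- sum(freqs > 0 & freqs >= spurious_tol)
    if (n_real > max(0, 3 * n - 5)) {
      stop("structure ", s$id, ": ", n_real, " real modes exceeds 3N-5 = ",
           3 * n - 5)
    }
    if (s$role == "transition_state" && n_imag != 1) {
      stop("transition state ", s$id, " must have exactly one imaginary mode, found ",
           n_imag)
    }
    if (s$role != "transition_state" && n_imag > 0) {
      stop(s$role, " ", s$id, " has ", n_imag,
           " imaginary mode(s) beyond the spurious tolerance")
    }
  }
  invisible(s)
}

#' @export
print.qest_structure <- function(x, ...) {
  cat(sprintf("<qest_structure %s> %d atoms (%s), role %s\n", x$id,
              length(x$atoms), paste(unique(x$atoms), collapse = ","), x$role))
  if (!is.null(x$frequencies)) {
    cat(sprintf("  %d frequencies, %d imaginary\n", length(x$frequencies),
                sum(x$frequencies < 0)))
  }
  invisible(x)
}

#' Read an XYZ-format structure
#'
#' Standard XYZ dialect: integer atom count, free comment line, then one
#' `symbol x y z` line per atom with coordinates in Angstrom.  Frequencies
#' and the electronic energy are unset until attached (XYZ has no field for
#' them); see [attach_frequencies()].
#'
#' @param x a file path, or a string containing the XYZ text itself (any
#'   input containing a newline is treated as literal text).
#' @param role,id passed to [structure_record()].
#' @return a `qest_structure`.
#' @export
#' @examples
#' read_xyz("1\ncomment\nH 0 0 0")
read_xyz <- function(x, role = "reactant", id = NULL) {
  lines <- if (length(x) > 1) {
    as.character(x)
  } else if (grepl("\n", x, fixed = TRUE)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    if (!file.exists(x)) stop("XYZ input is neither literal text nor an existing file: ", x)
    readLines(x)
  }
  if (length(lines) < 1) stop("empty XYZ input")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("line 1: malformed atom count '", lines[1], "'")
  comment <- if (length(lines) >= 2) lines[2] else ""
  if (length(lines) < n + 2) {
    stop("expected ", n, " coordinate lines, found ", max(0, length(lines) - 2))
  }
  atoms <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- n_line <- i + 2
    fields <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(fields) < 4) stop("line ", ln, ": expected 'symbol x y z', got '", lines[ln], "'")
    sym <- fields[1]
    if (!sym %in% names(.atomic_weights)) {
      stop("line ", ln, ": unknown element symbol '", sym, "'")
    }
    xyz <- suppressWarnings(as.numeric(fields[2:4]))
    if (anyNA(xyz)) stop("line ", ln, ": non-numeric coordinate in '", lines[ln], "'")
    atoms[i] <- sym
    coords[i, ] <- xyz
  }
  structure_record(atoms, coords, role = role, id = id, comment = comment)
}

#' Write a structure in XYZ format
#'
#' @param s a `qest_structure`.
#' @param file optional path; if `NULL` the XYZ text is returned as a string.
#' @param digits printed coordinate precision.
#' @return the XYZ text, invisibly if written to a file.
#' @export
write_xyz <- function(s, file = NULL, digits = 8) {
  stopifnot(inherits(s, "qest_structure"))
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  body <- vapply(seq_along(s$atoms), function(i) {
    sprintf(fmt, s$atoms[i], s$coords[i, 1], s$coords[i, 2], s$coords[i, 3])
  }, character(1))
  txt <- paste(c(length(s$atoms), s$comment %||% "", body), collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Attach frequencies and energy to a structure
#'
#' @param s a `qest_structure`.
#' @param frequencies harmonic wavenumbers, cm^-1 (negative = imaginary).
#' @param electronic_energy optional ground-state energy, hartree.
#' @param multiplicity optional spin multiplicity.
#' @param role optional role reassignment.
#' @param spurious_tol passed to [validate_structure()].
#' @return the updated, validated `qest_structure`.
#' @export
attach_frequencies <- function(s, frequencies, electronic_energy = NULL,
                               multiplicity = NULL, role = NULL,
                               spurious_tol = 1.0) {
  stopifnot(inherits(s, "qest_structure"))
  s$frequencies <- as.numeric(frequencies)
  if (!is.null(electronic_energy)) s$electronic_energy <- as.numeric(electronic_energy)
  if (!is.null(multiplicity)) s$multiplicity <- as.integer(multiplicity)
  if (!is.null(role)) {
    s$role <- match.arg(role, c("reactant", "transition_state", "product"))
  }
  validate_structure(s, spurious_tol = spurious_tol)
  s
}

#' Read a frequency sidecar file
#'
#' Plain text, one wavenumber (cm^-1) per line; blank lines and `#`-comments
#' are ignored.
#'
#' @param file path to the sidecar file.
#' @return numeric vector of wavenumbers.
#' @export
read_frequency_file <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  v <- suppressWarnings(as.numeric(lines))
  if (anyNA(v)) stop("non-numeric frequency line(s) in ", file)
  v
}

# ---- JSON structure / reaction records -------------------------------------

.structure_to_list <- function(s) {
  list(id = s$id, atoms = s$atoms,
       coords = unname(apply(s$coords, 1, as.numeric, simplify = FALSE)),
       frequencies = s$frequencies, energy = s$electronic_energy,
       multiplicity = s$multiplicity, role = s$role, comment = s$comment)
}

.structure_from_list <- function(x) {
  structure_record(
    atoms = unlist(x$atoms),
    coords = do.call(rbind, lapply(x$coords, as.numeric)),
    frequencies = if (length(x$frequencies)) as.numeric(unlist(x$frequencies)) else NULL,
    electronic_energy = x$energy %||% NA_real_,
    multiplicity = x$multiplicity %||% 1L,
    role = x$role %||% "reactant", id = x$id, comment = x$comment %||% "")
}

#' Write / read JSON dataset records for structures and reactions
#'
#' The JSON record format carries `{id, atoms, coords, frequencies, energy,
#' multiplicity, role}` per structure; a reactions file is a JSON array of
#' `{reaction_id, ea_hartree, temperatures, reactant, ts, product}`.
#'
#' @param reactions list of `qest_reaction` records.
#' @param file output / input path.
#' @return `read_reactions_json` returns a list of `qest_reaction`.
#' @export
write_reactions_json <- function(reactions, file) {
  payload <- lapply(reactions, function(r) {
    list(reaction_id = r$reaction_id, ea_hartree = r$ea,
         temperatures = r$temperatures,
         reactant = .structure_to_list(r$reactant),
         ts = .structure_to_list(r$ts),
         product = .structure_to_list(r$product))
  })
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname write_reactions_json
#' @export
read_reactions_json <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = FALSE)
  lapply(payload, function(x) {
    reaction_record(
      reaction_id = x$reaction_id,
      reactant = .structure_from_list(x$reactant),
      ts = .structure_from_list(x$ts),
      product = .structure_from_list(x$product),
      ea = as.numeric(x$ea_hartree),
      temperatures = as.numeric(unlist(x$temperatures)))
  })
}

#' Reaction record
#'
#' Groups the reactant, transition-state and product structures of one
#' unimolecular gas-phase reaction with its activation energy (hartree,
#' the TS - reactant ground-state energy gap) and the per-reaction set of
#' sampled temperatures.
#'
#' @param reaction_id identifier string.
#' @param reactant,ts,product `qest_structure` objects with matching roles.
#' @param ea activation energy, hartree.
#' @param temperatures numeric vector of temperatures, K (may be empty and
#'   sampled later by the dataset builder).
#' @return an object of class `qest_reaction`.
#' @export
reaction_record <- function(reaction_id, reactant, ts, product, ea,
                            temperatures = numeric(0)) {
  stopifnot(inherits(reactant, "qest_structure"),
            inherits(ts, "qest_structure"),
            inherits(product, "qest_structure"))
  if (reactant$role != "reactant") stop("first structure must have role 'reactant'")
  if (ts$role != "transition_state") stop("second structure must have role 'transition_state'")
  if (product$role != "product") stop("third structure must have role 'product'")
  temperatures <- as.numeric(temperatures)
  if (anyDuplicated(temperatures)) stop("temperatures must be pairwise distinct")
  r <- list(reaction_id = as.character(reaction_id), reactant = reactant,
            ts = ts, product = product, ea = as.numeric(ea),
            temperatures = temperatures)
  class(r) <- "qest_reaction"
  r
}

#' @export
print.qest_reaction <- function(x, ...) {
  cat(sprintf("<qest_reaction %s> Ea = %.4f hartree, %d temperatures\n",
              x$reaction_id, x$ea, length(x$temperatures)))
  invisible(x)
}
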