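# Structure readers and binding-core extraction.
#
# Atom tables are plain data.frames with columns
#   serial  : integer, source-file atom index (unique within a structure)
#   element : chemical element symbol, normalised ("Cl", not "CL")
#   x, y, z : coordinates in Angstrom
#   charge  : partial charge in elementary-charge units (NA when absent)

#' Recognised element symbols
#'
#' The element universes used by the element-specific bipartite graphs.
#' Distance-mode graphs use heavy atoms only; electrostatic-mode graphs add
#' hydrogen on both sides because H dominates short-range electrostatics.
#'
#' @format Character vectors of element symbols, in the fixed order that
#'   defines the feature-vector layout.
#' @name element_universe
NULL

#' @rdname element_universe
#' @export
PROTEIN_ELEMENTS_DISTANCE <- c("C", "N", "O", "S")

#' @rdname element_universe
#' @export
LIGAND_ELEMENTS_DISTANCE <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

#' @rdname element_universe
#' @export
PROTEIN_ELEMENTS_ELECTROSTATIC <- c("C", "N", "O", "S", "H")

#' @rdname element_universe
#' @export
LIGAND_ELEMENTS_ELECTROSTATIC <- c("C", "N", "O", "S", "P", "F", "Cl", "Br",
                                   "I", "H")

# All symbols this package will ever see in practice; used only to sanity
# check normalisation, never to silently drop atoms.
.known_elements <- c(
  "H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I",
  "B", "Si", "Se", "Na", "K", "Mg", "Ca", "Zn", "Fe", "Mn", "Cu", "Co",
  "Ni", "Cd", "Hg", "As", "D"
)

.water_resids <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

#' Normalise an element symbol
#'
#' Upper-cases the first character and lower-cases the rest, so that PDB
#' column values such as `"CL"` become `"Cl"`.
#'
#' @param x character vector of raw symbols.
#' @return character vector of normalised symbols.
#' @keywords internal
normalize_element <- function(x) {
  x <- gsub("[^A-Za-z]", "", x)
  out <- ifelse(
    nchar(x) == 0L, "",
    paste0(toupper(substr(x, 1L, 1L)), tolower(substr(x, 2L, nchar(x))))
  )
  out
}

# Derive an element from a PDB/PQR atom-name field when the element column
# is blank.  Two-letter elements (Cl, Br, ...) are recognised from the first
# two alphabetic characters; everything else falls back to the first letter.
.element_from_name <- function(name) {
  vapply(name, function(nm) {
    letters_only <- gsub("[^A-Za-z]", "", nm)
    if (nchar(letters_only) == 0L) return("")
    two <- normalize_element(substr(letters_only, 1L, 2L))
    if (two %in% c("Cl", "Br", "Fe", "Zn", "Mg", "Na", "Ca", "Se")) {
      return(two)
    }
    normalize_element(substr(letters_only, 1L, 1L))
  }, character(1), USE.NAMES = FALSE)
}

.atom_table <- function(serial, element, x, y, z, charge = NA_real_) {
  bad <- !is.finite(x) | !is.finite(y) | !is.finite(z)
  if (any(bad)) {
    stop("non-finite coordinates for atom serial(s): ",
         paste(serial[bad], collapse = ", "))
  }
  data.frame(
    serial = as.integer(serial),
    element = as.character(element),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    charge = as.numeric(charge),
    stringsAsFactors = FALSE
  )
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records into an atom table.  The element is taken from
#' the PDB element column (columns 77-78) when present, falling back to the
#' atom-name field.  Hydrogens are retained (they are needed for the
#' electrostatic mode).  Water residues are dropped; alternate locations
#' other than blank or "A" are dropped so the atom set is deterministic.
#'
#' @param path path to a PDB file.
#' @param keep_waters keep water residues (default `FALSE`).
#' @return a data.frame of atoms (columns `serial`, `element`, `x`, `y`,
#'   `z`, `charge`).
#' @export
read_protein_structure <- function(path, keep_waters = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("no ATOM/HETATM records in '", path, "'")
  }
  # altloc: keep blank or "A" only
  alt <- at$alt
  keep <- is.na(alt) | alt == "" | alt == "A"
  if (!keep_waters) keep <- keep & !(toupper(at$resid) %in% .water_resids)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no usable atoms left in '", path, "'")
  elem <- normalize_element(at$elesy)
  blank <- is.na(elem) | elem == ""
  if (any(blank)) elem[blank] <- .element_from_name(at$elety[blank])
  bad <- !(elem %in% .known_elements)
  if (any(bad)) {
    stop("unrecognised element symbol(s) ",
         paste(unique(elem[bad]), collapse = ", "),
         " in '", path, "' (e.g. atom serial ", at$eleno[which(bad)[1]], ")")
  }
  .atom_table(at$eleno, elem, at$x, at$y, at$z)
}

# MOL2 SYBYL atom types carry the element before the first dot ("C.ar").
.element_from_sybyl <- function(type) {
  normalize_element(sub("\\..*$", "", type))
}

#' Read a ligand structure from a MOL2 or SDF file
#'
#' For MOL2 the per-atom charge column populates `charge`; a MOL2 file whose
#' charge type is `NO_CHARGES` yields atoms with absent charges.  For SDF
#' (V2000 atom block) charges are absent.
#'
#' @param path path to a `.mol2`, `.sdf` or `.mol` file.
#' @return a data.frame of atoms.
#' @export
read_ligand_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mol2") {
    .read_mol2_atoms(path)
  } else if (ext %in% c("sdf", "mol")) {
    .read_sdf_atoms(path)
  } else {
    stop("unknown ligand file extension '.", ext,
         "' (expected .mol2, .sdf or .mol)")
  }
}

.read_mol2_atoms <- function(path) {
  mol <- withCallingHandlers(
    tryCatch(
      bio3d::read.mol2(path),
      error = function(e) stop("failed to parse MOL2 file '", path, "': ",
                               conditionMessage(e))
    ),
    # bond records carry no atom information; their absence is fine
    warning = function(w) {
      if (grepl("No BOND records", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  at <- mol$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atoms in MOL2 file '", path, "'")
  elem <- .element_from_sybyl(at$elety)
  charge <- if ("charge" %in% names(at)) as.numeric(at$charge) else NA_real_
  # a MOL2 written with NO_CHARGES carries a column of zeros or NAs; bio3d
  # returns whatever is printed, so absent columns are the only "no charge"
  .atom_table(at$eleno, elem, at$x, at$y, at$z, charge)
}

.read_sdf_atoms <- function(path) {
  sdf <- tryCatch(
    ChemmineR::read.SDFset(path),
    error = function(e) stop("failed to parse SDF file '", path, "': ",
                             conditionMessage(e))
  )
  if (length(sdf) == 0L) stop("no molecules in SDF file '", path, "'")
  ab <- ChemmineR::atomblock(sdf[[1]])
  if (is.null(ab) || nrow(ab) == 0L) stop("empty atom block in '", path, "'")
  elem <- normalize_element(sub("_.*$", "", rownames(ab)))
  .atom_table(seq_len(nrow(ab)), elem, ab[, 1], ab[, 2], ab[, 3])
}

#' Attach partial charges from a PQR file
#'
#' Matches PQR records to structure atoms by serial number and copies the
#' charge column.  Unmatched atoms keep an absent charge and are reported;
#' if fewer than `min_match` of the structure's atoms are matched the files
#' are assumed to be mispaired and an error is raised.
#'
#' @param structure atom table (from [read_protein_structure()]).
#' @param path path to a PQR file.
#' @param min_match minimum matched fraction before erroring (default 0.9).
#' @return the structure with its `charge` column populated.
#' @export
attach_charges <- function(structure, path, min_match = 0.9) {
  if (!file.exists(path)) stop("file not found: ", path)
  pqr <- tryCatch(
    bio3d::read.pqr(path),
    error = function(e) stop("failed to parse PQR file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pqr$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atoms in PQR file '", path, "'")
  # bio3d stores the PQR charge in the occupancy slot "o"
  idx <- match(structure$serial, as.integer(at$eleno))
  matched <- !is.na(idx)
  frac <- mean(matched)
  if (frac < min_match) {
    stop(sprintf(
      "only %.0f%% of atoms matched between structure and PQR '%s'; wrong file pairing?",
      100 * frac, path))
  }
  structure$charge[matched] <- as.numeric(at$o)[idx[matched]]
  if (any(!matched)) {
    warning("no PQR charge for atom serial(s): ",
            paste(structure$serial[!matched], collapse = ", "))
  }
  structure
}

#' Extract the binding core of a protein-ligand pair
#'
#' Keeps every protein atom whose minimum Euclidean distance to any ligand
#' atom is at most `cutoff` (inclusive); the ligand is kept whole.  The
#' default 10 Angstrom cutoff matches the filtration's upper endpoint so no
#' discarded atom could ever enter a thresholded graph.
#'
#' @param protein,ligand atom tables.
#' @param cutoff core cutoff in Angstrom (default 10).
#' @param label optional binding-affinity label (pKd/pKi).
#' @param id optional complex identifier.
#' @return a `molecular_complex` object: list with elements
#'   `protein` and `ligand` (atom tables), `label`, `id`.
#' @export
extract_binding_core <- function(protein, ligand, cutoff = 10,
                                 label = NA_real_, id = "complex") {
  stopifnot(is.data.frame(protein), is.data.frame(ligand))
  if (nrow(protein) == 0L || nrow(ligand) == 0L) {
    stop("protein and ligand structures must be non-empty")
  }
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  pd <- .pairwise_distances(protein, ligand)
  mind <- apply(pd, 1L, min)
  core <- protein[mind <= cutoff, , drop = FALSE]
  if (nrow(core) == 0L) {
    stop("no protein atom within ", cutoff,
         " Angstrom of the ligand: no binding-site contact")
  }
  molecular_complex(core, ligand, label = label, id = id)
}

#' Construct a molecular complex
#'
#' @param protein,ligand atom tables (non-empty, disjoint serials are not
#'   required: the two sides index separate structures).
#' @param label optional affinity label (pKd/pKi units).
#' @param id identifier string.
#' @return object of class `molecular_complex`.
#' @export
molecular_complex <- function(protein, ligand, label = NA_real_,
                              id = "complex") {
  stopifnot(is.data.frame(protein), is.data.frame(ligand))
  if (nrow(protein) == 0L || nrow(ligand) == 0L) {
    stop("both atom lists must be non-empty")
  }
  structure(
    list(protein = protein, ligand = ligand,
         label = as.numeric(label), id = as.character(id)),
    class = "molecular_complex"
  )
}

#' @export
print.molecular_complex <- function(x, ...) {
  cat("Molecular complex '", x$id, "'\n", sep = "")
  cat("  protein atoms:", nrow(x$protein),
      " (", paste(sort(unique(x$protein$element)), collapse = ","), ")\n")
  cat("  ligand atoms: ", nrow(x$ligand),
      " (", paste(sort(unique(x$ligand$element)), collapse = ","), ")\n")
  if (!is.na(x$label)) cat("  label (pKd/pKi):", format(x$label), "\n")
  invisible(x)
}

.pairwise_distances <- function(a, b) {
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rep(1, nrow(bx))) +
    outer(rep(1, nrow(ax)), rowSums(bx^2)) - 2 * ax %*% t(bx)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Write an atom table as a minimal PDB file
#'
#' Coordinates are written at 3-decimal PDB precision.  Intended for
#' serialising synthetic fixtures so the file-reading path is testable.
#'
#' @param atoms atom table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_atoms <- function(atoms, path) {
  el_col <- ifelse(nchar(atoms$element) == 1L,
                   paste0(" ", atoms$element), atoms$element)
  name <- ifelse(nchar(atoms$element) == 1L,
                 sprintf(" %s%-2d", atoms$element,
                         (seq_len(nrow(atoms)) - 1L) %% 100L),
                 sprintf("%s%-2d", toupper(atoms$element),
                         (seq_len(nrow(atoms)) - 1L) %% 100L))
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$serial, substr(name, 1, 4), "UNK", 1L,
    atoms$x, atoms$y, atoms$z, 1.0, 0.0, toupper(el_col))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write an atom table as a minimal MOL2 file
#'
#' Charges (when present) are written in the standard per-atom charge
#' column with charge type `USER_CHARGES`.
#'
#' @param atoms atom table.
#' @param path output path.
#' @param name molecule name.
#' @return `path`, invisibly.
#' @export
write_mol2_atoms <- function(atoms, path, name = "synthetic") {
  has_charge <- !all(is.na(atoms$charge))
  charge_type <- if (has_charge) "USER_CHARGES" else "NO_CHARGES"
  hdr <- c("@<TRIPOS>MOLECULE", name,
           sprintf("%d 0 0 0 0", nrow(atoms)),
           "SMALL", charge_type, "@<TRIPOS>ATOM")
  ch <- ifelse(is.na(atoms$charge), 0, atoms$charge)
  rows <- sprintf("%7d %-8s %9.4f %9.4f %9.4f %-6s %5d %-8s %9.4f",
                  atoms$serial,
                  paste0(toupper(atoms$element), seq_len(nrow(atoms))),
                  atoms$x, atoms$y, atoms$z, atoms$element, 1L, "LIG", ch)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
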