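#' Van der Waals radii by element
#'
#' Bondi-type radii (Angstrom) used for steric clash tests in the accessible
#' volume engine and for solvent-accessible surface areas. Unknown elements
#' fall back to the carbon radius.
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

guess_element <- function(elety) {
  # first alphabetic character of the PDB atom name is the element for
  # standard protein atoms (no two-letter metals expected here)
  toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", elety)), 1, 1))
}

#' Load a protein structure from PDB text or file
#'
#' Thin wrapper around `bio3d::read.pdb` that returns a uniform atom table
#' used by the accessible-volume engine and the structural metrics.
#'
#' @param source Path to a PDB file, or a character vector of PDB lines.
#' @return Object of class `structure_model`: list with `atoms` (data.frame
#'   `eleno, elety, resid, chain, resno, x, y, z, elem, vdw`) and the
#'   underlying `pdb` object.
#' @export
load_structure <- function(source) {
  path <- source
  if (length(source) > 1L || grepl("\n", source[1]) ||
      (!file.exists(source[1]) && grepl("^(ATOM|HETATM|HEADER|REMARK)", source[1]))) {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(source, "\n")), path)
    on.exit(unlink(path))
  }
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("malformed PDB input: ",
                                           conditionMessage(e)))
  a <- pdb$atom
  if (nrow(a) == 0L) stop("malformed PDB input: no ATOM/HETATM records parsed")
  if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))) {
    bad <- which(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))
    stop("malformed PDB input: unparseable coordinates at atom record(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- guess_element(a$elety)
  } else {
    elem[is.na(elem) | elem == ""] <- guess_element(a$elety[is.na(elem) | elem == ""])
  }
  atoms <- data.frame(
    eleno = a$eleno, elety = a$elety, resid = a$resid,
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    resno = a$resno, x = a$x, y = a$y, z = a$z,
    elem = toupper(elem), stringsAsFactors = FALSE
  )
  if (anyDuplicated(atoms$eleno)) stop("duplicate atom identifiers in PDB")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in PDB")
  }
  atoms$vdw <- vdw_radius(atoms$elem)
  structure(list(atoms = atoms, pdb = pdb), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, chains %s\n", nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Coordinate matrix of (a selection of) a structure
#'
#' @param structure `structure_model`.
#' @param chain Optional chain id(s) to keep.
#' @param resno Optional residue number(s) to keep.
#' @param elety Optional atom name(s) to keep (e.g. `"CA"`).
#' @return Numeric matrix with columns x, y, z (Angstrom).
#' @export
structure_coords <- function(structure, chain = NULL, resno = NULL,
                             elety = NULL) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  as.matrix(a[keep, c("x", "y", "z")])
}

#' Build a toy structure and its PDB representation
#'
#' Constructs a `structure_model` from an explicit atom list and writes it
#' through the standard PDB writer, so coordinates round-trip at PDB
#' precision (0.001 Angstrom). Used to build small synthetic test structures
#' (single atoms, walls, dimers with dummy cysteine attachment sites) that
#' stand in for crystallographic inputs.
#'
#' @param atoms data.frame with columns `x, y, z` (Angstrom) and optionally
#'   `elety` (atom name, default "CA"), `elem` (element, default from name),
#'   `chain` (default "A"), `resno` (default sequential), `resid` (default
#'   "GLY").
#' @param file Optional path for the PDB file; a tempfile by default.
#' @return List with `structure` (`structure_model`), `file` and `pdb_text`.
#' @export
make_toy_structure <- function(atoms, file = tempfile(fileext = ".pdb")) {
  stopifnot(is.data.frame(atoms), all(c("x", "y", "z") %in% names(atoms)))
  n <- nrow(atoms)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("coordinates must be finite")
  }
  elety <- atoms$elety %||% rep("CA", n)
  chain <- atoms$chain %||% rep("A", n)
  resno <- atoms$resno %||% seq_len(n)
  resid <- atoms$resid %||% rep("GLY", n)
  key <- paste(chain, resno, elety)
  if (anyDuplicated(key)) stop("duplicate atom identifiers (chain/resno/name)")
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  elem <- atoms$elem %||% guess_element(elety)
  bio3d::write.pdb(file = file, xyz = xyz, resno = resno, chain = chain,
                   resid = resid, elety = elety, elesy = elem,
                   eleno = seq_len(n))
  list(structure = load_structure(file), file = file,
       pdb_text = readLines(file))
}
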