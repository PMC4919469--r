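# Lightweight atomic-structure container: a data.frame of heavy atoms
# with author residue numbering, built from a PDB file (via bio3d) or by
# the synthetic geometry generators.

#' Build a structure object from an atom table
#'
#' @param atoms data.frame with columns \code{chain}, \code{residue_number}
#'   (integer, author numbering), \code{residue_type} (3-letter code),
#'   \code{atom_name}, \code{element}, \code{x}, \code{y}, \code{z}
#'   (Angstrom).
#' @param model_id model number the atoms came from (NMR ensembles).
#' @return object of class \code{"protein_structure"}.
#' @export
protein_structure <- function(atoms, model_id = 1L) {
  need <- c("chain", "residue_number", "residue_type", "atom_name",
            "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("protein_structure: missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1L) stop("protein_structure: need at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("protein_structure: coordinates must be finite")
  atoms$residue_number <- as.integer(atoms$residue_number)
  structure(list(atoms = atoms[, need], model_id = as.integer(model_id)),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("Protein structure: %d atoms, %d residues, model %d\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$residue_number))),
              x$model_id))
  invisible(x)
}

#' Read a PDB file into a structure object
#'
#' Only the requested model of a multi-model (NMR ensemble) file is kept
#' (default: first).  Author residue numbering is honored; no renumbering
#' is performed.
#'
#' @param path PDB file (ATOM/HETATM records).
#' @param model model number for multi-model files (default 1).
#' @param keep_hydrogens keep H atoms (default FALSE; they are excluded
#'   from SASA anyway).
#' @return a \code{\link{protein_structure}}.
#' @export
read_structure <- function(path, model = 1L, keep_hydrogens = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nmod <- if (!is.null(pdb$xyz) && is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model > nmod) stop("read_structure: file has only ", nmod, " model(s)")
  if (nmod > 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  elem <- at$elesy
  blank <- is.na(elem) | elem == ""
  if (any(blank))  # fall back to first letter of the atom name
    elem[blank] <- substr(gsub("[0-9]", "", at$elety[blank]), 1, 1)
  atoms <- data.frame(chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
                      residue_number = at$resno,
                      residue_type = at$resid,
                      atom_name = at$elety,
                      element = toupper(elem),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  if (!keep_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  protein_structure(atoms, model_id = model)
}

#' Write a structure object to a PDB file
#'
#' @param struct a \code{\link{protein_structure}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(struct, path) {
  a <- struct$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$residue_number, resid = a$residue_type,
                   eleno = seq_len(nrow(a)), elety = a$atom_name,
                   chain = a$chain, elesy = a$element)
  invisible(path)
}
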