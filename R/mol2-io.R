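## minimal SYBYL atom typing from element + connectivity degree
.sybylType <- function(element, degree) {
  el <- toupper(element)
  switch(el,
    H = "H",
    C = if (degree >= 4L) "C.3" else if (degree == 3L) "C.2" else "C.1",
    N = if (degree >= 3L) "N.3" else if (degree == 2L) "N.2" else "N.1",
    O = if (degree >= 2L) "O.3" else "O.2",
    S = "S.3", ZN = "Zn", F = "F", CL = "Cl", BR = "Br", I = "I",
    P = "P.3",
    el)
}

#' Write a complex as TRIPOS MOL2 with partial charges
#'
#' All atoms of the complex (target, ligand, waters, ions in order) are
#' written to a TRIPOS MOL2 file with per-atom partial charges in the
#' charge column; the bond block is perceived from interatomic distances
#' ([perceiveBonds()], single bonds).  The charge vector must supply one
#' charge per atom in complex atom order.
#'
#' @param model A [ComplexModel-class].
#' @param charges A [ChargeSet-class] with one charge per complex atom.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeMOL2 <- function(model, charges, path) {
  a <- atoms(model)
  if (length(charges@charges) != nrow(a))
    stop(sprintf("charge/atom count mismatch: %d charges for %d atoms",
                 length(charges@charges), nrow(a)))
  s <- molecularStructure(transform(a, role = "ligand"), label = "mol2")
  bonds <- perceiveBonds(s)
  degree <- tabulate(c(bonds$i, bonds$j), nbins = nrow(a))
  atomDf <- data.frame(
    eleno = seq_len(nrow(a)), elena = a$name,
    x = a$x, y = a$y, z = a$z,
    elety = vapply(seq_len(nrow(a)),
                   function(i) .sybylType(a$element[i], degree[i]),
                   character(1)),
    resno = a$resid, resid = paste0(a$resname, a$resid),
    charge = charges@charges, statbit = NA_character_,
    stringsAsFactors = FALSE)
  bondDf <- data.frame(id = seq_len(nrow(bonds)), origin = bonds$i,
                       target = bonds$j, type = rep("1", nrow(bonds)),
                       statbit = NA_character_)
  mol <- structure(list(atom = atomDf, bond = bondDf, substructure = NULL,
                        xyz = bio3d::as.xyz(matrix(as.numeric(t(as.matrix(
                          a[, c("x", "y", "z")]))), nrow = 1L)),
                        info = c(nrow(atomDf), nrow(bondDf), 1, NA, NA),
                        name = "peprefine export"),
                   class = "mol2")
  bio3d::write.mol2(mol, file = path)
  invisible(path)
}

#' Read a TRIPOS MOL2 file
#'
#' @param path MOL2 file.
#' @return list with `structure` (a [MolecularStructure-class], role
#'   "ligand") and `charges` (a [ChargeSet-class]; charge sum rounded to
#'   the nearest integer is used as the formal total).
#' @export
readMOL2 <- function(path) {
  m <- bio3d::read.mol2(path)
  el <- sub("\\..*$", "", m$atom$elety)
  a <- data.frame(serial = as.integer(m$atom$eleno), name = m$atom$elena,
                  element = el,
                  resname = toupper(sub("[0-9]+$", "", m$atom$resid)),
                  resid = as.integer(m$atom$resno), chain = " ",
                  x = m$atom$x, y = m$atom$y, z = m$atom$z,
                  heavy = toupper(el) != "H", role = "ligand",
                  stringsAsFactors = FALSE)
  ch <- m$atom$charge
  list(structure = molecularStructure(a, label = m$name),
       charges = new("ChargeSet", charges = ch,
                     totalFormalCharge = sum(ch),
                     method = "mol2"))
}
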