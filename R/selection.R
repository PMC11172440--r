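.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Construct an AtomSelection predicate
#'
#' @param kind one of "all_heavy", "backbone", "calpha", "n_terminal_k",
#'   "custom".
#' @param k residue count for `n_terminal_k` (default 5, the tightly
#'   bound N-terminal head of a histone H3 tail).
#' @param names atom names for `custom`.
#' @return An unresolved [AtomSelection-class].
#' @examples
#' atomSelection("n_terminal_k", k = 5)
#' @export
atomSelection <- function(kind = "all_heavy", k = 5L, names = character()) {
  new("AtomSelection", kind = kind, k = as.integer(k), names = names)
}

.resolveOnAtoms <- function(a, sel, ligandChain = FALSE) {
  switch(sel@kind,
    all_heavy = which(a$heavy),
    backbone = which(a$heavy & a$name %in% c("N", "CA", "C", "O")),
    calpha = which(a$name == "CA" & a$resname %in% .AA3),
    n_terminal_k = {
      if (!ligandChain)
        stop("n_terminal_k is defined on the ligand chain only")
      resOrder <- unique(a$resid)
      if (sel@k > length(resOrder))
        stop(sprintf("k = %d exceeds ligand length %d", sel@k, length(resOrder)))
      which(a$heavy & a$resid %in% resOrder[seq_len(sel@k)])
    },
    custom = which(a$name %in% sel@names),
    stop("unknown selection kind: ", sel@kind))
}

#' Resolve a selection against one component of a complex
#'
#' Populates the atom indices of a selection predicate against the atoms
#' of the given role.  `all_heavy` excludes hydrogens; `calpha` selects
#' CA atoms of amino-acid residues; `n_terminal_k` selects heavy atoms of
#' the first k residues of the ligand chain.
#'
#' @param model A [ComplexModel-class].
#' @param sel An [AtomSelection-class] (see [atomSelection()]).
#' @param on role to resolve against: "target" or "ligand".
#' @return The selection with `indices` populated (row indices into the
#'   component's atom table).
#' @export
resolveSelection <- function(model, sel, on = c("ligand", "target")) {
  on <- match.arg(on)
  a <- atoms(slot(model, on))
  idx <- .resolveOnAtoms(a, sel, ligandChain = (on == "ligand"))
  if (!length(idx))
    stop(sprintf("selection '%s' resolves to no atoms on %s", sel@kind, on))
  sel@indices <- as.integer(idx)
  sel
}

#' Pair corresponding atoms between two structures
#'
#' Atoms are paired by (chain, residue index, atom name); snapshots and
#' references derive from the same topology, so this identifies the same
#' physical atom in both.  Pairs are ordered by `a`'s atom order and every
#' selected atom of `a` is paired exactly once.
#'
#' @param a,b [MolecularStructure-class] objects covering the selection.
#' @param sel an [AtomSelection-class]; if unresolved it is resolved
#'   against `a` (for `n_terminal_k`, `a` is taken to be the ligand
#'   chain).
#' @return list with integer vectors `ia`, `ib` (row indices into the
#'   atom tables of `a` and `b`).
#' @export
correspond <- function(a, b, sel = atomSelection("all_heavy")) {
  aa <- atoms(a); ab <- atoms(b)
  ia <- if (length(sel@indices)) sel@indices
        else .resolveOnAtoms(aa, sel, ligandChain = TRUE)
  if (!length(ia)) stop("selection resolves to no atoms")
  keyA <- paste(aa$chain, aa$resid, aa$name)[ia]
  keyB <- paste(ab$chain, ab$resid, ab$name)
  ib <- match(keyA, keyB)
  if (anyNA(ib)) {
    miss <- keyA[is.na(ib)]
    stop(sprintf("no corresponding atom in '%s' for: %s",
                 b@label, paste(utils::head(miss, 10L), collapse = "; ")))
  }
  list(ia = as.integer(ia), ib = as.integer(ib))
}
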