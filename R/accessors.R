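#' Construct a MolecularStructure
#'
#' @param atoms data.frame with the canonical atom columns (see
#'   [emptyAtoms()]); the `heavy` column is filled in from `element` if
#'   missing.
#' @param label character label.
#' @return A [MolecularStructure-class] object.
#' @examples
#' a <- emptyAtoms()
#' molecularStructure(a, label = "empty")
#' @export
molecularStructure <- function(atoms = emptyAtoms(), label = "") {
  if (is.null(atoms$heavy)) atoms$heavy <- toupper(atoms$element) != "H"
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL
  new("MolecularStructure", atoms = atoms[, .atomColumns], label = label)
}

#' Construct a ComplexModel from role-tagged components
#'
#' @param target,ligand,waters,ions [MolecularStructure-class] objects
#'   (may be empty).
#' @return A [ComplexModel-class] object.
#' @export
complexModel <- function(target = molecularStructure(),
                         ligand = molecularStructure(),
                         waters = molecularStructure(),
                         ions = molecularStructure()) {
  new("ComplexModel", target = target, ligand = ligand,
      waters = waters, ions = ions)
}

#' @rdname atoms
#' @export
setGeneric("atoms", function(x, ...) standardGeneric("atoms"))

#' Atom table accessors
#'
#' `atoms()` returns the atom data frame of a structure, or the row-bound
#' atom table of a whole complex (target, ligand, waters, ions in order).
#' `coords()` returns the n x 3 coordinate matrix in Angstrom.
#' `nAtoms()` counts atoms.
#'
#' @param x A [MolecularStructure-class] or [ComplexModel-class].
#' @param ... Unused.
#' @return `atoms()`: data.frame; `coords()`: numeric matrix;
#'   `nAtoms()`: integer.
#' @aliases atoms coords nAtoms
#' @export
setMethod("atoms", "MolecularStructure", function(x, ...) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "ComplexModel", function(x, ...) {
  rbind(x@target@atoms, x@ligand@atoms, x@waters@atoms, x@ions@atoms)
})

#' @rdname atoms
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname atoms
#' @export
setMethod("coords", "MolecularStructure", function(x, ...) {
  as.matrix(x@atoms[, c("x", "y", "z")])
})

#' @rdname atoms
#' @export
setMethod("coords", "ComplexModel", function(x, ...) {
  as.matrix(atoms(x)[, c("x", "y", "z")])
})

#' @rdname atoms
#' @export
setGeneric("nAtoms", function(x, ...) standardGeneric("nAtoms"))

#' @rdname atoms
#' @export
setMethod("nAtoms", "MolecularStructure", function(x, ...) nrow(x@atoms))

#' @rdname atoms
#' @export
setMethod("nAtoms", "ComplexModel", function(x, ...) nrow(atoms(x)))

#' Component accessors for ComplexModel
#'
#' @param x A [ComplexModel-class].
#' @return The requested [MolecularStructure-class] component.
#' @aliases target ligand waters ions
#' @rdname components
#' @export
setGeneric("target", function(x) standardGeneric("target"))
#' @rdname components
#' @export
setMethod("target", "ComplexModel", function(x) x@target)
#' @rdname components
#' @export
setGeneric("ligand", function(x) standardGeneric("ligand"))
#' @rdname components
#' @export
setMethod("ligand", "ComplexModel", function(x) x@ligand)
#' @rdname components
#' @export
setGeneric("waters", function(x) standardGeneric("waters"))
#' @rdname components
#' @export
setMethod("waters", "ComplexModel", function(x) x@waters)
#' @rdname components
#' @export
setGeneric("ions", function(x) standardGeneric("ions"))
#' @rdname components
#' @export
setMethod("ions", "ComplexModel", function(x) x@ions)

#' Replace coordinates of a structure
#'
#' @param x A [MolecularStructure-class].
#' @param value n x 3 numeric matrix in Angstrom.
#' @return The structure with updated coordinates.
#' @rdname setCoords
#' @export
setGeneric("setCoords", function(x, value) standardGeneric("setCoords"))

#' @rdname setCoords
#' @export
setMethod("setCoords", "MolecularStructure", function(x, value) {
  stopifnot(nrow(value) == nAtoms(x), ncol(value) == 3L)
  x@atoms$x <- value[, 1L]; x@atoms$y <- value[, 2L]; x@atoms$z <- value[, 3L]
  x
})

#' Residue table of a structure
#'
#' One row per residue in atom order, with chain, residue index and name.
#'
#' @param x A [MolecularStructure-class].
#' @return data.frame with columns chain, resid, resname.
#' @export
residues <- function(x) {
  a <- atoms(x)
  unique(a[, c("chain", "resid", "resname")])
}

setMethod("show", "MolecularStructure", function(object) {
  a <- object@atoms
  cat(sprintf("MolecularStructure '%s': %d atoms, %d residues\n",
              object@label, nrow(a), nrow(residues(object))))
})

setMethod("show", "ComplexModel", function(object) {
  cat("ComplexModel\n")
  for (p in c("target", "ligand", "waters", "ions")) {
    s <- slot(object, p)
    cat(sprintf("  %-7s %5d atoms, %4d residues\n",
                p, nAtoms(s), nrow(residues(s))))
  }
})

setMethod("show", "AtomSelection", function(object) {
  cat(sprintf("AtomSelection kind='%s'%s: %d resolved atoms\n",
              object@kind,
              if (object@kind == "n_terminal_k") sprintf(" (k=%d)", object@k) else "",
              length(object@indices)))
})

setMethod("show", "RefinementReport", function(object) {
  cat(sprintf(paste0("RefinementReport: RMSD_start %.2f A, RMSD_best %.2f A ",
                     "(t = %.1f ns)\n  dRMSD %.2f A (%.1f%%), RF %.2f 1/ns, ",
                     "%d frames\n"),
              object@rmsdStart, object@rmsdBest, object@bestFrameTime,
              object@deltaRmsd, object@deltaRmsdPercent, object@rf,
              length(object@perFrameRmsd)))
})

setMethod("show", "WaterMatchResult", function(object) {
  cat(sprintf("WaterMatchResult: %d/%d matched (< %.2f A), SR = %s\n",
              nrow(object@matches), object@nReference, object@tolerance,
              if (is.na(object@successRate)) "undefined (empty reference)"
              else sprintf("%.1f%%", object@successRate)))
})

setMethod("show", "EnergyProfile", function(object) {
  cat(sprintf("EnergyProfile: %d ligand residues, total E_inter %.2f kcal/mol\n",
              nrow(object@residues), sum(object@residues$eInter)))
})

setMethod("show", "ProtocolSpec", function(object) {
  cat(sprintf(paste0("ProtocolSpec %s: initial %g ns + SA %g ns (max %g K)",
                     "%s\n  restraints: %s%s\n"),
              object@id, object@initialMdNs, sum(object@saSteps$duration),
              object@saMaxTemp,
              if (object@finalFlexMdNs > 0)
                sprintf(" + flexible %g ns", object@finalFlexMdNs) else "",
              object@restraintScheme,
              if (object@truncatePeptide) ", truncated peptide" else ""))
})

setMethod("show", "TrajectorySeries", function(object) {
  cat(sprintf("TrajectorySeries: %d frames at %g ns spacing (%g ns total)\n",
              length(object@frames), object@frameSpacing,
              length(object@frames) * object@frameSpacing))
})

#' Accessors for refinement reports
#'
#' @param x A [RefinementReport-class].
#' @return Numeric scalar (or vector for `perFrameRmsd`).
#' @aliases rmsdStart rmsdBest deltaRmsdValue deltaRmsdPercent
#'   residenceFrequency perFrameRmsd
#' @rdname report-accessors
#' @export
rmsdStart <- function(x) x@rmsdStart
#' @rdname report-accessors
#' @export
rmsdBest <- function(x) x@rmsdBest
#' @rdname report-accessors
#' @export
deltaRmsdValue <- function(x) x@deltaRmsd
#' @rdname report-accessors
#' @export
deltaRmsdPercent <- function(x) x@deltaRmsdPercent
#' @rdname report-accessors
#' @export
residenceFrequency <- function(x) x@rf
#' @rdname report-accessors
#' @export
perFrameRmsd <- function(x) x@perFrameRmsd

#' Accessors for water match results
#'
#' @param x A [WaterMatchResult-class].
#' @return `successRate()`: percent (NA for an empty reference set);
#'   `waterMatches()`: data.frame of matched pairs.
#' @rdname watermatch-accessors
#' @export
successRate <- function(x) x@successRate
#' @rdname watermatch-accessors
#' @export
waterMatches <- function(x) x@matches

#' Accessors for energy profiles
#'
#' @param x An [EnergyProfile-class].
#' @return `energyTable()`: per-residue data.frame with eLJ, eCoulomb,
#'   eInter in kcal/mol.
#' @rdname energy-accessors
#' @export
energyTable <- function(x) x@residues

#' @rdname protocol-accessors
#' @export
protocolId <- function(x) x@id
#' Accessors for protocol specifications
#'
#' @param x A [ProtocolSpec-class].
#' @return `protocolId()`: character; `saSteps()`: the plateau ladder
#'   data.frame; `stageLengths()`: named numeric vector of stage lengths
#'   in ns (initial, sa, flex).
#' @aliases protocolId saSteps stageLengths
#' @rdname protocol-accessors
#' @export
saSteps <- function(x) x@saSteps
#' @rdname protocol-accessors
#' @export
stageLengths <- function(x) {
  c(initial = x@initialMdNs, sa = sum(x@saSteps$duration),
    flex = x@finalFlexMdNs)
}
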