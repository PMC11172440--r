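#' Construct a RigidTransform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric vector, Angstrom.
#' @return A [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = translation)
}

#' Apply or invert a rigid transform
#'
#' `applyTransform()` maps coordinates x to R x + t; it accepts an n x 3
#' matrix, a [MolecularStructure-class] or a whole [ComplexModel-class]
#' (all components move together).  `invertTransform()` returns the
#' inverse transform.
#'
#' @param x coordinates or structure to transform.
#' @param tr A [RigidTransform-class].
#' @return Same class as `x`.
#' @rdname applyTransform
#' @export
setGeneric("applyTransform", function(x, tr) standardGeneric("applyTransform"))

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "matrix", function(x, tr) {
  sweep(x %*% t(tr@rotation), 2L, tr@translation, "+")
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "MolecularStructure", function(x, tr) {
  if (!nAtoms(x)) return(x)
  setCoords(x, applyTransform(coords(x), tr))
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "ComplexModel", function(x, tr) {
  for (p in c("target", "ligand", "waters", "ions"))
    slot(x, p) <- applyTransform(slot(x, p), tr)
  x
})

#' @rdname applyTransform
#' @export
invertTransform <- function(tr) {
  Rt <- t(tr@rotation)
  rigidTransform(Rt, as.numeric(-Rt %*% tr@translation))
}

## Kabsch least-squares rotation on centred coordinate pairs; proper
## rotation enforced by sign-flipping the smallest singular direction.
.kabsch <- function(P, Q) {
  H <- crossprod(P, Q)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  sv$v %*% D %*% t(sv$u)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the proper rigid-body transform that minimizes the RMSD of
#' the selected, corresponded atoms of `mobile` onto `reference` —
#' typically the target C-alpha atoms, the fit used before any ligand
#' RMSD is measured.  Reflections are forbidden: the returned rotation
#' has determinant +1.
#'
#' @param mobile,reference [ComplexModel-class] objects sharing topology
#'   over the selection.
#' @param sel An [AtomSelection-class]; default C-alpha.
#' @param on component the selection refers to (default "target").
#' @return A [RigidTransform-class] mapping `mobile` coordinates onto
#'   `reference`.
#' @examples
#' cfg <- fixtureConfig(seed = 1)
#' m <- makeToyComplex(cfg)
#' tr <- superposeKabsch(m$docked, m$reference)
#' @export
superposeKabsch <- function(mobile, reference,
                            sel = atomSelection("calpha"),
                            on = "target") {
  selR <- resolveSelection(mobile, sel, on = on)
  pr <- correspond(slot(mobile, on), slot(reference, on), selR)
  P <- coords(slot(mobile, on))[pr$ia, , drop = FALSE]
  Q <- coords(slot(reference, on))[pr$ib, , drop = FALSE]
  if (nrow(P) < 3L) stop("superposition needs at least 3 paired atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  ## collinearity check: rank of the centred cloud
  if (sum(svd(Pc)$d > 1e-8) < 2L)
    stop("degenerate (collinear) selection geometry")
  R <- .kabsch(Pc, Qc)
  rigidTransform(R, as.numeric(cq - R %*% cp))
}
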