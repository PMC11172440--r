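## single-bond covalent radii (Angstrom) for distance-based bond perception
.COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
                F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, ZN = 1.22,
                "NA" = 1.66, MG = 1.41, K = 2.03, FE = 1.32, MN = 1.39,
                CU = 1.32, CD = 1.44)

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance lies between 0.4 Angstrom and
#' the sum of their covalent radii plus `tol`.  Adequate for standard
#' biomolecular geometries; no bond orders are assigned (single by
#' default, see [writeMOL2()]).
#'
#' @param structure A [MolecularStructure-class].
#' @param tol slack added to the covalent-radius sum (default 0.45 A).
#' @return data.frame with columns i, j (atom row indices, i < j) and
#'   dist (Angstrom).
#' @export
perceiveBonds <- function(structure, tol = 0.45) {
  a <- atoms(structure)
  n <- nrow(a)
  empty <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (n < 2L) return(empty)
  el <- toupper(a$element)
  r <- .COV_RADII[el]
  if (anyNA(r))
    stop("no covalent radius for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "))
  d <- as.matrix(stats::dist(coords(structure)))
  lim <- outer(r, r, "+") + tol
  hit <- which(d > 0.4 & d < lim & upper.tri(d), arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  data.frame(i = hit[, 1L], j = hit[, 2L], dist = d[hit])
}

## PEOE electronegativity coefficients chi(q) = a + b q + c q^2 by
## element/hybridization (Gasteiger-Marsili parameter set); chiPlus is
## the cation electronegativity a + b + c used as the damping
## denominator, with the special value 20.02 for hydrogen.
.PEOE <- local({
  tab <- rbind(
    H     = c(7.17,  6.24, -0.56),
    C.sp3 = c(7.98,  9.18,  1.88),
    C.sp2 = c(8.79,  9.32,  1.51),
    C.sp1 = c(10.39, 9.45,  0.73),
    N.sp3 = c(11.54, 10.82, 1.36),
    N.sp2 = c(12.87, 11.15, 0.85),
    N.sp1 = c(15.68, 11.70, -0.27),
    O.sp3 = c(14.18, 12.92, 1.39),
    O.sp2 = c(17.07, 13.79, 0.47),
    F     = c(14.66, 13.85, 2.31),
    CL    = c(11.00, 9.69,  1.35),
    BR    = c(10.08, 8.47,  1.16),
    I     = c(9.90,  7.96,  0.96),
    S.sp3 = c(10.14, 9.13,  1.38))
  colnames(tab) <- c("a", "b", "c")
  data.frame(tab, chiPlus = ifelse(rownames(tab) == "H", 20.02,
                                   rowSums(tab)))
})

## nominal charges for isolated monoatomic ions (no PEOE parameters)
.ION_CHARGES <- c(ZN = 2, MG = 2, "NA" = 1, K = 1, CL = -1, MN = 2,
                  FE = 2, CU = 2, CD = 2)

## hybridization from connectivity: degree counts all bonded neighbours
.peoeType <- function(element, degree, atomName) {
  el <- toupper(element)
  switch(el,
    H = "H",
    C = if (degree >= 4L) "C.sp3" else if (degree == 3L) "C.sp2" else "C.sp1",
    N = if (degree >= 3L) "N.sp3" else if (degree == 2L) "N.sp2" else "N.sp1",
    O = if (degree >= 2L) "O.sp3" else "O.sp2",
    S = "S.sp3",
    F = "F", CL = "CL", BR = "BR", I = "I",
    stop(sprintf("no PEOE parameters for element '%s' (atom %s)",
                 element, atomName)))
}

#' Gasteiger-Marsili partial charges (PEOE)
#'
#' Iterative partial equalization of orbital electronegativities: in each
#' iteration n, charge flows across every bond from the less to the more
#' electronegative atom, scaled by the damping factor (1/2)^n and by the
#' cation electronegativity of the donor atom; atom electronegativities
#' chi(q) = a + b q + c q^2 are updated from the accumulated charges.
#' The sum of charges is conserved exactly, equal to the total formal
#' charge.  Hybridization is perceived from connectivity
#' ([perceiveBonds()]), so hydrogens should be present where their
#' charges matter (polar hydrogens at minimum).  Isolated monoatomic
#' ions (Zn2+, Na+, Cl-, ...) keep their nominal ionic charge and do not
#' take part in the equalization.
#'
#' @param structure A [MolecularStructure-class].
#' @param iterations damping iterations (default 6).
#' @param formalCharges optional numeric vector of per-atom formal
#'   charges (default all zero).
#' @param bonds optional precomputed bond table from [perceiveBonds()].
#' @return A [ChargeSet-class] with one charge per atom, in elementary
#'   charge units.
#' @references Gasteiger, J. and Marsili, M. (1980) Iterative partial
#'   equalization of orbital electronegativity: a rapid access to atomic
#'   charges. Tetrahedron 36, 3219-3228.
#' @export
assignGasteiger <- function(structure, iterations = 6L,
                            formalCharges = NULL, bonds = NULL) {
  a <- atoms(structure)
  n <- nrow(a)
  if (is.null(formalCharges)) formalCharges <- numeric(n)
  stopifnot(length(formalCharges) == n)
  if (is.null(bonds)) bonds <- perceiveBonds(structure)
  degree <- tabulate(c(bonds$i, bonds$j), nbins = n)
  ## isolated monoatomic ions carry their nominal ionic charge and take
  ## no part in the equalization
  ion <- degree == 0L & toupper(a$element) %in% names(.ION_CHARGES)
  formalCharges[ion & formalCharges == 0] <-
    .ION_CHARGES[toupper(a$element[ion & formalCharges == 0])]
  live <- which(!ion)
  type <- rep("H", n)
  type[live] <- vapply(live,
                 function(i) .peoeType(a$element[i], degree[i], a$name[i]),
                 character(1))
  p <- .PEOE[type, ]
  q <- as.numeric(formalCharges)
  if (nrow(bonds)) {
    damp <- 0.5
    for (iter in seq_len(iterations)) {
      chi <- p$a + p$b * q + p$c * q^2
      dq <- numeric(n)
      for (bi in seq_len(nrow(bonds))) {
        i <- bonds$i[bi]; j <- bonds$j[bi]
        if (chi[i] == chi[j]) next
        if (chi[i] < chi[j]) { lo <- i; hi <- j } else { lo <- j; hi <- i }
        t <- (chi[hi] - chi[lo]) / p$chiPlus[lo] * damp
        dq[lo] <- dq[lo] + t       # donor becomes more positive
        dq[hi] <- dq[hi] - t       # acceptor gains electron density
      }
      q <- q + dq
      damp <- damp * 0.5
    }
  }
  new("ChargeSet", charges = q, totalFormalCharge = sum(formalCharges),
      method = "gasteiger")
}

#' Merge nonpolar hydrogens into their carbons (united-atom charges)
#'
#' AutoDock-style polar-hydrogen preparation: after all-atom charge
#' assignment, the charge of every hydrogen bonded to carbon is folded
#' into that carbon and the hydrogen is dropped; hydrogens on N, O and S
#' (polar) are retained.  The total charge is unchanged.
#'
#' @param structure A [MolecularStructure-class].
#' @param charges matching [ChargeSet-class] (e.g. from
#'   [assignGasteiger()]).
#' @return list with the reduced `structure` and its `charges`.
#' @export
mergeNonpolarH <- function(structure, charges) {
  a <- atoms(structure)
  stopifnot(length(charges@charges) == nrow(a))
  bonds <- perceiveBonds(structure)
  q <- charges@charges
  drop <- logical(nrow(a))
  isH <- toupper(a$element) == "H"
  for (bi in seq_len(nrow(bonds))) {
    i <- bonds$i[bi]; j <- bonds$j[bi]
    if (isH[i] && toupper(a$element[j]) == "C") { q[j] <- q[j] + q[i]; drop[i] <- TRUE }
    if (isH[j] && toupper(a$element[i]) == "C") { q[i] <- q[i] + q[j]; drop[j] <- TRUE }
  }
  list(structure = molecularStructure(a[!drop, , drop = FALSE],
                                      label = structure@label),
       charges = new("ChargeSet", charges = q[!drop],
                     totalFormalCharge = charges@totalFormalCharge,
                     method = paste0(charges@method, "+unitedC")))
}
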