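#' Amber-style Lennard-Jones parameter table
#'
#' Per-atom-type half-minimum radii R_i (Angstrom, Rmin/2 so that
#' R_ij = R_i + R_j is the pair minimum) and well depths eps_i (kcal/mol)
#' in the Amber force-field convention, shipped as plain text under
#' `extdata/amber_lj.csv`.  Values follow the parm99/ff99SB Lennard-Jones
#' block for protein atom classes plus a structural Zn2+ entry.
#'
#' @return data.frame with columns type, R, eps.
#' @export
amberLJTable <- function() {
  utils::read.csv(system.file("extdata", "amber_lj.csv",
                              package = "peprefine"),
                  stringsAsFactors = FALSE)
}

## element fallback types for atoms with no name-based assignment
.LJ_ELEMENT_FALLBACK <- c(C = "CT", N = "N", O = "O", S = "S", H = "HC",
                          P = "P", ZN = "Zn")

#' Assign Amber LJ atom types by residue/atom-name lookup
#'
#' Protein atoms are mapped by PDB atom name (backbone C -> C, carbonyl
#' and carboxylate O -> O/O2, hydroxyl O -> OH, all N -> N, aliphatic
#' C -> CT, ...); anything unmatched falls back to an element default
#' with a warning.
#'
#' @param structure A [MolecularStructure-class].
#' @return character vector of LJ type names, one per atom.
#' @export
assignLJTypes <- function(structure) {
  a <- atoms(structure)
  el <- toupper(a$element)
  nm <- a$name
  type <- rep(NA_character_, nrow(a))
  type[el == "C"] <- "CT"
  type[el == "C" & nm == "C"] <- "C"
  type[el == "C" & nm == "CZ" & a$resname %in% c("ARG", "PHE", "TYR")] <- "CA"
  type[el == "C" & nm == "CD" & a$resname %in% c("GLN", "GLU")] <- "C"
  type[el == "N"] <- "N"
  type[el == "N" & nm == "NZ"] <- "N3"
  type[el == "N" & nm %in% c("NH1", "NH2", "NE")] <- "N2"
  type[el == "O"] <- "O"
  type[el == "O" & nm %in% c("OXT", "OD1", "OD2", "OE1", "OE2")] <- "O2"
  type[el == "O" & nm %in% c("OG", "OG1", "OH")] <- "OH"
  type[el == "S"] <- "S"
  type[el == "H"] <- "HC"
  type[el == "H" & substr(nm, 1, 2) %in% c("H", "HN")] <- "HC"
  type[el == "ZN"] <- "Zn"
  unk <- is.na(type)
  if (any(unk)) {
    fb <- .LJ_ELEMENT_FALLBACK[el[unk]]
    if (anyNA(fb))
      stop("no LJ parameters for element(s): ",
           paste(unique(el[unk][is.na(fb)]), collapse = ", "))
    warning("element-default LJ types used for atoms: ",
            paste(unique(nm[unk]), collapse = ", "))
    type[unk] <- fb
  }
  type
}

#' Sigmoidal distance-dependent dielectric model
#'
#' eps_r(r) = A + B / (1 + k exp(-lambda B r)) with B = eps0 - A.  The
#' defaults are the Mehler-Solmajer constants A = -8.5525,
#' lambda = 0.003627, k = 7.7839 and eps0 = 78.4 (bulk water at 25 C),
#' the standard parameterization of this functional form.  eps_r rises
#' monotonically from its short-range value toward the bulk-water
#' asymptote, screening long-range Coulomb interactions.
#'
#' @param A,lambda,k,eps0Water model constants.
#' @return A [DielectricModel-class].
#' @export
dielectricModel <- function(A = -8.5525, lambda = 0.003627, k = 7.7839,
                            eps0Water = 78.4) {
  new("DielectricModel", A = A, lambda = lambda, k = k,
      eps0Water = eps0Water)
}

#' Evaluate the distance-dependent dielectric
#'
#' @param r distance(s) in Angstrom, non-negative.
#' @param model A [DielectricModel-class].
#' @return eps_r(r), dimensionless, same length as `r`.
#' @examples
#' epsilonR(1e9)  # ~78.4, the bulk-water limit
#' @export
epsilonR <- function(r, model = dielectricModel()) {
  stopifnot(all(r >= 0))
  B <- model@eps0Water - model@A
  model@A + B / (1 + model@k * exp(-model@lambda * B * r))
}

#' Lennard-Jones pair coefficients under Amber combination rules
#'
#' R_ij = R_i + R_j, eps_ij = sqrt(eps_i eps_j), A_ij = eps_ij R_ij^12,
#' B_ij = 2 eps_ij R_ij^6, so the pair potential A/r^12 - B/r^6 has its
#' minimum -eps_ij at r = R_ij.
#'
#' @param typeI,typeJ LJ type names present in `table`.
#' @param table data.frame from [amberLJTable()].
#' @return named numeric vector with elements A and B (kcal/mol * A^12,
#'   kcal/mol * A^6).
#' @export
ljPairParams <- function(typeI, typeJ, table = amberLJTable()) {
  ri <- match(typeI, table$type); rj <- match(typeJ, table$type)
  if (is.na(ri)) stop("unknown LJ type: ", typeI)
  if (is.na(rj)) stop("unknown LJ type: ", typeJ)
  Rij <- table$R[ri] + table$R[rj]
  eij <- sqrt(table$eps[ri] * table$eps[rj])
  c(A = eij * Rij^12, B = 2 * eij * Rij^6)
}

## electrostatic constant: q_i q_j / r in e^2/Angstrom -> kcal/mol
.K_ELEC <- 332.06

#' Per-residue target-ligand interaction energy
#'
#' E_inter = E_LJ + E_Coulomb summed over all (target atom, ligand atom)
#' pairs, decomposed per ligand residue.  The Lennard-Jones term uses
#' Amber combination rules ([ljPairParams()]); the Coulomb term is
#' q_i q_j * 332.06 / (eps_r(r) * r) kcal/mol with the sigmoidal
#' distance-dependent dielectric ([epsilonR()]).  No distance cutoff is
#' applied (full double sum); waters and ions are excluded from both
#' sums.
#'
#' @param model A [ComplexModel-class].
#' @param targetCharges,ligandCharges [ChargeSet-class] objects covering
#'   the target and ligand atoms; defaults are Gasteiger charges
#'   computed on the atoms as given ([assignGasteiger()]).
#' @param table LJ parameter table ([amberLJTable()]).
#' @param dielectric A [DielectricModel-class].
#' @return An [EnergyProfile-class] with one row per ligand residue.
#' @export
perResidueEinter <- function(model,
                             targetCharges = NULL, ligandCharges = NULL,
                             table = amberLJTable(),
                             dielectric = dielectricModel()) {
  tg <- target(model); lg <- ligand(model)
  if (!nAtoms(tg) || !nAtoms(lg)) stop("complex must have target and ligand atoms")
  if (is.null(targetCharges)) targetCharges <- assignGasteiger(tg)
  if (is.null(ligandCharges)) ligandCharges <- assignGasteiger(lg)
  qT <- targetCharges@charges; qL <- ligandCharges@charges
  stopifnot(length(qT) == nAtoms(tg), length(qL) == nAtoms(lg))
  tyT <- assignLJTypes(tg); tyL <- assignLJTypes(lg)
  iT <- match(tyT, table$type); iL <- match(tyL, table$type)
  XT <- coords(tg); XL <- coords(lg)
  d2 <- outer(rowSums(XT^2), rowSums(XL^2), "+") - 2 * XT %*% t(XL)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 1e-6)) stop("coincident target/ligand atoms (r = 0)")
  Rij <- outer(table$R[iT], table$R[iL], "+")
  eij <- sqrt(outer(table$eps[iT], table$eps[iL]))
  r6 <- (Rij / r)^6
  eLJ <- eij * (r6^2 - 2 * r6)                    # A/r^12 - B/r^6
  eC <- .K_ELEC * outer(qT, qL) / (epsilonR(r, dielectric) * r)
  la <- atoms(lg)
  resKey <- paste(la$chain, la$resid)
  resOrder <- unique(resKey)
  rows <- lapply(resOrder, function(k) {
    colsel <- resKey == k
    data.frame(resid = la$resid[colsel][1L],
               resname = la$resname[colsel][1L],
               eLJ = sum(eLJ[, colsel]),
               eCoulomb = sum(eC[, colsel]))
  })
  res <- do.call(rbind, rows)
  res$eInter <- res$eLJ + res$eCoulomb
  new("EnergyProfile", residues = res)
}

#' Total target-ligand interaction energy
#'
#' Sum of the per-residue E_inter values; equals the un-partitioned
#' whole-ligand double sum by construction.
#'
#' @param profile An [EnergyProfile-class].
#' @return kcal/mol (0 for an empty profile).
#' @export
totalEinter <- function(profile) {
  sum(profile@residues$eInter)
}

#' Flag anchoring residues that dominate the interaction energy
#'
#' Peptides often bind through a few conserved anchoring residues (for
#' histone H3: A1, R2 and K4) whose favorable per-residue E_inter
#' dominates the total.  Residues whose (negative) E_inter contributes at
#' least `fraction` of the total favorable energy are flagged.
#'
#' @param profile An [EnergyProfile-class].
#' @param fraction dominance threshold (default 0.4).
#' @return data.frame of the profile rows with an added `share` column,
#'   restricted to flagged residues, ordered by increasing E_inter.
#' @export
anchoringResidues <- function(profile, fraction = 0.4) {
  r <- profile@residues
  tot <- sum(r$eInter[r$eInter < 0])
  if (tot >= 0) return(cbind(r[0, ], share = numeric()))
  r$share <- ifelse(r$eInter < 0, r$eInter / tot, 0)
  out <- r[r$share >= fraction, , drop = FALSE]
  out[order(out$eInter), , drop = FALSE]
}
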