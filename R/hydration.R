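#' Construct a WaterSet
#'
#' @param oxygens n x 3 matrix of water oxygen coordinates, Angstrom.
#' @param ids integer water residue ids (default 1..n).
#' @param source "predicted", "crystallographic" or "trajectory".
#' @return A [WaterSet-class].
#' @export
waterSet <- function(oxygens, ids = seq_len(nrow(oxygens)),
                     source = "predicted") {
  new("WaterSet", oxygens = oxygens, ids = as.integer(ids), source = source)
}

#' Water oxygens of a complex as a WaterSet
#'
#' @param model A [ComplexModel-class].
#' @param source source tag for the resulting set.
#' @return A [WaterSet-class] with one oxygen per water residue.
#' @export
complexWaterSet <- function(model, source = "crystallographic") {
  a <- atoms(waters(model))
  o <- a[toupper(a$element) == "O", , drop = FALSE]
  waterSet(as.matrix(o[, c("x", "y", "z")]), ids = o$resid, source = source)
}

## min distance from each row of `pts` to any row of `ref`
.minDistTo <- function(pts, ref) {
  if (!nrow(pts)) return(numeric())
  if (!nrow(ref)) return(rep(Inf, nrow(pts)))
  apply(pts, 1L, function(p) {
    sqrt(min(colSums((t(ref) - p)^2)))
  })
}

.heavyCoords <- function(s) {
  a <- atoms(s)
  as.matrix(a[a$heavy, c("x", "y", "z"), drop = FALSE])
}

#' Remove waters clashing with the docked ligand and merge the complex
#'
#' Pre-MD hydration editing: a hydrated target and a docked ligand are
#' placed in a common frame, and every water whose oxygen lies strictly
#' closer than `dmin` to any ligand heavy atom is removed as a whole
#' residue (default dmin 1.75 Angstrom).  All surviving waters are kept
#' untouched and the merged complex (target, ligand, surviving waters,
#' ions) is returned.
#'
#' @param hydratedTarget [ComplexModel-class] carrying target, predicted
#'   waters and any structural ions.
#' @param ligand docked ligand [MolecularStructure-class].
#' @param dmin minimum allowed water-oxygen/ligand-heavy-atom distance,
#'   Angstrom; a water at exactly `dmin` is retained.
#' @return merged [ComplexModel-class].
#' @export
stripClashingWaters <- function(hydratedTarget, ligand, dmin = 1.75) {
  stopifnot(dmin > 0)
  wa <- atoms(waters(hydratedTarget))
  lig <- .heavyCoords(ligand)
  if (nrow(wa) && nrow(lig)) {
    ox <- wa[toupper(wa$element) == "O", , drop = FALSE]
    d <- .minDistTo(as.matrix(ox[, c("x", "y", "z")]), lig)
    clash <- ox$resid[d < dmin]
    wa <- wa[!(wa$resid %in% clash), , drop = FALSE]
  }
  complexModel(target = target(hydratedTarget), ligand = ligand,
               waters = molecularStructure(wa, label = "waters"),
               ions = ions(hydratedTarget))
}

#' Interface waters of a complex
#'
#' Waters whose oxygen lies within `dmax` (default 3.5 Angstrom,
#' non-strict) of at least one target heavy atom and at least one ligand
#' heavy atom — the reference positions for water-match scoring.
#'
#' @param model A [ComplexModel-class] with target, ligand and waters.
#' @param dmax distance threshold in Angstrom.
#' @param source source tag of the returned set.
#' @return A [WaterSet-class].
#' @export
interfaceWaters <- function(model, dmax = 3.5, source = "crystallographic") {
  ws <- complexWaterSet(model, source)
  if (!nrow(ws@oxygens)) return(ws)
  dT <- .minDistTo(ws@oxygens, .heavyCoords(target(model)))
  dL <- .minDistTo(ws@oxygens, .heavyCoords(ligand(model)))
  keep <- dT <= dmax & dL <= dmax
  waterSet(ws@oxygens[keep, , drop = FALSE], ws@ids[keep], source)
}

#' Match predicted against reference water positions
#'
#' One-to-one greedy matching by ascending oxygen-oxygen distance among
#' all pairs strictly below the tolerance (default 1.5 Angstrom); ties on
#' equal distance are broken by the lower reference id.  The success rate
#' SR = 100 * matches / reference count.  Greedy matching coincides with
#' the maximum bipartite matching whenever candidate sites are well
#' separated.
#'
#' @param predicted,reference [WaterSet-class] objects.
#' @param tolerance match tolerance in Angstrom.
#' @return A [WaterMatchResult-class]; for an empty reference set the
#'   success rate is `NA` (flagged undefined, not 0).
#' @export
matchWaters <- function(predicted, reference, tolerance = 1.5) {
  stopifnot(tolerance > 0)
  np <- nrow(predicted@oxygens); nr <- nrow(reference@oxygens)
  pairs <- data.frame(predicted = integer(), reference = integer(),
                      distance = numeric())
  if (np && nr) {
    d <- as.matrix(stats::dist(rbind(predicted@oxygens, reference@oxygens)))
    d <- d[seq_len(np), np + seq_len(nr), drop = FALSE]
    cand <- which(d < tolerance, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d[cand], reference@ids[cand[, 2L]], predicted@ids[cand[, 1L]])
      cand <- cand[ord, , drop = FALSE]
      usedP <- logical(np); usedR <- logical(nr)
      for (i in seq_len(nrow(cand))) {
        p <- cand[i, 1L]; r <- cand[i, 2L]
        if (!usedP[p] && !usedR[r]) {
          usedP[p] <- TRUE; usedR[r] <- TRUE
          pairs <- rbind(pairs, data.frame(
            predicted = predicted@ids[p], reference = reference@ids[r],
            distance = d[p, r]))
        }
      }
    }
  }
  sr <- if (nr == 0L) NA_real_ else 100 * nrow(pairs) / nr
  new("WaterMatchResult", matches = pairs, successRate = sr,
      nReference = as.integer(nr), tolerance = tolerance)
}

#' Find bridging waters at the target-ligand interface
#'
#' A bridging water is simultaneously within hydrogen-bond distance
#' (default 3.5 Angstrom) of a polar (N or O) ligand atom and a polar
#' target atom, forming a water-mediated contact that stabilizes the
#' complex.  One bridge is emitted per water, for its closest
#' (ligand atom, target atom) pair; no angle criterion is applied since
#' pre-MD coordinates lack reliable hydrogen positions.
#'
#' @param model A [ComplexModel-class].
#' @param hbondCutoff donor-acceptor distance cutoff in Angstrom.
#' @return data.frame with columns water (residue id), ligandResid,
#'   ligandAtom, targetResid, targetAtom, dLigand, dTarget; zero rows for
#'   a dry complex.
#' @export
findWaterBridges <- function(model, hbondCutoff = 3.5) {
  stopifnot(hbondCutoff > 0)
  polar <- function(s) {
    a <- atoms(s)
    a[toupper(a$element) %in% c("N", "O"), , drop = FALSE]
  }
  lp <- polar(ligand(model)); tp <- polar(target(model))
  ws <- complexWaterSet(model)
  out <- data.frame(water = integer(), ligandResid = integer(),
                    ligandAtom = character(), targetResid = integer(),
                    targetAtom = character(), dLigand = numeric(),
                    dTarget = numeric())
  if (!nrow(ws@oxygens) || !nrow(lp) || !nrow(tp)) return(out)
  lc <- as.matrix(lp[, c("x", "y", "z")])
  tc <- as.matrix(tp[, c("x", "y", "z")])
  for (i in seq_len(nrow(ws@oxygens))) {
    o <- ws@oxygens[i, ]
    dl <- sqrt(colSums((t(lc) - o)^2))
    dt <- sqrt(colSums((t(tc) - o)^2))
    if (min(dl) <= hbondCutoff && min(dt) <= hbondCutoff) {
      il <- which.min(dl); it <- which.min(dt)
      out <- rbind(out, data.frame(
        water = ws@ids[i],
        ligandResid = lp$resid[il], ligandAtom = lp$name[il],
        targetResid = tp$resid[it], targetAtom = tp$name[it],
        dLigand = dl[il], dTarget = dt[it]))
    }
  }
  out
}

#' Count water bridges per ligand residue
#'
#' @param bridges data.frame from [findWaterBridges()].
#' @return data.frame with columns ligandResid and n, one row per ligand
#'   residue engaged in at least one water bridge.
#' @export
bridgesPerResidue <- function(bridges) {
  if (!nrow(bridges))
    return(data.frame(ligandResid = integer(), n = integer()))
  tab <- table(bridges$ligandResid)
  data.frame(ligandResid = as.integer(names(tab)), n = as.integer(tab))
}
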