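#' Heavy-atom ligand RMSD after target C-alpha fitting
#'
#' Superposes the calculated complex onto the reference using the fit
#' selection on the target (C-alpha by default), then measures
#' sqrt(sum |C_i - R_i|^2 / N) over the corresponded ligand selection.
#' The ligand atoms themselves are never re-fit, so rigid displacement of
#' the whole complex is absorbed while genuine ligand error is not.
#'
#' @param calc,ref [ComplexModel-class]: calculated (docked or snapshot)
#'   and experimental reference complexes.
#' @param sel ligand [AtomSelection-class] measured over (default
#'   all heavy atoms).
#' @param fitSel target selection used for superposition (default
#'   C-alpha); `NULL` skips fitting and compares coordinates as given.
#' @return RMSD in Angstrom.
#' @examples
#' m <- makeToyComplex(fixtureConfig(seed = 1, rmsdStart = 3))
#' rmsd(m$docked, m$reference)   # 3 by construction
#' @export
rmsd <- function(calc, ref, sel = atomSelection("all_heavy"),
                 fitSel = atomSelection("calpha")) {
  if (!is.null(fitSel)) {
    tr <- superposeKabsch(calc, ref, fitSel, on = "target")
    calc <- applyTransform(calc, tr)
  }
  selR <- resolveSelection(calc, sel, on = "ligand")
  pr <- correspond(ligand(calc), ligand(ref), selR)
  d <- coords(ligand(calc))[pr$ia, , drop = FALSE] -
       coords(ligand(ref))[pr$ib, , drop = FALSE]
  sqrt(sum(d * d) / nrow(d))
}

#' Refinement improvement: delta-RMSD and its percentage
#'
#' dRMSD = RMSD_start - RMSD_best and dRMSD% = 100 * dRMSD / RMSD_start;
#' negative when refinement worsened the starting pose.
#'
#' @param rmsdStart starting (docked) RMSD in Angstrom; must be positive.
#' @param rmsdBest best refined RMSD in Angstrom.
#' @return list with elements `delta` (Angstrom) and `percent`.
#' @examples
#' deltaRMSD(27.18, 4.41)   # 22.77 A, 83.8 %
#' @export
deltaRMSD <- function(rmsdStart, rmsdBest) {
  if (!is.numeric(rmsdStart) || rmsdStart <= 0)
    stop("rmsdStart must be positive")
  delta <- rmsdStart - rmsdBest
  list(delta = delta, percent = 100 * delta / rmsdStart)
}

.frameTimes <- function(traj) {
  seq_along(traj@frames) * traj@frameSpacing
}

.frameStage <- function(traj) {
  b <- traj@stageBoundaries
  t <- .frameTimes(traj)
  if (!nrow(b)) return(rep(NA_character_, length(t)))
  idx <- findInterval(t, b$time)
  ifelse(idx >= 1L, b$stage[pmax(idx, 1L)], NA_character_)
}

#' Trajectory refinement report
#'
#' Computes the per-frame ligand RMSD against the experimental reference
#' (each frame target-C-alpha fitted), the best RMSD over the run (the
#' docked start counts as the frame at t = 0, excluded from RF counting),
#' the improvement delta-RMSD, and the residence frequency
#' RF = (frames improving the start by at least `rfCutoff`) / simulation
#' time in ns.  With 0.1 ns spacing the maximal RF is 10 per ns; values
#' above 0.5 per ns indicate a complex of high kinetic stability.
#'
#' @param traj A [TrajectorySeries-class].
#' @param ref experimental reference [ComplexModel-class].
#' @param start docked starting [ComplexModel-class].
#' @param sel ligand selection (default all heavy atoms).
#' @param rfCutoff improvement cutoff in Angstrom (default 1).
#' @param fitSel target fit selection (default C-alpha).
#' @param stages optional character vector of stage labels; when given,
#'   only frames within those stages enter the best-frame search, the
#'   RF count and the reported per-frame RMSD vector (the RF denominator
#'   stays the full simulation time).
#' @return A [RefinementReport-class].
#' @export
trajectoryReport <- function(traj, ref, start,
                             sel = atomSelection("all_heavy"),
                             rfCutoff = 1,
                             fitSel = atomSelection("calpha"),
                             stages = NULL) {
  if (!length(traj@frames)) stop("empty trajectory")
  r0 <- rmsd(start, ref, sel, fitSel)
  rr <- vapply(traj@frames, rmsd, numeric(1), ref = ref, sel = sel,
               fitSel = fitSel)
  times <- .frameTimes(traj)
  use <- rep(TRUE, length(rr))
  if (!is.null(stages)) use <- .frameStage(traj) %in% stages
  totalTime <- length(traj@frames) * traj@frameSpacing
  nImp <- sum(use & (r0 - rr >= rfCutoff))
  cand <- c(r0, rr[use])
  candT <- c(0, times[use])
  best <- which.min(cand)
  new("RefinementReport",
      rmsdStart = r0, rmsdBest = cand[best], bestFrameTime = candT[best],
      deltaRmsd = r0 - cand[best],
      deltaRmsdPercent = 100 * (r0 - cand[best]) / r0,
      rf = nImp / totalTime, perFrameRmsd = rr[use])
}

#' N-terminal refinement report
#'
#' As [trajectoryReport()] but restricted to the heavy atoms of the first
#' `k` N-terminal ligand residues — the tightly bound head of a histone
#' H3 tail, whose binding geometry is well defined while the C-terminal
#' region is mobile.
#'
#' @inheritParams trajectoryReport
#' @param k number of N-terminal residues (default 5).
#' @return A [RefinementReport-class].
#' @export
nTerminalReport <- function(traj, ref, start, k = 5L, rfCutoff = 1,
                            fitSel = atomSelection("calpha"),
                            stages = NULL) {
  nres <- nrow(residues(ligand(ref)))
  if (k < 1L || k > nres)
    stop(sprintf("k must lie in 1..%d", nres))
  trajectoryReport(traj, ref, start, sel = atomSelection("n_terminal_k", k),
                   rfCutoff = rfCutoff, fitSel = fitSel, stages = stages)
}
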