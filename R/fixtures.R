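#' Fixture generator configuration
#'
#' Study-scale defaults mirror the histone H3 refinement setting: a
#' 10-residue H3-tail peptide ("ARTKQTARKS"), a docked pose displaced by
#' 8 Angstrom from the reference (a typical starting error for
#' fast-docked histone peptides), 400 trajectory frames at 0.1 ns
#' spacing (the 40 ns of a 15+40 ns protocol extracted at the snapshot
#' interval), 12 interface and 30 bulk waters, and 0.1 Angstrom
#' positional noise.
#'
#' @param seed integer RNG seed (Mersenne-Twister, seeded locally so the
#'   caller's RNG state is untouched).
#' @param nTargetResidues residues in the rigid toy target (two strands
#'   flanking a shallow groove).
#' @param peptideLength ligand residues, a prefix of the 21-residue
#'   histone H3 tail ARTKQTARKSTGGKAPRKQLA.
#' @param nInterfaceWaters,nBulkWaters planted water counts.
#' @param noiseSigma per-atom isotropic Gaussian noise, Angstrom.
#' @param nFrames,frameSpacing trajectory frames and spacing (ns).
#' @param improvingFraction fraction of frames moved to within the
#'   residence-frequency cutoff of the reference.
#' @param rmsdStart planted starting RMSD of the docked pose, Angstrom.
#' @return A [FixtureConfig-class].
#' @export
fixtureConfig <- function(seed = 1L, nTargetResidues = 20L,
                          peptideLength = 10L, nInterfaceWaters = 12L,
                          nBulkWaters = 30L, noiseSigma = 0.1,
                          nFrames = 400L, frameSpacing = 0.1,
                          improvingFraction = 0.5, rmsdStart = 8) {
  new("FixtureConfig", seed = as.integer(seed),
      nTargetResidues = as.integer(nTargetResidues),
      peptideLength = as.integer(peptideLength),
      nInterfaceWaters = as.integer(nInterfaceWaters),
      nBulkWaters = as.integer(nBulkWaters), noiseSigma = noiseSigma,
      nFrames = as.integer(nFrames), frameSpacing = frameSpacing,
      improvingFraction = improvingFraction, rmsdStart = rmsdStart)
}

.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

## natural-extension reference frame placement: position D with bond
## |CD|, angle B-C-D and torsion A-B-C-D (degrees)
.placeAtom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  C + d[1L] * bc + d[2L] * m + d[3L] * n
}

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.H3_TAIL <- "ARTKQTARKSTGGKAPRKQLA"

## side-chain internal-coordinate templates: ref atoms A,B,C then
## bond/angle/torsion (degrees); CB handled separately for all residues
.SIDE_TEMPLATES <- list(
  ALA = list(),
  GLY = list(),
  SER = list(list("OG",  "O", c("N", "CA", "CB"), 1.417, 110.8, 180)),
  THR = list(list("OG1", "O", c("N", "CA", "CB"), 1.430, 109.6, 60),
             list("CG2", "C", c("N", "CA", "CB"), 1.520, 110.5, -60)),
  LYS = list(list("CG",  "C", c("N", "CA", "CB"), 1.520, 114.0, 180),
             list("CD",  "C", c("CA", "CB", "CG"), 1.520, 111.0, 180),
             list("CE",  "C", c("CB", "CG", "CD"), 1.520, 111.0, 180),
             list("NZ",  "N", c("CG", "CD", "CE"), 1.470, 110.0, 180)),
  ARG = list(list("CG",  "C", c("N", "CA", "CB"), 1.520, 114.0, 180),
             list("CD",  "C", c("CA", "CB", "CG"), 1.520, 111.0, 180),
             list("NE",  "N", c("CB", "CG", "CD"), 1.460, 112.0, 180),
             list("CZ",  "C", c("CG", "CD", "NE"), 1.330, 124.0, 180),
             list("NH1", "N", c("CD", "NE", "CZ"), 1.330, 120.0, 0),
             list("NH2", "N", c("CD", "NE", "CZ"), 1.330, 120.0, 180)),
  GLN = list(list("CG",  "C", c("N", "CA", "CB"), 1.520, 114.0, 180),
             list("CD",  "C", c("CA", "CB", "CG"), 1.520, 112.0, 180),
             list("OE1", "O", c("CB", "CG", "CD"), 1.230, 121.0, 0),
             list("NE2", "N", c("CB", "CG", "CD"), 1.330, 117.0, 180)),
  PRO = list(list("CG",  "C", c("N", "CA", "CB"), 1.490, 104.0, 30),
             list("CD",  "C", c("CA", "CB", "CG"), 1.500, 105.0, -35)),
  LEU = list(list("CG",  "C", c("N", "CA", "CB"), 1.530, 116.0, 180),
             list("CD1", "C", c("CA", "CB", "CG"), 1.520, 110.0, 60),
             list("CD2", "C", c("CA", "CB", "CG"), 1.520, 110.0, 180)))

## extended-chain peptide builder (phi -139, psi 135, omega 180) with
## idealized bond geometry; returns the canonical atom data.frame
.buildChain <- function(sequence3, chain, role, firstResid = 1L,
                        serialStart = 1L) {
  phi <- -139; psi <- 135
  rows <- list(); serial <- serialStart
  addAtom <- function(name, element, resname, resid, pos) {
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, element = element, resname = resname,
      resid = resid, chain = chain, x = pos[1L], y = pos[2L], z = pos[3L],
      heavy = element != "H", role = role, stringsAsFactors = FALSE)
    serial <<- serial + 1L
  }
  n <- length(sequence3)
  Npos <- CApos <- Cpos <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == 1L) {
      Npos[[i]] <- c(0, 0, 0)
      CApos[[i]] <- c(1.458, 0, 0)
      th <- 111.2 * pi / 180
      Cpos[[i]] <- CApos[[i]] + 1.525 * c(-cos(th), sin(th), 0)
    } else {
      Npos[[i]] <- .placeAtom(Npos[[i - 1L]], CApos[[i - 1L]], Cpos[[i - 1L]],
                              1.329, 116.2, psi)
      CApos[[i]] <- .placeAtom(CApos[[i - 1L]], Cpos[[i - 1L]], Npos[[i]],
                               1.458, 121.7, 180)
      Cpos[[i]] <- .placeAtom(Cpos[[i - 1L]], Npos[[i]], CApos[[i]],
                              1.525, 111.2, phi)
    }
  }
  for (i in seq_len(n)) {
    res <- sequence3[i]; resid <- firstResid + i - 1L
    pos <- list(N = Npos[[i]], CA = CApos[[i]], C = Cpos[[i]])
    addAtom("N", "N", res, resid, pos$N)
    addAtom("CA", "C", res, resid, pos$CA)
    addAtom("C", "C", res, resid, pos$C)
    pos$O <- .placeAtom(pos$N, pos$CA, pos$C, 1.231, 120.8, psi + 180)
    addAtom("O", "O", res, resid, pos$O)
    if (res != "GLY") {
      pos$CB <- .placeAtom(pos$N, pos$C, pos$CA, 1.530, 110.5, 122.5)
      addAtom("CB", "C", res, resid, pos$CB)
      for (tp in .SIDE_TEMPLATES[[res]]) {
        ref <- tp[[3L]]
        pos[[tp[[1L]]]] <- .placeAtom(pos[[ref[1L]]], pos[[ref[2L]]],
                                      pos[[ref[3L]]], tp[[4L]], tp[[5L]],
                                      tp[[6L]])
        addAtom(tp[[1L]], tp[[2L]], res, resid, pos[[tp[[1L]]]])
      }
    }
  }
  do.call(rbind, rows)
}

.seq3 <- function(oneLetter) {
  unname(.AA1TO3[strsplit(oneLetter, "")[[1L]]])
}

## rotate a built chain so its principal axis lies along x (second along
## y), centred at the origin; makes groove offsets truly perpendicular
.alignToX <- function(a) {
  X <- as.matrix(a[, c("x", "y", "z")])
  X <- sweep(X, 2L, colMeans(X))
  V <- svd(X)$v
  if (det(V) < 0) V[, 3L] <- -V[, 3L]
  X <- X %*% V
  a$x <- X[, 1L]; a$y <- X[, 2L]; a$z <- X[, 3L]
  a
}

#' Build a deterministic toy docked/reference complex pair
#'
#' Constructs a rigid toy target — two extended strands flanking a
#' shallow groove, plus one structural Zn2+ ion — and a linear histone
#' H3 tail peptide lying in the groove (the reference pose).  The docked
#' pose is the same peptide rigidly translated out of the groove so that
#' its heavy-atom RMSD to the reference, after target C-alpha fitting,
#' equals `rmsdStart` exactly.  Atom names follow PDB amino-acid
#' conventions so selections, truncation and MOL2 typing behave as on
#' real structures.
#'
#' @param cfg A [FixtureConfig-class].
#' @return list with elements `docked` and `reference`, both
#'   [ComplexModel-class].
#' @examples
#' m <- makeToyComplex(fixtureConfig(seed = 7, rmsdStart = 3))
#' rmsd(m$docked, m$reference)
#' @export
makeToyComplex <- function(cfg) {
  seqPep <- .seq3(substr(.H3_TAIL, 1L, cfg@peptideLength))
  lig <- .alignToX(.buildChain(seqPep, chain = "B", role = "ligand"))
  ## point the peptide side chains along z so the flanking strands can
  ## hug the backbone: rotate 90 degrees about x
  tmp <- lig$y; lig$y <- lig$z; lig$z <- -tmp
  n1 <- ceiling(cfg@nTargetResidues / 2)
  n2 <- cfg@nTargetResidues - n1
  tseq <- function(k) rep(c("ALA", "SER", "GLY", "THR"), length.out = k)
  gap <- 3.2                       # groove clearance, Angstrom
  s1 <- .alignToX(.buildChain(tseq(n1), chain = "A", role = "target",
                              serialStart = 1000L))
  s1$y <- s1$y - min(s1$y) + max(lig$y) + gap
  s2 <- NULL
  if (n2 > 0L) {
    s2 <- .alignToX(.buildChain(tseq(n2), chain = "A", role = "target",
                                firstResid = n1 + 1L, serialStart = 2000L))
    s2$y <- s2$y - max(s2$y) + min(lig$y) - gap
  }
  ta <- rbind(s1, s2)
  zn <- data.frame(serial = 5000L, name = "ZN", element = "Zn",
                   resname = "ZN", resid = 901L, chain = "A",
                   x = max(ta$x) + 6, y = 8, z = 0, heavy = TRUE,
                   role = "ion", stringsAsFactors = FALSE)
  reference <- complexModel(
    target = molecularStructure(ta, label = "toy-target"),
    ligand = molecularStructure(lig, label = "toy-peptide"),
    ions = molecularStructure(zn, label = "toy-ions"))
  dockedLig <- lig
  dockedLig$z <- dockedLig$z + cfg@rmsdStart   # uniform shift: RMSD = |shift|
  docked <- complexModel(
    target = molecularStructure(ta, label = "toy-target"),
    ligand = molecularStructure(dockedLig, label = "toy-peptide-docked"),
    ions = molecularStructure(zn, label = "toy-ions"))
  list(docked = docked, reference = reference)
}

.randomSmallTransform <- function(maxAngleDeg = 8, maxShift = 1.5) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -maxAngleDeg, maxAngleDeg) * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigidTransform(R, stats::runif(3, -maxShift, maxShift))
}

#' Build a synthetic refinement trajectory with planted RF
#'
#' Frames interpolate the ligand from the docked pose toward the
#' reference with seeded Gaussian positional noise; deviations are then
#' rescaled toward the reference so that each frame's fitted heavy-atom
#' RMSD is pinned exactly, making the planted improving-frame count —
#' `round(improvingFraction * nFrames)`, placed at the end of the run as
#' in a converging refinement — recover exactly under the 1 Angstrom
#' residence-frequency cutoff.  Improving frames sit 1.5 Angstrom below
#' the starting RMSD, non-improving frames 0.4 Angstrom below.  Each
#' whole frame additionally receives a random rigid-body displacement,
#' which target C-alpha fitting must absorb.
#'
#' @param docked,reference [ComplexModel-class] pair from
#'   [makeToyComplex()].
#' @param cfg A [FixtureConfig-class]; `rmsdStart` must exceed 1.5 when
#'   any improving frames are requested.
#' @return A [TrajectorySeries-class] with
#'   `attr(, "nImproving")` recording the planted count.
#' @export
makeTrajectory <- function(docked, reference, cfg) {
  r0 <- rmsd(docked, reference)
  nImp <- round(cfg@improvingFraction * cfg@nFrames)
  if (nImp > 0L && r0 <= 1.5)
    stop("rmsdStart must exceed 1.5 Angstrom to plant improving frames")
  improving <- seq_len(cfg@nFrames) > cfg@nFrames - nImp
  rTarget <- ifelse(improving, r0 - 1.5, r0 - 0.4)
  refLig <- coords(ligand(reference))
  dockLig <- coords(ligand(docked))
  heavy <- atoms(ligand(reference))$heavy
  frames <- .withSeed(cfg@seed, lapply(seq_len(cfg@nFrames), function(i) {
    s <- rTarget[i] / r0
    L <- refLig + s * (dockLig - refLig)
    L <- L + matrix(stats::rnorm(length(L), sd = cfg@noiseSigma), ncol = 3L)
    D <- L - refLig
    cur <- sqrt(sum(D[heavy, ]^2) / sum(heavy))
    L <- refLig + (rTarget[i] / cur) * D
    fr <- reference
    fr@ligand <- setCoords(fr@ligand, L)
    applyTransform(fr, .randomSmallTransform())
  }))
  out <- trajectorySeries(frames, cfg@frameSpacing)
  attr(out, "nImproving") <- nImp
  out
}

#' Plant interface and bulk waters with a known match fraction
#'
#' Builds the toy complex, plants `nInterfaceWaters` reference waters at
#' midpoints between ligand and target heavy atoms (within 3.5 Angstrom
#' of both partners) plus `nBulkWaters` far from either, and derives a
#' predicted set by displacing reference oxygens perpendicular to the
#' interface: `round(matchFraction * nInterfaceWaters)` by 0.5 Angstrom
#' (inside the 1.5 Angstrom match tolerance) and the rest by 2.0
#' Angstrom (outside it).  Planted sites are at least 3 Angstrom apart,
#' so greedy matching coincides with the optimal assignment.
#'
#' @param cfg A [FixtureConfig-class].
#' @param matchFraction fraction of predicted interface waters placed
#'   within the match tolerance (default 0.86, the mean pre-MD hydration
#'   performance on histone systems with crystallographic interface
#'   waters).
#' @return list with `predicted` and `reference` [WaterSet-class]
#'   objects, and `complex`: the reference [ComplexModel-class] carrying
#'   reference interface plus bulk waters as its water component.
#' @export
makeHydrationLayout <- function(cfg, matchFraction = 0.86) {
  m <- makeToyComplex(cfg)
  ref <- m$reference
  la <- atoms(ligand(ref)); ta <- atoms(target(ref))
  nW <- cfg@nInterfaceWaters
  lh <- as.matrix(la[la$heavy, c("x", "y", "z"), drop = FALSE])
  th <- as.matrix(ta[ta$heavy, c("x", "y", "z"), drop = FALSE])
  ## candidate sites: midpoints of close (ligand, target) heavy-atom
  ## pairs, so each site is within dmax of both partners; greedily keep
  ## sites at least 3 Angstrom apart so match candidate sets stay disjoint
  d2 <- outer(rowSums(lh^2), rowSums(th^2), "+") - 2 * lh %*% t(th)
  cand <- which(d2 <= 6.7^2, arr.ind = TRUE)
  if (!nrow(cand) && nW > 0L) stop("no close target-ligand atom pairs to anchor waters")
  cand <- cand[order(d2[cand]), , drop = FALSE]
  pos <- matrix(NA_real_, 0L, 3L)
  for (i in seq_len(nrow(cand))) {
    if (nrow(pos) >= nW) break
    A <- lh[cand[i, 1L], ]; B <- th[cand[i, 2L], ]
    d <- sqrt(sum((A - B)^2))
    ## feasible z-jitter keeping the site within 3.4 A of both anchors
    dzMax <- sqrt(max(3.4^2 - (d / 2)^2, 0))
    for (dz in c(0, 1.2, -1.2, 2.4, -2.4)) {
      if (abs(dz) > dzMax) next
      W <- (A + B) / 2 + c(0, 0, dz)
      if (!nrow(pos) || min(sqrt(colSums((t(pos) - W)^2))) >= 3.6) {
        pos <- rbind(pos, W)
        break
      }
    }
  }
  if (nrow(pos) < nW)
    stop(sprintf("could only place %d of %d interface waters", nrow(pos), nW))
  rownames(pos) <- NULL
  refIds <- seq_len(nW)
  bulk <- if (cfg@nBulkWaters > 0L)
    cbind(min(la$x) - 12 - 3.1 * seq_len(cfg@nBulkWaters),
          max(ta$y) + 12, 10)
  else matrix(numeric(), 0L, 3L)
  nMatch <- round(matchFraction * nW)
  disp <- ifelse(seq_len(nW) <= nMatch, 0.5, 2.0)
  pred <- pos + cbind(0, 0, disp * rep_len(c(1, -1), nW))
  allW <- rbind(pos, bulk)
  wa <- data.frame(serial = 6000L + seq_len(nrow(allW)),
                   name = "O", element = "O", resname = "HOH",
                   resid = 500L + seq_len(nrow(allW)), chain = "W",
                   x = allW[, 1L], y = allW[, 2L], z = allW[, 3L],
                   heavy = TRUE, role = "water", stringsAsFactors = FALSE)
  ref@waters <- molecularStructure(wa, label = "planted-waters")
  list(predicted = waterSet(pred, ids = 1000L + refIds, source = "predicted"),
       reference = waterSet(pos, ids = refIds, source = "crystallographic"),
       complex = ref)
}

#' Plant bridging waters around one ligand residue
#'
#' Places `n` waters at midpoints between a side-chain polar atom of the
#' chosen ligand residue (e.g. the Lys4 NZ of a histone H3 tail) and its
#' `n` nearest polar target atoms, each midpoint within hydrogen-bond
#' distance of both, so [findWaterBridges()] recovers exactly `n`
#' bridges at that residue.
#'
#' @param model A [ComplexModel-class] (waters are replaced).
#' @param residueIndex ligand residue index (default 4).
#' @param n bridges to plant (default 3).
#' @param hbondCutoff hydrogen-bond distance cutoff, Angstrom.
#' @return the complex with the planted waters.
#' @export
plantWaterBridges <- function(model, residueIndex = 4L, n = 3L,
                              hbondCutoff = 3.5) {
  la <- atoms(ligand(model)); ta <- atoms(target(model))
  polarL <- la[la$resid == residueIndex &
               toupper(la$element) %in% c("N", "O"), , drop = FALSE]
  if (!nrow(polarL)) stop("ligand residue has no polar atoms")
  polarT <- ta[toupper(ta$element) %in% c("N", "O"), , drop = FALSE]
  tc <- as.matrix(polarT[, c("x", "y", "z")])
  allPolarL <- la[toupper(la$element) %in% c("N", "O"), , drop = FALSE]
  lc <- as.matrix(allPolarL[, c("x", "y", "z")])
  ## place waters on ligand-anchor -> target-atom segments such that the
  ## water is within the cutoff of both ends, at least 1 Angstrom from
  ## previously planted waters, and closest (among ligand polar atoms)
  ## to the requested residue so the bridge attributes there
  mid <- matrix(NA_real_, 0L, 3L)
  usedT <- integer()
  for (i in seq_len(nrow(polarL))) {
    A <- as.numeric(polarL[i, c("x", "y", "z")])
    d <- sqrt(colSums((t(tc) - A)^2))
    for (j in setdiff(order(d), usedT)) {
      if (nrow(mid) >= n) break
      if (d[j] > 2 * hbondCutoff) break
      B <- tc[j, ]
      for (frac in c(0.5, 0.45, 0.55, 0.4, 0.6)) {
        W <- A + frac * (B - A)
        if (sqrt(sum((W - A)^2)) > hbondCutoff ||
            sqrt(sum((W - B)^2)) > hbondCutoff) next
        dl <- sqrt(colSums((t(lc) - W)^2))
        sep <- if (nrow(mid)) min(sqrt(colSums((t(mid) - W)^2))) else Inf
        if (allPolarL$resid[which.min(dl)] == residueIndex && sep >= 1.0) {
          mid <- rbind(mid, W)
          usedT <- c(usedT, j)
          break
        }
      }
    }
    if (nrow(mid) >= n) break
  }
  if (nrow(mid) < n)
    stop(sprintf("could only plant %d of %d bridges at residue %d",
                 nrow(mid), n, residueIndex))
  wa <- data.frame(serial = 7000L + seq_len(n), name = "O", element = "O",
                   resname = "HOH", resid = 700L + seq_len(n), chain = "W",
                   x = mid[, 1L], y = mid[, 2L], z = mid[, 3L],
                   heavy = TRUE, role = "water", stringsAsFactors = FALSE)
  model@waters <- molecularStructure(wa, label = "bridge-waters")
  model
}

#' Write a complete fixture set to disk
#'
#' Produces docked.pdb, reference.pdb, a frames/ directory of snapshot
#' PDBs, waters_pred.pdb, waters_ref.pdb and manifest.json with the
#' planted ground-truth values (starting RMSD, improving-frame count,
#' water match fraction).
#'
#' @param cfg A [FixtureConfig-class].
#' @param dir output directory (created if needed).
#' @param matchFraction passed to [makeHydrationLayout()].
#' @return Invisibly, the manifest as a list.
#' @export
writeFixtureSet <- function(cfg, dir, matchFraction = 0.86) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writeFixtureSet requires the jsonlite package")
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  m <- makeToyComplex(cfg)
  hyd <- makeHydrationLayout(cfg, matchFraction)
  writePDB(m$docked, file.path(dir, "docked.pdb"))
  # the reference carries the planted interface + bulk waters
  writePDB(hyd$complex, file.path(dir, "reference.pdb"))
  traj <- makeTrajectory(m$docked, m$reference, cfg)
  for (i in seq_along(traj@frames))
    writePDB(traj@frames[[i]],
             file.path(dir, "frames", sprintf("frame_%04d.pdb", i)))
  wsToModel <- function(ws) {
    o <- ws@oxygens
    complexModel(waters = molecularStructure(data.frame(
      serial = seq_len(nrow(o)), name = "O", element = "O",
      resname = "HOH", resid = ws@ids, chain = "W",
      x = o[, 1L], y = o[, 2L], z = o[, 3L], heavy = TRUE, role = "water",
      stringsAsFactors = FALSE), label = ws@source))
  }
  writePDB(wsToModel(hyd$predicted), file.path(dir, "waters_pred.pdb"))
  writePDB(wsToModel(hyd$reference), file.path(dir, "waters_ref.pdb"))
  manifest <- list(seed = cfg@seed, rmsdStart = cfg@rmsdStart,
                   nFrames = cfg@nFrames, frameSpacing = cfg@frameSpacing,
                   nImproving = attr(traj, "nImproving"),
                   nInterfaceWaters = cfg@nInterfaceWaters,
                   nBulkWaters = cfg@nBulkWaters,
                   matchFraction = matchFraction,
                   roleMap = list(A = "target", B = "ligand"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
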