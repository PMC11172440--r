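#' @import methods
NULL

.ROLES <- c("target", "ligand", "water", "ion")
.WATER_NAMES <- c("HOH", "SOL", "WAT")

.atomColumns <- c("serial", "name", "element", "resname", "resid", "chain",
                  "x", "y", "z", "heavy", "role")

#' Empty atom table
#'
#' Returns a zero-row data frame with the canonical atom columns used by
#' [MolecularStructure()]: serial, name, element, resname, resid, chain,
#' x/y/z (Angstrom), heavy (logical, element != H) and role (one of
#' target/ligand/water/ion).
#'
#' @return A zero-row `data.frame`.
#' @export
emptyAtoms <- function() {
  data.frame(serial = integer(), name = character(), element = character(),
             resname = character(), resid = integer(), chain = character(),
             x = numeric(), y = numeric(), z = numeric(),
             heavy = logical(), role = character(),
             stringsAsFactors = FALSE)
}

#' Class "MolecularStructure"
#'
#' An ordered atom table for one structural component (target protein,
#' peptide ligand, waters or ions).  Each row is one atom with serial,
#' atom name, element symbol, residue name/index, chain identifier,
#' Cartesian coordinates in Angstrom, a heavy-atom flag and a role tag.
#'
#' @slot atoms data.frame with columns serial, name, element, resname,
#'   resid, chain, x, y, z, heavy, role.
#' @slot label character scalar naming the structure.
#' @export
setClass("MolecularStructure",
         representation(atoms = "data.frame", label = "character"),
         prototype(atoms = emptyAtoms(), label = ""))

setValidity("MolecularStructure", function(object) {
  a <- object@atoms
  msg <- character()
  if (!all(.atomColumns %in% names(a)))
    return(paste("atom table must have columns:",
                 paste(.atomColumns, collapse = ", ")))
  if (nrow(a)) {
    if (anyDuplicated(a$serial)) msg <- c(msg, "atom serials must be unique")
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      msg <- c(msg, "coordinates must be finite")
    if (any(!nzchar(a$element))) msg <- c(msg, "element symbols must be non-empty")
    if (!identical(a$heavy, toupper(a$element) != "H"))
      msg <- c(msg, "heavy flag inconsistent with element")
    if (!all(a$role %in% .ROLES))
      msg <- c(msg, "role must be one of target/ligand/water/ion")
    w <- a$role == "water"
    if (any(w)) {
      if (!all(a$resname[w] %in% .WATER_NAMES))
        msg <- c(msg, "water residues must be named HOH/SOL/WAT")
      sz <- table(paste(a$chain[w], a$resid[w]))
      if (!all(sz %in% c(1L, 3L)))
        msg <- c(msg, "each water residue must have 1 or 3 atoms")
    }
    key <- paste(a$chain, a$resid, a$resname)
    if (anyDuplicated(rle(key)$values))
      msg <- c(msg, "residues must group contiguous atoms")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Class "ComplexModel"
#'
#' A docked or experimental target-ligand complex, with atoms partitioned
#' by role into four [MolecularStructure-class] components.  Structural
#' Zn2+ ions are carried separately but are treated as heavy atoms of the
#' target wherever position restraints or restraint selections apply.
#'
#' @slot target,ligand,waters,ions [MolecularStructure-class] components.
#' @export
setClass("ComplexModel",
         representation(target = "MolecularStructure",
                        ligand = "MolecularStructure",
                        waters = "MolecularStructure",
                        ions   = "MolecularStructure"))

setValidity("ComplexModel", function(object) {
  chk <- function(part, role) {
    a <- slot(object, part)@atoms
    if (nrow(a) && !all(a$role == role))
      sprintf("all atoms in '%s' must have role '%s'", part, role) else NULL
  }
  msg <- c(chk("target", "target"), chk("ligand", "ligand"),
           chk("waters", "water"), chk("ions", "ion"))
  lg <- object@ligand@atoms
  if (nrow(lg)) {
    if (length(unique(lg$chain)) != 1L)
      msg <- c(msg, "ligand residues must form a single chain")
    ri <- unique(lg$resid)
    if (!identical(ri, seq(min(ri), max(ri))))
      msg <- c(msg, "ligand residue indices must be consecutive")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Class "AtomSelection"
#'
#' A reusable atom-selection predicate plus, once resolved against a
#' structure, the strictly increasing atom indices it selects.  Kinds:
#' \describe{
#'   \item{all_heavy}{every non-hydrogen atom;}
#'   \item{backbone}{protein backbone heavy atoms (N, CA, C, O);}
#'   \item{calpha}{CA atoms of amino-acid residues;}
#'   \item{n_terminal_k}{heavy atoms of ligand residues 1..k;}
#'   \item{custom}{an explicit atom-name list.}
#' }
#'
#' @slot kind character, one of the kinds above.
#' @slot k integer, residue count for `n_terminal_k`.
#' @slot names character, atom names for `custom`.
#' @slot indices integer, resolved atom indices (strictly increasing).
#' @export
setClass("AtomSelection",
         representation(kind = "character", k = "integer",
                        names = "character", indices = "integer"),
         prototype(kind = "all_heavy", k = NA_integer_,
                   names = character(), indices = integer()))

setValidity("AtomSelection", function(object) {
  kinds <- c("all_heavy", "backbone", "calpha", "n_terminal_k", "custom")
  if (!object@kind %in% kinds)
    return(paste("kind must be one of", paste(kinds, collapse = ", ")))
  if (object@kind == "n_terminal_k" &&
      (is.na(object@k) || object@k < 1L))
    return("n_terminal_k requires k >= 1")
  if (length(object@indices) > 1L && any(diff(object@indices) <= 0L))
    return("resolved indices must be strictly increasing")
  TRUE
})

#' Class "RigidTransform"
#'
#' A proper rigid-body transform y = R x + t (rotation then translation)
#' in Angstrom, as returned by [superposeKabsch()].
#'
#' @slot rotation 3x3 orthonormal matrix with det +1.
#' @slot translation length-3 numeric vector.
#' @export
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8) return("rotation not orthonormal")
  if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det +1)")
  TRUE
})

#' Class "TrajectorySeries"
#'
#' A time-ordered series of complex snapshots with uniform frame spacing
#' in nanoseconds, as extracted from an MD trajectory at fixed intervals.
#' Optional stage boundaries label which refinement stage (initial MD,
#' simulated annealing, final flexible MD) each time span belongs to.
#'
#' @slot frames list of [ComplexModel-class] snapshots.
#' @slot frameSpacing numeric, ns between consecutive frames (default 0.1).
#' @slot stageBoundaries data.frame with columns `time` (ns) and `stage`.
#' @export
setClass("TrajectorySeries",
         representation(frames = "list", frameSpacing = "numeric",
                        stageBoundaries = "data.frame"),
         prototype(frameSpacing = 0.1,
                   stageBoundaries = data.frame(time = numeric(),
                                                stage = character())))

setValidity("TrajectorySeries", function(object) {
  if (!length(object@frames)) return("trajectory must have at least one frame")
  if (!all(vapply(object@frames, is, logical(1), "ComplexModel")))
    return("frames must be ComplexModel objects")
  if (object@frameSpacing <= 0) return("frame spacing must be positive")
  b <- object@stageBoundaries
  if (nrow(b) && is.unsorted(b$time)) return("stage boundary times must be monotone")
  TRUE
})

#' Class "RefinementReport"
#'
#' Summary of one refinement run: starting RMSD of the docked pose, the
#' best RMSD over the trajectory (the docked start counts as the frame at
#' t = 0), the improvement delta-RMSD in Angstrom and as a percentage of
#' the start, and the residence frequency RF in 1/ns.
#'
#' @slot rmsdStart,rmsdBest,deltaRmsd numeric, Angstrom.
#' @slot bestFrameTime numeric, ns (0 when the start is never improved on).
#' @slot deltaRmsdPercent numeric, percent of the starting RMSD.
#' @slot rf numeric, improving frames per ns of simulation time.
#' @slot perFrameRmsd numeric vector, per-frame ligand RMSD in Angstrom.
#' @export
setClass("RefinementReport",
         representation(rmsdStart = "numeric", rmsdBest = "numeric",
                        bestFrameTime = "numeric", deltaRmsd = "numeric",
                        deltaRmsdPercent = "numeric", rf = "numeric",
                        perFrameRmsd = "numeric"))

setValidity("RefinementReport", function(object) {
  tol <- 1e-9
  if (object@rmsdBest > min(c(object@perFrameRmsd, object@rmsdStart)) + tol)
    return("rmsdBest must not exceed the minimum of per-frame RMSDs and the start")
  if (abs(object@deltaRmsd - (object@rmsdStart - object@rmsdBest)) > tol)
    return("deltaRmsd must equal rmsdStart - rmsdBest")
  if (abs(object@deltaRmsdPercent - 100 * object@deltaRmsd / object@rmsdStart) > 1e-6)
    return("deltaRmsdPercent inconsistent")
  if (object@rf < 0) return("rf must be non-negative")
  TRUE
})

#' Class "WaterSet"
#'
#' Water oxygen positions (one per water residue) with residue ids and a
#' source tag (predicted, crystallographic or trajectory).
#'
#' @slot oxygens numeric matrix, n x 3, Angstrom.
#' @slot ids integer residue ids, one per oxygen.
#' @slot source character scalar.
#' @export
setClass("WaterSet",
         representation(oxygens = "matrix", ids = "integer",
                        source = "character"),
         prototype(oxygens = matrix(numeric(), 0L, 3L), ids = integer(),
                   source = "predicted"))

setValidity("WaterSet", function(object) {
  if (ncol(object@oxygens) != 3L) return("oxygens must be an n x 3 matrix")
  if (nrow(object@oxygens) != length(object@ids))
    return("one id per oxygen required")
  if (anyDuplicated(object@ids)) return("water residue ids must be unique")
  if (!object@source %in% c("predicted", "crystallographic", "trajectory"))
    return("source must be predicted/crystallographic/trajectory")
  TRUE
})

#' Class "WaterMatchResult"
#'
#' One-to-one matching of predicted against reference water oxygens within
#' a distance tolerance, and the resulting success rate
#' SR = 100 * matches / reference count.
#'
#' @slot matches data.frame with columns predicted, reference, distance.
#' @slot successRate numeric, percent (NA when the reference set is empty).
#' @slot nReference integer.
#' @slot tolerance numeric, Angstrom.
#' @export
setClass("WaterMatchResult",
         representation(matches = "data.frame", successRate = "numeric",
                        nReference = "integer", tolerance = "numeric"))

setValidity("WaterMatchResult", function(object) {
  m <- object@matches
  if (anyDuplicated(m$predicted) || anyDuplicated(m$reference))
    return("matching must be one-to-one")
  if (nrow(m) && any(m$distance >= object@tolerance))
    return("every match distance must be below the tolerance")
  if (object@nReference > 0L &&
      abs(object@successRate - 100 * nrow(m) / object@nReference) > 1e-9)
    return("successRate inconsistent with match count")
  TRUE
})

#' Class "ChargeSet"
#'
#' Per-atom partial charges in elementary charge units, conserving the
#' total formal charge of the molecule.
#'
#' @slot charges numeric vector, e.
#' @slot totalFormalCharge numeric scalar, e.
#' @slot method character tag (e.g. "gasteiger").
#' @export
setClass("ChargeSet",
         representation(charges = "numeric", totalFormalCharge = "numeric",
                        method = "character"))

setValidity("ChargeSet", function(object) {
  if (length(object@charges) &&
      abs(sum(object@charges) - object@totalFormalCharge) > 1e-6)
    return("charges must sum to the total formal charge within 1e-6 e")
  TRUE
})

#' Class "DielectricModel"
#'
#' Sigmoidal distance-dependent dielectric
#' eps_r(r) = A + B / (1 + k * exp(-lambda * B * r)) with B = eps0 - A,
#' where eps0 is the dielectric constant of bulk water at 25 C.  Defaults
#' are the Mehler-Solmajer constants; see [dielectricModel()].
#'
#' @slot A,lambda,k,eps0Water numeric constants.
#' @export
setClass("DielectricModel",
         representation(A = "numeric", lambda = "numeric", k = "numeric",
                        eps0Water = "numeric"))

setValidity("DielectricModel", function(object) {
  B <- object@eps0Water - object@A
  if (B <= 0) return("eps0Water must exceed A")
  if (object@k <= 0 || object@lambda <= 0) return("k and lambda must be positive")
  TRUE
})

#' Class "EnergyProfile"
#'
#' Per-ligand-residue decomposition of the target-ligand interaction
#' energy E_inter = E_LJ + E_Coulomb, in kcal/mol.
#'
#' @slot residues data.frame with columns resid, resname, eLJ, eCoulomb,
#'   eInter.
#' @export
setClass("EnergyProfile", representation(residues = "data.frame"))

setValidity("EnergyProfile", function(object) {
  r <- object@residues
  need <- c("resid", "resname", "eLJ", "eCoulomb", "eInter")
  if (!all(need %in% names(r)))
    return(paste("residues must have columns:", paste(need, collapse = ", ")))
  if (nrow(r) && max(abs(r$eInter - (r$eLJ + r$eCoulomb))) > 1e-9)
    return("eInter must equal eLJ + eCoulomb per residue")
  TRUE
})

#' Class "ProtocolSpec"
#'
#' One of the six post-docking MD refinement protocols P1-P6: stage
#' lengths in ns, the simulated-annealing plateau ladder, the target
#' restraint scheme, and whether the peptide C-terminal tail is truncated.
#'
#' @slot id character, "P1".."P6".
#' @slot initialMdNs numeric, length of the initial equilibrium MD stage.
#' @slot saMaxTemp numeric, maximal SA temperature in K.
#' @slot saSteps data.frame with columns `temperature` (K) and
#'   `duration` (ns); the plateau ladder, palindromic in temperature.
#' @slot finalFlexMdNs numeric, length of the final fully flexible MD
#'   stage (0 when the protocol skips it).
#' @slot restraintScheme character, one of all_heavy_target,
#'   calpha_target, release_binding_site.
#' @slot truncatePeptide logical.
#' @slot bindingSiteRadius numeric, Angstrom (contact shell for restraint
#'   release under release_binding_site).
#' @export
setClass("ProtocolSpec",
         representation(id = "character", initialMdNs = "numeric",
                        saMaxTemp = "numeric", saSteps = "data.frame",
                        finalFlexMdNs = "numeric", restraintScheme = "character",
                        truncatePeptide = "logical",
                        bindingSiteRadius = "numeric"),
         prototype(bindingSiteRadius = 5))

setValidity("ProtocolSpec", function(object) {
  s <- object@saSteps
  if (!all(c("temperature", "duration") %in% names(s)))
    return("saSteps must have temperature and duration columns")
  if (nrow(s)) {
    if (any(s$temperature <= 0) || any(s$duration <= 0))
      return("SA temperatures and durations must be positive")
    if (!identical(s$temperature, rev(s$temperature)))
      return("SA plateau temperatures must be palindromic")
    if (sum(s$temperature == max(s$temperature)) != 1L)
      return("maximal SA temperature must appear exactly once")
  }
  if (!object@restraintScheme %in%
      c("all_heavy_target", "calpha_target", "release_binding_site"))
    return("unknown restraint scheme")
  TRUE
})

#' Class "MDPDocument"
#'
#' An ordered key-value parameter document for one simulation stage, in
#' GROMACS mdp dialect.  Deterministic for a fixed protocol and stage, so
#' emitted documents are golden-file testable.
#'
#' @slot keys,values character vectors of equal length.
#' @slot stage character, one of em_sd, em_cg, init_md, sa_md, flex_md.
#' @export
setClass("MDPDocument",
         representation(keys = "character", values = "character",
                        stage = "character"))

setValidity("MDPDocument", function(object) {
  if (length(object@keys) != length(object@values))
    return("keys and values must have equal length")
  if (anyDuplicated(object@keys)) return("duplicate mdp keys")
  TRUE
})

#' Class "FixtureConfig"
#'
#' Configuration of the deterministic synthetic-structure generator; see
#' [fixtureConfig()].  Identical seed and configuration give bit-identical
#' output (R's Mersenne-Twister RNG, seeded locally).
#'
#' @slot seed integer RNG seed.
#' @slot nTargetResidues,peptideLength,nInterfaceWaters,nBulkWaters,nFrames
#'   integer counts.
#' @slot noiseSigma numeric, Angstrom.
#' @slot frameSpacing numeric, ns.
#' @slot improvingFraction numeric in \[0, 1\]: fraction of trajectory
#'   frames moved to within the residence-frequency cutoff of the
#'   reference.
#' @slot rmsdStart numeric, Angstrom, planted starting RMSD of the docked
#'   pose.
#' @export
setClass("FixtureConfig",
         representation(seed = "integer", nTargetResidues = "integer",
                        peptideLength = "integer", nInterfaceWaters = "integer",
                        nBulkWaters = "integer", noiseSigma = "numeric",
                        nFrames = "integer", frameSpacing = "numeric",
                        improvingFraction = "numeric", rmsdStart = "numeric"))

setValidity("FixtureConfig", function(object) {
  counts <- c(object@nTargetResidues, object@peptideLength,
              object@nInterfaceWaters, object@nBulkWaters, object@nFrames)
  if (any(counts < 0L)) return("counts must be non-negative")
  if (object@improvingFraction < 0 || object@improvingFraction > 1)
    return("improvingFraction must lie in [0, 1]")
  if (object@frameSpacing <= 0) return("frameSpacing must be positive")
  if (object@rmsdStart < 0) return("rmsdStart must be non-negative")
  TRUE
})
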