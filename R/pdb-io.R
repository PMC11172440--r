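.ION_RESNAMES <- c("ZN", "NA", "CL", "MG", "K", "MN", "FE", "CU", "CD")

## light pre-scan so format errors carry a line number (bio3d does the
## actual parsing)
.scanPdbLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("unparseable PDB record at line %d: truncated", i))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop(sprintf("unparseable PDB record at line %d: bad coordinates", i))
  }
  invisible(lines)
}

.elementFromAtom <- function(elesy, elety) {
  e <- toupper(trimws(elesy))
  miss <- is.na(e) | !nzchar(e)
  if (any(miss)) {
    guess <- suppressWarnings(bio3d::atom2ele(elety[miss], rescue = TRUE))
    e[miss] <- toupper(guess)
  }
  substr(e, 2, nchar(e)) <- tolower(substr(e, 2, nchar(e)))
  e
}

## highest occupancy wins; first record on a tie
.dropAltloc <- function(at) {
  alt <- at$alt
  if (all(is.na(alt) | alt == "")) return(at)
  grp <- paste(at$chain, at$resno, at$resid, at$elety)
  keep <- unlist(lapply(split(seq_len(nrow(at)), grp), function(idx) {
    if (length(idx) == 1L) return(idx)
    o <- at$o[idx]
    o[is.na(o)] <- 1
    idx[which.max(o)]      # which.max takes the first on ties
  }), use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

.atomsFromBio3d <- function(at, roleMap) {
  element <- .elementFromAtom(at$elesy, at$elety)
  resname <- toupper(trimws(at$resid))
  chain <- ifelse(is.na(at$chain) | at$chain == "", " ", at$chain)
  role <- rep(NA_character_, nrow(at))
  role[resname %in% .WATER_NAMES] <- "water"
  isIon <- resname %in% .ION_RESNAMES & at$type == "HETATM"
  role[isIon] <- "ion"
  unresolved <- is.na(role)
  if (any(unresolved)) {
    if (is.null(roleMap))
      stop("no role mapping supplied; provide roleMap = c(<chain> = 'target'/'ligand')")
    mapped <- roleMap[chain[unresolved]]
    if (anyNA(mapped)) {
      bad <- sort(unique(chain[unresolved][is.na(mapped)]))
      stop(sprintf("chain(s) %s not covered by the role mapping",
                   paste(sQuote(bad), collapse = ", ")))
    }
    role[unresolved] <- mapped
  }
  resname[role == "water"] <- "HOH"
  data.frame(serial = as.integer(at$eleno), name = trimws(at$elety),
             element = element, resname = resname,
             resid = as.integer(at$resno), chain = chain,
             x = at$x, y = at$y, z = at$z,
             heavy = toupper(element) != "H", role = role,
             stringsAsFactors = FALSE)
}

.splitRoles <- function(a, label) {
  pick <- function(r) molecularStructure(a[a$role == r, , drop = FALSE],
                                         label = paste0(label, ":", r))
  complexModel(target = pick("target"), ligand = pick("ligand"),
               waters = pick("water"), ions = pick("ion"))
}

#' Read a PDB file into a ComplexModel
#'
#' Parses ATOM/HETATM records and partitions atoms by role.  Waters
#' (residue names HOH/SOL/WAT) and monoatomic ions (e.g. structural Zn2+)
#' are recognized automatically; every other chain must be assigned to
#' `"target"` or `"ligand"` through `roleMap`.  Hydrogens are kept but
#' flagged non-heavy; alternate locations are reduced to the
#' highest-occupancy record (first on ties).
#'
#' @param path PDB file.
#' @param roleMap named character vector mapping chain id to
#'   "target"/"ligand", e.g. `c(A = "target", B = "ligand")`.
#' @param model model number to extract from a multi-model file (default 1).
#' @return A [ComplexModel-class].
#' @seealso [writePDB()], [readPDBModels()] for NMR-style ensembles.
#' @export
readPDB <- function(path, roleMap = NULL, model = 1L) {
  mods <- readPDBModels(path, roleMap)
  if (model < 1L || model > length(mods))
    stop(sprintf("model %d not present (%d models)", model, length(mods)))
  mods[[model]]
}

#' Read every model of a (possibly multi-model) PDB file
#'
#' NMR entries deposit an ensemble of models; each is returned as one
#' [ComplexModel-class] sharing the same topology.
#'
#' @inheritParams readPDB
#' @return list of [ComplexModel-class], one per model.
#' @export
readPDBModels <- function(path, roleMap = NULL) {
  .scanPdbLines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- .dropAltloc(pdb$atom)
  a <- .atomsFromBio3d(at, roleMap)
  label <- sub("\\.pdb$", "", basename(path))
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod) || nmod <= 1L) return(list(.splitRoles(a, label)))
  ## multi-model coordinates: column-major x1,y1,z1,... per model row;
  ## bio3d's atom table holds model 1, select the altloc-retained rows
  rows <- match(at$eleno, pdb$atom$eleno)
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)[rows, , drop = FALSE]
    ai <- a
    ai$x <- xyz[, 1L]; ai$y <- xyz[, 2L]; ai$z <- xyz[, 3L]
    .splitRoles(ai, sprintf("%s#%d", label, m))
  })
}

#' Write a ComplexModel as a PDB file
#'
#' Standard ATOM/HETATM records with coordinates at 3 decimals; waters
#' are written with residue name HOH, waters and ions as HETATM.  An
#' empty complex produces a file holding only the END record.
#'
#' @param model A [ComplexModel-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writePDB <- function(model, path) {
  a <- atoms(model)
  if (!nrow(a)) {
    writeLines("END", path)
    return(invisible(path))
  }
  type <- ifelse(a$role %in% c("water", "ion"), "HETATM", "ATOM")
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = type, resno = a$resid, resid = a$resname,
                   eleno = a$serial, elety = a$name, chain = a$chain,
                   elesy = toupper(a$element), o = rep(1, nrow(a)),
                   b = rep(0, nrow(a)))
  invisible(path)
}

#' Read a snapshot trajectory
#'
#' Accepts either a directory of numbered PDB snapshot files (sorted by
#' name) or a single multi-model PDB, as produced by extracting frames
#' from an MD trajectory at fixed intervals.
#'
#' @param path directory of `*.pdb` files, or one multi-model PDB file.
#' @param roleMap chain-to-role mapping passed to [readPDB()].
#' @param frameSpacing ns between consecutive frames (default 0.1).
#' @param stageBoundaries optional data.frame with columns `time` (ns)
#'   and `stage` labelling protocol stages.
#' @return A [TrajectorySeries-class].
#' @export
readTrajectory <- function(path, roleMap = NULL, frameSpacing = 0.1,
                           stageBoundaries = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (!length(files)) stop("no .pdb files in directory ", path)
    frames <- lapply(files, readPDB, roleMap = roleMap)
  } else {
    frames <- readPDBModels(path, roleMap)
  }
  trajectorySeries(frames, frameSpacing, stageBoundaries)
}

#' Construct a TrajectorySeries
#'
#' @param frames list of [ComplexModel-class] snapshots, time-ordered.
#' @param frameSpacing ns between frames.
#' @param stageBoundaries optional data.frame (`time`, `stage`).
#' @return A [TrajectorySeries-class].
#' @export
trajectorySeries <- function(frames, frameSpacing = 0.1,
                             stageBoundaries = NULL) {
  if (is.null(stageBoundaries))
    stageBoundaries <- data.frame(time = numeric(), stage = character())
  new("TrajectorySeries", frames = frames, frameSpacing = frameSpacing,
      stageBoundaries = stageBoundaries)
}
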