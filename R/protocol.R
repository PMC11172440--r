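.saLadder <- function(maxTemp, holdNs) {
  if (maxTemp == 323) {
    temps <- c(300, 310, 323, 310, 300)
    dur <- c(2.5, 2.5, holdNs, 2.5, 2.5)
  } else if (maxTemp == 353) {
    up <- c(300, 311, 325, 339, 353)
    temps <- c(up, rev(up)[-1L])
    dur <- c(rep(1.2, 4L), holdNs, rep(1.2, 4L))
  } else stop("unsupported maximal SA temperature: ", maxTemp)
  data.frame(temperature = temps, duration = dur)
}

.protocolSpec <- function(id, initial, maxTemp, hold, flex, scheme, trunc,
                          saTotal) {
  steps <- .saLadder(maxTemp, hold)
  ## reconcile the ladder arithmetic with the nominal SA stage length by
  ## extending the final base-temperature plateau (P2: 19.6 vs 20 ns)
  gap <- saTotal - sum(steps$duration)
  if (abs(gap) > 1e-9)
    steps$duration[nrow(steps)] <- steps$duration[nrow(steps)] + gap
  new("ProtocolSpec", id = id, initialMdNs = initial, saMaxTemp = maxTemp,
      saSteps = steps, finalFlexMdNs = flex, restraintScheme = scheme,
      truncatePeptide = trunc)
}

#' The six built-in MD refinement protocols P1-P6
#'
#' Each protocol is up to three consecutive MD stages: an initial
#' equilibrium MD, a simulated-annealing MD, and (P1/P2 only) a final
#' fully flexible MD.  Stage lengths are 5+20(+20) ns for P1/P2,
#' 15+40 ns for P3/P5 and 10+30 ns for P4/P6.  The SA ladder climbs
#' 300-310-323 K in 2.5 ns plateaus (maximal plateau held 10/30/20/30/20
#' ns for P1/P3/P4/P5/P6) or, for P2, 300-311-325-339-353 K in 1.2 ns
#' plateaus with the 353 K plateau held 10 ns.  P4 and P6 release the
#' position restraints on binding-site residues; P5 and P6 truncate the
#' peptide C-terminal tail.
#'
#' @return named list of six [ProtocolSpec-class] objects.
#' @examples
#' stageLengths(builtinProtocols()$P4)
#' @export
builtinProtocols <- function() {
  list(
    P1 = .protocolSpec("P1", 5, 323, 10, 20, "all_heavy_target", FALSE, 20),
    P2 = .protocolSpec("P2", 5, 353, 10, 20, "all_heavy_target", FALSE, 20),
    P3 = .protocolSpec("P3", 15, 323, 30, 0, "all_heavy_target", FALSE, 40),
    P4 = .protocolSpec("P4", 10, 323, 20, 0, "release_binding_site", FALSE, 30),
    P5 = .protocolSpec("P5", 15, 323, 30, 0, "all_heavy_target", TRUE, 40),
    P6 = .protocolSpec("P6", 10, 323, 20, 0, "release_binding_site", TRUE, 30))
}

#' Simulated-annealing schedule as annealing points
#'
#' Renders the plateau ladder of a protocol as (time, temperature)
#' annealing points: each plateau contributes its start and end point at
#' its temperature, with a short 0.01 ns set-point ramp between
#' consecutive plateaus so that times are strictly increasing (GROMACS
#' interpolates linearly between points).  The schedule starts and ends
#' at the base temperature.
#'
#' @param spec A [ProtocolSpec-class].
#' @return data.frame with columns `time` (ns) and `temperature` (K).
#' @examples
#' tail(saSchedule(builtinProtocols()$P1), 1)   # (20 ns, 300 K)
#' @export
saSchedule <- function(spec) {
  s <- spec@saSteps
  if (!nrow(s)) return(data.frame(time = numeric(), temperature = numeric()))
  ramp <- 0.01
  ends <- cumsum(s$duration)
  starts <- c(0, ends[-length(ends)])
  time <- c(rbind(starts, ifelse(seq_along(ends) < length(ends),
                                 ends - ramp, ends)))
  temperature <- rep(s$temperature, each = 2L)
  data.frame(time = time, temperature = temperature)
}

.mdpCommon <- function(lengthNs, refT = 300) {
  nsteps <- format(round(lengthNs * 1e3 / 0.002), scientific = FALSE)
  c("integrator" = "md", "dt" = "0.002", "nsteps" = nsteps,
    "nstxout" = "5000", "nstenergy" = "5000",           # every 10 ps
    "tcoupl" = "v-rescale", "tc-grps" = "Protein Non-Protein",
    "tau-t" = "0.1 0.1", "ref-t" = sprintf("%g %g", refT, refT),
    "pcoupl" = "Parrinello-Rahman", "tau-p" = "0.5", "ref-p" = "1.0",
    "compressibility" = "4.5e-5",
    "coulombtype" = "PME", "fourierspacing" = "0.12",
    "rcoulomb" = "1.1", "rvdw" = "1.1",
    "constraint-algorithm" = "lincs", "constraints" = "h-bonds")
}

#' Emit the parameter document for one protocol stage
#'
#' Builds the GROMACS-style mdp document for the requested stage of a
#' protocol: steepest-descent or conjugate-gradient energy minimization
#' (convergence thresholds 1000 and 10 kJ/mol/nm), the initial
#' equilibrium MD, the simulated-annealing MD (with the annealing point
#' block from [saSchedule()]), or the final fully flexible MD (P1/P2
#' only).  Fixed parameters follow the common simulation setup: 2 fs time
#' step, v-rescale thermostat (tau 0.1 ps, 300 K), Parrinello-Rahman
#' barostat at 1 bar (tau 0.5 ps, compressibility 4.5e-5 per bar), PME
#' with 0.12 nm Fourier spacing, an 11 Angstrom van der Waals cutoff,
#' LINCS constraints, position-restraint force constant 1000
#' kJ/mol/nm^2, and output every 10 ps.
#'
#' @param spec A [ProtocolSpec-class].
#' @param stage one of "em_sd", "em_cg", "init_md", "sa_md", "flex_md".
#' @return An [MDPDocument-class]; deterministic for a fixed spec/stage.
#' @export
emitMDP <- function(spec, stage = c("em_sd", "em_cg", "init_md", "sa_md",
                                    "flex_md")) {
  stage <- match.arg(stage)
  kv <- switch(stage,
    em_sd = c("integrator" = "steep", "emtol" = "1000", "emstep" = "0.01",
              "nsteps" = "50000",
              "coulombtype" = "PME", "fourierspacing" = "0.12",
              "rcoulomb" = "1.1", "rvdw" = "1.1",
              "define" = "-DPOSRES", "posre-fc" = "1000"),
    em_cg = c("integrator" = "cg", "emtol" = "10", "emstep" = "0.01",
              "nsteps" = "50000",
              "coulombtype" = "PME", "fourierspacing" = "0.12",
              "rcoulomb" = "1.1", "rvdw" = "1.1",
              "define" = "-DPOSRES", "posre-fc" = "1000"),
    init_md = c(.mdpCommon(spec@initialMdNs),
                "define" = "-DPOSRES", "posre-fc" = "1000",
                "restraint-scheme" = spec@restraintScheme),
    sa_md = {
      sched <- saSchedule(spec)
      c(.mdpCommon(sum(spec@saSteps$duration)),
        "define" = "-DPOSRES", "posre-fc" = "1000",
        "restraint-scheme" = spec@restraintScheme,
        "annealing" = "single single",
        "annealing-npoints" = sprintf("%d %d", nrow(sched), nrow(sched)),
        "annealing-time" = paste(rep(sprintf("%g", sched$time), 2L),
                                 collapse = " "),
        "annealing-temp" = paste(rep(sprintf("%g", sched$temperature), 2L),
                                 collapse = " "))
    },
    flex_md = {
      if (spec@finalFlexMdNs <= 0)
        stop(sprintf("protocol %s has no final flexible MD stage", spec@id))
      .mdpCommon(spec@finalFlexMdNs)
    })
  new("MDPDocument", keys = names(kv), values = unname(kv), stage = stage)
}

#' Render, write and parse mdp documents
#'
#' `formatMDP()` renders the ordered key-value pairs as `key = value`
#' lines; `writeMDP()` writes them to a file; `parseMDP()` reads such a
#' file (or character vector) back into an [MDPDocument-class], so a
#' written document round-trips unchanged.
#'
#' @param doc An [MDPDocument-class].
#' @param path output (or input) file path.
#' @param x character vector of lines, or a file path for `parseMDP`.
#' @param stage stage tag to attach on parse.
#' @return `formatMDP()`: character vector; `parseMDP()`: an
#'   [MDPDocument-class].
#' @rdname mdp-io
#' @export
formatMDP <- function(doc) {
  sprintf("%-22s = %s", doc@keys, doc@values)
}

#' @rdname mdp-io
#' @export
writeMDP <- function(doc, path) {
  writeLines(formatMDP(doc), path)
  invisible(path)
}

#' @rdname mdp-io
#' @export
parseMDP <- function(x, stage = "parsed") {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*;", lines)]
  bad <- which(!grepl("=", lines, fixed = TRUE))
  if (length(bad)) stop("unparseable mdp line: ", lines[bad[1L]])
  new("MDPDocument",
      keys = trimws(sub("=.*$", "", lines)),
      values = trimws(sub("^[^=]*=", "", lines)), stage = stage)
}

#' Binding-site restraint-release selection
#'
#' For protocols that release the binding pocket (P4/P6): target residues
#' with any heavy atom within `radius` of any docked-ligand heavy atom
#' are released from position restraints; all other target heavy atoms —
#' and structural Zn2+ ions, always treated as heavy atoms of the target
#' — stay restrained.  The default 5 Angstrom radius is a standard
#' contact-shell definition.
#'
#' @param model A [ComplexModel-class] with the docked ligand in place.
#' @param radius contact radius in Angstrom (> 0).
#' @return A resolved [AtomSelection-class] (kind "custom") whose indices
#'   are the heavy target atoms of the released residues; possibly empty
#'   when the ligand is far from the target.
#' @seealso [restrainedIndices()] for the complementary restrained set.
#' @export
bindingSiteSelection <- function(model, radius = 5) {
  stopifnot(radius > 0)
  ta <- atoms(target(model))
  lig <- .heavyCoords(ligand(model))
  released <- integer()
  if (nrow(ta) && nrow(lig)) {
    th <- which(ta$heavy)
    d <- .minDistTo(as.matrix(ta[th, c("x", "y", "z")]), lig)
    contact <- unique(ta[th[d <= radius], c("chain", "resid")])
    if (nrow(contact)) {
      key <- paste(ta$chain, ta$resid)
      released <- which(ta$heavy & key %in% paste(contact$chain, contact$resid))
    }
  }
  sel <- atomSelection("custom")
  sel@indices <- as.integer(released)
  sel
}

#' Restrained target heavy atoms under a release selection
#'
#' @param model A [ComplexModel-class].
#' @param released selection from [bindingSiteSelection()].
#' @return integer indices (into the target atom table) of restrained
#'   heavy atoms; Zn2+ and other ions are carried in the `ions` component
#'   and are always restrained.
#' @export
restrainedIndices <- function(model, released) {
  ta <- atoms(target(model))
  setdiff(which(ta$heavy), released@indices)
}

#' Truncate the peptide C-terminal tail
#'
#' Removes ligand residues beyond the first `keepN`, capping the new
#' C-terminus by completing the last residue's carbonyl to a carboxylate
#' (an OXT atom mirrored from O about the CA-C axis).  Used by protocols
#' P5/P6 to remove C-terminal tails with no role in target binding;
#' default length 5 matches the tightly bound N-terminal head.
#'
#' @param ligand ligand [MolecularStructure-class].
#' @param keepN residues to keep, 1 <= keepN <= peptide length.
#' @return truncated [MolecularStructure-class].
#' @export
truncatePeptide <- function(ligand, keepN = 5L) {
  a <- atoms(ligand)
  resOrder <- unique(a$resid)
  if (keepN < 1L || keepN > length(resOrder))
    stop(sprintf("keepN must lie in 1..%d", length(resOrder)))
  if (keepN == length(resOrder)) return(ligand)
  keep <- a$resid %in% resOrder[seq_len(keepN)]
  a <- a[keep, , drop = FALSE]
  last <- a$resid == resOrder[keepN]
  if (!any(a$name[last] == "OXT")) {
    ca <- a[last & a$name == "CA", ]; cc <- a[last & a$name == "C", ]
    oo <- a[last & a$name == "O", ]
    if (nrow(ca) == 1L && nrow(cc) == 1L && nrow(oo) == 1L) {
      u <- c(cc$x - ca$x, cc$y - ca$y, cc$z - ca$z)
      u <- u / sqrt(sum(u^2))
      v <- c(oo$x - ca$x, oo$y - ca$y, oo$z - ca$z)
      w <- 2 * sum(v * u) * u - v              # reflect O about the CA-C axis
      oxt <- oo
      oxt$name <- "OXT"
      oxt$serial <- max(a$serial) + 1L
      oxt$x <- ca$x + w[1L]; oxt$y <- ca$y + w[2L]; oxt$z <- ca$z + w[3L]
      a <- rbind(a, oxt)
    }
  }
  molecularStructure(a, label = paste0(ligand@label, ":trunc", keepN))
}
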