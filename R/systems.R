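#' Benchmark histone H3 reader-domain systems
#'
#' The ten target-histone H3 peptide systems used to benchmark
#' post-docking MD refinement: apo/holo PDB accessions, target name,
#' peptide sequence, binding constant, and the heavy-atom RMSD of the
#' fast-docked starting pose (RMSD_start, Angstrom).  Shipped as plain
#' text under `extdata/histone_systems.csv`.
#'
#' @return data.frame, one row per system.
#' @examples
#' subset(histoneSystems(), pdbApo == "3o33")$rmsdStart
#' @export
histoneSystems <- function() {
  utils::read.csv(system.file("extdata", "histone_systems.csv",
                              package = "peprefine"),
                  stringsAsFactors = FALSE)
}

#' Reported refinement outcomes for worked examples
#'
#' Published best-refined RMSD values (or absolute improvements) for the
#' worked refinement examples on the benchmark systems, used to
#' recompute the delta-RMSD improvement arithmetic: system 3o33 under P4
#' with and without pre-MD interface hydration, 3qln under P4, and 4qf2
#' started from its holo target.
#'
#' @return data.frame with columns system, protocol, condition,
#'   rmsdStart, rmsdBest, deltaRmsd (Angstrom; NA where the source
#'   reports the other quantity).
#' @export
refinementOutcomes <- function() {
  utils::read.csv(system.file("extdata", "refinement_outcomes.csv",
                              package = "peprefine"),
                  stringsAsFactors = FALSE)
}
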