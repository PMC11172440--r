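test_that("a minimal PDB with one water parses into a single water residue", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH W 501       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  H1  HOH W 501       0.957   0.000   0.000  1.00  0.00           H",
    "HETATM    3  H2  HOH W 501      -0.240   0.927   0.000  1.00  0.00           H"),
    path)
  m <- readPDB(path)
  expect_equal(nAtoms(waters(m)), 3L)
  expect_equal(nrow(residues(waters(m))), 1L)
  expect_equal(sum(atoms(waters(m))$heavy), 1L)
})

test_that("PDB write/read round-trips coordinates at format precision", {
  hyd <- makeHydrationLayout(fixtureConfig(seed = 11))
  path <- withr::local_tempfile(fileext = ".pdb")
  writePDB(hyd$complex, path)
  back <- readPDB(path, roleMap = toyRoleMap)
  expect_equal(nAtoms(back), nAtoms(hyd$complex))
  expect_equal(coords(back), round(coords(hyd$complex), 3),
               ignore_attr = TRUE)
  expect_equal(nAtoms(ions(back)), 1L)           # Zn HETATM preserved
  expect_equal(atoms(ions(back))$resname, "ZN")
})

test_that("an empty complex writes a file holding only the END record", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writePDB(complexModel(), path)
  expect_identical(readLines(path), "END")
})

test_that("unknown chains without a role mapping raise a configuration error", {
  m <- makeToyComplex(fixtureConfig(seed = 1))
  path <- withr::local_tempfile(fileext = ".pdb")
  writePDB(m$reference, path)
  expect_error(readPDB(path), "role mapping")
  expect_error(readPDB(path, roleMap = c(A = "target")), "'B'")
})

test_that("unparseable records are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       bad     0.000   0.000  1.00  0.00           C"),
    path)
  expect_error(readPDB(path, roleMap = c(A = "target")), "line 2")
})

test_that("alternate locations keep the highest occupancy, first on ties", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       4.000   0.000   0.000  0.50  0.00           C"),
    path)
  m <- readPDB(path, roleMap = c(A = "target"))
  a <- atoms(target(m))
  expect_equal(nrow(a), 2L)
  expect_equal(a$x[a$name == "CA"], 2.000)   # higher occupancy
  expect_equal(a$x[a$name == "CB"], 3.000)   # first record on tie
})

test_that("selections resolve as specified for heavy, calpha and N-terminal kinds", {
  # relabel the lone water as a ligand so it can stand alone
  a <- atoms(mkWaterMolecule()); a$role <- "ligand"; a$resname <- "LIG"
  lone <- complexModel(ligand = molecularStructure(a))
  sel <- resolveSelection(lone, atomSelection("all_heavy"), on = "ligand")
  expect_equal(length(sel@indices), 1L)

  m <- makeToyComplex(fixtureConfig(seed = 2, peptideLength = 10))
  nt <- resolveSelection(m$reference, atomSelection("n_terminal_k", k = 5),
                         on = "ligand")
  la <- atoms(ligand(m$reference))
  expect_true(all(la$resid[nt@indices] <= 5))
  expect_setequal(unique(la$resid[nt@indices]), 1:5)
  expect_true(all(la$heavy[nt@indices]))

  m15 <- makeToyComplex(fixtureConfig(seed = 2, peptideLength = 15))
  ca <- resolveSelection(m15$reference, atomSelection("calpha"), on = "ligand")
  expect_equal(length(ca@indices), 15L)
  expect_error(resolveSelection(m$reference,
                                atomSelection("n_terminal_k", k = 99),
                                on = "ligand"),
               "exceeds ligand length")
})

test_that("correspond pairs atoms by identity and reports missing partners", {
  m <- makeToyComplex(fixtureConfig(seed = 4))
  lig <- ligand(m$reference)
  pr <- correspond(lig, lig)
  expect_identical(pr$ia, pr$ib)

  trunc <- truncatePeptide(lig, 5)
  sel <- atomSelection("n_terminal_k", k = 5)
  pr2 <- correspond(lig, trunc, sel)
  expect_equal(length(pr2$ia), sum(atoms(lig)$heavy & atoms(lig)$resid <= 5))

  bad <- atoms(lig)
  bad$name[bad$name == "CA" & bad$resid == 3] <- "CX"
  badS <- molecularStructure(bad)
  expect_error(correspond(lig, badS), "3 CA")
})

test_that("correspond is symmetric up to pair order", {
  m <- makeToyComplex(fixtureConfig(seed = 5))
  a <- ligand(m$docked); b <- ligand(m$reference)
  ab <- correspond(a, b)
  ba <- correspond(b, a)
  expect_identical(ab$ia[order(ab$ia)], ba$ib[order(ba$ib)])
  expect_identical(ab$ib[order(ab$ia)], ba$ia[order(ba$ib)])
})

test_that("superposition recovers an applied rigid transform exactly", {
  m <- makeToyComplex(fixtureConfig(seed = 6))
  ref <- m$reference
  mob <- applyTransform(ref, rigidTransform(
    matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3), c(1, 2, 3)))
  tr <- superposeKabsch(mob, ref)
  expect_s4_class(tr, "RigidTransform")
  fitted <- applyTransform(mob, tr)
  expect_lt(max(abs(coords(fitted) - coords(ref))), 1e-9)

  trId <- superposeKabsch(ref, ref)
  expect_lt(max(abs(trId@rotation - diag(3))), 1e-9)
  expect_lt(max(abs(trId@translation)), 1e-9)
})

test_that("Kabsch RMSD matches the quaternion-eigenvalue oracle under noise", {
  set.seed(42)
  for (rep in 1:5) {
    P <- matrix(rnorm(30, sd = 4), 10, 3)
    Q <- sweep(P %*% t(randomRotation()), 2, rnorm(3), "+") +
      matrix(rnorm(30, sd = 0.1), 10, 3)
    mk <- function(X) mkStruct(paste0("C", 1:10), rep("C", 10),
                               X[, 1], X[, 2], X[, 3],
                               resname = "ALA", role = "target", chain = "A")
    cm <- function(X) complexModel(target = mk(X))
    sel <- atomSelection("all_heavy")
    tr <- superposeKabsch(cm(Q), cm(P), sel)
    fitQ <- applyTransform(Q, tr)
    got <- sqrt(sum((fitQ - P)^2) / 10)
    expect_equal(got, quaternionRmsd(P, Q), tolerance = 1e-8)
  }
})

test_that("perturbing the optimal rotation never decreases the fit RMSD", {
  set.seed(7)
  P <- matrix(rnorm(30, sd = 3), 10, 3)
  Q <- P + matrix(rnorm(30, sd = 0.3), 10, 3)
  mk <- function(X) complexModel(target = mkStruct(
    paste0("C", 1:10), rep("C", 10), X[, 1], X[, 2], X[, 3],
    resname = "ALA", role = "target", chain = "A"))
  tr <- superposeKabsch(mk(Q), mk(P), atomSelection("all_heavy"))
  base <- sqrt(sum((applyTransform(Q, tr) - P)^2) / 10)
  for (i in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 1e-4, 0.05)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    Rp <- (diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)) %*% tr@rotation
    trP <- rigidTransform(Rp, tr@translation)
    pert <- sqrt(sum((sweep(Q %*% t(Rp), 2, tr@translation, "+") - P)^2) / 10)
    expect_gte(pert, base - 1e-12)
  }
})

test_that("degenerate superposition geometry is rejected", {
  X <- cbind(seq_len(5), 0, 0)   # collinear
  mk <- function(X) complexModel(target = mkStruct(
    paste0("C", 1:5), rep("C", 5), X[, 1], X[, 2], X[, 3],
    resname = "ALA", role = "target", chain = "A"))
  expect_error(superposeKabsch(mk(X), mk(X), atomSelection("all_heavy")),
               "collinear|degenerate")
})

test_that("MOL2 export writes charges that survive a round trip", {
  w <- mkWaterMolecule()
  aw <- atoms(w); aw$role <- "ligand"; aw$resname <- "LIG"
  wl <- molecularStructure(aw)
  ch <- assignGasteiger(wl)
  path <- withr::local_tempfile(fileext = ".mol2")
  writeMOL2(complexModel(ligand = wl), ch, path)
  txt <- readLines(path)
  expect_true(any(grepl("@<TRIPOS>ATOM", txt)))
  back <- readMOL2(path)
  expect_lt(max(abs(back$charges@charges - ch@charges)), 1e-4)
  expect_lt(abs(sum(back$charges@charges)), 2e-4)

  lig <- ligand(makeToyComplex(fixtureConfig(seed = 8))$reference)
  chL <- assignGasteiger(lig)
  path2 <- withr::local_tempfile(fileext = ".mol2")
  writeMOL2(complexModel(ligand = lig), chL, path2)
  back2 <- readMOL2(path2)
  expect_lt(max(abs(back2$charges@charges - chL@charges)), 1e-4)
  expect_error(writeMOL2(complexModel(ligand = lig), ch, path2),
               "mismatch")
})
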