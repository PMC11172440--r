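test_that("PEOE charges: isolated atom stays at its formal charge", {
  lone <- mkStruct("C1", "C", 0, 0, 0)
  expect_equal(assignGasteiger(lone)@charges, 0)
  charged <- assignGasteiger(lone, formalCharges = 1)
  expect_equal(charged@charges, 1)
})

test_that("PEOE charges conserve the total formal charge on arbitrary molecules", {
  mols <- list(mkWaterMolecule(), mkMethanol(), mkEthylamine(),
               ligand(makeToyComplex(fixtureConfig(seed = 31))$reference))
  for (m in mols) {
    ch <- assignGasteiger(m)
    expect_lt(abs(sum(ch@charges)), 1e-6)
  }
  eth <- mkEthylamine()
  fc <- c(0, 0, 1, rep(0, 7))           # protonated amine
  chp <- assignGasteiger(eth, formalCharges = fc)
  expect_equal(sum(chp@charges), 1, tolerance = 1e-6)
})

test_that("PEOE charges agree with an independent Gasteiger implementation", {
  # reference values computed with OpenBabel 3.1 (--partialcharge
  # gasteiger) on the same geometries, frozen at 4 decimals
  cases <- list(
    list(mkWaterMolecule(), c(-0.4105, 0.2052, 0.2052)),
    list(mkMethanol(), c(0.0330, -0.3982, 0.0521, 0.0521, 0.0521, 0.2090)),
    list(mkEthylamine(), c(-0.0528, -0.0097, -0.3302, 0.0242, 0.0242,
                           0.0242, 0.0419, 0.0419, 0.1182, 0.1182)))
  for (cs in cases) {
    got <- assignGasteiger(cs[[1]])@charges
    expect_lt(max(abs(got - cs[[2]])), 0.01)
  }
})

test_that("an element without PEOE parameters is reported by atom", {
  bad <- mkStruct(c("C1", "ZN"), c("C", "Zn"), c(0, 1.9), 0, 0)
  expect_error(assignGasteiger(bad), "ZN")
})

test_that("merging nonpolar hydrogens preserves the total charge", {
  m <- mkMethanol()
  ch <- assignGasteiger(m)
  red <- mergeNonpolarH(m, ch)
  expect_equal(nAtoms(red$structure), 3L)   # C, O, polar H
  expect_equal(sum(red$charges@charges), sum(ch@charges), tolerance = 1e-12)
  expect_true("HO" %in% atoms(red$structure)$name)
})

test_that("the sigmoidal dielectric has the closed-form limits and monotone rise", {
  dm <- dielectricModel()
  expect_equal(epsilonR(1e9, dm), 78.4, tolerance = 1e-9)
  A <- -8.5525; B <- 78.4 - A; k <- 7.7839; lam <- 0.003627
  expect_equal(epsilonR(0, dm), A + B / (1 + k))
  r <- seq(1, 20, by = 0.25)
  vals <- epsilonR(r, dm)
  # naive symbolic evaluation oracle
  expect_equal(vals, A + B / (1 + k * exp(-lam * B * r)), tolerance = 1e-12)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 1))
})

test_that("LJ pair coefficients follow the Amber combination rules", {
  tab <- amberLJTable()
  # zero well depth on either side zeroes both coefficients
  ab <- ljPairParams("HO", "CT", tab)
  expect_equal(unname(ab), c(0, 0))
  # identical types: minimum at r = 2 R_i with depth eps_i
  ctct <- ljPairParams("CT", "CT", tab)
  Ri <- tab$R[tab$type == "CT"]; ei <- tab$eps[tab$type == "CT"]
  pot <- function(r) ctct["A"] / r^12 - ctct["B"] / r^6
  expect_equal(unname(pot(2 * Ri)), -ei, tolerance = 1e-12)
  expect_gt(pot(2 * Ri - 1e-4), pot(2 * Ri))
  expect_gt(pot(2 * Ri + 1e-4), pot(2 * Ri))
  # carbon-oxygen pair against direct arithmetic
  co <- ljPairParams("CT", "O", tab)
  Rij <- 1.9080 + 1.6612; eij <- sqrt(0.1094 * 0.2100)
  expect_equal(unname(co["A"]), eij * Rij^12, tolerance = 1e-9)
  expect_equal(unname(co["B"]), 2 * eij * Rij^6, tolerance = 1e-9)
  expect_error(ljPairParams("XX", "CT", tab), "unknown LJ type")
})

test_that("interaction energies vanish for a far-separated ligand", {
  m <- makeToyComplex(fixtureConfig(seed = 32, peptideLength = 5))
  far <- m$reference
  a <- atoms(ligand(far)); a$x <- a$x + 500
  far@ligand <- molecularStructure(a)
  prof <- suppressWarnings(perResidueEinter(far))
  expect_true(all(abs(energyTable(prof)$eInter) < 1e-3))
})

test_that("a single charge pair reproduces the screened-Coulomb closed form", {
  tgt <- mkStruct("DU1", "N", 0, 0, 0, resname = "DUM", chain = "A",
                  role = "target")
  lig <- mkStruct("DU2", "N", 10, 0, 0, resname = "DUM", chain = "B")
  cx <- complexModel(target = tgt, ligand = lig)
  qp <- new("ChargeSet", charges = 1, totalFormalCharge = 1, method = "manual")
  qm <- new("ChargeSet", charges = -1, totalFormalCharge = -1, method = "manual")
  zeroLJ <- data.frame(type = "N", R = 1.824, eps = 0)
  prof <- perResidueEinter(cx, targetCharges = qp, ligandCharges = qm,
                           table = zeroLJ)
  expected <- -332.06 / (epsilonR(10) * 10)
  expect_equal(totalEinter(prof), expected, tolerance = 1e-12)
  expect_equal(energyTable(prof)$eLJ, 0)
})

test_that("per-residue energies partition the brute-force double sum exactly", {
  m <- makeToyComplex(fixtureConfig(seed = 33, peptideLength = 6))
  cx <- m$reference
  chT <- assignGasteiger(target(cx))
  chL <- assignGasteiger(ligand(cx))
  prof <- suppressWarnings(
    perResidueEinter(cx, targetCharges = chT, ligandCharges = chL))
  # independent brute-force double loop
  tab <- amberLJTable()
  tyT <- suppressWarnings(assignLJTypes(target(cx)))
  tyL <- suppressWarnings(assignLJTypes(ligand(cx)))
  XT <- coords(target(cx)); XL <- coords(ligand(cx))
  la <- atoms(ligand(cx))
  eTot <- 0; eRes <- setNames(numeric(6), as.character(1:6))
  for (i in seq_len(nrow(XT))) for (j in seq_len(nrow(XL))) {
    r <- sqrt(sum((XT[i, ] - XL[j, ])^2))
    ab <- ljPairParams(tyT[i], tyL[j], tab)
    e <- ab["A"] / r^12 - ab["B"] / r^6 +
      332.06 * chT@charges[i] * chL@charges[j] / (epsilonR(r) * r)
    eTot <- eTot + e
    eRes[as.character(la$resid[j])] <- eRes[as.character(la$resid[j])] + e
  }
  expect_equal(totalEinter(prof), unname(eTot), tolerance = 1e-9)
  expect_equal(energyTable(prof)$eInter, unname(eRes), tolerance = 1e-9)
  expect_equal(energyTable(prof)$eInter,
               energyTable(prof)$eLJ + energyTable(prof)$eCoulomb)
})

test_that("swapping target and ligand leaves the total interaction energy unchanged", {
  m <- makeToyComplex(fixtureConfig(seed = 34, peptideLength = 4,
                                    nTargetResidues = 6))
  cx <- m$reference
  chT <- assignGasteiger(target(cx))
  chL <- assignGasteiger(ligand(cx))
  fwd <- suppressWarnings(
    perResidueEinter(cx, targetCharges = chT, ligandCharges = chL))
  # swap roles (relabel atoms so validity holds)
  ta <- atoms(target(cx)); ta$role <- "ligand"; ta$chain <- "B"
  ta$resid <- as.integer(ta$resid)
  la <- atoms(ligand(cx)); la$role <- "target"; la$chain <- "A"
  swapped <- complexModel(target = molecularStructure(la),
                          ligand = molecularStructure(ta))
  rev <- suppressWarnings(
    perResidueEinter(swapped, targetCharges = chL, ligandCharges = chT))
  expect_equal(totalEinter(rev), totalEinter(fwd), tolerance = 1e-9)
})

test_that("the Coulomb term sign follows the charge product", {
  tgt <- mkStruct("DU1", "N", 0, 0, 0, resname = "DUM", chain = "A",
                  role = "target")
  lig <- mkStruct("DU2", "N", 8, 0, 0, resname = "DUM", chain = "B")
  cx <- complexModel(target = tgt, ligand = lig)
  zeroLJ <- data.frame(type = "N", R = 1.824, eps = 0)
  for (qq in list(c(1, 1), c(1, -1), c(-1, -1))) {
    prof <- perResidueEinter(
      cx,
      targetCharges = new("ChargeSet", charges = qq[1],
                          totalFormalCharge = qq[1], method = "m"),
      ligandCharges = new("ChargeSet", charges = qq[2],
                          totalFormalCharge = qq[2], method = "m"),
      table = zeroLJ)
    expect_equal(sign(totalEinter(prof)), sign(qq[1] * qq[2]))
  }
})

test_that("coincident atoms raise a geometry error", {
  tgt <- mkStruct("DU1", "N", 0, 0, 0, resname = "DUM", chain = "A",
                  role = "target")
  lig <- mkStruct("DU2", "N", 0, 0, 0, resname = "DUM", chain = "B")
  expect_error(suppressWarnings(
    perResidueEinter(complexModel(target = tgt, ligand = lig))),
    "r = 0|coincident")
})

test_that("an empty profile totals zero and dominance flags the right residue", {
  empty <- new("EnergyProfile", residues = data.frame(
    resid = integer(), resname = character(), eLJ = numeric(),
    eCoulomb = numeric(), eInter = numeric()))
  expect_equal(totalEinter(empty), 0)

  prof <- new("EnergyProfile", residues = data.frame(
    resid = 1:4, resname = c("ALA", "ARG", "THR", "LYS"),
    eLJ = c(-1, -8, -0.5, -2), eCoulomb = c(-1, -12, 0.5, -2),
    eInter = c(-2, -20, 0, -4)))
  dom <- anchoringResidues(prof, fraction = 0.4)
  expect_equal(dom$resname, "ARG")
  expect_gt(dom$share, 0.5)              # R2 carries over half the total
})
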