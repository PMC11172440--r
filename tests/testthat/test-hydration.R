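# all-pairs distance oracle: water oxygen indices within d of any heavy
# atom of a structure
oracleWithin <- function(oxy, struct, d) {
  a <- atoms(struct)
  H <- as.matrix(a[a$heavy, c("x", "y", "z"), drop = FALSE])
  which(vapply(seq_len(nrow(oxy)), function(i) {
    min(sqrt(colSums((t(H) - oxy[i, ])^2))) <= d
  }, logical(1)))
}

test_that("water stripping removes exactly the clashing residues", {
  hyd <- makeHydrationLayout(fixtureConfig(seed = 21))
  cx <- hyd$complex
  ht <- complexModel(target = target(cx), waters = waters(cx),
                     ions = ions(cx))
  merged <- stripClashingWaters(ht, ligand(cx), dmin = 1.75)
  # oracle: strict < dmin to any ligand heavy atom
  ws <- complexWaterSet(cx)
  a <- atoms(ligand(cx))
  H <- as.matrix(a[a$heavy, c("x", "y", "z")])
  dmin <- vapply(seq_len(nrow(ws@oxygens)), function(i)
    min(sqrt(colSums((t(H) - ws@oxygens[i, ])^2))), numeric(1))
  expectSurvive <- sort(ws@ids[dmin >= 1.75])
  expect_identical(sort(atoms(waters(merged))$resid), expectSurvive)
  expect_equal(nAtoms(target(merged)), nAtoms(target(cx)))
  expect_equal(nAtoms(ions(merged)), nAtoms(ions(cx)))
})

test_that("stripping boundary is strict: a water exactly at dmin survives", {
  lig <- mkStruct("C1", "C", 0, 0, 0)
  mkHyd <- function(z) complexModel(
    target = mkStruct("CA", "C", 10, c(0, 1, 2), 0, resname = "ALA",
                      resid = 1:3, chain = "A", role = "target"),
    waters = mkWaterStruct(matrix(c(0, 0, z), 1)))
  farKept <- stripClashingWaters(mkHyd(5), lig)
  expect_equal(nAtoms(waters(farKept)), 1L)
  atLimit <- stripClashingWaters(mkHyd(1.75), lig)
  expect_equal(nAtoms(waters(atLimit)), 1L)      # exactly dmin: retained
  inside <- stripClashingWaters(mkHyd(1.0), lig)
  expect_equal(nAtoms(waters(inside)), 0L)
})

test_that("interface waters require proximity to both partners", {
  tgt <- mkStruct("CA", "C", c(0, 2, 4), 0, 0, resname = "ALA",
                  resid = 1:3, chain = "A", role = "target")
  lig <- mkStruct(c("C1", "C2"), "C", c(0, 2), 6, 0, chain = "B")
  nearTargetOnly <- matrix(c(0, -3, 0), 1)
  between <- matrix(c(1, 3, 0), 1)        # 3.0 from each partner
  cx <- complexModel(target = tgt, ligand = lig,
                     waters = mkWaterStruct(rbind(nearTargetOnly, between)))
  ws <- interfaceWaters(cx, dmax = 3.5)
  expect_equal(nrow(ws@oxygens), 1L)
  expect_equal(ws@ids, 502L)
})

test_that("planted interface waters are recovered exactly against the all-pairs oracle", {
  cfg <- fixtureConfig(seed = 22, nInterfaceWaters = 12, nBulkWaters = 30)
  hyd <- makeHydrationLayout(cfg)
  ws <- interfaceWaters(hyd$complex, dmax = 3.5)
  expect_equal(nrow(ws@oxygens), 12L)
  all <- complexWaterSet(hyd$complex)
  nearT <- oracleWithin(all@oxygens, target(hyd$complex), 3.5)
  nearL <- oracleWithin(all@oxygens, ligand(hyd$complex), 3.5)
  expect_identical(sort(ws@ids), sort(all@ids[intersect(nearT, nearL)]))
})

test_that("interface membership is nested in the distance threshold", {
  hyd <- makeHydrationLayout(fixtureConfig(seed = 23))
  w1 <- interfaceWaters(hyd$complex, dmax = 2.5)
  w2 <- interfaceWaters(hyd$complex, dmax = 3.5)
  w3 <- interfaceWaters(hyd$complex, dmax = 5.0)
  expect_true(all(w1@ids %in% w2@ids))
  expect_true(all(w2@ids %in% w3@ids))
})

test_that("water matching handles the trivial and empty cases", {
  oxy <- matrix(runif(30, 0, 50), 10, 3)
  same <- matchWaters(waterSet(oxy, source = "predicted"),
                      waterSet(oxy, source = "crystallographic"))
  expect_equal(successRate(same), 100)

  far <- waterSet(oxy + 2.0 / sqrt(3), source = "predicted")
  none <- matchWaters(far, waterSet(oxy, source = "crystallographic"))
  expect_equal(successRate(none), 0)

  empty <- matchWaters(waterSet(oxy, source = "predicted"),
                       waterSet(matrix(numeric(), 0, 3),
                                source = "crystallographic"))
  expect_true(is.na(successRate(empty)))
})

test_that("86 of 100 predictions within tolerance give an 86% success rate", {
  grid <- as.matrix(expand.grid(x = seq(0, 45, 5), y = seq(0, 45, 5)))
  refO <- cbind(grid, 0)[1:100, ]
  disp <- ifelse(seq_len(100) <= 86, 0.5, 2.0)
  predO <- refO + cbind(0, 0, disp)
  res <- matchWaters(waterSet(predO, source = "predicted"),
                     waterSet(refO, source = "crystallographic"),
                     tolerance = 1.5)
  expect_equal(successRate(res), 86)
  expect_equal(nrow(waterMatches(res)), 86L)
  expect_true(all(waterMatches(res)$distance < 1.5))
})

test_that("greedy matching equals the maximum bipartite matching on planted sites", {
  hyd <- makeHydrationLayout(fixtureConfig(seed = 24), matchFraction = 0.75)
  res <- matchWaters(hyd$predicted, hyd$reference)
  # independent maximum-matching oracle over the candidate graph
  d <- as.matrix(dist(rbind(hyd$predicted@oxygens, hyd$reference@oxygens)))
  np <- nrow(hyd$predicted@oxygens); nr <- nrow(hyd$reference@oxygens)
  d <- d[seq_len(np), np + seq_len(nr), drop = FALSE]
  edges <- which(d < 1.5, arr.ind = TRUE)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, np), rep(TRUE, nr)),
    edges = as.vector(t(cbind(edges[, 1], np + edges[, 2]))))
  opt <- igraph::max_bipartite_match(g)$matching_size
  expect_equal(nrow(waterMatches(res)), opt)
})

test_that("success rate is monotone non-decreasing in the tolerance", {
  hyd <- makeHydrationLayout(fixtureConfig(seed = 25), matchFraction = 0.5)
  srs <- vapply(c(0.3, 0.8, 1.5, 2.5, 4), function(tol)
    successRate(matchWaters(hyd$predicted, hyd$reference, tol)), numeric(1))
  expect_true(all(diff(srs) >= 0))
})

test_that("a dry complex yields no water bridges", {
  m <- makeToyComplex(fixtureConfig(seed = 26))
  expect_equal(nrow(findWaterBridges(m$reference)), 0L)
})

test_that("a water within H-bond reach of both partners forms one bridge", {
  tgt <- mkStruct(c("CA", "OD1"), c("C", "O"), c(0, 0), c(5.7, 2.9), c(0, 0),
                  resname = "ASP", resid = 7L, chain = "A", role = "target")
  lig <- mkStruct(c("CE", "NZ"), c("C", "N"), c(0, 0), c(-4, -2.8), c(0, 0),
                  resname = "LYS", resid = 4L, chain = "B")
  cx <- complexModel(target = tgt, ligand = lig,
                     waters = mkWaterStruct(matrix(c(0, 0, 0), 1)))
  br <- findWaterBridges(cx)
  expect_equal(nrow(br), 1L)
  expect_equal(br$ligandAtom, "NZ")
  expect_equal(br$targetAtom, "OD1")
  expect_equal(br$ligandResid, 4L)
})

test_that("three planted bridges at one residue are all recovered", {
  m <- makeToyComplex(fixtureConfig(seed = 27))
  cx <- plantWaterBridges(m$reference, residueIndex = 4, n = 3)
  br <- findWaterBridges(cx, hbondCutoff = 3.5)
  per <- bridgesPerResidue(br)
  expect_equal(per$n[per$ligandResid == 4], 3L)
  # distance-enumeration oracle: every planted water is within the
  # cutoff of at least one polar atom on each side
  ws <- complexWaterSet(cx)
  la <- atoms(ligand(cx)); ta <- atoms(target(cx))
  lp <- as.matrix(la[la$element %in% c("N", "O"), c("x", "y", "z")])
  tp <- as.matrix(ta[ta$element %in% c("N", "O"), c("x", "y", "z")])
  for (i in seq_len(nrow(ws@oxygens))) {
    expect_lte(min(sqrt(colSums((t(lp) - ws@oxygens[i, ])^2))), 3.5)
    expect_lte(min(sqrt(colSums((t(tp) - ws@oxygens[i, ])^2))), 3.5)
  }
})
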