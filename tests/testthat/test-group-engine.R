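decompOf <- function(smiles, ...) {
  decompose(normalizeConventions(parseSmiles(smiles), ...), ctab)
}

test_that("worked-example molecules decompose into their published group vectors", {
  dk <- decompOf("C1(=C)OC(=O)C1")
  expect_equal(groupMultiset(dk), c(
    "Angle90|" = 4L, "C sp2|C=CO" = 1L, "C sp2|CO=O" = 1L,
    "C sp2|H2=C" = 1L, "C sp3|H2C2" = 1L, "O|C2(2pi)" = 1L))

  expect_equal(groupMultiset(decompOf("CC(=O)C")),
               c("C sp2|C2=O" = 1L, "C sp3|H3C" = 2L))
  expect_equal(groupMultiset(decompOf("OO")), c("O|HO" = 2L))
  expect_equal(groupMultiset(decompOf("C1CC1")),
               c("Angle60|" = 3L, "C sp3|H2C2" = 3L))
})

test_that("pi-environment counting matches the reference spellings", {
  ph <- decompOf("Oc1ccccc1")
  expect_equal(ordinaryGroups(ph)[["O|HC(pi)"]], 1L)
  gz <- decompOf("[NH3+]CC([O-])=O")
  expect_equal(groupMultiset(gz), c(
    "C sp2|CO=O(-)" = 1L, "C sp3|H2CN(+)" = 1L, "N(+) sp3|H3C" = 1L))
  ## ester oxygen sees one pi neighbor, the dialkyl ether none
  est <- decompOf("CC(=O)OC")
  expect_equal(ordinaryGroups(est)[["O|C2(pi)"]], 1L)
  eth <- decompOf("COC")
  expect_equal(ordinaryGroups(eth)[["O|C2"]], 1L)
  ## hypervalent sulfur is not a pi neighbor: bisulfate O-H renders plain HS
  bis <- decompOf("OS(=O)(=O)[O-]")
  expect_equal(groupMultiset(bis), c("O|HS" = 1L, "S4|O2=O2(-)" = 1L))
})

test_that("charged-fragment grammar covers imidazolium, nitrate and dicyanamide", {
  bmim <- decompOf("CCCCn1cc[n+](C)c1.[Cl-]")
  g <- ordinaryGroups(bmim)
  expect_equal(g[["C(+) aromatic|H:N2"]], 1L)
  expect_equal(g[["N aromatic|C2:C(+)"]], 2L)
  expect_equal(g[["C sp2|H=CN"]], 2L)
  expect_equal(g[["C sp3|H3N"]], 1L)
  expect_length(uncoveredAtoms(bmim), 0)

  no3 <- decompOf("[O-][N+]([O-])=O")
  expect_equal(groupMultiset(no3), c("N(+) sp2|O2=O(-)" = 1L))
  dca <- decompOf("N#C[N-]C#N")
  expect_equal(groupMultiset(dca), c("C sp|N#N(-)" = 2L, "N(-)|C2" = 1L))
})

test_that("atom classification covers the valence classes and charge tags", {
  sulfone <- normalizeConventions(parseSmiles("CS(=O)(=O)C"))
  s <- which(atoms(sulfone)$element == "S")
  expect_equal(classifyAtom(sulfone, s), "S4")
  expect_equal(encodeNeighbors(sulfone, s), "C2=O2")
  sulfide <- normalizeConventions(parseSmiles("CSC"))
  s <- which(atoms(sulfide)$element == "S")
  expect_equal(classifyAtom(sulfide, s), "S2")
  tma <- normalizeConventions(parseSmiles("C[N+](C)(C)C"))
  n <- which(atoms(tma)$element == "N")
  expect_equal(classifyAtom(tma, n), "N(+) sp3")
  expect_equal(encodeNeighbors(tma, n), "C4")
  p3 <- normalizeConventions(parseSmiles("CP(C)C"))
  p <- which(atoms(p3)$element == "P")
  expect_equal(classifyAtom(p3, p), "P3")
})

test_that("iodine is rendered J in neighbor descriptors", {
  mei <- decompOf("CCI")
  expect_equal(ordinaryGroups(mei)[["C sp3|H2CJ"]], 1L)
})

test_that("backbone coverage: every degree>=2 atom yields one group or one uncovered entry", {
  for (smi in c("C1(=C)OC(=O)C1", "CCCCn1cc[n+](C)c1.[Cl-]",
                "[NH3+]CC([O-])=O", "Oc1ccccc1", "C",
                "CC(C)(C)C", "OS(=O)(=O)[O-]")) {
    m <- normalizeConventions(parseSmiles(smi))
    d <- decompose(m, ctab)
    deg <- vapply(seq_len(atomCount(m)),
                  function(i) hcgroups:::degreeOf(m, i), integer(1))
    n_backbone <- sum(atoms(m)$element != "H" & deg >= 2)
    expect_equal(sum(ordinaryGroups(d)) + length(uncoveredAtoms(d)),
                 n_backbone, label = smi)
  }
})

test_that("methane renders an unknown H4 key and is reported uncovered, not fatal", {
  d <- decompOf("C")
  expect_length(ordinaryGroups(d), 0)
  expect_length(uncoveredAtoms(d), 1)
})

test_that("decomposition is invariant under atom reindexing", {
  set.seed(42)
  for (smi in c("C1(=C)OC(=O)C1", "CCCCn1cc[n+](C)c1.[Cl-]",
                "[NH3+]CC([O-])=O", "Oc1ccccc1", "CC(=O)OC")) {
    ref <- decompOf(smi)
    base <- normalizeConventions(parseSmiles(smi))
    for (rep in 1:3) {
      pm <- permuteAtoms(base)
      d <- decompose(pm, ctab)
      expect_equal(groupMultiset(d), groupMultiset(ref),
                   label = paste(smi, "perm", rep))
    }
  }
})

test_that("topology-only angle groups fire for 3- and 4-rings but never 5-rings", {
  expect_equal(unname(detectAngleGroups(parseSmiles("C1CC1"))["Angle60"]), 3L)
  expect_equal(unname(detectAngleGroups(parseSmiles("C1(=C)OC(=O)C1"))["Angle90"]), 4L)
  expect_equal(sum(detectAngleGroups(parseSmiles("O=C1CCCC1"))), 0L)
  expect_equal(sum(detectAngleGroups(parseSmiles("O=C1CCCCC1"))), 0L)
})

test_that("3D angle binning classifies the idealized square ring", {
  dk3d <- parseMolfile(hcgroups:::diketene3dMolBlock())
  ang <- detectAngleGroups(dk3d, "use_3d")
  expect_equal(unname(ang["Angle90"]), 4L)
  expect_equal(unname(ang["Angle60"] + ang["Angle102"]), 0L)
  ## the full 3D decomposition matches the topological one
  d <- decompose(normalizeConventions(dk3d), ctab, "use_3d")
  expect_equal(groupMultiset(d), groupMultiset(decompOf("C1(=C)OC(=O)C1")))
})

test_that("H-bridge detection flips across the 1.75 A threshold without touching atom groups", {
  on <- hcgroups:::hbondPairMolecule(1.6)
  off <- hcgroups:::hbondPairMolecule(1.9)
  expect_equal(detectHbondGroups(on), 1L)
  expect_equal(detectHbondGroups(off), 0L)
  don <- decompose(normalizeConventions(on), ctab, "use_3d")
  doff <- decompose(normalizeConventions(off), ctab, "use_3d")
  expect_equal(ordinaryGroups(don), ordinaryGroups(doff))
  expect_equal(specialGroups(don)[["H|H Acceptor"]], 1L)
  expect_false("H|H Acceptor" %in% names(specialGroups(doff)))
  ## no acidic hydrogen, no bridge
  eth <- hhContactFixture(3.5)
  expect_equal(detectHbondGroups(eth), 0L)
})

test_that("H-H contacts are binned by distance and exclude geminal/vicinal pairs", {
  expect_equal(unname(detectHhContacts(hhContactFixture(1.9))), c(1L, 0L))
  expect_equal(unname(detectHhContacts(hhContactFixture(2.15))), c(0L, 1L))
  expect_equal(unname(detectHhContacts(hhContactFixture(3.0))), c(0L, 0L))
})

test_that("geometry-dependent detectors refuse topology-only molecules", {
  flat <- parseSmiles("OCCO")
  expect_error(detectHbondGroups(flat), "GeometryRequired")
  expect_error(detectHhContacts(flat), "GeometryRequired")
  expect_error(detectAngleGroups(parseSmiles("C1CC1"), "use_3d"),
               "GeometryRequired")
})
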