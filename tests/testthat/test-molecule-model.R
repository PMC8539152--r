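test_that("SMILES parsing materializes explicit hydrogens and perceives structure", {
  h2o2 <- parseSmiles("OO", "hydrogen peroxide")
  expect_equal(unname(elementCounts(h2o2)[c("O", "H")]), c(2L, 2L))
  expect_equal(nrow(bonds(h2o2)), 3)  # O-O plus two O-H
  oo <- bonds(h2o2)[bonds(h2o2)$a1 <= 2 & bonds(h2o2)$a2 <= 2, ]
  expect_equal(oo$order, "single")

  ace <- parseSmiles("CC(=O)C", "acetone")
  a <- atoms(ace)
  cidx <- which(a$element == "C")
  expect_equal(sort(a$hyb[cidx]), c("sp2", "sp3", "sp3"))
  expect_equal(a$hyb[a$element == "O"], "sp2")
  expect_equal(sum(a$element == "H"), 6)

  dk <- parseSmiles("C1(=C)OC(=O)C1", "diketene")
  expect_equal(unname(elementCounts(dk)[c("C", "O", "H")]), c(4L, 2L, 4L))
  rings <- hcgroups:::smallestRings(dk)
  expect_length(rings, 1)
  expect_length(rings[[1]], 4)
  expect_false(dk@has3d)
})

test_that("unsupported elements and malformed SMILES are rejected at parse time", {
  expect_error(parseSmiles("[Fe]"), "UnsupportedElement")
  expect_error(parseSmiles("[Na+].[Cl-]"), "UnsupportedElement")
  expect_error(parseSmiles("C1CC"), "ParseError")
  expect_error(parseSmiles("C(C"), "ParseError")
})

test_that("charged bracket atoms carry formal charges and adjusted valences", {
  tma <- parseSmiles("C[N+](C)(C)C")
  expect_equal(netCharge(tma), 1)
  n <- which(atoms(tma)$element == "N")
  expect_equal(length(hcgroups:::neighborsOf(tma, n)), 4)
  gly <- parseSmiles("[NH3+]CC([O-])=O")
  expect_equal(netCharge(gly), 0)
  expect_equal(sum(atoms(gly)$element == "H"), 5)
})

test_that("V2000 MOL blocks parse with coordinates, charges and 3D detection", {
  dk3d <- parseMolfile(hcgroups:::diketene3dMolBlock())
  expect_true(dk3d@has3d)
  expect_equal(atomCount(dk3d), 10)
  expect_equal(molName(dk3d), "diketene")
  ## minimal 2-atom double-bonded record, no 3D
  mol <- parseMolfile(c("o2-analog", "", "",
                        "  2  1  0  0  0  0  0  0  0  0999 V2000",
                        "    0.0000    0.0000    0.0000 O   0  0",
                        "    1.2000    0.0000    0.0000 O   0  0",
                        "  1  2  2  0",
                        "M  END"))
  expect_equal(nrow(bonds(mol)), 1)
  expect_equal(bonds(mol)$order, "double")
  expect_false(mol@has3d)
  expect_error(parseMolfile(c("x", "", "", "  0  0  0     0  0  0 V3000")),
               "V3000")
})

test_that("multi-record SDF reads in file order and round-trips through the writer", {
  fx <- fixtureMolecules()
  mols <- fx[c("acetone", "glycine_zwitterion", "phenol")]
  sdf <- writeSdf(mols, fields = list(c(note = "a"), NULL, NULL))
  back <- readSdf(paste(sdf, collapse = "\n"))
  expect_length(back, 3)
  for (i in seq_along(mols)) {
    expect_equal(elementCounts(back[[i]]), elementCounts(mols[[i]]))
    expect_equal(sort(bonds(back[[i]])$order), sort(bonds(mols[[i]])$order))
    expect_equal(sort(atoms(back[[i]])$charge), sort(atoms(mols[[i]])$charge))
  }
})

test_that("SMILES writer round-trips structure-defining content", {
  for (smi in c("CC(=O)C", "[NH3+]CC([O-])=O", "Oc1ccccc1",
                "CCCCn1cc[n+](C)c1.[Cl-]", "C1(=C)OC(=O)C1")) {
    m1 <- normalizeConventions(parseSmiles(smi))
    m2 <- normalizeConventions(parseSmiles(writeSmiles(m1)))
    expect_equal(elementCounts(m2), elementCounts(m1), label = smi)
    expect_equal(sort(bonds(m2)$order), sort(bonds(m1)$order), label = smi)
    expect_equal(netCharge(m2), netCharge(m1), label = smi)
  }
})

test_that("kekulized six-rings are rewritten to six aromatic bonds", {
  bz <- normalizeConventions(parseSmiles("C1=CC=CC=C1", "benzene"))
  expect_equal(sum(bonds(bz)$order == "aromatic"), 6)
  py <- normalizeConventions(parseSmiles("c1ccncc1", "pyridine"))
  expect_equal(sum(bonds(py)$order == "aromatic"), 6)
  ## a cross-conjugated ring must not aromatize
  bq <- normalizeConventions(parseSmiles("O=C1C=CC(=O)C=C1", "benzoquinone"))
  expect_equal(sum(bonds(bq)$order == "aromatic"), 0)
})

test_that("five-ring heteroaromatics are kekulized, not aromatic-typed", {
  th <- normalizeConventions(parseSmiles("c1ccsc1", "thiophene"))
  expect_equal(sum(bonds(th)$order == "aromatic"), 0)
  expect_equal(sum(bonds(th)$order == "double"), 2)
  s <- which(atoms(th)$element == "S")
  expect_false(atoms(th)$aromatic[s])
  ind <- normalizeConventions(parseSmiles("c1ccc2[nH]ccc2c1", "indole"))
  expect_equal(sum(bonds(ind)$order == "aromatic"), 6)  # benzene ring only
  expect_equal(sum(bonds(ind)$order == "double"), 1)    # pyrrole C2=C3
})

test_that("imidazolium keeps only the N-C(+)-N fragment aromatic with the charge on carbon", {
  im <- normalizeConventions(parseSmiles("CCn1cc[n+](C)c1", "EMIM"))
  a <- atoms(im)
  cplus <- which(a$element == "C" & a$charge == 1)
  expect_length(cplus, 1)
  expect_true(all(a$charge[a$element == "N"] == 0))
  nb <- hcgroups:::neighborsOf(im, cplus)
  expect_setequal(a$element[nb], c("N", "N", "H"))
  expect_equal(sum(bonds(im)$order == "aromatic"), 2)
  expect_equal(sum(bonds(im)$order == "double"), 1)
})

test_that("guanidinium drawn with N(+) is normalized to an aromatic C(+) center", {
  g <- normalizeConventions(parseSmiles("CN(C)C(=[NH2+])N(C)C", "TMG-H+"))
  a <- atoms(g)
  cplus <- which(a$element == "C" & a$charge == 1)
  expect_length(cplus, 1)
  kb <- hcgroups:::bondsOf(g, cplus)
  expect_equal(sort(bonds(g)$order[kb]), rep("aromatic", 3))
  expect_equal(netCharge(g), 1)
})

test_that("normalizeConventions is idempotent and conserves net charge", {
  for (smi in c("C1=CC=CC=C1", "CCn1cc[n+](C)c1", "NCC(O)=O",
                "CN(C)C(=[NH2+])N(C)C", "c1ccsc1")) {
    for (pol in c("as_drawn", "auto")) {
      m1 <- normalizeConventions(parseSmiles(smi), pol)
      m2 <- normalizeConventions(m1, pol)
      expect_equal(atoms(m2), atoms(m1), label = paste(smi, pol))
      expect_equal(bonds(m2), bonds(m1), label = paste(smi, pol))
      expect_equal(netCharge(m1), netCharge(parseSmiles(smi)),
                   label = paste(smi, pol))
    }
  }
})

test_that("zwitterion policy moves the acid proton only for eligible bases", {
  gly <- normalizeConventions(parseSmiles("NCC(O)=O", "glycine"), "auto")
  a <- atoms(gly)
  expect_equal(sum(a$charge == 1 & a$element == "N"), 1)
  expect_equal(sum(a$charge == -1 & a$element == "O"), 1)
  expect_equal(netCharge(gly), 0)
  ## as_drawn leaves the neutral form alone
  gly2 <- normalizeConventions(parseSmiles("NCC(O)=O"), "as_drawn")
  expect_true(all(atoms(gly2)$charge == 0))
  ## the anilino nitrogen of N-phenylglycine is not basic enough
  npg <- normalizeConventions(parseSmiles("OC(=O)CNc1ccccc1"), "auto")
  expect_true(all(atoms(npg)$charge == 0))
  ## secondary amines (sarcosine) are left as drawn too
  sar <- normalizeConventions(parseSmiles("CNCC(O)=O"), "auto")
  expect_true(all(atoms(sar)$charge == 0))
})
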