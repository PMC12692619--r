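test_that("PDB and mmCIF parse to the same model; empty files error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTestPDB(f, nres = 3L)
  m <- readStructure(f)
  expect_s4_class(m, "StructureModel")
  expect_identical(modelResidues(m), c(1L, 2L, 3L))
  expect_identical(nrow(modelAtoms(m)), 12L)

  g <- withr::local_tempfile(fileext = ".cif")
  writeTestCIF(g, nres = 3L)
  m2 <- readStructure(g)
  expect_equal(modelAtoms(m2)$resno, modelAtoms(m)$resno)
  expect_equal(modelAtoms(m2)$element, modelAtoms(m)$element)
  expect_equal(modelAtoms(m2)[, c("x", "y", "z", "b")],
               modelAtoms(m)[, c("x", "y", "z", "b")],
               tolerance = 1e-6)

  e <- withr::local_tempfile(fileext = ".pdb")
  file.create(e)
  expect_error(readStructure(e), "empty")
})

mkModel <- function(atoms) new("StructureModel", chain = "A", atoms = atoms)

test_that("Shrake-Rupley matches the closed-form sphere and is additive/occluding", {
  one <- mkModel(data.frame(resno = 1L, resid = "GLY", element = "C",
                            x = 0, y = 0, z = 0, b = 50))
  asa1 <- as.numeric(shrakeRupleySasa(one, nPoints = 960))
  exact <- 4 * pi * (1.70 + 1.4)^2
  expect_lt(abs(asa1 - exact) / exact, 0.01)

  far <- mkModel(data.frame(resno = 1:2, resid = "GLY", element = "C",
                            x = c(0, 50), y = 0, z = 0, b = 50))
  expect_equal(sum(shrakeRupleySasa(far, nPoints = 960)), 2 * asa1,
               tolerance = 1e-6)

  dup <- mkModel(data.frame(resno = c(1L, 1L), resid = "GLY",
                            element = "C", x = c(0, 1.0), y = 0, z = 0,
                            b = 50))
  at <- attr(shrakeRupleySasa(dup, nPoints = 960), "atomASA")
  expect_true(all(at < asa1))

  bad <- mkModel(data.frame(resno = 1L, resid = "GLY", element = "ZZ",
                            x = 0, y = 0, z = 0, b = 50))
  expect_error(shrakeRupleySasa(bad), "ZZ")
})

test_that("SASA is rigid-motion invariant and converges with point count", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTestPDB(f, nres = 4L)
  m <- readStructure(f)
  base <- shrakeRupleySasa(m, nPoints = 960)

  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  g <- withr::local_tempfile(fileext = ".pdb")
  writeTestPDB(g, nres = 4L, shift = c(11, -3, 7), rot = rot)
  moved <- shrakeRupleySasa(readStructure(g), nPoints = 960)
  expect_true(all(abs(moved - base) / base < 0.005))

  a240 <- sum(shrakeRupleySasa(m, nPoints = 240))
  a960 <- sum(base)
  a3840 <- sum(shrakeRupleySasa(m, nPoints = 3840))
  expect_lt(abs(a3840 - a960), abs(a960 - a240))

  # conservation: residue sums equal the per-atom total
  expect_equal(sum(base), sum(attr(base, "atomASA")))
})

test_that("RSA normalises by residue type and respects rigid motion", {
  expect_equal(relativeAccessibility(0, "GLY"), 0)
  expect_error(relativeAccessibility(10, "XYZ"), "XYZ")
  one <- mkModel(data.frame(resno = 1L, resid = "GLY", element = "C",
                            x = 0, y = 0, z = 0, b = 50))
  rsa <- relativeAccessibility(shrakeRupleySasa(one, nPoints = 960),
                               "GLY")
  expect_gt(rsa, 0.9)  # isolated residue: near or above 1
})

test_that("epitope reports carry RSA, pLDDT (auto-scaled) and exposure", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTestPDB(f, nres = 10L, b = 90)
  m <- readStructure(f)
  rep1 <- epitopeReport(m, "1~10", nPoints = 240)
  expect_true(rep1$exposed)         # extended chain is fully accessible
  expect_equal(rep1$meanPLDDT, 90)
  expect_gt(rep1$meanRSA, 0.25)

  g <- withr::local_tempfile(fileext = ".pdb")
  writeTestPDB(g, nres = 10L, b = 0.9)  # 0-1 scale in the file
  expect_equal(epitopeReport(readStructure(g), "1~10",
                             nPoints = 240)$meanPLDDT, 90)
  expect_equal(modelQuality(readStructure(g)), 90)

  expect_error(epitopeReport(m, "8~12", nPoints = 240), "outside")
  # offset maps sequence coordinates into model numbering
  rep2 <- epitopeReport(m, "1~5", offset = 5L, nPoints = 240)
  expect_identical(rep2$start, 1L)
})
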