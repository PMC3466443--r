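# Molecule parsing, SDF round trips, and substructure matching.

test_that("SMILES parsing builds the expected graphs", {
  eth <- parseSmiles("CCO")
  expect_equal(nrow(atoms(eth)), 3L)
  expect_equal(nrow(bonds(eth)), 2L)
  expect_true(all(bonds(eth)$order == 1L))

  benz <- parseSmiles("c1ccccc1")
  expect_equal(nrow(atoms(benz)), 6L)
  expect_true(all(atoms(benz)$aromatic))
  expect_equal(sum(bonds(benz)$order == 4L), 6L)

  # C1CC1C: cyclopropane ring + methyl, hand-enumerated
  mcp <- parseSmiles("C1CC1C")
  expect_equal(nrow(atoms(mcp)), 4L)
  expect_equal(nrow(bonds(mcp)), 4L)
  ring <- ScaffoldScreen:::.cpp_ring_bonds(4L, bonds(mcp)$i - 1L, bonds(mcp)$j - 1L)
  expect_equal(sum(ring), 3L)

  # kekulized aromatics perceive to the same graph as lowercase aromatics
  expect_true(molsIsomorphic(parseSmiles("C1=CC=CC=C1"), benz))
  expect_true(molsIsomorphic(parseSmiles("C1=CC=NC=C1"), parseSmiles("c1ccncc1")))

  # charges and explicit hydrogens
  ac <- parseSmiles("CC(=O)[O-]")
  expect_equal(sum(atoms(ac)$charge), -1L)
  expect_equal(implicitHydrogens(parseSmiles("c1cc[nH]c1")), c(1L, 1L, 1L, 1L, 1L))
})

test_that("malformed SMILES fail with the offending position", {
  expect_error(parseSmiles("CC(O"), "unclosed branch")
  expect_error(parseSmiles("C1CC"), "unclosed ring")
  expect_error(parseSmiles("C[Zz]C"), "position 2")
  expect_error(parseSmiles(""), "empty")
})

test_that("SMILES write -> parse round trip is an isomorphism", {
  smis <- c("CCO", "c1ccccc1", "Cc1ccc(N)cc1O", "CC(=O)[O-]", "c1ccc2ncccc2c1",
            "C1CC1C", "c1cc[nH]c1", "O=C(O)c1ccccc1", "ClC(Br)I", "CC(C)(C)C#N")
  for (s in smis) {
    mol <- parseSmiles(s)
    expect_true(molsIsomorphic(mol, parseSmiles(molToSmiles(mol))), info = s)
  }
  # grammar-generated molecules (valid valences) round trip too
  for (k in 1:10) {
    mol <- decorateMolecule(generateScaffold(k, min_atoms = 10L), seed = k + 50L)
    expect_true(molsIsomorphic(mol, parseSmiles(molToSmiles(mol))), info = k)
  }
})

test_that("SDF reading preserves records, properties and charges", {
  path <- tempfile(fileext = ".sdf")
  writeToySDF(path)
  lib <- readSDF(path)
  expect_equal(length(lib), 2L)
  expect_equal(compoundIds(lib), c("ethanol", "propane"))
  expect_identical(compoundProperties(lib)["ethanol", "PUBCHEM_ACTIVITY_SCORE"], "87")

  # corrupt record among 3 -> library of 2, skip count 1
  path2 <- tempfile(fileext = ".sdf")
  writeToySDF(path2, corrupt_record = TRUE)
  expect_message(lib2 <- readSDF(path2), "1 SDF record")
  expect_equal(length(lib2), 2L)
  expect_equal(attr(lib2, "skipped"), 1L)

  expect_error(readSDF(tempfile()), "cannot read")
})

test_that("SDF write -> read round trips structures, charges and properties", {
  mols <- list(parseSmiles("CC(=O)[O-]", name = "acetate"),
               parseSmiles("c1ccc2ncccc2c1", name = "quinoline"))
  lib <- CompoundLibrary(mols, properties = data.frame(
    PUBCHEM_ACTIVITY_SCORE = c("40", "0")))
  path <- tempfile(fileext = ".sdf")
  writeSDF(lib, path)
  back <- readSDF(path)
  expect_equal(compoundIds(back), c("acetate", "quinoline"))
  expect_true(molsIsomorphic(back[["acetate"]], mols[[1]]))
  expect_true(molsIsomorphic(back[["quinoline"]], mols[[2]]))
  expect_identical(compoundProperties(back)$PUBCHEM_ACTIVITY_SCORE, c("40", "0"))
})

test_that("V3000 records are rejected", {
  path <- tempfile(fileext = ".sdf")
  writeLines(c("x", "", "", "  0  0  0     0  0            999 V3000",
               "M  END", "$$$$"), path)
  expect_error(readSDF(path), "V3000")
})

test_that("substructure matching follows the element/bond-order policy", {
  benz <- parseSmiles("c1ccccc1")
  tol <- parseSmiles("Cc1ccccc1")
  expect_true(isSubstructure(benz, tol))
  expect_false(isSubstructure(tol, benz))      # query larger than any match
  # aromatic is its own bond order: cyclohexane does not contain benzene
  expect_false(isSubstructure(benz, parseSmiles("C1CCCCC1")))
  # non-induced: a 3-carbon path embeds in cyclopropane
  expect_true(isSubstructure(parseSmiles("CCC"), parseSmiles("C1CC1")))
  expect_error(isSubstructure(benz,
    MolecularGraph(data.frame(element = character()))), "non-empty")
})

test_that("is_substructure agrees with the exhaustive mapping oracle", {
  set.seed(421)
  checked <- 0L
  for (rep in 1:200) {
    q <- randomMolGraph(sample(2:5, 1))
    t <- randomMolGraph(sample(4:8, 1))
    expect_identical(isSubstructure(q, t), oracleIsSubstructure(q, t))
    expect_true(isSubstructure(t, t))          # self-substructure
    checked <- checked + 1L
  }
  expect_equal(checked, 200L)
})

test_that("salts are reduced to the largest fragment with a log entry", {
  salt <- parseSmiles("CC(=O)[O-].CCO")
  expect_equal(max(fragmentIds(salt)), 2L)
  big <- largestFragment(salt)
  expect_equal(nrow(atoms(big)), 4L)
  lib <- CompoundLibrary(list(salt, parseSmiles("CCO")), ids = c("a", "b"))
  expect_message(std <- standardizeLibrary(lib), "1 multi-fragment")
  expect_equal(heavyAtomCount(std[["a"]]), 4L)
})

test_that("library accessors and id handling behave", {
  lib <- CompoundLibrary(list(parseSmiles("CCO"), parseSmiles("CCC")),
                         ids = c("x", "y"))
  expect_equal(length(lib), 2L)
  expect_equal(compoundIds(lib["y"]), "y")
  expect_equal(heavyAtomCount(lib[["x"]]), 3L)
  expect_warning(CompoundLibrary(list(parseSmiles("C"), parseSmiles("C")),
                                 ids = c("a", "a")), "unique")
})
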