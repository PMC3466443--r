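# Pharmacophore typing, fingerprint bits, Burden eigenvalues, properties,
# matrix assembly and constant-bit filtering.

test_that("pharmacophore classes follow the rule table", {
  eth <- parseSmiles("CCO")
  cl <- assignPharmacophoreClasses(eth)
  expect_true(cl[3, "donor"] && cl[3, "acceptor"])         # hydroxyl oxygen
  expect_false(any(cl[3, c("posIonizable", "negIonizable", "hydrophobe")]))

  benz <- assignPharmacophoreClasses(parseSmiles("c1ccccc1"))
  expect_true(all(benz[, "aromatic"] & benz[, "hydrophobe"]))

  # acetate anion: charged O is negative-ionizable acceptor, not donor
  ac <- parseSmiles("CC(=O)[O-]")
  cla <- assignPharmacophoreClasses(ac)
  o_minus <- which(atoms(ac)$charge == -1L)
  expect_true(cla[o_minus, "negIonizable"] && cla[o_minus, "acceptor"])
  expect_false(cla[o_minus, "donor"])

  # carboxylic acid OH is negative-ionizable too
  acid <- parseSmiles("CC(=O)O")
  claa <- assignPharmacophoreClasses(acid)
  oh <- which(implicitHydrogens(acid) > 0 & atoms(acid)$element == "O")
  expect_true(claa[oh, "negIonizable"])

  # aliphatic amine is positive-ionizable, amide nitrogen is not
  expect_true(assignPharmacophoreClasses(parseSmiles("CCN"))[3, "posIonizable"])
  amide <- parseSmiles("CC(=O)NC")
  expect_false(assignPharmacophoreClasses(amide)[4, "posIonizable"])
})

test_that("fingerprint layout and edge cases", {
  expect_length(fingerprintColumnNames(), 147L)
  expect_false(anyDuplicated(fingerprintColumnNames()) > 0)

  # methane: no feature atoms at all
  expect_equal(sum(pharmacophoreFingerprint(parseSmiles("C"))), 0L)

  # ethanol: single heteroatom; same-atom pairs excluded so no
  # (donor,acceptor) or (acceptor,acceptor) bit fires
  fp <- pharmacophoreFingerprint(parseSmiles("CCO"))
  expect_true(all(fp[grep("PP_acceptor_acceptor", names(fp))] == 0L))
  expect_true(all(fp[grep("PP_donor_acceptor", names(fp))] == 0L))
  # but O..CH3 (donor/acceptor vs hydrophobe) at distance 2 fires
  expect_equal(unname(fp["PP_donor_hydrophobe_d2"]), 1L)

  # diaminobenzene donor-donor distances: meta 4 bonds, para 5 bonds
  meta <- pharmacophoreFingerprint(parseSmiles("Nc1cccc(N)c1"))
  expect_equal(unname(meta["PP_donor_donor_d4"]), 1L)
  para <- pharmacophoreFingerprint(parseSmiles("Nc1ccc(N)cc1"))
  expect_equal(unname(para["PP_donor_donor_d5"]), 1L)
  expect_equal(unname(para["PP_donor_donor_d4"]), 0L)

  # distances of 7 or more pool into the top bin
  longchain <- pharmacophoreFingerprint(parseSmiles("OCCCCCCCCO"))
  expect_equal(unname(longchain["PP_donor_donor_d7plus"]), 1L)
})

test_that("Burden descriptors match closed forms and ordering", {
  # single atom: every eigenvalue equals the atomic weight per scheme
  single <- burdenDescriptors(parseSmiles("O"))
  expect_equal(unname(single[paste0("BN_EN_", c("lo1", "lo4", "hi1", "hi4"))]),
               rep(3.44, 4))

  # ethane: closed-form 2x2 eigenvalues w +/- 0.11 (terminal correction)
  et <- burdenDescriptors(parseSmiles("CC"))
  expect_equal(unname(et["BN_EN_lo1"]), 2.55 - 0.11, tolerance = 1e-12)
  expect_equal(unname(et["BN_EN_hi4"]), 2.55 + 0.11, tolerance = 1e-12)

  # smallest <= largest within each scheme, for any molecule
  for (smi in c("CCO", "c1ccccc1", "CC(=O)Nc1ccc(O)cc1")) {
    bd <- burdenDescriptors(parseSmiles(smi))
    for (w in c("EN", "Q", "LP")) {
      expect_true(bd[paste0("BN_", w, "_lo1")] <= bd[paste0("BN_", w, "_hi4")])
      expect_false(is.unsorted(bd[paste0("BN_", w, "_lo", 1:4)]))
      expect_false(is.unsorted(bd[paste0("BN_", w, "_hi", 1:4)]))
    }
  }
})

test_that("Gasteiger-style charges are sane", {
  q <- gasteigerCharges(parseSmiles("CCO"))
  expect_equal(sum(q), 0, tolerance = 1e-9)      # neutral molecule
  expect_true(q[3] < 0)                          # oxygen pulls density
  expect_true(q[2] > q[1])                       # alpha carbon more positive
})

test_that("property descriptors match hand counts", {
  met <- propertyDescriptors(parseSmiles("C"))
  expect_equal(unname(met[c("HBD", "HBA", "RotB", "Rings", "HeavyAtoms")]),
               c(0, 0, 0, 0, 1))
  expect_equal(unname(met["MW"]), 16.043, tolerance = 1e-3)

  eth <- propertyDescriptors(parseSmiles("CCO"))
  expect_equal(unname(eth[c("HBD", "HBA")]), c(1, 1))

  biph <- propertyDescriptors(parseSmiles("c1ccc(cc1)-c1ccccc1"))
  expect_equal(unname(biph[c("Rings", "RotB", "HeavyAtoms")]), c(2, 1, 12))

  # TPSA: phenol = one hydroxyl contribution
  expect_equal(unname(propertyDescriptors(parseSmiles("Oc1ccccc1"))["TPSA"]),
               20.23)
})

test_that("featurization yields a stable 179-column matrix", {
  lib <- CompoundLibrary(list(parseSmiles("CCO"), parseSmiles("c1ccccc1"),
                              parseSmiles("CCO")), ids = c("a", "b", "a2"))
  dm <- featurizeLibrary(lib)
  expect_s4_class(dm, "DescriptorMatrix")
  expect_equal(dim(descriptorValues(dm)), c(3L, 179L))
  expect_equal(colnames(descriptorValues(dm)), descriptorColumnNames())
  expect_equal(sum(binaryColumns(dm)), 147L)
  # duplicate compounds get identical rows; repeated runs identical
  expect_equal(descriptorValues(dm)["a", ], descriptorValues(dm)["a2", ])
  dm2 <- featurizeLibrary(lib)
  expect_identical(descriptorValues(dm), descriptorValues(dm2))
})

test_that("fingerprint and Burden blocks are invariant under atom reindexing", {
  set.seed(77)
  for (smi in c("Cc1ccc(N)cc1O", "CC(=O)Nc1ccc(O)cc1", "c1ccc2ncccc2c1")) {
    mol <- parseSmiles(smi)
    perm <- sample(nrow(atoms(mol)))
    pmol <- permuteAtoms(mol, perm)
    expect_identical(pharmacophoreFingerprint(mol), pharmacophoreFingerprint(pmol))
    expect_equal(burdenDescriptors(mol), burdenDescriptors(pmol), tolerance = 1e-9)
    expect_equal(propertyDescriptors(mol), propertyDescriptors(pmol), tolerance = 1e-9)
  }
})

test_that("constant-bit filtering removes exactly the constant binary columns", {
  x <- cbind(b_allzero = c(0, 0, 0), b_allone = c(1, 1, 1),
             b_mixed = c(0, 1, 0), b_rare = c(1, 0, 0),
             cont_const = c(2.5, 2.5, 2.5))
  dm <- descriptorMatrix(x, binary = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  f <- filterConstantBits(dm)
  expect_equal(colnames(descriptorValues(f)), c("b_mixed", "b_rare", "cont_const"))
  expect_equal(sum(retainedColumns(f)), 3L)
  expect_length(retainedColumns(f), 5L)
  # continuous constants survive; filtering is idempotent
  expect_identical(descriptorValues(filterConstantBits(f)), descriptorValues(f))
})

test_that("descriptor matrices round trip through CSV + JSON sidecar", {
  lib <- CompoundLibrary(list(parseSmiles("CCO"), parseSmiles("CCN")),
                         ids = c("a", "b"))
  dm <- filterConstantBits(featurizeLibrary(lib))
  path <- tempfile(fileext = ".csv")
  writeDescriptorMatrix(dm, path)
  back <- readDescriptorMatrix(path)
  expect_equal(descriptorValues(back), descriptorValues(dm), tolerance = 1e-12)
  expect_equal(retainedColumns(back), retainedColumns(dm))
  expect_equal(binaryColumns(back), binaryColumns(dm))
})
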