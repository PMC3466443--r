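# MCS, hierarchical clustering, occurrence counting and enrichment
# statistics.

test_that("MCS handles the basic identities", {
  benz <- parseSmiles("c1ccccc1")
  self <- mcs(benz, benz)
  expect_equal(attr(self, "size"), 6L)

  m <- mcs(parseSmiles("CCO"), parseSmiles("CCCO"))
  expect_equal(attr(m, "size"), 3L)
  expect_true(isSubstructure(m, parseSmiles("CCO")))
  expect_true(isSubstructure(m, parseSmiles("CCCO")))

  # no shared element: empty result
  none <- mcs(parseSmiles("CC"), parseSmiles("O"))
  expect_equal(attr(none, "size"), 0L)

  # below the floor: NULL, cheaply
  expect_null(mcs(parseSmiles("CCO"), parseSmiles("CCCO"), min_atoms = 10L))
  expect_error(mcs(benz, MolecularGraph(data.frame(element = character()))),
               "non-empty")
})

test_that("MCS size matches the exhaustive oracle and is symmetric", {
  set.seed(31)
  for (rep in 1:200) {
    a <- randomMolGraph(sample(3:7, 1))
    b <- randomMolGraph(sample(3:8, 1))
    sz <- attr(mcs(a, b), "size")
    expect_equal(sz, oracleMcsSize(a, b), info = rep)
    expect_equal(sz, attr(mcs(b, a), "size"))           # symmetry
    expect_lte(sz, min(heavyAtomCount(a), heavyAtomCount(b)))
  }
})

test_that("the returned MCS graph embeds in both inputs", {
  set.seed(32)
  for (rep in 1:30) {
    a <- randomMolGraph(sample(4:8, 1))
    b <- randomMolGraph(sample(4:8, 1))
    m <- mcs(a, b)
    if (attr(m, "size") > 0L) {
      expect_true(isSubstructure(m, a))
      expect_true(isSubstructure(m, b))
    }
  }
})

test_that("clustering merges on large shared scaffolds and respects the floor", {
  core <- parseSmiles("c1ccc2ncccc2c1CC")            # 12 heavy atoms
  m1 <- decorateMolecule(core, seed = 1)
  m2 <- decorateMolecule(core, seed = 2)
  lib <- CompoundLibrary(list(m1, m2), ids = c("m1", "m2"))
  h <- hierarchicalMcsCluster(lib, min_mcs_atoms = 10L)
  top <- suppressMessages(topLevelClusters(h))
  expect_equal(nrow(top), 1L)
  expect_equal(sort(top$members[[1]]), c("m1", "m2"))
  rep_scaffold <- attr(top, "scaffolds")[[1]]
  expect_true(isSubstructure(core, rep_scaffold) || molsIsomorphic(core, rep_scaffold))
  expect_true(isSubstructure(rep_scaffold, m1))
  expect_true(isSubstructure(rep_scaffold, m2))

  # only a 4-atom fragment in common: threshold blocks the merge
  l2 <- CompoundLibrary(list(parseSmiles("CCCCc1ccccc1"), parseSmiles("CCCCC1CCNCC1")),
                        ids = c("x", "y"))
  h2 <- hierarchicalMcsCluster(l2, min_mcs_atoms = 10L)
  expect_equal(h2@levels, 1L)
  expect_message(t2 <- topLevelClusters(h2), "2 singleton")
  expect_equal(nrow(t2), 0L)
})

test_that("every non-singleton cluster's scaffold embeds in all its members", {
  cfg <- syntheticAssayConfig(n_actives = 40, n_inactives = 40,
                              counterscreen_fraction = 0, seed = 33)
  assay <- suppressWarnings(generateAssay(cfg))
  lib <- assay$library[assay$truth$id[assay$truth$class == "active"]]
  h <- suppressMessages(hierarchicalMcsCluster(lib))
  top <- suppressMessages(topLevelClusters(h))
  for (r in seq_len(nrow(top))) {
    scf <- attr(top, "scaffolds")[[r]]
    for (mid in top$members[[r]])
      expect_true(isSubstructure(scf, lib[[mid]]), info = paste(r, mid))
    expect_gte(heavyAtomCount(scf), 10L)
    expect_gte(top$n_members[r], 2L)
  }
})

test_that("occurrence counting counts each molecule at most once", {
  benz <- parseSmiles("c1ccccc1")
  lib <- CompoundLibrary(list(
    parseSmiles("Cc1ccccc1"),          # contains benzene
    parseSmiles("c1ccccc1"),           # is benzene
    parseSmiles("c1ccc(cc1)-c1ccccc1"),# two benzenes, counted once
    parseSmiles("C1CCCCC1"),
    parseSmiles("CCO")),
    ids = paste0("m", 1:5))
  expect_equal(countOccurrences(benz, lib), 3L)
  expect_equal(countOccurrences(parseSmiles("FCl"), lib), 0L)
  expect_lte(countOccurrences(benz, lib), length(lib))
})

test_that("enrichment statistics reproduce the published miR-21 table", {
  counts <- mir21ScaffoldCounts()
  printed_chi <- c(1144.377, 579.406, 93.197, 66.565, 69.573, 50.204, 72.564,
                   33.804, 24.158, 39.091, 25.217, 14.563, 11.505, 13.566)
  printed_ef <- c(75.49, 49.32, 8.22, 7.07, 6.91, 5.44, 4.37, 4.19, 3.76,
                  3.58, 3.52, 3.14, 2.67, 2.58)
  for (k in seq_len(nrow(counts))) {
    r <- enrichmentTest(counts$actives[k], counts$inactives[k],
                        attr(counts, "N_act"), attr(counts, "N_inact"))
    expect_lt(abs(r$chi_square - printed_chi[k]), 0.01)
    expect_lt(abs(r$enrichment_factor - printed_ef[k]), 0.0101)
    expect_lt(r$p_value, 0.01)
  }
})

test_that("enrichment test handles the degenerate corners", {
  # equal frequencies: independence
  r <- enrichmentTest(10, 100, 1000, 10000)
  expect_equal(r$chi_square, 0, tolerance = 1e-12)
  expect_equal(r$enrichment_factor, 1)
  # absent from inactives: infinite EF
  r0 <- enrichmentTest(5, 0, 100, 10000)
  expect_true(is.infinite(r0$enrichment_factor))
  expect_error(enrichmentTest(0, 0, 10, 10), "undefined")
  expect_error(enrichmentTest(11, 0, 10, 10), "invalid counts")
})

test_that("chi-square is invariant under transposing the 2x2 table", {
  set.seed(34)
  for (rep in 1:20) {
    a <- sample(0:50, 1); cc <- sample(0:500, 1)
    if (a + cc == 0) a <- 1
    r1 <- enrichmentTest(a, cc, 100, 5000)
    # transposed table: (a, c) vs (N_act - a, N_inact - c) as the two rows
    tab <- rbind(c(a, 100 - a), c(cc, 5000 - cc))
    r2 <- suppressWarnings(stats::chisq.test(t(tab), correct = FALSE))
    expect_equal(r1$chi_square, unname(r2$statistic), tolerance = 1e-12)
  }
})

test_that("selection thresholds are strict and sorted by EF", {
  res <- rbind(
    enrichmentTest(19, 86, 883, 301747, "keep_high"),
    enrichmentTest(8, 10, 883, 301747, "below_freq"),        # 0.91% < 1%
    enrichmentTest(14, 1852, 883, 301747, "keep_low"))
  sel <- selectEnriched(res)
  expect_equal(sel$scaffold_id, c("keep_high", "keep_low"))
  expect_false(is.unsorted(rev(sel$enrichment_factor)))
  # frequency threshold is strict: > 1% of 883 requires a >= 9
  expect_true(all(sel$a >= 9))

  # EF boundary is strict: 4% vs 2% is significant but EF = 2 exactly
  boundary <- enrichmentTest(40, 400, 1000, 20000, "ef2")
  expect_equal(boundary$enrichment_factor, 2)
  expect_lt(boundary$p_value, 0.01)
  expect_equal(nrow(selectEnriched(boundary)), 0L)
})
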