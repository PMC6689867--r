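test_that("the graph parser recovers atoms, bonds, charges and rings", {
  g <- smilesGraph("CC1=CC(=O)Oc2ccccc21")
  expect_equal(nrow(g$atoms), 12)
  expect_equal(nrow(g$bonds), 13)  # 12 atoms, 2 rings
  expect_equal(sum(g$atoms$aromatic), 6)
  g2 <- smilesGraph("CC(=O)[O-]")
  expect_equal(g2$atoms$charge, c(0L, 0L, 0L, -1L))
  g3 <- smilesGraph("C[C@@H](N)O")
  expect_true(any(g3$atoms$stereo))
  # ring-closure bond orders: explicit double at the closure digit
  g4 <- smilesGraph("C1CC=1")
  expect_true(any(g4$bonds$order == 2))
})

test_that("heavy atoms and metal detection follow the organic subset", {
  expect_equal(heavyAtomCount(c("CCO", "c1ccccc1", "[NH4+]")), c(3L, 6L, 1L))
  expect_true(containsMetal("[Fe+2]"))
  expect_true(containsMetal("CC[Na]"))
  expect_false(containsMetal("C[Si](C)C"))
  expect_false(containsMetal("CC(=O)[Se]C"))
})

test_that("circular fragments are deterministic and radius-monotone", {
  f2 <- atomFragments("CCOc1ccccc1", radius = 2)
  expect_identical(f2, atomFragments("CCOc1ccccc1", radius = 2))
  f0 <- atomFragments("CCOc1ccccc1", radius = 0)
  expect_true(all(f0 %in% atomFragments("CCOc1ccccc1", radius = 1)))
  # methane-like single atom has one fragment per radius
  expect_length(atomFragments("C", radius = 2, unique = FALSE), 3)
})

test_that("Tanimoto similarity is a proper similarity", {
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4, 5)), 0.4)  # 2 / 5
  expect_equal(tanimoto(c(7, 9), c(1, 2)), 0)
  set.seed(42)
  for (i in 1:20) {
    a <- sample(100, sample(1:20, 1))
    b <- sample(100, sample(1:20, 1))
    expect_equal(tanimoto(a, a), 1)
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    t <- tanimoto(a, b)
    expect_gte(t, 0); expect_lte(t, 1)
  }
  # identical molecules -> identical fingerprints -> similarity 1
  expect_equal(tanimoto(ecfpBits("c1ccccc1O"), ecfpBits("c1ccccc1O")), 1)
})

test_that("framework scaffolds strip side chains and keep linkers", {
  expect_equal(extractScaffold("c1ccccc1"), "c1ccccc1")
  expect_equal(extractScaffold("Cc1ccccc1"), "c1ccccc1")  # toluene
  expect_equal(extractScaffold("CCCCCCCCCC"), "")          # acyclic
  # two rings joined by a carbonyl linker keep the C=O
  expect_equal(extractScaffold("O=C(c1ccccc1)c1ccccc1"),
               canonicalizeSmiles("O=C(c1ccccc1)c1ccccc1"))
  # acetophenone side chain is removed entirely
  expect_equal(extractScaffold("CC(=O)c1ccccc1"), "c1ccccc1")
  # scaffold extraction is idempotent
  fc <- smiles(smallFixture(30, seed = 5))
  sc <- extractScaffold(fc)
  cyc <- sc[!is.na(sc) & nzchar(sc)]
  expect_identical(extractScaffold(cyc), cyc)
})

test_that("descriptor counts match hand-counted molecules", {
  expect_equal(aromaticRingSystems(c("c1ccccc1", "c1ccc2ccccc2c1",
                                     "c1ccccc1Cc1ccccc1", "CCCC")),
               c(1L, 1L, 2L, 0L))
  expect_equal(rotatableBonds(c("CCCC", "CC", "c1ccccc1CCc1ccccc1")),
               c(1L, 0L, 3L))
  prof <- descriptorProfile(c("CCCCCCCCCC", "c1ccccc1"))
  expect_named(prof, c("smiles", "clogp", "mw", "hbd", "hba", "rotb",
                       "aromsys", "tpsa"))
  # decane: molecular weight from atomic masses, no donors/acceptors
  expect_equal(prof$mw[1], 142.28, tolerance = 0.1 / 142.28)
  expect_equal(prof$hbd[1], 0L)
  expect_equal(prof$rotb[1], 7L)
  expect_equal(prof$aromsys[1], 0L)
  expect_equal(prof$aromsys[2], 1L)
})
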