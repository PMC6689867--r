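test_that("curation applies the size, metal and duplicate filters", {
  raw <- c("CCO",                 # 3 heavy atoms: too small
           "CCCCCCCCCC",          # exactly 10: kept (inclusive bound)
           "CCCCCCCCCCC", "CCCCCCCCCCC",  # duplicate pair
           "[Fe+2]",              # metal
           "C[Si](C)(C)CCCCCCCC", # Si is in the organic subset: kept
           "not_a_smiles",
           paste0(rep("C", 101), collapse = ""))  # 101 atoms: too large
  cur <- curateCorpus(raw)
  counts <- cur@metadata$curation$counts
  expect_equal(unname(counts["too_small"]), 1)
  expect_equal(unname(counts["metal"]), 1)
  expect_equal(unname(counts["too_large"]), 1)
  expect_equal(unname(counts["duplicate"]), 1)
  expect_equal(unname(counts["unparseable"]), 1)
  expect_equal(unname(counts["kept"]), 3)
  expect_true(all(heavyAtoms(cur) >= 10 & heavyAtoms(cur) <= 100))
  # every kept SMILES is canonical: re-canonicalizing is a no-op
  expect_identical(canonicalizeSmiles(smiles(cur)), smiles(cur))
  expect_false(anyDuplicated(smiles(cur)) > 0)
})

test_that("curation is idempotent", {
  fc <- smallFixture(30, seed = 5)
  once <- curateCorpus(smiles(fc))
  twice <- curateCorpus(smiles(once))
  expect_identical(smiles(once), smiles(twice))
})

test_that("curating nothing usable is an error", {
  expect_error(curateCorpus(c("CCO", "zzz")), "every molecule")
})

test_that("fold splits are disjoint, exhaustive and balanced", {
  fc <- smallFixture(43, seed = 9)
  fs <- splitFolds(fc, k = 5, seed = 3)
  sizes <- vapply(folds(fs), length, integer(1))
  expect_equal(sum(sizes), 43)
  expect_lte(diff(range(sizes)), 1)
  all_smi <- unlist(lapply(folds(fs), smiles))
  expect_setequal(all_smi, smiles(fc))
  expect_equal(anyDuplicated(all_smi), 0)
  # determinism
  fs2 <- splitFolds(fc, k = 5, seed = 3)
  expect_identical(lapply(folds(fs), smiles), lapply(folds(fs2), smiles))
  # different seed shuffles differently
  fs3 <- splitFolds(fc, k = 5, seed = 4)
  expect_false(identical(lapply(folds(fs), smiles),
                         lapply(folds(fs3), smiles)))
  expect_error(splitFolds(fc, k = 44, seed = 1), "exceeds")
  # 10 molecules into 5 folds of 2
  fs4 <- splitFolds(smallFixture(30, seed = 5)[1:10], k = 5, seed = 1)
  expect_equal(vapply(folds(fs4), length, integer(1)), rep(2L, 5))
})

test_that("fixture corpora are reproducible, valid and pass curation", {
  a <- fixtureCorpus(25, seed = 4)
  b <- fixtureCorpus(25, seed = 4)
  expect_identical(smiles(a), smiles(b))
  expect_false(identical(smiles(a), smiles(fixtureCorpus(25, seed = 5))))
  expect_true(all(isValidSmiles(smiles(a))))
  expect_true(all(heavyAtoms(a) >= 10 & heavyAtoms(a) <= 100))
  cur <- curateCorpus(smiles(a))
  expect_equal(length(cur), 25L)
})

test_that("stereo and bracket flags control the fixture grammar", {
  with_br <- fixtureCorpus(40, seed = 8, withStereo = TRUE,
                           withBrackets = TRUE)
  toks <- unique(unlist(tokenizeSmiles(smiles(with_br))))
  expect_true(any(grepl("^\\[", toks)))
  without <- fixtureCorpus(40, seed = 8, withStereo = FALSE,
                           withBrackets = FALSE)
  expect_false(any(grepl("@|\\+|-\\]",
                         unlist(tokenizeSmiles(smiles(without))))))
})

test_that("SMILES files round-trip through read/write", {
  fc <- smallFixture(30, seed = 5)
  path <- withr::local_tempfile(fileext = ".smi")
  writeSmiles(fc, path)
  back <- readSmiles(path)
  expect_identical(back$smiles, smiles(fc))
  expect_identical(back$id, sourceId(fc))
})
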