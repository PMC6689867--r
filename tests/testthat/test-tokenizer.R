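test_that("bracket expressions, halogens and %NN closures are single tokens", {
  expect_equal(tokenizeSmiles("CCO")[[1]], c("C", "C", "O"))
  expect_equal(tokenizeSmiles("C[C@@H](N)O")[[1]],
               c("C", "[C@@H]", "(", "N", ")", "O"))
  expect_equal(tokenizeSmiles("c1ccccc1Cl")[[1]],
               c("c", "1", "c", "c", "c", "c", "c", "1", "Cl"))
  expect_equal(tokenizeSmiles("C%12CC%12")[[1]],
               c("C", "%12", "C", "C", "%12"))
  expect_equal(tokenizeSmiles("CC(=O)[O-]")[[1]],
               c("C", "C", "(", "=", "O", ")", "[O-]"))
})

test_that("tokenization concatenates back to the input", {
  smis <- smiles(smallFixture(60, seed = 3))
  joined <- vapply(tokenizeSmiles(smis), paste, character(1), collapse = "")
  expect_identical(joined, smis)
})

test_that("unbalanced brackets are a tokenization error", {
  expect_error(tokenizeSmiles("C[C@@H(N)O"), "unbalanced")
  expect_error(tokenizeSmiles("C]C"), "unbalanced")
})

test_that("vocabulary collects sorted corpus tokens and reserves specials", {
  v <- buildVocabulary(c("CCO", "CCN"))
  expect_identical(vocabTokens(v), c("C", "N", "O"))
  expect_identical(outputWidth(v), 5L)
  # deterministic regardless of corpus order
  v2 <- buildVocabulary(c("CCN", "CCO"))
  expect_identical(vocabTokens(v), vocabTokens(v2))
  # id map is a bijection over 0..len+2
  idx <- c(0L, 1L, 2L, molgru:::vocabIndex(v))
  expect_setequal(idx, 0:(length(vocabTokens(v)) + 2L))
})

test_that("encode brackets the token ids with start/end markers", {
  v <- buildVocabulary(c("CCO", "CCN"))
  # C=3, N=4, O=5 under lexicographic ordering
  expect_identical(encodeSmiles("CCO", v), c(1L, 3L, 3L, 5L, 2L))
  expect_error(encodeSmiles("CCF", v), "F")
})

test_that("decode inverts encode and flags missing end markers", {
  v <- buildVocabulary(c("CCO", "CCN", "C1CC1", "C[C@@H](N)O"))
  for (s in c("CCO", "C1CC1", "C[C@@H](N)O")) {
    out <- decodeTokens(encodeSmiles(s, v), v)
    expect_identical(as.character(out), s)
    expect_false(attr(out, "truncated"))
  }
  # pad after end is ignored
  ids <- c(encodeSmiles("CCO", v), 0L, 0L)
  expect_identical(as.character(decodeTokens(ids, v)), "CCO")
  # no end marker -> truncated decode of what is there
  out <- decodeTokens(c(1L, 3L, 3L), v)
  expect_true(attr(out, "truncated"))
})

test_that("vocabulary serialization round-trips bit-exactly", {
  v <- buildVocabulary(smiles(smallFixture()))
  path <- withr::local_tempfile(fileext = ".txt")
  writeVocabulary(v, path)
  v2 <- readVocabulary(path)
  expect_identical(vocabTokens(v), vocabTokens(v2))
  expect_error(readVocabulary(system.file("DESCRIPTION", package = "molgru")),
               "reserved markers")
})

test_that("bracket grouping never yields more tokens than characters", {
  smis <- smiles(smallFixture(60, seed = 3))
  ntok <- lengths(tokenizeSmiles(smis))
  expect_true(all(ntok <= nchar(smis)))
  expect_lte(mean(ntok), mean(nchar(smis)))
})
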