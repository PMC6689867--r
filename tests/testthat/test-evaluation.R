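# Validation-battery tests: exact set-algebra oracles for the reproduction
# and scaffold metrics, a hand-computed NP-likeness toy model, descriptor
# spot checks and the t-SNE contract.

test_that("reproduction rate equals the brute-force intersection", {
  gen <- moleculeSet(c("CCO", "CCN", "CCCC", "c1ccccc1"), name = "gen")
  tst <- moleculeSet(c("CCO", "c1ccccc1", "CCCCC"), name = "test")
  rr <- reproductionRate(gen, tst)
  brute <- sum(vapply(smiles(tst), function(s) s %in% smiles(gen),
                      logical(1)))
  expect_identical(rr$rp, as.integer(brute))
  expect_equal(rr$rpp, brute / length(tst))
  expect_equal(reproductionRate(gen, gen)$rpp, 1.0)
  disj <- moleculeSet(c("CCCCCCCC", "CCCCCCCCC"), name = "d")
  expect_equal(reproductionRate(gen, disj)$rpp, 0.0)
  expect_error(reproductionRate(gen, moleculeSet(character(0))), "empty")
})

test_that("scaffold novelty counts are exact set algebra", {
  gen <- moleculeSet(c("Cc1ccccc1", "CC1CCCCC1", "Cc1ccncc1"), "gen")
  train <- moleculeSet(c("CCc1ccccc1", "CCCCCCCCCC"), "train")
  test <- moleculeSet(c("CCC1CCCCC1",  "CCc1ccco1"), "test")
  sn <- scaffoldNovelty(gen, train, test)
  # brute-force oracle on independently extracted scaffold sets
  sg <- setdiff(unique(extractScaffold(smiles(gen))), "")
  st <- setdiff(unique(extractScaffold(smiles(train))), "")
  se <- setdiff(unique(extractScaffold(smiles(test))), "")
  expect_equal(unname(sn$counts["new"]),
               sum(!(sg %in% st) & !(sg %in% se)))
  expect_equal(unname(sn$counts["shared_train"]), sum(sg %in% st))
  expect_equal(unname(sn$counts["shared_test_only"]),
               sum(sg %in% se & !(sg %in% st)))
  # gen == train -> nothing new
  same <- scaffoldNovelty(gen, gen, NULL)
  expect_equal(unname(same$counts["new"]), 0L)
})

test_that("nearest-neighbour similarities honour self-exclusion", {
  a <- c("c1ccccc1", "c1ccncc1", "C1CCCCC1")
  nn_self <- nnSimilarity(a, a)
  expect_true(all(nn_self$values < 1))
  nn_all <- nnSimilarity(a, a, selfExclude = FALSE)
  expect_true(all(nn_all$values == 1))
  expect_equal(sum(nn_all$histogram$count), length(a))
  b <- c("CCCCCCCCCC")  # acyclic: disjoint fingerprint bits from benzene
  expect_equal(nnSimilarity("c1ccccc1", b)$values, 0)
})

test_that("NP-likeness matches a hand-computed two-molecule toy model", {
  # np corpus = {"C"}, synthetic = {"N"}: each contributes one fragment
  # per radius (0,1,2), each once. With Laplace smoothing k=1 and 3 total
  # occurrences per corpus, every np fragment scores
  # ln((1+1)/(3+1)) - ln((0+1)/(3+1)) = ln 2, so score("C") = 3 ln 2 / 1.
  npm <- buildNpModel("C", "N", radius = 2)
  expect_equal(npLikeness("C", npm), 3 * log(2), tolerance = 1e-12)
  expect_equal(npLikeness("N", npm), -3 * log(2), tolerance = 1e-12)
  # fragments with equal relative frequency cancel out to zero
  npm0 <- buildNpModel(c("CCO"), c("CCO"), radius = 2)
  expect_equal(npLikeness("CCO", npm0), 0, tolerance = 1e-12)
})

test_that("NP scores separate the reference corpora they were built from", {
  np_ref <- smiles(smallFixture(40, seed = 11))
  syn_ref <- c("CC(C)Cc1ccc(C)cc1C(N)=O", "CCN(CC)CCNC(=O)c1ccccc1",
               "CCOC(=O)N1CCN(CC1)C(=O)OCC", "CN1CCN(CC1)c1ccccn1",
               "CCOc1ccccc1OC", "CC(=O)Nc1ccc(OCC)cc1")
  npm <- buildNpModel(np_ref, syn_ref, radius = 2)
  expect_gt(mean(npLikeness(np_ref, npm)), mean(npLikeness(syn_ref, npm)))
})

test_that("chemotype counting finds coumarin derivatives", {
  smis <- c("O=c1ccc2ccccc2o1",          # coumarin itself
            "CC1=CC(=O)Oc2ccccc21",      # 4-methylcoumarin
            "CCO", "c1ccccc1")
  hits <- matchesSmarts(smis, coumarinSmarts())
  expect_identical(hits, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(chemotypeCount(smis, coumarinSmarts()), 2L)
  expect_error(matchesSmarts("CCO", "not_a_smarts(("), "invalid SMARTS")
})

test_that("t-SNE embeds descriptors deterministically", {
  fc <- smallFixture(40, seed = 11)
  prof <- descriptorProfile(smiles(fc))
  emb <- embedTsne(prof, seed = 5, perplexity = 5, maxIter = 150)
  expect_equal(dim(emb), c(40L, 2L))
  expect_identical(emb, embedTsne(prof, seed = 5, perplexity = 5,
                                  maxIter = 150))
  # duplicated rows map to nearly coincident points
  X <- prof[c(1, 1, 2:25), ]
  e2 <- embedTsne(X, seed = 2, perplexity = 4, maxIter = 200)
  d_dup <- sqrt(sum((e2[1, ] - e2[2, ])^2))
  d_other <- median(as.matrix(dist(e2))[upper.tri(diag(26))])
  expect_lt(d_dup, d_other)
  expect_error(embedTsne(prof[1:5, ], perplexity = 30), "too few rows")
})

test_that("evaluateLibrary assembles a coherent report", {
  m <- degenerateModel()
  sr <- sampleSmiles(m, 50, seed = 2)
  train <- moleculeSet(c("CCN", "CCCC"), "train")
  test <- moleculeSet(c("CCO", "CCCCC"), "test")
  rep <- evaluateLibrary(sr, train, test)
  expect_gte(rep@validityRate, 0); expect_lte(rep@validityRate, 1)
  expect_gte(rep@uniquenessRate, 0); expect_lte(rep@uniquenessRate, 1)
  expect_gte(rep@noveltyRate, 0); expect_lte(rep@noveltyRate, 1)
  expect_equal(rep@rp, 1L)           # CCO reproduced
  expect_equal(rep@rpp, 0.5)
  dir <- withr::local_tempdir()
  writeReport(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$rp, 1L)
})
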