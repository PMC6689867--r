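# End-to-end driver tests at miniature scale: structure and determinism
# of the cross-validated reproduction protocol and the transfer grid.
# Scientific (directional) assertions about transfer learning live in the
# acceptance suite, where a properly trained base model is available.

test_that("the cross-validation driver emits a complete, valid table", {
  fc <- smallFixture(40, seed = 11)
  cfg <- tinyConfig(hiddenDim = 24L, batchSize = 16L)
  res <- runCvExperiment(fc, cfg, k = 4L, repeats = 1L, epochs = 3L,
                         seeds = 7L, sampleSize = 12L, patience = 0L)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$rpp >= 0 & res$rpp <= 1))
  expect_true(all(res$test_size == 10L))
  expect_true(all(res$train_size == 30L))
  smry <- summarizeCvExperiment(res)
  expect_equal(nrow(smry), 1L)
  expect_equal(smry$rpp_mean, mean(res$rpp))
})

test_that("the cross-validation driver is reproducible for fixed seeds", {
  fc <- smallFixture(30, seed = 5)
  cfg <- tinyConfig(hiddenDim = 16L, batchSize = 16L)
  r1 <- runCvExperiment(fc, cfg, k = 3L, repeats = 1L, epochs = 2L,
                        seeds = 5L, sampleSize = 8L, patience = 0L)
  r2 <- runCvExperiment(fc, cfg, k = 3L, repeats = 1L, epochs = 2L,
                        seeds = 5L, sampleSize = 8L, patience = 0L)
  expect_identical(r1, r2)
})

test_that("the transfer grid runs all arms and a degenerate epoch grid", {
  fc <- smallFixture(40, seed = 11)
  cfg <- tinyConfig(hiddenDim = 24L, batchSize = 16L)
  base <- cached("xfer_base",
                 trainGruModel(fc, cfg, epochs = 25L, seed = 3,
                               patience = 0L))
  focused <- fc[grepl("1", smiles(fc))][1:8]  # any ring-bearing subset
  res <- runTransferExperiment(base, focused, chemotype = "c1ccccc1",
                               pretrainCorpus = NULL, epochsGrid = 1L,
                               sampleSize = 10L, seed = 2,
                               directConfig = cfg)
  expect_equal(nrow(res), 3L)  # pretrained + direct + transfer
  expect_setequal(res$arm, c("pretrained", "direct", "transfer"))
  expect_true(all(res$chemotype_frac >= 0 & res$chemotype_frac <= 1))
  expect_true(all(res$sample_size == 10L))
})

test_that("experiment configuration reads YAML with model overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("epochs: 7", "folds: 4", "repeats: 2",
               "seeds: [11, 12]", "model:",
               "  hidden_dim: 32", "  num_layers: 2",
               "  learning_rate: 0.005"), path)
  cfg <- readExperimentConfig(path)
  expect_equal(cfg$epochs, 7)
  expect_equal(cfg$folds, 4)
  expect_equal(cfg$model@hiddenDim, 32L)
  expect_equal(cfg$model@numLayers, 2L)
  expect_equal(cfg$model@learningRate, 0.005)
  expect_equal(cfg$model@embeddingDim, 64L)  # untouched default
  writeLines(c("corpus: /nonexistent/file.smi"), path)
  expect_error(readExperimentConfig(path), "not found")
})
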