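# Shared lightweight fixtures. Heavier trained models are built once, on
# first use, inside .fixture_cache.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tinyVocab <- function() buildVocabulary(c("CCO", "CCN", "C1CC1", "C=C(N)O"))

tinyConfig <- function(...) {
  args <- list(...)
  do.call(gruConfig, utils::modifyList(
    list(embeddingDim = 8L, hiddenDim = 16L, numLayers = 2L,
         learningRate = 0.01, batchSize = 8L, maxLen = 40L), args))
}

smallFixture <- function(n = 40, seed = 11) {
  cached(paste0("fix", n, "_", seed), fixtureCorpus(n, seed = seed))
}

# An effectively deterministic model: trained to memorize the single
# molecule "CCO", then its output logits sharpened so sampling emits
# "CCO" with probability indistinguishable from one.
degenerateModel <- function() {
  cached("degen", {
    vocab <- buildVocabulary(c("CCO", "CCN"))
    m <- trainGruModel(rep("CCO", 8), tinyConfig(), epochs = 120L,
                       seed = 2, vocab = vocab, patience = 0L)
    m@params$Wo <- m@params$Wo * 10
    m@params$bo <- m@params$bo * 10
    m
  })
}
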