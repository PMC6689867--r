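# End-to-end experiment drivers: the k-fold reproduction protocol
# (train on k-1 folds, sample a training-library-sized unique set
# excluding the training folds, count test-fold molecules reproduced) and
# the transfer-learning grid (pre-trained vs direct vs transfer arms over
# an epoch grid). Every row of the result tables is regenerable from its
# logged seed.

#' Read an experiment configuration from YAML
#'
#' Recognized fields: \code{corpus} (SMILES file path), \code{epochs},
#' \code{folds} (default 5), \code{repeats} (default 3), \code{seeds}
#' (one per repeat), \code{sample_multipliers}, \code{transfer_epochs}
#' (default 20, 50, 100), and \code{model} overrides
#' (\code{embedding_dim}, \code{hidden_dim}, \code{num_layers},
#' \code{learning_rate}, \code{batch_size}, \code{max_len}).
#'
#' @param path YAML file.
#' @return a list with a validated \code{model} \linkS4class{GruConfig}.
#' @export
readExperimentConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$corpus) && !file.exists(cfg$corpus))
    stop("corpus file not found: ", cfg$corpus)
  m <- cfg$model
  cfg$model <- gruConfig(
    embeddingDim = m$embedding_dim %||% 64L,
    hiddenDim = m$hidden_dim %||% 512L,
    numLayers = m$num_layers %||% 3L,
    learningRate = m$learning_rate %||% 0.001,
    batchSize = m$batch_size %||% 128L,
    maxLen = m$max_len %||% 140L)
  cfg$folds <- cfg$folds %||% 5L
  cfg$repeats <- cfg$repeats %||% 3L
  cfg$epochs <- cfg$epochs %||% 20L
  cfg$transfer_epochs <- cfg$transfer_epochs %||% c(20L, 50L, 100L)
  if (is.null(cfg$seeds)) cfg$seeds <- seq_len(cfg$repeats)
  if (length(cfg$seeds) < cfg$repeats)
    stop("need at least ", cfg$repeats, " seeds")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validated reproduction experiment
#'
#' For each repeat and each fold: train on the other folds, collect a
#' unique generated library of \code{sampleSize} molecules excluding the
#' training folds, and report RP / RPP against the held-out fold. The
#' vocabulary for every fold model is built on the full corpus so that
#' held-out molecules are always encodable.
#'
#' @param corpus a \linkS4class{MoleculeSet}.
#' @param config a \linkS4class{GruConfig}.
#' @param k number of folds.
#' @param repeats number of independent repetitions.
#' @param epochs training epochs per fold model.
#' @param seeds one integer seed per repeat (drives the fold split, the
#'   training and the sampling of that repeat).
#' @param sampleSize generated-library size per fold; defaults to the
#'   corpus size, the reference protocol.
#' @param patience,minDelta plateau early-stopping rule passed to
#'   \code{\link{trainGruModel}}.
#' @param verbose print progress?
#' @return data.frame with one row per repeat x fold (\code{repeat_},
#'   \code{fold}, \code{seed}, \code{train_size}, \code{test_size},
#'   \code{sample_size}, \code{rp}, \code{rpp}) with per-repeat mean/SD
#'   rows available via \code{\link{summarizeCvExperiment}}.
#' @export
runCvExperiment <- function(corpus, config = gruConfig(), k = 5L,
                            repeats = 3L, epochs = 20L,
                            seeds = seq_len(repeats),
                            sampleSize = NULL, patience = 3L,
                            minDelta = 1e-3, verbose = FALSE) {
  stopifnot(is(corpus, "MoleculeSet"), length(seeds) >= repeats)
  if (is.null(sampleSize)) sampleSize <- length(corpus@smiles)
  vocab <- buildVocabulary(corpus)
  rows <- list()
  for (r in seq_len(repeats)) {
    seed <- as.integer(seeds[r])
    split <- splitFolds(corpus, k = k, seed = seed)
    for (f in seq_len(k)) {
      test <- split@folds[[f]]
      train <- do.call(mergeSets, c(unname(split@folds[-f]),
                                    list(name = "train")))
      model <- trainGruModel(train, config, epochs = epochs,
                             seed = deriveSeed(seed, f),
                             vocab = vocab, patience = patience,
                             minDelta = minDelta, verbose = verbose)
      gen <- collectUnique(model, sampleSize, exclude = train,
                           seed = deriveSeed(seed, 100L + f))
      rr <- reproductionRate(gen, test)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f, seed = seed,
        train_size = length(train@smiles),
        test_size = length(test@smiles),
        sample_size = sampleSize, rp = rr$rp, rpp = rr$rpp)
      if (verbose)
        message(sprintf("repeat %d fold %d: RP %d RPP %.3f", r, f,
                        rr$rp, rr$rpp))
    }
  }
  do.call(rbind, rows)
}

#' Per-repeat summary of a cross-validation experiment
#'
#' @param results data.frame from \code{\link{runCvExperiment}}.
#' @return data.frame with per-repeat mean and SD of RP and RPP.
#' @export
summarizeCvExperiment <- function(results) {
  sp <- split(results, results$repeat_)
  do.call(rbind, lapply(sp, function(d) data.frame(
    repeat_ = d$repeat_[1],
    rp_mean = mean(d$rp), rp_sd = stats::sd(d$rp),
    rpp_mean = mean(d$rpp), rpp_sd = stats::sd(d$rpp))))
}

#' Transfer-learning experiment grid
#'
#' Compares three arms at each epoch setting: the pre-trained model as-is
#' (\code{pretrained}), a model trained from scratch on the focused
#' library only (\code{direct}, vocabulary built from the focused corpus
#' alone), and the pre-trained model fine-tuned on the focused library
#' (\code{transfer}). Each arm generates \code{sampleSize} unique
#' molecules excluding the focused and pre-training corpora, then counts
#' chemotype matches and distinct scaffolds; when a bioactive reference
#' library is supplied the overlap with it is reported as \code{rp}.
#'
#' @param pretrained a trained \linkS4class{GruModel}.
#' @param focused \linkS4class{MoleculeSet} sharing the target chemotype.
#' @param chemotype SMARTS pattern of the chemotype.
#' @param pretrainCorpus the corpus the model was pre-trained on
#'   (excluded from sampling alongside \code{focused}).
#' @param epochsGrid integer vector of fine-tuning epoch settings.
#' @param sampleSize unique molecules generated per arm.
#' @param reference optional bioactive reference \linkS4class{MoleculeSet}.
#' @param seed integer seed.
#' @param directConfig \linkS4class{GruConfig} for the direct arm
#'   (defaults to the pre-trained model's).
#' @param verbose print progress?
#' @return data.frame: one row per arm x epoch setting with
#'   \code{chemotype_n}, \code{chemotype_frac}, \code{scaffold_n},
#'   \code{rp} columns. The pretrained arm appears once (epoch
#'   \code{NA}).
#' @export
runTransferExperiment <- function(pretrained, focused, chemotype,
                                  pretrainCorpus = NULL,
                                  epochsGrid = c(20L, 50L, 100L),
                                  sampleSize = 1000L, reference = NULL,
                                  seed = 1L, directConfig = NULL,
                                  verbose = FALSE) {
  stopifnot(is(pretrained, "GruModel"), is(focused, "MoleculeSet"))
  if (is.null(directConfig)) directConfig <- pretrained@config
  excl <- if (is.null(pretrainCorpus)) focused
          else mergeSets(focused, pretrainCorpus, name = "exclude")
  evalArm <- function(model, arm, ep) {
    off <- 37L * (if (is.na(ep)) 0L else ep) + nchar(arm)
    gen <- collectUnique(model, sampleSize, exclude = excl,
                         seed = deriveSeed(seed, off))
    nchem <- chemotypeCount(gen, chemotype)
    scafs <- extractScaffold(gen)
    scafs <- unique(scafs[!is.na(scafs) & nzchar(scafs)])
    rp <- if (is.null(reference)) NA_integer_
          else reproductionRate(gen, reference)$rp
    if (verbose)
      message(sprintf("%s (epochs %s): %d/%d chemotype, %d scaffolds",
                      arm, ep, nchem, sampleSize, length(scafs)))
    data.frame(arm = arm, epochs = ep, sample_size = sampleSize,
               chemotype_n = nchem,
               chemotype_frac = nchem / sampleSize,
               scaffold_n = length(scafs), rp = rp,
               stringsAsFactors = FALSE)
  }
  rows <- list(evalArm(pretrained, "pretrained", NA_integer_))
  for (ep in epochsGrid) {
    direct <- trainGruModel(focused, directConfig, epochs = ep,
                            seed = deriveSeed(seed, ep), patience = 0L)
    rows[[length(rows) + 1L]] <- evalArm(direct, "direct", ep)
    transfer <- fineTuneGruModel(pretrained, focused, epochs = ep,
                                 seed = deriveSeed(seed, ep + 1L))
    rows[[length(rows) + 1L]] <- evalArm(transfer, "transfer", ep)
  }
  do.call(rbind, rows)
}
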