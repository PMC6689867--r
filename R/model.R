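# The generative network: token embedding, stacked GRU, softmax output.
# The batched forward/backward passes live in src/gru.cpp; this file holds
# parameter management, the ADAM training loop, and a plain-R single-step
# reference implementation used as an independent oracle in the tests.
#
# Gate equations (update-gate convention):
#   r_t = sigmoid(Wx_r x_t + Wh_r h_{t-1} + b_r)
#   z_t = sigmoid(Wx_z x_t + Wh_z h_{t-1} + b_z)
#   cand_t = tanh(Wx_n x_t + Wh_n (r_t * h_{t-1}) + b_n)
#   h_t = (1 - z_t) * h_{t-1} + z_t * cand_t
# so z_t -> 1 recovers the candidate state and z_t -> 0 keeps h_{t-1}.

#' @useDynLib molgru, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Create a model configuration
#'
#' Defaults are the reference architecture: 64-dimensional embedding,
#' three GRU layers of 512 units, ADAM with learning rate 0.001, batch
#' size 128. \code{maxLen} caps sampled sequences at 140 tokens (about the
#' corpus mean plus three standard deviations of token counts).
#'
#' @param embeddingDim,hiddenDim,numLayers,learningRate,batchSize,maxLen
#'   see \linkS4class{GruConfig}.
#' @return a \linkS4class{GruConfig}.
#' @export
gruConfig <- function(embeddingDim = 64L, hiddenDim = 512L, numLayers = 3L,
                      learningRate = 0.001, batchSize = 128L,
                      maxLen = 140L) {
  new("GruConfig", embeddingDim = as.integer(embeddingDim),
      hiddenDim = as.integer(hiddenDim), numLayers = as.integer(numLayers),
      learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), maxLen = as.integer(maxLen))
}

#' Initialize an untrained model
#'
#' Parameters are drawn uniformly from
#' \code{[-1/sqrt(hiddenDim), 1/sqrt(hiddenDim)]}; biases start at zero.
#' Deterministic per seed.
#'
#' @param vocab a \linkS4class{SmilesVocabulary}.
#' @param config a \linkS4class{GruConfig}.
#' @param seed integer seed.
#' @return a \linkS4class{GruModel}.
#' @export
initGruModel <- function(vocab, config = gruConfig(), seed = 1L) {
  stopifnot(is(vocab, "SmilesVocabulary"), is(config, "GruConfig"))
  V <- outputWidth(vocab)
  e <- config@embeddingDim
  H <- config@hiddenDim
  L <- config@numLayers
  s <- 1 / sqrt(H)
  params <- withSeed(seed, {
    layers <- lapply(seq_len(L), function(l) {
      din <- if (l == 1L) e else H
      list(Wx = matrix(stats::runif(3 * H * din, -s, s), 3 * H, din),
           Wh = matrix(stats::runif(3 * H * H, -s, s), 3 * H, H),
           b = rep(0, 3 * H))
    })
    list(E = matrix(stats::runif(V * e, -s, s), V, e),
         layers = layers,
         Wo = matrix(stats::runif(V * H, -s, s), V, H),
         bo = rep(0, V))
  })
  new("GruModel", config = config, vocabulary = vocab, params = params,
      log = data.frame(epoch = integer(0), loss = numeric(0),
                       validity = numeric(0)))
}

#' One GRU step (reference implementation)
#'
#' Plain-R evaluation of a single time step for one example: embeds
#' nothing (takes the already-embedded input vector), updates every layer's
#' hidden state, and returns the output-layer logits. This mirrors the
#' compiled batched kernel and serves as its independent check.
#'
#' @param params model parameter list (\code{model@params}).
#' @param x numeric vector, the embedded input token (length embeddingDim).
#' @param h list of per-layer hidden-state vectors (length numLayers, each
#'   of length hiddenDim).
#' @return list with \code{logits} (length vocab width), \code{h} (updated
#'   hidden states), and the top layer's gate activations \code{r},
#'   \code{z}, \code{cand} for inspection.
#' @export
gruStep <- function(params, x, h) {
  sig <- function(v) 1 / (1 + exp(-v))
  L <- length(params$layers)
  H <- length(h[[1]])
  inp <- x
  gates <- NULL
  for (l in seq_len(L)) {
    ly <- params$layers[[l]]
    pre <- as.vector(ly$Wx %*% inp) + ly$b
    preh <- as.vector(ly$Wh[seq_len(2 * H), ] %*% h[[l]])
    r <- sig(pre[seq_len(H)] + preh[seq_len(H)])
    z <- sig(pre[H + seq_len(H)] + preh[H + seq_len(H)])
    cand <- tanh(pre[2 * H + seq_len(H)] +
                 as.vector(ly$Wh[2 * H + seq_len(H), ] %*% (r * h[[l]])))
    h[[l]] <- (1 - z) * h[[l]] + z * cand
    inp <- h[[l]]
    gates <- list(r = r, z = z, cand = cand)
  }
  logits <- as.vector(params$Wo %*% inp) + params$bo
  c(list(logits = logits, h = h), gates)
}

#' Per-step next-token probabilities of a sequence
#'
#' Runs the compiled forward pass over one encoded sequence and returns
#' the softmax distribution at every step (columns) over the vocabulary
#' width (rows). Column t conditions on tokens 1..t.
#'
#' @param model a \linkS4class{GruModel}.
#' @param ids integer id vector from \code{\link{encodeSmiles}}.
#' @return matrix, vocab width x (length(ids) - 1).
#' @export
stepProbabilities <- function(model, ids) {
  X <- matrix(as.integer(ids), ncol = 1)
  out <- .cpp_gru_forward(model@params, X, TRUE)
  out$probs
}

#' Negative log-likelihood of an encoded sequence
#'
#' The training loss of one molecule: \code{-sum(log P(x_t | x_<t))} over
#' tokens 2..end (natural log), padding excluded. Non-negative.
#'
#' @param model a \linkS4class{GruModel}.
#' @param ids integer ids (start/end bracketed), or a list of such vectors.
#' @return total NLL (single sequence) or vector of NLLs.
#' @export
sequenceLoss <- function(model, ids) {
  if (is.list(ids))
    return(vapply(ids, function(s) sequenceLoss(model, s), numeric(1)))
  stopifnot(length(ids) >= 2)
  X <- matrix(as.integer(ids), ncol = 1)
  .cpp_gru_forward(model@params, X, FALSE)$nll
}

# ---- ADAM over nested parameter lists -------------------------------------

paramMap <- function(f, ...) {
  lists <- list(...)
  walk <- function(...) {
    els <- list(...)
    if (is.list(els[[1]])) do.call(Map, c(list(walk), els))
    else do.call(f, els)
  }
  do.call(walk, lists)
}

zerosLike <- function(params) paramMap(function(p) p * 0, params)

adamStep <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- paramMap(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- paramMap(function(v, g) b2 * v + (1 - b2) * g * g, state$v,
                      grads)
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  params <- paramMap(function(p, m, v) {
    p - lr * (m / c1) / (sqrt(v / c2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

padBatch <- function(seqs) {
  T <- max(lengths(seqs))
  X <- matrix(0L, T, length(seqs))
  for (b in seq_along(seqs)) X[seq_along(seqs[[b]]), b] <- seqs[[b]]
  X
}

runEpochs <- function(params, config, seqs, epochs, seed, vocab,
                      minDelta, patience, monitorValidity,
                      validitySample, verbose) {
  lr <- config@learningRate
  bs <- config@batchSize
  state <- list(t = 0, m = zerosLike(params), v = zerosLike(params))
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    validity = numeric(0))
  prev_loss <- Inf
  stalled <- 0L
  n <- length(seqs)
  for (ep in seq_len(epochs)) {
    ord <- withSeed(deriveSeed(seed, ep), sample.int(n))
    tot_nll <- 0
    tot_tok <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      X <- padBatch(seqs[idx])
      g <- .cpp_gru_grad(params, X)
      if (!is.finite(g$nll))
        stop("training diverged (non-finite loss) at epoch ", ep)
      # mean-per-token gradient keeps the learning rate length-invariant
      grads <- paramMap(function(x) x / g$ntok, g$grads)
      upd <- adamStep(params, grads, state, lr)
      params <- upd$params
      state <- upd$state
      tot_nll <- tot_nll + g$nll
      tot_tok <- tot_tok + g$ntok
    }
    loss <- tot_nll / tot_tok
    validity <- NA_real_
    if (monitorValidity) {
      tmp <- new("GruModel", config = config, vocabulary = vocab,
                 params = params, log = log)
      sr <- sampleSmiles(tmp, validitySample, seed = deriveSeed(seed, ep))
      validity <- mean(sr$valid)
    }
    log <- rbind(log, data.frame(epoch = ep, loss = loss,
                                 validity = validity))
    if (verbose)
      message(sprintf("epoch %3d  loss/token %.4f%s", ep, loss,
                      if (is.na(validity)) ""
                      else sprintf("  validity %.3f", validity)))
    if (patience > 0L) {
      if (prev_loss - loss < minDelta) stalled <- stalled + 1L
      else stalled <- 0L
      prev_loss <- loss
      if (stalled >= patience) break
    } else prev_loss <- loss
  }
  list(params = params, log = log)
}

#' Train the GRU language model on a corpus
#'
#' Minimizes the mean per-token negative log-likelihood with ADAM
#' (\code{beta1 = 0.9}, \code{beta2 = 0.999}). Sequences are padded into
#' random minibatches with the padding masked out of the loss, so variable
#' lengths do not bias it. Training runs for at most \code{epochs} epochs
#' and stops early when the epoch loss improves by less than
#' \code{minDelta} for \code{patience} consecutive epochs
#' (\code{patience = 0} disables early stopping). Optionally, after every
#' epoch 512 strings are sampled and their validity rate logged.
#'
#' One seed controls initialization, shuffling, and the monitoring samples,
#' so a rerun with the same seed reproduces the run.
#'
#' @param x a \linkS4class{MoleculeSet} or character vector of SMILES.
#' @param config a \linkS4class{GruConfig}.
#' @param epochs maximum number of epochs.
#' @param seed integer seed.
#' @param vocab optional \linkS4class{SmilesVocabulary}; built from the
#'   corpus when missing.
#' @param minDelta,patience plateau stopping rule (see Details).
#' @param monitorValidity sample 512 strings per epoch and log validity?
#' @param validitySample number of monitoring samples per epoch.
#' @param verbose print per-epoch progress?
#' @return a trained \linkS4class{GruModel}; \code{trainingLog(model)}
#'   holds the per-epoch loss (and validity when monitored).
#' @export
trainGruModel <- function(x, config = gruConfig(), epochs = 20L,
                          seed = 1L, vocab = NULL, minDelta = 1e-3,
                          patience = 3L, monitorValidity = FALSE,
                          validitySample = 512L, verbose = FALSE) {
  if (is(x, "MoleculeSet")) x <- x@smiles
  stopifnot(length(x) > 0, epochs >= 1)
  if (is.null(vocab)) vocab <- buildVocabulary(x)
  seqs <- encodeCorpus(x, vocab)
  model <- initGruModel(vocab, config, seed)
  res <- runEpochs(model@params, config, seqs, epochs, seed, vocab,
                   minDelta, patience, monitorValidity, validitySample,
                   verbose)
  new("GruModel", config = config, vocabulary = vocab,
      params = res$params, log = res$log)
}

#' Fine-tune a trained model on a focused corpus
#'
#' Transfer learning: continues training from the given parameter state on
#' a (typically small, chemotype-focused) corpus. The vocabulary is frozen;
#' molecules using tokens outside it are an error. All parameters are
#' updated (no layers are frozen). \code{epochs = 0} returns the input
#' state unchanged.
#'
#' @param model a trained \linkS4class{GruModel}.
#' @param x focused corpus (\linkS4class{MoleculeSet} or character).
#' @param epochs number of fine-tuning epochs.
#' @param seed integer seed.
#' @param ... passed to the training loop (\code{minDelta},
#'   \code{patience}, \code{monitorValidity}, ...).
#' @return a \linkS4class{GruModel} with updated parameters; the log holds
#'   only the fine-tuning epochs.
#' @export
fineTuneGruModel <- function(model, x, epochs = 20L, seed = 1L,
                             minDelta = 1e-3, patience = 0L,
                             monitorValidity = FALSE,
                             validitySample = 512L, verbose = FALSE) {
  stopifnot(is(model, "GruModel"), epochs >= 0)
  if (is(x, "MoleculeSet")) x <- x@smiles
  if (epochs == 0L) return(model)
  seqs <- encodeCorpus(x, model@vocabulary)  # errors on OOV tokens
  res <- runEpochs(model@params, model@config, seqs, epochs, seed,
                   model@vocabulary, minDelta, patience, monitorValidity,
                   validitySample, verbose)
  new("GruModel", config = model@config, vocabulary = model@vocabulary,
      params = res$params, log = res$log)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding configuration, vocabulary and
#' parameters; loading reproduces bit-identical outputs.
#'
#' @param model a \linkS4class{GruModel}.
#' @param path checkpoint file path.
#' @export
saveGruModel <- function(model, path) {
  stopifnot(is(model, "GruModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveGruModel
#' @return \code{readGruModel}: the restored \linkS4class{GruModel}.
#' @export
readGruModel <- function(path) {
  m <- readRDS(path)
  if (!is(m, "GruModel")) stop("not a GruModel checkpoint: ", path)
  m
}
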