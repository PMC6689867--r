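# Autoregressive sampling: feed <START>, draw each next token from the
# softmax distribution (temperature 1, plain multinomial), feed it back,
# stop at <END> or at the length cap. Sequences that never emit <END>
# within maxLen tokens are marked truncated and invalid.

deriveSeed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}

#' Sample SMILES strings from a model
#'
#' @param model a \linkS4class{GruModel}.
#' @param n number of samples.
#' @param seed integer seed (sampling is deterministic per seed).
#' @param maxLen token-length cap; defaults to the model configuration.
#' @return data.frame with one row per sample: \code{token_string} (raw
#'   decoded string), \code{smiles} (canonical SMILES, \code{NA} when the
#'   string does not parse), \code{valid} (parses under the toolkit and is
#'   not truncated), \code{truncated}, \code{length_tokens}.
#' @export
sampleSmiles <- function(model, n, seed = 1L, maxLen = NULL) {
  stopifnot(is(model, "GruModel"), n >= 1)
  if (is.null(maxLen)) maxLen <- model@config@maxLen
  ids <- .cpp_gru_sample(model@params, as.integer(n), as.integer(maxLen),
                         START_ID, END_ID, deriveSeed(seed))
  vocab <- model@vocabulary
  ntok <- ncol(ids)  # maxLen x n matrix
  token_string <- character(n)
  length_tokens <- integer(n)
  truncated <- logical(n)
  for (b in seq_len(n)) {
    col <- ids[, b]
    len <- sum(col != 0L)
    length_tokens[b] <- len
    truncated[b] <- len == maxLen
    toks <- col[col != 0L]
    # a resampled <START> (id 1) decodes to "?", which never parses
    tk <- rep("?", length(toks))
    sel <- toks >= 3L
    tk[sel] <- vocab@tokens[toks[sel] - 2L]
    token_string[b] <- paste(tk, collapse = "")
  }
  can <- canonicalizeSmiles(ifelse(truncated | !nzchar(token_string),
                                   NA_character_, token_string))
  valid <- !is.na(can)
  data.frame(token_string = token_string, smiles = can, valid = valid,
             truncated = truncated, length_tokens = length_tokens,
             stringsAsFactors = FALSE)
}

#' Collect unique valid molecules from a model
#'
#' Samples repeatedly until \code{target} valid, mutually unique (by
#' canonical SMILES) molecules absent from \code{exclude} have been
#' collected. Attempts are bounded by \code{maxAttempts} raw samples; if
#' the budget is exhausted first, an error reports the progress.
#'
#' @param model a \linkS4class{GruModel}.
#' @param target number of molecules to collect.
#' @param exclude a \linkS4class{MoleculeSet} (or character vector) of
#'   canonical SMILES to exclude (e.g. the training library); \code{NULL}
#'   excludes nothing.
#' @param seed integer seed.
#' @param maxAttempts raw-sample budget (default \code{50 * target}).
#' @param batchSize raw samples drawn per round.
#' @param name label for the returned set.
#' @return a \linkS4class{MoleculeSet} of \code{target} molecules;
#'   \code{metadata$sampling} records attempts, validity and uniqueness
#'   counters.
#' @export
collectUnique <- function(model, target, exclude = NULL, seed = 1L,
                          maxAttempts = NULL, batchSize = 1024L,
                          name = "generated") {
  stopifnot(target >= 1)
  if (is.null(maxAttempts)) maxAttempts <- 50L * target
  excl <- if (is.null(exclude)) character(0)
          else if (is(exclude, "MoleculeSet")) exclude@smiles
          else as.character(exclude)
  got <- character(0)
  attempts <- 0L
  nvalid <- 0L
  round <- 0L
  while (length(got) < target && attempts < maxAttempts) {
    round <- round + 1L
    nb <- min(batchSize, maxAttempts - attempts)
    sr <- sampleSmiles(model, nb, seed = deriveSeed(seed, round))
    attempts <- attempts + nb
    ok <- sr$smiles[sr$valid]
    nvalid <- nvalid + length(ok)
    new_smi <- setdiff(ok, c(got, excl))
    got <- c(got, new_smi)
  }
  if (length(got) < target)
    stop("sampling budget exhausted: collected ", length(got), "/", target,
         " unique molecules in ", attempts, " attempts (",
         nvalid, " valid)")
  got <- got[seq_len(target)]
  new("MoleculeSet", smiles = got, heavyAtoms = heavyAtomCount(got),
      sourceId = paste0("gen", seq_len(target)), name = name,
      metadata = list(sampling = list(attempts = attempts,
                                      valid = nvalid, seed = seed)))
}
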