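# Bracket-aware SMILES tokenization.
#
# A token is (a) an entire bracket-atom expression "[...]", so charge,
# chirality, isotope and explicit-H annotations travel as one unit; (b) a
# two-letter halogen Cl or Br; (c) a two-digit ring closure %NN; or (d) a
# single character. This keeps chiral centres and charged atoms as single
# alphabet symbols instead of scattering them over several characters.

TOKEN_REGEX <- "\\[[^][]*\\]|Cl|Br|%[0-9][0-9]|."

#' Tokenize SMILES strings
#'
#' Splits each SMILES string into model tokens: bracket-atom expressions
#' (\code{[C@@H]}, \code{[NH3+]}, ...) are single tokens, as are \code{Cl},
#' \code{Br} and two-digit ring closures \code{\%NN}; every other character
#' is its own token. Concatenating the tokens reproduces the input exactly.
#'
#' @param x character vector of SMILES strings.
#' @return a list of character vectors, one per input string.
#' @examples
#' tokenizeSmiles("C[C@@H](N)O")[[1]]
#' @export
tokenizeSmiles <- function(x) {
  stopifnot(is.character(x), all(nzchar(x)))
  out <- regmatches(x, gregexpr(TOKEN_REGEX, x))
  bad <- vapply(out, function(tk) any(tk %in% c("[", "]")), logical(1))
  if (any(bad))
    stop("unbalanced square bracket in SMILES: ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  out
}

#' Build the token vocabulary of a corpus
#'
#' Collects every token occurring in the corpus under
#' \code{\link{tokenizeSmiles}} and stores them in lexicographic order
#' (deterministic, so checkpoints are portable across sessions).
#'
#' @param x a \linkS4class{MoleculeSet} or character vector of SMILES.
#' @return a \linkS4class{SmilesVocabulary}.
#' @export
buildVocabulary <- function(x) {
  if (is(x, "MoleculeSet")) x <- x@smiles
  stopifnot(length(x) > 0)
  toks <- sort(unique(unlist(tokenizeSmiles(x))), method = "radix")
  new("SmilesVocabulary", tokens = toks)
}

vocabIndex <- function(vocab) {
  idx <- seq_along(vocab@tokens) + 2L
  names(idx) <- vocab@tokens
  idx
}

#' Encode a SMILES string as model token ids
#'
#' Returns the integer id sequence \code{<START>, tokens..., <END>} under
#' the model id scheme (\code{<START>} = 1, \code{<END>} = 2, corpus tokens
#' from 3; 0 is reserved for padding).
#'
#' @param x a single SMILES string.
#' @param vocab a \linkS4class{SmilesVocabulary}.
#' @return integer vector of ids.
#' @export
encodeSmiles <- function(x, vocab) {
  stopifnot(length(x) == 1L, is(vocab, "SmilesVocabulary"))
  tk <- tokenizeSmiles(x)[[1]]
  idx <- vocabIndex(vocab)[tk]
  if (anyNA(idx)) {
    missing <- unique(tk[is.na(idx)])
    stop("token(s) not in vocabulary: ", paste(missing, collapse = ", "))
  }
  c(START_ID, unname(idx), END_ID)
}

#' Encode a whole corpus
#'
#' @param x a \linkS4class{MoleculeSet} or character vector.
#' @param vocab a \linkS4class{SmilesVocabulary}.
#' @return list of integer id vectors (start/end bracketed).
#' @export
encodeCorpus <- function(x, vocab) {
  if (is(x, "MoleculeSet")) x <- x@smiles
  idx <- vocabIndex(vocab)
  toks <- tokenizeSmiles(x)
  lapply(seq_along(x), function(i) {
    tk <- toks[[i]]
    id <- idx[tk]
    if (anyNA(id))
      stop("token(s) not in vocabulary in '", x[i], "': ",
           paste(unique(tk[is.na(id)]), collapse = ", "))
    c(START_ID, unname(id), END_ID)
  })
}

#' Decode model token ids back to a SMILES string
#'
#' Concatenates the token strings between the start marker and the first
#' end marker. Ids after the first end marker (padding) are ignored. When
#' no end marker is present the available tokens are decoded and the result
#' carries attribute \code{truncated = TRUE}.
#'
#' @param ids integer vector of model token ids.
#' @param vocab a \linkS4class{SmilesVocabulary}.
#' @return single string; attribute \code{truncated} flags a missing end
#'   marker.
#' @export
decodeTokens <- function(ids, vocab) {
  stopifnot(is(vocab, "SmilesVocabulary"))
  ids <- as.integer(ids)
  if (length(ids) && ids[1] == START_ID) ids <- ids[-1]
  endpos <- match(END_ID, ids)
  truncated <- is.na(endpos)
  if (!truncated) ids <- ids[seq_len(endpos - 1L)]
  ids <- ids[ids != PAD_ID]
  if (any(ids < 3L | ids > length(vocab@tokens) + 2L))
    stop("id out of range for vocabulary")
  out <- paste(vocab@tokens[ids - 2L], collapse = "")
  attr(out, "truncated") <- truncated
  out
}

#' Write a vocabulary to a plain-text file
#'
#' One token per line, the three reserved markers first
#' (\code{<PAD>}, \code{<START>}, \code{<END>}), then the corpus tokens in
#' their stored order. \code{\link{readVocabulary}} round-trips bit-exactly.
#'
#' @param vocab a \linkS4class{SmilesVocabulary}.
#' @param path output file path (UTF-8).
#' @export
writeVocabulary <- function(vocab, path) {
  stopifnot(is(vocab, "SmilesVocabulary"))
  writeLines(c(PAD_TOKEN, START_TOKEN, END_TOKEN, vocab@tokens), path,
             useBytes = TRUE)
  invisible(path)
}

#' @rdname writeVocabulary
#' @param path file written by \code{writeVocabulary}.
#' @return \code{readVocabulary}: a \linkS4class{SmilesVocabulary}.
#' @export
readVocabulary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L ||
      !identical(lines[1:3], c(PAD_TOKEN, START_TOKEN, END_TOKEN)))
    stop("not a vocabulary file: reserved markers missing")
  new("SmilesVocabulary", tokens = lines[-(1:3)])
}
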