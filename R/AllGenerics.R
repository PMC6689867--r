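PAD_TOKEN <- "<PAD>"
START_TOKEN <- "<START>"
END_TOKEN <- "<END>"
PAD_ID <- 0L
START_ID <- 1L
END_ID <- 2L

#' Extract the SMILES strings of a molecule set
#' @param x a \linkS4class{MoleculeSet}.
#' @return character vector of canonical SMILES.
#' @export
setGeneric("smiles", function(x) standardGeneric("smiles"))

#' @rdname smiles
#' @export
setMethod("smiles", "MoleculeSet", function(x) x@smiles)

#' Heavy-atom counts of a molecule set
#' @param x a \linkS4class{MoleculeSet}.
#' @export
setGeneric("heavyAtoms", function(x) standardGeneric("heavyAtoms"))

#' @rdname heavyAtoms
#' @export
setMethod("heavyAtoms", "MoleculeSet", function(x) x@heavyAtoms)

#' Source tags of a molecule set
#' @param x a \linkS4class{MoleculeSet}.
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname sourceId
#' @export
setMethod("sourceId", "MoleculeSet", function(x) x@sourceId)

#' Name label of an object
#' @param x a \linkS4class{MoleculeSet}.
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @rdname setName
#' @export
setMethod("setName", "MoleculeSet", function(x) x@name)

#' @export
setMethod("length", "MoleculeSet", function(x) length(x@smiles))

#' Subset a molecule set
#' @param x a \linkS4class{MoleculeSet}.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = TRUE) {
  new("MoleculeSet", smiles = x@smiles[i], heavyAtoms = x@heavyAtoms[i],
      sourceId = x@sourceId[i], name = x@name, metadata = x@metadata)
})

#' Corpus tokens of a vocabulary (specials excluded)
#' @param x a \linkS4class{SmilesVocabulary}.
#' @export
setGeneric("vocabTokens", function(x) standardGeneric("vocabTokens"))

#' @rdname vocabTokens
#' @export
setMethod("vocabTokens", "SmilesVocabulary", function(x) x@tokens)

#' @export
setMethod("length", "SmilesVocabulary", function(x) length(x@tokens))

#' Output-layer width of a vocabulary
#'
#' Number of classes the model predicts over: the corpus tokens plus the
#' \code{<START>} and \code{<END>} markers (padding is masked, not
#' predicted).
#' @param x a \linkS4class{SmilesVocabulary}.
#' @export
outputWidth <- function(x) {
  stopifnot(is(x, "SmilesVocabulary"))
  length(x@tokens) + 2L
}

#' Folds of a split
#' @param x a \linkS4class{FoldSplit}.
#' @export
setGeneric("folds", function(x) standardGeneric("folds"))

#' @rdname folds
#' @export
setMethod("folds", "FoldSplit", function(x) x@folds)

#' Per-epoch training log of a model
#' @param x a \linkS4class{GruModel}.
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))

#' @rdname trainingLog
#' @export
setMethod("trainingLog", "GruModel", function(x) x@log)

#' Vocabulary of a model
#' @param x a \linkS4class{GruModel}.
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' @rdname vocabulary
#' @export
setMethod("vocabulary", "GruModel", function(x) x@vocabulary)

#' Configuration of a model
#' @param x a \linkS4class{GruModel}.
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname modelConfig
#' @export
setMethod("modelConfig", "GruModel", function(x) x@config)
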