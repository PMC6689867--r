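#' @import methods
NULL

#' A curated set of molecules
#'
#' Ordered collection of unique canonical SMILES with per-molecule heavy-atom
#' counts and opaque source tags. All set operations in the package
#' (uniqueness, novelty, reproduction) are defined on the canonical SMILES
#' held by this class, so two \code{MoleculeSet} objects are comparable only
#' if produced with the same chemistry-toolkit version.
#'
#' @slot smiles canonical SMILES strings, no duplicates.
#' @slot heavyAtoms integer non-hydrogen atom count per molecule.
#' @slot sourceId opaque per-molecule tag (e.g. input line id).
#' @slot name label for the set (e.g. "training", "generated").
#' @slot metadata free-form list; \code{curateCorpus} stores its rejection
#'   log here.
#'
#' @aliases MoleculeSet-class
#' @exportClass MoleculeSet
setClass("MoleculeSet",
  representation(
    smiles = "character",
    heavyAtoms = "integer",
    sourceId = "character",
    name = "character",
    metadata = "list"
  ),
  prototype(name = "corpus", metadata = list())
)

setValidity("MoleculeSet", function(object) {
  n <- length(object@smiles)
  if (length(object@heavyAtoms) != n || length(object@sourceId) != n)
    return("smiles, heavyAtoms and sourceId must have equal length")
  if (anyDuplicated(object@smiles))
    return("duplicate canonical SMILES in MoleculeSet")
  if (length(object@name) != 1L) return("name must be a single string")
  TRUE
})

#' Token vocabulary of a SMILES corpus
#'
#' Holds the sorted distinct tokens observed in a corpus under the
#' bracket-grouping tokenization, plus the three reserved markers. Integer
#' ids used by the model are: \code{<PAD>} = 0 (mask, never embedded),
#' \code{<START>} = 1, \code{<END>} = 2, corpus tokens = 3, 4, ... in the
#' stored order. The network's output layer has \code{length(tokens) + 2}
#' classes (pad is masked out of the loss, not predicted).
#'
#' @slot tokens sorted distinct corpus tokens (specials excluded).
#' @aliases SmilesVocabulary-class
#' @exportClass SmilesVocabulary
setClass("SmilesVocabulary", representation(tokens = "character"))

setValidity("SmilesVocabulary", function(object) {
  tk <- object@tokens
  if (any(tk == "")) return("empty token string")
  if (anyDuplicated(tk)) return("duplicate tokens")
  if (any(tk %in% c(PAD_TOKEN, START_TOKEN, END_TOKEN)))
    return("reserved marker used as a corpus token")
  br <- grepl("^\\[", tk)
  if (any(br != grepl("\\]$", tk)))
    return("bracket tokens must start with '[' and end with ']'")
  TRUE
})

#' Configuration of the GRU language model
#'
#' Defaults are the reference architecture: 64-unit embedding, 3 GRU layers
#' of 512 units, ADAM with learning rate 0.001 and batch size 128.
#'
#' @slot embeddingDim embedding width.
#' @slot hiddenDim GRU units per layer.
#' @slot numLayers number of stacked GRU layers.
#' @slot learningRate ADAM learning rate.
#' @slot batchSize minibatch size.
#' @slot maxLen sampling length cap in tokens.
#' @aliases GruConfig-class
#' @exportClass GruConfig
setClass("GruConfig",
  representation(
    embeddingDim = "integer",
    hiddenDim = "integer",
    numLayers = "integer",
    learningRate = "numeric",
    batchSize = "integer",
    maxLen = "integer"
  )
)

setValidity("GruConfig", function(object) {
  if (object@embeddingDim < 1L || object@hiddenDim < 1L ||
      object@numLayers < 1L || object@batchSize < 1L || object@maxLen < 2L)
    return("all dimensions must be positive")
  if (object@learningRate <= 0) return("learningRate must be positive")
  TRUE
})

#' A trained (or freshly initialized) GRU SMILES model
#'
#' @slot config a \linkS4class{GruConfig}.
#' @slot vocabulary the \linkS4class{SmilesVocabulary} the model was built
#'   over; frozen for the model's lifetime (fine-tuning keeps it).
#' @slot params list of parameter matrices (embedding, per-layer GRU gate
#'   weights, output projection).
#' @slot log per-epoch data.frame: mean loss per token and, when monitored,
#'   the validity rate of 512 sampled strings.
#' @aliases GruModel-class
#' @exportClass GruModel
setClass("GruModel",
  representation(
    config = "GruConfig",
    vocabulary = "SmilesVocabulary",
    params = "list",
    log = "data.frame"
  )
)

#' Disjoint fold partition of a molecule set
#'
#' @slot folds list of \linkS4class{MoleculeSet}, pairwise disjoint, whose
#'   union is the input set; sizes differ by at most one.
#' @slot seed integer seed that produced the shuffle.
#' @aliases FoldSplit-class
#' @exportClass FoldSplit
setClass("FoldSplit", representation(folds = "list", seed = "integer"))

setValidity("FoldSplit", function(object) {
  if (!all(vapply(object@folds, is, logical(1), "MoleculeSet")))
    return("folds must be MoleculeSet objects")
  all_smi <- unlist(lapply(object@folds, function(f) f@smiles))
  if (anyDuplicated(all_smi)) return("folds are not disjoint")
  sizes <- vapply(object@folds, function(f) length(f@smiles), integer(1))
  if (length(sizes) && diff(range(sizes)) > 1L)
    return("fold sizes differ by more than 1")
  TRUE
})

#' Natural-product-likeness fragment score table
#'
#' Per-fragment log-odds of atom-centered circular fragments between a
#' natural-product reference corpus and a synthetic reference corpus, with
#' Laplace smoothing. A molecule's score is the mean over its unique
#' fragments' log-odds... see \code{\link{npLikeness}} for the exact form.
#'
#' @slot scores named numeric vector, names are fragment identifiers.
#' @slot radius maximum circular-fragment radius (bonds).
#' @slot smoothing additive smoothing count.
#' @aliases NpScoreModel-class
#' @exportClass NpScoreModel
setClass("NpScoreModel",
  representation(scores = "numeric", radius = "integer", smoothing = "numeric")
)

#' Library validation report
#'
#' @slot validityRate fraction of raw samples parsing as molecules.
#' @slot uniquenessRate unique fraction among valid samples.
#' @slot noveltyRate fraction of unique valid samples absent from training.
#' @slot rp count of test-library molecules reproduced.
#' @slot rpp \code{rp / |test|}.
#' @slot scaffoldCounts integer vector: \code{new}, \code{shared_train},
#'   \code{shared_test_only}.
#' @slot similarityHistogram data.frame \code{bin_left,bin_right,count} of
#'   nearest-neighbour Tanimoto similarities (generated vs training
#'   scaffolds).
#' @slot npLikenessMeanSd numeric length-2: mean and SD of NP-likeness of
#'   the generated set (NA when no score model supplied).
#' @aliases EvaluationReport-class
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(
    validityRate = "numeric",
    uniquenessRate = "numeric",
    noveltyRate = "numeric",
    rp = "integer",
    rpp = "numeric",
    scaffoldCounts = "integer",
    similarityHistogram = "data.frame",
    npLikenessMeanSd = "numeric"
  )
)

# ---- show methods ---------------------------------------------------------

setMethod("show", "MoleculeSet", function(object) {
  cat(sprintf("MoleculeSet '%s' with %d molecules\n",
              object@name, length(object@smiles)))
  if (length(object@smiles)) {
    k <- min(3L, length(object@smiles))
    cat(sprintf("  heavy atoms: %d-%d\n", min(object@heavyAtoms),
                max(object@heavyAtoms)))
    cat("  head:", paste(utils::head(object@smiles, k), collapse = "  "),
        "\n")
  }
})

setMethod("show", "SmilesVocabulary", function(object) {
  cat(sprintf(
    "SmilesVocabulary: %d corpus tokens + <START>/<END>/<PAD> (output width %d)\n",
    length(object@tokens), length(object@tokens) + 2L))
})

setMethod("show", "GruConfig", function(object) {
  cat(sprintf(
    "GruConfig: embedding %d, %d x GRU(%d), lr %g, batch %d, maxLen %d\n",
    object@embeddingDim, object@numLayers, object@hiddenDim,
    object@learningRate, object@batchSize, object@maxLen))
})

setMethod("show", "GruModel", function(object) {
  show(object@config)
  show(object@vocabulary)
  if (nrow(object@log))
    cat(sprintf("  trained %d epochs, final loss/token %.4f\n",
                max(object@log$epoch), utils::tail(object@log$loss, 1)))
  else cat("  untrained (initialized parameters)\n")
})

setMethod("show", "FoldSplit", function(object) {
  cat(sprintf("FoldSplit: %d folds of sizes %s (seed %d)\n",
              length(object@folds),
              paste(vapply(object@folds, function(f) length(f@smiles),
                           integer(1)), collapse = "/"),
              object@seed))
})

setMethod("show", "NpScoreModel", function(object) {
  cat(sprintf("NpScoreModel: %d fragments, radius %d, smoothing %g\n",
              length(object@scores), object@radius, object@smoothing))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  cat(sprintf("  validity   %.3f\n  uniqueness %.3f\n  novelty    %.3f\n",
              object@validityRate, object@uniquenessRate,
              object@noveltyRate))
  cat(sprintf("  RP %d (RPP %.3f)\n", object@rp, object@rpp))
  cat("  scaffolds:",
      paste(names(object@scaffoldCounts), object@scaffoldCounts,
            sep = "=", collapse = " "), "\n")
})
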