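# Natural-product-likeness: a Bayesian log-odds score over atom-centered
# circular fragments, contrasting a natural-product reference corpus with
# a synthetic reference corpus. Fragments seen mostly in natural products
# contribute positively, fragments typical of synthetic chemistry
# negatively. The score table is built from two reference corpora (no
# pre-fitted table ships with the package); scores are comparable only
# between molecules scored with the same table.

#' Build a natural-product-likeness score table
#'
#' Counts atom-centered circular fragments (radii 0..\code{radius}, see
#' \code{\link{atomFragments}}) in the two reference corpora and stores,
#' per fragment, the log-odds of its relative frequency with additive
#' (Laplace) smoothing:
#' \deqn{s(f) = \ln\frac{(c_{np}(f) + k) / (N_{np} + k)}{(c_{syn}(f) + k) / (N_{syn} + k)}}
#' where \eqn{c} are fragment occurrence counts and \eqn{N} the total
#' occurrences in each corpus. A fragment with equal relative frequency in
#' both corpora scores zero; a fragment absent from the synthetic corpus
#' scores positively.
#'
#' @param npCorpus \linkS4class{MoleculeSet} (or character) of
#'   natural-product-like reference molecules.
#' @param synCorpus reference corpus of synthetic molecules.
#' @param radius maximum fragment radius (default 2, the usual
#'   atom-environment setting).
#' @param smoothing additive smoothing count \eqn{k}.
#' @return an \linkS4class{NpScoreModel}.
#' @export
buildNpModel <- function(npCorpus, synCorpus, radius = 2L, smoothing = 1) {
  getsmi <- function(x) if (is(x, "MoleculeSet")) x@smiles else x
  np <- getsmi(npCorpus); syn <- getsmi(synCorpus)
  stopifnot(length(np) > 0, length(syn) > 0)
  countFrags <- function(smis) {
    tab <- table(unlist(lapply(smis, function(s)
      atomFragments(s, radius = radius, unique = FALSE))))
    stats::setNames(as.numeric(tab), names(tab))
  }
  cnp <- countFrags(np)
  csyn <- countFrags(syn)
  frags <- union(names(cnp), names(csyn))
  a <- ifelse(frags %in% names(cnp), cnp[frags], 0)
  b <- ifelse(frags %in% names(csyn), csyn[frags], 0)
  Nnp <- sum(cnp); Nsyn <- sum(csyn)
  scores <- log(((a + smoothing) / (Nnp + smoothing)) /
                ((b + smoothing) / (Nsyn + smoothing)))
  new("NpScoreModel", scores = stats::setNames(as.numeric(scores), frags),
      radius = as.integer(radius), smoothing = as.numeric(smoothing))
}

#' Natural-product-likeness score of molecules
#'
#' Sum of the score-table log-odds over the molecule's distinct
#' atom-centered fragments, normalized by heavy-atom count, with the tails
#' softly compressed beyond +/-4 (scores above 4 become
#' \code{4 + log10(score - 3)}, symmetrically below -4) so single extreme
#' fragments cannot dominate. Fragments absent from the table contribute
#' zero.
#'
#' @param x a \linkS4class{MoleculeSet} or character vector of SMILES.
#' @param model an \linkS4class{NpScoreModel}.
#' @return numeric vector of scores.
#' @export
npLikeness <- function(x, model) {
  if (is(x, "MoleculeSet")) x <- x@smiles
  stopifnot(is(model, "NpScoreModel"))
  vapply(x, function(s) {
    g <- smilesGraph(s)
    frags <- as.character(atomFragments(g, radius = model@radius,
                                        unique = TRUE))
    natoms <- sum(g$atoms$element != "H")
    if (!natoms) stop("molecule with no heavy atoms: ", s)
    sc <- model@scores[frags]
    sc[is.na(sc)] <- 0
    score <- sum(sc) / natoms
    if (score > 4) score <- 4 + log10(score - 3)
    if (score < -4) score <- -4 - log10(-score - 3)
    score
  }, numeric(1), USE.NAMES = FALSE)
}
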