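# Validation battery for generated libraries: reproduction of held-out
# molecules, scaffold diversity/novelty, nearest-neighbour fingerprint
# similarity, physicochemical profiling, and chemotype counting. All set
# operations are exact set algebra on canonical SMILES.

#' Reproduction rate of a test library
#'
#' RP is the number of test-library molecules that also occur in the
#' generated library (intersection of canonical SMILES); RPP is
#' \code{RP / |test|}.
#'
#' @param generated,test \linkS4class{MoleculeSet} objects (canonical).
#' @return list with \code{rp} (integer) and \code{rpp} (fraction).
#' @export
reproductionRate <- function(generated, test) {
  gs <- if (is(generated, "MoleculeSet")) generated@smiles else generated
  ts <- if (is(test, "MoleculeSet")) test@smiles else test
  if (!length(ts)) stop("empty test corpus")
  rp <- length(intersect(gs, ts))
  list(rp = as.integer(rp), rpp = rp / length(ts))
}

#' Reproduction rate as a function of generated-library size
#'
#' Draws cumulative unique sample sets of sizes
#' \code{multipliers * length(test)} from the model (excluding
#' \code{exclude}) and reports RPP at each size. Cumulative sets grow, so
#' RPP is non-decreasing in size.
#'
#' @param model a trained \linkS4class{GruModel}.
#' @param test held-out \linkS4class{MoleculeSet}.
#' @param multipliers positive integers (library size in multiples of
#'   \code{|test|}).
#' @param exclude molecules excluded from sampling (training library).
#' @param seed integer seed.
#' @param ... passed to \code{\link{collectUnique}}.
#' @return data.frame with columns \code{multiplier}, \code{size},
#'   \code{rp}, \code{rpp}.
#' @export
reproductionCurve <- function(model, test, multipliers = c(1, 5, 10),
                              exclude = NULL, seed = 1L, ...) {
  stopifnot(all(multipliers > 0))
  multipliers <- sort(unique(as.integer(multipliers)))
  nt <- length(test@smiles)
  big <- collectUnique(model, max(multipliers) * nt, exclude = exclude,
                       seed = seed, ...)
  out <- lapply(multipliers, function(m) {
    rr <- reproductionRate(big@smiles[seq_len(m * nt)], test)
    data.frame(multiplier = m, size = m * nt, rp = rr$rp, rpp = rr$rpp)
  })
  do.call(rbind, out)
}

#' Scaffold sets and novelty counts
#'
#' Extracts framework scaffolds (see \code{\link{extractScaffold}}) of the
#' generated, training and test libraries and reports set-algebra counts:
#' \code{new} = scaffolds only in the generated library,
#' \code{shared_train} = generated scaffolds present in the training
#' library, \code{shared_test_only} = generated scaffolds present in the
#' test library but not the training library. The empty (acyclic) scaffold
#' marker is dropped before counting.
#'
#' @param gen,train,test \linkS4class{MoleculeSet} objects.
#' @return list with \code{counts} (named integer vector) and the three
#'   scaffold character vectors \code{gen}, \code{train}, \code{test}.
#' @export
scaffoldNovelty <- function(gen, train, test = NULL) {
  scafs <- function(x) {
    s <- extractScaffold(x)
    unique(s[!is.na(s) & nzchar(s)])
  }
  sg <- scafs(gen)
  st <- scafs(train)
  se <- if (is.null(test)) character(0) else scafs(test)
  counts <- c(
    new = length(setdiff(sg, union(st, se))),
    shared_train = length(intersect(sg, st)),
    shared_test_only = length(setdiff(intersect(sg, se), st))
  )
  list(counts = counts, gen = sg, train = st, test = se)
}

#' Nearest-neighbour Tanimoto similarity distribution
#'
#' For every molecule (scaffold) in \code{a}, the maximum Tanimoto
#' similarity of its hashed circular fingerprint (radius 3, 2048 bits —
#' the ECFP6 setting) to any member of \code{b}. When \code{a} and
#' \code{b} are the same set, the self-match is excluded.
#'
#' @param a,b character vectors of SMILES (or scaffold SMILES).
#' @param selfExclude drop the identical-index match (defaults to TRUE
#'   when \code{a} and \code{b} are identical vectors).
#' @param radius,nbits fingerprint parameters.
#' @return list with \code{values} (per-\code{a} nearest-neighbour
#'   similarities) and \code{histogram} (data.frame \code{bin_left},
#'   \code{bin_right}, \code{count}; 10 bins on [0, 1]).
#' @export
nnSimilarity <- function(a, b, selfExclude = identical(a, b),
                         radius = 3L, nbits = 2048L) {
  stopifnot(length(a) > 0, length(b) > 0)
  fa <- lapply(a, ecfpBits, radius = radius, nbits = nbits)
  fb <- if (identical(a, b)) fa
        else lapply(b, ecfpBits, radius = radius, nbits = nbits)
  vals <- vapply(seq_along(fa), function(i) {
    sims <- vapply(seq_along(fb), function(j) {
      if (selfExclude && i == j) return(-Inf)
      tanimoto(fa[[i]], fb[[j]])
    }, numeric(1))
    max(sims)
  }, numeric(1))
  vals[!is.finite(vals)] <- NA_real_
  breaks <- seq(0, 1, by = 0.1)
  cut_idx <- pmin(pmax(findInterval(vals, breaks, rightmost.closed = TRUE),
                       1L), 10L)
  counts <- tabulate(cut_idx[!is.na(vals)], nbins = 10L)
  list(values = vals,
       histogram = data.frame(bin_left = breaks[-11], bin_right = breaks[-1],
                              count = counts))
}

#' Physicochemical descriptor profile
#'
#' The seven-descriptor panel used for chemical-space maps: cLogP,
#' molecular weight, hydrogen-bond donors, hydrogen-bond acceptors,
#' rotatable bonds, number of aromatic ring systems (fused systems count
#' once), and topological polar surface area. LogP/MW/HBD/HBA/TPSA come
#' from the chemistry toolkit; rotatable bonds and aromatic ring systems
#' are computed on the molecular graph.
#'
#' @param x a \linkS4class{MoleculeSet} or character vector of SMILES.
#' @return data.frame with columns \code{smiles}, \code{clogp}, \code{mw},
#'   \code{hbd}, \code{hba}, \code{rotb}, \code{aromsys}, \code{tpsa}.
#' @export
descriptorProfile <- function(x) {
  if (is(x, "MoleculeSet")) x <- x@smiles
  stopifnot(length(x) > 0)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(
    x, paste0("m", seq_along(x)))))
  pr <- ChemmineR::propOB(sdf)
  data.frame(
    smiles = x,
    clogp = as.numeric(pr$logP),
    mw = as.numeric(pr$MW),
    hbd = as.integer(pr$HBD),
    hba = as.integer(pr$HBA2),
    rotb = rotatableBonds(x),
    aromsys = aromaticRingSystems(x),
    tpsa = as.numeric(pr$TPSA),
    stringsAsFactors = FALSE
  )
}

#' Full evaluation of a generated library
#'
#' Bundles the validation battery into one report: validity and
#' uniqueness of the raw samples, novelty against the training library,
#' reproduction of the test library, scaffold novelty counts, the
#' nearest-neighbour scaffold similarity histogram (generated vs training),
#' and optionally NP-likeness statistics.
#'
#' @param samples data.frame from \code{\link{sampleSmiles}} (raw samples
#'   including invalid ones).
#' @param train,test \linkS4class{MoleculeSet} objects.
#' @param npModel optional \linkS4class{NpScoreModel}.
#' @return an \linkS4class{EvaluationReport}.
#' @export
evaluateLibrary <- function(samples, train, test, npModel = NULL) {
  stopifnot(is.data.frame(samples), is(train, "MoleculeSet"),
            is(test, "MoleculeSet"))
  validity <- mean(samples$valid)
  valid_smi <- samples$smiles[samples$valid]
  uniq <- unique(valid_smi)
  uniqueness <- if (length(valid_smi)) length(uniq) / length(valid_smi)
                else 0
  novel <- setdiff(uniq, train@smiles)
  novelty <- if (length(uniq)) length(novel) / length(uniq) else 0
  rr <- reproductionRate(uniq, test)
  sn <- scaffoldNovelty(moleculeSetQuiet(novel), train, test)
  hist <- if (length(sn$gen) && length(sn$train))
    nnSimilarity(sn$gen, sn$train)$histogram
  else data.frame(bin_left = numeric(0), bin_right = numeric(0),
                  count = integer(0))
  npms <- c(NA_real_, NA_real_)
  if (!is.null(npModel) && length(uniq)) {
    sc <- npLikeness(uniq, npModel)
    npms <- c(mean(sc), stats::sd(sc))
  }
  new("EvaluationReport", validityRate = validity,
      uniquenessRate = uniqueness, noveltyRate = novelty,
      rp = rr$rp, rpp = rr$rpp,
      scaffoldCounts = sn$counts, similarityHistogram = hist,
      npLikenessMeanSd = npms)
}

# MoleculeSet from canonical SMILES that may be empty.
moleculeSetQuiet <- function(smi, name = "set") {
  new("MoleculeSet", smiles = smi,
      heavyAtoms = if (length(smi)) heavyAtomCount(smi) else integer(0),
      sourceId = as.character(seq_along(smi)), name = name)
}

#' Write an evaluation report to disk
#'
#' Scalar metrics as JSON and TSV, the similarity histogram as TSV
#' (\code{bin_left}, \code{bin_right}, \code{count}).
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param dir output directory (created if needed).
#' @export
writeReport <- function(report, dir) {
  stopifnot(is(report, "EvaluationReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- list(
    validity_rate = report@validityRate,
    uniqueness_rate = report@uniquenessRate,
    novelty_rate = report@noveltyRate,
    rp = report@rp, rpp = report@rpp,
    scaffold_new = unname(report@scaffoldCounts["new"]),
    scaffold_shared_train = unname(report@scaffoldCounts["shared_train"]),
    scaffold_shared_test_only =
      unname(report@scaffoldCounts["shared_test_only"]),
    np_likeness_mean = report@npLikenessMeanSd[1],
    np_likeness_sd = report@npLikenessMeanSd[2]
  )
  jsonlite::write_json(scalars, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.table(
    data.frame(metric = names(scalars),
               value = unlist(lapply(scalars, function(v)
                 if (is.null(v)) NA else v))),
    file.path(dir, "report.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(report@similarityHistogram,
                     file.path(dir, "similarity_histogram.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
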