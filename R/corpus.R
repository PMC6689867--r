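# Corpus curation and I/O. The curation rules mirror the preparation of the
# biogenic training library: drop molecules that fail to parse, contain a
# metal element (anything outside the organic subset), have fewer than 10 or
# more than 100 non-hydrogen atoms, and collapse duplicates by canonical
# SMILES.

#' Read a SMILES file
#'
#' Plain-text, one molecule per line, optional whitespace-separated id
#' after the SMILES (SMILES-first dialect). UTF-8.
#'
#' @param path file path.
#' @return data.frame with columns \code{smiles} and \code{id}.
#' @export
readSmiles <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  smi <- sub("[ \t].*$", "", lines)
  id <- ifelse(grepl("[ \t]", lines), sub("^[^ \t]+[ \t]+", "", lines),
               as.character(seq_along(lines)))
  data.frame(smiles = smi, id = id, stringsAsFactors = FALSE)
}

#' Write molecules to a SMILES file
#'
#' @param x a \linkS4class{MoleculeSet} or character vector of SMILES.
#' @param path output path.
#' @param ids optional id column; defaults to the set's source tags.
#' @export
writeSmiles <- function(x, path, ids = NULL) {
  if (is(x, "MoleculeSet")) {
    if (is.null(ids)) ids <- x@sourceId
    x <- x@smiles
  }
  lines <- if (is.null(ids)) x else paste(x, ids)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a MoleculeSet from already-canonical SMILES
#'
#' Thin constructor used internally and by tests; input must already be
#' canonical and duplicate-free (use \code{\link{curateCorpus}} for raw
#' input).
#' @param smiles canonical SMILES.
#' @param name set label.
#' @param sourceId per-molecule tags.
#' @return a \linkS4class{MoleculeSet}.
#' @export
moleculeSet <- function(smiles, name = "corpus",
                        sourceId = as.character(seq_along(smiles))) {
  new("MoleculeSet", smiles = as.character(smiles),
      heavyAtoms = heavyAtomCount(smiles), sourceId = sourceId,
      name = name)
}

#' Curate a raw SMILES corpus
#'
#' Canonicalizes every input, then drops (in this order of attribution)
#' unparseable strings, molecules containing a metal element, molecules
#' with fewer than \code{minHeavy} or more than \code{maxHeavy} heavy
#' atoms (bounds inclusive: 10 and 100 heavy atoms survive the defaults),
#' and duplicate canonical SMILES. Rejection counts are stored in the
#' result's \code{metadata$curation} together with the toolkit version.
#'
#' @param raw character vector of SMILES, or a data.frame from
#'   \code{\link{readSmiles}}.
#' @param name label for the curated set.
#' @param minHeavy,maxHeavy inclusive heavy-atom bounds.
#' @return a \linkS4class{MoleculeSet}.
#' @export
curateCorpus <- function(raw, name = "corpus", minHeavy = 10L,
                         maxHeavy = 100L) {
  if (is.data.frame(raw)) {
    ids <- raw$id
    raw <- raw$smiles
  } else {
    ids <- as.character(seq_along(raw))
  }
  stopifnot(length(raw) > 0)
  can <- canonicalizeSmiles(raw)
  unparseable <- is.na(can)

  metal <- rep(FALSE, length(raw))
  too_small <- rep(FALSE, length(raw))
  too_large <- rep(FALSE, length(raw))
  ok <- which(!unparseable)
  if (length(ok)) {
    ha <- heavyAtomCount(can[ok])
    metal[ok] <- containsMetal(can[ok])
    too_small[ok] <- !metal[ok] & ha < minHeavy
    too_large[ok] <- !metal[ok] & ha > maxHeavy
  }
  keep <- !unparseable & !metal & !too_small & !too_large
  dup <- keep & duplicated(can)
  keep <- keep & !dup

  counts <- c(input = length(raw), unparseable = sum(unparseable),
              metal = sum(metal), too_small = sum(too_small),
              too_large = sum(too_large), duplicate = sum(dup),
              kept = sum(keep))
  if (!any(keep))
    stop("curation removed every molecule (input ", length(raw), ")")

  obj <- new("MoleculeSet", smiles = can[keep],
             heavyAtoms = heavyAtomCount(can[keep]),
             sourceId = ids[keep], name = name,
             metadata = list(curation = list(
               counts = counts, toolkit = toolkitVersion(),
               minHeavy = minHeavy, maxHeavy = maxHeavy)))
  obj
}

#' Randomly partition a molecule set into k folds
#'
#' Deterministic for a fixed seed. Fold sizes differ by at most one
#' (remainder molecules are spread one per fold).
#'
#' @param x a \linkS4class{MoleculeSet}.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return a \linkS4class{FoldSplit}.
#' @export
splitFolds <- function(x, k = 5L, seed = 1L) {
  stopifnot(is(x, "MoleculeSet"), k >= 2L)
  n <- length(x@smiles)
  if (k > n) stop("k (", k, ") exceeds corpus size (", n, ")")
  # molecules in shuffled order are dealt round-robin over the folds
  perm <- withSeed(seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- rep(seq_len(k), length.out = n)
  fs <- lapply(seq_len(k), function(f) {
    idx <- which(fold_of == f)
    new("MoleculeSet", smiles = x@smiles[idx], heavyAtoms = x@heavyAtoms[idx],
        sourceId = x@sourceId[idx], name = paste0(x@name, "_fold", f))
  })
  new("FoldSplit", folds = fs, seed = as.integer(seed))
}

#' Merge molecule sets
#'
#' Union of the given sets (duplicates collapsed, first occurrence kept).
#' @param ... \linkS4class{MoleculeSet} objects.
#' @param name label of the union.
#' @return a \linkS4class{MoleculeSet}.
#' @export
mergeSets <- function(..., name = "merged") {
  sets <- list(...)
  smi <- unlist(lapply(sets, function(s) s@smiles))
  ha <- unlist(lapply(sets, function(s) s@heavyAtoms))
  id <- unlist(lapply(sets, function(s) s@sourceId))
  keep <- !duplicated(smi)
  new("MoleculeSet", smiles = smi[keep], heavyAtoms = as.integer(ha[keep]),
      sourceId = id[keep], name = name)
}

# Run code under a temporary RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- synthetic fixture corpus ---------------------------------------------

# Stochastic SMILES grammar for self-contained test corpora: alkyl chains,
# branches, aryl/heteroaryl and saturated rings, ether/amine/carbonyl
# substitutions, optional tetrahedral stereocentres ([C@H]/[C@@H] with four
# distinct substituents) and charged bracket atoms ([NH3+], [O-]).
fixtureFragments <- function(with_stereo, with_brackets) {
  rings <- c("c1ccccc1", "c1ccncc1", "c1ccco1", "c1cccs1", "C1CCCCC1",
             "C1CCNCC1", "c1ccc2ccccc2c1", "CC1=CC(=O)Oc2ccccc21")
  chains <- c("CC", "CCC", "CCCC", "CC(C)C", "CCO", "CCN", "CC=C",
              "CCS", "CC(=O)C", "CC(=O)O", "CC(=O)N", "C#N", "COC")
  stereo <- c("C[C@H](N)C(=O)O", "C[C@@H](O)CC", "O[C@H]1CCC[C@@H]1O",
              "C[C@H](CC)CO")
  brackets <- c("CC[NH3+]", "CC(=O)[O-]", "C[N+](C)(C)C")
  list(rings = rings, chains = chains,
       stereo = if (with_stereo) stereo else character(0),
       brackets = if (with_brackets) brackets else character(0))
}

generateOneFixture <- function(frag) {
  pool <- c(frag$chains, frag$rings, frag$stereo, frag$brackets)
  wts <- c(rep(3, length(frag$chains)), rep(4, length(frag$rings)),
           rep(2, length(frag$stereo)), rep(1, length(frag$brackets)))
  k <- sample(2:4, 1)
  parts <- sample(pool, k, replace = TRUE, prob = wts)
  # chain fragments together with single bonds; occasionally branch
  out <- parts[1]
  for (p in parts[-1]) {
    if (stats::runif(1) < 0.3) out <- paste0(out, "(", p, ")")
    else out <- paste0(out, p)
  }
  out
}

#' Generate a synthetic fixture corpus
#'
#' Builds \code{n} unique, valid, curated molecules from a small stochastic
#' SMILES grammar (alkyl/aryl skeletons, heteroatoms, ring systems,
#' optional tetrahedral stereocentres and charged bracket atoms). Every
#' emitted molecule survives \code{\link{curateCorpus}} with the default
#' size filters. Deterministic for a fixed seed.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @param withStereo include stereocentre-bearing fragments?
#' @param withBrackets include charged bracket-atom fragments?
#' @param name label of the returned set.
#' @return a \linkS4class{MoleculeSet} of \code{n} canonical SMILES.
#' @export
fixtureCorpus <- function(n, seed = 1L, withStereo = TRUE,
                          withBrackets = TRUE, name = "fixture") {
  stopifnot(n >= 1)
  frag <- fixtureFragments(withStereo, withBrackets)
  seen <- character(0)
  withSeed(seed, {
    attempts <- 0L
    max_attempts <- 200L + 60L * n
    while (length(seen) < n && attempts < max_attempts) {
      batch <- max(64L, n - length(seen))
      raw <- vapply(seq_len(batch), function(i) generateOneFixture(frag),
                    character(1))
      attempts <- attempts + batch
      can <- canonicalizeSmiles(raw)
      can <- can[!is.na(can)]
      ha <- heavyAtomCount(can)
      can <- can[ha >= 10L & ha <= 100L]
      seen <- unique(c(seen, can))
    }
  })
  if (length(seen) < n)
    stop("fixture generation exhausted attempt budget (got ",
         length(seen), "/", n, ")")
  smi <- seen[seq_len(n)]
  new("MoleculeSet", smiles = smi, heavyAtoms = heavyAtomCount(smi),
      sourceId = paste0("fix", seq_len(n)), name = name)
}
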