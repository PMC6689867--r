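# Bridge to the chemistry toolkit (OpenBabel). Canonicalization and parse
# validation go through the obabel executable in one batch call per request:
# each input line carries its index as the molecule title, so invalid lines
# (which OpenBabel drops) map back to NA without any per-molecule overhead.

obabelPath <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("obabel executable not found on PATH")
  p
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the toolkit's canonical form with stereochemistry
#' preserved. Strings that do not parse yield \code{NA}. Canonicalization
#' is idempotent; canonical strings are the basis of every set operation in
#' the package and are toolkit-version-sensitive (see
#' \code{\link{toolkitVersion}}).
#'
#' @param x character vector of SMILES.
#' @return character vector, same length, \code{NA} where unparseable.
#' @export
canonicalizeSmiles <- function(x) {
  stopifnot(is.character(x))
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & nzchar(x) & !grepl("[\t\n ]", x)
  if (!any(ok)) return(out)
  idx <- which(ok)
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".smi")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(x[idx], seq_along(idx)), fin, useBytes = TRUE)
  system2(obabelPath(), c("-ismi", fin, "-ocan", "-O", fout, "-e"),
          stdout = FALSE, stderr = FALSE)
  res <- if (file.exists(fout)) readLines(fout, encoding = "UTF-8") else character()
  if (length(res)) {
    parts <- strsplit(res, "\t", fixed = TRUE)
    keep <- lengths(parts) == 2L
    parts <- parts[keep]
    smi <- vapply(parts, `[[`, character(1), 1L)
    pos <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
    good <- !is.na(pos) & nzchar(smi)
    out[idx[pos[good]]] <- smi[good]
  }
  out
}

#' Test whether SMILES strings parse as molecules
#'
#' @param x character vector of SMILES.
#' @return logical vector; \code{TRUE} where the toolkit parses the string.
#' @export
isValidSmiles <- function(x) !is.na(canonicalizeSmiles(x))

#' Chemistry toolkit version string
#'
#' Canonical SMILES differ between toolkit versions, so logs of every
#' experiment record this.
#' @return single string, e.g. \code{"Open Babel 3.1.1"}.
#' @export
toolkitVersion <- function() {
  v <- tryCatch(
    system2(obabelPath(), "-V", stdout = TRUE, stderr = FALSE),
    error = function(e) "Open Babel (version unknown)")
  sub(" -- .*", "", v[1])
}

#' Count molecules matching a SMARTS substructure
#'
#' Substructure matching via the toolkit's SMARTS engine. Used for
#' chemotype counting (e.g. coumarin derivatives in a generated library).
#'
#' @param x a \linkS4class{MoleculeSet} or character vector of SMILES.
#' @param smarts a single SMARTS pattern. Note the toolkit's aromaticity
#'   perception applies: e.g. coumarin's pyranone ring is perceived
#'   aromatic, so aromatic-form patterns should be used for fused
#'   heteroaromatics (see \code{\link{coumarinSmarts}}).
#' @return logical vector: which molecules contain the substructure.
#' @export
matchesSmarts <- function(x, smarts) {
  if (is(x, "MoleculeSet")) x <- x@smiles
  stopifnot(is.character(smarts), length(smarts) == 1L, nzchar(smarts))
  if (!length(x)) return(logical(0))
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".smi")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  ferr <- tempfile(fileext = ".txt")
  on.exit(unlink(ferr), add = TRUE)
  writeLines(paste(x, seq_along(x)), fin, useBytes = TRUE)
  # stderr redirection makes system2 go through a shell: quote the pattern
  system2(obabelPath(),
          c("-ismi", fin, "-osmi", "-O", fout, "-e", "-s", shQuote(smarts)),
          stdout = FALSE, stderr = ferr)
  if (file.exists(ferr) &&
      any(grepl("SMARTS Error", readLines(ferr, warn = FALSE))))
    stop("invalid SMARTS pattern: ", smarts)
  out <- logical(length(x))
  if (file.exists(fout)) {
    res <- readLines(fout, encoding = "UTF-8")
    if (length(res)) {
      pos <- suppressWarnings(as.integer(sub(".*\t", "", res)))
      out[pos[!is.na(pos)]] <- TRUE
    }
  }
  out
}

#' @rdname matchesSmarts
#' @return \code{chemotypeCount}: integer count of matching molecules.
#' @export
chemotypeCount <- function(x, smarts) {
  ok <- matchesSmarts(x, smarts)
  sum(ok)
}

#' SMARTS pattern for the coumarin (2H-chromen-2-one) chemotype
#'
#' Expressed in aromatic form because the toolkit perceives the fused
#' benzopyranone as aromatic.
#' @return single SMARTS string.
#' @export
coumarinSmarts <- function() "o1c(=O)ccc2ccccc12"
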