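# Molecular graph layer built on top of the tokenizer: converts a (toolkit-
# canonical) SMILES string into an atom/bond graph. Powers heavy-atom
# counting, metal detection, atom-centered circular fragments (ECFP-style
# fingerprints and the NP-likeness score), framework-scaffold extraction,
# rotatable-bond and aromatic-ring-system counts. Validity checking and
# canonicalization stay with the toolkit (see R/chem.R); this parser only
# needs to read well-formed SMILES.

ORGANIC_SET <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
                 "Se", "Br", "I")
ALIPHATIC_ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")
BOND_CHARS <- c("-" = 1L, "=" = 2L, "#" = 3L, "$" = 4L, ":" = 1L,
                "/" = 1L, "\\" = 1L)

parseBracketAtom <- function(tok) {
  m <- regmatches(tok, regexec(
    "^\\[([0-9]*)([A-Z][a-z]?|[a-z][a-z]?|\\*)(@{1,2})?(H([0-9]*))?(\\+[0-9]*|-[0-9]*|\\++|-+)?\\]$",
    tok))[[1]]
  if (!length(m)) stop("cannot parse bracket atom token: ", tok)
  sym <- m[3]
  aromatic <- grepl("^[a-z]", sym)
  element <- if (sym == "*") "*" else
    paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  hfield <- m[5]
  nH <- if (!nzchar(hfield)) 0L
        else if (nzchar(m[6])) as.integer(m[6]) else 1L
  chg <- m[7]
  charge <- if (!nzchar(chg)) 0L
  else if (chg %in% c("+", "++", "+++")) nchar(chg)
  else if (grepl("^\\+[0-9]+$", chg)) as.integer(substring(chg, 2))
  else if (chg %in% c("-", "--", "---")) -nchar(chg)
  else -as.integer(substring(chg, 2))
  list(element = element, aromatic = aromatic, charge = as.integer(charge),
       nH = nH, stereo = nzchar(m[4]))
}

#' Parse a SMILES string into a molecular graph
#'
#' Intended for toolkit-canonical SMILES; returns the heavy-atom graph
#' (explicit bracket hydrogens are recorded as a count, not as nodes).
#'
#' @param x a single SMILES string.
#' @return list with \code{atoms} (data.frame: element, aromatic, charge,
#'   nH, stereo) and \code{bonds} (data.frame: i, j, order, aromatic).
#' @export
smilesGraph <- function(x) {
  toks <- tokenizeSmiles(x)[[1]]
  element <- character(0); aromatic <- logical(0); charge <- integer(0)
  nH <- integer(0); stereo <- logical(0)
  bi <- integer(0); bj <- integer(0); border <- integer(0)
  barom <- logical(0)
  prev <- NA_integer_
  stack <- integer(0)
  pending <- NA_integer_  # explicit bond symbol awaiting the next atom
  pending_arom <- FALSE
  ring <- list()  # closure digit -> c(atom, order, arom)

  addAtom <- function(el, arom, chg, h, st) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    nH[length(nH) + 1L] <<- h
    stereo[length(stereo) + 1L] <<- st
    length(element)
  }
  addBond <- function(a, b, ord, arom) {
    bi[length(bi) + 1L] <<- a; bj[length(bj) + 1L] <<- b
    border[length(border) + 1L] <<- ord
    barom[length(barom) + 1L] <<- arom
  }
  connect <- function(a) {
    force(a)  # a's constructor grows the atom vectors; run it first
    if (!is.na(prev)) {
      if (!is.na(pending)) {
        addBond(prev, a, pending, pending_arom)
      } else if (aromatic[prev] && aromatic[a]) {
        addBond(prev, a, 1L, TRUE)
      } else {
        addBond(prev, a, 1L, FALSE)
      }
    }
    pending <<- NA_integer_; pending_arom <<- FALSE
    prev <<- a
  }
  closeRing <- function(key) {
    if (!is.null(ring[[key]])) {
      op <- ring[[key]]
      a <- op$atom
      ord <- if (!is.na(pending)) pending else op$order
      arom <- if (!is.na(pending)) pending_arom
              else if (!is.na(op$order)) op$arom
              else (aromatic[a] && aromatic[prev])
      if (is.na(ord)) ord <- 1L
      addBond(a, prev, ord, arom)
      ring[[key]] <<- NULL
    } else {
      ring[[key]] <<- list(atom = prev, order = pending,
                           arom = pending_arom)
    }
    pending <<- NA_integer_; pending_arom <<- FALSE
  }

  for (tok in toks) {
    if (tok %in% ALIPHATIC_ORGANIC) {
      connect(addAtom(tok, FALSE, 0L, NA_integer_, FALSE))
    } else if (tok %in% AROMATIC_ORGANIC) {
      connect(addAtom(toupper(tok), TRUE, 0L, NA_integer_, FALSE))
    } else if (tok == "*") {
      connect(addAtom("*", FALSE, 0L, NA_integer_, FALSE))
    } else if (startsWith(tok, "[")) {
      at <- parseBracketAtom(tok)
      connect(addAtom(at$element, at$aromatic, at$charge, at$nH, at$stereo))
    } else if (tok %in% names(BOND_CHARS)) {
      pending <- unname(BOND_CHARS[tok])
      pending_arom <- tok == ":"
    } else if (grepl("^[0-9]$", tok)) {
      closeRing(tok)
    } else if (startsWith(tok, "%")) {
      closeRing(substring(tok, 2))
    } else if (tok == "(") {
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES: ", x)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ".") {
      prev <- NA_integer_
    } else {
      stop("unsupported SMILES token '", tok, "' in: ", x)
    }
  }
  if (length(ring)) stop("unclosed ring bond in SMILES: ", x)
  list(
    atoms = data.frame(element = element, aromatic = aromatic,
                       charge = charge, nH = nH, stereo = stereo,
                       stringsAsFactors = FALSE),
    bonds = data.frame(i = bi, j = bj, order = border, aromatic = barom)
  )
}

#' Heavy-atom count of SMILES strings
#'
#' Number of non-hydrogen atoms (bracket \code{[H]} atoms excluded).
#' @param x character vector of SMILES.
#' @return integer vector.
#' @export
heavyAtomCount <- function(x) {
  vapply(x, function(s) {
    g <- smilesGraph(s)
    sum(g$atoms$element != "H")
  }, integer(1), USE.NAMES = FALSE)
}

#' Does a molecule contain a metal element?
#'
#' Any atom outside the organic subset
#' \{H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I\} counts as a metal
#' (the standard organic-subset convention; wildcards count too).
#' @param x character vector of SMILES.
#' @return logical vector.
#' @export
containsMetal <- function(x) {
  vapply(x, function(s) {
    g <- smilesGraph(s)
    !all(g$atoms$element %in% ORGANIC_SET)
  }, logical(1), USE.NAMES = FALSE)
}

# ---- atom-centered circular fragments -------------------------------------

HASH_MOD <- 2147483647

hashInts <- function(ints) {
  h <- 7
  for (x in ints) h <- (h * 31 + (x %% HASH_MOD)) %% HASH_MOD
  h
}

bondCode <- function(order, aromatic) ifelse(aromatic, 5L, order)

adjacencyList <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[k]; j <- g$bonds$j[k]
      bc <- bondCode(g$bonds$order[k], g$bonds$aromatic[k])
      adj[[i]] <- rbind(adj[[i]], c(j, bc))
      adj[[j]] <- rbind(adj[[j]], c(i, bc))
    }
  }
  adj
}

#' Atom-centered circular fragment identifiers
#'
#' Morgan-style iterated neighbourhood hashing. The radius-0 identifier
#' encodes (element, aromaticity, charge, degree, bond-order sum); each
#' iteration folds in the sorted (bond type, neighbour identifier) pairs.
#' Returns all identifiers for radii \code{0..radius} over all atoms.
#'
#' @param x a single SMILES string or a graph from \code{\link{smilesGraph}}.
#' @param radius maximum neighbourhood radius in bonds.
#' @param unique drop duplicate identifiers within the molecule?
#' @return integer-valued numeric vector of fragment identifiers.
#' @export
atomFragments <- function(x, radius = 2L, unique = TRUE) {
  g <- if (is.character(x)) smilesGraph(x) else x
  n <- nrow(g$atoms)
  if (n == 0L) return(numeric(0))
  adj <- adjacencyList(g)
  elno <- match(g$atoms$element, c(ORGANIC_SET, "*"), nomatch = 99L)
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a), integer(1))
  bsum <- vapply(adj, function(a) if (is.null(a)) 0L else sum(a[, 2]),
                 integer(1))
  code <- vapply(seq_len(n), function(a) {
    hashInts(c(elno[a], as.integer(g$atoms$aromatic[a]), g$atoms$charge[a],
               deg[a], bsum[a]))
  }, numeric(1))
  out <- code
  r <- 0L
  while (r < radius) {
    r <- r + 1L
    code <- vapply(seq_len(n), function(a) {
      nb <- adj[[a]]
      if (is.null(nb)) return(hashInts(c(r, code[a])))
      pairs <- cbind(nb[, 2], code[nb[, 1]])
      ord <- order(pairs[, 1], pairs[, 2])
      hashInts(c(r, code[a], as.vector(t(pairs[ord, , drop = FALSE]))))
    }, numeric(1))
    out <- c(out, code)
  }
  if (unique) unique(out) else out
}

#' Hashed circular fingerprint (ECFP-style)
#'
#' Circular fingerprint of the given radius hashed onto \code{nbits} bits;
#' radius 3 with 2048 bits corresponds to the usual ECFP6 setting.
#'
#' @param x SMILES string or \code{\link{smilesGraph}} result.
#' @param radius neighbourhood radius (3 = ECFP6).
#' @param nbits fingerprint length.
#' @return sorted integer vector of on-bit positions (0-based).
#' @export
ecfpBits <- function(x, radius = 3L, nbits = 2048L) {
  frags <- atomFragments(x, radius = radius, unique = TRUE)
  sort(unique(as.integer(frags %% nbits)))
}

#' Tanimoto similarity of two bit sets
#'
#' @param a,b integer vectors of on-bit positions.
#' @return \code{|a intersect b| / |a union b|}; 1 when both are empty.
#' @export
tanimoto <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# ---- framework scaffolds ---------------------------------------------------

# Atom indices retained by the framework scaffold: ring atoms, linker atoms
# between rings, plus atoms attached to those by a double/triple bond
# (e.g. exocyclic carbonyl oxygens on a linker).
scaffoldAtomSet <- function(g) {
  n <- nrow(g$atoms)
  if (n == 0L || nrow(g$bonds) == 0L) return(integer(0))
  keep <- rep(TRUE, n)
  deg <- function() {
    d <- integer(n)
    for (k in seq_len(nrow(g$bonds))) {
      if (keep[g$bonds$i[k]] && keep[g$bonds$j[k]]) {
        d[g$bonds$i[k]] <- d[g$bonds$i[k]] + 1L
        d[g$bonds$j[k]] <- d[g$bonds$j[k]] + 1L
      }
    }
    d
  }
  repeat {
    d <- deg()
    prune <- keep & d <= 1L
    if (!any(prune)) break
    keep[prune] <- FALSE
  }
  core <- which(keep)
  if (!length(core)) return(integer(0))
  # add back multiply-bonded substituents of core atoms
  extra <- integer(0)
  for (k in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[k] >= 2L && !g$bonds$aromatic[k]) {
      i <- g$bonds$i[k]; j <- g$bonds$j[k]
      if (keep[i] && !keep[j]) extra <- c(extra, j)
      if (keep[j] && !keep[i]) extra <- c(extra, i)
    }
  }
  sort(unique(c(core, extra)))
}

# Minimal V2000 MOL block for an induced subgraph; aromatic bonds written
# as type 4, charges via M CHG, explicit hydrogens materialized so that
# aromatic NH survives the round trip through the toolkit.
molBlock <- function(g, atoms, title = "") {
  idx <- match(seq_len(nrow(g$atoms)), atoms)
  sub <- g$atoms[atoms, , drop = FALSE]
  bonds <- g$bonds[g$bonds$i %in% atoms & g$bonds$j %in% atoms, ,
                   drop = FALSE]
  nh <- ifelse(is.na(sub$nH), 0L, sub$nH)
  natoms <- nrow(sub) + sum(nh)
  nbonds <- nrow(bonds) + sum(nh)
  lines <- c(title, "  molgru", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     natoms, nbonds))
  for (a in seq_len(nrow(sub))) {
    el <- if (sub$element[a] == "*") "A" else sub$element[a]
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, el))
  }
  for (h in seq_len(sum(nh))) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, "H"))
  }
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      ord <- if (bonds$aromatic[k]) 4L else bonds$order[k]
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                idx[bonds$i[k]], idx[bonds$j[k]], ord))
    }
  }
  hpos <- nrow(sub)
  for (a in seq_len(nrow(sub))) {
    if (nh[a] > 0L) for (q in seq_len(nh[a])) {
      hpos <- hpos + 1L
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", a, hpos, 1L))
    }
  }
  chg <- which(sub$charge != 0L)
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, sub$charge[chg]),
                                    collapse = "")))
  }
  c(lines, "M  END")
}

#' Framework scaffold of molecules
#'
#' Ring systems plus the linkers connecting them, with side chains removed
#' (substituents attached by a double or triple bond to a retained atom are
#' kept). Acyclic molecules map to the empty-scaffold marker \code{""}.
#' Scaffolds are returned as canonical SMILES; stereochemistry is dropped
#' (side-chain removal invalidates most stereocentres).
#'
#' @param x a \linkS4class{MoleculeSet} or character vector of SMILES.
#' @return character vector of canonical scaffold SMILES (\code{""} for
#'   acyclic molecules, \code{NA} if the scaffold fails to re-parse).
#' @export
extractScaffold <- function(x) {
  if (is(x, "MoleculeSet")) x <- x@smiles
  out <- rep("", length(x))
  if (!length(x)) return(out)
  graphs <- lapply(x, smilesGraph)
  sets <- lapply(graphs, scaffoldAtomSet)
  nonempty <- which(lengths(sets) > 0L)
  if (!length(nonempty)) return(out)
  sdf <- unlist(lapply(nonempty, function(k) {
    g <- graphs[[k]]
    g$atoms$stereo <- FALSE
    c(molBlock(g, sets[[k]], title = as.character(k)), "$$$$")
  }))
  fin <- tempfile(fileext = ".sdf")
  fout <- tempfile(fileext = ".smi")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(sdf, fin, useBytes = TRUE)
  system2(obabelPath(), c("-isdf", fin, "-ocan", "-O", fout, "-e"),
          stdout = FALSE, stderr = FALSE)
  out[nonempty] <- NA_character_
  if (file.exists(fout)) {
    res <- readLines(fout, encoding = "UTF-8")
    parts <- strsplit(res, "\t", fixed = TRUE)
    parts <- parts[lengths(parts) == 2L]
    for (p in parts) {
      k <- suppressWarnings(as.integer(p[2]))
      if (!is.na(k) && nzchar(p[1])) out[k] <- p[1]
    }
  }
  out
}

# ---- simple 2D descriptors from the graph ---------------------------------

#' Rotatable-bond count
#'
#' Single, non-aromatic, acyclic bonds between two non-terminal heavy
#' atoms (the simple topological definition; amide bonds are not excluded).
#' @param x character vector of SMILES.
#' @return integer vector.
#' @export
rotatableBonds <- function(x) {
  vapply(x, function(s) {
    g <- smilesGraph(s)
    if (!nrow(g$bonds)) return(0L)
    gr <- igraph::graph_from_edgelist(
      as.matrix(g$bonds[, c("i", "j")]), directed = FALSE)
    if (igraph::vcount(gr) < nrow(g$atoms))
      gr <- igraph::add_vertices(gr, nrow(g$atoms) - igraph::vcount(gr))
    deg <- igraph::degree(gr)
    br <- igraph::bridges(gr)  # acyclic bonds are exactly the bridges
    cnt <- 0L
    for (e in br) {
      k <- as.integer(e)
      i <- g$bonds$i[k]; j <- g$bonds$j[k]
      if (g$bonds$order[k] == 1L && !g$bonds$aromatic[k] &&
          deg[i] >= 2L && deg[j] >= 2L)
        cnt <- cnt + 1L
    }
    cnt
  }, integer(1), USE.NAMES = FALSE)
}

#' Aromatic ring-system count
#'
#' Number of connected components of the subgraph induced by aromatic
#' bonds: fused aromatic rings count once (e.g. naphthalene = 1).
#' @param x character vector of SMILES.
#' @return integer vector.
#' @export
aromaticRingSystems <- function(x) {
  vapply(x, function(s) {
    g <- smilesGraph(s)
    ab <- g$bonds[g$bonds$aromatic, , drop = FALSE]
    if (!nrow(ab)) return(0L)
    gr <- igraph::graph_from_edgelist(as.matrix(ab[, c("i", "j")]),
                                      directed = FALSE)
    sum(igraph::components(gr)$csize > 1L)
  }, integer(1), USE.NAMES = FALSE)
}
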