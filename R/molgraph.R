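## Molecular-graph substrate. Structure parsing and writing is delegated to
## ChemmineR (SDF) and ChemmineOB/OpenBabel (SMILES <-> molblock, canonical
## SMILES, aromaticity perception); graph surgery (fragmentation, joining)
## operates on the MolGraph data frames directly.

.emptyAtoms <- function() {
  data.frame(elem = character(), charge = integer(), iso = integer(),
             arom = logical(), hcount = integer(),
             x = numeric(), y = numeric(), z = numeric(),
             stringsAsFactors = FALSE)
}

.emptyBonds <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = integer())
}

.newMolGraph <- function(atoms, bonds) {
  rownames(atoms) <- NULL
  if (nrow(bonds)) rownames(bonds) <- NULL
  new("MolGraph", atoms = atoms, bonds = bonds)
}

## legacy V2000 atom-line charge codes
.CHG_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
               `5` = -1L, `6` = -2L, `7` = -3L)

## ---- molblock writing ------------------------------------------------------

.mLines <- function(tag, idx, val) {
  keep <- which(val != 0L)
  if (!length(keep)) return(character())
  chunks <- split(keep, ceiling(seq_along(keep) / 8))
  vapply(chunks, function(ix) {
    paste0("M  ", tag, sprintf("%3d", length(ix)),
           paste0(sprintf("%4d%4d", idx[ix], val[ix]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

.graphToMolblock <- function(g, title = "") {
  a <- g@atoms; b <- g@bonds
  hdr <- c(title, "  ScaffoldSpace", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b))
  ## legacy atom-line charge codes: +3..+1 -> 1..3, -1..-3 -> 5..7
  chgCode <- c(1L, 2L, 3L, 5L, 6L, 7L)[match(a$charge, c(3L, 2L, 1L, -1L, -2L, -3L))]
  chgCode[is.na(chgCode)] <- 0L
  atomLines <- sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$elem, chgCode)
  bondLines <- if (nrow(b)) sprintf("%3d%3d%3d  0  0  0  0", b$a1, b$a2, b$order) else character()
  props <- c(.mLines("CHG", seq_len(nrow(a)), a$charge),
             .mLines("ISO", seq_len(nrow(a)), a$iso))
  paste(c(hdr, counts, atomLines, bondLines, props, "M  END", "$$$$"), collapse = "\n")
}

.graphsToSdfText <- function(graphs, titles = as.character(seq_along(graphs))) {
  paste0(paste(mapply(.graphToMolblock, graphs, titles), collapse = "\n"), "\n")
}

## ---- molblock reading (via ChemmineR, supplemented with M CHG / M ISO) ----

.recordToGraph <- function(sdf, rawLines) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  elem <- sub("_.*$", "", rownames(ab))
  chgcode <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else integer(n)
  charge <- .CHG_CODE[as.character(chgcode)]
  charge[is.na(charge)] <- 0L
  iso <- integer(n)
  ## M CHG supersedes the legacy atom-line codes; M ISO is the only isotope
  ## channel OpenBabel writes. ChemmineR drops both, so scan the raw record.
  for (ln in grep("^M  (CHG|ISO)", rawLines, value = TRUE)) {
    tag <- substr(ln, 4, 6)
    k <- as.integer(substr(ln, 7, 9))
    if (tag == "CHG") charge <- integer(n)  # reset legacy once M CHG present
    for (j in seq_len(k)) {
      off <- 10 + (j - 1) * 8
      ai <- as.integer(substr(ln, off, off + 3))
      vv <- as.integer(substr(ln, off + 4, off + 7))
      if (is.na(ai) || ai < 1 || ai > n) next
      if (tag == "CHG") charge[ai] <- vv else iso[ai] <- vv
    }
  }
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) .emptyBonds() else
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  ## the metal "R" or "*" dummy: ChemmineR keeps element text as-is
  elem[elem %in% c("R", "R#")] <- "*"
  atoms <- data.frame(elem = elem, charge = charge, iso = iso,
                      arom = FALSE, hcount = 0L,
                      x = as.numeric(ab[, 1]), y = as.numeric(ab[, 2]),
                      z = as.numeric(ab[, 3]), stringsAsFactors = FALSE)
  .newMolGraph(atoms, bonds)
}

## ChemmineR's validity check refuses bond-less records (e.g. water); parse
## those directly off the fixed-width V2000 atom block
.fallbackRecordToGraph <- function(rawLines) {
  n <- as.integer(substr(rawLines[4], 1, 3))
  nb <- as.integer(substr(rawLines[4], 4, 6))
  if (is.na(n) || n < 1 || is.na(nb) || nb != 0) stop("unsupported record")
  al <- rawLines[5:(4 + n)]
  atoms <- data.frame(
    elem = trimws(substr(al, 32, 34)), charge = 0L, iso = 0L,
    arom = FALSE, hcount = 0L,
    x = as.numeric(substr(al, 1, 10)), y = as.numeric(substr(al, 11, 20)),
    z = as.numeric(substr(al, 21, 30)), stringsAsFactors = FALSE)
  g <- .newMolGraph(atoms, .emptyBonds())
  for (ln in grep("^M  CHG", rawLines, value = TRUE)) {
    k <- as.integer(substr(ln, 7, 9))
    for (j in seq_len(k)) {
      off <- 10 + (j - 1) * 8
      ai <- as.integer(substr(ln, off, off + 3))
      g@atoms$charge[ai] <- as.integer(substr(ln, off + 4, off + 7))
    }
  }
  g
}

.sdfFileToGraphs <- function(path) {
  str <- ChemmineR::read.SDFstr(path)
  set <- suppressWarnings(as(str, "SDFset"))
  ok <- ChemmineR::validSDF(set)
  raw <- str@a
  for (i in which(!ok)) {
    g <- tryCatch(.fallbackRecordToGraph(raw[[i]]), error = function(e) NULL)
    if (!is.null(g)) {
      ok[i] <- NA  # marker: use fallback graph
      attr(ok, sprintf("fb%d", i)) <- g
    }
  }
  graphs <- lapply(which(ok | is.na(ok)), function(i) {
    if (is.na(ok[i])) attr(ok, sprintf("fb%d", i)) else
      .recordToGraph(set[[i]], raw[[i]])
  })
  valid <- ok | is.na(ok)
  valid[is.na(valid)] <- TRUE
  list(graphs = graphs, sdfset = set, raw = raw, valid = valid)
}

.sdfTextToGraphs <- function(text) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(text, tf)
  .sdfFileToGraphs(tf)
}

## ---- perception (aromaticity + implicit hydrogens) via OpenBabel -----------

.AROM_SET <- c("c", "n", "o", "s", "p", "se", "as", "b")

## Tag every atom with a unique isotope, round-trip molblock -> SMILES through
## OpenBabel, and read per-atom aromaticity and hydrogen counts off the
## bracket atoms. The isotope value maps each token back to its atom index,
## so no atom-order assumption is needed.
.annotatePerception <- function(graphs) {
  if (!length(graphs)) return(graphs)
  offset <- 500L
  tagged <- lapply(graphs, function(g) {
    g@atoms$iso <- offset + seq_len(nrow(g@atoms))
    g
  })
  txt <- .graphsToSdfText(tagged, titles = as.character(seq_along(tagged)))
  out <- ChemmineOB::convertFormat("SDF", "SMI", txt)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    gi <- suppressWarnings(as.integer(parts[2]))
    if (is.na(gi)) next
    toks <- regmatches(parts[1], gregexpr("\\[[^]]+\\]", parts[1]))[[1]]
    for (tok in toks) {
      inner <- substr(tok, 2, nchar(tok) - 1)
      m <- regmatches(inner, regexec("^([0-9]+)(se|as|[A-Z][a-z]?|[a-z]|\\*)", inner))[[1]]
      if (length(m) < 3) next
      ai <- as.integer(m[2]) - offset
      if (is.na(ai) || ai < 1 || ai > nrow(graphs[[gi]]@atoms)) next
      graphs[[gi]]@atoms$arom[ai] <- m[3] %in% .AROM_SET
      hm <- regmatches(inner, regexec("H([0-9]*)", inner))[[1]]
      hc <- if (length(hm)) { if (nzchar(hm[2])) as.integer(hm[2]) else 1L } else 0L
      graphs[[gi]]@atoms$hcount[ai] <- hc
    }
  }
  graphs
}

## ---- SMILES parsing / writing ---------------------------------------------

#' Parse SMILES strings into molecular graphs
#'
#' Conversion goes through OpenBabel, so aromatic perception, implicit
#' hydrogens, formal charges and isotope labels (used for attachment-point
#' ports) follow its model. Unparseable entries yield \code{NULL}.
#'
#' @param smiles character vector of SMILES.
#' @return list of \linkS4class{MolGraph} (or NULL per failed entry).
#' @export
parseSmiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- vector("list", length(smiles))
  if (!length(smiles)) return(out)
  input <- paste(paste0(smiles, " ", seq_along(smiles)), collapse = "\n")
  sdfTxt <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", input),
                     error = function(e) "")
  if (nzchar(sdfTxt)) {
    parsed <- .sdfTextToGraphs(sdfTxt)
    heads <- vapply(parsed$raw[parsed$valid][seq_along(parsed$graphs)],
                    function(r) r[1], character(1))
    idx <- suppressWarnings(as.integer(heads))
    graphs <- .annotatePerception(parsed$graphs)
    for (j in seq_along(graphs)) if (!is.na(idx[j])) out[[idx[j]]] <- graphs[[j]]
  }
  ## OpenBabel aborts a batch at the first invalid entry; retry the
  ## unconverted tail one by one so one bad SMILES cannot mask the rest
  missing <- which(vapply(out, is.null, logical(1)))
  if (length(missing) && length(smiles) > 1) {
    for (i in missing) out[i] <- parseSmiles(smiles[i])  # keeps NULL slots
  }
  out
}

.parseSmilesOne <- function(smi) {
  g <- parseSmiles(smi)[[1]]
  if (is.null(g)) stop(sprintf("unparseable SMILES: '%s'", smi))
  g
}

#' Canonical SMILES of molecular graphs
#'
#' Canonicalization is constitutional: coordinates are dropped before
#' conversion so no stereodescriptors are perceived from 3D geometry.
#' Scaffolds and fragments are 2D substructures throughout this package,
#' and identity/deduplication must not depend on the pose a structure was
#' observed in.
#'
#' @param graphs list of \linkS4class{MolGraph} (or a single MolGraph).
#' @return character vector; NA where canonicalization failed.
#' @export
canonicalSmiles <- function(graphs) {
  if (is(graphs, "MolGraph")) graphs <- list(graphs)
  if (!length(graphs)) return(character())
  graphs <- lapply(graphs, function(g) {
    g@atoms$x <- 0; g@atoms$y <- 0; g@atoms$z <- 0
    g
  })
  txt <- .graphsToSdfText(graphs, titles = as.character(seq_along(graphs)))
  out <- ChemmineOB::convertFormat("SDF", "CAN", txt)
  res <- rep(NA_character_, length(graphs))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  for (ln in lines[nzchar(lines)]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    gi <- suppressWarnings(as.integer(parts[2]))
    if (!is.na(gi) && nzchar(parts[1])) res[gi] <- parts[1]
  }
  res
}

#' Canonicalize SMILES strings
#'
#' Constitutional canonicalization: stereodescriptors are stripped first
#' (see \code{\link{canonicalSmiles}}).
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES; NA where parsing failed.
#' @export
canonicalizeSmiles <- function(smiles) {
  if (!length(smiles)) return(character())
  smiles <- gsub("@|/|\\\\", "", smiles)
  input <- paste(paste0(smiles, " ", seq_along(smiles)), collapse = "\n")
  out <- ChemmineOB::convertFormat("SMI", "CAN", input)
  res <- rep(NA_character_, length(smiles))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  for (ln in lines[nzchar(lines)]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    gi <- suppressWarnings(as.integer(parts[2]))
    if (!is.na(gi) && nzchar(parts[1])) res[gi] <- parts[1]
  }
  res
}

## ---- graph utilities -------------------------------------------------------

.toIgraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g@bonds)) g@bonds[, c("a1", "a2")] else data.frame(a1 = integer(), a2 = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(g@atoms))))
}

.neighborList <- function(g) {
  n <- nrow(g@atoms)
  nb <- vector("list", n)
  for (i in seq_len(nrow(g@bonds))) {
    a <- g@bonds$a1[i]; b <- g@bonds$a2[i]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  nb
}

## logical vector over bonds: TRUE if the bond lies in a ring
.ringBondMask <- function(g) {
  if (!nrow(g@bonds)) return(logical())
  ig <- .toIgraph(g)
  br <- igraph::bridges(ig)
  mask <- rep(TRUE, nrow(g@bonds))
  if (length(br)) mask[as.integer(br)] <- FALSE
  mask
}

.ringAtomMask <- function(g) {
  mask <- rep(FALSE, nrow(g@atoms))
  rb <- .ringBondMask(g)
  if (any(rb)) {
    mask[unique(c(g@bonds$a1[rb], g@bonds$a2[rb]))] <- TRUE
  }
  mask
}

.componentsOf <- function(nAtoms, bonds) {
  ig <- igraph::graph_from_data_frame(
    d = if (nrow(bonds)) bonds[, c("a1", "a2")] else data.frame(a1 = integer(), a2 = integer()),
    directed = FALSE, vertices = data.frame(name = seq_len(nAtoms)))
  igraph::components(ig)$membership
}

## Smallest ring through each ring bond (a standard SSSR approximation good
## for the molecule sizes this package handles). Returns list of atom-index
## vectors, deduplicated.
.smallestRings <- function(g) {
  rb <- which(.ringBondMask(g))
  if (!length(rb)) return(list())
  ig <- .toIgraph(g)
  rings <- list()
  seen <- character()
  for (bi in rb) {
    u <- g@bonds$a1[bi]; v <- g@bonds$a2[bi]
    ig2 <- igraph::delete_edges(ig, bi)
    sp <- suppressWarnings(igraph::shortest_paths(ig2, from = u, to = v)$vpath[[1]])
    if (!length(sp)) next
    ring <- sort(as.integer(igraph::as_ids(sp)))
    key <- paste(ring, collapse = ",")
    if (!key %in% seen) { seen <- c(seen, key); rings[[length(rings) + 1]] <- ring }
  }
  rings
}

## extract the induced subgraph on `atomIdx`, capping each severed bond in
## `cutBonds` (row indices into g@bonds) with a dummy atom of the same order
.fragmentGraph <- function(g, atomIdx, cutBonds, portIso = NULL) {
  atomIdx <- sort(atomIdx)
  remap <- match(seq_len(nrow(g@atoms)), atomIdx)
  atoms <- g@atoms[atomIdx, , drop = FALSE]
  keepB <- g@bonds$a1 %in% atomIdx & g@bonds$a2 %in% atomIdx
  bonds <- g@bonds[keepB, , drop = FALSE]
  if (nrow(bonds)) {
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  }
  portAtoms <- integer()
  for (k in seq_along(cutBonds)) {
    bi <- cutBonds[k]
    a <- g@bonds$a1[bi]; b <- g@bonds$a2[bi]
    inside <- if (a %in% atomIdx) a else b
    dummy <- data.frame(elem = "*", charge = 0L,
                        iso = if (!is.null(portIso)) portIso[k] else 0L,
                        arom = FALSE, hcount = 0L,
                        x = g@atoms$x[if (a %in% atomIdx) b else a],
                        y = g@atoms$y[if (a %in% atomIdx) b else a],
                        z = g@atoms$z[if (a %in% atomIdx) b else a],
                        stringsAsFactors = FALSE)
    atoms <- rbind(atoms, dummy)
    bonds <- rbind(bonds, data.frame(a1 = remap[inside], a2 = nrow(atoms),
                                     order = g@bonds$order[bi]))
    portAtoms <- c(portAtoms, nrow(atoms))
  }
  gg <- .newMolGraph(atoms, bonds)
  attr(gg, "atomMap") <- atomIdx
  attr(gg, "portAtoms") <- portAtoms
  gg
}

.dummyAtoms <- function(g) which(g@atoms$elem == "*")

## join two graphs by fusing dummy `da` of g1 with dummy `db` of g2:
## the bond is formed between the dummies' neighbors, dummies are dropped
.fuseAt <- function(g1, da, g2, db, order = 1L) {
  nb1 <- .neighborList(g1)[[da]]
  nb2 <- .neighborList(g2)[[db]]
  if (length(nb1) != 1 || length(nb2) != 1)
    stop("attachment dummies must have exactly one neighbor")
  n1 <- nrow(g1@atoms)
  atoms <- rbind(g1@atoms, g2@atoms)
  b2 <- g2@bonds
  if (nrow(b2)) { b2$a1 <- b2$a1 + n1; b2$a2 <- b2$a2 + n1 }
  bonds <- rbind(g1@bonds, b2,
                 data.frame(a1 = nb1, a2 = nb2 + n1, order = order))
  drop <- c(da, db + n1)
  keep <- setdiff(seq_len(nrow(atoms)), drop)
  remap <- match(seq_len(nrow(atoms)), keep)
  atoms <- atoms[keep, , drop = FALSE]
  bonds <- bonds[!(bonds$a1 %in% drop | bonds$a2 %in% drop), , drop = FALSE]
  if (nrow(bonds)) { bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2] }
  gg <- .newMolGraph(atoms, bonds)
  attr(gg, "origin") <- c(attr(g1, "origin") %||% rep("g1", n1),
                          attr(g2, "origin") %||% rep("g2", nrow(g2@atoms)))[keep]
  gg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.STD_VALENCE <- c("B" = 3, "C" = 4, "N" = 3, "O" = 2, "F" = 1, "Si" = 4,
                  "P" = 5, "S" = 6, "Cl" = 1, "Br" = 1, "I" = 3, "*" = 8,
                  "H" = 1)

## maximum bonding capacity given element and formal charge
.maxValence <- function(elem, charge) {
  base <- .STD_VALENCE[elem]
  base[is.na(base)] <- 6
  adj <- ifelse(elem %in% c("N", "O", "P", "S"), charge,
                ifelse(elem == "C", -abs(charge), 0))
  pmax(base + adj, 0)
}

## TRUE if no heavy-atom bond-order sum exceeds the element's capacity
.validValence <- function(g) {
  n <- nrow(g@atoms)
  deg <- numeric(n)
  for (i in seq_len(nrow(g@bonds))) {
    deg[g@bonds$a1[i]] <- deg[g@bonds$a1[i]] + g@bonds$order[i]
    deg[g@bonds$a2[i]] <- deg[g@bonds$a2[i]] + g@bonds$order[i]
  }
  all(deg <= .maxValence(g@atoms$elem, g@atoms$charge))
}

## heavy-atom count excluding attachment dummies
.heavyCount <- function(g) sum(g@atoms$elem != "*")

#' @describeIn MolGraph-class number of atoms (including attachment dummies)
#' @param object,x a MolGraph
#' @export
setMethod("length", "MolGraph", function(x) nrow(x@atoms))

setMethod("show", "MolGraph", function(object) {
  cat(sprintf("MolGraph: %d atoms (%d heavy), %d bonds\n",
              nrow(object@atoms), .heavyCount(object), nrow(object@bonds)))
})

setMethod("show", "Pose", function(object) {
  cat(sprintf("Pose '%s': %d atoms, %d bonds, %d properties\n",
              object@structureId, nrow(object@atoms), nrow(object@bonds),
              length(object@properties)))
})

setMethod("show", "Scaffold", function(object) {
  cat(sprintf("Scaffold [%s] ports={%s}\n", object@smiles,
              paste(object@ports, collapse = ",")))
})
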