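## Primary-scaffold extraction: the smallest retrosynthetic fragment with at
## least one attachment point and at least one ring whose atoms realize all
## key pharmacophore points of the matched hypothesis; plus neutralization,
## crude-set aggregation, and peripheral fragment harvesting.

#' Neutralize formal charges in SMILES
#'
#' Sets the formal charge of every charged atom to zero wherever the charge
#' can be removed by a hydrogen-count adjustment without violating standard
#' valence; atoms where this is impossible (e.g. quaternary nitrogen) keep
#' their charge and are flagged.
#'
#' @param smiles character vector.
#' @return data.frame with columns \code{smiles} (neutralized canonical
#'   SMILES) and \code{unneutralizable} (TRUE if any charge had to stay).
#' @export
neutralizeSmiles <- function(smiles) {
  graphs <- parseSmiles(smiles)
  bad <- vapply(graphs, is.null, logical(1))
  if (any(bad)) stop(sprintf("unparseable SMILES: %s",
                             paste(smiles[bad], collapse = ", ")))
  flags <- logical(length(graphs))
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    chg <- which(g@atoms$charge != 0L)
    if (!length(chg)) next
    ordSum <- numeric(nrow(g@atoms))
    for (i in seq_len(nrow(g@bonds))) {
      ordSum[g@bonds$a1[i]] <- ordSum[g@bonds$a1[i]] + g@bonds$order[i]
      ordSum[g@bonds$a2[i]] <- ordSum[g@bonds$a2[i]] + g@bonds$order[i]
    }
    for (i in chg) {
      if (ordSum[i] <= .maxValence(g@atoms$elem[i], 0L)) {
        g@atoms$charge[i] <- 0L
      } else {
        flags[k] <- TRUE
      }
    }
    graphs[[k]] <- g
  }
  data.frame(smiles = canonicalSmiles(graphs), unneutralizable = flags,
             stringsAsFactors = FALSE)
}

## classify a point cloud centroid against the hypothesis: "left" if nearer
## to the closest HYD key point than to the closest polar (HBD/HBA) key
## point, else "right" (ties break right)
.classifySide <- function(centroid, hyp) {
  keyPts <- Filter(function(p) p@key, hyp@points)
  dHyd <- suppressWarnings(min(vapply(
    Filter(function(p) p@ptype == "HYD", keyPts),
    function(p) sqrt(sum((centroid - p@center)^2)), numeric(1))))
  dPol <- suppressWarnings(min(vapply(
    Filter(function(p) p@ptype %in% c("HBD", "HBA"), keyPts),
    function(p) sqrt(sum((centroid - p@center)^2)), numeric(1))))
  if (!is.finite(dHyd) || !is.finite(dPol))
    stop("hypothesis lacks the HYD and polar key points needed for side classification")
  list(side = if (dHyd < dPol) "left" else "right", dHyd = dHyd, dPol = dPol)
}

#' Extract the primary scaffold of a docked pose
#'
#' The primary scaffold is the smallest BRICS fragment (counting heavy
#' atoms, attachment points excluded) among all retrosynthetic
#' intermediates that (i) has at least one attachment point, (ii) contains
#' at least one ring, and (iii) contains every atom realizing a key
#' pharmacophore point of the matched hypothesis. Ties break to the
#' lexicographically smallest canonical SMILES.
#'
#' Port labels on the extracted scaffold follow the side classification of
#' the fragment lost at each cut: port 1 for a hydrophobic-side (left)
#' periphery, port 2 for a polar-side (right) one, port 3 auxiliary.
#'
#' @param pose a \linkS4class{Pose}.
#' @param hyp a \linkS4class{PharmacophoreHypothesis}; poses that do not
#'   match all key points yield NULL.
#' @param maxCuts maximum simultaneous BRICS cuts (default 6).
#' @param definitions feature definitions for matching.
#' @return a \linkS4class{Scaffold} with attributes \code{atomMap} (parent
#'   atom indices), \code{cutBonds} (parent bond rows, ordered as the port
#'   labels), \code{portLabels}, and \code{keyAtoms}; or NULL (with a
#'   logged message) when no fragment qualifies.
#' @export
extractPrimaryScaffold <- function(pose, hyp, maxCuts = 6L,
                                   definitions = featureDefinitions()) {
  rep <- matchHypothesis(pose, hyp, definitions)
  if (!rep@allKeyMatched) {
    message(sprintf("pose %s: key points not matched", pose@structureId))
    return(NULL)
  }
  cands <- bricsFragments(pose, maxCuts)
  ok <- Filter(function(cc) {
    cc$nPorts >= 1 && cc$hasRing && all(rep@keyAtoms %in% cc$atomMap)
  }, cands)
  if (!length(ok)) {
    message(sprintf("pose %s: no ring-bearing key-covering fragment",
                    pose@structureId))
    return(NULL)
  }
  nh <- vapply(ok, `[[`, numeric(1), "nHeavy")
  smi <- vapply(ok, `[[`, character(1), "smiles")
  best <- ok[[order(nh, smi)[1]]]
  ## label ports by the side of the lost periphery at each severed bond
  g <- pose
  cutB <- best$cutBonds
  sideInfo <- lapply(cutB, function(bi) {
    a <- g@bonds$a1[bi]; b <- g@bonds$a2[bi]
    outside <- if (a %in% best$atomMap) b else a
    ## periphery = component of pose minus scaffold atoms containing `outside`
    keep <- setdiff(seq_len(nrow(g@atoms)), best$atomMap)
    mem2 <- .componentsOf(nrow(g@atoms),
                          g@bonds[g@bonds$a1 %in% keep & g@bonds$a2 %in% keep, ,
                                  drop = FALSE])
    piece <- which(mem2 == mem2[outside] & seq_len(nrow(g@atoms)) %in% keep)
    centroid <- colMeans(as.matrix(g@atoms[piece, c("x", "y", "z"), drop = FALSE]))
    .classifySide(centroid, hyp)
  })
  sides <- vapply(sideInfo, `[[`, character(1), "side")
  dHyd <- vapply(sideInfo, `[[`, numeric(1), "dHyd")
  ## deterministic label assignment: left ports get 1 (nearest-HYD first),
  ## right ports get 2, overflow gets the remaining labels in order
  ord <- order(sides != "left", dHyd)
  labels <- integer(length(cutB))
  pool <- 1:3
  for (k in ord) {
    want <- if (sides[k] == "left") 1L else 2L
    labels[k] <- if (want %in% pool) want else min(pool)
    pool <- setdiff(pool, labels[k])
  }
  frag <- .fragmentGraph(pose, best$atomMap, cutB, portIso = labels)
  smiles <- canonicalSmiles(frag)
  sc <- new("Scaffold", smiles = smiles, ports = sort(labels))
  attr(sc, "atomMap") <- best$atomMap
  attr(sc, "cutBonds") <- cutB
  attr(sc, "portLabels") <- labels
  attr(sc, "keyAtoms") <- rep@keyAtoms
  sc
}

#' Aggregate primary scaffolds into a crude scaffold set
#'
#' Neutralizes, canonicalizes and deduplicates scaffold records, drops
#' members with more than 3 attachment points, and merges provenance per
#' canonical scaffold.
#'
#' @param records data.frame with columns \code{scaffold} (SMILES),
#'   \code{molecule_id}, \code{experiment_id}.
#' @return a \linkS4class{CrudeScaffoldSet}; rejected-record count in
#'   \code{attr(, "rejected")}.
#' @export
collectCrudeScaffolds <- function(records) {
  if (!nrow(records)) {
    return(new("CrudeScaffoldSet",
               table = data.frame(scaffold = character(), nPorts = integer()),
               provenance = list()))
  }
  stopifnot(all(c("scaffold", "molecule_id", "experiment_id") %in% names(records)))
  neut <- neutralizeSmiles(records$scaffold)
  graphs <- parseSmiles(neut$smiles)
  nPorts <- vapply(graphs, function(g) if (is.null(g)) NA_integer_ else
    length(.dummyAtoms(g)), integer(1))
  keep <- !is.na(nPorts) & nPorts >= 1 & nPorts <= 3
  rejected <- sum(!keep)
  smi <- neut$smiles[keep]
  ids <- records[keep, c("molecule_id", "experiment_id"), drop = FALSE]
  uniq <- !duplicated(smi)
  tab <- data.frame(scaffold = smi[uniq], nPorts = nPorts[keep][uniq],
                    stringsAsFactors = FALSE)
  prov <- lapply(tab$scaffold, function(s) {
    ids[smi == s, , drop = FALSE]
  })
  out <- new("CrudeScaffoldSet", table = tab, provenance = prov)
  attr(out, "rejected") <- rejected
  out
}

setMethod("show", "CrudeScaffoldSet", function(object) {
  cat(sprintf("CrudeScaffoldSet: %d unique scaffolds (%s)\n",
              nrow(object@table),
              paste(sprintf("%d-port: %d", 1:3,
                            tabulate(object@table$nPorts, 3)), collapse = ", ")))
})

#' @describeIn CrudeScaffoldSet-class number of unique scaffolds
#' @param x a CrudeScaffoldSet
#' @export
setMethod("length", "CrudeScaffoldSet", function(x) nrow(x@table))

#' Scaffold table accessor
#'
#' @param x a \linkS4class{CrudeScaffoldSet}.
#' @return data.frame with scaffold SMILES and port counts.
#' @export
scaffoldTable <- function(x) x@table

#' Harvest peripheral fragments of a pose around its scaffold
#'
#' Excises the scaffold atoms and returns the remaining connected pieces,
#' each capped with one attachment point at the severed bond. A piece
#' severed at more than one bond (fused periphery) violates the
#' exactly-one-port invariant and is excluded with a warning. Sides are
#' classified geometrically: left if the piece centroid (parent-pose
#' coordinates) is nearer the HYD key point than the nearest polar
#' (HBD/HBA) key point, else right (ties break right).
#'
#' @param pose a \linkS4class{Pose}.
#' @param scaffoldAtoms integer vector of pose atom indices covered by the
#'   scaffold (e.g. \code{attr(scaffold, "atomMap")} from
#'   \code{\link{extractPrimaryScaffold}}).
#' @param hyp a \linkS4class{PharmacophoreHypothesis} with HYD and polar key
#'   points.
#' @return list of \linkS4class{FragmentRecord}.
#' @export
extractPeripheralFragments <- function(pose, scaffoldAtoms, hyp) {
  n <- nrow(pose@atoms)
  if (!length(scaffoldAtoms) || any(scaffoldAtoms < 1 | scaffoldAtoms > n))
    stop("scaffoldAtoms is not a valid atom map into the pose")
  keyPts <- Filter(function(p) p@key, hyp@points)
  if (!any(vapply(keyPts, function(p) p@ptype == "HYD", logical(1))) ||
      !any(vapply(keyPts, function(p) p@ptype %in% c("HBD", "HBA"), logical(1))))
    stop("hypothesis lacks the HYD and polar key points needed for side classification")
  keep <- setdiff(seq_len(n), scaffoldAtoms)
  if (!length(keep)) return(list())
  memb <- .componentsOf(n, pose@bonds[pose@bonds$a1 %in% keep &
                                        pose@bonds$a2 %in% keep, , drop = FALSE])
  out <- list()
  for (pc in unique(memb[keep])) {
    piece <- intersect(which(memb == pc), keep)
    sever <- which((pose@bonds$a1 %in% piece & pose@bonds$a2 %in% scaffoldAtoms) |
                     (pose@bonds$a2 %in% piece & pose@bonds$a1 %in% scaffoldAtoms))
    if (length(sever) != 1) {
      warning(sprintf("periphery with %d scaffold bonds excluded (pose %s)",
                      length(sever), pose@structureId))
      next
    }
    frag <- .fragmentGraph(pose, piece, sever)
    centroid <- colMeans(as.matrix(pose@atoms[piece, c("x", "y", "z"), drop = FALSE]))
    side <- .classifySide(centroid, hyp)$side
    out[[length(out) + 1]] <-
      new("FragmentRecord", smiles = canonicalSmiles(frag), side = side,
          sourceId = pose@structureId)
  }
  out
}

setMethod("show", "FragmentRecord", function(object) {
  cat(sprintf("FragmentRecord [%s] side=%s source=%s\n",
              object@smiles, object@side, object@sourceId))
})
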