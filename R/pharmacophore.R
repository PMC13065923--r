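## Pharmacophore feature perception on 3D poses and geometric matching
## against typed hypothesis points. Feature definitions are transparent
## graph predicates (documented below) rather than an opaque perception
## engine, and can be overridden per call.

#' Default pharmacophore feature definitions
#'
#' A minimal, documented catalogue mapping structural environments to
#' feature types, in the spirit of published pharmacophore definitions:
#' \describe{
#'   \item{HBD}{N or O bearing at least one hydrogen.}
#'   \item{HBA}{N or O with an available lone pair: excludes amide and
#'     sulfonamide nitrogens, aromatic N-H, and positively charged atoms.}
#'   \item{HYD}{maximal connected groups of hydrophobic atoms: carbons with
#'     no N/O/P neighbor, thioether sulfurs, and halogens on carbon.}
#'   \item{AROM}{aromatic rings, one feature per smallest ring, centroid at
#'     the ring center.}
#'   \item{POS/NEG}{formally charged atoms without an adjacent opposite
#'     charge (so zwitterionic motifs like nitro do not register).}
#' }
#' Each definition is a function of a \linkS4class{MolGraph} returning a
#' list of atom-index vectors; users may supply their own named list of
#' such functions to override or extend the catalogue.
#'
#' @return named list of definition functions.
#' @export
featureDefinitions <- function() {
  list(
    HBD = function(g) {
      idx <- which(g@atoms$elem %in% c("N", "O") & g@atoms$hcount >= 1)
      lapply(idx, identity)
    },
    HBA = function(g) {
      nb <- .neighborList(g)
      a <- g@atoms
      hasAcylNeighbor <- function(i) {
        any(vapply(nb[[i]], function(j) {
          if (!a$elem[j] %in% c("C", "S")) return(FALSE)
          any(g@bonds$order == 2 &
                ((g@bonds$a1 == j & a$elem[g@bonds$a2] == "O") |
                   (g@bonds$a2 == j & a$elem[g@bonds$a1] == "O")))
        }, logical(1)))
      }
      idx <- which(vapply(seq_len(nrow(a)), function(i) {
        if (!a$elem[i] %in% c("N", "O")) return(FALSE)
        if (a$charge[i] > 0) return(FALSE)
        if (a$elem[i] == "N") {
          if (a$arom[i] && a$hcount[i] > 0) return(FALSE)   # pyrrole-type
          if (hasAcylNeighbor(i)) return(FALSE)             # amide/sulfonamide
        }
        TRUE
      }, logical(1)))
      lapply(idx, identity)
    },
    HYD = function(g) {
      nb <- .neighborList(g)
      a <- g@atoms
      hyd <- vapply(seq_len(nrow(a)), function(i) {
        if (a$charge[i] != 0) return(FALSE)
        el <- a$elem[i]
        if (el == "C") return(!any(a$elem[nb[[i]]] %in% c("N", "O", "P")))
        if (el == "S") return(length(nb[[i]]) > 0 && all(a$elem[nb[[i]]] == "C"))
        if (el %in% c("F", "Cl", "Br", "I"))
          return(length(nb[[i]]) == 1 && a$elem[nb[[i]]] == "C")
        FALSE
      }, logical(1))
      idx <- which(hyd)
      if (!length(idx)) return(list())
      sub <- g@bonds[g@bonds$a1 %in% idx & g@bonds$a2 %in% idx, , drop = FALSE]
      memb <- .componentsOf(nrow(a), sub)
      comps <- split(seq_len(nrow(a)), memb)
      comps <- Filter(function(cc) all(cc %in% idx), comps)
      unname(comps)
    },
    AROM = function(g) {
      rings <- .smallestRings(g)
      Filter(function(r) all(g@atoms$arom[r]), rings)
    },
    POS = function(g) {
      nb <- .neighborList(g)
      idx <- which(g@atoms$charge > 0 &
                     !vapply(seq_len(nrow(g@atoms)),
                             function(i) any(g@atoms$charge[nb[[i]]] < 0),
                             logical(1)))
      lapply(idx, identity)
    },
    NEG = function(g) {
      nb <- .neighborList(g)
      idx <- which(g@atoms$charge < 0 &
                     !vapply(seq_len(nrow(g@atoms)),
                             function(i) any(g@atoms$charge[nb[[i]]] > 0),
                             logical(1)))
      lapply(idx, identity)
    }
  )
}

#' Perceive pharmacophore features on a pose
#'
#' @param pose a \linkS4class{Pose} (or any MolGraph with coordinates).
#' @param definitions named list of definition functions (see
#'   \code{\link{featureDefinitions}}).
#' @return list of feature instances, each a list with \code{ptype},
#'   \code{atoms} (indices into the pose) and \code{centroid} (unweighted
#'   mean of member-atom coordinates).
#' @export
perceiveFeatures <- function(pose, definitions = featureDefinitions()) {
  if (!length(definitions)) stop("empty feature definition set")
  xyz <- as.matrix(pose@atoms[, c("x", "y", "z")])
  out <- list()
  for (ptype in names(definitions)) {
    for (atoms in definitions[[ptype]](pose)) {
      atoms <- as.integer(atoms)
      if (!length(atoms)) next
      out[[length(out) + 1]] <- list(
        ptype = ptype, atoms = atoms,
        centroid = colMeans(xyz[atoms, , drop = FALSE]))
    }
  }
  out
}

#' Test one hypothesis point against perceived features
#'
#' A point is matched if some feature of the same type has its centroid
#' within Euclidean distance \code{radius} of the point center (boundary
#' inclusive). The best feature is the nearest such feature; ties break to
#' the lowest atom index for determinism.
#'
#' @param features list from \code{\link{perceiveFeatures}}.
#' @param point a \linkS4class{PharmacophorePoint}.
#' @return list with \code{matched}, \code{best} (feature or NULL),
#'   \code{distance}.
#' @export
pointMatched <- function(features, point) {
  cand <- Filter(function(f) f$ptype == point@ptype, features)
  if (!length(cand)) return(list(matched = FALSE, best = NULL, distance = NA_real_))
  d <- vapply(cand, function(f) sqrt(sum((f$centroid - point@center)^2)), numeric(1))
  ord <- order(d, vapply(cand, function(f) min(f$atoms), integer(1)))
  best <- cand[[ord[1]]]
  dist <- d[ord[1]]
  list(matched = dist <= point@radius, best = if (dist <= point@radius) best else NULL,
       distance = dist)
}

#' Match a pose against a pharmacophore hypothesis
#'
#' @param pose a \linkS4class{Pose}.
#' @param hyp a \linkS4class{PharmacophoreHypothesis}.
#' @param definitions feature definitions (see
#'   \code{\link{featureDefinitions}}).
#' @return a \linkS4class{MatchReport}; \code{keyAtoms} is the union of the
#'   best features' atoms over the matched key points.
#' @export
matchHypothesis <- function(pose, hyp, definitions = featureDefinitions()) {
  feats <- perceiveFeatures(pose, definitions)
  res <- lapply(hyp@points, function(p) pointMatched(feats, p))
  perPoint <- data.frame(
    ptype = vapply(hyp@points, function(p) p@ptype, character(1)),
    key = vapply(hyp@points, function(p) p@key, logical(1)),
    matched = vapply(res, function(r) r$matched, logical(1)),
    distance = vapply(res, function(r) r$distance, numeric(1)))
  keyIdx <- which(perPoint$key)
  allKey <- all(perPoint$matched[keyIdx])
  keyAtoms <- sort(unique(unlist(lapply(res[keyIdx], function(r)
    if (!is.null(r$best)) r$best$atoms else integer()))))
  new("MatchReport", perPoint = perPoint,
      bestFeatures = lapply(res, function(r) r$best),
      allKeyMatched = allKey, keyAtoms = as.integer(keyAtoms))
}

setMethod("show", "MatchReport", function(object) {
  cat(sprintf("MatchReport: %d/%d points matched, allKeyMatched=%s, %d key atoms\n",
              sum(object@perPoint$matched), nrow(object@perPoint),
              object@allKeyMatched, length(object@keyAtoms)))
})

#' Construct a pharmacophore point
#'
#' @param ptype feature type (HBD, HBA, HYD, AROM, POS, NEG).
#' @param center numeric xyz (Angstrom).
#' @param radius tolerance radius (Angstrom).
#' @param key mandatory-point flag.
#' @return a \linkS4class{PharmacophorePoint}.
#' @export
pharmacophorePoint <- function(ptype, center, radius, key = TRUE) {
  new("PharmacophorePoint", ptype = ptype, center = as.numeric(center),
      radius = as.numeric(radius), key = key)
}

#' Construct a pharmacophore hypothesis
#'
#' @param name hypothesis name.
#' @param points list of \linkS4class{PharmacophorePoint}.
#' @return a \linkS4class{PharmacophoreHypothesis}.
#' @export
pharmacophoreHypothesis <- function(name, points) {
  new("PharmacophoreHypothesis", name = name, points = points)
}
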