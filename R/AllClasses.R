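#' @import methods
NULL

#' Molecular graph
#'
#' Lightweight molecular graph used throughout the package: a data frame of
#' atoms (element, formal charge, isotope label, aromatic flag, implicit
#' hydrogen count, 3D coordinates in Angstrom) and a data frame of bonds
#' (atom indices and integer bond order, kekulized). Dummy atoms (element
#' \code{"*"}) mark attachment points; their isotope label carries the port
#' number.
#'
#' @slot atoms data.frame with columns \code{elem}, \code{charge},
#'   \code{iso}, \code{arom}, \code{hcount}, \code{x}, \code{y}, \code{z}.
#' @slot bonds data.frame with columns \code{a1}, \code{a2}, \code{order}.
#' @exportClass MolGraph
setClass("MolGraph", representation(atoms = "data.frame", bonds = "data.frame"))

setValidity("MolGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  need <- c("elem", "charge", "iso", "arom", "hcount", "x", "y", "z")
  if (!all(need %in% names(a))) return("atoms missing required columns")
  if (nrow(b) > 0) {
    if (!all(c("a1", "a2", "order") %in% names(b))) return("bonds missing columns")
    if (any(b$a1 < 1 | b$a1 > nrow(a) | b$a2 < 1 | b$a2 > nrow(a)))
      return("bond atom index out of range")
    if (any(b$a1 == b$a2)) return("self-bond")
  }
  TRUE
})

#' Docked pose
#'
#' A molecule with explicit 3D coordinates plus the screening-record
#' properties carried by its SD record. The unit of scaffold extraction.
#'
#' @slot structureId single string identifying the record.
#' @slot properties named character vector of SD properties, preserved
#'   verbatim.
#' @exportClass Pose
setClass("Pose", contains = "MolGraph",
         representation(structureId = "character", properties = "character"))

setValidity("Pose", function(object) {
  if (length(object@structureId) != 1 || !nzchar(object@structureId))
    return("structureId must be a non-empty string")
  if (nrow(object@atoms) && any(!is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
    return("non-finite coordinates")
  TRUE
})

#' Scaffold
#'
#' A 2D structure stored as canonical SMILES with 1-3 labeled attachment
#' points. Port 1 is the hydrophobic-side vector, port 2 the polar-side
#' vector, port 3 auxiliary. Attachment points are dummy atoms whose isotope
#' label encodes the port number (\code{[1*]}, \code{[2*]}, \code{[3*]}).
#'
#' @slot smiles canonical SMILES string.
#' @slot ports integer vector of port labels present, sorted.
#' @exportClass Scaffold
setClass("Scaffold", representation(smiles = "character", ports = "integer"))

setValidity("Scaffold", function(object) {
  if (length(object@smiles) != 1 || !nzchar(object@smiles)) return("empty smiles")
  n <- length(object@ports)
  if (n < 1 || n > 3) return("scaffold must have 1-3 ports")
  if (anyDuplicated(object@ports)) return("duplicate port labels")
  TRUE
})

#' Peripheral fragment record
#'
#' A monovalent fragment harvested from a virtual hit after excising its
#' scaffold, classified by the binding-site side it decorated.
#'
#' @slot smiles SMILES with exactly one attachment point.
#' @slot side \code{"left"} (hydrophobic subpocket) or \code{"right"}
#'   (polar subpocket).
#' @slot sourceId identifier of the pose it was harvested from.
#' @exportClass FragmentRecord
setClass("FragmentRecord",
         representation(smiles = "character", side = "character",
                        sourceId = "character"))

setValidity("FragmentRecord", function(object) {
  if (!object@side %in% c("left", "right")) return("side must be left or right")
  TRUE
})

#' Pharmacophore point
#'
#' A typed sphere in 3D space that a ligand feature of the same type must
#' occupy. Points flagged \code{key} form the mandatory subset that gates
#' scaffold acceptance.
#'
#' @slot ptype one of HBD, HBA, HYD, AROM, POS, NEG.
#' @slot center numeric xyz in Angstrom.
#' @slot radius tolerance radius in Angstrom, > 0.
#' @slot key logical flag.
#' @exportClass PharmacophorePoint
setClass("PharmacophorePoint",
         representation(ptype = "character", center = "numeric",
                        radius = "numeric", key = "logical"))

.FEATURE_TYPES <- c("HBD", "HBA", "HYD", "AROM", "POS", "NEG")

setValidity("PharmacophorePoint", function(object) {
  if (!object@ptype %in% .FEATURE_TYPES)
    return(sprintf("unknown feature type '%s'", object@ptype))
  if (length(object@center) != 3 || any(!is.finite(object@center)))
    return("center must be finite xyz")
  if (length(object@radius) != 1 || !is.finite(object@radius) || object@radius <= 0)
    return("radius must be > 0")
  TRUE
})

#' Pharmacophore hypothesis
#'
#' A named set of typed 3D points, at least one of which is flagged key.
#'
#' @slot name hypothesis name (e.g. a configuration label).
#' @slot points list of \linkS4class{PharmacophorePoint}.
#' @exportClass PharmacophoreHypothesis
setClass("PharmacophoreHypothesis",
         representation(name = "character", points = "list"))

setValidity("PharmacophoreHypothesis", function(object) {
  if (length(object@points) < 1) return("hypothesis needs at least one point")
  if (!all(vapply(object@points, is, logical(1), "PharmacophorePoint")))
    return("points must be PharmacophorePoint objects")
  if (!any(vapply(object@points, function(p) p@key, logical(1))))
    return("hypothesis needs at least one key point")
  TRUE
})

#' Match report
#'
#' Result of matching a pose against a hypothesis: per-point matched flags,
#' the best (nearest) matching feature per point, whether every key point
#' matched, and the union of atom indices realizing the matched key points.
#'
#' @slot perPoint data.frame with one row per hypothesis point: \code{ptype},
#'   \code{key}, \code{matched}, \code{distance}.
#' @slot bestFeatures list parallel to points: matched FeatureInstance-style
#'   list (\code{ptype}, \code{atoms}, \code{centroid}) or NULL.
#' @slot allKeyMatched logical.
#' @slot keyAtoms integer vector of pose atom indices.
#' @exportClass MatchReport
setClass("MatchReport",
         representation(perPoint = "data.frame", bestFeatures = "list",
                        allKeyMatched = "logical", keyAtoms = "integer"))

#' Crude scaffold set
#'
#' Deduplicated, neutralized scaffolds extracted from virtual hits, with
#' provenance back to the molecules and experiments they came from.
#'
#' @slot table data.frame with columns \code{scaffold} (canonical SMILES),
#'   \code{nPorts}.
#' @slot provenance list parallel to rows: data.frame with
#'   \code{molecule_id}, \code{experiment_id}.
#' @exportClass CrudeScaffoldSet
setClass("CrudeScaffoldSet",
         representation(table = "data.frame", provenance = "list"))

#' Enumeration specification
#'
#' An implicit Cartesian-product space: bivalent/monovalent scaffolds times a
#' left fragment set times a right fragment set, with optional per-scaffold
#' sample sizes and a seed.
#'
#' @slot scaffolds list of \linkS4class{Scaffold}.
#' @slot left,right character vectors of monovalent fragment SMILES.
#' @slot kLeft,kRight integer sample sizes (NA when full enumeration).
#' @slot seed integer seed for sampling.
#' @exportClass EnumerationSpec
setClass("EnumerationSpec",
         representation(scaffolds = "list", left = "character",
                        right = "character", kLeft = "integer",
                        kRight = "integer", seed = "integer"))

setValidity("EnumerationSpec", function(object) {
  if (!all(vapply(object@scaffolds, is, logical(1), "Scaffold")))
    return("scaffolds must be Scaffold objects")
  np <- vapply(object@scaffolds, function(s) length(s@ports), integer(1))
  if (any(np > 2)) return("enumeration requires mono- or bivalent scaffolds")
  if (!is.na(object@kLeft) && object@kLeft < 1) return("kLeft must be >= 1")
  if (!is.na(object@kRight) && object@kRight < 1) return("kRight must be >= 1")
  TRUE
})

#' Exact space count
#'
#' Cardinality of an implicit combinatorial space, carried as a decimal
#' big-integer string so counts beyond 2^63 never overflow, with a numeric
#' view for convenience.
#'
#' @slot nScaffolds,nLeft,nRight integer set sizes.
#' @slot total decimal string, exact.
#' @slot totalNumeric numeric view of total (exact below 2^53).
#' @exportClass SpaceCount
setClass("SpaceCount",
         representation(nScaffolds = "integer", nLeft = "integer",
                        nRight = "integer", total = "character",
                        totalNumeric = "numeric"))

#' Structural-alert rule set
#'
#' Named collection of substructure alerts (SMARTS) used for medicinal
#' chemistry filtering.
#'
#' @slot name set name (minimal, moderate, covalent, or custom).
#' @slot rules data.frame with columns \code{rule_id}, \code{pattern},
#'   \code{description}.
#' @exportClass AlertRuleSet
setClass("AlertRuleSet", representation(name = "character", rules = "data.frame"))

setValidity("AlertRuleSet", function(object) {
  r <- object@rules
  if (!all(c("rule_id", "pattern", "description") %in% names(r)))
    return("rules must have rule_id, pattern, description")
  if (anyDuplicated(r$rule_id)) return("duplicate rule_id")
  TRUE
})

#' Reward configuration
#'
#' Controls reward shaping for generative loops: plain pass-through of a
#' base scorer, constant reward value (CRV) equalization, or CRV plus a
#' similarity penalty against already-generated structures (SPAG).
#'
#' @slot mode one of \code{"default"}, \code{"CRV"}, \code{"CRV+SPAG"}.
#' @slot constantValue positive constant reward.
#' @slot penaltyWeight nonnegative SPAG weight.
#' @exportClass RewardConfig
setClass("RewardConfig",
         representation(mode = "character", constantValue = "numeric",
                        penaltyWeight = "numeric"))

setValidity("RewardConfig", function(object) {
  if (!object@mode %in% c("default", "CRV", "CRV+SPAG")) return("unknown mode")
  if (object@constantValue <= 0) return("constantValue must be > 0")
  if (object@penaltyWeight < 0) return("penaltyWeight must be >= 0")
  TRUE
})

#' Archive of generated structures
#'
#' Mutable fingerprint archive over previously accepted structures, backed
#' by an environment so insertion works by reference inside loops.
#'
#' @slot env environment with \code{fps} (list of fingerprint bit vectors)
#'   and \code{smiles} (character vector, insertion order).
#' @exportClass GenerationArchive
setClass("GenerationArchive", representation(env = "environment"))

#' Hit-rate estimate
#'
#' Virtual-hit-rate point estimate with a 95\% Wilson score interval, on the
#' percent scale.
#'
#' @slot hits,n integer counts.
#' @slot ratePercent point estimate, percent.
#' @slot ci95 numeric length-2 (lo, hi), percent.
#' @exportClass HitRateResult
setClass("HitRateResult",
         representation(hits = "numeric", n = "numeric",
                        ratePercent = "numeric", ci95 = "numeric"))

setValidity("HitRateResult", function(object) {
  if (object@n <= 0) return("n must be > 0")
  if (object@hits < 0 || object@hits > object@n) return("hits out of range")
  TRUE
})
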