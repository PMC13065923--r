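## Synthetic-data generation: toy pharmacophore hypotheses and 3D "docked"
## poses assembled from known scaffolds and known left/right fragments with
## planted ground truth, so every downstream stage is testable offline.
## Coordinates are constructed geometrically (feature atoms placed at the
## hypothesis centers, everything else parked in neutral regions) rather
## than physically embedded: downstream logic consumes coordinates only
## through distance tests, so chemical realism of the geometry is not
## required.

#' Toy pharmacophore hypothesis
#'
#' The default style emulates a three-point layout -- one hydrophobic
#' point, one acceptor, one donor, all key -- at fixed documented
#' coordinates: HYD at (0,0,0), HBA at (5,0,0), HBD at (7.5,2,0) Angstrom.
#'
#' @param style \code{"G1-like"} for the default 3-point layout,
#'   \code{"custom"} to supply \code{points}.
#' @param radii tolerance radius in Angstrom applied to the default points
#'   (recycled).
#' @param points for \code{style = "custom"}: list of
#'   \linkS4class{PharmacophorePoint} (at least one key point).
#' @return a \linkS4class{PharmacophoreHypothesis}.
#' @export
makeToyHypothesis <- function(style = c("G1-like", "custom"), radii = 1.0,
                              points = NULL) {
  style <- match.arg(style)
  if (style == "custom") {
    if (is.null(points)) stop("custom style requires points")
    return(new("PharmacophoreHypothesis", name = "custom", points = points))
  }
  radii <- rep_len(radii, 3)
  new("PharmacophoreHypothesis", name = "G1-like", points = list(
    pharmacophorePoint("HYD", c(0, 0, 0), radii[1], key = TRUE),
    pharmacophorePoint("HBA", c(5, 0, 0), radii[2], key = TRUE),
    pharmacophorePoint("HBD", c(7.5, 2, 0), radii[3], key = TRUE)))
}

#' Default fixture pools
#'
#' Six bivalent ring scaffolds bearing donor+acceptor motifs, eight
#' hydrophobic (ether-linked) left fragments and eight polar right
#' fragments. The ether/acyl junctions are retrosynthetically cleavable, so
#' a pose assembled from these pools can be taken apart again by the
#' fragmentation engine.
#'
#' @return character vector of SMILES.
#' @export
defaultScaffoldPool <- function() {
  c("[1*]c1cc(N)c(O)cc1[2*]",
    "[1*]c1c(N)cc(O)cc1[2*]",
    "[1*]c1cc(N)cc(O)c1[2*]",
    "[1*]c1nc(N)c(O)cc1[2*]",
    "[1*]c1cc(N)c(O)c(C)c1[2*]",
    "[1*]c1cc(N)c(O)c(Cl)c1[2*]")
}

#' @rdname defaultScaffoldPool
#' @export
defaultLeftPool <- function() {
  c("*OC", "*OCC", "*OCCC", "*OC(C)C", "*OCCCC", "*OCC(C)C", "*OC(C)CC",
    "*OCC(C)(C)C")
}

#' @rdname defaultScaffoldPool
#' @export
defaultRightPool <- function() {
  c("*C(=O)N", "*C(=O)O", "*C(=O)NC", "*NC(=O)C", "*C(=O)C", "*OC(=O)C",
    "*C(=O)NCC", "*NC(=O)CC")
}

## place k atoms on a circle of radius r around center (centroid = center)
.circleCoords <- function(k, center, r = 0.8, zstep = 0.05) {
  if (k == 1) return(matrix(center, nrow = 1))
  ang <- 2 * pi * (seq_len(k) - 1) / k
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang),
        center[3] + zstep * (seq_len(k) - mean(seq_len(k))))
}

## pick the designated feature instances realized by scaffold atoms:
## one single-atom HBD, one single-atom HBA (distinct atoms), and the
## largest HYD component; NULL when the combination is infeasible
.designateFeatures <- function(g, scAtoms) {
  defs <- featureDefinitions()
  hbd <- Filter(function(a) length(a) == 1 && all(a %in% scAtoms), defs$HBD(g))
  hba <- Filter(function(a) length(a) == 1 && all(a %in% scAtoms), defs$HBA(g))
  hyd <- Filter(function(a) all(a %in% scAtoms), defs$HYD(g))
  if (!length(hbd) || !length(hba) || !length(hyd)) return(NULL)
  for (d in hbd) for (a in hba) {
    if (d[[1]] != a[[1]]) {
      hydBest <- hyd[[order(-lengths(hyd))[1]]]
      return(list(hbd = d[[1]], hba = a[[1]], hyd = hydBest))
    }
  }
  NULL
}

#' Generate a synthetic docked-pose library with planted ground truth
#'
#' Each pose is scaffold + left + right joined at the ports, with synthetic
#' coordinates placing the scaffold's designated donor, acceptor and
#' hydrophobic-group atoms exactly at the hypothesis centers (plus Gaussian
#' noise of \code{noiseSd}), the left fragment displaced toward the HYD
#' point and the right fragment toward the polar points. Pool combinations
#' that cannot realize all key features on the scaffold are skipped with a
#' warning.
#'
#' @param n number of poses.
#' @param scaffoldPool,leftPool,rightPool SMILES pools (defaults ship with
#'   the package).
#' @param hyp a \linkS4class{PharmacophoreHypothesis} with HYD, HBA and HBD
#'   key points (default \code{makeToyHypothesis()}).
#' @param noiseSd coordinate noise standard deviation in Angstrom.
#' @param rngSeed integer seed; the library is reproducible under it.
#' @return list with \code{poses} (list of \linkS4class{Pose}) and
#'   \code{truth} (data.frame pose_id / scaffold / left / right, canonical
#'   SMILES).
#' @export
makeToyLibrary <- function(n, scaffoldPool = defaultScaffoldPool(),
                           leftPool = defaultLeftPool(),
                           rightPool = defaultRightPool(),
                           hyp = makeToyHypothesis(),
                           noiseSd = 0, rngSeed = 1L) {
  stopifnot(n >= 1, length(scaffoldPool) > 0, length(leftPool) > 0,
            length(rightPool) > 0)
  set.seed(rngSeed)
  scObjs <- lapply(scaffoldPool, asScaffold)
  scGraphs <- lapply(scObjs, .scaffoldGraph)
  leftGraphs <- lapply(leftPool, .fragmentOneDummy)
  rightGraphs <- lapply(rightPool, .fragmentOneDummy)
  leftCanon <- canonicalSmiles(leftGraphs)
  rightCanon <- canonicalSmiles(rightGraphs)
  ctr <- function(pt) Filter(function(p) p@ptype == pt & p@key, hyp@points)[[1]]@center
  cHYD <- ctr("HYD"); cHBA <- ctr("HBA"); cHBD <- ctr("HBD")
  parkS <- c(3.0, -3.0, 1.5)
  parkL <- cHYD + c(-2.5, 0, 0)
  parkR <- cHBD + c(2.0, 0.5, 0.5)
  poses <- list()
  truth <- list()
  badCombos <- 0L
  i <- 0L
  attempts <- 0L
  while (i < n && attempts < 20L * n) {
    attempts <- attempts + 1L
    si <- sample(length(scGraphs), 1)
    li <- sample(length(leftGraphs), 1)
    ri <- sample(length(rightGraphs), 1)
    scG <- scGraphs[[si]]
    attr(scG, "origin") <- rep("S", nrow(scG@atoms))
    lG <- leftGraphs[[li]]; attr(lG, "origin") <- rep("L", nrow(lG@atoms))
    rG <- rightGraphs[[ri]]; attr(rG, "origin") <- rep("R", nrow(rG@atoms))
    gg <- .joinGraphRaw(scG, scObjs[[si]]@ports, lG, rG)
    if (is.null(gg)) { badCombos <- badCombos + 1L; next }
    origin <- attr(gg, "origin")
    scAtoms <- which(origin == "S")
    des <- .designateFeatures(gg, scAtoms)
    if (is.null(des)) {
      warning(sprintf("pool combination cannot realize all key features: %s",
                      scaffoldPool[si]))
      badCombos <- badCombos + 1L
      next
    }
    i <- i + 1L
    ## park each part, then pin the designated feature atoms to the centers
    for (part in list(list("S", parkS), list("L", parkL), list("R", parkR))) {
      idx <- which(origin == part[[1]])
      if (!length(idx)) next
      xyz <- .circleCoords(length(idx), part[[2]], r = 0.9)
      gg@atoms$x[idx] <- xyz[, 1]; gg@atoms$y[idx] <- xyz[, 2]
      gg@atoms$z[idx] <- xyz[, 3]
    }
    hydXyz <- .circleCoords(length(des$hyd), cHYD, r = 0.8)
    gg@atoms$x[des$hyd] <- hydXyz[, 1]
    gg@atoms$y[des$hyd] <- hydXyz[, 2]
    gg@atoms$z[des$hyd] <- hydXyz[, 3]
    gg@atoms$x[des$hba] <- cHBA[1]; gg@atoms$y[des$hba] <- cHBA[2]
    gg@atoms$z[des$hba] <- cHBA[3]
    gg@atoms$x[des$hbd] <- cHBD[1]; gg@atoms$y[des$hbd] <- cHBD[2]
    gg@atoms$z[des$hbd] <- cHBD[3]
    if (noiseSd > 0) {
      m <- nrow(gg@atoms)
      gg@atoms$x <- gg@atoms$x + stats::rnorm(m, 0, noiseSd)
      gg@atoms$y <- gg@atoms$y + stats::rnorm(m, 0, noiseSd)
      gg@atoms$z <- gg@atoms$z + stats::rnorm(m, 0, noiseSd)
    }
    pid <- sprintf("fix_%04d", i)
    poses[[i]] <- new("Pose", atoms = gg@atoms, bonds = gg@bonds,
                      structureId = pid,
                      properties = c("Structure ID" = pid,
                                     "Experiment_config" = "toy"))
    truth[[i]] <- data.frame(pose_id = pid,
                             scaffold = scObjs[[si]]@smiles,
                             left = leftCanon[li], right = rightCanon[ri],
                             stringsAsFactors = FALSE)
  }
  if (i < n) stop("too many infeasible pool combinations")
  out <- list(poses = poses, truth = do.call(rbind, truth))
  attr(out, "skippedCombos") <- badCombos
  out
}
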