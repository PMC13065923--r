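## Reward shaping for generative loops: Constant Reward Value (CRV)
## equalization, Similarity Penalty to Already Generated (SPAG), a toy
## mutation-based generator to demonstrate their effect, and diversity
## reporting. CRV prevents a generator from farming one high-scoring
## cluster by giving every filter-passing structure the same reward; SPAG
## additionally penalizes candidates proportionally to their maximum
## fingerprint similarity against the archive of prior generations.

#' Construct a reward configuration
#'
#' @param mode \code{"default"} (pass the base score through), \code{"CRV"}
#'   (equalize to \code{constantValue}) or \code{"CRV+SPAG"} (equalize,
#'   then penalize by similarity to already-generated structures).
#' @param constantValue the CRV constant, > 0.
#' @param penaltyWeight linear SPAG weight, >= 0.
#' @return a \linkS4class{RewardConfig}.
#' @export
rewardConfig <- function(mode = c("default", "CRV", "CRV+SPAG"),
                         constantValue = 1, penaltyWeight = 1) {
  new("RewardConfig", mode = match.arg(mode),
      constantValue = as.numeric(constantValue),
      penaltyWeight = as.numeric(penaltyWeight))
}

#' Create an empty generation archive
#'
#' @return a \linkS4class{GenerationArchive}.
#' @export
newGenerationArchive <- function() {
  e <- new.env(parent = emptyenv())
  e$fps <- list()
  e$smiles <- character()
  new("GenerationArchive", env = e)
}

#' @describeIn GenerationArchive-class number of archived structures
#' @param x a GenerationArchive
#' @export
setMethod("length", "GenerationArchive", function(x) length(x@env$smiles))

setMethod("show", "GenerationArchive", function(object) {
  cat(sprintf("GenerationArchive: %d structures\n", length(object)))
})

## OpenBabel FP2 path fingerprints as raw bit vectors (logical)
.fingerprints <- function(smiles) {
  conv <- .smilesToSdfset(smiles)
  out <- vector("list", length(smiles))
  if (is.null(conv$sdfset)) return(out)
  fp <- ChemmineR::fingerprintOB(conv$sdfset, "FP2")
  m <- methods::getMethod("as.matrix", "FPset")(fp)
  idx <- which(conv$ok)
  for (j in seq_len(nrow(m))) out[[idx[j]]] <- as.logical(m[j, ])
  out
}

.tanimoto <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Maximum similarity of a candidate to the archive
#'
#' @param fp candidate fingerprint (logical vector) or SMILES.
#' @param archive a \linkS4class{GenerationArchive}.
#' @return Tanimoto similarity in [0, 1]; 0 for an empty archive.
#' @export
archiveMaxSimilarity <- function(fp, archive) {
  if (is.character(fp)) fp <- .fingerprints(fp)[[1]]
  if (is.null(fp) || !length(archive@env$fps)) return(0)
  max(vapply(archive@env$fps, .tanimoto, numeric(1), a = fp))
}

#' Insert a structure into the archive
#'
#' @param archive a \linkS4class{GenerationArchive}.
#' @param smiles structure SMILES.
#' @param fp optional precomputed fingerprint.
#' @return invisibly, the archive.
#' @export
archiveInsert <- function(archive, smiles, fp = NULL) {
  if (is.null(fp)) fp <- .fingerprints(smiles)[[1]]
  archive@env$fps[[length(archive@env$fps) + 1]] <- fp
  archive@env$smiles <- c(archive@env$smiles, smiles)
  invisible(archive)
}

#' Constant Reward Value
#'
#' Every structure that passed all filters receives exactly the configured
#' constant; failing structures are rejected (reward NA).
#'
#' @param passedAllFilters logical vector.
#' @param config a \linkS4class{RewardConfig}.
#' @return numeric vector: \code{constantValue} or NA.
#' @export
crvReward <- function(passedAllFilters, config = rewardConfig("CRV")) {
  ifelse(passedAllFilters, config@constantValue, NA_real_)
}

#' Similarity penalty to already generated structures
#'
#' \code{reward = max(0, base - penaltyWeight * sMax)} where \code{sMax} is
#' the maximum fingerprint similarity of the candidate to any archive
#' member (0 for an empty archive). The candidate is then inserted into the
#' archive.
#'
#' @param smiles candidate SMILES (must already have passed filters).
#' @param base base reward before penalty.
#' @param archive a \linkS4class{GenerationArchive} (mutated in place).
#' @param config a \linkS4class{RewardConfig}.
#' @return list with \code{reward} and \code{sMax}.
#' @export
spagPenalty <- function(smiles, base, archive, config = rewardConfig("CRV+SPAG")) {
  fp <- .fingerprints(smiles)[[1]]
  sMax <- archiveMaxSimilarity(fp, archive)
  archiveInsert(archive, smiles, fp)
  list(reward = max(0, base - config@penaltyWeight * sMax), sMax = sMax)
}

#' Similarity scorer against a fixed target
#'
#' Returns a base scorer assigning each structure its Tanimoto similarity
#' to a fixed target chemotype, zeroed below \code{threshold}. The
#' threshold models the filtering behavior of a screening reward stack:
#' structures scoring below it receive no reward and are dropped. Used as
#' the "default" reward in demonstrations: a generator maximizing it only
#' survives inside the target's cluster, which is exactly the
#' concentration behavior CRV+SPAG counteracts.
#'
#' @param target target SMILES.
#' @param threshold similarity below which the score is 0.
#' @return function(smiles) -> score in \{0\} U [threshold, 1].
#' @export
similarityScorer <- function(target, threshold = 0) {
  tfp <- .fingerprints(target)[[1]]
  if (is.null(tfp)) stop(sprintf("unparseable target: %s", target))
  function(smiles) {
    fps <- .fingerprints(smiles)
    s <- vapply(fps, function(f) if (is.null(f)) 0 else .tanimoto(tfp, f),
                numeric(1))
    ifelse(s >= threshold, s, 0)
  }
}

## ---- toy generator ---------------------------------------------------------

.DEFAULT_MUTATION_POOL <- c("*C", "*O", "*N", "*F", "*Cl", "*C(C)C", "*OC",
                            "*C(=O)N", "*c1ccccc1")

## one random structural edit; returns a MolGraph or NULL when infeasible
.mutateGraph <- function(g, pool) {
  op <- sample(3, 1)
  nb <- .neighborList(g)
  if (op == 1) {
    ## element substitution on a non-aromatic carbon or N/O
    cand <- which(!g@atoms$arom & g@atoms$elem %in% c("C", "N", "O") &
                    g@atoms$charge == 0)
    if (!length(cand)) return(NULL)
    i <- cand[sample(length(cand), 1)]
    ordSum <- sum(g@bonds$order[g@bonds$a1 == i | g@bonds$a2 == i])
    to <- setdiff(c("C", "N", "O"), g@atoms$elem[i])
    to <- to[.maxValence(to, 0L) >= ordSum]
    if (!length(to)) return(NULL)
    g@atoms$elem[i] <- to[sample(length(to), 1)]
    g
  } else if (op == 2) {
    ## add a substituent from the pool at a carbon with a free valence
    ordSum <- numeric(nrow(g@atoms))
    for (k in seq_len(nrow(g@bonds))) {
      ordSum[g@bonds$a1[k]] <- ordSum[g@bonds$a1[k]] + g@bonds$order[k]
      ordSum[g@bonds$a2[k]] <- ordSum[g@bonds$a2[k]] + g@bonds$order[k]
    }
    cand <- which(g@atoms$elem == "C" & !g@atoms$arom & ordSum <= 3)
    if (!length(cand)) return(NULL)
    i <- cand[sample(length(cand), 1)]
    fragG <- .parseSmilesOne(pool[sample(length(pool), 1)])
    da <- .dummyAtoms(fragG)[1]
    ## splice: bond i to the fragment dummy's neighbor
    tmp <- g
    tmp@atoms <- rbind(tmp@atoms, data.frame(elem = "*", charge = 0L, iso = 0L,
                                             arom = FALSE, hcount = 0L,
                                             x = 0, y = 0, z = 0))
    tmp@bonds <- rbind(tmp@bonds,
                       data.frame(a1 = i, a2 = nrow(tmp@atoms), order = 1L))
    .fuseAt(tmp, nrow(tmp@atoms), fragG, da)
  } else {
    ## remove a terminal heavy atom
    deg <- lengths(nb)
    cand <- which(deg == 1 & g@atoms$elem != "*")
    if (length(cand) < 1 || nrow(g@atoms) <= 4) return(NULL)
    i <- cand[sample(length(cand), 1)]
    keep <- setdiff(seq_len(nrow(g@atoms)), i)
    remap <- match(seq_len(nrow(g@atoms)), keep)
    bonds <- g@bonds[g@bonds$a1 != i & g@bonds$a2 != i, , drop = FALSE]
    if (nrow(bonds)) { bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2] }
    .newMolGraph(g@atoms[keep, , drop = FALSE], bonds)
  }
}

#' Toy mutation-based generative loop
#'
#' A desk-scale iterative mutate-score-select loop used to demonstrate
#' reward shaping: each iteration picks a parent with probability
#' proportional to its reward, applies a random structural edit (element
#' substitution, substituent addition from a pool, terminal deletion),
#' filters the candidate, scores it under the configured reward mode, and
#' accepts structures with a nonzero reward. Deterministic under
#' \code{rngSeed}.
#'
#' @param seeds seed SMILES (parseable, nonempty).
#' @param scorer function(smiles) -> base score in [0, 1] for the default
#'   mode (also used as the pre-CRV filter threshold driver); defaults to a
#'   constant 1.
#' @param config a \linkS4class{RewardConfig}.
#' @param nIterations number of mutation attempts.
#' @param rngSeed integer seed.
#' @param ruleset structural-alert set applied as the filter.
#' @param pool substituent pool for the addition move.
#' @return list with \code{accepted} (data.frame smiles/reward/iteration),
#'   \code{nProposed}, \code{nRejected}.
#' @export
toyGenerate <- function(seeds, scorer = NULL, config = rewardConfig("default"),
                        nIterations = 100L, rngSeed = 1L,
                        ruleset = "minimal",
                        pool = .DEFAULT_MUTATION_POOL) {
  if (!length(seeds)) stop("empty seed set")
  if (is.null(scorer)) scorer <- function(smiles) rep(1, length(smiles))
  if (is.character(ruleset)) ruleset <- loadAlertRules(ruleset)
  set.seed(rngSeed)
  seedSmi <- canonicalizeSmiles(seeds)
  if (anyNA(seedSmi)) stop("unparseable seed SMILES")
  archive <- newGenerationArchive()
  scoreOf <- function(smi, passed) {
    if (!passed) return(NA_real_)
    base <- switch(config@mode,
                   "default" = scorer(smi),
                   crvReward(TRUE, config))
    if (config@mode == "CRV+SPAG") {
      spagPenalty(smi, base, archive, config)$reward
    } else base
  }
  ## start from the filter-passing seeds
  verd <- mcfFilter(seedSmi, ruleset)
  accepted <- data.frame(smiles = character(), reward = numeric(),
                         iteration = integer(), stringsAsFactors = FALSE)
  for (k in seq_along(seedSmi)) {
    r <- scoreOf(seedSmi[k], verd$passed[k])
    if (!is.na(r) && r > 0) {
      accepted <- rbind(accepted, data.frame(
        smiles = seedSmi[k], reward = r, iteration = 0L))
    }
  }
  graphsCache <- new.env(parent = emptyenv())
  getGraph <- function(smi) {
    if (is.null(graphsCache[[smi]])) graphsCache[[smi]] <- .parseSmilesOne(smi)
    graphsCache[[smi]]
  }
  nRejected <- 0L
  for (it in seq_len(nIterations)) {
    popSmi <- if (nrow(accepted)) accepted$smiles else seedSmi
    popW <- if (nrow(accepted)) accepted$reward else rep(1, length(seedSmi))
    parent <- popSmi[sample(length(popSmi), 1, prob = popW)]
    child <- tryCatch(.mutateGraph(getGraph(parent), pool),
                      error = function(e) NULL)
    if (is.null(child) || !.validValence(child)) { nRejected <- nRejected + 1L; next }
    smi <- canonicalSmiles(child)
    if (is.na(smi) || smi %in% accepted$smiles) { nRejected <- nRejected + 1L; next }
    passed <- mcfFilter(smi, ruleset)$passed[1]
    r <- scoreOf(smi, passed)
    if (is.na(r) || r <= 0) { nRejected <- nRejected + 1L; next }
    accepted <- rbind(accepted, data.frame(smiles = smi, reward = r,
                                           iteration = it))
  }
  list(accepted = accepted, nProposed = nIterations, nRejected = nRejected)
}

## ---- diversity reporting ---------------------------------------------------

## Bemis-Murcko-style framework: iteratively strip terminal atoms until only
## rings and linkers remain; molecules without rings have no framework
.bemisMurcko <- function(g) {
  repeat {
    deg <- lengths(.neighborList(g))
    drop <- which(deg <= 1 & !.ringAtomMask(g))
    if (nrow(g@atoms) == 0 || !length(drop)) break
    keep <- setdiff(seq_len(nrow(g@atoms)), drop)
    remap <- match(seq_len(nrow(g@atoms)), keep)
    bonds <- g@bonds[!(g@bonds$a1 %in% drop | g@bonds$a2 %in% drop), , drop = FALSE]
    if (nrow(bonds)) { bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2] }
    g <- .newMolGraph(g@atoms[keep, , drop = FALSE], bonds)
  }
  if (!any(.ringAtomMask(g))) return(NA_character_)
  canonicalSmiles(g)
}

## primary scaffold of a 2D structure: the same minimal ring-bearing
## >=1-port fragment rule, without the pharmacophore gate (no 3D pose)
.primaryScaffold2D <- function(g, maxCuts = 6L) {
  cands <- bricsFragments(g, maxCuts)
  ok <- Filter(function(cc) cc$nPorts >= 1 && cc$hasRing, cands)
  if (!length(ok)) return(NA_character_)
  nh <- vapply(ok, `[[`, numeric(1), "nHeavy")
  smi <- vapply(ok, `[[`, character(1), "smiles")
  ## strip port labels for counting: identity of the 2D substructure
  smi[order(nh, smi)[1]]
}

#' Scaffold-diversity report
#'
#' Counts unique primary scaffolds (pharmacophore-gated when poses and a
#' hypothesis are supplied; otherwise the minimal ring-bearing fragment
#' rule on the 2D structures) and unique Bemis-Murcko-style frameworks as
#' a baseline.
#'
#' @param molecules character vector of SMILES, or list of
#'   \linkS4class{Pose}.
#' @param hyp optional \linkS4class{PharmacophoreHypothesis} (poses only).
#' @param maxCuts maximum BRICS cuts.
#' @return list with \code{nUniquePrimaryScaffolds},
#'   \code{nUniqueBemisMurcko}, and \code{counts} (per-scaffold table).
#' @export
diversityReport <- function(molecules, hyp = NULL, maxCuts = 6L) {
  if (!length(molecules)) {
    return(list(nUniquePrimaryScaffolds = 0L, nUniqueBemisMurcko = 0L,
                counts = data.frame(scaffold = character(), n = integer())))
  }
  if (is.character(molecules)) {
    molecules <- unique(molecules)
    graphs <- parseSmiles(molecules)
    graphs <- Filter(Negate(is.null), graphs)
    prim <- vapply(graphs, .primaryScaffold2D, character(1), maxCuts = maxCuts)
    bm <- vapply(graphs, .bemisMurcko, character(1))
  } else {
    dedup <- !duplicated(vapply(molecules, canonicalSmiles, character(1)))
    molecules <- molecules[dedup]
    prim <- vapply(molecules, function(p) {
      if (is.null(hyp)) return(.primaryScaffold2D(p, maxCuts))
      sc <- extractPrimaryScaffold(p, hyp, maxCuts)
      if (is.null(sc)) NA_character_ else sc@smiles
    }, character(1))
    bm <- vapply(molecules, .bemisMurcko, character(1))
  }
  tab <- as.data.frame(table(scaffold = prim[!is.na(prim)]),
                       stringsAsFactors = FALSE)
  names(tab) <- c("scaffold", "n")
  list(nUniquePrimaryScaffolds = length(unique(prim[!is.na(prim)])),
       nUniqueBemisMurcko = length(unique(bm[!is.na(bm)])),
       counts = tab)
}
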