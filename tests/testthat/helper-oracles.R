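# Independent oracles and shared fixtures for the suite.

# Brute-force fragment oracle: enumerate every subset of <= maxCuts cleavable
# bonds, split the graph, and collect the distinct connected pieces by their
# sorted parent-atom sets. Independent of the quotient-tree enumeration used
# by bricsFragments().
bruteforceFragmentSets <- function(g, maxCuts = 6L) {
  cb <- bricsBonds(g)
  n <- nrow(g@atoms)
  compMembership <- function(bonds) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
      a <- find(bonds$a1[k]); b <- find(bonds$a2[k])
      if (a != b) parent[a] <- b
    }
    vapply(seq_len(n), find, integer(1))
  }
  keys <- character()
  sets <- list()
  kmax <- min(length(cb), maxCuts)
  for (sz in 0:kmax) {
    combos <- if (sz == 0) list(integer()) else {
      idx <- utils::combn(seq_along(cb), sz)   # avoid combn's scalar pitfall
      lapply(seq_len(ncol(idx)), function(j) cb[idx[, j]])
    }
    for (cut in combos) {
      keep <- g@bonds[setdiff(seq_len(nrow(g@bonds)), cut), , drop = FALSE]
      memb <- compMembership(keep)
      for (cc in unique(memb)) {
        atoms <- which(memb == cc)
        key <- paste(atoms, collapse = ",")
        if (!key %in% keys) { keys <- c(keys, key); sets[[key]] <- atoms }
      }
    }
  }
  unname(sets)
}

# RDKit reference for BRICS-cleavable bonds, called through the system
# python; returns sorted 1-based (a1, a2) pairs.
rdkitBricsBonds <- function(smiles) {
  script <- paste(
    "import sys, json",
    "from rdkit import Chem",
    "from rdkit.Chem import BRICS",
    "out = {}",
    "for smi in sys.argv[1:]:",
    "    m = Chem.MolFromSmiles(smi)",
    "    out[smi] = sorted(tuple(sorted(b[0])) for b in BRICS.FindBRICSBonds(m))",
    "print(json.dumps(out))", sep = "\n")
  tf <- tempfile(fileext = ".py")
  writeLines(script, tf)
  on.exit(unlink(tf))
  res <- suppressWarnings(system2("python", c(tf, shQuote(smiles)),
                                  stdout = TRUE, stderr = FALSE))
  jsonlite::fromJSON(paste(res, collapse = ""))
}

# memoized fixture library so several test files can share one build
.fixtureCache <- new.env(parent = emptyenv())
fixtureLibrary <- function(n = 30, noiseSd = 0, rngSeed = 101) {
  key <- sprintf("lib_%d_%g_%d", n, noiseSd, rngSeed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- makeToyLibrary(n, noiseSd = noiseSd,
                                           rngSeed = rngSeed)
  .fixtureCache[[key]]
}

fixtureHypothesis <- function() makeToyHypothesis()

# rotate+translate a coordinate matrix (rigid motion used by invariance tests)
rigidMotion <- function(xyz, angles = c(0.4, -0.7, 1.1), shift = c(3, -2, 5)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  sweep(xyz %*% t(Rz %*% Ry %*% Rx), 2, shift, `+`)
}

transformPose <- function(pose, angles = c(0.4, -0.7, 1.1), shift = c(3, -2, 5)) {
  xyz <- rigidMotion(as.matrix(pose@atoms[, c("x", "y", "z")]), angles, shift)
  pose@atoms$x <- xyz[, 1]; pose@atoms$y <- xyz[, 2]; pose@atoms$z <- xyz[, 3]
  pose
}

transformHypothesis <- function(hyp, angles = c(0.4, -0.7, 1.1), shift = c(3, -2, 5)) {
  hyp@points <- lapply(hyp@points, function(p) {
    p@center <- as.numeric(rigidMotion(matrix(p@center, 1), angles, shift))
    p
  })
  hyp
}
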