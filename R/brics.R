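## Retrosynthetic (BRICS-style) bond cleavage. The sixteen chemical
## environments and their compatibility matrix follow the published BRICS
## scheme (Degen et al., "On the Art of Compiling and Using 'Drug-Like'
## Chemical Fragment Spaces"), implemented here as transparent atom
## predicates over the MolGraph substrate. Bonds are only ever cut when
## acyclic, so ring systems survive fragmentation intact.

.bricsContext <- function(g) {
  nb <- .neighborList(g)
  n <- nrow(g@atoms)
  deg <- lengths(nb)
  ringB <- .ringBondMask(g)
  ringA <- rep(FALSE, n)
  if (any(ringB)) ringA[unique(c(g@bonds$a1[ringB], g@bonds$a2[ringB]))] <- TRUE
  ## per-atom bond views
  bondsAt <- vector("list", n)
  for (bi in seq_len(nrow(g@bonds))) {
    a <- g@bonds$a1[bi]; b <- g@bonds$a2[bi]
    bondsAt[[a]] <- rbind(bondsAt[[a]],
                          data.frame(other = b, order = g@bonds$order[bi],
                                     ring = ringB[bi]))
    bondsAt[[b]] <- rbind(bondsAt[[b]],
                          data.frame(other = a, order = g@bonds$order[bi],
                                     ring = ringB[bi]))
  }
  list(nb = nb, deg = deg, ringA = ringA, ringB = ringB, bondsAt = bondsAt)
}

## does atom i match BRICS environment `env` (label without the L prefix)
.bricsEnv <- function(g, ctx, i, env) {
  a <- g@atoms
  el <- a$elem[i]; ar <- a$arom[i]
  ba <- ctx$bondsAt[[i]]
  if (is.null(ba)) ba <- data.frame(other = integer(), order = integer(), ring = logical())
  deg <- ctx$deg[i]
  other <- ba$other
  hasDoubleO <- any(ba$order == 2 & a$elem[other] == "O")
  switch(env,
    "1" = el == "C" && !ar && deg == 3 && hasDoubleO,
    "3" = el == "O" && !ar && deg == 2 &&
      any(ba$order == 1 & !ba$ring & (a$elem[other] == "C" | a$elem[other] == "*")),
    "4" = el == "C" && !ar && deg >= 2 && !any(ba$order >= 2) &&
      any(ba$order == 1 & !ba$ring & (a$elem[other] %in% c("C") | a$arom[other])),
    "5" = el == "N" && !ar && deg >= 2 && !any(ba$order >= 2) &&
      all(a$elem[other] %in% c("C", "S", "*")) &&
      !(ctx$ringA[i] && any(ba$ring & a$elem[other] == "C" &
                              vapply(other, function(j) {
                                bj <- ctx$bondsAt[[j]]
                                any(bj$order == 2 & a$elem[bj$other] == "O")
                              }, logical(1)))),
    "6" = el == "C" && !ar && deg == 3 && !ctx$ringA[i] && hasDoubleO &&
      any(ba$order == 1 & !ba$ring &
            (a$elem[other] %in% c("C", "N", "O", "*") | a$arom[other])),
    "7" = el == "C" && !ar && deg %in% c(2, 3) &&
      any(ba$order == 1 & (a$elem[other] == "C" | a$arom[other])),
    "8" = el == "C" && !ar && !ctx$ringA[i] && deg >= 2 && !any(ba$order >= 2),
    "9" = el == "N" && ar && a$charge[i] == 0 &&
      sum(a$arom[other] & a$elem[other] %in% c("C", "N", "O", "S")) >= 2,
    "10" = el == "N" && !ar && ctx$ringA[i] &&
      any(ba$ring & a$elem[other] == "C" &
            vapply(other, function(j) {
              bj <- ctx$bondsAt[[j]]
              any(bj$order == 2 & a$elem[bj$other] == "O")
            }, logical(1))) &&
      sum(ba$ring) >= 2,
    "11" = el == "S" && !ar && deg == 2 &&
      any(ba$order == 1 & !ba$ring & (a$elem[other] %in% c("C", "*") | a$arom[other])),
    "12" = el == "S" && deg == 4 && sum(ba$order == 2 & a$elem[other] == "O") == 2,
    "13" = el == "C" && !ar && ctx$ringA[i] &&
      any(ba$ring & ba$order == 1 & !a$arom[other] &
            a$elem[other] %in% c("N", "O", "S")) &&
      sum(ba$ring & ba$order == 1 & !a$arom[other] &
            a$elem[other] %in% c("C", "N", "O", "S")) >= 2,
    "14" = el == "C" && ar &&
      any(a$arom[other] & a$elem[other] %in% c("N", "O", "S")) &&
      sum(a$arom[other] & a$elem[other] %in% c("C", "N", "O", "S")) >= 2,
    "15" = el == "C" && !ar && ctx$ringA[i] &&
      sum(ba$ring & ba$order == 1 & a$elem[other] == "C" & !a$arom[other]) >= 2,
    "16" = el == "C" && ar && sum(a$arom[other] & a$elem[other] == "C") >= 2,
    FALSE)
}

.BRICS_PAIRS <- rbind(
  data.frame(i = "1",  j = c("3", "5", "10"), bond = 1L),
  data.frame(i = "3",  j = c("4", "13", "14", "15", "16"), bond = 1L),
  data.frame(i = "4",  j = c("5", "11"), bond = 1L),
  data.frame(i = "5",  j = c("12", "13", "14", "15", "16"), bond = 1L),
  data.frame(i = "6",  j = c("13", "14", "15", "16"), bond = 1L),
  data.frame(i = "7",  j = "7", bond = 2L),
  data.frame(i = "8",  j = c("9", "10", "13", "14", "15", "16"), bond = 1L),
  data.frame(i = "9",  j = c("13", "14", "15", "16"), bond = 1L),
  data.frame(i = "10", j = c("13", "14", "15", "16"), bond = 1L),
  data.frame(i = "11", j = c("13", "14", "15", "16"), bond = 1L),
  data.frame(i = "13", j = c("14", "15", "16"), bond = 1L),
  data.frame(i = "14", j = c("14", "15", "16"), bond = 1L),
  data.frame(i = "15", j = "16", bond = 1L),
  data.frame(i = "16", j = "16", bond = 1L))

#' Find BRICS-cleavable bonds
#'
#' Returns the acyclic bonds whose two atoms match a compatible pair of
#' BRICS environments. Ring bonds are never cleavable.
#'
#' @param g a \linkS4class{MolGraph}.
#' @return integer vector of row indices into \code{g@bonds}, with the
#'   matched environment pair as attribute \code{envs} (data.frame).
#' @export
bricsBonds <- function(g) {
  if (!nrow(g@bonds)) return(integer())
  ctx <- .bricsContext(g)
  envCache <- new.env()
  envOf <- function(i, env) {
    key <- paste0(i, "_", env)
    if (is.null(envCache[[key]])) envCache[[key]] <- .bricsEnv(g, ctx, i, env)
    envCache[[key]]
  }
  hits <- integer()
  envI <- character(); envJ <- character()
  for (bi in seq_len(nrow(g@bonds))) {
    if (ctx$ringB[bi]) next
    u <- g@bonds$a1[bi]; v <- g@bonds$a2[bi]
    ord <- g@bonds$order[bi]
    found <- FALSE
    for (r in seq_len(nrow(.BRICS_PAIRS))) {
      if (.BRICS_PAIRS$bond[r] != ord) next
      ei <- .BRICS_PAIRS$i[r]; ej <- .BRICS_PAIRS$j[r]
      if ((envOf(u, ei) && envOf(v, ej)) || (envOf(v, ei) && envOf(u, ej))) {
        hits <- c(hits, bi); envI <- c(envI, ei); envJ <- c(envJ, ej)
        found <- TRUE
        break
      }
    }
  }
  attr(hits, "envs") <- data.frame(i = envI, j = envJ)
  hits
}

## enumerate all connected subsets of nodes of the (undirected) piece graph
## given as adjacency list; classic grow-from-anchor enumeration
.connectedSubsets <- function(adj) {
  n <- length(adj)
  out <- list()
  rec <- function(cur, ext, anchor) {
    out[[length(out) + 1]] <<- cur
    while (length(ext)) {
      v <- ext[1]
      ext <- ext[-1]
      newNbrs <- setdiff(adj[[v]], c(cur, ext))
      newNbrs <- newNbrs[newNbrs > anchor]
      rec(c(cur, v), c(ext, newNbrs), anchor)
    }
  }
  for (r in seq_len(n)) {
    nbr <- adj[[r]][adj[[r]] > r]
    rec(r, nbr, r)
  }
  out
}

#' BRICS fragmentation keeping retrosynthetic intermediates
#'
#' Enumerates every connected fragment obtainable by cleaving any subset of
#' at most \code{maxCuts} BRICS-cleavable bonds -- partial decompositions
#' included, not only the leaf fragments. Each fragment carries attachment
#' points at its cut positions and a map back to the parent's atom indices.
#'
#' Because cleavable bonds are always acyclic, cutting all of them splits
#' the molecule into elementary pieces whose quotient graph is a forest;
#' fragments correspond to connected subtrees, and the subtree's boundary
#' edges are exactly the cuts needed to liberate it.
#'
#' @param g a \linkS4class{MolGraph} (e.g. a \linkS4class{Pose}).
#' @param maxCuts maximum number of simultaneous cuts (default 6).
#' @return list of fragment candidates; each is a list with \code{graph},
#'   \code{smiles} (canonical), \code{atomMap} (parent atom indices),
#'   \code{cutBonds} (parent bond rows), \code{nHeavy}, \code{nPorts},
#'   \code{hasRing}.
#' @export
bricsFragments <- function(g, maxCuts = 6L) {
  stopifnot(maxCuts >= 1)
  cb <- bricsBonds(g)
  n <- nrow(g@atoms)
  keepBonds <- setdiff(seq_len(nrow(g@bonds)), cb)
  memb <- .componentsOf(n, g@bonds[keepBonds, , drop = FALSE])
  nPieces <- max(memb)
  pieceAtoms <- split(seq_len(n), memb)
  ## quotient graph over pieces, edges = cleavable bonds
  adj <- vector("list", nPieces)
  edgePieces <- cbind(memb[g@bonds$a1[cb]], memb[g@bonds$a2[cb]])
  for (k in seq_along(cb)) {
    p <- edgePieces[k, 1]; q <- edgePieces[k, 2]
    adj[[p]] <- union(adj[[p]], q)
    adj[[q]] <- union(adj[[q]], p)
  }
  if (nPieces > 22)
    warning(sprintf("%d BRICS pieces; fragment enumeration may be large", nPieces))
  subsets <- .connectedSubsets(adj)
  ringB <- .ringBondMask(g)
  cands <- list()
  for (ss in subsets) {
    inSet <- memb %in% ss
    boundary <- cb[xor(edgePieces[, 1] %in% ss, edgePieces[, 2] %in% ss)]
    if (length(boundary) > maxCuts) next
    atomIdx <- which(inSet)
    frag <- .fragmentGraph(g, atomIdx, boundary)
    hasRing <- any(ringB & g@bonds$a1 %in% atomIdx & g@bonds$a2 %in% atomIdx)
    cands[[length(cands) + 1]] <- list(
      graph = frag, smiles = NA_character_, atomMap = atomIdx,
      cutBonds = boundary, nHeavy = length(atomIdx),
      nPorts = length(boundary), hasRing = hasRing)
  }
  smis <- canonicalSmiles(lapply(cands, `[[`, "graph"))
  for (k in seq_along(cands)) cands[[k]]$smiles <- smis[k]
  cands
}
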