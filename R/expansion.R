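## Trivalent -> bivalent scaffold expansion: combinatorial replacement of
## one aromatic-carbon attachment point with small capping fragments, so
## the final scaffold set contains only mono- and bivalent members.

#' Default capping fragments for trivalent expansion
#'
#' Typical small aromatic substituents: hydrogen (port deletion), methyl,
#' fluoro, chloro, methoxy, cyano, trifluoromethyl. Shipped as an editable
#' file under \code{inst/extdata/capping_fragments.smi}; this accessor reads
#' it. The entry \code{[H]} is the hydrogen cap.
#'
#' @return character vector of monovalent fragment SMILES.
#' @export
defaultCappingFragments <- function() {
  path <- system.file("extdata", "capping_fragments.smi",
                      package = "ScaffoldSpace", mustWork = TRUE)
  readLines(path)
}

.capGraph <- function(cap) {
  if (cap == "[H]") return(NULL)  # hydrogen cap: delete the port
  g <- .parseSmilesOne(cap)
  if (length(.dummyAtoms(g)) != 1)
    stop(sprintf("capping fragment must have exactly one attachment point: %s", cap))
  g
}

## drop dummy atom `da`, letting the neighbor regain an implicit hydrogen
.deletePort <- function(g, da) {
  keep <- setdiff(seq_len(nrow(g@atoms)), da)
  remap <- match(seq_len(nrow(g@atoms)), keep)
  bonds <- g@bonds[!(g@bonds$a1 == da | g@bonds$a2 == da), , drop = FALSE]
  if (nrow(bonds)) { bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2] }
  .newMolGraph(g@atoms[keep, , drop = FALSE], bonds)
}

#' Expand a trivalent scaffold into bivalent scaffolds
#'
#' Mono- and bivalent scaffolds pass through unchanged. For a trivalent
#' scaffold, every attachment point sitting on an aromatic carbon is
#' combinatorially replaced by every capping fragment; results are
#' canonicalized and deduplicated. A trivalent scaffold with no
#' aromatic-carbon port is not expandable and yields an empty list.
#'
#' After replacement the two surviving ports are relabeled 1 and 2 in the
#' order of their previous labels.
#'
#' @param scaffold a \linkS4class{Scaffold}.
#' @param cappingSet character vector of monovalent fragment SMILES
#'   (\code{[H]} deletes the port).
#' @return list of \linkS4class{Scaffold}.
#' @export
expandTrivalent <- function(scaffold, cappingSet = defaultCappingFragments()) {
  if (!length(cappingSet)) stop("empty capping set")
  if (length(scaffold@ports) <= 2) return(list(scaffold))
  g <- .scaffoldGraph(scaffold)
  du <- .dummyAtoms(g)
  nb <- .neighborList(g)
  aromPorts <- du[vapply(du, function(d) {
    j <- nb[[d]]
    length(j) == 1 && g@atoms$arom[j] && g@atoms$elem[j] == "C"
  }, logical(1))]
  if (!length(aromPorts)) {
    message(sprintf("trivalent scaffold has no aromatic-carbon port: %s",
                    scaffold@smiles))
    return(list())
  }
  capGraphs <- lapply(cappingSet, .capGraph)
  results <- list()
  for (port in aromPorts) {
    for (ci in seq_along(cappingSet)) {
      cg <- capGraphs[[ci]]
      gg <- if (is.null(cg)) .deletePort(g, port)
            else .fuseAt(g, port, cg, .dummyAtoms(cg))
      if (!.validValence(gg)) next
      ## relabel surviving ports 1,2 preserving their previous order
      sd <- .dummyAtoms(gg)
      gg@atoms$iso[sd[order(gg@atoms$iso[sd])]] <- seq_along(sd)
      results[[length(results) + 1]] <- gg
    }
  }
  smis <- canonicalSmiles(results)
  keep <- !is.na(smis) & !duplicated(smis)
  lapply(which(keep), function(k)
    new("Scaffold", smiles = smis[k],
        ports = sort(results[[k]]@atoms$iso[.dummyAtoms(results[[k]])])))
}

#' Finalize a crude scaffold set into mono-/bivalent scaffolds
#'
#' Takes the union of unchanged mono- and bivalent crude scaffolds and all
#' expansions of the trivalent ones, canonical-deduplicated.
#'
#' @param crude a \linkS4class{CrudeScaffoldSet}.
#' @param cappingSet capping fragments (see \code{\link{expandTrivalent}}).
#' @return list of \linkS4class{Scaffold}, with per-source counts in
#'   \code{attr(, "counts")}.
#' @export
finalizeScaffoldSet <- function(crude, cappingSet = defaultCappingFragments()) {
  tab <- crude@table
  out <- list()
  nKept <- 0L; nExpanded <- 0L; nUnexpandable <- 0L
  for (i in seq_len(nrow(tab))) {
    sc <- asScaffold(tab$scaffold[i])
    if (length(sc@ports) <= 2) {
      out[[length(out) + 1]] <- sc
      nKept <- nKept + 1L
    } else {
      ex <- expandTrivalent(sc, cappingSet)
      if (!length(ex)) nUnexpandable <- nUnexpandable + 1L
      else nExpanded <- nExpanded + 1L
      out <- c(out, ex)
    }
  }
  smis <- vapply(out, function(s) s@smiles, character(1))
  out <- out[!duplicated(smis)]
  attr(out, "counts") <- c(kept = nKept, expanded = nExpanded,
                           unexpandable = nUnexpandable,
                           final = length(out))
  out
}
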