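## The combinatorial explosion engine: implicit Cartesian-product spaces
## over (scaffold x left fragment x right fragment) with exact counting,
## deterministic streaming enumeration, and seeded per-scaffold sub-sampling.
## Counting never enumerates and never touches floating point.

#' Construct an enumeration specification
#'
#' @param scaffolds list of mono-/bivalent \linkS4class{Scaffold} objects.
#' @param left,right character vectors of monovalent fragment SMILES
#'   (left fuses at port 1, right at port 2).
#' @param kLeft,kRight optional per-scaffold sample sizes (both or neither).
#' @param seed integer seed, required when sampling.
#' @return an \linkS4class{EnumerationSpec}.
#' @export
enumerationSpec <- function(scaffolds, left, right,
                            kLeft = NA_integer_, kRight = NA_integer_,
                            seed = NA_integer_) {
  new("EnumerationSpec", scaffolds = scaffolds,
      left = as.character(left), right = as.character(right),
      kLeft = as.integer(kLeft), kRight = as.integer(kRight),
      seed = as.integer(seed))
}

.perScaffoldCounts <- function(spec) {
  nl <- length(spec@left); nr <- length(spec@right)
  if (!is.na(spec@kLeft)) nl <- min(spec@kLeft, nl)
  if (!is.na(spec@kRight)) nr <- min(spec@kRight, nr)
  t(vapply(spec@scaffolds, function(s) {
    c(l = if (1L %in% s@ports) nl else 1L,
      r = if (2L %in% s@ports) nr else 1L)
  }, c(l = 0L, r = 0L)))
}

#' Count an implicit combinatorial space exactly
#'
#' Pure integer arithmetic, no enumeration; the total is carried as a
#' decimal big-integer string so counts beyond 2^63 cannot overflow.
#'
#' @param spec an \linkS4class{EnumerationSpec}.
#' @return a \linkS4class{SpaceCount}.
#' @export
countSpace <- function(spec) {
  cc <- .perScaffoldCounts(spec)
  if (!length(spec@scaffolds) || !nrow(cc)) {
    total <- "0"
  } else {
    perScaffold <- cc[, "l"] * cc[, "r"]  # each factor <= 2^31, product < 2^53
    if (length(unique(perScaffold)) == 1) {
      total <- bigProduct(nrow(cc), perScaffold[1])
    } else {
      total <- bigSum(as.list(perScaffold))
    }
  }
  new("SpaceCount", nScaffolds = length(spec@scaffolds),
      nLeft = length(spec@left), nRight = length(spec@right),
      total = total, totalNumeric = as.numeric(total))
}

setMethod("show", "SpaceCount", function(object) {
  cat(sprintf("SpaceCount: %d scaffolds x %d left x %d right = %s structures\n",
              object@nScaffolds, object@nLeft, object@nRight, object@total))
})

#' Join a scaffold with peripheral fragments
#'
#' Forms single bonds between each port atom's neighbor and the fragment's
#' attachment neighbor, removes the dummy atoms, and canonicalizes. A left
#' fragment must be supplied exactly when the scaffold has port 1, a right
#' fragment exactly when it has port 2.
#'
#' @param scaffold a \linkS4class{Scaffold} (or its SMILES).
#' @param left,right monovalent fragment SMILES, or NULL.
#' @return canonical product SMILES, or NA when the junction would violate
#'   valence.
#' @export
joinFragments <- function(scaffold, left = NULL, right = NULL) {
  if (is.character(scaffold)) scaffold <- asScaffold(scaffold)
  g <- .scaffoldGraph(scaffold)
  .joinGraph(g, scaffold@ports,
             if (!is.null(left)) .fragmentOneDummy(left) else NULL,
             if (!is.null(right)) .fragmentOneDummy(right) else NULL)
}

.fragmentOneDummy <- function(smiles) {
  g <- .parseSmilesOne(smiles)
  if (length(.dummyAtoms(g)) != 1)
    stop(sprintf("fragment must have exactly one attachment point: %s", smiles))
  g
}

## low-level join on parsed graphs; returns canonical SMILES or NA
.joinGraph <- function(g, ports, leftG, rightG) {
  gg <- .joinGraphRaw(g, ports, leftG, rightG)
  if (is.null(gg)) return(NA_character_)
  canonicalSmiles(gg)
}

.joinGraphRaw <- function(g, ports, leftG, rightG) {
  has1 <- 1L %in% ports; has2 <- 2L %in% ports
  if (has1 != !is.null(leftG))
    stop("left fragment required exactly when the scaffold has port 1")
  if (has2 != !is.null(rightG))
    stop("right fragment required exactly when the scaffold has port 2")
  gg <- g
  if (has1) {
    da <- .dummyAtoms(gg)
    da <- da[gg@atoms$iso[da] == 1L]
    gg <- .fuseAt(gg, da, leftG, .dummyAtoms(leftG))
  }
  if (has2) {
    da <- .dummyAtoms(gg)
    da <- da[gg@atoms$iso[da] == 2L]
    gg <- .fuseAt(gg, da, rightG, .dummyAtoms(rightG))
  }
  if (!.validValence(gg)) return(NULL)
  gg
}

## core streaming loop shared by full enumeration and sampling
.streamProducts <- function(spec, leftIdxOf, rightIdxOf, out = NULL,
                            chunkSize = 500L) {
  scGraphs <- lapply(spec@scaffolds, .scaffoldGraph)
  leftG <- lapply(spec@left, .fragmentOneDummy)
  rightG <- lapply(spec@right, .fragmentOneDummy)
  writer <- if (!is.null(out)) smilesCsvWriter(out)
  rows <- list(); emitted <- 0L; skipped <- 0L
  buf <- list(); bufMeta <- list()
  flush <- function() {
    if (!length(buf)) return()
    smis <- canonicalSmiles(buf)
    okv <- !is.na(smis)
    skipped <<- skipped + sum(!okv)
    emitted <<- emitted + sum(okv)
    if (!is.null(writer)) {
      writer$write(smis[okv])
    } else {
      for (k in which(okv)) {
        m <- bufMeta[[k]]
        rows[[length(rows) + 1]] <<- data.frame(
          scaffold_index = m[1], left_index = m[2], right_index = m[3],
          smiles = smis[k], stringsAsFactors = FALSE)
      }
    }
    buf <<- list(); bufMeta <<- list()
  }
  for (si in seq_along(spec@scaffolds)) {
    ports <- spec@scaffolds[[si]]@ports
    li <- if (1L %in% ports) leftIdxOf(si) else NA_integer_
    ri <- if (2L %in% ports) rightIdxOf(si) else NA_integer_
    for (l in (if (all(is.na(li))) NA_integer_ else li)) {
      for (r in (if (all(is.na(ri))) NA_integer_ else ri)) {
        gg <- tryCatch(
          .joinGraphRaw(scGraphs[[si]], ports,
                        if (!is.na(l)) leftG[[l]] else NULL,
                        if (!is.na(r)) rightG[[r]] else NULL),
          error = function(e) NULL)
        if (is.null(gg)) { skipped <- skipped + 1L; next }
        buf[[length(buf) + 1]] <- gg
        bufMeta[[length(bufMeta) + 1]] <- c(si, l, r)
        if (length(buf) >= chunkSize) flush()
      }
    }
  }
  flush()
  if (!is.null(writer)) {
    writer$close()
    list(emitted = emitted, skipped = skipped, path = out)
  } else {
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(scaffold_index = integer(), left_index = integer(),
                 right_index = integer(), smiles = character())
    attr(df, "skipped") <- skipped
    df
  }
}

#' Enumerate the full Cartesian product
#'
#' Deterministic lexicographic order over (scaffold, left, right). With
#' \code{out} set, products stream to a single-column SMILES CSV at
#' constant memory and a summary is returned; otherwise a data.frame of
#' (scaffold_index, left_index, right_index, smiles) is returned with the
#' skipped-junction count as attribute \code{skipped}. Valence-invalid
#' junctions are skipped and counted, never fatal.
#'
#' @param spec an \linkS4class{EnumerationSpec} without sampling parameters.
#' @param out optional output CSV path (gzip by extension).
#' @param chunkSize canonicalization batch size.
#' @return data.frame or summary list (see above).
#' @export
enumerateProducts <- function(spec, out = NULL, chunkSize = 500L) {
  if (!is.na(spec@kLeft) || !is.na(spec@kRight))
    stop("spec has sampling parameters set; use sampleProducts()")
  nl <- length(spec@left); nr <- length(spec@right)
  .streamProducts(spec,
                  leftIdxOf = function(si) if (nl) seq_len(nl) else NA_integer_,
                  rightIdxOf = function(si) if (nr) seq_len(nr) else NA_integer_,
                  out = out, chunkSize = chunkSize)
}

## deterministic per-scaffold seed derivation (kept below 2^31)
.perScaffoldSeed <- function(seed, scaffoldIndex) {
  ((abs(as.numeric(seed)) %% 65536) * 19349663 + scaffoldIndex * 83492791) %%
    2147483647
}

#' Sample the Cartesian product per scaffold
#'
#' For each scaffold independently, draws \code{min(kLeft, |left|)} left and
#' \code{min(kRight, |right|)} right fragments uniformly without
#' replacement, using a generator seeded deterministically by (seed,
#' scaffold index), and emits their full cross product. Reruns with the
#' same seed are byte-identical.
#'
#' @param spec an \linkS4class{EnumerationSpec} with \code{kLeft},
#'   \code{kRight} and \code{seed} set.
#' @param out optional output CSV path.
#' @param chunkSize canonicalization batch size.
#' @return as \code{\link{enumerateProducts}}.
#' @export
sampleProducts <- function(spec, out = NULL, chunkSize = 500L) {
  if (is.na(spec@kLeft) || is.na(spec@kRight) || is.na(spec@seed))
    stop("sampling requires kLeft, kRight and seed")
  nl <- length(spec@left); nr <- length(spec@right)
  pick <- function(si, n, k, salt) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(.perScaffoldSeed(spec@seed + salt, si))
    sort(sample.int(n, min(k, n)))
  }
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  .streamProducts(spec,
                  leftIdxOf = function(si) pick(si, nl, spec@kLeft, 0L),
                  rightIdxOf = function(si) pick(si, nr, spec@kRight, 1L),
                  out = out, chunkSize = chunkSize)
}
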