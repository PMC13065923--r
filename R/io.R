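## Readers and writers for the external representations the tool touches:
## SDF poses with properties, SMILES CSV libraries, scaffold/fragment CSVs
## with attachment-point conventions, and JSON pharmacophore hypotheses.

.openMaybeGz <- function(path, mode = "") {
  ## unopened by default: read.csv/read.delim then open and close it themselves
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

.ID_ALIASES <- c("Structure ID", "Structure_ID", "structure_id", "StructureID")

#' Read 3D poses from an SD file
#'
#' One \linkS4class{Pose} per parsable V2000/V3000 record; V3000 records are
#' normalized through OpenBabel first. Properties are preserved verbatim.
#' Records without 3D coordinates (all-zero z and a 2D dimensionality flag)
#' and unparsable records are skipped with a warning; their count is
#' available as \code{attr(result, "skipped")}.
#'
#' The structure identifier is taken from a \code{Structure ID} property
#' (spelling aliases accepted) and falls back to the molecule title.
#'
#' @param path SD file path.
#' @return list of \linkS4class{Pose}, with attribute \code{skipped}.
#' @export
readSdfPoses <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  txt <- readLines(path, warn = FALSE)
  if (any(grepl("V3000", txt, fixed = TRUE))) {
    ## normalize V3000 records to V2000 through OpenBabel; the empty option
    ## frame suppresses convertFormat's default 2D-coordinate regeneration,
    ## which would destroy the pose geometry
    txt <- strsplit(ChemmineOB::convertFormat(
      "SDF", "SDF", paste(c(txt, ""), collapse = "\n"),
      options = data.frame(names = character(), args = character())),
      "\n")[[1]]
  }
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  parsed <- .sdfFileToGraphs(tf)
  nRec <- length(parsed$raw)
  skipped <- sum(!parsed$valid)
  graphs <- .annotatePerception(parsed$graphs)
  validIdx <- which(parsed$valid)
  poses <- list()
  for (j in seq_along(graphs)) {
    g <- graphs[[j]]
    i <- validIdx[j]
    raw <- parsed$raw[[i]]
    flag2d <- grepl("2D", raw[2], fixed = TRUE)
    if (nrow(g@atoms) == 0 || (flag2d && all(g@atoms$z == 0))) {
      skipped <- skipped + 1L
      warning(sprintf("record %d skipped: no 3D coordinates", i))
      next
    }
    props <- .datablockChar(parsed$sdfset[[i]])
    sid <- props[.ID_ALIASES][!is.na(props[.ID_ALIASES])]
    sid <- if (length(sid)) sid[[1]] else trimws(raw[1])
    if (!nzchar(sid)) sid <- sprintf("record_%d", i)
    poses[[length(poses) + 1]] <-
      new("Pose", atoms = g@atoms, bonds = g@bonds,
          structureId = sid, properties = props)
  }
  if (!length(poses)) stop(sprintf("no parsable 3D records in %s", path))
  if (skipped > 0)
    warning(sprintf("%d of %d records skipped", skipped, nRec))
  attr(poses, "skipped") <- skipped
  poses
}

.datablockChar <- function(sdf) {
  db <- ChemmineR::datablock(sdf)
  if (!length(db)) return(setNames(character(), character()))
  setNames(as.character(db), names(db))
}

#' Write poses to an SD file
#'
#' @param poses list of \linkS4class{Pose}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSdfPoses <- function(poses, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in poses) {
    mb <- .graphToMolblock(p, title = p@structureId)
    mb <- sub("\\n\\$\\$\\$\\$$", "", mb)
    writeLines(mb, con)
    for (k in names(p@properties)) {
      writeLines(c(sprintf(">  <%s>", k), p@properties[[k]], ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

## ---- scaffolds -------------------------------------------------------------

#' Build a Scaffold from SMILES
#'
#' Canonicalizes the SMILES and resolves attachment-point port labels. Port
#' identity is read from isotope annotations (\code{[1*]}, \code{[2*]},
#' \code{[3*]}) when present; bare \code{*} attachment points are assigned
#' ports in canonical atom order. Scaffolds must carry 1-3 attachment points
#' and at least one ring.
#'
#' @param smiles SMILES with attachment-point dummy atoms.
#' @param requireRing enforce the at-least-one-ring invariant (default TRUE).
#' @return a \linkS4class{Scaffold}.
#' @export
asScaffold <- function(smiles, requireRing = TRUE) {
  g <- .parseSmilesOne(smiles)
  du <- .dummyAtoms(g)
  if (length(du) < 1 || length(du) > 3)
    stop(sprintf("scaffold must have 1-3 attachment points, got %d: %s",
                 length(du), smiles))
  if (requireRing && !any(.ringAtomMask(g)))
    stop(sprintf("scaffold must contain a ring: %s", smiles))
  labels <- g@atoms$iso[du]
  if (any(labels < 1 | labels > 3) || anyDuplicated(labels[labels > 0])) {
    g@atoms$iso[du] <- seq_along(du)  # canonical-order assignment
    labels <- seq_along(du)
  }
  smi <- canonicalSmiles(g)
  if (is.na(smi)) stop(sprintf("cannot canonicalize scaffold: %s", smiles))
  new("Scaffold", smiles = smi, ports = sort(as.integer(labels)))
}

.scaffoldGraph <- function(scaffold) .parseSmilesOne(scaffold@smiles)

#' Read scaffolds from a CSV table
#'
#' Expects a header row with a scaffold SMILES column (default candidates
#' \code{scaffold} then \code{smiles}); gzip is autodetected by extension.
#' Records whose SMILES carry 0 or more than 3 attachment points, or do not
#' parse, are rejected and counted in \code{attr(result, "rejected")}.
#'
#' @param path CSV path (optionally .gz).
#' @param column column name(s) to look for, in order of preference.
#' @return list of \linkS4class{Scaffold} with attribute \code{rejected};
#'   provenance columns (molecule_id, experiment_id) preserved as attribute
#'   \code{table} when present.
#' @export
readScaffoldCsv <- function(path, column = c("scaffold", "smiles")) {
  df <- utils::read.csv(.openMaybeGz(path), stringsAsFactors = FALSE,
                        check.names = FALSE)
  col <- column[column %in% names(df)][1]
  if (is.na(col)) stop(sprintf("no scaffold column (%s) in %s",
                               paste(column, collapse = "/"), path))
  out <- list()
  rejected <- 0L
  for (i in seq_len(nrow(df))) {
    sc <- tryCatch(asScaffold(df[[col]][i]), error = function(e) NULL)
    if (is.null(sc)) { rejected <- rejected + 1L; next }
    out[[length(out) + 1]] <- sc
  }
  attr(out, "rejected") <- rejected
  attr(out, "table") <- df
  out
}

#' Write scaffolds to CSV
#'
#' @param scaffolds list of \linkS4class{Scaffold} or a
#'   \linkS4class{CrudeScaffoldSet}.
#' @param path output CSV path (optionally .gz).
#' @return invisibly, the path.
#' @export
writeScaffoldCsv <- function(scaffolds, path) {
  if (is(scaffolds, "CrudeScaffoldSet")) {
    tab <- scaffolds@table
    prov <- scaffolds@provenance
    rows <- lapply(seq_len(nrow(tab)), function(i) {
      p <- prov[[i]]
      data.frame(molecule_id = paste(unique(p$molecule_id), collapse = ";"),
                 scaffold = tab$scaffold[i],
                 experiment_id = paste(unique(p$experiment_id), collapse = ";"))
    })
    df <- do.call(rbind, rows)
  } else {
    df <- data.frame(scaffold = vapply(scaffolds, function(s) s@smiles, character(1)))
  }
  con <- .openMaybeGz(path, "w")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- SMILES CSV ------------------------------------------------------------

#' Read a SMILES column from CSV
#'
#' @param path CSV path (optionally .gz); header row required.
#' @param column column name (default \code{smiles}).
#' @return character vector of SMILES.
#' @export
readSmilesCsv <- function(path, column = "smiles") {
  df <- utils::read.csv(.openMaybeGz(path), stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!column %in% names(df)) stop(sprintf("no '%s' column in %s", column, path))
  as.character(df[[column]])
}

#' Write a single-column SMILES CSV
#'
#' @param smiles character vector.
#' @param path output path (gzip by .gz extension).
#' @param column header name.
#' @return invisibly, the path.
#' @export
writeSmilesCsv <- function(smiles, path, column = "smiles") {
  con <- .openMaybeGz(path, "w")
  on.exit(close(con))
  writeLines(c(column, smiles), con)
  invisible(path)
}

#' Open a streaming single-column SMILES CSV writer
#'
#' Returns a writer object with \code{$write(chunk)} and \code{$close()},
#' holding only one chunk in memory at a time; used by the enumeration
#' engine to emit arbitrarily long libraries at constant memory.
#'
#' @param path output path (gzip by .gz extension).
#' @param column header name.
#' @return list with functions \code{write} and \code{close}.
#' @export
smilesCsvWriter <- function(path, column = "smiles") {
  con <- .openMaybeGz(path, "w")
  writeLines(column, con)
  list(write = function(chunk) writeLines(chunk, con),
       close = function() close(con))
}

## ---- hypotheses ------------------------------------------------------------

#' Read a pharmacophore hypothesis from JSON
#'
#' The file holds \code{name} and \code{points}, each point with
#' \code{type}, \code{center} (xyz, Angstrom), \code{radius} (Angstrom) and
#' a \code{key} flag. At least one key point is required; unknown feature
#' types and nonpositive radii are fatal.
#'
#' @param path JSON path.
#' @return a \linkS4class{PharmacophoreHypothesis}.
#' @export
readHypothesis <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$points) || !length(j$points)) stop("hypothesis has no points")
  pts <- lapply(j$points, function(p) {
    if (is.null(p$type) || !p$type %in% .FEATURE_TYPES)
      stop(sprintf("unknown feature type '%s'", p$type %||% "<missing>"))
    if (is.null(p$radius) || p$radius <= 0)
      stop("pharmacophore point radius must be > 0")
    new("PharmacophorePoint", ptype = p$type,
        center = as.numeric(unlist(p$center)),
        radius = as.numeric(p$radius),
        key = isTRUE(p$key))
  })
  new("PharmacophoreHypothesis",
      name = if (!is.null(j$name)) j$name else "hypothesis", points = pts)
}

#' Write a pharmacophore hypothesis to JSON
#'
#' @param hyp a \linkS4class{PharmacophoreHypothesis}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeHypothesis <- function(hyp, path) {
  j <- list(name = hyp@name,
            points = lapply(hyp@points, function(p)
              list(type = p@ptype, center = p@center, radius = p@radius,
                   key = p@key)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
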