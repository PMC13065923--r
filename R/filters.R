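## Medicinal-chemistry structural-alert (MCF) filtering and basic physchem
## descriptor annotation. The shipped minimal/moderate/covalent rule sets
## are assembled from public structural-alert collections; they are NOT the
## proprietary rule sets used in large screening platforms -- the rule-set
## file format is the stable contract, not the contents. SMARTS matching is
## delegated to OpenBabel.

#' Load a structural-alert rule set
#'
#' Built-in sets are \code{minimal}, \code{moderate} (a superset of
#' minimal, enforced at load time) and \code{covalent} (electrophilic
#' warheads). A path to a custom tab-separated file
#' (\code{rule_id<TAB>pattern<TAB>description}) is also accepted.
#'
#' @param name built-in set name or file path.
#' @return an \linkS4class{AlertRuleSet}.
#' @export
loadAlertRules <- function(name = c("minimal", "moderate", "covalent")) {
  if (length(name) > 1) name <- name[1]
  builtin <- name %in% c("minimal", "moderate", "covalent")
  path <- if (builtin) {
    system.file("extdata", "mcf", paste0(name, ".tsv"),
                package = "ScaffoldSpace", mustWork = TRUE)
  } else name
  if (!file.exists(path)) stop(sprintf("no such rule file: %s", path))
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  rs <- new("AlertRuleSet", name = if (builtin) name else basename(path),
            rules = df[, c("rule_id", "pattern", "description")])
  if (name == "moderate") {
    minIds <- loadAlertRules("minimal")@rules$rule_id
    if (!all(minIds %in% rs@rules$rule_id))
      stop("rule containment violated: moderate must include every minimal rule")
  }
  rs
}

setMethod("show", "AlertRuleSet", function(object) {
  cat(sprintf("AlertRuleSet '%s': %d rules\n", object@name, nrow(object@rules)))
})

.smilesToSdfset <- function(smiles) {
  graphs <- parseSmiles(smiles)
  ok <- !vapply(graphs, is.null, logical(1))
  if (!any(ok)) return(list(sdfset = NULL, ok = ok))
  txt <- .graphsToSdfText(graphs[ok], titles = paste0("m", which(ok)))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  list(sdfset = ChemmineR::read.SDFset(tf), ok = ok)
}

#' Screen SMILES against a structural-alert rule set
#'
#' Inputs are canonicalized before matching, so verdicts are independent of
#' the kekulization variant and of input order. Every matching rule is
#' listed; unparseable SMILES fail with the pseudo-hit \code{UNPARSEABLE}.
#'
#' @param smiles character vector.
#' @param ruleset an \linkS4class{AlertRuleSet} or built-in set name.
#' @param invert if TRUE, pass molecules that hit at least one rule
#'   (e.g. to select rather than exclude covalent warheads).
#' @return data.frame with columns \code{smiles}, \code{passed},
#'   \code{hits} (semicolon-joined rule ids).
#' @export
mcfFilter <- function(smiles, ruleset = "minimal", invert = FALSE) {
  if (is.character(ruleset)) ruleset <- loadAlertRules(ruleset)
  conv <- .smilesToSdfset(smiles)
  hits <- rep("", length(smiles))
  hits[!conv$ok] <- "UNPARSEABLE"
  if (!is.null(conv$sdfset)) {
    idx <- which(conv$ok)
    for (r in seq_len(nrow(ruleset@rules))) {
      counts <- suppressWarnings(ChemmineR::smartsSearchOB(
        conv$sdfset, ruleset@rules$pattern[r], uniqueMatches = FALSE))
      hit <- which(counts > 0)
      for (h in hit) {
        i <- idx[h]
        hits[i] <- if (nzchar(hits[i]))
          paste(hits[i], ruleset@rules$rule_id[r], sep = ";")
        else ruleset@rules$rule_id[r]
      }
    }
  }
  passed <- !nzchar(hits)
  if (invert) passed <- nzchar(hits) & hits != "UNPARSEABLE"
  data.frame(smiles = smiles, passed = passed, hits = hits,
             stringsAsFactors = FALSE)
}

.ATOMIC_WEIGHTS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                     F = 18.998, Si = 28.085, P = 30.974, S = 32.06,
                     Cl = 35.45, Br = 79.904, I = 126.904)

#' Annotate basic 2D descriptors
#'
#' Average molecular weight (g/mol) from standard atomic weights including
#' implicit hydrogens, plus hydrogen-bond acceptor and donor counts using
#' the same donor/acceptor definitions as the pharmacophore module (one
#' count per donor/acceptor heavy atom), so the two modules can never
#' disagree on what counts as a donor or acceptor.
#'
#' @param smiles character vector.
#' @return data.frame with columns \code{smiles}, \code{MW}, \code{HBA},
#'   \code{HBD}.
#' @export
annotateDescriptors <- function(smiles) {
  graphs <- parseSmiles(smiles)
  bad <- vapply(graphs, is.null, logical(1))
  if (any(bad)) stop(sprintf("unparseable SMILES: %s",
                             paste(smiles[bad], collapse = ", ")))
  defs <- featureDefinitions()
  rows <- lapply(graphs, function(g) {
    w <- .ATOMIC_WEIGHTS[g@atoms$elem]
    w[is.na(w)] <- 0
    mw <- sum(w) + sum(g@atoms$hcount) * .ATOMIC_WEIGHTS[["H"]]
    data.frame(MW = mw,
               HBA = length(defs$HBA(g)),
               HBD = length(defs$HBD(g)))
  })
  cbind(data.frame(smiles = smiles, stringsAsFactors = FALSE),
        do.call(rbind, rows))
}
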