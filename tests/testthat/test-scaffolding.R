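test_that("cleavable-bond detection agrees with the reference implementation", {
  mols <- c("CCOc1ccc(CC(=O)N)cc1", "c1ccccc1NC(=O)C", "C1CCCCC1NC(=O)C",
            "CC(=O)OCCc1ccccc1", "c1ccc(cc1)Cc1ccncc1", "CCCC", "c1ccccc1",
            "CN1CCN(CC1)C(=O)c1ccc(F)cc1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
            "O=S(=O)(N)c1ccc(N)cc1", "CC=CC(C)C", "COc1cc(N)c(O)cc1C(=O)NC")
  ref <- rdkitBricsBonds(mols)
  for (smi in mols) {
    g <- parseSmiles(smi)[[1]]
    cb <- bricsBonds(g)
    mine <- if (length(cb)) {
      m <- t(apply(cbind(g@bonds$a1[cb], g@bonds$a2[cb]) - 1L, 1, sort))
      m[order(m[, 1], m[, 2]), , drop = FALSE]
    } else matrix(integer(), ncol = 2)
    r <- ref[[smi]]
    r <- if (length(r)) matrix(as.integer(r), ncol = 2) else matrix(integer(), ncol = 2)
    expect_equal(unname(mine), unname(r), info = smi)
  }
})

test_that("fragment enumeration matches the brute-force cut-subset oracle", {
  mols <- c("CCc1ccccc1",            # one cleavable bond
            "CCc1ccccc1CC",          # two cuts on a linear backbone
            "c1ccccc1",              # none
            "CCOc1ccc(CC(=O)N)cc1",  # mixed environments
            "CN1CCN(CC1)C(=O)c1ccc(F)cc1")
  for (smi in mols) {
    g <- parseSmiles(smi)[[1]]
    frags <- bricsFragments(g, maxCuts = 6L)
    mineSets <- sort(vapply(frags, function(f) paste(f$atomMap, collapse = ","),
                            character(1)))
    oracleSets <- sort(vapply(bruteforceFragmentSets(g, 6L), paste,
                              character(1), collapse = ","))
    expect_identical(mineSets, oracleSets, info = smi)
  }
})

test_that("fragment counts follow the single- and double-cut arithmetic", {
  # one cleavable bond: the parent plus its two pieces
  g <- parseSmiles("CCc1ccccc1")[[1]]
  frags <- bricsFragments(g)
  expect_length(frags, 3)
  expect_identical(sort(vapply(frags, `[[`, numeric(1), "nPorts")), c(0, 1, 1))

  # two cuts on a linear backbone: pieces A, B, C, AB, BC, ABC
  g2 <- parseSmiles("CCc1ccccc1CC")[[1]]
  expect_length(bricsFragments(g2), 6)

  # no cleavable bond: only the 0-port parent, which cannot become a scaffold
  g3 <- parseSmiles("c1ccccc1")[[1]]
  frags3 <- bricsFragments(g3)
  expect_length(frags3, 1)
  expect_identical(frags3[[1]]$nPorts, 0L)
})

test_that("primary scaffold extraction recovers planted scaffolds at zero noise", {
  lib <- fixtureLibrary(30)
  hyp <- fixtureHypothesis()
  hits <- 0
  for (i in seq_along(lib$poses)) {
    sc <- extractPrimaryScaffold(lib$poses[[i]], hyp)
    expect_false(is.null(sc))
    if (sc@smiles == lib$truth$scaffold[i]) hits <- hits + 1
    expect_gte(length(sc@ports), 1)
    expect_lte(length(sc@ports), 3)
  }
  expect_gte(hits / length(lib$poses), 0.95)
})

test_that("extraction refuses acyclic and port-less cases", {
  # acyclic molecule: no fragment has a ring
  g <- parseSmiles("NCCCO")[[1]]
  pose <- new("Pose", atoms = g@atoms, bonds = g@bonds,
              structureId = "acyclic", properties = character())
  hyp <- makeToyHypothesis("custom", points = list(
    pharmacophorePoint("HBD", unlist(g@atoms[1, c("x", "y", "z")]), 2)))
  expect_null(suppressMessages(extractPrimaryScaffold(pose, hyp)))

  # ring molecule with no cleavable bond: single 0-port candidate, no scaffold
  g2 <- parseSmiles("Oc1ccccc1")[[1]]
  pose2 <- new("Pose", atoms = g2@atoms, bonds = g2@bonds,
               structureId = "phenol", properties = character())
  oIdx <- which(g2@atoms$elem == "O")
  hyp2 <- makeToyHypothesis("custom", points = list(
    pharmacophorePoint("HBD", unlist(g2@atoms[oIdx, c("x", "y", "z")]), 1)))
  expect_message(out <- extractPrimaryScaffold(pose2, hyp2),
                 "no ring-bearing")
  expect_null(out)

  # pose that does not match the hypothesis yields NULL up front
  lib <- fixtureLibrary(2)
  far <- lib$poses[[1]]
  far@atoms$x <- far@atoms$x + 50
  expect_message(out2 <- extractPrimaryScaffold(far, fixtureHypothesis()),
                 "key points not matched")
  expect_null(out2)
})

test_that("neutralization follows the set-charge-to-zero rule", {
  res <- neutralizeSmiles(c("[NH3+]CC(=O)[O-]", "c1ccccc1", "C[N+](C)(C)C"))
  expect_identical(res$smiles[1], canonicalizeSmiles("NCC(=O)O"))
  expect_identical(res$smiles[2], canonicalizeSmiles("c1ccccc1"))
  expect_false(res$unneutralizable[1])
  expect_false(res$unneutralizable[2])
  expect_true(res$unneutralizable[3])
  expect_identical(res$smiles[3], canonicalizeSmiles("C[N+](C)(C)C"))
  expect_error(neutralizeSmiles("xxx"), "unparseable")
})

test_that("crude scaffold aggregation dedups, filters ports and merges provenance", {
  rec <- data.frame(
    scaffold = c("[1*]c1ccc(O)cc1", "Oc1ccc(cc1)[1*]",  # same after canonicalization
                 "[1*]C([2*])([3*])c1ccc(cc1)[1*]",     # 4 ports -> dropped
                 "[1*]c1ccncc1"),
    molecule_id = c("m1", "m2", "m3", "m4"),
    experiment_id = c("e1", "e2", "e1", "e1"),
    stringsAsFactors = FALSE)
  cs <- collectCrudeScaffolds(rec)
  expect_identical(length(cs), 2L)
  expect_identical(attr(cs, "rejected"), 1L)
  prov <- cs@provenance[[1]]
  expect_setequal(prov$molecule_id, c("m1", "m2"))

  empty <- collectCrudeScaffolds(data.frame(scaffold = character(),
                                            molecule_id = character(),
                                            experiment_id = character()))
  expect_identical(length(empty), 0L)

  # idempotence: re-collecting the collected set changes nothing
  again <- collectCrudeScaffolds(data.frame(
    scaffold = scaffoldTable(cs)$scaffold,
    molecule_id = "x", experiment_id = "y"))
  expect_identical(scaffoldTable(again)$scaffold, scaffoldTable(cs)$scaffold)
})

test_that("peripheral fragments recover planted sides and rejoin to the parent", {
  lib <- fixtureLibrary(15)
  hyp <- fixtureHypothesis()
  for (i in seq_along(lib$poses)) {
    p <- lib$poses[[i]]
    sc <- extractPrimaryScaffold(p, hyp)
    per <- extractPeripheralFragments(p, attr(sc, "atomMap"), hyp)
    expect_length(per, 2)
    sides <- vapply(per, function(f) f@side, character(1))
    smis <- vapply(per, function(f) f@smiles, character(1))
    expect_identical(smis[sides == "left"], lib$truth$left[i])
    expect_identical(smis[sides == "right"], lib$truth$right[i])
    rejoined <- joinFragments(sc, smis[sides == "left"], smis[sides == "right"])
    expect_identical(rejoined, canonicalSmiles(p))
  }
})

test_that("degenerate peripheral cases behave as specified", {
  lib <- fixtureLibrary(2)
  hyp <- fixtureHypothesis()
  p <- lib$poses[[1]]
  # pose identical to scaffold: nothing peripheral
  expect_length(extractPeripheralFragments(p, seq_len(nrow(p@atoms)), hyp), 0)
  # fused periphery (two severed bonds) excluded with a warning
  g <- parseSmiles("c1ccc2c(c1)CCCC2")[[1]]
  tetralin <- new("Pose", atoms = g@atoms, bonds = g@bonds,
                  structureId = "tetralin", properties = character())
  aromAtoms <- which(g@atoms$arom)
  expect_warning(out <- extractPeripheralFragments(tetralin, aromAtoms, hyp),
                 "excluded")
  expect_length(out, 0)
  # invalid atom map is an error
  expect_error(extractPeripheralFragments(p, c(0L, 999L), hyp), "atom map")
})
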