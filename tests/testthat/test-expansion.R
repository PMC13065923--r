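test_that("trivalent expansion replaces aromatic-carbon ports combinatorially", {
  caps5 <- c("*C", "*F", "*Cl", "*OC", "*C#N")
  # exactly one aromatic-carbon port (ports 1 and 2 are aliphatic)
  tri <- asScaffold("[1*]C(C[2*])c1ccc(cc1)[3*]")
  ex <- expandTrivalent(tri, caps5)
  expect_length(ex, 5)
  expect_true(all(vapply(ex, function(s) length(s@ports) == 2, logical(1))))
  expect_true(all(vapply(ex, function(s) identical(s@ports, c(1L, 2L)),
                         logical(1))))

  # all three ports aromatic: upper bound 3 * m, deduplicated below it for a
  # symmetric scaffold
  tri2 <- asScaffold("[1*]c1cc([2*])cc([3*])c1")
  ex2 <- expandTrivalent(tri2, caps5)
  expect_lte(length(ex2), 3 * length(caps5))
  expect_gt(length(ex2), 0)

  # bivalent input passes through unchanged
  bi <- asScaffold("[1*]c1ccc(cc1)[2*]")
  expect_identical(expandTrivalent(bi, caps5), list(bi))

  # trivalent with no aromatic-carbon port is not expandable
  tri3 <- asScaffold("[1*]C([2*])([3*])C1CCCC1")
  expect_message(ex3 <- expandTrivalent(tri3, caps5), "no aromatic-carbon")
  expect_length(ex3, 0)

  # malformed capping fragment is a fatal configuration error
  expect_error(expandTrivalent(tri, c("*C*")), "exactly one attachment")
  expect_error(expandTrivalent(tri, character()), "empty")
})

test_that("hydrogen cap deletes the port", {
  tri <- asScaffold("[1*]C(C[2*])c1ccc(cc1)[3*]")
  ex <- expandTrivalent(tri, "[H]")
  expect_length(ex, 1)
  expect_identical(ex[[1]]@smiles,
                   asScaffold("[1*]C(C[2*])c1ccccc1")@smiles)
})

test_that("expansion commutes with canonicalization", {
  caps <- c("*C", "*OC")
  tri <- asScaffold("[3*]c1ccc(cc1)C([1*])C[2*]")   # same scaffold, other writing
  triCanon <- asScaffold(tri@smiles)
  a <- sort(vapply(expandTrivalent(tri, caps), function(s) s@smiles, character(1)))
  b <- sort(vapply(expandTrivalent(triCanon, caps), function(s) s@smiles, character(1)))
  expect_identical(a, b)
})

test_that("finalized scaffold sets contain no trivalent members", {
  rec <- data.frame(
    scaffold = c("[1*]c1ccc(O)cc1",                 # monovalent, kept
                 "[1*]C(C[2*])c1ccc(cc1)[3*]",      # trivalent, expandable
                 "[1*]C([2*])([3*])C1CCCC1"),       # trivalent, unexpandable
    molecule_id = c("m1", "m2", "m3"),
    experiment_id = "e1", stringsAsFactors = FALSE)
  crude <- collectCrudeScaffolds(rec)
  caps3 <- c("*C", "*F", "*Cl")
  fin <- suppressMessages(finalizeScaffoldSet(crude, caps3))
  expect_identical(length(fin), 4L)  # 1 mono + 3 expansions
  expect_true(all(vapply(fin, function(s) length(s@ports) <= 2, logical(1))))
  cnt <- attr(fin, "counts")
  expect_identical(unname(cnt["kept"]), 1L)
  expect_identical(unname(cnt["unexpandable"]), 1L)

  emptyFin <- finalizeScaffoldSet(collectCrudeScaffolds(
    data.frame(scaffold = character(), molecule_id = character(),
               experiment_id = character())), caps3)
  expect_length(emptyFin, 0)
})
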