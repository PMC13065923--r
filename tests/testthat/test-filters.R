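test_that("structural alerts flag matching substructures and pass clean input", {
  v <- mcfFilter(c("Cc1ccccc1",            # toluene: alert-free
                   "NN",                   # hydrazine
                   "O=[N+]([O-])c1ccccc1", # nitro
                   "definitely)not(smiles"),
                 "minimal")
  expect_true(v$passed[1])
  expect_false(v$passed[2]); expect_match(v$hits[2], "MCF09")
  expect_false(v$passed[3]); expect_match(v$hits[3], "MCF01")
  expect_false(v$passed[4]); expect_identical(v$hits[4], "UNPARSEABLE")

  cov <- mcfFilter(c("C=CC(=O)NC", "Cc1ccccc1"), "covalent")
  expect_false(cov$passed[1])
  expect_match(cov$hits[1], "COV01")
  expect_true(cov$passed[2])

  # invert mode selects the warhead-bearing molecules instead
  inv <- mcfFilter(c("C=CC(=O)NC", "Cc1ccccc1"), "covalent", invert = TRUE)
  expect_true(inv$passed[1]); expect_false(inv$passed[2])
})

test_that("minimal-subset containment holds and moderate inherits failures", {
  mod <- loadAlertRules("moderate")
  minl <- loadAlertRules("minimal")
  expect_true(all(minl@rules$rule_id %in% mod@rules$rule_id))
  bad <- c("NN", "O=[N+]([O-])c1ccccc1", "CC(=O)OO")
  vMin <- mcfFilter(bad, minl)
  vMod <- mcfFilter(bad, mod)
  expect_true(all(!vMod$passed[!vMin$passed]))
})

test_that("filtering is idempotent and kekulization-independent", {
  input <- c("Cc1ccccc1", "NN", "c1ccc2c(c1)cccc2", "CCOC(=O)C")
  v1 <- mcfFilter(input, "moderate")
  survivors <- v1$smiles[v1$passed]
  v2 <- mcfFilter(survivors, "moderate")
  expect_true(all(v2$passed))

  arom <- mcfFilter("c1ccccc1C=CC(=O)C", "moderate")
  kek <- mcfFilter("C1=CC=CC=C1C=CC(=O)C", "moderate")
  expect_identical(arom$passed, kek$passed)
  expect_identical(arom$hits, kek$hits)
})

test_that("descriptor annotation matches hand-derived values", {
  d <- annotateDescriptors(c("O", "c1ccccc1", "NCC(=O)O"))
  expect_equal(d$MW[1], 18.02, tolerance = 0.01)
  expect_identical(d$HBD[1], 1L); expect_identical(d$HBA[1], 1L)
  expect_identical(d$HBD[2], 0L); expect_identical(d$HBA[2], 0L)
  # glycine: donors N and O-H; acceptors N and both oxygens
  expect_identical(d$HBD[3], 2L); expect_identical(d$HBA[3], 3L)
  expect_equal(d$MW[3], 75.07, tolerance = 0.01)
  expect_error(annotateDescriptors("not-parseable"), "unparseable")
})

test_that("descriptor MW agrees with an independent calculator", {
  smis <- c("Cc1ccccc1", "NCC(=O)O", "CC(=O)Nc1ccc(O)cc1")
  mine <- annotateDescriptors(smis)$MW
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(smis, paste0("m", seq_along(smis)))))
  ref <- ChemmineR::propOB(sdf)$MW
  expect_equal(unname(mine), unname(ref), tolerance = 0.01)
})
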