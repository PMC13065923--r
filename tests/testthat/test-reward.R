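test_that("CRV equalizes rewards for all filter-passing structures", {
  cfg <- rewardConfig("CRV", constantValue = 1.0)
  expect_identical(crvReward(TRUE, cfg), 1.0)
  expect_true(is.na(crvReward(FALSE, cfg)))
  r <- crvReward(rep(TRUE, 25), cfg)
  expect_identical(stats::var(r), 0)
  expect_error(rewardConfig("CRV", constantValue = 0))
})

test_that("SPAG penalty follows max-similarity against the archive", {
  cfg <- rewardConfig("CRV+SPAG", constantValue = 1, penaltyWeight = 1)
  arch <- newGenerationArchive()
  r0 <- spagPenalty("Cc1ccccc1", 1, arch, cfg)
  expect_identical(r0$sMax, 0)        # empty archive: no penalty
  expect_identical(r0$reward, 1)
  r1 <- spagPenalty("Cc1ccccc1", 1, arch, cfg)
  expect_identical(r1$sMax, 1)        # identical to an archive member
  expect_identical(r1$reward, 0)
  expect_identical(length(arch), 2L)
})

test_that("archive max-similarity agrees with a brute-force pairwise scan", {
  members <- c("Cc1ccccc1", "CCO", "c1ccncc1", "CC(=O)Nc1ccc(O)cc1")
  cand <- "Cc1ccccc1O"
  arch <- newGenerationArchive()
  for (m in members) archiveInsert(arch, m)
  mine <- archiveMaxSimilarity(cand, arch)
  # independent brute-force scan over ChemmineR-derived fingerprint bits
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(c(members, cand), paste0("m", seq_len(length(members) + 1)))))
  fps <- methods::getMethod("as.matrix", "FPset")(
    ChemmineR::fingerprintOB(sdf, "FP2"))
  cf <- as.logical(fps[length(members) + 1, ])
  ref <- max(vapply(seq_along(members), function(i) {
    b <- as.logical(fps[i, ])
    sum(cf & b) / sum(cf | b)
  }, numeric(1)))
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("growing the archive never increases a candidate's reward", {
  cfg <- rewardConfig("CRV+SPAG")
  cand <- "Cc1ccc(O)cc1"
  arch <- newGenerationArchive()
  prev <- Inf
  for (m in c("CCCCCC", "c1ccccc1", "Cc1ccccc1", "Cc1ccc(N)cc1")) {
    archiveInsert(arch, m)
    s <- archiveMaxSimilarity(cand, arch)
    reward <- max(0, cfg@constantValue - cfg@penaltyWeight * s)
    expect_lte(reward, prev)
    prev <- reward
  }
})

test_that("archive order does not change the maximum similarity", {
  members <- c("CCO", "Cc1ccccc1", "c1ccncc1", "CCCN")
  cand <- "CCOC"
  a1 <- newGenerationArchive(); a2 <- newGenerationArchive()
  for (m in members) archiveInsert(a1, m)
  for (m in rev(members)) archiveInsert(a2, m)
  expect_identical(archiveMaxSimilarity(cand, a1),
                   archiveMaxSimilarity(cand, a2))
})

test_that("toy generation is deterministic and respects zero iterations", {
  seeds <- c("Cc1ccc(O)cc1", "c1ccncc1CC")
  r0 <- toyGenerate(seeds, nIterations = 0L, rngSeed = 5)
  expect_true(all(r0$accepted$smiles %in% canonicalizeSmiles(seeds)))
  a <- toyGenerate(seeds, nIterations = 25L, rngSeed = 9,
                   config = rewardConfig("CRV+SPAG"))
  b <- toyGenerate(seeds, nIterations = 25L, rngSeed = 9,
                   config = rewardConfig("CRV+SPAG"))
  expect_identical(a$accepted, b$accepted)
  expect_error(toyGenerate(character()), "empty")
})

test_that("diversity report counts planted scaffolds and ignores duplication", {
  lib <- fixtureLibrary(20)
  hyp <- fixtureHypothesis()
  div <- diversityReport(lib$poses, hyp)
  expect_identical(div$nUniquePrimaryScaffolds,
                   length(unique(lib$truth$scaffold)))

  smis <- c("Cc1ccccc1CC(=O)N", "c1ccncc1CCO")
  d1 <- diversityReport(smis)
  d2 <- diversityReport(rep(smis, 3))
  expect_identical(d1$nUniquePrimaryScaffolds, d2$nUniquePrimaryScaffolds)
  expect_identical(d1$nUniqueBemisMurcko, d2$nUniqueBemisMurcko)

  d0 <- diversityReport(character())
  expect_identical(d0$nUniquePrimaryScaffolds, 0L)
  expect_identical(d0$nUniqueBemisMurcko, 0L)
})
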