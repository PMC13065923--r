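poseFromSmiles <- function(smiles) {
  g <- parseSmiles(smiles)[[1]]
  new("Pose", atoms = g@atoms, bonds = g@bonds, structureId = smiles,
      properties = character())
}

test_that("feature perception follows the documented definitions", {
  methanol <- poseFromSmiles("CO")
  f <- perceiveFeatures(methanol)
  types <- vapply(f, `[[`, character(1), "ptype")
  oIdx <- which(methanol@atoms$elem == "O")
  expect_setequal(types, c("HBD", "HBA"))
  expect_true(all(vapply(f, function(x) identical(x$atoms, oIdx), logical(1))))

  benzene <- poseFromSmiles("c1ccccc1")
  f <- perceiveFeatures(benzene)
  types <- vapply(f, `[[`, character(1), "ptype")
  expect_setequal(types, c("HYD", "AROM"))
  arom <- f[[which(types == "AROM")]]
  expect_length(arom$atoms, 6)
  ringCenter <- colMeans(as.matrix(benzene@atoms[, c("x", "y", "z")]))
  expect_equal(as.numeric(arom$centroid), as.numeric(ringCenter), tolerance = 1e-8)

  butane <- poseFromSmiles("CCCC")
  f <- perceiveFeatures(butane)
  expect_identical(unique(vapply(f, `[[`, character(1), "ptype")), "HYD")

  expect_error(perceiveFeatures(butane, definitions = list()), "empty")
})

test_that("point matching is boundary-inclusive with nearest-feature choice", {
  feats <- list(
    list(ptype = "HBD", atoms = 1L, centroid = c(0, 0, 0)),
    list(ptype = "HBD", atoms = 2L, centroid = c(0.5, 0, 0)),
    list(ptype = "HBA", atoms = 3L, centroid = c(0, 0, 0)))
  pt <- pharmacophorePoint("HBD", c(0, 0, 0), 1.0)
  m <- pointMatched(feats, pt)
  expect_true(m$matched)
  expect_identical(m$best$atoms, 1L)
  expect_equal(m$distance, 0)

  # distance exactly equal to the radius still matches
  ptEdge <- pharmacophorePoint("HBD", c(1.0, 0, 0), 1.0)
  expect_true(pointMatched(feats[1], ptEdge)$matched)
  ptOut <- pharmacophorePoint("HBD", c(1.0 + 1e-9, 0, 0), 1.0)
  expect_false(pointMatched(feats[1], ptOut)$matched)

  # type mismatch never matches
  ptNeg <- pharmacophorePoint("NEG", c(0, 0, 0), 5)
  expect_false(pointMatched(feats, ptNeg)$matched)
})

test_that("point matching agrees with a brute-force scan on small poses", {
  lib <- fixtureLibrary(5)
  hyp <- fixtureHypothesis()
  for (p in lib$poses) {
    feats <- perceiveFeatures(p)
    for (pt in hyp@points) {
      m <- pointMatched(feats, pt)
      # independent scan over all (feature, point) pairs
      d <- vapply(feats, function(f)
        if (f$ptype == pt@ptype) sqrt(sum((f$centroid - pt@center)^2)) else Inf,
        numeric(1))
      expect_identical(m$matched, any(d <= pt@radius))
      if (m$matched) expect_equal(m$distance, min(d))
    }
  }
})

test_that("hypothesis matching gates on key points and reports key atoms", {
  lib <- fixtureLibrary(10)
  hyp <- fixtureHypothesis()
  for (p in lib$poses[1:5]) {
    rep <- matchHypothesis(p, hyp)
    expect_true(rep@allKeyMatched)
    expect_gt(length(rep@keyAtoms), 0)
  }
  # pose translated far away no longer matches
  far <- lib$poses[[1]]
  far@atoms$x <- far@atoms$x + 100
  rep <- matchHypothesis(far, hyp)
  expect_false(rep@allKeyMatched)
})

test_that("matching is invariant under joint rigid motion", {
  lib <- fixtureLibrary(5)
  hyp <- fixtureHypothesis()
  for (p in lib$poses) {
    r1 <- matchHypothesis(p, hyp)
    r2 <- matchHypothesis(transformPose(p), transformHypothesis(hyp))
    expect_identical(r1@perPoint$matched, r2@perPoint$matched)
    expect_identical(r1@allKeyMatched, r2@allKeyMatched)
    expect_identical(r1@keyAtoms, r2@keyAtoms)
    expect_equal(r1@perPoint$distance, r2@perPoint$distance, tolerance = 1e-8)
  }
})

test_that("enlarging any radius never unmatches a matched point", {
  lib <- fixtureLibrary(5, noiseSd = 0.5, rngSeed = 33)
  hyp <- fixtureHypothesis()
  for (p in lib$poses) {
    before <- matchHypothesis(p, hyp)@perPoint$matched
    hyp2 <- hyp
    hyp2@points <- lapply(hyp2@points, function(pt) { pt@radius <- pt@radius * 3; pt })
    after <- matchHypothesis(p, hyp2)@perPoint$matched
    expect_true(all(after[before]))
  }
})
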