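test_that("joining forms single bonds at the labeled ports", {
  expect_identical(joinFragments("[1*]c1ccc(cc1)[2*]", "C*", "OC*"),
                   canonicalizeSmiles("Cc1ccc(CO)cc1"))
  expect_identical(joinFragments("[1*]c1ccccc1", "C*"),
                   canonicalizeSmiles("Cc1ccccc1"))
  expect_error(joinFragments("[1*]c1ccc(cc1)[2*]", left = "C*"),
               "right fragment required")
  expect_error(joinFragments("[1*]c1ccccc1", left = NULL), "left fragment")
  expect_error(joinFragments("[1*]c1ccccc1", left = "*C*"), "exactly one")
})

test_that("space counting is exact integer arithmetic at any magnitude", {
  scB <- asScaffold("[1*]c1ccc(cc1)[2*]")
  scM <- asScaffold("[1*]c1ccccc1")

  spec <- enumerationSpec(rep(list(scB), 11935),
                          sprintf("L%d", 1:1288), sprintf("R%d", 1:7985))
  expect_identical(countSpace(spec)@total, "122747655800")

  specK <- enumerationSpec(rep(list(scB), 11935),
                           sprintf("L%d", 1:1288), sprintf("R%d", 1:7985),
                           kLeft = 100L, kRight = 100L, seed = 1L)
  expect_identical(countSpace(specK)@total, "119350000")

  # mixed mono/bivalent scaffolds count per-port
  specMix <- enumerationSpec(list(scB, scM), sprintf("L%d", 1:3),
                             sprintf("R%d", 1:4))
  expect_identical(countSpace(specMix)@total, "15")  # 3*4 + 3*1

  expect_identical(countSpace(enumerationSpec(list(), character(),
                                              character()))@total, "0")
  expect_identical(countSpace(enumerationSpec(list(scB), character(),
                                              sprintf("R%d", 1:5)))@total, "0")
})

test_that("big-integer arithmetic survives beyond 2^63", {
  expect_identical(bigProduct(2^40, 2^40), format(2^80, scientific = FALSE))
  ref <- suppressWarnings(system2(
    "python", c("-c", shQuote("print(123456789123 * 987654321987 * 31)")),
    stdout = TRUE))
  expect_identical(bigProduct(123456789123, 987654321987, 31), ref)
  expect_identical(bigSum(list("9999999999999999999999", 1)),
                   "10000000000000000000000")
})

test_that("streamed enumeration length plus skips equals the exact count", {
  pool <- list(asScaffold("[1*]c1ccc(cc1)[2*]"),
               asScaffold("[1*]c1ccccc1"),
               asScaffold("[1*]c1cc(C)c(cc1C)[2*]"),
               asScaffold("[2*]c1ccncc1"))
  lefts <- c("*C", "*CC", "*OC", "*C(C)C", "*F")
  rights <- c("*N", "*OC", "*C(=O)N", "*Cl")
  set.seed(77)
  for (rep in 1:8) {
    sc <- sample(pool, sample(1:3, 1))
    l <- sample(lefts, sample(1:4, 1))
    r <- sample(rights, sample(1:3, 1))
    spec <- enumerationSpec(sc, l, r)
    df <- enumerateProducts(spec)
    expect_identical(as.character(nrow(df) + attr(df, "skipped")),
                     countSpace(spec)@total)
    parsed <- parseSmiles(df$smiles)
    expect_false(any(vapply(parsed, is.null, logical(1))))
  }
})

test_that("enumeration order and content are deterministic", {
  spec <- enumerationSpec(list(asScaffold("[1*]c1ccc(cc1)[2*]")),
                          c("*C", "*CC", "*OC"), c("*N", "*F"))
  a <- enumerateProducts(spec)
  b <- enumerateProducts(spec)
  expect_identical(a, b)
  expect_identical(nrow(a), 6L)
  # lexicographic over (scaffold, left, right)
  expect_identical(a$left_index, rep(1:3, each = 2))
  expect_identical(a$right_index, rep(1:2, 3))
  # a sampled spec must be refused
  specK <- enumerationSpec(list(asScaffold("[1*]c1ccccc1")), c("*C"), c("*F"),
                           kLeft = 1L, kRight = 1L, seed = 3L)
  expect_error(enumerateProducts(specK), "sampleProducts")
})

test_that("seeded sampling is reproducible and exhaustive when k exceeds the pool", {
  sc <- list(asScaffold("[1*]c1ccc(cc1)[2*]"), asScaffold("[1*]c1ccncc1[2*]"))
  lefts <- paste0("*", c("C", "CC", "CCC", "CCCC", "OC", "OCC"))
  rights <- paste0("*", c("F", "Cl", "N", "OC"))
  spec <- enumerationSpec(sc, lefts, rights, kLeft = 3L, kRight = 2L, seed = 42L)
  s1 <- sampleProducts(spec)
  s2 <- sampleProducts(spec)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 2L * 3L * 2L)
  # file route is byte-identical too
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  sampleProducts(spec, out = f1); sampleProducts(spec, out = f2)
  expect_identical(readLines(f1), readLines(f2))
  # k larger than the pool uses every fragment
  specAll <- enumerationSpec(sc[1], lefts, rights, kLeft = 99L, kRight = 99L,
                             seed = 7L)
  expect_identical(nrow(sampleProducts(specAll)),
                   length(lefts) * length(rights))
  expect_error(sampleProducts(enumerationSpec(sc, lefts, rights)),
               "requires kLeft")
})

test_that("per-scaffold sampling is uniform over fragments", {
  sc <- list(asScaffold("[1*]c1ccccc1"))
  lefts <- paste0("*", c("C", "CC", "CCC", "N", "O", "F"))
  counts <- integer(length(lefts))
  nSeeds <- 300
  for (seed in seq_len(nSeeds)) {
    spec <- enumerationSpec(sc, lefts, character(), kLeft = 2L, kRight = 1L,
                            seed = seed)
    picked <- unique(sampleProducts(spec)$left_index)
    counts[picked] <- counts[picked] + 1L
  }
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})
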