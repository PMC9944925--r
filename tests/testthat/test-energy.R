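test_that("evalStructureEnergy sums pair terms and penalises non-canonical pairs", {
  hp <- parseDotBracket("(((...)))")
  r <- evalStructureEnergy("GGGAAACCC", hp)
  expect_equal(r$energy, -9)
  expect_equal(r$incompatible, 0L)

  r2 <- evalStructureEnergy("GGGAAACCA", hp)   # G-A pair forced: -3 -3 +6
  expect_equal(r2$energy, 0)
  expect_equal(r2$incompatible, 1L)

  open <- parseDotBracket(".........")
  expect_equal(evalStructureEnergy("GCGCAUAUG", open)$energy, 0)

  expect_error(evalStructureEnergy("GGGAAACCA", hp, energyParams(strict = TRUE)),
               "non-canonical")
  expect_error(evalStructureEnergy("GGGAAA", hp), "length mismatch")
})

test_that("energy is additive over pairs", {
  set.seed(7)
  for (rep in 1:10) {
    toy <- generateToyInstance(24, 5, seed = rep)
    s <- randomRna(24)
    total <- evalStructureEnergy(s, toy@target)$energy
    p <- basePairs(toy@target)
    single <- sum(vapply(seq_len(nrow(p)), function(r) {
      one <- parseDotBracket(paste(ifelse(seq_len(24) == p[r, 1], "(",
                              ifelse(seq_len(24) == p[r, 2], ")", ".")),
                              collapse = ""))
      evalStructureEnergy(s, one)$energy
    }, numeric(1)))
    expect_equal(total, single)
  }
})

test_that("mfeFold finds the exact optimum with a deterministic traceback", {
  r <- mfeFold("GGGAAACCC")
  expect_identical(dotBracket(r$structure), "(((...)))")
  expect_equal(r$energy, -9)

  r2 <- mfeFold("AAAAAAA")
  expect_identical(dotBracket(r2$structure), ".......")
  expect_equal(r2$energy, 0)

  r3 <- mfeFold("GAAAC")
  expect_identical(dotBracket(r3$structure), "(...)")
  expect_equal(r3$energy, -3)

  set.seed(11)
  s <- randomRna(40)
  expect_identical(dotBracket(mfeFold(s)$structure), dotBracket(mfeFold(s)$structure))
})

test_that("enumerateStructures lists every nested canonical structure once", {
  expect_equal(length(enumerateStructures("AAAA")), 1L)

  e <- enumerateStructures("GAAAC")
  expect_setequal(vapply(e, function(x) dotBracket(x$structure), character(1)),
                  c(".....", "(...)"))

  expect_equal(length(enumerateStructures("GGGAAACCC")),
               countStructuresOracle("GGGAAACCC"))
  set.seed(5)
  for (rep in 1:10) {
    s <- randomRna(sample(8:16, 1))
    e <- enumerateStructures(s)
    expect_equal(length(e), countStructuresOracle(s))
    dbs <- vapply(e, function(x) dotBracket(x$structure), character(1))
    expect_false(anyDuplicated(dbs) > 0)
  }
  expect_error(enumerateStructures(randomRna(23)), "22")
})

test_that("mfeFold energy equals the exhaustive-enumeration minimum", {
  set.seed(19)
  for (rep in 1:60) {
    s <- randomRna(sample(8:18, 1))
    brute <- min(vapply(enumerateStructures(s), `[[`, numeric(1), "energy"))
    expect_identical(mfeFold(s)$energy, brute)
  }
})

test_that("delta is target minus MFE energy and never negative", {
  hp <- parseDotBracket("(((...)))")
  expect_equal(deltaGap(deltaScore("GGGAAACCC", hp)), 0)
  expect_equal(deltaGap(deltaScore("GGGAAACCC", parseDotBracket("........."))), 9)
  expect_equal(deltaGap(deltaScore("AAAAAAAAA", parseDotBracket("........."))), 0)

  set.seed(23)
  for (rep in 1:40) {
    s <- randomRna(sample(14:25, 1))
    toy <- generateToyInstance(nchar(s), sample(2:4, 1), seed = rep)
    ds <- deltaScore(s, toy@target)
    expect_gte(deltaGap(ds), 0)
    expect_equal(deltaGap(ds), targetEnergy(ds) - mfeEnergy(ds))
  }
})

test_that("the builtin engine routed through the adapter reproduces deltaScore", {
  eng <- builtinEngine()
  set.seed(31)
  for (rep in 1:10) {
    toy <- generateToyInstance(20, 4, seed = rep)
    s <- randomRna(20)
    a <- deltaScore(s, toy@target)
    b <- deltaScoreEngine(s, toy@target, eng)
    expect_identical(deltaGap(a), deltaGap(b))
    expect_identical(targetEnergy(a), targetEnergy(b))
    expect_identical(incompatiblePairs(a), incompatiblePairs(b))
  }
})

test_that("the external engine honours the delta contract or fails loudly", {
  if (nzchar(Sys.which("RNAfold")) && nzchar(Sys.which("RNAeval"))) {
    eng <- viennaEngine()
    target <- parseDotBracket("(((((......)))))....")
    set.seed(37)
    for (rep in 1:3) {
      ds <- deltaScoreEngine(randomRna(20), target, eng)
      expect_gte(deltaGap(ds), 0)
    }
    # a perfect GC hairpin folds to its target in any sensible model
    ds <- deltaScoreEngine("GGGGGAAAAAACCCCCAAAA", target, eng)
    expect_equal(deltaGap(ds), 0)
  } else {
    expect_error(viennaEngine(), "unavailable")
  }
})
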