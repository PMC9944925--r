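test_that("findRepeats reports exactly the maximal runs at or above the threshold", {
  r <- findRepeats("AAAAGCGC", k = 4)
  expect_equal(r$start, 1L); expect_equal(r$end, 4L); expect_equal(r$nucleotide, "A")
  expect_equal(nrow(findRepeats("AUCG", k = 4)), 0L)
  r2 <- findRepeats("GGGGGAUUUU", k = 4)
  expect_equal(r2$start, c(1L, 7L))
  expect_equal(r2$end, c(5L, 10L))
  expect_equal(r2$nucleotide, c("G", "U"))
  expect_error(findRepeats("AAAA", k = 1), "k")
})

test_that("flipPair swaps partners, is an involution, and keeps wobble canonical", {
  hp <- parseDotBracket("(...)")
  expect_identical(flipPair("GAAAC", hp, c(1, 5)), "CAAAG")
  expect_identical(flipPair(flipPair("GAAAC", hp, c(1, 5)), hp, c(1, 5)), "GAAAC")
  flipped <- flipPair("GAAAU", hp, c(1, 5))         # G-U -> U-G
  expect_identical(flipped, "UAAAG")
  expect_equal(evalStructureEnergy(flipped, hp)$incompatible, 0L)
  expect_error(flipPair("GAAAC", hp, c(2, 4)), "not a pair")
})

test_that("switchPairType writes the requested canonical combination", {
  hp <- parseDotBracket("(...)")
  expect_identical(switchPairType("AAAAU", hp, c(1, 5), "CG"), "CAAAG")
  expect_identical(switchPairType("GAAAC", hp, c(1, 5), "GC"), "GAAAC")  # identity
  set.seed(71)
  for (to in c("AU", "UA", "CG", "GC")) {
    out <- switchPairType(randomRna(5), hp, c(1, 5), to)
    expect_equal(evalStructureEnergy(out, hp)$incompatible, 0L)
  }
})

test_that("wobbleToWcProposals offers both single-nucleotide fixes per wobble pair", {
  ss <- parseDotBracket("((...))")
  props <- wobbleToWcProposals("GGAAAUC", ss)       # pair (2,6) is G-U
  expect_equal(nrow(props), 2L)
  expect_setequal(props$sequence, c("GGAAACC", "GAAAAUC"))
  for (r in seq_len(nrow(props)))
    expect_equal(nrow(mutationsBetween("GGAAAUC", props$sequence[r])), 1L)
  expect_equal(nrow(wobbleToWcProposals("GGAAACC", ss)), 0L)
})

test_that("breakRepeatProposals respects pairing, locks and the IUPAC mask", {
  seq <- "AAAAGGGGCCCC"
  ss <- parseDotBracket("....((....))")
  run <- findRepeats(seq, k = 4)[1, ]               # positions 1-4, unpaired

  csFree <- constraintSet(12, budget = 12)
  p1 <- breakRepeatProposals(seq, ss, run, csFree)
  expect_equal(nrow(p1), 12L)                       # 4 positions x 3 alternatives
  expect_false(any(p1$paired))

  csLocked <- constraintSet(12, locked = 1:4, budget = 12)
  expect_equal(nrow(breakRepeatProposals(seq, ss, run, csLocked)), 0L)

  csMask <- constraintSet(12, mask = "RRRRNNNNNNNN", budget = 12)
  pm <- breakRepeatProposals(seq, ss, run, csMask)
  expect_equal(nrow(pm), 4L)
  expect_true(all(pm$to == "G"))                    # A -> G is the only masked move

  # a run overlapping paired positions yields flagged double proposals
  run2 <- data.frame(start = 5L, end = 8L)          # 5,6 paired; 7,8 unpaired
  p2 <- breakRepeatProposals(seq, ss, run2, csFree)
  expect_true(any(p2$paired) && any(!p2$paired))
  for (r in which(p2$paired)) {
    muts <- mutationsBetween(seq, p2$sequence[r])
    expect_lte(nrow(muts), 2L)
    expect_equal(evalStructureEnergy(p2$sequence[r], ss)$incompatible, 0L)
  }
})

test_that("classifyMutations recovers the generating operator classes", {
  db <- "((((...))))....."
  ss <- parseDotBracket(db)
  wt <- "GAUGAAACAUCAAAAA"
  stopifnot(evalStructureEnergy(wt, ss)$incompatible == 0L)

  # flip pair (1,11): G-C -> C-G
  d1 <- flipPair(wt, ss, c(1, 11))
  c1 <- classifyMutations(wt, d1, ss)
  expect_equal(c1$class, "PAIR_FLIP")
  expect_equal(c1$position, 1L)

  # AU -> CG switch at pair (2,10)
  d2 <- switchPairType(wt, ss, c(2, 10), "CG")
  c2 <- classifyMutations(wt, d2, ss)
  expect_equal(c2$class, "PAIR_TYPE_SWITCH")

  # wobble fix: pair (3,9) U-A -> make it wobble first, then fix G-U -> G-C
  wtW <- switchPairType(wt, ss, c(3, 9), "GC")
  wtW <- paste0(substr(wtW, 1, 8), "U", substr(wtW, 10, 16))  # G-U wobble
  fix <- wobbleToWcProposals(wtW, ss)
  cw <- classifyMutations(wtW, fix$sequence[1], ss)
  expect_equal(cw$class, "WOBBLE_TO_WC")

  # WC -> wobble, pair broken, unpaired substitution
  dWob <- paste0(substr(wt, 1, 10), "U", substr(wt, 12, 16))  # G-C -> G-U at (1,11)
  expect_equal(classifyMutations(wt, dWob, ss)$class, "WC_TO_WOBBLE")
  dBrk <- paste0(substr(wt, 1, 10), "A", substr(wt, 12, 16))  # G-C -> G-A
  expect_equal(classifyMutations(wt, dBrk, ss)$class, "PAIR_BROKEN")
  dUnp <- paste0(substr(wt, 1, 15), "C")
  expect_equal(classifyMutations(wt, dUnp, ss)$class, "UNPAIRED_SUBSTITUTION")

  # composite design: all operator classes recovered together, and the
  # classes partition the mutated positions
  comp <- flipPair(wt, ss, c(1, 11))
  comp <- switchPairType(comp, ss, c(2, 10), "CG")
  comp <- paste0(substr(comp, 1, 15), "G")
  cc <- classifyMutations(wt, comp, ss)
  expect_setequal(cc$class, c("PAIR_FLIP", "PAIR_TYPE_SWITCH", "UNPAIRED_SUBSTITUTION"))
  mutated <- mutationsBetween(wt, comp)$position
  covered <- unlist(lapply(seq_len(nrow(cc)), function(r)
    c(cc$position[r], cc$partner[r])))
  covered <- covered[!is.na(covered)]
  expect_true(all(mutated %in% covered))
  expect_false(anyDuplicated(covered) > 0)
})

test_that("every mutated position receives exactly one class on random designs", {
  set.seed(83)
  for (rep in 1:10) {
    toy <- generateToyInstance(30, 7, seed = rep)
    wt <- toy@witness
    ch <- strsplit(wt, "")[[1]]
    idx <- sample(30, 6)
    ch[idx] <- vapply(idx, function(p) sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1),
                      character(1))
    design <- paste(ch, collapse = "")
    cl <- classifyMutations(wt, design, toy@target)
    mutated <- mutationsBetween(wt, design)$position
    pt <- pairTable(toy@target)
    for (p in mutated) {
      hits <- sum(cl$position == p | (!is.na(cl$partner) & cl$partner == p))
      expect_equal(hits, 1L)
    }
    expect_true(all(cl$class %in% c("PAIR_FLIP", "PAIR_TYPE_SWITCH", "WOBBLE_TO_WC",
                                    "WC_TO_WOBBLE", "PAIR_BROKEN",
                                    "UNPAIRED_SUBSTITUTION")))
  }
})
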