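test_that("proposeMove samples uniformly over legal (position, nucleotide) moves", {
  wt <- "GAUCGAUCGA"
  cs <- constraintSet(10, budget = 10)
  set.seed(1)
  n <- 10000
  keys <- character(n)
  for (i in seq_len(n)) {
    mv <- proposeMove(wt, wt, cs)
    keys[i] <- paste0(mv$position, mv$to)
  }
  counts <- table(keys)
  expect_length(counts, 30L)          # 10 positions x 3 alternatives
  p <- 1 / 30
  band <- 3 * sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) <= band))
})

test_that("proposeMove honours locks and a saturated budget, and reports exhaustion", {
  wt <- "GAUC"
  allLocked <- constraintSet(4, locked = 1:4, budget = 4)
  expect_error(proposeMove(wt, wt, allLocked), class = "ribodesign_exhausted")

  # budget saturated: only already-mutated positions may change
  cs <- constraintSet(4, budget = 1)
  state <- "AAUC"                     # one mutation at position 1
  set.seed(2)
  for (i in 1:50) {
    mv <- proposeMove(state, wt, cs)
    expect_equal(mv$position, 1L)
  }

  # saturated budget with every mutated position locked: nothing to propose
  stuck <- constraintSet(4, locked = 1, budget = 0)
  expect_error(proposeMove(wt, wt, stuck), class = "ribodesign_exhausted")

  # iupac_restricted mode keeps proposals inside mask plus wild type
  csMask <- constraintSet(4, mask = "RNNN", budget = 4)
  set.seed(3)
  for (i in 1:30) {
    mv <- proposeMove(wt, wt, csMask, mode = "iupac_restricted")
    if (mv$position == 1L) expect_true(mv$to %in% c("A"))  # G -> A only (R = A/G)
  }
})

test_that("the Metropolis criterion accepts downhill always and uphill exponentially", {
  expect_true(all(metropolisAccept(5, 3, 1)))
  expect_true(all(metropolisAccept(rep(3, 100), rep(3, 100), 0.5)))  # equal: accept

  set.seed(4)
  acc <- metropolisAccept(rep(3, 2e4), rep(4, 2e4), 1.0)
  expect_lt(abs(mean(acc) - exp(-1)), 0.01)

  # greedy limit: uphill never accepted
  expect_false(any(metropolisAccept(rep(3, 1e4), rep(4, 1e4), 1e-6)))
  expect_error(metropolisAccept(1, 2, 0), "temperature")
})

test_that("trajectories are deterministic, replayable, and respect hard constraints", {
  toy <- generateToyInstance(30, 8, seed = 21, nLocked = 3)
  par <- mcParams(steps = 150)
  t1 <- runTrajectory(toy@wt, toy@target, toy@constraints, par, seed = 77)
  t2 <- runTrajectory(toy@wt, toy@target, toy@constraints, par, seed = 77)
  expect_identical(t1@moves, t2@moves)
  expect_identical(t1@finalSequence, t2@finalSequence)

  t0 <- runTrajectory(toy@wt, toy@target, toy@constraints, mcParams(steps = 0))
  expect_identical(t0@finalSequence, toy@wt)
  expect_equal(t0@finalDelta, deltaGap(deltaScore(toy@wt, toy@target)))

  states <- trajectoryStates(t1)
  expect_identical(states$sequence[nrow(states)], t1@finalSequence)
  wtc <- strsplit(toy@wt, "")[[1]]
  for (r in seq_len(nrow(states))) {
    ch <- strsplit(states$sequence[r], "")[[1]]
    expect_identical(ch[toy@constraints@locked], wtc[toy@constraints@locked])
    expect_lte(sum(ch != wtc), toy@constraints@budget)
  }
  expect_false(any(t1@moves$position %in% toy@constraints@locked))
})

test_that("a fully locked instance ends gracefully as exhausted", {
  toy <- generateToyInstance(20, 4, seed = 31)
  csAll <- constraintSet(20, locked = 1:20, budget = 2)
  tr <- runTrajectory(toy@wt, toy@target, csAll, mcParams(steps = 10))
  expect_true(tr@exhausted)
  expect_equal(nrow(tr@moves), 0L)
  expect_identical(tr@finalSequence, toy@wt)
})

test_that("in the greedy limit delta never increases along accepted moves", {
  toy <- generateToyInstance(30, 8, seed = 41)
  tr <- runTrajectory(toy@wt, toy@target, toy@constraints,
                      mcParams(steps = 200, temperature = 1e-6), seed = 5)
  acc <- tr@moves[tr@moves$accepted, ]
  expect_true(all(acc$delta_after <= acc$delta_before + 1e-12))
})

test_that("a single curative substitution is found by a greedy trajectory", {
  # construct an instance one mutation from delta 0, certified by scanning
  # all single mutants by brute force
  toy <- generateToyInstance(24, 6, seed = 51)
  wt <- toy@witness
  ch <- strsplit(wt, "")[[1]]
  p1 <- basePairs(toy@target)[1, 1]
  ch[p1] <- "A"                               # break one G-C pair
  start <- paste(ch, collapse = "")
  singles <- unlist(lapply(seq_len(24), function(p) {
    vapply(setdiff(c("A", "C", "G", "U"), strsplit(start, "")[[1]][p]), function(nt) {
      s2 <- strsplit(start, "")[[1]]; s2[p] <- nt; paste(s2, collapse = "")
    }, character(1))
  }))
  curing <- singles[vapply(singles, function(s)
    deltaGap(deltaScore(s, toy@target)) == 0, logical(1))]
  expect_gt(length(curing), 0)

  cs <- constraintSet(24, budget = 2)
  tr <- runTrajectory(start, toy@target, cs,
                      mcParams(steps = 240, temperature = 1e-6), seed = 9)
  expect_equal(tr@finalDelta, 0)
})

test_that("on a flat landscape the chain's stationary distribution is uniform", {
  # 6-mer over {A, C} (no canonical pair possible), open-chain target:
  # delta is identically 0, so every proposal is accepted and the walk
  # should visit all 64 sequences uniformly
  wt <- "AAAAAA"
  target <- parseDotBracket("......")
  cs <- constraintSet(6, mask = "MMMMMM", budget = 6)
  tr <- runTrajectory(wt, target, cs,
                      mcParams(steps = 1e5, mode = "iupac_restricted"), seed = 13)
  expect_true(all(tr@moves$accepted))
  states <- trajectoryStates(tr)
  thin <- states$sequence[seq(1000, nrow(states), by = 25)]
  counts <- table(factor(thin, levels = apply(
    expand.grid(rep(list(c("A", "C")), 6))[, 6:1], 1, paste, collapse = "")))
  expect_length(counts, 64L)
  expect_true(all(counts > 0))
  chisq <- sum((counts - length(thin) / 64)^2 / (length(thin) / 64))
  expect_lt(chisq, qchisq(0.999, df = 63))
})

test_that("selectBestPerMutationCount matches a brute-force scan and reports missing counts", {
  recs <- data.frame(
    sequence = c("s1", "s2", "s3"), mutations = c(2L, 2L, 3L),
    delta = c(1.5, 0.5, 0.2), trajectory = 1L, step = 1:3,
    stringsAsFactors = FALSE)
  pool <- new("DesignPool", wt = "AAAA", records = recs)
  sel <- selectBestPerMutationCount(pool, 2)
  expect_identical(sel$selected$sequence, "s2")
  expect_identical(selectBestPerMutationCount(pool, 4)$missing, 4L)

  set.seed(61)
  big <- data.frame(
    sequence = vapply(1:200, function(i) randomRna(12), character(1)),
    mutations = sample(1:8, 200, replace = TRUE),
    delta = round(runif(200, 0, 5), 2),
    trajectory = sample(1:5, 200, replace = TRUE),
    step = 1:200, stringsAsFactors = FALSE)
  pool2 <- new("DesignPool", wt = "AAAA", records = big)
  sel2 <- selectBestPerMutationCount(pool2, 1:10)
  for (m in 1:10) {
    sub <- big[big$mutations == m, ]
    if (!nrow(sub)) {
      expect_true(m %in% sel2$missing)
    } else {
      best <- sub[order(sub$delta, sub$sequence), ][1, ]
      got <- sel2$selected[sel2$selected$mutations == m, ]
      expect_identical(got$sequence, best$sequence)
      expect_identical(got$delta, best$delta)
    }
  }
})
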