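## reporting_fixtures: design curation against activity tables, pool
## summaries, and a synthetic puzzle generator so the whole pipeline is
## testable without any external data.

#' Curate robust designs from an activity table
#'
#' Applies the two-sided robustness cut used to shortlist high-diversity,
#' high-performing designs: at least \code{minMutations} mutations and
#' activity at least \code{minActivity} of wild type (defaults 6 and 0.80).
#' Input row order is preserved; the filter is idempotent.
#'
#' @param records data frame with (at least) columns \code{mutations} and
#'   \code{activity} (fraction of the wild-type maximum).
#' @param minMutations minimum mutation count (default 6).
#' @param minActivity minimum relative activity (default 0.80).
#' @return the qualifying subset of \code{records}, in input order.
#' @examples
#' tbl <- data.frame(name = c("d1", "d2"), mutations = c(7, 5),
#'                   activity = c(0.85, 0.95))
#' filterRobustDesigns(tbl)  # only d1
#' @export
filterRobustDesigns <- function(records, minMutations = 6L, minActivity = 0.80) {
  need <- c("mutations", "activity")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  records[records$mutations >= minMutations & records$activity >= minActivity, ,
          drop = FALSE]
}

## Sample a random nested structure with exactly nPairs pairs by repeatedly
## drawing a uniformly random legal pair insertion. A single greedy pass can
## paint itself into a corner (early pairs fragment the free positions), so
## feasible draws are retried; true infeasibility (a single helix could not
## hold nPairs pairs) errors immediately.
.sampleStructure <- function(L, nPairs, minLoop = 3L, maxRestarts = 100L) {
  if (nPairs > floor((L - minLoop) / 2) || (nPairs >= 1L && L < minLoop + 2L))
    stop(sprintf("infeasible geometry: cannot place %d nested pairs in %d nt (minLoop %d)",
                 nPairs, L, minLoop))
  onePass <- function() {
    pairs <- matrix(integer(0), ncol = 2L)
    partner <- integer(L)
    for (n in seq_len(nPairs)) {
      free <- which(partner == 0L)
      cand <- NULL
      for (i in free) {
        js <- free[free > i + minLoop]
        if (!length(js)) next
        ok <- vapply(js, function(j) {
          if (nrow(pairs) == 0L) return(TRUE)
          !any((pairs[, 1L] > i & pairs[, 1L] < j & pairs[, 2L] > j) |
               (pairs[, 1L] < i & pairs[, 2L] > i & pairs[, 2L] < j))
        }, logical(1))
        if (any(ok)) cand <- rbind(cand, cbind(i, js[ok]))
      }
      if (is.null(cand) || !nrow(cand)) return(NULL)
      pick <- cand[sample.int(nrow(cand), 1L), ]
      pairs <- rbind(pairs, pick)
      partner[pick[1L]] <- pick[2L]; partner[pick[2L]] <- pick[1L]
    }
    pairs
  }
  for (r in seq_len(maxRestarts)) {
    pairs <- onePass()
    if (!is.null(pairs)) return(.newStructure(L, pairs, minLoop))
  }
  stop(sprintf("could not sample a %d-pair structure on %d nt in %d attempts",
               nPairs, L, maxRestarts))
}

#' Generate a synthetic, certified-solvable design puzzle
#'
#' Builds a benchmark instance in three steps: (1) sample a random nested
#' target structure with \code{nPairs} pairs; (2) construct a witness
#' sequence that realises every target pair as G-C and fills unpaired
#' positions with A — under the built-in model no alternative structure of
#' that sequence can beat the target, so the witness has energy gap exactly
#' 0 (verified by [mfeFold()] at generation time); (3) corrupt between 1 and
#' \code{budget} randomly chosen paired positions to produce the "wild type"
#' starting point, so the witness stays within the mutation budget and
#' solver success is certifiable. Locked positions are drawn from
#' uncorrupted positions only, keeping the instance solvable. With
#' \code{nPairs = 0} the target is the open chain and the sequence is drawn
#' over \{A, C\}, which admits no canonical pair, so every reachable
#' sequence has gap 0. Deterministic per seed.
#'
#' @param L sequence length.
#' @param nPairs number of target pairs.
#' @param budgetFraction mutation budget as a fraction of \code{L}
#'   (default 0.10).
#' @param seed generator seed.
#' @param nLocked number of locked positions to draw (default 0).
#' @param energy an [EnergyParams-class].
#' @return a [ToyInstance-class].
#' @examples
#' generateToyInstance(30, 8, seed = 1)
#' @export
generateToyInstance <- function(L, nPairs, budgetFraction = 0.10, seed = 1L,
                                nLocked = 0L, energy = energyParams()) {
  stopifnot(L >= 1L, nPairs >= 0L)
  set.seed(seed)
  budget <- mutationBudget(L, budgetFraction)
  if (nPairs == 0L) {
    target <- .newStructure(L, matrix(integer(0), ncol = 2L), energy@minLoop)
    wt <- paste(sample(c("A", "C"), L, replace = TRUE), collapse = "")
    locked <- if (nLocked > 0L) sample.int(L, min(nLocked, L)) else integer(0)
    cs <- constraintSet(L, locked = locked, budget = budget)
    return(new("ToyInstance", wt = wt, target = target, constraints = cs,
               witness = wt, solvable = TRUE, seed = as.integer(seed)))
  }
  target <- .sampleStructure(L, nPairs, energy@minLoop)
  p <- basePairs(target)
  ch <- rep("A", L)
  ch[p[, 1L]] <- "G"
  ch[p[, 2L]] <- "C"
  witness <- paste(ch, collapse = "")
  stopifnot(deltaGap(deltaScore(witness, target, energy)) == 0)
  paired <- sort(c(p[, 1L], p[, 2L]))
  nCorrupt <- if (budget >= 1L) sample.int(min(budget, length(paired)), 1L) else 0L
  corrupt <- if (nCorrupt > 0L) sample(paired, nCorrupt) else integer(0)
  wtCh <- ch
  for (pos in corrupt)
    wtCh[pos] <- sample(setdiff(RNA_ALPHABET, wtCh[pos]), 1L)
  lockable <- setdiff(seq_len(L), corrupt)
  locked <- if (nLocked > 0L) sample(lockable, min(nLocked, length(lockable))) else integer(0)
  cs <- constraintSet(L, locked = locked, budget = budget)
  new("ToyInstance", wt = paste(wtCh, collapse = ""), target = target,
      constraints = cs, witness = witness, solvable = TRUE,
      seed = as.integer(seed))
}

#' Summarize a design pool by mutation count
#'
#' Per-mutation-count aggregation of a [DesignPool-class]: number of designs
#' and the minimum and median energy gap — the table behind plots of delta
#' against mutation count.
#'
#' @param pool a [DesignPool-class].
#' @return data frame with columns \code{mutations}, \code{n},
#'   \code{minDelta}, \code{medianDelta}, ascending by mutation count.
#' @export
summarizePool <- function(pool) {
  stopifnot(is(pool, "DesignPool"))
  recs <- poolRecords(pool)
  if (!nrow(recs)) stop("empty design pool")
  counts <- sort(unique(recs$mutations))
  do.call(rbind, lapply(counts, function(m) {
    d <- recs$delta[recs$mutations == m]
    data.frame(mutations = m, n = length(d), minDelta = min(d),
               medianDelta = median(d))
  }))
}
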