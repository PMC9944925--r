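## mc_designer: constrained Metropolis Monte Carlo sequence design.
##
## Trajectories start from the wild-type sequence and propose single-
## nucleotide substitutions; moves that reduce the energy gap to the target
## structure are accepted unconditionally, worsening moves pass the
## Metropolis criterion at a fixed temperature. Locked positions and the
## mutation budget are hard proposal filters: an illegal state is never
## visited, not rejected after the fact.

.exhaustionError <- function() {
  stop(errorCondition(
    "no legal move: all positions locked or budget saturated with no reverting moves",
    class = c("ribodesign_exhausted", "error", "condition")))
}

## Enumerate every legal (position, nucleotide) move as a data.frame.
## `state`/`wt` are character vectors of single nucleotides.
.legalMoves <- function(state, wt, cs, mode) {
  L <- length(state)
  hamming <- sum(state != wt)
  saturated <- hamming >= cs@budget
  positions <- setdiff(seq_len(L), cs@locked)
  if (saturated) positions <- positions[state[positions] != wt[positions]]
  pos <- integer(0); to <- character(0)
  useMask <- identical(mode, "iupac_restricted") && length(cs@mask) > 0L
  for (p in positions) {
    allowed <- if (useMask) union(iupacSet(cs@mask[p]), wt[p]) else RNA_ALPHABET
    alts <- setdiff(allowed, state[p])
    if (length(alts)) {
      pos <- c(pos, rep.int(p, length(alts)))
      to <- c(to, alts)
    }
  }
  list(position = pos, to = to)
}

#' Propose a single-nucleotide move under constraints
#'
#' Uniformly samples one legal (position, alternative nucleotide) move:
#' locked positions are excluded, the alternatives at a position are the
#' three other nucleotides (or the IUPAC-mask set plus the wild-type
#' nucleotide in \code{"iupac_restricted"} mode, so reverting is always
#' possible), and no move may push the Hamming distance to wild type above
#' the budget. When no legal move exists — every position locked, or the
#' budget saturated with nothing to revert — an error of class
#' \code{"ribodesign_exhausted"} is raised.
#'
#' @param state current sequence (RNA string).
#' @param wt wild-type sequence.
#' @param cs a [ConstraintSet-class].
#' @param mode \code{"free"} or \code{"iupac_restricted"}.
#' @return list with elements \code{position}, \code{from}, \code{to}.
#' @export
proposeMove <- function(state, wt, cs, mode = "free") {
  st <- .seqChars(state)
  wtc <- .seqChars(wt)
  mv <- .legalMoves(st, wtc, cs, mode)
  if (!length(mv$position)) .exhaustionError()
  k <- sample.int(length(mv$position), 1L)
  list(position = mv$position[k], from = st[mv$position[k]], to = mv$to[k])
}

#' Metropolis acceptance criterion
#'
#' Moves that do not increase the energy gap are accepted unconditionally;
#' a move increasing the gap by \code{d} is accepted with probability
#' \code{exp(-d / temperature)}. Vectorised; one uniform draw is consumed
#' per decision regardless of direction, so the random stream is
#' reproducible.
#'
#' @param deltaOld,deltaNew energy gaps before and after the move.
#' @param temperature Metropolis temperature, > 0.
#' @return logical vector of acceptances.
#' @examples
#' set.seed(1); mean(metropolisAccept(3, 4, 1.0))  # ~ exp(-1)
#' @export
metropolisAccept <- function(deltaOld, deltaNew, temperature) {
  stopifnot(temperature > 0)
  n <- max(length(deltaOld), length(deltaNew))
  deltaOld <- rep_len(deltaOld, n)
  deltaNew <- rep_len(deltaNew, n)
  u <- runif(n)
  deltaNew <= deltaOld | u < exp(-(deltaNew - deltaOld) / temperature)
}

#' Run one Metropolis Monte Carlo design trajectory
#'
#' Starts from the wild-type sequence and performs \code{params@steps}
#' proposals, logging every one. Deterministic for a fixed seed. If the
#' constraint system leaves no legal move the trajectory ends gracefully
#' with a partial log and \code{exhausted = TRUE}.
#'
#' @param wt wild-type RNA string.
#' @param target target [SecondaryStructure-class].
#' @param cs a [ConstraintSet-class].
#' @param params an [MCParams-class].
#' @param seed RNG seed (default \code{params@baseSeed}).
#' @param energy an [EnergyParams-class].
#' @return a [Trajectory-class].
#' @examples
#' toy <- generateToyInstance(20, 4, seed = 7)
#' tr <- runTrajectory(toy@wt, toy@target, toy@constraints,
#'                     mcParams(steps = 50), seed = 7)
#' @export
runTrajectory <- function(wt, target, cs, params = mcParams(),
                          seed = params@baseSeed, energy = energyParams()) {
  stopifnot(is(params, "MCParams"), is(cs, "ConstraintSet"))
  if (nchar(wt) != structureLength(target) || nchar(wt) != cs@length)
    stop("wild type, target and constraint set disagree on length")
  set.seed(seed)
  wtc <- .seqChars(wt)
  state <- wtc
  stateInt <- .encodeSeq(wt)
  tp <- basePairs(target)
  dNow <- .cpp_delta(stateInt, tp, energy@eGC, energy@eAU, energy@eGU,
                     energy@incompatPenalty, energy@minLoop)$delta
  n <- params@steps
  step <- integer(n); position <- integer(n)
  from <- character(n); to <- character(n)
  dBefore <- numeric(n); dAfter <- numeric(n); acc <- logical(n)
  exhausted <- FALSE
  done <- 0L
  for (s in seq_len(n)) {
    mv <- tryCatch(.legalMoves(state, wtc, cs, params@mode),
                   error = function(e) NULL)
    if (is.null(mv) || !length(mv$position)) { exhausted <- TRUE; break }
    k <- sample.int(length(mv$position), 1L)
    p <- mv$position[k]
    nt <- mv$to[k]
    oldInt <- stateInt[p]
    stateInt[p] <- match(nt, RNA_ALPHABET) - 1L
    dNew <- .cpp_delta(stateInt, tp, energy@eGC, energy@eAU, energy@eGU,
                       energy@incompatPenalty, energy@minLoop)$delta
    a <- metropolisAccept(dNow, dNew, params@temperature)
    step[s] <- s; position[s] <- p; from[s] <- state[p]; to[s] <- nt
    dBefore[s] <- dNow; dAfter[s] <- dNew; acc[s] <- a
    if (a) {
      state[p] <- nt
      dNow <- dNew
    } else {
      stateInt[p] <- oldInt
    }
    done <- s
  }
  keep <- seq_len(done)
  moves <- data.frame(step = step[keep], position = position[keep],
                      from = from[keep], to = to[keep],
                      delta_before = dBefore[keep], delta_after = dAfter[keep],
                      accepted = acc[keep], stringsAsFactors = FALSE)
  new("Trajectory", seed = as.integer(seed), wt = wt,
      finalSequence = paste(state, collapse = ""), finalDelta = dNow,
      moves = moves, exhausted = exhausted)
}

#' Replay a trajectory's accepted states
#'
#' Reconstructs every accepted intermediate sequence from the move log,
#' starting at the wild type (step 0).
#'
#' @param traj a [Trajectory-class].
#' @return data frame with columns \code{step}, \code{sequence},
#'   \code{delta}, \code{mutations} (Hamming distance to wild type).
#' @export
trajectoryStates <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  ch <- .seqChars(traj@wt)
  wtc <- ch
  d0 <- if (nrow(traj@moves)) traj@moves$delta_before[1L] else traj@finalDelta
  acc <- traj@moves[traj@moves$accepted, , drop = FALSE]
  n <- nrow(acc)
  steps <- integer(n + 1L); seqs <- character(n + 1L)
  deltas <- numeric(n + 1L); mutN <- integer(n + 1L)
  steps[1L] <- 0L; seqs[1L] <- paste(ch, collapse = ""); deltas[1L] <- d0
  hamming <- 0L
  for (r in seq_len(n)) {
    p <- acc$position[r]
    wasMut <- ch[p] != wtc[p]
    ch[p] <- acc$to[r]
    isMut <- ch[p] != wtc[p]
    hamming <- hamming + (isMut - wasMut)
    steps[r + 1L] <- acc$step[r]
    seqs[r + 1L] <- paste(ch, collapse = "")
    deltas[r + 1L] <- acc$delta_after[r]
    mutN[r + 1L] <- hamming
  }
  data.frame(step = steps, sequence = seqs, delta = deltas,
             mutations = mutN, stringsAsFactors = FALSE)
}

#' Run a campaign of independent trajectories and pool the designs
#'
#' Launches \code{params@nTrajectories} trajectories (trajectory \code{k}
#' seeded with \code{params@baseSeed + k}) and collects every accepted state
#' — not only endpoints — into a [DesignPool-class], mirroring the protocol
#' in which all sequences visited by the trajectories are taken together
#' before per-mutation-count selection.
#'
#' @inheritParams runTrajectory
#' @return list with elements \code{pool} ([DesignPool-class]) and
#'   \code{trajectories} (list of [Trajectory-class]).
#' @export
runCampaign <- function(wt, target, cs, params = mcParams(),
                        energy = energyParams()) {
  trajs <- lapply(seq_len(params@nTrajectories), function(k) {
    runTrajectory(wt, target, cs, params, seed = params@baseSeed + k,
                  energy = energy)
  })
  recs <- do.call(rbind, lapply(trajs, function(tr) {
    st <- trajectoryStates(tr)
    st <- st[st$step > 0L, , drop = FALSE]   # accepted states only
    if (!nrow(st)) return(NULL)
    data.frame(sequence = st$sequence, mutations = st$mutations,
               delta = st$delta, trajectory = tr@seed, step = st$step,
               stringsAsFactors = FALSE)
  }))
  if (is.null(recs))
    recs <- data.frame(sequence = character(0), mutations = integer(0),
                       delta = numeric(0), trajectory = integer(0),
                       step = integer(0), stringsAsFactors = FALSE)
  list(pool = new("DesignPool", wt = wt, records = recs),
       trajectories = trajs)
}

#' Select the lowest-delta design at each mutation count
#'
#' The pool-selection protocol used for the computational-prediction
#' comparison: for each requested mutation count present in the pool, the
#' record with the smallest energy gap is returned (ties broken by the
#' lexicographically smallest sequence); requested counts with no record in
#' the pool are reported as missing, never silently dropped.
#'
#' @param pool a [DesignPool-class].
#' @param counts integer vector of requested mutation counts.
#' @return list with elements \code{selected} (data frame, one row per found
#'   count) and \code{missing} (integer vector of absent counts).
#' @export
selectBestPerMutationCount <- function(pool, counts) {
  stopifnot(is(pool, "DesignPool"))
  recs <- poolRecords(pool)
  if (!nrow(recs)) stop("empty design pool")
  counts <- sort(unique(as.integer(counts)))
  rows <- list(); missing <- integer(0)
  for (m in counts) {
    sub <- recs[recs$mutations == m, , drop = FALSE]
    if (!nrow(sub)) { missing <- c(missing, m); next }
    sub <- sub[order(sub$delta, sub$sequence), , drop = FALSE]
    rows[[length(rows) + 1L]] <- sub[1L, , drop = FALSE]
  }
  selected <- if (length(rows)) do.call(rbind, rows) else recs[0L, , drop = FALSE]
  rownames(selected) <- NULL
  list(selected = selected, missing = missing)
}
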