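#' @useDynLib RiboDesign, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats runif median setNames
#' @importFrom utils head read.table write.table
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")

## ---- SecondaryStructure -----------------------------------------------------

#' Nested RNA secondary structure
#'
#' An \code{SecondaryStructure} holds a set of base pairs over a sequence of a
#' given length. Pairs are stored 1-based with \code{i < j}, each position
#' belongs to at most one pair, pairs are non-crossing (nested), and every
#' hairpin loop encloses at least \code{minLoop} unpaired residues. This is the
#' "target" structure of a design problem: the experimentally known fold the
#' designed sequence must keep energetically favourable.
#'
#' @slot length sequence length the structure refers to.
#' @slot pairs integer matrix with columns \code{i}, \code{j}, sorted by
#'   \code{i}; zero rows encode the open chain.
#' @slot minLoop minimum number of unpaired residues in a hairpin loop
#'   (default 3, shared with the energy model).
#'
#' @seealso [parseDotBracket()], [parseCT()], [dotBracket()]
#' @export
setClass("SecondaryStructure",
  representation(length = "integer", pairs = "matrix", minLoop = "integer"))

setValidity("SecondaryStructure", function(object) {
  L <- object@length
  p <- object@pairs
  if (length(L) != 1L || is.na(L) || L < 1L) return("length must be a single positive integer")
  if (!is.numeric(p) || ncol(p) != 2L) return("pairs must be a two-column matrix")
  if (nrow(p) == 0L) return(TRUE)
  if (any(p < 1L) || any(p > L)) return("pair positions outside [1, length]")
  if (any(p[, 1L] >= p[, 2L])) return("pairs must satisfy i < j")
  if (anyDuplicated(c(p[, 1L], p[, 2L]))) return("a position occurs in more than one pair")
  if (any(p[, 2L] - p[, 1L] - 1L < object@minLoop))
    return(sprintf("hairpin loop shorter than minLoop = %d", object@minLoop))
  ## nesting: no i < k < j < l
  n <- nrow(p)
  for (r in seq_len(n)) {
    i <- p[r, 1L]; j <- p[r, 2L]
    crossing <- (p[, 1L] > i & p[, 1L] < j & p[, 2L] > j) |
                (p[, 1L] < i & p[, 2L] > i & p[, 2L] < j)
    if (any(crossing)) return("crossing (pseudoknotted) pairs are not allowed")
  }
  TRUE
})

.newStructure <- function(length, pairs, minLoop = 3L) {
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  if (nrow(pairs) > 1L) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  new("SecondaryStructure", length = as.integer(length), pairs = pairs,
      minLoop = as.integer(minLoop))
}

#' @describeIn SecondaryStructure-class number of residues covered
#' @param x,object a \code{SecondaryStructure}
#' @export
structureLength <- function(x) x@length

#' @describeIn SecondaryStructure-class the pair matrix (columns \code{i}, \code{j})
#' @export
basePairs <- function(x) x@pairs

#' @describeIn SecondaryStructure-class partner vector: position of the paired
#'   residue, 0 when unpaired
#' @export
pairTable <- function(x) {
  pt <- integer(x@length)
  p <- x@pairs
  pt[p[, 1L]] <- p[, 2L]
  pt[p[, 2L]] <- p[, 1L]
  pt
}

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure of length %d with %d pairs\n  %s\n",
              object@length, nrow(object@pairs), dotBracket(object)))
})

## ---- EnergyParams -----------------------------------------------------------

#' Pair-additive energy model parameters
#'
#' The built-in energy model assigns each canonical base pair a fixed
#' stabilising energy (GC strongest, then AU, then the GU wobble pair) and
#' charges a positive penalty for every non-canonical pair a target structure
#' forces; unpaired residues contribute nothing. The penalty is finite so that
#' Monte Carlo trajectories can traverse intermediate states; \code{strict}
#' turns a forced non-canonical pair into an error instead.
#'
#' @slot eGC,eAU,eGU pair energies in arbitrary units; must satisfy
#'   \code{eGC <= eAU <= eGU < 0}.
#' @slot incompatPenalty positive energy charged per forced non-canonical pair.
#' @slot minLoop minimum hairpin-loop size used by the fold.
#' @slot strict error on non-canonical forced pairs instead of penalising.
#' @export
setClass("EnergyParams",
  representation(eGC = "numeric", eAU = "numeric", eGU = "numeric",
                 incompatPenalty = "numeric", minLoop = "integer",
                 strict = "logical"))

setValidity("EnergyParams", function(object) {
  with_slots <- c(object@eGC, object@eAU, object@eGU, object@incompatPenalty)
  if (any(is.na(with_slots))) return("energy parameters must be finite")
  if (!(object@eGC <= object@eAU && object@eAU <= object@eGU && object@eGU < 0))
    return("pair energies must satisfy eGC <= eAU <= eGU < 0")
  if (object@incompatPenalty <= 0) return("incompatPenalty must be positive")
  if (object@minLoop < 0L) return("minLoop must be non-negative")
  TRUE
})

#' Construct energy-model parameters
#'
#' @param eGC,eAU,eGU canonical pair energies (defaults -3, -2, -1).
#' @param incompatPenalty penalty per forced non-canonical pair (default +6).
#' @param minLoop minimum hairpin-loop size (default 3).
#' @param strict if \code{TRUE}, forced non-canonical pairs are an error.
#' @return an [EnergyParams-class] object.
#' @examples
#' energyParams()
#' @export
energyParams <- function(eGC = -3, eAU = -2, eGU = -1, incompatPenalty = 6,
                         minLoop = 3L, strict = FALSE) {
  new("EnergyParams", eGC = as.numeric(eGC), eAU = as.numeric(eAU),
      eGU = as.numeric(eGU), incompatPenalty = as.numeric(incompatPenalty),
      minLoop = as.integer(minLoop), strict = strict)
}

setMethod("show", "EnergyParams", function(object) {
  cat(sprintf(
    "EnergyParams: GC %.2f, AU %.2f, GU %.2f; incompatible pair +%.2f; minLoop %d%s\n",
    object@eGC, object@eAU, object@eGU, object@incompatPenalty, object@minLoop,
    if (object@strict) " (strict)" else ""))
})

## ---- DeltaScore -------------------------------------------------------------

#' Energy-gap score of a sequence against a target structure
#'
#' \code{delta = targetEnergy - mfeEnergy}: how far the target structure is
#' from being an optimal fold of the sequence. A delta of 0 means the target
#' is (one of) the sequence's minimum free energy structures. The gap is
#' non-negative by construction: dropping the incompatible pairs from the
#' target yields a valid structure at least as good, and the MFE is at least
#' as good as that.
#'
#' @slot targetEnergy energy the sequence assigns to the target structure.
#' @slot mfeEnergy energy of the sequence's MFE structure.
#' @slot delta the gap, \code{targetEnergy - mfeEnergy}.
#' @slot incompatiblePairs number of target pairs the sequence cannot form
#'   canonically.
#' @export
setClass("DeltaScore",
  representation(targetEnergy = "numeric", mfeEnergy = "numeric",
                 delta = "numeric", incompatiblePairs = "integer"))

setValidity("DeltaScore", function(object) {
  if (abs(object@delta - (object@targetEnergy - object@mfeEnergy)) > 1e-9)
    return("delta must equal targetEnergy - mfeEnergy")
  if (object@delta < -1e-9) return("delta must be non-negative")
  TRUE
})

#' @describeIn DeltaScore-class the energy gap
#' @param x,object a \code{DeltaScore}
#' @export
deltaGap <- function(x) x@delta

#' @describeIn DeltaScore-class energy of the target structure
#' @export
targetEnergy <- function(x) x@targetEnergy

#' @describeIn DeltaScore-class energy of the MFE structure
#' @export
mfeEnergy <- function(x) x@mfeEnergy

#' @describeIn DeltaScore-class count of forced non-canonical target pairs
#' @export
incompatiblePairs <- function(x) x@incompatiblePairs

setMethod("show", "DeltaScore", function(object) {
  cat(sprintf("DeltaScore: delta %.3f (target %.3f, MFE %.3f, %d incompatible pairs)\n",
              object@delta, object@targetEnergy, object@mfeEnergy,
              object@incompatiblePairs))
})

## ---- ConstraintSet / ConstraintReport --------------------------------------

#' Design constraint system
#'
#' Bundles the puzzle constraints applied to candidate designs: a hard
#' mutation budget (maximum Hamming distance to wild type), positions locked
#' to their wild-type identity, an optional per-position IUPAC conservation
#' mask (which substitutions are observed in related organisms), and an
#' optional advisory list of protein-contact positions. Locks and the budget
#' are hard constraints for the Monte Carlo designer; mask and contacts are
#' reported, never enforced.
#'
#' @slot length length of the wild-type sequence the constraints refer to.
#' @slot locked 1-based positions that must keep their wild-type nucleotide.
#' @slot mask character vector of per-position IUPAC symbols (length 0 = no
#'   mask).
#' @slot budget maximum number of mutations tolerated.
#' @slot contacts advisory 1-based positions contacting ribosomal proteins.
#' @seealso [constraintSet()], [checkDesign()], [mutationBudget()]
#' @export
setClass("ConstraintSet",
  representation(length = "integer", locked = "integer", mask = "character",
                 budget = "integer", contacts = "integer"))

setValidity("ConstraintSet", function(object) {
  L <- object@length
  if (length(L) != 1L || L < 1L) return("length must be a single positive integer")
  if (length(object@locked) && (any(object@locked < 1L) || any(object@locked > L)))
    return("locked positions outside [1, length]")
  if (anyDuplicated(object@locked)) return("duplicated locked positions")
  if (length(object@mask) && length(object@mask) != L)
    return("mask must cover every position")
  if (length(object@mask) && !all(object@mask %in% names(IUPAC_SETS)))
    return("mask contains a symbol outside the IUPAC nucleotide code")
  if (object@budget < 0L) return("budget must be non-negative")
  if (length(object@contacts) && (any(object@contacts < 1L) || any(object@contacts > L)))
    return("contact positions outside [1, length]")
  TRUE
})

#' Construct a constraint set
#'
#' @param length wild-type sequence length.
#' @param locked integer vector of locked 1-based positions.
#' @param mask IUPAC mask: either a single string of length \code{length} or a
#'   character vector of per-position symbols; \code{NULL} for no mask.
#' @param budget maximum mutation count; defaults to the 5\% convention,
#'   \code{mutationBudget(length, 0.05)}.
#' @param contacts advisory protein-contact positions.
#' @return a [ConstraintSet-class].
#' @examples
#' constraintSet(30, locked = c(1, 2), budget = 3)
#' @export
constraintSet <- function(length, locked = integer(0), mask = NULL,
                          budget = mutationBudget(length, 0.05),
                          contacts = integer(0)) {
  if (!is.null(mask)) {
    if (length(mask) == 1L && nchar(mask) > 1L) mask <- strsplit(mask, "")[[1]]
    mask <- toupper(as.character(mask))
  } else mask <- character(0)
  new("ConstraintSet", length = as.integer(length),
      locked = sort(unique(as.integer(locked))), mask = mask,
      budget = as.integer(budget),
      contacts = sort(unique(as.integer(contacts))))
}

setMethod("show", "ConstraintSet", function(object) {
  cat(sprintf("ConstraintSet over %d nt: budget %d, %d locked, mask %s, %d contact positions\n",
              object@length, object@budget, length(object@locked),
              if (length(object@mask)) "present" else "none",
              length(object@contacts)))
})

#' Constraint compliance report for one design
#'
#' @slot mutationCount Hamming distance between design and wild type.
#' @slot budgetOk \code{TRUE} iff \code{mutationCount <= budget}.
#' @slot lockedViolations mutated positions that were locked.
#' @slot iupacViolations mutated positions whose design nucleotide falls
#'   outside the IUPAC mask.
#' @slot contactMutations mutated positions on the advisory contact list.
#' @seealso [checkDesign()]
#' @export
setClass("ConstraintReport",
  representation(mutationCount = "integer", budgetOk = "logical",
                 lockedViolations = "integer", iupacViolations = "integer",
                 contactMutations = "integer"))

setMethod("show", "ConstraintReport", function(object) {
  cat(sprintf(
    "ConstraintReport: %d mutations (budget %s), locked violations: %s, IUPAC violations: %s, contact mutations: %s\n",
    object@mutationCount, if (object@budgetOk) "ok" else "EXCEEDED",
    if (length(object@lockedViolations)) paste(object@lockedViolations, collapse = ",") else "none",
    if (length(object@iupacViolations)) paste(object@iupacViolations, collapse = ",") else "none",
    if (length(object@contactMutations)) paste(object@contactMutations, collapse = ",") else "none"))
})

## ---- MCParams / Trajectory / DesignPool ------------------------------------

#' Monte Carlo design parameters
#'
#' @slot temperature Metropolis temperature in energy-model units; worsening
#'   moves with gap increase \code{d} are accepted with probability
#'   \code{exp(-d / temperature)}.
#' @slot steps proposals per trajectory.
#' @slot nTrajectories number of independent trajectories in a campaign.
#' @slot baseSeed trajectory \code{k} is seeded with \code{baseSeed + k}.
#' @slot mode \code{"free"} (any of the 3 alternative nucleotides) or
#'   \code{"iupac_restricted"} (alternatives limited to the mask).
#' @export
setClass("MCParams",
  representation(temperature = "numeric", steps = "integer",
                 nTrajectories = "integer", baseSeed = "integer",
                 mode = "character"))

setValidity("MCParams", function(object) {
  if (object@temperature <= 0) return("temperature must be positive")
  if (object@steps < 0L) return("steps must be non-negative")
  if (object@nTrajectories < 1L) return("need at least one trajectory")
  if (!object@mode %in% c("free", "iupac_restricted"))
    return('mode must be "free" or "iupac_restricted"')
  TRUE
})

#' Construct Monte Carlo parameters
#'
#' The default temperature of 1.0 (in built-in energy units) is held constant
#' along the trajectory; there is no annealing schedule.
#'
#' @param temperature Metropolis temperature, > 0.
#' @param steps proposals per trajectory.
#' @param nTrajectories trajectories per campaign.
#' @param baseSeed base RNG seed; trajectory \code{k} uses \code{baseSeed + k}.
#' @param mode proposal mode, \code{"free"} or \code{"iupac_restricted"}.
#' @return an [MCParams-class].
#' @export
mcParams <- function(temperature = 1.0, steps = 100L, nTrajectories = 1L,
                     baseSeed = 1L, mode = c("free", "iupac_restricted")) {
  new("MCParams", temperature = as.numeric(temperature),
      steps = as.integer(steps), nTrajectories = as.integer(nTrajectories),
      baseSeed = as.integer(baseSeed), mode = match.arg(mode))
}

#' One seeded Metropolis Monte Carlo design trajectory
#'
#' The \code{moves} log records every proposal: step, position, the nucleotide
#' replaced and proposed, the energy gap before and after, and whether the
#' move passed the Metropolis criterion. Replaying the accepted moves from the
#' wild-type sequence reproduces \code{finalSequence} exactly.
#'
#' @slot seed RNG seed the trajectory ran under.
#' @slot wt wild-type (starting) sequence.
#' @slot finalSequence sequence after the last accepted move.
#' @slot finalDelta energy gap of \code{finalSequence}.
#' @slot moves data frame log of all proposals.
#' @slot exhausted \code{TRUE} if the trajectory stopped early because no
#'   legal move existed.
#' @seealso [runTrajectory()], [trajectoryStates()]
#' @export
setClass("Trajectory",
  representation(seed = "integer", wt = "character", finalSequence = "character",
                 finalDelta = "numeric", moves = "data.frame",
                 exhausted = "logical"))

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory (seed %d): %d proposals, %d accepted, final delta %.3f%s\n",
              object@seed, nrow(object@moves), sum(object@moves$accepted),
              object@finalDelta,
              if (object@exhausted) " [stopped: no legal move]" else ""))
})

#' Pool of candidate designs harvested from Monte Carlo trajectories
#'
#' Every accepted state of every trajectory enters the pool (not only the
#' endpoints), together with its mutation count relative to wild type, its
#' energy gap, and its provenance (trajectory seed and step).
#'
#' @slot wt wild-type sequence the mutation counts refer to.
#' @slot records data frame with columns \code{sequence}, \code{mutations},
#'   \code{delta}, \code{trajectory}, \code{step}.
#' @seealso [runCampaign()], [selectBestPerMutationCount()], [summarizePool()]
#' @export
setClass("DesignPool",
  representation(wt = "character", records = "data.frame"))

setValidity("DesignPool", function(object) {
  need <- c("sequence", "mutations", "delta", "trajectory", "step")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' @describeIn DesignPool-class the records data frame
#' @param x,object a \code{DesignPool}
#' @export
poolRecords <- function(x) x@records

#' @describeIn DesignPool-class the wild-type sequence
#' @export
poolWildType <- function(x) x@wt

setMethod("show", "DesignPool", function(object) {
  cat(sprintf("DesignPool: %d designs from %d trajectories (wild type %d nt)\n",
              nrow(object@records), length(unique(object@records$trajectory)),
              nchar(object@wt)))
})

## ---- ToyInstance ------------------------------------------------------------

#' Synthetic design puzzle
#'
#' A self-contained benchmark instance: a wild-type sequence, a target
#' structure, and a constraint set. When \code{solvable}, a witness sequence
#' with energy gap exactly 0 and within the mutation budget is stored, so
#' solver success can be certified.
#'
#' @slot wt starting sequence handed to the designer.
#' @slot target the target [SecondaryStructure-class].
#' @slot constraints the [ConstraintSet-class] in force.
#' @slot witness a delta-0 sequence within budget (empty when not solvable).
#' @slot solvable whether a stored witness certifies solvability.
#' @slot seed generator seed.
#' @seealso [generateToyInstance()]
#' @export
setClass("ToyInstance",
  representation(wt = "character", target = "SecondaryStructure",
                 constraints = "ConstraintSet", witness = "character",
                 solvable = "logical", seed = "integer"))

setMethod("show", "ToyInstance", function(object) {
  cat(sprintf("ToyInstance (seed %d): %d nt, %d target pairs, budget %d%s\n",
              object@seed, nchar(object@wt), nrow(basePairs(object@target)),
              object@constraints@budget,
              if (object@solvable) ", solvable (witness stored)" else ""))
})

## ---- FoldEngine -------------------------------------------------------------

#' Pluggable folding engine
#'
#' Adapter contract for computing the energy-gap score with an arbitrary
#' engine: \code{evalFun(sequence, structure)} returns the energy the engine
#' assigns to a given structure, \code{foldFun(sequence)} returns
#' \code{list(structure =, energy =)} for the engine's MFE fold. The rest of
#' the package is engine-agnostic; [builtinEngine()] routes the built-in
#' model through this interface and [viennaEngine()] wraps the ViennaRNA
#' command-line programs when they are installed.
#'
#' @slot name engine label.
#' @slot foldFun MFE fold function.
#' @slot evalFun structure-energy evaluation function.
#' @seealso [deltaScoreEngine()]
#' @export
setClass("FoldEngine",
  representation(name = "character", foldFun = "function", evalFun = "function"))

setMethod("show", "FoldEngine", function(object) {
  cat(sprintf("FoldEngine: %s\n", object@name))
})
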