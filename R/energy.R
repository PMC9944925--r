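## energy: structure energies, MFE folding and the energy-gap ("delta") score.
##
## The built-in model is deliberately simple and fully checkable: each
## canonical pair contributes a fixed energy (GC < AU < GU < 0), a forced
## non-canonical pair costs a finite positive penalty, unpaired residues cost
## nothing. The MFE is the exact minimum over all nested canonical structures
## (O(n^3) dynamic program in C++), so an exhaustive enumeration oracle can
## certify it on small sequences.

CANONICAL_PAIRS <- c("GC", "CG", "AU", "UA", "GU", "UG")
WC_PAIRS <- c("GC", "CG", "AU", "UA")
WOBBLE_PAIRS <- c("GU", "UG")

.isCanonical <- function(a, b) paste0(a, b) %in% CANONICAL_PAIRS

#' Energy a sequence assigns to a fixed secondary structure
#'
#' Sums the pair energies over the structure's base pairs. A pair the
#' sequence cannot form canonically contributes \code{+incompatPenalty} and
#' is counted; with \code{strict = TRUE} in the parameters it is an error
#' instead.
#'
#' @param seq RNA string (see [normalizeSequence()]).
#' @param ss a [SecondaryStructure-class] of matching length.
#' @param params an [EnergyParams-class]; default [energyParams()].
#' @return list with elements \code{energy} and \code{incompatible} (count of
#'   non-canonical forced pairs).
#' @examples
#' evalStructureEnergy("GGGAAACCC", parseDotBracket("(((...)))"))
#' @export
evalStructureEnergy <- function(seq, ss, params = energyParams()) {
  if (nchar(seq) != structureLength(ss))
    stop(sprintf("length mismatch: sequence %d nt, structure %d nt",
                 nchar(seq), structureLength(ss)))
  res <- .cpp_eval_energy(.encodeSeq(seq), basePairs(ss),
                          params@eGC, params@eAU, params@eGU,
                          params@incompatPenalty)
  if (params@strict && res$incompatible > 0L)
    stop(sprintf("%d non-canonical pair(s) forced by the structure (strict mode)",
                 res$incompatible))
  res
}

#' Minimum free energy structure under the built-in model
#'
#' Exact minimum over all nested structures built from canonical pairs
#' (GC/CG, AU/UA and the GU/UG wobble) respecting the hairpin-loop minimum.
#' The traceback is deterministic: a position is left unpaired whenever that
#' ties the optimum, and among pairing partners the smallest index wins, so
#' identical inputs give identical structures.
#'
#' @inheritParams evalStructureEnergy
#' @return list with elements \code{structure} ([SecondaryStructure-class])
#'   and \code{energy}.
#' @examples
#' mfeFold("GGGAAACCC")
#' @export
mfeFold <- function(seq, params = energyParams()) {
  res <- .cpp_mfe(.encodeSeq(seq), params@eGC, params@eAU, params@eGU,
                  params@minLoop)
  list(structure = .newStructure(nchar(seq), res$pairs, params@minLoop),
       energy = res$energy)
}

#' Exhaustively enumerate all valid structures of a short sequence
#'
#' Every nested canonical structure (including the open chain) exactly once,
#' with its energy. Intended as a brute-force certificate for [mfeFold()];
#' guarded to sequences of at most 22 nt against combinatorial blow-up.
#'
#' @inheritParams evalStructureEnergy
#' @return list of \code{list(structure =, energy =)}.
#' @examples
#' length(enumerateStructures("GAAAC"))  # open chain + the single (1,5) pair
#' @export
enumerateStructures <- function(seq, params = energyParams()) {
  n <- nchar(seq)
  if (n > 22L) stop("enumerateStructures is limited to sequences of <= 22 nt")
  ch <- .seqChars(seq)
  minLoop <- params@minLoop
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2L)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1L, j)                       # i unpaired
    ks <- if (i + minLoop + 1L <= j) seq.int(i + minLoop + 1L, j) else integer(0)
    for (k in ks) {
      if (!.isCanonical(ch[i], ch[k])) next
      left <- rec(i + 1L, k - 1L)
      right <- rec(k + 1L, j)
      for (l in left) for (r in right)
        out <- c(out, list(rbind(c(i, k), l, r)))
    }
    memo[[key]] <- out
    out
  }
  mats <- if (n == 1L) list(matrix(integer(0), ncol = 2L)) else rec(1L, n)
  lapply(mats, function(m) {
    ss <- .newStructure(n, m, minLoop)
    list(structure = ss,
         energy = .cpp_eval_energy(.encodeSeq(seq), basePairs(ss),
                                   params@eGC, params@eAU, params@eGU,
                                   params@incompatPenalty)$energy)
  })
}

#' Energy-gap ("delta") score of a sequence against a target structure
#'
#' \code{delta} is the energy of the target structure under the sequence
#' minus the energy of the sequence's MFE structure; it is zero exactly when
#' the target is an optimal fold, and non-negative always. This is the
#' quantity the Monte Carlo designer minimises.
#'
#' @param seq RNA string.
#' @param target target [SecondaryStructure-class].
#' @param params an [EnergyParams-class].
#' @return a [DeltaScore-class].
#' @examples
#' deltaGap(deltaScore("GGGAAACCC", parseDotBracket("(((...)))")))  # 0
#' @export
deltaScore <- function(seq, target, params = energyParams()) {
  if (nchar(seq) != structureLength(target))
    stop(sprintf("length mismatch: sequence %d nt, target %d nt",
                 nchar(seq), structureLength(target)))
  res <- .cpp_delta(.encodeSeq(seq), basePairs(target),
                    params@eGC, params@eAU, params@eGU,
                    params@incompatPenalty, params@minLoop)
  if (params@strict && res$incompatible > 0L)
    stop(sprintf("%d non-canonical pair(s) forced by the target (strict mode)",
                 res$incompatible))
  new("DeltaScore", targetEnergy = res$target_energy,
      mfeEnergy = res$mfe_energy, delta = res$delta,
      incompatiblePairs = as.integer(res$incompatible))
}

## ---- engine adapter ---------------------------------------------------------

#' Built-in model as a pluggable engine
#'
#' Routes the built-in pair-additive model through the [FoldEngine-class]
#' adapter interface, so code written against the adapter reproduces
#' [deltaScore()] bit-exactly.
#'
#' @param params an [EnergyParams-class].
#' @return a [FoldEngine-class].
#' @export
builtinEngine <- function(params = energyParams()) {
  new("FoldEngine", name = "builtin",
      foldFun = function(seq) mfeFold(seq, params),
      evalFun = function(seq, ss) evalStructureEnergy(seq, ss, params)$energy)
}

.viennaEnergy <- function(line) {
  m <- regmatches(line, regexpr("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", line))
  if (!length(m)) stop("could not parse an energy from ViennaRNA output: ", line)
  as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
}

#' ViennaRNA command-line programs as an external engine
#'
#' Wraps \code{RNAfold}/\code{RNAeval} (the nearest-neighbour Turner model)
#' behind the [FoldEngine-class] adapter. Energies are in kcal/mol and are not
#' comparable in magnitude to the built-in model's units, but the energy-gap
#' contract (\code{delta >= 0}) holds for any engine. If the binaries are not
#' on the \code{PATH} this is an explicit error, never a silent fallback.
#'
#' @return a [FoldEngine-class].
#' @export
viennaEngine <- function() {
  fold <- Sys.which("RNAfold")
  eval_ <- Sys.which("RNAeval")
  if (!nzchar(fold) || !nzchar(eval_))
    stop("ViennaRNA engine unavailable: RNAfold/RNAeval not found on PATH")
  new("FoldEngine", name = "vienna",
    foldFun = function(seq) {
      out <- system2(fold, c("--noPS"), input = seq, stdout = TRUE, stderr = FALSE)
      line <- out[2L]
      db <- strsplit(line, " ", fixed = TRUE)[[1]][1L]
      list(structure = parseDotBracket(db, minLoop = 3L),
           energy = .viennaEnergy(line))
    },
    evalFun = function(seq, ss) {
      out <- system2(eval_, character(0),
                     input = paste(seq, dotBracket(ss), sep = "\n"),
                     stdout = TRUE, stderr = FALSE)
      .viennaEnergy(out[2L])
    })
}

#' Energy-gap score through a pluggable engine
#'
#' Same contract as [deltaScore()], computed by an arbitrary
#' [FoldEngine-class]: the gap between the engine's energy for the target
#' structure and its MFE energy. The incompatible-pair count is a property of
#' sequence and target alone (non-canonical forced pairs) and is computed
#' engine-independently.
#'
#' @param seq RNA string.
#' @param target target [SecondaryStructure-class].
#' @param engine a [FoldEngine-class]; e.g. [builtinEngine()] or
#'   [viennaEngine()].
#' @return a [DeltaScore-class].
#' @export
deltaScoreEngine <- function(seq, target, engine) {
  if (!is(engine, "FoldEngine")) stop("engine must be a FoldEngine")
  te <- engine@evalFun(seq, target)
  mfe <- engine@foldFun(seq)
  ch <- .seqChars(seq)
  p <- basePairs(target)
  incompat <- sum(!vapply(seq_len(nrow(p)),
                          function(r) .isCanonical(ch[p[r, 1L]], ch[p[r, 2L]]),
                          logical(1)))
  new("DeltaScore", targetEnergy = te, mfeEnergy = mfe$energy,
      delta = te - mfe$energy, incompatiblePairs = as.integer(incompat))
}
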