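## strategies: deterministic design operators and mutation classifiers
## modelled on the tactics that dominated successful community rRNA designs:
## flipping base pairs, switching AU pairs to CG and back, converting wobble
## pairs to Watson-Crick pairs, and breaking runs of identical nucleotides.
## Operators are pure (they return new sequences) so they can also serve as
## proposal kernels for the Monte Carlo designer.

#' Find maximal runs of identical nucleotides
#'
#' @param seq RNA string.
#' @param k minimum run length to report (>= 2; default 4).
#' @return data frame with columns \code{start}, \code{end},
#'   \code{nucleotide}, \code{length}, ascending by start.
#' @examples
#' findRepeats("GGGGGAUUUU", k = 4)
#' @export
findRepeats <- function(seq, k = 4L) {
  stopifnot(k >= 2L)
  r <- rle(.seqChars(seq))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= k
  data.frame(start = starts[keep], end = ends[keep],
             nucleotide = r$values[keep], length = r$lengths[keep],
             stringsAsFactors = FALSE)
}

.checkTargetPair <- function(target, pair) {
  pair <- as.integer(pair)
  p <- basePairs(target)
  hit <- which(p[, 1L] == min(pair) & p[, 2L] == max(pair))
  if (!length(hit))
    stop(sprintf("(%d, %d) is not a pair of the target structure", pair[1L], pair[2L]))
  c(min(pair), max(pair))
}

#' Flip a target base pair
#'
#' Swaps the nucleotides at the two partners of a target pair (e.g. G-C
#' becomes C-G, G-U becomes U-G); all other positions are untouched. Applying
#' the operator twice restores the original sequence.
#'
#' @param seq RNA string.
#' @param target target [SecondaryStructure-class].
#' @param pair integer vector \code{c(i, j)}; must be a target pair.
#' @return the modified RNA string.
#' @examples
#' flipPair("GAAAC", parseDotBracket("(...)"), c(1, 5))  # "CAAAG"
#' @export
flipPair <- function(seq, target, pair) {
  ij <- .checkTargetPair(target, pair)
  ch <- .seqChars(seq)
  ch[ij] <- ch[rev(ij)]
  paste(ch, collapse = "")
}

#' Set a target pair to a requested canonical combination
#'
#' The AU-to-CG switch (and back) in operator form: both partner positions
#' are written with the requested Watson-Crick combination, so the affected
#' pair is always canonical afterwards.
#'
#' @inheritParams flipPair
#' @param to one of \code{"AU"}, \code{"UA"}, \code{"CG"}, \code{"GC"}; the
#'   first letter goes to the 5' partner.
#' @return the modified RNA string.
#' @export
switchPairType <- function(seq, target, pair, to = c("AU", "UA", "CG", "GC")) {
  to <- match.arg(to)
  ij <- .checkTargetPair(target, pair)
  ch <- .seqChars(seq)
  ch[ij[1L]] <- substr(to, 1L, 1L)
  ch[ij[2L]] <- substr(to, 2L, 2L)
  paste(ch, collapse = "")
}

#' Single-mutation fixes of wobble target pairs
#'
#' For every target pair the sequence realises as G-U (or U-G), the two
#' one-nucleotide conversions to a Watson-Crick pair: U to C (giving G-C)
#' and G to A (giving A-U).
#'
#' @param seq RNA string.
#' @param target target [SecondaryStructure-class].
#' @return data frame with columns \code{i}, \code{j}, \code{position},
#'   \code{from}, \code{to}, \code{sequence}; zero rows when the sequence has
#'   no wobble target pairs.
#' @export
wobbleToWcProposals <- function(seq, target) {
  ch <- .seqChars(seq)
  p <- basePairs(target)
  out <- data.frame(i = integer(0), j = integer(0), position = integer(0),
                    from = character(0), to = character(0),
                    sequence = character(0), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(p))) {
    i <- p[r, 1L]; j <- p[r, 2L]
    duo <- paste0(ch[i], ch[j])
    if (!duo %in% WOBBLE_PAIRS) next
    gPos <- if (ch[i] == "G") i else j
    uPos <- if (ch[i] == "U") i else j
    fix <- function(pos, nt) {
      mod <- ch; mod[pos] <- nt
      data.frame(i = i, j = j, position = pos, from = ch[pos], to = nt,
                 sequence = paste(mod, collapse = ""), stringsAsFactors = FALSE)
    }
    out <- rbind(out, fix(uPos, "C"), fix(gPos, "A"))
  }
  out
}

#' Single- and double-mutation proposals that break a nucleotide run
#'
#' For each position of the run that is unpaired in the target and not
#' locked, every alternative nucleotide the IUPAC mask allows is offered as a
#' one-mutation proposal. Positions that are paired in the target are offered
#' only as pair-preserving double proposals (both partners rewritten to a
#' canonical pair) and flagged as such.
#'
#' @param seq RNA string.
#' @param target target [SecondaryStructure-class].
#' @param run one row of [findRepeats()] output (or a list with
#'   \code{start}, \code{end}).
#' @param cs a [ConstraintSet-class].
#' @return data frame with columns \code{position}, \code{from}, \code{to},
#'   \code{partnerPosition}, \code{partnerFrom}, \code{partnerTo},
#'   \code{paired}, \code{sequence}.
#' @export
breakRepeatProposals <- function(seq, target, run, cs) {
  ch <- .seqChars(seq)
  pt <- pairTable(target)
  useMask <- length(cs@mask) > 0L
  rows <- list()
  for (p in seq.int(run$start, run$end)) {
    if (p %in% cs@locked) next
    allowed <- if (useMask) iupacSet(cs@mask[p]) else RNA_ALPHABET
    q <- pt[p]
    if (q == 0L) {
      for (nt in setdiff(allowed, ch[p])) {
        mod <- ch; mod[p] <- nt
        rows[[length(rows) + 1L]] <- data.frame(
          position = p, from = ch[p], to = nt,
          partnerPosition = NA_integer_, partnerFrom = NA_character_,
          partnerTo = NA_character_, paired = FALSE,
          sequence = paste(mod, collapse = ""), stringsAsFactors = FALSE)
      }
    } else {
      if (q %in% cs@locked) next
      allowedQ <- if (useMask) iupacSet(cs@mask[q]) else RNA_ALPHABET
      for (duo in CANONICAL_PAIRS) {
        a <- substr(duo, 1L, 1L); b <- substr(duo, 2L, 2L)
        ntP <- if (p < q) a else b
        ntQ <- if (p < q) b else a
        if (ntP == ch[p]) next                      # must change the run position
        if (!(ntP %in% allowed) || !(ntQ %in% allowedQ)) next
        mod <- ch; mod[p] <- ntP; mod[q] <- ntQ
        rows[[length(rows) + 1L]] <- data.frame(
          position = p, from = ch[p], to = ntP,
          partnerPosition = q, partnerFrom = ch[q], partnerTo = ntQ,
          paired = TRUE, sequence = paste(mod, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(position = integer(0), from = character(0),
                      to = character(0), partnerPosition = integer(0),
                      partnerFrom = character(0), partnerTo = character(0),
                      paired = logical(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

MUTATION_CLASSES <- c("PAIR_FLIP", "PAIR_TYPE_SWITCH", "WOBBLE_TO_WC",
                      "WC_TO_WOBBLE", "PAIR_BROKEN", "UNPAIRED_SUBSTITUTION")

#' Classify the mutations of a design by their effect on target pairing
#'
#' Each mutated position is assigned exactly one class. Mutations at
#' positions unpaired in the target are \code{UNPAIRED_SUBSTITUTION}. A
#' mutated target pair is classified once, reported at its 5' partner:
#' the same unordered nucleotide pair in reversed orientation is a
#' \code{PAIR_FLIP}; a canonical-to-canonical change between Watson-Crick
#' types is a \code{PAIR_TYPE_SWITCH}; wobble to Watson-Crick is
#' \code{WOBBLE_TO_WC} and the reverse \code{WC_TO_WOBBLE}; a canonical pair
#' turned non-canonical is \code{PAIR_BROKEN}. A non-canonical wild-type pair
#' made canonical is classified by the resulting pair type.
#'
#' @param wt,design equal-length RNA strings.
#' @param target target [SecondaryStructure-class] of matching length.
#' @return data frame with columns \code{position} (reporting position: the
#'   mutated position, or the 5' partner for pairs), \code{partner}
#'   (\code{NA} for unpaired), \code{class}.
#' @examples
#' classifyMutations("GAAAC", "CAAAG", parseDotBracket("(...)"))  # PAIR_FLIP
#' @export
classifyMutations <- function(wt, design, target) {
  if (nchar(wt) != nchar(design) || nchar(wt) != structureLength(target))
    stop("wild type, design and target must have equal lengths")
  a <- .seqChars(wt); b <- .seqChars(design)
  pt <- pairTable(target)
  muts <- which(a != b)
  seen <- logical(length(a))
  rows <- list()
  for (p in muts) {
    if (seen[p]) next
    q <- pt[p]
    if (q == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = p, partner = NA_integer_, class = "UNPAIRED_SUBSTITUTION",
        stringsAsFactors = FALSE)
      next
    }
    i <- min(p, q); j <- max(p, q)
    seen[i] <- seen[j] <- TRUE
    wtDuo <- paste0(a[i], a[j]); dDuo <- paste0(b[i], b[j])
    cls <-
      if (b[i] == a[j] && b[j] == a[i] && wtDuo != dDuo) "PAIR_FLIP"
      else if (!dDuo %in% CANONICAL_PAIRS) "PAIR_BROKEN"
      else if (wtDuo %in% WOBBLE_PAIRS && dDuo %in% WC_PAIRS) "WOBBLE_TO_WC"
      else if (dDuo %in% WOBBLE_PAIRS) "WC_TO_WOBBLE"
      else "PAIR_TYPE_SWITCH"
    rows[[length(rows) + 1L]] <- data.frame(
      position = i, partner = j, class = cls, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(position = integer(0), partner = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$position), , drop = FALSE]
}
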