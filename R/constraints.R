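## constraints: mutation budgets, locked positions, IUPAC conservation masks
## and protein-contact reporting.

#' Standard IUPAC degenerate nucleotide code
#'
#' The bijection between the 15 IUPAC symbols and the non-empty subsets of
#' \{A, C, G, U\}; e.g. Y = U or C, W = A or U.
#'
#' @format named list: symbol to sorted character vector of nucleotides.
#' @export
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U"))

#' Decode an IUPAC symbol to its nucleotide set
#'
#' @param symbol single IUPAC symbol (case-insensitive; T is read as U).
#' @return sorted character vector of allowed nucleotides.
#' @examples
#' iupacSet("Y")  # C U
#' @export
iupacSet <- function(symbol) {
  stopifnot(is.character(symbol), length(symbol) == 1L)
  s <- chartr("T", "U", toupper(symbol))
  set <- IUPAC_SETS[[s]]
  if (is.null(set)) stop(sprintf("'%s' is not an IUPAC nucleotide symbol", symbol))
  set
}

#' Encode a nucleotide set as its IUPAC symbol
#'
#' Inverse of [iupacSet()] over all 15 symbols.
#'
#' @param set non-empty character vector of nucleotides (T accepted as U).
#' @return single IUPAC symbol.
#' @examples
#' iupacSymbol(c("U", "C"))  # "Y"
#' @export
iupacSymbol <- function(set) {
  set <- sort(unique(chartr("T", "U", toupper(set))))
  if (!length(set)) stop("empty nucleotide set has no IUPAC symbol")
  if (!all(set %in% RNA_ALPHABET)) stop("set may only contain A, C, G, U")
  key <- paste(set, collapse = "")
  hit <- names(IUPAC_SETS)[vapply(IUPAC_SETS, function(s) paste(s, collapse = "") == key,
                                  logical(1))]
  hit[1L]
}

#' Mutation budget from a length and a fraction
#'
#' The design puzzles cap the number of mutations at a fixed fraction of the
#' rRNA length, rounded down: 5\% of the 1534-nt 16S puzzle gives 76, 5\% of
#' the 2904-nt 23S gives 145.
#'
#' @param L sequence length (>= 1).
#' @param fraction allowed mutation fraction in \[0, 1\] (default 0.05).
#' @return integer budget, \code{floor(fraction * L)}.
#' @examples
#' mutationBudget(1534, 0.05)  # 76
#' mutationBudget(2904, 0.05)  # 145
#' @export
mutationBudget <- function(L, fraction = 0.05) {
  stopifnot(L >= 1, fraction >= 0, fraction <= 1)
  ## guard against 0.05 * L landing a hair below an exact integer in binary
  as.integer(floor(fraction * L + 1e-9))
}

#' Build an IUPAC conservation mask from a multiple alignment
#'
#' For every reference position, the IUPAC symbol of the set of nucleotides
#' observed in that alignment column (gaps ignored), optionally thresholded
#' at a minimum column frequency. The mask is reported in degapped reference
#' coordinates. With the default \code{minFreq = 0} any observed nucleotide
#' is allowed; a column in which nothing clears the threshold falls back
#' to \code{N}.
#'
#' @param aln named character vector of equal-length gapped sequences
#'   (\code{A,C,G,U,-}), e.g. from \code{readFastaRNA(path, gapped = TRUE)}.
#' @param reference name of the reference row.
#' @param minFreq minimum frequency (among non-gap characters) for a
#'   nucleotide to enter the mask.
#' @return single character string of IUPAC symbols, one per reference
#'   position.
#' @examples
#' buildIupacMask(c(ref = "AUG", other = "AUA"), "ref")  # "AUR"
#' @export
buildIupacMask <- function(aln, reference, minFreq = 0) {
  stopifnot(is.character(aln), length(aln) >= 1L)
  if (length(unique(nchar(aln))) != 1L) stop("alignment rows differ in length")
  if (!reference %in% names(aln))
    stop(sprintf("reference row '%s' not found in the alignment", reference))
  mat <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  refRow <- mat[which(names(aln) == reference)[1L], ]
  cols <- which(refRow != "-")
  symbols <- vapply(cols, function(j) {
    nts <- mat[, j]
    nts <- nts[nts != "-"]
    if (!length(nts)) return("N")
    if (minFreq > 0) {
      freq <- table(nts) / length(nts)
      nts <- names(freq)[freq >= minFreq]
      if (!length(nts)) return("N")
    }
    iupacSymbol(nts)
  }, character(1))
  paste(symbols, collapse = "")
}

#' Check a design against a constraint set
#'
#' Computes the mutation list against wild type and reports budget
#' compliance, locked-position violations, IUPAC-mask violations (a mutated
#' position whose design nucleotide is outside the mask; unmutated positions
#' are exempt by definition) and advisory protein-contact mutations.
#'
#' @param wt,design equal-length RNA strings.
#' @param cs a [ConstraintSet-class] sized to the sequences.
#' @return a [ConstraintReport-class].
#' @examples
#' cs <- constraintSet(4, locked = 2, budget = 2)
#' checkDesign("AUGC", "AAGC", cs)
#' @export
checkDesign <- function(wt, design, cs) {
  stopifnot(is(cs, "ConstraintSet"))
  if (nchar(wt) != cs@length || nchar(design) != cs@length)
    stop("sequence lengths do not match the constraint set")
  muts <- mutationsBetween(wt, design)
  iupacViol <- integer(0)
  if (length(cs@mask) && nrow(muts)) {
    bad <- vapply(seq_len(nrow(muts)), function(r) {
      !(muts$new[r] %in% iupacSet(cs@mask[muts$position[r]]))
    }, logical(1))
    iupacViol <- muts$position[bad]
  }
  new("ConstraintReport",
      mutationCount = nrow(muts),
      budgetOk = nrow(muts) <= cs@budget,
      lockedViolations = intersect(muts$position, cs@locked),
      iupacViolations = iupacViol,
      contactMutations = intersect(muts$position, cs@contacts))
}
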