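## structure_io: parsing, validation and serialisation of sequences,
## alignments and secondary structures. All user-facing coordinates are
## 1-based inclusive (rRNA residue-numbering convention).

.seqChars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.encodeSeq <- function(x) {
  m <- match(.seqChars(x), RNA_ALPHABET) - 1L
  if (anyNA(m)) stop("sequence contains a non-ACGU character; run normalizeSequence() first")
  m
}

.decodeSeq <- function(ints) paste(RNA_ALPHABET[ints + 1L], collapse = "")

#' Normalize a raw nucleotide string to RNA
#'
#' Whitespace is stripped, lower case is raised, and T is silently replaced by
#' U (the rRNA genes are supplied as DNA templates). Any other character is an
#' error naming the offending 1-based position.
#'
#' @param raw character scalar with the raw sequence.
#' @return a plain character string over \code{A,C,G,U}.
#' @examples
#' normalizeSequence("acgt")   # "ACGU"
#' @export
normalizeSequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- toupper(gsub("\\s", "", raw))
  if (nchar(s) == 0L) stop("empty sequence")
  s <- chartr("T", "U", s)
  bad <- which(!(.seqChars(s) %in% RNA_ALPHABET))
  if (length(bad))
    stop(sprintf("invalid alphabet: character '%s' at position %d (expected A/C/G/U/T)",
                 substr(s, bad[1L], bad[1L]), bad[1L]))
  s
}

#' Parse dot-bracket notation into a secondary structure
#'
#' Accepts the plain \code{"()."} dialect only. Bracket families used for
#' pseudoknot annotation (\code{[]}, \code{\{\}}, \code{<>}, lower-case
#' letters) are rejected with a dedicated error: the energy model here, like
#' the models behind the ribosome design puzzles, omits pseudoknots.
#'
#' @param text dot-bracket string.
#' @param minLoop minimum hairpin-loop size (default 3).
#' @return a [SecondaryStructure-class].
#' @examples
#' parseDotBracket("(((...)))")
#' @export
parseDotBracket <- function(text, minLoop = 3L) {
  stopifnot(is.character(text), length(text) == 1L)
  ch <- .seqChars(gsub("\\s", "", text))
  if (length(ch) == 0L) stop("empty dot-bracket string")
  if (any(ch %in% c("[", "]", "{", "}", "<", ">") | grepl("[a-z]", ch)))
    stop("pseudoknots unsupported: only the '(', ')', '.' dot-bracket dialect is accepted")
  bad <- which(!ch %in% c("(", ")", "."))
  if (length(bad))
    stop(sprintf("invalid dot-bracket character '%s' at position %d", ch[bad[1L]], bad[1L]))
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") stack <- c(stack, k)
    else if (ch[k] == ")") {
      if (!length(stack)) stop(sprintf("unbalanced brackets: unmatched ')' at position %d", k))
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs <- rbind(pairs, c(i, k))
    }
  }
  if (length(stack))
    stop(sprintf("unbalanced brackets: unmatched '(' at position %d", stack[1L]))
  .newStructure(length(ch), pairs, minLoop)
}

#' Serialize a secondary structure to dot-bracket notation
#'
#' @param x a [SecondaryStructure-class].
#' @return dot-bracket string; inverse of [parseDotBracket()].
#' @export
dotBracket <- function(x) {
  stopifnot(is(x, "SecondaryStructure"))
  out <- rep(".", x@length)
  p <- basePairs(x)
  out[p[, 1L]] <- "("
  out[p[, 2L]] <- ")"
  paste(out, collapse = "")
}

#' Read / write Vienna-style dot-bracket files
#'
#' The three-line convention: a \code{>name} header, the sequence, the
#' dot-bracket line; files may hold several such records.
#'
#' @param path file path.
#' @param minLoop minimum hairpin-loop size for parsing.
#' @return \code{readDotBracket}: a list of records, each with elements
#'   \code{name}, \code{sequence} and \code{structure}.
#' @export
readDotBracket <- function(path, minLoop = 3L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' headers found in dot-bracket file")
  lapply(starts, function(s) {
    if (s + 2L > length(lines)) stop("truncated dot-bracket record at end of file")
    list(name = sub("^>\\s*", "", lines[s]),
         sequence = normalizeSequence(lines[s + 1L]),
         structure = parseDotBracket(lines[s + 2L], minLoop = minLoop))
  })
}

#' @rdname readDotBracket
#' @param name record name.
#' @param sequence RNA sequence.
#' @param structure a [SecondaryStructure-class] matching the sequence length.
#' @export
writeDotBracket <- function(name, sequence, structure, path) {
  stopifnot(nchar(sequence) == structureLength(structure))
  writeLines(c(paste0(">", name), sequence, dotBracket(structure)), path)
  invisible(path)
}

#' Parse a CT (connectivity table) file
#'
#' Standard six-column CT: residue index, base, previous, next, pairing
#' partner (0 = unpaired), natural index. Pairing must be symmetric; crossing
#' pairs are rejected by the structure validity check.
#'
#' @param path path to a CT file.
#' @param minLoop minimum hairpin-loop size.
#' @return list with elements \code{sequence} (normalized string) and
#'   \code{structure} ([SecondaryStructure-class]).
#' @export
parseCT <- function(path, minLoop = 3L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("CT file too short")
  n <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1]][1L])
  if (is.na(n) || length(lines) - 1L < n) stop("CT header count does not match row count")
  rows <- do.call(rbind, lapply(lines[2:(n + 1L)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 6L) stop("CT row with fewer than 6 columns")
    f[1:6]
  }))
  idx <- as.integer(rows[, 1L])
  if (!identical(idx, seq_len(n))) stop("CT rows must be numbered 1..n in order")
  partner <- as.integer(rows[, 5L])
  if (any(is.na(partner)) || any(partner < 0L) || any(partner > n))
    stop("CT pair column outside [0, n]")
  for (i in seq_len(n)) {
    j <- partner[i]
    if (j != 0L && partner[j] != i)
      stop(sprintf("asymmetric CT pairing: row %d points to %d but row %d points to %d",
                   i, j, j, partner[j]))
  }
  sel <- which(partner > idx)
  pairs <- cbind(idx[sel], partner[sel])
  list(sequence = normalizeSequence(paste(rows[, 2L], collapse = "")),
       structure = .newStructure(n, pairs, minLoop))
}

#' Read / write RNA FASTA files
#'
#' Multi-record FASTA via Biostrings; sequences are normalized (T to U,
#' upper case). An alignment is simply an equal-length FASTA with gaps kept
#' as \code{-}.
#'
#' @param path file path.
#' @param gapped keep \code{-} gap characters (for alignments).
#' @return \code{readFastaRNA}: named character vector of sequences.
#' @export
readFastaRNA <- function(path, gapped = FALSE) {
  x <- Biostrings::readBStringSet(path)
  out <- vapply(as.character(x), function(s) {
    if (gapped) {
      s <- toupper(gsub("\\s", "", s))
      s <- chartr("T", "U", s)
      bad <- which(!(.seqChars(s) %in% c(RNA_ALPHABET, "-")))
      if (length(bad))
        stop(sprintf("invalid alignment character '%s' at position %d",
                     substr(s, bad[1L], bad[1L]), bad[1L]))
      s
    } else normalizeSequence(s)
  }, character(1))
  names(out) <- names(x)
  out
}

#' @rdname readFastaRNA
#' @param seqs named character vector of sequences.
#' @export
writeFastaRNA <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a position-list file
#'
#' One 1-based integer per line, optionally followed by a whitespace-separated
#' IUPAC symbol; \code{#} starts a comment. Used for locked-position and
#' protein-contact lists.
#'
#' @param path file path.
#' @return data frame with columns \code{position} and \code{symbol}
#'   (\code{NA} where no symbol was given).
#' @export
readPositionList <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(data.frame(position = integer(0), symbol = character(0)))
  parts <- strsplit(lines, "\\s+")
  pos <- suppressWarnings(vapply(parts, function(p) as.integer(p[1L]), integer(1)))
  if (anyNA(pos)) stop("non-integer position in position-list file")
  sym <- vapply(parts, function(p) if (length(p) > 1L) toupper(p[2L]) else NA_character_,
                character(1))
  data.frame(position = pos, symbol = sym, stringsAsFactors = FALSE)
}

#' List the mutations separating two sequences
#'
#' One row per differing position, in ascending position order; the number of
#' rows is the Hamming distance.
#'
#' @param wt,design equal-length RNA strings.
#' @return data frame with columns \code{position}, \code{wt}, \code{new}.
#' @examples
#' mutationsBetween("AUGC", "AUCC")
#' @export
mutationsBetween <- function(wt, design) {
  if (nchar(wt) != nchar(design))
    stop(sprintf("length mismatch: wild type %d nt, design %d nt", nchar(wt), nchar(design)))
  a <- .seqChars(wt); b <- .seqChars(design)
  d <- which(a != b)
  data.frame(position = d, wt = a[d], new = b[d], stringsAsFactors = FALSE)
}

#' Apply a mutation list to a sequence
#'
#' Inverse of [mutationsBetween()]: applying \code{mutationsBetween(a, b)}
#' to \code{a} reconstructs \code{b}. The wild-type column is checked against
#' the sequence being mutated.
#'
#' @param seq RNA string.
#' @param mutations data frame with columns \code{position}, \code{wt},
#'   \code{new}.
#' @return mutated RNA string.
#' @export
applyMutations <- function(seq, mutations) {
  ch <- .seqChars(seq)
  if (nrow(mutations)) {
    if (any(mutations$position < 1L | mutations$position > length(ch)))
      stop("mutation position outside the sequence")
    mismatch <- ch[mutations$position] != mutations$wt
    if (any(mismatch))
      stop(sprintf("mutation list does not match the sequence at position %d",
                   mutations$position[which(mismatch)[1L]]))
    ch[mutations$position] <- mutations$new
  }
  paste(ch, collapse = "")
}
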