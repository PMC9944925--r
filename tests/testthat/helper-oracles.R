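# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own DP/parsing code paths.

randomRna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                               collapse = "")

# O(n^2) crossing-pair checker over a pair matrix
hasCrossingPairs <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2L) return(FALSE)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    i <- pairs[a, 1L]; j <- pairs[a, 2L]
    k <- pairs[b, 1L]; l <- pairs[b, 2L]
    if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) return(TRUE)
  }
  FALSE
}

# Independent count of nested canonical structures (counting recurrence,
# no structure materialisation) — a second oracle for enumerateStructures
countStructuresOracle <- function(seq, minLoop = 3L) {
  ch <- strsplit(seq, "")[[1]]
  canon <- c("GC", "CG", "AU", "UA", "GU", "UG")
  n <- length(ch)
  memo <- matrix(NA_real_, n + 1L, n + 1L)
  cnt <- function(i, j) {
    if (i >= j) return(1)
    if (!is.na(memo[i, j])) return(memo[i, j])
    total <- cnt(i + 1L, j)
    ks <- if (i + minLoop + 1L <= j) (i + minLoop + 1L):j else integer(0)
    for (k in ks) {
      if (!(paste0(ch[i], ch[k]) %in% canon)) next
      total <- total + cnt(i + 1L, k - 1L) * cnt(k + 1L, j)
    }
    memo[i, j] <<- total
    total
  }
  cnt(1L, n)
}

# Per-column alignment scan, independent of buildIupacMask internals
maskColumnOracle <- function(aln, reference, minFreq = 0) {
  mat <- do.call(rbind, strsplit(unname(aln), ""))
  ref <- strsplit(aln[[reference]], "")[[1]]
  cols <- which(ref != "-")
  lapply(cols, function(j) {
    nts <- mat[, j]
    nts <- nts[nts != "-"]
    if (minFreq > 0) {
      tab <- table(nts)
      nts <- names(tab)[tab / sum(tab) >= minFreq]
    }
    sort(unique(nts))
  })
}
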