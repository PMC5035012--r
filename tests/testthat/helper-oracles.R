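# Independent oracles used across the suite: a plain-R affine-gap DP
# (score only), an exhaustive zinc-finger quadruple enumerator, a
# set-expansion IUPAC matcher, and small sequence generators.

rchars <- function(n, alphabet) sample(alphabet, n, replace = TRUE)
rdna <- function(n) paste0(rchars(n, c("A", "C", "G", "T")), collapse = "")

# protein with elevated C/H content so zinc-finger-like patterns occur
rprot <- function(n) paste0(
  rchars(n, c(rep(c("A", "G", "L", "S", "T", "V", "E", "K"), 2), "C", "C",
              "H", "H")), collapse = "")

# full-DP affine-gap score (three-state Gotoh written independently of
# the package's compiled aligner; gap of length L costs open + L * ext)
oracleAlignScore <- function(a, b, match = 1, mismatch = -1,
                             gapOpen = -2, gapExt = -1, local = FALSE) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (!local) {
    X[seq_len(n) + 1, 1] <- gapOpen + seq_len(n) * gapExt
    Y[1, seq_len(m) + 1] <- gapOpen + seq_len(m) * gapExt
  }
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      d <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1],
               if (local) 0 else NEG)
      M[i, j] <- d + s
      X[i, j] <- max(M[i - 1, j] + gapOpen + gapExt, X[i - 1, j] + gapExt)
      Y[i, j] <- max(M[i, j - 1] + gapOpen + gapExt, Y[i, j - 1] + gapExt)
      if (local) best <- max(best, M[i, j])
    }
  }
  if (local) best else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# rescore a returned alignment from its gapped strings
rescoreAlignment <- function(aAln, bAln, match = 1, mismatch = -1,
                             gapOpen = -2, gapExt = -1) {
  a <- strsplit(aAln, "")[[1]]
  b <- strsplit(bAln, "")[[1]]
  sc <- 0
  inGap <- FALSE
  for (k in seq_along(a)) {
    if (a[k] == "-" || b[k] == "-") {
      sc <- sc + gapExt + if (inGap) 0 else gapOpen
      inGap <- TRUE
    } else {
      sc <- sc + if (a[k] == b[k]) match else mismatch
      inGap <- FALSE
    }
  }
  sc
}

# exhaustive enumeration of zinc-finger index quadruples with the same
# leftmost-minimal selection and resume-after-match rule as the scanner
oracleZincFingers <- function(protein, regionEnd = nchar(protein),
                              spacing = c(2, 4, 8, 20, 3, 5)) {
  ch <- strsplit(substr(protein, 1, regionEnd), "")[[1]]
  n <- length(ch)
  res <- list()
  p <- 1
  repeat {
    found <- NULL
    for (c1 in p:n) {
      if (ch[c1] != "C") next
      for (c2 in (c1 + spacing[1] + 1):(c1 + spacing[2] + 1)) {
        if (c2 > n || ch[c2] != "C") next
        for (h in (c2 + spacing[3] + 1):(c2 + spacing[4] + 1)) {
          if (h > n || ch[h] != "H") next
          for (x in (h + spacing[5] + 1):(h + spacing[6] + 1)) {
            if (x > n || !(ch[x] %in% c("H", "C"))) next
            found <- c(c1, c2, h, x)
            break
          }
          if (!is.null(found)) break
        }
        if (!is.null(found)) break
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) break
    res[[length(res) + 1]] <- data.frame(
      kind = if (ch[found[4]] == "H") "CCHH" else "CCHC",
      start = found[1], end = found[4], stringsAsFactors = FALSE)
    p <- found[4] + 1
    if (p > n) break
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(kind = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
}

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

expandPrimerOracle <- function(primer) {
  sets <- lapply(strsplit(primer, "")[[1]], function(cc) IUPAC_ORACLE[[cc]])
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

# naive all-positions motif scan (U/T equivalent)
oracleFindMotif <- function(seq, motif) {
  seq <- chartr("U", "T", toupper(seq))
  motif <- chartr("U", "T", toupper(motif))
  n <- nchar(seq); m <- nchar(motif)
  hits <- integer(0)
  if (n >= m)
    for (i in 1:(n - m + 1))
      if (substr(seq, i, i + m - 1) == motif) hits <- c(hits, i)
  data.frame(start = hits, end = hits + m - 1L)
}

# count all occurrences of a pattern on both strands by brute force
countBothStrands <- function(seq, pattern) {
  naiveCount <- function(s, p) {
    n <- nchar(s); m <- nchar(p); k <- 0
    if (n >= m) for (i in 1:(n - m + 1))
      if (substr(s, i, i + m - 1) == p) k <- k + 1
    k
  }
  naiveCount(seq, pattern) + naiveCount(revComp(seq), pattern)
}
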