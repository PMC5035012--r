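## Virtual PCR with IUPAC-degenerate primers: the in-silico counterpart of
## the RT-domain-forward x 28S-reverse amplification strategy used to
## recover R2 3' halves from genomic DNA.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' The built-in R2 degenerate-PCR primer panel
#'
#' Four forward primers from the conserved RT domain (R2IF1/R2IIF1 outer,
#' R2IF2/R2IIF2 nested) and four reverse primers from the 28S rRNA gene
#' downstream of the canonical insertion site.
#'
#' @return Named character vector of IUPAC primer sequences.
#' @export
#' @examples
#' r2Primers()[["R2IF1"]]
r2Primers <- function() R2_PRIMERS

R2_PRIMERS <- c(
  R2IF1   = "AAGCARGGNGAYCCNCTNTC",
  R2IIF1  = "GTNAARCARGGNGAYCCNCT",
  R2IF2   = "GCYYTRGCGTTYGCNGAYGA",
  R2IIF2  = "CTNGCNTTYGCNGAYGAYYT",
  `28S_R-198` = "GCCTCCCACTTATYCTACACC",
  `28S_R-147` = "GTCAAGCTCAACAGGGTCTTCT",
  `28S_R-B` = "ATCCATTCATGCGCGTCACT",
  `28S_R-A` = "TAGATGACGAGGCATTTGGC")

.checkPrimer <- function(primer) {
  chars <- s2c(toupper(primer))
  if (length(chars) == 0L) stop("primer must be non-empty")
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad) > 0L)
    stop("invalid IUPAC code '", chars[bad[1L]], "' at position ", bad[1L])
  chars
}

.resolvePrimer <- function(x) {
  if (length(x) == 1L && x %in% names(R2_PRIMERS)) R2_PRIMERS[[x]] else x
}

#' Degeneracy of an IUPAC primer
#'
#' The number of concrete oligonucleotides the degenerate primer
#' represents: the product over positions of the number of bases each
#' IUPAC code admits.
#'
#' @param primer IUPAC primer sequence, or the name of a built-in primer
#'   (see [r2Primers()]).
#' @return Integer degeneracy.
#' @export
#' @examples
#' degeneracy("R2IF1")  # 256
degeneracy <- function(primer) {
  chars <- .checkPrimer(.resolvePrimer(primer))
  prod(vapply(chars, function(cc) length(IUPAC_SETS[[cc]]), integer(1L)))
}

#' Match a degenerate primer at one template position
#'
#' `TRUE` iff at every offset the template base lies in the primer code's
#' allowed set. Ambiguity codes in the template never match a degenerate
#' primer code except by exact code identity.
#'
#' @param primer IUPAC primer sequence or built-in primer name.
#' @param template Nucleotide string.
#' @param pos 1-based position of the primer's first base on the template.
#' @return Logical scalar.
#' @export
iupacMatch <- function(primer, template, pos) {
  primer <- .resolvePrimer(primer)
  pchars <- .checkPrimer(primer)
  m <- length(pchars)
  if (pos < 1L || pos > nchar(template) - m + 1L)
    stop("pos out of range for this primer/template pair")
  tchars <- s2c(toupper(substr(template, pos, pos + m - 1L)))
  all(vapply(seq_len(m), function(j)
    tchars[j] %in% IUPAC_SETS[[pchars[j]]] || tchars[j] == pchars[j],
    logical(1L)))
}

## All 1-based start positions where `primer` matches `template` with at
## most maxMismatch mismatching positions (vectorized over positions).
.scanPrimer <- function(template, primer, maxMismatch = 0L) {
  pchars <- .checkPrimer(primer)
  m <- length(pchars)
  n <- nchar(template)
  if (n < m) return(integer(0))
  tchars <- s2c(toupper(template))
  nwin <- n - m + 1L
  mism <- integer(nwin)
  for (j in seq_len(m)) {
    cc <- tchars[j:(j + nwin - 1L)]
    ok <- cc %in% IUPAC_SETS[[pchars[j]]] | cc == pchars[j]
    mism <- mism + !ok
  }
  which(mism <= maxMismatch)
}

#' Virtual PCR over one or more templates
#'
#' Enumerates every primer-pair product: the forward primer annealing on
#' one strand, the reverse primer on the other, facing inward, with
#' product length in `(0, maxLen]`. Both orientations of each template are
#' scanned; coordinates are reported on the plus strand, 1-based
#' inclusive, spanning the outermost primer bases. Matching is exact
#' IUPAC matching by default; `maxMismatch` relaxes it (degenerate primer
#' sites decay with their elements, which is one way genuine families can
#' escape PCR detection).
#'
#' @param templates Named character vector, [Biostrings::DNAStringSet], or
#'   a [GenomeBundle-class].
#' @param fwd,rev Primer sequences or built-in primer names.
#' @param maxLen Maximum product length in bp (default 3000, the scale
#'   implied by a 2-minute extension step plus margin).
#' @param maxMismatch Mismatches tolerated per primer site.
#' @return `data.frame` with columns `contig`, `start`, `end`, `length`,
#'   `fwd_primer`, `rev_primer`, `orientation`, sorted by
#'   (contig, start, end). Zero rows is a valid result.
#' @export
virtualPCR <- function(templates, fwd, rev, maxLen = 3000L, maxMismatch = 0L) {
  fwdSeq <- .resolvePrimer(fwd)
  revSeq <- .resolvePrimer(rev)
  fwdName <- if (is.character(fwd) && fwd %in% names(R2_PRIMERS)) fwd else "fwd"
  revName <- if (is.character(rev) && rev %in% names(R2_PRIMERS)) rev else "rev"
  if (is(templates, "GenomeBundle")) templates <- genomeSeq(templates)
  if (is(templates, "XStringSet"))
    templates <- setNames(as.character(templates), names(templates))
  if (is.null(names(templates)))
    names(templates) <- paste0("seq", seq_along(templates))
  lf <- nchar(fwdSeq); lr <- nchar(revSeq)
  if (maxLen <= lf + lr) stop("maxLen must exceed the combined primer length")

  rows <- list()
  addProducts <- function(contig, starts, ends, orientation) {
    if (length(starts) == 0L || length(ends) == 0L) return()
    grid <- expand.grid(start = starts, end = ends)
    grid$length <- grid$end - grid$start + 1L
    grid <- grid[grid$length > 0L & grid$length <= maxLen, , drop = FALSE]
    if (nrow(grid) > 0L)
      rows[[length(rows) + 1L]] <<- data.frame(
        contig = contig, start = grid$start, end = grid$end,
        length = grid$length, fwd_primer = fwdName, rev_primer = revName,
        orientation = orientation, stringsAsFactors = FALSE)
  }

  for (contig in names(templates)) {
    tpl <- templates[[contig]]
    ## plus orientation: fwd on plus strand, rev on minus strand
    f <- .scanPrimer(tpl, fwdSeq, maxMismatch)
    r <- .scanPrimer(tpl, revComp(revSeq), maxMismatch)
    addProducts(contig, f, r + lr - 1L, "+")
    ## minus orientation: fwd on minus strand, rev on plus strand
    f2 <- .scanPrimer(tpl, revComp(fwdSeq), maxMismatch)
    r2 <- .scanPrimer(tpl, revSeq, maxMismatch)
    addProducts(contig, r2, f2 + lf - 1L, "-")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               length = integer(0), fwd_primer = character(0),
               rev_primer = character(0), orientation = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract amplicon sequences for virtual PCR calls
#'
#' @param templates Same input accepted by [virtualPCR()].
#' @param calls A call table from [virtualPCR()].
#' @return A [Biostrings::DNAStringSet] of plus-strand amplicon sequences.
#' @export
ampliconSeqs <- function(templates, calls) {
  if (is(templates, "GenomeBundle")) templates <- genomeSeq(templates)
  if (is(templates, "XStringSet"))
    templates <- setNames(as.character(templates), names(templates))
  seqs <- vapply(seq_len(nrow(calls)), function(i)
    substr(templates[[calls$contig[i]]], calls$start[i], calls$end[i]),
    character(1L))
  Biostrings::DNAStringSet(setNames(seqs, sprintf(
    "%s:%d-%d(%s)", calls$contig, calls$start, calls$end, calls$orientation)))
}
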