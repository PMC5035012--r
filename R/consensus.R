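## Majority-rule consensus and pairwise identity.

#' Majority-rule consensus of aligned copies
#'
#' Per column, the most frequent A/C/G/T symbol wins; columns whose gap
#' frequency reaches `gapRuleFraction` are omitted from the consensus; N
#' never wins a majority (all-N columns emit N). Base ties are broken by
#' the fixed order A < C < G < T and flagged.
#'
#' @param aln Equal-length gapped rows: character vector,
#'   [Biostrings::DNAStringSet] or `DNAMultipleAlignment` (alphabet
#'   A, C, G, T, N, `-`).
#' @param gapRuleFraction Gap frequency at or above which a column is
#'   dropped.
#' @return The consensus string, with attributes `tied_columns` and
#'   `dropped_columns` (1-based alignment-column indices).
#' @export
#' @examples
#' majorityConsensus(c("A-GT", "ACGT", "A-GT"))  # "AGT"
majorityConsensus <- function(aln, gapRuleFraction = 0.5) {
  if (is(aln, "DNAMultipleAlignment")) aln <- as(aln, "DNAStringSet")
  if (is(aln, "XStringSet")) aln <- as.character(aln)
  if (length(aln) < 2L) stop("need at least 2 aligned rows")
  if (length(unique(nchar(aln))) != 1L) stop("rows must have equal length")
  mat <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  ok <- mat %in% c("A", "C", "G", "T", "N", "-")
  if (!all(ok)) stop("alignment alphabet must be A, C, G, T, N, -")
  ncol_aln <- ncol(mat)
  nrow_aln <- nrow(mat)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(mat == b), numeric(ncol_aln))
  if (ncol_aln == 1L) counts <- matrix(counts, nrow = 1L,
                                       dimnames = list(NULL, bases))
  gapFreq <- colSums(mat == "-") / nrow_aln
  dropped <- which(gapFreq >= gapRuleFraction)
  top <- apply(counts, 1L, max)
  pick <- apply(counts, 1L, which.max)      # ties -> lowest index = A<C<G<T
  tied <- which(rowSums(counts == top) > 1L & top > 0L)
  cons <- ifelse(top == 0L, "N", bases[pick])
  keep <- setdiff(seq_len(ncol_aln), dropped)
  out <- c2s(cons[keep])
  attr(out, "tied_columns") <- setdiff(tied, dropped)
  attr(out, "dropped_columns") <- dropped
  out
}

#' Pairwise identity between two sequences
#'
#' Globally aligns the two sequences (same affine scoring as the junction
#' caller) and reports identity. The denominator convention matters when
#' comparing against published percentages: `"aligned_columns"` counts
#' matches over all aligned columns (dual-gap columns excluded);
#' `"shorter_seq"` divides by the length of the shorter input.
#'
#' @param a,b Sequences (strings or `XString`).
#' @param regionLen Optional: truncate both inputs to their first
#'   `regionLen` bases first (e.g. 100 for 5'-terminal conservation
#'   comparisons).
#' @param denominator Identity denominator convention.
#' @param ... Scoring overrides passed to [needlemanWunsch()].
#' @return Identity fraction in `[0, 1]`.
#' @export
#' @examples
#' pairwiseIdentity("AAAA", "AATA")  # 0.75
pairwiseIdentity <- function(a, b, regionLen = NULL,
                             denominator = c("aligned_columns", "shorter_seq"),
                             ...) {
  denominator <- match.arg(denominator)
  a <- as.character(a); b <- as.character(b)
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  if (!is.null(regionLen)) {
    a <- substr(a, 1L, regionLen)
    b <- substr(b, 1L, regionLen)
  }
  res <- needlemanWunsch(a, b, ...)
  av <- s2c(res$a_aln); bv <- s2c(res$b_aln)
  keep <- !(av == "-" & bv == "-")
  matches <- sum(av[keep] == bv[keep] & av[keep] != "-")
  den <- switch(denominator,
                aligned_columns = sum(keep),
                shorter_seq = min(nchar(a), nchar(b)))
  matches / den
}

#' Stack located copies into an aligned set on consensus coordinates
#'
#' Places each copy's sequence at its consensus-coordinate range (from
#' [findCopies()]), padding with gaps, to produce equal-length rows ready
#' for [majorityConsensus()]. This ungapped projection is a utility for
#' substitution-decayed synthetic copies; indel-rich copies would need a
#' true multiple aligner.
#'
#' @param copies [GenomicRanges::GRanges] from [findCopies()].
#' @param genome Genome sequences.
#' @param consensusLen Length of the family consensus (columns of the
#'   stack).
#' @return Named character vector of equal-length gapped rows.
#' @export
stackCopies <- function(copies, genome, consensusLen) {
  genome <- .asNamedChar(genome)
  if (is.null(names(genome))) names(genome) <- "seq1"
  rows <- vapply(seq_along(copies), function(i) {
    gr <- copies[i]
    seqc <- substr(genome[[as.character(GenomicRanges::seqnames(gr))]],
                   GenomicRanges::start(gr), GenomicRanges::end(gr))
    if (as.character(GenomicRanges::strand(gr)) == "-") seqc <- revComp(seqc)
    cs <- gr$cons_start; ce <- gr$cons_end
    if (ce - cs + 1L != nchar(seqc)) # ungapped projection requires equal span
      return(strrep("-", consensusLen))
    paste0(strrep("-", cs - 1L), seqc, strrep("-", consensusLen - ce))
  }, character(1L))
  setNames(rows, copies$copy_id)
}
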