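## R-facing wrappers for the compiled affine-gap aligner. Scoring default
## (match +1, mismatch -1, gap open -2, gap extend -1; a gap of length L
## costs gapOpen + L * gapExt) is shared by the junction caller and the
## identity computations so all reported identities are comparable.

.alignIdentity <- function(aAln, bAln) {
  if (nchar(aAln) == 0L) return(0)
  a <- s2c(aAln); b <- s2c(bAln)
  keep <- !(a == "-" & b == "-")
  sum(a[keep] == b[keep] & a[keep] != "-") / sum(keep)
}

#' Local (Smith-Waterman) pairwise alignment
#'
#' Affine-gap local alignment of two plain sequences. Coordinates of the
#' aligned region are 1-based inclusive; an all-negative scoring pair
#' yields an empty alignment with score 0.
#'
#' @param a,b Sequences (plain strings; DNA or protein).
#' @param match,mismatch,gapOpen,gapExt Scoring parameters; a gap of
#'   length L costs `gapOpen + L * gapExt`.
#' @return List with `score`, aligned strings `a_aln`/`b_aln`, 1-based
#'   aligned ranges `a_start`/`a_end`/`b_start`/`b_end`, and `identity`
#'   (matches over aligned columns).
#' @export
#' @examples
#' smithWaterman("ACGTACGT", "TTACGTTT")$identity
smithWaterman <- function(a, b, match = 1, mismatch = -1,
                          gapOpen = -2, gapExt = -1) {
  res <- .align_cpp(as.character(a), as.character(b), match, mismatch,
                    gapOpen, gapExt, TRUE)
  res$identity <- .alignIdentity(res$a_aln, res$b_aln)
  res
}

#' Global (Needleman-Wunsch) pairwise alignment
#'
#' @inheritParams smithWaterman
#' @return Same structure as [smithWaterman()]; the aligned range always
#'   spans both full sequences.
#' @export
needlemanWunsch <- function(a, b, match = 1, mismatch = -1,
                            gapOpen = -2, gapExt = -1) {
  res <- .align_cpp(as.character(a), as.character(b), match, mismatch,
                    gapOpen, gapExt, FALSE)
  res$identity <- .alignIdentity(res$a_aln, res$b_aln)
  res
}
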