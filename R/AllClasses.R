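#' @import Biostrings
#' @import S4Vectors
NULL

#' TargetReference: a 28S/18S target with its canonical insertion site
#'
#' Holds the rRNA target sequence that site-specific R2 elements integrate
#' into, together with the canonical insertion site. The site is stored as
#' the number of target bases preceding the insertion point: an element
#' integrating canonically sits between positions `canonicalSite` and
#' `canonicalSite + 1` (1-based) of the target.
#'
#' @slot name Sequence name.
#' @slot sequence A [Biostrings::DNAString] with unambiguous bases.
#' @slot canonicalSite Integer; number of bases upstream of the insertion
#'   point, in `[0, length(sequence)]`.
#' @slot geneLabel Gene label, typically `"28S"` or `"18S"`.
#' @exportClass TargetReference
setClass("TargetReference",
         representation(name = "character", sequence = "DNAString",
                        canonicalSite = "integer", geneLabel = "character"))

setValidity("TargetReference", function(object) {
  msg <- character(0)
  if (length(object@sequence) == 0L)
    msg <- c(msg, "sequence must be non-empty")
  if (!all(s2c(as.character(object@sequence)) %in% DNA_BASES_PLAIN))
    msg <- c(msg, "sequence must contain only unambiguous bases (A/C/G/T)")
  cs <- object@canonicalSite
  if (length(cs) != 1L || is.na(cs) || cs < 0L || cs > length(object@sequence))
    msg <- c(msg, "canonicalSite must lie in [0, length(sequence)]")
  if (length(msg)) msg else TRUE
})

#' Construct a TargetReference
#'
#' @param name Sequence name.
#' @param sequence Nucleotide string or [Biostrings::DNAString].
#' @param canonicalSite Integer; bases preceding the insertion point.
#' @param geneLabel Gene label (default `"28S"`).
#' @return A [TargetReference-class] object.
#' @export
TargetReference <- function(name, sequence, canonicalSite, geneLabel = "28S") {
  new("TargetReference", name = as.character(name),
      sequence = Biostrings::DNAString(as.character(sequence)),
      canonicalSite = as.integer(canonicalSite),
      geneLabel = as.character(geneLabel))
}

#' ElementFamily: a simulated or user-supplied R2 family consensus
#'
#' @slot familyId Family identifier.
#' @slot consensus Nucleotide consensus ([Biostrings::DNAString]).
#' @slot protein Translation of the single long ORF ([Biostrings::AAString];
#'   may be empty if no ORF is known).
#' @slot clade Clade label (`"R2A"`, `"R2B"`, `"R2C"`, `"R2D"` or
#'   `"unknown"`).
#' @slot info List of generator annotations (ORF coordinates, ribozyme
#'   motif position, embedded 3' UTR target segment, primer-site
#'   positions); empty for user-supplied families.
#' @exportClass ElementFamily
setClass("ElementFamily",
         representation(familyId = "character", consensus = "DNAString",
                        protein = "AAString", clade = "character",
                        info = "list"))

setValidity("ElementFamily", function(object) {
  if (length(object@consensus) == 0L) return("consensus must be non-empty")
  if (!object@clade %in% c("R2A", "R2B", "R2C", "R2D", "unknown"))
    return("clade must be one of R2A, R2B, R2C, R2D, unknown")
  TRUE
})

#' Construct an ElementFamily
#'
#' @param familyId Family identifier.
#' @param consensus Nucleotide consensus string or `DNAString`.
#' @param protein Optional ORF translation (string or `AAString`).
#' @param clade Clade label; `"unknown"` if not yet classified.
#' @param info Optional list of annotations.
#' @return An [ElementFamily-class] object.
#' @export
ElementFamily <- function(familyId, consensus, protein = "",
                          clade = "unknown", info = list()) {
  new("ElementFamily", familyId = as.character(familyId),
      consensus = Biostrings::DNAString(as.character(consensus)),
      protein = Biostrings::AAString(as.character(protein)),
      clade = clade, info = info)
}

#' GenomeBundle: synthetic genome plus its ground truth
#'
#' The simulator's output: genome sequence(s), the families that were
#' inserted, the target reference, and a truth table giving the exact
#' location and parameters of every inserted copy (1-based inclusive
#' coordinates).
#'
#' @slot genome A [Biostrings::DNAStringSet].
#' @slot truth A `data.frame` with columns `copy_id`, `family_id`,
#'   `contig`, `start`, `end`, `strand`, `offset5`, `offset3`,
#'   `truncate5`, `nonspecific`, `divergence`.
#' @slot families List of [ElementFamily-class] objects.
#' @slot target The [TargetReference-class] used.
#' @slot params List of simulation parameters (n_units, spacer_len, seed).
#' @exportClass GenomeBundle
setClass("GenomeBundle",
         representation(genome = "DNAStringSet", truth = "data.frame",
                        families = "list", target = "TargetReference",
                        params = "list"))

setValidity("GenomeBundle", function(object) {
  tr <- object@truth
  need <- c("copy_id", "family_id", "contig", "start", "end", "strand",
            "offset5", "offset3", "truncate5", "nonspecific", "divergence")
  if (!all(need %in% names(tr)))
    return(paste("truth table must have columns:", paste(need, collapse = ", ")))
  if (nrow(tr) > 0L) {
    lens <- setNames(width(object@genome), names(object@genome))
    if (!all(tr$contig %in% names(lens)))
      return("truth contigs must name genome sequences")
    if (any(tr$start < 1L) || any(tr$end > lens[tr$contig]))
      return("truth intervals must lie within their contig")
  }
  TRUE
})

## ---- generics & accessors -------------------------------------------------

#' @rdname TargetReference-class
#' @param x,object A package object.
#' @export
setGeneric("targetSeq", function(x) standardGeneric("targetSeq"))
#' @rdname TargetReference-class
#' @export
setGeneric("canonicalSite", function(x) standardGeneric("canonicalSite"))
#' @rdname TargetReference-class
#' @export
setGeneric("geneLabel", function(x) standardGeneric("geneLabel"))
#' @rdname ElementFamily-class
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))
#' @rdname ElementFamily-class
#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))
#' @rdname ElementFamily-class
#' @export
setGeneric("proteinSeq", function(x) standardGeneric("proteinSeq"))
#' @rdname ElementFamily-class
#' @export
setGeneric("cladeLabel", function(x) standardGeneric("cladeLabel"))
#' @rdname ElementFamily-class
#' @export
setGeneric("familyInfo", function(x) standardGeneric("familyInfo"))
#' @rdname GenomeBundle-class
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname GenomeBundle-class
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname GenomeBundle-class
#' @export
setGeneric("familyList", function(x) standardGeneric("familyList"))
#' @rdname GenomeBundle-class
#' @export
setGeneric("targetRef", function(x) standardGeneric("targetRef"))

#' @rdname TargetReference-class
#' @export
setMethod("targetSeq", "TargetReference", function(x) x@sequence)
#' @rdname TargetReference-class
#' @export
setMethod("canonicalSite", "TargetReference", function(x) x@canonicalSite)
#' @rdname TargetReference-class
#' @export
setMethod("geneLabel", "TargetReference", function(x) x@geneLabel)
#' @rdname ElementFamily-class
#' @export
setMethod("familyId", "ElementFamily", function(x) x@familyId)
#' @rdname ElementFamily-class
#' @export
setMethod("consensusSeq", "ElementFamily", function(x) x@consensus)
#' @rdname ElementFamily-class
#' @export
setMethod("proteinSeq", "ElementFamily", function(x) x@protein)
#' @rdname ElementFamily-class
#' @export
setMethod("cladeLabel", "ElementFamily", function(x) x@clade)
#' @rdname ElementFamily-class
#' @export
setMethod("familyInfo", "ElementFamily", function(x) x@info)
#' @rdname GenomeBundle-class
#' @export
setMethod("genomeSeq", "GenomeBundle", function(x) x@genome)
#' @rdname GenomeBundle-class
#' @export
setMethod("truthTable", "GenomeBundle", function(x) x@truth)
#' @rdname GenomeBundle-class
#' @export
setMethod("familyList", "GenomeBundle", function(x) x@families)
#' @rdname GenomeBundle-class
#' @export
setMethod("targetRef", "GenomeBundle", function(x) x@target)

#' @rdname TargetReference-class
#' @export
setMethod("show", "TargetReference", function(object) {
  cat(sprintf("TargetReference '%s' (%s): %d bp, canonical site after base %d\n",
              object@name, object@geneLabel, length(object@sequence),
              object@canonicalSite))
})

#' @rdname ElementFamily-class
#' @export
setMethod("show", "ElementFamily", function(object) {
  cat(sprintf("ElementFamily '%s' [%s]: %d bp consensus, %d aa ORF product\n",
              object@familyId, object@clade, length(object@consensus),
              length(object@protein)))
  if (!is.null(object@info$ribozyme_pos))
    cat(sprintf("  ribozyme motif at %d-%d (5' UTR)\n",
                object@info$ribozyme_pos, object@info$ribozyme_pos + 10L))
  if (!is.null(object@info$utr3_segment))
    cat(sprintf("  28S-like 3' UTR segment: %d bp at identity %.2f\n",
                object@info$utr3_segment$length,
                object@info$utr3_segment$identity))
})

#' @rdname GenomeBundle-class
#' @export
setMethod("show", "GenomeBundle", function(object) {
  cat(sprintf("GenomeBundle: %d contig(s), %s bp total; %d inserted copies from %d families\n",
              length(object@genome),
              format(sum(width(object@genome)), big.mark = ","),
              nrow(object@truth), length(object@families)))
})
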