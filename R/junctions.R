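## Copy discovery and insertion-junction analysis.
##
## Junction offsets are measured on the target's coordinate system: the 5'
## offset is the number of target bases immediately upstream of the
## canonical site missing at the junction (0 = canonical 5' junction,
## positive = that much 28S replaced by the element), and the 3' offset is
## the analogous downstream quantity. Bottom-strand cleavage at the
## canonical site is essentially invariant while top-strand cleavage
## varies, so the default tolerances are asymmetric (tol5 = 2, tol3 = 0).

#' @import GenomicRanges
#' @import IRanges
NULL

.asNamedChar <- function(x) {
  if (is(x, "GenomeBundle")) x <- genomeSeq(x)
  if (is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  if (is(x, "XString")) x <- as.character(x)
  if (is.null(names(x)) && length(x) > 1L)
    names(x) <- paste0("seq", seq_along(x))
  x
}

## k-mer seed pairs (1-based genome/consensus positions) for one strand
.seedPairs <- function(gseq, cseq, k) {
  nc <- nchar(cseq); ng <- nchar(gseq)
  if (nc < k || ng < k) return(data.frame(gpos = integer(0), cpos = integer(0)))
  ck <- substring(cseq, seq_len(nc - k + 1L), seq_len(nc - k + 1L) + k - 1L)
  idx <- split(seq_along(ck), ck)
  gk <- substring(gseq, seq_len(ng - k + 1L), seq_len(ng - k + 1L) + k - 1L)
  hit <- which(gk %in% names(idx))
  if (length(hit) == 0L) return(data.frame(gpos = integer(0), cpos = integer(0)))
  cl <- idx[gk[hit]]
  data.frame(gpos = rep(hit, lengths(cl)), cpos = unlist(cl, use.names = FALSE))
}

## chain seeds on one strand into candidate copies and refine boundaries
## by ungapped X-drop extension along the dominant diagonal
.chainCandidates <- function(gseq, cseq, k, chainGap, band, xdrop) {
  sp <- .seedPairs(gseq, cseq, k)
  if (nrow(sp) == 0L) return(NULL)
  sp$diag <- sp$gpos - sp$cpos
  sp <- sp[order(sp$diag, sp$gpos), ]
  ## per-diagonal runs broken at genomic gaps > chainGap
  brk <- c(TRUE, diff(sp$diag) != 0L | diff(sp$gpos) > chainGap)
  sp$chain <- cumsum(brk)
  chains <- lapply(split(sp, sp$chain), function(ch) {
    data.frame(gstart = min(ch$gpos), gend = max(ch$gpos) + k - 1L,
               cstart = min(ch$cpos), cend = max(ch$cpos) + k - 1L,
               diag = ch$diag[1L], nseed = nrow(ch))
  })
  chains <- do.call(rbind, chains)
  chains <- chains[order(chains$gstart), , drop = FALSE]
  ## merge chains on nearby diagonals whose genomic extents are close
  merged <- list()
  cur <- chains[1L, , drop = FALSE]
  flush <- function(cl) {
    best <- cl[which.max(cl$gend - cl$gstart + cl$nseed), , drop = FALSE]
    data.frame(gstart = min(cl$gstart), gend = max(cl$gend),
               diag = best$diag,
               ag = best$gstart, ac = best$gstart - best$diag,
               ag2 = best$gend, ac2 = best$gend - best$diag)
  }
  if (nrow(chains) > 1L) {
    for (i in 2:nrow(chains)) {
      ch <- chains[i, , drop = FALSE]
      if (any(abs(ch$diag - cur$diag) <= band) &&
          ch$gstart - max(cur$gend) <= chainGap) {
        cur <- rbind(cur, ch)
      } else {
        merged[[length(merged) + 1L]] <- flush(cur)
        cur <- ch
      }
    }
  }
  merged[[length(merged) + 1L]] <- flush(cur)
  cands <- do.call(rbind, merged)
  ## X-drop refinement from the dominant diagonal's anchors
  nc <- nchar(cseq); ng <- nchar(gseq)
  segIdentity <- function(gfrom, gto, cfrom, cto) {
    mean(s2c(substr(gseq, gfrom, gto)) == s2c(substr(cseq, cfrom, cto)))
  }
  out <- lapply(seq_len(nrow(cands)), function(i) {
    cd <- cands[i, ]
    extL <- .xdrop_extend_cpp(gseq, cseq, cd$ag, cd$ac, -1L, 1, -3, xdrop)
    extR <- .xdrop_extend_cpp(gseq, cseq, cd$ag2, cd$ac2, 1L, 1, -3, xdrop)
    gs <- cd$ag - extL; ge <- cd$ag2 + extR
    cs <- cd$ac - extL; ce <- cd$ac2 + extR
    ## snap to the consensus ends: a short terminal cluster of mutations
    ## stops the X-drop a few bases early, but a true element copy runs
    ## to the end of the consensus; extend when the missing tail still
    ## looks element-derived (identity well above random)
    tR <- nc - ce
    if (tR > 0L && tR <= 25L && ge + tR <= ng &&
        segIdentity(ge + 1L, ge + tR, ce + 1L, nc) >= 0.5) {
      ge <- ge + tR; ce <- nc
    }
    tL <- cs - 1L
    if (tL > 0L && tL <= 25L && gs - tL >= 1L &&
        segIdentity(gs - tL, gs - 1L, 1L, tL) >= 0.5) {
      gs <- gs - tL; cs <- 1L
    }
    data.frame(gstart = gs, gend = ge, cstart = cs, cend = ce,
               identity = segIdentity(gs, ge, cs, ce))
  })
  do.call(rbind, out)
}

#' Locate copies of an element family in a genome
#'
#' k-mer seeded, ungapped X-drop-extended search on both strands, with
#' chained seeds merged into copy candidates and overlapping candidates
#' resolved best-hit-first. This is the package's lightweight stand-in for
#' an iterative homology screen; it assumes copy decay is dominated by
#' substitutions.
#'
#' @param genome Named character vector, [Biostrings::DNAStringSet] or
#'   [GenomeBundle-class].
#' @param family [ElementFamily-class] or a consensus string.
#' @param k Seed length (8-32).
#' @param minLen Minimum reported copy length (bp).
#' @param minIdentity Minimum ungapped identity to the consensus (>= 0.6).
#' @param chainGap Maximum seed gap (bp) bridged within one copy.
#' @param band Diagonal tolerance when merging seed chains.
#' @param xdrop Score drop terminating boundary extension.
#' @return A [GenomicRanges::GRanges] (1-based inclusive) with metadata
#'   columns `copy_id`, `family_id`, `identity`, `cons_start`, `cons_end`.
#' @export
findCopies <- function(genome, family, k = 12L, minLen = 100L,
                       minIdentity = 0.7, chainGap = 400L, band = 15L,
                       xdrop = 12) {
  stopifnot(k >= 8L, k <= 32L, minIdentity >= 0.6)
  genome <- .asNamedChar(genome)
  famId <- if (is(family, "ElementFamily")) familyId(family) else "family"
  cseq <- if (is(family, "ElementFamily"))
    as.character(consensusSeq(family)) else as.character(family)
  if (any(nchar(genome) == 0L) || nchar(cseq) == 0L)
    stop("empty genome or consensus")
  if (is.null(names(genome))) names(genome) <- "seq1"

  rows <- list()
  for (contig in names(genome)) {
    gseq <- genome[[contig]]
    n <- nchar(gseq)
    for (strand in c("+", "-")) {
      gs <- if (strand == "+") gseq else revComp(gseq)
      cand <- .chainCandidates(gs, cseq, k, chainGap, band, xdrop)
      if (is.null(cand) || nrow(cand) == 0L) next
      if (strand == "-") {
        tmp <- cand$gstart
        cand$gstart <- n - cand$gend + 1L
        cand$gend <- n - tmp + 1L
      }
      cand$contig <- contig
      cand$strand <- strand
      rows[[length(rows) + 1L]] <- cand
    }
  }
  empty <- GenomicRanges::GRanges(
    seqnames = character(0), ranges = IRanges::IRanges(),
    strand = character(0), copy_id = character(0), family_id = character(0),
    identity = numeric(0), cons_start = integer(0), cons_end = integer(0))
  if (length(rows) == 0L) return(empty)
  cand <- do.call(rbind, rows)
  cand <- cand[cand$gend - cand$gstart + 1L >= minLen &
               cand$identity >= minIdentity, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  ## best-hit resolution: keep non-overlapping candidates, best first
  cand$score <- (cand$gend - cand$gstart + 1L) * cand$identity
  cand <- cand[order(-cand$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1L):nrow(cand)
      ov <- cand$contig[later] == cand$contig[i] &
        cand$gstart[later] <= cand$gend[i] &
        cand$gend[later] >= cand$gstart[i]
      keep[later][ov] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$contig, cand$gstart), , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = cand$contig,
    ranges = IRanges::IRanges(start = cand$gstart, end = cand$gend),
    strand = cand$strand,
    copy_id = sprintf("%s.c%02d", famId, seq_len(nrow(cand))),
    family_id = famId, identity = cand$identity,
    cons_start = cand$cstart, cons_end = cand$cend)
}

#' Drop copy calls that are really target-gene sequence
#'
#' Families carrying a 28S-derived segment in their 3' UTR cause every
#' intact 28S unit to produce a short spurious "copy" call. This filter
#' removes calls whose genomic sequence is essentially explained by the
#' target gene itself: a local alignment to the target covering at least
#' `maxCover` of the call at identity at least the call's identity to the
#' element consensus. Genuine element copies are orders of magnitude
#' longer than their target-derived segment and survive.
#'
#' @param copies [GenomicRanges::GRanges] from [findCopies()].
#' @param genome Genome sequences.
#' @param target [TargetReference-class].
#' @param maxCover Fraction of the call the target alignment must cover
#'   for the call to be discarded.
#' @return The filtered `GRanges`.
#' @export
maskTargetMatches <- function(copies, genome, target, maxCover = 0.8) {
  if (length(copies) == 0L) return(copies)
  genome <- .asNamedChar(genome)
  if (is.null(names(genome))) names(genome) <- "seq1"
  tgt <- as.character(targetSeq(target))
  drop <- vapply(seq_along(copies), function(i) {
    gr <- copies[i]
    seg <- substr(genome[[as.character(GenomicRanges::seqnames(gr))]],
                  GenomicRanges::start(gr), GenomicRanges::end(gr))
    res <- smithWaterman(seg, tgt)
    cov <- (res$a_end - res$a_start + 1L) / nchar(seg)
    cov >= maxCover && res$identity >= gr$identity
  }, logical(1L))
  copies[!drop]
}

## align one flank to the target (plus strand) and project the element
## boundary onto target coordinates
.projectFlank <- function(flank, tgt, side, minId, minLen, swParams) {
  if (nchar(flank) == 0L)
    return(list(pos = NA_integer_, identity = NA_real_, gap = NA_integer_))
  res <- do.call(smithWaterman, c(list(flank, tgt), swParams))
  av <- s2c(res$a_aln); bv <- s2c(res$b_aln)
  ## qualification identity is matches over the whole flank window:
  ## positions outside the local alignment count as mismatches. True 28S
  ## flanks score near 1; the best gappy local alignment random spacer
  ## achieves against a 28S-sized target stays near 0.4-0.55.
  windowId <- sum(av == bv & av != "-") / nchar(flank)
  if (nchar(flank) < minLen || windowId < minId)
    return(list(pos = NA_integer_, identity = windowId,
                gap = NA_integer_))
  if (side == 5L) {
    ## flank bases between the aligned block and the element boundary:
    ## usually residue from a slightly miscalled boundary, never projected
    tail <- nchar(flank) - res$a_end
    list(pos = res$b_end, identity = windowId, gap = tail)
  } else {
    lead <- res$a_start - 1L
    list(pos = res$b_start, identity = windowId, gap = lead)
  }
}

#' Call 5'/3' insertion junctions against the target reference
#'
#' For each located copy, the `window` bases flanking the element in the
#' genome are locally aligned to the target reference; the element
#' boundary is projected onto target coordinates and offsets relative to
#' the canonical site are computed (`offset5` = upstream target bases
#' missing, `offset3` = downstream). Any unaligned slack between the
#' aligned flank block and the element boundary (a small target-site
#' alteration, or residue from a slightly miscalled boundary) is excluded
#' from the projection and reported in `flank5_gap`/`flank3_gap`.
#' Specificity: `canonical` when both
#' offsets are within tolerance, `shifted_5prime`/`shifted_3prime` when
#' one side is displaced, `non_adjacent` when neither flank reaches
#' `minFlankIdentity` over `minFlankLen` aligned columns. When only one
#' flank qualifies the missing side is treated as displaced.
#'
#' @param copies [GenomicRanges::GRanges] from [findCopies()] (or a
#'   truth-table-like `data.frame` with `contig`, `start`, `end`,
#'   `strand`, `copy_id`, `family_id`).
#' @param genome Genome sequences (same forms as [findCopies()]).
#' @param target A [TargetReference-class].
#' @param window Flank window length (>= 30 bp).
#' @param minFlankIdentity,minFlankLen Flank-hit qualification: the flank
#'   must be at least `minFlankLen` long and its matches to the target,
#'   counted over the whole flank window (unaligned positions count as
#'   mismatches), must reach `minFlankIdentity`.
#' @param tol5,tol3 Offset tolerances (bp) for the canonical call;
#'   asymmetric by default.
#' @param swParams Optional list of scoring overrides for the aligner.
#' @return `data.frame`, one row per copy: flank hit positions and
#'   identities, offsets, junction gaps, `specificity`, plus a
#'   `truncated_flank` flag for copies at contig edges.
#' @export
callJunctions <- function(copies, genome, target, window = 60L,
                          minFlankIdentity = 0.8, minFlankLen = 30L,
                          tol5 = 2L, tol3 = 0L, swParams = list()) {
  stopifnot(window >= 30L)
  genome <- .asNamedChar(genome)
  if (is.null(names(genome))) names(genome) <- "seq1"
  if (is(copies, "GRanges")) {
    df <- data.frame(contig = as.character(GenomicRanges::seqnames(copies)),
                     start = GenomicRanges::start(copies),
                     end = GenomicRanges::end(copies),
                     strand = as.character(GenomicRanges::strand(copies)),
                     copy_id = copies$copy_id, family_id = copies$family_id,
                     stringsAsFactors = FALSE)
  } else df <- as.data.frame(copies)
  if (nrow(df) == 0L)
    return(cbind(df, data.frame(flank5_target_pos = integer(0),
                                flank5_identity = numeric(0),
                                flank3_target_pos = integer(0),
                                flank3_identity = numeric(0),
                                offset5 = integer(0), offset3 = integer(0),
                                flank5_gap = integer(0),
                                flank3_gap = integer(0),
                                truncated_flank = logical(0),
                                specificity = character(0))))
  tgt <- as.character(targetSeq(target))
  cs <- canonicalSite(target)

  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    gseq <- genome[[r$contig]]
    upFrom <- max(1L, r$start - window)
    up <- substr(gseq, upFrom, r$start - 1L)
    down <- substr(gseq, r$end + 1L, min(nchar(gseq), r$end + window))
    truncated <- nchar(up) < window || nchar(down) < window
    h5 <- .projectFlank(up, tgt, 5L, minFlankIdentity, minFlankLen, swParams)
    h3 <- .projectFlank(down, tgt, 3L, minFlankIdentity, minFlankLen, swParams)
    offset5 <- if (is.na(h5$pos)) NA_integer_ else cs - h5$pos
    offset3 <- if (is.na(h3$pos)) NA_integer_ else h3$pos - (cs + 1L)
    ok5 <- !is.na(offset5); ok3 <- !is.na(offset3)
    in5 <- ok5 && abs(offset5) <= tol5
    in3 <- ok3 && abs(offset3) <= tol3
    specificity <- if (!ok5 && !ok3) "non_adjacent"
      else if (in5 && in3) "canonical"
      else if (ok5 && ok3) {
        if (!in5 && in3) "shifted_5prime"
        else if (in5 && !in3) "shifted_3prime"
        else if (abs(offset5) >= abs(offset3)) "shifted_5prime"
        else "shifted_3prime"
      }
      else if (ok5) { if (in5) "shifted_3prime" else "shifted_5prime" }
      else { if (in3) "shifted_5prime" else "shifted_3prime" }
    data.frame(r, flank5_target_pos = h5$pos, flank5_identity = h5$identity,
               flank3_target_pos = h3$pos, flank3_identity = h3$identity,
               offset5 = offset5, offset3 = offset3,
               flank5_gap = h5$gap, flank3_gap = h3$gap,
               truncated_flank = truncated, specificity = specificity,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify family-level target specificity
#'
#' Aggregates per-copy junction calls into a family verdict:
#' `non_specific` when no copy is adjacent to the target gene,
#' `target_specific` when the adjacent fraction reaches
#' `specificFraction`, `partially_specific` otherwise (e.g. a two-copy
#' family with exactly one copy adjacent to the 28S gene).
#'
#' @param calls Junction-call table from [callJunctions()]; may contain
#'   several families (grouped by `family_id`).
#' @param specificFraction Minimum adjacent fraction for
#'   `target_specific`.
#' @return `data.frame` with one row per family: `family_id`, `n_copies`,
#'   `n_adjacent`, `n_non_adjacent`, `verdict`, `modal_offset5` (most
#'   frequent defined 5' offset; ties broken toward the smallest value).
#' @export
classifyFamily <- function(calls, specificFraction = 0.9) {
  stopifnot(nrow(calls) >= 1L)
  rows <- lapply(split(calls, calls$family_id), function(g) {
    n <- nrow(g)
    nAdj <- sum(g$specificity != "non_adjacent")
    verdict <- if (nAdj == 0L) "non_specific"
      else if (nAdj / n >= specificFraction) "target_specific"
      else "partially_specific"
    off <- g$offset5[!is.na(g$offset5)]
    modal <- if (length(off) == 0L) NA_integer_ else {
      tab <- table(off)
      cand <- as.integer(names(tab)[tab == max(tab)])
      min(cand)
    }
    data.frame(family_id = g$family_id[1L], n_copies = n, n_adjacent = nAdj,
               n_non_adjacent = n - nAdj, verdict = verdict,
               modal_offset5 = modal, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Detect a 28S-derived segment in a family's 3' UTR
#'
#' Locally aligns the 3'-terminal `utrWindow` bases of the family
#' consensus to the target reference. A qualifying hit (at least
#' `minHitLen` aligned columns at identity >= `minHitIdentity`, a floor
#' that rejects the short noisy local alignments random sequence produces
#' against a 28S-sized target) whose identity is *below* the identity of
#' the true downstream flanks (`flankIdentity`, measured from genomic
#' copies) indicates an element-internal, degraded 28S-like segment
#' rather than true flanking 28S; equal-or-higher identity is
#' indistinguishable from flank and reported as not internal.
#'
#' @param family [ElementFamily-class] (consensus >= 500 bp).
#' @param target [TargetReference-class].
#' @param flankIdentity Identity of true downstream flanks to the target.
#' @param minHitLen Minimum aligned columns for a qualifying hit (>= 30).
#' @param minHitIdentity Minimum identity for a qualifying hit.
#' @param marginIdentity Identity must fall below
#'   `flankIdentity - marginIdentity` to call the segment internal; the
#'   margin absorbs local-alignment noise (e.g. low-scoring extensions
#'   into random UTR sequence around an otherwise exact segment).
#' @param utrWindow 3'-terminal span searched (bp).
#' @param swParams Optional aligner scoring overrides.
#' @return One-row `data.frame`: `family_id`, `utr_start`, `utr_end`
#'   (element coordinates), `target_start`, `target_end`, `identity`,
#'   `flank_identity`, `is_utr_internal`.
#' @export
detectTargetLikeUTR <- function(family, target, flankIdentity,
                                minHitLen = 30L, minHitIdentity = 0.7,
                                marginIdentity = 0.02, utrWindow = 300L,
                                swParams = list()) {
  stopifnot(minHitLen >= 30L)
  cseq <- as.character(consensusSeq(family))
  if (nchar(cseq) < 500L) stop("family consensus must be >= 500 bp")
  from <- max(1L, nchar(cseq) - utrWindow + 1L)
  utr <- substr(cseq, from, nchar(cseq))
  res <- do.call(smithWaterman, c(list(utr, as.character(targetSeq(target))),
                                  swParams))
  hit <- nchar(res$a_aln) >= minHitLen && res$identity >= minHitIdentity
  if (!hit)
    return(data.frame(family_id = familyId(family), utr_start = NA_integer_,
                      utr_end = NA_integer_, target_start = NA_integer_,
                      target_end = NA_integer_, identity = NA_real_,
                      flank_identity = flankIdentity,
                      is_utr_internal = FALSE, stringsAsFactors = FALSE))
  data.frame(family_id = familyId(family),
             utr_start = from + res$a_start - 1L,
             utr_end = from + res$a_end - 1L,
             target_start = res$b_start, target_end = res$b_end,
             identity = res$identity, flank_identity = flankIdentity,
             is_utr_internal = res$identity < flankIdentity - marginIdentity,
             stringsAsFactors = FALSE)
}

#' Find exact occurrences of a nucleotide motif
#'
#' U and T are treated as equivalent (RNA motifs can be searched in DNA
#' and vice versa). Coordinates are 1-based inclusive.
#'
#' @param seq Nucleotide string (or `XString`).
#' @param motif Non-empty motif string.
#' @return `data.frame` with columns `start`, `end`; zero rows when the
#'   motif is absent.
#' @export
#' @examples
#' findMotif(paste0(strrep("A", 36), "CCTCCTCGTGG"), "CCUCCUCGUGG")
findMotif <- function(seq, motif) {
  if (nchar(motif) == 0L) stop("motif must be non-empty")
  s <- chartr("Uu", "Tt", toupper(as.character(seq)))
  m <- chartr("Uu", "Tt", toupper(as.character(motif)))
  n <- nchar(s); k <- nchar(m)
  if (n < k) return(data.frame(start = integer(0), end = integer(0)))
  ## occurrences may overlap, so scan all windows
  idx <- seq_len(n - k + 1L)
  hits <- idx[substring(s, idx, idx + k - 1L) == m]
  data.frame(start = hits, end = hits + k - 1L)
}
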