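## Synthetic rDNA-array genome simulator.
##
## The simulator builds tandem 28S-like units carrying R2 insertions of
## known junction geometry, so every downstream caller (copy finder,
## junction caller, clade typer, consensus and tree builders) can be
## tested against an exact ground truth.

## The two reverse primers anchored in the 28S downstream of the canonical
## insertion site. Their reverse complements define the synthetic 28S core:
## revComp(R28S_A) | revComp(R28S_B), with the canonical site at the block
## junction, so a canonical insertion leaves revComp(R28S_B) immediately 3'
## of the element.
R28S_A <- "TAGATGACGAGGCATTTGGC"
R28S_B <- "ATCCATTCATGCGCGTCACT"

## HDV-like ribozyme core motif (DNA form of the conserved CCUCCUCGUGG).
RIBOZYME_MOTIF <- "CCTCCTCGTGG"

ZF_CLADE_PROFILE <- list(
  R2A = c("CCHH", "CCHH", "CCHC"),
  R2B = c("CCHH", "CCHC"),
  R2C = c("CCHH", "CCHH"),
  R2D = c("CCHH"))

#' Build the synthetic 28S target reference
#'
#' Constructs a synthetic 28S segment whose core is the concatenation of
#' the reverse complements of the two 28S reverse primers (R28S_A block,
#' then R28S_B block), with the canonical insertion site at the junction
#' between the blocks, padded by `flankLen` random bases on each side.
#' This is a documented synthetic convention for the junction context, not
#' a claim about the biological 28S sequence. The construction is rejected
#' and resampled until each primer's reverse complement occurs exactly
#' once in the final sequence (on either strand), so primer-site scans are
#' unambiguous.
#'
#' @param flankLen Number of random bases added on each side (>= 0).
#' @param seed Optional integer seed.
#' @param name Sequence name.
#' @return A [TargetReference-class] with
#'   `canonicalSite = flankLen + 20`.
#' @export
#' @examples
#' tr <- buildTargetReference(flankLen = 0)
#' as.character(targetSeq(tr))
#' canonicalSite(tr)
buildTargetReference <- function(flankLen = 200L, seed = NULL,
                                 name = "28S_synthetic") {
  stopifnot(flankLen >= 0L)
  core5 <- revComp(R28S_A)
  core3 <- revComp(R28S_B)
  withSeed(seed, {
    for (attempt in 1:50) {
      seqc <- paste0(randDNA(flankLen), core5, core3, randDNA(flankLen))
      n5 <- .countOccurrences(seqc, core5) + .countOccurrences(revComp(seqc), core5)
      n3 <- .countOccurrences(seqc, core3) + .countOccurrences(revComp(seqc), core3)
      if (n5 == 1L && n3 == 1L) break
    }
    TargetReference(name, seqc, canonicalSite = flankLen + 20L)
  })
}

.countOccurrences <- function(x, pattern) {
  m <- gregexpr(pattern, x, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

## codon sets per amino acid, stop codons excluded
.aa2codons <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

## seeded reverse translation (random synonymous codons)
.revTranslate <- function(aa) {
  chars <- s2c(aa)
  codons <- vapply(chars, function(a) {
    cs <- .aa2codons[[a]]
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, character(1L), USE.NAMES = FALSE)
  c2s(codons)
}

## one zinc finger at the protein level: C-x(3)-C-x(12)-H-x(4)-[H|C]
.zfProtein <- function(kind) {
  paste0("C", c2s(sample(AA_FILLER, 3L, replace = TRUE)),
         "C", c2s(sample(AA_FILLER, 12L, replace = TRUE)),
         "H", c2s(sample(AA_FILLER, 4L, replace = TRUE)),
         substr(kind, 4L, 4L))
}

## all concrete instantiations of an IUPAC primer, deterministic order
.expandPrimer <- function(primer) {
  sets <- lapply(s2c(primer), function(cc) IUPAC_SETS[[cc]])
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste0, collapse = "")
}

## splice a concrete primer-site instantiation into orfDNA at a
## codon-aligned nt offset, choosing the first instantiation that keeps
## the reading frame free of stop codons
.splicePrimerSite <- function(orfDNA, primer, ntStart) {
  cands <- .expandPrimer(primer)
  span0 <- ntStart - ((ntStart - 1L) %% 3L)          # codon-aligned start
  for (cand in cands) {
    trial <- paste0(substr(orfDNA, 1L, ntStart - 1L), cand,
                    substr(orfDNA, ntStart + nchar(cand), nchar(orfDNA)))
    spanEnd <- ntStart + nchar(cand) - 1L
    spanEnd <- spanEnd + (3L - (spanEnd %% 3L)) %% 3L
    codons <- substring(trial, seq(span0, spanEnd - 2L, by = 3L),
                        seq(span0 + 2L, spanEnd, by = 3L))
    if (!any(Biostrings::GENETIC_CODE[codons] == "*")) {
      return(trial)
    }
  }
  stop("could not embed primer site without creating a stop codon")
}

#' Simulate an R2 element family consensus
#'
#' Builds a full-length element: a 5' UTR (optionally carrying the
#' HDV-like ribozyme core motif `CCTCCTCGTGG` at a recorded position), a
#' single long ORF encoding the clade's zinc-finger complement followed by
#' an RT block containing exact binding sites for the nested degenerate
#' primers R2IIF2 and R2IF2, and a 3' UTR optionally carrying a degraded
#' copy of the 28S sequence downstream of the canonical site (emulating
#' families whose 3' UTR is partly 28S-derived). The zinc-finger region
#' occupies a fixed-length block so ORF products from different clades are
#' directly stackable.
#'
#' @param clade One of `"R2A"`, `"R2B"`, `"R2C"`, `"R2D"`.
#' @param totalLen Total element length in bp (>= 2000).
#' @param target [TargetReference-class]; required when
#'   `utr3TargetSegment` is given.
#' @param utr3TargetSegment `NULL`, or `list(length =, identity =)` with
#'   identity in `(0.5, 1]`: embeds that much 28S downstream-of-site
#'   sequence, mutated to the requested identity, inside the 3' UTR.
#' @param ribozyme Logical; embed the ribozyme motif in the 5' UTR.
#' @param ribozymePos 1-based motif start within the element.
#' @param utr5Len,utr3Len UTR lengths in bp.
#' @param familyId Family name (default derived from the clade).
#' @param seed Optional integer seed.
#' @return An [ElementFamily-class]; `familyInfo()` records the ORF
#'   coordinates, primer-site and motif positions and the 3' UTR segment.
#' @export
simulateElementFamily <- function(clade = c("R2A", "R2B", "R2C", "R2D"),
                                  totalLen = 3500L, target = NULL,
                                  utr3TargetSegment = NULL, ribozyme = TRUE,
                                  ribozymePos = 37L, utr5Len = 500L,
                                  utr3Len = 300L, familyId = NULL,
                                  seed = NULL) {
  clade <- match.arg(clade)
  totalLen <- as.integer(totalLen)
  stopifnot(totalLen >= 2000L)
  if (!is.null(utr3TargetSegment)) {
    idf <- utr3TargetSegment$identity
    if (is.null(idf) || idf <= 0.5 || idf > 1)
      stop("utr3TargetSegment identity must lie in (0.5, 1]")
    if (is.null(target))
      stop("utr3TargetSegment requires a TargetReference")
  }
  orfLen <- totalLen - utr5Len - utr3Len
  orfLen <- orfLen - (orfLen %% 3L)
  utr3Len <- totalLen - utr5Len - orfLen
  if (orfLen < 900L) stop("totalLen leaves too little room for the ORF")
  nAA <- orfLen %/% 3L - 1L                     # last codon is the stop
  if (is.null(familyId)) familyId <- paste0(clade, "-sim")

  withSeed(seed, {
    result <- NULL
    for (attempt in 1:25) {
      ## --- protein layout: M | zinc-finger block (120 aa) | filler RT ---
      fingers <- vapply(ZF_CLADE_PROFILE[[clade]], .zfProtein, character(1L))
      zfBlock <- paste0(fingers, collapse = c2s(sample(AA_FILLER, 8L, replace = TRUE)))
      zfBlock <- paste0(zfBlock,
                        c2s(sample(AA_FILLER, 120L - nchar(zfBlock), replace = TRUE)))
      filler <- c2s(sample(AA_FILLER, nAA - 1L - 120L, replace = TRUE))
      protein <- paste0("M", zfBlock, filler)
      orfDNA <- paste0(.revTranslate(protein), "TAA")

      ## --- embed nested forward primer sites in the RT block ---
      aaII <- round(nAA * 0.50)
      ntII <- (aaII - 1L) * 3L + 1L
      ntI <- ntII + 3L * 12L
      orfDNA <- .splicePrimerSite(orfDNA, R2_PRIMERS[["R2IIF2"]], ntII)
      orfDNA <- .splicePrimerSite(orfDNA, R2_PRIMERS[["R2IF2"]], ntI)

      ## --- UTRs ---
      utr5 <- randDNA(utr5Len)
      if (ribozyme) {
        stopifnot(ribozymePos >= 1L,
                  ribozymePos + nchar(RIBOZYME_MOTIF) - 1L <= utr5Len)
        substr(utr5, ribozymePos, ribozymePos + nchar(RIBOZYME_MOTIF) - 1L) <-
          RIBOZYME_MOTIF
      }
      utr3 <- randDNA(utr3Len)
      segInfo <- NULL
      if (!is.null(utr3TargetSegment)) {
        L <- as.integer(utr3TargetSegment$length)
        cs <- canonicalSite(target)
        down <- substr(as.character(targetSeq(target)), cs + 1L, cs + L)
        if (nchar(down) < L)
          stop("target has fewer than ", L, " bases downstream of the site")
        segStart <- utr3Len - 30L - L + 1L
        if (segStart < 1L)
          stop("utr3Len too short for the requested 28S-like segment")
        mutated <- .mutateToIdentity(down, utr3TargetSegment$identity)
        substr(utr3, segStart, segStart + L - 1L) <- mutated
        segInfo <- list(length = L, identity = utr3TargetSegment$identity,
                        utr_start = utr5Len + orfLen + segStart,
                        utr_end = utr5Len + orfLen + segStart + L - 1L,
                        target_start = cs + 1L, target_end = cs + L)
      }

      consensus <- paste0(utr5, orfDNA, utr3)
      ## reject rare chance duplicates of the ribozyme motif
      if (ribozyme && .countOccurrences(consensus, RIBOZYME_MOTIF) != 1L) next
      protFinal <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(orfDNA, 1L, orfLen - 3L))))
      info <- list(orf_start = utr5Len + 1L, orf_end = utr5Len + orfLen,
                   primer_sites = c(R2IIF2 = utr5Len + ntII, R2IF2 = utr5Len + ntI),
                   utr3_segment = segInfo)
      if (ribozyme) info$ribozyme_pos <- as.integer(ribozymePos)
      result <- ElementFamily(familyId, consensus, protFinal, clade, info)
      break
    }
    if (is.null(result))
      stop("failed to build a family without a duplicated ribozyme motif")
    result
  })
}

#' Describe one element insertion for the simulator
#'
#' @param familyId Family to insert (must match a simulated family).
#' @param offset5 28S bases immediately upstream of the canonical site
#'   deleted by the insertion (0 = canonical 5' junction).
#' @param offset3 28S bases immediately downstream deleted (0 = canonical).
#' @param truncate5 Element 5' bases removed (5'-truncated copy).
#' @param nonspecific If `TRUE`, the copy is placed at a random position
#'   inside intergenic spacer sequence instead of the 28S site; offsets
#'   must then be 0.
#' @param divergence Per-base substitution probability applied to the copy.
#' @param strand `"+"` or `"-"` orientation of the inserted copy.
#' @return A one-row `data.frame`; rows can be `rbind`-ed into a spec table.
#' @export
insertionSpec <- function(familyId, offset5 = 0L, offset3 = 0L,
                          truncate5 = 0L, nonspecific = FALSE,
                          divergence = 0, strand = "+") {
  stopifnot(offset5 >= 0L, offset3 >= 0L, truncate5 >= 0L,
            divergence >= 0, divergence < 0.5, strand %in% c("+", "-"))
  if (nonspecific && (offset5 != 0L || offset3 != 0L))
    stop("offsets must be 0 for nonspecific insertions")
  data.frame(family_id = familyId, offset5 = as.integer(offset5),
             offset3 = as.integer(offset3), truncate5 = as.integer(truncate5),
             nonspecific = nonspecific, divergence = divergence,
             strand = strand, stringsAsFactors = FALSE)
}

#' Insert element copies into a tandem rDNA array
#'
#' Builds a single-contig genome of `nUnits` tandem copies of the target
#' gene separated (and flanked) by fixed-length random spacers. Each
#' site-specific spec consumes one unit in order: `offset5` bases upstream
#' and `offset3` bases downstream of the canonical site are deleted and
#' the (possibly 5'-truncated, mutated, strand-flipped) element copy is
#' spliced in. Nonspecific specs are placed at random positions inside
#' spacers. The returned truth table records every copy's exact location
#' and parameters (1-based inclusive coordinates).
#'
#' @param target A [TargetReference-class].
#' @param families A list of [ElementFamily-class] (or a single one).
#' @param specs A spec table from [insertionSpec()] rows (or a list of
#'   them); may have zero rows.
#' @param nUnits Number of tandem target units (>= number of site-specific
#'   specs).
#' @param spacerLen Spacer length in bp.
#' @param indels Logical; include indels in copy decay (at one tenth of
#'   the substitution rate).
#' @param seed Optional integer seed; the same (specs, seed) pair
#'   reproduces a byte-identical genome and truth table.
#' @param contigName Name of the single output contig.
#' @return A [GenomeBundle-class].
#' @export
insertCopies <- function(target, families, specs, nUnits, spacerLen = 1000L,
                         indels = FALSE, seed = NULL, contigName = "array1") {
  if (is(families, "ElementFamily")) families <- list(families)
  names(families) <- vapply(families, familyId, character(1L))
  if (is.list(specs) && !is.data.frame(specs)) specs <- do.call(rbind, specs)
  if (is.null(specs)) specs <- insertionSpec("x")[0L, ]
  nUnits <- as.integer(nUnits)
  stopifnot(nUnits >= 1L, spacerLen >= 0L)
  tgt <- as.character(targetSeq(target))
  cs <- canonicalSite(target)
  if (nrow(specs) > 0L) {
    if (!all(specs$family_id %in% names(families)))
      stop("spec references unknown family: ",
           paste(setdiff(specs$family_id, names(families)), collapse = ", "))
    if (any(specs$offset5 > cs))
      stop("offset5 exceeds available target sequence upstream of the site")
    if (any(specs$offset3 > nchar(tgt) - cs))
      stop("offset3 exceeds available target sequence downstream of the site")
  }
  site <- specs[!specs$nonspecific, , drop = FALSE]
  nons <- specs[specs$nonspecific, , drop = FALSE]
  if (nrow(site) > nUnits)
    stop("more site-specific specs (", nrow(site), ") than units (", nUnits, ")")

  withSeed(seed, {
    makeCopySeq <- function(spec) {
      el <- as.character(consensusSeq(families[[spec$family_id]]))
      if (spec$truncate5 > 0L) {
        if (spec$truncate5 >= nchar(el)) stop("truncate5 removes the whole element")
        el <- substr(el, spec$truncate5 + 1L, nchar(el))
      }
      el <- mutateSequence(el, spec$divergence, indels = indels)
      if (spec$strand == "-") el <- revComp(el)
      el
    }

    spacers <- replicate(nUnits + 1L, randDNA(spacerLen))
    ## nonspecific placements: (spacer index, position-after within spacer)
    nsPlace <- NULL
    if (nrow(nons) > 0L) {
      ## keep a margin from the spacer ends: a copy dropped right next to
      ## an rDNA unit would carry a true 28S flank and the nonspecific
      ## truth label would be wrong
      margin <- min(100L, as.integer(spacerLen) %/% 4L)
      lo <- margin; hi <- spacerLen - margin
      if (hi < lo) { lo <- 0L; hi <- spacerLen }
      nsPlace <- data.frame(
        row = seq_len(nrow(nons)),
        spacer = sample.int(nUnits + 1L, nrow(nons), replace = TRUE),
        at = vapply(seq_len(nrow(nons)), function(i)
          lo + sample.int(hi - lo + 1L, 1L) - 1L, integer(1L)))
    }

    pieces <- character(0)
    truth <- list()
    gpos <- 0L                       # bases emitted so far
    copyN <- 0L

    emitSpacer <- function(si) {
      sp <- spacers[si]
      rows <- if (is.null(nsPlace)) integer(0) else
        nsPlace$row[nsPlace$spacer == si]
      if (length(rows) > 0L) {
        ord <- rows[order(nsPlace$at[match(rows, nsPlace$row)])]
        out <- character(0)
        prev <- 0L
        for (r in ord) {
          at <- nsPlace$at[nsPlace$row == r]
          spec <- nons[r, , drop = FALSE]
          el <- makeCopySeq(spec)
          out <- c(out, substr(sp, prev + 1L, at), el)
          copyN <<- copyN + 1L
          st <- gpos + sum(nchar(out)) - nchar(el) + 1L
          truth[[length(truth) + 1L]] <<- data.frame(
            copy_id = sprintf("copy%02d", copyN), family_id = spec$family_id,
            contig = contigName, start = st, end = st + nchar(el) - 1L,
            strand = spec$strand, offset5 = NA_integer_, offset3 = NA_integer_,
            truncate5 = spec$truncate5, nonspecific = TRUE,
            divergence = spec$divergence, stringsAsFactors = FALSE)
          prev <- at
        }
        out <- c(out, substr(sp, prev + 1L, nchar(sp)))
        sp <- paste0(out, collapse = "")
      }
      pieces <<- c(pieces, sp)
      gpos <<- gpos + nchar(sp)
    }

    for (u in seq_len(nUnits)) {
      emitSpacer(u)
      if (u <= nrow(site)) {
        spec <- site[u, , drop = FALSE]
        el <- makeCopySeq(spec)
        left <- substr(tgt, 1L, cs - spec$offset5)
        right <- substr(tgt, cs + spec$offset3 + 1L, nchar(tgt))
        unit <- paste0(left, el, right)
        copyN <- copyN + 1L
        st <- gpos + nchar(left) + 1L
        truth[[length(truth) + 1L]] <- data.frame(
          copy_id = sprintf("copy%02d", copyN), family_id = spec$family_id,
          contig = contigName, start = st, end = st + nchar(el) - 1L,
          strand = spec$strand, offset5 = spec$offset5, offset3 = spec$offset3,
          truncate5 = spec$truncate5, nonspecific = FALSE,
          divergence = spec$divergence, stringsAsFactors = FALSE)
      } else {
        unit <- tgt
      }
      pieces <- c(pieces, unit)
      gpos <- gpos + nchar(unit)
    }
    emitSpacer(nUnits + 1L)

    genome <- Biostrings::DNAStringSet(setNames(paste0(pieces, collapse = ""),
                                                contigName))
    truthDF <- if (length(truth)) do.call(rbind, truth) else
      data.frame(copy_id = character(0), family_id = character(0),
                 contig = character(0), start = integer(0), end = integer(0),
                 strand = character(0), offset5 = integer(0),
                 offset3 = integer(0), truncate5 = integer(0),
                 nonspecific = logical(0), divergence = numeric(0),
                 stringsAsFactors = FALSE)
    ## order rows by genomic start for readability
    truthDF <- truthDF[order(truthDF$start), , drop = FALSE]
    rownames(truthDF) <- NULL
    new("GenomeBundle", genome = genome, truth = truthDF,
        families = families, target = target,
        params = list(n_units = nUnits, spacer_len = as.integer(spacerLen),
                      seed = seed, indels = indels))
  })
}

#' Write a GenomeBundle to disk
#'
#' Emits `genome.fasta` (60-column wrap), `truth.tsv` (tab-separated with
#' header) and `copies.gff3` (feature type `mobile_genetic_element`, with
#' `ID`, `family_id`, `offset5`, `offset3`, `truncate5`, `nonspecific`
#' attributes) into `dir`.
#'
#' @param bundle A [GenomeBundle-class].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeGenomeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  tsv <- file.path(dir, "truth.tsv")
  gff <- file.path(dir, "copies.gff3")
  Biostrings::writeXStringSet(genomeSeq(bundle), fa, width = 60L)
  write.table(truthTable(bundle), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(truthTable(bundle)) == 0L) {
    writeLines("##gff-version 3", gff)
  } else {
    rtracklayer::export(.truthToGRanges(truthTable(bundle)), gff,
                        format = "gff3")
  }
  invisible(c(fasta = fa, truth = tsv, gff3 = gff))
}

.truthToGRanges <- function(tr) {
  gr <- GenomicRanges::GRanges(
    seqnames = tr$contig,
    ranges = IRanges::IRanges(start = tr$start, end = tr$end),
    strand = tr$strand)
  gr$source <- rep("rDNAretro", nrow(tr))
  gr$type <- rep("mobile_genetic_element", nrow(tr))
  gr$ID <- tr$copy_id
  gr$family_id <- tr$family_id
  gr$offset5 <- tr$offset5
  gr$offset3 <- tr$offset3
  gr$truncate5 <- tr$truncate5
  gr$nonspecific <- tolower(as.character(tr$nonspecific))
  gr
}

#' Read a target reference from a FASTA file
#'
#' @param fasta Path to a single-sequence FASTA.
#' @param canonicalSite Number of bases preceding the insertion point.
#' @param geneLabel Gene label (default `"28S"`).
#' @return A [TargetReference-class].
#' @export
readTargetReference <- function(fasta, canonicalSite, geneLabel = "28S") {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1L) stop("expected a single-sequence FASTA")
  TargetReference(names(ss)[1L], as.character(ss[[1L]]), canonicalSite,
                  geneLabel)
}
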