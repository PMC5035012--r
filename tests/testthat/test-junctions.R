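makeBundle <- function(specs, seed = 3, nUnits = NULL, famSeed = 11,
                       spacerLen = 1000, clade = "R2A", totalLen = 3500) {
  tr <- buildTargetReference(flankLen = 200, seed = 1)
  fam <- simulateElementFamily(clade, seed = famSeed, familyId = "fam",
                               totalLen = totalLen)
  if (is.null(nUnits)) nUnits <- max(1, sum(!specs$nonspecific))
  list(tr = tr, fam = fam,
       bundle = insertCopies(tr, fam, specs, nUnits = nUnits,
                             spacerLen = spacerLen, seed = seed))
}

test_that("the consensus finds itself as one full-length perfect copy", {
  fam <- simulateElementFamily("R2A", seed = 2, familyId = "f")
  g <- c(chr = as.character(consensusSeq(fam)))
  cp <- findCopies(g, fam)
  expect_identical(length(cp), 1L)
  expect_identical(GenomicRanges::start(cp), 1L)
  expect_identical(GenomicRanges::end(cp), nchar(g[[1]]))
  expect_identical(cp$identity, 1)
  expect_identical(as.character(GenomicRanges::strand(cp)), "+")
})

test_that("a genome without insertions yields no copies", {
  tr <- buildTargetReference(flankLen = 200, seed = 1)
  fam <- simulateElementFamily("R2A", seed = 2, familyId = "f")
  b <- insertCopies(tr, fam, NULL, nUnits = 3, spacerLen = 800, seed = 4)
  expect_identical(length(findCopies(b, fam)), 0L)
  expect_error(findCopies(character(0), fam))
})

test_that("recall is complete with small boundary error at 5% divergence", {
  for (seed in c(21, 22, 23)) {
    specs <- rbind(insertionSpec("fam", divergence = 0.05),
                   insertionSpec("fam", offset5 = 110, divergence = 0.05),
                   insertionSpec("fam", divergence = 0.05, strand = "-"),
                   insertionSpec("fam", nonspecific = TRUE,
                                 divergence = 0.05))
    mb <- makeBundle(specs, seed = seed)
    cp <- findCopies(mb$bundle, mb$fam)
    tt <- truthTable(mb$bundle)
    expect_identical(length(cp), nrow(tt))
    ov <- GenomicRanges::findOverlaps(
      cp, GenomicRanges::GRanges(tt$contig,
                                 IRanges::IRanges(tt$start, tt$end)))
    expect_identical(length(ov), nrow(tt))   # one-to-one
    hit <- S4Vectors::subjectHits(ov)
    expect_true(all(abs(GenomicRanges::start(cp) - tt$start[hit]) <= 5))
    expect_true(all(abs(GenomicRanges::end(cp) - tt$end[hit]) <= 5))
    expect_identical(as.character(GenomicRanges::strand(cp)),
                     tt$strand[hit])
  }
})

test_that("canonical, shifted and truncated insertions round-trip exactly", {
  specs <- rbind(insertionSpec("fam"),
                 insertionSpec("fam", offset5 = 110),
                 insertionSpec("fam", offset5 = 130),
                 insertionSpec("fam", offset5 = 15),
                 insertionSpec("fam", offset3 = 12),
                 insertionSpec("fam", truncate5 = 1500, strand = "-"))
  mb <- makeBundle(specs)
  calls <- callJunctions(findCopies(mb$bundle, mb$fam), mb$bundle, mb$tr)
  calls <- calls[order(calls$start), ]
  expect_identical(calls$offset5, c(0L, 110L, 130L, 15L, 0L, 0L))
  expect_identical(calls$offset3, c(0L, 0L, 0L, 0L, 12L, 0L))
  expect_identical(calls$specificity,
                   c("canonical", "shifted_5prime", "shifted_5prime",
                     "shifted_5prime", "shifted_3prime", "canonical"))
})

test_that("copies in spacer sequence are non-adjacent", {
  # spacer flanks are random sequence: their best local alignment to the
  # 28S target must stay below the qualification threshold, trial after
  # trial
  nonAdj <- 0L
  n <- 25L
  for (i in seq_len(n)) {
    specs <- insertionSpec("fam", nonspecific = TRUE)
    mb <- makeBundle(specs, seed = 100 + i, nUnits = 1)
    calls <- callJunctions(findCopies(mb$bundle, mb$fam), mb$bundle, mb$tr)
    expect_identical(nrow(calls), 1L)
    if (calls$specificity == "non_adjacent") nonAdj <- nonAdj + 1L
    expect_true(is.na(calls$offset5) || calls$flank5_identity >= 0.8)
  }
  expect_identical(nonAdj, n)
})

test_that("family verdicts follow adjacency", {
  canonical <- data.frame(family_id = "f1", specificity = rep("canonical", 10),
                          offset5 = rep(0L, 10))
  fs <- classifyFamily(canonical)
  expect_identical(fs$verdict, "target_specific")
  expect_identical(fs$modal_offset5, 0L)
  twoCopy <- data.frame(family_id = "f2",
                        specificity = c("canonical", "non_adjacent"),
                        offset5 = c(0L, NA))
  expect_identical(classifyFamily(twoCopy)$verdict, "partially_specific")
  nonspec <- data.frame(family_id = "f3",
                        specificity = rep("non_adjacent", 30),
                        offset5 = rep(NA_integer_, 30))
  fs3 <- classifyFamily(nonspec)
  expect_identical(fs3$verdict, "non_specific")
  expect_identical(fs3$n_adjacent, 0L)
  # modal offset ties break toward the smallest value
  mixed <- data.frame(family_id = "f4",
                      specificity = rep("canonical", 4),
                      offset5 = c(110L, 0L, 110L, 0L))
  expect_identical(classifyFamily(mixed)$modal_offset5, 0L)
})

test_that("28S-like 3' UTR segments are called internal only when degraded", {
  tr <- buildTargetReference(flankLen = 200, seed = 1)
  withSeg <- simulateElementFamily("R2B", target = tr, seed = 5,
                                   familyId = "seg",
                                   utr3TargetSegment = list(length = 150,
                                                            identity = 0.85))
  hit <- detectTargetLikeUTR(withSeg, tr, flankIdentity = 0.99)
  expect_true(hit$is_utr_internal)
  expect_true(abs(hit$identity - 0.85) <= 0.06)
  # no 28S-like UTR: no qualifying hit
  plain <- simulateElementFamily("R2D", seed = 6, familyId = "plain")
  miss <- detectTargetLikeUTR(plain, tr, flankIdentity = 0.99)
  expect_false(miss$is_utr_internal)
  expect_true(is.na(miss$utr_start))
  # an exact-copy UTR segment is indistinguishable from true flank
  exact <- simulateElementFamily("R2B", target = tr, seed = 7,
                                 familyId = "exact",
                                 utr3TargetSegment = list(length = 150,
                                                          identity = 1.0))
  amb <- detectTargetLikeUTR(exact, tr, flankIdentity = 1.0)
  expect_false(amb$is_utr_internal)
  expect_gte(amb$identity, 0.95)
})

test_that("motif search matches a naive scan and uses 1-based inclusive", {
  seq1 <- paste0(strrep("A", 36), "CCTCCTCGTGG", rdna(50))
  hits <- findMotif(seq1, "CCUCCUCGUGG")
  expect_identical(hits$start, 37L)
  expect_identical(hits$end, 47L)
  expect_identical(nrow(findMotif("ACGTACGT", "TTT")), 0L)
  expect_error(findMotif("ACGT", ""), "non-empty")
  set.seed(66)
  for (i in 1:100) {
    s <- rdna(200)
    m <- rdna(sample(3:6, 1))
    expect_identical(findMotif(s, m), oracleFindMotif(s, m), info = m)
  }
})

test_that("target-gene matches are masked out of copy calls", {
  tr <- buildTargetReference(flankLen = 200, seed = 1)
  fam <- simulateElementFamily("R2B", target = tr, seed = 5, familyId = "seg",
                               utr3TargetSegment = list(length = 150,
                                                        identity = 0.85))
  b <- insertCopies(tr, fam, insertionSpec("seg"), nUnits = 4,
                    spacerLen = 1000, seed = 9)
  raw <- findCopies(b, fam)
  # the UTR segment also hits the downstream 28S of all four units
  expect_identical(length(raw), 5L)
  kept <- maskTargetMatches(raw, b, tr)
  expect_identical(length(kept), 1L)
  expect_identical(GenomicRanges::start(kept), truthTable(b)$start[1])
})
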