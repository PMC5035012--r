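REV_A <- revComp("TAGATGACGAGGCATTTGGC")  # upstream 28S block
REV_B <- revComp("ATCCATTCATGCGCGTCACT")  # downstream 28S block

test_that("target reference core is the primer-derived 28S convention", {
  tr <- buildTargetReference(flankLen = 0)
  expect_identical(as.character(targetSeq(tr)), paste0(REV_A, REV_B))
  expect_identical(canonicalSite(tr), 20L)
  # downstream block found exactly once, immediately after the site
  hits <- oracleFindMotif(as.character(targetSeq(tr)), REV_B)
  expect_identical(hits$start, 21L)
})

test_that("each primer block occurs exactly once, even with random flanks", {
  tr <- buildTargetReference(flankLen = 200, seed = 1)
  seqc <- as.character(targetSeq(tr))
  expect_identical(nchar(seqc), 440L)
  expect_identical(canonicalSite(tr), 220L)
  expect_equal(countBothStrands(seqc, REV_A), 1)
  expect_equal(countBothStrands(seqc, REV_B), 1)
})

test_that("simulated families carry their clade's zinc-finger complement", {
  profiles <- list(R2A = c("CCHH", "CCHH", "CCHC"), R2B = c("CCHH", "CCHC"),
                   R2C = c("CCHH", "CCHH"), R2D = c("CCHH"))
  for (clade in names(profiles)) {
    fam <- simulateElementFamily(clade, seed = 5)
    zf <- detectZincFingers(proteinSeq(fam))
    expect_identical(zf$kind, profiles[[clade]], info = clade)
    expect_identical(classifyClade(zf)$clade, clade)
  }
})

test_that("embedded features round-trip: ribozyme motif, primer sites, ORF", {
  fam <- simulateElementFamily("R2B", seed = 11, ribozymePos = 37)
  hits <- findMotif(consensusSeq(fam), "CCTCCTCGTGG")
  expect_identical(hits$start, 37L)
  expect_identical(hits$end, 47L)
  info <- familyInfo(fam)
  cons <- as.character(consensusSeq(fam))
  expect_true(iupacMatch("R2IF2", cons, info$primer_sites[["R2IF2"]]))
  expect_true(iupacMatch("R2IIF2", cons, info$primer_sites[["R2IIF2"]]))
  # single long ORF: no internal stop in the translation
  expect_false(grepl("*", as.character(proteinSeq(fam)), fixed = TRUE))
})

test_that("3' UTR target segment is embedded at the requested identity", {
  tr <- buildTargetReference(flankLen = 200, seed = 1)
  fam <- simulateElementFamily("R2A", target = tr, seed = 7,
                               utr3TargetSegment = list(length = 150,
                                                        identity = 0.85))
  info <- familyInfo(fam)$utr3_segment
  seg <- substr(as.character(consensusSeq(fam)), info$utr_start, info$utr_end)
  down <- substr(as.character(targetSeq(tr)), info$target_start,
                 info$target_end)
  obs <- mean(strsplit(seg, "")[[1]] == strsplit(down, "")[[1]])
  expect_true(abs(obs - 0.85) <= 0.05)
  # invalid identities are rejected
  expect_error(simulateElementFamily("R2A", target = tr,
                                     utr3TargetSegment = list(length = 150,
                                                              identity = 0.5)),
               "identity")
  expect_error(simulateElementFamily("R2A", target = tr,
                                     utr3TargetSegment = list(length = 150,
                                                              identity = 1.2)),
               "identity")
})

test_that("canonical insertion preserves the downstream 28S block", {
  tr <- buildTargetReference(flankLen = 200, seed = 1)
  fam <- simulateElementFamily("R2A", seed = 3, familyId = "fam1")
  b <- insertCopies(tr, fam, insertionSpec("fam1"), nUnits = 2,
                    spacerLen = 500, seed = 2)
  tt <- truthTable(b)
  g <- as.character(genomeSeq(b)[[1]])
  expect_identical(substr(g, tt$end[1] + 1, tt$end[1] + 20), REV_B)
  # and the 20 bases before the element are the upstream block
  expect_identical(substr(g, tt$start[1] - 20, tt$start[1] - 1), REV_A)
})

test_that("zero specs yield an array of exact target copies", {
  tr <- buildTargetReference(flankLen = 50, seed = 4)
  fam <- simulateElementFamily("R2D", seed = 3, familyId = "fam1")
  b <- insertCopies(tr, fam, NULL, nUnits = 3, spacerLen = 300, seed = 2)
  expect_identical(nrow(truthTable(b)), 0L)
  g <- as.character(genomeSeq(b)[[1]])
  hits <- oracleFindMotif(g, as.character(targetSeq(tr)))
  expect_identical(nrow(hits), 3L)
})

test_that("a 110 bp 5' offset deletes exactly that upstream target block", {
  tr <- buildTargetReference(flankLen = 200, seed = 1)
  fam <- simulateElementFamily("R2A", seed = 3, familyId = "fam1")
  b <- insertCopies(tr, fam, insertionSpec("fam1", offset5 = 110),
                    nUnits = 1, spacerLen = 400, seed = 2)
  g <- as.character(genomeSeq(b)[[1]])
  cs <- canonicalSite(tr)
  tgt <- as.character(targetSeq(tr))
  deleted <- substr(tgt, cs - 110 + 1, cs)       # the replaced 28S block
  kept <- substr(tgt, cs - 110 - 19, cs - 110)   # last 20 retained bases
  expect_identical(nrow(oracleFindMotif(g, deleted)), 0L)
  expect_identical(nrow(oracleFindMotif(g, kept)), 1L)
  expect_identical(truthTable(b)$offset5, 110L)
})

test_that("genome length obeys the conservation law", {
  tr <- buildTargetReference(flankLen = 200, seed = 1)
  famA <- simulateElementFamily("R2A", seed = 3, familyId = "famA")
  famB <- simulateElementFamily("R2B", seed = 4, familyId = "famB",
                                totalLen = 2600)
  specs <- rbind(insertionSpec("famA", offset5 = 110),
                 insertionSpec("famA", truncate5 = 700),
                 insertionSpec("famB", offset3 = 15),
                 insertionSpec("famB", nonspecific = TRUE))
  b <- insertCopies(tr, list(famA, famB), specs, nUnits = 5,
                    spacerLen = 777, seed = 6)
  lenTarget <- nchar(as.character(targetSeq(tr)))
  expected <- 5 * lenTarget + 6 * 777 +
    (3500 - 110) + (3500 - 700) + (2600 - 15) + 2600
  expect_equal(nchar(as.character(genomeSeq(b)[[1]])), expected)
})

test_that("identical (specs, seed) reproduce byte-identical outputs", {
  tr <- buildTargetReference(flankLen = 100, seed = 1)
  fam <- simulateElementFamily("R2C", seed = 3, familyId = "famC")
  specs <- rbind(insertionSpec("famC", divergence = 0.05),
                 insertionSpec("famC", nonspecific = TRUE, divergence = 0.1))
  b1 <- insertCopies(tr, fam, specs, nUnits = 3, spacerLen = 400, seed = 99)
  b2 <- insertCopies(tr, fam, specs, nUnits = 3, spacerLen = 400, seed = 99)
  d1 <- file.path(tempdir(), "bundle1"); d2 <- file.path(tempdir(), "bundle2")
  writeGenomeBundle(b1, d1); writeGenomeBundle(b2, d2)
  for (f in c("genome.fasta", "truth.tsv", "copies.gff3"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("truth intervals extract to copies near their source consensus", {
  tr <- buildTargetReference(flankLen = 200, seed = 1)
  fam <- simulateElementFamily("R2A", seed = 3, familyId = "famA")
  for (div in c(0, 0.05, 0.15)) {
    specs <- rbind(insertionSpec("famA", divergence = div),
                   insertionSpec("famA", truncate5 = 500, divergence = div,
                                 strand = "-"))
    b <- insertCopies(tr, fam, specs, nUnits = 2, spacerLen = 500,
                      seed = 7 + round(100 * div))
    g <- as.character(genomeSeq(b)[[1]])
    cons <- as.character(consensusSeq(fam))
    for (i in seq_len(nrow(truthTable(b)))) {
      row <- truthTable(b)[i, ]
      seg <- substr(g, row$start, row$end)
      if (row$strand == "-") seg <- revComp(seg)
      ref <- substr(cons, row$truncate5 + 1, nchar(cons))
      obs <- mean(strsplit(seg, "")[[1]] == strsplit(ref, "")[[1]])
      expect_true(obs >= 1 - div - 0.03,
                  info = sprintf("div=%.2f copy=%d identity=%.3f", div, i, obs))
    }
  }
})

test_that("invalid insertion requests are rejected", {
  tr <- buildTargetReference(flankLen = 10, seed = 1)
  fam <- simulateElementFamily("R2D", seed = 3, familyId = "famD")
  expect_error(insertCopies(tr, fam, rbind(insertionSpec("famD"),
                                           insertionSpec("famD")),
                            nUnits = 1, seed = 1), "more site-specific")
  expect_error(insertCopies(tr, fam, insertionSpec("famD", offset5 = 100),
                            nUnits = 1, seed = 1), "offset5")
  expect_error(insertionSpec("famD", nonspecific = TRUE, offset5 = 5),
               "nonspecific")
})
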