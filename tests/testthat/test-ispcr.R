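test_that("degeneracy is the product of per-position code sizes", {
  expect_identical(degeneracy("ACGT"), 1)
  # R2IF1 = AAGCARGGNGAYCCNCTNTC: R*N*Y*N*N = 2*4*2*4*4
  expect_identical(degeneracy("R2IF1"), 256)
  for (k in 1:6) {
    primer <- strrep("N", k)
    expect_identical(degeneracy(primer), 4^k)
    expect_identical(length(expandPrimerOracle(primer)), length(unique(
      expandPrimerOracle(primer))))
    expect_identical(degeneracy(primer), as.numeric(length(
      expandPrimerOracle(primer))))
  }
  expect_error(degeneracy("ACGJ"), "position 4")
  expect_error(degeneracy(""), "non-empty")
})

test_that("IUPAC matching semantics", {
  expect_true(iupacMatch("AR", "AG", 1))
  expect_false(iupacMatch("AR", "AC", 1))
  # template ambiguity codes only match by exact code identity
  expect_true(iupacMatch("AN", "AN", 1))
  expect_false(iupacMatch("AN", "AR", 1))
  expect_error(iupacMatch("ACGT", "ACG", 1), "out of range")
  expect_error(iupacMatch("AC", "ACGT", 4), "out of range")
})

test_that("IUPAC matching agrees with a set-expansion oracle", {
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D",
             "H", "V", "N")
  set.seed(33)
  for (i in 1:500) {
    m <- sample(2:6, 1)
    primer <- paste0(sample(codes, m, replace = TRUE), collapse = "")
    template <- rdna(m)
    want <- template %in% expandPrimerOracle(primer)
    expect_identical(iupacMatch(primer, template, 1), want,
                     info = paste(primer, template))
  }
})

test_that("a constructed template yields exactly one amplicon", {
  set.seed(12)
  fwd <- "GCATTACGGA"
  rev <- "TTGACCAGTA"
  tpl <- c(chr = paste0(rdna(50), fwd, strrep("A", 100), revComp(rev),
                        rdna(50)))
  amp <- virtualPCR(tpl, fwd, rev, maxLen = 500)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$length, nchar(fwd) + 100L + nchar(rev))
  expect_identical(amp$start, 51L)
  # PCR is orientation-symmetric: swapped primers give the same product
  # from the minus orientation
  swapped <- virtualPCR(tpl, rev, fwd, maxLen = 500)
  expect_identical(swapped$start, amp$start)
  expect_identical(swapped$end, amp$end)
  expect_identical(swapped$orientation, "-")
})

test_that("virtual PCR equals a brute-force scan over all position pairs", {
  bruteForce <- function(tpl, fwd, rev, maxLen) {
    n <- nchar(tpl)
    lf <- nchar(fwd); lr <- nchar(rev)
    hits <- list()
    scan <- function(primer) {
      lp <- nchar(primer)
      which(vapply(seq_len(n - lp + 1),
                   function(p) iupacMatch(primer, tpl, p), logical(1)))
    }
    addAll <- function(starts, ends, ori) {
      for (s in starts) for (e in ends) {
        len <- e - s + 1
        if (len > 0 && len <= maxLen)
          hits[[length(hits) + 1]] <<- c(s, e, ori)
      }
    }
    addAll(scan(fwd), scan(revComp(rev)) + lr - 1, "+")
    addAll(scan(rev), scan(revComp(fwd)) + lf - 1, "-")
    if (!length(hits)) return(NULL)
    m <- do.call(rbind, hits)
    m[order(as.integer(m[, 1]), as.integer(m[, 2])), , drop = FALSE]
  }
  codes <- c("A", "C", "G", "T", "R", "Y", "N")
  set.seed(44)
  for (i in 1:12) {
    fwd <- paste0(sample(codes, 7, replace = TRUE), collapse = "")
    rev <- paste0(sample(codes, 7, replace = TRUE), collapse = "")
    tpl <- rdna(1500)
    got <- virtualPCR(c(t1 = tpl), fwd, rev, maxLen = 800)
    want <- bruteForce(tpl, fwd, rev, 800)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(nrow(got), nrow(want))
      expect_identical(got$start, as.integer(want[, 1]))
      expect_identical(got$end, as.integer(want[, 2]))
      expect_identical(got$orientation, unname(want[, 3]))
    }
  }
})

test_that("strand symmetry: reverse-complemented template mirrors products", {
  set.seed(9)
  fwd <- "GCYTTRGC"
  rev <- "ATCCATTR"
  tpl <- paste0(rdna(300), "GCCTTGGC", rdna(100), revComp("ATCCATTA"),
                rdna(300))
  n <- nchar(tpl)
  a <- virtualPCR(c(x = tpl), fwd, rev, maxLen = 400)
  b <- virtualPCR(c(x = revComp(tpl)), fwd, rev, maxLen = 400)
  expect_identical(nrow(a), nrow(b))
  expect_setequal(n - a$end + 1L, b$start)
  expect_setequal(n - a$start + 1L, b$end)
})

test_that("RT-forward x 28S-reverse geometry on a synthetic insertion", {
  tr <- buildTargetReference(flankLen = 200, seed = 1)
  fam <- simulateElementFamily("R2A", seed = 11, familyId = "famA")
  b <- insertCopies(tr, fam, insertionSpec("famA"), nUnits = 3,
                    spacerLen = 1000, seed = 5)
  tt <- truthTable(b)
  info <- familyInfo(fam)
  # R2IF2 sits in the element's RT block; 28S_R-B binds immediately
  # downstream of the canonical site: exactly one product, spanning from
  # the primer site to 20 bp past the element end
  amp <- virtualPCR(b, "R2IF2", "28S_R-B", maxLen = 3000)
  expect_identical(nrow(amp), 1L)
  expect_equal(amp$start, tt$start[1] + info$primer_sites[["R2IF2"]] - 1)
  expect_identical(amp$end, tt$end[1] + 20L)
  # 28S_R-A's binding site lies upstream of the canonical site, on the
  # wrong side of the element; the next unit's site is out of reach
  ampA <- virtualPCR(b, "R2IF2", "28S_R-A", maxLen = 3000)
  expect_identical(nrow(ampA), 0L)
  # amplicon sequences extract to the called coordinates
  seqs <- ampliconSeqs(b, amp)
  expect_identical(width(seqs), amp$length)
})
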