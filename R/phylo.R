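## Distance phylogeny: p-distance, Saitou-Nei neighbor joining, column
## bootstrap. Deliberately model-free: the package's phylogenetic claims
## are about clade clustering of synthetic families, for which
## proportion-of-differences distances are sufficient.

MISSING_RESIDUES <- c("-", "X", "?", "*", ".")

.alnMatrix <- function(aln) {
  if (is(aln, "XStringSet")) aln <- setNames(as.character(aln), names(aln))
  if (is.matrix(aln)) return(aln)
  if (is.null(names(aln))) names(aln) <- paste0("taxon", seq_along(aln))
  if (length(unique(nchar(aln))) != 1L) stop("rows must have equal length")
  mat <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(mat) <- names(aln)
  mat
}

#' p-distance matrix from an alignment
#'
#' `d[i, j]` = mismatches / compared columns. Gap and ambiguity symbols
#' (`-`, `X`, `?`, `*`, `.`) are never compared: under
#' `deletion = "pairwise"` each pair uses its own comparable columns;
#' under `"complete"` any column with a missing symbol in any row is
#' dropped for all pairs.
#'
#' @param aln Equal-length rows: named character vector, `XStringSet` or
#'   character matrix.
#' @param deletion Missing-data rule.
#' @return Symmetric numeric matrix with zero diagonal, labelled by row
#'   names.
#' @export
pDistance <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  mat <- .alnMatrix(aln)
  n <- nrow(mat)
  stopifnot(n >= 2L)
  miss <- matrix(mat %in% MISSING_RESIDUES, nrow = n)
  if (deletion == "complete") {
    keep <- colSums(miss) == 0L
    mat <- mat[, keep, drop = FALSE]
    miss <- miss[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- !miss[i, ] & !miss[j, ]
      if (!any(comp))
        stop("no comparable columns between '", rownames(mat)[i], "' and '",
             rownames(mat)[j], "'")
      d[i, j] <- d[j, i] <- mean(mat[i, comp] != mat[j, comp])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration, deterministic for a given matrix:
#' ties in the Q criterion are broken by the lexicographically smallest
#' label pair (internal nodes are keyed by their smallest leaf label).
#' Negative branch lengths are clamped to zero and counted in the
#' `negative_edges` attribute.
#'
#' @param dm Symmetric distance matrix with dimnames (or a [stats::dist]).
#' @return An unrooted `phylo` (ape) tree.
#' @export
njTree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm), nrow(dm) >= 3L)
  if (!all(is.finite(dm))) stop("distances must be finite")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(dm)))
  d <- dm
  dimnames(d) <- NULL
  ## per active node: newick fragment, sort key (smallest leaf label)
  frag <- labels
  key <- labels
  nneg <- 0L
  fmt <- function(x) sprintf("%.10g", max(0, x))
  clamp <- function(x) { if (x < 0) nneg <<- nneg + 1L; max(0, x) }

  while (nrow(d) > 2L) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pairKey <- apply(cand, 1L, function(ij) {
      ks <- sort(c(key[ij[1L]], key[ij[2L]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(pairKey)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- clamp(d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    lj <- clamp(d[i, j] - li)
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    newKey <- min(key[i], key[j])
    dNew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dNew[keep]),
               c(dNew[keep], 0))
    frag <- c(frag[keep], newFrag)
    key <- c(key[keep], newKey)
  }
  ## join the last two nodes on a single edge
  a <- frag[1L]; b <- frag[2L]; dd <- clamp(d[1L, 2L])
  if (startsWith(a, "(")) {
    inner <- substr(a, 2L, nchar(a) - 1L)
    nwk <- sprintf("(%s,%s:%s);", inner, b, fmt(dd))
  } else if (startsWith(b, "(")) {
    inner <- substr(b, 2L, nchar(b) - 1L)
    nwk <- sprintf("(%s,%s:%s);", inner, a, fmt(dd))
  } else stop("need at least 3 taxa")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_edges") <- nneg
  tree
}

## canonical string key for the non-trivial bipartition induced by a
## clade's tip set (complemented so the alphabetically first tip is
## always excluded)
.bipartKey <- function(tips, allTips) {
  ref <- sort(allTips)[1L]
  side <- sort(tips)
  if (ref %in% side) side <- sort(setdiff(allTips, tips))
  paste(side, collapse = "\r")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' @param tree A `phylo` object.
#' @return Character vector of canonical bipartition keys, one per
#'   internal edge.
#' @export
treeBipartitions <- function(tree) {
  allTips <- tree$tip.label
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx) .bipartKey(allTips[idx], allTips),
                 character(1L))
  sizes <- lengths(pp)
  unique(keys[sizes >= 2L & sizes <= length(allTips) - 2L])
}

#' Is a set of tips a connected subtree (clade) of an unrooted tree?
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels.
#' @return Logical scalar.
#' @export
isCladeMonophyletic <- function(tree, tips) {
  n <- length(tree$tip.label)
  if (length(tips) <= 1L || length(tips) >= n - 1L) return(TRUE)
  .bipartKey(tips, tree$tip.label) %in% treeBipartitions(tree)
}

#' Neighbor-joining tree with column-bootstrap support
#'
#' Resamples alignment columns with replacement `nReps` times, rebuilds
#' the NJ tree for each replicate, and labels each internal edge of the
#' full-data tree with the percentage of replicates containing the same
#' bipartition (stored in `node.label` of the child node).
#'
#' @param aln Alignment (same forms as [pDistance()]).
#' @param nReps Number of replicates (>= 1).
#' @param seed Optional integer seed.
#' @param deletion Missing-data rule for [pDistance()].
#' @return The full-data `phylo` tree with bootstrap percentages as
#'   internal node labels.
#' @export
bootstrapSupport <- function(aln, nReps = 100L, seed = NULL,
                             deletion = "pairwise") {
  stopifnot(nReps >= 1L)
  mat <- .alnMatrix(aln)
  main <- njTree(pDistance(mat, deletion))
  keysMain <- treeBipartitions(main)
  counts <- setNames(numeric(length(keysMain)), keysMain)
  withSeed(seed, {
    for (b in seq_len(nReps)) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      rep_tree <- njTree(pDistance(mat[, cols, drop = FALSE], deletion))
      hit <- keysMain %in% treeBipartitions(rep_tree)
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- round(100 * counts / nReps)
  ## map supports onto internal nodes of the main tree
  allTips <- main$tip.label
  pp <- ape::prop.part(main)
  lab <- vapply(seq_along(pp), function(k) {
    sz <- length(pp[[k]])
    if (sz < 2L || sz > length(allTips) - 2L) return("")
    keyk <- .bipartKey(allTips[pp[[k]]], allTips)
    if (keyk %in% names(support)) as.character(support[[keyk]]) else ""
  }, character(1L))
  main$node.label <- lab
  main
}
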