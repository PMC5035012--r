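## Zinc-finger motif detection and R2 clade assignment.
##
## R2 clades are distinguished by the number and type of zinc fingers
## N-terminal (proximal) to the reverse transcriptase domain:
## R2A = CCHH + CCHH + CCHC, R2B = CCHH + CCHC, R2C = CCHH + CCHH,
## R2D = CCHH. The finger itself is matched by the spacing pattern
## C-x(2,4)-C-x(8,20)-H-x(3,5)-[H|C]; the identity of the fourth
## coordinating residue (H or C) determines the finger type.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y", "*")

#' Detect CCHH/CCHC zinc fingers in a protein
#'
#' Scans the region N-terminal to the RT domain for the spacing pattern
#' `C-x(2,4)-C-x(8,20)-H-x(3,5)-[H|C]`. Matching is leftmost-first with
#' minimal extents, resuming after each match, so reported fingers never
#' overlap and the count is deterministic. Spacing bounds admit the
#' classical Cys2His2 geometry and are configurable.
#'
#' @param protein Amino-acid string (or [Biostrings::AAString]).
#' @param regionEnd Optional 1-based position marking the start of the RT
#'   domain; only residues before it are scanned. Default: the N-terminal
#'   40% of the protein (fingers sit upstream of the RT domain).
#' @param spacing Integer vector
#'   `c(x1min, x1max, x2min, x2max, x3min, x3max)` of spacer bounds.
#' @return `data.frame` with columns `kind` (`"CCHH"`/`"CCHC"`), `start`
#'   and `end` (1-based inclusive positions of the first and last
#'   coordinating residue).
#' @export
#' @examples
#' detectZincFingers("AAACAACAAAAAAAAAAHAAAHAAA", regionEnd = 26)
detectZincFingers <- function(protein, regionEnd = NULL,
                              spacing = c(2L, 4L, 8L, 20L, 3L, 5L)) {
  protein <- toupper(as.character(protein))
  if (nchar(protein) == 0L) stop("protein must be non-empty")
  chars <- s2c(protein)
  bad <- which(!chars %in% AA_LETTERS)
  if (length(bad) > 0L)
    stop("non-amino-acid character '", chars[bad[1L]], "' at position ",
         bad[1L])
  if (is.null(regionEnd)) regionEnd <- max(1L, floor(0.4 * nchar(protein)))
  region <- substr(protein, 1L, regionEnd)
  pat <- sprintf("C.{%d,%d}?C.{%d,%d}?H.{%d,%d}?[HC]",
                 spacing[1L], spacing[2L], spacing[3L], spacing[4L],
                 spacing[5L], spacing[6L])
  m <- gregexpr(pat, region, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(kind = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  ends <- starts + lens - 1L
  kind <- ifelse(substring(region, ends, ends) == "H", "CCHH", "CCHC")
  data.frame(kind = kind, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' Assign an R2 clade from a zinc-finger complement
#'
#' Pure function of the multiset of finger kinds:
#' (2 CCHH, 1 CCHC) = R2A; (1, 1) = R2B; (2, 0) = R2C; (1, 0) = R2D;
#' any other combination = `"unknown"` (a valid outcome, never an error).
#'
#' @param fingers A `data.frame` from [detectZincFingers()], or a
#'   character vector of finger kinds.
#' @return List with `clade`, `n_cchh`, `n_cchc` and the `evidence` table.
#' @export
#' @examples
#' classifyClade(c("CCHH", "CCHC", "CCHH"))$clade  # "R2A"
classifyClade <- function(fingers) {
  kinds <- if (is.data.frame(fingers)) fingers$kind else as.character(fingers)
  n_cchh <- sum(kinds == "CCHH")
  n_cchc <- sum(kinds == "CCHC")
  key <- paste(n_cchh, n_cchc)
  clade <- switch(key, "2 1" = "R2A", "1 1" = "R2B", "2 0" = "R2C",
                  "1 0" = "R2D", "unknown")
  list(clade = clade, n_cchh = n_cchh, n_cchc = n_cchc,
       evidence = if (is.data.frame(fingers)) fingers else
         data.frame(kind = kinds, start = rep(NA_integer_, length(kinds)),
                    end = rep(NA_integer_, length(kinds)),
                    stringsAsFactors = FALSE))
}

#' Batch zinc-finger scan over a protein set
#'
#' @param proteins Named character vector, [Biostrings::AAStringSet], or a
#'   path to a protein FASTA file.
#' @param ... Passed to [detectZincFingers()].
#' @return `data.frame` with one row per protein: `id`, `clade`,
#'   `n_cchh`, `n_cchc`, and `fingers` (1-based `kind:start-end` spans,
#'   comma-separated).
#' @export
scanProteins <- function(proteins, ...) {
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins))
    proteins <- Biostrings::readAAStringSet(proteins)
  if (is(proteins, "XStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  if (is.null(names(proteins)))
    names(proteins) <- paste0("protein", seq_along(proteins))
  rows <- lapply(names(proteins), function(id) {
    zf <- detectZincFingers(proteins[[id]], ...)
    cc <- classifyClade(zf)
    data.frame(id = id, clade = cc$clade, n_cchh = cc$n_cchh,
               n_cchc = cc$n_cchc,
               fingers = paste(sprintf("%s:%d-%d", zf$kind, zf$start, zf$end),
                               collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
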