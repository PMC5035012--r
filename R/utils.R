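#' @useDynLib rDNAretro, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats runif rgeom setNames
#' @importFrom utils write.table
NULL

DNA_BASES_PLAIN <- c("A", "C", "G", "T")

s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
c2s <- function(x) paste0(x, collapse = "")

#' Reverse complement of a plain nucleotide string
#'
#' Thin wrapper around [chartr()] handling IUPAC ambiguity codes; kept as a
#' plain-string utility so the simulator and scanners avoid repeated
#' XString coercions on short fragments.
#'
#' @param x A single nucleotide string (IUPAC codes allowed).
#' @return The reverse complement as a character scalar.
#' @export
#' @examples
#' revComp("ATCCATTCATGCGCGTCACT")
revComp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTRYSWKMBDHVNacgt", "TGCAYRSWMKVHDBNtgca", x)
  c2s(rev(s2c(comp)))
}

## Evaluate `code` under a temporary RNG state seeded with `seed`
## (NULL = use the current stream). Restores the caller's stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic per-stage substream seed (kept below 2^31).
deriveSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% 2147483629)
}

randDNA <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  c2s(sample(DNA_BASES_PLAIN, n, replace = TRUE, prob = p))
}

## Per-base substitution at rate `rate`; substituted bases always change.
## Returns chars with attribute "positions" (1-based substituted sites).
.mutateChars <- function(chars, rate, alphabet = DNA_BASES_PLAIN) {
  n <- length(chars)
  hit <- which(runif(n) < rate)
  for (i in hit) chars[i] <- sample(setdiff(alphabet, chars[i]), 1L)
  attr(chars, "positions") <- hit
  chars
}

## Mutate to an (approximately exact) target identity: round((1-id)*n)
## distinct positions are substituted, each to a different base.
.mutateToIdentity <- function(x, identity, alphabet = DNA_BASES_PLAIN) {
  chars <- s2c(x)
  k <- round((1 - identity) * length(chars))
  if (k > 0L) {
    pos <- sample.int(length(chars), k)
    for (i in pos) chars[i] <- sample(setdiff(alphabet, chars[i]), 1L)
  }
  c2s(chars)
}

#' Mutate a sequence under the simulator's decay model
#'
#' Applies independent per-base substitutions at rate `divergence`; when
#' `indels = TRUE`, insertions/deletions occur at one tenth of the
#' substitution rate with geometric lengths (mean 2), emulating the decay
#' of old element copies.
#'
#' @param x Nucleotide (or protein, with `alphabet`) string.
#' @param divergence Per-base substitution probability in `[0, 0.5)`.
#' @param indels Logical; also apply indels at `divergence / 10`.
#' @param seed Optional integer seed (`NULL` = current RNG stream).
#' @param alphabet Residue alphabet used for substitutions.
#' @return The mutated string.
#' @export
mutateSequence <- function(x, divergence, indels = FALSE, seed = NULL,
                           alphabet = DNA_BASES_PLAIN) {
  stopifnot(divergence >= 0, divergence < 0.5)
  withSeed(seed, {
    chars <- .mutateChars(s2c(x), divergence, alphabet)
    attr(chars, "positions") <- NULL
    if (indels && divergence > 0) {
      rate <- divergence / 10
      n <- length(chars)
      ev <- which(runif(n) < rate)
      if (length(ev) > 0L) {
        out <- vector("list", n)
        del_until <- 0L
        for (i in seq_len(n)) {
          if (i %in% ev) {
            len <- rgeom(1L, 1 / 2) + 1L
            if (runif(1L) < 0.5) { # insertion before base i
              out[[i]] <- c(sample(alphabet, len, replace = TRUE), chars[i])
            } else {             # deletion starting at base i
              del_until <- max(del_until, i + len - 1L)
              out[[i]] <- character(0)
            }
          } else if (i <= del_until) {
            out[[i]] <- character(0)
          } else {
            out[[i]] <- chars[i]
          }
        }
        chars <- unlist(out)
      }
    }
    c2s(chars)
  })
}

## Protein alphabet without C and H (so random filler can never seed a
## spurious zinc finger).
AA_FILLER <- c("A", "D", "E", "F", "G", "I", "K", "L", "M", "N", "P", "Q",
               "R", "S", "T", "V", "W", "Y")

#' Mutate a protein sequence at a fixed per-residue rate
#'
#' @inheritParams mutateSequence
#' @param x Amino-acid string.
#' @export
mutateProtein <- function(x, divergence, seed = NULL) {
  mutateSequence(x, divergence, indels = FALSE, seed = seed,
                 alphabet = c(AA_FILLER, "C", "H"))
}
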