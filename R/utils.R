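## Shared low-level helpers: rounding conventions, sequence/character utilities
## and the seeded diagonal matcher used by repeat masking, specificity
## screening and genome hit counting.

#' Percentage with half-away-from-zero rounding
#'
#' Computes `100 * numerator / denominator` and rounds half away from zero to
#' the requested number of decimals. This is the rounding convention used by
#' every percentage in the package's reports (e.g. 22.03 prints as 22 and
#' 92.506 as 93), matching how capture studies conventionally print
#' percentages, rather than R's banker's rounding.
#'
#' @param numerator,denominator Non-negative counts; `denominator` must be > 0.
#' @param digits Number of decimal places (default 0).
#' @return A numeric percentage.
#' @examples
#' percentRounded(200, 908)      # 22
#' percentRounded(1617, 1748)    # 93
#' @export
percentRounded <- function(numerator, denominator, digits = 0) {
  if (any(denominator == 0)) {
    stop("percentRounded: denominator must be non-zero")
  }
  roundHalfAway(100 * numerator / denominator, digits)
}

#' Round half away from zero
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfAway <- function(x, digits = 0) {
  f <- 10^digits
  # nudge by a relative epsilon so values like 0.5 stored as 0.49999999998
  # after division still round up
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Position relative to the ATG start codon
#'
#' Converts genomic positions into the ATG-relative offsets used in promoter
#' reports, where the base immediately upstream of the A of ATG is -1. On the
#' minus strand "upstream" means genomically downstream of the ATG.
#'
#' @param pos 1-based genomic positions.
#' @param atg_pos 1-based genomic coordinate of the A of ATG.
#' @param strand `"+"` or `"-"`.
#' @return Integer offsets (negative upstream of the ATG, 0 at the A itself).
#' @examples
#' atgOffset(9858, 10001, "+")  # -143
#' @export
atgOffset <- function(pos, atg_pos, strand = "+") {
  strand <- rep(as.character(strand), length.out = length(pos))
  ifelse(strand == "-", as.integer(atg_pos) - as.integer(pos),
         as.integer(pos) - as.integer(atg_pos))
}

## ---- internal character-sequence helpers -----------------------------------

.charVec <- function(x) {
  strsplit(as.character(x), "", fixed = TRUE)[[1]]
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
           a = "t", c = "g", g = "c", t = "a", n = "n")

.revcomp <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

.compChar <- function(chars) {
  out <- .COMP[chars]
  out[is.na(out)] <- "N"
  unname(out)
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Mutate a character vector of DNA at a per-base substitution rate; returns
## the mutated vector. Substitutions always change the base.
.mutateChars <- function(chars, rate) {
  n <- length(chars)
  hit <- which(runif(n) < rate)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], .substituteBase, character(1))
  }
  chars
}

.substituteBase <- function(b) {
  sample(setdiff(c("A", "C", "G", "T"), b), 1)
}

## ---- seeded diagonal matcher -----------------------------------------------

## Find candidate gapless placements of `pattern` (character scalar) against a
## set of chromosomes (list of character vectors) by exact seed matching:
## every seed_len-mer of the pattern taken every seed_step bases is looked up
## exactly; each hit defines an alignment diagonal (placement of the whole
## pattern). Returns a data.frame(chrom, strand, start) of distinct placements
## (1-based start of the pattern on the + strand of the chromosome; for
## strand "-" the reverse complement of the pattern is placed there).
.diagonalPlacements <- function(pattern, chromChars, seed_len = 16,
                                seed_step = 8) {
  plen <- nchar(pattern)
  if (plen < seed_len) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0)))
  }
  offs <- unique(c(seq(1L, plen - seed_len + 1L, by = seed_step),
                   plen - seed_len + 1L))
  seeds <- substring(pattern, offs, offs + seed_len - 1L)
  keep <- !grepl("[^ACGT]", seeds)
  offs <- offs[keep]; seeds <- seeds[keep]
  if (!length(seeds)) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0)))
  }
  pd <- PDict(DNAStringSet(seeds))
  ## minus strand: place revcomp(pattern); seed k of pattern corresponds to
  ## revcomp(seed) at mirrored offset within revcomp(pattern)
  pdR <- PDict(reverseComplement(DNAStringSet(seeds)))
  res <- list()
  for (cn in names(chromChars)) {
    subj <- DNAString(paste(chromChars[[cn]], collapse = ""))
    hitsF <- matchPDict(pd, subj)
    starts <- unlist(startIndex(hitsF), use.names = FALSE)
    widths <- rep.int(offs, lengths(startIndex(hitsF)))
    if (length(starts)) {
      diagF <- starts - widths + 1L
      res[[length(res) + 1L]] <- data.frame(
        chrom = cn, strand = "+", start = unique(diagF))
    }
    hitsR <- matchPDict(pdR, subj)
    startsR <- unlist(startIndex(hitsR), use.names = FALSE)
    offsR <- rep.int(offs, lengths(startIndex(hitsR)))
    if (length(startsR)) {
      ## seed occupies pattern[off .. off+seed_len-1]; in revcomp placement of
      ## full pattern starting at S, that seed sits at
      ## S + (plen - (off + seed_len - 1)) .. hence:
      diagR <- startsR - (plen - (offsR + seed_len - 1L))
      res[[length(res) + 1L]] <- data.frame(
        chrom = cn, strand = "-", start = unique(diagR))
    }
  }
  if (!length(res)) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0)))
  }
  out <- do.call(rbind, res)
  unique(out)
}

## Mismatch vector of a gapless placement: pattern (character scalar) placed at
## `start` on chromosome character vector `cc` ("+" places pattern itself,
## "-" places its reverse complement). Positions outside the chromosome are
## clipped; returns list(mism = logical vector, from = first pattern index
## aligned). mism[i] refers to pattern position from + i - 1.
.placementMismatch <- function(pattern, cc, start, strand) {
  plen <- nchar(pattern)
  pchars <- .charVec(if (strand == "-") .revcomp(pattern) else pattern)
  lo <- max(1L, start)
  hi <- min(length(cc), start + plen - 1L)
  if (hi < lo) return(NULL)
  idx <- lo:hi
  pidx <- idx - start + 1L
  list(mism = pchars[pidx] != cc[idx], from = pidx[1L])
}

## Sliding-window minimum mismatch count: does any window of length w have
## at most maxmm mismatches? Returns logical positions (window starts) that
## qualify, or integer(0).
.qualifyingWindows <- function(mism, w, maxmm) {
  n <- length(mism)
  if (n < w) return(integer(0))
  cs <- c(0L, cumsum(as.integer(mism)))
  starts <- seq_len(n - w + 1L)
  counts <- cs[starts + w] - cs[starts]
  starts[counts <= maxmm]
}
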