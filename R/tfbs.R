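## Transcription factor binding site scanning: exact IUPAC consensus
## matching, species deduplication, gain/loss across SNP alleles in an
## 11 bp window, and motif content of deletion spans.

#' Load an IUPAC consensus motif library
#'
#' Reads a TSV with columns `name`, `species`, `consensus`. Rows with
#' identical (name, consensus) are collapsed into one motif whose `species`
#' field joins all source species with `;`. An invalid IUPAC character is an
#' error naming the offending row.
#'
#' @param path Path to the motif TSV.
#' @return A [MotifLibrary-class].
#' @export
loadMotifs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "species", "consensus")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("motif TSV missing columns: ", paste(miss, collapse = ", "))
  }
  df$consensus <- toupper(df$consensus)
  bad <- which(grepl("[^ACGTRYSWKMBDHVN]", df$consensus) |
                 nchar(df$consensus) == 0)
  if (length(bad)) {
    stop("invalid IUPAC consensus in motif row(s): ",
         paste(bad, collapse = ", "))
  }
  key <- paste(df$name, df$consensus, sep = "\r")
  sp <- vapply(split(df$species, key), function(s)
    paste(unique(s), collapse = ";"), character(1))
  first <- !duplicated(key)
  out <- df[first, c("name", "consensus"), drop = FALSE]
  out$species <- unname(sp[paste(out$name, out$consensus, sep = "\r")])
  new("MotifLibrary",
      motifs = data.frame(name = out$name, species = out$species,
                          consensus = out$consensus,
                          stringsAsFactors = FALSE))
}

.IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

#' Scan a sequence for exact (100% match) motif occurrences
#'
#' Every position and strand where a consensus matches exactly under IUPAC
#' expansion is reported; `N` in the scanned sequence never matches.
#' Species-duplicate hits (same motif name over the same matched interval)
#' are collapsed to one.
#'
#' @param seq Character scalar over A/C/G/T/N.
#' @param library A [MotifLibrary-class].
#' @param both_strands Scan the reverse complement of each motif as well
#'   (default TRUE).
#' @return A data.frame of hits: `name`, `species`, `start`, `end` (1-based
#'   on `seq`), `strand`, `match` (the matched substring of `seq`).
#' @export
## Positions (1-based) where an IUPAC consensus matches exactly; bases in
## the scanned sequence outside A/C/G/T (notably N) never match.
.iupacMatchPositions <- function(seqChars, consensus) {
  w <- nchar(consensus)
  n <- length(seqChars)
  if (w > n) return(integer(0))
  sets <- .IUPAC_SETS[.charVec(consensus)]
  cand <- which(seqChars[seq_len(n - w + 1L)] %in% sets[[1]])
  for (j in seq_len(w)[-1]) {
    if (!length(cand)) break
    cand <- cand[seqChars[cand + j - 1L] %in% sets[[j]]]
  }
  cand
}

scanMotifs <- function(seq, library, both_strands = TRUE) {
  mt <- motifTable(library)
  empty <- data.frame(name = character(0), species = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), match = character(0))
  if (!nrow(mt) || nchar(seq) == 0) return(empty)
  seqChars <- .charVec(toupper(seq))
  rows <- list()
  for (i in seq_len(nrow(mt))) {
    w <- nchar(mt$consensus[i])
    pats <- list(`+` = mt$consensus[i])
    if (both_strands) pats[["-"]] <- .revcomp(mt$consensus[i])
    for (strand in names(pats)) {
      pos <- .iupacMatchPositions(seqChars, pats[[strand]])
      if (!length(pos)) next
      rows[[length(rows) + 1L]] <- data.frame(
        name = mt$name[i], species = mt$species[i],
        start = pos, end = pos + w - 1L,
        strand = strand,
        match = substring(paste(seqChars, collapse = ""), pos,
                          pos + w - 1L))
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$name, out$strand), , drop = FALSE]
  dup <- duplicated(out[, c("name", "start", "end")])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' TFBS gain/loss across a SNP in an 11 bp window
#'
#' Extracts the window of `flank` bases either side of the SNP (truncated at
#' the sequence boundaries rather than shifted), scans the wild-type and
#' mutant windows, and reports motifs gained and lost. Motif identity for
#' the set difference is (name, matched substring): a motif counts as lost
#' when no interval of the mutant window matches it with the same matched
#' sequence content.
#'
#' @param ref_seq Character scalar: reference sequence containing the SNP.
#' @param snp_pos 1-based SNP position within `ref_seq`.
#' @param alt Alternative base.
#' @param library A [MotifLibrary-class].
#' @param flank Bases either side of the SNP (default 5, i.e. an 11 bp
#'   fragment).
#' @param both_strands Passed to [scanMotifs()].
#' @return A list with `wt_hits`, `alt_hits` (deduped hit tables of the two
#'   windows), `gained`, `lost` (motif name vectors) and `window`
#'   (the genomic interval scanned, 1-based on `ref_seq`).
#' @export
snpWindowDelta <- function(ref_seq, snp_pos, alt, library, flank = 5,
                           both_strands = TRUE) {
  n <- nchar(ref_seq)
  if (snp_pos < 1 || snp_pos > n) stop("snp_pos outside sequence")
  lo <- max(1L, snp_pos - flank)
  hi <- min(n, snp_pos + flank)
  wt <- substring(ref_seq, lo, hi)
  altChars <- .charVec(wt)
  altChars[snp_pos - lo + 1L] <- alt
  mut <- paste(altChars, collapse = "")
  wtHits <- scanMotifs(wt, library, both_strands)
  altHits <- scanMotifs(mut, library, both_strands)
  keyW <- paste(wtHits$name, wtHits$match, sep = "\r")
  keyA <- paste(altHits$name, altHits$match, sep = "\r")
  list(wt_hits = wtHits, alt_hits = altHits,
       gained = unique(altHits$name[!(keyA %in% keyW)]),
       lost = unique(wtHits$name[!(keyW %in% keyA)]),
       window = c(lo, hi))
}

#' Motif content of a deletion span
#'
#' Counts deduplicated exact motif occurrences within a deleted reference
#' sequence; zero is a perfectly valid outcome (a third of observed small
#' deletions contain no recognized site at all).
#'
#' @param deletion_seq Character scalar: the deleted reference sequence.
#' @param library A [MotifLibrary-class].
#' @param both_strands Passed to [scanMotifs()].
#' @return A list with `count` and `hits`.
#' @export
deletionTfbsContent <- function(deletion_seq, library, both_strands = TRUE) {
  if (nchar(deletion_seq) == 0) {
    return(list(count = 0L,
                hits = scanMotifs("", library, both_strands)))
  }
  hits <- scanMotifs(deletion_seq, library, both_strands)
  list(count = nrow(hits), hits = hits)
}
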