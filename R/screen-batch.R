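## Batched seeded specificity screen: one PDict over all probe seeds, one
## matchPDict pass per chromosome and strand, then gapless verification of
## every candidate diagonal.

.batchedScreen <- function(seqs, genome, seed_len, min_identity,
                           min_aln_len, seed_step = 8) {
  nP <- length(seqs)
  plen <- nchar(seqs)
  maxmm <- floor((1 - min_identity) * min_aln_len)
  offsList <- lapply(plen, function(L) {
    if (L < seed_len) return(integer(0))
    unique(c(seq(1L, L - seed_len + 1L, by = seed_step),
             L - seed_len + 1L))
  })
  seedProbe <- rep(seq_len(nP), lengths(offsList))
  seedOff <- unlist(offsList, use.names = FALSE)
  seeds <- substring(seqs[seedProbe], seedOff, seedOff + seed_len - 1L)
  ok <- !grepl("[^ACGT]", seeds)
  seedProbe <- seedProbe[ok]; seedOff <- seedOff[ok]; seeds <- seeds[ok]
  counts <- integer(nP)
  if (!length(seeds)) return(counts)
  pd <- PDict(DNAStringSet(seeds))
  pdR <- PDict(reverseComplement(DNAStringSet(seeds)))
  chromChars <- lapply(as.character(genome), .charVec)
  pchars <- strsplit(seqs, "", fixed = TRUE)
  rchars <- lapply(seqs, function(s) .charVec(.revcomp(s)))
  for (cn in names(chromChars)) {
    cc <- chromChars[[cn]]
    subj <- DNAString(paste(cc, collapse = ""))
    for (strand in c("+", "-")) {
      hits <- matchPDict(if (strand == "+") pd else pdR, subj)
      si <- startIndex(hits)
      ns <- lengths(si)
      if (!sum(ns)) next
      starts <- unlist(si, use.names = FALSE)
      rows <- rep.int(seq_along(seeds), ns)
      pIdx <- seedProbe[rows]; off <- seedOff[rows]
      dg <- if (strand == "+") starts - off + 1L else
        starts - (plen[pIdx] - (off + seed_len - 1L))
      cand <- unique(cbind(pIdx, dg))
      for (r in seq_len(nrow(cand))) {
        p <- cand[r, 1]; d <- cand[r, 2]
        pc <- if (strand == "+") pchars[[p]] else rchars[[p]]
        lo <- max(1L, d); hi <- min(length(cc), d + plen[p] - 1L)
        if (hi - lo + 1L < min_aln_len) next
        mism <- pc[(lo:hi) - d + 1L] != cc[lo:hi]
        if (length(.qualifyingWindows(mism, min_aln_len, maxmm))) {
          counts[p] <- counts[p] + 1L
        }
      }
    }
  }
  counts
}
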