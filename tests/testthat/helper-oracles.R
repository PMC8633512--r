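# Independent brute-force oracles. These deliberately share no code with the
# package implementations: naive loops, their own IUPAC table, no seeding or
# windowed shortcuts.

ORACLE_IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

oracleComp <- c(A = "T", C = "G", G = "C", T = "A",
                R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                B = "V", V = "B", D = "H", H = "D", N = "N")

oracleRevcomp <- function(x) {
  paste(rev(oracleComp[strsplit(x, "")[[1]]]), collapse = "")
}

# every (motif, position, strand) where the consensus matches 100%
oracleScan <- function(seq, motifs, both_strands = TRUE) {
  sc <- strsplit(toupper(seq), "")[[1]]
  hits <- list()
  for (r in seq_len(nrow(motifs))) {
    for (strand in if (both_strands) c("+", "-") else "+") {
      cons <- if (strand == "+") motifs$consensus[r] else
        oracleRevcomp(motifs$consensus[r])
      mc <- strsplit(cons, "")[[1]]
      w <- length(mc)
      if (w > length(sc)) next
      for (p in 1:(length(sc) - w + 1)) {
        ok <- TRUE
        for (j in 1:w) {
          if (!(sc[p + j - 1] %in% ORACLE_IUPAC[[mc[j]]])) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          hits[[length(hits) + 1]] <- data.frame(
            name = motifs$name[r], start = p, end = p + w - 1,
            strand = strand)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  out <- unique(do.call(rbind, hits))
  # same species-dedup convention as the scanner: one hit per
  # (name, interval)
  out <- out[order(out$start, out$name, out$strand), ]
  out[!duplicated(out[, c("name", "start", "end")]), ]
}

# exhaustive hairpin search: all (arm1 start, arm2 start, stem) triples
oracleHairpin <- function(seq, min_stem = 20, max_loop = 200,
                          min_identity = 0.8, min_loop = 3) {
  sc <- strsplit(toupper(seq), "")[[1]]
  n <- length(sc)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- NULL
  for (i in 1:n) {
    for (j in 1:n) {
      maxs <- min(n - j + 1, j - i - min_loop)
      if (maxs < min_stem) next
      for (s in min_stem:maxs) {
        loop <- j - (i + s)
        if (loop < min_loop || loop > max_loop) next
        if (i + s - 1 > n || j + s - 1 > n) next
        matches <- 0
        for (t in 0:(s - 1)) {
          a <- sc[i + t]
          b <- sc[j + s - 1 - t]
          if (!is.na(comp[a]) && comp[a] == b) matches <- matches + 1
        }
        if (matches / s < min_identity) next
        score <- 2 * matches - s
        if (is.null(best) || score > best$score ||
            (score == best$score && i < best$arm1[1]) ||
            (score == best$score && i == best$arm1[1] && s > best$stem_len)) {
          best <- list(stem_len = s, loop_len = loop,
                       identity = matches / s, score = score,
                       arm1 = c(i, i + s - 1), arm2 = c(j, j + s - 1))
        }
      }
    }
  }
  best
}

# naive cliff-edge deletion scan over a depth vector
oracleCliff <- function(d, flank_depth = 10, floor_depth = 0,
                        min_len = 21, max_edge = 5) {
  n <- length(d)
  out <- list()
  i <- 1
  while (i <= n) {
    if (d[i] <= floor_depth) {
      j <- i
      while (j < n && d[j + 1] <= floor_depth) j <- j + 1
      size <- j - i + 1
      if (size >= min_len && i > 1 && j < n) {
        leftOk <- any(d[max(1, i - max_edge):(i - 1)] >= flank_depth)
        rightOk <- any(d[(j + 1):min(n, j + max_edge)] >= flank_depth)
        if (leftOk && rightOk) {
          out[[length(out) + 1]] <- c(start = i, end = j, size = size)
        }
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      size = integer(0)))
  }
  as.data.frame(do.call(rbind, out))
}

# exhaustive probe placement scan: every position, both strands; a site
# counts when some window of min_aln_len has at most the allowed mismatches
oracleHybSites <- function(probe, chromSeqs, min_identity = 0.9,
                           min_aln_len = 80) {
  pc <- strsplit(probe, "")[[1]]
  rc <- strsplit(oracleRevcomp(probe), "")[[1]]
  plen <- length(pc)
  maxmm <- floor((1 - min_identity) * min_aln_len)
  count <- 0
  for (cs in chromSeqs) {
    cc <- strsplit(cs, "")[[1]]
    L <- length(cc)
    if (L < plen) next
    for (chars in list(pc, rc)) {
      for (p in 1:(L - plen + 1)) {
        mism <- chars != cc[p:(p + plen - 1)]
        found <- FALSE
        for (w0 in 1:(plen - min_aln_len + 1)) {
          if (sum(mism[w0:(w0 + min_aln_len - 1)]) <= maxmm) {
            found <- TRUE
            break
          }
        }
        if (found) count <- count + 1
      }
    }
  }
  count
}

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
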