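## Structural variants from depth space: cliff-edge coverage-gap deletions,
## small-InDel catalogues, repeat-library annotation with nested/chimeric
## decomposition, and MITE-style hairpin prediction.

#' Detect cliff-edge deletions in a depth profile
#'
#' Finds maximal runs of depth at or below `floor_depth` of length at least
#' `min_len` that are flanked on both sides by depth at least `flank_depth`
#' reached within `max_edge` bases (the "cliff edge"). Runs touching the
#' window boundaries cannot be sized and are reported separately as
#' truncated (promoter-absent candidates, not deletions).
#'
#' @param depths Integer per-base depth vector over a profile window.
#' @param flank_depth Depth the flanks must reach (default 10).
#' @param floor_depth Maximum depth inside the gap (default 0).
#' @param min_len Minimum gap length (default 21; smaller events are VCF
#'   InDel territory).
#' @param max_edge Maximum bases over which depth may fall from flank to
#'   floor (default 5).
#' @return A list with `deletions` (data.frame `start`, `end`, `size`,
#'   `left_edge`, `right_edge`, `class` in `large` (>100 bp) / `mid`
#'   (21-100 bp), window-local 1-based closed coordinates) and `truncated`
#'   (runs touching the window edges: `start`, `end`, `size`).
#' @export
detectCliffDeletions <- function(depths, flank_depth = 10, floor_depth = 0,
                                 min_len = 21, max_edge = 5) {
  d <- as.integer(depths)
  n <- length(d)
  low <- d <= floor_depth
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs$size <- runs$end - runs$start + 1L
  runs <- runs[runs$size >= min_len, , drop = FALSE]
  touch <- runs$start == 1L | runs$end == n
  truncated <- runs[touch, , drop = FALSE]
  runs <- runs[!touch, , drop = FALSE]
  if (nrow(runs)) {
    edgeLeft <- vapply(seq_len(nrow(runs)), function(i) {
      lo <- max(1L, runs$start[i] - max_edge)
      pos <- which(d[lo:(runs$start[i] - 1L)] >= flank_depth)
      if (!length(pos)) return(NA_real_)
      runs$start[i] - (lo + max(pos) - 1L)  # bp from last flank base to gap
    }, numeric(1))
    edgeRight <- vapply(seq_len(nrow(runs)), function(i) {
      hi <- min(n, runs$end[i] + max_edge)
      pos <- which(d[(runs$end[i] + 1L):hi] >= flank_depth)
      if (!length(pos)) return(NA_real_)
      min(pos)
    }, numeric(1))
    ok <- !is.na(edgeLeft) & !is.na(edgeRight)
    runs$left_edge <- edgeLeft
    runs$right_edge <- edgeRight
    runs <- runs[ok, , drop = FALSE]
    runs$class <- ifelse(runs$size > 100, "large", "mid")
  } else {
    runs$left_edge <- integer(0)
    runs$right_edge <- integer(0)
    runs$class <- character(0)
  }
  list(deletions = runs, truncated = truncated[, c("start", "end", "size")])
}

#' Catalogue homozygous SNPs and small InDels
#'
#' @param variants A homozygous-filtered variant table carrying
#'   `accession_id` and optionally `gene_id` columns.
#' @return A list with `per_accession` (`accession_id`, `n_snps`,
#'   `n_indels`) and, when `gene_id` is present, `per_gene` (`accession_id`,
#'   `gene_id`, `n_snps`, `n_indels`).
#' @export
catalogueSmallIndels <- function(variants) {
  if (!nrow(variants)) {
    out <- list(per_accession = data.frame(accession_id = character(0),
                                           n_snps = integer(0),
                                           n_indels = integer(0)))
    if ("gene_id" %in% colnames(variants)) {
      out$per_gene <- data.frame(accession_id = character(0),
                                 gene_id = character(0),
                                 n_snps = integer(0), n_indels = integer(0))
    }
    return(out)
  }
  cnt <- function(df) data.frame(
    n_snps = sum(df$vtype == "SNP"),
    n_indels = sum(df$vtype == "InDel"))
  perAcc <- do.call(rbind, lapply(
    split(variants, variants$accession_id), cnt))
  perAcc <- data.frame(accession_id = rownames(perAcc), perAcc,
                       row.names = NULL)
  out <- list(per_accession = perAcc)
  if ("gene_id" %in% colnames(variants)) {
    key <- paste(variants$accession_id, variants$gene_id, sep = "|")
    perGene <- do.call(rbind, lapply(split(variants, key), cnt))
    ids <- do.call(rbind, strsplit(rownames(perGene), "|", fixed = TRUE))
    out$per_gene <- data.frame(accession_id = ids[, 1], gene_id = ids[, 2],
                               perGene, row.names = NULL)
  }
  out
}

#' Annotate a deletion sequence against a repeat library
#'
#' Finds all gapless local matches of every library element (both
#' orientations) to the deletion's reference sequence, above the identity
#' and length thresholds. Matches of one element on different alignment
#' diagonals (e.g. the two halves of an element interrupted by a nested
#' insertion) are retained as separate hits; an element's span is the range
#' of all its hits. A hit lying strictly inside another element's span is
#' marked nested, and the chimera flag is set when two or more distinct
#' elements jointly cover at least 80% of the deletion.
#'
#' @param deletion_seq Character scalar: the deleted reference sequence.
#' @param repeat_library A [Biostrings::DNAStringSet].
#' @param min_identity Minimum identity of a hit (default 0.8).
#' @param min_len Minimum hit length (default 30).
#' @param seed_len Exact seed length for candidate diagonals.
#' @return A list with `hits` (data.frame `name`, `q_start`, `q_end`,
#'   `identity`, `orientation`, `nested`), `spans` (per-element hit span)
#'   and `chimera` (logical).
#' @export
annotateDeletionRepeats <- function(deletion_seq, repeat_library,
                                    min_identity = 0.8, min_len = 30,
                                    seed_len = 16) {
  if (!length(repeat_library)) stop("empty repeat library")
  delChars <- list(del = .charVec(deletion_seq))
  n <- length(delChars$del)
  maxmm <- floor((1 - min_identity) * min_len)
  hits <- list()
  for (nm in names(repeat_library)) {
    el <- as.character(repeat_library[[nm]])
    pl <- .diagonalPlacements(el, delChars, seed_len = seed_len)
    for (k in seq_len(nrow(pl))) {
      pm <- .placementMismatch(el, delChars$del, pl$start[k], pl$strand[k])
      if (is.null(pm)) next
      qs <- .qualifyingWindows(pm$mism, min_len, maxmm)
      if (!length(qs)) next
      g0 <- max(1L, pl$start[k])
      merged <- reduce(IRanges(g0 + qs - 1L, width = min_len))
      for (j in seq_along(merged)) {
        lo <- start(merged[j]); hi <- min(end(merged[j]), n)
        mismSeg <- pm$mism[(lo - g0 + 1L):(hi - g0 + 1L)]
        hits[[length(hits) + 1L]] <- data.frame(
          name = nm, q_start = lo, q_end = hi,
          identity = 1 - sum(mismSeg) / (hi - lo + 1L),
          orientation = pl$strand[k])
      }
    }
  }
  if (!length(hits)) {
    return(list(hits = data.frame(name = character(0),
                                  q_start = integer(0), q_end = integer(0),
                                  identity = numeric(0),
                                  orientation = character(0),
                                  nested = logical(0)),
                spans = data.frame(name = character(0),
                                   span_start = integer(0),
                                   span_end = integer(0)),
                chimera = FALSE))
  }
  h <- do.call(rbind, hits)
  h <- h[order(h$q_start, h$q_end), , drop = FALSE]
  spans <- do.call(rbind, lapply(split(h, h$name), function(x)
    data.frame(name = x$name[1], span_start = min(x$q_start),
               span_end = max(x$q_end))))
  h$nested <- vapply(seq_len(nrow(h)), function(i) {
    other <- spans[spans$name != h$name[i], , drop = FALSE]
    any(h$q_start[i] > other$span_start & h$q_end[i] < other$span_end)
  }, logical(1))
  jointCov <- sum(width(reduce(IRanges(h$q_start, h$q_end))))
  chimera <- length(unique(h$name)) >= 2 && jointCov >= 0.8 * n
  list(hits = h, spans = data.frame(spans, row.names = NULL),
       chimera = chimera)
}

#' Find the best MITE-style hairpin in a sequence
#'
#' Searches all pairs of equal-length, non-overlapping, gapless arm
#' intervals (a, b), b after a, where the reverse complement of the first
#' arm matches the second at the required identity, the stem is at least
#' `min_stem` bases and the loop between the arms is between 3 and
#' `max_loop` bases. The score is matched bases minus mismatches; ties are
#' broken by leftmost first arm, then by longest stem.
#'
#' @param seq Character scalar (A/C/G/T/N; N never pairs).
#' @param min_stem Minimum stem length (default 20).
#' @param max_loop Maximum loop length (default 200).
#' @param min_stem_identity Minimum fraction of complementary stem positions
#'   (default 0.8).
#' @return `NULL` when no hairpin qualifies, otherwise a list with
#'   `stem_len`, `loop_len`, `identity`, `score`, `arm1` and `arm2`
#'   (1-based closed intervals).
#' @export
findHairpin <- function(seq, min_stem = 20, max_loop = 200,
                        min_stem_identity = 0.8) {
  cc <- .charVec(toupper(seq))
  n <- length(cc)
  if (n < 2 * min_stem) return(NULL)
  comp <- .compChar(cc)
  best <- NULL
  minLoop <- 3L
  for (D in (2L * min_stem + minLoop + 1L):(2L * n - minLoop - 1L)) {
    uMin <- max(1L, D - n)
    uMax <- (D - minLoop - 1L) %/% 2L       # arm A end bound from loop >= 3
    if (uMax - uMin + 1L < min_stem) next
    u <- uMin:uMax
    m <- cc[u] == comp[D - u] & cc[u] != "N" & cc[D - u] != "N"
    cm <- c(0L, cumsum(as.integer(m)))
    len <- length(u)
    ## enumerate all (i, e) windows; i, e are indices into u
    eIdx <- seq_len(len)
    ## loop length for arm-A end u[e]: D - 2*u[e] - 1, constrain to max_loop
    loopLen <- D - 2L * u - 1L
    eOk <- which(loopLen <= max_loop & loopLen >= minLoop)
    if (!length(eOk)) next
    for (e in eOk) {
      if (e < min_stem) next
      iCand <- seq_len(e - min_stem + 1L)
      s <- e - iCand + 1L
      matches <- cm[e + 1L] - cm[iCand]
      ident <- matches / s
      score <- 2L * matches - s
      ok <- ident >= min_stem_identity
      if (!any(ok)) next
      k <- which(ok)
      kb <- k[order(-score[k], iCand[k], -s[k])][1]
      cand <- list(stem_len = s[kb], loop_len = loopLen[e],
                   identity = ident[kb], score = score[kb],
                   arm1 = c(u[iCand[kb]], u[e]),
                   arm2 = c(D - u[e], D - u[iCand[kb]]))
      if (is.null(best) ||
          cand$score > best$score ||
          (cand$score == best$score && cand$arm1[1] < best$arm1[1]) ||
          (cand$score == best$score && cand$arm1[1] == best$arm1[1] &&
             cand$stem_len > best$stem_len)) {
        best <- cand
      }
    }
  }
  best
}

#' Count genomic loci matching a query sequence
#'
#' Counts genomic sites (both strands) where the query aligns gaplessly over
#' at least `min_cover` of its length at identity at least `min_identity`.
#'
#' @param seq Character scalar query.
#' @param genome A [Biostrings::DNAStringSet].
#' @param min_identity Minimum identity (default 0.9).
#' @param min_cover Minimum fraction of the query length that must align
#'   (default 0.9).
#' @param seed_len Exact seed length.
#' @return Integer count of distinct qualifying placements.
#' @export
genomeHitCount <- function(seq, genome, min_identity = 0.9,
                           min_cover = 0.9, seed_len = 16) {
  chromChars <- lapply(as.character(genome), .charVec)
  w <- ceiling(min_cover * nchar(seq))
  maxmm <- floor((1 - min_identity) * w)
  pl <- .diagonalPlacements(seq, chromChars, seed_len = seed_len)
  if (!nrow(pl)) return(0L)
  ok <- vapply(seq_len(nrow(pl)), function(k) {
    pm <- .placementMismatch(seq, chromChars[[pl$chrom[k]]],
                             pl$start[k], pl$strand[k])
    if (is.null(pm)) return(FALSE)
    length(.qualifyingWindows(pm$mism, w, maxmm)) > 0
  }, logical(1))
  sum(ok)
}
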