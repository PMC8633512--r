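## Capture depth profiling: captured intervals, annotation-partitioned
## lengths, subgenome specificity verdicts and polymorphism rates.

#' Maximal intervals with depth at or above a threshold
#'
#' @param depths Integer per-base depth vector (a profile window).
#' @param min_depth Minimum coverage to count a base as captured
#'   (default 10).
#' @return An [IRanges::IRanges] of maximal runs with depth >= `min_depth`,
#'   1-based within the window, sorted.
#' @export
capturedIntervals <- function(depths, min_depth = 10) {
  ok <- as.integer(depths) >= min_depth
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  IRanges(starts[r$values], ends[r$values])
}

#' Partition captured intervals by annotation
#'
#' Intersects the captured intervals of one accession x gene with the gene's
#' annotation partitions and reports captured basepairs per partition:
#' promoter, 5'UTR, their sum (the target sequence) and any additional
#' exon/intron sequence, plus the total and the maximum read depth.
#'
#' @param intervals Captured intervals (window-local, from
#'   [capturedIntervals()]).
#' @param depths The depth vector the intervals were derived from.
#' @param window A GRanges of length 1: the genomic window the profile
#'   covers.
#' @param partitions The gene's partition GRanges (metadata column `part`).
#' @return A one-row data.frame with `promoter_bp`, `five_utr_bp`,
#'   `target_bp`, `exon_intron_bp`, `total_bp`, `max_depth`.
#' @export
partitionLengths <- function(intervals, depths, window, partitions) {
  gIv <- shift(intervals, start(window) - 1L)  # window-local -> genomic
  bpIn <- function(partNames) {
    p <- partitions[partitions$part %in% partNames]
    if (!length(p)) return(0L)
    sum(width(intersect(gIv, reduce(ranges(p)))))
  }
  promoter_bp <- bpIn("promoter")
  five_utr_bp <- bpIn("five_utr")
  exon_intron_bp <- bpIn(c("exon", "intron"))
  data.frame(promoter_bp = promoter_bp, five_utr_bp = five_utr_bp,
             target_bp = promoter_bp + five_utr_bp,
             exon_intron_bp = exon_intron_bp,
             total_bp = promoter_bp + five_utr_bp + exon_intron_bp,
             max_depth = if (length(depths)) max(as.integer(depths)) else 0L)
}

#' Capture summaries for one accession across all targets
#'
#' @param profiles Named list (by gene_id) of depth vectors over the profile
#'   windows (as from [readDepthProfiles()]).
#' @param targetset A [TargetSet-class].
#' @param min_depth Minimum depth for a base to count as captured.
#' @return A data.frame, one row per gene, with the partition lengths of
#'   [partitionLengths()] plus `gene_id`, `subgenome`, `captured_fraction`
#'   (of the target interval).
#' @export
captureSummaries <- function(profiles, targetset, min_depth = 10) {
  tg <- targetRanges(targetset)
  parts <- targetPartitions(targetset)
  win <- profileWindows(targetset)
  gids <- tg$gene_id
  sgs <- tg$subgenome
  tWidth <- width(tg)
  wStart <- start(win)
  ## window-local partition intervals per gene, precomputed as plain IRanges
  partLocal <- lapply(seq_along(gids), function(i) {
    p <- parts[[gids[i]]]
    list(part = p$part,
         ir = IRanges(start(p) - wStart[i] + 1L, end(p) - wStart[i] + 1L))
  })
  rows <- lapply(seq_along(gids), function(i) {
    d <- profiles[[gids[i]]]
    if (is.null(d)) d <- integer(width(win)[i])
    iv <- capturedIntervals(d, min_depth)
    pp <- partLocal[[i]]
    bpIn <- function(nms) {
      sel <- pp$part %in% nms
      if (!any(sel)) return(0L)
      sum(width(intersect(iv, reduce(pp$ir[sel]))))
    }
    promoter_bp <- bpIn("promoter")
    five_utr_bp <- bpIn("five_utr")
    exon_intron_bp <- bpIn(c("exon", "intron"))
    data.frame(promoter_bp = promoter_bp, five_utr_bp = five_utr_bp,
               target_bp = promoter_bp + five_utr_bp,
               exon_intron_bp = exon_intron_bp,
               total_bp = promoter_bp + five_utr_bp + exon_intron_bp,
               max_depth = if (length(d)) max(as.integer(d)) else 0L,
               gene_id = gids[i], subgenome = sgs[i],
               captured_fraction = (promoter_bp + five_utr_bp) / tWidth[i])
  })
  do.call(rbind, rows)
}

#' Subgenome capture fractions and specificity verdict for one accession
#'
#' A homoeologue counts as captured when its captured target bases reach
#' `min_captured_bp`. Percentages per subgenome are reported both over
#' captured homoeologue counts and over captured bases (the two conventions
#' differ only slightly in practice). The verdict is `pass` when the
#' observed subgenome presence is a subset of the expected pattern and at
#' least one homoeologue was captured, otherwise `warn`.
#'
#' @param summaries Output of [captureSummaries()] for one accession.
#' @param expected Expected subgenome presence (from [expectedPattern()]);
#'   `NULL` skips the verdict.
#' @param min_captured_bp Minimum captured bases for a homoeologue to count
#'   (default 200; excludes stray fragments).
#' @return A list with `counts`, `percent_by_count`, `percent_by_bases`
#'   (named by subgenome), `observed` (subgenomes present), and `verdict`.
#' @export
subgenomeCaptureFractions <- function(summaries, expected = NULL,
                                      min_captured_bp = 200) {
  sgs <- sort(unique(summaries$subgenome))
  cap <- summaries[summaries$target_bp >= min_captured_bp, , drop = FALSE]
  counts <- vapply(sgs, function(s) sum(cap$subgenome == s), numeric(1))
  bases <- vapply(sgs, function(s)
    sum(cap$target_bp[cap$subgenome == s]), numeric(1))
  pctC <- if (sum(counts) > 0)
    percentRounded(counts, sum(counts), 1) else counts * 0
  pctB <- if (sum(bases) > 0)
    percentRounded(bases, sum(bases), 1) else bases * 0
  observed <- sgs[counts > 0]
  verdict <- "pass"
  if (sum(counts) == 0) verdict <- "warn"
  if (!is.null(expected) && length(setdiff(observed, expected)))
    verdict <- "warn"
  list(counts = counts, percent_by_count = pctC, percent_by_bases = pctB,
       observed = observed, verdict = verdict)
}

#' Expected subgenome presence for a genome composition
#'
#' Maps an accession's genome composition onto the reference subgenomes via
#' a relatedness table (by default A^m relates to A, S to B and U to D, the
#' last reflecting that the U genome shows closest similarity to the D
#' subgenome).
#'
#' @param composition Character vector (or comma-joined string) of subgenome
#'   labels, e.g. `c("A","A","B","B","D","D")` or `"Am,Am"`.
#' @param relatedness Named character vector mapping labels to reference
#'   subgenomes.
#' @return Sorted character vector of expected subgenomes.
#' @export
expectedPattern <- function(composition,
                            relatedness = c(A = "A", B = "B", D = "D",
                                            Am = "A", S = "B", U = "D")) {
  labs <- if (length(composition) == 1 && grepl(",", composition))
    strsplit(composition, ",", fixed = TRUE)[[1]] else composition
  labs <- trimws(labs)
  unknown <- setdiff(labs, names(relatedness))
  if (length(unknown)) {
    stop("unknown subgenome label(s) without relatedness entry: ",
         paste(unique(unknown), collapse = ", "))
  }
  sort(unique(unname(relatedness[labs])))
}

#' Homozygous polymorphism frequency per kilobase
#'
#' @param n_variants Homozygous variant count.
#' @param captured_bp Captured bases (collapsed to 1x) used as denominator.
#' @param digits Decimals to report (default 1).
#' @return Rate per kbp, rounded half away from zero.
#' @export
polymorphismFrequency <- function(n_variants, captured_bp, digits = 1) {
  if (any(captured_bp <= 0)) {
    stop("polymorphismFrequency: captured_bp must be positive")
  }
  roundHalfAway(1000 * n_variants / captured_bp, digits)
}

#' Self-check of the reference accession against its own assembly
#'
#' Counts targets where the reference accession itself carries homozygous
#' variants relative to the reference sequence, the total number of such
#' variants and the mean variants per analysed promoter. On a synthetic
#' panel this must be zero by construction; on real data it measures
#' stock-versus-assembly divergence.
#'
#' @param variants Homozygous-filtered variant table of the reference
#'   accession (see [homozygousFilter()]).
#' @param targetset A [TargetSet-class].
#' @return A list with `n_targets_with_snps`, `n_snps`,
#'   `mean_snps_per_promoter` (1 decimal, over all targets) and
#'   `percent_targets` (0 decimals).
#' @export
referenceSelfCheck <- function(variants, targetset) {
  tg <- targetRanges(targetset)
  nT <- length(tg)
  hits <- 0L; total <- 0L
  if (nrow(variants)) {
    vgr <- GRanges(variants$chrom, IRanges(variants$pos, variants$pos))
    ov <- countOverlaps(tg, vgr)
    hits <- sum(ov > 0)
    total <- sum(ov)
  }
  list(n_targets_with_snps = as.integer(hits), n_snps = as.integer(total),
       mean_snps_per_promoter = roundHalfAway(total / nT, 1),
       percent_targets = percentRounded(hits, nT, 0))
}
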